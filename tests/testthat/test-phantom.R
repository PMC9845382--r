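test_that("parameter invariants are enforced with informative errors", {
  expect_error(phantom_params(intensity_sc = 0.5, intensity_epidermis = 0.6),
               "intensity_sc > intensity_epidermis")
  expect_error(phantom_params(intensity_air = -0.1), "intensity_air")
  expect_error(phantom_params(sc_thickness = 0), "sc_thickness")
  expect_error(phantom_params(surface_depth_mean = 200,
                              epidermis_thickness_mean = 60), "image_height")
})

test_that("speckle-free flat-surface phantom has identical A-scans", {
  p <- phantom_params(image_width = 64, speckle_enabled = FALSE,
                      surface_undulation_amp = 0)
  out <- generate_phantom(p)
  img <- as.matrix(out$image)
  for (j in 2:ncol(img)) expect_identical(img[, j], img[, 1])
})

test_that("dermis follows the exponential decay law exactly (speckle off)", {
  p <- phantom_params(image_width = 8, speckle_enabled = FALSE,
                      surface_undulation_amp = 0, surface_depth_mean = 20,
                      sc_thickness = 3, epidermis_thickness_mean = 20,
                      dermis_decay_length = 60)
  out <- generate_phantom(p)
  img <- as.matrix(out$image)
  first_dermis <- 20 + 3 + 20 + 1
  # pixel exactly 2 decay lengths below the DEJ
  expect_equal(img[first_dermis + 120, 1],
               p$intensity_dermis_top * exp(-2), tolerance = 1e-12)
  # and at the first dermis row, the full top intensity
  expect_equal(img[first_dermis, 1], p$intensity_dermis_top, tolerance = 1e-12)
})

test_that("speckle is unit-mean: dermis-top sample mean within 3 SE", {
  # Monte-Carlo oracle for the SE of the unit-mean Rayleigh speckle variate
  se_mc <- with_seed_test(7, {
    draws <- octoneclass:::rayleigh_unit_mean(2e5)
    sd(draws) / sqrt(10000)
  })
  p <- phantom_params(image_height = 64, image_width = 400,
                      surface_depth_mean = 10, sc_thickness = 2,
                      epidermis_thickness_mean = 10,
                      surface_undulation_amp = 0, rng_seed = 42)
  out <- generate_phantom(p)
  first_dermis <- 10 + 2 + 10 + 1
  # 25 dermis rows x 400 columns = 10,000 pixels, detrended by the decay law
  rows <- first_dermis:(first_dermis + 24)
  img <- as.matrix(out$image)
  template <- p$intensity_dermis_top *
    exp(-(rows - first_dermis) / p$dermis_decay_length)
  vals <- sweep(img[rows, ], 1, template, "/") * p$intensity_dermis_top
  expect_lt(abs(mean(vals) - p$intensity_dermis_top),
            3 * se_mc * p$intensity_dermis_top)
})

test_that("generated datasets are deterministic in the seed", {
  p <- phantom_params(image_width = 64)
  a <- generate_dataset(p, 3, seed = 7)
  b <- generate_dataset(p, 3, seed = 7)
  expect_identical(a, b)
  c <- generate_dataset(p, 3, seed = 8)
  expect_false(identical(a, c))
  expect_error(generate_dataset(p, 0, seed = 1), "n_images")
})

test_that("35 images of 2048 A-scans yield 2240 patches of 32 A-scans", {
  p <- phantom_params(image_height = 64, image_width = 2048,
                      surface_depth_mean = 10, sc_thickness = 2,
                      epidermis_thickness_mean = 10)
  data <- generate_dataset(p, 35, seed = 3)
  n_patches <- sum(vapply(data, function(d)
    length(split_into_patches(d$image)), integer(1)))
  expect_identical(n_patches, 35L * 64L)
})

test_that("ground-truth masks are vertically ordered air-SC-epidermis-dermis", {
  data <- generate_dataset(phantom_params(image_width = 96), 3, seed = 5)
  for (d in data) {
    lab <- as.matrix(d$mask)
    for (j in seq_len(ncol(lab))) {
      col <- lab[, j]
      # ordering with no backward transition
      expect_true(all(diff(col) >= 0), info = paste("column", j))
      expect_true(all(col %in% 0:3))
    }
  }
})

test_that("noise-free dermis crosses the epidermis level exactly once", {
  p <- phantom_params(image_width = 4, speckle_enabled = FALSE,
                      surface_undulation_amp = 0)
  out <- generate_phantom(p)
  img <- as.matrix(out$image)
  lab <- as.matrix(out$mask)
  dermis <- img[lab[, 1] == 3, 1]
  crossing_depth <- p$dermis_decay_length *
    log(p$intensity_dermis_top / p$intensity_epidermis)
  above <- dermis > p$intensity_epidermis
  expect_true(all(above[seq_len(floor(crossing_depth))]))
  expect_true(!any(above[-seq_len(ceiling(crossing_depth) + 1)]))
})

test_that("mean speckled image converges to the noise-free template", {
  base <- phantom_params(image_height = 48, image_width = 16,
                         surface_depth_mean = 8, sc_thickness = 2,
                         epidermis_thickness_mean = 8,
                         surface_undulation_amp = 0)
  p_clean <- do.call(phantom_params, utils::modifyList(
    unclass(base), list(speckle_enabled = FALSE)))
  tmpl <- as.matrix(generate_phantom(p_clean)$image)
  n_rep <- 1000
  acc <- matrix(0, 48, 16)
  for (k in seq_len(n_rep)) {
    p <- do.call(phantom_params, utils::modifyList(unclass(base),
                                                   list(rng_seed = 1000 + k)))
    acc <- acc + as.matrix(generate_phantom(p)$image)
  }
  avg <- acc / n_rep
  # unit-mean Rayleigh: sd ~ 0.52 * template, so SE ~ template * 0.52 / sqrt(n)
  tol <- 5 * 0.523 / sqrt(n_rep)
  expect_true(all(abs(avg - tmpl) <= tol * pmax(tmpl, 1e-12) + 1e-12))
})
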