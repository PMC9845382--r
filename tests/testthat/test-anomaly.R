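# A small deterministic phantom patch + ground-truth mask for operator tests.
toy_patch <- function(height = 64, width = 8, seed = 77, speckle = TRUE) {
  p <- phantom_params(image_height = height, image_width = width,
                      surface_depth_mean = 8, sc_thickness = 2,
                      epidermis_thickness_mean = 10,
                      surface_undulation_amp = 0,
                      speckle_enabled = speckle, rng_seed = seed)
  generate_phantom(p)
}

small_bounds <- list(height = c(6L, 10L), width = c(2L, 4L))

test_that("anomaly specs validate their factors", {
  expect_error(anomaly_spec("bcc", bcc_factor = 0), "bcc_factor")
  expect_error(anomaly_spec("bcc", bcc_factor = 1.2), "bcc_factor")
  expect_error(anomaly_spec("scc", scc_factor = 0.9), "scc_factor")
})

test_that("BCC scales pixels below the onset to exactly 75% and no others", {
  d <- toy_patch()
  out <- synthesize_bcc(d$image, d$mask, anomaly_spec("bcc", rng_seed = 3))
  z0 <- attr(out, "onset_row")
  img <- as.matrix(d$image); res <- as.matrix(out)
  dermis_rows <- which(rowSums(as.matrix(d$mask) == 3) > 0)
  expect_gte(z0, min(dermis_rows)); expect_lte(z0, max(dermis_rows))
  for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
    if (i >= z0) expect_identical(res[i, j], img[i, j] * 0.75)
    else expect_identical(res[i, j], img[i, j])
  }
})

test_that("BCC onset forced to the first dermis row scales every dermis pixel", {
  d <- toy_patch()
  lab <- as.matrix(d$mask)
  first_dermis <- min(which(rowSums(lab == 3) > 0))
  # restrict the mask's dermis to a single row so the onset draw is forced
  lab2 <- lab
  lab2[lab2 == 3L] <- 0L
  lab2[first_dermis, ] <- 3L
  out <- synthesize_bcc(d$image, oct_mask(lab2), anomaly_spec("bcc", rng_seed = 1))
  expect_identical(attr(out, "onset_row"), first_dermis)
  img <- as.matrix(d$image)
  sel <- lab == 3L # every true dermis pixel lies at or below the onset
  expect_true(all(as.matrix(out)[sel] == img[sel] * 0.75))
})

test_that("SCC scales a reproducible below-surface rectangle by exactly 25%", {
  d <- toy_patch()
  spec <- anomaly_spec("scc", scc_region_bounds = small_bounds, rng_seed = 5)
  out <- synthesize_scc(d$image, d$mask, spec)
  r <- attr(out, "region")
  img <- as.matrix(d$image); res <- as.matrix(out)
  inside <- matrix(FALSE, nrow(img), ncol(img))
  inside[r["row0"]:r["row1"], r["col0"]:r["col1"]] <- TRUE
  expect_identical(res[inside], img[inside] * 1.25)
  expect_identical(res[!inside], img[!inside])
  # fully below the surface: no air pixel in the region
  expect_true(all(as.matrix(d$mask)[inside] != 0L))
  # replay with the same seed reproduces the same rectangle and image
  out2 <- synthesize_scc(d$image, d$mask, spec)
  expect_identical(attr(out2, "region"), r)
  expect_identical(as.matrix(out2), res)
  # infeasible bounds raise a parameter error
  expect_error(synthesize_scc(d$image, d$mask,
                              anomaly_spec("scc",
                                           scc_region_bounds = list(
                                             height = c(500L, 600L),
                                             width = c(2L, 4L)))),
               "infeasible")
})

test_that("DEJ disruption flattens shared depth structure, preserving the mean", {
  # columns all identical -> output constant at mean_z(Abar)
  col <- c(0.2, 1, 4, 2, 1, 0.5, 0.25, 0.1)
  img <- oct_image(matrix(col, 8, 5))
  out <- synthesize_dej_disruption(img)
  expect_equal(as.numeric(out), rep(mean(col), 40), tolerance = 1e-12)

  # overall mean magnitude is preserved on a speckled phantom
  d <- toy_patch()
  out2 <- synthesize_dej_disruption(d$image)
  expect_equal(mean(out2), mean(as.matrix(d$image)), tolerance = 1e-10)

  # hand-computed 3x3 case: one bright column against identical others
  m <- matrix(c(2, 4, 1,
                2, 4, 1,
                4, 8, 2), 3, 3) # third column doubled
  abar <- rowMeans(m)
  want <- m / abar * mean(abar)
  got <- synthesize_dej_disruption(oct_image(m))
  expect_equal(as.matrix(got), want, tolerance = 1e-12,
               ignore_attr = TRUE)
  # the bright column keeps its relative contrast, shared profile is flat
  expect_equal(as.matrix(got)[, 1], as.matrix(got)[, 2], tolerance = 1e-12)
  expect_equal(as.matrix(got)[, 3] / as.matrix(got)[, 1], rep(2, 3),
               tolerance = 1e-12)

  expect_error(synthesize_dej_disruption(oct_image(matrix(0, 4, 4))),
               class = "octoneclass_degenerate_error")
  expect_error(synthesize_dej_disruption(oct_image(matrix(1, 4, 1))),
               "A-scans")
})

test_that("operators with unit factors return the input bitwise", {
  d <- toy_patch()
  out_b <- synthesize_bcc(d$image, d$mask,
                          anomaly_spec("bcc", bcc_factor = 1, rng_seed = 2))
  expect_identical(as.vector(unclass(out_b)), as.vector(unclass(d$image)))
  out_s <- synthesize_scc(d$image, d$mask,
                          anomaly_spec("scc", scc_factor = 1,
                                       scc_region_bounds = small_bounds,
                                       rng_seed = 2))
  expect_identical(as.vector(unclass(out_s)), as.vector(unclass(d$image)))
})

test_that("operators preserve shape and non-negativity and shift layer means", {
  d <- toy_patch()
  img <- as.matrix(d$image); lab <- as.matrix(d$mask)
  bcc <- synthesize_bcc(d$image, d$mask, anomaly_spec("bcc", rng_seed = 4))
  scc <- synthesize_scc(d$image, d$mask,
                        anomaly_spec("scc", scc_region_bounds = small_bounds,
                                     rng_seed = 4))
  dej <- synthesize_dej_disruption(d$image)
  for (out in list(bcc, scc, dej)) {
    expect_identical(dim(as.matrix(out)), dim(img))
    expect_true(all(as.matrix(out) >= 0))
  }
  expect_lt(mean(as.matrix(bcc)[lab == 3]), mean(img[lab == 3]))
  r <- attr(scc, "region")
  inside <- matrix(FALSE, nrow(img), ncol(img))
  inside[r["row0"]:r["row1"], r["col0"]:r["col1"]] <- TRUE
  expect_gt(mean(as.matrix(scc)[inside]), mean(img[inside]))
})

test_that("the 4-way dataset has 4x the patches with a 3:1 abnormal ratio", {
  d <- toy_patch(width = 6)
  ds <- build_anomaly_dataset(list(d$image), list(d$mask), seed = 1,
                              scc_region_bounds = small_bounds)
  expect_length(ds, 4)
  expect_identical(sort(vapply(ds, `[[`, character(1), "class")),
                   c("bcc", "dej", "normal", "scc"))
  labs <- vapply(ds, `[[`, character(1), "label")
  expect_identical(sum(labs == "abnormal"), 3L * sum(labs == "normal"))

  # the study-scale count: 1116 normal patches expand to 4464
  many <- replicate(1116, d, simplify = FALSE)
  ds2 <- build_anomaly_dataset(lapply(many, `[[`, "image"),
                               lapply(many, `[[`, "mask"), seed = 2,
                               scc_region_bounds = small_bounds)
  expect_length(ds2, 4464)
  labs2 <- vapply(ds2, `[[`, character(1), "label")
  expect_identical(sum(labs2 == "abnormal"), 3348L)
  expect_error(build_anomaly_dataset(list(), list(), 1), "empty")
})
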