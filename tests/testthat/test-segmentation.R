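test_that("patch splitting follows the left-aligned remainder-discarding rule", {
  img <- oct_image(matrix(runif(256 * 2048), 256, 2048))
  expect_length(split_into_patches(img), 64)
  img8 <- oct_image(matrix(runif(256 * 256), 256, 256))
  expect_length(split_into_patches(img8), 8)
  img70 <- oct_image(matrix(runif(16 * 70), 16, 70))
  ps <- split_into_patches(img70)
  expect_length(ps, 2)
  expect_identical(vapply(ps, attr, integer(1), "lateral_offset"), c(0L, 32L))
  expect_equal(as.matrix(ps[[2]]), as.matrix(img70)[, 33:64],
               ignore_attr = TRUE)
  expect_error(split_into_patches(oct_image(matrix(1, 4, 10))), "narrower")
})

test_that("encoder channel widths follow the doubling rule from base 16", {
  expect_identical(octoneclass:::unet_channels(unet_config()),
                   c(16L, 32L, 64L, 128L, 256L))
  model <- build_unet(unet_config(), seed = 1)
  widths <- vapply(model$params$enc, function(st) nrow(st$conv1$W), integer(1))
  expect_identical(widths, c(16L, 32L, 64L, 128L, 256L))
})

test_that("building rejects inputs not divisible by the downsampling factor", {
  expect_error(build_unet(unet_config(input_height = 250, input_width = 32)),
               "divisible")
  expect_error(build_unet(unet_config(input_height = 256, input_width = 30)),
               "divisible")
})

test_that("initialization is deterministic and zero weights give class ties", {
  m1 <- build_unet(unet_config(), seed = 9)
  m2 <- build_unet(unet_config(), seed = 9)
  expect_identical(m1$params, m2$params)
  m3 <- build_unet(unet_config(), seed = 10)
  expect_false(identical(m1$params, m3$params))

  # zero weights: every class score equal -> tie broken to lowest index (air)
  zm <- build_unet(tiny_unet_config(), seed = 1)
  flat <- octoneclass:::flatten_params(zm$params)
  for (k in names(flat)) {
    w <- flat[[k]]; w[] <- 0
    zm$params <- octoneclass:::assign_by_path(zm$params, k, w)
  }
  patch <- matrix(runif(16 * 8), 16, 8)
  fwd <- octoneclass:::unet_forward(zm, patch)
  expect_true(all(fwd$logits == 0))
  expect_true(all(segment(zm, patch) == 0L))
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_unet_config()
  m <- build_unet(cfg, seed = 42)
  # nudge all biases off zero so no pre-activation sits exactly on the ReLU
  # kink (where one-sided derivatives legitimately differ)
  flat <- octoneclass:::flatten_params(m$params)
  set.seed(5)
  for (k in grep("\\.b$", names(flat), value = TRUE)) {
    w <- flat[[k]] + rnorm(length(flat[[k]]), 0, 0.05)
    m$params <- octoneclass:::assign_by_path(m$params, k, w)
  }
  set.seed(1)
  x <- matrix(runif(16 * 8), 16, 8)
  lab <- matrix(sample(0:2, 16 * 8, TRUE), 16, 8)
  fwd <- octoneclass:::unet_forward(m, x, cache = TRUE)
  ce <- octoneclass:::softmax_ce(fwd$logits, lab)
  g <- octoneclass:::flatten_params(octoneclass:::unet_backward(m, fwd, ce$dlogits))
  pf <- octoneclass:::flatten_params(m$params)
  loss_at <- function(mm) {
    f <- octoneclass:::unet_forward(mm, x)
    octoneclass:::softmax_ce(f$logits, lab)$loss
  }
  set.seed(2)
  for (k in names(pf)) {
    for (rep in 1:3) {
      i <- sample(length(pf[[k]]), 1)
      eps <- 1e-6
      m2 <- m
      w <- pf[[k]]; w[i] <- w[i] + eps
      m2$params <- octoneclass:::assign_by_path(m2$params, k, w)
      up <- loss_at(m2)
      w[i] <- pf[[k]][i] - eps
      m2$params <- octoneclass:::assign_by_path(m2$params, k, w)
      dn <- loss_at(m2)
      num <- (up - dn) / (2 * eps)
      expect_equal(g[[k]][i], num, tolerance = 1e-4,
                   info = paste("param", k, "index", i))
    }
  }
})

test_that("training memorizes a single repeated example", {
  cfg <- unet_config(input_height = 32, input_width = 8, n_classes = 4,
                     n_stages = 2, base_features = 4)
  m <- build_unet(cfg, seed = 3)
  set.seed(4)
  patch <- matrix(runif(32 * 8), 32, 8) + 0.2
  lab <- matrix(rep(c(0L, 1L, 2L, 3L), each = 8 * 8), 32, 8)
  m <- train_unet(m, rep(list(patch), 8), rep(list(lab), 8),
                  train_config(batch_size = 8, epochs = 250, seed = 5))
  pred <- segment(m, patch)
  expect_gt(mean(pred == lab), 0.99)
  # loss log decreases from start to end
  expect_lt(tail(m$log$loss, 1), m$log$loss[1])
})

test_that("training is deterministic and rejects invalid labels", {
  cfg <- tiny_unet_config()
  set.seed(6)
  patches <- replicate(4, matrix(runif(16 * 8), 16, 8), simplify = FALSE)
  masks <- replicate(4, matrix(sample(0:2, 128, TRUE), 16, 8), simplify = FALSE)
  m0 <- build_unet(cfg, seed = 7)
  t1 <- train_unet(m0, patches, masks, train_config(batch_size = 2, epochs = 2,
                                                    seed = 8))
  t2 <- train_unet(m0, patches, masks, train_config(batch_size = 2, epochs = 2,
                                                    seed = 8))
  expect_identical(t1$params, t2$params)

  bad <- masks
  bad[[3]][1, 1] <- 7L
  expect_error(train_unet(m0, patches, bad, train_config()), "patch 3")
})

test_that("fixture-trained network segments held-out phantoms accurately", {
  model <- fixture_unet()
  # the recorded training loss decreased overall
  expect_lt(tail(model$log$loss, 1), model$log$loss[1])
  accs <- c()
  for (d in fixture_heldout()) {
    tp <- split_into_patches(d$image)
    tm <- split_into_patches(d$mask)
    for (k in seq_along(tp)) {
      pred <- segment(model, tp[[k]])
      expect_identical(dim(pred), dim(tp[[k]]))
      expect_true(all(pred %in% 0:3))
      accs <- c(accs, mean(pred == as.matrix(tm[[k]])))
    }
  }
  expect_gte(mean(accs), 0.90)
})

test_that("speckle-free phantoms are segmented at least as well as speckled", {
  model <- fixture_unet()
  base <- unclass(fixture_phantom_params(width = 64L))
  acc_for <- function(speckle) {
    p <- do.call(phantom_params, utils::modifyList(base, list(
      speckle_enabled = speckle, rng_seed = 123L, image_width = 64L)))
    d <- generate_phantom(p)
    tp <- split_into_patches(d$image)
    tm <- split_into_patches(d$mask)
    mean(vapply(seq_along(tp), function(k)
      mean(segment(model, tp[[k]]) == as.matrix(tm[[k]])), numeric(1)))
  }
  expect_gt(acc_for(FALSE), acc_for(TRUE))
})

test_that("the signal-free region above the surface is labeled air", {
  model <- fixture_unet()
  d <- fixture_heldout()[[1]]
  tp <- split_into_patches(d$image)[[1]]
  tm <- split_into_patches(d$mask)[[1]]
  pred <- segment(model, tp)
  expect_gt(mean(pred[as.matrix(tm) == 0L] == 0L), 0.5)
})

test_that("checkpoint round-trip preserves forward outputs bitwise", {
  model <- fixture_unet()
  path <- tempfile(fileext = ".rds")
  save_unet(model, path)
  reloaded <- load_unet(path)
  patch <- split_into_patches(fixture_heldout()[[1]]$image)[[1]]
  f1 <- octoneclass:::unet_forward(model, patch)
  f2 <- octoneclass:::unet_forward(reloaded, patch)
  expect_identical(f1$features, f2$features)
  expect_identical(f1$logits, f2$logits)
  unlink(path)
})
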