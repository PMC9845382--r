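#' U-Net architecture configuration
#'
#' Encoder/decoder segmentation network for OCT skin patches. The encoder has
#' `n_stages` stages of (3x3 conv, ReLU, 3x3 conv, ReLU, 2x2 max-pool); the
#' final stage acts as the bridge and omits its pool so a 256x32 input stays
#' shape-valid, giving `n_stages - 1` down/up-samplings. Each decoder stage is
#' (2x2 up-conv, ReLU, skip concatenation, 3x3 conv, ReLU, 3x3 conv, ReLU).
#' Channel widths double per stage from `base_features`; the last decoder
#' ReLU emits exactly `base_features` channels (16 by default), which are the
#' per-pixel features reused for one-class classification. All convolutions
#' use same-padding so output size equals input size.
#'
#' @param input_height,input_width input patch size in pixels (256 x 32).
#' @param n_classes number of segmentation classes (4 skin layers).
#' @param n_stages encoder (= decoder) stage count.
#' @param base_features channels of the first encoder / last decoder stage.
#' @param channel_growth width multiplier per encoder stage.
#' @return A `unet_config` list.
#' @export
unet_config <- function(input_height = 256, input_width = 32, n_classes = 4,
                        n_stages = 5, base_features = 16, channel_growth = 2) {
  if (n_stages < 2) stop_param("unet_config: n_stages must be >= 2")
  if (base_features < 1) stop_param("unet_config: base_features must be >= 1")
  structure(list(input_height = as.integer(input_height),
                 input_width = as.integer(input_width),
                 n_classes = as.integer(n_classes),
                 n_stages = as.integer(n_stages),
                 base_features = as.integer(base_features),
                 channel_growth = channel_growth,
                 bridge_has_pool = FALSE),
            class = "unet_config")
}

unet_channels <- function(config) {
  as.integer(config$base_features * config$channel_growth^(seq_len(config$n_stages) - 1))
}

unet_downsample_factor <- function(config) 2L^(config$n_stages - 1L)

he_init <- function(nout, nin_eff) {
  matrix(rnorm(nout * nin_eff, sd = sqrt(2 / nin_eff)), nout, nin_eff)
}

#' Build an untrained U-Net
#'
#' Allocates He-initialized weights for the configured architecture.
#' Initialization is deterministic for a fixed seed.
#'
#' @param config a [unet_config()].
#' @param seed integer seed for weight initialization.
#' @return An `oct_unet` model (untrained).
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  f <- unet_downsample_factor(config)
  if (config$input_height %% f != 0 || config$input_width %% f != 0)
    stop_param("build_unet: input size ", config$input_height, "x",
               config$input_width, " not divisible by the total ",
               "downsampling factor ", f)
  ch <- unet_channels(config)
  S <- config$n_stages
  with_seed(seed, {
    enc <- lapply(seq_len(S), function(s) {
      cin <- if (s == 1) 1L else ch[s - 1]
      list(conv1 = list(W = he_init(ch[s], cin * 9), b = numeric(ch[s])),
           conv2 = list(W = he_init(ch[s], ch[s] * 9), b = numeric(ch[s])))
    })
    dec <- lapply(seq_len(S - 1), function(d) {
      cprev <- ch[S - d + 1]
      ct <- ch[S - d]
      list(up = list(W = he_init(ct, cprev * 4), b = numeric(ct)),
           conv1 = list(W = he_init(ct, 2 * ct * 9), b = numeric(ct)),
           conv2 = list(W = he_init(ct, ct * 9), b = numeric(ct)))
    })
    head <- list(W = he_init(config$n_classes, ch[1]), b = numeric(config$n_classes))
    structure(list(config = config,
                   params = list(enc = enc, dec = dec, head = head),
                   provenance = list(init_seed = as.integer(seed),
                                     trained = FALSE),
                   log = NULL),
              class = "oct_unet")
  })
}

as_patch_matrix <- function(model, patch, who) {
  m <- unclass(as.matrix(patch))
  cfg <- model$config
  if (nrow(m) != cfg$input_height || ncol(m) != cfg$input_width)
    stop_input(who, ": patch is ", nrow(m), "x", ncol(m), " but the model ",
               "expects ", cfg$input_height, "x", cfg$input_width)
  m
}

# Full forward pass. Returns the last-decoder-ReLU feature tensor
# (H x W x base_features), per-pixel class logits (H x W x n_classes) and,
# when cache = TRUE, every intermediate needed for backprop.
unet_forward <- function(model, patch, cache = FALSE) {
  m <- as_patch_matrix(model, patch, "unet_forward")
  p <- model$params
  S <- model$config$n_stages
  x <- array(m, c(nrow(m), ncol(m), 1L))
  skips <- vector("list", S - 1)
  cc <- if (cache) list(enc = vector("list", S), dec = vector("list", S - 1))
  for (s in seq_len(S)) {
    xin <- x
    a1 <- cpp_conv3_fw(xin, p$enc[[s]]$conv1$W, p$enc[[s]]$conv1$b, TRUE)
    a2 <- cpp_conv3_fw(a1, p$enc[[s]]$conv2$W, p$enc[[s]]$conv2$b, TRUE)
    if (s < S) {
      skips[[s]] <- a2
      pool <- cpp_maxpool_fw(a2)
      x <- pool$y
      if (cache) cc$enc[[s]] <- list(xin = xin, a1 = a1, a2 = a2, idx = pool$idx)
    } else {
      x <- a2
      if (cache) cc$enc[[s]] <- list(xin = xin, a1 = a1, a2 = a2)
    }
  }
  for (d in seq_len(S - 1)) {
    xin <- x
    aup <- cpp_upconv_fw(xin, p$dec[[d]]$up$W, p$dec[[d]]$up$b, TRUE)
    skip <- skips[[S - d]]
    catx <- array(c(aup, skip), c(dim(aup)[1], dim(aup)[2],
                                  dim(aup)[3] + dim(skip)[3]))
    a1 <- cpp_conv3_fw(catx, p$dec[[d]]$conv1$W, p$dec[[d]]$conv1$b, TRUE)
    a2 <- cpp_conv3_fw(a1, p$dec[[d]]$conv2$W, p$dec[[d]]$conv2$b, TRUE)
    if (cache) cc$dec[[d]] <- list(xin = xin, aup = aup, catx = catx,
                                   a1 = a1, a2 = a2)
    x <- a2
  }
  feat <- x # H x W x base_features, post-ReLU
  H <- dim(feat)[1]; W <- dim(feat)[2]
  fm <- matrix(feat, H * W, dim(feat)[3])
  logits_m <- fm %*% t(p$head$W)
  logits_m <- sweep(logits_m, 2, p$head$b, "+")
  out <- list(features = feat,
              logits = array(logits_m, c(H, W, model$config$n_classes)))
  if (cache) { cc$feat_mat <- fm; out$cache <- cc }
  out
}

# Backward pass from d(loss)/d(logits); returns gradients shaped like params.
unet_backward <- function(model, fwd, dlogits) {
  p <- model$params
  S <- model$config$n_stages
  cc <- fwd$cache
  H <- dim(dlogits)[1]; W <- dim(dlogits)[2]
  dlm <- matrix(dlogits, H * W, dim(dlogits)[3])
  g <- list(enc = vector("list", S), dec = vector("list", S - 1), head = NULL)
  g$head <- list(W = t(dlm) %*% cc$feat_mat, b = colSums(dlm))
  dx <- array(dlm %*% p$head$W, dim(fwd$features))
  dskip <- vector("list", S - 1)
  for (d in rev(seq_len(S - 1))) {
    st <- cc$dec[[d]]
    dx[st$a2 <= 0] <- 0
    b2 <- cpp_conv3_bw(st$a1, p$dec[[d]]$conv2$W, dx)
    da1 <- b2$dx; da1[st$a1 <= 0] <- 0
    b1 <- cpp_conv3_bw(st$catx, p$dec[[d]]$conv1$W, da1)
    cu <- dim(st$aup)[3]
    dcat <- b1$dx
    daup <- dcat[, , seq_len(cu), drop = FALSE]
    dskip[[S - d]] <- dcat[, , cu + seq_len(dim(dcat)[3] - cu), drop = FALSE]
    daup[st$aup <= 0] <- 0
    bu <- cpp_upconv_bw(st$xin, p$dec[[d]]$up$W, daup)
    g$dec[[d]] <- list(up = list(W = bu$dw, b = as.numeric(bu$db)),
                       conv1 = list(W = b1$dw, b = as.numeric(b1$db)),
                       conv2 = list(W = b2$dw, b = as.numeric(b2$db)))
    dx <- bu$dx
  }
  for (s in rev(seq_len(S))) {
    st <- cc$enc[[s]]
    if (s < S) {
      da2 <- cpp_maxpool_bw(dx, st$idx, dim(st$a2)[1], dim(st$a2)[2])
      da2 <- da2 + dskip[[s]]
    } else {
      da2 <- dx
    }
    da2[st$a2 <= 0] <- 0
    b2 <- cpp_conv3_bw(st$a1, p$enc[[s]]$conv2$W, da2)
    da1 <- b2$dx; da1[st$a1 <= 0] <- 0
    b1 <- cpp_conv3_bw(st$xin, p$enc[[s]]$conv1$W, da1)
    g$enc[[s]] <- list(conv1 = list(W = b1$dw, b = as.numeric(b1$db)),
                       conv2 = list(W = b2$dw, b = as.numeric(b2$db)))
    dx <- b1$dx
  }
  g
}

# Pixel-mean softmax cross-entropy and its gradient w.r.t. logits.
softmax_ce <- function(logits, labels) {
  H <- dim(logits)[1]; W <- dim(logits)[2]; K <- dim(logits)[3]
  lm <- matrix(logits, H * W, K)
  lm <- lm - apply(lm, 1, max)
  e <- exp(lm)
  prob <- e / rowSums(e)
  idx <- cbind(seq_len(H * W), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(prob[idx], 1e-300)))
  dprob <- prob
  dprob[idx] <- dprob[idx] - 1
  list(loss = loss, dlogits = array(dprob / (H * W), c(H, W, K)))
}

flatten_params <- function(p, prefix = "") {
  if (is.list(p) && is.null(dim(p))) {
    out <- list()
    nm <- names(p)
    if (is.null(nm)) nm <- as.character(seq_along(p))
    for (i in seq_along(p))
      out <- c(out, flatten_params(p[[i]], paste0(prefix, ".", nm[i])))
    out
  } else {
    stats::setNames(list(p), prefix)
  }
}

assign_by_path <- function(p, path, value) {
  keys <- strsplit(sub("^\\.", "", path), ".", fixed = TRUE)[[1]]
  expr <- "p"
  for (k in keys) {
    expr <- if (grepl("^[0-9]+$", k)) paste0(expr, "[[", k, "]]")
    else paste0(expr, "[[\"", k, "\"]]")
  }
  eval(parse(text = paste0(expr, " <- value")))
  p
}

#' Training configuration for the segmentation network
#'
#' Defaults follow the standard recipe for this task: ADAM, mini-batch 40,
#' initial learning rate 1e-3, 10 epochs, pixelwise cross-entropy loss.
#'
#' @param batch_size mini-batch size.
#' @param lr initial learning rate.
#' @param epochs number of passes over the training set (>= 1).
#' @param seed integer seed controlling shuffling.
#' @param validation_fraction fraction of patches held out for a per-epoch
#'   validation loss (0 disables).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 40, lr = 1e-3, epochs = 10, seed = 1L,
                         validation_fraction = 0) {
  if (epochs < 1) stop_param("train_config: epochs must be >= 1")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop_param("train_config: validation_fraction must be in [0, 1)")
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

#' Train the U-Net on (patch, mask) pairs
#'
#' ADAM with pixelwise softmax cross-entropy. Fully deterministic for fixed
#' seeds and data order; the per-epoch mean training loss is recorded in
#' `model$log`.
#'
#' @param model an `oct_unet` from [build_unet()].
#' @param patches list of input patches (matrices or [oct_image]s) matching
#'   the model input size.
#' @param masks list of matching [oct_mask()]s (labels 0-3).
#' @param cfg a [train_config()].
#' @return The trained model with a `log` data frame (epoch, loss).
#' @export
train_unet <- function(model, patches, masks, cfg = train_config()) {
  if (length(patches) != length(masks))
    stop_input("train_unet: patches and masks must have equal length")
  if (length(patches) < 1) stop_input("train_unet: no training data")
  for (i in seq_along(masks)) {
    lab <- as.matrix(masks[[i]])
    if (any(!(lab %in% 0:3)))
      stop(errorCondition(paste0("train_unet: mask of patch ", i,
                                 " has labels outside {0..3}"),
           class = c("octoneclass_data_error", "error")))
  }
  n <- length(patches)
  n_val <- floor(cfg$validation_fraction * n)
  with_seed(derive_seed(cfg$seed, 0L), {
    perm <- sample.int(n)
  })
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  if (length(tr_idx) < 1) stop_input("train_unet: no patches left for training")

  flat <- flatten_params(model$params)
  mstate <- lapply(flat, function(w) array(0, dim(w) %||% length(w)))
  vstate <- mstate
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  log <- data.frame(epoch = integer(0), loss = numeric(0),
                    val_loss = numeric(0))

  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(derive_seed(cfg$seed, ep), sample(tr_idx))
    ep_losses <- numeric(0)
    for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
      batch <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
      gacc <- NULL
      bloss <- 0
      for (i in batch) {
        fwd <- unet_forward(model, patches[[i]], cache = TRUE)
        ce <- softmax_ce(fwd$logits, as.matrix(masks[[i]]))
        bloss <- bloss + ce$loss
        g <- flatten_params(unet_backward(model, fwd, ce$dlogits))
        if (is.null(gacc)) gacc <- g
        else for (k in seq_along(gacc)) gacc[[k]] <- gacc[[k]] + g[[k]]
      }
      nb <- length(batch)
      bloss <- bloss / nb
      ep_losses <- c(ep_losses, bloss)
      step <- step + 1L
      lr_t <- cfg$lr * sqrt(1 - beta2^step) / (1 - beta1^step)
      for (k in seq_along(flat)) {
        gk <- gacc[[k]] / nb
        mstate[[k]] <- beta1 * mstate[[k]] + (1 - beta1) * gk
        vstate[[k]] <- beta2 * vstate[[k]] + (1 - beta2) * gk * gk
        flat[[k]] <- flat[[k]] - lr_t * mstate[[k]] / (sqrt(vstate[[k]]) + eps)
      }
      for (k in names(flat)) model$params <- assign_by_path(model$params, k, flat[[k]])
    }
    vl <- NA_real_
    if (length(val_idx) > 0) {
      vl <- mean(vapply(val_idx, function(i) {
        fwd <- unet_forward(model, patches[[i]])
        softmax_ce(fwd$logits, as.matrix(masks[[i]]))$loss
      }, numeric(1)))
    }
    log <- rbind(log, data.frame(epoch = ep, loss = mean(ep_losses), val_loss = vl))
  }
  model$log <- log
  model$provenance$trained <- TRUE
  model$provenance$train_seed <- cfg$seed
  model$provenance$n_patches <- length(tr_idx)
  model$provenance$data_checksum <- sum(vapply(patches, function(x) sum(as.matrix(x)),
                                               numeric(1)))
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment an OCT patch into the four skin layers
#'
#' Per-pixel argmax over the class scores; ties are broken toward the lowest
#' class index (air first).
#'
#' @param model trained `oct_unet`.
#' @param patch input patch matching the model input size.
#' @return An [oct_mask()] of predicted labels.
#' @export
segment <- function(model, patch) {
  fwd <- unet_forward(model, patch)
  H <- dim(fwd$logits)[1]; W <- dim(fwd$logits)[2]
  lm <- matrix(fwd$logits, H * W, dim(fwd$logits)[3])
  lab <- max.col(lm, ties.method = "first") - 1L
  oct_mask(matrix(lab, H, W))
}

#' Split a B-scan into non-overlapping lateral patches
#'
#' Left-aligned windows of `patch_width` A-scans; a trailing remainder
#' narrower than `patch_width` is discarded. Each patch records its 0-based
#' lateral offset within the parent image as attribute `lateral_offset`.
#'
#' @param image an [oct_image()] (or plain matrix).
#' @param patch_width patch width in A-scans (default 32).
#' @return A list of patches.
#' @export
split_into_patches <- function(image, patch_width = 32L) {
  m <- as.matrix(image)
  if (ncol(m) < patch_width)
    stop_input("split_into_patches: image width ", ncol(m),
               " is narrower than patch_width ", patch_width)
  n <- ncol(m) %/% patch_width
  lapply(seq_len(n), function(k) {
    j0 <- (k - 1L) * patch_width
    p <- m[, (j0 + 1):(j0 + patch_width), drop = FALSE]
    attr(p, "lateral_offset") <- j0
    if (inherits(image, "oct_image")) {
      attr(p, "axial_spacing") <- attr(image, "axial_spacing")
      attr(p, "lateral_spacing") <- attr(image, "lateral_spacing")
      class(p) <- c("oct_image", "matrix")
    } else if (inherits(image, "oct_mask")) {
      class(p) <- c("oct_mask", "matrix")
    }
    p
  })
}

#' Save / load a U-Net checkpoint
#'
#' The checkpoint is a single-file archive of config, weights and training
#' provenance; a reloaded model produces bitwise-identical forward outputs.
#'
#' @param model an `oct_unet`.
#' @param path file path.
#' @return `load_unet` returns the model; `save_unet` the path, invisibly.
#' @export
save_unet <- function(model, path) {
  stopifnot(inherits(model, "oct_unet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "oct_unet")) stop_input("load_unet: not a U-Net checkpoint")
  model
}
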