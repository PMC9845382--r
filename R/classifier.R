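#' One-class SVM configuration
#'
#' Radial-basis-function one-class SVM in the nu-formulation: `nu` upper
#' bounds the fraction of training (normal) examples treated as outliers.
#' `kernel_scale = "auto"` standardizes features with training statistics and
#' sets the RBF bandwidth by the median pairwise distance heuristic on a
#' subsample of at most 1000 training rows (fixed seed).
#'
#' @param nu outlier fraction in (0, 1); default 0.08.
#' @param kernel_scale `"auto"` or an explicit positive bandwidth sigma
#'   (kernel `exp(-||x - y||^2 / (2 sigma^2))` on standardized features).
#' @param feature_group which [featurize_patch()] group the model expects.
#' @param seed integer seed for the bandwidth subsample.
#' @return An `ocsvm_config` list.
#' @export
ocsvm_config <- function(nu = 0.08, kernel_scale = "auto",
                         feature_group = c("e_and_d", "all", "epidermis",
                                           "dermis"),
                         seed = 1L) {
  feature_group <- match.arg(feature_group)
  if (!(is.numeric(nu) && nu > 0 && nu < 1))
    stop_param("ocsvm_config: violated '0 < nu < 1'")
  if (!identical(kernel_scale, "auto") &&
      !(is.numeric(kernel_scale) && kernel_scale > 0))
    stop_param("ocsvm_config: kernel_scale must be 'auto' or a positive number")
  structure(list(nu = nu, kernel_scale = kernel_scale,
                 feature_group = feature_group, seed = as.integer(seed)),
            class = "ocsvm_config")
}

#' Train a one-class SVM on normal-tissue feature vectors
#'
#' All training rows must come from normal tissue. Features are standardized
#' to zero mean / unit variance using training statistics; the RBF bandwidth
#' follows the config. The decision score is positive inside the learned
#' normal region, so roughly a fraction `nu` of training rows score negative.
#'
#' @param features numeric matrix, one feature vector per row (>= 10 rows).
#' @param config an [ocsvm_config()].
#' @return An `oct_ocsvm` model.
#' @export
train_ocsvm <- function(features, config = ocsvm_config()) {
  x <- as.matrix(features)
  if (nrow(x) < 10)
    stop(errorCondition("train_ocsvm: need at least 10 training rows",
                        class = c("octoneclass_data_error", "error")))
  if (any(!is.finite(x)))
    stop(errorCondition("train_ocsvm: features must be finite",
                        class = c("octoneclass_data_error", "error")))
  center <- colMeans(x)
  scale_ <- apply(x, 2, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  xs <- sweep(sweep(x, 2, center, "-"), 2, scale_, "/")
  if (identical(config$kernel_scale, "auto")) {
    idx <- if (nrow(xs) > 1000)
      with_seed(config$seed, sample.int(nrow(xs), 1000)) else seq_len(nrow(xs))
    sigma <- stats::median(stats::dist(xs[idx, , drop = FALSE]))
    if (!is.finite(sigma) || sigma <= 0) sigma <- sqrt(ncol(xs))
  } else sigma <- config$kernel_scale
  gamma <- 1 / (2 * sigma^2)
  fit <- e1071::svm(x = xs, y = NULL, type = "one-classification",
                    kernel = "radial", nu = config$nu, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, center = center, scale = scale_, sigma = sigma,
                 gamma = gamma, config = config, n_features = ncol(x),
                 n_train = nrow(x)),
            class = "oct_ocsvm")
}

#' Map feature vectors to one-class prediction scores
#'
#' Positive score: normal tissue; negative score: abnormal tissue. A score
#' of exactly zero is classified abnormal.
#'
#' @param model an `oct_ocsvm` from [train_ocsvm()].
#' @param x a `feature_vector`, numeric vector, or matrix (one row per
#'   vector). A `feature_vector` whose group differs from the model's
#'   configured group is rejected.
#' @return Numeric score(s).
#' @export
predict_score <- function(model, x) {
  if (inherits(x, "feature_vector") &&
      !identical(attr(x, "group"), model$config$feature_group))
    stop_input("predict_score: feature group '", attr(x, "group"),
               "' does not match the model's group '",
               model$config$feature_group, "'")
  xm <- if (is.matrix(x)) x else matrix(as.numeric(x), nrow = 1)
  if (ncol(xm) != model$n_features)
    stop_input("predict_score: expected ", model$n_features,
               " features, got ", ncol(xm))
  xs <- sweep(sweep(xm, 2, model$center, "-"), 2, model$scale, "/")
  pr <- predict(model$fit, xs, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values"))
}

score_to_label <- function(score) ifelse(score > 0, "normal", "abnormal")

#' Classify a whole B-scan by averaging patch scores
#'
#' Splits the image into non-overlapping 32-A-scan patches, featurizes each
#' with the model's configured group, and averages the patch scores; the mean
#' score's sign decides the image-level call (a 256-A-scan image yields
#' exactly 8 patch scores). Degenerate patches (empty pixel group) are
#' skipped with a warning.
#'
#' @param model trained `oct_ocsvm`.
#' @param segmenter trained `oct_unet` feature extractor.
#' @param image an [oct_image()] with width >= 32.
#' @param patch_width patch width in A-scans.
#' @return List with `mean_score`, `classification` (`"normal"`/`"abnormal"`)
#'   and `patch_scores`.
#' @export
classify_image <- function(model, segmenter, image, patch_width = 32L) {
  patches <- split_into_patches(image, patch_width)
  grp <- model$config$feature_group
  scores <- numeric(0)
  for (k in seq_along(patches)) {
    fv <- featurize_patch_groups(segmenter, patches[[k]], groups = grp,
                                 on_degenerate = "null")[[grp]]
    if (is.null(fv)) {
      warning("classify_image: skipping degenerate patch ", k,
              " (empty '", grp, "' group)")
      next
    }
    scores <- c(scores, predict_score(model, fv))
  }
  if (length(scores) == 0)
    stop(errorCondition("classify_image: all patches degenerate",
                        class = c("octoneclass_classification_error", "error")))
  ms <- mean(scores)
  list(mean_score = ms, classification = score_to_label(ms),
       patch_scores = scores)
}

#' Save / load a one-class SVM model
#'
#' Single-file archive preserving support vectors, standardization and
#' provenance; reloaded models reproduce scores bitwise.
#'
#' @param model an `oct_ocsvm`.
#' @param path file path.
#' @return `load_ocsvm` returns the model; `save_ocsvm` the path, invisibly.
#' @export
save_ocsvm <- function(model, path) {
  stopifnot(inherits(model, "oct_ocsvm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_ocsvm
#' @export
load_ocsvm <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "oct_ocsvm")) stop_input("load_ocsvm: not an SVM archive")
  model
}
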