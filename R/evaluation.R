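#' Reproducible 50/50 patch split
#'
#' Disjoint train/test split with `ceiling(fraction * n)` items in the
#' training part; identical for identical seeds.
#'
#' @param x list (or vector) of items, n >= 2.
#' @param fraction training fraction (default 0.5).
#' @param seed integer seed.
#' @return List with `train` and `test` index vectors and the split items.
#' @export
split_train_test <- function(x, fraction = 0.5, seed = 1L) {
  n <- length(x)
  if (n < 2) stop_input("split_train_test: need at least 2 items")
  n_train <- ceiling(fraction * n)
  idx <- with_seed(seed, sample.int(n))
  tr <- sort(idx[seq_len(n_train)])
  te <- sort(idx[-seq_len(n_train)])
  list(train = x[tr], test = x[te], train_idx = tr, test_idx = te,
       seed = as.integer(seed))
}

#' Rank-based ROC AUC
#'
#' Probability that a randomly chosen normal example outranks a randomly
#' chosen abnormal one, with ties counted one half (Wilcoxon / Mann-Whitney
#' formulation). The positive class is `"normal"`: higher scores mean more
#' normal, matching the one-class sign convention.
#'
#' @param scores numeric prediction scores.
#' @param labels `"normal"`/`"abnormal"` (or logical: TRUE = normal).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- normalize_labels(labels)
  if (!any(pos) || all(pos))
    stop(errorCondition("roc_auc: both classes must be present",
                        class = c("octoneclass_eval_error", "error")))
  r <- rank(scores) # ties averaged
  n1 <- sum(pos); n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  lab <- as.character(labels)
  if (!all(lab %in% c("normal", "abnormal")))
    stop_input("labels must be 'normal'/'abnormal' (or logical)")
  lab == "normal"
}

#' Classification accuracy at the zero-score threshold
#'
#' Fraction of examples where the sign rule (positive score = normal)
#' matches the label; the threshold is fixed at 0, not tuned.
#'
#' @inheritParams roc_auc
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_at_zero <- function(scores, labels) {
  if (length(scores) == 0) stop_input("accuracy_at_zero: empty input")
  pos <- normalize_labels(labels)
  mean((scores > 0) == pos)
}

confusion_at_zero <- function(scores, labels) {
  pos <- normalize_labels(labels)
  pred <- scores > 0
  c(tn = sum(pos & pred), fa = sum(pos & !pred),   # normal called normal / abnormal
    miss = sum(!pos & pred), hit = sum(!pos & !pred)) # abnormal called normal / abnormal
}

#' Outlier-ratio sweep on normal-only test data
#'
#' Trains one classifier per `nu` on the same normal training features and
#' reports the fraction of normal test patches classified normal. Higher
#' outlier ratios classify a larger share of normal examples as abnormal, so
#' the curve should decrease.
#'
#' @param train_features matrix of normal training feature vectors.
#' @param test_features_normal matrix of normal test feature vectors.
#' @param nu_grid numeric vector of outlier fractions (>= 2 values).
#' @param config base [ocsvm_config()]; `nu` is overridden per grid point.
#' @return data.frame (nu, normal_rate) with attribute `monotone_decreasing`.
#' @export
outlier_ratio_sweep <- function(train_features, test_features_normal,
                                nu_grid = c(0.02, 0.05, 0.08, 0.15, 0.20),
                                config = ocsvm_config()) {
  if (length(nu_grid) < 2)
    stop_param("outlier_ratio_sweep: nu_grid needs at least 2 values")
  rates <- vapply(nu_grid, function(nu) {
    cfg <- config; cfg$nu <- nu
    m <- train_ocsvm(train_features, cfg)
    mean(predict_score(m, test_features_normal) > 0)
  }, numeric(1))
  out <- data.frame(nu = nu_grid, normal_rate = rates)
  attr(out, "monotone_decreasing") <- !is.unsorted(rev(rates))
  out
}

#' Benchmark configuration
#'
#' Describes the end-to-end evaluation protocol at desk scale: `n_images`
#' phantom B-scans of `image_width` A-scans give about
#' `n_images * image_width / 32` patches (2240 by default);
#' patches are split 50/50, the network is trained on a subset of
#' the training half, one-class SVMs are trained per feature group on normal
#' training features, and a 4-way test set (normal + BCC + SCC + DEJ) is
#' built from the held-out patches.
#'
#' @param n_images number of phantom B-scans.
#' @param image_width A-scans per B-scan.
#' @param phantom base [phantom_params()].
#' @param seed global seed; stage seeds are derived from it.
#' @param nu outlier fraction for the reported classifiers.
#' @param groups feature groups to evaluate.
#' @param n_seg_train number of (patch, mask) pairs used to train the
#'   segmentation network (drawn from the training half).
#' @param seg_epochs,seg_batch segmentation training schedule.
#' @param nu_grid optional grid for an outlier-ratio sweep (NULL skips).
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_images = 35, image_width = 2048,
                             phantom = phantom_params(image_width = image_width),
                             seed = 1L, nu = 0.08,
                             groups = c("e_and_d", "epidermis", "dermis", "all"),
                             n_seg_train = 48, seg_epochs = 10, seg_batch = 8,
                             nu_grid = NULL) {
  phantom$image_width <- as.integer(image_width)
  structure(list(n_images = as.integer(n_images),
                 image_width = as.integer(image_width), phantom = phantom,
                 seed = as.integer(seed), nu = nu, groups = groups,
                 n_seg_train = as.integer(n_seg_train),
                 seg_epochs = as.integer(seg_epochs),
                 seg_batch = as.integer(seg_batch), nu_grid = nu_grid),
            class = "benchmark_config")
}

featurize_set <- function(model, patches, groups) {
  rows <- lapply(patches, function(p)
    featurize_patch_groups(model, p, groups = groups, on_degenerate = "null"))
  out <- lapply(groups, function(g) {
    vecs <- lapply(rows, `[[`, g)
    ok <- !vapply(vecs, is.null, logical(1))
    mat <- if (any(ok)) do.call(rbind, lapply(vecs[ok], as.numeric)) else NULL
    list(mat = mat, ok = ok)
  })
  stats::setNames(out, groups)
}

#' Run the phantom benchmark
#'
#' Generates phantoms, trains the segmentation network, extracts pooled
#' features with the network's own segmentation, trains one one-class SVM
#' per feature group on normal training features, scores the 4-way synthetic
#' test set, and reports per-group AUC, zero-threshold accuracy and
#' confusion counts. Fully deterministic for a fixed config.
#'
#' @param config a [benchmark_config()].
#' @param segmenter optional pre-trained `oct_unet` to reuse (skips
#'   segmentation training).
#' @param verbose print stage progress?
#' @return An `oct_eval_report`.
#' @export
run_benchmark <- function(config = benchmark_config(), segmenter = NULL,
                          verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("benchmark: generating %d phantoms (width %d)", config$n_images,
      config$image_width)
  data <- generate_dataset(config$phantom, config$n_images,
                           seed = derive_seed(config$seed, 1L))
  patches <- list(); masks <- list()
  for (d in data) {
    pp <- split_into_patches(d$image)
    mm <- split_into_patches(d$mask)
    patches <- c(patches, pp)
    masks <- c(masks, mm)
  }
  n <- length(patches)
  say("benchmark: %d patches", n)
  sp <- split_train_test(seq_len(n), fraction = 0.5,
                         seed = derive_seed(config$seed, 2L))
  tr <- sp$train_idx; te <- sp$test_idx

  if (is.null(segmenter)) {
    seg_idx <- with_seed(derive_seed(config$seed, 3L),
                         sample(tr, min(config$n_seg_train, length(tr))))
    say("benchmark: training U-Net on %d patches", length(seg_idx))
    segmenter <- build_unet(unet_config(), seed = derive_seed(config$seed, 4L))
    segmenter <- train_unet(segmenter, patches[seg_idx], masks[seg_idx],
                            train_config(batch_size = config$seg_batch,
                                         epochs = config$seg_epochs,
                                         seed = derive_seed(config$seed, 5L)))
  }

  say("benchmark: featurizing %d training patches", length(tr))
  train_feats <- featurize_set(segmenter, patches[tr], config$groups)

  say("benchmark: building 4-way test set from %d held-out patches", length(te))
  test_set <- build_anomaly_dataset(patches[te], masks[te],
                                    seed = derive_seed(config$seed, 6L))
  test_patches <- lapply(test_set, `[[`, "patch")
  test_labels <- vapply(test_set, `[[`, character(1), "label")
  test_classes <- vapply(test_set, `[[`, character(1), "class")
  say("benchmark: featurizing %d test patches", length(test_patches))
  test_feats <- featurize_set(segmenter, test_patches, config$groups)

  groups_out <- list()
  for (g in config$groups) {
    xtr <- train_feats[[g]]$mat
    if (is.null(xtr) || nrow(xtr) < 10) {
      groups_out[[g]] <- list(error = "insufficient non-degenerate training rows")
      next
    }
    svm <- train_ocsvm(xtr, ocsvm_config(nu = config$nu, feature_group = g,
                                         seed = derive_seed(config$seed, 7L)))
    ok <- test_feats[[g]]$ok
    sc <- predict_score(svm, test_feats[[g]]$mat)
    lab <- test_labels[ok]
    cls <- test_classes[ok]
    per_class_auc <- sapply(c("bcc", "scc", "dej"), function(cl) {
      sel <- cls %in% c("normal", cl)
      roc_auc(sc[sel], lab[sel])
    })
    groups_out[[g]] <- list(
      auc = roc_auc(sc, lab),
      accuracy = accuracy_at_zero(sc, lab),
      confusion = confusion_at_zero(sc, lab),
      per_class_auc = per_class_auc,
      n_scored = sum(ok), n_dropped = sum(!ok),
      train_rows = nrow(xtr), train_dropped = sum(!train_feats[[g]]$ok))
  }

  sweep_df <- NULL
  if (!is.null(config$nu_grid)) {
    g0 <- config$groups[1]
    ok0 <- test_feats[[g0]]$ok
    xnorm <- test_feats[[g0]]$mat[test_labels[ok0] == "normal", , drop = FALSE]
    sweep_df <- outlier_ratio_sweep(train_feats[[g0]]$mat, xnorm,
                                    config$nu_grid,
                                    ocsvm_config(feature_group = g0))
  }

  structure(list(groups = groups_out, nu = config$nu, sweep = sweep_df,
                 n_train = length(tr), n_test4 = length(test_patches),
                 seed = config$seed,
                 seg_log = segmenter$log),
            class = "oct_eval_report")
}

#' @export
print.oct_eval_report <- function(x, ...) {
  cat(sprintf("<oct_eval_report> nu = %.2f, %d train patches, %d 4-way test patches\n",
              x$nu, x$n_train, x$n_test4))
  for (g in names(x$groups)) {
    r <- x$groups[[g]]
    if (!is.null(r$error)) { cat(sprintf("  %-10s %s\n", g, r$error)); next }
    cat(sprintf("  %-10s AUC = %.3f  accuracy = %.3f  (dropped %d)\n",
                g, r$auc, r$accuracy, r$n_dropped))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `oct_eval_report`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  invisible(path)
}
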