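#' Extract per-pixel features from the trained network
#'
#' Forward-propagates a patch to the last ReLU of the last decoder stage and
#' returns its activations: one `base_features`-dimensional (16 by default)
#' non-negative vector per pixel.
#'
#' @param model trained `oct_unet`.
#' @param patch input patch matching the model input size.
#' @return A `pixel_feature_map`: array (depth x lateral x n_features).
#' @export
extract_pixel_features <- function(model, patch) {
  fwd <- unet_forward(model, patch)
  structure(fwd$features, class = "pixel_feature_map")
}

feature_groups <- c("all", "epidermis", "dermis", "e_and_d")

new_feature_vector <- function(values, group) {
  structure(as.numeric(values), group = group, class = "feature_vector")
}

#' Pool per-pixel features over a labeled pixel group
#'
#' Averages the per-pixel activations over the pixels of one group of the
#' segmentation mask: `"all"` means every pixel not labeled air (stratum
#' corneum included), `"epidermis"` and `"dermis"` are the respective layers
#' (stratum corneum excluded). The mask should be the network's own
#' segmentation of the same patch, not ground truth.
#'
#' @param fmap a `pixel_feature_map` from [extract_pixel_features()].
#' @param mask an [oct_mask()] with the same spatial size.
#' @param group `"all"`, `"epidermis"` or `"dermis"`.
#' @return A `feature_vector` of length `n_features` with a `group` attribute.
#' @export
pool_features <- function(fmap, mask, group = c("all", "epidermis", "dermis")) {
  group <- match.arg(group)
  fm <- unclass(fmap)
  lab <- as.matrix(mask)
  if (!all(dim(lab) == dim(fm)[1:2]))
    stop_input("pool_features: mask size does not match the feature map")
  sel <- switch(group,
                all = lab != OCT_LABELS[["AIR"]],
                epidermis = lab == OCT_LABELS[["EPIDERMIS"]],
                dermis = lab == OCT_LABELS[["DERMIS"]])
  if (!any(sel))
    stop_degenerate(paste0("pool_features: pixel group '", group,
                           "' is empty for this patch"), group = group)
  k <- dim(fm)[3]
  fmat <- matrix(fm, prod(dim(fm)[1:2]), k)
  new_feature_vector(colMeans(fmat[as.vector(sel), , drop = FALSE]), group)
}

#' Concatenate epidermis and dermis feature vectors
#'
#' Forms the combined predictor (epidermis block first, dermis block second),
#' 32-dimensional for the default 16-feature network.
#'
#' @param x_e epidermis `feature_vector`.
#' @param x_d dermis `feature_vector`.
#' @return A `feature_vector` with group `"e_and_d"`.
#' @export
concat_features <- function(x_e, x_d) {
  if (!identical(attr(x_e, "group"), "epidermis"))
    stop_input("concat_features: first argument must have group 'epidermis'")
  if (!identical(attr(x_d, "group"), "dermis"))
    stop_input("concat_features: second argument must have group 'dermis'")
  if (length(x_e) != length(x_d))
    stop_input("concat_features: inputs must have equal length")
  new_feature_vector(c(as.numeric(x_e), as.numeric(x_d)), "e_and_d")
}

#' Featurize a patch end to end
#'
#' Runs one forward pass, segments the patch with the network's own argmax
#' labels, and pools the per-pixel activations for the requested group
#' (concatenating epidermis and dermis blocks for `"e_and_d"`).
#'
#' @param model trained `oct_unet`.
#' @param patch input patch.
#' @param group one of `"all"`, `"epidermis"`, `"dermis"`, `"e_and_d"`.
#' @return A `feature_vector` (length 16 for single groups, 32 for
#'   `"e_and_d"` with the default network).
#' @export
featurize_patch <- function(model, patch,
                            group = c("e_and_d", "all", "epidermis", "dermis")) {
  group <- match.arg(group)
  featurize_patch_groups(model, patch, groups = group)[[group]]
}

#' Featurize a patch for several groups with one forward pass
#'
#' Shares the (expensive) network forward pass across pixel groups; used by
#' the evaluation module, where every patch is scored under all four
#' predictors. Degenerate groups (no pixels) yield `NULL` entries when
#' `on_degenerate = "null"`, or raise when `"error"`.
#'
#' @inheritParams featurize_patch
#' @param groups character vector of groups to pool.
#' @param on_degenerate `"error"` or `"null"`.
#' @return Named list of `feature_vector`s (or `NULL`s).
#' @export
featurize_patch_groups <- function(model, patch, groups = feature_groups,
                                   on_degenerate = c("error", "null")) {
  on_degenerate <- match.arg(on_degenerate)
  fwd <- unet_forward(model, patch)
  H <- dim(fwd$logits)[1]; W <- dim(fwd$logits)[2]
  lm <- matrix(fwd$logits, H * W, dim(fwd$logits)[3])
  mask <- oct_mask(matrix(max.col(lm, ties.method = "first") - 1L, H, W))
  fmap <- structure(fwd$features, class = "pixel_feature_map")
  pool_or <- function(g) {
    tryCatch(pool_features(fmap, mask, g), octoneclass_degenerate_error = function(e) {
      if (on_degenerate == "error") stop(e)
      NULL
    })
  }
  out <- stats::setNames(vector("list", length(groups)), groups)
  need_e <- "e_and_d" %in% groups
  xe <- if ("epidermis" %in% groups || need_e) pool_or("epidermis")
  xd <- if ("dermis" %in% groups || need_e) pool_or("dermis")
  for (g in groups) {
    out[[g]] <- switch(g,
      all = pool_or("all"),
      epidermis = xe,
      dermis = xd,
      e_and_d = if (is.null(xe) || is.null(xd)) {
        if (on_degenerate == "error")
          stop_degenerate("featurize_patch_groups: empty epidermis or dermis group",
                          group = "e_and_d")
        NULL
      } else concat_features(xe, xd))
  }
  out
}
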