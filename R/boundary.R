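# Daubechies-4 orthogonal filter pair.
d4_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  list(h = h, g = c(h[4], -h[3], h[2], -h[1]))
}

# One periodic analysis step: signal of even length n -> (approx, detail).
dwt_step <- function(s) {
  f <- d4_filters()
  n <- length(s)
  k <- seq.int(0, n / 2 - 1)
  a <- numeric(n / 2); d <- numeric(n / 2)
  for (m in 0:3) {
    idx <- ((2 * k + m) %% n) + 1
    a <- a + f$h[m + 1] * s[idx]
    d <- d + f$g[m + 1] * s[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  f <- d4_filters()
  n <- 2 * length(a)
  s <- numeric(n)
  k <- seq.int(0, length(a) - 1)
  for (m in 0:3) {
    idx <- ((2 * k + m) %% n) + 1
    contrib <- f$h[m + 1] * a + f$g[m + 1] * d
    s[idx] <- s[idx] + contrib
  }
  s
}

# Multi-level periodic D4 DWT of a signal padded to a multiple of 2^level.
dwt_d4 <- function(x, level) {
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- dwt_step(a)
    a <- st$a
    details[[l]] <- st$d
  }
  list(approx = a, details = details)
}

idwt_d4 <- function(w) {
  a <- w$approx
  for (l in rev(seq_along(w$details))) a <- idwt_step(a, w$details[[l]])
  a
}

soft_threshold <- function(x, thr) sign(x) * pmax(abs(x) - thr, 0)

#' Denoise a score trace by wavelet-domain soft thresholding
#'
#' Daubechies-4 discrete wavelet transform at level
#' `min(3, floor(log2(n)) - 2)`, soft thresholding of all detail
#' coefficients at the universal threshold `sigma * sqrt(2 log n)` with
#' `sigma` estimated from the median absolute deviation of the finest-scale
#' details, then inverse transform. The input is symmetrically padded to a
#' multiple of `2^level` and truncated back, so output length equals input
#' length. A constant trace is returned unchanged.
#'
#' @param scores numeric vector (>= 8 samples).
#' @param level decomposition depth; default as above.
#' @return The filtered scores.
#' @export
denoise_scores <- function(scores, level = NULL) {
  x <- as.numeric(scores)
  n <- length(x)
  if (n < 8) stop_input("denoise_scores: need at least 8 samples")
  if (is.null(level)) level <- min(3L, as.integer(floor(log2(n))) - 2L)
  level <- max(1L, as.integer(level))
  blk <- 2L^level
  n_pad <- ceiling(n / blk) * blk
  xp <- if (n_pad > n) c(x, x[n - seq_len(n_pad - n) + 1]) else x # reflect right
  w <- dwt_d4(xp, level)
  sigma <- stats::median(abs(w$details[[1]])) / 0.6745
  thr <- sigma * sqrt(2 * log(n))
  if (sigma > 0)
    w$details <- lapply(w$details, soft_threshold, thr = thr)
  idwt_d4(w)[seq_len(n)]
}

#' Spatially resolved one-class score trace along a B-scan
#'
#' Slides a 32-A-scan window across the image with the given stride; each
#' window is featurized with the classifier's configured group and scored.
#' Position is the window center (A-scan units, 1-based column index scale).
#' With `stride = 32` the trace reduces to the non-overlapping patches of
#' [classify_image()].
#'
#' @param model trained `oct_ocsvm`.
#' @param segmenter trained `oct_unet`.
#' @param image an [oct_image()] with width >= 32.
#' @param stride window advance in A-scans (1 to 32); default 1.
#' @param window window width in A-scans.
#' @return A `score_trace`: list with `positions`, `scores` and (after
#'   [denoise_trace()]) `filtered`.
#' @export
score_trace <- function(model, segmenter, image, stride = 1L, window = 32L) {
  m <- as.matrix(image)
  if (ncol(m) < window)
    stop_input("score_trace: image width ", ncol(m), " < window ", window)
  if (stride < 1 || stride > window)
    stop_param("score_trace: stride must be in 1..", window)
  starts <- seq.int(1L, ncol(m) - window + 1L, by = stride)
  grp <- model$config$feature_group
  positions <- numeric(0); scores <- numeric(0)
  for (s0 in starts) {
    patch <- m[, s0:(s0 + window - 1L), drop = FALSE]
    fv <- featurize_patch_groups(segmenter, patch, groups = grp,
                                 on_degenerate = "null")[[grp]]
    if (is.null(fv)) next
    positions <- c(positions, s0 + (window - 1) / 2)
    scores <- c(scores, predict_score(model, fv))
  }
  if (length(scores) == 0)
    stop_input("score_trace: no scorable windows")
  structure(list(positions = positions, scores = scores, filtered = NULL,
                 stride = stride, window = window),
            class = "score_trace")
}

#' Fill the filtered component of a score trace
#'
#' Convenience wrapper applying [denoise_scores()] to `trace$scores`.
#'
#' @param trace a `score_trace`.
#' @return The trace with `filtered` set.
#' @export
denoise_trace <- function(trace) {
  trace$filtered <- denoise_scores(trace$scores)
  trace
}

#' Detect normal/abnormal boundaries from a filtered score trace
#'
#' Takes the first-order difference of the filtered scores and reports local
#' extrema of its magnitude exceeding `min_jump` as boundaries. The sign of
#' the difference gives the crossing direction (score dropping:
#' normal to abnormal). An empty result (no extremum above `min_jump`) is
#' not an error. In the single-boundary case the global peak of the
#' difference magnitude marks the tissue edge.
#'
#' @param trace a `score_trace` with `filtered` present (see
#'   [denoise_trace()]).
#' @param min_jump minimum difference magnitude for a boundary, in score
#'   units. See [calibrate_min_jump()] for a data-driven choice from
#'   normal-only traces.
#' @return data.frame with columns `position` (midpoint between the two
#'   window centers), `direction` and `magnitude`.
#' @export
detect_boundary <- function(trace, min_jump) {
  if (is.null(trace$filtered))
    stop_input("detect_boundary: trace has no filtered scores; ",
               "run denoise_trace() first")
  f <- trace$filtered
  if (length(f) < 2)
    return(data.frame(position = numeric(0), direction = character(0),
                      magnitude = numeric(0)))
  d <- diff(f)
  ad <- abs(d)
  n <- length(d)
  left <- c(-Inf, ad[-n])
  right <- c(ad[-1], -Inf)
  is_peak <- ad > min_jump & ad >= right & ad > left # >= right: plateau keeps first
  idx <- which(is_peak)
  data.frame(
    position = (trace$positions[idx] + trace$positions[idx + 1]) / 2,
    direction = ifelse(d[idx] < 0, "normal_to_abnormal", "abnormal_to_normal"),
    magnitude = ad[idx])
}

#' Calibrate the boundary jump threshold from normal-only traces
#'
#' Returns half the 95th percentile of the absolute first difference of the
#' filtered scores pooled over traces from normal tissue, a conservative
#' floor below genuine normal/abnormal transitions.
#'
#' @param traces list of `score_trace`s from normal tissue (filtered filled
#'   in automatically when absent).
#' @return Numeric threshold.
#' @export
calibrate_min_jump <- function(traces) {
  diffs <- unlist(lapply(traces, function(tr) {
    if (is.null(tr$filtered)) tr <- denoise_trace(tr)
    abs(diff(tr$filtered))
  }))
  0.5 * as.numeric(stats::quantile(diffs, 0.95))
}

#' Export a score trace and its boundaries
#'
#' Writes the trace as CSV (position, raw score, filtered score) and the
#' boundaries as a BED-like 3-column point file in 0-based half-open A-scan
#' coordinates.
#'
#' @param trace a `score_trace`.
#' @param boundaries data.frame from [detect_boundary()].
#' @param csv_path,bed_path output file paths (NULL skips either).
#' @return Invisibly, the trace data.frame.
#' @export
export_trace <- function(trace, boundaries = NULL, csv_path = NULL,
                         bed_path = NULL) {
  df <- data.frame(position = trace$positions, score = trace$scores,
                   filtered = trace$filtered %||% NA_real_)
  if (!is.null(csv_path)) utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(bed_path) && !is.null(boundaries)) {
    start0 <- pmax(0L, as.integer(floor(boundaries$position)) - 1L)
    bed <- data.frame(chrom = "scan", start = start0, end = start0 + 1L,
                      name = boundaries$direction)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(df)
}
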