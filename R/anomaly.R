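#' Specification of a synthetic abnormality operator
#'
#' The three operators emulate hallmark OCT signatures of abnormal skin on
#' the linear magnitude image: BCC-like attenuation (signal reduced to 75%
#' of its value from a random depth within the dermis downward), SCC-like
#' focal brightening (signal enhanced by 25% inside a random sub-surface
#' region), and DEJ disruption (per-A-scan normalization by the averaged
#' depth profile, which flattens the shared layer structure).
#'
#' @param kind `"bcc"`, `"scc"` or `"dej"`.
#' @param bcc_factor multiplier applied below the BCC onset depth (0.75).
#' @param scc_factor multiplier applied inside the SCC region (1.25).
#' @param scc_region_bounds list with integer ranges `height` and `width`
#'   (pixels) for the SCC region.
#' @param rng_seed integer seed for the random geometry.
#' @return An `anomaly_spec` list.
#' @export
anomaly_spec <- function(kind = c("bcc", "scc", "dej"), bcc_factor = 0.75,
                         scc_factor = 1.25,
                         scc_region_bounds = list(height = c(20L, 60L),
                                                  width = c(8L, 24L)),
                         rng_seed = 1L) {
  kind <- match.arg(kind)
  if (!(bcc_factor > 0 && bcc_factor <= 1))
    stop_param("anomaly_spec: violated '0 < bcc_factor <= 1'")
  if (!(scc_factor >= 1))
    stop_param("anomaly_spec: violated 'scc_factor >= 1'")
  structure(list(kind = kind, bcc_factor = bcc_factor, scc_factor = scc_factor,
                 scc_region_bounds = scc_region_bounds,
                 rng_seed = as.integer(rng_seed)),
            class = "anomaly_spec")
}

# Uniform integer draw on [lo, hi] that is safe when lo == hi (plain
# sample(x, 1) would sample 1:x).
sample_int_range <- function(lo, hi) {
  if (lo > hi) stop_param("empty integer range [", lo, ", ", hi, "]")
  if (lo == hi) as.integer(lo) else as.integer(sample(seq(lo, hi), 1))
}

keep_oct_attrs <- function(template, m) {
  if (inherits(template, "oct_image"))
    oct_image(m, attr(template, "axial_spacing") %||% 5,
              attr(template, "lateral_spacing") %||% 17)
  else m
}

#' Synthesize a BCC-like image
#'
#' Draws one onset row uniformly from the dermis depth range of the patch
#' and scales every pixel at or below it (across all columns) to
#' `bcc_factor` (75%) of its original value; everything above is untouched.
#'
#' @param image an [oct_image()].
#' @param mask its segmentation mask (must contain dermis in every column).
#' @param spec an [anomaly_spec()].
#' @return The modified image; attribute `onset_row` records the drawn row.
#' @export
synthesize_bcc <- function(image, mask, spec = anomaly_spec("bcc")) {
  m <- as.matrix(image)
  lab <- as.matrix(mask)
  dermis_cols <- colSums(lab == OCT_LABELS[["DERMIS"]]) > 0
  if (!all(dermis_cols))
    stop_degenerate("synthesize_bcc: mask has columns without dermis pixels")
  dermis_rows <- which(rowSums(lab == OCT_LABELS[["DERMIS"]]) > 0)
  z0 <- with_seed(spec$rng_seed,
                  sample_int_range(min(dermis_rows), max(dermis_rows)))
  out <- m
  out[z0:nrow(m), ] <- out[z0:nrow(m), ] * spec$bcc_factor
  res <- keep_oct_attrs(image, out)
  attr(res, "onset_row") <- z0
  res
}

#' Synthesize an SCC-like image
#'
#' Scales a random axis-aligned rectangular region, lying fully below the
#' detected skin surface, by `scc_factor` (+25%); pixels outside the region
#' are untouched. Region height/width are drawn from `scc_region_bounds`.
#'
#' @inheritParams synthesize_bcc
#' @return The modified image; attribute `region` records
#'   `c(row0, row1, col0, col1)`.
#' @export
synthesize_scc <- function(image, mask, spec = anomaly_spec("scc")) {
  m <- as.matrix(image)
  lab <- as.matrix(mask)
  H <- nrow(m); W <- ncol(m)
  if (any(colSums(lab != OCT_LABELS[["AIR"]]) == 0))
    stop_degenerate("synthesize_scc: mask has columns without tissue pixels")
  surface <- apply(lab != OCT_LABELS[["AIR"]], 2, function(col) which(col)[1])
  b <- spec$scc_region_bounds
  with_seed(spec$rng_seed, {
    h <- sample_int_range(b$height[1], b$height[2])
    w <- sample_int_range(b$width[1], b$width[2])
    if (w > W || h > H)
      stop_param("synthesize_scc: region bounds infeasible for a ", H, "x", W,
                 " image")
    c0 <- sample_int_range(1L, W - w + 1L)
    top_min <- max(surface[c0:(c0 + w - 1)]) + 1L
    if (top_min + h - 1 > H)
      stop_param("synthesize_scc: no feasible region placement below the ",
                 "surface for height ", h)
    r0 <- sample_int_range(top_min, H - h + 1L)
  })
  out <- m
  out[r0:(r0 + h - 1), c0:(c0 + w - 1)] <-
    out[r0:(r0 + h - 1), c0:(c0 + w - 1)] * spec$scc_factor
  res <- keep_oct_attrs(image, out)
  attr(res, "region") <- c(row0 = r0, row1 = r0 + h - 1, col0 = c0,
                           col1 = c0 + w - 1)
  res
}

#' Synthesize a DEJ-disrupted image
#'
#' Normalizes each A-scan by the image's averaged depth profile
#' `Abar(z) = mean_x image(z, x)` and rescales by `mean_z(Abar)` so the
#' overall mean magnitude is preserved. The shared layered depth structure
#' (including the DEJ contrast) is flattened while per-column deviations
#' survive.
#'
#' @param image an [oct_image()] with at least 2 A-scans.
#' @return The normalized image.
#' @export
synthesize_dej_disruption <- function(image) {
  m <- as.matrix(image)
  if (ncol(m) < 2)
    stop_input("synthesize_dej_disruption: image must have >= 2 A-scans")
  if (all(m == 0))
    stop_degenerate("synthesize_dej_disruption: all-zero image")
  abar <- rowMeans(m)
  eps <- 1e-6 * max(m)
  out <- m / pmax(abar, eps) * mean(abar)
  keep_oct_attrs(image, out)
}

#' Build a labeled 4-way anomaly dataset from normal patches
#'
#' For every normal patch, adds one BCC-like, one SCC-like and one
#' DEJ-disrupted variant, so the output has `4 * length(patches)` entries.
#' Anomaly geometry uses per-patch child seeds derived from `seed`.
#'
#' @param patches list of normal patches ([oct_image]s or matrices).
#' @param masks list of matching segmentation masks (used by the BCC and SCC
#'   operators to locate dermis and surface).
#' @param seed integer master seed.
#' @param bcc_factor,scc_factor,scc_region_bounds passed to [anomaly_spec()].
#' @return A list of entries `list(patch, class, label, source)` where
#'   `class` is one of `"normal"`, `"bcc"`, `"scc"`, `"dej"` and `label` is
#'   `"normal"` or `"abnormal"`.
#' @export
build_anomaly_dataset <- function(patches, masks, seed = 1L, bcc_factor = 0.75,
                                  scc_factor = 1.25,
                                  scc_region_bounds = list(height = c(20L, 60L),
                                                           width = c(8L, 24L))) {
  if (length(patches) < 1) stop_input("build_anomaly_dataset: empty input")
  if (length(masks) != length(patches))
    stop_input("build_anomaly_dataset: patches and masks must have equal length")
  out <- vector("list", 4L * length(patches))
  k <- 0L
  for (i in seq_along(patches)) {
    img <- patches[[i]]; msk <- masks[[i]]
    sb <- anomaly_spec("bcc", bcc_factor = bcc_factor,
                       scc_region_bounds = scc_region_bounds,
                       rng_seed = derive_seed(seed, 3L * i))
    ss <- anomaly_spec("scc", scc_factor = scc_factor,
                       scc_region_bounds = scc_region_bounds,
                       rng_seed = derive_seed(seed, 3L * i + 1L))
    variants <- list(normal = img,
                     bcc = synthesize_bcc(img, msk, sb),
                     scc = synthesize_scc(img, msk, ss),
                     dej = synthesize_dej_disruption(img))
    for (cls in names(variants)) {
      k <- k + 1L
      out[[k]] <- list(patch = variants[[cls]], class = cls,
                       label = if (cls == "normal") "normal" else "abnormal",
                       source = i)
    }
  }
  out
}
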