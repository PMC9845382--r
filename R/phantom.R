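#' OCT B-scan image container
#'
#' A 2D non-negative magnitude image. Row index is depth (z, row 1 at the
#' air side), column index is the lateral A-scan position. Pixel spacings are
#' carried as attributes so physical extents can be computed
#' (defaults: 5 um axial, 17 um lateral sampling).
#'
#' @param pixels numeric matrix of non-negative magnitudes (depth x lateral).
#' @param axial_spacing axial pixel spacing in micrometres.
#' @param lateral_spacing lateral A-scan spacing in micrometres.
#' @return An `oct_image`: the matrix with spacing attributes.
#' @export
oct_image <- function(pixels, axial_spacing = 5, lateral_spacing = 17) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop_input("oct_image: pixels must be numeric")
  if (any(!is.finite(pixels))) stop_input("oct_image: pixels must be finite")
  if (any(pixels < 0)) stop_input("oct_image: magnitudes must be non-negative")
  structure(pixels, axial_spacing = axial_spacing,
            lateral_spacing = lateral_spacing, class = c("oct_image", "matrix"))
}

#' @export
print.oct_image <- function(x, ...) {
  cat(sprintf("<oct_image> %d x %d px (%.2f mm deep x %.2f mm wide)\n",
              nrow(x), ncol(x),
              nrow(x) * attr(x, "axial_spacing") / 1000,
              ncol(x) * attr(x, "lateral_spacing") / 1000))
  invisible(x)
}

#' Segmentation mask container
#'
#' Per-pixel integer labels using the [OCT_LABELS] encoding.
#'
#' @param labels integer matrix with values in `0:3`.
#' @return An `oct_mask`.
#' @export
oct_mask <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (any(!(labels %in% 0:3)))
    stop_input("oct_mask: labels must be in {0 (air), 1 (SC), 2 (epidermis), 3 (dermis)}")
  structure(labels, class = c("oct_mask", "matrix"))
}

#' Parameters of the synthetic layered-skin phantom
#'
#' Describes a normal-skin B-scan as the classifier assumes it: a signal-free
#' air region, a thin bright stratum corneum, an epidermis of reduced
#' brightness with a clearly visible dermis-epidermis junction (DEJ), and a
#' dermis whose magnitude decays exponentially with depth. Speckle is
#' modelled as i.i.d. multiplicative unit-mean Rayleigh noise so the expected
#' image equals the noise-free template.
#'
#' @param image_height image depth in pixels.
#' @param image_width number of A-scans.
#' @param axial_spacing,lateral_spacing pixel spacings in micrometres.
#' @param surface_depth_mean mean air-skin surface row (pixels from top).
#' @param surface_undulation_amp amplitude of the smooth random surface
#'   undulation, in pixels (0 gives a flat surface).
#' @param sc_thickness stratum corneum thickness in pixels (thin, 2-5).
#' @param epidermis_thickness_mean epidermis thickness in pixels.
#' @param intensity_air noise-floor mean magnitude.
#' @param intensity_sc stratum corneum mean magnitude (the brightest layer).
#' @param intensity_epidermis epidermis mean magnitude (below `intensity_sc`).
#' @param intensity_dermis_top dermis magnitude at the DEJ.
#' @param dermis_decay_length exponential decay constant of the dermis signal,
#'   in pixels.
#' @param speckle_enabled multiply each pixel by unit-mean Rayleigh speckle?
#' @param rng_seed integer seed controlling surface shape and speckle.
#' @return A validated `phantom_params` list.
#' @export
phantom_params <- function(image_height = 256, image_width = 512,
                           axial_spacing = 5, lateral_spacing = 17,
                           surface_depth_mean = 20, surface_undulation_amp = 6,
                           sc_thickness = 3, epidermis_thickness_mean = 20,
                           intensity_air = 0.05, intensity_sc = 1.0,
                           intensity_epidermis = 0.55,
                           intensity_dermis_top = 0.75,
                           dermis_decay_length = 60,
                           speckle_enabled = TRUE, rng_seed = 1L) {
  p <- list(image_height = image_height, image_width = image_width,
            axial_spacing = axial_spacing, lateral_spacing = lateral_spacing,
            surface_depth_mean = surface_depth_mean,
            surface_undulation_amp = surface_undulation_amp,
            sc_thickness = sc_thickness,
            epidermis_thickness_mean = epidermis_thickness_mean,
            intensity_air = intensity_air, intensity_sc = intensity_sc,
            intensity_epidermis = intensity_epidermis,
            intensity_dermis_top = intensity_dermis_top,
            dermis_decay_length = dermis_decay_length,
            speckle_enabled = isTRUE(speckle_enabled),
            rng_seed = as.integer(rng_seed))
  validate_phantom_params(p)
  structure(p, class = "phantom_params")
}

validate_phantom_params <- function(p) {
  if (!(p$intensity_air >= 0))
    stop_param("phantom_params: violated 'intensity_air >= 0'")
  if (!(p$intensity_epidermis > p$intensity_air))
    stop_param("phantom_params: violated 'intensity_epidermis > intensity_air'")
  if (!(p$intensity_sc > p$intensity_epidermis))
    stop_param("phantom_params: violated 'intensity_sc > intensity_epidermis'")
  for (f in c("sc_thickness", "epidermis_thickness_mean", "dermis_decay_length",
              "image_height", "image_width", "axial_spacing", "lateral_spacing"))
    if (!(p[[f]] > 0)) stop_param("phantom_params: violated '", f, " > 0'")
  if (p$surface_undulation_amp < 0)
    stop_param("phantom_params: violated 'surface_undulation_amp >= 0'")
  if (!(p$surface_depth_mean + p$sc_thickness + p$epidermis_thickness_mean + 1 <
          p$image_height))
    stop_param("phantom_params: violated 'surface + SC + epidermis ",
               "thicknesses + 1 < image_height'")
  invisible(p)
}

# Smooth low-frequency random curve in [-1, 1]: a few random-phase sinusoids
# with periods long relative to a 32-A-scan patch, normalized to unit max.
smooth_undulation <- function(width) {
  periods <- c(96, 160, 256, 416)
  phases <- runif(length(periods), 0, 2 * pi)
  amps <- runif(length(periods), 0.5, 1)
  x <- seq_len(width)
  s <- rep(0, width)
  for (k in seq_along(periods))
    s <- s + amps[k] * sin(2 * pi * x / periods[k] + phases[k])
  m <- max(abs(s))
  if (m == 0) rep(0, width) else s / m
}

# Unit-mean Rayleigh variates (sigma = sqrt(2/pi)), the standard magnitude
# statistic of fully developed speckle.
rayleigh_unit_mean <- function(n) {
  sqrt(2 / pi) * sqrt(-2 * log(runif(n)))
}

#' Generate a synthetic normal-skin OCT B-scan with its ground-truth mask
#'
#' Builds the noise-free layer template (air at the noise floor, bright
#' stratum corneum, dimmer epidermis, exponentially decaying dermis), bends
#' the surface by a smooth random undulation, and (optionally) multiplies
#' every pixel by i.i.d. unit-mean Rayleigh speckle. Deterministic for a
#' fixed `rng_seed`.
#'
#' @param params a [phantom_params()] object.
#' @return A list with elements `image` ([oct_image]) and `mask` ([oct_mask]).
#' @export
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params")) params <- do.call(phantom_params, params)
  validate_phantom_params(params)
  H <- params$image_height; W <- params$image_width
  with_seed(params$rng_seed, {
    und <- if (params$surface_undulation_amp > 0)
      round(params$surface_undulation_amp * smooth_undulation(W)) else rep(0, W)
    surface <- pmax(1, round(params$surface_depth_mean) + und) # last air row
    img <- matrix(params$intensity_air, H, W)
    lab <- matrix(OCT_LABELS[["AIR"]], H, W)
    for (x in seq_len(W)) {
      s <- surface[x]
      sc_top <- s + 1
      sc_bot <- min(H, s + params$sc_thickness)
      ep_top <- sc_bot + 1
      ep_bot <- min(H, sc_bot + params$epidermis_thickness_mean)
      if (sc_bot >= sc_top) {
        img[sc_top:sc_bot, x] <- params$intensity_sc
        lab[sc_top:sc_bot, x] <- OCT_LABELS[["SC"]]
      }
      if (ep_bot >= ep_top) {
        img[ep_top:ep_bot, x] <- params$intensity_epidermis
        lab[ep_top:ep_bot, x] <- OCT_LABELS[["EPIDERMIS"]]
      }
      if (ep_bot < H) {
        d <- 0:(H - ep_bot - 1) # pixels below the DEJ, 0 at the first dermis row
        img[(ep_bot + 1):H, x] <-
          params$intensity_dermis_top * exp(-d / params$dermis_decay_length)
        lab[(ep_bot + 1):H, x] <- OCT_LABELS[["DERMIS"]]
      }
    }
    if (params$speckle_enabled)
      img <- img * matrix(rayleigh_unit_mean(H * W), H, W)
    list(image = oct_image(img, params$axial_spacing, params$lateral_spacing),
         mask = oct_mask(lab))
  })
}

#' Generate a reproducible set of phantom B-scans
#'
#' Each image uses an independent child seed derived deterministically from
#' `(seed, index)`, with per-image jitter of the surface depth, stratum
#' corneum thickness (kept within 2-5 px) and epidermis thickness (+/- 30%)
#' to create inter-image variability.
#'
#' @param params base [phantom_params()]; per-image seeds override `rng_seed`.
#' @param n_images number of images (>= 1).
#' @param seed integer master seed.
#' @return A list of `list(image, mask)` pairs of length `n_images`.
#' @export
generate_dataset <- function(params, n_images, seed = 1L) {
  if (!is.numeric(n_images) || n_images < 1)
    stop_param("generate_dataset: n_images must be >= 1")
  n_images <- as.integer(n_images)
  lapply(seq_len(n_images), function(i) {
    child <- derive_seed(seed, i)
    p <- unclass(params)
    with_seed(child, {
      p$surface_depth_mean <- max(2, round(params$surface_depth_mean +
                                             runif(1, -5, 5)))
      p$sc_thickness <- max(2L, min(5L, params$sc_thickness +
                                      sample(c(-1L, 0L, 1L), 1)))
      p$epidermis_thickness_mean <-
        max(4, round(params$epidermis_thickness_mean * runif(1, 0.7, 1.3)))
    })
    p$rng_seed <- derive_seed(child, 1L)
    generate_phantom(do.call(phantom_params, p))
  })
}
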