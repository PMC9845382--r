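#' Read and write OCT images and masks as TIFF
#'
#' Images are stored as single-channel 32-bit float TIFF in linear magnitude;
#' masks as 8-bit TIFF with the label encoding AIR=0, SC=1, EPIDERMIS=2,
#' DERMIS=3. A JSON sidecar (`<path>.json`) stores pixel spacings and
#' arbitrary generation parameters.
#'
#' @param image an [oct_image()].
#' @param path TIFF file path.
#' @param params optional list stored in the JSON sidecar.
#' @return `write_*` return the path invisibly; `read_*` the object.
#' @export
write_oct_tiff <- function(image, path, params = NULL) {
  m <- as.matrix(image)
  # float TIFF storage is only defined on [0, 1]; normalize and record the
  # scale in the sidecar
  scale <- max(m, 1)
  tiff::writeTIFF(m / scale, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(axial_spacing = attr(image, "axial_spacing") %||% 5,
               lateral_spacing = attr(image, "lateral_spacing") %||% 17,
               magnitude_scale = scale,
               params = params)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_oct_tiff
#' @export
read_oct_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  side_path <- paste0(path, ".json")
  ax <- 5; lat <- 17; scale <- 1
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    ax <- side$axial_spacing %||% 5
    lat <- side$lateral_spacing %||% 17
    scale <- side$magnitude_scale %||% 1
  }
  oct_image(m * scale, ax, lat)
}

#' @rdname write_oct_tiff
#' @param mask an [oct_mask()].
#' @export
write_mask_tiff <- function(mask, path) {
  m <- as.matrix(mask)
  tiff::writeTIFF(m / 255, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_oct_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3) m <- m[, , 1]
  oct_mask(m)
}

#' Write a feature matrix as CSV
#'
#' One row per patch: `patch_id`, `group`, then the feature columns
#' (`f1..fK`).
#'
#' @param features numeric matrix (rows = patches).
#' @param group feature group name.
#' @param path output CSV path.
#' @param patch_ids optional identifiers (default row numbers).
#' @return The path, invisibly.
#' @export
write_features_csv <- function(features, group, path, patch_ids = NULL) {
  features <- as.matrix(features)
  ids <- patch_ids %||% seq_len(nrow(features))
  df <- data.frame(patch_id = ids, group = group, features)
  names(df)[-(1:2)] <- paste0("f", seq_len(ncol(features)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path)
  mat <- as.matrix(df[, grep("^f[0-9]+$", names(df)), drop = FALSE])
  attr(mat, "group") <- df$group[1]
  attr(mat, "patch_ids") <- df$patch_id
  mat
}
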