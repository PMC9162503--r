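#' Read a multifocus stack from a multi-page TIFF and YAML sidecar
#'
#' The sidecar carries what TIFF tags cannot: the per-slice EFTL currents,
#' pixel pitch, bit depth, the intensity scale used to normalize pages for
#' storage, and (optionally) the effective blur coefficient `R0` and optics
#' constants.
#'
#' @param tiff_path Multi-page TIFF (8/16-bit grayscale or RGB, or 32-bit
#'   float normalized pages).
#' @param metadata_path YAML sidecar with at least `currents_mA`.
#' @return A [multifocus_stack()]; sidecar extras (`R0`, `optics`, `notes`)
#'   are attached as attributes.
#' @export
read_stack <- function(tiff_path, metadata_path) {
  if (!file.exists(tiff_path)) stop_arg(paste("no such TIFF:", tiff_path))
  if (!file.exists(metadata_path)) stop_arg(paste("no such metadata:", metadata_path))
  meta <- yaml::read_yaml(metadata_path)
  if (is.null(meta$currents_mA)) stop_arg("metadata lacks currents_mA")
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$currents_mA))
    stop_arg(sprintf("TIFF has %d pages but metadata lists %d currents",
                     length(pages), length(meta$currents_mA)))
  scale <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L && dim(p)[3] == 4L) p <- p[, , 1:3]  # drop alpha
    p * scale
  })
  st <- multifocus_stack(
    slices, meta$currents_mA,
    pixel_pitch_um = if (is.null(meta$pixel_pitch_um)) 5.5 else meta$pixel_pitch_um,
    bit_depth = if (is.null(meta$bit_depth)) NA else meta$bit_depth,
    registered = isTRUE(meta$registered))
  attr(st, "R0") <- meta$R0
  attr(st, "notes") <- meta$notes
  st
}

#' Write a multifocus stack to a multi-page TIFF and YAML sidecar
#'
#' Integer bit depths are stored as 8/16-bit pages; float stacks as 32-bit
#' pages. Pages are normalized to `[0, 1]` by an intensity scale recorded
#' in the sidecar (dtype maximum for integer data, the stack maximum for
#' float), so the round trip is lossless to storage precision.
#'
#' @param stack A [multifocus_stack()].
#' @param tiff_path,metadata_path Output paths.
#' @param R0 Optional blur coefficient (px/mA) recorded in the sidecar.
#' @param notes Optional free-text acquisition notes.
#' @return Invisibly, `c(tiff_path, metadata_path)`.
#' @export
write_stack <- function(stack, tiff_path, metadata_path, R0 = NULL,
                        notes = NULL) {
  stopifnot(inherits(stack, "multifocus_stack"))
  bd <- stack$bit_depth
  if (is.na(bd)) {
    scale <- max(vapply(stack$slices, max, numeric(1)), 1e-300)
    bits <- 32L
  } else {
    if (!bd %in% c(8L, 16L)) stop_arg("bit_depth must be 8, 16 or NA (float)")
    scale <- 2^bd - 1
    bits <- as.integer(bd)
  }
  pages <- lapply(stack$slices, function(s) pmin(pmax(s / scale, 0), 1))
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = bits, reduce = FALSE)
  meta <- list(currents_mA = stack$currents_mA,
               pixel_pitch_um = stack$pixel_pitch_um,
               bit_depth = if (is.na(bd)) NULL else bd,
               registered = stack$registered,
               intensity_scale = scale,
               n_slices = n_slices(stack))
  if (!is.null(R0)) meta$R0 <- R0
  if (!is.null(notes)) meta$notes <- notes
  yaml::write_yaml(meta, metadata_path)
  invisible(c(tiff_path, metadata_path))
}

# Clip to [0, 1] against a dtype maximum and write PNG or (float) TIFF by
# extension.
write_image <- function(img, path, max_value = 255) {
  x <- pmin(pmax(img / max_value, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(x, path)
  } else {
    tiff::writeTIFF(x, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}
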