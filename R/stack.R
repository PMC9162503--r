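#' Multifocus image stack
#'
#' The central container: an ordered set of images of the same scene, each
#' acquired with a different EFTL drive current (hence a different focal
#' plane), together with the per-slice currents and sensor metadata.
#'
#' @param slices List of numeric matrices (grayscale, rows = y, cols = x) or
#'   H x W x 3 arrays (RGB); all slices must share dimensions and channel
#'   count, with non-negative intensities.
#' @param currents_mA Numeric vector of EFTL drive currents, one per slice.
#' @param pixel_pitch_um Sensor pixel pitch, micrometers.
#' @param bit_depth Nominal bit depth of the acquisition (8 or 16) or `NA`
#'   for floating-point data; used only for export scaling and unit-scale
#'   metrics.
#' @param registered Logical; whether the stack has been registered to a
#'   common field of view and energy.
#' @return An object of class `multifocus_stack`.
#' @examples
#' s <- multifocus_stack(list(matrix(1, 4, 4), matrix(2, 4, 4)), c(50, 0))
#' n_slices(s)
#' @export
multifocus_stack <- function(slices, currents_mA, pixel_pitch_um = 5.5,
                             bit_depth = 8, registered = FALSE) {
  if (!is.list(slices) || length(slices) < 1L)
    stop_arg("a multifocus stack needs at least one slice")
  if (length(currents_mA) != length(slices))
    stop_arg(sprintf("currents (%d) do not match slice count (%d)",
                     length(currents_mA), length(slices)))
  dims <- lapply(slices, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop_arg("all slices must share identical dimensions and channel count")
  if (any(vapply(slices, function(s) any(!is.finite(s)), logical(1))))
    stop_arg("slices contain non-finite values")
  if (any(vapply(slices, function(s) any(s < 0), logical(1))))
    stop_arg("slice intensities must be non-negative")
  structure(list(
    slices = slices,
    currents_mA = as.numeric(currents_mA),
    pixel_pitch_um = pixel_pitch_um,
    bit_depth = bit_depth,
    registered = isTRUE(registered)
  ), class = "multifocus_stack")
}

#' Number of slices in a stack
#' @param stack A [multifocus_stack()].
#' @return Integer slice count N.
#' @export
n_slices <- function(stack) length(stack$slices)

#' @export
print.multifocus_stack <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<multifocus_stack> N = %d slices, %d x %d px%s\n",
              n_slices(x), d[1], d[2],
              if (length(d) == 3) sprintf(" x %d channels", d[3]) else ""))
  cat(sprintf("  currents: %g to %g mA; pixel pitch %g um; %s; %s\n",
              max(x$currents_mA), min(x$currents_mA), x$pixel_pitch_um,
              if (is.na(x$bit_depth)) "float" else paste0(x$bit_depth, "-bit"),
              if (x$registered) "registered" else "unregistered"))
  invisible(x)
}

#' Total radiant energy of an image
#'
#' Sum of all pixel intensities (channels included for RGB). Because the
#' illumination path is unaffected by the EFTL, this quantity is conserved
#' across the slices of a stack, which is the basis of registration.
#'
#' @param image Numeric matrix or H x W x 3 array.
#' @return Scalar energy.
#' @examples
#' total_energy(matrix(1, 2, 2))  # 4
#' @export
total_energy <- function(image) {
  if (length(image) == 0) stop_arg("empty image")
  sum(image)
}

# dtype maximum used for unit-scale metrics and export clipping.
dtype_max <- function(stack_or_depth) {
  bd <- if (inherits(stack_or_depth, "multifocus_stack"))
    stack_or_depth$bit_depth else stack_or_depth
  if (is.na(bd)) 1 else 2^bd - 1
}
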