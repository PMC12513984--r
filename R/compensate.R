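#' Compensation parameters
#'
#' Settings for shadow-artifact compensation of the flow image by the
#' inverted, Gaussian-blurred structural image. The blur scale is given in
#' physical units so that the same setting means the same thing on both
#' device grids; the default 15 um (about 2 px at 7.5 um/px, about 5 px at
#' 2.9 um/px) smooths over single capillaries while staying well below the
#' size of a druse.
#'
#' @param blur_sigma_um Gaussian sigma in um (>= 0; 0 disables smoothing).
#' @param output_rescale if `TRUE` (default) the compensated image is
#'   affinely mapped to span `[0, 1]` before thresholding, mirroring the
#'   display-range stretch applied by interactive pipelines.
#' @return an object of class `CompensationParams`.
#' @export
compensation_params <- function(blur_sigma_um = 15, output_rescale = TRUE) {
  stopifnot(blur_sigma_um >= 0, is.logical(output_rescale))
  structure(list(blur_sigma_um = blur_sigma_um, output_rescale = output_rescale),
            class = "CompensationParams")
}

#' Invert a normalized image
#'
#' The "invert" step of the compensation recipe: returns `1 - img`
#' element-wise. Input must already be normalized to `[0, 1]`; normalization
#' is the caller's job (images loaded from 16-bit TIFF are divided by the
#' dtype maximum, never stretched per-image).
#'
#' @param img numeric matrix with values in `[0, 1]`.
#' @return the inverted matrix.
#' @export
invert_image <- function(img) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (!in_unit_range(img)) {
    stop("image values outside [0, 1]; normalize before inverting")
  }
  1 - img
}

#' Compensate a flow image for signal attenuation
#'
#' Multiplies the flow image by the inverted, Gaussian-blurred structural
#' image: regions shadowed in the structural channel (e.g., under drusen) are
#' boosted in the flow channel, reducing attenuation-induced false flow
#' deficits. With `output_rescale` the product is affinely mapped to span
#' `[0, 1]`; a constant product maps to zero.
#'
#' @param flow flow image matrix in `[0, 1]`.
#' @param structural registered structural image matrix in `[0, 1]`, same
#'   shape as `flow`.
#' @param params a [compensation_params()] object.
#' @param pixel_size_um physical pixel pitch, used to convert the blur sigma
#'   to pixels.
#' @return compensated flow matrix, same shape.
#' @examples
#' flow <- matrix(runif(64), 8, 8)
#' structural <- matrix(0.8, 8, 8)
#' comp <- compensate(flow, structural, compensation_params(), pixel_size_um = 7.5)
#' @export
compensate <- function(flow, structural, params = compensation_params(),
                       pixel_size_um) {
  stopifnot(inherits(params, "CompensationParams"), pixel_size_um > 0)
  if (!all(dim(flow) == dim(structural))) {
    stop("flow and structural images must have the same shape")
  }
  if (!in_unit_range(flow) || !in_unit_range(structural)) {
    stop("image values outside [0, 1]; normalize before compensating")
  }
  w <- invert_image(structural)
  sigma_px <- params$blur_sigma_um / pixel_size_um
  if (sigma_px > 0) w <- gaussian_blur(w, sigma_px)
  out <- flow * w
  if (params$output_rescale) {
    rng <- range(out)
    if (rng[2] > rng[1]) {
      out <- (out - rng[1]) / (rng[2] - rng[1])
    } else {
      out <- matrix(0, nrow(out), ncol(out))
    }
  }
  out
}
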