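# Low-level image helpers shared by the compensation and thresholding steps.
# All neighborhood operations use reflect padding (edge pixel mirrored:
# c b a | a b c ... z y x), the convention fixed throughout the package.

reflect_index <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  if (r >= n) stop("padding radius (", r, ") must be smaller than the image dimension (", n, ")")
  c(r:1, seq_len(n), n:(n - r + 1L))
}

pad_reflect <- function(img, r) {
  img[reflect_index(nrow(img), r), reflect_index(ncol(img), r), drop = FALSE]
}

#' Offsets of a circular (disc) neighborhood
#'
#' Integer offsets `(dx, dy)` with `dx^2 + dy^2 <= radius^2`, the Fiji-style
#' circular window used by local thresholding.
#'
#' @param radius window radius in pixels (>= 1).
#' @return two-column integer matrix of offsets, one row per pixel in the disc.
#' @keywords internal
disc_offsets <- function(radius) {
  stopifnot(radius >= 1)
  d <- seq.int(-radius, radius)
  g <- expand.grid(dx = d, dy = d)
  as.matrix(g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE])
}

# Local mean and (population) SD over the disc neighborhood of each pixel,
# computed by accumulating reflect-padded shifted copies of the image.
local_disc_stats <- function(img, radius) {
  n <- nrow(img); m <- ncol(img)
  if (radius >= min(n, m)) {
    stop("window radius (", radius, ") must be smaller than the smallest image dimension (",
         min(n, m), ")")
  }
  off <- disc_offsets(radius)
  pad <- pad_reflect(img, radius)
  s1 <- matrix(0, n, m)
  s2 <- matrix(0, n, m)
  ri <- seq_len(n) + radius
  ci <- seq_len(m) + radius
  for (i in seq_len(nrow(off))) {
    sh <- pad[ri + off[i, 1L], ci + off[i, 2L]]
    s1 <- s1 + sh
    s2 <- s2 + sh * sh
  }
  k <- nrow(off)
  mu <- s1 / k
  list(mean = mu, sd = sqrt(pmax(s2 / k - mu * mu, 0)), n = k)
}

#' Gaussian blur with reflect padding
#'
#' Separable Gaussian smoothing. The kernel is truncated at 3 sigma and
#' renormalized; borders are handled by reflect padding.
#'
#' @param img numeric matrix.
#' @param sigma_px Gaussian standard deviation in pixels; 0 returns the input.
#' @return blurred matrix, same dimensions.
#' @export
gaussian_blur <- function(img, sigma_px) {
  stopifnot(is.matrix(img), is.numeric(img), sigma_px >= 0)
  if (sigma_px == 0) return(img)
  h <- max(1L, as.integer(ceiling(3 * sigma_px)))
  h <- min(h, min(dim(img)) - 1L)  # padding cannot exceed the image
  kern <- stats::dnorm(seq.int(-h, h), sd = sigma_px)
  kern <- kern / sum(kern)
  n <- nrow(img); m <- ncol(img)
  pad <- pad_reflect(img, h)
  # rows (first dimension)
  tmp <- matrix(0, n, m + 2L * h)
  for (o in seq.int(-h, h)) tmp <- tmp + kern[o + h + 1L] * pad[seq_len(n) + h + o, , drop = FALSE]
  out <- matrix(0, n, m)
  for (o in seq.int(-h, h)) out <- out + kern[o + h + 1L] * tmp[, seq_len(m) + h + o, drop = FALSE]
  out
}

# Resampling onto a square device grid. Refuses to upsample: the reference
# (truth) grid must be at least as fine as the target. Default "sample"
# emulates OCTA acquisition -- each device pixel is one A-scan at a lateral
# beam position, i.e., the reference field point-sampled at the pixel center
# -- and keeps vessel/void edges sharp. "bilinear" (EBImage) interpolates,
# which smears edges and biases flow-deficit fractions upward.
resample_to_grid <- function(img, out_px, method = c("sample", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is.matrix(img), out_px >= 1)
  if (out_px > nrow(img) || out_px > ncol(img)) {
    stop("device grid (", out_px, " px) is finer than the reference grid (",
         nrow(img), " px); refusing to upsample ground truth")
  }
  if (out_px == nrow(img) && out_px == ncol(img)) return(img)
  if (method == "bilinear") {
    out <- EBImage::resize(img, w = out_px, h = out_px, filter = "bilinear")
    return(matrix(as.numeric(out), out_px, out_px))
  }
  # pixel centers of the device grid mapped to nearest reference pixel
  ix <- pmin(nrow(img), pmax(1L, as.integer(round((seq_len(out_px) - 0.5) * nrow(img) / out_px + 0.5))))
  iy <- pmin(ncol(img), pmax(1L, as.integer(round((seq_len(out_px) - 0.5) * ncol(img) / out_px + 0.5))))
  img[ix, iy, drop = FALSE]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

in_unit_range <- function(img, tol = 1e-9) {
  rng <- range(img)
  rng[1] >= -tol && rng[2] <= 1 + tol
}
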