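#' OCTA device profiles
#'
#' Scan geometry and sampling of the three acquisition modes compared by the
#' pipeline: a swept-source instrument (`"ss"`, 1050 nm class, 1024 x 1024 px
#' over 3 x 3 mm) and a spectral-domain instrument (840 nm class, 400 x 400 px
#' over 3 x 3 mm) in non-averaged (`"sd_v1"`) and four-volume averaged
#' (`"sd_v4"`) modes. Volume averaging is modeled purely as noise reduction:
#' the rendered noise is the mean of `n_averaged_volumes` independent draws,
#' so the four-volume mode has half the single-volume noise SD.
#'
#' @param name device label, one of `"ss"`, `"sd_v1"`, `"sd_v4"`
#'   (case-insensitive; `"SS"`, `"SD_V1"`, `"SD_V4"` also accepted).
#' @param scan_extent_mm physical width/height of the square scan in mm.
#' @param grid_px pixels per side of the en-face grid.
#' @param noise_sd additive noise SD of a single acquired volume, in
#'   normalized intensity units.
#' @param n_averaged_volumes number of volumes averaged (1 or 4 here).
#' @return an object of class `DeviceProfile`.
#' @examples
#' dev <- device_profile("sd_v1")
#' pixel_size_um(dev)  # 7.5 um on the 3 mm / 400 px grid
#' @export
device_profile <- function(name = c("ss", "sd_v1", "sd_v4"),
                           scan_extent_mm = NULL, grid_px = NULL,
                           noise_sd = NULL, n_averaged_volumes = NULL) {
  key <- tolower(as.character(name)[1L])
  defaults <- list(
    ss    = list(name = "SS",    scan_extent_mm = 3, grid_px = 1024L, noise_sd = 0.05, n_averaged_volumes = 1L),
    sd_v1 = list(name = "SD_V1", scan_extent_mm = 3, grid_px = 400L,  noise_sd = 0.08, n_averaged_volumes = 1L),
    sd_v4 = list(name = "SD_V4", scan_extent_mm = 3, grid_px = 400L,  noise_sd = 0.08, n_averaged_volumes = 4L)
  )
  if (!key %in% names(defaults)) {
    stop("unknown device label '", name[1L], "'; expected one of ss, sd_v1, sd_v4")
  }
  prof <- defaults[[key]]
  if (!is.null(scan_extent_mm)) prof$scan_extent_mm <- scan_extent_mm
  if (!is.null(grid_px)) prof$grid_px <- as.integer(grid_px)
  if (!is.null(noise_sd)) prof$noise_sd <- noise_sd
  if (!is.null(n_averaged_volumes)) prof$n_averaged_volumes <- as.integer(n_averaged_volumes)
  stopifnot(prof$grid_px > 0, prof$scan_extent_mm > 0,
            prof$noise_sd >= 0, prof$n_averaged_volumes >= 1)
  ps <- 1000 * prof$scan_extent_mm / prof$grid_px
  stopifnot(is.finite(ps), ps > 0)
  structure(prof, class = "DeviceProfile")
}

#' Physical pixel pitch of a device grid
#'
#' @param device a `DeviceProfile`.
#' @return pixel size in micrometers.
#' @export
pixel_size_um <- function(device) {
  stopifnot(inherits(device, "DeviceProfile"))
  1000 * device$scan_extent_mm / device$grid_px
}

#' @export
print.DeviceProfile <- function(x, ...) {
  cat(sprintf("OCTA device profile: %s\n  %g x %g mm, %d x %d px (%.3g um/px)\n",
              x$name, x$scan_extent_mm, x$scan_extent_mm, x$grid_px, x$grid_px,
              pixel_size_um(x)))
  cat(sprintf("  noise SD %.3g, %d averaged volume(s)\n", x$noise_sd, x$n_averaged_volumes))
  invisible(x)
}
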