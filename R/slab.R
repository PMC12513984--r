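#' Choriocapillaris slab specification
#'
#' An axial window below Bruch's membrane (BM): offsets of the inner
#' (shallower) and outer boundary, both in um, measured along the axial axis,
#' positive downward, boundaries inclusive.
#'
#' @param name slab label.
#' @param z_inner_um inner boundary offset below BM (>= 0).
#' @param z_outer_um outer boundary offset below BM (> `z_inner_um`).
#' @return an object of class `SlabSpec`.
#' @export
slab_spec <- function(name, z_inner_um, z_outer_um) {
  stopifnot(is.character(name), length(name) == 1,
            z_inner_um >= 0, z_outer_um > z_inner_um)
  structure(list(name = name, z_inner_um = z_inner_um, z_outer_um = z_outer_um),
            class = "SlabSpec")
}

#' @export
print.SlabSpec <- function(x, ...) {
  cat(sprintf("CC slab '%s': %g-%g um below BM\n", x$name, x$z_inner_um, x$z_outer_um))
  invisible(x)
}

#' The five standard choriocapillaris slabs for a device
#'
#' Returns the five CC slabs compared by the pipeline: the device's automatic
#' slab plus the fixed windows 11-21, 21-31, 31-41 and 16-31 um below BM. The
#' automatic slab is device-specific: 0-20 um below BM on the swept-source
#' instrument, 9-31 um below BM on the spectral-domain instrument (both
#' acquisition modes).
#'
#' @param device a `DeviceProfile` or a device label accepted by
#'   [device_profile()].
#' @return named list of five `SlabSpec` objects
#'   (`auto`, `11-21`, `21-31`, `31-41`, `16-31`).
#' @examples
#' names(slab_catalog("ss"))
#' slab_catalog("ss")$auto
#' @export
slab_catalog <- function(device) {
  if (!inherits(device, "DeviceProfile")) device <- device_profile(device)
  auto <- switch(device$name,
                 SS = slab_spec("auto", 0, 20),
                 SD_V1 = ,
                 SD_V4 = slab_spec("auto", 9, 31),
                 stop("unknown device label '", device$name, "'"))
  list(
    "auto"  = auto,
    "11-21" = slab_spec("11-21", 11, 21),
    "21-31" = slab_spec("21-31", 21, 31),
    "31-41" = slab_spec("31-41", 31, 41),
    "16-31" = slab_spec("16-31", 16, 31)
  )
}

#' Extract an en-face image from a volume over a CC slab
#'
#' For each lateral pixel the volume is sampled at uniformly spaced depths
#' spanning `[bm + z_inner, bm + z_outer]` (inclusive bounds, spacing at most
#' the axial step) with linear interpolation between voxel planes, and the
#' samples are combined by the projection statistic (mean by default; max
#' available).
#'
#' @param volume an `OctaVolume` from [generate_volume()] or a compatible
#'   list with `vol`, `axial_step_um`, `bm_depth_map`.
#' @param slab a `SlabSpec`.
#' @param projection `"mean"` (default) or `"max"`.
#' @return numeric matrix, the en-face projection.
#' @export
extract_enface <- function(volume, slab, projection = c("mean", "max")) {
  projection <- match.arg(projection)
  stopifnot(inherits(slab, "SlabSpec"))
  vol <- volume$vol
  step <- volume$axial_step_um
  bm <- volume$bm_depth_map
  nx <- dim(vol)[1]; ny <- dim(vol)[2]; nz <- dim(vol)[3]
  stopifnot(all(dim(bm) == c(nx, ny)))
  max_depth <- (nz - 1) * step

  lo <- bm + slab$z_inner_um
  hi <- bm + slab$z_outer_um
  bad <- sum(hi > max_depth + 1e-9 | lo < -1e-9)
  if (bad > 0) {
    stop("slab window exits the volume at ", bad, " lateral pixel(s)")
  }

  thickness <- slab$z_outer_um - slab$z_inner_um
  m <- as.integer(ceiling(thickness / step)) + 1L   # spacing <= step, endpoints included
  offsets <- seq(0, thickness, length.out = m)

  npx <- nx * ny
  base_idx <- seq_len(npx)
  acc <- NULL
  for (s in offsets) {
    d <- as.vector(lo) + s                # absolute depth per lateral pixel
    kf <- d / step                        # fractional plane index (0-based)
    k0 <- pmin(floor(kf), nz - 2)         # keep k0+1 in range at the top plane
    frac <- kf - k0
    v0 <- vol[base_idx + k0 * npx]
    v1 <- vol[base_idx + (k0 + 1) * npx]
    val <- (1 - frac) * v0 + frac * v1
    if (is.null(acc)) {
      acc <- if (projection == "mean") val else val
    } else {
      acc <- if (projection == "mean") acc + val else pmax(acc, val)
    }
  }
  if (projection == "mean") acc <- acc / m
  matrix(acc, nx, ny)
}
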