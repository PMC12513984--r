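#' Parameters of the synthetic choriocapillaris mesh
#'
#' The generator emulates the macular choriocapillaris as a quasi-periodic
#' capillary mesh: vessel diameters average 16-20 um with edge-to-edge gaps of
#' 5-20 um, so the intercapillary distance (ICD, one vessel width plus one
#' physiological void) falls in the 21-40 um range. The mesh is synthesized as
#' band-pass-filtered seeded noise whose dominant spatial period lies in the
#' ICD band, thresholded to the vessel/gap duty cycle, after which additional
#' disc-shaped flow voids are carved until the true flow-deficit fraction is
#' within +/- 0.01 of `target_fd_fraction`.
#'
#' When `duty_cycle` is `NULL` (default) the thresholding quantile adapts so
#' that the intrinsic (mesh) void fraction never exceeds the target: any
#' target in `[0, 1]` is then reachable. Supplying a fixed `duty_cycle` pins
#' the intrinsic void fraction at `1 - duty_cycle`; targets below that floor
#' are then unreachable and reported as an error.
#'
#' @param vessel_diameter_um capillary diameter range in um.
#' @param edge_gap_um edge-to-edge inter-vessel gap range in um.
#' @param target_fd_fraction desired true flow-deficit fraction in `[0, 1]`.
#' @param planted_void_radius_um radius of the carved pathological flow voids.
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param duty_cycle optional fixed vessel area fraction; `NULL` adapts.
#' @return an object of class `VesselNetworkParams`.
#' @export
vessel_params <- function(vessel_diameter_um = c(16, 20),
                          edge_gap_um = c(5, 20),
                          target_fd_fraction = 0.45,
                          planted_void_radius_um = 50,
                          seed = 1L,
                          duty_cycle = NULL) {
  stopifnot(length(vessel_diameter_um) == 2, all(vessel_diameter_um > 0),
            length(edge_gap_um) == 2, all(edge_gap_um > 0),
            target_fd_fraction >= 0, target_fd_fraction <= 1,
            planted_void_radius_um > 0)
  if (!is.null(duty_cycle)) stopifnot(duty_cycle > 0, duty_cycle < 1)
  icd_um <- c(min(vessel_diameter_um) + min(edge_gap_um),
              max(vessel_diameter_um) + max(edge_gap_um))
  structure(list(
    vessel_diameter_um = sort(vessel_diameter_um),
    edge_gap_um = sort(edge_gap_um),
    icd_um = icd_um,
    target_fd_fraction = target_fd_fraction,
    planted_void_radius_um = planted_void_radius_um,
    duty_cycle = duty_cycle,
    seed = as.integer(seed)
  ), class = "VesselNetworkParams")
}

#' Generate a ground-truth choriocapillaris flow field
#'
#' Produces a continuous flow field on a fine reference grid together with the
#' exact flow-deficit mask (the zero-flow set) and its pixel fraction. The
#' default reference grid, 1024 px over 3 mm (~2.93 um/px), matches the
#' swept-source en-face grid so that rendering to that device needs no
#' resampling.
#'
#' @param params a [vessel_params()] object.
#' @param fine_grid_px reference grid side in pixels.
#' @param extent_mm physical side length in mm.
#' @return an object of class `GroundTruth` with elements `flow_field`
#'   (matrix in `[0, 1]`), `fd_mask_true` (logical matrix, `TRUE` = no flow),
#'   `fd_fraction_true`, `pixel_size_um`, `extent_mm` and `params`.
#' @examples
#' gt <- generate_cc_pattern(vessel_params(target_fd_fraction = 0.4, seed = 7),
#'                           fine_grid_px = 256)
#' gt$fd_fraction_true
#' @export
generate_cc_pattern <- function(params, fine_grid_px = 1024L, extent_mm = 3) {
  stopifnot(inherits(params, "VesselNetworkParams"), fine_grid_px >= 16, extent_mm > 0)
  px_um <- 1000 * extent_mm / fine_grid_px
  if (px_um > 4 + 1e-9) {
    warning("reference pixel (", signif(px_um, 3),
            " um) is coarser than 4 um; minimum vessels are under-resolved")
  }
  n <- as.integer(fine_grid_px)
  target <- params$target_fd_fraction

  if (target >= 1) {
    flow <- matrix(0, n, n)
    return(new_ground_truth(flow, px_um, extent_mm, params))
  }

  set.seed(params$seed)
  noise <- matrix(stats::rnorm(n * n), n, n)

  # Band-pass in the ICD frequency band: dominant period at the mid-ICD.
  f_axis <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * px_um)  # cycles/um
  fr <- sqrt(outer(f_axis^2, f_axis^2, `+`))
  f_lo <- 1 / params$icd_um[2]
  f_hi <- 1 / params$icd_um[1]
  f0 <- (f_lo + f_hi) / 2
  sig_f <- (f_hi - f_lo) / 4
  H <- exp(-((fr - f0)^2) / (2 * sig_f^2))
  field <- Re(stats::fft(stats::fft(noise) * H, inverse = TRUE)) / (n * n)
  field <- (field - mean(field)) / stats::sd(field)

  # Vessel/gap duty cycle from the mean geometry; intrinsic void = 1 - duty.
  d_mean <- mean(params$vessel_diameter_um)
  g_mean <- mean(params$edge_gap_um)
  duty_geom <- d_mean / (d_mean + g_mean)
  if (is.null(params$duty_cycle)) {
    void0 <- min(1 - duty_geom, target)
  } else {
    void0 <- 1 - params$duty_cycle
    if (target < void0 - 1e-9) {
      stop(sprintf(paste0("target_fd_fraction (%.3f) is below the mesh's intrinsic void ",
                          "fraction (%.3f) at the fixed duty cycle; achievable floor is %.3f"),
                   target, void0, void0))
    }
  }

  # Threshold at the exact order statistic so the initial void count is exact.
  k0 <- round(void0 * n * n)
  if (k0 > 0) {
    thr <- sort(field, partial = k0)[k0]
    vessel <- field > thr
  } else {
    thr <- min(field) - 1
    vessel <- matrix(TRUE, n, n)
  }

  # Flow intensity on vessels: affine map of the mesh field into [0.55, 1],
  # leaving voids exactly zero so fd_mask_true is the zero-flow set.
  flow <- matrix(0, n, n)
  if (any(vessel)) {
    v <- (field[vessel] - thr) / (max(field) - thr)
    flow[vessel] <- 0.55 + 0.45 * v
  }

  # Carve disc-shaped pathological voids until within +/- 0.01 of target.
  tol <- 0.005
  r_px <- params$planted_void_radius_um / px_um
  frac <- mean(flow == 0)
  guard <- 0L
  while (frac < target - tol && guard < 50000L) {
    cx <- stats::runif(1, 1, n)
    cy <- stats::runif(1, 1, n)
    x0 <- max(1L, floor(cx - r_px)); x1 <- min(n, ceiling(cx + r_px))
    y0 <- max(1L, floor(cy - r_px)); y1 <- min(n, ceiling(cy + r_px))
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
    sub <- flow[xs, ys, drop = FALSE]
    sub[d2 <= r_px^2] <- 0
    flow[xs, ys] <- sub
    frac <- mean(flow == 0)
    guard <- guard + 1L
  }
  if (frac < target - tol) {
    stop(sprintf("could not reach target_fd_fraction %.3f (achieved %.3f)", target, frac))
  }
  new_ground_truth(flow, px_um, extent_mm, params)
}

new_ground_truth <- function(flow, px_um, extent_mm, params) {
  mask <- flow == 0
  structure(list(
    flow_field = flow,
    fd_mask_true = mask,
    fd_fraction_true = mean(mask),
    pixel_size_um = px_um,
    extent_mm = extent_mm,
    params = params
  ), class = "GroundTruth")
}

#' @export
print.GroundTruth <- function(x, ...) {
  cat(sprintf("Synthetic CC ground truth: %d x %d px (%.3g um/px), FD fraction %.4f\n",
              nrow(x$flow_field), ncol(x$flow_field), x$pixel_size_um, x$fd_fraction_true))
  invisible(x)
}

#' Drusen-like attenuation field
#'
#' Multiplicative shadow field in `(0, 1]` on the reference grid. Each druse
#' is a disc with a flat core at `min_attenuation` and a cosine-tapered rim
#' (outer `rim_fraction` of the radius) rising smoothly back to 1; the factor
#' is exactly 1 outside all drusen footprints. Large soft drusen strongly
#' attenuate the OCTA signal beneath them, hence the deep default core. The
#' same field multiplies the structural and the flow channel at render time
#' -- the premise that makes inverted-structural compensation meaningful.
#'
#' @param grid_px side of the reference grid in pixels.
#' @param extent_mm physical side length in mm.
#' @param n_drusen number of drusen discs (0 gives a unit field).
#' @param drusen_radius_um druse radius in um.
#' @param min_attenuation attenuation factor in the druse core, in `(0, 1]`.
#' @param rim_fraction fraction of the radius over which the cosine edge
#'   taper runs, in `(0, 1]`.
#' @param seed integer seed for druse placement.
#' @return an object of class `ShadowField` with the `attenuation_map` matrix.
#' @export
shadow_field <- function(grid_px, extent_mm = 3, n_drusen = 5,
                         drusen_radius_um = 125, min_attenuation = 0.15,
                         rim_fraction = 0.3, seed = 1L) {
  stopifnot(grid_px >= 8, n_drusen >= 0, drusen_radius_um > 0,
            min_attenuation > 0, min_attenuation <= 1,
            rim_fraction > 0, rim_fraction <= 1)
  n <- as.integer(grid_px)
  px_um <- 1000 * extent_mm / n
  map <- matrix(1, n, n)
  if (n_drusen > 0) {
    set.seed(as.integer(seed))
    r_px <- drusen_radius_um / px_um
    core <- 1 - rim_fraction
    for (i in seq_len(n_drusen)) {
      cx <- stats::runif(1, 1, n)
      cy <- stats::runif(1, 1, n)
      x0 <- max(1L, floor(cx - r_px)); x1 <- min(n, ceiling(cx + r_px))
      y0 <- max(1L, floor(cy - r_px)); y1 <- min(n, ceiling(cy + r_px))
      xs <- x0:x1; ys <- y0:y1
      d <- sqrt(outer((xs - cx)^2, (ys - cy)^2, `+`)) / r_px
      # taper = 1 in the core, cosine ramp to 0 across the rim, 0 outside
      taper <- ifelse(d <= core, 1,
                      ifelse(d <= 1, 0.5 * (1 + cos(pi * (d - core) / rim_fraction)), 0))
      factor <- 1 - (1 - min_attenuation) * taper
      map[xs, ys] <- map[xs, ys] * factor
    }
  }
  structure(list(attenuation_map = map, n_drusen = n_drusen,
                 drusen_radius_um = drusen_radius_um,
                 min_attenuation = min_attenuation,
                 pixel_size_um = px_um, extent_mm = extent_mm,
                 seed = as.integer(seed)),
            class = "ShadowField")
}

#' Render a device en-face image pair from ground truth
#'
#' Applies the shadow field to both channels, resamples to the device grid
#' (bilinear; upsampling of the truth is refused), adds the mean of
#' `n_averaged_volumes` independent Gaussian noise draws per channel, and
#' clips to `[0, 1]`. The structural channel starts from a constant baseline
#' tissue reflectance of 0.8 before attenuation. Channel alignment is exact.
#'
#' @param truth a `GroundTruth`.
#' @param shadow a `ShadowField` on the same grid, or `NULL` for no shadowing.
#' @param device a `DeviceProfile`.
#' @param seed integer seed for the noise draws.
#' @return an object of class `EnFacePair` with `flow` and `structural`
#'   matrices in `[0, 1]`, plus device metadata.
#' @export
render_device_image <- function(truth, shadow = NULL, device, seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"), inherits(device, "DeviceProfile"))
  n_ref <- nrow(truth$flow_field)
  if (is.null(shadow)) {
    att <- matrix(1, n_ref, n_ref)
  } else {
    stopifnot(inherits(shadow, "ShadowField"))
    if (!all(dim(shadow$attenuation_map) == dim(truth$flow_field))) {
      stop("shadow field and ground truth must share the reference grid")
    }
    att <- shadow$attenuation_map
  }
  structural_baseline <- 0.8
  flow_ref <- truth$flow_field * att
  struct_ref <- structural_baseline * att

  gp <- device$grid_px
  flow_dev <- resample_to_grid(flow_ref, gp)
  struct_dev <- resample_to_grid(struct_ref, gp)

  set.seed(as.integer(seed))
  nv <- device$n_averaged_volumes
  add_noise <- function(img) {
    if (device$noise_sd == 0) return(img)
    acc <- matrix(0, gp, gp)
    for (i in seq_len(nv)) acc <- acc + matrix(stats::rnorm(gp * gp, sd = device$noise_sd), gp, gp)
    img + acc / nv
  }
  flow_img <- clip01(add_noise(flow_dev))
  struct_img <- clip01(add_noise(struct_dev))

  structure(list(flow = flow_img, structural = struct_img,
                 device = device, pixel_size_um = pixel_size_um(device),
                 seed = as.integer(seed)),
            class = "EnFacePair")
}

#' @export
print.EnFacePair <- function(x, ...) {
  cat(sprintf("En-face OCTA pair (%s): %d x %d px, %.3g um/px\n",
              x$device$name, nrow(x$flow), ncol(x$flow), x$pixel_size_um))
  invisible(x)
}

#' Build a synthetic 3-D OCTA volume below a Bruch's-membrane surface
#'
#' For every lateral position, voxels at depth `d` below the local BM carry
#' the truth flow intensity weighted by `depth_profile(d)`; voxels above the
#' BM carry no choriocapillaris signal. Supports testing slab extraction
#' against tilted or irregular BM surfaces.
#'
#' @param truth a `GroundTruth` (sets the lateral grid).
#' @param bm_depth_map matrix of BM depths in um, same lateral shape as the
#'   truth grid.
#' @param axial_step_um axial sampling step in um (must be <= 2 so that 10-um
#'   slabs contain at least 5 samples).
#' @param depth_profile function of depth-below-BM (um) returning an axial
#'   intensity weight; default: constant 1 on `[0, 41]` um.
#' @param max_depth_um deepest voxel plane to generate, measured from zero.
#' @return an object of class `OctaVolume`: `vol` (x, y, z array),
#'   `axial_step_um`, `bm_depth_map`.
#' @export
generate_volume <- function(truth, bm_depth_map, axial_step_um = 2,
                            depth_profile = function(d) as.numeric(d <= 41),
                            max_depth_um = NULL) {
  stopifnot(inherits(truth, "GroundTruth"), axial_step_um > 0)
  if (axial_step_um > 2 + 1e-12) {
    stop("axial_step_um must be <= 2 um so that 10-um slabs contain >= 5 samples")
  }
  flow <- truth$flow_field
  if (!all(dim(bm_depth_map) == dim(flow))) {
    stop("bm_depth_map shape ", paste(dim(bm_depth_map), collapse = "x"),
         " does not match the truth grid ", paste(dim(flow), collapse = "x"))
  }
  if (is.null(max_depth_um)) max_depth_um <- max(bm_depth_map) + 50
  nz <- as.integer(floor(max_depth_um / axial_step_um)) + 1L
  nx <- nrow(flow); ny <- ncol(flow)
  vol <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    z <- (k - 1L) * axial_step_um
    d <- z - bm_depth_map          # depth below local BM
    w <- ifelse(d >= 0, depth_profile(d), 0)
    vol[, , k] <- flow * w
  }
  structure(list(vol = vol, axial_step_um = axial_step_um,
                 bm_depth_map = bm_depth_map),
            class = "OctaVolume")
}
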