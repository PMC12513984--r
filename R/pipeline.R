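#' Default pipeline configuration
#'
#' A complete run configuration for the simulate -> compensate -> binarize ->
#' quantify -> compare pipeline. Defaults encode the standard processing
#' settings: 3 x 3 mm scans, the three device profiles, the five CC slabs,
#' Phansalkar radius 4 px, 8-connectivity, no particle-size filter. The
#' synthetic cohort draws a per-eye base flow-deficit fraction uniformly in
#' `[0.35, 0.55]`; each eye shares one capillary mesh across slabs
#' (slab-specific carving depth = base + `slab_shift`, zero by default), so
#' slab measurements are correlated within an eye.
#'
#' @param n_eyes number of synthetic eyes.
#' @param devices device labels to include.
#' @param seed master seed; all per-eye/device seeds derive from it.
#' @param fine_grid_px reference grid for the ground truth.
#' @param n_drusen drusen per eye (0 disables shadowing).
#' @param slab_shift named numeric vector of per-slab FD-fraction offsets.
#' @return a `RunConfig` list.
#' @export
default_run_config <- function(n_eyes = 5L,
                               devices = c("ss", "sd_v1", "sd_v4"),
                               seed = 1L,
                               fine_grid_px = 1024L,
                               n_drusen = 4L,
                               slab_shift = NULL) {
  slabs <- names(slab_catalog("ss"))
  if (is.null(slab_shift)) slab_shift <- stats::setNames(rep(0, length(slabs)), slabs)
  structure(list(
    n_eyes = as.integer(n_eyes),
    devices = devices,
    slabs = slabs,
    slab_shift = slab_shift,
    seed = as.integer(seed),
    fine_grid_px = as.integer(fine_grid_px),
    extent_mm = 3,
    base_fd_range = c(0.35, 0.55),
    n_drusen = as.integer(n_drusen),
    drusen_radius_um = 125,
    min_attenuation = 0.4,
    compensation = list(blur_sigma_um = 15, output_rescale = TRUE),
    phansalkar = list(radius_px = 4L, k = 0.25, r = 0.5, p = 2, q = 10),
    quantify = list(min_size_um2 = 0, connectivity = 8)
  ), class = "RunConfig")
}

#' Validate a run configuration
#'
#' Checks device and slab names against the catalogs and basic ranges;
#' errors name the offending entry.
#'
#' @param config a `RunConfig` (or plain list with the same fields).
#' @return the validated config, invisibly.
#' @export
validate_run_config <- function(config) {
  known_devices <- c("ss", "sd_v1", "sd_v4")
  for (d in config$devices) {
    if (!tolower(d) %in% known_devices) {
      stop("unknown device '", d, "' in config; expected one of ",
           paste(known_devices, collapse = ", "))
    }
  }
  known_slabs <- names(slab_catalog("ss"))
  for (s in config$slabs) {
    if (!s %in% known_slabs) {
      stop("unknown slab '", s, "' in config; expected one of ",
           paste(known_slabs, collapse = ", "))
    }
  }
  stopifnot(config$n_eyes >= 1, config$fine_grid_px >= 64,
            all(config$base_fd_range >= 0), all(config$base_fd_range <= 1))
  invisible(config)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `RunConfig`.
#' @return `read_run_config` returns a validated `RunConfig`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  cfg$slab_shift <- unlist(cfg$slab_shift)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Deterministic per-cell seed, kept well below 2^31.
cell_seed <- function(master, eye, dev_i = 0L, slab_i = 0L) {
  (as.integer(master) * 7919L + eye * 1009L + dev_i * 101L + slab_i * 13L) %% 2000000011L
}

#' Simulate one eye: per-slab ground truths and a shadow field
#'
#' One capillary mesh per eye (fixed by the eye seed) is carved to a
#' slab-specific flow-deficit fraction, so slabs of the same eye are highly
#' correlated, as in real eyes.
#'
#' @param config a `RunConfig`.
#' @param eye eye index (1-based).
#' @return list with `truths` (named by slab), `shadow` (or NULL), and
#'   `base_fd`.
#' @export
simulate_eye <- function(config, eye) {
  es <- cell_seed(config$seed, eye)
  set.seed(es)
  base_fd <- stats::runif(1, config$base_fd_range[1], config$base_fd_range[2])
  truths <- list()
  for (s in config$slabs) {
    target <- min(max(base_fd + config$slab_shift[[s]], 0.02), 0.98)
    vp <- vessel_params(target_fd_fraction = target, seed = es)
    truths[[s]] <- generate_cc_pattern(vp, fine_grid_px = config$fine_grid_px,
                                       extent_mm = config$extent_mm)
  }
  shadow <- NULL
  if (config$n_drusen > 0) {
    shadow <- shadow_field(config$fine_grid_px, config$extent_mm,
                           n_drusen = config$n_drusen,
                           drusen_radius_um = config$drusen_radius_um,
                           min_attenuation = config$min_attenuation,
                           seed = cell_seed(config$seed, eye, 99L))
  }
  list(truths = truths, shadow = shadow, base_fd = base_fd)
}

#' Simulate a cohort of en-face pairs to disk
#'
#' Writes, for every eye x device x slab cell, the flow/structural TIFF pair
#' with JSON sidecar and the ground-truth FD mask, under
#' `dir/eye<e>/<device>/<slab>_*`.
#'
#' @param config a `RunConfig`.
#' @param dir output directory.
#' @return invisibly, a data.frame of written cells.
#' @export
simulate_cohort <- function(config, dir) {
  validate_run_config(config)
  written <- NULL
  for (eye in seq_len(config$n_eyes)) {
    sim <- simulate_eye(config, eye)
    for (di in seq_along(config$devices)) {
      dev <- device_profile(config$devices[di])
      for (si in seq_along(config$slabs)) {
        s <- config$slabs[si]
        pair <- render_device_image(sim$truths[[s]], sim$shadow, dev,
                                    seed = cell_seed(config$seed, eye, di, si))
        sub <- file.path(dir, sprintf("eye%02d", eye), tolower(dev$name))
        write_enface_pair(pair, sub, prefix = gsub("[^0-9a-z]", "_", s))
        truth_mask <- fd_mask(sim$truths[[s]]$fd_mask_true,
                              sim$truths[[s]]$pixel_size_um)
        write_mask_tiff(truth_mask,
                        file.path(sub, paste0(gsub("[^0-9a-z]", "_", s), "_truth.tif")))
        written <- rbind(written, data.frame(eye_id = eye, device = dev$name,
                                             slab = s, dir = sub,
                                             stringsAsFactors = FALSE))
      }
    }
  }
  invisible(written)
}

#' Quantify one en-face pair through the processing chain
#'
#' compensate -> Phansalkar binarize -> particle metrics, with the settings
#' of the given config.
#'
#' @param pair an `EnFacePair`.
#' @param config a `RunConfig` (for the processing parameters).
#' @return an `FDMetrics`.
#' @export
quantify_pair <- function(pair, config = default_run_config()) {
  cp <- do.call(compensation_params, config$compensation)
  pp <- do.call(phansalkar_params, config$phansalkar)
  comp <- compensate(pair$flow, pair$structural, cp, pair$pixel_size_um)
  msk <- phansalkar_threshold(comp, pp, pair$pixel_size_um,
                              provenance = list(device = pair$device$name))
  quantify_fd(msk, min_size_um2 = config$quantify$min_size_um2,
              connectivity = config$quantify$connectivity)
}

#' Run the full pipeline
#'
#' Simulates the synthetic cohort, processes every eye x device x slab cell
#' (compensation, Phansalkar thresholding, particle metrics), writes the
#' per-image metrics CSV, the device/slab comparison tables, the ICC table,
#' and a JSON run report with seeds and a parameter hash. Deterministic for
#' a fixed config.
#'
#' @param config a `RunConfig`.
#' @param out_dir run output directory (created).
#' @return invisibly, a list with `metrics` (data.frame), `tables` (from
#'   [build_comparison_tables()]), and the output paths.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- params_hash(unclass(config))
  rows <- NULL
  for (eye in seq_len(config$n_eyes)) {
    sim <- simulate_eye(config, eye)
    for (di in seq_along(config$devices)) {
      dev <- device_profile(config$devices[di])
      for (si in seq_along(config$slabs)) {
        s <- config$slabs[si]
        pair <- render_device_image(sim$truths[[s]], sim$shadow, dev,
                                    seed = cell_seed(config$seed, eye, di, si))
        met <- quantify_pair(pair, config)
        rows <- rbind(rows, data.frame(
          eye_id = eye, device = dev$name, slab = s,
          fd_percent = met$fd_percent, fd_count = met$fd_count,
          mean_fd_size_um2 = met$mean_fd_size_um2,
          total_fd_area_mm2 = met$total_fd_area_mm2,
          fd_fraction_true = sim$truths[[s]]$fd_fraction_true,
          pixel_size_um = met$pixel_size_um,
          params_hash = hash,
          stringsAsFactors = FALSE))
      }
    }
  }
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(rows, metrics_path, row.names = FALSE)

  tables <- NULL
  if (length(config$devices) >= 2 && config$n_eyes >= 3) {
    tables <- build_comparison_tables(rows)
    utils::write.csv(tables$table1, file.path(out_dir, "table1_analogue.csv"),
                     row.names = FALSE)
    if (!is.null(tables$table2)) {
      utils::write.csv(tables$table2, file.path(out_dir, "table2_analogue.csv"),
                       row.names = FALSE)
    }
    if (!is.null(tables$icc)) {
      utils::write.csv(tables$icc, file.path(out_dir, "icc.csv"), row.names = FALSE)
    }
  }
  report <- list(config = unclass(config), params_hash = hash,
                 n_rows = nrow(rows),
                 timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(list(metrics = rows, tables = tables,
                 paths = list(metrics = metrics_path, out_dir = out_dir)))
}
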