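# Image and sidecar I/O. Intensities are stored as 16-bit grayscale TIFF and
# normalized at load time by the dtype maximum (the tiff package does this),
# never by per-image min/max stretching, so thresholding behavior does not
# silently depend on the image's own range.

#' Write an en-face pair to disk
#'
#' Writes the flow and structural channels as single-channel 16-bit TIFF
#' files plus a JSON sidecar with device metadata
#' (`device`, `scan_extent_mm`, `grid_px`, `pixel_size_um`, `seed`).
#'
#' @param pair an `EnFacePair`.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return invisibly, the paths written.
#' @export
write_enface_pair <- function(pair, dir, prefix = "enface") {
  stopifnot(inherits(pair, "EnFacePair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    flow = file.path(dir, paste0(prefix, "_flow.tif")),
    structural = file.path(dir, paste0(prefix, "_structural.tif")),
    sidecar = file.path(dir, paste0(prefix, ".json"))
  )
  tiff::writeTIFF(t(pair$flow), paths$flow, bits.per.sample = 16)
  tiff::writeTIFF(t(pair$structural), paths$structural, bits.per.sample = 16)
  meta <- list(device = pair$device$name,
               scan_extent_mm = pair$device$scan_extent_mm,
               grid_px = pair$device$grid_px,
               pixel_size_um = pair$pixel_size_um,
               seed = pair$seed)
  jsonlite::write_json(meta, paths$sidecar, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read an en-face pair written by [write_enface_pair()]
#'
#' @param dir directory containing the files.
#' @param prefix file name prefix used at write time.
#' @return an `EnFacePair`.
#' @export
read_enface_pair <- function(dir, prefix = "enface") {
  meta <- jsonlite::read_json(file.path(dir, paste0(prefix, ".json")),
                              simplifyVector = TRUE)
  device <- device_profile(meta$device, scan_extent_mm = meta$scan_extent_mm,
                           grid_px = meta$grid_px)
  flow <- t(tiff::readTIFF(file.path(dir, paste0(prefix, "_flow.tif"))))
  structural <- t(tiff::readTIFF(file.path(dir, paste0(prefix, "_structural.tif"))))
  structure(list(flow = flow, structural = structural, device = device,
                 pixel_size_um = meta$pixel_size_um, seed = meta$seed),
            class = "EnFacePair")
}

#' Write a flow-deficit mask as 8-bit TIFF
#'
#' FD pixels are stored as 255 and flow pixels as 0, with a JSON sidecar of
#' the thresholding parameters.
#'
#' @param fdmask an `FDMask`.
#' @param path output TIFF path (`.json` sidecar written next to it).
#' @return invisibly, `path`.
#' @export
write_mask_tiff <- function(fdmask, path) {
  stopifnot(inherits(fdmask, "FDMask"))
  tiff::writeTIFF(t(fdmask$mask * 1.0), path, bits.per.sample = 8)
  meta <- list(pixel_size_um = fdmask$pixel_size_um,
               params = unclass(fdmask$params),
               provenance = fdmask$provenance)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a flow-deficit mask written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @return an `FDMask`.
#' @export
read_mask_tiff <- function(path) {
  img <- t(tiff::readTIFF(path))
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  fd_mask(img > 0.5, meta$pixel_size_um, provenance = as.list(meta$provenance))
}

# Deterministic short hash of a parameter list (md5 of its canonical JSON).
params_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), tf)
  substr(unname(tools::md5sum(tf)), 1, 12)
}
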