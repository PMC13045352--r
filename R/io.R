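sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a volume as multi-page TIFF with a JSON side-car
#'
#' Pages are z-slices (32-bit float); the voxel size (nm), channel and free
#' metadata go into `<file>.json` next to the TIFF, the exchange convention
#' used throughout the toolkit.
#'
#' @param vol An [image_volume].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[3]), function(z) t(vol$data[, , z]))
  # 32-bit float pages round-trip any intensity range; writeTIFF warns about
  # values outside [0,1] even then, so that warning is muffled
  withCallingHandlers(
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE),
    warning = function(w) {
      if (grepl("outside the \\[0, 1\\] range", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  meta <- list(voxel_nm = vol$voxel, origin_nm = vol$origin,
               channel = vol$channel, axes = "pages are z; page rows are y",
               dims = d)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume from a multi-page TIFF
#'
#' Voxel size resolution order: TIFF resolution tags (when tagged in a
#' physical unit), then the JSON side-car written by [write_volume], then the
#' explicit `voxel` override. A missing voxel size from all three sources is
#' an error -- a size of 1 nm is never silently assumed.
#'
#' @param path TIFF file path.
#' @param voxel Optional explicit voxel size 3-vector (nm).
#' @return An [image_volume].
#' @export
read_volume <- function(path, voxel = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(ncol(pages[[1]]), nrow(pages[[1]]), length(pages))
  arr <- array(0, d)
  for (z in seq_along(pages)) arr[, , z] <- t(pages[[z]])
  vx <- NULL; channel <- ""; origin <- c(0, 0, 0)
  info <- attributes(pages[[1]])
  if (!is.null(info$x.resolution) && !is.null(info$resolution.unit) &&
      info$resolution.unit %in% c("cm", "inch")) {
    scale_nm <- if (info$resolution.unit == "cm") 1e7 else 2.54e7
    vx <- c(scale_nm / info$x.resolution,
            scale_nm / (info$y.resolution %||% info$x.resolution), NA)
  }
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(vx) || any(!is.finite(vx))) vx <- as.numeric(meta$voxel_nm)
    channel <- meta$channel %||% ""
    if (!is.null(meta$origin_nm)) origin <- as.numeric(meta$origin_nm)
  }
  if ((is.null(vx) || any(!is.finite(vx))) && !is.null(voxel))
    vx <- check_vec3(voxel, "voxel", positive = TRUE)
  if (is.null(vx) || any(!is.finite(vx)))
    stop("voxel size unavailable: no TIFF resolution tags, no side-car JSON, ",
         "and no 'voxel' override given", call. = FALSE)
  image_volume(arr, vx, channel = channel, origin = origin)
}

#' Write analysis artifacts with a checksummed manifest
#'
#' Each artifact is written by its own handler (data.frame to CSV, list to
#' JSON, [image_volume] to TIFF+side-car, [surface_mesh] to PLY) and recorded
#' in `manifest.json` with type, md5 checksum and the hash of the producing
#' configuration, so reruns are verifiable.
#'
#' @param artifacts Named list of objects to write.
#' @param out_dir Output directory (created if needed).
#' @param config The run configuration echoed next to the outputs.
#' @param overwrite Allow overwriting existing files.
#' @return The manifest, invisibly.
#' @export
write_outputs <- function(artifacts, out_dir, config = list(),
                          overwrite = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(textConnection_md5(cfg_json)))
  entries <- list()
  for (nm in names(artifacts)) {
    obj <- artifacts[[nm]]
    if (inherits(obj, "image_volume")) {
      fn <- file.path(out_dir, paste0(nm, ".tif")); type <- "volume"
      if (file.exists(fn) && !overwrite) stop_collision(fn)
      write_volume(obj, fn)
      files <- c(fn, sidecar_path(fn))
    } else if (inherits(obj, "surface_mesh")) {
      fn <- file.path(out_dir, paste0(nm, ".ply")); type <- "mesh"
      if (file.exists(fn) && !overwrite) stop_collision(fn)
      write_mesh_ply(obj, fn)
      files <- fn
    } else if (is.data.frame(obj)) {
      fn <- file.path(out_dir, paste0(nm, ".csv")); type <- "table"
      if (file.exists(fn) && !overwrite) stop_collision(fn)
      utils::write.csv(obj, fn, row.names = FALSE)
      files <- fn
    } else {
      fn <- file.path(out_dir, paste0(nm, ".json")); type <- "json"
      if (file.exists(fn) && !overwrite) stop_collision(fn)
      jsonlite::write_json(obj, fn, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
      files <- fn
    }
    for (f in files)
      entries[[length(entries) + 1L]] <-
        list(file = basename(f), type = type,
             md5 = unname(tools::md5sum(f)), config_md5 = cfg_hash)
  }
  cfgfile <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfgfile)
  manifest <- list(config_md5 = cfg_hash, artifacts = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

stop_collision <- function(fn) {
  stop(sprintf("output '%s' exists (use overwrite = TRUE)", fn), call. = FALSE)
}

# md5 of a string via a temp file (tools::md5sum works on files)
textConnection_md5 <- function(txt) {
  tf <- tempfile()
  writeLines(txt, tf)
  tf
}
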