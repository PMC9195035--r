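# Persistence: images as flat binary float arrays (or TIFF when the `tiff`
# package is available) with a JSON sidecar carrying the panel geometry and
# acquisition metadata; stats as CSV/JSON; acquisition manifests; scenario
# configuration in YAML.

geometry_to_list <- function(g)
  list(n_rows = g$n_rows, n_cols = g$n_cols, pitch_iso = g$pitch_iso,
       sid = g$sid, shift_x = g$shift_x, shift_y = g$shift_y,
       sid_ref = g$sid_ref)

geometry_from_list <- function(l)
  panel_geometry(l$n_rows, l$n_cols, l$pitch_iso, l$sid,
                 l$shift_x, l$shift_y, l$sid_ref)

#' Save a raw image to disk
#'
#' Writes the pixel array as little-endian float64 (`.bin`) or 32-bit float
#' TIFF (`.tif`, requires the `tiff` package), plus a `.json` sidecar with
#' the geometry and acquisition metadata.
#'
#' @param img a [raw_image()].
#' @param path output path; the sidecar replaces the extension with `.json`.
#' @return `path`, invisibly.
#' @export
save_raw_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "tif" || ext == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("writing TIFF requires the 'tiff' package; use a .bin path instead")
    tiff::writeTIFF(img$pixels / max(img$pixels), path, bits.per.sample = 32L)
    scale <- max(img$pixels)
  } else {
    con <- file(path, "wb")
    writeBin(as.vector(img$pixels), con, size = 8, endian = "little")
    close(con)
    scale <- 1
  }
  meta <- list(geometry = geometry_to_list(img$geometry), mu = img$mu,
               field_x = img$field_x, field_y = img$field_y, kind = img$kind,
               storage_scale = scale, format = if (scale == 1) "bin" else "tiff")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Load a raw image from disk
#'
#' @param path a `.bin` or `.tif` path written by [save_raw_image()]; the
#'   JSON sidecar must sit next to it.
#' @return a [raw_image()].
#' @export
load_raw_image <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing metadata sidecar '%s' (geometry and acquisition metadata are required)", sc))
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  need <- c("n_rows", "n_cols", "pitch_iso", "sid", "shift_x", "shift_y", "sid_ref")
  miss <- setdiff(need, names(meta$geometry))
  if (length(miss))
    stop(sprintf("sidecar is missing geometry field(s): %s",
                 paste(miss, collapse = ", ")))
  g <- geometry_from_list(meta$geometry)
  ext <- tolower(tools::file_ext(path))
  if (ext == "tif" || ext == "tiff") {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package")
    px <- tiff::readTIFF(path) * meta$storage_scale
  } else {
    n <- g$n_rows * g$n_cols
    if (file.size(path) != 8 * n)
      stop("pixel data size does not match the sidecar geometry")
    con <- file(path, "rb")
    px <- matrix(readBin(con, "double", n = n, size = 8, endian = "little"),
                 g$n_rows, g$n_cols)
    close(con)
  }
  if (length(px) != g$n_rows * g$n_cols)
    stop("pixel data size does not match the sidecar geometry")
  raw_image(matrix(px, g$n_rows, g$n_cols), g, mu = meta$mu,
            field_x = meta$field_x, field_y = meta$field_y, kind = meta$kind)
}

#' Write an acquisition manifest
#'
#' @param entries data.frame with one row per image (path, kind, shift, sid,
#'   mu, field, seed columns as available).
#' @param path output JSON path.
#' @param config_hash optional scenario-configuration digest.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path, config_hash = NULL) {
  jsonlite::write_json(list(entries = entries, config_hash = config_hash),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an acquisition manifest
#'
#' @param path manifest JSON path.
#' @return list with `entries` data.frame and `config_hash`; errors if any
#'   referenced image path is missing.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(path)
  full <- file.path(base, m$entries$path)
  missing <- !file.exists(full)
  if (any(missing))
    stop(sprintf("manifest references missing image file(s): %s",
                 paste(m$entries$path[missing], collapse = ", ")))
  m$entries$path <- full
  m
}

#' Write deviation / repeatability statistics
#'
#' One row per comparison, as CSV and JSON side by side.
#'
#' @param stats data.frame of statistics.
#' @param path_base output path without extension.
#' @return the two paths, invisibly.
#' @export
write_stats <- function(stats, path_base) {
  csv <- paste0(path_base, ".csv"); js <- paste0(path_base, ".json")
  utils::write.csv(stats, csv, row.names = FALSE)
  jsonlite::write_json(stats, js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, js))
}

#' Load a scenario from a YAML configuration
#'
#' Top-level keys `geometry`, `beam`, `defects`, `noise` and `name`; each
#' maps directly onto the corresponding constructor's arguments, with
#' omitted fields taking the constructor defaults.
#'
#' @param path YAML file path.
#' @return a `psm_scenario`.
#' @export
scenario_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(f, args) do.call(f, if (is.null(args)) list() else args)
  defects <- cfg$defects
  if (!is.null(defects$blob_defects))
    defects$blob_defects <- lapply(defects$blob_defects, as.list)
  scenario(geom = build(panel_geometry, cfg$geometry),
           beam = build(beam_model, cfg$beam),
           defects = build(panel_defect_model, defects),
           noise = build(acquisition_noise, cfg$noise),
           name = if (is.null(cfg$name)) "yaml-scenario" else cfg$name)
}

#' Save a simulated acquisition to a directory
#'
#' Writes every image of a method acquisition as `.bin` + sidecar and a
#' manifest JSON describing them.
#'
#' @param acq a `cmn_acquisition` or `radial_acquisition` (the two
#'   image-list layouts; ABDF sequence sets are written per net average).
#' @param dir output directory (created).
#' @return manifest path, invisibly.
#' @export
save_acquisition <- function(acq, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  put <- function(img, name) {
    p <- file.path(dir, paste0(name, ".bin"))
    save_raw_image(img, p)
    rows[[length(rows) + 1L]] <<- data.frame(
      path = basename(p), kind = img$kind, shift_x = img$geometry$shift_x,
      shift_y = img$geometry$shift_y, sid = img$geometry$sid, mu = img$mu,
      field_x = img$field_x, field_y = img$field_y)
  }
  if (inherits(acq, "cmn_acquisition")) {
    put(acq$reference, "reference")
    for (k in seq_along(acq$offsets))
      put(acq$offsets[[k]], sprintf("offset_%02d", k))
    put(acq$wide, "wide")
  } else if (inherits(acq, "radial_acquisition")) {
    put(acq$ideal, "ideal")
    put(acq$measured, "measured")
  } else stop("unsupported acquisition type for directory export")
  write_manifest(do.call(rbind, rows), file.path(dir, "manifest.json"))
}
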