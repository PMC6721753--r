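# On-disk interchange: 16-bit multi-page TIFF per channel with a JSON
# sidecar carrying the channel map, pixel pitch and intensity scale, and a
# plain-CSV ground-truth table.

#' Write a rendered well to multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel (`<well>_<channel>.tif`, one page
#' per frame) plus `<well>_metadata.json` with the channel names, pixel
#' pitch, frame count, intensity scale (a.u. per digital number) and any
#' exposure-time metadata.
#'
#' @param images Array (rows, cols, channels, frames) from [render_well()].
#' @param dir Output directory (created if needed).
#' @param optics The [optics_config()] used for rendering.
#' @param well_id Basename prefix.
#' @param scale Intensity a.u. mapped to the full 16-bit range; defaults to
#'   a power-of-two ceiling of the image maximum.
#' @return Invisibly, the metadata list.
#' @export
write_well_images <- function(images, dir, optics, well_id = "well1",
                              scale = NULL) {
  stopifnot(length(dim(images)) == 4)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  channels <- dimnames(images)[[3]]
  if (is.null(channels)) channels <- optics$channel_names
  if (is.null(scale)) scale <- 2^ceiling(log2(max(images, 1)))
  for (k in seq_along(channels)) {
    pages <- lapply(seq_len(dim(images)[4]), function(f)
      pmin(pmax(images[, , k, f] / scale, 0), 1))
    tiff::writeTIFF(pages, file.path(dir, paste0(well_id, "_", channels[k],
                                                 ".tif")),
                    bits.per.sample = 16L)
  }
  meta <- list(well_id = well_id, channels = channels,
               pixel_pitch_um = optics$pixel_pitch,
               frame_shape = dim(images)[1:2], frames = dim(images)[4],
               intensity_scale = scale,
               exposure_ms = optics$exposure_ms)
  jsonlite::write_json(meta, file.path(dir, paste0(well_id, "_metadata.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(meta)
}

#' Read a well written by [write_well_images()]
#'
#' @param dir Directory holding the TIFFs and metadata sidecar.
#' @param well_id Basename prefix.
#' @return List with `images` (rows x cols x channels x frames, in original
#'   a.u.) and `metadata`.
#' @export
read_well_images <- function(dir, well_id = "well1") {
  meta <- jsonlite::fromJSON(file.path(dir, paste0(well_id, "_metadata.json")))
  channels <- meta$channels
  images <- array(0, dim = c(meta$frame_shape[1], meta$frame_shape[2],
                             length(channels), meta$frames),
                  dimnames = list(NULL, NULL, channels, NULL))
  for (k in seq_along(channels)) {
    pages <- tiff::readTIFF(file.path(dir, paste0(well_id, "_", channels[k],
                                                  ".tif")), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    for (f in seq_along(pages))
      images[, , k, f] <- pages[[f]] * meta$intensity_scale
  }
  list(images = images, metadata = meta)
}

#' Write / read a ground-truth particle table
#'
#' Plain CSV with columns `particle_id`, `well_id`, `frame_id`, `class`,
#' `row`, `col`, `diameter_um`, `defocus_sigma`, `clipped` and one
#' `intensity_<channel>` column per channel.
#'
#' @param truth Ground truth from [sample_well()].
#' @param path CSV file path.
#' @return `path` invisibly (write) or the table (read).
#' @export
write_ground_truth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
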