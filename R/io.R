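# Scene, trace and configuration I/O. Scenes travel as multipage 32-bit
# TIFF (channel-major page order: all z of GFP, then kisspeptin, then
# synaptophysin) plus a JSON sidecar carrying voxel sizes, expansion
# factor, modality, channel order and the intensity scale used to map
# counts into the TIFF's [0, 1] range.

#' Write a scene to TIFF + JSON sidecar
#'
#' @param scene An [exm_scene()].
#' @param path Output TIFF path.
#' @param meta_path Output JSON sidecar path (defaults to `path` with a
#'   `.json` extension).
#' @return Invisibly, the metadata list written.
#' @export
write_scene <- function(scene, path, meta_path = NULL) {
  stopifnot(inherits(scene, "exm_scene"))
  if (is.null(meta_path)) meta_path <- sub("\\.tiff?$", ".json", path)
  chans <- names(scene$channels)
  lo <- min(vapply(scene$channels, min, 0))
  hi <- max(vapply(scene$channels, max, 0))
  scale <- max(hi - lo, 1e-12)
  pages <- list()
  for (ch in chans) {
    a <- (scene$channels[[ch]] - lo) / scale
    for (k in seq_len(dim(a)[3])) {
      pages[[length(pages) + 1L]] <- a[, , k]
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  meta <- list(voxel_xy = scene$voxel_xy, voxel_z = scene$voxel_z,
               expansion_factor = scene$expansion_factor,
               modality = scene$modality, channels = chans,
               n_z = dim(scene$channels[[1]])[3],
               intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Load a scene from TIFF + JSON sidecar
#'
#' Validates the sidecar (all required fields present, page count
#' consistent with `n_z` x number of channels) and reconstructs the
#' channel arrays on their original intensity scale.
#'
#' @param path TIFF path.
#' @param meta_path JSON sidecar path.
#' @return An [exm_scene()].
#' @export
load_scene <- function(path, meta_path) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  if (!file.exists(meta_path)) stop("metadata JSON not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  required <- c("voxel_xy", "voxel_z", "expansion_factor", "modality",
                "channels", "n_z")
  missing <- setdiff(required, names(meta))
  if (length(missing)) {
    stop("scene metadata is missing field(s): ",
         paste(missing, collapse = ", "))
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  n_ch <- length(meta$channels)
  if (length(pages) != n_ch * meta$n_z) {
    stop(sprintf(
      "page count mismatch: %d pages in TIFF but metadata declares %d channels x %d z-planes",
      length(pages), n_ch, meta$n_z))
  }
  off <- if (is.null(meta$intensity_offset)) 0 else meta$intensity_offset
  scl <- if (is.null(meta$intensity_scale)) 1 else meta$intensity_scale
  d <- dim(pages[[1]])
  arrs <- list()
  for (ci in seq_len(n_ch)) {
    a <- array(0, c(d[1], d[2], meta$n_z))
    for (k in seq_len(meta$n_z)) {
      a[, , k] <- pages[[(ci - 1) * meta$n_z + k]]
    }
    arrs[[meta$channels[ci]]] <- a * scl + off
  }
  exm_scene(arrs$gfp, arrs$kisspeptin, arrs$synaptophysin,
            voxel_xy = meta$voxel_xy, voxel_z = meta$voxel_z,
            expansion_factor = meta$expansion_factor,
            modality = meta$modality)
}

#' Write / read ROI traces as long-format CSV
#'
#' The CSV has columns `roi_id`, `time_s`, `F`; recording-level metadata
#' (frame rate, puff window, baseline frames) travels in a JSON sidecar.
#'
#' @param traces List of [roi_trace()] objects.
#' @param path Output CSV path.
#' @param meta_path JSON sidecar path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path, meta_path = NULL) {
  if (is.null(meta_path)) meta_path <- sub("\\.csv$", ".json", path)
  long <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(roi_id = tr$roi_id, time_s = tr$times, F = tr$f)
  }))
  write.csv(long, path, row.names = FALSE)
  t1 <- traces[[1]]
  jsonlite::write_json(
    list(frame_rate = t1$frame_rate, puff_start_s = t1$puff_window[1],
         puff_end_s = t1$puff_window[2],
         baseline_frames = t1$baseline_frames),
    meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path, meta_path) {
  long <- read.csv(path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  lapply(split(long, long$roi_id), function(d) {
    d <- d[order(d$time_s), ]
    roi_trace(d$time_s, d$F,
              puff_window = c(meta$puff_start_s, meta$puff_end_s),
              baseline_frames = meta$baseline_frames,
              frame_rate = meta$frame_rate, roi_id = d$roi_id[1])
  })
}
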