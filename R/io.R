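#' Write a stack as multi-frame TIFF with a YAML sidecar
#'
#' Frames are stored as 32-bit float TIFF. TIFF float samples are written in
#' `[0, 1]`, so intensities are affinely rescaled and the original range is
#' recorded in the sidecar (`<prefix>.yaml`) together with the timestamps,
#' event frames, pixel size and signal kind; [read_stack()] restores the
#' original values.
#'
#' @param stack a [perfusion_stack()].
#' @param prefix output path prefix; writes `<prefix>.tif` and
#'   `<prefix>.yaml`.
#' @param ischemic_side optional side annotation carried in the sidecar.
#' @return `prefix`, invisibly.
#' @export
write_stack <- function(stack, prefix, ischemic_side = NULL) {
  stopifnot(inherits(stack, "perfusion_stack"))
  rng <- range(stack$frames)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  frames <- lapply(seq_len(n_frames(stack)), function(t) {
    (stack$frames[, , t] - rng[1]) / scale
  })
  tiff::writeTIFF(frames, paste0(prefix, ".tif"), bits.per.sample = 32L)
  meta <- list(signal = stack$signal,
               pixel_size_mm = stack$pixel_size,
               injection_frame = stack$injection_frame,
               reperfusion_frame = stack$reperfusion_frame,
               intensity_min = rng[1], intensity_max = rng[2],
               timestamps_s = as.numeric(stack$timestamps))
  if (!is.null(ischemic_side)) meta$ischemic_side <- ischemic_side
  yaml::write_yaml(meta, paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Read a stack written by [write_stack()]
#'
#' @param prefix path prefix of the `.tif` / `.yaml` pair.
#' @return A [perfusion_stack()]; the sidecar's `ischemic_side`, if present,
#'   is attached as attribute `"ischemic_side"`.
#' @export
read_stack <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  frames <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  scale <- meta$intensity_max - meta$intensity_min
  if (scale <= 0) scale <- 1
  arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (t in seq_along(frames)) {
    arr[, , t] <- frames[[t]] * scale + meta$intensity_min
  }
  out <- perfusion_stack(arr, timestamps = unlist(meta$timestamps_s),
                         injection_frame = meta$injection_frame,
                         reperfusion_frame = meta$reperfusion_frame,
                         pixel_size = meta$pixel_size_mm,
                         signal = meta$signal)
  if (!is.null(meta$ischemic_side)) {
    attr(out, "ischemic_side") <- meta$ischemic_side
  }
  out
}

#' Write / read a boolean or label mask as single-frame TIFF
#'
#' Logical masks are stored as 0/1; integer label maps (e.g. hemisphere
#' labels 0/1/2) are scaled by their maximum, recorded in the file as
#' distinct gray levels.
#'
#' @param mask logical or small-integer matrix.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  m <- mask + 0   # keep dims; logical -> 0/1
  top <- max(m)
  if (top > 0) m <- m / top
  tiff::writeTIFF(m, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @param n_levels number of label levels stored (2 for a boolean mask);
#'   used to undo the gray-level scaling.
#' @return `read_mask()`: an integer matrix (or logical when
#'   `n_levels = 2`).
#' @export
read_mask <- function(path, n_levels = 2) {
  m <- tiff::readTIFF(path)
  lab <- matrix(as.integer(round(m * (n_levels - 1))), nrow(m), ncol(m))
  if (n_levels == 2) lab == 1L else lab
}

#' Write tidy traces or a core track as CSV
#'
#' @param x a `trace_set` or `core_track` data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy trace CSV written by [write_traces_csv()]
#'
#' @param path CSV path.
#' @return A data frame.
#' @export
read_traces_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
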