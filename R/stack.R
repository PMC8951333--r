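#' Perfusion / hemoglobin image time series
#'
#' Container for a time-ordered stack of 2D intensity frames as produced by
#' combined laser-speckle (flow) and multispectral reflectance (oxy-/
#' deoxyhemoglobin) imaging of the exposed mouse skull. Frames are stored as
#' a `height x width x n_frames` array; timestamps are seconds from the start
#' of the recording. The injection and reperfusion frames are the events
#' marked during acquisition and are used downstream to align all results so
#' that reperfusion is minute 0.
#'
#' Flow frames must be nonnegative; oxy-/deoxyhemoglobin frames are
#' concentration signals and may be signed.
#'
#' @param frames numeric array `[height, width, n_frames]`, or a matrix for a
#'   single frame.
#' @param timestamps numeric vector of frame times in seconds, strictly
#'   increasing, one per frame.
#' @param injection_frame,reperfusion_frame 1-based frame indices of the EV
#'   injection and of reperfusion onset; the injection precedes reperfusion
#'   (EVs are given during occlusion).
#' @param pixel_size pixel edge length in mm.
#' @param signal one of `"flow"`, `"oxyHb"`, `"deoxyHb"`.
#' @return An object of class `perfusion_stack`.
#' @export
perfusion_stack <- function(frames, timestamps, injection_frame,
                            reperfusion_frame, pixel_size = 0.1,
                            signal = c("flow", "oxyHb", "deoxyHb")) {
  signal <- match.arg(signal)
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stopf("invariant violated: 'frames' must be a [height, width, n] array")
  }
  n <- dim(frames)[3L]
  if (length(timestamps) != n) {
    stopf("invariant violated: %d timestamps for %d frames", length(timestamps), n)
  }
  if (n > 1L && any(diff(timestamps) <= 0)) {
    stopf("invariant violated: timestamps must be strictly increasing")
  }
  injection_frame <- as.integer(injection_frame)
  reperfusion_frame <- as.integer(reperfusion_frame)
  for (ev in c(injection = injection_frame, reperfusion = reperfusion_frame)) {
    if (is.na(ev) || ev < 1L || ev > n) {
      stopf("invariant violated: event frame index %s outside 1..%d", ev, n)
    }
  }
  if (injection_frame >= reperfusion_frame) {
    stopf("invariant violated: injection_frame (%d) must precede reperfusion_frame (%d)",
          injection_frame, reperfusion_frame)
  }
  if (signal == "flow" && any(frames < 0)) {
    stopf("invariant violated: flow frames must be nonnegative")
  }
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  structure(
    list(frames = frames, timestamps = as.numeric(timestamps),
         injection_frame = injection_frame,
         reperfusion_frame = reperfusion_frame,
         pixel_size = pixel_size, signal = signal),
    class = "perfusion_stack")
}

#' @export
print.perfusion_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<perfusion_stack> %s signal, %d x %d px, %d frames (%.0f-%.0f s)\n",
              x$signal, d[1], d[2], d[3],
              x$timestamps[1], x$timestamps[d[3]]))
  cat(sprintf("  injection at frame %d, reperfusion at frame %d, pixel %.3g mm\n",
              x$injection_frame, x$reperfusion_frame, x$pixel_size))
  invisible(x)
}

#' @export
dim.perfusion_stack <- function(x) dim(x$frames)

n_frames <- function(stack) dim(stack$frames)[3L]

#' Hemisphere geometry
#'
#' Per-pixel label map separating the two hemispheres from background.
#' Labels: 0 = background, 1 = healthy hemisphere, 2 = ischemic hemisphere.
#' Both hemispheres must be non-empty and are disjoint by construction.
#'
#' @param labels integer matrix with values in \{0, 1, 2\}.
#' @param ischemic_side `"left"` or `"right"` (which anatomical side label 2
#'   occupies; metadata only).
#' @return An object of class `hemisphere_geometry`.
#' @export
hemisphere_geometry <- function(labels, ischemic_side = c("left", "right")) {
  ischemic_side <- match.arg(ischemic_side)
  if (!is.matrix(labels) || !all(labels %in% 0:2)) {
    stopf("invariant violated: 'labels' must be a matrix with values 0/1/2")
  }
  if (!any(labels == 1L) || !any(labels == 2L)) {
    stopf("invariant violated: both hemispheres must be non-empty")
  }
  structure(list(labels = labels, ischemic_side = ischemic_side),
            class = "hemisphere_geometry")
}

#' @export
print.hemisphere_geometry <- function(x, ...) {
  cat(sprintf("<hemisphere_geometry> %d x %d px, ischemic side: %s (healthy %d px, ischemic %d px)\n",
              nrow(x$labels), ncol(x$labels), x$ischemic_side,
              sum(x$labels == 1L), sum(x$labels == 2L)))
  invisible(x)
}

healthy_pixels <- function(geometry) geometry$labels == 1L
ischemic_pixels <- function(geometry) geometry$labels == 2L
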