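#' Reduce a 1 frame/s stack to 1 frame/min
#'
#' Temporal downsampling used before all hemodynamic analysis: each output
#' frame is the pixelwise mean of the source frames falling in one whole
#' minute of recording. A trailing partial minute is dropped, and the event
#' frame indices are remapped to the minute that contains them.
#'
#' @param stack a [perfusion_stack()] sampled at about one frame per second.
#' @return A [perfusion_stack()] with one frame per minute; timestamps are
#'   the minute start times.
#' @export
downsample_to_minutes <- function(stack) {
  stopifnot(inherits(stack, "perfusion_stack"))
  n <- n_frames(stack)
  if (n < 60L) {
    stopf("downsampling requires at least one whole minute of frames (got %d)", n)
  }
  ts <- stack$timestamps
  bin <- floor(ts / 60)
  frame_rate <- 1 / stats::median(diff(ts))
  expected <- round(60 * frame_rate)
  counts <- table(bin)
  keep <- as.numeric(names(counts))[counts >= expected]
  keep <- sort(keep)
  if (length(keep) == 0L) {
    stopf("no complete minute in the recording")
  }
  h <- dim(stack$frames)[1]; w <- dim(stack$frames)[2]
  out <- array(0, dim = c(h, w, length(keep)))
  for (i in seq_along(keep)) {
    idx <- which(bin == keep[i])
    out[, , i] <- rowMeans(stack$frames[, , idx, drop = FALSE], dims = 2)
  }
  remap <- function(frame) {
    m <- match(floor(ts[frame] / 60), keep)
    if (is.na(m)) length(keep) else m
  }
  inj <- remap(stack$injection_frame)
  rep_ <- remap(stack$reperfusion_frame)
  if (inj >= rep_) inj <- max(1L, rep_ - 1L)  # events in one minute collapse
  perfusion_stack(out, timestamps = 60 * keep,
                  injection_frame = inj, reperfusion_frame = rep_,
                  pixel_size = stack$pixel_size, signal = stack$signal)
}

#' Pixelwise pre-reperfusion mean map
#'
#' The reference map all static analyses are based on: the pixelwise mean of
#' every frame strictly before the reperfusion frame.
#'
#' @param stack a [perfusion_stack()].
#' @return Numeric matrix of the stack's frame size.
#' @export
reference_map <- function(stack) {
  stopifnot(inherits(stack, "perfusion_stack"))
  idx <- seq_len(stack$reperfusion_frame - 1L)
  if (length(idx) == 0L) {
    stopf("no frames before the reperfusion frame")
  }
  rowMeans(stack$frames[, , idx, drop = FALSE], dims = 2)
}

#' Mask out large vessels by intensity thresholding
#'
#' Big cortical vessels appear as bright structures in the perfusion maps
#' and would contaminate parenchymal statistics; they are masked by
#' thresholding the pre-reperfusion reference map at a high percentile of
#' its non-background intensities. Vessel pixels are excluded from every
#' downstream region statistic.
#'
#' @param reference pre-reperfusion mean map (see [reference_map()]).
#' @param geometry a [hemisphere_geometry()].
#' @param q percentile threshold in (50, 100); default 95.
#' @return An object of class `vessel_mask`: the boolean map, the intensity
#'   threshold used and a method tag.
#' @export
detect_vessels <- function(reference, geometry, q = 95) {
  stopifnot(is.matrix(reference), inherits(geometry, "hemisphere_geometry"))
  if (!(q > 50 && q < 100)) {
    stopf("vessel percentile q must lie in (50, 100), got %g", q)
  }
  nonbg <- geometry$labels > 0L
  vals <- reference[nonbg]
  if (diff(range(vals)) == 0) {
    warnf("reference map is constant over the brain; vessel mask is empty")
    mask <- matrix(FALSE, nrow(reference), ncol(reference))
    thr <- Inf
  } else {
    thr <- stats::quantile(vals, q / 100, names = FALSE)
    mask <- reference > thr & nonbg
  }
  structure(list(mask = mask, threshold = thr,
                 method = sprintf("percentile_%g", q)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %d px, threshold %.4g (%s)\n",
              sum(x$mask), x$threshold, x$method))
  invisible(x)
}

#' Healthy-hemisphere pre-reperfusion baseline
#'
#' The perfusion baseline B: the mean flow intensity over healthy-hemisphere
#' non-vessel pixels, across all frames strictly before reperfusion. All
#' core/penumbra thresholds are fractions of B.
#'
#' @param stack a flow [perfusion_stack()] (normally downsampled to minutes).
#' @param geometry a [hemisphere_geometry()].
#' @param vessels a [detect_vessels()] mask.
#' @return The scalar baseline B in the stack's intensity units.
#' @export
compute_baseline <- function(stack, geometry, vessels) {
  stopifnot(inherits(stack, "perfusion_stack"),
            inherits(geometry, "hemisphere_geometry"),
            inherits(vessels, "vessel_mask"))
  if (stack$signal != "flow") {
    stopf("baseline is defined on the flow signal, not '%s'", stack$signal)
  }
  idx <- seq_len(stack$reperfusion_frame - 1L)
  if (length(idx) == 0L) stopf("no frames before the reperfusion frame")
  px <- healthy_pixels(geometry) & !vessels$mask
  if (!any(px)) stopf("no healthy-hemisphere parenchyma pixels")
  mean(vapply(idx, function(t) mean(stack$frames[, , t][px]), numeric(1)))
}

#' Classify perfusion values relative to baseline
#'
#' Interval rule for baseline-relative flow: ischemic core below 33% of
#' baseline, penumbra from 33% to 70% inclusive, normally perfused above
#' 70%. Boundary values 33% and 70% fall in the penumbra so the three
#' intervals tile exactly.
#'
#' @param values perfusion intensities (same units as `baseline`).
#' @param baseline the baseline B (> 0).
#' @param theta_core,theta_normal thresholds as fractions of B;
#'   `0 < theta_core < theta_normal < 1`.
#' @return Character vector in `c("core", "penumbra", "normal")`.
#' @export
classify_perfusion <- function(values, baseline, theta_core = 0.33,
                               theta_normal = 0.70) {
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  check_number(theta_core, "theta_core", 0, 1, TRUE, TRUE)
  check_number(theta_normal, "theta_normal", 0, 1, TRUE, TRUE)
  if (theta_core >= theta_normal) {
    stopf("invariant violated: theta_core < theta_normal required")
  }
  rel <- values / baseline
  ifelse(rel < theta_core, "core",
         ifelse(rel <= theta_normal, "penumbra", "normal"))
}

#' Static core / penumbra / normal region masks
#'
#' Segments the ischemic-hemisphere parenchyma from the pre-reperfusion mean
#' flow map: pixels below `theta_core * B` form the ischemic core, pixels up
#' to `theta_normal * B` the penumbra, brighter pixels the normally perfused
#' area. The three masks are pairwise disjoint and together tile the
#' ischemic-hemisphere non-vessel pixels. These static masks define the
#' regions whose flow and hemoglobin traces are followed over reperfusion.
#'
#' @inheritParams compute_baseline
#' @param baseline the scalar baseline B from [compute_baseline()].
#' @param theta_core,theta_normal segmentation thresholds as fractions of B.
#' @return An object of class `region_masks` with boolean maps `core`,
#'   `penumbra`, `normal`, the baseline and thresholds used, and the frame
#'   range averaged for the reference map.
#' @export
build_region_masks <- function(stack, geometry, vessels, baseline,
                               theta_core = 0.33, theta_normal = 0.70) {
  stopifnot(inherits(stack, "perfusion_stack"),
            inherits(geometry, "hemisphere_geometry"),
            inherits(vessels, "vessel_mask"))
  if (stack$signal != "flow") {
    stopf("region masks are defined on the flow signal, not '%s'", stack$signal)
  }
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  ref <- reference_map(stack)
  par <- ischemic_pixels(geometry) & !vessels$mask
  cls <- matrix(classify_perfusion(ref, baseline, theta_core, theta_normal),
                nrow(ref), ncol(ref))
  structure(
    list(core = cls == "core" & par,
         penumbra = cls == "penumbra" & par,
         normal = cls == "normal" & par,
         baseline = baseline, theta_core = theta_core,
         theta_normal = theta_normal,
         reference_frames = c(1L, stack$reperfusion_frame - 1L)),
    class = "region_masks")
}

#' @export
print.region_masks <- function(x, ...) {
  cat(sprintf("<region_masks> core %d px, penumbra %d px, normal %d px\n",
              sum(x$core), sum(x$penumbra), sum(x$normal)))
  cat(sprintf("  baseline %.4g, thresholds %.2f / %.2f of baseline, reference frames %d-%d\n",
              x$baseline, x$theta_core, x$theta_normal,
              x$reference_frames[1], x$reference_frames[2]))
  invisible(x)
}

#' Track the ischemic core over time
#'
#' Dynamic per-frame classification: for every (downsampled) frame, the
#' pixels of the ischemic-hemisphere parenchyma with flow below
#' `theta_core * B` are counted as the ischemic core. The fraction is the
#' count over the total ischemic-hemisphere non-vessel pixel count, i.e. the
#' core as a proportion of the hemisphere, and the time axis is in minutes
#' with reperfusion at 0.
#'
#' @inheritParams build_region_masks
#' @param theta_core core threshold as a fraction of B.
#' @return A data frame of class `core_track` with columns `frame`,
#'   `time_min`, `count`, `fraction`.
#' @export
track_core <- function(stack, geometry, vessels, baseline,
                       theta_core = 0.33) {
  stopifnot(inherits(stack, "perfusion_stack"),
            inherits(geometry, "hemisphere_geometry"),
            inherits(vessels, "vessel_mask"))
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  check_number(theta_core, "theta_core", 0, 1, TRUE, TRUE)
  par <- ischemic_pixels(geometry) & !vessels$mask
  denom <- sum(par)
  if (denom == 0L) stopf("no ischemic-hemisphere parenchyma pixels")
  thr <- theta_core * baseline
  counts <- vapply(seq_len(n_frames(stack)), function(t) {
    sum(stack$frames[, , t][par] < thr)
  }, numeric(1))
  out <- data.frame(
    frame = seq_len(n_frames(stack)),
    time_min = (stack$timestamps -
                  stack$timestamps[stack$reperfusion_frame]) / 60,
    count = counts, fraction = counts / denom)
  class(out) <- c("core_track", "data.frame")
  attr(out, "theta_core") <- theta_core
  attr(out, "baseline") <- baseline
  out
}

#' Extract relative region traces scaled to start at 1
#'
#' For each signal (flow, oxyHb, deoxyHb) and each region mask, computes the
#' per-frame mean over the mask's pixels and divides the whole trace by its
#' first value, so every trace starts at exactly 1. The time axis is in
#' minutes with the reperfusion frame at 0.
#'
#' @param stacks a [perfusion_stack()] or a list of them (one per signal);
#'   all must share frame geometry, frame count and event indices.
#' @param masks a [build_region_masks()] result (or any list of boolean
#'   matrices named `core`, `penumbra`, `normal`).
#' @param regions which regions to extract.
#' @return A tidy data frame of class `trace_set` with columns `time_min`,
#'   `region`, `signal`, `value`; each (region, signal) trace has first
#'   value exactly 1.
#' @export
extract_region_traces <- function(stacks, masks,
                                  regions = c("core", "penumbra", "normal")) {
  if (inherits(stacks, "perfusion_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1L)
  d0 <- dim(stacks[[1]]$frames); rep0 <- stacks[[1]]$reperfusion_frame
  for (s in stacks) {
    stopifnot(inherits(s, "perfusion_stack"))
    if (!identical(dim(s$frames), d0) || s$reperfusion_frame != rep0) {
      stopf("all stacks must share frame geometry and event indices")
    }
  }
  out <- list()
  for (s in stacks) {
    tmin <- (s$timestamps - s$timestamps[s$reperfusion_frame]) / 60
    for (rg in regions) {
      m <- masks[[rg]]
      if (is.null(m) || !any(m)) {
        warnf("region '%s' mask is empty; trace omitted", rg)
        next
      }
      v <- vapply(seq_len(n_frames(s)), function(t) mean(s$frames[, , t][m]),
                  numeric(1))
      if (v[1] == 0) {
        stopf("first value of region '%s' (%s) trace is 0; cannot scale to 1",
              rg, s$signal)
      }
      v <- v / v[1]
      v[1] <- 1  # exact by contract, immune to rounding
      out[[length(out) + 1L]] <- data.frame(
        time_min = tmin, region = rg, signal = s$signal, value = v)
    }
  }
  if (length(out) == 0L) stopf("no non-empty region masks")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("trace_set", "data.frame")
  res
}

#' Full hemodynamic analysis of one animal
#'
#' Convenience wrapper running the standard chain on a flow stack (plus any
#' hemoglobin stacks): downsample to one frame per minute, build the
#' reference map, mask vessels, compute the healthy-hemisphere baseline,
#' segment core/penumbra/normal, track the dynamic core and extract the
#' relative region traces.
#'
#' @param flow a flow [perfusion_stack()] at ~1 frame/s.
#' @param geometry a [hemisphere_geometry()].
#' @param hb_stacks optional list of hemoglobin stacks at the same sampling.
#' @param vessel_q vessel-masking percentile.
#' @param theta_core,theta_normal segmentation thresholds.
#' @return List with the downsampled stacks, `vessels`, `baseline`, `masks`,
#'   `core_track` and `traces`.
#' @export
analyze_hemodynamics <- function(flow, geometry, hb_stacks = list(),
                                 vessel_q = 95, theta_core = 0.33,
                                 theta_normal = 0.70) {
  flow_min <- downsample_to_minutes(flow)
  hb_min <- lapply(hb_stacks, downsample_to_minutes)
  ref <- reference_map(flow_min)
  vessels <- detect_vessels(ref, geometry, q = vessel_q)
  B <- compute_baseline(flow_min, geometry, vessels)
  masks <- build_region_masks(flow_min, geometry, vessels, B,
                              theta_core, theta_normal)
  track <- track_core(flow_min, geometry, vessels, B, theta_core)
  traces <- extract_region_traces(c(list(flow_min), hb_min), masks)
  list(flow = flow_min, hb = hb_min, vessels = vessels, baseline = B,
       masks = masks, core_track = track, traces = traces)
}
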