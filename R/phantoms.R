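#' Specification of a synthetic perfusion phantom
#'
#' Describes a two-hemisphere cortical field imaged from above: bright
#' vessels over parenchyma, an elliptical ischemic core with a penumbral
#' annulus in the ischemic hemisphere, programmable perfusion deficits, and
#' single-exponential recovery toward a plateau after reperfusion. The
#' phantom is the validation substrate for the whole hemodynamic pipeline:
#' every generated stack carries its own ground truth.
#'
#' All geometry is in pixel units; physical units enter only through
#' `pixel_size`. Perfusion targets are fractions of the healthy baseline.
#'
#' @param height,width image size in pixels.
#' @param pixel_size pixel edge length, mm.
#' @param margin background border width, pixels.
#' @param midline column index of the last column of the left hemisphere;
#'   default splits the field in half.
#' @param ischemic_side which hemisphere carries the lesion.
#' @param n_vessels,vessel_width,vessel_multiplier number of bright vessel
#'   strips, their width (px) and their intensity as a multiple (> 1) of
#'   baseline. Vessel pixels carry `baseline * vessel_multiplier` regardless
#'   of the region they cross, so vessel masking is consequential.
#' @param core_center `(row, col)` of the core ellipse; default centers it in
#'   the ischemic hemisphere.
#' @param core_semiaxes `(row semi-axis, col semi-axis)` of the core, px.
#' @param core_perfusion pre-reperfusion core perfusion, fraction of baseline.
#' @param penumbra_width width of the penumbral annulus around the core, px.
#' @param penumbra_perfusion pre-reperfusion penumbra perfusion, fraction of
#'   baseline; must exceed `core_perfusion` and be below 1.
#' @param baseline healthy parenchyma intensity, arbitrary perfusion units.
#' @param noise_sd additive Gaussian noise SD, same units (perfusion frames
#'   are truncated at zero).
#' @param frame_rate frames per second.
#' @param duration recording length, seconds.
#' @param occlusion_frame,injection_frame,reperfusion_frame 1-based frame
#'   indices of the events; strictly increasing and within the recording.
#'   Frames before `occlusion_frame` are fully perfused.
#' @param recovery per-region reperfusion kinetics: a list with elements
#'   `core`, `penumbra`, `normal`, each `list(plateau=, tau=)` — the plateau
#'   perfusion (fraction of baseline) and exponential time constant (s).
#' @param seed integer RNG seed; identical spec + seed reproduce the stack
#'   bit for bit.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_perfusion_phantom()], [generate_hemoglobin_phantom()]
#' @export
phantom_spec <- function(height = 64, width = 96, pixel_size = 0.1,
                         margin = 2, midline = NULL,
                         ischemic_side = c("left", "right"),
                         n_vessels = 2, vessel_width = 2,
                         vessel_multiplier = 3,
                         core_center = NULL, core_semiaxes = c(16, 12),
                         core_perfusion = 0.2,
                         penumbra_width = 6, penumbra_perfusion = 0.5,
                         baseline = 100, noise_sd = 2,
                         frame_rate = 1, duration = 900,
                         occlusion_frame = 1, injection_frame = 241,
                         reperfusion_frame = 481,
                         recovery = list(
                           core = list(plateau = 0.6, tau = 120),
                           penumbra = list(plateau = 0.9, tau = 90),
                           normal = list(plateau = 1.0, tau = 60)),
                         seed = 1L) {
  ischemic_side <- match.arg(ischemic_side)
  if (is.null(midline)) midline <- width %/% 2L
  n_frames <- as.integer(round(duration * frame_rate))

  check_number(height, "height", lower = 8)
  check_number(width, "width", lower = 8)
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(core_perfusion, "core_perfusion", lower = 0, upper = 1)
  check_number(penumbra_perfusion, "penumbra_perfusion", lower = 0, upper = 1)
  if (!(core_perfusion < penumbra_perfusion && penumbra_perfusion < 1)) {
    stopf("invariant violated: need core_perfusion < penumbra_perfusion < 1 (got %g, %g)",
          core_perfusion, penumbra_perfusion)
  }
  check_number(vessel_multiplier, "vessel_multiplier", lower = 1,
               strict_lower = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(baseline, "baseline", lower = 0, strict_lower = TRUE)
  ev <- c(occlusion_frame, injection_frame, reperfusion_frame)
  if (any(diff(ev) <= 0)) {
    stopf("invariant violated: event frames must be strictly increasing (got %s)",
          paste(ev, collapse = ", "))
  }
  if (ev[1] < 1 || ev[3] > n_frames) {
    stopf("invariant violated: event frames must lie within 1..%d", n_frames)
  }
  for (rg in c("core", "penumbra", "normal")) {
    if (is.null(recovery[[rg]]) ||
        !all(c("plateau", "tau") %in% names(recovery[[rg]]))) {
      stopf("invariant violated: recovery$%s must provide plateau and tau", rg)
    }
    check_number(recovery[[rg]]$plateau, paste0("recovery$", rg, "$plateau"),
                 lower = 0, upper = 1)
    check_number(recovery[[rg]]$tau, paste0("recovery$", rg, "$tau"),
                 lower = 0, strict_lower = TRUE)
  }

  # hemisphere column range on the ischemic side
  cols <- if (ischemic_side == "left") c(margin + 1L, midline) else
    c(midline + 1L, width - margin)
  rows <- c(margin + 1L, height - margin)
  if (is.null(core_center)) {
    core_center <- c(round(mean(rows)), round(mean(cols)))
  }
  reach <- core_semiaxes + penumbra_width
  if (core_center[1] - reach[1] < rows[1] || core_center[1] + reach[1] > rows[2] ||
      core_center[2] - reach[2] < cols[1] || core_center[2] + reach[2] > cols[2]) {
    stopf("invariant violated: core ellipse plus penumbra (semi-axes %d+%d, %d+%d px) does not fit inside the ischemic hemisphere",
          core_semiaxes[1], penumbra_width, core_semiaxes[2], penumbra_width)
  }

  structure(
    list(height = as.integer(height), width = as.integer(width),
         pixel_size = pixel_size, margin = as.integer(margin),
         midline = as.integer(midline), ischemic_side = ischemic_side,
         n_vessels = as.integer(n_vessels),
         vessel_width = as.integer(vessel_width),
         vessel_multiplier = vessel_multiplier,
         core_center = as.numeric(core_center),
         core_semiaxes = as.numeric(core_semiaxes),
         core_perfusion = core_perfusion,
         penumbra_width = as.integer(penumbra_width),
         penumbra_perfusion = penumbra_perfusion,
         baseline = baseline, noise_sd = noise_sd,
         frame_rate = frame_rate, duration = duration,
         n_frames = n_frames,
         occlusion_frame = as.integer(occlusion_frame),
         injection_frame = as.integer(injection_frame),
         reperfusion_frame = as.integer(reperfusion_frame),
         recovery = recovery, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %d x %d px, %d frames @ %g fps; ischemic side %s\n",
              x$height, x$width, x$n_frames, x$frame_rate, x$ischemic_side))
  cat(sprintf("  core %.2f / penumbra %.2f of baseline %g; noise SD %g; seed %d\n",
              x$core_perfusion, x$penumbra_perfusion, x$baseline, x$noise_sd,
              x$seed))
  invisible(x)
}

#' Core semi-axes that occupy a target fraction of the hemisphere
#'
#' Convenience for building phantoms whose true ischemic core covers a given
#' fraction of the ischemic-hemisphere parenchyma (the quantity the core
#' tracker reports). Solves `pi * a * b = fraction * hemisphere_area` for an
#' ellipse with a fixed row/col aspect ratio.
#'
#' @param fraction target core fraction of the hemisphere, in (0, 1).
#' @param height,width,margin,midline field geometry as in [phantom_spec()].
#' @param aspect row semi-axis over column semi-axis.
#' @return Numeric `(row semi-axis, col semi-axis)` in pixels.
#' @export
core_semiaxes_for_fraction <- function(fraction, height = 64, width = 96,
                                       margin = 2, midline = NULL,
                                       aspect = 4 / 3) {
  check_number(fraction, "fraction", 0, 1, TRUE, TRUE)
  if (is.null(midline)) midline <- width %/% 2L
  hemi_area <- (height - 2 * margin) * (midline - margin)
  b <- sqrt(fraction * hemi_area / (pi * aspect))
  c(aspect * b, b)
}

# -- internal geometry builders ----------------------------------------------

phantom_labels <- function(spec) {
  lab <- matrix(0L, spec$height, spec$width)
  rows <- (spec$margin + 1L):(spec$height - spec$margin)
  lcols <- (spec$margin + 1L):spec$midline
  rcols <- (spec$midline + 1L):(spec$width - spec$margin)
  if (spec$ischemic_side == "left") {
    lab[rows, lcols] <- 2L; lab[rows, rcols] <- 1L
  } else {
    lab[rows, lcols] <- 1L; lab[rows, rcols] <- 2L
  }
  lab
}

# Straight near-vertical bright strips crossing the brain; placement is
# seeded so the mask is part of the reproducible phantom.
phantom_vessels <- function(spec, labels) {
  mask <- matrix(FALSE, spec$height, spec$width)
  if (spec$n_vessels < 1L) return(mask)
  rows <- (spec$margin + 1L):(spec$height - spec$margin)
  brain_cols <- c(spec$margin + 1L, spec$width - spec$margin)
  x0 <- runif(spec$n_vessels, brain_cols[1], brain_cols[2])
  slope <- tan(runif(spec$n_vessels, -pi / 6, pi / 6))
  for (v in seq_len(spec$n_vessels)) {
    centre <- x0[v] + slope[v] * (rows - rows[1])
    for (i in seq_along(rows)) {
      c1 <- max(brain_cols[1], round(centre[i]))
      c2 <- min(brain_cols[2], c1 + spec$vessel_width - 1L)
      if (c1 <= c2) mask[rows[i], c1:c2] <- TRUE
    }
  }
  mask & labels > 0L
}

ellipse_mask <- function(height, width, center, semiaxes) {
  r <- matrix(seq_len(height), height, width)
  c <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((r - center[1]) / semiaxes[1])^2 + ((c - center[2]) / semiaxes[2])^2 <= 1
}

phantom_region_masks <- function(spec, labels, vessels) {
  core_ell <- ellipse_mask(spec$height, spec$width, spec$core_center,
                           spec$core_semiaxes)
  outer_ell <- ellipse_mask(spec$height, spec$width, spec$core_center,
                            spec$core_semiaxes + spec$penumbra_width)
  isch <- labels == 2L & !vessels
  list(core = core_ell & isch,
       penumbra = outer_ell & !core_ell & isch,
       normal = isch & !outer_ell)
}

# Programmed perfusion (fraction of baseline) for one region over the frame
# times: 1 before occlusion, the deficit level during occlusion, then
# exponential relaxation toward the plateau after reperfusion.
region_time_course <- function(deficit, plateau, tau, times, t_occ, t_rep) {
  f <- ifelse(times < t_occ, 1, deficit)
  post <- times >= t_rep
  f[post] <- plateau + (deficit - plateau) * exp(-(times[post] - t_rep) / tau)
  f
}

phantom_time_courses <- function(spec) {
  times <- (seq_len(spec$n_frames) - 1) / spec$frame_rate
  t_occ <- (spec$occlusion_frame - 1) / spec$frame_rate
  t_rep <- (spec$reperfusion_frame - 1) / spec$frame_rate
  rec <- spec$recovery
  list(times = times,
       core = region_time_course(spec$core_perfusion, rec$core$plateau,
                                 rec$core$tau, times, t_occ, t_rep),
       penumbra = region_time_course(spec$penumbra_perfusion,
                                     rec$penumbra$plateau, rec$penumbra$tau,
                                     times, t_occ, t_rep),
       normal = region_time_course(1, rec$normal$plateau, rec$normal$tau,
                                   times, t_occ, t_rep))
}

#' Generate a perfusion phantom with ground truth
#'
#' Renders the field described by a [phantom_spec()] into a flow
#' [perfusion_stack()]: healthy parenchyma at the baseline intensity, core
#' and penumbra at their programmed fractions of baseline during occlusion,
#' exponential recovery after reperfusion, vessels at
#' `baseline * vessel_multiplier` throughout, plus additive Gaussian noise
#' truncated at zero. The returned ground truth carries the hemisphere
#' label map, the vessel mask, the true core/penumbra/normal masks (which
#' partition the ischemic-hemisphere parenchyma), the true core-fraction
#' time series and the true relative region traces.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `stack` ([perfusion_stack()]), `geometry`
#'   ([hemisphere_geometry()]) and `truth` (class `phantom_truth`).
#' @export
generate_perfusion_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    labels <- phantom_labels(spec)
    vessels <- phantom_vessels(spec, labels)
    regions <- phantom_region_masks(spec, labels, vessels)
    tc <- phantom_time_courses(spec)

    # region code per pixel: 1 bg, 2 healthy, 3 core, 4 penumbra,
    # 5 normal-ischemic, 6 vessel
    code <- matrix(1L, spec$height, spec$width)
    code[labels == 1L] <- 2L
    code[regions$core] <- 3L
    code[regions$penumbra] <- 4L
    code[regions$normal] <- 5L
    code[vessels] <- 6L

    frames <- array(0, dim = c(spec$height, spec$width, spec$n_frames))
    for (t in seq_len(spec$n_frames)) {
      lut <- c(0, spec$baseline,
               spec$baseline * tc$core[t],
               spec$baseline * tc$penumbra[t],
               spec$baseline * tc$normal[t],
               spec$baseline * spec$vessel_multiplier)
      frames[, , t] <- lut[code]
    }
    if (spec$noise_sd > 0) {
      brain <- code > 1L
      noise <- array(rnorm(length(frames), sd = spec$noise_sd), dim = dim(frames))
      noise[array(!brain, dim = dim(frames))] <- 0
      frames <- pmax(frames + noise, 0)
    }

    truth <- phantom_truth(spec, labels, vessels, regions, tc,
                           signals = list(flow = tc))
    stack <- perfusion_stack(frames, timestamps = tc$times,
                             injection_frame = spec$injection_frame,
                             reperfusion_frame = spec$reperfusion_frame,
                             pixel_size = spec$pixel_size, signal = "flow")
    list(stack = stack,
         geometry = hemisphere_geometry(labels, spec$ischemic_side),
         truth = truth)
  })
}

phantom_truth <- function(spec, labels, vessels, regions, flow_tc, signals) {
  parenchyma <- sum(labels == 2L & !vessels)
  n_core <- sum(regions$core); n_pen <- sum(regions$penumbra)
  n_norm <- sum(regions$normal)
  frac <- (n_core * (flow_tc$core < 0.33) +
           n_pen * (flow_tc$penumbra < 0.33) +
           n_norm * (flow_tc$normal < 0.33)) / parenchyma
  traces <- do.call(rbind, lapply(names(signals), function(sig) {
    tc <- signals[[sig]]
    do.call(rbind, lapply(c("core", "penumbra", "normal"), function(rg) {
      data.frame(time_s = tc$times, signal = sig, region = rg,
                 value = tc[[rg]] / tc[[rg]][1])
    }))
  }))
  structure(
    list(labels = labels, vessel_mask = vessels,
         core = regions$core, penumbra = regions$penumbra,
         normal = regions$normal,
         core_fraction = data.frame(frame = seq_along(frac),
                                    time_s = flow_tc$times, fraction = frac),
         region_traces = traces, spec = spec),
    class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> core %d px, penumbra %d px, normal %d px, vessels %d px\n",
              sum(x$core), sum(x$penumbra), sum(x$normal), sum(x$vessel_mask)))
  invisible(x)
}

#' Generate an oxy-/deoxyhemoglobin phantom with ground truth
#'
#' Renders signed hemoglobin concentration signals on the same geometry as
#' the perfusion phantom. Each region follows a programmed step during
#' occlusion and a single-exponential relaxation toward a plateau after
#' reperfusion, expressed as fractions of a resting hemoglobin level so the
#' downstream "scale to start at 1" convention applies directly. By default
#' the deoxyhemoglobin dynamics mirror the oxyhemoglobin dynamics about the
#' resting level (oxy up means deoxy down), as in cortical ischemia.
#'
#' @param spec a [phantom_spec()] (geometry, events, noise and seed are
#'   shared with the flow phantom).
#' @param oxy_dynamics per-region oxyhemoglobin programme: list with
#'   `core`, `penumbra`, `normal`, each `list(deficit=, plateau=, tau=)`
#'   in fractions of the resting level / seconds.
#' @param hb_baseline resting hemoglobin signal level (arbitrary
#'   concentration units).
#' @param mirror_deoxy if `TRUE`, deoxy dynamics are `2 - oxy` (mirror about
#'   rest); otherwise supply `deoxy_dynamics`.
#' @param deoxy_dynamics as `oxy_dynamics`, used when `mirror_deoxy = FALSE`.
#' @return A list with `oxy` and `deoxy` ([perfusion_stack()]s), `geometry`
#'   and `truth`; the truth's `region_traces` has one block per signal.
#' @export
generate_hemoglobin_phantom <- function(spec,
                                        oxy_dynamics = list(
                                          core = list(deficit = 0.6, plateau = 1.5, tau = 120),
                                          penumbra = list(deficit = 0.8, plateau = 1.2, tau = 90),
                                          normal = list(deficit = 1.0, plateau = 1.0, tau = 60)),
                                        hb_baseline = 50,
                                        mirror_deoxy = TRUE,
                                        deoxy_dynamics = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  check_number(hb_baseline, "hb_baseline", lower = 0, strict_lower = TRUE)
  tc_for <- function(dyn, times, t_occ, t_rep) {
    out <- list(times = times)
    for (rg in c("core", "penumbra", "normal")) {
      d <- dyn[[rg]]
      out[[rg]] <- region_time_course(d$deficit, d$plateau, d$tau,
                                      times, t_occ, t_rep)
    }
    out
  }
  with_seed(spec$seed, {
    labels <- phantom_labels(spec)
    vessels <- phantom_vessels(spec, labels)
    regions <- phantom_region_masks(spec, labels, vessels)
    times <- (seq_len(spec$n_frames) - 1) / spec$frame_rate
    t_occ <- (spec$occlusion_frame - 1) / spec$frame_rate
    t_rep <- (spec$reperfusion_frame - 1) / spec$frame_rate

    oxy_tc <- tc_for(oxy_dynamics, times, t_occ, t_rep)
    deoxy_tc <- if (mirror_deoxy) {
      m <- oxy_tc
      for (rg in c("core", "penumbra", "normal")) m[[rg]] <- 2 - oxy_tc[[rg]]
      m
    } else {
      if (is.null(deoxy_dynamics)) {
        stopf("deoxy_dynamics must be supplied when mirror_deoxy = FALSE")
      }
      tc_for(deoxy_dynamics, times, t_occ, t_rep)
    }

    code <- matrix(1L, spec$height, spec$width)
    code[labels == 1L] <- 2L
    code[regions$core] <- 3L
    code[regions$penumbra] <- 4L
    code[regions$normal] <- 5L
    code[vessels] <- 6L

    render <- function(tc, signal) {
      frames <- array(0, dim = c(spec$height, spec$width, spec$n_frames))
      for (t in seq_len(spec$n_frames)) {
        lut <- c(0, hb_baseline,
                 hb_baseline * tc$core[t], hb_baseline * tc$penumbra[t],
                 hb_baseline * tc$normal[t], hb_baseline)
        frames[, , t] <- lut[code]
      }
      if (spec$noise_sd > 0) {
        brain <- code > 1L
        noise <- array(rnorm(length(frames), sd = spec$noise_sd),
                       dim = dim(frames))
        noise[array(!brain, dim = dim(frames))] <- 0
        frames <- frames + noise   # hemoglobin signals are signed
      }
      perfusion_stack(frames, timestamps = times,
                      injection_frame = spec$injection_frame,
                      reperfusion_frame = spec$reperfusion_frame,
                      pixel_size = spec$pixel_size, signal = signal)
    }
    oxy <- render(oxy_tc, "oxyHb")
    deoxy <- render(deoxy_tc, "deoxyHb")

    flow_tc <- phantom_time_courses(spec)
    truth <- phantom_truth(spec, labels, vessels, regions, flow_tc,
                           signals = list(oxyHb = oxy_tc, deoxyHb = deoxy_tc))
    list(oxy = oxy, deoxy = deoxy,
         geometry = hemisphere_geometry(labels, spec$ischemic_side),
         truth = truth)
  })
}

#' Generate serial cross-section areas of a known solid
#'
#' Produces exact analytic cross-sectional areas of a cylinder or sphere on
#' equidistant section planes, together with the analytic volume — the
#' oracle for the Cavalieri estimator. Planes default to the systematic
#' midpoint design (first plane at half a spacing into the object); set
#' `random_start = TRUE` for the classical uniform random start on `[0, d)`.
#'
#' @param shape `"cylinder"` or `"sphere"`.
#' @param radius radius, mm.
#' @param length cylinder length, mm (ignored for spheres).
#' @param d section spacing, mm (> 0).
#' @param random_start use a uniform random start instead of the midpoint
#'   offset.
#' @param seed RNG seed for the random start.
#' @return List with `series` (a [section_series()]), `volume` (analytic,
#'   mm^3) and `planes` (section positions, mm).
#' @export
generate_section_series <- function(shape = c("cylinder", "sphere"),
                                    radius = 1, length = 3, d = 0.6,
                                    random_start = FALSE, seed = NULL) {
  shape <- match.arg(shape)
  check_number(radius, "radius", lower = 0, strict_lower = TRUE)
  check_number(d, "d", lower = 0, strict_lower = TRUE)
  extent <- switch(shape, cylinder = {
    check_number(length, "length", lower = 0, strict_lower = TRUE)
    c(0, length)
  }, sphere = c(-radius, radius))
  if (d > diff(extent)) {
    stopf("invariant violated: spacing d = %g exceeds the object extent %g",
          d, diff(extent))
  }
  offset <- if (random_start) with_seed(seed, runif(1, 0, d)) else d / 2
  planes <- seq(extent[1] + offset, extent[2], by = d)
  planes <- planes[planes < extent[2]]
  areas <- switch(shape,
                  cylinder = rep(pi * radius^2, length(planes)),
                  sphere = pi * pmax(radius^2 - planes^2, 0))
  volume <- switch(shape,
                   cylinder = pi * radius^2 * length,
                   sphere = 4 / 3 * pi * radius^3)
  list(series = section_series(areas, d), volume = volume, planes = planes)
}

#' Generate a two-channel IHC phantom (vessels + IgG leak)
#'
#' Builds a CD31 (endothelium) / IgG co-staining phantom: the field is split
#' into infarct, penumbra and healthy bands; each band receives vertical
#' vessel strips up to a target area density, and an IgG-positive pixel set
#' sized as a programmed fraction of that band's vessel area. Three ROIs per
#' band are laid out, and the ground truth stores, over each band's ROI
#' union, the exact positive pixel counts and the IgG/CD31 area ratio the
#' quantification pipeline should recover.
#'
#' @param height,width image size, px.
#' @param pixel_size mm per pixel.
#' @param vessel_density target CD31-positive area fraction per band.
#' @param leak_fraction named fractions (of CD31 area) of IgG-positive area
#'   for `infarct`, `penumbra`, `healthy`.
#' @param noise_sd Gaussian background noise SD on both channels (positive
#'   pixels have intensity 1, background 0).
#' @param seed RNG seed.
#' @return List with `image` (class `two_channel_image`), `rois`
#'   (a [roi_set()]) and `truth` (per-region pixel counts and ratios plus
#'   the exact channel masks).
#' @export
generate_ihc_image <- function(height = 90, width = 240, pixel_size = 0.02,
                               vessel_density = 0.12,
                               leak_fraction = c(infarct = 0.5,
                                                 penumbra = 0.3,
                                                 healthy = 0.05),
                               noise_sd = 0, seed = 1L) {
  regions <- c("infarct", "penumbra", "healthy")
  if (!all(regions %in% names(leak_fraction))) {
    stopf("leak_fraction must be named for %s", paste(regions, collapse = ", "))
  }
  for (rg in regions) {
    check_number(leak_fraction[[rg]], paste0("leak_fraction$", rg), 0, 1)
  }
  with_seed(seed, {
    cd31 <- matrix(FALSE, height, width)
    igg <- matrix(FALSE, height, width)
    band_w <- width %/% 3L
    bands <- list(infarct = 1:band_w,
                  penumbra = (band_w + 1L):(2L * band_w),
                  healthy = (2L * band_w + 1L):width)
    for (rg in regions) {
      cols <- bands[[rg]]
      target <- round(vessel_density * height * length(cols))
      # vertical vessel strips of width 2 until the band reaches its density
      while (sum(cd31[, cols]) < target) {
        c0 <- sample(cols[-length(cols)], 1L)
        cd31[, c0:(c0 + 1L)] <- TRUE
      }
      n_leak <- round(leak_fraction[[rg]] * sum(cd31[, cols]))
      if (n_leak > 0) {
        idx <- which(!igg[, cols])
        pick <- sample(idx, min(n_leak, length(idx)))
        sub <- igg[, cols]; sub[pick] <- TRUE; igg[, cols] <- sub
      }
    }

    # three ROIs per band, vertically stacked in the band's center
    roi_h <- height %/% 4L
    roi_w <- band_w - 8L
    rois <- do.call(rbind, lapply(regions, function(rg) {
      col0 <- bands[[rg]][1] + 4L
      data.frame(label = rg,
                 row = c(1L, roi_h + 3L, 2L * roi_h + 5L),
                 col = col0, height = roi_h, width = roi_w)
    }))
    rois <- roi_set(rois)

    truth <- do.call(rbind, lapply(regions, function(rg) {
      sel <- rois$rois[rois$rois$label == rg, ]
      in_union <- matrix(FALSE, height, width)
      for (i in seq_len(nrow(sel))) {
        in_union[sel$row[i]:(sel$row[i] + sel$height[i] - 1L),
                 sel$col[i]:(sel$col[i] + sel$width[i] - 1L)] <- TRUE
      }
      n_cd31 <- sum(cd31 & in_union); n_igg <- sum(igg & in_union)
      data.frame(region = rg, cd31_px = n_cd31, igg_px = n_igg,
                 ratio = if (n_cd31 > 0) n_igg / n_cd31 else NA_real_)
    }))

    mk <- function(mask) {
      img <- matrix(0, height, width)
      img[mask] <- 1
      if (noise_sd > 0) img <- pmax(img + matrix(rnorm(length(img), sd = noise_sd), height, width), 0)
      img
    }
    image <- two_channel_image(cd31 = mk(cd31), igg = mk(igg),
                               pixel_size = pixel_size)
    list(image = image, rois = rois,
         truth = list(regions = truth, cd31_mask = cd31, igg_mask = igg))
  })
}

#' Generate an EV-homing fluorescence phantom
#'
#' Whole-brain fluorescence scan after injection of labeled extracellular
#' vesicles: two hemispheres with programmed mean intensities plus Gaussian
#' noise (truncated at zero), and paired equal-area square ROIs — 1 mm^2 by
#' default, mirrored across the midline — in the territory of the middle
#' cerebral artery. Ground truth is the programmed ischemic/healthy
#' intensity ratio.
#'
#' @param height,width image size, px.
#' @param pixel_size mm per pixel (default 0.02 mm = 20 um scan resolution).
#' @param mean_healthy,mean_ischemic hemisphere mean intensities.
#' @param noise_sd Gaussian noise SD.
#' @param n_rois paired ROIs per hemisphere.
#' @param roi_area_mm2 area of each square ROI, mm^2.
#' @param seed RNG seed.
#' @return List with `image` (matrix), `rois` (a [roi_set()] with labels
#'   `ischemic` / `healthy`), `pixel_size` and `truth` (programmed ratio).
#' @export
generate_homing_image <- function(height = 120, width = 220,
                                  pixel_size = 0.02,
                                  mean_healthy = 100, mean_ischemic = 200,
                                  noise_sd = 10, n_rois = 4,
                                  roi_area_mm2 = 1, seed = 1L) {
  check_number(mean_healthy, "mean_healthy", lower = 0, strict_lower = TRUE)
  check_number(mean_ischemic, "mean_ischemic", lower = 0)
  side <- round(sqrt(roi_area_mm2) / pixel_size)
  half <- width %/% 2L
  if (side + 2L > half || side + 2L > height) {
    stopf("ROI side %d px does not fit the %d x %d field", side, height, width)
  }
  with_seed(seed, {
    img <- matrix(mean_healthy, height, width)
    img[, (half + 1L):width] <- mean_ischemic
    if (noise_sd > 0) {
      img <- pmax(img + matrix(rnorm(length(img), sd = noise_sd),
                               height, width), 0)
    }
    # paired ROIs mirrored across the midline, stacked with small jitter-free
    # systematic spacing
    rows <- round(seq(1, height - side, length.out = n_rois))
    col_h <- max(1L, (half - side) %/% 2L)
    col_i <- half + col_h
    rois <- rbind(
      data.frame(label = "healthy", row = rows, col = col_h,
                 height = side, width = side),
      data.frame(label = "ischemic", row = rows, col = col_i,
                 height = side, width = side))
    list(image = img, rois = roi_set(rois), pixel_size = pixel_size,
         truth = list(ratio = mean_ischemic / mean_healthy))
  })
}

#' Generate behavioral trial tables with programmed group effects
#'
#' Simulates the behavioral battery of a tMCAO efficacy study: Hargreaves
#' paw-withdrawal latencies (five trials per paw per session), corner-test
#' turn sequences (ten trials per session) and daily five-point neuroscores,
#' for several treatment groups with programmable effect sizes.
#'
#' Latencies are Gaussian about `latency_mean` (truncated at 0.1 s); the
#' stroke adds `latency_effect[group]` seconds to the affected (right) paw
#' post-surgery. The post-surgery right-turn probability is
#' `p_right[group]` (0.5 pre-surgery). Neuroscores are drawn from
#' `score_probs[[group]]` over scores 0..4.
#'
#' @param n_per_group animals per group.
#' @param groups group labels; names of the effect vectors.
#' @param latency_mean,latency_sd baseline Hargreaves latency mean/SD, s.
#' @param latency_effect named per-group added latency on the affected paw
#'   post-surgery, s.
#' @param p_right named per-group post-surgery right-turn probability.
#' @param score_probs named list of per-group probabilities over scores 0:4.
#' @param seed RNG seed.
#' @return List of data frames `hargreaves` (animal, group, day, paw, trial,
#'   latency_s), `corner` (animal, group, day, trial, turn) and `neuroscore`
#'   (animal, group, day, score).
#' @export
generate_behavior_dataset <- function(n_per_group = 12,
                                      groups = c("vehicle", "preEV", "postEV"),
                                      latency_mean = 5, latency_sd = 1,
                                      latency_effect = c(vehicle = 3,
                                                         preEV = 2.5,
                                                         postEV = 1.5),
                                      p_right = c(vehicle = 0.8,
                                                  preEV = 0.75,
                                                  postEV = 0.65),
                                      score_probs = NULL,
                                      seed = 1L) {
  if (is.null(score_probs)) {
    score_probs <- stats::setNames(
      rep(list(c(0.05, 0.35, 0.35, 0.2, 0.05)), length(groups)), groups)
  }
  stopifnot(all(groups %in% names(latency_effect)),
            all(groups %in% names(p_right)),
            all(groups %in% names(score_probs)))
  with_seed(seed, {
    animals <- data.frame(
      animal = sprintf("m%03d", seq_len(n_per_group * length(groups))),
      group = rep(groups, each = n_per_group))
    rlat <- function(n, mu) pmax(rnorm(n, mu, latency_sd), 0.1)
    harg <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
      g <- animals$group[i]
      do.call(rbind, lapply(c(0, 7), function(day) {
        do.call(rbind, lapply(c("left", "right"), function(paw) {
          mu <- latency_mean +
            if (day > 0 && paw == "right") latency_effect[[g]] else 0
          data.frame(animal = animals$animal[i], group = g, day = day,
                     paw = paw, trial = 1:5, latency_s = rlat(5, mu))
        }))
      }))
    }))
    corner <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
      g <- animals$group[i]
      do.call(rbind, lapply(c(0, 3), function(day) {
        p <- if (day == 0) 0.5 else p_right[[g]]
        data.frame(animal = animals$animal[i], group = g, day = day,
                   trial = 1:10,
                   turn = ifelse(stats::runif(10) < p, "R", "L"))
      }))
    }))
    score <- do.call(rbind, lapply(seq_len(nrow(animals)), function(i) {
      g <- animals$group[i]
      data.frame(animal = animals$animal[i], group = g, day = 1,
                 score = sample(0:4, 1, prob = score_probs[[g]]))
    }))
    rownames(harg) <- rownames(corner) <- rownames(score) <- NULL
    list(hargreaves = harg, corner = corner, neuroscore = score)
  })
}
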