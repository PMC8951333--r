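test_that("minute downsampling averages whole minutes and drops partials", {
  n <- 240
  frames <- array(rep(1, 4 * 6 * n), dim = c(4, 6, n))
  st <- perfusion_stack(frames, timestamps = seq_len(n) - 1,
                        injection_frame = 10, reperfusion_frame = 100)
  ds <- downsample_to_minutes(st)
  expect_equal(dim(ds$frames)[3], 4)          # 240 frames at 1 fps -> 4
  expect_true(all(ds$frames == 1))            # mean of constants

  # one pixel counts 0..59 in its minute -> 29.5
  frames2 <- array(0, dim = c(2, 2, 130))
  frames2[1, 1, 1:60] <- 0:59
  st2 <- perfusion_stack(frames2, timestamps = 0:129,
                         injection_frame = 5, reperfusion_frame = 90)
  ds2 <- downsample_to_minutes(st2)
  expect_equal(dim(ds2$frames)[3], 2)         # trailing 10 frames dropped
  expect_equal(ds2$frames[1, 1, 1], 29.5)

  # event indices remapped to the containing minute
  expect_equal(ds2$reperfusion_frame, 2)      # 89 s lies in minute 2
  expect_error(downsample_to_minutes(
    perfusion_stack(array(1, c(2, 2, 30)), 0:29, 1, 20)),
    "whole minute")
})

test_that("downsampled frames equal brute-force minute means bit-exactly on integers", {
  set.seed(1)
  n <- 180
  frames <- array(sample(0:500, 3 * 4 * n, replace = TRUE), dim = c(3, 4, n))
  st <- perfusion_stack(frames, timestamps = seq_len(n) - 1,
                        injection_frame = 30, reperfusion_frame = 120)
  ds <- downsample_to_minutes(st)
  for (m in 1:3) {
    brute <- apply(frames[, , ((m - 1) * 60 + 1):(m * 60)], c(1, 2), mean)
    expect_identical(ds$frames[, , m], brute)
  }
})

test_that("vessel detection thresholds the reference map at a percentile", {
  sp <- quick_spec(noise_sd = 2, seed = 5)
  ph <- generate_perfusion_phantom(sp)
  ds <- downsample_to_minutes(ph$stack)
  ref <- reference_map(ds)
  v95 <- detect_vessels(ref, ph$geometry, q = 95)
  truth <- ph$truth$vessel_mask
  parench <- ph$truth$labels > 0L & !truth
  expect_gte(sum(v95$mask & truth) / sum(truth), 0.90)
  expect_lte(sum(v95$mask & parench) / sum(parench), 0.02)

  v99 <- detect_vessels(ref, ph$geometry, q = 99)
  expect_true(all(v95$mask[v99$mask]))        # q = 99 mask nested in q = 95

  flat <- matrix(7, nrow(ref), ncol(ref))
  expect_warning(ve <- detect_vessels(flat, ph$geometry, q = 95), "constant")
  expect_false(any(ve$mask))
  expect_error(detect_vessels(ref, ph$geometry, q = 40), "50, 100")
})

test_that("baseline is the pre-reperfusion healthy-hemisphere parenchyma mean", {
  st <- flat_stack(healthy_vals = c(90, 110, 300),
                   ischemic_vals = c(20, 20, 80),
                   injection_frame = 1, reperfusion_frame = 3)
  geo <- flat_geometry()
  expect_equal(compute_baseline(st, geo, empty_vessels()), 100)

  # bright pixels under the vessel mask leave the baseline unchanged
  vm <- empty_vessels()
  vm$mask[1:2, 7] <- TRUE
  st2 <- st
  st2$frames[1:2, 7, ] <- 1e6
  expect_equal(compute_baseline(st2, geo, vm),
               compute_baseline(st, geo, vm))

  st3 <- flat_stack(c(100, 100), c(20, 20), injection_frame = 1,
                    reperfusion_frame = 2)
  st3$reperfusion_frame <- 1L
  expect_error(compute_baseline(st3, geo, empty_vessels()),
               "no frames before")
  expect_error(compute_baseline(
    perfusion_stack(st$frames, st$timestamps, 1, 3, signal = "oxyHb"),
    geo, empty_vessels()), "flow")
})

test_that("core/penumbra/normal intervals tile with boundaries in the penumbra", {
  cls <- classify_perfusion(c(32.9, 33.0, 70.0, 70.1), baseline = 100)
  expect_equal(cls, c("core", "penumbra", "penumbra", "normal"))
  expect_error(classify_perfusion(1, baseline = 0), "baseline")
  expect_error(classify_perfusion(1, 100, theta_core = 0.8,
                                  theta_normal = 0.7), "theta_core")
})

test_that("region masks partition the parenchyma and match phantom truth", {
  sp <- quick_spec(noise_sd = 2, seed = 9)
  ph <- generate_perfusion_phantom(sp)
  res <- analyze_hemodynamics(ph$stack, ph$geometry)
  m <- res$masks
  parench <- ph$truth$labels == 2L & !res$vessels$mask
  expect_false(any(m$core & m$penumbra))
  expect_false(any(m$core & m$normal))
  expect_false(any(m$penumbra & m$normal))
  expect_identical(m$core | m$penumbra | m$normal, parench)
  for (rg in c("core", "penumbra", "normal")) {
    expect_gte(jaccard(m[[rg]] & !ph$truth$vessel_mask, ph$truth[[rg]]), 0.95)
  }

  # uniform flow at baseline -> everything normal
  stf <- flat_stack(c(100, 100, 100), c(100, 100, 100))
  mm <- build_region_masks(stf, flat_geometry(), empty_vessels(), 100)
  expect_false(any(mm$core))
  expect_false(any(mm$penumbra))
  expect_identical(mm$normal, ischemic <- flat_geometry()$labels == 2L)
  expect_error(build_region_masks(stf, flat_geometry(), empty_vessels(), 0),
               "baseline")
})

test_that("raising the core threshold never shrinks the core mask", {
  sp <- quick_spec(noise_sd = 2, seed = 13)
  ph <- generate_perfusion_phantom(sp)
  ds <- downsample_to_minutes(ph$stack)
  vs <- detect_vessels(reference_map(ds), ph$geometry)
  B <- compute_baseline(ds, ph$geometry, vs)
  last <- NULL
  for (th in c(0.2, 0.33, 0.5, 0.65)) {
    m <- build_region_masks(ds, ph$geometry, vs, B, theta_core = th)
    if (!is.null(last)) expect_true(all(m$core[last]))
    last <- m$core
  }
})

test_that("core tracking reports the hemisphere fraction below threshold", {
  sp <- quick_spec(noise_sd = 0, core_perfusion = 0.2, seed = 3)
  ph <- generate_perfusion_phantom(sp)
  ds <- downsample_to_minutes(ph$stack)
  vs <- detect_vessels(reference_map(ds), ph$geometry)
  B <- compute_baseline(ds, ph$geometry, vs)
  ct <- track_core(ds, ph$geometry, vs, B)
  truth_frac <- sum(ph$truth$core) /
    sum(ph$truth$labels == 2L & !ph$truth$vessel_mask)
  pre <- ct$time_min < 0
  expect_equal(ct$fraction[pre], rep(truth_frac, sum(pre)), tolerance = 1e-12)
  expect_true(all(ct$fraction >= 0 & ct$fraction <= 1))

  # core perfusion stepping from 0.2 to a 0.6 plateau empties the core
  expect_lt(tail(ct$fraction, 1), 0.01)
})

test_that("deepening the penumbra deficit never decreases per-frame core counts", {
  base <- quick_spec(noise_sd = 2, penumbra_perfusion = 0.5, seed = 21)
  deep <- quick_spec(noise_sd = 2, penumbra_perfusion = 0.3, seed = 21)
  track_of <- function(sp) {
    ph <- generate_perfusion_phantom(sp)
    ds <- downsample_to_minutes(ph$stack)
    vs <- detect_vessels(reference_map(ds), ph$geometry)
    track_core(ds, ph$geometry, vs, compute_baseline(ds, ph$geometry, vs))
  }
  expect_true(all(track_of(deep)$count >= track_of(base)$count))
})

test_that("every extracted trace starts at exactly 1 and recovers plateaus", {
  sp <- phantom_spec(noise_sd = 0, duration = 1500, injection_frame = 241,
                     reperfusion_frame = 481)
  ph <- generate_perfusion_phantom(sp)
  res <- analyze_hemodynamics(ph$stack, ph$geometry)
  first <- tapply(seq_len(nrow(res$traces)),
                  interaction(res$traces$region, res$traces$signal, drop = TRUE),
                  function(i) res$traces$value[i[which.min(res$traces$time_min[i])]])
  expect_true(all(unlist(first) == 1))
  core <- res$traces[res$traces$region == "core", ]
  expect_equal(tail(core$value, 1),
               sp$recovery$core$plateau / sp$core_perfusion,
               tolerance = 0.02)

  # constant stack -> all traces identically 1
  stf <- flat_stack(rep(5, 4), rep(5, 4))
  mm <- list(core = flat_geometry()$labels == 2L)
  tr <- extract_region_traces(stf, mm, regions = "core")
  expect_true(all(tr$value == 1))
})

test_that("trace extraction rejects unscalable input and omits empty regions", {
  stf <- flat_stack(c(0, 1, 2), c(0, 1, 2))
  masks <- list(core = flat_geometry()$labels == 2L,
                penumbra = matrix(FALSE, 6, 8))
  expect_warning(expect_error(
    extract_region_traces(stf, masks, regions = c("penumbra", "core")),
    "cannot scale"), "empty")
})

test_that("arbitrary values under the vessel mask change no region statistic", {
  sp <- quick_spec(noise_sd = 2, seed = 17)
  ph <- generate_perfusion_phantom(sp)
  res <- analyze_hemodynamics(ph$stack, ph$geometry)
  ds <- downsample_to_minutes(ph$stack)
  vs <- res$vessels
  ds2 <- ds
  ds2$frames[array(vs$mask, dim = dim(ds2$frames))] <- 1e7
  B2 <- compute_baseline(ds2, ph$geometry, vs)
  expect_identical(B2, res$baseline)
  m2 <- build_region_masks(ds2, ph$geometry, vs, B2)
  expect_identical(m2$core, res$masks$core)
  expect_identical(m2$penumbra, res$masks$penumbra)
  ct2 <- track_core(ds2, ph$geometry, vs, B2)
  expect_identical(ct2$count, res$core_track$count)
  tr2 <- extract_region_traces(ds2, m2)
  expect_identical(tr2$value,
                   extract_region_traces(ds, res$masks)$value)
})
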