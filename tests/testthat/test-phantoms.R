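test_that("noiseless perfusion phantom reproduces programmed intensities exactly", {
  sp <- quick_spec(noise_sd = 0, core_perfusion = 0.2,
                   penumbra_perfusion = 0.5, baseline = 100)
  ph <- generate_perfusion_phantom(sp)
  pre <- ph$stack$frames[, , sp$reperfusion_frame - 1L]
  expect_true(all(pre[ph$truth$core] == 20))
  expect_true(all(pre[ph$truth$penumbra] == 50))
  expect_true(all(pre[ph$truth$normal] == 100))
  expect_true(all(pre[ph$truth$labels == 1L & !ph$truth$vessel_mask] == 100))
  expect_true(all(pre[ph$truth$vessel_mask] == 100 * sp$vessel_multiplier))
  expect_true(all(pre[ph$truth$labels == 0L] == 0))
})

test_that("identical spec and seed give bit-identical stacks", {
  sp <- quick_spec(seed = 42)
  a <- generate_perfusion_phantom(sp)
  b <- generate_perfusion_phantom(sp)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth$vessel_mask, b$truth$vessel_mask)
  c <- generate_perfusion_phantom(quick_spec(seed = 43))
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("ground-truth masks partition the ischemic-hemisphere parenchyma", {
  for (seed in 1:5) {
    ph <- generate_perfusion_phantom(quick_spec(seed = seed))
    tr <- ph$truth
    parenchyma <- tr$labels == 2L & !tr$vessel_mask
    expect_false(any(tr$core & tr$penumbra))
    expect_false(any(tr$core & tr$normal))
    expect_false(any(tr$penumbra & tr$normal))
    expect_identical(tr$core | tr$penumbra | tr$normal, parenchyma)
    expect_true(all(tr$core_fraction$fraction >= 0 &
                      tr$core_fraction$fraction <= 1))
  }
})

test_that("invalid phantom specs fail naming the violated invariant", {
  expect_error(quick_spec(core_perfusion = 0.6, penumbra_perfusion = 0.5),
               "core_perfusion < penumbra_perfusion")
  expect_error(quick_spec(penumbra_perfusion = 1.2), "penumbra_perfusion")
  expect_error(phantom_spec(duration = 300, injection_frame = 121,
                            reperfusion_frame = 121),
               "strictly increasing")
  expect_error(phantom_spec(duration = 300, injection_frame = 61,
                            reperfusion_frame = 400),
               "within 1..300", fixed = TRUE)
  expect_error(quick_spec(core_semiaxes = c(40, 40)), "does not fit")
  expect_error(quick_spec(vessel_multiplier = 1), "vessel_multiplier")
})

test_that("downstream segmentation recovers the programmed core from a noisy phantom", {
  sp <- quick_spec(noise_sd = 2, core_perfusion = 0.2, seed = 7)
  ph <- generate_perfusion_phantom(sp)
  res <- analyze_hemodynamics(ph$stack, ph$geometry)
  sens <- sum(res$masks$core & ph$truth$core) / sum(ph$truth$core)
  expect_gte(sens, 0.95)
})

test_that("hemoglobin phantom with zero dynamics yields constant traces", {
  flat <- list(deficit = 1, plateau = 1, tau = 60)
  sp <- quick_spec(noise_sd = 0)
  hb <- generate_hemoglobin_phantom(
    sp, oxy_dynamics = list(core = flat, penumbra = flat, normal = flat))
  tr <- extract_region_traces(
    list(downsample_to_minutes(hb$oxy), downsample_to_minutes(hb$deoxy)),
    hb$truth[c("core", "penumbra", "normal")])
  expect_true(all(tr$value == 1))
})

test_that("programmed oxyHb rise is recovered and mirrored deoxyHb anti-correlates", {
  sp <- phantom_spec(noise_sd = 0, duration = 1500, injection_frame = 241,
                     reperfusion_frame = 481)
  hb <- generate_hemoglobin_phantom(
    sp, oxy_dynamics = list(core = list(deficit = 1, plateau = 1.5, tau = 60),
                            penumbra = list(deficit = 1, plateau = 1.2, tau = 60),
                            normal = list(deficit = 1, plateau = 1, tau = 60)))
  tr <- extract_region_traces(
    list(downsample_to_minutes(hb$oxy), downsample_to_minutes(hb$deoxy)),
    hb$truth[c("core", "penumbra", "normal")])
  core_oxy <- tr$value[tr$region == "core" & tr$signal == "oxyHb"]
  core_deoxy <- tr$value[tr$region == "core" & tr$signal == "deoxyHb"]
  expect_equal(tail(core_oxy, 1), 1.5, tolerance = 0.02)
  expect_lt(cor(core_oxy[-1], core_deoxy[-1]), -0.9)
})

test_that("section-series generator returns exact analytic cross-sections", {
  cyl <- generate_section_series("cylinder", radius = 1, length = 3, d = 0.6)
  expect_equal(cyl$series$areas, rep(pi, 5))
  expect_equal(cyl$volume, 3 * pi)
  sph <- generate_section_series("sphere", radius = 1, d = 0.25)
  expect_equal(sph$series$areas, pi * (1 - sph$planes^2))
  expect_error(generate_section_series("cylinder", d = 0),
               "'d'")
})

test_that("IHC phantom leak fractions set the whole-band IgG/CD31 ratio", {
  zero <- generate_ihc_image(leak_fraction = c(infarct = 0, penumbra = 0,
                                               healthy = 0), seed = 2)
  expect_true(all(zero$truth$regions$igg_px == 0))
  expect_true(all(zero$truth$regions$ratio == 0))
  half <- generate_ihc_image(leak_fraction = c(infarct = 0.5, penumbra = 0.5,
                                               healthy = 0.5), seed = 2)
  band <- ncol(half$truth$cd31_mask) %/% 3
  for (i in 1:3) {
    cols <- ((i - 1) * band + 1):(i * band)
    nv <- sum(half$truth$cd31_mask[, cols])
    nl <- sum(half$truth$igg_mask[, cols])
    expect_equal(nl / nv, 0.5, tolerance = 1 / nv * 2)
  }
})

test_that("homing phantom programs the hemisphere intensity ratio", {
  eq <- generate_homing_image(mean_healthy = 100, mean_ischemic = 100,
                              noise_sd = 0, seed = 1)
  mf <- roi_mean_fluorescence(eq$image, eq$rois)
  r <- normalize_hemispheres(mf$mean_intensity[mf$label == "ischemic"],
                             mf$mean_intensity[mf$label == "healthy"])
  expect_identical(r$ratio, 1)
  dbl <- generate_homing_image(mean_healthy = 100, mean_ischemic = 200,
                               noise_sd = 0, seed = 1)
  mf2 <- roi_mean_fluorescence(dbl$image, dbl$rois)
  r2 <- normalize_hemispheres(mf2$mean_intensity[mf2$label == "ischemic"],
                              mf2$mean_intensity[mf2$label == "healthy"])
  expect_identical(r2$ratio, 2)
  expect_equal(dbl$truth$ratio, 2)
})

test_that("behavior generator realizes programmed group effects", {
  # no effect: post-surgery group means agree within sampling error
  flat <- generate_behavior_dataset(
    n_per_group = 40,
    latency_effect = c(vehicle = 2, preEV = 2, postEV = 2),
    p_right = c(vehicle = 0.7, preEV = 0.7, postEV = 0.7), seed = 11)
  sb <- summarize_behavior(flat$hargreaves, flat$corner)
  post <- sb$hargreaves[sb$hargreaves$day == 7 & sb$hargreaves$paw == "right", ]
  mns <- tapply(post$latency_s, post$group, mean)
  expect_lt(max(mns) - min(mns), 3 * 1 / sqrt(40) * 2)
  # law of large numbers on the corner test at n = 1000
  big <- generate_behavior_dataset(
    n_per_group = 1000, groups = "vehicle",
    latency_effect = c(vehicle = 2), p_right = c(vehicle = 0.8), seed = 3)
  sb2 <- summarize_behavior(corner = big$corner)
  day3 <- sb2$corner[sb2$corner$day == 3, ]
  expect_equal(mean(day3$right_freq), 0.8, tolerance = 0.01)
})
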