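test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_plots = 4), "at least 5")
  expect_error(sim_config(fis_probs = c(0.5, 0.5, 0.1, -0.05, -0.05)),
               "non-negative")
  expect_error(sim_config(fis_probs = c(0.3, 0.3, 0.3, 0.05, 0.06)), "sum to 1")
  expect_error(sim_config(canopy_temp_mean_c = rep(60, 5)), "cooler")
  expect_error(sim_config(canopy_ndvi_mean = rep(0.05, 5)), "NDVI")
  expect_error(sim_config(gsd_mm_ms = c(`20` = 50, `50` = 34.7, `80` = 55.6)),
               "increasing")
  expect_error(sim_config(band_gains = c(-1, 1, 1, 1, 1)), "positive")
})

test_that("generation is deterministic and draws FIS from the configured mix", {
  cfg <- small_config(n = 60, seed = 11)
  f1 <- generate_field(cfg)
  f2 <- generate_field(cfg)
  expect_identical(f1, f2)
  expect_equal(nrow(f1$manifest), 60)
  expect_true(all(f1$manifest$fis %in% 1:5))
  # FIS histogram within multinomial noise of the configured proportions
  counts <- tabulate(f1$manifest$fis, 5)
  expected <- 60 * cfg$fis_probs
  tol <- 3 * sqrt(60 * cfg$fis_probs * (1 - cfg$fis_probs))
  expect_true(all(abs(counts - expected) <= tol))
})

test_that("scenes have the promised structure", {
  fld <- small_field()
  for (sc in fld$scenes[1:5]) {
    expect_true(all(sc$reflectance >= 0 & sc$reflectance <= 1))
    expect_true(all(is.finite(sc$thermal)))
    expect_identical(dim(sc$truth_mask), dim(sc$reflectance)[1:2])
    expect_true(sc$fis %in% 1:5)
    # canopy cooler than background, greener than soil
    expect_lt(mean(sc$thermal[sc$thermal_class == 1]),
              mean(sc$thermal[sc$thermal_class != 1]))
    nd <- compute_ndvi(as_stack(sc))$ndvi
    expect_gt(mean(nd[sc$class_map == 1]), mean(nd[sc$class_map == 2]))
  }
})

test_that("zero-noise canopy NDVI equals the configured mean exactly", {
  fld <- noisefree_field()
  cfg <- fld$config
  for (sc in fld$scenes) {
    nd <- compute_ndvi(as_stack(sc), sc$truth_mask)
    expect_equal(nd$mean, cfg$canopy_ndvi_mean[sc$fis], tolerance = 1e-12)
    tm <- sc$thermal_class == 1
    expect_equal(mean(sc$thermal[tm]), cfg$canopy_temp_mean_c[sc$fis])
  }
})

test_that("zero canopy area yields degenerate all-background scenes", {
  cfg <- noisefree_config(n = 5, canopy_area_frac = rep(0, 5))
  fld <- generate_field(cfg)
  for (sc in fld$scenes) {
    expect_false(any(sc$truth_mask))
    expect_true(sc$degenerate)
  }
})

test_that("noise-free FIS ordering: hotter, browner, smaller at high FIS", {
  cfg <- sim_config(n_plots = 50, seed = 21, noise_sd_refl = 0,
                    noise_sd_thermal = 0, plot_sd_temp = 0, plot_sd_ndvi = 0,
                    plot_sd_area = 0,
                    fis_probs = rep(0.2, 5))  # balanced draw for group means
  fld <- generate_field(cfg)
  st <- t(sapply(fld$scenes, function(sc) {
    c(fis = sc$fis,
      temp = mean(sc$thermal[sc$thermal_class == 1]),
      ndvi = compute_ndvi(as_stack(sc), sc$truth_mask)$mean,
      area = sum(sc$truth_mask))
  }))
  by_fis <- apply(st[, -1], 2, function(v) tapply(v, st[, "fis"], mean))
  expect_true(all(diff(by_fis[, "temp"]) > 0))
  expect_true(all(diff(by_fis[, "ndvi"]) < 0))
  expect_true(all(diff(by_fis[, "area"]) < 0))
})

test_that("area-average resampling matches a brute-force overlap oracle", {
  set.seed(42)
  m <- matrix(rnorm(144), 12, 12)
  ratio <- 2.7
  out <- resample_area(m, ratio)
  # oracle: integrate unit input cells over each output footprint
  n_out <- floor(12 / ratio)
  oracle <- matrix(0, n_out, n_out)
  for (i in seq_len(n_out)) for (j in seq_len(n_out)) {
    acc <- 0; wt <- 0
    for (r in 1:12) for (cc in 1:12) {
      ov_r <- max(0, min(i * ratio, r) - max((i - 1) * ratio, r - 1))
      ov_c <- max(0, min(j * ratio, cc) - max((j - 1) * ratio, cc - 1))
      acc <- acc + ov_r * ov_c * m[r, cc]
      wt <- wt + ov_r * ov_c
    }
    oracle[i, j] <- acc / wt
  }
  expect_equal(out, oracle, tolerance = 1e-12)
  # block-mean special case
  expect_equal(resample_area(matrix(1:16, 4, 4), 2),
               matrix(c(3.5, 5.5, 11.5, 13.5), 2, 2), tolerance = 1e-12)
})

test_that("mixed pixels warm a cool canopy surrounded by hot soil", {
  m <- matrix(52, 12, 12)
  m[4:9, 4:9] <- 39
  coarse <- resample_area(m, 2.7)
  cmask <- resample_area((m == 39) * 1, 2.7) >= 0.5
  expect_gt(mean(coarse[cmask]), 39)
})

test_that("attenuation has its closed form on a constant raster", {
  cfg <- small_config(n = 5)
  fld <- generate_field(cfg)
  sc <- fld$scenes[[1]]
  sc$thermal[] <- 45
  out <- degrade_to_height(sc, 80, cfg)
  tau <- cfg$attenuation_tau[["80"]]
  expect_equal(unique(round(as.vector(out$thermal), 10)),
               round(tau * 45 + (1 - tau) * cfg$ambient_temp_c, 10))
})

test_that("degrading to 20 m is the identity and unknown heights error", {
  fld <- small_field()
  sc <- fld$scenes[[1]]
  expect_identical(degrade_to_height(sc, 20, fld$config), sc)
  expect_error(degrade_to_height(sc, 65, fld$config), "unknown")
})

test_that("height degradation reproduces the field-observed directions", {
  cfg <- small_config(n = 40, seed = 11)
  f20 <- generate_field(cfg)
  f50 <- degrade_field(f20, 50)
  f80 <- degrade_field(f20, 80)
  ft20 <- pipeline_features(f20)
  ft50 <- pipeline_features(f50)
  ft80 <- pipeline_features(f80)
  # apparent canopy temperature rises with height (mixed pixels + blur beat
  # attenuation); NDVI falls; nearly every plot individually follows suit
  expect_lt(mean(ft20$canopy_temp_c), mean(ft50$canopy_temp_c))
  expect_lt(mean(ft50$canopy_temp_c), mean(ft80$canopy_temp_c))
  # for the hottest, smallest canopies the attenuation loss and mixing gain
  # nearly cancel between 50 and 80 m, so a few plots may tie or flip
  expect_gte(mean(ft50$canopy_temp_c >= ft20$canopy_temp_c), 0.90)
  expect_gte(mean(ft80$canopy_temp_c >= ft50$canopy_temp_c), 0.90)
  expect_gt(mean(ft20$ndvi_mean), mean(ft50$ndvi_mean))
  expect_gt(mean(ft50$ndvi_mean), mean(ft80$ndvi_mean))
  expect_gte(mean(ft50$ndvi_mean <= ft20$ndvi_mean), 0.95)
  expect_gte(mean(ft80$ndvi_mean <= ft50$ndvi_mean), 0.95)
  # pure-soil temperature drops with height (attenuation dominates)
  soil_mean <- function(f) sapply(f$scenes, function(sc) {
    s <- sc$thermal_class == 2
    if (any(s)) mean(sc$thermal[s]) else NA_real_
  })
  s20 <- soil_mean(f20); s50 <- soil_mean(f50); s80 <- soil_mean(f80)
  ok <- complete.cases(s20, s50, s80)
  expect_true(all(s50[ok] <= s20[ok]))
  expect_true(all(s80[ok] <= s50[ok]))
})

test_that("rendering satisfies the forward-model contracts", {
  cfg <- small_config(n = 5, seed = 9)
  fld <- generate_field(cfg)
  sc <- fld$scenes[[1]]
  cap <- render_raw_capture(sc, cfg)
  for (b in 1:5) {
    expect_true(all(cap$dn_bands[[b]] >= 0 & cap$dn_bands[[b]] <= 65535))
    expect_true(all(cap$dn_bands[[b]] == round(cap$dn_bands[[b]])))
  }
  # zero reflectance renders to zero DN
  sc0 <- sc; sc0$reflectance[] <- 0
  cap0 <- render_raw_capture(sc0, cfg)
  expect_true(all(sapply(cap0$dn_bands, function(m) all(m == 0))))
  # doubling exposure doubles DN (pre-clip) but calibration is unchanged
  cfg2 <- cfg; cfg2$band_exposures <- cfg$band_exposures * 2
  cap2 <- render_raw_capture(sc, cfg2)
  for (b in 1:5)
    expect_true(max(abs(cap2$dn_bands[[b]] - 2 * cap$dn_bands[[b]])) <= 1.5)
  r1 <- unified_factor_reflectance(cap)
  r2 <- unified_factor_reflectance(cap2)
  expect_lt(max(abs(r1 - r2)), 1e-4)
  cfg_bad <- cfg; cfg_bad$band_gains[1] <- 0
  expect_error(render_raw_capture(sc, cfg_bad), "positive")
})

test_that("render -> calibrate round trip recovers reflectance to quantization", {
  cfg <- small_config(n = 5, seed = 13)
  fld <- generate_field(cfg)
  sc <- fld$scenes[[2]]
  cap <- render_raw_capture(sc, cfg)
  rec <- unified_factor_reflectance(cap)
  expect_lt(max(abs(unclass(rec) - sc$reflectance)), 1e-4)
  expect_identical(attr(rec, "n_clipped"), 0L)
})
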