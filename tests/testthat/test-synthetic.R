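# Synthetic pseudo-ensemble generator: determinism, closed-form
# consistency, amplification structure, parameter recovery.

test_that("config validation rejects degenerate setups", {
  expect_error(small_config(reference_window = c(2050, 2059),
                            target_window = c(2005, 2014)), "degenerate")
  expect_error(small_config(year_range = c(2000, 2010)), "degenerate")
  expect_error(small_config(npp_trend_field = matrix(-0.1, 10, 16)),
               "both increasing and decreasing")
  expect_error(member_spec("m", lambda_te = 0.1, d_c = c(3, 2, 1)),
               "non-decreasing")
  expect_error(member_spec("m", lambda_te = 0.1, baseline_te = 1.2),
               "baseline_te")
})

test_that("same seed gives a bit-identical ensemble", {
  cfg <- small_config(seed = 5, noise_sd = 0.05)
  e1 <- generate_ensemble(cfg)
  e2 <- generate_ensemble(cfg)
  expect_identical(e1$npp$values, e2$npp$values)
  expect_identical(e1$sst$values, e2$sst$values)
  for (k in seq_along(e1$members)) {
    expect_identical(e1$members[[k]]$tcb$values, e2$members[[k]]$tcb$values)
  }
  # different seed differs
  e3 <- generate_ensemble(small_config(seed = 6, noise_sd = 0.05))
  expect_false(identical(e1$npp$values, e3$npp$values))
})

test_that("noise-free forcing changes equal the trend fields by construction", {
  cfg <- small_config(noise_sd = 0)
  fc <- generate_forcings(cfg)
  dn <- relative_change_pct(
    window_climatology(fc$npp, cfg$reference_window),
    window_climatology(fc$npp, cfg$target_window), quiet = TRUE) / 100
  dT <- absolute_change(window_climatology(fc$sst, cfg$reference_window),
                        window_climatology(fc$sst, cfg$target_window))
  ocean <- cfg$grid$ocean_mask
  expect_equal(dn[ocean], cfg$npp_trend_field[ocean], tolerance = 1e-12)
  expect_equal(dT[ocean], cfg$sst_trend_field[ocean], tolerance = 1e-12)
})

test_that("analytic_expected_change matches its closed form", {
  expect_identical(analytic_expected_change(0, 0, 0.3, 4), 0)
  expect_equal(analytic_expected_change(-0.10, 0, 0.2, 5), -0.10)
  # frozen numeric evaluation of (1 + n) * exp(-lambda*d*dT) - 1
  expect_equal(analytic_expected_change(-0.10, 2, 0.1, 3),
               -0.5060695275153762, tolerance = 1e-15)
  # lambda*d*dT = ln(2), n = -0.10 -> 0.9/2 - 1
  expect_equal(analytic_expected_change(-0.10, log(2), 1, 1), -0.55)
  # strong warming inverts a positive NPP change
  expect_lt(analytic_expected_change(0.10, 5, 0.2, 4), 0)
})

test_that("noise-free member changes equal the closed form everywhere", {
  cfg <- small_config(noise_sd = 0)
  fc <- generate_forcings(cfg)
  spec <- cfg$members[[4]]
  m <- generate_member_response(cfg, spec, fc$sst, fc$npp)
  ocean <- cfg$grid$ocean_mask
  for (k in c(1L, 3L, 6L)) {
    ref <- window_climatology(m$class_biomass[[k]], cfg$reference_window)
    fut <- window_climatology(m$class_biomass[[k]], cfg$target_window)
    measured <- fut / ref - 1
    expected <- analytic_expected_change(cfg$npp_trend_field,
                                         cfg$sst_trend_field,
                                         spec$lambda_te, spec$d_c[k])
    expect_lt(max(abs(measured - expected)[ocean] /
                    pmax(abs(expected[ocean]), 1e-12)), 1e-10)
  }
})

test_that("lambda = 0 member tracks NPP exactly in every class", {
  cfg <- small_config(noise_sd = 0)
  fc <- generate_forcings(cfg)
  m <- generate_member_response(cfg, cfg$members[[1]], fc$sst, fc$npp)
  ocean <- cfg$grid$ocean_mask
  for (k in seq_along(m$class_biomass)) {
    ref <- window_climatology(m$class_biomass[[k]], cfg$reference_window)
    fut <- window_climatology(m$class_biomass[[k]], cfg$target_window)
    expect_equal((fut / ref - 1)[ocean], cfg$npp_trend_field[ocean],
                 tolerance = 1e-10)
  }
})

test_that("tcb equals the sum of class biomasses", {
  cfg <- small_config(noise_sd = 0.05)
  e <- generate_ensemble(cfg)
  for (m in e$members) {
    s <- Reduce(`+`, lapply(m$class_biomass, function(f) {
      v <- f$values; v[is.na(v)] <- 0; v
    }))
    tv <- m$tcb$values; tv[is.na(tv)] <- 0
    expect_lt(max(abs(s - tv) / pmax(abs(tv), 1e-12)), 1e-9)
  }
})

test_that("amplification grows with trophic distance when NPP falls", {
  cfg <- small_config(noise_sd = 0)
  fc <- generate_forcings(cfg)
  spec <- cfg$members[[5]] # lambda = 0.2
  m <- generate_member_response(cfg, spec, fc$sst, fc$npp)
  ocean <- cfg$grid$ocean_mask & cfg$npp_trend_field < 0
  deltas <- sapply(seq_along(m$class_biomass), function(k) {
    ref <- window_climatology(m$class_biomass[[k]], cfg$reference_window)
    fut <- window_climatology(m$class_biomass[[k]], cfg$target_window)
    (fut / ref - 1)[ocean]
  })
  n <- cfg$npp_trend_field[ocean]
  # |delta_c| exceeds |n| and grows monotonically with d_c, cellwise
  expect_true(all(abs(deltas) > abs(n)))
  expect_true(all(diff(t(deltas)) < 0))
})

test_that("ground_truth_types equals classify_map on noise-free output", {
  cfg <- small_config(noise_sd = 0)
  fc <- generate_forcings(cfg)
  for (i in c(2L, 4L)) {
    spec <- cfg$members[[i]]
    m <- generate_member_response(cfg, spec, fc$sst, fc$npp)
    ch <- compute_change_maps(fc$npp, m$tcb, fc$sst,
                              cfg$reference_window, cfg$target_window,
                              quiet = TRUE)
    expect_identical(classify_map(ch)$codes, ground_truth_types(cfg, spec)$codes)
  }
})

test_that("lambda is recovered by regression at noise_sd = 0.05", {
  cfg <- synthetic_config(seed = 31L, grid_shape = c(24L, 48L),
                          noise_sd = 0.05)
  expect_gte(sum(cfg$grid$ocean_mask), 500) # needs a decent cell count
  fc <- generate_forcings(cfg)
  spec <- cfg$members[[4]]
  m <- generate_member_response(cfg, spec, fc$sst, fc$npp)
  dT <- absolute_change(window_climatology(fc$sst, cfg$reference_window),
                        window_climatology(fc$sst, cfg$target_window))
  n <- relative_change_pct(window_climatology(fc$npp, cfg$reference_window),
                           window_climatology(fc$npp, cfg$target_window),
                           quiet = TRUE) / 100
  xs <- c(); ys <- c()
  for (k in seq_along(spec$d_c)) {
    dc <- relative_change_pct(
      window_climatology(m$class_biomass[[k]], cfg$reference_window),
      window_climatology(m$class_biomass[[k]], cfg$target_window),
      quiet = TRUE) / 100
    sel <- cfg$grid$ocean_mask & !is.na(dc) & (1 + dc) > 0
    ys <- c(ys, log(1 + dc[sel]) - log(1 + n[sel]))
    xs <- c(xs, -spec$d_c[k] * dT[sel])
  }
  lambda_hat <- unname(stats::coef(stats::lm(ys ~ xs + 0))[1])
  expect_lt(abs(lambda_hat - spec$lambda_te) / spec$lambda_te, 0.05)
})
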