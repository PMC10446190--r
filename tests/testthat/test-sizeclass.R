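# Class schemes, TL->weight conversion, per-class changes and profiles.

test_that("class_scheme validates bins and builds labels", {
  s <- default_weight_scheme()
  expect_identical(s$labels,
                   c("1-10g", "10-100g", "100g-1kg", "1-10kg", "10-100kg",
                     ">100kg"))
  expect_error(class_scheme("weight", c(10, 1)), "ascending")
  s2 <- class_scheme("length", c(0, 30, 90, Inf))
  expect_identical(s2$labels[3], ">90")
})

test_that("tl_weight_map rows are proper fractions and identity maps work", {
  # identity: TL bins congruent to weight bins under the log-linear relation
  m <- tl_weight_map(tl_breaks = c(2, 3, 4),
                     weight_breaks = c(1, 100, 10000), ppmr = 100, tl0 = 2,
                     w0 = 1)
  expect_equal(m$mapping, diag(2), ignore_attr = TRUE)
  # fractions sum to one whatever the offsets
  m2 <- tl_weight_map(c(2, 2.7, 3.1, 4.5), c(1, 10, 100, 1e3, Inf),
                      ppmr = 31.6, tl0 = 2.2, w0 = 3)
  expect_equal(rowSums(m2$mapping), rep(1, 3))
  expect_true(all(m2$mapping >= 0))
  # explicit mapping is validated
  expect_error(tl_weight_map(c(2, 3), c(1, 10),
                             mapping = matrix(0.5, 1, 1)), "summing to 1")
})

test_that("convert_tl_to_weight conserves biomass per cell-year", {
  g <- ta_grid(c(-30, 0, 30), c(-90, 0, 90),
               ocean_mask = matrix(c(rep(TRUE, 8), FALSE), 3, 3))
  set.seed(4)
  tl_fields <- lapply(1:3, function(i) {
    gridded_field(g, 2000:2004, array(runif(45, 1, 5), c(3, 3, 5)),
                  paste0("b_tl", i))
  })
  map <- tl_weight_map(c(2, 3, 4, 5), c(1, 100, 1e4, Inf), ppmr = 100,
                       tl0 = 2, w0 = 1)
  wf <- convert_tl_to_weight(tl_fields, map)
  tot_tl <- Reduce(`+`, lapply(tl_fields, `[[`, "values"))
  tot_w <- Reduce(`+`, lapply(wf, `[[`, "values"))
  ok <- !is.na(tot_tl)
  expect_lt(max(abs(tot_w[ok] - tot_tl[ok]) / tot_tl[ok]), 1e-9)
  # 2 TL bins split 50/50 into 2 weight bins
  half <- tl_weight_map(c(2, 3), c(1, 10, 100),
                        mapping = matrix(c(0.5, 0.5), 1))
  wf2 <- convert_tl_to_weight(tl_fields[1], half)
  expect_equal(wf2[[1]]$values, 0.5 * tl_fields[[1]]$values)
  expect_equal(wf2[[2]]$values, 0.5 * tl_fields[[1]]$values)
  expect_error(convert_tl_to_weight(tl_fields[1:2], map), "TL-bin fields")
})

test_that("per-class changes follow the closed form ordering", {
  cfg <- small_config(noise_sd = 0)
  fc <- generate_forcings(cfg)
  # lambda = 0: every class equals the NPP change
  m0 <- generate_member_response(cfg, cfg$members[[1]], fc$sst, fc$npp)
  pc0 <- per_class_relative_change(m0, cfg$reference_window,
                                   cfg$target_window)
  gnpp <- 100 * (area_weighted_mean((1 + cfg$npp_trend_field) *
                                      trophamp:::synth_npp0(cfg$grid),
                                    cfg$grid) /
                   area_weighted_mean(trophamp:::synth_npp0(cfg$grid),
                                      cfg$grid) - 1)
  expect_equal(pc0$delta_b_pct, rep(pc0$delta_b_pct[1], 6), tolerance = 1e-9)
  # lambda > 0 with declining NPP: strictly more negative with size
  spec <- cfg$members[[4]]
  m <- generate_member_response(cfg, spec, fc$sst, fc$npp)
  pc <- per_class_relative_change(m, cfg$reference_window,
                                  cfg$target_window)
  expect_identical(pc$class_label, spec$class_scheme$labels)
  expect_true(all(diff(pc$delta_b_pct) < 0))
})

test_that("tcb change equals the biomass-weighted combination of classes", {
  cfg <- small_config(seed = 13, noise_sd = 0.05)
  e <- generate_ensemble(cfg)
  m <- e$members[[3]]
  ref_t <- window_climatology(m$tcb, cfg$reference_window)
  fut_t <- window_climatology(m$tcb, cfg$target_window)
  num <- 0; den <- 0
  for (f in m$class_biomass) {
    num <- num + window_climatology(f, cfg$target_window)
    den <- den + window_climatology(f, cfg$reference_window)
  }
  ok <- cfg$grid$ocean_mask
  expect_equal((fut_t / ref_t)[ok], (num / den)[ok], tolerance = 1e-9)
})

test_that("amplification_profile diagnostics track the d_c gradient", {
  cfg <- small_config(seed = 17, noise_sd = 0.05)
  e <- generate_ensemble(cfg)
  # EcoTroph-like: increasing trophic distance
  pr <- amplification_profile(e$members[[5]], e$npp, cfg$reference_window,
                              cfg$target_window)
  expect_identical(attr(pr, "diagnostic"), "increasing magnitude")
  expect_true(all(c("class_label", "delta_b_pct", "r") %in% names(pr)))
  # lambda = 0: flat
  pr0 <- amplification_profile(e$members[[1]], e$npp, cfg$reference_window,
                               cfg$target_window)
  expect_identical(attr(pr0, "diagnostic"), "flat")
  # Macroecological-like: d_c constant across classes -> flat
  specc <- member_spec("constMEM", 0.15, d_c = rep(2L, 6))
  mc <- generate_member_response(cfg, specc, e$sst, e$npp)
  prc <- amplification_profile(mc, e$npp, cfg$reference_window,
                               cfg$target_window)
  expect_identical(attr(prc, "diagnostic"), "flat")
  # single-class scheme equals the tcb change
  spec1 <- member_spec("oneclass", 0.1, d_c = 2L,
                       class_scheme = class_scheme("weight", c(1, Inf),
                                                   "all"))
  m1 <- generate_member_response(cfg, spec1, e$sst, e$npp)
  pc1 <- per_class_relative_change(m1, cfg$reference_window,
                                   cfg$target_window)
  ref_t <- area_weighted_mean(window_climatology(m1$tcb,
                                                 cfg$reference_window),
                              cfg$grid)
  fut_t <- area_weighted_mean(window_climatology(m1$tcb,
                                                 cfg$target_window),
                              cfg$grid)
  expect_equal(pc1$delta_b_pct, 100 * (fut_t / ref_t - 1), tolerance = 1e-9)
})
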