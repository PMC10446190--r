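# Six-type response classification and the R ratio.

test_that("compute_r reproduces the worked ratios", {
  expect_identical(compute_r(-30, -10), 3)
  expect_identical(compute_r(-5, -10), 0.5)
  expect_identical(compute_r(-22, 10), -2.2)
  # zero-denominator sentinels
  expect_identical(compute_r(5, 0), Inf)
  expect_identical(compute_r(-5, 0), -Inf)
  expect_true(is.na(compute_r(0, 0)))
})

test_that("classify_cell applies the definitions and boundary rules", {
  expect_identical(as.character(classify_cell(-30, -10)),
                   "negative_amplification")
  expect_identical(as.character(classify_cell(4, 10)),
                   "positive_attenuation")
  expect_identical(as.character(classify_cell(-5, 10)),
                   "negative_inversion")
  expect_identical(as.character(classify_cell(25, 10)),
                   "positive_amplification")
  expect_identical(as.character(classify_cell(12, -10)),
                   "positive_inversion")
  expect_identical(as.character(classify_cell(-4, -10)),
                   "negative_attenuation")
  # boundary rules: R exactly 1 -> attenuation; dB = 0 -> undefined;
  # dNPP = 0 with dB != 0 -> signed inversion
  expect_identical(as.character(classify_cell(-10, -10)),
                   "negative_attenuation")
  expect_identical(as.character(classify_cell(0, 10)), "undefined")
  expect_identical(as.character(classify_cell(3, 0)), "positive_inversion")
  expect_identical(as.character(classify_cell(NA, 5)), "undefined")
})

test_that("classifier and R are consistent on random pairs (property)", {
  set.seed(2024)
  n <- 5000
  db <- runif(n, -60, 60)
  dn <- runif(n, -30, 30)
  keep <- abs(dn) >= 1
  db <- db[keep]; dn <- dn[keep]
  r <- compute_r(db, dn)
  ty <- as.character(classify_cell(db, dn))
  amp <- grepl("amplification", ty)
  att <- grepl("attenuation", ty)
  inv <- grepl("inversion", ty)
  expect_identical(amp, r > 1)
  expect_identical(att, r > 0 & r <= 1)
  expect_identical(inv, r < 0)
  # sign prefix records the biomass direction
  expect_identical(grepl("^positive", ty), db > 0)
})

test_that("negating both changes swaps positive/negative and fixes R", {
  set.seed(7)
  db <- runif(200, -50, 50); dn <- runif(200, -20, 20)
  t1 <- as.character(classify_cell(db, dn))
  t2 <- as.character(classify_cell(-db, -dn))
  swapped <- ifelse(startsWith(t1, "positive"),
                    sub("^positive", "negative", t1),
                    sub("^negative", "positive", t1))
  expect_identical(t2[t1 != "undefined"], swapped[t1 != "undefined"])
  expect_equal(compute_r(db, dn), compute_r(-db, -dn))
})

test_that("classify_map handles all-land grids and masks", {
  g <- ta_grid(c(-10, 10), c(0, 90), ocean_mask = matrix(FALSE, 2, 2))
  npp <- gridded_field(g, 2000:2019, array(1, c(2, 2, 20)), "npp")
  tcb <- gridded_field(g, 2000:2019, array(1, c(2, 2, 20)), "tcb")
  ch <- compute_change_maps(npp, tcb, NULL, c(2000, 2009), c(2010, 2019),
                            quiet = TRUE)
  tm <- classify_map(ch)
  expect_true(all(tm$codes == 7L))
})

test_that("type_area_fractions partitions the ocean", {
  cfg <- small_config(noise_sd = 0.05)
  e <- generate_ensemble(cfg)
  ch <- compute_change_maps(e$npp, e$members[[3]]$tcb, e$sst,
                            cfg$reference_window, cfg$target_window,
                            quiet = TRUE)
  tm <- classify_map(ch)
  fr <- type_area_fractions(tm)
  expect_equal(sum(fr), 1, tolerance = 1e-9)
  # subsetting to NPP-decline cells still partitions
  fr2 <- type_area_fractions(tm, subset = ch$delta_npp_pct < 0)
  expect_equal(sum(fr2), 1, tolerance = 1e-9)
  # uniform map of one type
  uni <- tm; uni$codes[cfg$grid$ocean_mask] <- 4L
  fru <- type_area_fractions(uni)
  expect_equal(unname(fru["negative_amplification"]), 1)
})

test_that("type_area_fractions matches a hand count on a 6x6 toy", {
  lat <- seq(-50, 50, by = 20); lon <- seq(-150, 150, by = 60)
  mask <- matrix(TRUE, 6, 6); mask[1, 1] <- FALSE; mask[6, 6] <- FALSE
  g <- ta_grid(lat, lon, ocean_mask = mask)
  codes <- matrix(4L, 6, 6); codes[4:6, ] <- 6L
  tm <- structure(list(codes = codes, grid = g,
                       levels = response_type_levels()),
                  class = "ta_typemap")
  fr <- type_area_fractions(tm, g)
  # independent arithmetic: cos weights over the ocean cells of each half
  w <- cos(lat * pi / 180)
  tot <- 6 * sum(w) - w[1] - w[6]
  expect_equal(unname(fr["negative_amplification"]),
               (6 * sum(w[1:3]) - w[1]) / tot)
  expect_equal(unname(fr["negative_inversion"]),
               (6 * sum(w[4:6]) - w[6]) / tot)
})

test_that("mean_r_by_type agrees with a brute-force oracle", {
  cfg <- small_config(seed = 12, noise_sd = 0.05)
  e <- generate_ensemble(cfg)
  ch <- compute_change_maps(e$npp, e$members[[4]]$tcb, e$sst,
                            cfg$reference_window, cfg$target_window,
                            quiet = TRUE)
  out <- mean_r_by_type(ch, trim = c(0, 100), npp_exclusion_pct = 1)
  # oracle: direct per-cell enumeration, independent of the implementation
  r <- ch$delta_b_pct / ch$delta_npp_pct
  ty <- as.character(classify_cell(ch$delta_b_pct, ch$delta_npp_pct))
  w <- cfg$grid$cell_area
  keep <- cfg$grid$ocean_mask & !is.na(r) & is.finite(r) &
    abs(ch$delta_npp_pct) >= 1
  for (i in seq_len(nrow(out))) {
    sel <- keep & ty == out$type[i]
    if (out$n[i] == 0) { expect_identical(sum(sel), 0L); next }
    expect_identical(sum(sel), out$n[i])
    mu <- sum(w[sel] * r[sel]) / sum(w[sel])
    expect_equal(out$mean_r[i], mu, tolerance = 1e-12)
    expect_equal(out$sd_r[i],
                 sqrt(sum(w[sel] * (r[sel] - mu)^2) / sum(w[sel])),
                 tolerance = 1e-12)
  }
})

test_that("trim = c(0, 100) equals untrimmed; trimming drops extremes", {
  # all cells identical: mean R exact, sd 0
  g <- ta_grid(seq(-40, 40, 20), seq(-120, 120, 60))
  npp <- gridded_field(g, 2000:2019,
                       array(rep(c(rep(10, 10), rep(9, 10)), each = 25),
                             c(5, 5, 20)), "npp")
  tcb <- gridded_field(g, 2000:2019,
                       array(rep(c(rep(10, 10), rep(7, 10)), each = 25),
                             c(5, 5, 20)), "tcb")
  ch <- compute_change_maps(npp, tcb, NULL, c(2000, 2009), c(2010, 2019),
                            quiet = TRUE)
  out <- mean_r_by_type(ch, trim = c(0, 100))
  row <- out[out$type == "negative_amplification", ]
  expect_equal(row$mean_r, 3)
  expect_equal(row$sd_r, 0)
  expect_identical(row$n, 25L)
})

test_that("r_anova reports a type effect on heterogeneous R samples", {
  set.seed(3)
  df <- data.frame(
    r = c(rnorm(50, 3, 0.2), rnorm(50, 0.5, 0.2)),
    type = rep(c("negative_amplification", "negative_attenuation"), each = 50),
    mem = rep(c("a", "b"), 50),
    esm = "one")
  tab <- r_anova(df)
  expect_true("type" %in% rownames(tab))
  expect_lt(tab["type", "Pr(>F)"], 0.05)
  expect_false("esm" %in% rownames(tab)) # single level dropped
})
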