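# Shared fixtures. Small configurations for unit tests; the default-size
# ensembles used by the acceptance tests are generated once per run and
# cached here (generation is seconds-scale but not free).

small_config <- function(seed = 7, noise_sd = 0, n_lat = 10, n_lon = 16,
                         ...) {
  args <- utils::modifyList(
    list(seed = seed, grid_shape = c(n_lat, n_lon),
         year_range = c(2000L, 2059L),
         reference_window = c(2005L, 2014L),
         target_window = c(2050L, 2059L),
         noise_sd = noise_sd),
    list(...))
  do.call(synthetic_config, args)
}

small_field <- function(values, lat = c(-30, -10, 10, 30),
                        lon = c(-90, 0, 90, 180) - 45,
                        years = 2000L, var_name = "npp", units = "u",
                        mask = NULL) {
  g <- ta_grid(lat, lon, ocean_mask = mask)
  gridded_field(g, years, values, var_name, units)
}

.ta_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.ta_cache[[key]])) .ta_cache[[key]] <- force(expr)
  .ta_cache[[key]]
}

# Default-size (45 x 90, 1950-2099, 5 members) ensembles for acceptance.
default_ensemble_nf <- function() {
  cached("ens_nf", {
    cfg <- synthetic_config(seed = 1L, noise_sd = 0)
    c(list(config = cfg), generate_ensemble(cfg))
  })
}

default_ensemble_noisy <- function() {
  cached("ens_noisy", {
    cfg <- synthetic_config(seed = 101L, noise_sd = 0.05)
    c(list(config = cfg), generate_ensemble(cfg))
  })
}

# Noise-free analytic tcb change per cell for a member spec (independent of
# the generator pipeline; mirrors the documented closed form).
oracle_tcb_change <- function(cfg, spec) {
  w <- spec$class_baseline_biomass / sum(spec$class_baseline_biomass)
  E <- 0
  for (k in seq_along(spec$d_c)) {
    E <- E + w[k] * exp(-spec$lambda_te * spec$d_c[k] * cfg$sst_trend_field)
  }
  (1 + cfg$npp_trend_field) * E - 1
}
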