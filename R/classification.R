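# Six-type biomass-response classification and the amplification ratio R.
#
# Per cell, the consumer-biomass change is compared with the NPP change:
# same sign and larger -> amplification; same sign and smaller ->
# attenuation; opposite sign -> inversion. A positive/negative prefix
# records the direction of the biomass change itself, giving six types.
# R = (biomass change %) / (NPP change %): R > 1 amplification,
# 0 < R < 1 attenuation, R < 0 inversion.

#' Response type levels and integer codes
#'
#' The six defined response types plus `"undefined"` (masked cells, zero
#' biomass change, or unclassifiable input). The integer code of a type is
#' its position in this vector; the same codes are used in NetCDF exports.
#'
#' @return Character vector of the seven level names.
#' @export
response_type_levels <- function() {
  c("positive_amplification", "positive_attenuation", "positive_inversion",
    "negative_amplification", "negative_attenuation", "negative_inversion",
    "undefined")
}

new_typemap <- function(type_factor, grid) {
  m <- matrix(as.integer(type_factor),
              length(grid$lat), length(grid$lon))
  structure(list(codes = m, grid = grid,
                 levels = response_type_levels()),
            class = "ta_typemap")
}

#' @export
print.ta_typemap <- function(x, ...) {
  tb <- table(factor(x$levels[x$codes], levels = x$levels))
  cat("<ta_typemap>\n")
  print(tb)
  invisible(x)
}

typemap_factor <- function(tm) {
  factor(tm$levels[tm$codes], levels = tm$levels)
}

#' Amplification ratio R
#'
#' `R = delta_b_pct / delta_npp_pct`, the per-cell ratio of relative
#' consumer-biomass change to relative NPP change. `R > 1` amplifies the
#' NPP change, `0 < R < 1` attenuates it, `R < 0` inverts it. A zero NPP
#' change with a nonzero biomass change yields a signed infinite sentinel
#' (excluded from all summary means); zero over zero yields `NA`.
#'
#' @param delta_b_pct,delta_npp_pct percent changes (vectors or matrices).
#' @return R, same shape as the inputs.
#' @examples
#' compute_r(-30, -10)  #  3   amplification of a decline
#' compute_r(-5, -10)   #  0.5 attenuation
#' compute_r(-22, 10)   # -2.2 inversion
#' @export
compute_r <- function(delta_b_pct, delta_npp_pct) {
  r <- delta_b_pct / delta_npp_pct
  zero_n <- !is.na(delta_npp_pct) & delta_npp_pct == 0
  r[zero_n] <- ifelse(is.na(delta_b_pct[zero_n]) | delta_b_pct[zero_n] == 0,
                      NA_real_, Inf * sign(delta_b_pct[zero_n]))
  r
}

#' Classify one or more cells into the six response types
#'
#' Vectorised. Boundary rules (sets of measure zero, fixed for
#' determinism): `|delta_b| == |delta_npp|` with equal signs (R exactly 1)
#' is attenuation — the comparison uses a tiny relative tolerance (1e-9)
#' so that analytically-on-the-boundary configurations (a
#' temperature-neutral model tracking NPP exactly) resolve identically
#' however the two changes were computed; a zero biomass change is
#' `undefined`; a zero NPP change with nonzero biomass change is an
#' inversion with the sign of the biomass change. `NA` input gives
#' `undefined`.
#'
#' @param delta_b_pct,delta_npp_pct percent changes.
#' @return Factor with levels [response_type_levels()].
#' @export
classify_cell <- function(delta_b_pct, delta_npp_pct) {
  db <- as.numeric(delta_b_pct); dn <- as.numeric(delta_npp_pct)
  out <- rep("undefined", length(db))
  ok <- !is.na(db) & !is.na(dn) & db != 0
  sgn <- ifelse(db > 0, "positive", "negative")
  base <- rep(NA_character_, length(db))
  same <- ok & dn != 0 & sign(db) == sign(dn)
  tol <- 1e-9
  base[same & abs(db) > abs(dn) * (1 + tol)] <- "amplification"
  base[same & abs(db) <= abs(dn) * (1 + tol)] <- "attenuation" # R = 1 tie
  base[ok & dn != 0 & sign(db) != sign(dn)] <- "inversion"
  base[ok & dn == 0] <- "inversion"                  # R = +-Inf sentinel
  has <- !is.na(base)
  out[has] <- paste(sgn[has], base[has], sep = "_")
  factor(out, levels = response_type_levels())
}

#' Classify a whole change map
#'
#' @param changes a `ta_changemaps` from [compute_change_maps()].
#' @return A `ta_typemap`: integer-coded per-cell types plus the grid;
#'   masked cells are `undefined`.
#' @export
classify_map <- function(changes) {
  stopifnot(inherits(changes, "ta_changemaps"))
  new_typemap(classify_cell(changes$delta_b_pct, changes$delta_npp_pct),
              changes$grid)
}

#' R ratio map
#'
#' @param changes a `ta_changemaps`.
#' @return `nlat x nlon` matrix of R values (`NA` where masked, signed
#'   `Inf` where the NPP change is exactly zero).
#' @export
r_ratio_map <- function(changes) {
  stopifnot(inherits(changes, "ta_changemaps"))
  compute_r(changes$delta_b_pct, changes$delta_npp_pct)
}

#' Area fraction of each response type
#'
#' Area-weighted fraction of every type (including `undefined`) within the
#' ocean, optionally restricted to a subset (e.g. cells where NPP
#' declines). Fractions sum to 1.
#'
#' @param type_map a `ta_typemap`.
#' @param grid the shared [ta_grid()] (defaults to the map's own grid).
#' @param subset optional logical matrix.
#' @param weighted cosine-latitude weights (default) or plain counting.
#' @return Named numeric vector over the seven levels.
#' @export
type_area_fractions <- function(type_map, grid = type_map$grid,
                                subset = NULL, weighted = TRUE) {
  stopifnot(inherits(type_map, "ta_typemap"))
  base <- grid$ocean_mask
  if (!is.null(subset)) base <- base & subset & !is.na(subset)
  if (!any(base)) stop("empty cell subset", call. = FALSE)
  w <- if (weighted) grid$cell_area else array(1, dim(grid$cell_area))
  tot <- sum(w[base])
  vapply(seq_along(type_map$levels), function(k) {
    sum(w[base & type_map$codes == k]) / tot
  }, 0) -> fr
  names(fr) <- type_map$levels
  fr
}

# Per-analysis percentile trim of an R sample: keep values within the
# [lo, hi] percentiles (inclusive). trim = c(0, 100) is a no-op. Infinite
# sentinels are always dropped first.
trim_r_sample <- function(r, trim = c(2.5, 97.5)) {
  keep <- is.finite(r)
  if (trim[1] > 0 || trim[2] < 100) {
    q <- stats::quantile(r[keep], probs = c(trim[1], trim[2]) / 100,
                         na.rm = TRUE, names = FALSE, type = 7)
    keep <- keep & r >= q[1] & r <= q[2]
  }
  keep & !is.na(keep)
}

#' Mean amplification ratio by response type
#'
#' Summary of R per response type after the standard exclusions: cells with
#' `|delta NPP| < npp_exclusion_pct` are dropped, then R is trimmed at the
#' given percentiles over all retained ocean cells of this map, then an
#' area-weighted mean and s.d. of R is computed within each type. Types
#' with no retained cells are reported with `n = 0` and `NA` statistics.
#'
#' @param changes a `ta_changemaps`.
#' @param trim percentile pair, default `c(2.5, 97.5)`; `c(0, 100)`
#'   disables trimming.
#' @param npp_exclusion_pct minimum `|delta NPP%|`, default 1.
#' @param weighted area weighting of the within-type statistics (default
#'   `TRUE`; `FALSE` gives the unweighted variant).
#' @return `data.frame(type, mean_r, sd_r, n)`, one row per defined type.
#' @export
mean_r_by_type <- function(changes, trim = c(2.5, 97.5),
                           npp_exclusion_pct = 1, weighted = TRUE) {
  stopifnot(inherits(changes, "ta_changemaps"))
  tm <- classify_map(changes)
  r <- r_ratio_map(changes)
  grid <- changes$grid
  retained <- grid$ocean_mask & !is.na(r) &
    !is.na(changes$delta_npp_pct) &
    abs(changes$delta_npp_pct) >= npp_exclusion_pct
  keep <- retained
  keep[retained] <- trim_r_sample(r[retained], trim)
  lv <- response_type_levels()[1:6]
  rows <- lapply(seq_along(lv), function(k) {
    sel <- keep & tm$codes == k
    n <- sum(sel)
    if (n == 0) {
      return(data.frame(type = lv[k], mean_r = NA_real_, sd_r = NA_real_,
                        n = 0L))
    }
    w <- if (weighted) grid$cell_area[sel] else rep(1, n)
    m <- sum(w * r[sel]) / sum(w)
    v <- sum(w * (r[sel] - m)^2) / sum(w)
    data.frame(type = lv[k], mean_r = m, sd_r = sqrt(v), n = as.integer(n))
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded_npp") <- sum(grid$ocean_mask & !is.na(r)) - sum(retained)
  attr(out, "n_trimmed") <- sum(retained) - sum(keep)
  out
}

#' Fixed-effects decomposition of R
#'
#' Convenience ANOVA of trimmed R samples on response type, ecosystem model
#' and forcing model, as used to report whether the magnitude of R depends
#' on those factors. Expects a long data frame with one retained cell per
#' row.
#'
#' @param df data frame with numeric `r` and factors/characters `type`,
#'   `mem`, `esm`.
#' @return The `anova` table of `lm(r ~ type + mem + esm)` (factors with a
#'   single level are dropped from the formula).
#' @export
r_anova <- function(df) {
  stopifnot(all(c("r", "type", "mem", "esm") %in% names(df)))
  terms <- c("type", "mem", "esm")
  terms <- terms[vapply(terms, function(t) length(unique(df[[t]])) > 1, TRUE)]
  if (length(terms) == 0) stop("no factor with >1 level", call. = FALSE)
  fml <- stats::as.formula(paste("r ~", paste(terms, collapse = " + ")))
  stats::anova(stats::lm(fml, data = df))
}
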