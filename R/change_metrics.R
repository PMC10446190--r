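# Decadal climatologies and change statistics: per-cell relative change
# maps, absolute SST change, and global annual change series.

#' Window climatology
#'
#' Per-cell arithmetic mean of an annual field over a window of years. A
#' cell enters the climatology only if all years of the window are present
#' there; otherwise it is masked for this statistic (all-or-nothing rule).
#'
#' @param field a [gridded_field()].
#' @param window `c(first, last)` years, inclusive; must lie within the
#'   field's time axis.
#' @return `nlat x nlon` numeric matrix, `NA` outside the ocean.
#' @export
window_climatology <- function(field, window) {
  stopifnot(inherits(field, "ta_field"))
  window <- as.integer(window)
  if (window[1] > window[2] || window[1] < min(field$years) ||
      window[2] > max(field$years)) {
    stop("window ", window[1], "-", window[2],
         " outside field years ", min(field$years), "-", max(field$years),
         call. = FALSE)
  }
  idx <- which(field$years >= window[1] & field$years <= window[2])
  sub <- field$values[, , idx, drop = FALSE]
  out <- rowMeans(sub, dims = 2L)              # NA if any year missing
  out
}

#' Per-cell relative change in percent
#'
#' `100 * (fut - ref) / ref`. Cells whose reference value is at or below
#' `eps` (near-zero NPP under ice, dried-out cells) are masked and counted;
#' the count is attached as attribute `n_degenerate` and reported via
#' `message()` when nonzero.
#'
#' @param ref,fut per-cell matrices on the same grid.
#' @param eps degenerate-reference threshold in data units.
#' @param quiet suppress the degenerate-cell message.
#' @return Matrix of percent changes.
#' @export
relative_change_pct <- function(ref, fut, eps = 1e-12, quiet = FALSE) {
  stopifnot(identical(dim(ref), dim(fut)))
  bad <- !is.na(ref) & ref <= eps
  out <- 100 * (fut - ref) / ref
  out[bad] <- NA_real_
  n_bad <- sum(bad)
  if (n_bad > 0 && !quiet) {
    message("relative_change_pct: masked ", n_bad,
            " cell(s) with reference <= ", eps)
  }
  attr(out, "n_degenerate") <- n_bad
  out
}

#' Per-cell absolute change
#'
#' `fut - ref`; used for SST, in degrees C.
#'
#' @param ref,fut per-cell matrices on the same grid.
#' @return Matrix of differences.
#' @export
absolute_change <- function(ref, fut) {
  stopifnot(identical(dim(ref), dim(fut)))
  fut - ref
}

#' Change maps between a reference and a target window
#'
#' The three per-cell change statistics of the analysis on one grid:
#' relative NPP change (%), relative total-consumer-biomass change (%) and
#' absolute SST change (degC), each as (target-window climatology) vs
#' (reference-window climatology).
#'
#' @param npp,tcb,sst [gridded_field()]s on one grid (any may be `NULL`,
#'   e.g. SST when only biomass response is needed).
#' @param reference_window,target_window year intervals; reference must
#'   precede the target and they must not overlap.
#' @param eps degenerate-reference threshold for the ratio statistics.
#' @param quiet passed to [relative_change_pct()].
#' @return An object of class `ta_changemaps` with elements
#'   `delta_npp_pct`, `delta_b_pct`, `delta_sst_degC`, `grid`,
#'   `reference_window`, `target_window`.
#' @export
compute_change_maps <- function(npp, tcb, sst = NULL,
                                reference_window = c(1995L, 2014L),
                                target_window = c(2090L, 2099L),
                                eps = 1e-12, quiet = FALSE) {
  reference_window <- as.integer(reference_window)
  target_window <- as.integer(target_window)
  if (reference_window[2] >= target_window[1]) {
    stop("windows must be disjoint with reference preceding target",
         call. = FALSE)
  }
  grid <- NULL
  for (f in list(npp, tcb, sst)) {
    if (is.null(f)) next
    if (is.null(grid)) grid <- f$grid else stopifnot_same_grid(grid, f$grid)
  }
  if (is.null(grid)) stop("at least one field is required", call. = FALSE)
  rel <- function(f) {
    if (is.null(f)) return(NULL)
    relative_change_pct(window_climatology(f, reference_window),
                        window_climatology(f, target_window),
                        eps = eps, quiet = quiet)
  }
  dsst <- if (is.null(sst)) NULL else
    absolute_change(window_climatology(sst, reference_window),
                    window_climatology(sst, target_window))
  structure(
    list(delta_npp_pct = rel(npp), delta_b_pct = rel(tcb),
         delta_sst_degC = dsst, grid = grid,
         reference_window = reference_window,
         target_window = target_window),
    class = "ta_changemaps")
}

#' Global annual change series
#'
#' For each year, the change of the area-weighted global-mean value relative
#' to the reference-window mean of that global-mean series (change of the
#' mean, not mean of per-cell changes; set `per_cell = TRUE` for the
#' alternative).
#'
#' @param field a [gridded_field()].
#' @param reference_window year interval within the data.
#' @param mode `"relative_pct"` (default) or `"absolute"`.
#' @param weighted cosine-latitude weighting (default) or plain averaging.
#' @param per_cell if `TRUE`, average the per-cell changes instead
#'   (mean-of-ratios variant).
#' @return Named numeric vector, one value per year.
#' @export
global_change_series <- function(field, reference_window = c(1995L, 2014L),
                                 mode = c("relative_pct", "absolute"),
                                 weighted = TRUE, per_cell = FALSE) {
  stopifnot(inherits(field, "ta_field"))
  mode <- match.arg(mode)
  reference_window <- as.integer(reference_window)
  ref_clim <- window_climatology(field, reference_window)
  years <- field$years
  out <- if (per_cell) {
    vapply(seq_along(years), function(i) {
      sl <- field$values[, , i]
      ch <- if (mode == "relative_pct") {
        relative_change_pct(ref_clim, sl, quiet = TRUE)
      } else absolute_change(ref_clim, sl)
      area_weighted_mean(ch, field$grid, weighted = weighted)
    }, 0)
  } else {
    gm <- vapply(seq_along(years), function(i) {
      area_weighted_mean(field$values[, , i], field$grid,
                         weighted = weighted)
    }, 0)
    gref <- mean(gm[years >= reference_window[1] &
                      years <= reference_window[2]])
    if (mode == "relative_pct") 100 * (gm - gref) / gref else gm - gref
  }
  names(out) <- years
  out
}
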