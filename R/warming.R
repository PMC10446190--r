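# R as a function of warming: SST-binned mean R curves split by the
# direction of NPP change, with the standard exclusion and trimming rules.

#' Warming-binned amplification curve
#'
#' Pools (cell, year) samples: for every year, per-cell annual changes vs
#' the reference climatology (`delta SST` in degC, `delta NPP%`,
#' `delta B%`), keeps the samples whose NPP change matches `direction` and
#' clears the `|delta NPP%| >= npp_exclusion_pct` floor, computes
#' `R = delta B% / delta NPP%` per sample, trims R at the given percentiles
#' over the retained samples, and averages R within fixed-width `delta SST`
#' bins, regardless of the year a sample comes from.
#'
#' @param member a [member_output()] (its `tcb` field is used).
#' @param npp,sst forcing fields on the same grid.
#' @param reference_window year interval for the reference climatology.
#' @param direction `"decrease"` or `"increase"` of NPP.
#' @param bin_width SST bin width in degC (default 0.1).
#' @param npp_exclusion_pct minimum `|delta NPP%|` (default 1).
#' @param trim R trim percentiles (default `c(2.5, 97.5)`).
#' @param end_of_century if `TRUE`, use only the between-window change maps
#'   (spatial binning of the end-of-century signal) instead of pooling all
#'   years; `target_window` is then required.
#' @param target_window used only when `end_of_century = TRUE`.
#' @param min_bin_n smallest sample count for a bin to be reported
#'   (default 1).
#' @return An object of class `ta_warmingcurve`: data frame `bins` with
#'   `bin_lo`, `bin_hi`, `bin_center`, `mean_r`, `sd_r`, `n`; plus
#'   `direction`, `mem_name`, `esm_name`, the retained trimmed `r_sample`
#'   and its `dsst_sample`. Empty retained set gives zero-row `bins` with
#'   an explanatory `note`.
#' @export
r_vs_warming <- function(member, npp, sst,
                         reference_window = c(1995L, 2014L),
                         direction = c("decrease", "increase"),
                         bin_width = 0.1,
                         npp_exclusion_pct = 1,
                         trim = c(2.5, 97.5),
                         end_of_century = FALSE,
                         target_window = c(2090L, 2099L),
                         min_bin_n = 1L) {
  stopifnot(inherits(member, "ta_member"), bin_width > 0)
  direction <- match.arg(direction)
  tcb <- member$tcb
  stopifnot_same_grid(tcb$grid, npp$grid, "tcb and npp")
  stopifnot_same_grid(tcb$grid, sst$grid, "tcb and sst")

  npp_ref <- window_climatology(npp, reference_window)
  tcb_ref <- window_climatology(tcb, reference_window)
  sst_ref <- window_climatology(sst, reference_window)

  if (end_of_century) {
    dn <- as.vector(relative_change_pct(
      npp_ref, window_climatology(npp, target_window), quiet = TRUE))
    db <- as.vector(relative_change_pct(
      tcb_ref, window_climatology(tcb, target_window), quiet = TRUE))
    dsst <- as.vector(window_climatology(sst, target_window) - sst_ref)
  } else {
    nt <- length(npp$years)
    rep_ref <- function(m) as.vector(array(m, c(dim(m), nt)))
    nref <- rep_ref(npp_ref); bref <- rep_ref(tcb_ref); sref <- rep_ref(sst_ref)
    dn <- 100 * (as.vector(npp$values) - nref) / nref
    db <- 100 * (as.vector(tcb$values) - bref) / bref
    dsst <- as.vector(sst$values) - sref
  }

  ok <- !is.na(dn) & !is.na(db) & !is.na(dsst) &
    abs(dn) >= npp_exclusion_pct &
    (if (direction == "decrease") dn < 0 else dn > 0)
  r <- db[ok] / dn[ok]
  dsst <- dsst[ok]
  keep <- trim_r_sample(r, trim)
  r <- r[keep]; dsst <- dsst[keep]

  empty <- function(note) {
    structure(list(
      bins = data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                        bin_center = numeric(0), mean_r = numeric(0),
                        sd_r = numeric(0), n = integer(0)),
      direction = direction, mem_name = member$mem_name,
      esm_name = member$esm_name, bin_width = bin_width,
      r_sample = numeric(0), dsst_sample = numeric(0), note = note),
      class = "ta_warmingcurve")
  }
  if (length(r) == 0) {
    return(empty(paste0("no (cell, year) samples retained for NPP ",
                        direction, " after the |dNPP| >= ",
                        npp_exclusion_pct, "% exclusion and trimming")))
  }

  lo_edge <- floor(min(dsst) / bin_width) * bin_width
  idx <- floor((dsst - lo_edge) / bin_width + 1e-9)
  agg <- tapply(r, idx, function(x) c(mean(x), stats::sd(x), length(x)))
  ids <- as.integer(names(agg))
  bins <- data.frame(
    bin_lo = lo_edge + ids * bin_width,
    bin_hi = lo_edge + (ids + 1) * bin_width,
    mean_r = vapply(agg, `[`, 0, 1),
    sd_r = vapply(agg, `[`, 0, 2),
    n = as.integer(vapply(agg, `[`, 0, 3)))
  bins$bin_center <- (bins$bin_lo + bins$bin_hi) / 2
  bins <- bins[order(bins$bin_lo), ]
  bins <- bins[bins$n >= min_bin_n,
               c("bin_lo", "bin_hi", "bin_center", "mean_r", "sd_r", "n")]
  rownames(bins) <- NULL
  structure(list(
    bins = bins, direction = direction, mem_name = member$mem_name,
    esm_name = member$esm_name, bin_width = bin_width,
    r_sample = r, dsst_sample = dsst, note = NULL),
    class = "ta_warmingcurve")
}

#' @export
print.ta_warmingcurve <- function(x, ...) {
  cat(sprintf("<ta_warmingcurve> %s/%s, NPP %s, %d bins, %d samples\n",
              x$mem_name, x$esm_name, x$direction, nrow(x$bins),
              length(x$r_sample)))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Correlation diagnostics of a warming curve
#'
#' Pearson correlation of the bin-mean R against the bin-center warming,
#' plus a Shapiro-Wilk normality statistic on the retained R sample as a
#' diagnostic (subsampled deterministically to 5000 if larger, the test's
#' upper limit).
#'
#' @param curve a `ta_warmingcurve`.
#' @return `list(pearson_r, p_value, shapiro_p, n_bins)`. A constant or
#'   too-short curve yields `NA` correlation with a `note`.
#' @export
warming_correlation <- function(curve) {
  stopifnot(inherits(curve, "ta_warmingcurve"))
  b <- curve$bins
  out <- list(pearson_r = NA_real_, p_value = NA_real_,
              shapiro_p = NA_real_, n_bins = nrow(b), note = NULL)
  if (nrow(b) < 3) {
    out$note <- "fewer than 3 bins; correlation undefined"
  } else if (stats::sd(b$mean_r) == 0 || stats::sd(b$bin_center) == 0) {
    out$note <- "constant input; correlation undefined"
  } else {
    ct <- stats::cor.test(b$bin_center, b$mean_r, method = "pearson")
    out$pearson_r <- unname(ct$estimate)
    out$p_value <- ct$p.value
  }
  r <- curve$r_sample
  if (length(r) >= 3) {
    if (length(r) > 5000) {
      r <- r[round(seq(1, length(r), length.out = 5000))]   # deterministic
    }
    if (stats::sd(r) > 0) out$shapiro_p <- stats::shapiro.test(r)$p.value
  }
  out
}
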