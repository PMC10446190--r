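# Multi-model agreement maps: per-cell majority vote of response types.

#' Majority vote of response types across ensemble members
#'
#' Per cell, the most frequent defined response type across the member type
#' maps. A cell "agrees" when that top count reaches `threshold` votes;
#' `undefined` votes never count toward a type but do reduce the number of
#' voting members at that cell. A tie between two types at or above the
#' threshold is conservatively marked as no agreement.
#'
#' @param type_maps list of `ta_typemap`s on one grid (>= 2).
#' @param threshold minimum votes for agreement (absolute count, as in a
#'   fixed 6-of-7 rule; must not exceed the number of maps).
#' @return An object of class `ta_agreement`: `modal_code` (integer matrix,
#'   code 7 = `undefined`/no data, `NA` = no agreement), `votes`,
#'   `n_members`, `threshold`, `grid`, `levels`.
#' @export
vote_agreement <- function(type_maps, threshold) {
  if (length(type_maps) < 2L) stop(">= 2 type maps required", call. = FALSE)
  threshold <- as.integer(threshold)
  if (threshold < 1L || threshold > length(type_maps)) {
    stop("threshold must be in 1..number of maps", call. = FALSE)
  }
  grid <- type_maps[[1]]$grid
  for (tm in type_maps) {
    stopifnot(inherits(tm, "ta_typemap"))
    stopifnot_same_grid(grid, tm$grid, "type maps")
  }
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  undef <- length(response_type_levels())       # code 7
  counts <- array(0L, c(nlat, nlon, undef))
  for (tm in type_maps) {
    for (k in seq_len(undef)) {
      counts[, , k] <- counts[, , k] + (tm$codes == k)
    }
  }
  defined <- counts[, , 1:6, drop = FALSE]
  best <- apply(defined, c(1, 2), max)
  nbest <- apply(defined, c(1, 2), function(x) sum(x == max(x) & max(x) > 0))
  modal <- apply(defined, c(1, 2), which.max)
  n_members <- apply(defined, c(1, 2), sum)     # members voting a defined type

  modal_code <- matrix(NA_integer_, nlat, nlon) # NA = no_agreement
  agree <- best >= threshold & nbest == 1L
  modal_code[agree] <- modal[agree]
  no_data <- n_members == 0L
  modal_code[no_data] <- undef
  votes <- best
  votes[no_data] <- 0L
  structure(
    list(modal_code = modal_code, votes = votes, n_members = n_members,
         threshold = threshold, grid = grid,
         levels = response_type_levels()),
    class = "ta_agreement")
}

#' @export
print.ta_agreement <- function(x, ...) {
  cat(sprintf("<ta_agreement> threshold %d, %.1f%% of ocean agreeing\n",
              x$threshold,
              100 * area_fraction(!is.na(x$modal_code) &
                                    x$modal_code <= 6L, x$grid)))
  invisible(x)
}

#' Area fractions of the agreement categories
#'
#' Area-weighted share of the ocean (or the whole grid area, including no
#' data) per agreement category: each of the six response types (agreed
#' cells), `no_agreement`, and `no_data`. Fractions sum to 1.
#'
#' @param agreement a `ta_agreement` from [vote_agreement()].
#' @param grid the grid (defaults to the map's own).
#' @param weighted area weighting (default) or plain counting.
#' @param ocean_only restrict to ocean cells (default `TRUE`).
#' @return Named numeric vector over the eight categories.
#' @export
agreement_area_fractions <- function(agreement, grid = agreement$grid,
                                     weighted = TRUE, ocean_only = TRUE) {
  stopifnot(inherits(agreement, "ta_agreement"))
  base <- if (ocean_only) grid$ocean_mask else
    array(TRUE, dim(grid$ocean_mask))
  w <- if (weighted) grid$cell_area else array(1, dim(grid$cell_area))
  tot <- sum(w[base])
  mc <- agreement$modal_code
  lv <- response_type_levels()[1:6]
  fr <- vapply(seq_along(lv), function(k) {
    sum(w[base & !is.na(mc) & mc == k]) / tot
  }, 0)
  names(fr) <- lv
  c(fr,
    no_agreement = sum(w[base & is.na(mc)]) / tot,
    no_data = sum(w[base & !is.na(mc) & mc == 7L]) / tot)
}
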