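# Standardised per-class biomass changes across heterogeneous class
# schemes, trophic-level -> weight-class conversion, and the per-class
# amplification profile.

#' Class scheme
#'
#' Describes how a model cuts the food web: by weight (g), by length (cm)
#' or by trophic level. Bins are ordered, non-overlapping and ascending;
#' the last bin may be open-ended (`Inf`).
#'
#' @param axis `"weight"`, `"length"` or `"trophic_level"`.
#' @param breaks numeric vector of `n_bins + 1` ascending bin edges (last
#'   may be `Inf`), in g, cm, or trophic-level units.
#' @param labels one label per bin; default built from the breaks.
#' @return An object of class `ta_classscheme`.
#' @examples
#' default_weight_scheme()   # 1-10g ... >100kg
#' @export
class_scheme <- function(axis = c("weight", "length", "trophic_level"),
                         breaks, labels = NULL) {
  axis <- match.arg(axis)
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2 || any(diff(breaks) <= 0)) {
    stop("breaks must be ascending with at least 2 edges", call. = FALSE)
  }
  n <- length(breaks) - 1L
  if (is.null(labels)) {
    labels <- paste0(breaks[-length(breaks)], "-", breaks[-1])
    if (is.infinite(breaks[length(breaks)])) {
      labels[n] <- paste0(">", breaks[n])
    }
  }
  if (length(labels) != n) stop("need one label per bin", call. = FALSE)
  structure(list(axis = axis, breaks = breaks,
                 labels = as.character(labels)),
            class = "ta_classscheme")
}

#' @rdname class_scheme
#' @param n_classes number of classes kept from the standard six weight
#'   classes (1-10g, 10-100g, 100g-1kg, 1-10kg, 10-100kg, >100kg).
#' @export
default_weight_scheme <- function(n_classes = 6L) {
  breaks <- c(1, 10, 100, 1e3, 1e4, 1e5, Inf)
  labels <- c("1-10g", "10-100g", "100g-1kg", "1-10kg", "10-100kg", ">100kg")
  stopifnot(n_classes >= 1L, n_classes <= 6L)
  br <- breaks[1:(n_classes + 1)]
  if (n_classes == 6L) br[7] <- Inf else br
  class_scheme("weight", breaks = br, labels = labels[1:n_classes])
}

#' Standardised per-class relative biomass change
#'
#' For each class of a member, the relative change (%) of the area-weighted
#' global mean biomass between the reference and target windows — the same
#' recipe as the total-consumer-biomass change, applied class by class.
#'
#' @param member a [member_output()] with class biomass fields.
#' @param reference_window,target_window year intervals.
#' @param weighted area weighting (default `TRUE`).
#' @return `data.frame(class_label, delta_b_pct)` in ascending class order;
#'   classes whose data are entirely masked are reported absent (dropped)
#'   with a message.
#' @export
per_class_relative_change <- function(member,
                                      reference_window = c(1995L, 2014L),
                                      target_window = c(2090L, 2099L),
                                      weighted = TRUE) {
  stopifnot(inherits(member, "ta_member"))
  if (length(member$class_biomass) == 0) {
    stop("member '", member$mem_name, "' has no class biomass fields",
         call. = FALSE)
  }
  rows <- lapply(names(member$class_biomass), function(lab) {
    f <- member$class_biomass[[lab]]
    ref <- window_climatology(f, reference_window)
    fut <- window_climatology(f, target_window)
    if (all(is.na(ref))) return(NULL)
    gref <- area_weighted_mean(ref, f$grid, weighted = weighted)
    gfut <- area_weighted_mean(fut, f$grid, weighted = weighted)
    data.frame(class_label = lab, delta_b_pct = 100 * (gfut - gref) / gref)
  })
  absent <- vapply(rows, is.null, TRUE)
  if (any(absent)) {
    message("per_class_relative_change: ", sum(absent),
            " class(es) entirely masked, reported absent")
  }
  out <- do.call(rbind, rows[!absent])
  rownames(out) <- NULL
  out
}

#' Trophic-level to weight-class conversion map
#'
#' Fractional assignment of trophic-level bins to weight bins. The default
#' construction assumes a log-linear relation between trophic level and
#' body weight, `TL(w) = tl0 + log(w/w0) / log(ppmr)` with predator-prey
#' mass ratio `ppmr`, and assigns each TL bin to weight bins by interval
#' overlap in TL space. This is an explicit stand-in for a model-specific
#' conversion table; supply `mapping` directly when the real table is
#' available.
#'
#' @param tl_breaks ascending trophic-level bin edges (n_tl + 1).
#' @param weight_breaks ascending weight bin edges in g (n_w + 1; last may
#'   be `Inf`).
#' @param ppmr predator-prey mass ratio; default 100 (one trophic step
#'   spans two decadal weight bins).
#' @param tl0 trophic level at reference weight `w0`; defaults place TL 2
#'   at the lower edge of the first weight bin.
#' @param w0 reference weight in g.
#' @param mapping optional ready-made `n_tl x n_w` fraction matrix (rows
#'   sum to 1); overrides the log-linear construction.
#' @return An object of class `ta_tlweightmap` with the fraction matrix
#'   `mapping` (rows = TL bins, columns = weight bins, row sums 1).
#' @export
tl_weight_map <- function(tl_breaks, weight_breaks, ppmr = 100,
                          tl0 = 2, w0 = weight_breaks[1], mapping = NULL) {
  tl_breaks <- as.numeric(tl_breaks)
  weight_breaks <- as.numeric(weight_breaks)
  n_tl <- length(tl_breaks) - 1L
  n_w <- length(weight_breaks) - 1L
  stopifnot(n_tl >= 1L, n_w >= 1L, all(diff(tl_breaks) > 0),
            all(diff(weight_breaks) > 0))
  if (is.null(mapping)) {
    # weight bin edges in TL space; outermost edges open so every TL bin
    # is fully covered (rows must sum to 1)
    tl_of_w <- tl0 + log(weight_breaks / w0) / log(ppmr)
    tl_of_w[1] <- -Inf
    tl_of_w[length(tl_of_w)] <- Inf
    mapping <- matrix(0, n_tl, n_w)
    for (i in seq_len(n_tl)) {
      a <- tl_breaks[i]; b <- tl_breaks[i + 1]
      for (j in seq_len(n_w)) {
        ov <- min(b, tl_of_w[j + 1]) - max(a, tl_of_w[j])
        mapping[i, j] <- max(ov, 0) / (b - a)
      }
    }
  }
  mapping <- as.matrix(mapping)
  if (!identical(dim(mapping), c(n_tl, n_w)) || any(mapping < 0) ||
      any(abs(rowSums(mapping) - 1) > 1e-9)) {
    stop("mapping must be ", n_tl, " x ", n_w,
         " with non-negative rows summing to 1 (every TL bin covered)",
         call. = FALSE)
  }
  structure(list(tl_breaks = tl_breaks, weight_breaks = weight_breaks,
                 mapping = mapping),
            class = "ta_tlweightmap")
}

#' Convert trophic-level biomass fields to weight-class fields
#'
#' Linear reallocation of biomass: each weight bin receives the mapped
#' fractions of every TL bin, per cell and year, before any change is
#' computed (biomass is conserved; relative changes are not linear, so the
#' order matters and is fixed).
#'
#' @param tl_fields list of [gridded_field()]s, one per TL bin, in
#'   ascending TL order.
#' @param map a [tl_weight_map()] covering all the TL bins.
#' @param labels output field labels, default `w1..wn`.
#' @return Named list of weight-bin [gridded_field()]s.
#' @export
convert_tl_to_weight <- function(tl_fields, map,
                                 labels = paste0("w", seq_len(ncol(map$mapping)))) {
  stopifnot(inherits(map, "ta_tlweightmap"))
  n_tl <- nrow(map$mapping); n_w <- ncol(map$mapping)
  if (length(tl_fields) != n_tl) {
    stop("need exactly ", n_tl, " TL-bin fields (uncovered TL bin?)",
         call. = FALSE)
  }
  g <- tl_fields[[1]]$grid; yrs <- tl_fields[[1]]$years
  for (f in tl_fields) {
    stopifnot(inherits(f, "ta_field"))
    stopifnot_same_grid(g, f$grid, "TL fields")
    stopifnot(identical(yrs, f$years))
  }
  out <- vector("list", n_w)
  for (j in seq_len(n_w)) {
    acc <- array(0, dim(tl_fields[[1]]$values))
    for (i in seq_len(n_tl)) {
      acc <- acc + map$mapping[i, j] * tl_fields[[i]]$values
    }
    out[[j]] <- gridded_field(g, yrs, acc, paste0("b_", labels[j]), "g m-2")
  }
  names(out) <- labels
  out
}

#' Per-class amplification profile
#'
#' Global per-class biomass changes and their amplification ratios against
#' one global NPP change, in ascending class order, with a monotonicity
#' diagnostic of the change magnitudes along the food web.
#'
#' @param member a [member_output()] with class fields.
#' @param npp the forcing NPP [gridded_field()].
#' @param reference_window,target_window year intervals.
#' @param weighted area weighting (default `TRUE`).
#' @param flat_tol spread (percentage points) below which the profile is
#'   called `"flat"`; also the slack for the strict orderings. Default 0.5.
#' @return `data.frame(class_label, delta_b_pct, r)` with attributes
#'   `delta_npp_pct` and `diagnostic` (one of `"flat"`,
#'   `"increasing magnitude"`, `"decreasing magnitude"`,
#'   `"non-monotone"`).
#' @export
amplification_profile <- function(member, npp,
                                  reference_window = c(1995L, 2014L),
                                  target_window = c(2090L, 2099L),
                                  weighted = TRUE, flat_tol = 0.5) {
  prof <- per_class_relative_change(member, reference_window, target_window,
                                    weighted = weighted)
  gref <- area_weighted_mean(window_climatology(npp, reference_window),
                             npp$grid, weighted = weighted)
  gfut <- area_weighted_mean(window_climatology(npp, target_window),
                             npp$grid, weighted = weighted)
  dnpp <- 100 * (gfut - gref) / gref
  prof$r <- compute_r(prof$delta_b_pct, dnpp)
  mag <- abs(prof$delta_b_pct)
  d <- diff(mag)
  diagnostic <-
    if (length(d) == 0 || max(mag) - min(mag) < flat_tol) "flat"
    else if (all(d > -flat_tol) && any(d > flat_tol)) "increasing magnitude"
    else if (all(d < flat_tol) && any(d < -flat_tol)) "decreasing magnitude"
    else "non-monotone"
  attr(prof, "delta_npp_pct") <- dnpp
  attr(prof, "diagnostic") <- diagnostic
  prof
}
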