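#' Regular latitude-longitude grid
#'
#' Container for a regular lat-lon grid with cosine-latitude area weights and
#' a shared land/ocean mask. All per-cell fields of one analysis live on one
#' such grid; mixing grids is an error everywhere in the package.
#'
#' @param lat numeric vector of cell-center latitudes in degrees north,
#'   strictly ascending, regularly spaced.
#' @param lon numeric vector of cell-center longitudes in degrees east,
#'   regularly spaced.
#' @param ocean_mask logical matrix `length(lat) x length(lon)`; `TRUE` marks
#'   ocean. Defaults to all-ocean.
#' @return An object of class `ta_grid`: a list with `lat`, `lon`,
#'   `cell_area` (relative weights, proportional to cos(latitude)) and
#'   `ocean_mask`.
#' @details Area weights depend only on latitude: `w = cos(lat * pi/180)`,
#'   floored at a tiny positive value so polar rows never get weight zero.
#' @examples
#' g <- ta_grid(lat = seq(-88, 88, by = 4), lon = seq(-178, 178, by = 4))
#' @export
ta_grid <- function(lat, lon, ocean_mask = NULL) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  check_regular_axis(lat, "lat", ascending = TRUE)
  check_regular_axis(lon, "lon")
  if (is.null(ocean_mask)) {
    ocean_mask <- matrix(TRUE, length(lat), length(lon))
  }
  ocean_mask <- as.matrix(ocean_mask)
  storage.mode(ocean_mask) <- "logical"
  if (!identical(dim(ocean_mask), c(length(lat), length(lon)))) {
    stop("ocean_mask must be a ", length(lat), " x ", length(lon),
         " logical matrix", call. = FALSE)
  }
  w <- pmax(cos(lat * pi / 180), 1e-8)
  structure(
    list(lat = lat, lon = lon,
         cell_area = matrix(w, length(lat), length(lon)),
         ocean_mask = ocean_mask),
    class = "ta_grid")
}

check_regular_axis <- function(x, name, ascending = FALSE, tol = 1e-6) {
  if (length(x) < 1 || anyNA(x)) {
    stop("axis '", name, "' must be non-empty and free of NA", call. = FALSE)
  }
  if (length(x) > 1) {
    d <- diff(x)
    if (ascending && any(d <= 0)) {
      stop("axis '", name, "' must be strictly ascending", call. = FALSE)
    }
    if (diff(range(abs(d))) > tol * max(abs(d))) {
      stop("axis '", name, "' is not regularly spaced", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.ta_grid <- function(x, ...) {
  cat(sprintf("<ta_grid> %d x %d cells, lat [%g, %g], lon [%g, %g], %.1f%% ocean\n",
              length(x$lat), length(x$lon), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon), 100 * mean(x$ocean_mask)))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-8) {
  isTRUE(all.equal(a$lat, b$lat, tolerance = tol)) &&
    isTRUE(all.equal(a$lon, b$lon, tolerance = tol)) &&
    identical(a$ocean_mask, b$ocean_mask)
}

stopifnot_same_grid <- function(a, b, what = "fields") {
  if (!grids_equal(a, b)) {
    stop("grid mismatch between ", what,
         " (lat/lon axes and ocean masks must be identical)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Area-weighted mean over ocean cells
#'
#' Mean of a per-cell slice over the ocean (optionally restricted to a
#' subset), weighted by relative cell area (proportional to cos(latitude)).
#'
#' @param values numeric matrix `nlat x nlon`; `NA` cells are skipped.
#' @param grid a [ta_grid()].
#' @param subset_mask optional logical matrix further restricting the cells.
#' @param weighted if `FALSE`, plain (unweighted) cell averaging — the
#'   sensitivity mode; default `TRUE`.
#' @return A single number.
#' @export
area_weighted_mean <- function(values, grid, subset_mask = NULL,
                               weighted = TRUE) {
  stopifnot(inherits(grid, "ta_grid"))
  values <- as.matrix(values)
  keep <- grid$ocean_mask & !is.na(values)
  if (!is.null(subset_mask)) keep <- keep & subset_mask
  if (!any(keep)) stop("area_weighted_mean: empty cell subset", call. = FALSE)
  w <- if (weighted) grid$cell_area[keep] else rep(1, sum(keep))
  sum(w * values[keep]) / sum(w)
}

#' Area fraction of a cell set within the ocean
#'
#' @param mask logical matrix of the cells of interest.
#' @param grid a [ta_grid()].
#' @param within optional logical matrix defining the reference area
#'   (default: the whole ocean).
#' @param weighted cosine-latitude weighting (default) or plain counting.
#' @return Fraction in `[0, 1]`.
#' @export
area_fraction <- function(mask, grid, within = NULL, weighted = TRUE) {
  stopifnot(inherits(grid, "ta_grid"))
  base <- grid$ocean_mask
  if (!is.null(within)) base <- base & within
  if (!any(base)) stop("area_fraction: empty reference area", call. = FALSE)
  w <- if (weighted) grid$cell_area else array(1, dim(grid$cell_area))
  sum(w[base & mask]) / sum(w[base])
}
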