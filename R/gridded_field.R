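#' Annual gridded field
#'
#' One variable (NPP, SST, total consumer biomass, or a per-class biomass) on
#' a regular lat-lon grid with an integer annual time axis. Values are stored
#' as a `nlat x nlon x nyear` array and are `NA` exactly on land.
#'
#' @param grid a [ta_grid()].
#' @param years strictly increasing, contiguous integer years.
#' @param values numeric array `nlat x nlon x nyear` (a matrix is accepted
#'   for a single year). Land cells are forced to `NA`.
#' @param var_name variable name, e.g. `"npp"`, `"sst"`, `"tcb"` or a class
#'   biomass label.
#' @param units free-text units, e.g. `"mol C m-2 yr-1"`, `"degC"`,
#'   `"g m-2"`.
#' @return An object of class `ta_field`.
#' @details NPP and biomass variables must be non-negative where present;
#'   violations are an error. Ocean cells must not be `NA` (the all-or-
#'   nothing missing rule for window statistics is applied downstream).
#' @export
gridded_field <- function(grid, years, values, var_name, units = "") {
  stopifnot(inherits(grid, "ta_grid"))
  years <- as.integer(years)
  if (length(years) > 1 && !all(diff(years) == 1L)) {
    stop("years must be strictly increasing and contiguous", call. = FALSE)
  }
  if (length(dim(values)) == 2L) values <- array(values, c(dim(values), 1L))
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  if (!identical(dim(values), c(nlat, nlon, length(years)))) {
    stop("values must be a ", nlat, " x ", nlon, " x ", length(years),
         " array", call. = FALSE)
  }
  land <- !grid$ocean_mask
  values[array(land, dim(values))] <- NA_real_
  if (var_name %in% c("npp", "tcb") || grepl("^b_", var_name)) {
    if (any(values < 0, na.rm = TRUE)) {
      stop("variable '", var_name, "' must be non-negative", call. = FALSE)
    }
  }
  structure(
    list(grid = grid, years = years, values = values,
         var_name = as.character(var_name), units = as.character(units)),
    class = "ta_field")
}

#' @export
print.ta_field <- function(x, ...) {
  cat(sprintf("<ta_field> '%s' [%s], years %d-%d, grid %d x %d\n",
              x$var_name, x$units, min(x$years), max(x$years),
              length(x$grid$lat), length(x$grid$lon)))
  invisible(x)
}

# nlat x nlon slice for one year
field_year <- function(field, year) {
  i <- match(as.integer(year), field$years)
  if (is.na(i)) stop("year ", year, " not in field", call. = FALSE)
  field$values[, , i]
}

fields_equal <- function(a, b, tol = 1e-12) {
  grids_equal(a$grid, b$grid) && identical(a$years, b$years) &&
    isTRUE(all.equal(a$values, b$values, tolerance = tol))
}

#' One (ecosystem model, forcing model) ensemble member
#'
#' Bundles the total consumer biomass field of one marine ecosystem model run
#' with its per-class biomass fields and the class scheme describing them.
#' Total consumer biomass is the biomass of all organisms above trophic
#' level 1; for synthetic members it equals the sum of the class biomasses.
#'
#' @param mem_name ecosystem-model identifier.
#' @param esm_name forcing-model identifier.
#' @param tcb total consumer biomass [ta_field()].
#' @param class_biomass named list of per-class [ta_field()]s, ascending
#'   class size; may be empty for models without class output.
#' @param class_scheme a [class_scheme()] describing the class axis, or
#'   `NULL` when `class_biomass` is empty.
#' @return An object of class `ta_member`.
#' @export
member_output <- function(mem_name, esm_name, tcb, class_biomass = list(),
                          class_scheme = NULL) {
  stopifnot(inherits(tcb, "ta_field"))
  for (f in class_biomass) {
    stopifnot(inherits(f, "ta_field"))
    stopifnot_same_grid(tcb$grid, f$grid, "member fields")
    if (!identical(f$years, tcb$years)) {
      stop("class biomass years must match tcb years", call. = FALSE)
    }
  }
  if (length(class_biomass) > 0 && is.null(class_scheme)) {
    stop("class_scheme required when class biomasses are present",
         call. = FALSE)
  }
  if (!is.null(class_scheme) &&
      length(class_biomass) != length(class_scheme$labels)) {
    stop("class_biomass and class_scheme length mismatch", call. = FALSE)
  }
  structure(
    list(mem_name = mem_name, esm_name = esm_name, tcb = tcb,
         class_biomass = class_biomass, class_scheme = class_scheme),
    class = "ta_member")
}

#' @export
print.ta_member <- function(x, ...) {
  cat(sprintf("<ta_member> %s / %s, %d classes, years %d-%d\n",
              x$mem_name, x$esm_name, length(x$class_biomass),
              min(x$tcb$years), max(x$tcb$years)))
  invisible(x)
}
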