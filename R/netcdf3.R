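# Minimal NetCDF-3 ("classic") reader/writer.
#
# No NetCDF library is available in the supported R stack, so the classic
# binary format is implemented directly: big-endian, header (dims, global
# attributes, variables) followed by per-variable data, record variables
# interleaved per record. Writing always produces version-1 (32-bit offset)
# files with fixed dimensions; reading also accepts version-2 (64-bit
# offset) files and record variables, which covers files produced by common
# tools (e.g. scipy) for ISIMIP-like annual per-variable layouts.
# netCDF-4/HDF5 files are rejected with a clear error.

NC_BYTE <- 1L; NC_CHAR <- 2L; NC_SHORT <- 3L
NC_INT <- 4L; NC_FLOAT <- 5L; NC_DOUBLE <- 6L
NC_DIMENSION <- 10L; NC_VARIABLE <- 11L; NC_ATTRIBUTE <- 12L
NC_FILL_DOUBLE <- 9.9692099683868690e+36

nc_type_size <- c(1L, 1L, 2L, 4L, 4L, 8L)

pad4 <- function(n) as.integer((n + 3L) %/% 4L) * 4L

# ---- writing ---------------------------------------------------------------

nc3_name_bytes <- function(name) 4L + pad4(nchar(name, type = "bytes"))

nc3_att_bytes <- function(att) {
  # att: list(name, type, values)
  n <- if (att$type == NC_CHAR) nchar(att$values, type = "bytes") else length(att$values)
  nc3_name_bytes(att$name) + 8L + pad4(n * nc_type_size[att$type])
}

nc3_write_name <- function(con, name) {
  n <- nchar(name, type = "bytes")
  writeBin(n, con, size = 4L, endian = "big")
  writeChar(name, con, nchars = n, eos = NULL)
  if (pad4(n) > n) writeBin(raw(pad4(n) - n), con)
}

nc3_write_values <- function(con, type, values) {
  if (type == NC_CHAR) {
    n <- nchar(values, type = "bytes")
    writeChar(values, con, nchars = n, eos = NULL)
  } else if (type == NC_INT) {
    n <- 4L * length(values)
    writeBin(as.integer(values), con, size = 4L, endian = "big")
  } else if (type == NC_DOUBLE) {
    n <- 8L * length(values)
    writeBin(as.double(values), con, size = 8L, endian = "big")
  } else if (type == NC_FLOAT) {
    n <- 4L * length(values)
    writeBin(as.double(values), con, size = 4L, endian = "big")
  } else stop("unsupported write type ", type, call. = FALSE)
  if (pad4(n) > n) writeBin(raw(pad4(n) - n), con)
  invisible(NULL)
}

nc3_write_attlist <- function(con, atts) {
  if (length(atts) == 0L) {
    writeBin(c(0L, 0L), con, size = 4L, endian = "big")
    return(invisible(NULL))
  }
  writeBin(c(NC_ATTRIBUTE, length(atts)), con, size = 4L, endian = "big")
  for (a in atts) {
    nc3_write_name(con, a$name)
    writeBin(a$type, con, size = 4L, endian = "big")
    n <- if (a$type == NC_CHAR) nchar(a$values, type = "bytes") else length(a$values)
    writeBin(as.integer(n), con, size = 4L, endian = "big")
    nc3_write_values(con, a$type, a$values)
  }
  invisible(NULL)
}

# dims: named integer vector; vars: list of list(name, dims (names), type,
# atts, data). All dims fixed (numrecs = 0).
nc3_write <- function(path, dims, vars) {
  dim_names <- names(dims)
  header <- 8L                                         # magic + numrecs
  header <- header + 8L + sum(vapply(dim_names, nc3_name_bytes, 0L) + 4L)
  header <- header + 8L                                # no global atts
  var_bytes <- vapply(vars, function(v) {
    nc3_name_bytes(v$name) + 4L + 4L * length(v$dims) +
      (if (length(v$atts)) 8L + sum(vapply(v$atts, nc3_att_bytes, 0L)) else 8L) +
      12L                                              # type + vsize + begin(v1)
  }, 0L)
  header <- header + 8L + sum(var_bytes)

  sizes <- vapply(vars, function(v) {
    pad4(prod(dims[v$dims]) * nc_type_size[v$type])
  }, 0)
  begins <- header + cumsum(c(0, sizes[-length(sizes)]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("CDF", con, nchars = 3L, eos = NULL)
  writeBin(as.raw(1L), con)
  writeBin(0L, con, size = 4L, endian = "big")         # numrecs
  writeBin(c(NC_DIMENSION, length(dims)), con, size = 4L, endian = "big")
  for (i in seq_along(dims)) {
    nc3_write_name(con, dim_names[i])
    writeBin(as.integer(dims[i]), con, size = 4L, endian = "big")
  }
  nc3_write_attlist(con, list())                       # global atts
  writeBin(c(NC_VARIABLE, length(vars)), con, size = 4L, endian = "big")
  for (i in seq_along(vars)) {
    v <- vars[[i]]
    nc3_write_name(con, v$name)
    writeBin(length(v$dims), con, size = 4L, endian = "big")
    writeBin(match(v$dims, dim_names) - 1L, con, size = 4L, endian = "big")
    nc3_write_attlist(con, v$atts)
    writeBin(v$type, con, size = 4L, endian = "big")
    writeBin(as.integer(pad4(prod(dims[v$dims]) * nc_type_size[v$type])),
             con, size = 4L, endian = "big")
    writeBin(as.integer(begins[i]), con, size = 4L, endian = "big")
  }
  for (i in seq_along(vars)) {
    stopifnot(seek(con) == begins[i])
    nc3_write_values(con, vars[[i]]$type, vars[[i]]$data)
  }
  invisible(path)
}

# ---- reading ---------------------------------------------------------------

nc3_read_name <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  s <- readChar(con, n, useBytes = TRUE)
  if (pad4(n) > n) readBin(con, "raw", pad4(n) - n)
  s
}

nc3_read_values <- function(con, type, n) {
  bytes <- n * nc_type_size[type]
  out <- switch(as.character(type),
    "1" = readBin(con, "integer", n, size = 1L, signed = TRUE),
    "2" = readChar(con, n, useBytes = TRUE),
    "3" = readBin(con, "integer", n, size = 2L, signed = TRUE, endian = "big"),
    "4" = readBin(con, "integer", n, size = 4L, endian = "big"),
    "5" = readBin(con, "numeric", n, size = 4L, endian = "big"),
    "6" = readBin(con, "numeric", n, size = 8L, endian = "big"),
    stop("unsupported NetCDF type ", type, call. = FALSE))
  if (pad4(bytes) > bytes) readBin(con, "raw", pad4(bytes) - bytes)
  out
}

nc3_read_attlist <- function(con) {
  tag <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  n <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (tag == 0L || n == 0L) return(list())
  atts <- vector("list", n)
  for (i in seq_len(n)) {
    name <- nc3_read_name(con)
    type <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    nel <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    atts[[i]] <- list(name = name, type = type,
                      values = nc3_read_values(con, type, nel))
  }
  names(atts) <- vapply(atts, `[[`, "", "name")
  atts
}

nc3_read_offset <- function(con, version) {
  if (version == 1L) {
    readBin(con, "integer", 1L, size = 4L, endian = "big")
  } else {
    hi <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    lo <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    if (lo < 0) lo <- lo + 2^32
    hi * 2^32 + lo
  }
}

# Parse a classic file completely. Returns list(dims, vars) where each var
# carries its data as a numeric vector in file (row-major) order.
nc3_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head4 <- readBin(con, "raw", 4L)
  if (!identical(head4[1:3], charToRaw("CDF"))) {
    if (identical(head4, as.raw(c(0x89, 0x48, 0x44, 0x46)))) {
      stop("'", path, "' looks like a netCDF-4/HDF5 file; only classic ",
           "NetCDF-3 is supported", call. = FALSE)
    }
    stop("'", path, "' is not a NetCDF classic file", call. = FALSE)
  }
  version <- as.integer(head4[4])
  if (!version %in% c(1L, 2L)) {
    stop("unsupported NetCDF classic version byte ", version, call. = FALSE)
  }
  numrecs <- readBin(con, "integer", 1L, size = 4L, endian = "big")

  tag <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  ndims <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  dims <- integer(0)
  if (tag == NC_DIMENSION && ndims > 0L) {
    dims <- integer(ndims); dn <- character(ndims)
    for (i in seq_len(ndims)) {
      dn[i] <- nc3_read_name(con)
      dims[i] <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    }
    names(dims) <- dn
  }
  rec_dim <- which(dims == 0L)
  nc3_read_attlist(con)                                # global atts, unused

  tag <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  nvars <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  vars <- list()
  if (tag == NC_VARIABLE && nvars > 0L) {
    vars <- vector("list", nvars)
    for (i in seq_len(nvars)) {
      name <- nc3_read_name(con)
      nd <- readBin(con, "integer", 1L, size = 4L, endian = "big")
      dimids <- if (nd > 0L) {
        readBin(con, "integer", nd, size = 4L, endian = "big") + 1L
      } else integer(0)
      atts <- nc3_read_attlist(con)
      type <- readBin(con, "integer", 1L, size = 4L, endian = "big")
      vsize <- readBin(con, "integer", 1L, size = 4L, endian = "big")
      begin <- nc3_read_offset(con, version)
      vars[[i]] <- list(name = name, dimids = dimids, atts = atts,
                        type = type, vsize = vsize, begin = begin)
    }
    names(vars) <- vapply(vars, `[[`, "", "name")
  }

  is_rec <- vapply(vars, function(v) {
    length(rec_dim) == 1L && length(v$dimids) > 0L && v$dimids[1] == rec_dim
  }, TRUE)
  recsize <- sum(vapply(vars[is_rec], `[[`, 0L, "vsize"))

  for (i in seq_along(vars)) {
    v <- vars[[i]]
    shape <- dims[v$dimids]
    if (is_rec[i]) {
      shape[1] <- numrecs
      per <- prod(dims[v$dimids[-1]])
      nrecvars <- sum(is_rec)
      out <- vector(if (v$type %in% c(NC_FLOAT, NC_DOUBLE)) "numeric" else "integer",
                    per * numrecs)
      step <- if (nrecvars == 1L) per * nc_type_size[v$type] else recsize
      for (r in seq_len(numrecs)) {
        seek(con, v$begin + (r - 1) * step)
        out[((r - 1) * per + 1):(r * per)] <-
          readBin(con, if (v$type %in% c(NC_FLOAT, NC_DOUBLE)) "numeric" else "integer",
                  per, size = nc_type_size[v$type], endian = "big",
                  signed = v$type != NC_CHAR)
      }
      vars[[i]]$data <- out
    } else {
      seek(con, v$begin)
      vars[[i]]$data <- nc3_read_values(con, v$type, prod(shape))
    }
    vars[[i]]$shape <- as.integer(shape)
    vars[[i]]$dim_names <- names(dims)[v$dimids]
  }
  list(dims = dims, vars = vars, numrecs = numrecs)
}

# ---- gridded-field interface ----------------------------------------------

#' Write an annual gridded field to NetCDF
#'
#' Writes one variable in the ISIMIP-like per-variable layout: classic
#' NetCDF-3, dimensions `(time, lat, lon)`, coordinate variables `lat`
#' (degrees north), `lon` (degrees east) and `time` (calendar years), a
#' `units` attribute and `_FillValue` on land cells.
#'
#' @param field a [gridded_field()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_gridded_netcdf <- function(field, path) {
  stopifnot(inherits(field, "ta_field"))
  nlat <- length(field$grid$lat); nlon <- length(field$grid$lon)
  nt <- length(field$years)
  vals <- field$values
  vals[is.na(vals)] <- NC_FILL_DOUBLE
  # file order: time slowest, lon fastest
  flat <- as.vector(aperm(vals, c(2L, 1L, 3L)))
  dims <- c(time = nt, lat = nlat, lon = nlon)
  vars <- list(
    list(name = "time", dims = "time", type = NC_INT,
         atts = list(list(name = "units", type = NC_CHAR, values = "year")),
         data = field$years),
    list(name = "lat", dims = "lat", type = NC_DOUBLE,
         atts = list(list(name = "units", type = NC_CHAR,
                          values = "degrees_north")),
         data = field$grid$lat),
    list(name = "lon", dims = "lon", type = NC_DOUBLE,
         atts = list(list(name = "units", type = NC_CHAR,
                          values = "degrees_east")),
         data = field$grid$lon),
    list(name = field$var_name, dims = c("time", "lat", "lon"),
         type = NC_DOUBLE,
         atts = list(
           list(name = "units", type = NC_CHAR,
                values = if (nzchar(field$units)) field$units else "1"),
           list(name = "_FillValue", type = NC_DOUBLE,
                values = NC_FILL_DOUBLE)),
         data = flat))
  nc3_write(path, dims, vars)
  invisible(path)
}

match_dim <- function(dim_names, aliases) {
  hit <- which(tolower(dim_names) %in% aliases)
  if (length(hit) != 1L) return(NA_integer_)
  hit
}

#' Read an annual gridded field from NetCDF
#'
#' Reads one `(time, lat, lon)` variable from a classic NetCDF-3 file. Axis
#' order and orientation are normalised internally (descending latitudes are
#' flipped); the ocean mask is inferred from cells that are missing in every
#' year. The time coordinate must be annual (consecutive years), either as
#' plain calendar years or `"years since <year>..."` CF units.
#'
#' @param path file path.
#' @param var_name variable to read.
#' @return A [gridded_field()].
#' @export
read_gridded_netcdf <- function(path, var_name) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  nc <- nc3_read(path)
  if (!var_name %in% names(nc$vars)) {
    stop("variable '", var_name, "' not found in ", path, " (has: ",
         paste(names(nc$vars), collapse = ", "), ")", call. = FALSE)
  }
  v <- nc$vars[[var_name]]
  if (length(v$dimids) != 3L) {
    stop("variable '", var_name, "' must have 3 dims (time, lat, lon)",
         call. = FALSE)
  }
  it <- match_dim(v$dim_names, c("time", "year"))
  ila <- match_dim(v$dim_names, c("lat", "latitude", "y"))
  ilo <- match_dim(v$dim_names, c("lon", "longitude", "x"))
  if (anyNA(c(it, ila, ilo))) {
    stop("cannot identify (time, lat, lon) among dims: ",
         paste(v$dim_names, collapse = ", "), call. = FALSE)
  }

  coord <- function(i, what) {
    cv <- nc$vars[[v$dim_names[i]]]
    if (is.null(cv)) stop("missing ", what, " coordinate variable '",
                          v$dim_names[i], "'", call. = FALSE)
    as.numeric(cv$data)
  }
  time_raw <- coord(it, "time")
  lat <- coord(ila, "lat")
  lon <- coord(ilo, "lon")

  tunits <- nc$vars[[v$dim_names[it]]]$atts[["units"]]
  years <- time_raw
  if (!is.null(tunits) && grepl("since", tunits$values)) {
    m <- regmatches(tunits$values,
                    regexec("^years? since\\s+(-?[0-9]+)", tunits$values))[[1]]
    if (length(m) == 2L) years <- time_raw + as.numeric(m[2])
  }
  if (any(abs(years - round(years)) > 1e-6) ||
      (length(years) > 1 && !all(diff(round(years)) == 1))) {
    stop("time axis of '", path, "' is not annual consecutive years",
         call. = FALSE)
  }
  years <- as.integer(round(years))

  # file data is row-major over v$dim order; build col-major then reorder
  arr <- array(v$data, dim = rev(v$shape))
  arr <- aperm(arr, rev(seq_len(3L)))          # now indexed in v$dim order
  arr <- aperm(arr, c(ila, ilo, it))           # -> (lat, lon, time)

  fv <- v$atts[["_FillValue"]]
  if (is.null(fv)) fv <- v$atts[["missing_value"]]
  if (!is.null(fv)) {
    fill <- as.numeric(fv$values[1])
    tol <- abs(fill) * 1e-5
    arr[!is.na(arr) & abs(arr - fill) <= tol] <- NA_real_
  }
  arr[is.nan(arr)] <- NA_real_
  arr[!is.na(arr) & abs(arr) > 9e36] <- NA_real_

  if (length(lat) > 1 && lat[1] > lat[2]) {
    lat <- rev(lat); arr <- arr[rev(seq_along(lat)), , , drop = FALSE]
  }
  if (length(lon) > 1 && is.unsorted(lon)) {
    o <- order(lon); lon <- lon[o]; arr <- arr[, o, , drop = FALSE]
  }
  ot <- order(years)
  years <- years[ot]; arr <- arr[, , ot, drop = FALSE]

  land <- apply(is.na(arr), c(1, 2), all)
  if (any(is.na(arr) & !array(land, dim(arr)))) {
    stop("variable '", var_name, "' has cells missing in some years only; ",
         "annual all-or-nothing masking is required", call. = FALSE)
  }
  units <- v$atts[["units"]]
  grid <- ta_grid(lat, lon, ocean_mask = !land)
  gridded_field(grid, years, arr, var_name,
                units = if (is.null(units)) "" else units$values)
}
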