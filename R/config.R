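# Declarative run configuration: a serialisable key/value tree (JSON, or
# YAML when the yaml package is available) that fully determines a run.

#' Build a run configuration
#'
#' A run is either synthetic (a [synthetic_config()] generated in-run from
#' the seed) or file-based (paths to per-variable NetCDF files). The
#' thresholds mirror the analysis knobs: agreement votes, the minimum
#' `|delta NPP%|`, the R trim percentiles and the SST bin width.
#'
#' @param synthetic `NULL`, or a list of arguments for
#'   [synthetic_config()] (e.g. `list(seed = 1, grid_shape = c(45, 90))`);
#'   member entries may be plain lists of [member_spec()] arguments.
#' @param inputs `NULL`, or
#'   `list(npp = path, sst = path, members = list(list(mem_name, esm_name,
#'   tcb = path, classes = named list of paths, class_axis, class_breaks)))`.
#' @param reference_window,target_window year intervals.
#' @param agreement_votes absolute vote threshold for [vote_agreement()].
#' @param npp_exclusion_pct minimum `|delta NPP%|` for R summaries.
#' @param trim R trim percentiles.
#' @param sst_bin_width warming-bin width in degC.
#' @param weighted cosine-latitude weighting of global statistics
#'   (`FALSE` switches to plain cell counting for sensitivity checks).
#' @param seed integer seed for the synthetic source.
#' @return An object of class `ta_runconfig`.
#' @export
run_config <- function(synthetic = NULL, inputs = NULL,
                       reference_window = c(1995L, 2014L),
                       target_window = c(2090L, 2099L),
                       agreement_votes = 4L,
                       npp_exclusion_pct = 1,
                       trim = c(2.5, 97.5),
                       sst_bin_width = 0.1,
                       weighted = TRUE,
                       seed = 1L) {
  if (is.null(synthetic) == is.null(inputs)) {
    stop("exactly one of 'synthetic' or 'inputs' must be given",
         call. = FALSE)
  }
  cfg <- structure(
    list(synthetic = synthetic, inputs = inputs,
         reference_window = as.integer(reference_window),
         target_window = as.integer(target_window),
         agreement_votes = as.integer(agreement_votes),
         npp_exclusion_pct = npp_exclusion_pct,
         trim = as.numeric(trim), sst_bin_width = sst_bin_width,
         weighted = isTRUE(weighted), seed = as.integer(seed)),
    class = "ta_runconfig")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$reference_window[2] >= cfg$target_window[1]) {
    stop("validation: reference window must precede target window",
         call. = FALSE)
  }
  if (cfg$sst_bin_width <= 0) {
    stop("validation: sst_bin_width must be > 0", call. = FALSE)
  }
  if (length(cfg$trim) != 2 || cfg$trim[1] < 0 || cfg$trim[2] > 100 ||
      cfg$trim[1] >= cfg$trim[2]) {
    stop("validation: trim must be percentiles c(lo, hi) in [0, 100]",
         call. = FALSE)
  }
  n_members <- if (!is.null(cfg$synthetic)) {
    length(resolve_synthetic(cfg)$members)
  } else {
    length(cfg$inputs$members)
  }
  if (n_members < 1) stop("validation: no members configured", call. = FALSE)
  if (cfg$agreement_votes > n_members) {
    stop("validation: agreement_votes (", cfg$agreement_votes,
         ") exceeds the number of members (", n_members, ")", call. = FALSE)
  }
  invisible(cfg)
}

# Materialise the ta_synthconfig described by a run config.
resolve_synthetic <- function(cfg) {
  args <- cfg$synthetic
  if (is.null(args$seed)) args$seed <- cfg$seed
  if (is.null(args$reference_window)) args$reference_window <- cfg$reference_window
  if (is.null(args$target_window)) args$target_window <- cfg$target_window
  if (!is.null(args$members) && !inherits(args$members[[1]], "ta_memberspec")) {
    args$members <- lapply(args$members, function(m) do.call(member_spec, m))
  }
  if (!is.null(args$grid_shape)) args$grid_shape <- unlist(args$grid_shape)
  do.call(synthetic_config, args)
}

#' Read a run configuration from a file
#'
#' JSON is always supported; `.yaml`/`.yml` files are read when the yaml
#' package is installed.
#'
#' @param path config file path.
#' @return A `ta_runconfig`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  tree <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package; ",
           "use JSON instead", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(tree), known)
  if (length(unknown)) {
    stop("validation: unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, tree)
}

# Plain-list view of a config for hashing/serialisation (drops classes,
# keeps values).
config_as_list <- function(cfg) {
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    } else {
      attributes(x) <- NULL
    }
    x
  }
  strip(unclass(cfg))
}
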