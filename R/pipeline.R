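# Config-driven end-to-end pipeline: generate (or load) -> change maps ->
# classification & R -> ensemble agreement -> warming curves -> size-class
# profiles, with every artifact written to disk and a machine-readable run
# manifest. Stage boundaries match the CLI subcommands.

write_map_netcdf <- function(values, grid, var_name, units, path, year) {
  f <- gridded_field(grid, year, array(values, c(dim(grid$cell_area), 1L)),
                     var_name, units)
  write_gridded_netcdf(f, path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ta_log <- function(quiet, ...) if (!quiet) message("[trophamp] ", ...)

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and writes all artifacts below
#' `out_dir`: `inputs/` (per-variable NetCDF), `changes/` (per-member
#' change maps, NetCDF + TSV), `classify/` (integer-coded type maps, R
#' maps, area-fraction and mean-R tables), `agree/` (agreement map and
#' fractions), `warming/` (binned R curves and correlations),
#' `sizeclasses/` (per-class profiles), and `manifest.json` (config hash,
#' versions, exclusion counts, artifact checksums). Identical config and
#' seed reproduce identical files.
#'
#' @param config a [run_config()] (or a path to a config file).
#' @param out_dir output directory, created if needed.
#' @param stages subset of
#'   `c("generate", "changes", "classify", "agree", "warming",
#'   "sizeclasses")`; stages not starting from scratch reload their inputs
#'   from `out_dir`. Default: all.
#' @param quiet suppress progress/exclusion logging.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("generate", "changes", "classify",
                                    "agree", "warming", "sizeclasses"),
                         quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "ta_runconfig"))
  validate_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  run_stage <- function(name, fun) {
    ta_log(quiet, "stage ", name, " ...")
    tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- inputs ----
  ens <- NULL
  if ("generate" %in% stages) {
    ens <- run_stage("generate", function() {
      if (is.null(config$synthetic)) {
        load_ensemble_inputs(config)
      } else {
        sc <- resolve_synthetic(config)
        e <- generate_ensemble(sc)
        dir.create(file.path(out_dir, "inputs"), showWarnings = FALSE)
        write_gridded_netcdf(e$npp, file.path(out_dir, "inputs", "npp.nc"))
        write_gridded_netcdf(e$sst, file.path(out_dir, "inputs", "sst.nc"))
        for (m in e$members) {
          write_gridded_netcdf(
            m$tcb, file.path(out_dir, "inputs",
                             sprintf("tcb_%s.nc", m$mem_name)))
          for (lab in names(m$class_biomass)) {
            write_gridded_netcdf(
              m$class_biomass[[lab]],
              file.path(out_dir, "inputs",
                        sprintf("b_%s_%s.nc", sanitize_label(lab),
                                m$mem_name)))
          }
        }
        e$synth <- sc
        e
      }
    })
  } else {
    ens <- run_stage("load-inputs", function() {
      load_pipeline_inputs(config, out_dir)
    })
  }

  results <- list(config = config, ensemble = ens)
  rw <- config$reference_window; tw <- config$target_window

  # ---- change maps ----
  if (any(c("changes", "classify", "agree", "sizeclasses") %in% stages)) {
    changes <- run_stage("changes", function() {
      lapply(ens$members, function(m) {
        compute_change_maps(ens$npp, m$tcb, ens$sst,
                            reference_window = rw, target_window = tw,
                            quiet = TRUE)
      })
    })
    results$changes <- changes
    if ("changes" %in% stages) {
      d <- file.path(out_dir, "changes")
      dir.create(d, showWarnings = FALSE)
      yr <- tw[1]
      for (nm in names(changes)) {
        ch <- changes[[nm]]
        write_map_netcdf(ch$delta_npp_pct, ch$grid, "delta_npp_pct", "%",
                         file.path(d, sprintf("delta_npp_pct_%s.nc", nm)), yr)
        write_map_netcdf(ch$delta_b_pct, ch$grid, "delta_b_pct", "%",
                         file.path(d, sprintf("delta_b_pct_%s.nc", nm)), yr)
        write_map_netcdf(ch$delta_sst_degC, ch$grid, "delta_sst", "degC",
                         file.path(d, sprintf("delta_sst_%s.nc", nm)), yr)
        write_tsv(change_maps_table(ch),
                  file.path(d, sprintf("changes_%s.tsv", nm)))
      }
      counts$degenerate_npp_cells <-
        sum(vapply(changes, function(ch)
          attr(ch$delta_npp_pct, "n_degenerate"), 0))
    }
  }

  # ---- classification & R ----
  if (any(c("classify", "agree") %in% stages)) {
    tmaps <- run_stage("classify", function() {
      lapply(results$changes, classify_map)
    })
    results$type_maps <- tmaps
    if ("classify" %in% stages) {
      d <- file.path(out_dir, "classify")
      dir.create(d, showWarnings = FALSE)
      yr <- tw[1]
      frac_rows <- list(); meanr_rows <- list(); excl <- 0L; trimmed <- 0L
      for (nm in names(tmaps)) {
        ch <- results$changes[[nm]]
        codes <- tmaps[[nm]]$codes
        codes_num <- array(as.numeric(codes), dim(codes))
        codes_num[!ch$grid$ocean_mask] <- NA_real_
        write_map_netcdf(codes_num, ch$grid, "response_type_code", "1",
                         file.path(d, sprintf("types_%s.nc", nm)), yr)
        rmap <- r_ratio_map(ch)
        rmap[!is.finite(rmap)] <- NA_real_
        write_map_netcdf(rmap, ch$grid, "r_ratio", "1",
                         file.path(d, sprintf("r_%s.nc", nm)), yr)
        mem <- ens$members[[nm]]
        fr <- type_area_fractions(tmaps[[nm]], weighted = config$weighted)
        frac_rows[[nm]] <- data.frame(
          mem = mem$mem_name, esm = mem$esm_name, subset = "ocean",
          type = names(fr), fraction = unname(fr))
        mr <- mean_r_by_type(ch, trim = config$trim,
                             npp_exclusion_pct = config$npp_exclusion_pct,
                             weighted = config$weighted)
        excl <- excl + attr(mr, "n_excluded_npp")
        trimmed <- trimmed + attr(mr, "n_trimmed")
        meanr_rows[[nm]] <- cbind(
          data.frame(mem = mem$mem_name, esm = mem$esm_name), mr)
      }
      write_tsv(do.call(rbind, frac_rows),
                file.path(d, "type_fractions.tsv"))
      write_tsv(do.call(rbind, meanr_rows),
                file.path(d, "mean_r_by_type.tsv"))
      write_tsv(data.frame(code = seq_along(response_type_levels()),
                           type = response_type_levels()),
                file.path(d, "type_codes.tsv"))
      counts$cells_excluded_npp_rule <- excl
      counts$cells_trimmed_r <- trimmed
      ta_log(quiet, "classify: ", excl, " cell(s) under the |dNPP| < ",
             config$npp_exclusion_pct, "% rule, ", trimmed,
             " trimmed from R summaries")
    }
  }

  # ---- agreement ----
  if ("agree" %in% stages) {
    agr <- run_stage("agree", function() {
      vote_agreement(results$type_maps, threshold = config$agreement_votes)
    })
    results$agreement <- agr
    d <- file.path(out_dir, "agree")
    dir.create(d, showWarnings = FALSE)
    codes <- agr$modal_code
    codes_num <- array(as.numeric(codes), dim(codes))
    codes_num[is.na(codes)] <- 8  # no_agreement sentinel code
    codes_num[!agr$grid$ocean_mask] <- NA_real_
    write_map_netcdf(codes_num, agr$grid, "agreement_code", "1",
                     file.path(d, "agreement.nc"), tw[1])
    fr <- agreement_area_fractions(agr, weighted = config$weighted)
    write_tsv(data.frame(category = names(fr), fraction = unname(fr)),
              file.path(d, "agreement_fractions.tsv"))
  }

  # ---- warming curves ----
  if ("warming" %in% stages) {
    curves <- run_stage("warming", function() {
      out <- list()
      for (nm in names(ens$members)) {
        for (dir_ in c("decrease", "increase")) {
          out[[paste(nm, dir_, sep = ".")]] <- r_vs_warming(
            ens$members[[nm]], ens$npp, ens$sst,
            reference_window = rw, direction = dir_,
            bin_width = config$sst_bin_width,
            npp_exclusion_pct = config$npp_exclusion_pct,
            trim = config$trim)
        }
      }
      out
    })
    results$warming_curves <- curves
    d <- file.path(out_dir, "warming")
    dir.create(d, showWarnings = FALSE)
    rows <- lapply(curves, function(cv) {
      if (nrow(cv$bins) == 0) return(NULL)
      cbind(data.frame(mem = cv$mem_name, esm = cv$esm_name,
                       direction = cv$direction), cv$bins)
    })
    write_tsv(do.call(rbind, c(rows, make.row.names = FALSE)),
              file.path(d, "warming_curves.tsv"))
    cors <- lapply(curves, function(cv) {
      wc <- warming_correlation(cv)
      data.frame(mem = cv$mem_name, esm = cv$esm_name,
                 direction = cv$direction, pearson_r = wc$pearson_r,
                 p_value = wc$p_value, shapiro_p = wc$shapiro_p,
                 n_bins = wc$n_bins)
    })
    write_tsv(do.call(rbind, c(cors, make.row.names = FALSE)),
              file.path(d, "warming_correlations.tsv"))
  }

  # ---- size classes ----
  if ("sizeclasses" %in% stages) {
    profs <- run_stage("sizeclasses", function() {
      out <- list()
      for (nm in names(ens$members)) {
        m <- ens$members[[nm]]
        if (length(m$class_biomass) == 0) next
        out[[nm]] <- amplification_profile(
          m, ens$npp, reference_window = rw, target_window = tw,
          weighted = config$weighted)
      }
      out
    })
    results$size_profiles <- profs
    d <- file.path(out_dir, "sizeclasses")
    dir.create(d, showWarnings = FALSE)
    rows <- lapply(names(profs), function(nm) {
      p <- profs[[nm]]
      m <- ens$members[[nm]]
      data.frame(mem = m$mem_name, esm = m$esm_name,
                 axis = m$class_scheme$axis, class = p$class_label,
                 delta_b_pct = p$delta_b_pct, r = p$r,
                 delta_npp_pct = attr(p, "delta_npp_pct"),
                 diagnostic = attr(p, "diagnostic"))
    })
    write_tsv(do.call(rbind, c(rows, make.row.names = FALSE)),
              file.path(d, "size_profiles.tsv"))
  }

  # ---- manifest ----
  files <- sort(setdiff(
    list.files(out_dir, recursive = TRUE),
    "manifest.json"))
  sums <- unname(tools::md5sum(file.path(out_dir, files)))
  manifest <- list(
    package = "trophamp",
    version = as.character(utils::packageVersion("trophamp")),
    seed = config$seed,
    config_hash = config_hash(config),
    stages = stages,
    counts = counts,
    artifacts = as.list(stats::setNames(sums, files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  ta_log(quiet, "done: ", length(files), " artifact(s) in ", out_dir)
  invisible(results)
}

sanitize_label <- function(x) gsub("[^A-Za-z0-9_]+", "_", x)

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_as_list(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

change_maps_table <- function(ch) {
  grid <- ch$grid
  idx <- which(grid$ocean_mask, arr.ind = TRUE)
  data.frame(
    lat = grid$lat[idx[, 1]], lon = grid$lon[idx[, 2]],
    delta_npp_pct = ch$delta_npp_pct[idx],
    delta_b_pct = ch$delta_b_pct[idx],
    delta_sst_degC = if (is.null(ch$delta_sst_degC)) NA_real_ else
      ch$delta_sst_degC[idx])
}

# Rebuild the ensemble structure from config-declared NetCDF paths.
load_ensemble_inputs <- function(config) {
  inp <- config$inputs
  npp <- read_gridded_netcdf(inp$npp, "npp")
  sst <- read_gridded_netcdf(inp$sst, "sst")
  members <- lapply(inp$members, function(m) {
    tcb <- read_gridded_netcdf(m$tcb, "tcb")
    cls <- list(); scheme <- NULL
    if (!is.null(m$classes) && length(m$classes) > 0) {
      cls <- lapply(names(m$classes), function(lab) {
        read_gridded_netcdf(m$classes[[lab]],
                            paste0("b_", sanitize_label(lab)))
      })
      names(cls) <- names(m$classes)
      scheme <- class_scheme(
        axis = if (is.null(m$class_axis)) "weight" else m$class_axis,
        breaks = if (is.null(m$class_breaks))
          seq_len(length(cls) + 1L) else unlist(m$class_breaks),
        labels = names(cls))
    }
    member_output(m$mem_name, m$esm_name, tcb, cls, scheme)
  })
  names(members) <- vapply(inp$members, `[[`, "", "mem_name")
  list(npp = npp, sst = sst, members = members)
}

# Reload a previous generate stage from out_dir/inputs (stage composition
# for the CLI subcommands).
load_pipeline_inputs <- function(config, out_dir) {
  d <- file.path(out_dir, "inputs")
  if (!is.null(config$inputs)) return(load_ensemble_inputs(config))
  if (!dir.exists(d)) {
    stop("no ", d, "; run the generate stage first", call. = FALSE)
  }
  sc <- resolve_synthetic(config)
  npp <- read_gridded_netcdf(file.path(d, "npp.nc"), "npp")
  sst <- read_gridded_netcdf(file.path(d, "sst.nc"), "sst")
  members <- lapply(sc$members, function(spec) {
    tcb <- read_gridded_netcdf(
      file.path(d, sprintf("tcb_%s.nc", spec$mem_name)), "tcb")
    labs <- spec$class_scheme$labels
    cls <- lapply(labs, function(lab) {
      read_gridded_netcdf(
        file.path(d, sprintf("b_%s_%s.nc", sanitize_label(lab),
                             spec$mem_name)),
        paste0("b_", lab))
    })
    names(cls) <- labs
    member_output(spec$mem_name, "synthESM", tcb, cls, spec$class_scheme)
  })
  names(members) <- vapply(sc$members, `[[`, "", "mem_name")
  list(npp = npp, sst = sst, members = members, synth = sc)
}
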