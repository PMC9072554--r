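# Configuration-driven orchestration of the full analysis:
# generate/ingest -> align -> fit -> profile -> compare variants -> report.
# Every stage writes its outputs under the configured directory and is
# reproducible from the configuration and seed alone.

.pipeline_schema <- function() {
  list(
    output_dir = "character", seed = "numeric",
    variants = "character",
    synthetic = c("compounds", "n_replicates", "sigma", "imaging_step",
                  "knockdowns"),
    dataset = "character",
    fit = c("free", "n_starts", "bound_decades", "anchors"),
    profiles = c("parameters"),
    compare = "logical",
    petab_export = "logical")
}

.validate_config <- function(config) {
  schema <- .pipeline_schema()
  unknown <- setdiff(names(config), names(schema))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  for (nm in c("synthetic", "fit", "profiles")) {
    if (!is.null(config[[nm]])) {
      bad <- setdiff(names(config[[nm]]), schema[[nm]])
      if (length(bad))
        stop("unknown keys in '", nm, "': ", paste(bad, collapse = ", "))
    }
  }
  if (is.null(config$synthetic) && is.null(config$dataset))
    stop("configuration must provide either 'synthetic' or 'dataset'")
  if (is.null(config$output_dir)) stop("'output_dir' is required")
  config
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data generation (synthetic) or ingestion (long
#' replicate table), replicate alignment, multi-start fitting of the
#' requested model variant(s), profile likelihoods, variant comparison
#' (when both variants are fitted) and a report (tables, diagnostic plots,
#' structured run log). All outputs land in `output_dir`; rerunning the
#' same configuration reproduces them bit-identically.
#'
#' @param config Path to a yaml configuration file, or an equivalent
#'   named list. Keys: `output_dir`, `seed`, `variants`,
#'   `synthetic` (`compounds`, `n_replicates`, `sigma`, `imaging_step`,
#'   `knockdowns`) or `dataset` (path to a replicate TSV with columns
#'   condition/experiment/observable/time/value), `fit` (`free`,
#'   `n_starts`, `bound_decades`, `anchors`), `profiles` (`parameters`),
#'   `compare`, `petab_export`. Unknown keys are rejected.
#' @return A results bundle (list) with the fits, profiles, comparison and
#'   file paths; written alongside as `run_log.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- .validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  variants <- config$variants %||% "hinge_latch"
  log <- list()
  t_start <- proc.time()[3]
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    val <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    log[[length(log) + 1L]] <<- list(stage = name,
                                     elapsed_s = round(proc.time()[3] - t0, 3))
    val
  }

  params <- reference_parameters()
  truth <- NULL
  reps <- stage("data", {
    if (!is.null(config$synthetic)) {
      sc <- config$synthetic
      des <- synthetic_design(
        compounds = sc$compounds %||% "DEM",
        n_replicates = sc$n_replicates %||% 3,
        sigma = sc$sigma %||% 0.1,
        imaging_times = seq(0, 48, by = sc$imaging_step %||% 2),
        knockdowns = isTRUE(sc$knockdowns))
      syn <- generate_dataset(des, params = params, seed = seed)
      truth <<- syn
      .write_tsv(syn$replicates, file.path(out_dir, "replicates.tsv"))
      syn$replicates
    } else {
      d <- utils::read.table(config$dataset, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
      d
    }
  })

  alignment <- stage("align", align_replicates(reps))
  .write_tsv(alignment$aligned, file.path(out_dir, "aligned.tsv"))
  .write_tsv(alignment$scalings, file.path(out_dir, "scalings.tsv"))

  dataset <- alignment$aligned
  dataset$value <- log(dataset$y); dataset$y <- NULL
  conds <- .conditions_from_dataset(dataset)

  fit_cfg <- config$fit %||% list()
  free <- unlist(fit_cfg$free) %||%
    c("kmod_DEM", "k_clear_auto", "V_mSRXN1", "kt_Srxn1")
  anchors <- unlist(fit_cfg$anchors) %||% c(Keap1 = 1)
  fits <- list()
  for (v in variants) {
    pb <- nrf2_problem(dataset, conds, params = params, variant = v,
                       free = free, anchors = anchors,
                       bound_decades = fit_cfg$bound_decades %||% 2)
    fits[[v]] <- stage(paste0("fit_", v),
                       nrf2_fit(pb, n_starts = fit_cfg$n_starts %||% 10,
                                seed = seed))
    est <- summary(fits[[v]])$coefficients
    est[] <- lapply(est, function(col)
      if (is.numeric(col)) signif(col, 10) else col)
    .write_tsv(est, file.path(out_dir, paste0("fit_", v, ".tsv")))
    if (isTRUE(config$petab_export))
      export_petab(pb, file.path(out_dir, paste0("petab_", v)),
                   fit = fits[[v]])
  }

  profiles <- NULL
  prof_par <- unlist((config$profiles %||% list())$parameters)
  if (length(prof_par)) {
    profiles <- stage("profiles",
                      profile(fits[[variants[1]]], which = prof_par))
    ci <- confint(profiles)
    .write_tsv(data.frame(parameter = rownames(ci),
                          estimate = vapply(profiles, `[[`, 0, "estimate"),
                          lower = ci[, 1], upper = ci[, 2],
                          class = vapply(profiles, `[[`, "", "class")),
               file.path(out_dir, "profiles.tsv"))
  }

  comparison <- NULL
  if (isTRUE(config$compare) && all(c("hinge_latch", "dissociation")
                                    %in% names(fits))) {
    comparison <- stage("compare",
                        compare_variants(fits$hinge_latch,
                                         fits$dissociation))
    write_comparison(comparison, file.path(out_dir, "comparison.json"))
  }

  stage("report", {
    grDevices::pdf(file.path(out_dir, "fit_plots.pdf"), width = 10,
                   height = 7)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(fits[[1]])
    TRUE
  })

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  run_log <- list(config_hash = cfg_hash, seed = seed,
                  total_elapsed_s = round(proc.time()[3] - t_start, 3),
                  stages = log)
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fits = fits, alignment = alignment, profiles = profiles,
                 comparison = comparison, config_hash = cfg_hash,
                 output_dir = out_dir, log = run_log))
}

# Reconstruct condition objects from the ids used in a dataset
# ("<compound>_<dose>" with optional "si<TARGET>_" prefix).
.conditions_from_dataset <- function(dataset) {
  ids <- unique(dataset$condition)
  conds <- lapply(ids, function(id) {
    parts <- strsplit(id, "_", fixed = TRUE)[[1]]
    kd <- knockdown()
    if (startsWith(parts[1], "si")) {
      kd <- knockdown(sub("^si", "", parts[1]))
      parts <- parts[-1]
    }
    if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
      stop("cannot parse condition id '", id,
           "'; expected '<compound>_<dose>'")
    tt <- sort(unique(dataset$time[dataset$condition == id]))
    condition(parts[1], as.numeric(parts[2]), kd = kd, times = tt, id = id)
  })
  names(conds) <- ids
  conds
}
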