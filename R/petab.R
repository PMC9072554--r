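# PEtab-style serialisation of the fitting problem: tab-separated
# parameter / observable / condition / measurement tables plus a yaml
# index. The tables follow the PEtab naming conventions (parameterId,
# observableId, simulationConditionId, measurement, time, parameterScale,
# nominalValue, estimate) with model-specific condition columns, so a
# problem can be archived, inspected and reconstructed bit-faithfully.

.fmt_num <- function(x) vapply(x, function(v) sprintf("%.17g", v), "")

.write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a fit problem as a PEtab-style file set
#'
#' Writes `parameters.tsv`, `observables.tsv`, `conditions.tsv`,
#' `measurements.tsv` and `problem.yaml` into a directory. Numeric values
#' are written with 17 significant digits so that the reimported problem
#' reproduces the likelihood exactly.
#'
#' @param problem An [nrf2_problem()].
#' @param fit Optional [nrf2_fit()]; its estimates are recorded in an
#'   `estimatedValue` column.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_petab <- function(problem, dir, fit = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  params <- problem$params
  tmpl <- problem$template
  est_val <- if (!is.null(fit)) fit$coefficients else NULL

  kin <- data.frame(parameterId = names(params),
                    parameterScale = "log10",
                    nominalValue = .fmt_num(unname(params)),
                    estimate = as.integer(names(params) %in% problem$free),
                    stringsAsFactors = FALSE)
  obs_par <- tmpl[tmpl$kind != "kinetic", , drop = FALSE]
  if (nrow(obs_par)) {
    nat <- ifelse(obs_par$trans == "log10", 10^obs_par$start, obs_par$start)
    kin <- rbind(kin, data.frame(parameterId = obs_par$name,
                                 parameterScale = ifelse(obs_par$trans == "log10",
                                                         "log10", "lin"),
                                 nominalValue = .fmt_num(nat),
                                 estimate = 1L, stringsAsFactors = FALSE))
  }
  lo <- hi <- rep(NA_character_, nrow(kin))
  i <- match(kin$parameterId, tmpl$name)
  sel <- !is.na(i)
  nat_b <- function(col) ifelse(tmpl$trans[i[sel]] == "log10",
                                10^tmpl[[col]][i[sel]], tmpl[[col]][i[sel]])
  lo[sel] <- .fmt_num(nat_b("lower")); hi[sel] <- .fmt_num(nat_b("upper"))
  kin$lowerBound <- lo; kin$upperBound <- hi
  if (!is.null(est_val)) {
    ev <- rep(NA_character_, nrow(kin))
    j <- match(kin$parameterId, names(est_val))
    ev[!is.na(j)] <- .fmt_num(unname(est_val[j[!is.na(j)]]))
    kin$estimatedValue <- ev
  }
  .write_tsv(kin, file.path(dir, "parameters.tsv"))

  m <- problem$map
  .write_tsv(data.frame(observableId = m$observable,
                        observableSpecies = m$species,
                        observableTransformation = "log",
                        scale = .fmt_num(m$scale), offset = .fmt_num(m$offset),
                        noiseSd = .fmt_num(m$sigma),
                        offsetFree = as.integer(m$offset_free),
                        noiseDistribution = "normal"),
             file.path(dir, "observables.tsv"))

  conds <- problem$conditions
  .write_tsv(data.frame(
    conditionId = names(conds),
    compound = vapply(conds, function(c) c$stimulus$compound, ""),
    dose = .fmt_num(vapply(conds, function(c) c$stimulus$dose, 0)),
    onset = .fmt_num(vapply(conds, function(c) c$stimulus$onset, 0)),
    centerOffset = .fmt_num(vapply(conds, function(c) c$stimulus$center_offset, 0)),
    width = .fmt_num(vapply(conds, function(c) c$stimulus$width, 0)),
    dmsoBackground = vapply(conds, function(c)
      as.integer(isTRUE(c$stimulus$dmso_background)), 0L),
    kdTarget = vapply(conds, function(c) c$knockdown$target, ""),
    kdFactor = vapply(conds, function(c)
      if (is.null(c$knockdown$factor)) "" else .fmt_num(c$knockdown$factor), ""),
    kdDuration = .fmt_num(vapply(conds, function(c) c$knockdown$duration, 0)),
    horizon = .fmt_num(vapply(conds, function(c) c$horizon, 0))),
    file.path(dir, "conditions.tsv"))

  d <- problem$dataset
  .write_tsv(data.frame(observableId = d$observable,
                        simulationConditionId = d$condition,
                        time = .fmt_num(d$time),
                        measurement = .fmt_num(d$value)),
             file.path(dir, "measurements.tsv"))

  yaml::write_yaml(list(
    format_version = 1,
    variant = problem$variant,
    free_parameters = as.list(problem$free),
    anchors = as.list(problem$anchors),
    rtol = problem$rtol, atol = problem$atol,
    parameter_file = "parameters.tsv", observable_files = "observables.tsv",
    condition_files = "conditions.tsv", measurement_files = "measurements.tsv"),
    file.path(dir, "problem.yaml"))
  invisible(dir)
}

#' Import a PEtab-style problem
#'
#' Reconstructs an [nrf2_problem()] from a directory written by
#' [export_petab()]. Schema violations are reported with the offending
#' file and row.
#'
#' @param dir Directory containing `problem.yaml` and the tables.
#' @return An `nrf2_problem`.
#' @export
import_petab <- function(dir) {
  yml_path <- file.path(dir, "problem.yaml")
  if (!file.exists(yml_path)) stop("problem.yaml not found in ", dir)
  yml <- yaml::read_yaml(yml_path)
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE, stringsAsFactors = FALSE)
  par_tab <- rd(yml$parameter_file)
  obs_tab <- rd(yml$observable_files)
  con_tab <- rd(yml$condition_files)
  mea_tab <- rd(yml$measurement_files)

  kin <- par_tab[par_tab$parameterId %in% .param_names(), ]
  params <- stats::setNames(as.numeric(kin$nominalValue), kin$parameterId)

  bad <- which(!(obs_tab$observableSpecies %in% species_names()))
  if (length(bad))
    stop("observables.tsv row ", bad[1], ": unknown species '",
         obs_tab$observableSpecies[bad[1]], "'")
  map <- data.frame(observable = obs_tab$observableId,
                    species = obs_tab$observableSpecies,
                    scale = as.numeric(obs_tab$scale),
                    offset = as.numeric(obs_tab$offset),
                    sigma = as.numeric(obs_tab$noiseSd),
                    offset_free = obs_tab$offsetFree == 1,
                    stringsAsFactors = FALSE)

  conds <- lapply(seq_len(nrow(con_tab)), function(i) {
    r <- con_tab[i, ]
    if (!r$compound %in% c("DEM", "DCF", "OMZ", "DMSO"))
      stop("conditions.tsv row ", i, ": unknown compound '", r$compound, "'")
    kd <- knockdown(r$kdTarget,
                    factor = if (identical(r$kdFactor, "") ||
                                 is.na(r$kdFactor)) NULL
                             else as.numeric(r$kdFactor),
                    duration = as.numeric(r$kdDuration))
    tt <- sort(unique(as.numeric(
      mea_tab$time[mea_tab$simulationConditionId == r$conditionId])))
    if (!length(tt)) tt <- 0
    cc <- condition(r$compound, as.numeric(r$dose), kd = kd, times = tt,
                    horizon = as.numeric(r$horizon),
                    dmso_background = r$dmsoBackground == 1,
                    id = r$conditionId)
    cc$stimulus$center_offset <- as.numeric(r$centerOffset)
    cc$stimulus$width <- as.numeric(r$width)
    cc
  })
  names(conds) <- con_tab$conditionId

  bad <- which(!(mea_tab$observableId %in% map$observable))
  if (length(bad))
    stop("measurements.tsv row ", bad[1], ": unknown observable '",
         mea_tab$observableId[bad[1]], "'")
  bad <- which(!(mea_tab$simulationConditionId %in% names(conds)))
  if (length(bad))
    stop("measurements.tsv row ", bad[1], ": unknown condition '",
         mea_tab$simulationConditionId[bad[1]], "'")
  dataset <- data.frame(condition = mea_tab$simulationConditionId,
                        observable = mea_tab$observableId,
                        time = as.numeric(mea_tab$time),
                        value = as.numeric(mea_tab$measurement),
                        stringsAsFactors = FALSE)

  free <- par_tab$parameterId[par_tab$estimate == 1]
  free <- intersect(free, c(.param_names(),
                            paste0("scale_", map$observable),
                            paste0("offset_", map$observable)))
  anchors <- unlist(yml$anchors)
  nrf2_problem(dataset, conds, params = params, map = map,
               variant = yml$variant, free = free, anchors = anchors,
               rtol = yml$rtol %||% 1e-6, atol = yml$atol %||% 1e-8)
}
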