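# Maximum-likelihood calibration. A fit problem couples a dataset (aligned
# log-scale measurements) with the conditions that generated it, an
# observation map, a parameter template and the set of free parameters.
# All rates are estimated on log10 scale inside box bounds; the objective
# is the -2 log-likelihood of the log-normal constant-sd error model, with
# the per-target noise sd concentrated out analytically (its ML estimate
# given the residuals is the root mean squared residual per target).

.SIGMA_MIN <- 1e-3

#' Define a fitting problem
#'
#' @param dataset Data frame with columns `condition`, `observable`,
#'   `time`, `value` (log-scale measurements, e.g. `log(y)` of aligned
#'   time courses).
#' @param conditions Named list of [condition()] objects covering every
#'   condition id in the dataset. Observation times are extended to the
#'   dataset times automatically.
#' @param params Full parameter template (fixed parameters keep these
#'   values; free parameters start here).
#' @param map Observation map (see [default_observation_map()]).
#' @param variant Model variant to fit.
#' @param free Character vector of free parameters: kinetic parameter
#'   names, and/or `"scale_<observable>"` / `"offset_<observable>"` for
#'   observation parameters.
#' @param anchors Steady-state anchors applied at every objective
#'   evaluation via [constrain_parameters()] (the anchored production
#'   rates are therefore not free parameters). `NULL` disables anchoring.
#' @param bound_decades Half-width of the log10 box bounds around the
#'   template values.
#' @param lower,upper Optional named overrides of the box bounds (natural
#'   scale).
#' @param rtol,atol Solver tolerances used during fitting.
#' @param sigma_mode `"concentrated"` (default): the per-target noise sds
#'   are profiled out analytically at every evaluation; `"fixed"`: the
#'   sds from the observation map are treated as known.
#' @return An object of class `nrf2_problem`.
#' @export
nrf2_problem <- function(dataset, conditions, params = reference_parameters(),
                         map = default_observation_map(),
                         variant = "hinge_latch", free = character(),
                         anchors = c(Keap1 = 1), bound_decades = 5,
                         lower = NULL, upper = NULL,
                         rtol = 1e-6, atol = 1e-8,
                         sigma_mode = c("concentrated", "fixed")) {
  sigma_mode <- match.arg(sigma_mode)
  need <- c("condition", "observable", "time", "value")
  miss <- setdiff(need, names(dataset))
  if (length(miss)) stop("dataset lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(dataset$value))) stop("non-finite dataset values")
  # canonical ordering so results do not depend on how the data arrived
  dataset <- dataset[order(dataset$condition, dataset$observable,
                           dataset$time), , drop = FALSE]
  rownames(dataset) <- NULL
  cids <- unique(dataset$condition)
  missc <- setdiff(cids, names(conditions))
  if (length(missc)) stop("no condition object for: ",
                          paste(missc, collapse = ", "))
  conditions <- conditions[sort(intersect(names(conditions), cids))]
  # extend each condition's observation times to the dataset's times
  for (id in names(conditions)) {
    tt <- sort(unique(dataset$time[dataset$condition == id]))
    cc <- conditions[[id]]
    cc$times <- sort(unique(c(cc$times, tt)))
    cc$horizon <- max(cc$horizon, tt)
    conditions[[id]] <- cc
  }
  params <- validate_parameters(params)
  bad <- setdiff(free, c(.param_names(),
                         paste0("scale_", map$observable),
                         paste0("offset_", map$observable)))
  if (length(bad)) stop("unknown free parameters: ", paste(bad, collapse = ", "))
  if (!is.null(anchors) && length(anchors)) {
    amap <- c(Keap1 = "p_Keap1", Nrf2 = "p_Nrf2", p62 = "p_p62", GSH = "b_GSH")
    clash <- intersect(free, amap[names(anchors)])
    if (length(clash))
      stop("parameters eliminated by the steady-state anchors cannot be free: ",
           paste(clash, collapse = ", "))
  }
  # per-record indices into the per-condition simulation matrices
  rec <- dataset
  rec$cond_i <- match(rec$condition, names(conditions))
  rec$obs_i <- match(rec$observable, map$observable)
  if (anyNA(rec$obs_i)) stop("dataset observable not in map")
  rec$row_i <- NA_integer_
  for (i in seq_along(conditions)) {
    sel <- rec$cond_i == i
    rec$row_i[sel] <- match(round(rec$time[sel], 9),
                            round(conditions[[i]]$times, 9))
  }
  if (anyNA(rec$row_i)) stop("internal: dataset time not in condition times")
  rec$col_i <- match(map$species[rec$obs_i], species_names()) + 1L

  tmpl <- .theta_template(params, map, free, bound_decades, lower, upper)
  structure(list(dataset = dataset, conditions = conditions, params = params,
                 map = map, variant = variant, free = free, anchors = anchors,
                 template = tmpl, rec = rec, rtol = rtol, atol = atol,
                 sigma_mode = sigma_mode, bound_decades = bound_decades),
            class = "nrf2_problem")
}

#' @export
print.nrf2_problem <- function(x, ...) {
  cat("Nrf2 fit problem (", x$variant, "): ", nrow(x$dataset),
      " records, ", length(x$conditions), " conditions, ",
      nrow(x$template), " free parameters\n", sep = "")
  invisible(x)
}

# Free-parameter table: name, kind, start/lower/upper on the internal
# (log10 for rates and scales, natural for offsets) scale.
.theta_template <- function(params, map, free, bound_decades, lower, upper) {
  if (!length(free))
    return(data.frame(name = character(), kind = character(),
                      trans = character(), start = numeric(),
                      lower = numeric(), upper = numeric()))
  rows <- lapply(free, function(nm) {
    if (nm %in% .param_names()) {
      v <- unname(params[nm])
      list(name = nm, kind = "kinetic", trans = "log10", nominal = v)
    } else if (startsWith(nm, "scale_")) {
      ob <- sub("^scale_", "", nm)
      v <- map$scale[map$observable == ob]
      list(name = nm, kind = "scale", trans = "log10", nominal = v)
    } else {
      ob <- sub("^offset_", "", nm)
      v <- map$offset[map$observable == ob]
      list(name = nm, kind = "offset", trans = "identity", nominal = v)
    }
  })
  tab <- do.call(rbind, lapply(rows, function(r) {
    if (r$trans == "log10") {
      st <- log10(r$nominal)
      lo <- st - bound_decades; hi <- st + bound_decades
    } else {
      st <- r$nominal; lo <- 0; hi <- max(10 * max(r$nominal, 0.1), 1)
    }
    data.frame(name = r$name, kind = r$kind, trans = r$trans,
               start = st, lower = lo, upper = hi,
               stringsAsFactors = FALSE)
  }))
  ovr <- function(tab, vals, col) {
    if (is.null(vals)) return(tab)
    i <- match(names(vals), tab$name)
    ok <- !is.na(i)
    tab[[col]][i[ok]] <- ifelse(tab$trans[i[ok]] == "log10",
                                log10(vals[ok]), vals[ok])
    tab
  }
  tab <- ovr(tab, lower, "lower")
  tab <- ovr(tab, upper, "upper")
  tab
}

# Map an internal theta vector onto (params, map).
.apply_theta <- function(problem, theta) {
  tmpl <- problem$template
  params <- problem$params
  map <- problem$map
  val <- ifelse(tmpl$trans == "log10", 10^theta, theta)
  for (i in seq_along(val)) {
    nm <- tmpl$name[i]
    if (tmpl$kind[i] == "kinetic") params[nm] <- val[i]
    else if (tmpl$kind[i] == "scale")
      map$scale[map$observable == sub("^scale_", "", nm)] <- val[i]
    else
      map$offset[map$observable == sub("^offset_", "", nm)] <- val[i]
  }
  list(params = params, map = map)
}

# Unweighted residuals (yhat - y) at a parameter point, or NULL on failure.
.problem_residuals_raw <- function(problem, params, map) {
  params <- tryCatch({
    if (!is.null(problem$anchors) && length(problem$anchors))
      constrain_parameters(params, problem$anchors, problem$variant)
    else params
  }, error = function(e) NULL)
  if (is.null(params)) return(NULL)
  # the anchored solve already produced the equilibrium state
  state0 <- attr(params, "state0")
  if (is.null(state0)) {
    ss <- tryCatch(solve_steady_state(problem$variant, params),
                   error = function(e) NULL)
    if (is.null(ss) || !ss$converged) return(NULL)
    state0 <- ss$state0
  }
  rec <- problem$rec
  sv <- numeric(nrow(rec))
  for (i in seq_along(problem$conditions)) {
    sel <- which(rec$cond_i == i)
    if (!length(sel)) next
    sim <- tryCatch(
      simulate_condition(problem$variant, params, problem$conditions[[i]],
                         state0 = state0, rtol = problem$rtol,
                         atol = problem$atol),
      error = function(e) NULL)
    if (is.null(sim)) return(NULL)
    sv[sel] <- sim[cbind(rec$row_i[sel], rec$col_i[sel])]
  }
  arg <- map$scale[rec$obs_i] * sv + map$offset[rec$obs_i]
  if (any(arg <= 0) || any(!is.finite(arg))) return(NULL)
  log(arg) - rec$value
}

# -2 log L; sigma concentrated out per target unless fixed values given.
.nll_from_raw <- function(raw, obs, sigma = NULL) {
  if (!is.null(sigma)) {
    s <- pmax(sigma[obs], .SIGMA_MIN)
    return(sum((raw / s)^2) + sum(log(s^2)))
  }
  v <- tapply(raw^2, obs, mean)
  sig <- pmax(sqrt(v), .SIGMA_MIN)
  n_t <- tapply(raw, obs, length)
  sum((v / sig^2) * n_t) + sum(n_t * log(sig^2))
}

# sigma vector to condition .nll_from_raw on, given the problem's mode.
.problem_sigma_fixed <- function(problem) {
  if (identical(problem$sigma_mode, "fixed"))
    stats::setNames(problem$map$sigma, problem$map$observable)
  else NULL
}

#' Evaluate the fit objective at a parameter point
#'
#' Computes the concentrated -2 log-likelihood (noise sds profiled out
#' analytically per target) for an internal parameter vector or for the
#' problem's template start.
#'
#' @param problem An [nrf2_problem()].
#' @param theta Named vector on the natural scale for the free parameters
#'   (default: template values).
#' @return Scalar -2 log L (`Inf` if the model cannot be evaluated), with
#'   attribute `sigma` (the per-target concentrated noise sds).
#' @export
problem_objective <- function(problem, theta = NULL) {
  tmpl <- problem$template
  th <- tmpl$start
  if (!is.null(theta)) {
    i <- match(names(theta), tmpl$name)
    if (anyNA(i)) stop("unknown free parameter in theta")
    th[i] <- ifelse(tmpl$trans[i] == "log10", log10(theta), theta)
  }
  pm <- .apply_theta(problem, th)
  raw <- .problem_residuals_raw(problem, pm$params, pm$map)
  if (is.null(raw)) return(Inf)
  obs <- problem$rec$observable
  sfix <- .problem_sigma_fixed(problem)
  out <- .nll_from_raw(raw, obs, sfix)
  attr(out, "sigma") <- if (is.null(sfix)) {
    v <- tapply(raw^2, obs, mean)
    pmax(sqrt(v), .SIGMA_MIN)
  } else sfix
  out
}

# One local fit from an internal-scale start vector. Iteratively reweighted
# trust-region least squares: sigma held fixed within each nls.lm run and
# re-estimated in closed form between runs (3 rounds are ample: the
# optimum location is independent of per-target weights only at
# convergence).
.fit_single <- function(problem, theta0, outer = 3, maxiter = 150) {
  tmpl <- problem$template
  obs <- problem$rec$observable
  n <- nrow(problem$rec)
  if (nrow(tmpl) == 0) {
    val <- problem_objective(problem)
    return(list(theta = numeric(0), objective = as.numeric(val),
                sigma = attr(val, "sigma"), converged = is.finite(val),
                message = "no free parameters"))
  }
  sig <- stats::setNames(problem$map$sigma, problem$map$observable)
  fixed_sigma <- identical(problem$sigma_mode, "fixed")
  if (fixed_sigma) outer <- 1
  theta <- pmin(pmax(theta0, tmpl$lower), tmpl$upper)
  last_obj <- Inf
  msg <- ""
  for (round in seq_len(outer)) {
    w <- pmax(sig[obs], .SIGMA_MIN)
    fn <- function(th) {
      pm <- .apply_theta(problem, th)
      raw <- .problem_residuals_raw(problem, pm$params, pm$map)
      if (is.null(raw)) return(rep(1e4, n))
      raw / w
    }
    res <- tryCatch(
      minpack.lm::nls.lm(par = theta, lower = tmpl$lower, upper = tmpl$upper,
                         fn = fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-12, ptol = 1e-10,
                           # forward-difference step must clear the ODE
                           # solver noise floor
                           epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(res)) return(list(theta = theta, objective = Inf,
                                  sigma = sig, converged = FALSE,
                                  message = "optimizer error"))
    theta <- pmin(pmax(res$par, tmpl$lower), tmpl$upper)
    pm <- .apply_theta(problem, theta)
    raw <- .problem_residuals_raw(problem, pm$params, pm$map)
    if (is.null(raw)) return(list(theta = theta, objective = Inf,
                                  sigma = sig, converged = FALSE,
                                  message = "infeasible optimum"))
    if (fixed_sigma) {
      obj <- .nll_from_raw(raw, obs, sig)
      msg <- res$message
      last_obj <- obj
      break
    }
    v <- tapply(raw^2, obs, mean)
    sig_new <- pmax(sqrt(v), .SIGMA_MIN)
    obj <- .nll_from_raw(raw, obs)
    msg <- res$message
    conv <- abs(last_obj - obj) < 1e-8 * (1 + abs(obj))
    sig[names(sig_new)] <- sig_new
    last_obj <- obj
    if (conv) break
  }
  list(theta = stats::setNames(theta, tmpl$name), objective = last_obj,
       sigma = sig, converged = is.finite(last_obj), message = msg)
}

#' Multi-start maximum-likelihood fit
#'
#' Draws Latin-hypercube start points over the free parameters' box bounds
#' (deterministically for a given seed), runs a trust-region least-squares
#' fit from each start with the per-target noise sds iteratively
#' re-estimated, and returns the results sorted by objective. Failed
#' starts are recorded, not fatal.
#'
#' @param problem An [nrf2_problem()].
#' @param n_starts Number of starts (>= 1).
#' @param seed Integer seed controlling the start points.
#' @param include_template Also start from the template values (counts
#'   towards `n_starts`).
#' @return List of per-start results (theta on the internal scale,
#'   objective, sigma, convergence flag), sorted by objective.
#' @export
fit_multistart <- function(problem, n_starts = 10, seed = 1,
                           include_template = TRUE) {
  stopifnot(n_starts >= 1)
  tmpl <- problem$template
  k <- nrow(tmpl)
  if (k == 0) return(list(.fit_single(problem, numeric(0))))
  set.seed(seed)
  n_lhs <- if (include_template) n_starts - 1 else n_starts
  starts <- list()
  if (include_template) starts[[1]] <- tmpl$start
  if (n_lhs > 0) {
    H <- lhs::randomLHS(n_lhs, k)
    for (i in seq_len(n_lhs))
      starts[[length(starts) + 1L]] <-
        tmpl$lower + H[i, ] * (tmpl$upper - tmpl$lower)
  }
  fits <- lapply(seq_along(starts), function(i) {
    f <- .fit_single(problem, starts[[i]])
    f$start_index <- i
    f$start <- starts[[i]]
    f
  })
  fits[order(vapply(fits, `[[`, 0, "objective"))]
}

#' Fit the Nrf2 pathway model
#'
#' The central model-fitting entry point: multi-start maximum-likelihood
#' calibration of the selected model variant against a dataset, returning
#' a fitted-model object with the usual accessor methods (`print`,
#' `summary`, `coef`, `logLik`, `predict`, `simulate`, `residuals`,
#' `fitted`, `plot`, `profile`, `confint`, `anova`).
#'
#' @param problem An [nrf2_problem()].
#' @param n_starts Number of multi-starts.
#' @param seed Seed for the start points.
#' @param start Optional named start values (natural scale); when given, a
#'   single local fit from this start is run instead of the multi-start.
#' @return An object of class `nrf2_fit`.
#' @export
nrf2_fit <- function(problem, n_starts = 10, seed = 1, start = NULL) {
  tmpl <- problem$template
  if (!is.null(start)) {
    th0 <- tmpl$start
    i <- match(names(start), tmpl$name)
    if (anyNA(i)) stop("unknown parameter in start")
    th0[i] <- ifelse(tmpl$trans[i] == "log10", log10(start), start)
    fits <- list(.fit_single(problem, th0))
  } else {
    fits <- fit_multistart(problem, n_starts, seed)
  }
  best <- fits[[1]]
  if (!is.finite(best$objective))
    stop("all starts failed; no finite objective")
  starts_tab <- data.frame(
    start = vapply(fits, function(f) f$start_index %||% NA_integer_, 0L),
    objective = vapply(fits, `[[`, 0, "objective"),
    converged = vapply(fits, `[[`, TRUE, "converged"))
  est <- if (nrow(tmpl)) stats::setNames(
    ifelse(tmpl$trans == "log10", 10^best$theta, best$theta), tmpl$name)
    else stats::setNames(numeric(0), character(0))
  pm <- .apply_theta(problem, if (nrow(tmpl)) best$theta else numeric(0))
  structure(list(problem = problem, theta = best$theta, coefficients = est,
                 sigma = best$sigma, objective = best$objective,
                 converged = best$converged, starts = starts_tab,
                 params = pm$params, map = pm$map, n_starts = length(fits),
                 seed = seed),
            class = "nrf2_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
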