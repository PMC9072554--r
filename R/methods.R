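# Accessor methods for fitted nrf2_fit objects, in the style of classic
# modelling packages.

#' @export
print.nrf2_fit <- function(x, ...) {
  cat("Nrf2 pathway model fit (variant: ", x$problem$variant, ")\n", sep = "")
  cat("  -2 log L: ", format(x$objective, digits = 8),
      "   records: ", nrow(x$problem$dataset),
      "   free parameters: ", length(x$coefficients), "\n", sep = "")
  cat("  starts: ", x$n_starts, " (best converged: ", x$converged, ")\n",
      sep = "")
  if (length(x$coefficients)) {
    cat("Estimates:\n")
    print(signif(x$coefficients, 4))
  }
  invisible(x)
}

#' @export
summary.nrf2_fit <- function(object, ...) {
  tmpl <- object$problem$template
  tab <- if (nrow(tmpl)) data.frame(
    parameter = tmpl$name,
    estimate = unname(object$coefficients),
    start = ifelse(tmpl$trans == "log10", 10^tmpl$start, tmpl$start),
    lower = ifelse(tmpl$trans == "log10", 10^tmpl$lower, tmpl$lower),
    upper = ifelse(tmpl$trans == "log10", 10^tmpl$upper, tmpl$upper),
    at_bound = object$theta <= tmpl$lower + 1e-8 |
               object$theta >= tmpl$upper - 1e-8)
  else data.frame()
  out <- list(call_variant = object$problem$variant, coefficients = tab,
              sigma = object$sigma, objective = object$objective,
              n_records = nrow(object$problem$dataset),
              starts = object$starts)
  class(out) <- "summary.nrf2_fit"
  out
}

#' @export
print.summary.nrf2_fit <- function(x, ...) {
  cat("Nrf2 pathway model fit (variant: ", x$call_variant, ")\n", sep = "")
  cat("-2 log L = ", format(x$objective, digits = 10), " over ",
      x$n_records, " records\n\n", sep = "")
  if (nrow(x$coefficients)) {
    print(x$coefficients, digits = 4, row.names = FALSE)
    cat("\n")
  }
  cat("Estimated noise sd (log units):\n")
  print(signif(x$sigma, 3))
  cat("\nMulti-start objectives (top 5):\n")
  print(utils::head(x$starts, 5), row.names = FALSE)
  invisible(x)
}

#' @export
coef.nrf2_fit <- function(object, ...) object$coefficients

#' @export
logLik.nrf2_fit <- function(object, ...) {
  structure(-object$objective / 2,
            df = length(object$coefficients) + length(object$sigma),
            nobs = nrow(object$problem$dataset), class = "logLik")
}

#' Model predictions from a fitted object
#'
#' Simulates the fitted model and returns either the log-scale observables
#' (matching the dataset's error model) or the raw species trajectories.
#'
#' @param object An `nrf2_fit`.
#' @param conditions Named list of [condition()] objects (default: the
#'   problem's conditions).
#' @param type `"observables"` (data frame of log-observables) or
#'   `"states"` (list of trajectory matrices).
#' @param times Optional replacement observation times applied to every
#'   condition.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.nrf2_fit <- function(object, conditions = NULL,
                             type = c("observables", "states"),
                             times = NULL, ...) {
  type <- match.arg(type)
  conds <- conditions %||% object$problem$conditions
  if (!is.null(times)) {
    conds <- lapply(conds, function(cc) {
      cc$times <- sort(unique(times)); cc$horizon <- max(cc$horizon, times); cc
    })
  }
  params <- object$params
  ss <- solve_steady_state(object$problem$variant, params)
  sims <- lapply(conds, function(cc)
    simulate_condition(object$problem$variant, params, cc,
                       state0 = ss$state0))
  if (type == "states") return(sims)
  out <- do.call(rbind, lapply(sims, predict_observables, map = object$map))
  rownames(out) <- NULL
  out
}

#' @export
fitted.nrf2_fit <- function(object, ...) {
  pm <- list(params = object$params, map = object$map)
  raw <- .problem_residuals_raw(object$problem, pm$params, pm$map)
  if (is.null(raw)) stop("fitted model cannot be evaluated")
  object$problem$dataset$value + raw
}

#' @export
residuals.nrf2_fit <- function(object, type = c("weighted", "raw"), ...) {
  type <- match.arg(type)
  raw <- fitted(object) - object$problem$dataset$value
  if (type == "raw") return(raw)
  raw / pmax(object$sigma[object$problem$dataset$observable], .SIGMA_MIN)
}

#' Simulate datasets from a fitted model
#'
#' Parametric-bootstrap style simulation: regenerates log-scale datasets
#' at the fitted parameters with the estimated per-target noise sds.
#'
#' @param object An `nrf2_fit`.
#' @param nsim Number of simulated datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames shaped like the problem's dataset.
#' @export
simulate.nrf2_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  yhat <- fitted(object)
  obs <- object$problem$dataset$observable
  sd_i <- pmax(object$sigma[obs], .SIGMA_MIN)
  lapply(seq_len(nsim), function(i) {
    d <- object$problem$dataset
    d$value <- yhat + stats::rnorm(length(yhat), 0, sd_i)
    d
  })
}

#' Plot data and fitted trajectories
#'
#' One panel per observable: measured log-scale data (points) overlaid
#' with the fitted model trajectories (lines) and a shaded band of +/- 1
#' estimated noise sd around the prediction.
#'
#' @param x An `nrf2_fit`.
#' @param observables Subset of observables to plot.
#' @param ... Unused.
#' @export
plot.nrf2_fit <- function(x, observables = NULL, ...) {
  d <- x$problem$dataset
  obs <- observables %||% unique(d$observable)
  preds <- predict(x, times = seq(0, max(d$time), length.out = 101))
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(obs)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  conds <- unique(d$condition)
  cols <- grDevices::hcl.colors(max(length(conds), 2), "viridis")
  for (ob in obs) {
    dd <- d[d$observable == ob, ]
    pp <- preds[preds$observable == ob, ]
    sig <- unname(x$sigma[ob])
    ylim <- range(c(dd$value, pp$yhat), finite = TRUE) + c(-1, 1) * sig
    graphics::plot(NA, xlim = range(pp$time), ylim = ylim, xlab = "time (h)",
                   ylab = "log signal", main = ob)
    for (i in seq_along(conds)) {
      pc <- pp[pp$condition == conds[i], ]
      graphics::polygon(c(pc$time, rev(pc$time)),
                        c(pc$yhat + sig, rev(pc$yhat - sig)),
                        col = grDevices::adjustcolor(cols[i], 0.15),
                        border = NA)
      graphics::lines(pc$time, pc$yhat, col = cols[i])
      dc <- dd[dd$condition == conds[i], ]
      graphics::points(dc$time, dc$value, col = cols[i], pch = 16,
                       cex = 0.6)
    }
  }
  invisible(x)
}
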