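# Profile likelihood. For a free parameter p, the profile is
# PL(p) = min over all other free parameters of -2 log L with p fixed.
# Confidence intervals are read off at the chi-square threshold
# (3.84 = 95% for one degree of freedom); flat profiles flag
# non-identifiability.

#' Profile likelihood for one parameter
#'
#' Steps the parameter away from its estimate in both directions with
#' adaptive step control, re-optimising all other free parameters at each
#' point (warm-started from the neighbouring point). Stepping stops when
#' the objective has risen by `delta_stop`, a box bound is reached, or
#' `max_steps` points have been taken. The 95% confidence interval is
#' obtained from interpolated crossings at `threshold`; a profile that
#' stays flat (spread below 0.01) is classified structurally
#' non-identifiable, and an interval open at a bound as practically
#' non-identifiable.
#'
#' @param fit An [nrf2_fit()] result.
#' @param parameter Name of one free parameter.
#' @param threshold Chi-square threshold for the CI (default 3.84, 95%
#'   for 1 df).
#' @param delta_stop Stop stepping once the profile exceeds this rise.
#' @param init_step Initial step on the internal (log10 or natural)
#'   scale.
#' @param max_steps Maximum points per direction.
#' @return An object of class `nrf2_profile`: `$grid` (data frame with
#'   `value` on the natural scale and `delta` = rise of -2 log L),
#'   `$ci`, `$class`, `$parameter`, `$estimate`, `$objective`.
#' @export
profile_likelihood <- function(fit, parameter, threshold = 3.84,
                               delta_stop = 5, init_step = 0.1,
                               max_steps = 30) {
  problem <- fit$problem
  tmpl <- problem$template
  j <- match(parameter, tmpl$name)
  if (is.na(j)) stop("not a free parameter: ", parameter)
  theta_hat <- fit$theta
  obj_hat <- fit$objective

  refit_at <- function(pval, warm) {
    # fix parameter j at pval, re-optimise the rest from the warm start
    sub_tmpl <- tmpl[-j, , drop = FALSE]
    sub_problem <- problem
    if (nrow(sub_tmpl) == 0) {
      th <- theta_hat; th[j] <- pval
      pm <- .apply_theta(problem, th)
      raw <- .problem_residuals_raw(problem, pm$params, pm$map)
      if (is.null(raw)) return(list(objective = Inf, theta = th))
      return(list(objective = .nll_from_raw(raw, problem$rec$observable,
                                            .problem_sigma_fixed(problem)),
                  theta = th))
    }
    pm_fix <- .apply_theta(problem, { th <- warm; th[j] <- pval; th })
    sub_problem$params <- pm_fix$params
    sub_problem$map <- pm_fix$map
    sub_problem$template <- sub_tmpl
    f <- .fit_single(sub_problem, warm[-j], outer = 2, maxiter = 80)
    th <- warm; th[j] <- pval
    if (length(f$theta)) th[-j] <- f$theta
    list(objective = f$objective, theta = th)
  }

  one_direction <- function(sign) {
    pts <- list()
    step <- init_step
    pval <- theta_hat[j]
    warm <- theta_hat
    last_delta <- 0
    for (k in seq_len(max_steps)) {
      pval_new <- pval + sign * step
      hit_bound <- FALSE
      if (pval_new < tmpl$lower[j]) { pval_new <- tmpl$lower[j]; hit_bound <- TRUE }
      if (pval_new > tmpl$upper[j]) { pval_new <- tmpl$upper[j]; hit_bound <- TRUE }
      r <- refit_at(pval_new, warm)
      delta <- r$objective - obj_hat
      if (!is.finite(delta)) {
        pts[[k]] <- data.frame(internal = pval_new, delta = NA_real_,
                               ok = FALSE)
        break
      }
      pts[[k]] <- data.frame(internal = pval_new, delta = delta, ok = TRUE)
      warm <- r$theta
      pval <- pval_new
      # adapt step towards ~0.4 rise per step
      inc <- abs(delta - last_delta)
      if (inc < 0.15) step <- min(step * 1.8, 1)
      else if (inc > 1) step <- max(step / 2, 1e-3)
      last_delta <- delta
      if (delta > delta_stop || hit_bound) break
    }
    do.call(rbind, pts)
  }

  up <- one_direction(+1)
  dn <- one_direction(-1)
  grid <- rbind(
    if (!is.null(dn)) dn[rev(seq_len(nrow(dn))), ],
    data.frame(internal = theta_hat[j], delta = 0, ok = TRUE),
    up)
  grid <- grid[grid$ok & is.finite(grid$delta), c("internal", "delta")]
  rownames(grid) <- NULL
  to_nat <- function(v) if (tmpl$trans[j] == "log10") 10^v else v
  grid$value <- to_nat(grid$internal)

  cross <- function(side) {
    g <- if (side < 0) grid[grid$internal <= theta_hat[j], ]
         else grid[grid$internal >= theta_hat[j], ]
    g <- g[order(g$internal), ]
    above <- which(g$delta > threshold)
    if (!length(above)) return(NA_real_)
    if (side < 0) {
      i <- max(above)
      if (i == nrow(g)) return(NA_real_)
      x1 <- g$internal[i]; x2 <- g$internal[i + 1]
      d1 <- g$delta[i]; d2 <- g$delta[i + 1]
    } else {
      i <- min(above)
      if (i == 1) return(NA_real_)
      x1 <- g$internal[i - 1]; x2 <- g$internal[i]
      d1 <- g$delta[i - 1]; d2 <- g$delta[i]
    }
    # bisect the bracket until the crossing is localised
    warm <- theta_hat
    for (it in 1:8) {
      if (abs(d2 - d1) < 1e-12) break
      xm <- x1 + (threshold - d1) / (d2 - d1) * (x2 - x1)
      dm <- refit_at(xm, warm)$objective - obj_hat
      if (!is.finite(dm)) break
      if (abs(dm - threshold) < 0.02) return(to_nat(xm))
      if ((dm > threshold) == (d2 > threshold)) { x2 <- xm; d2 <- dm }
      else { x1 <- xm; d1 <- dm }
    }
    to_nat(x1 + (threshold - d1) / (d2 - d1) * (x2 - x1))
  }
  spread <- max(grid$delta)
  lo <- cross(-1); hi <- cross(+1)
  cls <- if (spread < 0.01) "structurally non-identifiable"
         else if (is.na(lo) || is.na(hi)) "practically non-identifiable"
         else "identifiable"
  structure(list(parameter = parameter, grid = grid,
                 ci = c(lower = lo, upper = hi),
                 class = cls, estimate = unname(fit$coefficients[parameter]),
                 objective = obj_hat, threshold = threshold),
            class = "nrf2_profile")
}

#' @export
print.nrf2_profile <- function(x, ...) {
  cat("Profile likelihood for ", x$parameter, " (", x$class, ")\n",
      "  estimate ", signif(x$estimate, 4), ", 95% CI [",
      signif(x$ci[1], 4), ", ", signif(x$ci[2], 4), "], ",
      nrow(x$grid), " profile points\n", sep = "")
  invisible(x)
}

#' @export
plot.nrf2_profile <- function(x, ...) {
  graphics::plot(x$grid$value, x$grid$delta, type = "b", log = "x",
                 xlab = x$parameter, ylab = expression(Delta ~ -2 * log ~ L),
                 main = paste0(x$parameter, " (", x$class, ")"))
  graphics::abline(h = x$threshold, lty = 2)
  graphics::abline(v = x$estimate, col = "grey50")
  invisible(x)
}

#' Profile all (or selected) free parameters of a fit
#'
#' @param fitted An `nrf2_fit`.
#' @param which Parameter names (default: all free).
#' @param ... Passed to [profile_likelihood()].
#' @return An object of class `nrf2_profiles` (named list of
#'   `nrf2_profile`).
#' @export
profile.nrf2_fit <- function(fitted, which = NULL, ...) {
  nms <- which %||% fitted$problem$template$name
  out <- lapply(nms, function(nm) profile_likelihood(fitted, nm, ...))
  names(out) <- nms
  class(out) <- "nrf2_profiles"
  out
}

#' @export
print.nrf2_profiles <- function(x, ...) {
  for (p in x) print(p)
  invisible(x)
}

#' @export
plot.nrf2_profiles <- function(x, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(x)))
  on.exit(graphics::par(old))
  for (p in x) plot(p)
  invisible(x)
}

#' @export
confint.nrf2_profiles <- function(object, parm = NULL, level = 0.95, ...) {
  nms <- parm %||% names(object)
  t(vapply(object[nms], function(p) p$ci, c(lower = 0, upper = 0)))
}

#' Profile-likelihood confidence intervals
#'
#' @param object An `nrf2_fit`.
#' @param parm Parameter names (default: all free parameters).
#' @param level Confidence level; converted to a chi-square threshold with
#'   1 degree of freedom.
#' @param ... Passed to [profile_likelihood()].
#' @return Matrix with columns `lower`, `upper` (NA marks an interval
#'   open at the bounds).
#' @export
confint.nrf2_fit <- function(object, parm = NULL, level = 0.95, ...) {
  thr <- stats::qchisq(level, df = 1)
  pr <- profile(object, which = parm, threshold = thr, ...)
  confint(pr)
}
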