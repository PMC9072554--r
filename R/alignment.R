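# Replicate alignment. Independent biological replicates differ by
# systematic multiplicative factors (cell number per well, light
# intensity). The scaling model S_{i,k,n} = y_{i,n} / s_k with
# log-normally distributed noise of constant sd condenses replicates into
# one average time course per condition. In log space the model is linear,
# so the maximum-likelihood fit is an exact two-way least-squares problem.

#' Align biological replicates under the scaling model
#'
#' Fits `S_{i,k,n} = y_{i,n} / s_k` by exact least squares on
#' `log S = log y - log s`, separately per observable (noise sd is
#' constant per target). Gauge: the first experiment of each observable
#' has `s = 1`.
#'
#' @param reps Data frame with columns `condition`, `experiment`,
#'   `observable`, `time`, `value` (positive signals).
#' @return An object of class `nrf2_alignment`: `$aligned` (one averaged
#'   time course per condition/observable/time, column `y`), `$scalings`
#'   (per observable and experiment), `$sigma` (per-observable residual
#'   sd), `$objective` (residual sum of squares in log space).
#' @export
align_replicates <- function(reps) {
  need <- c("condition", "experiment", "observable", "time", "value")
  miss <- setdiff(need, names(reps))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(reps) == 0) stop("empty replicate set")
  if (any(!is.finite(reps$value) | reps$value <= 0))
    stop("signals must be positive and finite (log-normal noise model)")

  per_obs <- lapply(split(reps, reps$observable), function(d) {
    ct <- interaction(d$condition, d$time, drop = TRUE)
    ex <- factor(d$experiment)
    logS <- log(d$value)
    if (nlevels(ex) == 1L) {
      # single experiment: gauge s = 1, y is the signal itself (averaged
      # over any duplicated time points)
      ybar <- tapply(logS, ct, mean)
      co_ct <- ybar
      logs <- stats::setNames(0, levels(ex))
      rss <- sum((logS - ybar[ct])^2)
    } else {
      fit <- stats::lm(logS ~ 0 + ct + ex)
      cf <- stats::coef(fit)
      co_ct <- cf[paste0("ct", levels(ct))]
      names(co_ct) <- levels(ct)
      logs_rest <- cf[paste0("ex", levels(ex)[-1])]
      logs <- stats::setNames(c(0, -as.numeric(logs_rest)), levels(ex))
      rss <- sum(stats::resid(fit)^2)
    }
    first <- !duplicated(ct)
    aligned <- data.frame(condition = d$condition[first],
                          observable = d$observable[first],
                          time = d$time[first],
                          y = exp(as.numeric(co_ct[as.character(ct[first])])),
                          stringsAsFactors = FALSE)
    aligned <- aligned[order(aligned$condition, aligned$time), ]
    scl <- data.frame(observable = d$observable[1],
                      experiment = names(logs), s = exp(unname(logs)),
                      stringsAsFactors = FALSE)
    n <- nrow(d)
    list(aligned = aligned, scalings = scl, rss = rss,
         sigma = sqrt(rss / n))
  })
  aligned <- do.call(rbind, lapply(per_obs, `[[`, "aligned"))
  rownames(aligned) <- NULL
  scalings <- do.call(rbind, lapply(per_obs, `[[`, "scalings"))
  rownames(scalings) <- NULL
  structure(list(aligned = aligned, scalings = scalings,
                 sigma = vapply(per_obs, `[[`, 0, "sigma"),
                 objective = sum(vapply(per_obs, `[[`, 0, "rss"))),
            class = "nrf2_alignment")
}

#' @export
print.nrf2_alignment <- function(x, ...) {
  cat("Replicate alignment:", nrow(x$aligned), "aligned points,",
      nrow(x$scalings), "experiment scalings, log-space RSS =",
      format(x$objective, digits = 4), "\n")
  invisible(x)
}

#' Merge two experiment series onto a common scale
#'
#' Different experiment series (e.g. the dose-response series and the
#' knock-down series) can carry both a scale and a systematic offset
#' relative to each other. The mixed scaling-offset model
#' `S_B = y / s + b` is fitted over the bridging conditions shared by both
#' series by 2-parameter nonlinear least squares on log residuals (the
#' offset breaks log-linearity, so no closed form exists). Gauge: series A
#' defines the common scale (`s = 1`, `b = 0`).
#'
#' @param series_A,series_B `nrf2_alignment` results (or their `$aligned`
#'   data frames).
#' @param bridge Character vector of condition ids present in both series
#'   (default: all shared conditions).
#' @return List with `s`, `b`, and `merged`: the union of both series on
#'   the common scale (series-B values transformed as `(S_B - b) * s`,
#'   bridging conditions taken from series A).
#' @export
merge_series <- function(series_A, series_B, bridge = NULL) {
  A <- if (inherits(series_A, "nrf2_alignment")) series_A$aligned else series_A
  B <- if (inherits(series_B, "nrf2_alignment")) series_B$aligned else series_B
  shared <- intersect(unique(A$condition), unique(B$condition))
  if (is.null(bridge)) bridge <- shared
  bridge <- intersect(bridge, shared)
  if (length(bridge) == 0) stop("no bridging condition shared by both series")
  key <- function(d) paste(d$condition, d$observable, round(d$time, 9))
  Ab <- A[A$condition %in% bridge, ]
  Bb <- B[B$condition %in% bridge, ]
  i <- match(key(Bb), key(Ab))
  ok <- !is.na(i)
  if (!any(ok)) stop("bridging conditions share no common time points")
  yA <- Ab$y[i[ok]]; sB <- Bb$y[ok]

  resid_fun <- function(par) {
    s <- exp(par[1]); b <- par[2]
    pred <- yA / s + b
    if (any(pred <= 0)) return(rep(1e6, length(pred)))
    log(pred) - log(sB)
  }
  fit <- minpack.lm::nls.lm(par = c(log_s = 0, b = 0), fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-15, ptol = 1e-15))
  s <- exp(fit$par[[1]]); b <- fit$par[[2]]
  B2 <- B[!(B$condition %in% bridge), ]
  B2$y <- (B2$y - b) * s
  if (any(B2$y <= 0))
    stop("offset correction produced non-positive values; series cannot be merged")
  merged <- rbind(A, B2)
  rownames(merged) <- NULL
  list(s = unname(s), b = unname(b), merged = merged,
       rss = sum(resid_fun(fit$par)^2))
}
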