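# Observation model: measured signals are related to model states by
#   y = log(s * x + b) + eps,   eps ~ N(0, sigma^2)
# with an unknown concentration scale s, a background offset b (free for
# the fluorescence observables, fixed to 0 for ratio-type qPCR and GSH
# measurements) and a constant per-target noise standard deviation sigma
# on the log scale.

#' Default observable-to-species map
#'
#' Maps the study's eight measured targets to model states: the Keap1-GFP
#' foci report the autophagosomal Keap1 pool, nuclear Nrf2-GFP maps to
#' nuclear Nrf2, cytoplasmic Srxn1-GFP to the Srxn1 protein, the four qPCR
#' targets to their mRNA species and total glutathione to the GSH pool.
#'
#' @param sigma Default per-target noise sd (log units).
#' @return Data frame with one row per observable: `observable`, `species`,
#'   `scale`, `offset`, `sigma`, and `offset_free` (background offsets are
#'   estimable only for the GFP reporters).
#' @export
default_observation_map <- function(sigma = 0.1) {
  data.frame(
    observable = c("Keap1_foci", "Nrf2_nuc", "Srxn1_cyt",
                   "mRNA_KEAP1", "mRNA_NFE2L2", "mRNA_SQSTM1", "mRNA_SRXN1",
                   "GSH_total"),
    species = c("Keap1_auto", "nNrf2", "Srxn1",
                "mKEAP1", "mNFE2L2", "mSQSTM1", "mSRXN1", "GSH"),
    scale = 1, offset = 0, sigma = sigma,
    offset_free = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Deterministic part of the observation function
#'
#' @param x Model state value(s), non-negative.
#' @param scale Concentration scale s > 0.
#' @param offset Background offset b >= 0.
#' @param observable Name used in error messages.
#' @return `log(scale * x + offset)`.
#' @export
observe <- function(x, scale = 1, offset = 0, observable = "observable") {
  arg <- scale * x + offset
  if (any(arg <= 0))
    stop("non-positive argument of log for ", observable,
         " (scale*x + offset must be > 0)")
  log(arg)
}

# Predicted log-observables for one simulated condition.
# Returns data.frame(condition, observable, time, yhat).
predict_observables <- function(sim, map, times = NULL) {
  cond <- attr(sim, "condition")
  tt <- sim[, "time"]
  rows <- if (is.null(times)) seq_along(tt) else match(times, tt)
  out <- do.call(rbind, lapply(seq_len(nrow(map)), function(i) {
    x <- sim[rows, map$species[i]]
    data.frame(condition = cond$id, observable = map$observable[i],
               time = tt[rows],
               yhat = observe(x, map$scale[i], map$offset[i],
                              map$observable[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Match dataset records to predictions; error if any record lacks one.
.match_records <- function(dataset, predictions) {
  key <- function(d) paste(d$condition, d$observable, round(d$time, 9))
  i <- match(key(dataset), key(predictions))
  if (anyNA(i))
    stop("missing simulation point(s) for record(s): ",
         paste(utils::head(key(dataset)[is.na(i)], 3), collapse = "; "))
  predictions$yhat[i]
}

#' Twice negative log-likelihood of a dataset
#'
#' Evaluates `sum_i [ ((yhat_i - y_i)/sigma_i)^2 + log(sigma_i^2) ]`, the
#' maximum-likelihood objective of the log-normal constant-sd error model.
#' `sigma` is constant per target and may be estimated as part of the
#' parameter vector; values are floored at `sigma_min` to avoid degeneracy
#' on (near-)noise-free data.
#'
#' @param dataset Data frame with columns `condition`, `observable`,
#'   `time`, `value` (log-scale data).
#' @param predictions Data frame with columns `condition`, `observable`,
#'   `time`, `yhat` covering every record.
#' @param sigma Named vector of per-observable noise sds (log units).
#' @param sigma_min Lower bound for sigma.
#' @return Scalar -2 log L.
#' @export
neg2_log_likelihood <- function(dataset, predictions, sigma,
                                sigma_min = 1e-3) {
  r <- residual_vector(dataset, predictions, sigma, sigma_min)
  sum(r^2) + attr(r, "sigma_penalty")
}

#' Weighted residual vector with noise penalty
#'
#' Least-squares form of the likelihood: returns the per-record weighted
#' residuals `(yhat_i - y_i)/sigma_i`; the attribute `sigma_penalty` holds
#' `sum_i log(sigma_i^2)` so that `sum(r^2) + penalty` equals
#' [neg2_log_likelihood()].
#'
#' @inheritParams neg2_log_likelihood
#' @return Numeric vector, one entry per dataset record, with attribute
#'   `sigma_penalty`.
#' @export
residual_vector <- function(dataset, predictions, sigma, sigma_min = 1e-3) {
  yhat <- .match_records(dataset, predictions)
  s <- pmax(sigma[dataset$observable], sigma_min)
  if (anyNA(s)) stop("sigma missing for observable(s): ",
                     paste(unique(dataset$observable[is.na(s)]), collapse = ", "))
  r <- (yhat - dataset$value) / s
  if (!all(is.finite(r))) stop("non-finite residuals")
  attr(r, "sigma_penalty") <- sum(log(s^2))
  r
}

# Closed-form per-target ML noise estimate: sigma^2 = mean squared residual.
.sigma_closed_form <- function(dataset, predictions, sigma_min = 1e-3) {
  yhat <- .match_records(dataset, predictions)
  res2 <- (yhat - dataset$value)^2
  v <- tapply(res2, dataset$observable, mean)
  pmax(sqrt(v), sigma_min)
}
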