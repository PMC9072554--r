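# Hypothesis comparison: the hinge-latch and dissociation variants fit the
# observable data comparably well; they are discriminated through the
# predicted internal Keap1-Nrf2 complex, which dips below its baseline
# immediately after the bolus only under dissociation.

#' Compare fits of the two mechanistic variants
#'
#' Reports both objectives and the post-treatment signature of the total
#' Keap1-Nrf2 complex for each fitted variant: pre-treatment baseline,
#' minimum within the first two hours after the bolus, and the sign of
#' the initial dip. Comparable objectives do not exclude either
#' hypothesis; the discrimination is mechanistic, not statistical.
#'
#' @param fit_hl Fit of the hinge-latch variant.
#' @param fit_diss Fit of the dissociation variant (same dataset).
#' @param cond Condition used for the signature simulation (default: the
#'   highest-dose condition of the shared problem).
#' @param window Hours after the bolus within which the minimum is taken.
#' @return An object of class `nrf2_variant_comparison`.
#' @export
compare_variants <- function(fit_hl, fit_diss, cond = NULL, window = 2) {
  if (!isTRUE(all.equal(fit_hl$problem$dataset, fit_diss$problem$dataset)))
    stop("fits were obtained on different datasets")
  if (is.null(cond)) {
    conds <- fit_hl$problem$conditions
    doses <- vapply(conds, function(cc) cc$stimulus$dose, 0)
    cond <- conds[[which.max(doses)]]
  }
  signature <- function(fit) {
    cc <- cond
    cc$times <- seq(0, max(window * 4, 8), by = 0.1)
    cc$horizon <- max(cc$times)
    sim <- simulate_condition(fit$problem$variant, fit$params, cc)
    ct <- complex_total(sim)
    tt <- sim[, "time"]
    baseline <- ct[1]
    min_w <- min(ct[tt <= window])
    list(variant = fit$problem$variant, baseline = baseline,
         min_within_window = min_w, dip = min_w - baseline,
         dips_below_baseline = min_w < baseline * (1 - 1e-6))
  }
  out <- list(
    objective_hl = fit_hl$objective,
    objective_diss = fit_diss$objective,
    objective_difference = fit_hl$objective - fit_diss$objective,
    signature_hl = signature(fit_hl),
    signature_diss = signature(fit_diss),
    condition = cond$id, window = window,
    note = paste("Fits of comparable quality do not exclude either",
                 "hypothesis; discrimination rests on the predicted",
                 "internal Keap1-Nrf2 complex dynamics."))
  class(out) <- "nrf2_variant_comparison"
  out
}

#' @export
print.nrf2_variant_comparison <- function(x, ...) {
  cat("Variant comparison on condition ", x$condition, "\n",
      "  -2 log L: hinge-latch ", format(x$objective_hl, digits = 8),
      ", dissociation ", format(x$objective_diss, digits = 8),
      " (difference ", format(x$objective_difference, digits = 4), ")\n",
      sep = "")
  s <- function(sg) cat("  ", sg$variant, ": baseline ",
                        signif(sg$baseline, 4), ", min(0-", x$window,
                        "h) ", signif(sg$min_within_window, 4),
                        ", dips below baseline: ", sg$dips_below_baseline,
                        "\n", sep = "")
  s(x$signature_hl); s(x$signature_diss)
  cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Serialise a variant comparison
#'
#' @param x An `nrf2_variant_comparison`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Per-compound parameters that may be freed in a compound extension.
.compound_free_sets <- function() {
  list(DEM = c("kmod_DEM", "kclear_DEM"),
       DCF = c("kmod_DCF", "kclear_DCF"),
       OMZ = c("kmod_OMZ", "kclear_OMZ", "d_Srxn1_OMZ", "V_mSRXN1_OMZ"))
}

#' Extend a fit with compound-specific parameters
#'
#' Joint refit of a problem with additional per-compound parameters freed
#' (association/clearance rates of the electrophile; for omeprazole also
#' the Srxn1 turnover rate and the Nrf2-dependent SRXN1 mRNA production),
#' with all shared parameters initialised at the base fit. The resulting
#' nested models can be compared with [anova.nrf2_fit()].
#'
#' @param problem Joint [nrf2_problem()] covering the compound's
#'   conditions.
#' @param base_fit Fit providing the shared-parameter starting point.
#' @param compound `"DEM"`, `"DCF"` or `"OMZ"`.
#' @param extra_free Per-compound parameters to free (subset of the
#'   compound's allowed set); empty means a plain joint refit from the
#'   base fit.
#' @return An `nrf2_fit` on the extended problem.
#' @export
fit_extension <- function(problem, base_fit, compound = c("DCF", "OMZ", "DEM"),
                          extra_free = character()) {
  compound <- match.arg(compound)
  allowed <- .compound_free_sets()[[compound]]
  bad <- setdiff(extra_free, allowed)
  if (length(bad))
    stop("not in the allowed per-compound set for ", compound, ": ",
         paste(bad, collapse = ", "))
  free2 <- union(problem$free, extra_free)
  problem2 <- nrf2_problem(problem$dataset, problem$conditions,
                           params = problem$params, map = problem$map,
                           variant = problem$variant, free = free2,
                           anchors = problem$anchors,
                           bound_decades = problem$bound_decades %||% 5,
                           rtol = problem$rtol, atol = problem$atol,
                           sigma_mode = problem$sigma_mode %||% "concentrated")
  start <- base_fit$coefficients
  extra_only <- setdiff(free2, names(start))
  if (length(extra_only)) {
    tmpl2 <- problem2$template
    i <- match(extra_only, tmpl2$name)
    start <- c(start, stats::setNames(
      ifelse(tmpl2$trans[i] == "log10", 10^tmpl2$start[i], tmpl2$start[i]),
      extra_only))
  }
  nrf2_fit(problem2, start = start)
}

#' Likelihood-ratio comparison of nested fits
#'
#' @param object,... Two or more `nrf2_fit` objects on the same dataset,
#'   nested and ordered by increasing number of free parameters.
#' @return Data frame with -2 log L, differences and chi-square p-values.
#' @export
anova.nrf2_fit <- function(object, ...) {
  fits <- c(list(object), list(...))
  k <- vapply(fits, function(f) length(f$coefficients), 0L)
  nll <- vapply(fits, `[[`, 0, "objective")
  d_nll <- c(NA, -diff(nll))
  d_df <- c(NA, diff(k))
  p <- ifelse(is.na(d_nll) | d_df <= 0, NA,
              stats::pchisq(d_nll, df = pmax(d_df, 1), lower.tail = FALSE))
  data.frame(free_parameters = k, neg2logL = nll, delta = d_nll,
             df = d_df, p_value = p)
}
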