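# Multi-start fitting, profile likelihood and variant/extension
# comparisons on small synthetic problems.

noise_free_problem <- function(free, doses = 316, step = 6,
                               obs = NULL, ...) {
  des <- synthetic_design(compounds = "DEM", n_replicates = 1, sigma = 0,
                          imaging_times = seq(0, 48, step),
                          doses = list(DEM = doses))
  syn <- generate_dataset(des, params = ref_params(), seed = 5)
  ds <- syn$truth
  names(ds)[names(ds) == "yhat"] <- "value"
  if (!is.null(obs)) ds <- ds[ds$observable %in% obs, ]
  nrf2_problem(ds, syn$conditions, params = ref_params(), free = free,
               anchors = full_anchors, ...)
}

test_that("a fit started at the truth of noise-free data stays there", {
  pb <- noise_free_problem(free = c("kmod_DEM", "V_mSRXN1"))
  truth <- ref_params()[c("kmod_DEM", "V_mSRXN1")]
  fit <- nrf2_fit(pb, start = truth)
  n <- nrow(pb$dataset)
  # analytic floor: all residuals ~0, sigma at its lower bound
  expect_equal(fit$objective, n * log(nrf2dyn:::.SIGMA_MIN^2),
               tolerance = 1e-6)
  expect_equal(coef(fit), truth, tolerance = 1e-4)
  expect_true(fit$converged)
})

test_that("multi-start draws are deterministic given the seed", {
  pb <- noise_free_problem(free = c("kmod_DEM", "V_mSRXN1"), step = 12,
                           obs = c("Srxn1_cyt", "mRNA_SRXN1"))
  f1 <- fit_multistart(pb, n_starts = 4, seed = 9)
  f2 <- fit_multistart(pb, n_starts = 4, seed = 9)
  s1 <- lapply(f1, `[[`, "start")[order(vapply(f1, `[[`, 0L, "start_index"))]
  s2 <- lapply(f2, `[[`, "start")[order(vapply(f2, `[[`, 0L, "start_index"))]
  expect_identical(s1, s2)
  f3 <- fit_multistart(pb, n_starts = 4, seed = 10)
  s3 <- lapply(f3, `[[`, "start")[order(vapply(f3, `[[`, 0L, "start_index"))]
  expect_false(identical(s1, s3))
})

test_that("parameters are recovered from noisy synthetic data", {
  fit <- recovery_fit()
  truth <- ref_params()[names(coef(fit))]
  expect_lt(max(abs(coef(fit) - truth) / truth), 0.15)
  # profile CI of each parameter covers the generating value
  for (nm in c("kmod_DEM", "V_mSRXN1")) {
    pr <- profile_likelihood(fit, nm)
    expect_identical(pr$class, "identifiable")
    expect_true(all(pr$grid$delta >= -1e-4))   # optimum is global on the profile
    expect_gte(unname(truth[nm]), pr$ci[["lower"]])
    expect_lte(unname(truth[nm]), pr$ci[["upper"]])
    expect_gte(pr$estimate, pr$ci[["lower"]])
    expect_lte(pr$estimate, pr$ci[["upper"]])
  }
})

test_that("a quadratic single-parameter problem has the textbook CI", {
  # one GSH record, fixed sigma: -2logL = ((log s - log 2)/sigma)^2 + const
  ds <- data.frame(condition = "DMSO_0", observable = "GSH_total",
                   time = 0, value = log(2 * 10))
  conds <- list(DMSO_0 = condition("DMSO", 0, times = 0,
                                   dmso_background = FALSE))
  map <- default_observation_map(sigma = 0.25)
  pb <- nrf2_problem(ds, conds, params = ref_params(), map = map,
                     free = "scale_GSH_total", anchors = full_anchors,
                     sigma_mode = "fixed")
  fit <- nrf2_fit(pb, n_starts = 1)
  expect_equal(unname(coef(fit)), 2, tolerance = 1e-6)
  pr <- profile_likelihood(fit, "scale_GSH_total", init_step = 0.02)
  # closed form: log s = log 2 +/- sigma * sqrt(3.84)
  expect_equal(unname(pr$ci[["lower"]]), 2 * exp(-0.25 * sqrt(3.84)),
               tolerance = 0.01)
  expect_equal(unname(pr$ci[["upper"]]), 2 * exp(0.25 * sqrt(3.84)),
               tolerance = 0.01)
})

test_that("a constructed scale symmetry yields a flat profile", {
  # Srxn1 enters the likelihood only through kt_Srxn1 * scale: freeing both
  # leaves their product identifiable but each factor arbitrary
  pb <- noise_free_problem(free = c("kt_Srxn1", "scale_Srxn1_cyt"),
                           step = 8, obs = "Srxn1_cyt")
  fit <- nrf2_fit(pb, start = stats::setNames(
    ref_params()["kt_Srxn1"], "kt_Srxn1"))
  pr <- profile_likelihood(fit, "kt_Srxn1", max_steps = 8)
  expect_identical(pr$class, "structurally non-identifiable")
  expect_lt(max(pr$grid$delta), 0.01)
})

test_that("identical fits compare as equal; variants differ by their dip", {
  fit <- recovery_fit()
  same <- compare_variants(fit, fit)
  expect_equal(same$objective_difference, 0)
  expect_identical(same$signature_hl$dips_below_baseline,
                   same$signature_diss$dips_below_baseline)

  pb_d <- nrf2_problem(small_dataset(), small_synth()$conditions,
                       params = ref_params(), variant = "dissociation",
                       free = c("kmod_DEM", "V_mSRXN1"),
                       anchors = full_anchors, bound_decades = 1.5)
  fit_d <- nrf2_fit(pb_d, n_starts = 3, seed = 2)
  cmp <- compare_variants(fit, fit_d)
  expect_false(cmp$signature_hl$dips_below_baseline)
  expect_true(cmp$signature_diss$dips_below_baseline)
  expect_match(cmp$note, "not exclude")
  tf <- tempfile(fileext = ".json")
  write_comparison(cmp, tf)
  back <- jsonlite::read_json(tf)
  expect_equal(back$objective_hl, cmp$objective_hl, tolerance = 1e-9)
  expect_error(compare_variants(fit, nrf2_fit(noise_free_problem(
    free = "kmod_DEM", step = 24, obs = "Srxn1_cyt"), n_starts = 1)),
    "different datasets")
})

omz_problem <- function(d_srxn_factor = 1, free = "kmod_OMZ",
                        sigma = 0.05) {
  p_gen <- ref_params()
  p_gen["d_Srxn1_OMZ"] <- p_gen["d_Srxn1_OMZ"] * d_srxn_factor
  des <- synthetic_design(compounds = "OMZ", n_replicates = 1,
                          sigma = sigma, imaging_times = seq(0, 48, 6),
                          doses = list(OMZ = c(94, 282)))
  syn <- generate_dataset(des, params = p_gen, seed = 31)
  ds <- syn$replicates
  ds$value <- log(ds$value)
  ds$experiment <- NULL
  nrf2_problem(ds, syn$conditions, params = ref_params(), free = free,
               anchors = full_anchors, bound_decades = 1.5,
               sigma_mode = "fixed",
               map = default_observation_map(sigma = max(sigma, 0.05)))
}

test_that("compound extension detects an altered Srxn1 turnover", {
  # data generated with the template's own OMZ parameters: freeing the
  # Srxn1 turnover should NOT give a significant improvement
  pb0 <- omz_problem(d_srxn_factor = 1)
  base0 <- nrf2_fit(pb0, n_starts = 1)
  ext0_same <- fit_extension(pb0, base0, "OMZ", character())
  expect_lt(abs(ext0_same$objective - base0$objective), 1e-6)
  ext0 <- fit_extension(pb0, base0, "OMZ", "d_Srxn1_OMZ")
  expect_lte(base0$objective - ext0$objective, 3.84)

  # data generated with a 2.5x faster Srxn1 turnover: freeing it is a
  # significant, recoverable improvement
  pb1 <- omz_problem(d_srxn_factor = 2.5)
  base1 <- nrf2_fit(pb1, n_starts = 1)
  ext1 <- fit_extension(pb1, base1, "OMZ", "d_Srxn1_OMZ")
  d_nll <- base1$objective - ext1$objective
  expect_gt(d_nll, 3.84)
  truth <- unname(ref_params()["d_Srxn1_OMZ"] * 2.5)
  expect_lt(abs(coef(ext1)[["d_Srxn1_OMZ"]] - truth) / truth, 0.25)
  tab <- anova(base1, ext1)
  expect_equal(tab$delta[2], d_nll)
  expect_lt(tab$p_value[2], 0.05)
  expect_error(fit_extension(pb1, base1, "OMZ", "kmod_DCF"), "allowed")
})

test_that("fit accessors behave like a classic model object", {
  fit <- recovery_fit()
  expect_output(print(fit), "-2 log L")
  s <- summary(fit)
  expect_s3_class(s, "summary.nrf2_fit")
  expect_output(print(s), "noise sd")
  ll <- logLik(fit)
  expect_equal(as.numeric(ll), -fit$objective / 2)
  expect_equal(length(fitted(fit)), nrow(fit$problem$dataset))
  r <- residuals(fit)
  expect_equal(mean(r^2), mean(residuals(fit, "raw")^2 /
                                 fit$sigma[fit$problem$dataset$observable]^2),
               tolerance = 1e-10)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_identical(dim(sims[[1]]), dim(fit$problem$dataset))
  pr <- predict(fit, times = c(0, 24))
  expect_true(all(c("condition", "observable", "time", "yhat") %in% names(pr)))
  tf <- tempfile(fileext = ".pdf")
  grDevices::pdf(tf)
  expect_silent(plot(fit, observables = c("Nrf2_nuc", "Srxn1_cyt")))
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
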