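# Synthetic-data generator. The study's measurements (microscopy reporter
# intensities, qPCR, total glutathione) are not publicly deposited, so the
# package ships a ground-truth parameter set and a generator that emulates
# the statistical structure the analysis assumes: multiplicative
# replicate-to-replicate scalings, log-normal noise with constant
# per-target sd, dose-dependent induction dynamics and knock-down-shifted
# baselines. Every downstream stage (alignment, fitting, profiles) is
# validated against this generator.

#' Reference ground-truth parameter set
#'
#' A hand-tuned parameter set whose simulations reproduce the qualitative
#' hallmarks of the measured Nrf2 response: a fast nuclear-Nrf2 rise
#' peaking 3-5 h after a DEM 316 uM bolus followed by slow relaxation;
#' KEAP1/SQSTM1/SRXN1 mRNA peaking around 8 h; flat NFE2L2 mRNA; a total
#' GSH rise of at most ~30 percent at the highest DEM dose; an initial
#' 5-10 percent dip of autophagosomal Keap1 within the first 3 h followed
#' by an increase; and Srxn1 still rising at 48 h for DEM 561 uM.
#' The basal steady state of free Keap1 is pinned at 1 (concentration
#' scale convention).
#'
#' @return Named parameter vector (see [validate_parameters()]).
#' @export
reference_parameters <- function() {
  p <- c(
    # production (p_Nrf2, p_Keap1, p_p62 are re-derived by the steady-state
    # anchor below; values here are consistent starting points)
    p_Nrf2 = 0.5, p_Keap1 = 0.1, kt_Keap1 = 0.06, p_p62 = 0.15,
    kt_p62 = 0.1, kt_Srxn1 = 0.016,
    ka_KN = 10, kd_KN = 0.1, kdeg_Nrf2c = 2, ka_Kp62 = 0.1,
    k_auto = 1, k_clear_auto = 0.05,
    k_in = 1, k_out = 0.2,
    b_mKEAP1 = 0.05, V_mKEAP1 = 1, K_mKEAP1 = 0.5, h_mKEAP1 = 2,
    b_mNFE2L2 = 0.25,
    b_mSQSTM1 = 0.05, V_mSQSTM1 = 1, K_mSQSTM1 = 0.5, h_mSQSTM1 = 2,
    b_mSRXN1 = 0.05, V_mSRXN1 = 1, K_mSRXN1 = 0.5, h_mSRXN1 = 2,
    b_GSH = 0.45, V_GSH = 0.65, K_GSH = 0.5, h_GSH = 2,
    k_conj = 0.0003,
    mod_free_frac = 1,
    d_Nrf2 = 0.1, d_Keap1 = 0.03, d_p62 = 0.05, d_cplx = 0.01,
    d_nNrf2 = 0.18,
    d_mKEAP1 = 0.2, d_mNFE2L2 = 0.2, d_mSQSTM1 = 0.1, d_mSRXN1 = 0.2,
    d_Srxn1 = 0.02, d_GSH = 0.05,
    kmod_DEM = 0.03, kclear_DEM = 2,
    kmod_DCF = 0.018, kclear_DCF = 2.5,
    kmod_OMZ = 0.06, kclear_OMZ = 2,
    d_Srxn1_OMZ = 0.05, V_mSRXN1_OMZ = 0.5,
    f_KEAP1 = 0.2, f_NFE2L2 = 0.25, f_SQSTM1 = 0.2,
    dmso_bg = 0.3
  )
  constrain_parameters(p, anchors = c(Keap1 = 1, Nrf2 = 0.05, p62 = 1,
                                      GSH = 10))
}

#' Synthetic study design
#'
#' The default design mirrors the study layout: DEM at 0/10/100/316/561 uM,
#' DCF at 100/316/500/1000 uM and OMZ at 4.7/23.5/47/94/188/282 uM;
#' hourly imaging of the three GFP reporters over 48 h; qPCR at 3/8/24 h;
#' total GSH at 0.5/1/2/5/10/24/48 h; knock-down arms
#' siCtrl/siKEAP1/siNFE2L2/siSQSTM1 under DMSO and DEM 316 uM with 72 h of
#' knock-down before treatment; three biological replicates per condition.
#'
#' @param compounds Subset of `c("DEM", "DCF", "OMZ")`.
#' @param n_replicates Biological replicates per condition (>= 1).
#' @param sigma Noise sd (log units) applied to every target.
#' @param scale_range Range of the log-uniform per-experiment scalings.
#' @param imaging_times,qpcr_times,gsh_times Observation times (h post
#'   treatment).
#' @param knockdowns Include the knock-down arms?
#' @param doses Optional named list overriding the per-compound dose sets
#'   (e.g. `list(DEM = 316)` for a single-dose study).
#' @return An object of class `nrf2_design`.
#' @export
synthetic_design <- function(compounds = "DEM", n_replicates = 3,
                             sigma = 0.1, scale_range = c(0.5, 2),
                             imaging_times = 0:48,
                             qpcr_times = c(3, 8, 24),
                             gsh_times = c(0.5, 1, 2, 5, 10, 24, 48),
                             knockdowns = FALSE, doses = NULL) {
  compounds <- match.arg(compounds, c("DEM", "DCF", "OMZ"), several.ok = TRUE)
  full <- list(DEM = c(0, 10, 100, 316, 561),
               DCF = c(100, 316, 500, 1000),
               OMZ = c(4.7, 23.5, 47, 94, 188, 282))
  if (!is.null(doses)) full[names(doses)] <- doses
  doses <- full
  if (n_replicates < 1) stop("need at least one replicate")
  structure(list(compounds = compounds, doses = doses[compounds],
                 n_replicates = n_replicates, sigma = sigma,
                 scale_range = scale_range,
                 imaging_times = imaging_times, qpcr_times = qpcr_times,
                 gsh_times = gsh_times, knockdowns = knockdowns),
            class = "nrf2_design")
}

# All conditions of a design, as nrf2_condition objects.
design_conditions <- function(design, params = NULL) {
  horizon <- max(design$imaging_times, design$gsh_times, design$qpcr_times)
  times <- sort(unique(c(design$imaging_times, design$qpcr_times,
                         design$gsh_times)))
  conds <- list()
  for (cpd in design$compounds) {
    for (dose in design$doses[[cpd]]) {
      cc <- if (dose == 0) "DMSO" else cpd
      conds[[length(conds) + 1L]] <-
        condition(cc, dose, times = times, horizon = horizon)
    }
  }
  if (isTRUE(design$knockdowns)) {
    for (tg in c("control", "KEAP1", "NFE2L2", "SQSTM1")) {
      for (dose in c(0, 316)) {
        cc <- if (dose == 0) "DMSO" else "DEM"
        conds[[length(conds) + 1L]] <-
          condition(cc, dose, kd = knockdown(tg), times = times,
                    horizon = horizon)
      }
    }
  }
  names(conds) <- vapply(conds, `[[`, "", "id")
  conds
}

# Observation times per observable class, as used by the generator and the
# measurement table.
.obs_times_for <- function(design, observable) {
  switch(substr(observable, 1, 4),
         mRNA = design$qpcr_times,
         GSH_ = design$gsh_times,
         design$imaging_times)
}

#' Generate a synthetic replicate dataset
#'
#' Simulates every condition of the design at the ground-truth parameters,
#' maps states to observables, divides by per-experiment scalings drawn
#' log-uniformly from the design's range (first experiment pinned at 1)
#' and multiplies by log-normal noise `exp(N(0, sigma^2))`. Deterministic
#' for a fixed seed.
#'
#' @param design An [synthetic_design()] object.
#' @param params Ground-truth parameter vector (default
#'   [reference_parameters()]).
#' @param variant Model variant used for the ground truth.
#' @param map Observation map (default [default_observation_map()]).
#' @param seed Integer seed.
#' @return List of class `nrf2_synth`: `$replicates` (long table:
#'   condition, experiment, observable, time, value), `$truth` (noise-free
#'   log-observables: condition, observable, time, yhat), `$scalings`
#'   (per experiment), `$params`, `$variant`, `$map`, `$conditions`.
#' @export
generate_dataset <- function(design = synthetic_design(),
                             params = reference_parameters(),
                             variant = "hinge_latch",
                             map = default_observation_map(design$sigma),
                             seed = 1) {
  set.seed(seed)
  conds <- design_conditions(design)
  ss <- solve_steady_state(variant, params)
  if (!ss$converged) stop("ground-truth parameters have no steady state")
  truth <- do.call(rbind, lapply(conds, function(cc) {
    sim <- simulate_condition(variant, params, cc, state0 = ss$state0)
    predict_observables(sim, map)
  }))
  rownames(truth) <- NULL
  # drop observation times that do not belong to an observable's assay
  keep <- mapply(function(obs, tt) tt %in% .obs_times_for(design, obs),
                 truth$observable, truth$time)
  truth <- truth[keep, ]

  n_rep <- design$n_replicates
  s_k <- c(1, exp(stats::runif(n_rep - 1, log(design$scale_range[1]),
                               log(design$scale_range[2]))))
  reps <- do.call(rbind, lapply(seq_len(n_rep), function(k) {
    eps <- stats::rnorm(nrow(truth), 0, design$sigma)
    data.frame(condition = truth$condition, experiment = paste0("exp", k),
               observable = truth$observable, time = truth$time,
               value = exp(truth$yhat) / s_k[k] * exp(eps),
               stringsAsFactors = FALSE)
  }))
  rownames(reps) <- NULL
  structure(list(replicates = reps, truth = truth,
                 scalings = stats::setNames(s_k, paste0("exp", seq_len(n_rep))),
                 params = params, variant = variant, map = map,
                 conditions = conds, design = design),
            class = "nrf2_synth")
}

#' Simulate the knock-down scenario
#'
#' Simulates the four siRNA arms (siCtrl, siKEAP1, siNFE2L2, siSQSTM1)
#' with 72 h of knock-down followed by DMSO or DEM 316 uM, at the
#' ground-truth parameters. Knock-downs shift the pre-treatment baselines:
#' siSQSTM1 lowers the autophagosomal Keap1 pool, siKEAP1 raises nuclear
#' Nrf2 and siNFE2L2 blunts the DEM-induced Srxn1 response.
#'
#' @param params Ground-truth parameters.
#' @param factors Named knock-down efficiency factors in (0, 1] for
#'   `KEAP1`, `NFE2L2`, `SQSTM1`; defaults to the factors stored in
#'   `params`.
#' @param variant Model variant.
#' @param times Observation times (h post treatment).
#' @param doses Treatment doses of DEM (0 = DMSO arm).
#' @return Named list of `nrf2_sim` trajectories, one per arm x dose.
#' @export
knockdown_scenario <- function(params = reference_parameters(),
                               factors = NULL, variant = "hinge_latch",
                               times = 0:24, doses = c(0, 316)) {
  targets <- c("control", "KEAP1", "NFE2L2", "SQSTM1")
  if (!is.null(factors)) {
    if (any(factors <= 0 | factors > 1))
      stop("knock-down factors must lie in (0, 1]")
    params[paste0("f_", names(factors))] <- factors
  }
  ss <- solve_steady_state(variant, params)
  out <- list()
  for (tg in targets) for (dose in doses) {
    cc <- condition(if (dose == 0) "DMSO" else "DEM", dose,
                    kd = knockdown(tg), times = times)
    out[[cc$id]] <- simulate_condition(variant, params, cc,
                                       state0 = ss$state0)
  }
  out
}
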