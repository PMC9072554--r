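#' Species of the Nrf2 pathway model
#'
#' The model tracks 15 species in a fixed order. Concentrations are in
#' arbitrary units (a.u.); the parametrisation convention pins the basal
#' steady-state concentration of free Keap1 to 1.
#'
#' \describe{
#'   \item{Keap1}{free, unmodified Keap1 dimer}
#'   \item{Nrf2}{free cytoplasmic Nrf2}
#'   \item{p62}{free p62 (SQSTM1), the autophagy adaptor}
#'   \item{K1N2_latch}{Keap1-Nrf2 complex bound at both the ETGE (hinge)
#'     and DLG (latch) motifs; the degradation-competent complex}
#'   \item{K1N2_mod}{stress-modified Keap1-Nrf2 complex, bound at the ETGE
#'     motif only; Nrf2 in this pool is protected from proteasomal
#'     degradation (populated only in the hinge-latch variant)}
#'   \item{K1p62}{Keap1-p62 complex en route to the autophagosome}
#'   \item{Keap1_auto}{autophagosomal Keap1 pool (the foci observable)}
#'   \item{nNrf2}{nuclear Nrf2}
#'   \item{mKEAP1, mNFE2L2, mSQSTM1, mSRXN1}{mRNA pools}
#'   \item{Srxn1}{sulfiredoxin-1 protein (pathway output reporter)}
#'   \item{GSH}{total glutathione pool}
#'   \item{Stress}{intracellular active electrophile}
#' }
#'
#' @return Character vector of the 15 species names, in model order.
#' @export
species_names <- function() {
  c("Keap1", "Nrf2", "p62", "K1N2_latch", "K1N2_mod", "K1p62",
    "Keap1_auto", "nNrf2", "mKEAP1", "mNFE2L2", "mSQSTM1", "mSRXN1",
    "Srxn1", "GSH", "Stress")
}

.N_SPECIES <- 15L

# Parameter names of the full model. Rates are per hour; second-order rates
# per (a.u. * hour); Hill constants in a.u.; knock-down factors dimensionless.
.param_names <- function() {
  c(
    # basal protein synthesis and mRNA-driven translation
    "p_Nrf2", "p_Keap1", "kt_Keap1", "p_p62", "kt_p62", "kt_Srxn1",
    # Keap1-Nrf2 binding / proteasomal degradation, p62 routing, autophagy
    "ka_KN", "kd_KN", "kdeg_Nrf2c", "ka_Kp62", "k_auto", "k_clear_auto",
    # nuclear shuttling of Nrf2
    "k_in", "k_out",
    # transcription: basal + Hill in nNrf2 (mNFE2L2 is constitutive)
    "b_mKEAP1", "V_mKEAP1", "K_mKEAP1", "h_mKEAP1",
    "b_mNFE2L2",
    "b_mSQSTM1", "V_mSQSTM1", "K_mSQSTM1", "h_mSQSTM1",
    "b_mSRXN1", "V_mSRXN1", "K_mSRXN1", "h_mSRXN1",
    # glutathione synthesis and conjugation
    "b_GSH", "V_GSH", "K_GSH", "h_GSH", "k_conj",
    # stress action on Keap1: complex-modification rate is per compound;
    # the free-Keap1 modification rate is mod_free_frac times it
    "mod_free_frac",
    # first-order turnover
    "d_Nrf2", "d_Keap1", "d_p62", "d_cplx", "d_nNrf2",
    "d_mKEAP1", "d_mNFE2L2", "d_mSQSTM1", "d_mSRXN1",
    "d_Srxn1", "d_GSH",
    # per-compound stress kinetics
    "kmod_DEM", "kclear_DEM", "kmod_DCF", "kclear_DCF",
    "kmod_OMZ", "kclear_OMZ",
    # omeprazole-specific overrides of Srxn1 turnover and SRXN1 induction
    "d_Srxn1_OMZ", "V_mSRXN1_OMZ",
    # siRNA knock-down efficiency factors (fraction of production retained)
    "f_KEAP1", "f_NFE2L2", "f_SQSTM1",
    # constant background electrophile input from the DMSO vehicle
    "dmso_bg"
  )
}

#' Validate a parameter set
#'
#' Checks that a named parameter vector is complete, positive and finite,
#' that Hill coefficients are >= 1 and knock-down factors lie in (0, 1].
#'
#' @param params Named numeric vector as returned by
#'   [reference_parameters()].
#' @return Invisibly, `params` (possibly reordered to canonical order).
#' @export
validate_parameters <- function(params) {
  need <- .param_names()
  miss <- setdiff(need, names(params))
  if (length(miss))
    stop("missing parameters: ", paste(miss, collapse = ", "))
  params <- params[need]
  if (!all(is.finite(params)))
    stop("non-finite parameter values")
  hills <- params[c("h_mKEAP1", "h_mSQSTM1", "h_mSRXN1", "h_GSH")]
  if (any(hills < 1)) stop("Hill coefficients must be >= 1")
  kd <- params[c("f_KEAP1", "f_NFE2L2", "f_SQSTM1")]
  if (any(kd <= 0 | kd > 1)) stop("knock-down factors must lie in (0, 1]")
  pos <- setdiff(need, "dmso_bg")  # background amplitude may be 0
  if (any(params[pos] <= 0)) stop("rates must be strictly positive")
  if (params["dmso_bg"] < 0) stop("dmso_bg must be >= 0")
  invisible(params)
}

# Resolve the per-compound parameter mapping into the generic slots the
# reaction network references. Shared parameters are identical across
# compounds; only the electrophile kinetics (and for OMZ the Srxn1
# turnover / SRXN1 induction Vmax) are compound specific.
resolve_params <- function(params, compound = "DEM") {
  compound <- match.arg(compound, c("DEM", "DCF", "OMZ", "DMSO"))
  # pure-vehicle conditions carry no electrophile bolus of their own; the
  # low-level background input is given DEM-like clearance kinetics
  cpd <- if (compound == "DMSO") "DEM" else compound
  out <- c(params,
    k_mod_cplx_eff   = unname(params[paste0("kmod_", cpd)]),
    k_mod_free_eff   = unname(params["mod_free_frac"] *
                              params[paste0("kmod_", cpd)]),
    k_clear_stress_eff = unname(params[paste0("kclear_", cpd)]),
    d_Srxn1_eff      = unname(if (cpd == "OMZ") params["d_Srxn1_OMZ"]
                              else params["d_Srxn1"]),
    V_mSRXN1_eff     = unname(if (cpd == "OMZ") params["V_mSRXN1_OMZ"]
                              else params["V_mSRXN1"]))
  out
}

#' Apply an siRNA knock-down switch to a parameter set
#'
#' Knock-downs are represented as a multiplicative switch on the production
#' rates of the targeted protein: both the basal synthesis rate and the
#' mRNA-driven translation rate (where one exists) are multiplied by the
#' knock-down efficiency factor. All other parameters are untouched;
#' a control knock-down returns the parameters unchanged.
#'
#' @param params Named parameter vector.
#' @param kd A knock-down specification from [knockdown()].
#' @return The modified parameter vector.
#' @export
apply_knockdown <- function(params, kd) {
  stopifnot(inherits(kd, "nrf2_knockdown"))
  if (kd$target == "control") return(params)
  f <- kd$factor
  if (is.null(f) || is.na(f))
    f <- unname(params[paste0("f_", kd$target)])
  if (f <= 0 || f > 1) stop("knock-down factor must lie in (0, 1]")
  slots <- switch(kd$target,
    KEAP1  = c("p_Keap1", "kt_Keap1"),
    NFE2L2 = "p_Nrf2",
    SQSTM1 = c("p_p62", "kt_p62"),
    stop("unknown knock-down target: ", kd$target))
  params[slots] <- params[slots] * f
  params
}

#' Specify an siRNA knock-down arm
#'
#' @param target One of `"control"`, `"KEAP1"`, `"NFE2L2"`, `"SQSTM1"`.
#' @param factor Efficiency factor in (0, 1] (fraction of protein production
#'   that remains). `NULL` means: take the fitted per-siRNA factor
#'   (`f_KEAP1`, `f_NFE2L2`, `f_SQSTM1`) from the parameter set at
#'   simulation time. Forced to 1 for the control.
#' @param duration Hours of knock-down before treatment onset (default 72).
#' @return An object of class `nrf2_knockdown`.
#' @export
knockdown <- function(target = "control", factor = NULL, duration = 72) {
  target <- match.arg(target, c("control", "KEAP1", "NFE2L2", "SQSTM1"))
  if (target == "control") factor <- 1
  if (!is.null(factor) && (factor <= 0 || factor > 1))
    stop("knock-down factor must lie in (0, 1]")
  if (duration < 0) stop("knock-down duration must be >= 0")
  structure(list(target = target, factor = factor, duration = duration),
            class = "nrf2_knockdown")
}
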