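#' Treatment stimulus: Gauss-shaped electrophile bolus
#'
#' A treatment is modelled as a Gaussian bolus of electrophile inflow that
#' is switched on at `onset`; the height of the Gaussian equals the nominal
#' dose. Wells also carry a constant low-amplitude background input from
#' the DMSO vehicle (switched on together with the bolus) when
#' `dmso_background` is set; the background amplitude is the model
#' parameter `dmso_bg`.
#'
#' @param compound `"DEM"`, `"DCF"`, `"OMZ"` or `"DMSO"` (vehicle only).
#' @param dose Nominal dose in uM; the peak height of the bolus.
#' @param onset Hours at which the treatment input switches on.
#' @param center_offset Hours from onset to the bolus peak (default 0.5).
#' @param width Gaussian width (standard deviation) in hours (default 0.25).
#' @param dmso_background Include the constant vehicle background input?
#' @return An object of class `nrf2_stimulus`.
#' @export
stimulus <- function(compound = "DEM", dose = 0, onset = 0,
                     center_offset = 0.5, width = 0.25,
                     dmso_background = TRUE) {
  compound <- match.arg(compound, c("DEM", "DCF", "OMZ", "DMSO"))
  if (dose < 0) stop("dose must be >= 0")
  if (width <= 0) stop("width must be > 0")
  if (onset < 0) stop("onset must be >= 0")
  structure(list(compound = compound, dose = dose, onset = onset,
                 center_offset = center_offset, width = width,
                 dmso_background = dmso_background),
            class = "nrf2_stimulus")
}

#' Evaluate the stimulus input at a time point
#'
#' Zero before onset; after onset, the Gaussian bolus
#' `dose * exp(-(t - onset - center_offset)^2 / (2 width^2))`
#' plus, if the spec carries the vehicle flag, the constant background
#' amplitude `bg`. The peak equals the dose at `t = onset + center_offset`.
#'
#' @param t Time in hours (vectorised).
#' @param spec A [stimulus()] object.
#' @param bg Background amplitude (the `dmso_bg` parameter value).
#' @return Electrophile inflow (uM/h equivalent, a.u.).
#' @export
stimulus_value <- function(t, spec, bg = 0) {
  stopifnot(is.finite(t))
  if (spec$dose < 0) stop("negative dose")
  on <- t >= spec$onset
  u <- ifelse(on,
              spec$dose * exp(-(t - spec$onset - spec$center_offset)^2 /
                                (2 * spec$width^2)),
              0)
  if (isTRUE(spec$dmso_background)) u <- u + ifelse(on, bg, 0)
  u
}

#' Define an experimental condition
#'
#' A condition couples a treatment stimulus with a knock-down arm and an
#' observation design. Time convention: for knock-down arms, t = 0 is the
#' start of the siRNA knock-down and the treatment bolus switches on at
#' `knockdown$duration` (72 h by default); otherwise treatment starts at
#' t = 0. Observation times are always relative to treatment onset.
#'
#' @param compound,dose Treatment (see [stimulus()]).
#' @param kd A [knockdown()] arm (default: control).
#' @param times Observation times in hours post treatment, sorted,
#'   non-negative.
#' @param horizon Simulation horizon post treatment (>= max(times)).
#' @param dmso_background Include the vehicle background input?
#' @param id Optional condition label; a default is composed from the
#'   treatment and knock-down.
#' @return An object of class `nrf2_condition`.
#' @export
condition <- function(compound = "DEM", dose = 0, kd = knockdown(),
                      times = 0:48, horizon = NULL,
                      dmso_background = TRUE, id = NULL) {
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0)) stop("observation times must be non-negative")
  if (is.null(horizon)) horizon <- max(times)
  if (horizon < max(times)) stop("horizon must cover observation times")
  onset <- if (kd$target == "control") 0 else kd$duration
  stim <- stimulus(compound, dose, onset = onset,
                   dmso_background = dmso_background)
  if (is.null(id)) {
    id <- paste0(compound, "_", dose)
    if (kd$target != "control") id <- paste0("si", kd$target, "_", id)
  }
  structure(list(id = id, stimulus = stim, knockdown = kd, times = times,
                 horizon = horizon),
            class = "nrf2_condition")
}

#' Simulate one experimental condition
#'
#' Pre-equilibrates the model to its untreated steady state, applies the
#' knock-down switch at t = 0 and the treatment bolus at its onset, and
#' integrates the stiff ODE system with `deSolve::lsoda`. The step size is
#' capped during the bolus window so the narrow Gaussian input is resolved.
#'
#' @param variant Model variant tag.
#' @param params Named parameter vector.
#' @param cond An [condition()] object.
#' @param state0 Optional pre-equilibrated initial state; computed via
#'   [solve_steady_state()] when omitted.
#' @param rtol,atol Solver tolerances.
#' @param engine `"auto"` uses the compiled right-hand side when the
#'   package's native code is loaded, `"r"` forces the interpreted
#'   reaction-network evaluator (the two are cross-checked in the test
#'   suite).
#' @return An object of class `nrf2_sim`: a numeric matrix with a `time`
#'   column (hours post treatment) and one column per species, with the
#'   condition and variant attached as attributes.
#' @export
simulate_condition <- function(variant, params, cond, state0 = NULL,
                               rtol = 1e-8, atol = 1e-10,
                               engine = c("auto", "compiled", "r")) {
  stopifnot(inherits(cond, "nrf2_condition"))
  engine <- match.arg(engine)
  if (engine == "auto")
    engine <- if (.compiled_available()) "compiled" else "r"
  stim <- cond$stimulus
  kd <- cond$knockdown
  if (is.null(state0)) {
    ss <- solve_steady_state(variant, params)
    if (!ss$converged)
      stop("steady-state pre-equilibration failed; parameters: ",
           paste(signif(params, 3), collapse = ","))
    state0 <- ss$state0
  }
  p_run <- apply_knockdown(params, kd)
  pr <- resolve_params(p_run, stim$compound)
  bg <- unname(params["dmso_bg"])
  if (engine == "compiled") {
    cpar <- .c_parms(pr, stim, bg, variant)
    f <- NULL
  } else {
    net <- build_model(variant)
    input_fun <- function(tt) stimulus_value(tt, stim, bg = bg)
    f <- make_rhs(net, pr, input_fun)
  }
  onset <- stim$onset
  t_end <- onset + cond$horizon
  out_times <- onset + cond$times
  pulse_end <- onset + stim$center_offset + 8 * stim$width
  if (t_end <= 0) {
    # observation at t = 0 only: the pre-equilibrated state itself
    res <- matrix(c(0, unname(state0)), nrow = length(out_times),
                  ncol = 16, byrow = TRUE)
    colnames(res) <- c("time", species_names())
    return(structure(res, class = c("nrf2_sim", "matrix"),
                     condition = cond, variant = variant))
  }

  run_seg <- function(y0, t0, t1, hmax = NULL) {
    tt <- sort(unique(c(t0, out_times[out_times > t0 & out_times <= t1], t1)))
    if (length(tt) < 2) return(NULL)
    args <- if (engine == "compiled")
      list(y = y0, times = tt, func = "nrf2_derivs", parms = cpar,
           dllname = "nrf2dyn", initfunc = "nrf2_initmod",
           rtol = rtol, atol = atol)
    else
      list(y = y0, times = tt, func = f, parms = NULL,
           rtol = rtol, atol = atol)
    if (!is.null(hmax)) args$hmax <- hmax
    m <- suppressWarnings(do.call(deSolve::lsoda, args))
    if (attr(m, "istate")[1] < 0)
      stop("ODE integration failed for condition ", cond$id,
           "; parameters: ", paste(signif(params, 4), collapse = ","))
    m
  }
  segs <- list()
  y <- unname(state0)
  t_cur <- 0
  brk <- unique(pmin(pmax(c(onset, pulse_end), 0), t_end))
  brk <- c(brk[brk > 0 & brk < t_end], t_end)
  for (i in seq_along(brk)) {
    t1 <- brk[i]
    # cap steps while the narrow bolus is active
    hmax <- if (t_cur >= onset - 1e-9 && t_cur < pulse_end)
      stim$width / 2 else NULL
    m <- run_seg(y, t_cur, t1, hmax)
    if (!is.null(m)) {
      segs[[length(segs) + 1L]] <- m
      y <- as.numeric(m[nrow(m), -1])
    }
    t_cur <- t1
  }
  traj <- do.call(rbind, lapply(segs, function(m) m[-1, , drop = FALSE]))
  traj <- rbind(segs[[1]][1, ], traj)
  keep <- match(round(out_times, 9), round(traj[, 1], 9))
  if (anyNA(keep)) stop("internal: requested output times missing")
  res <- traj[keep, , drop = FALSE]
  lo <- min(res[, -1])
  if (lo < -1e-6)
    stop("negative concentrations beyond solver tolerance (", signif(lo, 3),
         ") for condition ", cond$id)
  res[, -1][res[, -1] < 0] <- 0
  res[, 1] <- res[, 1] - onset
  colnames(res) <- c("time", species_names())
  structure(res, class = c("nrf2_sim", "matrix"), condition = cond,
            variant = variant)
}

# Is the package's native right-hand side available?
.compiled_available <- function() {
  is.loaded("nrf2_derivs", PACKAGE = "nrf2dyn") || is.loaded("nrf2_derivs")
}

# Assemble the parameter vector expected by the compiled RHS
# (layout documented in src/nrf2_rhs.c).
.c_parms <- function(pr, stim = NULL, bg = 0, variant = "hinge_latch") {
  nm <- c("p_Nrf2", "p_Keap1", "kt_Keap1", "p_p62", "kt_p62", "kt_Srxn1",
          "ka_KN", "kd_KN", "kdeg_Nrf2c", "ka_Kp62", "k_auto",
          "k_clear_auto", "k_in", "k_out",
          "b_mKEAP1", "V_mKEAP1", "K_mKEAP1", "h_mKEAP1",
          "b_mNFE2L2",
          "b_mSQSTM1", "V_mSQSTM1", "K_mSQSTM1", "h_mSQSTM1",
          "b_mSRXN1", "V_mSRXN1_eff", "K_mSRXN1", "h_mSRXN1",
          "b_GSH", "V_GSH", "K_GSH", "h_GSH",
          "k_conj",
          "d_Nrf2", "d_Keap1", "d_p62", "d_cplx", "d_nNrf2",
          "d_mKEAP1", "d_mNFE2L2", "d_mSQSTM1", "d_mSRXN1",
          "d_Srxn1_eff", "d_GSH",
          "k_mod_free_eff", "k_mod_cplx_eff", "k_clear_stress_eff")
  v <- unname(pr[nm])
  if (anyNA(v)) stop("unresolved parameters for compiled model")
  stimv <- if (is.null(stim)) c(0, 0, 0.5, 0.25, 0) else
    c(stim$dose, stim$onset, stim$center_offset, stim$width,
      if (isTRUE(stim$dmso_background)) bg else 0)
  c(v, if (identical(variant, "dissociation")) 1 else 0, stimv)
}

#' Total Keap1-Nrf2 complex time course
#'
#' Sums the latch-bound and stress-modified complex pools. In the
#' dissociation variant the modified pool is structurally zero, so the
#' total reduces to the latch complex. This is the quantity whose
#' post-treatment behaviour discriminates the two mechanistic hypotheses:
#' under dissociation it dips below its pre-treatment baseline immediately
#' after the bolus, under hinge-latch it does not.
#'
#' @param sim An `nrf2_sim` trajectory matrix (or any matrix with columns
#'   `K1N2_latch` and `K1N2_mod`).
#' @return Numeric vector, one value per row of `sim`.
#' @export
complex_total <- function(sim) {
  cols <- colnames(sim)
  if (!("K1N2_latch" %in% cols))
    stop("missing species column K1N2_latch")
  tot <- sim[, "K1N2_latch"]
  if ("K1N2_mod" %in% cols) tot <- tot + sim[, "K1N2_mod"]
  unname(tot)
}
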