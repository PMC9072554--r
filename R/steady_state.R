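# Steady-state machinery. The model is assumed to be in equilibrium at
# t = 0 (no electrophile input); this both supplies the initial state for
# every simulation and, via constrain_parameters(), ties production rates
# to anchored steady-state concentrations so they drop out of the free
# parameter set.

# Fixed-point cascade over the per-species balance equations; used as the
# heuristic start for Newton and for pre-simulation.
.heuristic_state <- function(pr) {
  g <- function(nm) unname(pr[nm])
  hill <- function(x, V, K, h) V * x^h / (K^h + x^h)
  N2 <- 0.1; K1 <- 1; p62 <- 1; nN <- 0.1
  latch <- 0; Kp <- 0
  for (it in 1:60) {
    nN_new <- g("k_in") * N2 / (g("k_out") + g("d_nNrf2"))
    nN <- 0.5 * nN + 0.5 * nN_new
    mK <- (g("b_mKEAP1") + hill(nN, g("V_mKEAP1"), g("K_mKEAP1"), g("h_mKEAP1"))) / g("d_mKEAP1")
    mS <- (g("b_mSQSTM1") + hill(nN, g("V_mSQSTM1"), g("K_mSQSTM1"), g("h_mSQSTM1"))) / g("d_mSQSTM1")
    latch <- g("ka_KN") * K1 * N2 / (g("kd_KN") + g("kdeg_Nrf2c") + g("d_cplx"))
    Kp <- g("ka_Kp62") * K1 * p62 / (g("k_auto") + g("d_cplx"))
    N2n <- (g("p_Nrf2") + g("kd_KN") * latch + g("k_out") * nN) /
      (g("ka_KN") * K1 + g("k_in") + g("d_Nrf2"))
    K1n <- (g("p_Keap1") + g("kt_Keap1") * mK +
              (g("kd_KN") + g("kdeg_Nrf2c")) * latch) /
      (g("ka_KN") * N2 + g("ka_Kp62") * p62 + g("d_Keap1"))
    p62n <- (g("p_p62") + g("kt_p62") * mS) / (g("ka_Kp62") * K1 + g("d_p62"))
    N2 <- 0.5 * N2 + 0.5 * N2n
    K1 <- 0.5 * K1 + 0.5 * K1n
    p62 <- 0.5 * p62 + 0.5 * p62n
  }
  mK <- (g("b_mKEAP1") + hill(nN, g("V_mKEAP1"), g("K_mKEAP1"), g("h_mKEAP1"))) / g("d_mKEAP1")
  mN <- g("b_mNFE2L2") / g("d_mNFE2L2")
  mS <- (g("b_mSQSTM1") + hill(nN, g("V_mSQSTM1"), g("K_mSQSTM1"), g("h_mSQSTM1"))) / g("d_mSQSTM1")
  mX <- (g("b_mSRXN1") + hill(nN, g("V_mSRXN1_eff"), g("K_mSRXN1"), g("h_mSRXN1"))) / g("d_mSRXN1")
  x <- c(K1, N2, p62, latch, 0, Kp,
         g("k_auto") * Kp / g("k_clear_auto"), nN, mK, mN, mS, mX,
         g("kt_Srxn1") * mX / g("d_Srxn1_eff"),
         (g("b_GSH") + hill(nN, g("V_GSH"), g("K_GSH"), g("h_GSH"))) / g("d_GSH"),
         0)
  names(x) <- species_names()
  pmax(x, 0)
}

.newton_root <- function(f, x0, tol = 1e-10, maxit = 60, lower = 0) {
  x <- x0
  fx <- f(x)
  n <- length(x)
  lower <- rep_len(lower, n)
  for (it in seq_len(maxit)) {
    nf <- max(abs(fx))
    if (nf < tol) return(list(x = x, f = fx, converged = TRUE))
    J <- matrix(0, n, n)
    for (i in seq_len(n)) {
      h <- 1e-7 * max(abs(x[i]), 1e-3)
      xp <- x; xp[i] <- xp[i] + h
      J[, i] <- (f(xp) - fx) / h
    }
    dx <- tryCatch(solve(J, -fx), error = function(e) NULL)
    if (is.null(dx)) dx <- tryCatch(qr.solve(J, -fx, tol = 1e-14),
                                    error = function(e) NULL)
    if (is.null(dx)) return(list(x = x, f = fx, converged = FALSE))
    lam <- 1
    ok <- FALSE
    for (k in 1:25) {
      xn <- pmax(x + lam * dx, lower)
      fn <- f(xn)
      if (all(is.finite(fn)) && max(abs(fn)) < nf * (1 - 1e-4 * lam) + 1e-14) {
        x <- xn; fx <- fn; ok <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!ok) return(list(x = x, f = fx, converged = max(abs(fx)) < tol))
  }
  list(x = x, f = fx, converged = max(abs(fx)) < tol)
}

#' Solve for the untreated steady state
#'
#' Computes the equilibrium concentration vector of the model with no
#' electrophile input, either by damped Newton root-finding from a
#' heuristic start (fast, default) or by long pre-simulation (1e4 h),
#' which serves both as an independent cross-check and as a fallback when
#' root-finding does not converge.
#'
#' @param variant Model variant tag.
#' @param params Named parameter vector.
#' @param tol Maximum-norm tolerance on the steady-state residual (1/h).
#' @param method `"auto"` (root-finding with pre-simulation fallback),
#'   `"rootfind"`, or `"presimulation"`. Root-finding starts the damped
#'   Newton iteration from the heuristic state after a brief relaxation
#'   integration, so that with multiple coexisting equilibria the root in
#'   the dynamically reached basin is selected.
#' @param presim_time Hours of pre-simulation for the fallback method.
#' @return An object of class `nrf2_steady`: list with `state0` (named,
#'   non-negative), `residual_norm`, `method` and `converged`.
#' @export
solve_steady_state <- function(variant = "hinge_latch", params,
                               tol = 1e-8,
                               method = c("auto", "rootfind", "presimulation"),
                               presim_time = 1e4) {
  method <- match.arg(method)
  net <- build_model(variant)
  pr <- resolve_params(params, "DEM")
  f0 <- make_rhs(net, pr, NULL)
  f <- function(x) f0(0, x, NULL)[[1]]
  x0 <- .heuristic_state(pr)

  relax <- function(from, hours, rtol = 1e-8, atol = 1e-10) {
    tt <- c(0, hours / 10, hours)
    m <- suppressWarnings(if (.compiled_available())
      deSolve::lsoda(unname(from), times = tt, func = "nrf2_derivs",
                     parms = .c_parms(pr, NULL, 0, variant),
                     dllname = "nrf2dyn", initfunc = "nrf2_initmod",
                     rtol = rtol, atol = atol)
    else
      deSolve::lsoda(unname(from), times = tt, func = f0, parms = NULL,
                     rtol = rtol, atol = atol))
    if (nrow(m) < 3) return(unname(from))
    pmax(as.numeric(m[nrow(m), -1]), 0)
  }
  presim <- function() relax(x0, presim_time, rtol = 1e-10, atol = 1e-12)

  if (method == "presimulation") {
    x <- presim()
    res <- max(abs(f(x)))
    out <- list(state0 = stats::setNames(x, net$species),
                residual_norm = res, method = "presimulation",
                converged = res < max(tol, 1e-7))
    return(structure(out, class = "nrf2_steady"))
  }

  # brief relaxation before Newton keeps the root in the reachable basin
  nr <- .newton_root(f, relax(x0, 1000), tol = tol)
  used <- "rootfind"
  if (!nr$converged && method == "auto") {
    x1 <- presim()
    nr2 <- .newton_root(f, x1, tol = tol)
    if (nr2$converged || max(abs(nr2$f)) < max(abs(nr$f))) {
      nr <- nr2
      used <- "presimulation"
    }
  }
  res <- max(abs(nr$f))
  structure(list(state0 = stats::setNames(pmax(nr$x, 0), net$species),
                 residual_norm = res, method = used,
                 converged = res < tol),
            class = "nrf2_steady")
}

#' @export
print.nrf2_steady <- function(x, ...) {
  cat("Nrf2 model steady state (", x$method, "): residual ",
      format(x$residual_norm, digits = 3), ", converged: ", x$converged,
      "\n", sep = "")
  print(round(x$state0, 6))
  invisible(x)
}

#' Constrain production rates via steady-state anchors
#'
#' Uses the t = 0 equilibrium assumption to eliminate free parameters:
#' for each anchored species, its production-rate parameter is re-solved so
#' that the steady state passes exactly through the anchored concentration.
#' Supported anchors and the parameter each one determines:
#' `Keap1` -> `p_Keap1`, `Nrf2` -> `p_Nrf2`, `p62` -> `p_p62`,
#' `GSH` -> `b_GSH`. The default convention pins free Keap1 at 1, which
#' also fixes the concentration scale of the model (removing the global
#' scaling symmetry between species scales and observation scales).
#'
#' Implementation: the production rates enter their balance equations
#' linearly, so the anchored system (remaining species free, anchored
#' concentrations pinned, production rates unknown) is solved by the same
#' damped Newton iteration used for the plain steady state.
#'
#' @param params Named parameter vector.
#' @param anchors Named numeric vector of target steady-state values, names
#'   among `Keap1`, `Nrf2`, `p62`, `GSH`. Empty anchors return `params`
#'   unchanged.
#' @param variant Model variant tag.
#' @return Parameter vector with the production rates replaced; attributes
#'   `state0` (the anchored steady state) attached.
#' @export
constrain_parameters <- function(params, anchors = c(Keap1 = 1),
                                 variant = "hinge_latch") {
  if (length(anchors) == 0) return(params)
  amap <- c(Keap1 = "p_Keap1", Nrf2 = "p_Nrf2", p62 = "p_p62", GSH = "b_GSH")
  bad <- setdiff(names(anchors), names(amap))
  if (length(bad)) stop("unsupported anchors: ", paste(bad, collapse = ", "))
  sp <- species_names()
  a_idx <- match(names(anchors), sp)
  free_idx <- setdiff(seq_along(sp), a_idx)
  pnames <- amap[names(anchors)]
  net <- build_model(variant)

  make_f <- function(p) {
    pr <- resolve_params(p, "DEM")
    f0 <- make_rhs(net, pr, NULL)
    function(x) f0(0, x, NULL)[[1]]
  }
  # unknowns: free species concentrations + log production rates
  obj <- function(u) {
    x <- numeric(length(sp))
    x[free_idx] <- pmax(u[seq_along(free_idx)], 0)
    x[a_idx] <- anchors
    p <- params
    p[pnames] <- exp(u[length(free_idx) + seq_along(pnames)])
    make_f(p)(x)
  }
  x0 <- .heuristic_state(resolve_params(params, "DEM"))
  u0 <- c(unname(x0[free_idx]), log(unname(params[pnames])))
  nr <- .newton_root(obj, u0, tol = 1e-11,
                     lower = c(rep(0, length(free_idx)),
                               rep(-Inf, length(pnames))))
  if (!nr$converged)
    stop("anchor set could not be satisfied (no positive-rate solution); ",
         "anchors: ", paste(names(anchors), collapse = ", "))
  rates <- exp(nr$x[length(free_idx) + seq_along(pnames)])
  if (any(!is.finite(rates) | rates <= 0))
    stop("anchor ", names(anchors)[which(!is.finite(rates) | rates <= 0)[1]],
         " requires a non-positive production rate")
  out <- params
  out[pnames] <- rates
  st <- numeric(length(sp)); st[free_idx] <- pmax(nr$x[seq_along(free_idx)], 0)
  st[a_idx] <- anchors
  attr(out, "state0") <- stats::setNames(st, sp)
  out
}
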