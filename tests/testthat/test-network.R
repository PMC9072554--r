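# Reaction network construction, stimulus input, knock-down switch and
# the right-hand side.

test_that("the two variants differ only in the stress-on-complex step", {
  hl <- build_model("hinge_latch")
  ds <- build_model("dissociation")
  expect_setequal(hl$species, species_names())
  expect_identical(hl$species, ds$species)
  expect_identical(hl$reactions$name, ds$reactions$name)
  j <- which(hl$reactions$name == "mod_complex")
  expect_identical(hl$reactions[-j, ], ds$reactions[-j, ])
  # hinge-latch keeps the complex (as K1N2_mod); dissociation releases Nrf2
  expect_identical(hl$reactions$products[j], "K1N2_mod")
  expect_identical(ds$reactions$products[j], "Nrf2")
  expect_equal(hl$S["K1N2_mod", j], 1)
  expect_equal(ds$S["K1N2_mod", j], 0)
  expect_equal(ds$S["Nrf2", j], 1)
  expect_error(build_model("both"), "arg")
})

test_that("binding and shuttling reactions conserve Keap1 and Nrf2 mass", {
  w_K <- w_N <- numeric(15)
  names(w_K) <- names(w_N) <- species_names()
  w_K[c("Keap1", "K1N2_latch", "K1N2_mod", "K1p62", "Keap1_auto")] <- 1
  w_N[c("Nrf2", "K1N2_latch", "K1N2_mod", "nNrf2")] <- 1
  for (v in c("hinge_latch", "dissociation")) {
    net <- build_model(v)
    bal_K <- drop(w_K %*% net$S)
    bal_N <- drop(w_N %*% net$S)
    conserving <- c("bind_KN", "unbind_KN", "bind_Kp62", "auto_flux",
                    "nrf2_import", "nrf2_export", "deg_Nrf2_proteasome")
    if (v == "hinge_latch") conserving <- c(conserving, "mod_complex")
    expect_true(all(bal_K[conserving] == 0))
    # total Keap1 changes only through synthesis and clearance terms
    src <- names(bal_K)[bal_K > 0]
    snk <- names(bal_K)[bal_K < 0]
    expect_setequal(src, c("prod_Keap1", "transl_Keap1"))
    clearance <- c("auto_clear", "mod_free_Keap1", "deg_Keap1",
                   "deg_latch", "deg_mod", "deg_K1p62")
    # under dissociation the stress-modified Keap1 leaves the pool as well
    if (v == "dissociation") clearance <- c(clearance, "mod_complex")
    expect_setequal(snk, clearance)
    # Nrf2 mass: conserved by binding/shuttling and by the stress step
    expect_true(all(bal_N[c("bind_KN", "unbind_KN", "nrf2_import",
                            "nrf2_export", "mod_complex")] == 0))
  }
})

test_that("the stimulus is a Gauss bolus with peak height equal to the dose", {
  sp <- stimulus("DEM", dose = 316, onset = 0, dmso_background = FALSE)
  expect_equal(stimulus_value(sp$center_offset, sp), 316)
  expect_equal(stimulus_value(-0.01, sp), 0)          # off before onset
  sp0 <- stimulus("DEM", dose = 0, onset = 0, dmso_background = FALSE)
  expect_equal(stimulus_value(seq(0, 48, 7), sp0), rep(0, 7))
  # six widths from the peak the bolus is numerically negligible
  expect_lt(stimulus_value(sp$center_offset + 6 * sp$width, sp), 1e-6 * 316)
  # background switches on with the treatment
  spb <- stimulus("DMSO", dose = 0, onset = 72, dmso_background = TRUE)
  expect_equal(stimulus_value(71.9, spb, bg = 0.3), 0)
  expect_equal(stimulus_value(100, spb, bg = 0.3), 0.3)
  expect_error(stimulus("DEM", dose = -1), "dose")
})

test_that("knock-down is a multiplicative switch on production rates", {
  p <- ref_params()
  expect_identical(apply_knockdown(p, knockdown("control")), p)
  kd <- apply_knockdown(p, knockdown("SQSTM1", factor = 0.2))
  expect_equal(unname(kd[c("p_p62", "kt_p62")]),
               unname(p[c("p_p62", "kt_p62")]) * 0.2)
  same <- setdiff(names(p), c("p_p62", "kt_p62"))
  expect_identical(kd[same], p[same])
  # vanishing efficiency factor drives the synthesis flux to zero
  kd0 <- apply_knockdown(p, knockdown("KEAP1", factor = 1e-12))
  st <- ref_steady()$state0
  r <- ode_rhs(st, 0, kd0, variant = "hinge_latch")
  flux_in <- kd0["p_Keap1"] + kd0["kt_Keap1"] * st["mKEAP1"]
  expect_lt(unname(flux_in), 1e-10)
  expect_error(knockdown("TP53"), "should be one of")
  bad <- structure(list(target = "TP53", factor = 0.5, duration = 72),
                   class = "nrf2_knockdown")
  expect_error(apply_knockdown(p, bad), "unknown knock-down target")
})

test_that("rhs vanishes in the absorbing state and at the steady state", {
  p <- ref_params()
  p0 <- p
  p0[c("p_Nrf2", "p_Keap1", "p_p62", "b_mKEAP1", "b_mNFE2L2", "b_mSQSTM1",
       "b_mSRXN1", "b_GSH")] <- 1e-300
  p0[c("V_mKEAP1", "V_mSQSTM1", "V_mSRXN1", "V_GSH")] <- 1e-300
  r0 <- ode_rhs(rep(0, 15), 0, p0, variant = "hinge_latch")
  expect_lt(max(abs(r0)), 1e-250)
  r <- ode_rhs(ref_steady()$state0, 0, p, variant = "hinge_latch")
  expect_lt(max(abs(r)), 1e-8)
  expect_error(ode_rhs(c(NA, rep(0, 14)), 0, p), "finite")
})

test_that("network evaluation matches a hand-written closed form", {
  # independent oracle: a 4-species sub-network coded directly
  rx <- function(name, re, pr, law, ...)
    c(list(name = name, reactants = re, products = pr, law = law),
      list(...))
  reactions <- list(
    rx("prod_A", "", "A", "mass_action", rate = "k1"),
    rx("bind", "A + B", "AB", "mass_action", rate = "k2"),
    rx("degA_in_AB", "AB", "B", "mass_action", rate = "k3"),
    rx("deg_A", "A", "", "mass_action", rate = "k4"),
    rx("tx_C", "", "C", "hill", basal = "b", vmax = "V", km = "K",
       hill = "h", modifier = "A"),
    rx("deg_C", "C", "", "mass_action", rate = "k5"))
  net <- nrf2dyn:::compile_network(reactions, c("A", "B", "AB", "C"), "toy")
  pars <- c(k1 = 0.7, k2 = 1.3, k3 = 0.4, k4 = 0.2, b = 0.1, V = 2,
            K = 0.5, h = 2, k5 = 0.3)
  f <- nrf2dyn:::make_rhs(net, pars, NULL)
  closed_form <- function(x) {
    A <- x[1]; B <- x[2]; AB <- x[3]; C <- x[4]
    hillA <- 2 * A^2 / (0.5^2 + A^2)
    c(0.7 - 1.3 * A * B - 0.2 * A,
      -1.3 * A * B + 0.4 * AB,
      1.3 * A * B - 0.4 * AB,
      0.1 + hillA - 0.3 * C)
  }
  set.seed(11)
  worst <- 0
  for (i in 1:100) {
    x <- runif(4, 0, 3)
    worst <- max(worst, max(abs(f(0, x, NULL)[[1]] - closed_form(x))))
  }
  expect_lt(worst, 1e-12)
})

test_that("compiled and interpreted right-hand sides give the same trajectories", {
  p <- ref_params()
  expect_true(nrf2dyn:::.compiled_available())
  cc <- condition("DEM", 316, times = seq(0, 24, 2))
  for (v in c("hinge_latch", "dissociation")) {
    sC <- simulate_condition(v, p, cc, state0 = ref_steady(v)$state0,
                             engine = "compiled")
    sR <- simulate_condition(v, p, cc, state0 = ref_steady(v)$state0,
                             engine = "r")
    expect_lt(max(abs(sC[, -1] - sR[, -1]) / pmax(abs(sR[, -1]), 1e-6)),
              1e-5)
  }
})
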