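# Deterministic simulation: steady-state invariance, solver refinement,
# qualitative response shape and the complex read-out.

test_that("an untreated system stays at its steady state", {
  p <- ref_params()
  cc <- condition("DMSO", 0, times = seq(0, 120, 10),
                  dmso_background = FALSE)
  sim <- simulate_condition("hinge_latch", p, cc,
                            state0 = ref_steady()$state0)
  base <- sim[1, -1]
  nz <- base > 0
  drift <- max(abs(sweep(sim[, -1][, nz, drop = FALSE], 2, base[nz], "/") - 1))
  expect_lt(drift, 1e-6)
  expect_true(all(abs(sim[, -1][, !nz]) < 1e-8))
})

test_that("tightening solver tolerances does not change the solution", {
  p <- ref_params()
  cc <- condition("DEM", 316, times = seq(0, 48, 2))
  s1 <- simulate_condition("hinge_latch", p, cc,
                           state0 = ref_steady()$state0,
                           rtol = 1e-8, atol = 1e-10)
  s2 <- simulate_condition("hinge_latch", p, cc,
                           state0 = ref_steady()$state0,
                           rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(s1[, -1] - s2[, -1]) / pmax(abs(s2[, -1]), 1e-6)), 1e-4)
})

test_that("trajectories stay non-negative across doses and variants", {
  for (v in c("hinge_latch", "dissociation"))
    for (d in c(0, 10, 561)) {
      sim <- ref_sim(v, d, step = 1)
      expect_true(all(sim[, -1] >= 0))
    }
})

test_that("nuclear Nrf2 rises fast, peaking 3-5 h after the DEM bolus", {
  sim <- ref_sim("hinge_latch", 316)
  tt <- sim[, "time"]
  t_peak <- tt[which.max(sim[, "nNrf2"])]
  expect_gte(t_peak, 3); expect_lte(t_peak, 5)
  # followed by slow relaxation: still clearly above baseline at 48 h
  expect_gt(sim[nrow(sim), "nNrf2"], sim[1, "nNrf2"] * 1.1)
})

test_that("NFE2L2 mRNA is flat and dose-independent in both variants", {
  for (v in c("hinge_latch", "dissociation")) {
    m0 <- ref_sim(v, 0)[, "mNFE2L2"]
    for (d in c(10, 316, 561)) {
      m <- ref_sim(v, d)[, "mNFE2L2"]
      expect_equal(m, m0, tolerance = 1e-9)
      expect_lt(diff(range(m)) / m[1], 1e-6)
    }
  }
})

test_that("the complex read-out sums the latch and modified pools", {
  sim <- ref_sim("hinge_latch", 316)
  expect_equal(complex_total(sim),
               unname(sim[, "K1N2_latch"] + sim[, "K1N2_mod"]))
  zero <- sim; zero[, -1] <- 0
  expect_true(all(complex_total(zero) == 0))
  expect_error(complex_total(sim[, c("time", "GSH")]), "K1N2_latch")
})

test_that("only the dissociation variant predicts a complex dip after DEM", {
  hl <- complex_total(ref_sim("hinge_latch", 316))
  ds <- complex_total(ref_sim("dissociation", 316))
  tt <- ref_sim("hinge_latch", 316)[, "time"]
  expect_true(all(hl >= hl[1] * (1 - 1e-6)))
  early <- tt <= 2
  expect_lt(min(ds[early]), ds[1])
  # and later a sharp increase back above baseline
  expect_gt(max(ds), ds[1])
})

test_that("knock-down arms shift baselines as predicted", {
  sims <- knockdown_scenario(ref_params(), times = c(0, 6, 12, 24))
  b <- function(id, sp) sims[[id]][1, sp]
  expect_lt(b("siSQSTM1_DMSO_0", "Keap1_auto"), b("DMSO_0", "Keap1_auto"))
  expect_gt(b("siKEAP1_DMSO_0", "nNrf2"), b("DMSO_0", "nNrf2"))
  resp <- function(id) {
    s <- sims[[id]]
    s[nrow(s), "Srxn1"] / s[1, "Srxn1"]
  }
  expect_lt(resp("siNFE2L2_DEM_316"), resp("DEM_316"))
  # full-efficiency factors reduce to the control arm
  s_ctrl <- knockdown_scenario(ref_params(),
                               factors = c(KEAP1 = 1, NFE2L2 = 1, SQSTM1 = 1),
                               times = c(0, 24), doses = 316)
  expect_equal(s_ctrl$siKEAP1_DEM_316[, -1], s_ctrl$DEM_316[, -1],
               tolerance = 1e-8, ignore_attr = TRUE)
})
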