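# Steady-state solving and the constraint-based parameter reduction.

test_that("isolated linear species reach production/degradation", {
  p <- ref_params()
  ss <- ref_steady()
  # NFE2L2 mRNA is constitutive: steady value b/d in closed form
  expect_equal(unname(ss$state0["mNFE2L2"]),
               unname(p["b_mNFE2L2"] / p["d_mNFE2L2"]), tolerance = 1e-9)
  expect_lt(ss$residual_norm, 1e-8)
  expect_true(ss$converged)
  expect_identical(ss$method, "rootfind")
})

test_that("root-finding agrees with long pre-simulation", {
  p <- ref_params()
  rt <- solve_steady_state("hinge_latch", p, method = "rootfind")
  ps <- solve_steady_state("hinge_latch", p, method = "presimulation")
  both <- pmax(abs(rt$state0), abs(ps$state0))
  nz <- both > 1e-10
  expect_lt(max(abs(rt$state0[nz] - ps$state0[nz]) / both[nz]), 1e-6)
})

test_that("random positive parameter draws give consistent equilibria", {
  p0 <- ref_params()
  set.seed(101)
  n_ok <- 0
  for (i in 1:12) {
    p <- p0 * exp(rnorm(length(p0), 0, 0.2))
    p[c("h_mKEAP1", "h_mSQSTM1", "h_mSRXN1", "h_GSH")] <-
      p0[c("h_mKEAP1", "h_mSQSTM1", "h_mSRXN1", "h_GSH")]
    p[c("f_KEAP1", "f_NFE2L2", "f_SQSTM1")] <- 0.3
    rt <- solve_steady_state("hinge_latch", p, method = "rootfind")
    ps <- solve_steady_state("hinge_latch", p, method = "presimulation")
    if (!rt$converged || !ps$converged) next
    n_ok <- n_ok + 1
    both <- pmax(abs(rt$state0), abs(ps$state0))
    nz <- both > 1e-10
    expect_lt(max(abs(rt$state0[nz] - ps$state0[nz]) / both[nz]), 1e-6)
  }
  expect_gt(n_ok, 6)
})

test_that("zero Nrf2 production empties the nuclear pool", {
  p <- ref_params()
  p["p_Nrf2"] <- 1e-300
  ss <- solve_steady_state("hinge_latch", p)
  expect_lt(unname(ss$state0["nNrf2"]), 1e-12)
  expect_lt(unname(ss$state0["K1N2_latch"]), 1e-12)
})

test_that("anchored production rates reproduce the anchors exactly", {
  p0 <- ref_params()
  # perturb the production rates, then re-derive them from the anchors
  p <- p0
  p[c("p_Keap1", "p_Nrf2", "p_p62", "b_GSH")] <-
    p0[c("p_Keap1", "p_Nrf2", "p_p62", "b_GSH")] * c(3, 0.5, 2, 1.5)
  pc <- constrain_parameters(p, full_anchors)
  expect_equal(unname(pc[c("p_Keap1", "p_Nrf2", "p_p62", "b_GSH")]),
               unname(p0[c("p_Keap1", "p_Nrf2", "p_p62", "b_GSH")]),
               tolerance = 1e-6)
  ss <- solve_steady_state("hinge_latch", pc)
  expect_equal(unname(ss$state0[names(full_anchors)]),
               unname(full_anchors), tolerance = 1e-8)
  # single anchor: only the Keap1 synthesis rate is re-solved
  pk <- constrain_parameters(p, c(Keap1 = 1))
  expect_identical(pk[setdiff(names(p), "p_Keap1")],
                   p[setdiff(names(p), "p_Keap1")])
  ssk <- solve_steady_state("hinge_latch", pk)
  expect_equal(unname(ssk$state0["Keap1"]), 1, tolerance = 1e-8)
  st <- attr(pc, "state0")
  r <- ode_rhs(st, 0, pc, variant = "hinge_latch")
  expect_lt(max(abs(r)), 1e-8)
})

test_that("no anchors is the identity; infeasible anchors are rejected", {
  p <- ref_params()
  expect_identical(constrain_parameters(p, NULL), p)
  expect_identical(constrain_parameters(p, numeric(0)), p)
  # an absurd anchor forces a negative production rate
  expect_error(constrain_parameters(p, c(Keap1 = 1e-9)), "anchor")
  expect_error(constrain_parameters(p, c(Stress = 1)), "unsupported")
})
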