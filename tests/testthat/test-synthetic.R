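# Ground-truth parameters and the synthetic replicate generator.

test_that("the reference parameters satisfy their qualitative anchors", {
  p <- ref_params()
  validate_parameters(p)
  expect_lt(ref_steady()$residual_norm, 1e-8)
  expect_equal(unname(ref_steady()$state0["Keap1"]), 1, tolerance = 1e-7)

  sim316 <- ref_sim("hinge_latch", 316)
  tt <- sim316[, "time"]
  t_peak <- tt[which.max(sim316[, "nNrf2"])]
  expect_gte(t_peak, 3); expect_lte(t_peak, 5)

  # induced mRNAs peak at the 8 h qPCR sampling point (of 3/8/24 h)
  iq <- match(c(3, 8, 24), tt)
  for (m in c("mKEAP1", "mSQSTM1", "mSRXN1")) {
    v <- sim316[iq, m]
    expect_gt(v[2], v[1]); expect_gt(v[2], v[3])
  }
  expect_lt(diff(range(sim316[, "mNFE2L2"])) / sim316[1, "mNFE2L2"], 1e-6)

  sim561 <- ref_sim("hinge_latch", 561)
  g <- sim561[, "GSH"]
  expect_lte(max(g) / g[1] - 1, 0.30)
  expect_gt(max(g) / g[1] - 1, 0.02)

  ka <- sim561[, "Keap1_auto"]
  dip3 <- 1 - min(ka[tt <= 3]) / ka[1]
  expect_gte(dip3, 0.04); expect_lte(dip3, 0.12)
  expect_gt(ka[length(ka)], ka[1])          # later rise above baseline

  sx <- sim561[, "Srxn1"]
  n <- length(sx)
  expect_gt(sx[n], sx[n - 1])               # still rising at 48 h
})

test_that("zero dose without background gives flat observables", {
  des <- synthetic_design(n_replicates = 1, sigma = 0,
                          imaging_times = c(0, 24, 48),
                          doses = list(DEM = 0))
  syn <- generate_dataset(des, params = ref_params(), seed = 1)
  # the DMSO_0 condition carries the vehicle background; rebuild it without
  cc <- condition("DMSO", 0, times = c(0, 24, 48), dmso_background = FALSE)
  sim <- simulate_condition("hinge_latch", ref_params(), cc)
  rel <- apply(sim[, -1], 2, function(x)
    if (max(x) == 0) 0 else diff(range(x)) / max(x))
  expect_lt(max(rel), 1e-6)
  # with sigma = 0 and a single experiment the replicates equal the truth
  m <- merge(syn$replicates, syn$truth,
             by = c("condition", "observable", "time"))
  expect_equal(m$value, exp(m$yhat), tolerance = 1e-12)
})

test_that("generation is deterministic for a fixed seed", {
  des <- synthetic_design(n_replicates = 2, imaging_times = c(0, 8, 24),
                          doses = list(DEM = c(0, 316)))
  a <- generate_dataset(des, params = ref_params(), seed = 99)
  b <- generate_dataset(des, params = ref_params(), seed = 99)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$scalings, b$scalings)
  c2 <- generate_dataset(des, params = ref_params(), seed = 100)
  expect_false(identical(a$replicates, c2$replicates))
})

test_that("the noise model has the designed log-normal spread", {
  des <- synthetic_design(n_replicates = 61, sigma = 0.1,
                          imaging_times = 0:48, doses = list(DEM = 316))
  syn <- generate_dataset(des, params = ref_params(), seed = 13)
  m <- merge(syn$replicates, syn$truth,
             by = c("condition", "observable", "time"))
  s_k <- syn$scalings[m$experiment]
  draws <- log(m$value * s_k) - m$yhat
  expect_gt(length(draws), 1e4)
  expect_lt(abs(sd(draws) - 0.1) / 0.1, 0.05)
  expect_lt(abs(mean(draws)), 0.005)
})

test_that("generator scalings are recovered by alignment", {
  syn <- small_synth()
  al <- align_replicates(syn$replicates)
  for (ob in unique(al$scalings$observable)) {
    s <- al$scalings$s[al$scalings$observable == ob]
    names(s) <- al$scalings$experiment[al$scalings$observable == ob]
    expect_lt(max(abs(s[names(syn$scalings)] - syn$scalings) /
                    syn$scalings), 0.1)
  }
})
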