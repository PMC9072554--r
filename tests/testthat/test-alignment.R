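# Replicate alignment under the log-normal scaling model and the mixed
# scaling-offset merge of experiment series.

make_reps <- function(y, s_k, sigma = 0, obs = "Nrf2_nuc", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_along(s_k), function(k) {
    data.frame(condition = y$condition, experiment = paste0("e", k),
               observable = obs, time = y$time,
               value = y$y / s_k[k] * exp(rnorm(nrow(y), 0, sigma)))
  }))
}

truth_tc <- function() {
  # five dose conditions x 20 time points, loosely shaped like reporter
  # induction curves
  conds <- c("DMSO_0", "DEM_10", "DEM_100", "DEM_316", "DEM_561")
  amp <- c(0, 0.2, 1, 2.5, 3.5)
  tt <- 0:19
  do.call(rbind, lapply(seq_along(conds), function(i) {
    data.frame(condition = conds[i], time = tt,
               y = 1 + amp[i] * (1 - exp(-tt / 8)))
  }))
}

test_that("a single experiment is returned as-is with unit scaling", {
  y <- truth_tc()
  al <- align_replicates(make_reps(y, 1))
  expect_equal(al$scalings$s, 1)
  expect_equal(al$aligned$y[order(al$aligned$condition, al$aligned$time)],
               y$y[order(y$condition, y$time)], tolerance = 1e-12)
})

test_that("noise-free replicates recover the constructed scaling exactly", {
  y <- truth_tc()
  al <- align_replicates(make_reps(y, c(1, 2)))  # replicate 2 is halved
  s <- al$scalings$s
  expect_equal(s[2] / s[1], 2, tolerance = 1e-10)
  a <- al$aligned[order(al$aligned$condition, al$aligned$time), ]
  expect_equal(a$y, y$y[order(y$condition, y$time)], tolerance = 1e-10)
  expect_error(align_replicates(transform(make_reps(y, 1), value = -value)),
               "positive")
})

test_that("scaling ratios are recovered within 2% under realistic noise", {
  y <- truth_tc()
  s_true <- c(1, 0.6, 1.7, 2.2)
  set.seed(123)
  rel_err <- replicate(100, {
    al <- align_replicates(make_reps(y, s_true, sigma = 0.1))
    s <- al$scalings$s
    mean(abs(s[-1] / s[1] - s_true[-1]) / s_true[-1])
  })
  expect_lt(mean(rel_err), 0.02)
})

test_that("gauge: rescaling one experiment moves only its scaling factor", {
  y <- truth_tc()
  reps <- make_reps(y, c(1, 2, 0.5), sigma = 0.05, seed = 5)
  al1 <- align_replicates(reps)
  reps2 <- reps
  reps2$value[reps2$experiment == "e3"] <-
    reps2$value[reps2$experiment == "e3"] * 10
  al2 <- align_replicates(reps2)
  expect_equal(al1$aligned$y, al2$aligned$y, tolerance = 1e-9)
  expect_equal(al2$scalings$s[3], al1$scalings$s[3] / 10, tolerance = 1e-9)
  expect_equal(al2$scalings$s[1:2], al1$scalings$s[1:2], tolerance = 1e-9)
})

test_that("merging identical series is the identity", {
  y <- truth_tc()
  al <- align_replicates(make_reps(y, 1))
  m <- merge_series(al, al)
  expect_equal(m$s, 1, tolerance = 1e-8)
  expect_equal(m$b, 0, tolerance = 1e-8)
})

test_that("the mixed scaling-offset merge recovers (s = 2, b = 0.3)", {
  y <- truth_tc()
  A <- align_replicates(make_reps(y, 1))$aligned
  B <- A
  B$y <- A$y / 2 + 0.3
  # a second, non-bridging condition rides along on series B
  extra <- data.frame(condition = "DEM_700", observable = "Nrf2_nuc",
                      time = 0:5, y = c(1, 1.5, 2, 2.5, 2, 1.8) / 2 + 0.3)
  B <- rbind(B, extra[, names(B)])
  m <- merge_series(A, B, bridge = c("DEM_316", "DMSO_0"))
  expect_equal(m$s, 2, tolerance = 1e-8)
  expect_equal(m$b, 0.3, tolerance = 1e-8)
  got <- m$merged[m$merged$condition == "DEM_700", "y"]
  expect_equal(got, (extra$y - 0.3) * 2, tolerance = 1e-8)
  expect_error(merge_series(A, extra), "bridging")
})

test_that("scale and offset are recovered within 5% under noise", {
  y <- truth_tc()
  set.seed(77)
  errs <- t(replicate(100, {
    A <- align_replicates(make_reps(y, 1))$aligned
    B <- A
    B$y <- (A$y / 2 + 0.3) * exp(rnorm(nrow(A), 0, 0.1))
    m <- merge_series(A, B)
    c(abs(m$s - 2) / 2, abs(m$b - 0.3) / 0.3)
  }))
  expect_lt(mean(errs[, 1]), 0.05)
  expect_lt(mean(errs[, 2]), 0.25)
})
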