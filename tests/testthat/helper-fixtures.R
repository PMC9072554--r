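# Shared fixtures, computed lazily and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

ref_params <- function() {
  if (is.null(.fixture_env$params))
    .fixture_env$params <- reference_parameters()
  .fixture_env$params
}

ref_steady <- function(variant = "hinge_latch") {
  key <- paste0("ss_", variant)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- solve_steady_state(variant, ref_params())
  .fixture_env[[key]]
}

ref_sim <- function(variant = "hinge_latch", dose = 316, step = 0.5) {
  key <- paste0("sim_", variant, "_", dose, "_", step)
  if (is.null(.fixture_env[[key]])) {
    cc <- condition(if (dose == 0) "DMSO" else "DEM", dose,
                    times = seq(0, 48, step))
    .fixture_env[[key]] <- simulate_condition(variant, ref_params(), cc,
                                              state0 = ref_steady(variant)$state0)
  }
  .fixture_env[[key]]
}

# A small noisy synthetic study (single-compound, coarse imaging) shared
# by the estimation tests.
small_synth <- function() {
  if (is.null(.fixture_env$synth)) {
    des <- synthetic_design(compounds = "DEM", n_replicates = 3,
                            sigma = 0.1, imaging_times = seq(0, 48, 4))
    .fixture_env$synth <- generate_dataset(des, params = ref_params(),
                                           seed = 42)
  }
  .fixture_env$synth
}

# Aligned log-scale dataset of the small study.
small_dataset <- function() {
  if (is.null(.fixture_env$small_ds)) {
    al <- align_replicates(small_synth()$replicates)
    d <- al$aligned
    d$value <- log(d$y)
    d$y <- NULL
    .fixture_env$small_ds <- d
  }
  .fixture_env$small_ds
}

full_anchors <- c(Keap1 = 1, Nrf2 = 0.05, p62 = 1, GSH = 10)

# Multi-start recovery fit on the small study, shared by several tests.
recovery_fit <- function() {
  if (is.null(.fixture_env$recovery_fit)) {
    pb <- nrf2_problem(small_dataset(), small_synth()$conditions,
                       params = ref_params(),
                       free = c("kmod_DEM", "k_clear_auto", "V_mSRXN1",
                                "kt_Srxn1"),
                       anchors = full_anchors, bound_decades = 1.5)
    .fixture_env$recovery_fit <- nrf2_fit(pb, n_starts = 5, seed = 2)
  }
  .fixture_env$recovery_fit
}
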