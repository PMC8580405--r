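test_that("identical seeds and specs give bit-identical signals", {
  spec <- oscillator_spec("Alpha1")
  cp <- coupling_spec("x", "y", "Alpha1", 0.5)
  a <- make_coupled_pair(spec, cp, snr = 2, duration_s = 10, seed = 7)
  b <- make_coupled_pair(spec, cp, snr = 2, duration_s = 10, seed = 7)
  expect_identical(a$recording$data, b$recording$data)
  c <- make_coupled_pair(spec, cp, snr = 2, duration_s = 10, seed = 8)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("coupling strength 0 stays at the noise floor, strength 1 noiseless saturates", {
  spec <- oscillator_spec("Alpha1")
  zero <- make_coupled_pair(spec, coupling_spec("x", "y", "Alpha1", 0),
                            snr = 1, duration_s = 300, seed = 11)
  expect_lt(band_icoh_of(zero$recording, "Alpha1")[1, 2], 0.1)

  full <- make_coupled_pair(spec, coupling_spec("x", "y", "Alpha1", 1),
                            snr = Inf, duration_s = 60, seed = 12)
  expect_gt(band_icoh_of(full$recording, "Alpha1")[1, 2], 0.9)
})

test_that("estimated icoh increases monotonically along the strength ladder", {
  strengths <- c(0, 0.2, 0.4, 0.6, 0.8)
  spec <- oscillator_spec("Alpha1")
  means <- sapply(strengths, function(s) {
    mean(sapply(1:4, function(sd) {
      cp <- make_coupled_pair(spec, coupling_spec("x", "y", "Alpha1", s),
                              snr = 1, duration_s = 120, seed = 100 + sd)
      band_icoh_of(cp$recording, "Alpha1")[1, 2]
    }))
  })
  expect_equal(cor(means, strengths, method = "spearman"), 1)
})

test_that("invalid oscillator, coupling, and pair parameters are rejected", {
  expect_error(oscillator_spec("Alpha1", center_hz = 20), "outside band")
  expect_error(coupling_spec("a", "a", "Alpha1", 0.5), "distinct")
  expect_error(coupling_spec("a", "b", "Alpha1", 1.5), "\\[0, 1\\]")
  expect_error(coupling_spec("a", "b", "Alpha1", 0.5, lag_s = 0), "nonzero")
  spec <- oscillator_spec("Beta2")  # upper edge 30 Hz
  expect_error(make_coupled_pair(spec, coupling_spec("a", "b", "Beta2", 0.5),
                                 duration_s = 10, fs = 50), "Nyquist")
  expect_error(make_coupled_pair(oscillator_spec("Alpha1"),
                                 coupling_spec("a", "b", "Alpha1", 0.5),
                                 duration_s = 2), "two epochs")
})

test_that("uncoupled regions under identity mixing show no band connectivity", {
  rec <- simulate_subject(reduced_atlas()$label, ground_truth(seed = 5),
                          duration_s = 300)
  sp <- epoch_spectra(segment_epochs(rec))
  for (b in band_table()$band) {
    expect_lt(max(imaginary_coherence(sp, b)), 0.1)
  }
})

test_that("instantaneous mixing inflates ordinary coherence but not icoh", {
  mix <- matrix(c(1, .6, 0, 0,
                  .6, 1, 0, 0,
                  0, 0, 1, .6,
                  0, 0, .6, 1), 4, 4)
  tr <- ground_truth(mixing = mixing_spec(mix), seed = 6)
  rec <- simulate_subject(letters[1:4], tr, duration_s = 300)
  sp <- epoch_spectra(segment_epochs(rec))
  icoh <- imaginary_coherence(sp, "Alpha")
  msc <- magnitude_squared_coherence(sp, "Alpha")
  expect_gt(msc[1, 2], 0.5)
  expect_gt(msc[3, 4], 0.5)
  expect_lt(max(icoh), 0.1)
})

test_that("an injected coupling dominates the simulated connectivity matrix", {
  cps <- list(coupling_spec("Occipital_Sup_L", "Occipital_Mid_L", "Alpha1", 0.8))
  rec <- simulate_subject(reduced_atlas()$label, ground_truth(couplings = cps, seed = 7),
                          duration_s = 60)
  M <- band_icoh_of(rec, "Alpha1")
  idx <- which(unclass(M) == max(M), arr.ind = TRUE)[1, ]
  expect_setequal(rownames(M)[idx], c("Occipital_Sup_L", "Occipital_Mid_L"))
})

test_that("simulate_subject validates regions and mixing dimensions", {
  tr <- ground_truth(couplings = list(coupling_spec("a", "zz", "Alpha", 0.5)), seed = 1)
  expect_error(simulate_subject(c("a", "b"), tr, duration_s = 5), "unknown region")
  expect_error(simulate_subject(c("a", "a"), ground_truth(seed = 1), duration_s = 5),
               "duplicate")
  tr2 <- ground_truth(mixing = mixing_spec(k = 3), seed = 1)
  expect_error(simulate_subject(c("a", "b"), tr2, duration_s = 5), "dimension")
})

test_that("cohort simulation is deterministic and records its ground truth", {
  cfg <- cohort_config(n_per_group = 2, duration_s = 12, effects = list(fov_cpl_slope = 0))
  a <- simulate_cohort(cfg, seed = 42)
  b <- simulate_cohort(cfg, seed = 42)
  expect_identical(a$behavior, b$behavior)
  expect_identical(a$recordings[[3]][["Post"]]$data, b$recordings[[3]][["Post"]]$data)
  expect_equal(nrow(a$behavior), 6)
  expect_true(all(fcnet:::cohort_schema() %in% names(a$behavior)))
  expect_length(a$truth$behavioral_effects$per_subject_couplings, 6 * 3)
  expect_setequal(unique(a$truth$behavioral_effects$assignment), c("Sham", "AC", "ACDC"))
})

test_that("a zero-effect cohort with frozen FOV has no responders", {
  cfg <- cohort_config(n_per_group = 3, make_recordings = FALSE,
                       effects = fcnet:::null_effects())
  sim <- simulate_cohort(cfg, seed = 9)
  expect_true(all(sim$behavior$fov_post == sim$behavior$fov_pre))
  labs <- classify_responders(sim$behavior)
  expect_equal(attr(labs, "n_responders"), 0)
  expect_equal(attr(labs, "n_nonresponders"), nrow(sim$behavior))
})

test_that("group sizes below 2 are rejected", {
  expect_error(cohort_config(n_per_group = 1), "group sizes")
})

test_that("the injected FOV-CPL association is recovered with a negative sign", {
  signs <- sapply(1:6, function(r) {
    cfg <- cohort_config(groups = "ACDC", n_per_group = 8,
                         timepoints = c("Pre", "Post"), duration_s = 30)
    sim <- simulate_cohort(cfg, seed = 500 + r)
    cpl <- sim$truth$behavioral_effects$cpl_post
    fov_change <- sim$behavior$fov_post - sim$behavior$fov_pre
    sign(cor(fov_change, cpl))
  })
  expect_true(all(signs == -1))
})
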