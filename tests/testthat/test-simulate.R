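mont <- build_standard_montage()

test_that("zero-amplitude systemics yield zero traces", {
  sys <- simulate_systemics(small_spec(), zero_noise(), 500, seed = 1)
  expect_true(all(sys$hbo == 0))
  expect_true(all(sys$hbr == 0))
})

test_that("mayer-only systemics peak spectrally near 0.1 Hz", {
  ns <- zero_noise()
  ns$mayer$amplitude <- 1
  sys <- simulate_systemics(session_spec(), ns, 6000, seed = 2,
                            n_channels = 4)
  for (j in 1:4) {
    sp <- stats::spec.pgram(stats::ts(sys$hbo[, j], frequency = 7.81),
                            plot = FALSE, taper = 0, spans = 5)
    fpeak <- sp$freq[which.max(sp$spec)]
    expect_gte(fpeak, 0.05); expect_lte(fpeak, 0.15)
  }
})

test_that("shared loadings force positive mean pairwise SC correlation", {
  sys <- simulate_systemics(session_spec(), noise_spec(), 4000, seed = 3)
  sc <- sys$hbo[, 17:24]
  cm <- stats::cor(sc)
  expect_gt(mean(cm[upper.tri(cm)]), 0)
})

test_that("null forward model produces constant unit intensity", {
  sim <- simulate_session(small_spec(), ground_truth(hbo_amplitude = 0),
                          zero_noise(), seed = 1)
  expect_true(all(abs(sim$session$intensity - 1) < 1e-12))
})

test_that("simulation is deterministic and positive", {
  a <- simulate_session(small_spec(), ground_truth(), noise_spec(), seed = 9)
  b <- simulate_session(small_spec(), ground_truth(), noise_spec(), seed = 9)
  expect_identical(a$session$intensity, b$session$intensity)
  expect_true(all(a$session$intensity > 0))
})

test_that("without motion the optical density has no jumps beyond the noise scale", {
  ns <- mild_noise(motion_rate = 0)
  sim <- simulate_session(small_spec(), ground_truth(), ns, seed = 4)
  od <- intensity_to_od(sim$session)
  d <- abs(diff(od$values[, "ch3", 1]))
  # jumps bounded by a small multiple of the white-noise step scale
  white_step <- stats::sd(diff(od$values[, "ch3", 1]))
  expect_lt(max(d), 8 * white_step)
})

test_that("short channels carry no task-locked component on average", {
  ns <- mild_noise()
  cors <- sapply(1:50, function(seed) {
    sim <- simulate_session(small_spec(), ground_truth(), ns, seed = seed)
    n_t <- dim(sim$session$intensity)[1]
    task <- build_task_design(sim$schedule, 7.81, n_t)
    od <- intensity_to_od(sim$session)
    mean(sapply(paste0("sc", 1:8), function(s)
      stats::cor(od$values[, s, 1], rowSums(task$X[, c("A", "V", "AV")]))))
  })
  se <- stats::sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors)), 3 * se + 0.02)
})

test_that("cohorts have per-subject schedules and honour determinism and variability", {
  spec <- small_spec(n_subjects = 16)
  co <- make_cohort(spec, ground_truth(), zero_noise(), seed = 5)
  expect_length(co$sessions, 16)
  onsets <- sapply(co$schedules, function(s) s$onset[2])
  expect_gt(length(unique(round(onsets, 6))), 1)

  co2 <- make_cohort(spec, ground_truth(), zero_noise(), seed = 5)
  expect_identical(co$sessions[[3]]$intensity, co2$sessions[[3]]$intensity)

  # zero between-subject SD: all subjects share the true betas
  tr0 <- ground_truth(between_subject_sd = 0)
  co3 <- make_cohort(small_spec(), tr0, zero_noise(), seed = 6)
  expect_identical(co3$subject_truths[[1]], co3$subject_truths[[4]])
})

test_that("increasing superficial share strictly degrades no-SC beta recovery", {
  spec <- small_spec(n_subjects = 3)
  rmses <- sapply(c(0.2, 0.5, 0.9), function(share) {
    ns <- mild_noise(share = share)
    co <- make_cohort(spec, ground_truth(between_subject_sd = 0), ns,
                      seed = 11)
    hemo <- lapply(co$sessions, preprocess_session)
    bt <- run_pipeline(hemo, pipeline_by_id(1), mont, co$schedules)
    beta_rmse(bt, co$subject_truths)
  })
  expect_true(all(diff(rmses) > 0))
})
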