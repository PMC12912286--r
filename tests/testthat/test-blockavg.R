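mont <- build_standard_montage()
fs_std <- 7.81

test_that("constant input averages to zero after baseline centering", {
  prep <- sim_and_preprocess(small_spec(), ground_truth(hbo_amplitude = 0),
                             zero_noise(), seed = 1)
  hemo <- prep$hemo
  hemo$values[] <- 3.14
  ea <- epoch_and_average(hemo, prep$schedule, mont)
  expect_lt(max(abs(ea$mean)), 1e-12)
})

test_that("window sample count follows the sampling grid", {
  prep <- sim_and_preprocess(small_spec(), ground_truth(), zero_noise(),
                             seed = 2)
  ea <- epoch_and_average(prep$hemo, prep$schedule, mont)
  n_per_curve <- sum(ea$condition == "V" & ea$roi == "occipital" &
                       ea$chromophore == "hbo")
  expect_equal(n_per_curve, floor(30 * fs_std) + 1)
  expect_equal(min(ea$time), round(-5 * fs_std) / fs_std)
})

test_that("simulated visual response peaks in the expected window with near-zero baseline", {
  prep <- sim_and_preprocess(session_spec(n_trials_per_condition = 10,
                                          n_subjects = 1),
                             ground_truth(), zero_noise(), seed = 3)
  ea <- epoch_and_average(prep$hemo, prep$schedule, mont)
  occ_v <- ea[ea$condition == "V" & ea$roi == "occipital" &
                ea$chromophore == "hbo", ]
  tpk <- occ_v$time[which.max(occ_v$mean)]
  expect_gte(tpk, 5); expect_lte(tpk, 15)
  # the baseline window carries the (real) tail of the previous trial's
  # response plus high-pass wobble, so it is small but not exactly zero
  base <- occ_v$mean[occ_v$time <= 0]
  expect_lt(mean(abs(base)), 0.2 * max(occ_v$mean))
  # HbR mirrors HbO with opposite sign
  occ_v_r <- ea[ea$condition == "V" & ea$roi == "occipital" &
                  ea$chromophore == "hbr", ]
  expect_lt(min(occ_v_r$mean), 0)
})

test_that("no-SC corrected average equals the plain average and residualization is idempotent", {
  prep <- sim_and_preprocess(small_spec(), ground_truth(), mild_noise(),
                             seed = 4)
  plain <- epoch_and_average(prep$hemo, prep$schedule, mont)
  none <- corrected_block_average(prep$hemo, prep$schedule,
                                  pipeline_by_id(1), mont)
  expect_equal(plain$mean, none$mean, tolerance = 1e-12)

  cfg <- pipeline_by_id(10)
  r1 <- scregress:::residualize_on_nuisance(prep$hemo, cfg, mont)
  r2 <- scregress:::residualize_on_nuisance(r1, cfg, mont)
  ach <- paste0("ch", mont$channels$id[mont$channels$roi != "excluded"])
  expect_equal(r1$values[, ach, ], r2$values[, ach, ], tolerance = 1e-6)
})

test_that("pooled-PCA correction shrinks a pure-systemic block average", {
  prep <- sim_and_preprocess(small_spec(), ground_truth(hbo_amplitude = 0),
                             mild_noise(), seed = 5)
  plain <- epoch_and_average(prep$hemo, prep$schedule, mont)
  corr <- corrected_block_average(prep$hemo, prep$schedule,
                                  pipeline_by_id(10), mont)
  amp <- function(ea) mean(abs(ea$mean[ea$chromophore == "hbo"]))
  expect_lt(amp(corr), amp(plain))
})

test_that("block-average sign concords with the GLM beta sign across seeds", {
  spec <- small_spec(n_subjects = 1)
  ok <- sapply(1:20, function(seed) {
    prep <- sim_and_preprocess(spec, ground_truth(), scaled_noise(0.3),
                               seed = seed)
    bt <- run_pipeline(list(prep$hemo), pipeline_by_id(10), mont,
                       list(prep$schedule))
    ea <- corrected_block_average(prep$hemo, prep$schedule,
                                  pipeline_by_id(10), mont)
    occ <- mont$channels$id[mont$channels$roi == "occipital"]
    b <- mean(bt$beta[bt$channel %in% occ & bt$condition == "V" &
                        bt$chromophore == "hbo"])
    curve <- ea[ea$condition == "V" & ea$roi == "occipital" &
                  ea$chromophore == "hbo", ]
    area <- mean(curve$mean[curve$time >= 0 & curve$time <= 15])
    sign(b) == sign(area)
  })
  expect_gte(mean(ok), 0.9)
})
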