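fs_std <- 7.81

test_that("intensity to optical density follows the mean-reference convention", {
  n <- 100
  arr <- array(1, dim = c(n, 1, 2), dimnames = list(NULL, "ch1", c("760", "850")))
  attr(arr, "fs") <- fs_std
  od <- intensity_to_od(arr)
  expect_true(all(od$values == 0))

  # one sample at half the mean gives dOD = ln 2 there (mean recomputed)
  x <- rep(1, n); x[50] <- NA
  # construct a series whose mean is exactly 1 with one sample at 1/2
  x <- rep(1 + 0.5 / (n - 1), n); x[50] <- 0.5
  arr[, 1, 1] <- x; arr[, 1, 2] <- x
  od <- intensity_to_od(arr)
  expect_equal(od$values[50, 1, 1], log(2), tolerance = 1e-12)

  # exp-inverse round trip reproduces I / mean(I)
  set.seed(1)
  y <- exp(stats::rnorm(n, 0, 0.01))
  arr[, 1, 1] <- y; arr[, 1, 2] <- y
  od <- intensity_to_od(arr)
  expect_equal(exp(-od$values[, 1, 1]), y / mean(y), tolerance = 1e-12)

  arr[1, 1, 1] <- -1
  expect_error(intensity_to_od(arr), "non-positive")
})

test_that("tddr passes artifact-free signals unchanged and repairs spikes", {
  expect_equal(tddr(numeric(64), fs = 1), numeric(64))

  # 0.05 Hz sinusoid: no improbable derivatives, identity repair
  t1 <- seq(0, 400, by = 1)          # fs = 1 Hz: no frequency split
  s <- sin(2 * pi * 0.05 * t1)
  y <- tddr(s, fs = 1)
  expect_lt(sqrt(mean((y - s)^2)) / sqrt(mean(s^2)), 0.05)

  # single large spike: derivative rejected, spike removed
  sp <- s; sp[200] <- sp[200] + 10
  y2 <- tddr(sp, fs = 1)
  expect_lt(abs(y2[200] - s[200]) / 10, 0.1)

  # step artifact at the recording rate: removed through the low band
  t2 <- seq(0, 200, by = 1 / fs_std)
  st <- sin(2 * pi * 0.05 * t2) + 5 * (t2 > 100)
  y3 <- tddr(st, fs_std)
  drop_size <- abs(mean(y3[t2 > 110]) - mean(y3[t2 < 90]) -
                     (mean(sin(2 * pi * 0.05 * t2[t2 > 110])) -
                        mean(sin(2 * pi * 0.05 * t2[t2 < 90]))))
  expect_lt(drop_size, 1)

  expect_error(tddr(c(1, NA, 3), fs = 1), "non-finite")
  expect_error(tddr(1:5, fs = 1), "too short")
})

test_that("sharp spike residue above the split is eliminated by the band-pass", {
  t2 <- seq(0, 300, by = 1 / fs_std)
  s <- sin(2 * pi * 0.05 * t2)
  sp <- s; k <- 1200; sp[k] <- sp[k] + 10
  chain <- function(x) bandpass(tddr(x, fs_std), fs_std)
  resid <- chain(sp) - chain(s)
  expect_lt(max(abs(resid)) / 10, 0.1)
})

test_that("band-pass rejects DC, kills cardiac band, preserves the passband", {
  n <- 6000
  t <- (seq_len(n) - 1) / fs_std
  mid <- 1500:4500
  y_dc <- bandpass(rep(1, n), fs_std)
  expect_lt(max(abs(y_dc[mid])), 1e-6)

  y_card <- bandpass(sin(2 * pi * 1.2 * t), fs_std)
  atten_db <- 20 * log10(stats::sd(y_card[mid]) / stats::sd(sin(2 * pi * 1.2 * t[mid])))
  expect_lt(atten_db, -40)

  x_pass <- sin(2 * pi * 0.05 * t)
  y_pass <- bandpass(x_pass, fs_std)
  expect_lt(abs(stats::sd(y_pass[mid]) / stats::sd(x_pass[mid]) - 1), 0.05)

  expect_error(bandpass(x_pass, fs_std, low = 0.01, high = 5), "band edges")
})

test_that("band-pass is zero-phase: cross-correlation peaks at lag 0", {
  n <- 4000
  t <- (seq_len(n) - 1) / fs_std
  x <- sin(2 * pi * 0.05 * t)
  y <- bandpass(x, fs_std)
  cc <- stats::ccf(y[500:3500], x[500:3500], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("Beer-Lambert conversion is an exact linear round trip", {
  m <- build_standard_montage()
  k <- mbll_constants()
  E <- k$extinction * 1e-6
  sn <- scregress:::series_names(m)
  set.seed(3)
  n <- 50
  conc <- array(stats::rnorm(n * length(sn) * 2), dim = c(n, length(sn), 2))
  od_vals <- array(NA_real_, dim = c(n, length(sn), 2),
                   dimnames = list(NULL, sn, c("760", "850")))
  dists <- scregress:::series_distances_cm(m)
  for (j in seq_along(sn)) {
    od_vals[, j, ] <- conc[, j, ] %*% t(E) * (dists[[sn[j]]] * k$ppf)
  }
  od <- structure(list(values = od_vals, fs = fs_std, series = sn,
                       wavelengths = c("760", "850")), class = "od_series")
  hemo <- od_to_conc(od, k, m)
  expect_equal(max(abs(hemo$values - conc)), 0, tolerance = 1e-10)

  # zero optical density maps to zero concentrations
  od$values[] <- 0
  hemo0 <- od_to_conc(od, k, m)
  expect_true(all(hemo0$values == 0))

  # doubling the distance halves recovered concentrations
  od$values <- od_vals
  m2 <- m
  m2$channels$distance_mm <- m$channels$distance_mm * 2
  m2$short_channels$distance_mm <- pmin(8, m$short_channels$distance_mm * 2)
  m2$short_channels$distance_mm <- m$short_channels$distance_mm   # keep SC invariant
  hemo_long2 <- od_to_conc(od, mbll_constants(ppf = k$ppf * 2), m)
  expect_equal(hemo_long2$values, hemo$values / 2, tolerance = 1e-12)

  expect_error(mbll_constants(extinction = rbind(c(1, 1), c(2, 2))),
               "singular")
})

test_that("full chain maps a null session to numerical silence and enforces stage order", {
  sim <- simulate_session(small_spec(), ground_truth(hbo_amplitude = 0),
                          zero_noise(), seed = 1)
  hemo <- preprocess_session(sim$session)
  expect_lt(max(abs(hemo$values)), 1e-8)
  expect_error(preprocess_session(sim$session,
                                  stages = c("od", "bandpass", "tddr", "mbll")),
               "stage order")
})

test_that("chain is linear in the hemoglobin input when artifacts are absent", {
  spec <- small_spec()
  tr_a <- ground_truth(hbo_amplitude = 0.4)
  tr_b <- ground_truth(hbo_amplitude = 0.7)
  h_a <- sim_and_preprocess(spec, tr_a, zero_noise(), seed = 5)$hemo
  h_b <- sim_and_preprocess(spec, tr_b, zero_noise(), seed = 5)$hemo
  tr_sum <- ground_truth(hbo_amplitude = 1.1)
  h_sum <- sim_and_preprocess(spec, tr_sum, zero_noise(), seed = 5)$hemo
  expect_lt(max(abs(h_sum$values - (h_a$values + h_b$values))),
            1e-4 * max(abs(h_sum$values)))
})

test_that("cardiac-only session loses its 1.2 Hz line through the chain", {
  ns <- zero_noise()
  ns$cardiac$amplitude <- 5
  ns$superficial_share <- 1
  sim <- simulate_session(small_spec(), ground_truth(hbo_amplitude = 0), ns,
                          seed = 2)
  od_raw <- intensity_to_od(sim$session)
  x_pre <- od_raw$values[, "ch5", 1]
  x_post <- bandpass(tddr(x_pre, fs_std), fs_std)
  pw <- function(x) {
    sp <- stats::spec.pgram(stats::ts(x, frequency = fs_std), plot = FALSE,
                            taper = 0)
    band <- sp$freq > 1.1 & sp$freq < 1.3
    sum(sp$spec[band])
  }
  expect_lt(pw(x_post) / pw(x_pre), 0.01)
})
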