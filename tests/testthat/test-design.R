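test_that("canonical HRF has the expected shape", {
  fs <- 7.81
  h <- canonical_hrf(fs)
  expect_equal(h[1], 0)
  tmax <- (which.max(h) - 1) / fs
  expect_gte(tmax, 4); expect_lte(tmax, 7)
  expect_equal(max(h), 1)
  expect_lt(abs(h[length(h)]), 0.01)
})

test_that("task design builds one HRF-convolved column per condition plus intercept", {
  fs <- 7.81
  spec <- session_spec()
  sch <- generate_schedule(spec, seed = 3)
  n <- scregress:::session_n_samples(sch, fs)
  d <- build_task_design(sch, fs, n)
  expect_equal(colnames(d$X), c("A", "V", "AV", "intercept"))
  expect_true(all(d$X[, "intercept"] == 1))
  # a single default trial peaks at 1 by normalization
  one <- sch[1, , drop = FALSE]
  class(one) <- class(sch)
  d1 <- build_task_design(one, fs, n)
  expect_equal(max(d1$X[, one$condition]), 1, tolerance = 1e-6)

  # empty schedule: condition columns identically zero
  empty <- sch[0, , drop = FALSE]
  class(empty) <- class(sch)
  d0 <- build_task_design(empty, fs, n)
  expect_true(all(d0$X[, c("A", "V", "AV")] == 0))

  # single A event: other columns zero, A nonnegative with one main lobe
  ev <- sch[sch$condition == "A", ][1, , drop = FALSE]
  class(ev) <- class(sch)
  dA <- build_task_design(ev, fs, n)
  expect_true(all(dA$X[, c("V", "AV")] == 0))
  expect_gte(min(dA$X[, "A"]), -0.2)   # undershoot only
  expect_equal(sum(diff(dA$X[, "A"] > 0.5)^2 > 0), 2)  # one main lobe

  # events beyond the series end are rejected
  expect_error(build_task_design(sch, fs, 100), "beyond the end")
})

test_that("ols fit matches the normal-equations oracle and basic identities", {
  # 5-sample toy system, expected betas frozen from (X'X)^-1 X'y
  X <- cbind(A = c(1, 2, 0, 1, 3), V = c(0, 1, 1, 2, 1),
             AV = c(2, 0, 1, 1, 0), intercept = 1)
  y <- c(3.2, 1.5, -0.7, 2.2, 4.1)
  oracle <- solve(t(X) %*% X, t(X) %*% y)
  task <- structure(list(X = X, fs = 1, conditions = c("A", "V", "AV")),
                    class = "task_design")
  fit <- fit_ols(y, task)
  expect_equal(unname(fit$beta), unname(drop(oracle)), tolerance = 1e-10)
  expect_equal(fit$dof, 1)

  # response in the design span: zero residual
  y_span <- drop(X %*% c(1, -2, 0.5, 3))
  fit2 <- fit_ols(y_span, task)
  expect_lt(fit2$rss / sum(y_span^2), 1e-16)

  # orthonormal design: betas are inner products
  Q <- qr.Q(qr(matrix(stats::rnorm(40), 10, 4)))
  colnames(Q) <- c("A", "V", "AV", "intercept")
  taskQ <- structure(list(X = Q, fs = 1, conditions = c("A", "V", "AV")),
                     class = "task_design")
  yq <- stats::rnorm(10)
  fitq <- fit_ols(yq, taskQ)
  expect_equal(unname(fitq$beta), unname(drop(t(Q) %*% yq)), tolerance = 1e-10)

  # degenerate input is rejected
  Xc <- cbind(A = 0, V = 0, AV = 0, intercept = 1)[rep(1, 5), ]
  taskc <- structure(list(X = Xc, fs = 1, conditions = c("A", "V", "AV")),
                     class = "task_design")
  expect_error(suppressWarnings(fit_ols(rep(0, 5), taskc)), "degenerate")
})

test_that("adding nuisance regressors never increases the residual sum of squares", {
  set.seed(8)
  n <- 200
  X <- cbind(A = stats::rnorm(n), V = stats::rnorm(n), AV = stats::rnorm(n),
             intercept = 1)
  task <- structure(list(X = X, fs = 1, conditions = c("A", "V", "AV")),
                    class = "task_design")
  y <- stats::rnorm(n)
  rss_prev <- fit_ols(y, task)$rss
  N <- matrix(stats::rnorm(n * 6), n, 6)
  for (k in 1:6) {
    nuis <- structure(list(X = N[, 1:k, drop = FALSE],
                           labels = paste0("z", 1:k)), class = "nuisance_set")
    rss_k <- fit_ols(y, task, nuis)$rss
    expect_lte(rss_k, rss_prev + 1e-10)
    rss_prev <- rss_k
  }
})
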