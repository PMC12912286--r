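# Ordinary-least-squares GLM per channel and chromophore.

#' Fit a single-channel GLM by ordinary least squares
#'
#' Combines the task design (condition regressors plus intercept) with the
#' nuisance set and solves the least-squares problem through a
#' rank-revealing QR decomposition. If the design is rank deficient the
#' minimum-norm solution is returned (via the singular value decomposition)
#' with a warning.
#'
#' @param y Numeric response time series.
#' @param task A `task_design`.
#' @param nuisance A `nuisance_set` (or `NULL` for none).
#' @return A `glm_fit`: list with `beta` (named vector over all regressors),
#'   `condition_betas` (the three task betas), `residual_variance`, `dof`,
#'   `rss`.
#' @export
fit_ols <- function(y, task, nuisance = NULL) {
  X <- task$X
  if (!is.null(nuisance) && ncol(nuisance$X) > 0) {
    N <- nuisance$X
    colnames(N) <- nuisance$labels
    X <- cbind(X, N)
  }
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in design or response")
  n <- length(y)
  p <- ncol(X)
  if (n <= p) stop("more regressors than samples")
  if (stats::var(y) == 0 && all(apply(X[, colnames(X) != "intercept",
                                        drop = FALSE], 2, stats::var) == 0))
    stop("degenerate fit: response and design are both constant")
  qr_x <- qr(X)
  if (qr_x$rank < p) {
    warning("rank-deficient design (rank ", qr_x$rank, " of ", p,
            "); returning the minimum-norm solution")
    sv <- svd(X)
    keep <- sv$d > 1e-10 * sv$d[1]
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(qr_x, y)
  }
  names(beta) <- colnames(X)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  dof <- n - qr_x$rank
  structure(list(beta = beta,
                 condition_betas = beta[task$conditions],
                 residual_variance = rss / dof,
                 dof = dof, rss = rss),
            class = "glm_fit")
}

#' Run one pipeline over a preprocessed cohort
#'
#' For every subject, analyzed channel and chromophore, fits the OLS GLM
#' with that subject's task design and the nuisance set prescribed by the
#' pipeline configuration, and assembles the beta table.
#'
#' The task regressors are passed through the same band-pass filter as the
#' data (`filter_design = TRUE`, the default): the data's slow components
#' are attenuated by preprocessing, and an estimator is unbiased only if its
#' design lives in the same filtered space. The shared PCA basis for the
#' pooled strategy is computed once per subject and reused for every channel
#' and chromophore.
#'
#' @param cohort List of preprocessed `hemo_series`, one per subject.
#' @param config A `pipeline_config` (or integer pipeline id).
#' @param montage The montage.
#' @param schedules List of `event_schedule`s aligned with `cohort`.
#' @param filter_design Band-pass the condition regressors like the data.
#' @param low,high Band edges used when `filter_design` is `TRUE`.
#' @return A `beta_table`: data frame with columns `subject`, `channel`,
#'   `roi`, `condition`, `chromophore`, `beta` and attribute `pipeline_id`.
#' @export
run_pipeline <- function(cohort, config, montage, schedules,
                         filter_design = TRUE, low = 0.01, high = 0.12) {
  if (is.numeric(config)) config <- pipeline_by_id(config)
  stopifnot(length(cohort) >= 1, length(schedules) == length(cohort))
  ach <- analyzed_channels(montage)
  rows <- vector("list", length(cohort))
  for (s in seq_along(cohort)) {
    hemo <- cohort[[s]]
    n_t <- dim(hemo$values)[1]
    task <- build_task_design(schedules[[s]], hemo$fs, n_t)
    if (filter_design) {
      for (cond in task$conditions)
        task$X[, cond] <- bandpass_vec(task$X[, cond], hemo$fs, low, high)
    }
    pca <- NULL
    if (config$method == "pooled_pca")
      pca <- sc_pca(hemo, scope_sc_ids(config$scope, montage))
    fit_cache <- new.env(parent = emptyenv())
    sub <- vector("list", nrow(ach) * 2L)
    k <- 0L
    for (chrom in c("hbo", "hbr")) {
      for (i in seq_len(nrow(ach))) {
        ch <- ach$id[i]
        nuis <- build_nuisance(config, hemo, ch, chrom, montage, pca = pca)
        y <- hemo$values[, paste0("ch", ch), chrom]
        key <- paste0("d|", paste(nuis$labels, collapse = "|"))
        cache <- get0(key, envir = fit_cache)
        if (is.null(cache)) {
          X <- task$X
          if (ncol(nuis$X) > 0) X <- cbind(X, nuis$X)
          qr_x <- qr(X)
          cache <- list(qr = qr_x, p = ncol(X), X = X)
          assign(key, cache, envir = fit_cache)
        }
        if (cache$qr$rank < cache$p) {
          fit <- fit_ols(y, task, nuis)   # falls back to min-norm with warning
          cb <- fit$condition_betas
        } else {
          beta <- qr.coef(cache$qr, y)
          names(beta) <- colnames(cache$X)
          cb <- beta[task$conditions]
        }
        k <- k + 1L
        sub[[k]] <- data.frame(subject = s, channel = ch, roi = ach$roi[i],
                               condition = task$conditions,
                               chromophore = chrom, beta = unname(cb),
                               stringsAsFactors = FALSE)
      }
    }
    rows[[s]] <- do.call(rbind, sub)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "pipeline_id") <- config$id
  class(out) <- c("beta_table", "data.frame")
  out
}
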