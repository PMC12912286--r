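# Pipeline validation metrics: channel-level emergence and
# between-condition contrasts, evaluated with directional Bayes factors.

# Modality-appropriate tests per ROI.
roi_emergence_conditions <- function(roi) {
  if (roi %in% c("left_temporal", "right_temporal")) c("A", "AV") else c("V", "AV")
}
roi_contrasts <- function(roi) {
  if (roi %in% c("left_temporal", "right_temporal"))
    list(c("A", "V"), c("AV", "V"))
  else
    list(c("V", "A"), c("AV", "A"))
}

#' Metric 1: emergence of modality-appropriate activation
#'
#' For every analyzed channel, runs one-tailed one-sample Bayes-factor
#' t-tests of the condition betas against zero across subjects: conditions
#' A and AV in temporal channels, V and AV in occipital channels; the
#' expected direction is positive for HbO and negative for HbR. A channel
#' is flagged emergent when any tested condition yields `BF10` above the
#' threshold.
#'
#' @param betas A `beta_table` from [run_pipeline()].
#' @param montage The montage.
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param threshold Evidence threshold on `BF10` (default 3, the lower edge
#'   of positive evidence).
#' @return A `channel_verdicts` data frame: one row per channel with the
#'   per-condition Bayes factors (`bf_A`, `bf_V`, `bf_AV`; `NA` where the
#'   condition is not tested in that ROI), `emergent`, and
#'   `emergent_conditions`.
#' @export
metric1_emergence <- function(betas, montage, chromophore = c("hbo", "hbr"),
                              threshold = 3) {
  chromophore <- match.arg(chromophore)
  direction <- if (chromophore == "hbo") "positive" else "negative"
  ach <- analyzed_channels(montage)
  n_sub <- length(unique(betas$subject))
  if (n_sub < 3) stop("need at least 3 subjects for group-level tests")
  rows <- lapply(seq_len(nrow(ach)), function(i) {
    ch <- ach$id[i]; roi <- ach$roi[i]
    conds <- roi_emergence_conditions(roi)
    bf <- c(A = NA_real_, V = NA_real_, AV = NA_real_)
    for (cond in conds) {
      x <- betas$beta[betas$channel == ch & betas$condition == cond &
                        betas$chromophore == chromophore]
      bf[cond] <- bf_one_sample(x, direction)$bf10
    }
    hits <- names(bf)[!is.na(bf) & bf > threshold]
    data.frame(channel = ch, roi = roi, chromophore = chromophore,
               bf_A = bf[["A"]], bf_V = bf[["V"]], bf_AV = bf[["AV"]],
               emergent = length(hits) > 0,
               emergent_conditions = paste(hits, collapse = "+"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pipeline_id") <- attr(betas, "pipeline_id")
  class(out) <- c("channel_verdicts", "data.frame")
  out
}

#' Metric 2: between-condition contrasts within emergent channels
#'
#' Pairwise one-tailed two-sample Bayes-factor t-tests across subjects,
#' evaluated only in channels flagged by [metric1_emergence()]: A vs V and
#' AV vs V in temporal channels, V vs A and AV vs A in occipital channels,
#' in the expected direction (first condition larger for HbO, smaller for
#' HbR). Channels that are not emergent keep `NA` contrasts (not evaluated,
#' as opposed to evaluated-and-negative).
#'
#' @param betas The `beta_table` used for metric 1.
#' @param verdicts The output of [metric1_emergence()].
#' @param chromophore `"hbo"` or `"hbr"`.
#' @param threshold Evidence threshold on `BF10`.
#' @return `verdicts` augmented with `contrast1`, `bf_contrast1`,
#'   `contrast2`, `bf_contrast2`, `contrast_flag`.
#' @export
metric2_contrasts <- function(betas, verdicts, chromophore = c("hbo", "hbr"),
                              threshold = 3) {
  chromophore <- match.arg(chromophore)
  direction <- if (chromophore == "hbo") "positive" else "negative"
  verdicts$contrast1 <- NA_character_
  verdicts$contrast2 <- NA_character_
  verdicts$bf_contrast1 <- NA_real_
  verdicts$bf_contrast2 <- NA_real_
  verdicts$contrast_flag <- NA
  for (i in seq_len(nrow(verdicts))) {
    if (!isTRUE(verdicts$emergent[i])) next
    ch <- verdicts$channel[i]
    prs <- roi_contrasts(verdicts$roi[i])
    bfs <- numeric(2)
    for (k in 1:2) {
      a <- betas$beta[betas$channel == ch & betas$condition == prs[[k]][1] &
                        betas$chromophore == chromophore]
      b <- betas$beta[betas$channel == ch & betas$condition == prs[[k]][2] &
                        betas$chromophore == chromophore]
      bfs[k] <- bf_two_sample(a, b, direction)$bf10
    }
    verdicts$contrast1[i] <- paste(prs[[1]], collapse = ">")
    verdicts$contrast2[i] <- paste(prs[[2]], collapse = ">")
    verdicts$bf_contrast1[i] <- bfs[1]
    verdicts$bf_contrast2[i] <- bfs[2]
    verdicts$contrast_flag[i] <- any(bfs > threshold)
  }
  verdicts
}

#' Evaluate one pipeline with both metrics and chromophores
#'
#' @param betas A `beta_table`.
#' @param montage The montage.
#' @param threshold Evidence threshold on `BF10`.
#' @return A `channel_verdicts` data frame covering both chromophores.
#' @export
evaluate_pipeline <- function(betas, montage, threshold = 3) {
  out <- do.call(rbind, lapply(c("hbo", "hbr"), function(chrom) {
    v <- metric1_emergence(betas, montage, chrom, threshold)
    metric2_contrasts(betas, v, chrom, threshold)
  }))
  attr(out, "pipeline_id") <- attr(betas, "pipeline_id")
  class(out) <- c("channel_verdicts", "data.frame")
  out
}

#' Summarize verdicts across pipelines
#'
#' Counts, per pipeline, ROI, chromophore and metric, the number of
#' channels flagged: metric 1 counts emergent channels; metric 2 counts
#' channels (among the emergent ones) with at least one expected-direction
#' contrast, so metric-2 counts can never exceed metric-1 counts.
#'
#' @param verdict_list List of `channel_verdicts` (one per pipeline), each
#'   carrying its `pipeline_id` attribute.
#' @return An `evaluation_summary` data frame: `pipeline_id`, `roi`,
#'   `chromophore`, `metric1`, `metric2`.
#' @export
summarize_evaluation <- function(verdict_list) {
  rows <- lapply(verdict_list, function(v) {
    pid <- attr(v, "pipeline_id")
    agg <- expand.grid(roi = c("left_temporal", "occipital", "right_temporal"),
                       chromophore = c("hbo", "hbr"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    agg$pipeline_id <- pid
    agg$metric1 <- NA_integer_
    agg$metric2 <- NA_integer_
    for (i in seq_len(nrow(agg))) {
      sel <- v$roi == agg$roi[i] & v$chromophore == agg$chromophore[i]
      agg$metric1[i] <- sum(v$emergent[sel], na.rm = TRUE)
      agg$metric2[i] <- sum(v$contrast_flag[sel], na.rm = TRUE)
    }
    agg[, c("pipeline_id", "roi", "chromophore", "metric1", "metric2")]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("evaluation_summary", "data.frame")
  out
}

#' Total metric counts per pipeline and chromophore
#'
#' @param summary An `evaluation_summary`.
#' @return Data frame with `pipeline_id`, `chromophore`, `metric1`,
#'   `metric2` summed over ROIs.
#' @export
total_counts <- function(summary) {
  agg <- stats::aggregate(cbind(metric1, metric2) ~ pipeline_id + chromophore,
                          data = summary, FUN = sum)
  agg[order(agg$chromophore, agg$pipeline_id), ]
}
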