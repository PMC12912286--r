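# The ten short-channel regression strategies.

#' Pipeline configuration
#'
#' A pipeline is identified by its short-channel scope (`none`: no SC
#' regression; `limited`: three SCs, one per lobe; `full`: all eight SCs)
#' and the nuisance construction method. Under the limited scope the pooled
#' approach is PCA-only; under the full scope raw pooling and PCA pooling
#' are both available.
#'
#' @param scope `"none"`, `"limited"` or `"full"`.
#' @param method `"nearest"`, `"correlated"`, `"mean"`, `"pooled_raw"` or
#'   `"pooled_pca"` (ignored for scope `"none"`).
#' @return A `pipeline_config` with fields `id` (1--10), `scope`, `method`,
#'   `label`.
#' @export
pipeline_config <- function(scope = c("none", "limited", "full"),
                            method = c("nearest", "correlated", "mean",
                                       "pooled_raw", "pooled_pca")) {
  scope <- match.arg(scope)
  reg <- pipeline_registry()
  if (scope == "none") {
    row <- reg[reg$scope == "none", , drop = FALSE]
  } else {
    method <- match.arg(method)
    row <- reg[reg$scope == scope & reg$method == method, , drop = FALSE]
    if (nrow(row) == 0)
      stop("no pipeline with scope '", scope, "' and method '", method,
           "' (raw pooling is only defined under full SC availability)")
  }
  structure(list(id = row$id, scope = row$scope, method = row$method,
                 label = row$label),
            class = "pipeline_config")
}

#' Registry of the ten pipelines
#'
#' @return Data frame with columns `id`, `scope`, `method`, `label`,
#'   `n_nuisance` (nuisance regressor count per fit).
#' @export
pipeline_registry <- function() {
  data.frame(
    id = 1:10,
    scope = c("none", rep("limited", 4), rep("full", 5)),
    method = c("none", "nearest", "correlated", "mean", "pooled_pca",
               "nearest", "correlated", "mean", "pooled_raw", "pooled_pca"),
    label = c("no SC", "3 SC nearest", "3 SC correlated", "3 SC mean",
              "3 SC pooled PCA", "all SC nearest", "all SC correlated",
              "all SC mean", "all SC pooled raw", "all SC pooled PCA"),
    n_nuisance = c(0, 1, 1, 2, 6, 1, 1, 2, 16, 16),
    stringsAsFactors = FALSE
  )
}

#' Pipeline configuration by id
#'
#' @param id Integer 1--10.
#' @return A `pipeline_config`.
#' @export
pipeline_by_id <- function(id) {
  reg <- pipeline_registry()
  row <- reg[reg$id == id, , drop = FALSE]
  if (nrow(row) != 1) stop("pipeline id must be in 1..10")
  structure(list(id = row$id, scope = row$scope, method = row$method,
                 label = row$label),
            class = "pipeline_config")
}

# Short-channel ids available under a scope.
scope_sc_ids <- function(scope, montage) {
  switch(scope,
         none = integer(0),
         limited = sort(unname(montage$limited_subset)),
         full = montage$short_channels$id,
         stop("unknown scope"))
}

# Matrix [time x (n_sc * 2)] of preprocessed SC traces, HbO block then HbR
# block, with labeled columns.
sc_matrix <- function(hemo, sc_ids) {
  cols_hbo <- hemo$values[, paste0("sc", sc_ids), "hbo", drop = FALSE]
  cols_hbr <- hemo$values[, paste0("sc", sc_ids), "hbr", drop = FALSE]
  m <- cbind(cols_hbo[, , 1, drop = TRUE], cols_hbr[, , 1, drop = TRUE])
  if (is.null(dim(m))) m <- matrix(m, ncol = 2)
  colnames(m) <- c(paste0("sc", sc_ids, "-hbo"), paste0("sc", sc_ids, "-hbr"))
  m
}

#' Principal components of the pooled short-channel matrix
#'
#' Concatenates all available SC traces of both chromophores into one
#' `[time x (2 n_sc)]` matrix, centers each column, and returns all
#' principal-component score time courses (singular value decomposition, no
#' variance scaling). Components whose singular value falls below
#' `1e-10 * max` are dropped with a warning (rank guard); otherwise all are
#' retained, i.e. 6 components under the limited scope and 16 under the
#' full scope.
#'
#' @param hemo A `hemo_series` containing the short channels.
#' @param sc_ids Integer SC ids to pool.
#' @return Matrix of component scores with columns `PC-1`, `PC-2`, ...
#' @export
sc_pca <- function(hemo, sc_ids) {
  m <- sc_matrix(hemo, sc_ids)
  mc <- scale(m, center = TRUE, scale = FALSE)
  sv <- svd(mc)
  keep <- sv$d >= 1e-10 * sv$d[1]
  if (!all(keep))
    warning(sum(!keep), " near-null principal components dropped (rank guard)")
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
  colnames(scores) <- paste0("PC-", seq_len(ncol(scores)))
  scores
}

#' Build the nuisance regressor set for one fit
#'
#' Implements the configured short-channel strategy for a given target long
#' channel and chromophore:
#' \describe{
#'   \item{none}{no regressors.}
#'   \item{nearest}{the single same-chromophore trace of the SC assigned by
#'     [nearest_sc()] (attached to the channel's source under the full
#'     scope; the lobe's SC under the limited scope).}
#'   \item{correlated}{the single same-chromophore SC trace with the highest
#'     Pearson correlation with the target channel's trace over the whole
#'     recording (ties broken by lowest SC id).}
#'   \item{mean}{two regressors: SC traces averaged separately for HbO and
#'     HbR.}
#'   \item{pooled_raw}{all SC traces of both chromophores.}
#'   \item{pooled_pca}{all principal components of the pooled, centered SC
#'     matrix (see [sc_pca()]); a precomputed score matrix can be supplied
#'     to reuse the per-subject decomposition.}
#' }
#'
#' @param config A `pipeline_config`.
#' @param hemo The subject's preprocessed `hemo_series` (long and short
#'   channels).
#' @param target_channel Channel id of the long channel being fit.
#' @param target_chromophore `"hbo"` or `"hbr"`.
#' @param montage The montage.
#' @param pca Optional precomputed [sc_pca()] score matrix.
#' @return A `nuisance_set`: list with `X` (matrix, possibly 0 columns) and
#'   `labels`.
#' @export
build_nuisance <- function(config, hemo, target_channel, target_chromophore,
                           montage, pca = NULL) {
  scope <- config$scope
  method <- config$method
  if (scope == "none" || method == "none") {
    return(structure(list(X = matrix(numeric(0), dim(hemo$values)[1], 0),
                          labels = character(0)),
                     class = "nuisance_set"))
  }
  sc_ids <- scope_sc_ids(scope, montage)
  missing_sc <- setdiff(paste0("sc", sc_ids), hemo$series)
  if (length(missing_sc))
    stop("hemo series lacks short channels required by scope '", scope,
         "': ", paste(missing_sc, collapse = ", "))
  if (method == "nearest") {
    sc <- nearest_sc(target_channel, scope = if (scope == "full") "full" else "limited",
                     montage = montage)
    x <- hemo$values[, paste0("sc", sc$id), target_chromophore]
    return(structure(list(X = matrix(x, ncol = 1),
                          labels = paste0("sc", sc$id, "-", target_chromophore)),
                     class = "nuisance_set"))
  }
  if (method == "correlated") {
    y <- hemo$values[, paste0("ch", target_channel), target_chromophore]
    cand <- hemo$values[, paste0("sc", sc_ids), target_chromophore, drop = FALSE]
    cors <- apply(cand[, , 1, drop = FALSE], 2, function(s) stats::cor(y, s))
    best <- sc_ids[which.max(cors)]   # which.max takes the first (lowest id) tie
    x <- hemo$values[, paste0("sc", best), target_chromophore]
    return(structure(list(X = matrix(x, ncol = 1),
                          labels = paste0("sc", best, "-", target_chromophore)),
                     class = "nuisance_set"))
  }
  if (method == "mean") {
    m <- sc_matrix(hemo, sc_ids)
    n_sc <- length(sc_ids)
    X <- cbind(rowMeans(m[, seq_len(n_sc), drop = FALSE]),
               rowMeans(m[, n_sc + seq_len(n_sc), drop = FALSE]))
    colnames(X) <- c("mean-HbO", "mean-HbR")
    return(structure(list(X = X, labels = colnames(X)),
                     class = "nuisance_set"))
  }
  if (method == "pooled_raw") {
    m <- sc_matrix(hemo, sc_ids)
    return(structure(list(X = m, labels = colnames(m)),
                     class = "nuisance_set"))
  }
  if (method == "pooled_pca") {
    if (is.null(pca)) pca <- sc_pca(hemo, sc_ids)
    return(structure(list(X = pca, labels = colnames(pca)),
                     class = "nuisance_set"))
  }
  stop("unknown method ", method)
}
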