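# Preprocessing chain: intensity -> optical density -> motion repair ->
# band-pass -> hemoglobin concentration changes.

#' Modified Beer-Lambert law constants
#'
#' Molar extinction coefficients at the two measurement wavelengths
#' (Gratzer-compiled values, as shipped by the standard fNIRS toolboxes), in
#' cm^-1 per mole/liter, together with the fixed partial pathlength factor.
#' Concentrations are expressed in micromolar and source--detector distances
#' in cm, so the 2x2 system per time point is
#' `dOD_lambda = sum_c eps(lambda, c) * 1e-6 * dC_c * d * ppf`.
#'
#' @param ppf Dimensionless pathlength factor applied identically at both
#'   wavelengths (toolbox default 0.1).
#' @param extinction 2x2 matrix, rows = wavelengths (760, 850 nm), columns =
#'   chromophores (HbO, HbR).
#' @return An object of class `mbll_constants`.
#' @export
mbll_constants <- function(ppf = 0.1,
                           extinction = rbind(`760` = c(hbo = 586.0,  hbr = 1548.52),
                                              `850` = c(hbo = 1058.0, hbr = 691.32))) {
  stopifnot(ppf > 0, is.matrix(extinction), all(dim(extinction) == c(2, 2)))
  if (abs(det(extinction)) < 1e-8 * max(abs(extinction))^2)
    stop("extinction matrix is singular; the two chromophores cannot be separated")
  structure(list(ppf = ppf, extinction = extinction), class = "mbll_constants")
}

#' Convert raw intensities to optical density changes
#'
#' `dOD(t) = -ln(I(t) / mean_t I)`, per channel and wavelength, so that the
#' temporal mean of each intensity series is the reference.
#'
#' @param raw A `raw_session` (see [simulate_session()]) or a plain numeric
#'   array `[time, series, wavelength]` of positive intensities.
#' @return An `od_series`: list with `values` (same shape), `fs`, `series`.
#' @export
intensity_to_od <- function(raw) {
  if (inherits(raw, "raw_session")) {
    intensity <- raw$intensity; fs <- raw$fs
  } else {
    intensity <- raw; fs <- attr(raw, "fs") %||% stop("fs attribute required")
  }
  if (any(!is.finite(intensity)) || any(intensity <= 0))
    stop("non-positive or non-finite intensity: corrupt input")
  od <- intensity
  for (j in seq_len(dim(intensity)[2])) {
    for (w in seq_len(dim(intensity)[3])) {
      x <- intensity[, j, w]
      od[, j, w] <- -log(x / mean(x))
    }
  }
  structure(list(values = od, fs = fs,
                 series = dimnames(intensity)[[2]],
                 wavelengths = dimnames(intensity)[[3]]),
            class = "od_series")
}

#' Temporal derivative distribution repair
#'
#' Motion-artifact correction driven by the distribution of the temporal
#' derivative. The signal is split at 0.5 Hz; on the low-frequency part the
#' derivative's location and scale are estimated by iteratively reweighted
#' robust estimation (Tukey biweight, tuning constant 4.685, scale
#' `1.4826 * median absolute deviation`). Derivative samples rejected by the
#' biweight (deviation beyond the tuning constant times the robust scale,
#' i.e. weight zero) are deemed statistically improbable rates of change and
#' are replaced by the robust mean; all other samples pass unchanged, so
#' artifact-free signals are returned identically. The repaired derivative
#' is integrated and recombined with the untouched high-frequency part.
#'
#' Sharp spikes faster than the 0.5 Hz split survive partially in the
#' high-frequency remainder by construction; the subsequent band-pass
#' ([bandpass()]) eliminates that remainder.
#'
#' @param od An `od_series`, or a numeric vector.
#' @param fs Sampling rate (taken from `od` when it is an `od_series`).
#' @return Same type as the input.
#' @export
tddr <- function(od, fs = NULL) {
  if (inherits(od, "od_series")) {
    out <- od
    out$values <- apply_series(od$values, function(x) tddr_vec(x, od$fs))
    return(out)
  }
  stopifnot(!is.null(fs))
  tddr_vec(od, fs)
}

tddr_vec <- function(x, fs) {
  if (any(!is.finite(x))) stop("non-finite input to tddr")
  n <- length(x)
  if (n < 10L) stop("series too short for tddr (need >= 10 samples)")
  m <- mean(x)
  x0 <- x - m
  fc <- 0.5 * 2 / fs
  if (fc < 1) {
    flt <- signal::butter(3, fc)
    xl <- pad_filtfilt(flt, x0)
    xh <- x0 - xl
  } else {
    xl <- x0
    xh <- numeric(n)
  }
  d <- diff(xl)
  w <- rep(1, n - 1L)
  tune <- 4.685
  mu <- Inf
  for (iter in seq_len(50L)) {
    mu0 <- mu
    mu <- sum(w * d) / sum(w)
    dev <- abs(d - mu)
    sigma <- 1.4826 * stats::median(dev)
    if (!is.finite(sigma) || sigma == 0) { w <- rep(1, n - 1L); mu <- 0; break }
    r <- dev / (sigma * tune)
    w <- ((1 - r^2) * (r < 1))^2
    if (is.finite(mu0) &&
        abs(mu - mu0) <= sqrt(.Machine$double.eps) * max(abs(mu), abs(mu0)))
      break
  }
  # repair only rejected samples; leave plausible rates of change untouched
  d_new <- ifelse(w > 0, d, mu)
  xl_new <- cumsum(c(0, d_new))
  xl_new <- xl_new - mean(xl_new) + mean(xl)
  xl_new + xh + m
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth low-pass (upper edge) and high-pass (lower
#' edge) in cascade, each applied forward and backward (zero phase,
#' effective eighth order) with reflective edge padding. The extreme
#' relative bandwidth at fNIRS sampling rates makes a directly designed
#' band-pass transfer function numerically unstable, so the cascade
#' realization is used.
#'
#' @param od An `od_series` or numeric vector.
#' @param fs Sampling rate in Hz (from the object when omitted).
#' @param low,high Band edges in Hz.
#' @return Same type as the input.
#' @export
bandpass <- function(od, fs = NULL, low = 0.01, high = 0.12) {
  if (inherits(od, "od_series") || inherits(od, "hemo_series")) {
    out <- od
    out$values <- apply_series(od$values,
                               function(x) bandpass_vec(x, od$fs, low, high))
    return(out)
  }
  stopifnot(!is.null(fs))
  bandpass_vec(od, fs, low, high)
}

bandpass_vec <- function(x, fs, low = 0.01, high = 0.12) {
  ny <- fs / 2
  if (!(low > 0 && low < high && high < ny))
    stop("band edges must satisfy 0 < low < high < fs/2")
  lp <- signal::butter(4, high / ny, type = "low")
  hp <- signal::butter(4, low / ny, type = "high")
  n_pad <- min(length(x) - 1L, as.integer(round(30 * fs)))
  # removing the mean first keeps the extreme-low-cutoff high-pass free of
  # numerical DC leakage
  y <- pad_filtfilt(lp, x - mean(x), n_pad)
  pad_filtfilt(hp, y, n_pad)
}

#' Optical density to hemoglobin concentration changes
#'
#' Solves, per channel and time point, the 2x2 modified Beer-Lambert system
#' linking the optical density changes at the two wavelengths to the HbO and
#' HbR concentration changes, scaled by the source--detector distance (cm)
#' and the fixed pathlength factor.
#'
#' @param od An `od_series` whose `series` follow the montage naming.
#' @param constants An [mbll_constants()].
#' @param montage The `fnirs_montage` supplying per-channel distances.
#' @return A `hemo_series`: `values[time, series, chromophore]` in uM.
#' @export
od_to_conc <- function(od, constants = mbll_constants(),
                       montage = build_standard_montage()) {
  E <- constants$extinction * 1e-6  # uM^-1 cm^-1
  dists <- series_distances_cm(montage)
  sn <- od$series
  vals <- od$values
  n_t <- dim(vals)[1]
  out <- array(NA_real_, dim = c(n_t, length(sn), 2),
               dimnames = list(NULL, sn, c("hbo", "hbr")))
  for (j in seq_along(sn)) {
    d <- dists[[sn[j]]]
    if (is.null(d)) stop("unknown series ", sn[j], " in montage")
    A <- E * d * constants$ppf
    sol <- solve(A, t(vals[, j, ]))   # 2 x n_t
    out[, j, 1] <- sol[1, ]
    out[, j, 2] <- sol[2, ]
  }
  structure(list(values = out, fs = od$fs, series = sn,
                 chromophores = c("hbo", "hbr")),
            class = "hemo_series")
}

# Per-series source-detector distance in cm, named by series.
series_distances_cm <- function(montage) {
  d <- c(montage$channels$distance_mm / 10,
         montage$short_channels$distance_mm / 10)
  names(d) <- series_names(montage)
  as.list(d)
}

#' Full preprocessing chain
#'
#' Applies, in this fixed order: intensity to optical density, temporal
#' derivative distribution repair, 0.01--0.12 Hz zero-phase band-pass, and
#' the modified Beer-Lambert conversion, to long and short channels alike.
#' The stage order is part of the analysis contract; requesting any other
#' order is a configuration error.
#'
#' @param raw A `raw_session`.
#' @param constants An [mbll_constants()].
#' @param low,high Band edges in Hz.
#' @param stages Stage order; must equal the canonical
#'   `c("od", "tddr", "bandpass", "mbll")`.
#' @return A `hemo_series`.
#' @export
preprocess_session <- function(raw, constants = mbll_constants(),
                               low = 0.01, high = 0.12,
                               stages = c("od", "tddr", "bandpass", "mbll")) {
  if (!identical(stages, c("od", "tddr", "bandpass", "mbll")))
    stop("unsupported stage order; the chain is fixed to ",
         "od -> tddr -> bandpass -> mbll")
  od <- intensity_to_od(raw)
  od <- tddr(od)
  od <- bandpass(od, low = low, high = high)
  od_to_conc(od, constants, raw$montage)
}

# Apply a vector function over the series/wavelength slices of a 3-d array.
apply_series <- function(values, f) {
  out <- values
  for (j in seq_len(dim(values)[2])) {
    for (w in seq_len(dim(values)[3])) {
      out[, j, w] <- f(values[, j, w])
    }
  }
  out
}

#' @export
print.hemo_series <- function(x, ...) {
  cat("hemo_series: ", dim(x$values)[1], " samples x ", dim(x$values)[2],
      " series x 2 chromophores @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' @export
print.od_series <- function(x, ...) {
  cat("od_series: ", dim(x$values)[1], " samples x ", dim(x$values)[2],
      " series x 2 wavelengths @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
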