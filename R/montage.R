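# Probe geometry: 8 sources, 8 detectors, 16 long channels (15 analyzed),
# 8 short 8-mm channels (one per source).

#' Build the standard audiovisual montage
#'
#' Constructs the fixed probe layout used throughout the package: 16 long
#' (25--40 mm) source--detector channels over the occipital and bilateral
#' temporal cortices, of which 15 are analyzed (channel 16 has no
#' left-hemisphere counterpart and is excluded from statistics), plus eight
#' short-separation channels (SCs), one attached to each source at 8 mm.
#'
#' Channels 1--4 cover the left temporal area, 5--11 the occipital area and
#' 12--15 the right temporal area. The montage also carries the
#' `limited_subset`: the three SCs (at sources C5, POz and CP6) retained when
#' simulating reduced short-channel availability, one per lobe.
#'
#' The 10--20 source/detector labels are a nominal reconstruction: only ROI
#' membership, the source attached to each channel, and the three
#' limited-subset sources enter any computation; scalp coordinates are
#' metadata for plotting and export.
#'
#' @return An object of class `fnirs_montage`: a list with elements
#'   `channels` (data frame: `id`, `source_label`, `detector_label`, `roi`,
#'   `distance_mm`), `short_channels` (data frame: `id`, `source_label`,
#'   `distance_mm`) and `limited_subset` (named integer vector of SC ids,
#'   one per ROI).
#' @examples
#' m <- build_standard_montage()
#' nrow(roi_channels(m, "occipital"))
#' @export
build_standard_montage <- function() {
  channels <- data.frame(
    id = 1:16,
    source_label = c("C5", "C5", "T7", "T7",
                     "O1", "O1", "POz", "Oz", "POz", "O2", "O2",
                     "CP6", "T8", "T8", "CP6", "CP6"),
    detector_label = c("CP5", "TP7", "TP7", "CP5",
                       "PO3", "Iz", "PO3", "Iz", "PO4", "Iz", "PO4",
                       "P8", "TP8", "FT8", "TP8", "FT8"),
    roi = c(rep("left_temporal", 4), rep("occipital", 7),
            rep("right_temporal", 4), "excluded"),
    distance_mm = c(30, 35, 30, 40,
                    30, 33, 31, 28, 31, 33, 30,
                    35, 30, 30, 32, 38),
    stringsAsFactors = FALSE
  )
  short_channels <- data.frame(
    id = 1:8,
    source_label = c("C5", "T7", "O1", "POz", "Oz", "O2", "CP6", "T8"),
    distance_mm = rep(8, 8),
    stringsAsFactors = FALSE
  )
  limited_subset <- c(left_temporal = 1L, occipital = 4L, right_temporal = 7L)
  m <- list(channels = channels, short_channels = short_channels,
            limited_subset = limited_subset)
  class(m) <- "fnirs_montage"
  validate_montage(m)
  m
}

validate_montage <- function(m) {
  ch <- m$channels
  stopifnot(!anyDuplicated(ch$id),
            all(ch$roi %in% c("left_temporal", "occipital", "right_temporal",
                              "excluded")),
            sum(ch$roi == "excluded") == 1,
            ch$id[ch$roi == "excluded"] == 16,
            all(ch$distance_mm[ch$roi != "excluded"] >= 25),
            all(ch$distance_mm[ch$roi != "excluded"] <= 40),
            sum(ch$roi != "excluded") == 15,
            sum(ch$roi == "occipital") == 7)
  sc <- m$short_channels
  stopifnot(nrow(sc) == 8, all(sc$distance_mm == 8),
            !anyDuplicated(sc$source_label))
  # every long-channel source must carry an SC
  stopifnot(all(ch$source_label %in% sc$source_label))
  stopifnot(length(m$limited_subset) == 3,
            all(m$limited_subset %in% sc$id))
  invisible(m)
}

#' @export
print.fnirs_montage <- function(x, ...) {
  n_roi <- table(x$channels$roi)
  cat("fNIRS montage: ", nrow(x$channels), " long channels (",
      sum(x$channels$roi != "excluded"), " analyzed), ",
      nrow(x$short_channels), " short channels\n", sep = "")
  cat("  ROIs:", paste(names(n_roi), n_roi, sep = "=", collapse = ", "), "\n")
  cat("  limited SC subset:",
      paste(names(x$limited_subset),
            x$short_channels$source_label[x$limited_subset],
            sep = "->", collapse = ", "), "\n")
  invisible(x)
}

#' Channels belonging to a region of interest
#'
#' @param montage An `fnirs_montage`.
#' @param roi One of `"left_temporal"`, `"occipital"`, `"right_temporal"`,
#'   `"excluded"`.
#' @return The rows of `montage$channels` with the requested ROI, sorted by
#'   channel id.
#' @export
roi_channels <- function(montage, roi) {
  roi <- match.arg(roi, c("left_temporal", "occipital", "right_temporal",
                          "excluded"))
  out <- montage$channels[montage$channels$roi == roi, , drop = FALSE]
  out[order(out$id), , drop = FALSE]
}

#' Short channel assigned to a long channel
#'
#' Under `scope = "full"` every long channel is paired with the SC physically
#' attached to its own source. Under `scope = "limited"` only three SCs are
#' available (one per lobe) and the channel is paired with the SC selected
#' for its ROI (C5 for the left temporal lobe, POz for the occipital lobe,
#' CP6 for the right temporal lobe).
#'
#' @param channel A single row of `montage$channels`, or a channel id.
#' @param scope `"full"` or `"limited"`.
#' @param montage An `fnirs_montage`.
#' @return The matching row of `montage$short_channels`.
#' @export
nearest_sc <- function(channel, scope = c("full", "limited"), montage) {
  scope <- match.arg(scope)
  if (is.numeric(channel)) {
    channel <- montage$channels[montage$channels$id == channel, , drop = FALSE]
    if (nrow(channel) != 1L) stop("unknown channel id")
  }
  if (channel$roi == "excluded") {
    stop("channel ", channel$id,
         " is excluded from analysis and has no assigned short channel")
  }
  sc <- montage$short_channels
  if (scope == "full") {
    out <- sc[sc$source_label == channel$source_label, , drop = FALSE]
  } else {
    out <- sc[sc$id == montage$limited_subset[[channel$roi]], , drop = FALSE]
  }
  stopifnot(nrow(out) == 1L)
  out
}

# Analyzed (non-excluded) channels, sorted by id
analyzed_channels <- function(montage) {
  ch <- montage$channels[montage$channels$roi != "excluded", , drop = FALSE]
  ch[order(ch$id), , drop = FALSE]
}

# Series naming shared by the simulator and preprocessing:
# long channels "ch<i>", short channels "sc<j>"
series_names <- function(montage) {
  c(paste0("ch", montage$channels$id),
    paste0("sc", montage$short_channels$id))
}
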