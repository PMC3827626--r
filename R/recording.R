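#' @keywords internal
"_PACKAGE"

# ---- Marker table ---------------------------------------------------------

MARKER_KINDS <- c("volume_sync", "slice_sync", "stimulus", "response", "r_peak")
MODALITIES <- c("auditory", "visual", "audiovisual", "none")
EMOTIONS <- c("angry", "happy", "neutral", "none")
CONGRUENCE <- c("CON", "INC", "n/a")

#' Construct a marker table
#'
#' Markers are stored as a plain `data.frame` with one row per event. All
#' onsets are 0-based sample indices into the recording they belong to, so
#' that they survive resampling by pure rescaling.
#'
#' @param onset_sample integer vector of 0-based sample offsets.
#' @param kind event kind, one of `"volume_sync"`, `"slice_sync"`,
#'   `"stimulus"`, `"response"`, `"r_peak"`.
#' @param modality stimulus modality (`"auditory"`, `"visual"`,
#'   `"audiovisual"`, `"none"`).
#' @param visual_emotion,auditory_emotion emotion of each stream
#'   (`"angry"`, `"happy"`, `"neutral"`, `"none"`).
#' @param congruence `"CON"`, `"INC"` or `"n/a"`. Audiovisual events are
#'   congruent iff the two emotions are equal.
#' @param response_code integer button code or `NA`.
#' @param uncertainty_ms non-negative presentation timing uncertainty.
#' @param excluded logical flag set by upstream QC (never silently dropped).
#' @param trial_id integer trial index or `NA` for non-trial events.
#' @return a `data.frame` of class `c("marker_table", "data.frame")`.
#' @export
new_markers <- function(onset_sample = integer(),
                        kind = character(),
                        modality = "none",
                        visual_emotion = "none",
                        auditory_emotion = "none",
                        congruence = "n/a",
                        response_code = NA_integer_,
                        uncertainty_ms = 0,
                        excluded = FALSE,
                        trial_id = NA_integer_) {
  n <- length(onset_sample)
  df <- data.frame(
    onset_sample = as.numeric(onset_sample),
    kind = rep_len(as.character(kind), n),
    modality = rep_len(as.character(modality), n),
    visual_emotion = rep_len(as.character(visual_emotion), n),
    auditory_emotion = rep_len(as.character(auditory_emotion), n),
    congruence = rep_len(as.character(congruence), n),
    response_code = rep_len(as.integer(response_code), n),
    uncertainty_ms = rep_len(as.numeric(uncertainty_ms), n),
    excluded = rep_len(as.logical(excluded), n),
    trial_id = rep_len(as.integer(trial_id), n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    stopifnot(all(df$kind %in% MARKER_KINDS),
              all(df$modality %in% MODALITIES),
              all(df$congruence %in% CONGRUENCE),
              all(df$uncertainty_ms >= 0))
    bad <- df$modality == "audiovisual" &
      df$congruence == "CON" &
      df$visual_emotion != df$auditory_emotion
    if (any(bad)) stop("CON markers must have equal visual and auditory emotions")
  }
  class(df) <- c("marker_table", "data.frame")
  df
}

# ---- Recording ------------------------------------------------------------

#' Construct a continuous multichannel EEG recording
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param channel_labels character vector, one label per row of `data`.
#' @param sampling_rate_hz positive sampling rate.
#' @param markers a marker table (see [new_markers()]).
#' @param reference reference label, or `"average"`.
#' @return object of class `recording`.
#' @export
new_recording <- function(data, channel_labels, sampling_rate_hz,
                          markers = new_markers(), reference = "none") {
  data <- as.matrix(data)
  if (nrow(data) != length(channel_labels))
    stop("data has ", nrow(data), " rows but ", length(channel_labels),
         " channel labels were given")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be > 0")
  if (nrow(markers) > 0 &&
      (any(markers$onset_sample < 0) ||
       any(markers$onset_sample >= ncol(data))))
    stop("marker onsets must lie within [0, n_samples)")
  structure(
    list(data = data,
         channel_labels = as.character(channel_labels),
         sampling_rate_hz = sampling_rate_hz,
         markers = markers,
         reference = reference),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), %d markers, ref=%s\n",
              nrow(x$data), ncol(x$data), x$sampling_rate_hz,
              ncol(x$data) / x$sampling_rate_hz, nrow(x$markers),
              x$reference))
  invisible(x)
}

#' Number of samples / duration helpers
#' @param rec a `recording`
#' @return integer sample count / duration in seconds
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
duration_s <- function(rec) ncol(rec$data) / rec$sampling_rate_hz

#' Select channels by label
#' @param rec a `recording`
#' @param labels channel labels to keep (order preserved as given)
#' @return a `recording` with the subset
#' @export
pick_channels <- function(rec, labels) {
  idx <- match(labels, rec$channel_labels)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(labels[is.na(idx)], collapse = ", "))
  rec$data <- rec$data[idx, , drop = FALSE]
  rec$channel_labels <- rec$channel_labels[idx]
  rec
}

# ---- Electrode set --------------------------------------------------------

#' Construct an electrode set
#'
#' @param labels channel labels.
#' @param positions_mm numeric matrix n x 3 (x right, y anterior, z superior).
#' @param fiducials named list with `nasion`, `lpa`, `rpa` 3-vectors (mm).
#' @param frame coordinate frame: `"digitizer"`, `"head"` or `"sphere"`.
#' @return object of class `electrode_set`.
#' @export
new_electrode_set <- function(labels, positions_mm, fiducials, frame = "digitizer") {
  positions_mm <- as.matrix(positions_mm)
  if (nrow(positions_mm) != length(labels))
    stop("one position per label required")
  if (ncol(positions_mm) != 3) stop("positions must be n x 3")
  stopifnot(frame %in% c("digitizer", "head", "sphere"))
  f <- rbind(fiducials$nasion, fiducials$lpa, fiducials$rpa)
  if (nrow(f) != 3) stop("fiducials must contain nasion, lpa, rpa")
  # collinearity check: area of fiducial triangle
  a <- f[2, ] - f[1, ]; b <- f[3, ] - f[1, ]
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  if (sqrt(sum(cr^2)) < 1e-6)
    stop("fiducials are collinear; cannot define a head frame")
  rownames(positions_mm) <- labels
  structure(list(labels = as.character(labels), positions_mm = positions_mm,
                 fiducials = fiducials, frame = frame),
            class = "electrode_set")
}

#' @export
print.electrode_set <- function(x, ...) {
  cat(sprintf("<electrode_set> %d electrodes, frame=%s\n",
              length(x$labels), x$frame))
  invisible(x)
}

# ---- 4D BOLD volume series ------------------------------------------------

#' Construct a 4D BOLD volume series
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param tr_s repetition time in seconds.
#' @param affine 4x4 voxel-to-world transform (mm).
#' @param n_discarded_leading volumes already discarded from the front.
#' @return object of class `volume_series`.
#' @export
new_volume_series <- function(data, tr_s, affine = NULL, n_discarded_leading = 0L) {
  if (length(dim(data)) != 4)
    stop("volume series requires 4D data (x,y,z,t); got ",
         length(dim(data)), "D")
  if (tr_s <= 0) stop("tr_s must be > 0")
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, tr_s = tr_s, affine = affine,
                 n_discarded_leading = as.integer(n_discarded_leading)),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %dx%dx%d voxels x %d volumes, TR=%g s\n",
              d[1], d[2], d[3], d[4], x$tr_s))
  invisible(x)
}

# ---- Trial records --------------------------------------------------------

#' Build trial records from stimulus markers
#'
#' One row per stimulus marker carrying condition, response and inclusion
#' bookkeeping used by behavioral scoring and the GLM confound set.
#'
#' @param markers a marker table; only `kind == "stimulus"` rows are used.
#' @return `data.frame` of class `trial_table`.
#' @export
trials_from_markers <- function(markers) {
  st <- markers[markers$kind == "stimulus", , drop = FALSE]
  df <- data.frame(
    trial_id = st$trial_id,
    onset_sample = st$onset_sample,
    modality = st$modality,
    visual_emotion = st$visual_emotion,
    auditory_emotion = st$auditory_emotion,
    congruence = st$congruence,
    uncertainty_ms = st$uncertainty_ms,
    response_code = st$response_code,
    correctness = NA_character_,
    inc_decision = "n/a",
    included = NA,
    stringsAsFactors = FALSE
  )
  class(df) <- c("trial_table", "data.frame")
  df
}
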