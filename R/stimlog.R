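# Stimulus timing log: a documented TSV schema (the acquisition software's
# proprietary layout is not reproduced). Columns:
#   onset_s  modality  visual_emotion  auditory_emotion  congruence
#   response_code  uncertainty_ms  trial_id
# response_code: integer button code, or NA for omitted responses.

#' Parse a stimulus timing log (TSV)
#'
#' Rows with presentation uncertainty above `max_uncertainty_ms` are
#' flagged `excluded = TRUE` but never dropped, so downstream exclusion is
#' explicit and auditable.
#'
#' @param log path to the TSV log.
#' @param sampling_rate_hz rate used to convert onset seconds to samples.
#' @param max_uncertainty_ms exclusion threshold (default 10 ms).
#' @return a marker table of `kind = "stimulus"` rows.
#' @export
parse_stimulus_log <- function(log, sampling_rate_hz,
                               max_uncertainty_ms = 10) {
  lines <- readLines(log, warn = FALSE)
  if (length(lines) < 1) stop("empty log file: ", log)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("onset_s", "modality", "visual_emotion", "auditory_emotion",
            "congruence", "response_code", "uncertainty_ms", "trial_id")
  miss <- setdiff(need, hdr)
  if (length(miss) > 0)
    stop("log is missing column(s): ", paste(miss, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(rows) != length(hdr))
  if (length(bad) > 0)
    stop("malformed log row at line ", bad[1] + 1L, " of ", log,
         " (expected ", length(hdr), " fields, got ",
         lengths(rows)[bad[1]], ")")
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(tab) <- hdr
  num <- function(x) suppressWarnings(as.numeric(x))
  onset <- num(tab$onset_s)
  unc <- num(tab$uncertainty_ms)
  if (anyNA(onset) || anyNA(unc)) {
    bad <- which(is.na(onset) | is.na(unc))[1]
    stop("malformed numeric field at line ", bad + 1L, " of ", log)
  }
  m <- new_markers(
    onset_sample = round(onset * sampling_rate_hz),
    kind = "stimulus",
    modality = tab$modality,
    visual_emotion = tab$visual_emotion,
    auditory_emotion = tab$auditory_emotion,
    congruence = tab$congruence,
    response_code = suppressWarnings(as.integer(tab$response_code)),
    uncertainty_ms = unc,
    trial_id = as.integer(tab$trial_id))
  m$excluded <- m$uncertainty_ms > max_uncertainty_ms
  m
}

#' Write a stimulus timing log (TSV)
#'
#' @param markers a marker table; only stimulus rows are written.
#' @param path destination TSV path.
#' @param sampling_rate_hz rate used to convert onset samples to seconds.
#' @return invisibly, `path`.
#' @export
write_stimulus_log <- function(markers, path, sampling_rate_hz) {
  st <- markers[markers$kind == "stimulus", , drop = FALSE]
  df <- data.frame(
    onset_s = st$onset_sample / sampling_rate_hz,
    modality = st$modality,
    visual_emotion = st$visual_emotion,
    auditory_emotion = st$auditory_emotion,
    congruence = st$congruence,
    response_code = st$response_code,
    uncertainty_ms = st$uncertainty_ms,
    trial_id = st$trial_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
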