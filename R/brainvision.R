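# BrainVision (.vhdr/.vmrk/.eeg) reader and writer.
# Dialect: binary IEEE float32, multiplexed, one marker line per event.
# Vectorized or ASCII variants are rejected with a clear message.

bv_marker_type <- c(volume_sync = "Response", slice_sync = "Response",
                    stimulus = "Stimulus", response = "Response",
                    r_peak = "Comment")

# Serialize marker metadata that BrainVision has no native field for into
# the marker description, so round trips are lossless.
bv_encode_desc <- function(m) {
  sprintf("%s|%s|%s|%s|%s|%s|%s|%s",
          m$kind, m$modality, m$visual_emotion, m$auditory_emotion,
          m$congruence,
          ifelse(is.na(m$response_code), "NA", m$response_code),
          format(m$uncertainty_ms, trim = TRUE),
          ifelse(is.na(m$trial_id), "NA", m$trial_id))
}

bv_decode_desc <- function(desc, onset) {
  parts <- strsplit(desc, "|", fixed = TRUE)
  k <- vapply(parts, `[`, "", 1)
  getf <- function(i, def) vapply(parts, function(p)
    if (length(p) >= i) p[i] else def, "")
  num_or_na <- function(x) suppressWarnings(as.integer(ifelse(x == "NA", NA, x)))
  new_markers(onset_sample = onset, kind = k,
              modality = getf(2, "none"),
              visual_emotion = getf(3, "none"),
              auditory_emotion = getf(4, "none"),
              congruence = getf(5, "n/a"),
              response_code = num_or_na(getf(6, "NA")),
              uncertainty_ms = as.numeric(getf(7, "0")),
              trial_id = num_or_na(getf(8, "NA")))
}

#' Write a recording as a BrainVision file triplet
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` (binary IEEE float32,
#' multiplexed). Channel resolution is fixed at 0.1 microvolt per unit,
#' a typical amplifier resolution.
#'
#' @param rec a `recording`.
#' @param stem output path without extension.
#' @param resolution_uv numeric, microvolts represented by one unit of the
#'   stored float (data are stored as value / resolution).
#' @return invisibly, the three paths written.
#' @export
write_brainvision <- function(rec, stem, resolution_uv = 0.1) {
  paths <- paste0(stem, c(".vhdr", ".vmrk", ".eeg"))
  nchan <- nrow(rec$data)
  base <- basename(stem)
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nchan),
    paste0("SamplingInterval=", format(1e6 / rec$sampling_rate_hz,
                                       scientific = FALSE)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(nchan), rec$channel_labels,
            format(resolution_uv, scientific = FALSE))
  )
  writeLines(hdr, paths[1], useBytes = TRUE)

  m <- rec$markers
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0"
  )
  if (nrow(m) > 0) {
    mk <- c(mk, sprintf("Mk%d=%s,%s,%d,1,0",
                        seq_len(nrow(m)) + 1L,
                        bv_marker_type[m$kind],
                        bv_encode_desc(m),
                        as.integer(m$onset_sample) + 1L))
  }
  writeLines(mk, paths[2], useBytes = TRUE)

  con <- file(paths[3], "wb")
  on.exit(close(con))
  writeBin(as.numeric(rec$data / resolution_uv), con, size = 4,
           endian = "little")
  invisible(paths)
}

bv_parse_ini <- function(lines) {
  sec <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      sec <- gsub("\\[|\\]", "", ln)
      out[[sec]] <- character()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(sec)) {
      out[[sec]] <- c(out[[sec]], ln)
    }
  }
  out
}

bv_kv <- function(section, key) {
  hit <- grep(paste0("^", key, "="), section, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  sub(paste0("^", key, "="), "", hit[1])
}

#' Read a BrainVision file triplet
#'
#' @param header_path path to the `.vhdr` header file.
#' @return a `recording` with markers parsed from the `.vmrk` file and data
#'   converted to microvolts using each channel's resolution.
#' @export
read_brainvision <- function(header_path) {
  if (!file.exists(header_path))
    stop("header file not found: ", header_path)
  dir <- dirname(header_path)
  ini <- bv_parse_ini(readLines(header_path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  fmt <- bv_kv(ci, "DataFormat")
  if (!identical(fmt, "BINARY"))
    stop("unsupported DataFormat '", fmt, "': only BINARY is supported")
  orient <- bv_kv(ci, "DataOrientation")
  if (!identical(orient, "MULTIPLEXED"))
    stop("unsupported DataOrientation '", orient,
         "': only MULTIPLEXED is supported")
  bfmt <- bv_kv(bi, "BinaryFormat")
  if (!identical(bfmt, "IEEE_FLOAT_32"))
    stop("unsupported BinaryFormat '", bfmt,
         "': only IEEE_FLOAT_32 is supported")
  nchan <- as.integer(bv_kv(ci, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(bv_kv(ci, "SamplingInterval"))

  chl <- ini[["Channel Infos"]]
  chparts <- strsplit(sub("^Ch[0-9]+=", "", chl), ",", fixed = TRUE)
  labels <- vapply(chparts, `[`, "", 1)
  res <- vapply(chparts, function(p) {
    r <- suppressWarnings(as.numeric(p[3]))
    if (is.na(r)) 1 else r
  }, 0)
  if (length(labels) != nchan)
    stop("channel-count mismatch: header declares ", nchan,
         " channels but lists ", length(labels))

  eeg_path <- file.path(dir, bv_kv(ci, "DataFile"))
  if (!file.exists(eeg_path))
    stop("data file referenced by header is missing: ", eeg_path)
  sz <- file.info(eeg_path)$size
  nsamp <- sz / (4 * nchan)
  if (nsamp != round(nsamp))
    stop("data file size is not a whole number of ", nchan,
         "-channel float32 frames")
  con <- file(eeg_path, "rb")
  raw <- readBin(con, "numeric", n = sz / 4, size = 4, endian = "little")
  close(con)
  data <- matrix(raw, nrow = nchan) * res

  mrk_path <- file.path(dir, bv_kv(ci, "MarkerFile"))
  markers <- new_markers()
  if (!is.na(mrk_path) && file.exists(mrk_path)) {
    mi <- bv_parse_ini(readLines(mrk_path, warn = FALSE))[["Marker Infos"]]
    if (length(mi) > 0) {
      body <- sub("^Mk[0-9]+=", "", mi)
      fields <- strsplit(body, ",")
      keep <- vapply(fields, function(f) f[1] != "New Segment", TRUE)
      fields <- fields[keep]
      if (length(fields) > 0) {
        desc <- vapply(fields, `[`, "", 2)
        onset <- vapply(fields, function(f) as.numeric(f[3]), 0) - 1
        markers <- bv_decode_desc(desc, onset)
      }
    }
  }
  new_recording(data, labels, fs, markers)
}
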