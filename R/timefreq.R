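# Trial segmentation, Morlet wavelet induced power, topographic alpha
# statistics and short-time FFT band power.

#' Morlet wavelet specification
#'
#' Convention: `c = f0 / sigma_f`, so the spectral s.d. is `sigma_f =
#' f0 / c` (c = 4.2 at 10.5 Hz gives 2.5 Hz) and the temporal s.d. is
#' `sigma_t = 1 / (2 pi sigma_f)`.
#'
#' @param f0_hz center frequency.
#' @param c_ratio ratio of center frequency to spectral s.d.
#' @return a `wavelet_spec` list with derived `sigma_f_hz`, `sigma_t_s`.
#' @export
wavelet_spec <- function(f0_hz, c_ratio = 4.2) {
  if (f0_hz <= 0) stop("f0_hz must be > 0")
  if (c_ratio <= 0) stop("c_ratio must be > 0")
  sigma_f <- f0_hz / c_ratio
  structure(list(f0_hz = f0_hz, c_ratio = c_ratio, sigma_f_hz = sigma_f,
                 sigma_t_s = 1 / (2 * pi * sigma_f)),
            class = "wavelet_spec")
}

# Sampled complex Morlet wavelet, amplitude-normalized so that a unit
# sinusoid at f0 yields plateau power 1.
morlet_wavelet <- function(spec, fs, n_sigma = 5) {
  st <- spec$sigma_t_s
  half <- ceiling(n_sigma * st * fs)
  t <- (-half:half) / fs
  g <- exp(-t^2 / (2 * st^2))
  w <- g * exp(1i * 2 * pi * spec$f0_hz * t)
  w * 2 / sum(g)
}

#' Segment a recording into stimulus-locked trials
#'
#' One segment per surviving stimulus marker; exclusions are logged by
#' reason: `edge` (segment outside the recording), `no_response`,
#' `error` (incorrect response on a non-INC trial; responded INC trials
#' are kept irrespective of correctness), `uncertainty` (presentation
#' uncertainty above 10 ms) and `amplitude` (any sample beyond the
#' threshold inside the segment).
#'
#' @param rec a `recording` (cleaned, 65-channel stage or any other).
#' @param markers stimulus markers (defaults to the recording's).
#' @param window_ms segment window relative to stimulus onset.
#' @param amp_thresh_uv amplitude exclusion threshold (microvolts).
#' @param trials optional scored `trial_table` used for the response and
#'   correctness rules; without it only edge/uncertainty/amplitude rules
#'   apply.
#' @return object of class `segments`: list with `data` (trials x
#'   channels x samples), `times_ms`, `fs`, `trials` (included rows) and
#'   `exclusions` (trial_id, reason).
#' @export
segment_trials <- function(rec, markers = NULL,
                           window_ms = c(-2000, 1000),
                           amp_thresh_uv = 125, trials = NULL) {
  if (is.null(markers)) markers <- rec$markers
  st <- markers[markers$kind == "stimulus", , drop = FALSE]
  fs <- rec$sampling_rate_hz
  i0 <- round(window_ms[1] / 1000 * fs)
  i1 <- round(window_ms[2] / 1000 * fs)
  n <- ncol(rec$data)
  excl <- data.frame(trial_id = integer(), reason = character())
  keep <- logical(nrow(st))
  reason <- character(nrow(st))
  for (i in seq_len(nrow(st))) {
    on <- st$onset_sample[i]
    tr <- if (!is.null(trials))
      trials[match(st$trial_id[i], trials$trial_id), ] else NULL
    if (on + i0 < 0 || on + i1 >= n) {
      reason[i] <- "edge"
    } else if (st$uncertainty_ms[i] > 10 || isTRUE(st$excluded[i])) {
      reason[i] <- "uncertainty"
    } else if (!is.null(tr) && !is.na(tr$correctness) &&
               tr$correctness == "omitted") {
      reason[i] <- "no_response"
    } else if (!is.null(tr) && !is.na(tr$correctness) &&
               tr$correctness == "incorrect" && tr$congruence != "INC") {
      reason[i] <- "error"
    } else {
      seg <- rec$data[, (on + i0 + 1):(on + i1 + 1), drop = FALSE]
      if (any(abs(seg) > amp_thresh_uv)) {
        reason[i] <- "amplitude"
      } else keep[i] <- TRUE
    }
  }
  kept <- which(keep)
  nsamp <- i1 - i0 + 1
  data <- array(NA_real_, c(length(kept), nrow(rec$data), nsamp))
  for (j in seq_along(kept)) {
    on <- st$onset_sample[kept[j]]
    data[j, , ] <- rec$data[, (on + i0 + 1):(on + i1 + 1)]
  }
  excl <- data.frame(trial_id = st$trial_id[!keep],
                     reason = reason[!keep], stringsAsFactors = FALSE)
  structure(list(data = data, channel_labels = rec$channel_labels,
                 times_ms = seq(i0, i1) / fs * 1000, fs = fs,
                 trial_info = st[kept, , drop = FALSE],
                 exclusions = excl),
            class = "segments")
}

#' @export
print.segments <- function(x, ...) {
  cat(sprintf("<segments> %d trials x %d channels x %d samples (%g..%g ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times_ms), max(x$times_ms)))
  if (nrow(x$exclusions) > 0)
    print(table(x$exclusions$reason))
  invisible(x)
}

#' Morlet continuous wavelet transform of segmented trials
#'
#' Per-trial complex convolution and squared magnitude ("induced" power:
#' power is computed per trial before any averaging). Samples within one
#' wavelet half-support of the segment edges are set to `NA` (invalid).
#'
#' @param segments a `segments` object.
#' @param freqs_hz frequencies to analyze.
#' @param c_ratio Morlet ratio f0/sigma_f (default 4.2).
#' @param channels optional channel subset (indices or labels).
#' @return a `tfr` object: `power` array (trials x channels x freqs x
#'   times), `times_ms`, `freqs_hz`, `baseline` (NULL until corrected),
#'   `kind = "induced"`.
#' @export
morlet_tfr <- function(segments, freqs_hz, c_ratio = 4.2, channels = NULL) {
  d <- segments$data
  if (is.character(channels))
    channels <- match(channels, segments$channel_labels)
  if (is.null(channels)) channels <- seq_len(dim(d)[2])
  fs <- segments$fs
  nt <- dim(d)[3]
  pow <- array(NA_real_, c(dim(d)[1], length(channels), length(freqs_hz), nt))
  for (fi in seq_along(freqs_hz)) {
    spec <- wavelet_spec(freqs_hz[fi], c_ratio)
    w <- morlet_wavelet(spec, fs)
    half <- (length(w) - 1) / 2
    if (length(w) > nt)
      stop("segment shorter than wavelet support at ", freqs_hz[fi], " Hz")
    for (tr in seq_len(dim(d)[1])) {
      for (ci in seq_along(channels)) {
        x <- d[tr, channels[ci], ]
        conv <- conv_complex_same(x, w)
        p <- Mod(conv)^2
        p[seq_len(half)] <- NA
        p[(nt - half + 1):nt] <- NA
        pow[tr, ci, fi, ] <- p
      }
    }
  }
  structure(list(power = pow, times_ms = segments$times_ms,
                 freqs_hz = freqs_hz,
                 channel_labels = segments$channel_labels[channels],
                 trial_info = segments$trial_info,
                 baseline = NULL, corrected = FALSE, kind = "induced"),
            class = "tfr")
}

# complex "same" convolution via FFT
conv_complex_same <- function(x, w) {
  n <- length(x); m <- length(w)
  half <- (m - 1) / 2
  N <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, rep(0, N - n)))
  W <- stats::fft(c(w, rep(0, N - m)))
  full <- stats::fft(X * W, inverse = TRUE) / N
  full[(half + 1):(half + n)]
}

#' Baseline-correct a TFR
#'
#' Subtracts (or divides into percent change) the mean baseline power per
#' trial, channel and frequency.
#'
#' @param tfr a `tfr` object.
#' @param window_ms baseline window (default -1500..-500 ms).
#' @param mode `"subtract"` or `"percent"`.
#' @return the corrected `tfr` (`corrected = TRUE`).
#' @export
baseline_correct <- function(tfr, window_ms = c(-1500, -500),
                             mode = c("subtract", "percent")) {
  mode <- match.arg(mode)
  sel <- tfr$times_ms >= window_ms[1] & tfr$times_ms <= window_ms[2]
  if (!any(sel))
    stop("baseline window ", window_ms[1], "..", window_ms[2],
         " ms lies outside the segment")
  base <- apply(tfr$power[, , , sel, drop = FALSE], 1:3, mean, na.rm = TRUE)
  nt <- dim(tfr$power)[4]
  for (ti in seq_len(nt)) {
    if (mode == "subtract") {
      tfr$power[, , , ti] <- tfr$power[, , , ti] - base
    } else {
      tfr$power[, , , ti] <- 100 * (tfr$power[, , , ti] - base) / base
    }
  }
  tfr$baseline <- window_ms
  tfr$corrected <- TRUE
  tfr$baseline_mode <- mode
  tfr
}

#' Topographic alpha-power statistic map
#'
#' Mean baseline-corrected power per channel in a frequency band and time
#' window, with an across-trial t statistic per channel; optionally a
#' CON-INC two-sample contrast.
#'
#' @param tfr a baseline-corrected `tfr`.
#' @param band_hz frequency band (default 8-13 Hz).
#' @param window_ms time window (default 200-400 ms).
#' @param contrast `"vs_baseline"` (one-sample t of corrected power
#'   against 0) or `"CON_vs_INC"` (two-sample t over trials).
#' @return `data.frame` with `channel`, `mean_power`, `t`, `p`.
#' @export
alpha_topography <- function(tfr, band_hz = c(8, 13),
                             window_ms = c(200, 400),
                             contrast = c("vs_baseline", "CON_vs_INC")) {
  contrast <- match.arg(contrast)
  if (!isTRUE(tfr$corrected))
    stop("alpha_topography needs a baseline-corrected tfr")
  fsel <- tfr$freqs_hz >= band_hz[1] & tfr$freqs_hz <= band_hz[2]
  tsel <- tfr$times_ms >= window_ms[1] & tfr$times_ms <= window_ms[2]
  vals <- apply(tfr$power[, , fsel, tsel, drop = FALSE], c(1, 2), mean,
                na.rm = TRUE)                       # trials x channels
  nch <- ncol(vals)
  if (contrast == "vs_baseline") {
    if (nrow(vals) < 2) stop("contrast needs >= 2 trials per cell")
    tt <- apply(vals, 2, function(v) {
      r <- stats::t.test(v)
      c(r$statistic, r$p.value)
    })
  } else {
    g <- tfr$trial_info$congruence
    if (sum(g == "CON") < 2 || sum(g == "INC") < 2)
      stop("contrast needs >= 2 trials per cell")
    tt <- apply(vals, 2, function(v) {
      r <- stats::t.test(v[g == "CON"], v[g == "INC"])
      c(r$statistic, r$p.value)
    })
  }
  data.frame(channel = tfr$channel_labels,
             mean_power = colMeans(vals),
             t = tt[1, ], p = tt[2, ], row.names = NULL)
}

#' Short-time FFT band power
#'
#' Hann-tapered FFT in sliding windows (default 500 ms windows, 100 ms
#' hop: 80% overlap); band power is the mean periodogram power over bins
#' inside the band. If `baseline_ms` is given, the mean power over all
#' windows fully contained in the baseline is subtracted per signal.
#'
#' @param x numeric vector or matrix (signals in rows).
#' @param fs sampling rate.
#' @param times_ms optional time axis of the samples (default starts at 0).
#' @param window_ms,hop_ms STFFT geometry.
#' @param band_hz frequency band to average.
#' @param baseline_ms optional baseline window, e.g. `c(-2000, 0)`.
#' @return matrix signals x windows with attribute `"centers_ms"`; a
#'   vector input returns a vector with the same attribute.
#' @export
stfft_power <- function(x, fs, times_ms = NULL, window_ms = 500,
                        hop_ms = 100, band_hz = c(8, 13),
                        baseline_ms = NULL) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1) else x
  n <- ncol(X)
  if (is.null(times_ms)) times_ms <- (seq_len(n) - 1) / fs * 1000
  wlen <- round(window_ms / 1000 * fs)
  hop <- round(hop_ms / 1000 * fs)
  if (hop > wlen) stop("hop must not exceed the window length")
  starts <- seq(1, n - wlen + 1, by = hop)
  centers <- times_ms[starts] + (wlen - 1) / 2 / fs * 1000
  taper <- 0.5 * (1 - cos(2 * pi * (seq_len(wlen) - 1) / (wlen - 1)))
  freqs <- (seq_len(wlen) - 1) * fs / wlen
  bsel <- freqs >= band_hz[1] & freqs <= band_hz[2] & freqs <= fs / 2
  if (!any(bsel)) stop("no FFT bin falls inside the band")
  U <- sum(taper^2)
  out <- matrix(NA_real_, nrow(X), length(starts))
  for (wi in seq_along(starts)) {
    seg <- X[, starts[wi]:(starts[wi] + wlen - 1), drop = FALSE]
    seg <- sweep(seg, 1, rowMeans(seg))
    ft <- t(stats::mvfft(t(seg * rep(taper, each = nrow(seg)))))
    psd <- (Mod(ft)^2) / (U * fs) * 2        # one-sided periodogram
    out[, wi] <- rowMeans(psd[, bsel, drop = FALSE])
  }
  if (!is.null(baseline_ms)) {
    wstart <- times_ms[starts]
    wend <- times_ms[starts + wlen - 1]
    base_sel <- wstart >= baseline_ms[1] & wend <= baseline_ms[2]
    if (!any(base_sel))
      stop("no STFFT window fully inside the baseline")
    out <- out - rowMeans(out[, base_sel, drop = FALSE])
  }
  attr(out, "centers_ms") <- centers
  if (vec) {
    v <- out[1, ]
    attr(v, "centers_ms") <- centers
    return(v)
  }
  out
}

#' Mean baseline-corrected Morlet band power per trial and channel
#'
#' Memory-light path for topographies: accumulates the band/window mean
#' without retaining the full TFR array.
#'
#' @param segments a `segments` object.
#' @param band_hz band, analyzed at 1 Hz steps.
#' @param window_ms post-stimulus window.
#' @param baseline_ms baseline window.
#' @param c_ratio Morlet ratio.
#' @return trials x channels matrix of corrected power.
#' @export
morlet_band_power <- function(segments, band_hz = c(8, 13),
                              window_ms = c(200, 400),
                              baseline_ms = c(-1500, -500), c_ratio = 4.2) {
  d <- segments$data
  fs <- segments$fs
  freqs <- seq(band_hz[1], band_hz[2])
  tsel <- segments$times_ms >= window_ms[1] &
    segments$times_ms <= window_ms[2]
  bsel <- segments$times_ms >= baseline_ms[1] &
    segments$times_ms <= baseline_ms[2]
  acc <- matrix(0, dim(d)[1], dim(d)[2])
  for (f in freqs) {
    w <- morlet_wavelet(wavelet_spec(f, c_ratio), fs)
    for (tr in seq_len(dim(d)[1])) {
      for (ch in seq_len(dim(d)[2])) {
        p <- Mod(conv_complex_same(d[tr, ch, ], w))^2
        acc[tr, ch] <- acc[tr, ch] +
          (mean(p[tsel]) - mean(p[bsel])) / length(freqs)
      }
    }
  }
  acc
}
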