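# Ground-truth cortical source activity, forward projection, in-scanner
# artifacts (MR gradient, ballistocardiogram, blinks) and coupled BOLD.

# 1/f (power) noise of length n and unit RMS, via FFT spectral shaping.
# Shaped at the next highly-composite length and truncated: session
# lengths routinely contain large prime factors that would make the FFT
# quadratic.
one_over_f_noise <- function(n) {
  n2 <- stats::nextn(n, 2)
  w <- stats::rnorm(n2)
  W <- stats::fft(w)
  f <- c(1, seq_len(n2 - 1))
  f <- pmin(f, n2 - f + 1)                # two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)] / n2
  x / stats::sd(x)
}

# Smooth 0/1 window over [w1, w2] seconds with raised-cosine ramps.
effect_window <- function(t, w1, w2, ramp = 0.05) {
  up <- (t - (w1 - ramp)) / ramp
  dn <- ((w2 + ramp) - t) / ramp
  pmin(pmax(pmin(up, dn), 0), 1)^2 * (3 - 2 * pmin(pmax(pmin(up, dn), 0), 1))
}

#' Source simulation specification
#'
#' Occipital vertices carry a continuous alpha oscillation whose envelope
#' drops by `suppression_depth` within the effect window after every
#' stimulus; frontal vertices gain `con_frontal_gain` envelope for
#' congruent audiovisual trials only; every vertex carries 1/f background.
#'
#' @param src a `source_space` used for simulation.
#' @param occipital,frontal vertex index sets (defaults: geodesic patches
#'   around the occipital pole and medial prefrontal direction).
#' @param alpha_f0_hz alpha center frequency.
#' @param suppression_depth fractional envelope drop in (0, 1]; 0 disables.
#' @param effect_window_s window of the event-locked effect (s).
#' @param con_frontal_gain fractional frontal envelope gain for CON trials.
#' @param depth_jitter_sd multiplicative trial-to-trial s.d. of the effect.
#' @param alpha_amp,background_amp source amplitudes (arbitrary units
#'   scaled at projection).
#' @param seed RNG seed.
#' @return a `source_sim_spec` list.
#' @export
source_sim_spec <- function(src,
                            occipital = source_patch(src, c(0, -1, -0.15), 30),
                            frontal = source_patch(src, c(0, 0.9, 0.45), 25),
                            alpha_f0_hz = 10.5,
                            suppression_depth = 0.5,
                            effect_window_s = c(0.2, 0.4),
                            con_frontal_gain = 0.5,
                            depth_jitter_sd = 0.1,
                            alpha_amp = 1, background_amp = 0.3,
                            seed = 1) {
  if (length(occipital) == 0 || length(frontal) == 0)
    stop("empty source patch")
  if (length(intersect(occipital, frontal)) > 0)
    stop("occipital and frontal patches must be disjoint")
  if (suppression_depth < 0 || suppression_depth > 1)
    stop("suppression_depth must be in [0, 1]")
  structure(list(src = src, occipital = occipital, frontal = frontal,
                 alpha_f0_hz = alpha_f0_hz,
                 suppression_depth = suppression_depth,
                 effect_window_s = effect_window_s,
                 con_frontal_gain = con_frontal_gain,
                 depth_jitter_sd = depth_jitter_sd,
                 alpha_amp = alpha_amp, background_amp = background_amp,
                 seed = seed),
            class = "source_sim_spec")
}

#' Simulate cortical source time courses
#'
#' @param spec a [source_sim_spec()].
#' @param markers marker table providing stimulus events.
#' @param sampling_rate_hz sampling rate of the generated time courses.
#' @param n_samples number of samples to generate.
#' @return list with `sources` (vertices x samples), `truth` (per-trial
#'   realized relative alpha-power change for the occipital and frontal
#'   patch) and the envelopes used.
#' @export
simulate_sources <- function(spec, markers, sampling_rate_hz, n_samples) {
  fs <- sampling_rate_hz
  st <- markers[markers$kind == "stimulus", , drop = FALSE]
  nv <- nrow(spec$src$vertices_mm)
  t <- seq_len(n_samples) / fs
  with_seed(spec$seed, {
    dj <- function(base) {
      v <- base * (1 + spec$depth_jitter_sd * stats::rnorm(nrow(st)))
      pmin(pmax(v, 0), 1)
    }
    occ_depth <- dj(spec$suppression_depth)
    fro_gain <- spec$con_frontal_gain *
      (1 + spec$depth_jitter_sd * stats::rnorm(nrow(st)))
    fro_gain[st$congruence != "CON"] <- 0

    env_occ <- rep(1, n_samples)
    env_fro <- rep(1, n_samples)
    for (i in seq_len(nrow(st))) {
      on <- st$onset_sample[i] / fs
      idx <- which(t >= on & t <= on + spec$effect_window_s[2] + 0.15)
      if (length(idx) == 0) next
      w <- effect_window(t[idx] - on, spec$effect_window_s[1],
                         spec$effect_window_s[2])
      env_occ[idx] <- env_occ[idx] * (1 - occ_depth[i] * w)
      env_fro[idx] <- env_fro[idx] * (1 + fro_gain[i] * w)
    }
    # alpha with finite coherence: instantaneous frequency wanders around
    # f0 (AR(1)-smoothed, s.d. ~0.5 Hz, correlation time ~0.5 s), as real
    # posterior alpha does; a phase-rigid sinusoid would be degenerate
    # (e.g. exactly TR-periodic when f0 * TR is an integer, so template
    # subtraction would remove the rhythm itself)
    phase0 <- stats::runif(1, 0, 2 * pi)
    rho <- exp(-1 / (0.5 * fs))
    innov <- stats::rnorm(n_samples)
    fj <- stats::filter(innov, rho, method = "recursive")
    fj <- as.numeric(fj) / stats::sd(fj) * 0.5
    osc <- sin(2 * pi * cumsum(spec$alpha_f0_hz + fj) / fs + phase0)
    S <- matrix(0, nv, n_samples)
    if (spec$background_amp > 0) {
      for (v in seq_len(nv))
        S[v, ] <- spec$background_amp * one_over_f_noise(n_samples)
    }
    S[spec$occipital, ] <- S[spec$occipital, , drop = FALSE] +
      matrix(spec$alpha_amp * osc * env_occ, length(spec$occipital),
             n_samples, byrow = TRUE)
    S[spec$frontal, ] <- S[spec$frontal, , drop = FALSE] +
      matrix(spec$alpha_amp * osc * env_fro, length(spec$frontal),
             n_samples, byrow = TRUE)
    truth <- data.frame(
      trial_id = st$trial_id,
      congruence = st$congruence,
      occ_alpha_change = (1 - occ_depth)^2 - 1,
      frontal_alpha_change = (1 + fro_gain)^2 - 1)
    list(sources = S, truth = truth, env_occ = env_occ, env_fro = env_fro,
         spec = spec)
  })
}

#' Project source activity to the sensors
#'
#' `data = L s + white noise`. The output is scaled so that the median
#' occipital-channel alpha RMS is `target_alpha_uv` microvolts, fixing the
#' arbitrary source units to a realistic sensor scale.
#'
#' @param leadfield a `leadfield` whose columns match the source rows.
#' @param sources vertices x samples matrix.
#' @param sampling_rate_hz sampling rate of `sources`.
#' @param markers markers to attach to the output recording.
#' @param sensor_noise_sd white sensor noise s.d. (microvolts).
#' @param target_alpha_uv sensor-scale calibration (microvolts RMS);
#'   `NA` disables scaling.
#' @param seed RNG seed for sensor noise.
#' @return a `recording` (microvolts).
#' @export
project_to_sensors <- function(leadfield, sources, sampling_rate_hz,
                               markers = new_markers(),
                               sensor_noise_sd = 2,
                               target_alpha_uv = 8, seed = 1) {
  if (ncol(leadfield$matrix) != nrow(sources))
    stop("leadfield has ", ncol(leadfield$matrix),
         " columns but sources has ", nrow(sources), " rows")
  X <- leadfield$matrix %*% sources
  if (!is.na(target_alpha_uv) && any(X != 0)) {
    post <- grepl("^(O|PO)", leadfield$channel_labels)
    ref_rms <- stats::median(sqrt(rowMeans(X[post, , drop = FALSE]^2)))
    if (ref_rms > 0) X <- X * (target_alpha_uv / ref_rms)
  }
  if (sensor_noise_sd > 0)
    X <- X + with_seed(seed + 77L,
                       matrix(stats::rnorm(length(X), sd = sensor_noise_sd),
                              nrow(X)))
  new_recording(X, leadfield$channel_labels, sampling_rate_hz, markers)
}

#' In-scanner artifact specification
#'
#' @param tr_s volume repetition time (s).
#' @param n_slices slices per volume (slice-locked gradient bursts).
#' @param gradient_amp_uv gradient artifact scale, much larger than EEG.
#' @param heart_rate_bpm,rr_jitter_sd_s cardiac rate and RR jitter.
#' @param bcg_amp_uv ballistocardiogram amplitude scale.
#' @param bcg_lag_s BCG onset lag after the R-peak.
#' @param bcg_beat_jitter multiplicative s.d. of per-beat BCG amplitude.
#' @param blink_rate_per_min,blink_amp_uv eye-blink rate and frontal peak
#'   amplitude.
#' @param seed RNG seed.
#' @return an `artifact_sim_spec` list.
#' @export
artifact_sim_spec <- function(tr_s = 2, n_slices = 34,
                              gradient_amp_uv = 1500,
                              heart_rate_bpm = 70, rr_jitter_sd_s = 0.03,
                              bcg_amp_uv = 50, bcg_lag_s = 0.21,
                              bcg_beat_jitter = 0.05,
                              blink_rate_per_min = 12, blink_amp_uv = 250,
                              seed = 1) {
  structure(list(tr_s = tr_s, n_slices = n_slices,
                 gradient_amp_uv = gradient_amp_uv,
                 heart_rate_bpm = heart_rate_bpm,
                 rr_jitter_sd_s = rr_jitter_sd_s,
                 bcg_amp_uv = bcg_amp_uv, bcg_lag_s = bcg_lag_s,
                 bcg_beat_jitter = bcg_beat_jitter,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_amp_uv = blink_amp_uv, seed = seed),
            class = "artifact_sim_spec")
}

# place a waveform additively at given onset samples (recycled per channel
# weight); operates in place on a channels x samples matrix
add_waveform <- function(X, chan_weights, wave, onsets, amp_jitter = NULL) {
  n <- ncol(X)
  lw <- length(wave)
  for (k in seq_along(onsets)) {
    i0 <- onsets[k] + 1L
    if (i0 > n) next
    i1 <- min(n, i0 + lw - 1L)
    seg <- wave[seq_len(i1 - i0 + 1L)]
    a <- if (is.null(amp_jitter)) 1 else amp_jitter[k]
    X[, i0:i1] <- X[, i0:i1] + outer(chan_weights * a, seg)
  }
  X
}

#' Add an exactly TR-periodic MR gradient artifact
#'
#' Per channel, a sum of slice-locked sawtooth bursts repeating exactly
#' every TR, starting at t = 0; volume_sync markers are appended at every
#' TR.
#'
#' @param rec a `recording`.
#' @param spec an [artifact_sim_spec()].
#' @return list `rec` (contaminated recording with volume_sync markers)
#'   and `artifact` (the pure artifact matrix, for oracles).
#' @export
add_gradient_artifact <- function(rec, spec) {
  fs <- rec$sampling_rate_hz
  period <- spec$tr_s * fs
  if (abs(period - round(period)) > 1e-9)
    stop("TR must be an integer number of samples at ", fs, " Hz")
  period <- as.integer(round(period))
  n <- ncol(rec$data)
  nchan <- nrow(rec$data)
  tt <- (seq_len(period) - 1) / period          # within-TR phase [0,1)
  slice_phase <- (tt * spec$n_slices) %% 1      # sawtooth per slice
  template_shape <- (slice_phase - 0.5) +
    0.3 * sin(2 * pi * 3 * slice_phase)
  with_seed(spec$seed + 11L, {
    amp <- spec$gradient_amp_uv * (0.5 + stats::runif(nchan)) *
      sample(c(-1, 1), nchan, replace = TRUE)
  })
  artifact <- if (spec$gradient_amp_uv == 0) {
    matrix(0, nchan, n)
  } else {
    reps <- ceiling(n / period)
    tiled <- rep(template_shape, reps)[seq_len(n)]
    outer(amp, tiled)
  }
  rec$data <- rec$data + artifact
  n_vols <- floor(n / period)
  vm <- new_markers(onset_sample = (seq_len(n_vols) - 1L) * period,
                    kind = "volume_sync")
  rec$markers <- rbind(rec$markers, vm)
  class(rec$markers) <- c("marker_table", "data.frame")
  list(rec = rec, artifact = artifact)
}

# stylized PQRST complex sampled at fs; returns waveform and R-peak offset
ecg_template <- function(fs) {
  t <- seq(0, 0.6, by = 1 / fs)
  g <- function(mu, sd, a) a * exp(-(t - mu)^2 / (2 * sd^2))
  w <- g(0.15, 0.025, 150) +          # P
    g(0.28, 0.008, -300) +            # Q
    g(0.30, 0.010, 1200) +            # R
    g(0.32, 0.008, -350) +            # S
    g(0.45, 0.035, 400)               # T
  list(wave = w, r_offset = round(0.30 * fs))
}

# smooth BCG pulse waveform (gaussian-windowed low-frequency wavelet)
bcg_template <- function(fs, dur = 0.5) {
  t <- seq(0, dur, by = 1 / fs)
  exp(-(t - dur / 2)^2 / (2 * 0.09^2)) * sin(2 * pi * 4.5 * (t - 0.1))
}

#' Add ballistocardiogram artifact and an ECG channel
#'
#' R-peaks at jittered RR intervals drive a stylized ECG trace (appended
#' as channel `"ECG"`) and, `bcg_lag_s` later, a fixed per-channel BCG
#' waveform with small amplitude jitter on the EEG channels. Ground-truth
#' r_peak markers are appended.
#'
#' @param rec a `recording` (EEG channels only).
#' @param spec an [artifact_sim_spec()].
#' @return list `rec` (with ECG channel and r_peak markers) and
#'   `r_peaks` (ground-truth R-peak samples), `bcg` (pure BCG matrix).
#' @export
add_bcg_and_ecg <- function(rec, spec) {
  fs <- rec$sampling_rate_hz
  n <- ncol(rec$data)
  nchan <- nrow(rec$data)
  with_seed(spec$seed + 23L, {
    rr_mean <- 60 / spec$heart_rate_bpm
    n_max <- ceiling(n / fs / rr_mean) + 10
    rr <- rr_mean + stats::rnorm(n_max, sd = spec$rr_jitter_sd_s)
    rr <- pmax(rr, 0.4)
    peaks_t <- cumsum(c(0.5, rr))
    peaks_t <- peaks_t[peaks_t < n / fs]
    peaks <- round(peaks_t * fs)
    chan_amp <- spec$bcg_amp_uv * (0.5 + stats::runif(nchan)) *
      sample(c(-1, 1), nchan, replace = TRUE)
    amp_jit <- 1 + spec$bcg_beat_jitter * stats::rnorm(length(peaks))

    bcg <- matrix(0, nchan, n)
    if (spec$bcg_amp_uv != 0) {
      wave <- bcg_template(fs)
      bcg <- add_waveform(bcg, chan_amp, wave,
                          peaks + round(spec$bcg_lag_s * fs), amp_jit)
    }
    rec$data <- rec$data + bcg
    ecg <- numeric(n)
    et <- ecg_template(fs)
    ecg <- add_waveform(matrix(ecg, 1), 1, et$wave, peaks - et$r_offset,
                        1 + 0.03 * stats::rnorm(length(peaks)))[1, ]
    ecg <- ecg + stats::rnorm(n, sd = 5)
    rec$data <- rbind(rec$data, ecg)
    rec$channel_labels <- c(rec$channel_labels, "ECG")
    rp <- new_markers(onset_sample = peaks, kind = "r_peak")
    rec$markers <- rbind(rec$markers, rp)
    class(rec$markers) <- c("marker_table", "data.frame")
    list(rec = rec, r_peaks = peaks, bcg = bcg)
  })
}

#' Add eye-blink artifacts
#'
#' Raised-cosine deflections of ~300 ms at Poisson times, weighted toward
#' frontal channels by the montage's anterior coordinate.
#'
#' @param rec a `recording` whose labels match `electrodes`.
#' @param electrodes an `electrode_set` giving channel geometry.
#' @param rate_per_min expected blink rate.
#' @param amp_uv peak amplitude at the most frontal channel.
#' @param seed RNG seed.
#' @return list `rec`, `blink_onsets` (samples) and `blink_regressor`
#'   (the blink time course, for ICA ground truth).
#' @export
add_blinks <- function(rec, electrodes, rate_per_min = 12, amp_uv = 250,
                       seed = 1) {
  fs <- rec$sampling_rate_hz
  n <- ncol(rec$data)
  idx <- match(rec$channel_labels, electrodes$labels)
  y <- electrodes$positions_mm[, 2]
  z <- electrodes$positions_mm[, 3]
  r <- sqrt(rowSums(electrodes$positions_mm^2))
  w <- pmax(y / r, 0)^3 * pmax(1 - z / r, 0.2)
  w <- w / max(w)
  weights <- ifelse(is.na(idx), 0, w[idx])
  with_seed(seed + 31L, {
    n_blinks <- stats::rpois(1, rate_per_min * n / fs / 60)
    onsets <- sort(sample.int(max(n - round(0.4 * fs), 1), n_blinks))
    dur <- round(0.3 * fs)
    tt <- seq_len(dur) / dur
    wave <- amp_uv * 0.5 * (1 - cos(2 * pi * tt))
    jit <- 1 + 0.25 * stats::rnorm(n_blinks)
    regressor <- numeric(n)
    for (k in seq_along(onsets)) {
      i0 <- onsets[k] + 1L
      i1 <- min(n, i0 + dur - 1L)
      regressor[i0:i1] <- regressor[i0:i1] + wave[seq_len(i1 - i0 + 1)] * jit[k]
    }
    rec$data <- rec$data + outer(weights, regressor)
    list(rec = rec, blink_onsets = onsets, blink_regressor = regressor,
         weights = weights)
  })
}

#' BOLD coupling specification
#'
#' @param grid volume grid dimensions (x, y, z).
#' @param coupled_mask logical 3D array of voxels coupled to the alpha
#'   regressor (default: a posterior cuboid).
#' @param k coupling gain; negative reproduces the inverse alpha-BOLD
#'   relation of occipital cortex.
#' @param noise_sd Gaussian noise s.d.
#' @param drift_amp low-frequency drift amplitude.
#' @param seed RNG seed.
#' @return a `coupling_sim_spec` list.
#' @export
coupling_sim_spec <- function(grid = c(20, 20, 10), coupled_mask = NULL,
                              k = -2, noise_sd = 1, drift_amp = 2,
                              seed = 1) {
  if (is.null(coupled_mask)) {
    # central-posterior box scaled to the grid ("visual cortex" stand-in)
    coupled_mask <- array(FALSE, grid)
    xr <- max(1, round(0.40 * grid[1])):max(1, round(0.65 * grid[1]))
    yr <- max(1, round(0.15 * grid[2])):max(1, round(0.40 * grid[2]))
    zr <- max(1, round(0.30 * grid[3])):max(1, round(0.60 * grid[3]))
    coupled_mask[xr, yr, zr] <- TRUE
  }
  if (!all(dim(coupled_mask) == grid))
    stop("coupled_mask dimensions must match grid")
  structure(list(grid = grid, coupled_mask = coupled_mask, k = k,
                 noise_sd = noise_sd, drift_amp = drift_amp, seed = seed),
            class = "coupling_sim_spec")
}

#' Simulate a BOLD series coupled to trial alpha power
#'
#' Coupled voxels follow `k` times the HRF-convolved trial-alpha stick
#' function (zero outside events); all voxels carry low-frequency drift
#' and Gaussian noise.
#'
#' @param markers marker table with stimulus events (onsets in samples at
#'   `eeg_rate_hz`).
#' @param trial_alpha per-trial alpha values (one per stimulus marker).
#' @param spec a [coupling_sim_spec()].
#' @param duration_s session duration (determines volume count).
#' @param tr_s repetition time.
#' @param eeg_rate_hz rate in which marker onsets are expressed.
#' @return list `vol` (a `volume_series`), `regressor` (TR-sampled
#'   coupled signal) and the spec.
#' @export
simulate_bold <- function(markers, trial_alpha, spec, duration_s,
                          tr_s = 2, eeg_rate_hz = 500) {
  st <- markers[markers$kind == "stimulus", , drop = FALSE]
  stopifnot(nrow(st) == length(trial_alpha))
  n_vol <- floor(duration_s / tr_s)
  onsets_s <- st$onset_sample / eeg_rate_hz
  reg <- hrf_regressor(onsets_s, trial_alpha, tr_s, n_vol)
  with_seed(spec$seed + 41L, {
    nx <- spec$grid[1]; ny <- spec$grid[2]; nz <- spec$grid[3]
    nvox <- nx * ny * nz
    dat <- matrix(stats::rnorm(nvox * n_vol, sd = spec$noise_sd),
                  nvox, n_vol)
    if (spec$drift_amp > 0) {
      tv <- seq_len(n_vol) * tr_s
      # scanner drift is conventionally < 0.01 Hz; within a desk-scale run
      # these components are near-linear and fall under the 128 s high-pass
      ph <- stats::runif(nvox, 0, 2 * pi)
      per <- stats::runif(nvox, 150, 400)
      drift <- spec$drift_amp *
        cos(outer(ph, rep(1, n_vol)) + 2 * pi * outer(1 / per, tv))
      dat <- dat + drift
    }
    cm <- which(as.vector(spec$coupled_mask))
    if (length(cm) > 0 && spec$k != 0)
      dat[cm, ] <- dat[cm, ] + rep(spec$k, length(cm)) %o% reg
    vol <- new_volume_series(array(dat, c(nx, ny, nz, n_vol)), tr_s,
                             affine = diag(c(3, 3, 3, 1)))
    list(vol = vol, regressor = reg, spec = spec)
  })
}
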