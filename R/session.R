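# End-to-end synthetic session generation and the canonical cleaning
# pipeline.

#' Simulate a complete synthetic EEG-fMRI session
#'
#' Generates the paradigm, behavior, ground-truth cortical sources with
#' occipital alpha suppression (and a frontal congruence effect),
#' projects them to the sensors, contaminates the EEG with blinks, an
#' exactly TR-periodic gradient artifact and R-peak-locked BCG (plus an
#' ECG channel), and produces a BOLD series negatively coupled to the
#' trial alpha values. Every ground-truth quantity is returned for
#' assertion.
#'
#' The default paradigm is a desk-scale session (4 blocks, 48 trials)
#' rather than the full 32-block session; pass
#' `paradigm = paradigm_spec()` for the full paradigm. All other
#' defaults (pause jitter, trial structure, artifact levels) are the
#' stated conditions regardless of scale.
#'
#' @param seed master seed; all stage seeds derive from it.
#' @param paradigm a [paradigm_spec()].
#' @param fs_hz EEG sampling rate for the simulation (500 Hz by default;
#'   the acquisition-rate chain 5000 to 500 Hz is exercised separately by
#'   unit tests to keep session runtimes sane).
#' @param artifact an [artifact_sim_spec()].
#' @param n_sources_per_hemisphere simulation source-space resolution.
#' @param suppression_depth,con_frontal_gain source-effect sizes.
#' @param bold_grid BOLD volume grid.
#' @param k_coupling BOLD coupling gain (negative).
#' @param with_artifacts set `FALSE` for a clean (artifact-free)
#'   recording.
#' @return list with `recording`, `bold` (`$vol`, `$regressor`),
#'   `paradigm` (markers/trials), `truth` (trial alpha changes, R-peaks,
#'   blink regressor, coupled mask, source patches), `leadfield`,
#'   `source_space`, `electrodes`, `head_model`.
#' @export
simulate_session <- function(seed = 1,
                             paradigm = paradigm_spec(
                               n_auditory = 1, n_visual = 1,
                               n_audiovisual = 2, seed = seed),
                             fs_hz = 500,
                             artifact = artifact_sim_spec(seed = seed),
                             n_sources_per_hemisphere = 48,
                             suppression_depth = 0.5,
                             con_frontal_gain = 0.5,
                             bold_grid = c(20, 20, 10),
                             k_coupling = -2,
                             with_artifacts = TRUE) {
  par <- build_paradigm(paradigm, fs_hz)
  par <- simulate_behavior(par, seed = seed)
  hm <- head_model()
  mon <- standard_montage()
  el <- coregister_electrodes(mon, hm)
  src <- source_space(hm, n_per_hemisphere = n_sources_per_hemisphere)
  sspec <- source_sim_spec(src, suppression_depth = suppression_depth,
                           con_frontal_gain = con_frontal_gain,
                           seed = seed)
  L <- compute_leadfield(hm, src, el)
  n_samp <- round(par$total_duration_s * fs_hz)
  ss <- simulate_sources(sspec, par$markers, fs_hz, n_samp)
  rec <- project_to_sensors(L, ss$sources, fs_hz, markers = par$markers,
                            seed = seed)
  truth <- list(trial_alpha = ss$truth, occipital = sspec$occipital,
                frontal = sspec$frontal)
  if (with_artifacts) {
    bl <- add_blinks(rec, el, seed = seed)
    rec <- bl$rec
    truth$blink_regressor <- bl$blink_regressor
    ga <- add_gradient_artifact(rec, artifact)
    rec <- ga$rec
    be <- add_bcg_and_ecg(rec, artifact)
    rec <- be$rec
    truth$r_peaks <- be$r_peaks
  }
  cspec <- coupling_sim_spec(grid = bold_grid, k = k_coupling, seed = seed)
  bold <- simulate_bold(par$markers, ss$truth$occ_alpha_change, cspec,
                        par$total_duration_s, tr_s = artifact$tr_s,
                        eeg_rate_hz = fs_hz)
  truth$coupled_mask <- cspec$coupled_mask
  truth$k <- k_coupling
  list(recording = rec, bold = bold, paradigm = par, truth = truth,
       leadfield = L, source_space = src, electrodes = el,
       head_model = hm)
}

#' Run the canonical in-scanner cleaning pipeline
#'
#' Order (enforced): gradient template subtraction, 70 Hz IIR lowpass,
#' downsample to 500 Hz (when above), R-peak detection + BCG template
#' subtraction, downsample to 250 Hz, +/-300 uV amplitude rejection,
#' 63-component ICA cleanup, average reference with AFz/FCz
#' pseudo-electrodes (65 channels out).
#'
#' @param rec a raw in-scanner `recording` (63 scalp channels + ECG).
#' @param electrodes an `electrode_set` covering the scalp channels.
#' @param template_window_n gradient/BCG sliding-template length.
#' @param amp_thresh_uv amplitude rejection threshold.
#' @param n_components ICA components (63).
#' @param seed seed for the ICA initialization.
#' @return list `rec` (cleaned 65-channel, 250 Hz), `report`
#'   (amplitude `rejection_report`), `ica` (`ica_decomposition`),
#'   `r_peaks` (detected, at the detection rate).
#' @export
clean_session <- function(rec, electrodes = standard_montage(),
                          template_window_n = 21, amp_thresh_uv = 300,
                          n_components = 63, seed = 1) {
  r <- remove_gradient(rec, template_window_n = template_window_n)
  r <- mark_stage(iir_lowpass(r, 70), "lowpass")
  if (r$sampling_rate_hz > 500) r <- resample(r, 500)
  peaks <- detect_r_peaks(r)
  r <- remove_bcg(r, r_peaks = peaks, n_average = template_window_n)
  if (r$sampling_rate_hz > 250) r <- resample(r, 250)
  ra <- reject_amplitude(r, threshold_uv = amp_thresh_uv)
  ic <- ica_clean(ra$rec, n_components = n_components, seed = seed)
  out <- rereference_and_interpolate(ic$rec, electrodes)
  list(rec = out, report = ra$report, ica = ic$decomposition,
       r_peaks = peaks)
}
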