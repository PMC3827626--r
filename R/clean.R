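# In-scanner EEG artifact removal: gradient template subtraction, R-peak
# detection, BCG template subtraction, amplitude rejection, ICA cleanup,
# average reference with spherical-spline pseudo-electrodes.
#
# Pipeline-order enforcement is evidence-based: an operation refuses to
# run while markers prove that an earlier artifact stage is still pending
# (e.g. BCG subtraction on data whose volume_sync markers show the
# gradient artifact has not been removed).

pipeline_history <- function(rec) {
  h <- rec$pipeline
  if (is.null(h)) character() else h
}

mark_stage <- function(rec, stage) {
  rec$pipeline <- c(pipeline_history(rec), stage)
  rec
}

assert_gradient_done <- function(rec, what) {
  if (any(rec$markers$kind == "volume_sync") &&
      !("gradient_removed" %in% pipeline_history(rec)))
    stop(what, " must run after gradient-artifact removal ",
         "(volume_sync markers present, gradient stage missing)")
}

assert_bcg_done <- function(rec, what) {
  if (any(rec$markers$kind == "r_peak") &&
      !("bcg_removed" %in% pipeline_history(rec)))
    stop(what, " must run after BCG removal ",
         "(r_peak markers present, BCG stage missing)")
}

# sliding-window column means of a matrix (window = half on both sides,
# clipped at the ends), via one matrix multiply
sliding_col_means <- function(M, half) {
  n <- ncol(M)
  W <- matrix(0, n, n)
  for (e in seq_len(n)) {
    lo <- max(1, e - half)
    hi <- min(n, e + half)
    W[lo:hi, e] <- 1 / (hi - lo + 1)
  }
  M %*% W
}

#' Remove the MR gradient artifact by sliding template subtraction
#'
#' Volume epochs are defined by the volume_sync markers; for each epoch
#' the per-channel average of the surrounding `template_window_n` epochs
#' is subtracted. A trailing partial epoch is corrected with the last
#' template.
#'
#' @param rec a `recording` containing volume_sync markers (or pass
#'   `volume_markers`).
#' @param volume_markers optional marker table overriding `rec$markers`.
#' @param template_window_n sliding window length in epochs (odd; 21).
#' @return the corrected `recording` (stage `"gradient_removed"`).
#' @export
remove_gradient <- function(rec, volume_markers = NULL,
                            template_window_n = 21) {
  m <- if (is.null(volume_markers)) rec$markers else volume_markers
  vs <- sort(m$onset_sample[m$kind == "volume_sync"])
  if (length(vs) < template_window_n)
    stop("need at least template_window_n = ", template_window_n,
         " volume epochs, got ", length(vs))
  sp <- diff(vs)
  if (max(sp) - min(sp) > 1)
    stop("irregular volume_sync spacing (range ", min(sp), "..", max(sp),
         " samples); template subtraction assumes exact periodicity")
  period <- as.integer(round(stats::median(sp)))
  n <- ncol(rec$data)
  nchan <- nrow(rec$data)
  n_ep <- length(vs)
  # channels x period x epochs
  ep_idx <- outer(seq_len(period), as.integer(vs), `+`)   # 1-based
  E <- array(0, c(nchan, period, n_ep))
  for (e in seq_len(n_ep)) {
    idx <- ep_idx[, e]
    idx <- idx[idx <= n]
    E[, seq_along(idx), e] <- rec$data[, idx, drop = FALSE]
  }
  half <- (template_window_n - 1) / 2
  TM <- sliding_col_means(matrix(E, ncol = n_ep), half)
  for (e in seq_len(n_ep)) {
    templ <- matrix(TM[, e], nchan, period)
    idx <- ep_idx[, e]
    keep <- idx <= n
    rec$data[, idx[keep]] <- rec$data[, idx[keep], drop = FALSE] -
      templ[, keep, drop = FALSE]
    last_templ <- templ
  }
  tail_start <- vs[n_ep] + period + 1
  if (tail_start <= n) {
    len <- min(n - tail_start + 1, period)
    rec$data[, tail_start:(tail_start + len - 1)] <-
      rec$data[, tail_start:(tail_start + len - 1), drop = FALSE] -
      last_templ[, seq_len(len), drop = FALSE]
  }
  mark_stage(rec, "gradient_removed")
}

#' Detect R-peaks in the ECG channel by template matching
#'
#' A pulse template is built from initial high-confidence peaks
#' (amplitude criterion with refractory period), then slid across the
#' channel as a normalized cross-correlation; correlation maxima above
#' `cc_thresh` under a refractory period are returned as R-peaks.
#'
#' @param rec a `recording` with an ECG channel.
#' @param ecg_label label of the ECG channel.
#' @param cc_thresh normalized cross-correlation threshold.
#' @param refractory_s minimum peak spacing.
#' @return integer vector of R-peak samples (0-based); empty with a
#'   warning for a flat channel.
#' @export
detect_r_peaks <- function(rec, ecg_label = "ECG", cc_thresh = 0.6,
                           refractory_s = 0.4) {
  ci <- match(ecg_label, rec$channel_labels)
  if (is.na(ci)) stop("no channel labelled ", ecg_label)
  x <- rec$data[ci, ]
  fs <- rec$sampling_rate_hz
  if (stats::sd(x) < 1e-9) {
    warning("ECG channel is flat; no R-peaks detected")
    return(integer())
  }
  refr <- round(refractory_s * fs)
  # seed peaks: samples above the 99th percentile of |x - median|
  dev <- x - stats::median(x)
  pol <- if (abs(min(dev)) > abs(max(dev))) -1 else 1
  dev <- dev * pol
  thr <- stats::quantile(dev, 0.99)
  cand <- which(dev > thr)
  seeds <- integer()
  last <- -refr
  for (s in cand) {
    if (s - last >= refr) {
      w0 <- max(1, s - refr %/% 2); w1 <- min(length(x), s + refr %/% 2)
      pk <- w0 - 1 + which.max(dev[w0:w1])
      if (length(seeds) == 0 || pk - seeds[length(seeds)] >= refr) {
        seeds <- c(seeds, pk)
        last <- pk
      }
    }
  }
  half <- round(0.2 * fs)
  seeds <- seeds[seeds > half & seeds < length(x) - half]
  if (length(seeds) < 3) {
    warning("too few high-confidence peaks to build an ECG template")
    return(integer())
  }
  tw <- vapply(seeds, function(s) dev[(s - half):(s + half)],
               numeric(2 * half + 1))
  templ <- rowMeans(tw)
  templ <- templ - mean(templ)
  tn <- sqrt(sum(templ^2))
  # normalized cross-correlation via rolling sums
  L <- length(templ)
  num <- as.numeric(stats::filter(dev, rev(templ), sides = 2))
  s1 <- as.numeric(stats::filter(dev, rep(1, L), sides = 2))
  s2 <- as.numeric(stats::filter(dev^2, rep(1, L), sides = 2))
  denom <- sqrt(pmax(s2 - s1^2 / L, 1e-12)) * tn
  cc <- num / denom
  cc[is.na(cc)] <- 0
  above <- which(cc > cc_thresh)
  peaks <- integer()
  last <- -refr
  i <- 1
  while (i <= length(above)) {
    j <- i
    while (j < length(above) && above[j + 1] - above[j] < refr %/% 2) j <- j + 1
    run <- above[i:j]
    pk <- run[which.max(cc[run])]
    # refine to the ECG extremum near the correlation peak
    w0 <- max(1, pk - 5); w1 <- min(length(x), pk + 5)
    pk <- w0 - 1 + which.max(dev[w0:w1])
    if (length(peaks) == 0 || pk - peaks[length(peaks)] >= refr)
      peaks <- c(peaks, pk)
    i <- j + 1
  }
  as.integer(peaks - 1L)    # 0-based like marker onsets
}

#' Remove the ballistocardiogram artifact by R-peak-locked averaging
#'
#' Per channel, epochs time-locked to `r_peaks + lag_s` are averaged over
#' a sliding window of `n_average` epochs and subtracted.
#'
#' @param rec a `recording`.
#' @param r_peaks R-peak samples (0-based); defaults to the recording's
#'   r_peak markers.
#' @param epoch_window_s epoch relative to the lagged R-peak.
#' @param n_average sliding average length in epochs.
#' @param lag_s BCG delay after the R-peak.
#' @return the corrected `recording` (stage `"bcg_removed"`).
#' @export
remove_bcg <- function(rec, r_peaks = NULL,
                       epoch_window_s = c(-0.1, 0.6), n_average = 21,
                       lag_s = 0.21) {
  assert_gradient_done(rec, "remove_bcg")
  if (is.null(r_peaks))
    r_peaks <- rec$markers$onset_sample[rec$markers$kind == "r_peak"]
  if (length(r_peaks) < 3) stop("need at least 3 R-peaks")
  fs <- rec$sampling_rate_hz
  i0 <- round((lag_s + epoch_window_s[1]) * fs)
  i1 <- round((lag_s + epoch_window_s[2]) * fs)
  L <- i1 - i0 + 1
  n <- ncol(rec$data)
  nchan <- nrow(rec$data)
  scalp <- rec$channel_labels != "ECG"
  starts_all <- as.integer(round(r_peaks)) + i0      # 0-based
  full <- starts_all >= 0 & starts_all + L <= n
  starts <- starts_all[full]
  n_ep <- length(starts)
  if (n_ep < 3) stop("need at least 3 fully contained BCG epochs")
  E <- array(0, c(sum(scalp), L, n_ep))
  D <- rec$data[scalp, , drop = FALSE]
  for (e in seq_len(n_ep))
    E[, , e] <- D[, (starts[e] + 1):(starts[e] + L)]
  half <- (n_average - 1) %/% 2
  TM <- sliding_col_means(matrix(E, ncol = n_ep), half)
  nsc <- sum(scalp)
  # subtract at every beat; truncated edge epochs use the nearest full
  # epoch's template, clipped to the recording
  full_idx <- cumsum(full)
  for (j in seq_along(starts_all)) {
    e <- min(max(full_idx[j], 1L), n_ep)
    templ <- matrix(TM[, e], nsc, L)
    a <- starts_all[j] + 1L
    b <- starts_all[j] + L
    ta <- max(1L, a); tb <- min(n, b)
    if (ta > tb) next
    D[, ta:tb] <- D[, ta:tb] - templ[, (ta - a + 1L):(tb - a + 1L),
                                     drop = FALSE]
  }
  rec$data[scalp, ] <- D
  mark_stage(rec, "bcg_removed")
}

#' Mark samples exceeding an amplitude threshold
#'
#' Samples whose absolute value exceeds `threshold_uv`, padded by
#' `pad_s`, are marked rejected per channel. Data are never deleted; the
#' mask travels with the recording (`rec$rejected`) and a
#' `rejection_report` summarizes per-channel fractions.
#'
#' @param rec a `recording`.
#' @param threshold_uv rejection threshold (default 300).
#' @param pad_s context padding around each excursion (s).
#' @param exclude_labels channels exempt from rejection (ECG).
#' @return list `rec` (with `$rejected` mask, stage
#'   `"amplitude_rejected"`) and `report` (a `rejection_report`).
#' @export
reject_amplitude <- function(rec, threshold_uv = 300, pad_s = 0.2,
                             exclude_labels = "ECG") {
  assert_gradient_done(rec, "reject_amplitude")
  assert_bcg_done(rec, "reject_amplitude")
  if (threshold_uv <= 0)
    warning("threshold ", threshold_uv,
            " rejects every sample; check units (microvolts)")
  n <- ncol(rec$data)
  pad <- round(pad_s * rec$sampling_rate_hz)
  mask <- matrix(FALSE, nrow(rec$data), n)
  for (ch in seq_len(nrow(rec$data))) {
    if (rec$channel_labels[ch] %in% exclude_labels) next
    bad <- abs(rec$data[ch, ]) >= threshold_uv
    if (threshold_uv <= 0) bad[] <- TRUE
    if (any(bad)) {
      idx <- which(bad)
      lo <- pmax(idx - pad, 1)
      hi <- pmin(idx + pad, n)
      for (k in seq_along(idx)) mask[ch, lo[k]:hi[k]] <- TRUE
    }
  }
  frac <- rowMeans(mask)
  names(frac) <- rec$channel_labels
  report <- structure(
    list(fraction_rejected = frac, threshold_uv = threshold_uv,
         pad_s = pad_s,
         n_samples = n),
    class = "rejection_report")
  rec$rejected <- mask
  rec <- mark_stage(rec, "amplitude_rejected")
  list(rec = rec, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> threshold %g uV, max fraction %.2f%%, mean %.2f%%\n",
              x$threshold_uv, 100 * max(x$fraction_rejected),
              100 * mean(x$fraction_rejected)))
  invisible(x)
}

# deterministic symmetric FastICA (logcosh contrast) on whitened data
# maxit note: with many components only the truly non-Gaussian
# (artifact) directions stabilize; the Gaussian bulk rotates forever, so
# the diagonal criterion rarely fires and maxit is the effective cost.
# 80 iterations are ample for the artifact directions.
fastica_core <- function(Z, n_comp, maxit = 80, tol = 1e-4, seed = 1) {
  W <- with_seed(seed, matrix(stats::rnorm(n_comp * n_comp), n_comp))
  sym_decorr <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12))) %*%
      t(e$vectors) %*% W
  }
  W <- sym_decorr(W)
  n <- ncol(Z)
  for (it in seq_len(maxit)) {
    G <- tanh(W %*% Z)
    gp <- rowMeans(1 - G^2)
    W1 <- tcrossprod(G, Z) / n - gp * W
    W1 <- sym_decorr(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  W
}

#' ICA-based removal of ocular and residual cardiac artifacts
#'
#' Decomposes the scalp channels into `n_components` independent
#' components (deterministic FastICA with log-cosh contrast), scores each
#' component against automatic rules, zeroes the flagged ones and
#' remixes. Rules: absolute correlation of the component time course with
#' the blink reference (mean of frontopolar channels) or with the ECG
#' channel above `cor_thresh`; or a frontally focal topography
#' (top-2 mixing weight share above `focal_share` on frontal channels)
#' combined with moderate blink correlation.
#'
#' @param rec a `recording`; the ECG channel is excluded from the
#'   decomposition but used as an artifact reference.
#' @param n_components number of components (63).
#' @param cor_thresh artifact-correlation threshold (0.7).
#' @param focal_share top-2 weight share defining a focal topography.
#' @param fit_subsample fit the unmixing on every k-th clean sample.
#' @param seed RNG seed for the FastICA initialization.
#' @return list `rec` (cleaned, stage `"ica_cleaned"`) and
#'   `decomposition` (an `ica_decomposition`).
#' @export
ica_clean <- function(rec, n_components = 63, cor_thresh = 0.7,
                      focal_share = 0.8, fit_subsample = 2, seed = 1) {
  assert_gradient_done(rec, "ica_clean")
  assert_bcg_done(rec, "ica_clean")
  scalp <- which(rec$channel_labels != "ECG")
  if (length(scalp) < n_components)
    stop("rank of the scalp data (", length(scalp),
         ") is below n_components = ", n_components,
         "; use fewer components")
  D <- rec$data[scalp, , drop = FALSE]
  mu <- rowMeans(D)
  Dc <- D - mu
  fit_cols <- seq(1, ncol(Dc), by = fit_subsample)
  if (!is.null(rec$rejected)) {
    good <- !apply(rec$rejected[scalp, fit_cols, drop = FALSE], 2, any)
    fit_cols <- fit_cols[good]
  }
  Zfit <- Dc[, fit_cols, drop = FALSE]
  C <- Zfit %*% t(Zfit) / ncol(Zfit)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[n_components] < 1e-10 * e$values[1])
    stop("data are rank deficient for ", n_components,
         " components; use fewer components")
  K <- diag(1 / sqrt(e$values[seq_len(n_components)])) %*%
    t(e$vectors[, seq_len(n_components), drop = FALSE])
  W <- fastica_core(K %*% Zfit, n_components, seed = seed)
  unmix <- W %*% K                             # components x channels
  S <- unmix %*% Dc                            # component time courses
  mix <- e$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(e$values[seq_len(n_components)])) %*% t(W)

  # ---- component scoring ----
  fp <- grepl("^Fp", rec$channel_labels[scalp])
  blink_ref <- if (any(fp)) colMeans(D[fp, , drop = FALSE]) else NULL
  ecg_i <- match("ECG", rec$channel_labels)
  ecg_ref <- if (!is.na(ecg_i)) rec$data[ecg_i, ] else NULL
  abs_cor <- function(ref) if (is.null(ref) || stats::sd(ref) == 0)
    rep(0, n_components) else abs(as.numeric(stats::cor(t(S), ref)))
  blink_cor <- abs_cor(blink_ref)
  ecg_cor <- abs_cor(ecg_ref)
  frontal <- grepl("^(Fp|AF|F)[0-9z]*$", rec$channel_labels[scalp])
  focality <- apply(mix, 2, function(m) {
    a <- abs(m)
    o <- order(a, decreasing = TRUE)[1:2]
    list(share = sum(a[o]) / sum(a), frontal = all(frontal[o]))
  })
  share <- vapply(focality, `[[`, 0, "share")
  focal_frontal <- vapply(focality, `[[`, TRUE, "frontal")
  flagged <- blink_cor > cor_thresh | ecg_cor > cor_thresh |
    (share > focal_share & focal_frontal & blink_cor > 0.3)

  keep <- !flagged
  cleaned <- mix[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] + mu
  rec$data[scalp, ] <- cleaned
  decomposition <- structure(
    list(unmixing = unmix, mixing = mix, n_components = n_components,
         scores = data.frame(component = seq_len(n_components),
                             blink_cor = blink_cor, ecg_cor = ecg_cor,
                             focal_share = share,
                             flagged = flagged)),
    class = "ica_decomposition")
  rec <- mark_stage(rec, "ica_cleaned")
  list(rec = rec, decomposition = decomposition)
}

# spherical spline basis g(cos gamma) (Perrin-style), order m, N terms
spline_g <- function(cosang, m = 4, n_terms = 50) {
  out <- array(0, dim(as.array(cosang)))
  x <- as.numeric(cosang)
  Pm1 <- rep(1, length(x))
  P <- x
  acc <- (2 * 1 + 1) / (1 * 2)^m * P
  for (n in 2:n_terms) {
    Pn <- ((2 * n - 1) * x * P - (n - 1) * Pm1) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * Pn
    Pm1 <- P; P <- Pn
  }
  array(acc / (4 * pi), dim(as.array(cosang)))
}

#' Spherical-spline interpolation of scalp potentials
#'
#' Perrin-style spherical splines (order `m = 4`) fitted to the source
#' electrodes, evaluated at target positions.
#'
#' @param values channels x samples matrix (or vector) at `from`.
#' @param from,to `electrode_set` objects (or position matrices).
#' @param m spline order.
#' @param lambda ridge regularization added to the spline system.
#' @return matrix targets x samples of interpolated values.
#' @export
spherical_spline_interpolate <- function(values, from, to, m = 4,
                                         lambda = 1e-5) {
  P <- if (inherits(from, "electrode_set")) from$positions_mm else from
  Q <- if (inherits(to, "electrode_set")) to$positions_mm else to
  if (is.null(dim(Q))) Q <- matrix(Q, 1)
  V <- if (is.null(dim(values))) matrix(values, ncol = 1) else values
  Pu <- P / sqrt(rowSums(P^2))
  Qu <- Q / sqrt(rowSums(Q^2))
  ne <- nrow(Pu)
  G <- spline_g(Pu %*% t(Pu), m = m)
  A <- rbind(cbind(G + diag(lambda, ne), rep(1, ne)),
             c(rep(1, ne), 0))
  sol <- solve(A, rbind(V, 0))
  Gt <- spline_g(Qu %*% t(Pu), m = m)
  Gt %*% sol[seq_len(ne), , drop = FALSE] +
    matrix(sol[ne + 1, ], nrow(Qu), ncol(V), byrow = TRUE)
}

#' Average reference and AFz/FCz pseudo-electrodes
#'
#' Synthesizes the reference and ground positions (AFz, FCz) by
#' spherical-spline interpolation from the 63 scalp channels, appends
#' them, then re-references all 65 scalp channels to their instantaneous
#' average.
#'
#' @param rec a `recording` with 63 scalp channels (ECG is dropped here;
#'   it has served its purpose).
#' @param positions an `electrode_set` covering the scalp channels.
#' @param targets labels of the pseudo-electrodes to synthesize.
#' @return a 65-channel average-referenced `recording`
#'   (stage `"rereferenced"`).
#' @export
rereference_and_interpolate <- function(rec, positions,
                                        targets = c("AFz", "FCz")) {
  assert_gradient_done(rec, "rereference_and_interpolate")
  assert_bcg_done(rec, "rereference_and_interpolate")
  scalp <- which(rec$channel_labels != "ECG")
  idx <- match(rec$channel_labels[scalp], positions$labels)
  if (anyNA(idx))
    stop("positions missing for: ",
         paste(rec$channel_labels[scalp][is.na(idx)], collapse = ", "))
  full <- standard_montage(include_pseudo = TRUE)
  tpos <- full$positions_mm[match(targets, full$labels), , drop = FALSE]
  interp <- spherical_spline_interpolate(rec$data[scalp, , drop = FALSE],
                                         positions$positions_mm[idx, ],
                                         tpos)
  data <- rbind(rec$data[scalp, , drop = FALSE], interp)
  labels <- c(rec$channel_labels[scalp], targets)
  data <- sweep(data, 2, colMeans(data))
  out <- new_recording(data, labels, rec$sampling_rate_hz, rec$markers,
                       reference = "average")
  if (!is.null(rec$rejected)) {
    out$rejected <- rbind(rec$rejected[scalp, , drop = FALSE],
                          matrix(FALSE, length(targets), ncol(data)))
  }
  out$pipeline <- c(pipeline_history(rec), "rereferenced")
  out
}
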