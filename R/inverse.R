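# Noise covariance, weighted minimum-norm inverse with noise-based
# normalization, and source-level contrast maps.

#' Estimate the sensor noise covariance from pre-stimulus data
#'
#' Sample covariance over the concatenated pre-stimulus samples of all
#' segments, with light diagonal loading for conditioning.
#'
#' @param segments a `segments` object (e.g. -2000..+1000 ms trials).
#' @param window_ms pre-stimulus window (default -2000..0 ms).
#' @param diag_load fraction of the mean diagonal added to the diagonal.
#' @return a `noise_cov`: list with `matrix` (channels x channels),
#'   `window_ms`, `n_samples`.
#' @export
estimate_noise_cov <- function(segments, window_ms = c(-2000, 0),
                               diag_load = 1e-3) {
  sel <- segments$times_ms >= window_ms[1] & segments$times_ms <= window_ms[2]
  if (!any(sel)) stop("noise window outside segments")
  d <- segments$data[, , sel, drop = FALSE]
  nch <- dim(d)[2]
  X <- matrix(aperm(d, c(2, 3, 1)), nrow = nch)   # channels x (time*trials)
  X <- X - rowMeans(X)
  C <- X %*% t(X) / ncol(X)
  C <- (C + t(C)) / 2
  C <- C + diag(diag_load * mean(diag(C)), nch)
  structure(list(matrix = C, window_ms = window_ms, n_samples = ncol(X),
                 channel_labels = segments$channel_labels),
            class = "noise_cov")
}

#' Build a weighted minimum-norm inverse operator
#'
#' Kernel `M = R L' (L R L' + lambda^2 C)^-1` with
#' `lambda^2 = trace(L R L') / (trace(C) snr^2)`; the noise-normalized
#' estimate divides each source by `sqrt((M C M')_ii)` so values are in
#' units of their predicted noise s.d.
#'
#' @param leadfield a `leadfield` (oriented: one column per source).
#' @param noise_cov a `noise_cov` (or plain matrix) matching the
#'   leadfield channels.
#' @param snr assumed amplitude SNR (default 5).
#' @param depth_weight depth-weighting exponent gamma: source weights
#'   `R_ii = ||L_i||^(-2 gamma)` (default 0.5, "weighted" minimum norm;
#'   0 disables).
#' @return an `inverse_operator`: `kernel` (sources x channels),
#'   `noise_norm`, `lambda2`, `snr`, `trace_fraction` (share of the
#'   regularization term in the Gram trace), `R_weights`.
#' @export
build_inverse <- function(leadfield, noise_cov, snr = 5,
                          depth_weight = 0.5) {
  L <- if (inherits(leadfield, "leadfield")) leadfield$matrix else leadfield
  C <- if (inherits(noise_cov, "noise_cov")) noise_cov$matrix else noise_cov
  if (nrow(L) != nrow(C))
    stop("leadfield (", nrow(L), " channels) and noise covariance (",
         nrow(C), ") disagree")
  cn <- sqrt(colSums(L^2))
  if (any(cn == 0)) stop("leadfield contains all-zero columns")
  R <- cn^(-2 * depth_weight)
  LRLt <- L %*% (R * t(L))
  lambda2 <- sum(diag(LRLt)) / (sum(diag(C)) * snr^2)
  G <- LRLt + lambda2 * C
  Gi <- tryCatch(solve(G), error = function(e)
    stop("Gram matrix is singular; increase snr-based regularization ",
         "(lambda must be > 0): ", conditionMessage(e)))
  M <- (R * t(L)) %*% Gi
  MC <- M %*% C
  noise_norm <- sqrt(pmax(rowSums(MC * M), 1e-300))
  structure(list(kernel = M, noise_norm = noise_norm, lambda2 = lambda2,
                 snr = snr, R_weights = R,
                 trace_fraction = lambda2 * sum(diag(C)) / sum(diag(G)),
                 channel_labels = if (inherits(leadfield, "leadfield"))
                   leadfield$channel_labels else NULL),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %d sources x %d channels, snr=%g, lambda2=%.3g (%.2f%% of Gram trace)\n",
              nrow(x$kernel), ncol(x$kernel), x$snr, x$lambda2,
              100 * x$trace_fraction))
  invisible(x)
}

#' Apply an inverse operator
#'
#' @param inv an `inverse_operator`.
#' @param y channels x time matrix (or vector).
#' @param noise_normalize divide each source by its predicted noise s.d.
#' @return sources x time matrix.
#' @export
apply_inverse <- function(inv, y, noise_normalize = TRUE) {
  Y <- if (is.null(dim(y))) matrix(y, ncol = 1) else y
  S <- inv$kernel %*% Y
  if (noise_normalize) S <- S / inv$noise_norm
  S
}

#' Source-level induced-alpha contrast map
#'
#' Projects each trial segment through the (noise-normalized) inverse,
#' computes baseline-corrected STFFT alpha power per vertex in the
#' analysis window, and tests per vertex across trials:
#' `"AV_vs_baseline"` (one-sample t over audiovisual trials) or
#' `"CON_vs_INC"` (two-sample t).
#'
#' @param inv an `inverse_operator`.
#' @param segments a `segments` object whose channels match the kernel.
#' @param band_hz alpha band.
#' @param window_ms analysis window (STFFT windows whose centers fall
#'   inside it are averaged).
#' @param baseline_ms STFFT baseline window.
#' @param contrast `"AV_vs_baseline"` or `"CON_vs_INC"`.
#' @param p_thresh significance threshold stored with the map.
#' @return a `source_stat_map`: `data.frame` per vertex (`t`, `p`,
#'   `mean`), plus attributes carrying window/band.
#' @export
source_contrast_map <- function(inv, segments, band_hz = c(8, 13),
                                window_ms = c(200, 400),
                                baseline_ms = c(-2000, 0),
                                contrast = c("AV_vs_baseline",
                                             "CON_vs_INC"),
                                p_thresh = 0.05) {
  contrast <- match.arg(contrast)
  vals <- source_trial_alpha(inv, segments, band_hz, window_ms,
                             baseline_ms)       # trials x vertices
  info <- segments$trial_info
  if (contrast == "AV_vs_baseline") {
    sel <- info$modality == "audiovisual"
    if (sum(sel) < 2) sel <- rep(TRUE, nrow(info))
    v <- vals[sel, , drop = FALSE]
    stat <- apply(v, 2, function(x) {
      r <- stats::t.test(x)
      c(r$statistic, r$p.value, mean(x))
    })
  } else {
    g <- info$congruence
    if (sum(g == "CON") < 2 || sum(g == "INC") < 2)
      stop("CON_vs_INC needs >= 2 trials per condition")
    stat <- apply(vals, 2, function(x) {
      r <- stats::t.test(x[g == "CON"], x[g == "INC"])
      c(r$statistic, r$p.value, mean(x[g == "CON"]) - mean(x[g == "INC"]))
    })
  }
  out <- data.frame(vertex = seq_len(ncol(vals)), t = stat[1, ],
                    p = stat[2, ], mean = stat[3, ])
  structure(list(table = out, contrast = contrast, band_hz = band_hz,
                 window_ms = window_ms, p_thresh = p_thresh),
            class = "source_stat_map")
}

# trials x vertices matrix of baseline-corrected induced alpha power at
# the source level (STFFT per vertex time course)
source_trial_alpha <- function(inv, segments, band_hz = c(8, 13),
                               window_ms = c(200, 400),
                               baseline_ms = c(-2000, 0),
                               vertices = NULL, weights = NULL) {
  K <- inv$kernel / inv$noise_norm
  if (!is.null(vertices)) K <- K[vertices, , drop = FALSE]
  nt <- dim(segments$data)[1]
  out <- matrix(NA_real_, nt, nrow(K))
  for (tr in seq_len(nt)) {
    src <- K %*% segments$data[tr, , ]
    bp <- stfft_power(src, segments$fs, times_ms = segments$times_ms,
                      band_hz = band_hz, baseline_ms = baseline_ms)
    centers <- attr(bp, "centers_ms")
    wsel <- centers >= window_ms[1] & centers <= window_ms[2]
    if (!any(wsel)) stop("no STFFT window centered inside ",
                         window_ms[1], "..", window_ms[2], " ms")
    out[tr, ] <- rowMeans(bp[, wsel, drop = FALSE])
  }
  if (!is.null(weights)) out <- out %*% (weights / sum(weights))
  out
}
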