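# EEG-informed fMRI: POI definition, single-trial POI alpha, trial
# scoring, HRF regressors, minimal BOLD preprocessing, voxelwise GLM and
# Monte-Carlo cluster thresholding.

#' Canonical double-gamma hemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, undershoot ratio 1/6, normalized to
#' unit peak.
#'
#' @param t_s time in seconds (vector).
#' @return HRF values.
#' @export
hrf_double_gamma <- function(t_s) {
  h <- stats::dgamma(t_s, shape = 6, rate = 1) -
    stats::dgamma(t_s, shape = 16, rate = 1) / 6
  h[t_s < 0] <- 0
  h / max(stats::dgamma(seq(0, 30, by = 0.001), shape = 6, rate = 1) -
            stats::dgamma(seq(0, 30, by = 0.001), shape = 16, rate = 1) / 6)
}

# event-amplitude stick function convolved with the HRF on a dt grid,
# decimated to the TR grid (volume onsets at (k-1)*tr)
hrf_regressor <- function(onsets_s, amplitudes, tr_s, n_volumes,
                          dt = 0.01) {
  stopifnot(length(onsets_s) == length(amplitudes))
  total <- n_volumes * tr_s
  ngrid <- ceiling(total / dt) + 1
  stick <- numeric(ngrid)
  gi <- round(onsets_s / dt) + 1
  keep <- gi >= 1 & gi <= ngrid
  for (k in which(keep)) stick[gi[k]] <- stick[gi[k]] + amplitudes[k]
  h <- hrf_double_gamma(seq(0, 60, by = dt))   # undershoot tail < 1e-10 by 60 s
  conv <- stats::convolve(stick, rev(h), type = "open")[seq_len(ngrid)]
  conv[round((seq_len(n_volumes) - 1) * tr_s / dt) + 1]
}

#' Build the single-trial alpha regressor
#'
#' A stick function at stimulus onsets scaled by each trial's alpha
#' value (zero outside events), convolved with the canonical double-gamma
#' HRF at 10 ms resolution and decimated to the TR grid.
#'
#' @param trial_values per-trial alpha values (one per stimulus marker).
#' @param markers marker table with the stimulus events.
#' @param tr_s repetition time.
#' @param n_volumes number of volumes the column must span.
#' @param eeg_rate_hz rate in which marker onsets are expressed.
#' @return numeric column of length `n_volumes`.
#' @export
build_alpha_regressor <- function(trial_values, markers, tr_s, n_volumes,
                                  eeg_rate_hz) {
  st <- markers[markers$kind == "stimulus", , drop = FALSE]
  stopifnot(nrow(st) == length(trial_values))
  hrf_regressor(st$onset_sample / eeg_rate_hz, trial_values, tr_s,
                n_volumes)
}

#' Assemble a design matrix on the TR grid
#'
#' @param columns named list of numeric columns (equal length).
#' @param drop_empty drop all-zero columns instead of failing.
#' @return a `design_matrix`: matrix with named columns, intercept first.
#' @export
design_matrix <- function(columns, drop_empty = FALSE) {
  X <- do.call(cbind, columns)
  colnames(X) <- names(columns)
  zero <- apply(X, 2, function(c) all(c == 0))
  if (any(zero)) {
    if (drop_empty) X <- X[, !zero, drop = FALSE]
    else stop("all-zero design column(s): ",
              paste(colnames(X)[zero], collapse = ", "))
  }
  X <- cbind(intercept = 1, X)
  class(X) <- c("design_matrix", class(X))
  X
}

#' Score trials for GLM inclusion and the confound predictor
#'
#' Auditory, visual and congruent audiovisual trials require a correct
#' response; incongruent trials require any response (irrespective of
#' correctness); omitted and incorrect non-INC trials form the confound
#' set.
#'
#' @param trials a `trial_table` with correctness filled in.
#' @return list `trials` (with `included` and `confound` logicals) and
#'   `summary` (see [behavior_summary()]).
#' @export
score_trials <- function(trials) {
  omitted <- trials$correctness == "omitted"
  inc <- trials$congruence == "INC"
  correct <- trials$correctness == "correct"
  trials$included <- ifelse(inc, !omitted, correct & !omitted)
  trials$confound <- !trials$included
  list(trials = trials, summary = behavior_summary(trials))
}

#' Extract single-trial POI alpha values
#'
#' Each trial's sensor segment is projected through the noise-normalized
#' inverse kernel restricted to the POI vertices; baseline-corrected
#' STFFT alpha power in the analysis window is averaged over vertices
#' with the POI weights.
#'
#' @param inv an `inverse_operator`.
#' @param segments a `segments` object.
#' @param poi a `poi` (see [define_poi()]).
#' @param window_ms analysis window (default 200-400 ms).
#' @param baseline_ms STFFT baseline.
#' @param band_hz alpha band.
#' @return numeric vector, one alpha value per segment trial.
#' @export
poi_alpha_timecourse <- function(inv, segments, poi,
                                 window_ms = c(200, 400),
                                 baseline_ms = c(-2000, 0),
                                 band_hz = c(8, 13)) {
  as.numeric(source_trial_alpha(inv, segments, band_hz, window_ms,
                                baseline_ms, vertices = poi$vertices,
                                weights = poi$weights))
}

#' Define patches of interest from a source statistic map
#'
#' Contiguous supra-threshold vertex clusters (adjacency = source-space
#' neighbours within `1.5 x` the typical edge length); the largest
#' cluster per hemisphere is returned, weights proportional to |t| and
#' normalized to sum 1.
#'
#' @param map a `source_stat_map`.
#' @param src the `source_space` the map lives on.
#' @param p_thresh voxelwise p threshold (default the map's).
#' @param sign restrict to `"neg"`, `"pos"` or `"any"` t values.
#' @param min_extent minimum cluster size in vertices.
#' @return list of `poi` objects (fields `vertices`, `weights`,
#'   `label`), largest first.
#' @export
define_poi <- function(map, src, p_thresh = NULL,
                       sign = c("any", "neg", "pos"), min_extent = 2) {
  sign <- match.arg(sign)
  if (is.null(p_thresh)) p_thresh <- map$p_thresh
  tb <- map$table
  supra <- tb$p < p_thresh
  if (sign == "neg") supra <- supra & tb$t < 0
  if (sign == "pos") supra <- supra & tb$t > 0
  idx <- which(supra)
  if (length(idx) == 0)
    stop("no supra-threshold vertex at p < ", p_thresh,
         "; relax the threshold or check the contrast")
  v <- src$vertices_mm[idx, , drop = FALSE]
  dthr <- 1.6 * src$edge_length_mm
  comp <- if (length(idx) == 1) {
    list(membership = 1, csize = 1)
  } else {
    dd <- as.matrix(stats::dist(v))
    adj <- which(dd < dthr & upper.tri(dd), arr.ind = TRUE)
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (nrow(adj) > 0) g <- igraph::add_edges(g, t(adj))
    igraph::components(g)
  }
  pois <- list()
  for (ci in order(comp$csize, decreasing = TRUE)) {
    members <- idx[comp$membership == ci]
    if (length(members) < min_extent) next
    w <- abs(tb$t[members])
    centroid <- colMeans(src$vertices_mm[members, , drop = FALSE])
    hemi <- if (centroid[1] < -2) "lh" else if (centroid[1] > 2) "rh"
      else "bilateral"
    region <- if (centroid[2] < 0) "occipital" else "prefrontal"
    pois[[length(pois) + 1]] <- structure(
      list(vertices = members, weights = w / sum(w),
           label = paste(hemi, region), centroid_mm = centroid),
      class = "poi")
  }
  if (length(pois) == 0)
    stop("no cluster reaches min_extent = ", min_extent)
  pois
}

# separable 3D Gaussian smoothing with edge renormalization (a constant
# volume stays constant everywhere)
gauss_smooth_3d <- function(a, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half):half)^2 / (2 * s^2))
    a <- convolve_axis(a, k, ax)
  }
  a
}

convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  half <- (length(k) - 1) / 2
  n <- dp[1]
  out <- matrix(0, n, ncol(m))
  norm <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - half - 1
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], , drop = FALSE]
    norm[ok] <- norm[ok] + k[j]
  }
  out <- out / norm
  ap <- array(out, dp)
  aperm(ap, order(perm))
}

#' Minimal BOLD preprocessing
#'
#' Discards the first two volumes, smooths each volume with a 3D
#' Gaussian kernel of the stated FWHM, then removes per voxel a linear
#' trend and discrete-cosine low-frequency drift up to `highpass_cutoff_s`.
#'
#' @param vol a `volume_series`.
#' @param fwhm_mm smoothing kernel FWHM (mm); 0 disables.
#' @param highpass_cutoff_s drop fluctuations slower than this period.
#' @param n_discard leading volumes to discard (default 2).
#' @return the preprocessed `volume_series`.
#' @export
preprocess_bold_minimal <- function(vol, fwhm_mm = 4,
                                    highpass_cutoff_s = 128,
                                    n_discard = 2) {
  d <- dim(vol$data)
  if (d[4] <= n_discard) stop("not enough volumes")
  data <- vol$data[, , , (n_discard + 1):d[4], drop = FALSE]
  nt <- dim(data)[4]
  vox_mm <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vox_mm
  if (fwhm_mm > 0) {
    for (t in seq_len(nt))
      data[, , , t] <- gauss_smooth_3d(data[, , , t], sigma_vox)
  }
  # high-pass: project out intercept, linear trend and DCT drift basis
  tv <- seq_len(nt)
  n_dct <- max(0, floor(2 * nt * vol$tr_s / highpass_cutoff_s))
  B <- cbind(1, tv - mean(tv))
  if (n_dct > 0) {
    for (kk in seq_len(n_dct))
      B <- cbind(B, cos(pi * kk * (tv - 0.5) / nt))
  }
  Y <- matrix(data, ncol = nt)                    # voxels x time
  fit <- Y %*% B %*% solve(crossprod(B)) %*% t(B)
  resid <- Y - fit
  # keep the voxel mean so the series stays interpretable
  resid <- resid + rowMeans(Y)
  out <- vol
  out$data <- array(resid, dim(data))
  out$n_discarded_leading <- vol$n_discarded_leading + as.integer(n_discard)
  out
}

#' Voxelwise GLM
#'
#' Ordinary least squares per voxel; for each named contrast returns
#' beta, t and the equivalent partial correlation
#' `r = t / sqrt(t^2 + df)`.
#'
#' @param vol a preprocessed `volume_series`.
#' @param X a `design_matrix` (rows = volumes).
#' @param contrasts named list of contrast vectors over the columns of
#'   `X`; default: one indicator contrast per non-intercept column.
#' @return list of `stat_volume` objects (fields `beta`, `t`, `r` 3D
#'   arrays, `df`, `contrast`).
#' @export
fit_glm <- function(vol, X, contrasts = NULL) {
  d <- dim(vol$data)
  nt <- d[4]
  if (nrow(X) != nt)
    stop("design has ", nrow(X), " rows but the series has ", nt,
         " volumes")
  if (is.null(contrasts)) {
    cn <- colnames(X)
    contrasts <- lapply(which(cn != "intercept"), function(i) {
      v <- numeric(ncol(X)); v[i] <- 1; v
    })
    names(contrasts) <- cn[cn != "intercept"]
  }
  Y <- t(matrix(vol$data, ncol = nt))             # time x voxels
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)                   # p x voxels
  resid <- Y - X %*% B
  df <- nt - qr(X)$rank
  sigma2 <- colSums(resid^2) / df
  out <- lapply(names(contrasts), function(nm) {
    cvec <- contrasts[[nm]]
    cb <- as.numeric(cvec %*% B)
    se <- sqrt(sigma2 * as.numeric(t(cvec) %*% XtXi %*% cvec))
    tt <- cb / se
    rr <- tt / sqrt(tt^2 + df)
    structure(list(beta = array(cb, d[1:3]), t = array(tt, d[1:3]),
                   r = array(rr, d[1:3]), df = df, contrast = nm),
              class = "stat_volume")
  })
  names(out) <- names(contrasts)
  out
}

# connected components of a logical 3D mask (face connectivity)
cluster_sizes_3d <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0) return(integer())
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1) * d[1] * d[2] + (pos[, 2] - 1) * d[1] + pos[, 1]
  lut <- integer(prod(d))
  lut[key] <- seq_along(idx)
  edges <- NULL
  for (ax in 1:3) {
    shift <- pos
    shift[, ax] <- shift[, ax] + 1
    ok <- shift[, ax] <= d[ax]
    k2 <- (shift[ok, 3] - 1) * d[1] * d[2] + (shift[ok, 2] - 1) * d[1] +
      shift[ok, 1]
    nb <- lut[k2]
    hit <- nb > 0
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$csize
}

#' Monte-Carlo cluster-extent threshold
#'
#' Simulates Gaussian noise volumes (optionally smoothed to the stated
#' FWHM and re-standardized), thresholds voxelwise at `voxel_p`
#' (two-sided) and records the maximum cluster size; the minimum cluster
#' size controlling family-wise error is the 95th percentile of that
#' null distribution plus one.
#'
#' @param grid volume dimensions.
#' @param voxel_p voxelwise threshold (must be < 1).
#' @param fwhm_mm assumed smoothness; 0 = independent voxels.
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param voxel_mm voxel size for the FWHM conversion.
#' @param alpha family-wise error level of the cluster threshold.
#' @param seed RNG seed.
#' @return a `cluster_threshold`: `min_cluster_size`, `voxel_p`,
#'   `n_iter`, `fwhm_mm`, `null_max_sizes`.
#' @export
cluster_threshold_mc <- function(grid, voxel_p = 0.05, fwhm_mm = 0,
                                 n_iter = 10000, voxel_mm = 3,
                                 alpha = 0.05, seed = 1) {
  if (voxel_p >= 1 || voxel_p <= 0)
    stop("voxel_p must lie strictly between 0 and 1")
  zc <- stats::qnorm(1 - voxel_p / 2)
  sigma_vox <- rep((fwhm_mm / (2 * sqrt(2 * log(2)))) / voxel_mm, 3)
  max_sizes <- with_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      z <- array(stats::rnorm(prod(grid)), grid)
      if (fwhm_mm > 0) {
        z <- gauss_smooth_3d(z, sigma_vox)
        z <- z / stats::sd(z)
      }
      cs <- cluster_sizes_3d(abs(z) > zc)
      if (length(cs) == 0) 0L else as.integer(max(cs))
    }, 0L)
  })
  structure(list(
    min_cluster_size = as.integer(
      stats::quantile(max_sizes, 1 - alpha, type = 1) + 1),
    voxel_p = voxel_p, n_iter = n_iter, fwhm_mm = fwhm_mm,
    alpha = alpha, null_max_sizes = max_sizes),
    class = "cluster_threshold")
}

#' Couple a POI alpha regressor to the BOLD series
#'
#' Fits the GLM with the alpha column (plus optional confound columns)
#' and returns the alpha contrast's stat volume, optionally with
#' cluster-extent thresholding applied.
#'
#' @param alpha_column TR-gridded HRF-convolved alpha regressor.
#' @param vol preprocessed `volume_series` with matching volume count.
#' @param confounds optional named list of confound columns.
#' @param cluster_thresh optional `cluster_threshold` to apply.
#' @param voxel_p voxel threshold used with `cluster_thresh`.
#' @return a `stat_volume` for the alpha regressor; if thresholded, an
#'   extra logical array `$signif` marks surviving voxels.
#' @export
couple <- function(alpha_column, vol, confounds = NULL,
                   cluster_thresh = NULL, voxel_p = 0.05) {
  cols <- c(list(alpha = alpha_column), confounds)
  X <- design_matrix(cols)
  cvec <- numeric(ncol(X)); cvec[colnames(X) == "alpha"] <- 1
  sv <- fit_glm(vol, X, contrasts = list(alpha = cvec))$alpha
  if (!is.null(cluster_thresh)) {
    df <- sv$df
    tc <- stats::qt(1 - voxel_p / 2, df)
    supra <- abs(sv$t) > tc
    sig <- array(FALSE, dim(supra))
    idx <- which(supra)
    if (length(idx) > 0) {
      comp <- cluster_components_3d(supra)
      keep <- comp$csize[comp$membership] >= cluster_thresh$min_cluster_size
      sig[idx[keep]] <- TRUE
    }
    sv$signif <- sig
    sv$cluster_threshold <- cluster_thresh$min_cluster_size
  }
  sv
}

# like cluster_sizes_3d but returning membership for the supra voxels
cluster_components_3d <- function(mask) {
  idx <- which(mask)
  d <- dim(mask)
  pos <- arrayInd(idx, d)
  lut <- integer(prod(d))
  key <- (pos[, 3] - 1) * d[1] * d[2] + (pos[, 2] - 1) * d[1] + pos[, 1]
  lut[key] <- seq_along(idx)
  edges <- NULL
  for (ax in 1:3) {
    shift <- pos
    shift[, ax] <- shift[, ax] + 1
    ok <- shift[, ax] <= d[ax]
    k2 <- (shift[ok, 3] - 1) * d[1] * d[2] + (shift[ok, 2] - 1) * d[1] +
      shift[ok, 1]
    nb <- lut[k2]
    hit <- nb > 0
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], nb[hit]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  igraph::components(g)
}
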