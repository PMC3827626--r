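# coupling: POI definition, single-trial POI alpha, trial scoring, HRF
# regressors, BOLD preprocessing, GLM, Monte-Carlo cluster threshold.

test_that("POI definition finds constructed blobs and errors sensibly", {
  hm <- head_model()
  src <- source_space(hm, n_per_hemisphere = 100)
  tb <- data.frame(vertex = seq_len(200), t = 0, p = 1, mean = 0)
  occ <- source_patch(src, occ_center, 25)
  fro <- source_patch(src, frontal_center, 20)
  tb$t[occ] <- -6; tb$p[occ] <- 1e-4
  tb$t[fro] <- 5; tb$p[fro] <- 1e-3
  map <- structure(list(table = tb, contrast = "AV_vs_baseline",
                        band_hz = c(8, 13), window_ms = c(200, 400),
                        p_thresh = 0.05), class = "source_stat_map")
  pois <- define_poi(map, src)
  expect_gte(length(pois), 2)
  got <- unlist(lapply(pois, function(p) p$vertices))
  expect_setequal(got, c(occ, fro))
  labs <- vapply(pois, function(p) p$label, "")
  expect_true(any(grepl("occipital", labs)))
  expect_true(any(grepl("prefrontal", labs)))
  for (p in pois) expect_equal(sum(p$weights), 1)
  # sign filter keeps only the negative blob
  pn <- define_poi(map, src, sign = "neg")
  expect_setequal(unlist(lapply(pn, function(p) p$vertices)), occ)
  # no supra-threshold vertex
  map0 <- map
  map0$table$p <- 1
  expect_error(define_poi(map0, src), "supra-threshold")
})

test_that("POI alpha values recover the simulated suppression", {
  sess <- default_session()
  ai <- analysis_inverse()
  seg <- cleaned_segments()
  m <- cached("map_av", function() source_contrast_map(ai$inv, seg))
  poi <- define_poi(m, ai$src, sign = "neg")[[1]]
  av <- cached("poi_alpha", function()
    poi_alpha_timecourse(ai$inv, seg, poi))
  tt <- stats::t.test(av, alternative = "less")
  expect_lt(tt$p.value, 0.01)
  # degenerate one-vertex POI equals that vertex's own time course power
  poi1 <- structure(list(vertices = poi$vertices[1], weights = 1,
                         label = "one"), class = "poi")
  a1 <- poi_alpha_timecourse(ai$inv, seg, poi1)
  direct <- alphacouple:::source_trial_alpha(ai$inv, seg,
                                             vertices = poi$vertices[1])
  expect_equal(a1, as.numeric(direct), tolerance = 1e-12)
})

test_that("no-effect simulation yields POI alpha indistinguishable from zero", {
  sess0 <- cached("session_null", function()
    simulate_session(seed = 5, suppression_depth = 0,
                     con_frontal_gain = 0))
  cl0 <- clean_session(sess0$recording)
  seg0 <- segment_trials(cl0$rec, trials = sess0$paradigm$trials)
  ai <- analysis_inverse()
  inv0 <- build_inverse(ai$L, estimate_noise_cov(seg0), snr = 5)
  occ_v <- which(apply(ai$src$vertices_mm, 1, angle_deg, b = occ_center) < 30)
  poi <- structure(list(vertices = occ_v,
                        weights = rep(1 / length(occ_v), length(occ_v)),
                        label = "occ"), class = "poi")
  av <- poi_alpha_timecourse(inv0, seg0, poi)
  tstat <- mean(av) / (stats::sd(av) / sqrt(length(av)))
  expect_lt(abs(tstat), 2)
})

test_that("trial scoring implements the inclusion and confound rules", {
  mk <- new_markers(onset_sample = (1:6) * 1000, kind = "stimulus",
                    modality = c("auditory", "visual", "audiovisual",
                                 "audiovisual", "audiovisual", "visual"),
                    visual_emotion = c("none", "happy", "happy", "happy",
                                       "angry", "angry"),
                    auditory_emotion = c("angry", "none", "happy", "angry",
                                         "happy", "none"),
                    congruence = c("n/a", "n/a", "CON", "INC", "INC",
                                   "n/a"),
                    trial_id = 1:6)
  tr <- trials_from_markers(mk)
  tr$correctness <- c("correct", "incorrect", "incorrect", "incorrect",
                      "omitted", "correct")
  sc <- score_trials(tr)
  # auditory correct: in; visual incorrect: confound; CON incorrect:
  # confound; INC incorrect but responded: in; INC omitted: confound
  expect_equal(sc$trials$included, c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(sc$trials$confound, !sc$trials$included)
  expect_true(is.data.frame(sc$summary))
})

test_that("alpha regressor equals the closed-form HRF for a unit event", {
  tr_s <- 2
  nvol <- 40
  mk <- new_markers(onset_sample = 10 * 500, kind = "stimulus",
                    trial_id = 1L)
  col <- build_alpha_regressor(1, mk, tr_s, nvol, eeg_rate_hz = 500)
  tv <- (seq_len(nvol) - 1) * tr_s
  oracle <- hrf_double_gamma(tv - 10)
  expect_lt(max(abs(col - oracle)), 1e-9)
  # zero alpha values give a zero column
  expect_true(all(build_alpha_regressor(0, mk, tr_s, nvol, 500) == 0))
  # two events superpose
  mk2 <- new_markers(onset_sample = c(10, 30) * 500, kind = "stimulus",
                     trial_id = 1:2)
  col2 <- build_alpha_regressor(c(1, -0.5), mk2, tr_s, nvol, 500)
  oracle2 <- hrf_double_gamma(tv - 10) - 0.5 * hrf_double_gamma(tv - 30)
  expect_lt(max(abs(col2 - oracle2)), 1e-9)
})

test_that("BOLD preprocessing: smoothing preserves constants, discards 2 volumes", {
  with_seed_test(40, {
    vol <- new_volume_series(array(rnorm(10 * 10 * 6 * 12), c(10, 10, 6, 12)),
                             2, diag(c(3, 3, 3, 1)))
  })
  pp <- preprocess_bold_minimal(vol, fwhm_mm = 4, highpass_cutoff_s = 1e9)
  expect_equal(dim(pp$data)[4], 10)
  expect_equal(pp$n_discarded_leading, 2L)
  # spatially constant volumes stay spatially constant: the renormalized
  # smoothing kernel must not distort them, interior or edge
  sm <- vol
  for (t in 1:12) sm$data[, , , t] <- t * 1.5
  sm2 <- preprocess_bold_minimal(sm, fwhm_mm = 4)
  for (t in 1:10) {
    v <- sm2$data[, , , t]
    expect_lt(max(v) - min(v), 1e-9)
  }
})

test_that("GLM: exact betas, orthogonality, brute-force oracle", {
  with_seed_test(41, {
    nvol <- 60
    x <- rnorm(nvol)
    conf <- rnorm(nvol)
    X <- design_matrix(list(alpha = x, conf = conf))
    grid <- c(4, 4, 2)
    dat <- array(rnorm(prod(grid) * nvol, sd = 0.5), c(grid, nvol))
  })
  dat[1, 1, 1, ] <- 2 * x +
    with_seed_test(42, rnorm(nvol, sd = 1e-6))  # (tiny noise: finite t)
  # a voxel orthogonal to every design column: all betas 0
  with_seed_test(48, {
    orth <- rnorm(nvol)
  })
  Xfull <- cbind(1, x, conf)
  orth <- orth - Xfull %*% solve(crossprod(Xfull), crossprod(Xfull, orth))
  dat[2, 1, 1, ] <- orth
  vol <- new_volume_series(dat, 2)
  res <- fit_glm(vol, X)
  expect_equal(res$alpha$beta[1, 1, 1], 2, tolerance = 1e-6)
  expect_lt(abs(res$alpha$t[2, 1, 1]), 1e-6)
  # brute-force per-voxel normal-equation oracle
  Y <- matrix(vol$data, ncol = nvol)
  cvec <- as.numeric(colnames(X) == "alpha")
  for (v in c(2, 5, 9, 25)) {
    fit <- stats::lm.fit(X, Y[v, ])
    bb <- fit$coefficients
    s2 <- sum(fit$residuals^2) / (nvol - ncol(X))
    se <- sqrt(s2 * (t(cvec) %*% solve(crossprod(X)) %*% cvec))
    t_or <- (cvec %*% bb) / se
    expect_equal(as.numeric(res$alpha$t)[v], as.numeric(t_or),
                 tolerance = 1e-8)
  }
  # scaling equivariance: beta scales by 1/a, t unchanged
  X2 <- design_matrix(list(alpha = 3 * x, conf = conf))
  res2 <- fit_glm(vol, X2)
  expect_equal(res2$alpha$beta, res$alpha$beta / 3, tolerance = 1e-10)
  expect_equal(res2$alpha$t, res$alpha$t, tolerance = 1e-8)
  # adding an orthogonal confound leaves the alpha beta unchanged
  oc <- as.numeric(orth / sqrt(sum(orth^2)))
  X3 <- design_matrix(list(alpha = x, conf = conf, extra = oc))
  res3 <- fit_glm(vol, X3)
  expect_lt(max(abs(res3$alpha$beta[1, 1, 1] - res$alpha$beta[1, 1, 1])),
            1e-10)
  expect_error(design_matrix(list(a = rep(0, 10))), "all-zero")
})

test_that("Monte-Carlo cluster threshold matches brute-force re-simulation", {
  grid <- c(10, 10, 10)
  ct <- cluster_threshold_mc(grid, voxel_p = 0.05, fwhm_mm = 0,
                             n_iter = 2000, seed = 7)
  # flood_sizes (helper): independent recursive flood-fill labelling
  zc <- stats::qnorm(1 - 0.05 / 2)
  with_seed_test(43, {
    mx <- vapply(seq_len(2000), function(i) {
      z <- array(rnorm(prod(grid)), grid)
      s <- flood_sizes(abs(z) > zc)
      if (length(s) == 0) 0L else max(s)
    }, 0L)
  })
  brute <- as.integer(stats::quantile(mx, 0.95, type = 1) + 1)
  expect_lte(abs(ct$min_cluster_size - brute), 1)
  expect_error(cluster_threshold_mc(grid, voxel_p = 1), "between")
})

test_that("cluster threshold is non-decreasing in smoothness", {
  grid <- c(10, 10, 10)
  th <- vapply(c(0, 2, 4), function(f)
    cluster_threshold_mc(grid, fwhm_mm = f, n_iter = 1500,
                         voxel_mm = 3, seed = 8)$min_cluster_size, 0L)
  expect_true(all(diff(th) >= 0))
})

test_that("couple: noiseless negative coupling gives r = -1 in coupled voxels", {
  par <- build_paradigm(paradigm_spec(n_auditory = 0, n_visual = 0,
                                      n_audiovisual = 1, seed = 44), 500)
  alpha <- rep(-0.75, 12)
  spn <- coupling_sim_spec(grid = c(6, 6, 3), k = -2, noise_sd = 0,
                           drift_amp = 0, seed = 3)
  sim <- simulate_bold(par$markers, alpha, spn, par$total_duration_s, 2, 500)
  nvol <- dim(sim$vol$data)[4]
  with_seed_test(45, {
    sim$vol$data <- sim$vol$data +
      array(rnorm(length(sim$vol$data), sd = 1e-8), dim(sim$vol$data))
  })
  sv <- couple(sim$regressor, sim$vol)
  expect_lt(max(sv$r[spn$coupled_mask]), -0.999)
})

test_that("injected coupling is recovered through the cluster threshold", {
  # noise at 50% of the coupled-signal s.d.; >= 90% of coupled voxels
  # survive with negative sign, false positives at the voxel level <= p
  par <- build_paradigm(paradigm_spec(n_auditory = 1, n_visual = 1,
                                      n_audiovisual = 2, seed = 46), 500)
  b <- simulate_behavior(par, seed = 46)
  with_seed_test(46, {
    alpha <- -0.75 * (1 + 0.1 * rnorm(48))
  })
  sig_sd <- NULL
  hits <- fps <- numeric(0)
  ct <- cluster_threshold_mc(c(12, 12, 6), voxel_p = 0.05, fwhm_mm = 0,
                             n_iter = 500, seed = 9)
  for (run in 1:5) {
    sp <- coupling_sim_spec(grid = c(12, 12, 6), k = -2, noise_sd = 0,
                            drift_amp = 0, seed = run)
    probe <- simulate_bold(b$markers, alpha, sp, par$total_duration_s, 2,
                           500)
    if (is.null(sig_sd))
      sig_sd <- stats::sd(-2 * probe$regressor)
    sp$noise_sd <- 0.5 * sig_sd
    sim <- simulate_bold(b$markers, alpha, sp, par$total_duration_s, 2,
                         500)
    vol <- preprocess_bold_minimal(sim$vol, fwhm_mm = 0)
    reg <- sim$regressor[-(1:2)]
    sv <- couple(reg, vol, cluster_thresh = ct, voxel_p = 0.05)
    cm <- sp$coupled_mask
    hits <- c(hits, mean(sv$signif[cm] & sv$r[cm] < 0))
    df <- sv$df
    tc <- stats::qt(1 - 0.05 / 2, df)
    fps <- c(fps, mean(abs(sv$t[!cm]) > tc))
  }
  expect_gte(mean(hits), 0.9)
  expect_lte(mean(fps), 0.05 + 0.02)
})

test_that("null coupling stays under control through the cluster threshold", {
  par <- build_paradigm(paradigm_spec(n_auditory = 0, n_visual = 0,
                                      n_audiovisual = 2, seed = 47), 500)
  alpha <- rep(-0.75, 24)
  ct <- cluster_threshold_mc(c(10, 10, 5), voxel_p = 0.05, fwhm_mm = 0,
                             n_iter = 500, seed = 10)
  nsig <- vapply(1:4, function(run) {
    sp <- coupling_sim_spec(grid = c(10, 10, 5), k = 0, noise_sd = 1,
                            drift_amp = 0, seed = run + 20)
    sim <- simulate_bold(par$markers, alpha, sp, par$total_duration_s, 2,
                         500)
    vol <- preprocess_bold_minimal(sim$vol, fwhm_mm = 0)
    sv <- couple(sim$regressor[-(1:2)], vol, cluster_thresh = ct)
    sum(sv$signif)
  }, 0)
  expect_lte(mean(nsig > 0), 0.5)
})

test_that("end-to-end: suppression and negative alpha-BOLD coupling recovered", {
  sess <- default_session()
  ai <- analysis_inverse()
  seg <- cleaned_segments()
  m <- cached("map_av", function() source_contrast_map(ai$inv, seg))
  poi <- define_poi(m, ai$src, sign = "neg")[[1]]
  expect_true(grepl("occipital", poi$label))
  av <- cached("poi_alpha", function()
    poi_alpha_timecourse(ai$inv, seg, poi))
  expect_lt(mean(av), 0)
  vol <- preprocess_bold_minimal(sess$bold$vol)
  nvol <- dim(vol$data)[4]
  reg <- build_alpha_regressor(av, seg$trial_info, 2, nvol + 2, 500)[-(1:2)]
  sv <- couple(reg, vol)
  cm <- sess$truth$coupled_mask
  expect_lt(mean(sv$r[cm]), -0.1)
  expect_lt(abs(mean(sv$r[!cm])), 0.05)
  # sign recovery across seeds at the regressor level (simulated BOLD
  # with the ground-truth alpha; 10 seeded runs)
  par <- sess$paradigm
  truth_alpha <- sess$truth$trial_alpha$occ_alpha_change
  neg <- vapply(1:10, function(s) {
    sp <- coupling_sim_spec(seed = s)
    sim <- simulate_bold(par$markers, truth_alpha, sp,
                         par$total_duration_s, 2, 500)
    vol <- preprocess_bold_minimal(sim$vol, fwhm_mm = 0)
    sv <- couple(sim$regressor[-(1:2)], vol)
    mean(sv$r[sp$coupled_mask] < 0)
  }, 0)
  expect_gte(mean(neg >= 0.95), 0.95)
})
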