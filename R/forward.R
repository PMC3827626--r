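# Four-shell concentric spherical head model and analytic lead fields.
#
# The potential of a current dipole inside shell 1 is expanded per Legendre
# degree n; within each shell V = (A r^n + B r^-(n+1)) x angular term, and
# the 7 unknown shell coefficients are obtained from potential and radial
# current continuity at the three inner interfaces plus the insulating
# outer boundary. Radii are normalized by the scalp radius so all powers
# stay in a numerically safe range up to the truncation degree.

#' Four-layer spherical head model
#'
#' @param scalp_radius_mm outer (scalp) radius.
#' @param radius_fractions radii of brain, CSF, skull, scalp shells as
#'   fractions of the scalp radius (strictly increasing, last = 1).
#' @param conductivities_sm conductivities (S/m) of brain, CSF, skull,
#'   scalp.
#' @param center_mm sphere center in head coordinates.
#' @return object of class `head_model`.
#' @export
head_model <- function(scalp_radius_mm = 92,
                       radius_fractions = c(0.87, 0.92, 0.96, 1.00),
                       conductivities_sm = c(0.33, 1.0, 0.0042, 0.33),
                       center_mm = c(0, 0, 0)) {
  stopifnot(length(radius_fractions) == 4, length(conductivities_sm) == 4)
  if (any(diff(radius_fractions) <= 0))
    stop("shell radii must be strictly increasing")
  if (any(conductivities_sm <= 0)) stop("conductivities must be > 0")
  structure(list(scalp_radius_mm = scalp_radius_mm,
                 radii_mm = radius_fractions * scalp_radius_mm,
                 conductivities_sm = conductivities_sm,
                 center_mm = center_mm),
            class = "head_model")
}

#' Spherical cortex source space
#'
#' Vertices are laid out per hemisphere with a Fibonacci lattice on a
#' sphere of `radius_frac` times the brain-shell radius, the hemisphere
#' axis pointing along +/-x, mirroring a decimated cortical mesh.
#' Orientations are radial (the "cortex normal" of a spherical cortex).
#'
#' @param head a `head_model`.
#' @param n_per_hemisphere vertices per hemisphere (<= 2500).
#' @param radius_frac source shell radius as a fraction of the brain shell.
#' @return object of class `source_space` with fields `vertices_mm`,
#'   `orientations`, `hemisphere` and `edge_length_mm` (typical
#'   nearest-neighbour spacing).
#' @export
source_space <- function(head, n_per_hemisphere = 2500, radius_frac = 0.85) {
  if (n_per_hemisphere > 2500)
    stop("source space is limited to 2500 vertices per hemisphere")
  r <- radius_frac * head$radii_mm[1]
  n <- n_per_hemisphere
  i <- seq_len(n)
  z <- (i - 0.5) / n                     # hemisphere: axis coordinate in (0,1)
  phi <- i * pi * (3 - sqrt(5))          # golden angle
  rho <- sqrt(1 - z^2)
  # axis +z mapped to +x (right hemisphere): (x,y,z) -> (z, rho cos, rho sin)
  right <- cbind(z, rho * cos(phi), rho * sin(phi))
  left <- right
  left[, 1] <- -left[, 1]
  verts <- rbind(left, right) * r
  ori <- rbind(left, right)              # radial unit normals
  hemi <- rep(c("lh", "rh"), each = n)
  edge <- sqrt(4 * pi * r^2 / (2 * n) * 2 / sqrt(3))
  structure(list(vertices_mm = verts, orientations = ori, hemisphere = hemi,
                 radius_mm = r, edge_length_mm = edge),
            class = "source_space")
}

#' Geodesic patch of source vertices
#'
#' @param src a `source_space`.
#' @param center_direction 3-vector; vertices within `angle_deg` of it are
#'   selected.
#' @param angle_deg geodesic radius in degrees.
#' @param min_vertices if the cap captures fewer vertices (coarse source
#'   spaces), fall back to the `min_vertices` nearest ones.
#' @return integer vertex indices.
#' @export
source_patch <- function(src, center_direction, angle_deg = 30,
                         min_vertices = 2) {
  u <- center_direction / sqrt(sum(center_direction^2))
  v <- src$vertices_mm / sqrt(rowSums(src$vertices_mm^2))
  ca <- as.numeric(v %*% u)
  idx <- which(ca > cos(angle_deg * pi / 180))
  if (length(idx) < min_vertices)
    idx <- order(ca, decreasing = TRUE)[seq_len(min_vertices)]
  sort(idx)
}

#' Co-register digitized electrodes to a spherical head model
#'
#' Rigid (rotation + translation) least-squares alignment of the digitized
#' fiducials to the model fiducials (nasion +y, preauricular points on
#' +/-x, all on the scalp sphere), followed by radial projection of each
#' electrode onto the scalp shell.
#'
#' @param digitized an `electrode_set` in digitizer coordinates.
#' @param head a `head_model`.
#' @return an `electrode_set` in the `"sphere"` frame with attribute
#'   `rms_projection_mm` (mean radial distance moved) and
#'   `rotation`/`translation` of the applied transform.
#' @export
coregister_electrodes <- function(digitized, head) {
  R4 <- head$radii_mm[4]
  target <- rbind(nasion = c(0, R4, 0), lpa = c(-R4, 0, 0), rpa = c(R4, 0, 0))
  f <- rbind(digitized$fiducials$nasion, digitized$fiducials$lpa,
             digitized$fiducials$rpa)
  ca <- colMeans(f); cb <- colMeans(target)
  H <- t(sweep(f, 2, ca)) %*% sweep(target, 2, cb)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cb - as.numeric(R %*% ca)
  xyz <- t(R %*% t(digitized$positions_mm) + tr)
  rad <- sqrt(rowSums(xyz^2))
  proj <- xyz * (R4 / rad)
  out <- new_electrode_set(
    digitized$labels, proj,
    fiducials = list(nasion = target[1, ], lpa = target[2, ],
                     rpa = target[3, ]),
    frame = "sphere")
  attr(out, "rms_projection_mm") <- sqrt(mean((rad - R4)^2))
  attr(out, "rotation") <- R
  attr(out, "translation") <- tr
  out
}

# Per-degree transfer coefficient: scalp-surface radial profile value
# (A4 + B4 at u = 1) per unit source coefficient B1, for dimensionless
# radii u (length 4, u[4] = 1) and conductivities s (length 4).
shell_transfer <- function(n_max, u, s) {
  vapply(seq_len(n_max), function(n) {
    # unknowns: A1, A2, B2, A3, B3, A4, B4 ; B1 = 1
    M <- matrix(0, 7, 7)
    rhs <- numeric(7)
    row <- 1
    for (j in 1:3) {
      uj <- u[j]
      iA <- c(1, 2, 4, 6)[j]          # A_j index
      iB <- c(NA, 3, 5, 7)[j]         # B_j index (B1 fixed)
      iA2 <- c(2, 4, 6)[j]            # A_{j+1}
      iB2 <- c(3, 5, 7)[j]            # B_{j+1}
      # potential continuity
      M[row, iA] <- uj^n
      if (!is.na(iB)) M[row, iB] <- uj^(-(n + 1))
      M[row, iA2] <- -uj^n
      M[row, iB2] <- -uj^(-(n + 1))
      if (j == 1) rhs[row] <- -uj^(-(n + 1))
      row <- row + 1
      # radial current continuity
      M[row, iA] <- s[j] * n * uj^(n - 1)
      if (!is.na(iB)) M[row, iB] <- -s[j] * (n + 1) * uj^(-(n + 2))
      M[row, iA2] <- -s[j + 1] * n * uj^(n - 1)
      M[row, iB2] <- s[j + 1] * (n + 1) * uj^(-(n + 2))
      if (j == 1) rhs[row] <- s[1] * (n + 1) * uj^(-(n + 2))
      row <- row + 1
    }
    # insulating outer boundary at u = 1
    M[7, 6] <- n
    M[7, 7] <- -(n + 1)
    sol <- solve(M, rhs)
    sol[6] + sol[7]                    # A4 + B4 at u = 1
  }, 0)
}

# Closed-form per-degree coefficient for a homogeneous sphere with
# insulating boundary (independent oracle for equal conductivities):
# A1 = (n+1)/n * B1 -> surface profile (2n+1)/n per unit B1.
single_sphere_transfer <- function(n_max) {
  n <- seq_len(n_max)
  (2 * n + 1) / n
}

legendre_accumulate <- function(X, n_max, coefs_P, coefs_P1, Wr, Wt) {
  # X: cos(theta) matrix; accumulates sum_n coefs_P[n]*P_n(X)*Wr +
  # coefs_P1[n]*P^1_n(X)*Wt, with P^1_n = sqrt(1-x^2) P'_n (no
  # Condon-Shortley phase).
  Pm1 <- matrix(1, nrow(X), ncol(X))   # P_0
  P <- X                               # P_1
  sq <- sqrt(pmax(1 - X^2, 0))
  acc <- coefs_P[1] * P * Wr +
    coefs_P1[1] * sq * Wt              # P^1_1 = sqrt(1-x^2)
  for (n in 2:n_max) {
    Pn <- ((2 * n - 1) * X * P - (n - 1) * Pm1) / n
    # P^1_n = -n (x P_n - P_{n-1}) / sqrt(1-x^2)
    num <- -n * (X * Pn - P)
    P1 <- ifelse(sq > 1e-12, num / sq, 0)
    acc <- acc + coefs_P[n] * Pn * Wr + coefs_P1[n] * P1 * Wt
    Pm1 <- P
    P <- Pn
  }
  acc
}

#' Compute an EEG lead field for a spherical head model
#'
#' Analytic concentric-shell potentials by truncated Legendre series,
#' average-referenced across electrodes. With oriented sources (the
#' default spherical-cortex normal constraint) one column per vertex is
#' returned; with `orientation = "free"` three columns (x, y, z unit
#' moments) per vertex.
#'
#' @param head a `head_model`.
#' @param src a `source_space`.
#' @param electrodes an `electrode_set` in the sphere frame (or any frame
#'   centered on the head model; positions are projected radially).
#' @param n_legendre series truncation degree (default 60).
#' @param orientation `"fixed"` (cortex-normal) or `"free"`.
#' @return object of class `leadfield`: list with `matrix`
#'   (electrodes x columns, volts per (A mm), for dipole moments in A mm
#'   and distances in mm scaled internally), `channel_labels`, `src_index`,
#'   `orientation`.
#' @export
compute_leadfield <- function(head, src, electrodes, n_legendre = 60,
                              orientation = c("fixed", "free")) {
  orientation <- match.arg(orientation)
  R4 <- head$radii_mm[4]
  u <- head$radii_mm / R4
  s <- head$conductivities_sm
  rs <- sqrt(rowSums(src$vertices_mm^2))
  if (any(rs >= head$radii_mm[1]))
    stop("all sources must lie strictly inside the brain shell")
  Tn <- shell_transfer(n_legendre, u, s)
  epos <- electrodes$positions_mm
  epos <- epos / sqrt(rowSums(epos^2))          # unit electrode directions
  sdir <- src$vertices_mm / ifelse(rs > 0, rs, 1)
  bu <- rs / R4

  moments <- if (orientation == "fixed") {
    list(src$orientations)
  } else {
    list(matrix(rep(c(1, 0, 0), each = nrow(sdir)), ncol = 3),
         matrix(rep(c(0, 1, 0), each = nrow(sdir)), ncol = 3),
         matrix(rep(c(0, 0, 1), each = nrow(sdir)), ncol = 3))
  }

  X <- epos %*% t(sdir)                         # cos(theta), nelec x nsrc
  ns <- seq_len(n_legendre)
  cols <- list()
  for (mset in moments) {
    m_r <- rowSums(mset * sdir)                 # radial moment per source
    m_tan <- mset - sdir * m_r                  # tangential moment vector
    # tangential unit direction from source toward each electrode:
    # e_perp = (e - (e.s) s)/|..| ; Wt = m_tan . e_perp
    num <- epos %*% t(m_tan) -
      X * matrix(rowSums(sdir * m_tan), nrow(X), ncol(X), byrow = TRUE)
    den <- sqrt(pmax(1 - X^2, 1e-24))
    Wt <- num / den
    Wr <- matrix(m_r, nrow(X), ncol(X), byrow = TRUE)
    # accumulate series; per-source power of (b/R) folded into coefs via
    # matrix trick: accumulate with coefficient 1 and scale inside loop
    V <- matrix(0, nrow(X), ncol(X))
    Pm1 <- matrix(1, nrow(X), ncol(X))
    P <- X
    sq <- sqrt(pmax(1 - X^2, 0))
    bpow <- matrix(1, nrow(X), ncol(X))         # (b/R)^(n-1), n = 1
    B <- matrix(bu, nrow(X), ncol(X), byrow = TRUE)
    P1 <- sq
    V <- V + Tn[1] * bpow * (1 * P * Wr + P1 * Wt)
    for (n in 2:n_legendre) {
      Pn <- ((2 * n - 1) * X * P - (n - 1) * Pm1) / n
      numP <- -n * (X * Pn - P)
      P1 <- ifelse(sq > 1e-12, numP / sq, 0)
      bpow <- bpow * B
      V <- V + Tn[n] * bpow * (n * Pn * Wr + P1 * Wt)
      Pm1 <- P
      P <- Pn
    }
    # prefactor 1/(4 pi sigma1 R^2); R in mm, moments in A mm -> volts*1e3;
    # absolute scale is irrelevant for inverse work but kept consistent
    V <- V / (4 * pi * s[1] * (R4 * 1e-3)^2) * 1e-6
    cols[[length(cols) + 1]] <- V
  }
  L <- if (length(cols) == 1) cols[[1]] else {
    out <- matrix(0, nrow(X), 3 * ncol(X))
    out[, seq(1, ncol(out), by = 3)] <- cols[[1]]
    out[, seq(2, ncol(out), by = 3)] <- cols[[2]]
    out[, seq(3, ncol(out), by = 3)] <- cols[[3]]
    out
  }
  L <- sweep(L, 2, colMeans(L))                 # average reference
  structure(list(matrix = L, channel_labels = electrodes$labels,
                 src_index = seq_len(nrow(sdir)),
                 orientation = orientation,
                 n_legendre = n_legendre),
            class = "leadfield")
}
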