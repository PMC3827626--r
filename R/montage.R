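# 63-channel scalp montage constructed by the classical 10-20 rules on a
# sphere: midline electrodes at 10/20% arc fractions of the nasion-inion
# great circle, an outer ring at 18-degree azimuth steps, and intermediate
# electrodes placed by spherical interpolation (slerp) between the midline
# electrode and the outer-ring electrode of the same row (e.g. F3 midway
# between Fz and F7 along the arc). AFz and FCz are deliberately absent:
# they serve as recording reference and ground and are reconstructed later
# as pseudo-electrodes by spherical-spline interpolation.

slerp <- function(a, b, f) {
  w <- acos(pmin(pmax(sum(a * b), -1), 1))
  if (w < 1e-12) return(a)
  (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
}

# unit vector from inclination (deg, from vertex) and azimuth (deg, 0 =
# anterior, positive = right, 180 = posterior)
sph_unit <- function(inc, az) {
  i <- inc * pi / 180
  a <- az * pi / 180
  c(sin(i) * sin(a), sin(i) * cos(a), cos(i))
}

montage_unit_vectors <- function() {
  pos <- list()
  # midline (AFz, FCz excluded on purpose)
  mid <- c(Fpz = 0, Fz = 0, Cz = 0, CPz = 180, Pz = 180, POz = 180, Oz = 180)
  mid_inc <- c(Fpz = 72, Fz = 36, Cz = 0, CPz = 18, Pz = 36, POz = 54, Oz = 72)
  for (lab in names(mid)) pos[[lab]] <- sph_unit(mid_inc[lab], mid[lab])
  # pseudo-electrode targets, kept separately
  pseudo <- list(AFz = sph_unit(54, 0), FCz = sph_unit(18, 0))
  # outer ring, 18 degree steps front to back (left side; right mirrored)
  ring <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90, TP7 = 108,
            P7 = 126, PO7 = 144, O1 = 162)
  for (lab in names(ring)) pos[[lab]] <- sph_unit(90, -ring[lab])
  # lower temporal row
  pos[["FT9"]] <- sph_unit(105, -72)
  pos[["TP9"]] <- sph_unit(105, -108)
  # intermediate rows: slerp(midline, outer, fraction)
  rows <- list(
    AF = list(mid = sph_unit(54, 0), out = pos[["AF7"]],
              labs = c(AF3 = 0.5)),
    F = list(mid = pos[["Fz"]], out = pos[["F7"]],
             labs = c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    FC = list(mid = sph_unit(18, 0), out = pos[["FT7"]],
              labs = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    C = list(mid = pos[["Cz"]], out = pos[["T7"]],
             labs = c(C1 = 0.25, C3 = 0.5, C5 = 0.75)),
    CP = list(mid = pos[["CPz"]], out = pos[["TP7"]],
              labs = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    P = list(mid = pos[["Pz"]], out = pos[["P7"]],
             labs = c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    PO = list(mid = pos[["POz"]], out = pos[["PO7"]],
              labs = c(PO3 = 0.5))
  )
  for (rw in rows) {
    for (lab in names(rw$labs))
      pos[[lab]] <- slerp(rw$mid, rw$out, rw$labs[[lab]])
  }
  # mirror left -> right (x sign flip); label number + 1
  mirror <- c(Fp1 = "Fp2", AF7 = "AF8", AF3 = "AF4", F7 = "F8", F5 = "F6",
              F3 = "F4", F1 = "F2", FT7 = "FT8", FC5 = "FC6", FC3 = "FC4",
              FC1 = "FC2", T7 = "T8", C5 = "C6", C3 = "C4", C1 = "C2",
              TP7 = "TP8", CP5 = "CP6", CP3 = "CP4", CP1 = "CP2",
              P7 = "P8", P5 = "P6", P3 = "P4", P1 = "P2", PO7 = "PO8",
              PO3 = "PO4", O1 = "O2", FT9 = "FT10", TP9 = "TP10")
  for (lab in names(mirror)) {
    v <- pos[[lab]]
    pos[[mirror[lab]]] <- c(-v[1], v[2], v[3])
  }
  list(scalp = pos, pseudo = pseudo)
}

#' Standard 63-channel scalp montage on a sphere
#'
#' The montage mirrors an MR-compatible 64-electrode cap in which the
#' midline electrodes anterior and posterior to Fz act as recording
#' reference and ground (AFz, FCz), leaving 63 scalp channels; the 64th
#' electrode is the ECG lead and carries no scalp position.
#'
#' @param radius_mm scalp sphere radius (default 92 mm).
#' @param include_pseudo if `TRUE`, append AFz and FCz positions (65
#'   positions total), e.g. as spherical-spline interpolation targets.
#' @return an `electrode_set` in the `"head"` frame (origin at sphere
#'   center, x right, y anterior, z superior), with fiducials on the
#'   equator.
#' @export
standard_montage <- function(radius_mm = 92, include_pseudo = FALSE) {
  mv <- montage_unit_vectors()
  pos <- mv$scalp
  if (include_pseudo) pos <- c(pos, mv$pseudo)
  labs <- names(pos)
  mat <- do.call(rbind, pos) * radius_mm
  fid <- list(nasion = sph_unit(90, 0) * radius_mm,
              lpa = sph_unit(90, -90) * radius_mm,
              rpa = sph_unit(90, 90) * radius_mm)
  new_electrode_set(labs, mat, fid, frame = "head")
}

#' Labels of posterior (occipital/parieto-occipital) channels
#' @param labels channel label vector to filter
#' @return the subset of `labels` over occipital and parieto-occipital sites
#' @export
posterior_channels <- function(labels) {
  labels[grepl("^(O|PO)", labels)]
}
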