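# Transmembrane-helix geometry: local axes from four consecutive Calpha
# atoms (the HELANAL bisector construction), tilt against the membrane
# normal, the chord bend angle at a chosen apex residue, and
# optimal-superposition (Kabsch) RMSD.

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length vector")
  v / n
}

#' Construct a helix trace
#'
#' @param coords numeric matrix (n x 3) of Calpha positions in Angstrom.
#' @param resid integer residue numbers, strictly increasing.
#' @return object of class `"HelixTrace"`.
#' @export
helix_trace <- function(coords, resid = seq_len(nrow(coords))) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 4) stop("helix trace needs at least 4 residues")
  if (length(resid) != nrow(coords) || is.unsorted(resid, strictly = TRUE))
    stop("residue numbers must be strictly increasing, one per Calpha")
  structure(list(coords = coords, resid = as.integer(resid)),
            class = "HelixTrace")
}

#' Extract a helix trace from a structure
#'
#' Pulls the CA atoms of a residue range within one monomer.
#'
#' @param structure a `Structure`.
#' @param coords coordinate matrix for the frame of interest (defaults to the
#'   reference frame).
#' @param monomer monomer index.
#' @param resid_range integer residues to include (e.g. `123:158` for TM3).
#' @return a [helix_trace()].
#' @export
helix_from_structure <- function(structure, monomer, resid_range,
                                 coords = structure$coords) {
  sel <- which(structure$monomer == monomer &
                 structure$atoms$name == "CA" &
                 structure$atoms$resid %in% resid_range)
  if (!length(sel)) stop("no CA atoms for monomer ", monomer,
                         " in the requested residue range")
  ord <- order(structure$atoms$resid[sel])
  helix_trace(coords[sel[ord], , drop = FALSE],
              structure$atoms$resid[sel][ord])
}

#' Local and global helix axes (HELANAL-style)
#'
#' For each window of four consecutive Calpha positions P1..P4, the bisectors
#' `B2 = (P1 - P2) + (P3 - P2)` and `B3 = (P2 - P3) + (P4 - P3)` are both
#' perpendicular to the local helix axis, so the local axis is
#' `unit(B2 x B3)`, sign-aligned to point from the first toward the last
#' residue. The global axis is the normalized mean of the local axes. This is
#' the direction-only simplification of the full algorithm: origin refinement
#' is omitted because tilt and bend need directions only.
#'
#' @param helix a `HelixTrace`.
#' @param degeneracy_tol windows whose bisector cross product has squared
#'   norm below this are skipped with a warning.
#' @return object of class `"AxisResult"`: `local_axes` (w x 3), `axis`
#'   (global unit vector), `origin` (centroid of the Calpha trace).
#' @export
local_helix_axes <- function(helix, degeneracy_tol = 1e-12) {
  p <- helix$coords
  n <- nrow(p)
  direction <- p[n, ] - p[1, ]
  axes <- matrix(NA_real_, n - 3, 3)
  skipped <- 0L
  for (w in seq_len(n - 3)) {
    P <- p[w:(w + 3), , drop = FALSE]
    B2 <- (P[1, ] - P[2, ]) + (P[3, ] - P[2, ])
    B3 <- (P[2, ] - P[3, ]) + (P[4, ] - P[3, ])
    ax <- c(B2[2] * B3[3] - B2[3] * B3[2],
            B2[3] * B3[1] - B2[1] * B3[3],
            B2[1] * B3[2] - B2[2] * B3[1])
    if (sum(ax^2) < degeneracy_tol) { skipped <- skipped + 1L; next }
    ax <- unit(ax)
    if (sum(ax * direction) < 0) ax <- -ax
    axes[w, ] <- ax
  }
  if (skipped > 0)
    warning(skipped, " degenerate (near-collinear) 4-Calpha window(s) skipped")
  axes <- axes[stats::complete.cases(axes), , drop = FALSE]
  if (!nrow(axes)) stop("all 4-Calpha windows degenerate: no helix axis")
  structure(list(local_axes = axes, axis = unit(colMeans(axes)),
                 origin = colMeans(p)),
            class = "AxisResult")
}

#' Helix tilt against the membrane normal
#'
#' Arc-cosine of the absolute dot product of the unit vectors, folding the
#' angle to 0-90 degrees: helix direction along the axis is arbitrary.
#'
#' @param axis helix axis vector (any length > 0).
#' @param normal membrane normal (default +z).
#' @return tilt in degrees, in \[0, 90\].
#' @export
tilt_angle <- function(axis, normal = c(0, 0, 1)) {
  a <- unit(axis); nrm <- unit(normal)
  acos(min(1, abs(sum(a * nrm)))) * 180 / pi
}

#' Bend angle of a helix at an apex residue
#'
#' The angle at the apex Calpha between the two chords connecting it to the
#' Calpha of each end residue (for claudin-15 TM3: apex 134, ends 123 on the
#' cytoplasmic side and 141 on the extracellular side). 180 degrees is a
#' straight chord pair; note that on an ideal helix the chords carry a radial
#' offset unless each arm spans a whole number of helical turns, so a
#' geometrically straight helix can read a few degrees below 180.
#'
#' @param helix a `HelixTrace`.
#' @param apex_residue residue number of the apex.
#' @param end_residues integer length-2 residue numbers of the two ends.
#' @return bend angle in degrees, in \[0, 180\].
#' @export
bend_angle <- function(helix, apex_residue, end_residues) {
  pos <- function(r) {
    i <- match(r, helix$resid)
    if (is.na(i)) stop("residue ", r, " not present in helix trace")
    helix$coords[i, ]
  }
  a <- pos(apex_residue)
  v1 <- unit(pos(end_residues[1]) - a)
  v2 <- unit(pos(end_residues[2]) - a)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Minimum root-mean-square deviation between two conformations over all
#' rigid rotations and translations, computed by SVD of the covariance of the
#' centered coordinates with the usual determinant correction against
#' improper rotations.
#'
#' @param ref numeric matrix (n x 3), reference coordinates (Angstrom).
#' @param mobile numeric matrix (n x 3), coordinates to superpose.
#' @param subset optional atom indices applied to both.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(ref, mobile, subset = NULL) {
  ref <- as.matrix(ref); mobile <- as.matrix(mobile)
  if (!is.null(subset)) {
    ref <- ref[subset, , drop = FALSE]
    mobile <- mobile[subset, , drop = FALSE]
  }
  if (nrow(ref) != nrow(mobile))
    stop("coordinate sets differ in atom count (", nrow(ref), " vs ",
         nrow(mobile), ")")
  if (nrow(ref) < 3) stop("need at least 3 atoms")
  x <- sweep(ref, 2, colMeans(ref))
  y <- sweep(mobile, 2, colMeans(mobile))
  s <- svd(crossprod(y, x))
  d <- sign(det(s$u %*% t(s$v)))
  e2 <- sum(x^2) + sum(y^2) - 2 * sum(s$d * c(1, 1, d))
  sqrt(max(0, e2) / nrow(x))
}

#' Per-frame angle series over a trajectory
#'
#' Evaluates a tilt or bend specification on every sampled frame, averaging
#' over monomers when several are selected, and summarizes with the sample
#' (n-1) standard deviation.
#'
#' @param traj a `Trajectory`.
#' @param monomers monomer indices carrying the helix.
#' @param resid_range helix residue range (e.g. `123:158`).
#' @param type `"tilt"` or `"bend"`.
#' @param apex_residue,end_residues bend parameters (see [bend_angle()]).
#' @param normal membrane normal for tilt.
#' @param stride_ps sampling interval (default 60 ps).
#' @param window optional `c(t_min, t_max)` ps, e.g. `last_window(traj, 100)`.
#' @return object of class `"AngleSeries"`: `time_ps`, `value_deg`
#'   (per-frame, monomer-averaged), `mean_deg`, `sd_deg` (sample sd),
#'   `n_frames`, `stride_ps`.
#' @export
angle_series <- function(traj, monomers, resid_range,
                         type = c("tilt", "bend"), apex_residue = NULL,
                         end_residues = NULL, normal = c(0, 0, 1),
                         stride_ps = 60, window = NULL) {
  type <- match.arg(type)
  if (type == "bend" && (is.null(apex_residue) || is.null(end_residues)))
    stop("bend series needs apex_residue and end_residues")
  idx <- frame_indices(traj, stride_ps = stride_ps, window = window)
  vals <- vapply(idx, function(i) {
    xyz <- traj$reader(i)
    per_mon <- vapply(monomers, function(m) {
      h <- helix_from_structure(traj$structure, m, resid_range, coords = xyz)
      if (type == "tilt")
        tilt_angle(local_helix_axes(h)$axis, normal)
      else
        bend_angle(h, apex_residue, end_residues)
    }, 1.0)
    mean(per_mon)
  }, 1.0)
  structure(list(time_ps = traj$times[idx], value_deg = vals,
                 mean_deg = mean(vals),
                 sd_deg = if (length(vals) > 1) stats::sd(vals) else 0,
                 n_frames = length(vals), stride_ps = stride_ps,
                 type = type),
            class = "AngleSeries")
}

#' Backbone RMSD series against the reference frame
#'
#' Kabsch RMSD of an atom subset against the structure's reference
#' coordinates, per sampled frame — per monomer, per monomer pair, or for any
#' atom selection (the strand-stability measure).
#'
#' @param traj a `Trajectory`.
#' @param subset atom indices (e.g. a backbone selection, or the union of a
#'   monomer pair's backbones).
#' @param stride_ps,window sampling control as in [angle_series()].
#' @return data.frame with `time_ps` and `rmsd_A`, plus attributes `mean` and
#'   `sd`.
#' @export
rmsd_series <- function(traj, subset, stride_ps = 60, window = NULL) {
  idx <- frame_indices(traj, stride_ps = stride_ps, window = window)
  ref <- traj$structure$coords[subset, , drop = FALSE]
  vals <- vapply(idx, function(i)
    kabsch_rmsd(ref, traj$reader(i)[subset, , drop = FALSE]), 1.0)
  out <- data.frame(time_ps = traj$times[idx], rmsd_A = vals)
  attr(out, "mean") <- mean(vals)
  attr(out, "sd") <- if (length(vals) > 1) stats::sd(vals) else 0
  out
}
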