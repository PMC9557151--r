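#' strandmech: mechanics of claudin tight-junction strands
#'
#' Tools to quantify the lateral mechanics of claudin strands in membranes:
#' worm-like-chain persistence length from tangent-angle correlations of the
#' tetramer-center trace, local curvature from sliding-window circle fits,
#' transmembrane-helix tilt and bend angles, optimal-superposition RMSD, and
#' residue-interface contact statistics, together with synthetic generators
#' (worm-like chains, kinked helices, contact series, toy strand structures)
#' that make every stage verifiable against known ground truth.
#'
#' @name strandmech-package
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Structures, groups, frames, trajectories
# ---------------------------------------------------------------------------

#' Construct a Structure object
#'
#' A `Structure` holds the topology of a strand system: one row per atom with
#' identifiers, a monomer assignment (atom -> claudin monomer index), and the
#' reference-frame Cartesian coordinates in Angstrom.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resid`, `resname`,
#'   `chain`, `element` (character `element` may be `NA`; it is then inferred
#'   from the first letter of the atom name).
#' @param coords numeric matrix, one row per atom, columns x/y/z (Angstrom).
#' @param monomer integer vector assigning each atom to a monomer index
#'   (1-based, contiguous).
#' @return an object of class `"Structure"`.
#' @export
structure_new <- function(atoms, coords, monomer) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(coords),
            nrow(atoms) == length(monomer))
  if (anyDuplicated(atoms$serial))
    stop("duplicate atom serial numbers: ",
         paste(unique(atoms$serial[duplicated(atoms$serial)]), collapse = ", "))
  if (anyNA(monomer))
    stop("atoms with no monomer assignment: rows ",
         paste(which(is.na(monomer)), collapse = ", "))
  monomer <- as.integer(factor(monomer, levels = unique(monomer)))
  if (anyNA(atoms$element) || any(atoms$element == "")) {
    atoms$element <- ifelse(is.na(atoms$element) | atoms$element == "",
                            substr(gsub("[^A-Za-z].*", "", atoms$name), 1, 1),
                            atoms$element)
  }
  # residue numbers must increase along each monomer chain
  for (m in unique(monomer)) {
    r <- atoms$resid[monomer == m]
    if (is.unsorted(r, strictly = FALSE))
      stop("residue numbers not ordered along monomer ", m)
  }
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  out <- list(atoms = atoms, coords = coords, monomer = monomer,
              n_monomers = length(unique(monomer)))
  class(out) <- "Structure"
  out
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure:", nrow(x$atoms), "atoms in", x$n_monomers, "monomers\n")
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Parses fixed-column ATOM/HETATM records. Monomer assignment uses, in order
#' of precedence: an explicit sidecar (`monomer_of` or `sidecar` JSON file),
#' then segment identifiers (columns 73-76) when present and strictly finer
#' than chain ids, then chain ids. Replicated strand systems exceed PDB's
#' single-character chain alphabet, which is why segment ids win when
#' available.
#'
#' @param path path to a PDB file.
#' @param monomer_of optional vector (length = atom count) of monomer labels
#'   overriding chains/segids.
#' @param sidecar optional path to a JSON sidecar with field `monomer`
#'   (per-atom monomer labels, in file order).
#' @return a [structure_new()] `Structure`; the file's coordinates become the
#'   reference frame.
#' @export
load_structure <- function(path, monomer_of = NULL, sidecar = NULL) {
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (!length(lines)) stop("no ATOM records found in ", path)
  bad <- which(nchar(lines) < 54)
  if (length(bad))
    stop("malformed PDB ATOM record (line too short) at ATOM line ", bad[1])
  fx <- function(a, b) trimws(substr(lines, a, b))
  serial <- suppressWarnings(as.integer(fx(7, 11)))
  if (anyNA(serial)) stop("malformed atom serial at ATOM line ",
                          which(is.na(serial))[1])
  atoms <- data.frame(
    serial  = serial,
    name    = fx(13, 16),
    resname = fx(18, 20),
    chain   = substr(lines, 22, 22),
    resid   = suppressWarnings(as.integer(fx(23, 26))),
    element = fx(77, 78),
    stringsAsFactors = FALSE)
  coords <- cbind(as.numeric(fx(31, 38)), as.numeric(fx(39, 46)),
                  as.numeric(fx(47, 54)))
  if (anyNA(coords)) stop("malformed coordinates at ATOM line ",
                          which(rowSums(is.na(coords)) > 0)[1])
  if (any(atoms$element == ""))
    warning("PDB lacks element column; elements inferred from atom names")
  segid <- fx(73, 76)
  if (!is.null(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    monomer_of <- sc$monomer
  }
  if (!is.null(monomer_of)) {
    if (length(monomer_of) != nrow(atoms))
      stop("monomer sidecar length (", length(monomer_of),
           ") does not match atom count (", nrow(atoms), ")")
    key <- monomer_of
  } else if (any(segid != "") &&
             length(unique(segid)) > length(unique(atoms$chain))) {
    key <- segid
  } else {
    key <- atoms$chain
  }
  structure_new(atoms, coords, key)
}

#' Write a structure to a PDB file
#'
#' @param structure a `Structure`.
#' @param path output path.
#' @param coords optional coordinate matrix to write instead of the
#'   structure's reference frame.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, coords = structure$coords) {
  a <- structure$atoms
  seg <- sprintf("%-4s", sprintf("M%03d", structure$monomer))
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f      %4s%2s",
    a$serial %% 100000, substr(a$name, 1, 4), substr(a$resname, 1, 3),
    substr(a$chain, 1, 1), a$resid %% 10000,
    coords[, 1], coords[, 2], coords[, 3], 1, 0, seg,
    substr(a$element, 1, 2))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Define atom groups on a structure
#'
#' A `GroupMap` collects the groupings the analyses need: tetramers (ordered
#' along the strand axis, four monomers each), optional rows of monomers
#' (ordered along the strand, for side-by-side neighbour pairs), optional
#' face-to-face monomer pairs, and named atom selections.
#'
#' @param tetramers list of integer vectors (length 4 each) of monomer
#'   indices, ordered along the strand.
#' @param rows optional list of ordered monomer-index vectors.
#' @param pairs optional list of length-2 monomer-index vectors
#'   (face-to-face partners).
#' @param selections optional named list of atom-index vectors (e.g. `"TM3"`,
#'   `"backbone"`, `"beta4"`).
#' @return an object of class `"GroupMap"`.
#' @export
group_map <- function(tetramers, rows = NULL, pairs = NULL,
                      selections = list()) {
  tetramers <- lapply(tetramers, as.integer)
  if (any(vapply(tetramers, length, 1L) != 4L))
    stop("every tetramer must contain exactly 4 monomer indices")
  all_m <- unlist(tetramers)
  if (anyDuplicated(all_m)) stop("tetramers are not disjoint")
  if (length(selections) && any(vapply(selections, length, 1L) == 0L))
    stop("empty named selection")
  out <- list(tetramers = tetramers, rows = rows, pairs = pairs,
              selections = selections)
  class(out) <- "GroupMap"
  out
}

#' Read a GroupMap from a JSON sidecar
#'
#' The sidecar holds `tetramers` (list of 4-vectors of monomer indices) and
#' optionally `rows`, `pairs` and `selections`.
#'
#' @param path JSON file path.
#' @return a [group_map()].
#' @export
load_group_map <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_list <- function(x) if (is.null(x)) NULL else
    if (is.matrix(x)) lapply(seq_len(nrow(x)), function(i) x[i, ]) else
      as.list(x)
  group_map(as_list(g$tetramers), rows = as_list(g$rows),
            pairs = as_list(g$pairs),
            selections = if (is.null(g$selections)) list() else
              lapply(g$selections, as.integer))
}

#' Construct a trajectory
#'
#' A `Trajectory` couples a `Structure` with a stream of coordinate frames.
#' Frames are supplied in memory, either as a list of per-frame coordinate
#' matrices or as a reader function `function(i)` returning frame `i`'s
#' matrix — the pluggable-reader seam for external formats.
#'
#' @param structure a `Structure`.
#' @param frames list of coordinate matrices (atoms x 3, Angstrom), or a
#'   function `(i) -> matrix` together with `n_frames`.
#' @param times numeric vector of frame times in ps (default `0, dt, ...`
#'   with `dt = 60` ps, the conventional sampling interval).
#' @param n_frames frame count, required when `frames` is a function.
#' @param dt_ps default frame spacing when `times` is missing.
#' @return an object of class `"Trajectory"`.
#' @export
trajectory <- function(structure, frames, times = NULL, n_frames = NULL,
                       dt_ps = 60) {
  reader <- if (is.function(frames)) {
    if (is.null(n_frames)) stop("n_frames required with a reader function")
    frames
  } else {
    n_frames <- length(frames)
    function(i) frames[[i]]
  }
  if (n_frames < 1) stop("empty trajectory")
  if (is.null(times)) times <- (seq_len(n_frames) - 1) * dt_ps
  if (length(times) != n_frames) stop("times length != frame count")
  if (is.unsorted(times)) stop("frame times must be non-decreasing")
  f1 <- reader(1)
  if (nrow(f1) != nrow(structure$atoms))
    stop("frame atom count (", nrow(f1), ") != structure atom count (",
         nrow(structure$atoms), ")")
  out <- list(structure = structure, reader = reader,
              n_frames = as.integer(n_frames), times = as.numeric(times))
  class(out) <- "Trajectory"
  out
}

#' @export
print.Trajectory <- function(x, ...) {
  cat("Trajectory:", x$n_frames, "frames,",
      nrow(x$structure$atoms), "atoms, t =", x$times[1], "..",
      x$times[x$n_frames], "ps\n")
  invisible(x)
}

#' Select frame indices at a sampling stride
#'
#' Nearest-frame selection at a fixed time interval, optionally restricted to
#' a trailing window (e.g. the last 100 ns of a trajectory).
#'
#' @param traj a `Trajectory`.
#' @param stride_ps sampling interval in ps (default 60 ps).
#' @param window optional numeric length-2 `c(t_min, t_max)` in ps; use
#'   [last_window()] for "last N ns".
#' @return integer vector of frame indices.
#' @export
frame_indices <- function(traj, stride_ps = 60, window = NULL) {
  t <- traj$times
  idx <- seq_along(t)
  if (!is.null(window)) {
    idx <- idx[t >= window[1] & t <= window[2]]
    if (!length(idx)) stop("empty time window")
  }
  tt <- t[idx]
  targets <- seq(tt[1], tt[length(tt)], by = stride_ps)
  sel <- vapply(targets, function(x) idx[which.min(abs(tt - x))], 1L)
  unique(sel)
}

#' Trailing time window of a trajectory
#'
#' @param traj a `Trajectory`.
#' @param ns window length in ns counted back from the last frame.
#' @return numeric `c(t_min, t_max)` in ps.
#' @export
last_window <- function(traj, ns) {
  tmax <- traj$times[traj$n_frames]
  c(tmax - ns * 1000, tmax)
}

# ---------------------------------------------------------------------------
# Per-frame geometry
# ---------------------------------------------------------------------------

#' Center of mass of an atom set
#'
#' @param coords coordinate matrix (atoms x 3).
#' @param atom_set integer indices into `coords`.
#' @param masses optional per-atom masses (full-length vector); unit masses
#'   when `NULL` (i.e. geometric center).
#' @return length-3 numeric position.
#' @export
center_of_mass <- function(coords, atom_set, masses = NULL) {
  if (!length(atom_set)) stop("empty atom set")
  x <- coords[atom_set, , drop = FALSE]
  if (is.null(masses)) return(colMeans(x))
  w <- masses[atom_set]
  colSums(x * w) / sum(w)
}

#' Tetramer centers along a strand
#'
#' For every sampled frame, the center of mass of each tetramer's atoms, in
#' the tetramer order of the `GroupMap` (i.e. along the strand axis). One
#' tetramer center is one data point of the 2D strand polymer.
#'
#' @param traj a `Trajectory`.
#' @param groups a `GroupMap` with non-empty `tetramers`.
#' @param frames integer frame indices (default all).
#' @param masses optional per-atom mass vector.
#' @return list (one element per frame) of matrices (tetramers x 3, Angstrom),
#'   with the frame times as attribute `"times"`.
#' @export
tetramer_centers <- function(traj, groups, frames = seq_len(traj$n_frames),
                             masses = NULL) {
  if (!length(groups$tetramers)) stop("GroupMap has no tetramers")
  mon <- traj$structure$monomer
  if (max(unlist(groups$tetramers)) > traj$structure$n_monomers)
    stop("tetramer references a monomer missing from the structure")
  # map each atom to its tetramer (NA if not in one)
  tet_of_mon <- rep(NA_integer_, traj$structure$n_monomers)
  for (k in seq_along(groups$tetramers))
    tet_of_mon[groups$tetramers[[k]]] <- k
  atom_tet <- tet_of_mon[mon]
  in_tet <- !is.na(atom_tet)
  grp <- atom_tet[in_tet]
  w <- if (is.null(masses)) rep(1, sum(in_tet)) else masses[in_tet]
  wsum <- rowsum(w, grp)
  out <- lapply(frames, function(i) {
    xyz <- traj$reader(i)[in_tet, , drop = FALSE]
    rowsum(xyz * w, grp) / as.vector(wsum)
  })
  attr(out, "times") <- traj$times[frames]
  out
}
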