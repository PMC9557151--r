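# Ground-truth generators. Every analysis stage in the package is exercised
# against data whose governing parameters are known by construction:
# worm-like chains at a set persistence length, ideal alpha-helices with an
# imposed kink, contact time-series with a set bound-state probability, and
# toy strand structures whose tetramer centers follow a supplied backbone.
#
# The worm-like-chain generator's defining identity is
#     sigma^2 = delta_s / l_p,
# the variance of the Gaussian tangent-angle increment per segment (the
# small-bend limit of the 2D worm-like chain), which makes the ensemble
# tangent correlation exp(-k * delta_s / (2 l_p)) exactly in expectation.

#' Parameters of the worm-like-chain ensemble generator
#'
#' Defaults mirror the regime of claudin strand simulations: 44 tetramer
#' centers at a ~3 nm spacing, persistence lengths of order 50-600 nm.
#'
#' @param n_points points per chain (>= 5).
#' @param ds segment length delta_s in nm.
#' @param lp persistence length in nm.
#' @param n_frames independent chain realizations.
#' @param seed RNG seed.
#' @param mixing frame-to-frame AR(1) correlation of the angle increments in
#'   \[0, 1); 0 (default) gives independent frames.
#' @return validated parameter list of class `"WLCParams"`.
#' @export
wlc_params <- function(n_points = 44, ds = 3.0, lp = 150, n_frames = 1000,
                       seed = 1, mixing = 0) {
  if (n_points < 5) stop("n_points must be >= 5")
  if (ds <= 0 || lp <= 0) stop("ds and lp must be positive")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (mixing < 0 || mixing >= 1) stop("mixing must be in [0, 1)")
  structure(list(n_points = as.integer(n_points), ds = ds, lp = lp,
                 n_frames = as.integer(n_frames), seed = seed,
                 mixing = mixing),
            class = "WLCParams")
}

#' Generate a worm-like-chain ensemble
#'
#' Per frame, segment headings follow the Gaussian random walk
#' `phi_{i+1} = phi_i + eps_i`, `eps_i ~ N(0, ds/lp)` (variance), and
#' positions advance by steps of length `ds` along each heading. Frames are
#' independent draws unless `mixing > 0`. Bit-reproducible under a fixed
#' seed.
#'
#' @param params a [wlc_params()].
#' @return list of `PolymerTrace` (one per frame) with attributes
#'   `"true_phi"` (frames x (n_points - 1) heading matrix — the generator's
#'   ground-truth tangent angles) and `"params"`.
#' @export
generate_wlc_ensemble <- function(params) {
  stopifnot(inherits(params, "WLCParams"))
  set.seed(params$seed)
  n <- params$n_points; f <- params$n_frames
  sigma <- sqrt(params$ds / params$lp)
  eps <- matrix(stats::rnorm(f * (n - 2), sd = sigma), nrow = f)
  if (params$mixing > 0 && f > 1) {
    rho <- params$mixing
    for (j in 2:f)
      eps[j, ] <- rho * eps[j - 1, ] + sqrt(1 - rho^2) * eps[j, ]
  }
  # headings phi_1..phi_{n-1}, phi_1 = 0; cumulative sums via triangular mult
  U <- upper.tri(diag(n - 2), diag = TRUE) * 1
  phi <- cbind(0, eps %*% U)
  UT <- upper.tri(diag(n - 1), diag = TRUE) * 1
  x <- cbind(0, params$ds * (cos(phi) %*% UT))
  y <- cbind(0, params$ds * (sin(phi) %*% UT))
  times <- (seq_len(f) - 1) * 60
  traces <- lapply(seq_len(f), function(i)
    polymer_trace(cbind(x[i, ], y[i, ]), time_ps = times[i]))
  attr(traces, "true_phi") <- phi
  attr(traces, "params") <- params
  traces
}

#' Ground-truth tangent profiles of a generated ensemble
#'
#' Wraps the generator's internal heading angles as `TangentProfile` objects
#' (one angle per segment, `ds` exact), for closed-form checks of the
#' correlation machinery independent of the central-difference estimator.
#'
#' @param ensemble output of [generate_wlc_ensemble()].
#' @return list of `TangentProfile`.
#' @export
true_tangent_profiles <- function(ensemble) {
  phi <- attr(ensemble, "true_phi")
  p <- attr(ensemble, "params")
  if (is.null(phi)) stop("ensemble carries no ground-truth angles")
  lapply(seq_len(nrow(phi)), function(i)
    structure(list(phi = phi[i, ], ds = rep(p$ds, length(phi[i, ]) - 1),
                   time_ps = (i - 1) * 60),
              class = "TangentProfile"))
}

#' Analytic worm-like-chain tangent correlation
#'
#' The expected 2D correlation at lag `k`:
#' `C(k) = exp(-k * ds / (2 * lp))`, i.e. the decay drops by a factor of e
#' over a contour distance of twice the persistence length.
#'
#' @param k lag (non-negative).
#' @param ds segment length (nm).
#' @param lp persistence length (nm).
#' @return expected correlation value(s).
#' @export
wlc_analytic_correlation <- function(k, ds, lp) {
  if (ds <= 0 || lp <= 0) stop("ds and lp must be positive")
  exp(-k * ds / (2 * lp))
}

#' Parameters of the kinked-helix generator
#'
#' Defaults build an ideal alpha-helix (rise 1.5 A, twist 100 deg, radius
#' 2.3 A per residue) shaped like claudin-15's TM3.
#'
#' @param n_residues helix length in residues.
#' @param rise,twist,radius per-residue helical parameters (A, deg, A).
#' @param kink_residue residue number at which the axis bends.
#' @param kink_angle bend of the downstream axis in degrees, in \[0, 60\].
#' @param resid_start first residue number (default 123, TM3 numbering).
#' @param noise_sd isotropic Gaussian coordinate noise sd (A).
#' @param seed RNG seed (used when `noise_sd > 0`).
#' @return validated list of class `"KinkedHelixParams"`.
#' @export
kinked_helix_params <- function(n_residues = 36, rise = 1.5, twist = 100,
                                radius = 2.3, kink_residue = 134,
                                kink_angle = 0, resid_start = 123,
                                noise_sd = 0, seed = 1) {
  k_idx <- kink_residue - resid_start + 1
  if (k_idx <= 1 || k_idx >= n_residues)
    stop("kink_residue must lie strictly inside the helix")
  if (kink_angle < 0 || kink_angle > 60)
    stop("kink_angle must be in [0, 60] degrees")
  structure(list(n_residues = as.integer(n_residues), rise = rise,
                 twist = twist, radius = radius,
                 kink_residue = as.integer(kink_residue),
                 kink_angle = kink_angle,
                 resid_start = as.integer(resid_start),
                 noise_sd = noise_sd, seed = seed),
            class = "KinkedHelixParams")
}

#' Generate a kinked ideal helix
#'
#' Calpha positions on a cylinder along +z up to the kink residue; beyond it
#' the remaining ideal helix is rigidly rotated by `kink_angle` about the
#' +x axis through the kink residue's position, emulating a proline-induced
#' bend of a transmembrane helix toward the membrane.
#'
#' @param params a [kinked_helix_params()].
#' @param n_frames when > 1, a list of noisy copies is returned (independent
#'   noise per frame).
#' @return a [helix_trace()] (or list of them when `n_frames > 1`), with the
#'   parameters attached as attribute `"params"`.
#' @export
generate_kinked_helix <- function(params, n_frames = 1) {
  stopifnot(inherits(params, "KinkedHelixParams"))
  n <- params$n_residues
  t <- (seq_len(n) - 1)
  omega <- params$twist * pi / 180
  ideal <- cbind(params$radius * cos(omega * t),
                 params$radius * sin(omega * t),
                 params$rise * t)
  k <- params$kink_residue - params$resid_start + 1
  chi <- params$kink_angle * pi / 180
  R <- rbind(c(1, 0, 0),
             c(0, cos(chi), -sin(chi)),
             c(0, sin(chi), cos(chi)))
  coords <- ideal
  if (chi != 0 && k < n) {
    post <- (k + 1):n
    coords[post, ] <- sweep(
      sweep(ideal[post, , drop = FALSE], 2, ideal[k, ]) %*% t(R),
      2, ideal[k, ], `+`)
  }
  resid <- params$resid_start + t
  make <- function(xyz) {
    h <- helix_trace(xyz, resid)
    attr(h, "params") <- params
    h
  }
  if (params$noise_sd > 0 || n_frames > 1) set.seed(params$seed)
  if (n_frames == 1) {
    if (params$noise_sd > 0)
      coords <- coords + matrix(stats::rnorm(3 * n, sd = params$noise_sd),
                                ncol = 3)
    return(make(coords))
  }
  lapply(seq_len(n_frames), function(i)
    make(coords + matrix(stats::rnorm(3 * n, sd = params$noise_sd),
                         ncol = 3)))
}

#' Parameters of the two-state contact-series generator
#'
#' Emulates an interface that is bound (short-distance state) with
#' probability `p` and unbound (long-distance tail) otherwise — the
#' mechanism behind bimodal / extended-tail pairwise-distance distributions.
#'
#' @param n_frames series length.
#' @param p bound-state probability in \[0, 1\].
#' @param bound_mean,bound_sd bound-state distance distribution (A).
#' @param unbound_mean,unbound_sd unbound-state distance distribution (A).
#' @param seed RNG seed.
#' @return validated list of class `"ContactGenParams"`.
#' @export
contact_gen_params <- function(n_frames = 10000, p = 0.82,
                               bound_mean = 4.0, bound_sd = 0.5,
                               unbound_mean = 8.5, unbound_sd = 0.8,
                               seed = 1) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (bound_mean <= 0 || unbound_mean <= 0 || bound_sd <= 0 || unbound_sd <= 0)
    stop("distance distribution parameters must be positive")
  structure(list(n_frames = as.integer(n_frames), p = p,
                 bound_mean = bound_mean, bound_sd = bound_sd,
                 unbound_mean = unbound_mean, unbound_sd = unbound_sd,
                 seed = seed),
            class = "ContactGenParams")
}

#' Generate a two-state contact distance series
#'
#' @param params a [contact_gen_params()].
#' @return a `ContactSeries` with attributes `"bound"` (logical ground
#'   truth) and `"params"`.
#' @export
generate_contact_series <- function(params) {
  stopifnot(inherits(params, "ContactGenParams"))
  set.seed(params$seed)
  n <- params$n_frames
  bound <- stats::runif(n) < params$p
  d <- ifelse(bound,
              stats::rnorm(n, params$bound_mean, params$bound_sd),
              stats::rnorm(n, params$unbound_mean, params$unbound_sd))
  d <- abs(d)
  d[d == 0] <- min(d[d > 0])
  s <- contact_series(d, time_ps = (seq_len(n) - 1) * 60,
                      label = "synthetic")
  attr(s, "bound") <- bound
  attr(s, "params") <- params
  s
}

#' Generate a toy strand structure and trajectory
#'
#' Builds a PDB-writable `Structure` whose tetramer centers follow a supplied
#' 2D backbone (nm, membrane plane), plus a `Trajectory` when several
#' backbone frames are given. Each tetramer holds four monomers offset
#' symmetrically about the backbone point, each monomer a small symmetric
#' cluster of unit-mass atoms, so every tetramer's center of mass reproduces
#' the backbone point exactly. This is the end-to-end fixture: write it out,
#' load it back, and the full centers -> projection -> correlation -> fit
#' pipeline must recover the backbone's statistics.
#'
#' @param backbone a single (n_tet x 2) matrix in nm, or a list of them (one
#'   per frame) such as `PolymerTrace` point sets.
#' @param atoms_per_monomer atoms per monomer (>= 1).
#' @param monomer_spread half-spacing of the four monomers about the
#'   tetramer center (A).
#' @return list: `structure`, `trajectory`, `groups` (tetramer `GroupMap`),
#'   `n_monomers`.
#' @export
generate_strand_fixture <- function(backbone, atoms_per_monomer = 4,
                                    monomer_spread = 4) {
  frames2d <- if (is.list(backbone) && !is.matrix(backbone)) {
    lapply(backbone, function(b) if (inherits(b, "PolymerTrace")) b$points
           else as.matrix(b))
  } else list(as.matrix(backbone))
  n_tet <- nrow(frames2d[[1]])
  n_monomers <- 4L * n_tet
  # monomer offsets within a tetramer (A), summing to zero
  mono_off <- rbind(c(monomer_spread, monomer_spread, 0),
                    c(-monomer_spread, monomer_spread, 0),
                    c(monomer_spread, -monomer_spread, 0),
                    c(-monomer_spread, -monomer_spread, 0))
  # atom offsets within a monomer (A), summing to zero
  base <- matrix(c(1.2, 0, 0, -1.2, 0, 0, 0, 1.2, 0, 0, -1.2, 0,
                   0, 0, 1.2, 0, 0, -1.2), ncol = 3, byrow = TRUE)
  at_off <- base[rep_len(seq_len(nrow(base)), atoms_per_monomer), ,
                 drop = FALSE]
  at_off <- sweep(at_off, 2, colMeans(at_off))
  n_atoms <- n_monomers * atoms_per_monomer
  monomer <- rep(seq_len(n_monomers), each = atoms_per_monomer)
  tet_of_atom <- (monomer - 1L) %/% 4L + 1L
  offsets <- mono_off[rep(rep(1:4, times = n_tet), each = atoms_per_monomer), ,
                      drop = FALSE] +
    at_off[rep(seq_len(atoms_per_monomer), times = n_monomers), , drop = FALSE]
  names_cycle <- c("CA", "CB", "CG", "CD", "CE", "CZ")
  atoms <- data.frame(
    serial = seq_len(n_atoms),
    name = names_cycle[(rep_len(seq_len(atoms_per_monomer), n_atoms) - 1) %%
                         length(names_cycle) + 1],
    resname = "GLY",
    chain = "A",
    resid = rep(seq_len(atoms_per_monomer), times = n_monomers),
    element = "C", stringsAsFactors = FALSE)
  coords_of <- function(b2d) {
    centers <- cbind(b2d * 10, 0)  # nm -> A, flat in z
    centers[tet_of_atom, , drop = FALSE] + offsets
  }
  struct <- structure_new(atoms, coords_of(frames2d[[1]]), monomer)
  traj <- trajectory(struct, lapply(frames2d, coords_of))
  groups <- group_map(split(seq_len(n_monomers),
                            rep(seq_len(n_tet), each = 4)))
  list(structure = struct, trajectory = traj, groups = groups,
       n_monomers = n_monomers)
}
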