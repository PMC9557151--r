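# Independent oracles and small fixture builders used across the suite.
# Oracles are deliberately naive (grid searches, flat averages) so they share
# no code path with the implementation they check.

# Brute-force circle fit: grid search over the center minimizing the summed
# squared orthogonal distance, radius = mean distance at the optimum.
brute_circle_radius <- function(pts, stages = 8, grid_n = 21) {
  cx <- mean(pts[, 1]); cy <- mean(pts[, 2])
  span <- 4 * max(diff(range(pts[, 1])), diff(range(pts[, 2])))
  best <- c(cx, cy)
  for (s in seq_len(stages)) {
    gx <- seq(best[1] - span, best[1] + span, length.out = grid_n)
    gy <- seq(best[2] - span, best[2] + span, length.out = grid_n)
    obj <- matrix(0, grid_n, grid_n)
    for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
      d <- sqrt((pts[, 1] - gx[i])^2 + (pts[, 2] - gy[j])^2)
      obj[i, j] <- sum((d - mean(d))^2)
    }
    w <- arrayInd(which.min(obj), dim(obj))
    best <- c(gx[w[1]], gy[w[2]])
    span <- span * 0.3   # keeps several old grid cells inside the new box
  }
  mean(sqrt((pts[, 1] - best[1])^2 + (pts[, 2] - best[2])^2))
}

# Brute-force superposition RMSD: dense zyz Euler grid with refinement.
euler_rot <- function(a, b, c) {
  rz <- function(t) rbind(c(cos(t), -sin(t), 0), c(sin(t), cos(t), 0),
                          c(0, 0, 1))
  ry <- function(t) rbind(c(cos(t), 0, sin(t)), c(0, 1, 0),
                          c(-sin(t), 0, cos(t)))
  rz(a) %*% ry(b) %*% rz(c)
}

brute_rmsd <- function(ref, mobile) {
  x <- sweep(ref, 2, colMeans(ref))
  y <- sweep(mobile, 2, colMeans(mobile))
  eval_r <- function(a, b, c) {
    r <- y %*% t(euler_rot(a, b, c))
    sqrt(mean(rowSums((x - r)^2)))
  }
  best <- Inf; arg <- c(0, 0, 0)
  for (a in seq(0, 2 * pi - 1e-9, by = 15 * pi / 180))
    for (b in seq(0, pi, by = 15 * pi / 180))
      for (c in seq(0, 2 * pi - 1e-9, by = 15 * pi / 180)) {
        v <- eval_r(a, b, c)
        if (v < best) { best <- v; arg <- c(a, b, c) }
      }
  step <- 15 * pi / 180
  for (stage in 1:6) {
    step <- step / 3
    g <- seq(-3, 3) * step
    for (da in g) for (db in g) for (dc in g) {
      v <- eval_r(arg[1] + da, arg[2] + db, arg[3] + dc)
      if (v < best) { best <- v; arg2 <- arg + c(da, db, dc) }
    }
    if (exists("arg2")) { arg <- arg2; rm(arg2) }
  }
  best
}

# Points on a circular arc with optional Gaussian noise.
arc_points <- function(n, center, radius, theta0, theta1, noise_sd = 0) {
  th <- seq(theta0, theta1, length.out = n)
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th)) +
    matrix(rnorm(2 * n, sd = noise_sd), ncol = 2)
}

rot2 <- function(theta) rbind(c(cos(theta), -sin(theta)),
                              c(sin(theta), cos(theta)))

# Toy multi-monomer structure carrying the claudin residues the contact
# module addresses. Monomer m sits at x = (m-1)*spacing.
toy_contact_structure <- function(n_monomers, spacing = 30) {
  per <- data.frame(
    resid   = c(58, 58, 65, 65, 67, 67, 68, 68, 79, 79, 146, 148, 148,
                155, 157, 157),
    name    = c("N", "O", "N", "O", "CB", "OG", "CB", "SD", "NH1", "NH2",
                "CZ", "OD1", "ND2", "NZ", "OE1", "OE2"),
    resname = c("LEU", "LEU", "PHE", "PHE", "SER", "SER", "MET", "MET",
                "ARG", "ARG", "PHE", "ASN", "ASN", "LYS", "GLU", "GLU"),
    element = c("N", "O", "N", "O", "C", "O", "C", "S", "N", "N",
                "C", "O", "N", "N", "O", "O"),
    stringsAsFactors = FALSE)
  k <- nrow(per)
  atoms <- do.call(rbind, lapply(seq_len(n_monomers), function(m) {
    a <- per
    a$chain <- LETTERS[(m - 1) %% 26 + 1]
    a
  }))
  atoms$serial <- seq_len(nrow(atoms))
  # deterministic in-monomer offsets keep all intra distances fixed
  off <- cbind(seq_len(k) * 1.3, (seq_len(k) %% 3) * 1.1,
               (seq_len(k) %% 5) * 0.9)
  coords <- do.call(rbind, lapply(seq_len(n_monomers), function(m)
    sweep(off, 2, c((m - 1) * spacing, 0, 0), `+`)))
  structure_new(atoms, coords, rep(seq_len(n_monomers), each = k))
}

# One-atom-per-monomer structure for distance fixtures.
point_structure <- function(positions, monomer = seq_len(nrow(positions))) {
  n <- nrow(positions)
  atoms <- data.frame(serial = 1:n, name = "CA", resname = "GLY",
                      chain = "A", resid = 1L, element = "C",
                      stringsAsFactors = FALSE)
  structure_new(atoms, positions, monomer)
}
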