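# Local curvature of the strand: least-squares circles over sliding windows.
#
# The algebraic (Kasa) fit solves the linear system obtained from writing the
# circle as x^2 + y^2 = a x + b y + c; center = (a/2, b/2) and
# radius = sqrt(c + a^2/4 + b^2/4). Near-collinear windows make the normal
# equations ill-conditioned; those fits are flagged degenerate and their
# curvature reported as 0 (a straight segment has zero curvature, not an
# undefined one).

#' Algebraic least-squares circle fit
#'
#' @param points numeric matrix (n x 2), n >= 3, in nm.
#' @param cond_max condition-number cutoff on the 3x3 normal matrix beyond
#'   which the window is declared degenerate (default 1e10).
#' @return object of class `"CircleFit"`: `center`, `radius` (nm; `Inf` when
#'   degenerate), `residual` (RMS orthogonal misfit, nm), `degenerate`.
#' @export
fit_circle <- function(points, cond_max = 1e10) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("circle fit needs at least 3 points")
  x <- points[, 1]; y <- points[, 2]
  if (all(x == x[1]) && all(y == y[1])) stop("all points coincident")
  # center the data for conditioning; the fit is translation-equivariant
  mx <- mean(x); my <- mean(y)
  u <- x - mx; v <- y - my
  A <- cbind(u, v, 1)
  b <- u^2 + v^2
  N <- crossprod(A)
  ev <- eigen(N, symmetric = TRUE, only.values = TRUE)$values
  if (ev[3] <= 0 || ev[1] / ev[3] > cond_max) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          residual = NA_real_, degenerate = TRUE),
                     class = "CircleFit"))
  }
  coef <- solve(N, crossprod(A, b))
  cu <- coef[1] / 2; cv <- coef[2] / 2
  r2 <- coef[3] + cu^2 + cv^2
  if (r2 <= 0) {
    return(structure(list(center = c(NA_real_, NA_real_), radius = Inf,
                          residual = NA_real_, degenerate = TRUE),
                     class = "CircleFit"))
  }
  r <- sqrt(r2)
  resid <- sqrt(mean((sqrt((u - cu)^2 + (v - cv)^2) - r)^2))
  structure(list(center = c(cu + mx, cv + my), radius = r,
                 residual = resid, degenerate = FALSE),
            class = "CircleFit")
}

#' Local curvature profile of one strand trace
#'
#' Fits a circle to the window `i - half_width .. i + half_width` around each
#' admissible position and records the curvature `kappa_i = 1/radius`.
#' Admissible positions exclude `max(half_width, end_exclude)` points at each
#' end: with the default `half_width = 5` and `end_exclude = 0`, a 44-point
#' trace yields positions i = 6..39 (34 values). Degenerate (near-straight)
#' windows contribute `kappa = 0`.
#'
#' @param trace a `PolymerTrace` (points in nm).
#' @param half_width window half-width in points (default 5).
#' @param end_exclude total end exclusion per side, in points; effective only
#'   beyond `half_width`.
#' @param cond_max degeneracy threshold, see [fit_circle()].
#' @return object of class `"CurvatureProfile"`: `position` (indices i),
#'   `kappa_per_um` (curvature, reciprocal micrometres), `degenerate`
#'   (logical per position), `time_ps`, `half_width`, `end_exclude`.
#' @export
local_curvature <- function(trace, half_width = 5, end_exclude = 0,
                            cond_max = 1e10) {
  p <- trace$points
  n <- nrow(p)
  margin <- max(half_width, end_exclude)
  lo <- margin + 1; hi <- n - margin
  if (lo > hi) stop("no admissible positions: trace too short for window")
  pos <- lo:hi
  kappa <- numeric(length(pos)); degen <- logical(length(pos))
  for (j in seq_along(pos)) {
    i <- pos[j]
    f <- fit_circle(p[(i - half_width):(i + half_width), , drop = FALSE],
                    cond_max = cond_max)
    degen[j] <- f$degenerate
    kappa[j] <- if (f$degenerate) 0 else 1 / f$radius
  }
  # nm^-1 -> um^-1
  structure(list(position = pos, kappa_per_um = kappa * 1000,
                 degenerate = degen, time_ps = trace$time_ps,
                 half_width = half_width, end_exclude = end_exclude),
            class = "CurvatureProfile")
}

#' Pooled curvature distribution over frames
#'
#' @param profiles a `CurvatureProfile` or list of them.
#' @param breaks passed to [graphics::hist] semantics via [base::cut]; here a
#'   number of bins or a vector of bin edges (reciprocal micrometres).
#' @return list: `mean`, `sd` (sample), `n`, `histogram` (data.frame with
#'   `bin_center`, `density`), all in reciprocal micrometres.
#' @export
curvature_summary <- function(profiles, breaks = 30) {
  if (inherits(profiles, "CurvatureProfile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile")
  k <- unlist(lapply(profiles, `[[`, "kappa_per_um"))
  h <- graphics::hist(k, breaks = breaks, plot = FALSE)
  list(mean = mean(k), sd = stats::sd(k), n = length(k),
       histogram = data.frame(bin_center = h$mids, density = h$density))
}

#' Time-averaged curvature along a strand ensemble
#'
#' Runs [local_curvature()] on every frame's trace and pools the values.
#'
#' @param traces list of `PolymerTrace`.
#' @inheritParams local_curvature
#' @return list with `summary` (see [curvature_summary()]) and `profiles`.
#' @export
curvature_pipeline <- function(traces, half_width = 5, end_exclude = 0) {
  profiles <- lapply(traces, local_curvature, half_width = half_width,
                     end_exclude = end_exclude)
  list(summary = curvature_summary(profiles), profiles = profiles)
}

#' Write per-position curvature values to CSV
#'
#' @param profiles list of `CurvatureProfile`.
#' @param path output CSV (`frame_time_ps, i, kappa_per_um`).
#' @return `path`, invisibly.
#' @export
write_curvature <- function(profiles, path) {
  df <- do.call(rbind, lapply(profiles, function(p)
    data.frame(frame_time_ps = p$time_ps, i = p$position,
               kappa_per_um = p$kappa_per_um)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
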