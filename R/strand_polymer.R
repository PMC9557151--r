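# Worm-like-chain analysis of the strand polymer.
#
# The strand is treated as a discrete 2D polymer in the membrane plane: one
# point per tetramer. The tangent angle at an interior point is the direction
# of the central-difference tangent vector
#     tau_i = (r_{i+1} - r_{i-1}) / |r_{i+1} - r_{i-1}|,
# the local contour fragment is delta_s_i = (|r_{i+1}-r_i| + |r_i-r_{i-1}|)/2,
# and the persistence length follows from the 2D worm-like-chain decay
#     <cos(phi(s) - phi(0))> = exp(-s / (2 l_p)),
# where the factor of two is the two-dimensional convention.

#' Construct a 2D polymer trace
#'
#' @param points numeric matrix (n x 2), ordered along the strand, in nm.
#' @param time_ps frame time in ps.
#' @return object of class `"PolymerTrace"`.
#' @export
polymer_trace <- function(points, time_ps = 0) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("PolymerTrace needs 2D points")
  if (nrow(points) < 3) stop("PolymerTrace needs at least 3 points")
  d <- sqrt(rowSums(diff(points)^2))
  if (any(d == 0))
    stop("coincident successive points at index ", which(d == 0)[1])
  structure(list(points = points, time_ps = time_ps), class = "PolymerTrace")
}

#' Project 3D strand centers into the membrane plane
#'
#' Drops the membrane-normal coordinate (default normal = z, so the trace
#' lives in the x-y plane) and optionally rescales units (tetramer centers
#' from structures are in Angstrom; polymer analyses are in nm).
#'
#' @param centers numeric matrix (n x 3) of tetramer centers for one frame.
#' @param plane integer length-2, the in-plane axes (default `c(1, 2)`).
#' @param scale multiplicative unit conversion applied to coordinates
#'   (use `0.1` for Angstrom input to get nm).
#' @param time_ps frame time in ps.
#' @return a [polymer_trace()].
#' @export
project_trace <- function(centers, plane = c(1, 2), scale = 1, time_ps = 0) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 3) stop("need at least 3 centers")
  polymer_trace(centers[, plane, drop = FALSE] * scale, time_ps = time_ps)
}

#' Tangent angles and contour fragments of a trace
#'
#' Central-difference tangent angles phi_i (radians, via `atan2`) and local
#' contour fragments delta_s_i for the interior points i = 2..n-1.
#'
#' @param trace a `PolymerTrace`.
#' @return object of class `"TangentProfile"` with fields `phi` (radians),
#'   `ds` (nm) and `time_ps`.
#' @export
tangent_profile <- function(trace) {
  p <- trace$points
  n <- nrow(p)
  fwd <- p[3:n, , drop = FALSE] - p[1:(n - 2), , drop = FALSE]
  if (any(rowSums(fwd^2) == 0))
    stop("zero tangent vector (r_{i+1} == r_{i-1}) at interior index ",
         which(rowSums(fwd^2) == 0)[1] + 1)
  phi <- atan2(fwd[, 2], fwd[, 1])
  seg <- sqrt(rowSums(diff(p)^2))
  ds <- (seg[-length(seg)] + seg[-1]) / 2
  structure(list(phi = phi, ds = ds, time_ps = trace$time_ps),
            class = "TangentProfile")
}

#' Mean contour fragment over an ensemble
#'
#' Pooled (count-weighted) mean of all delta_s_i over positions and frames —
#' a flat average over every local fragment in the ensemble.
#'
#' @param profiles a `TangentProfile` or list of them.
#' @return delta_s in nm.
#' @export
mean_segment_length <- function(profiles) {
  if (inherits(profiles, "TangentProfile")) profiles <- list(profiles)
  if (!length(profiles)) stop("need at least one profile")
  mean(unlist(lapply(profiles, `[[`, "ds")))
}

#' Tangent-angle correlation function
#'
#' For each lag k, the mean of `cos(phi_{i+k} - phi_i)` over all position
#' pairs with separation k, pooled across frames (a single ensemble average).
#' C(0) = 1 by construction. Angles enter only inside cosines of differences,
#' so no angle unwrapping is needed.
#'
#' @param profiles list of `TangentProfile` (one per frame).
#' @param k_max largest lag; must be smaller than the interior point count.
#' @return object of class `"CorrelationFunction"`: fields `lag`, `C`,
#'   `count` (pairs pooled per lag) and `n_frames`.
#' @export
tangent_correlation <- function(profiles, k_max) {
  if (inherits(profiles, "TangentProfile")) profiles <- list(profiles)
  n_int <- vapply(profiles, function(p) length(p$phi), 1L)
  if (k_max >= min(n_int))
    stop("k_max (", k_max, ") must be below the interior point count (",
         min(n_int), ")")
  sums <- numeric(k_max)
  counts <- numeric(k_max)
  if (length(unique(n_int)) == 1L) {
    # equal-length fast path: stack angles into a frames x positions matrix
    phi <- do.call(rbind, lapply(profiles, `[[`, "phi"))
    m <- ncol(phi)
    for (k in seq_len(k_max)) {
      d <- phi[, (1 + k):m, drop = FALSE] - phi[, 1:(m - k), drop = FALSE]
      sums[k] <- sum(cos(d))
      counts[k] <- length(d)
    }
  } else {
    for (p in profiles) {
      phi <- p$phi
      m <- length(phi)
      for (k in seq_len(min(k_max, m - 1))) {
        d <- phi[(1 + k):m] - phi[1:(m - k)]
        sums[k] <- sums[k] + sum(cos(d))
        counts[k] <- counts[k] + length(d)
      }
    }
  }
  structure(list(lag = 0:k_max, C = c(1, sums / counts),
                 count = c(sum(n_int), counts), n_frames = length(profiles)),
            class = "CorrelationFunction")
}

#' Fit the worm-like-chain persistence length
#'
#' Ordinary least squares of `ln C(k)` against contour separation
#' `s = k * delta_s` over the lag prefix `k = 1..K`. K is the longest prefix
#' (K >= 3) whose fit attains `R^2 >= r2_cutoff`; lags with `C <= 0` or
#' non-finite terminate the usable range. The persistence length is
#' `l_p = -1 / (2 * slope)` — the 2D convention. The intercept is free and
#' unused: discretization of the tangent offsets the correlation by a
#' k-independent factor that a forced zero intercept would fold into the
#' slope and bias l_p.
#'
#' @param corr a `CorrelationFunction`.
#' @param ds mean contour fragment delta_s in nm (see
#'   [mean_segment_length()]).
#' @param r2_cutoff minimum R-squared for the fitted prefix (default 0.95).
#' @return object of class `"PersistenceEstimate"`: `lp_nm` (NA when no
#'   measurable decay), `slope`, `intercept`, `r2`, `lags_used`, `ds_nm`,
#'   `n_frames`, `flag`.
#' @export
fit_persistence_length <- function(corr, ds, r2_cutoff = 0.95) {
  C <- corr$C[corr$lag > 0]
  k <- corr$lag[corr$lag > 0]
  usable <- which(!(is.finite(C) & C > 0))
  n_use <- if (length(usable)) usable[1] - 1 else length(C)
  if (n_use < 3)
    stop("correlation decays too fast / too noisy: fewer than 3 usable lags")
  s <- k[seq_len(n_use)] * ds
  y <- log(C[seq_len(n_use)])
  fit_prefix <- function(K) {
    f <- stats::lm.fit(cbind(1, s[1:K]), y[1:K])
    ssr <- sum(f$residuals^2)
    sst <- sum((y[1:K] - mean(y[1:K]))^2)
    list(slope = f$coefficients[2], intercept = f$coefficients[1],
         r2 = if (sst > 0) 1 - ssr / sst else 1)
  }
  best <- NULL; bestK <- NA_integer_
  for (K in 3:n_use) {
    f <- fit_prefix(K)
    if (f$r2 >= r2_cutoff) { best <- f; bestK <- K }
  }
  below <- is.null(best)
  if (below) { best <- fit_prefix(3); bestK <- 3L }  # reported with flag
  slope <- unname(best$slope)
  flag <- if (slope >= 0) "no measurable decay" else
    if (below) "r2 below cutoff" else "ok"
  structure(list(
    lp_nm = if (slope < 0) -1 / (2 * slope) else NA_real_,
    ds_nm = ds, slope = slope, intercept = unname(best$intercept),
    r2 = best$r2, lags_used = bestK, n_frames = corr$n_frames, flag = flag),
    class = "PersistenceEstimate")
}

#' @export
print.PersistenceEstimate <- function(x, ...) {
  cat("Persistence length: ",
      if (is.na(x$lp_nm)) x$flag else sprintf("%.1f nm", x$lp_nm),
      sprintf("  (delta_s = %.3g nm, R2 = %.4f, %d lags, %d frames)\n",
              x$ds_nm, x$r2, x$lags_used, x$n_frames), sep = "")
  invisible(x)
}

#' Persistence length of a strand-center ensemble, end to end
#'
#' Convenience wrapper: project each frame's tetramer centers to the membrane
#' plane, build tangent profiles, pool the correlation function and fit l_p.
#'
#' @param centers list of per-frame center matrices (n x 3) or `PolymerTrace`
#'   list.
#' @param k_max largest correlation lag (default: half the interior count).
#' @param r2_cutoff R-squared cutoff for the fit prefix.
#' @param plane,scale passed to [project_trace()] when `centers` are 3D.
#' @return list with `estimate` (`PersistenceEstimate`), `correlation`
#'   (`CorrelationFunction`) and `ds_nm`.
#' @export
persistence_pipeline <- function(centers, k_max = NULL, r2_cutoff = 0.95,
                                 plane = c(1, 2), scale = 1) {
  traces <- if (inherits(centers[[1]], "PolymerTrace")) centers else
    lapply(centers, project_trace, plane = plane, scale = scale)
  profiles <- lapply(traces, tangent_profile)
  if (is.null(k_max))
    k_max <- max(3L, min(vapply(profiles, function(p) length(p$phi), 1L)) %/% 2L)
  corr <- tangent_correlation(profiles, k_max)
  ds <- mean_segment_length(profiles)
  list(estimate = fit_persistence_length(corr, ds, r2_cutoff),
       correlation = corr, ds_nm = ds)
}

#' Write a correlation function and fit summary to disk
#'
#' @param result a [persistence_pipeline()] result.
#' @param csv_path output CSV (`lag, s_nm, C, count`).
#' @param json_path optional JSON summary path.
#' @return `csv_path`, invisibly.
#' @export
write_persistence <- function(result, csv_path, json_path = NULL) {
  corr <- result$correlation
  utils::write.csv(data.frame(lag = corr$lag, s_nm = corr$lag * result$ds_nm,
                              C = corr$C, count = corr$count),
                   csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    e <- result$estimate
    jsonlite::write_json(
      list(lp_nm = e$lp_nm, slope = e$slope, intercept = e$intercept,
           r2 = e$r2, lags_used = e$lags_used, ds_nm = e$ds_nm,
           n_frames = e$n_frames, flag = e$flag),
      json_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(csv_path)
}
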