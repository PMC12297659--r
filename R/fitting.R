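# Exhaustive rigid-body search of a candidate model into a target density.
#
# For every rotation on a deterministic quasi-uniform grid the rotated
# candidate is simulated and slid across the target with an FFT-based
# locally normalized (masked Pearson) correlation scan; pooled poses pass
# non-maximum suppression and the best survive, optionally polished by
# coordinate-ascent refinement. Scores are plain Pearson correlations
# within the moving map's auto-mask, so they are invariant to affine
# intensity changes of the target.

ROTGRID_C_AXIS <- 2.0   # axis-grid density constant (empirically tuned so
ROTGRID_C_PSI <- 1.4    # that covering stays within 1.5 * delta)

#' Fitting parameters
#'
#' @param delta angular step in degrees (0 < delta <= 60).
#' @param top_n number of fits kept after non-maximum suppression.
#' @param nms_translation suppression radius in Å (default 2 voxels,
#'   resolved at fit time when NULL).
#' @param nms_rotation suppression radius in degrees (default `delta`).
#' @param refine polish kept fits by local coordinate ascent.
#' @param mask_level fraction-of-max threshold defining the moving mask.
#' @return An object of class `fit_params`.
#' @export
fit_params <- function(delta = 15, top_n = 20, nms_translation = NULL,
                       nms_rotation = NULL, refine = FALSE,
                       mask_level = 0.1) {
  if (delta <= 0 || delta > 60)
    stop("delta must be in (0, 60] degrees", call. = FALSE)
  if (top_n < 1) stop("top_n must be >= 1", call. = FALSE)
  structure(list(delta = delta, top_n = as.integer(top_n),
                 nms_translation = nms_translation,
                 nms_rotation = if (is.null(nms_rotation)) delta
                                else nms_rotation,
                 refine = isTRUE(refine), mask_level = mask_level),
            class = "fit_params")
}

#' Deterministic quasi-uniform rotation grid
#'
#' Hopf-style construction: a Fibonacci grid of axis directions combined
#' with uniform in-plane angles, with the identity rotation prepended. The
#' grid is dense enough that any rotation lies within 1.5 * delta geodesic
#' of some grid point (property-tested by random sampling); its size grows
#' as delta shrinks.
#'
#' @param delta angular step in degrees (0 < delta <= 60).
#' @return A matrix with one unit quaternion (w, x, y, z) per row.
#' @export
rotation_grid <- function(delta) {
  if (delta <= 0 || delta > 60)
    stop("delta must be in (0, 60] degrees", call. = FALSE)
  d <- delta * pi / 180
  n_axis <- max(1L, ceiling((ROTGRID_C_AXIS / d)^2))
  n_psi <- max(1L, ceiling(2 * pi / (ROTGRID_C_PSI * d)))
  ga <- pi * (3 - sqrt(5))
  Q <- matrix(0, 1L + n_axis * n_psi, 4)
  Q[1, ] <- c(1, 0, 0, 0)
  r <- 2L
  for (i in seq_len(n_axis)) {
    z <- 1 - 2 * (i - 0.5) / n_axis
    rho <- sqrt(max(0, 1 - z^2))
    phi <- (i - 1) * ga
    n <- c(rho * cos(phi), rho * sin(phi), z)
    v <- c(-n[2], n[1], 0)
    s <- sqrt(sum(v^2))
    qa <- if (s < 1e-12) {
      if (n[3] > 0) c(1, 0, 0, 0) else c(0, 1, 0, 0)
    } else quat_from_axis_angle(v / s, atan2(s, n[3]) * 180 / pi)
    for (k in seq_len(n_psi)) {
      Q[r, ] <- quat_mul(qa, quat_from_axis_angle(c(0, 0, 1),
                                                  360 * (k - 1) / n_psi))
      r <- r + 1L
    }
  }
  Q
}

#' FFT translational correlation scan
#'
#' For every integer-voxel offset at which the moving map lies fully
#' inside the target, the Pearson correlation between the moving map
#' (within its fraction-of-max auto-mask) and the overlapping target
#' region. Computed by FFT cross-correlation and defined to equal the
#' direct sliding-window Pearson correlation.
#'
#' @param moving,target [density_map]s with equal voxel sizes; the moving
#'   grid must fit inside the target grid.
#' @param mask_level fraction-of-max level for the moving auto-mask.
#' @return A 3-D array of correlation values, one per offset (0-based
#'   offset `(i-1, j-1, k-1)` at index `[i, j, k]`), with attribute
#'   `n_mask` (number of mask voxels scored at every offset).
#' @export
translational_scan <- function(moving, target, mask_level = 0.1) {
  stopifnot(inherits(moving, "density_map"), inherits(target, "density_map"))
  if (abs(moving$voxel_size - target$voxel_size) >
      1e-6 * target$voxel_size)
    stop("voxel sizes differ; resample required before scanning",
         call. = FALSE)
  if (any(dim(moving$values) > dim(target$values)))
    stop("moving map does not fit inside target", call. = FALSE)
  prep <- cpp_scan_prepare(target$values)
  scan_with_prep(moving$values,
                 auto_mask(moving, "fraction_of_max", mask_level), prep)
}

scan_with_prep <- function(mov_values, mask, prep) {
  out <- cpp_cc_scan(mov_values, mask * 1.0, prep$FB, prep$FB2, prep$mean_sq)
  structure(out$cc, n_mask = out$n_mask)
}

# Apply pose (q, t) about centroid ctr to a coordinate matrix.
apply_pose <- function(xyz, q, t, ctr) {
  sweep(quat_rotate(q, sweep(xyz, 2, ctr)), 2, ctr + t, "+")
}

#' Fit a candidate domain into a target density
#'
#' Scans every rotation-grid orientation with the FFT translational scan,
#' pools all poses, applies non-maximum suppression (a pose is suppressed
#' only when a better kept pose is within `nms_translation` AND
#' `nms_rotation`), and returns the `top_n` fits by correlation. The pose
#' maps candidate point x to `R (x - c) + c + t` with c the candidate
#' centroid.
#'
#' @param candidate an [atomic_model].
#' @param target a [density_map].
#' @param sim a [simulation_params] (voxel size must match the target).
#' @param fp a [fit_params].
#' @param candidate_id id string recorded in the results.
#' @return A data frame of class `fit_results` with columns
#'   `candidate_id`, `rank`, `cc`, `overlap_voxels`, `q1..q4`,
#'   `tx`, `ty`, `tz`; attribute `scan_moments` holds the count, mean and
#'   sd of the Fisher-transformed correlations over every scanned pose
#'   (the scan null used by [global_scores()]).
#' @export
fit_domain <- function(candidate, target, sim, fp = fit_params(),
                       candidate_id = "candidate") {
  stopifnot(inherits(fp, "fit_params"), inherits(sim, "simulation_params"))
  if (!inherits(candidate, "atomic_model") || nrow(candidate) == 0L)
    stop("candidate must be a non-empty atomic_model", call. = FALSE)
  vox <- target$voxel_size
  if (abs(sim$voxel_size - vox) > 1e-6 * vox)
    stop("simulation voxel size must match the target map", call. = FALSE)
  sigma <- sim$resolution / GAUSS_FWHM
  xyz <- coords_of(candidate)
  ctr <- colMeans(xyz)
  xyz0 <- sweep(xyz, 2, ctr)
  half <- max(sqrt(rowSums(xyz0^2))) + GAUSS_RCUT * sigma
  mhalf <- ceiling(half / vox)
  mdim <- rep(2L * mhalf + 1L, 3)
  tdim <- dim(target$values)
  if (any(mdim > tdim))
    stop("candidate extent exceeds the target map", call. = FALSE)
  morigin <- ctr - mhalf * vox
  nms_t <- if (is.null(fp$nms_translation)) 2 * vox else fp$nms_translation
  w <- atom_weights(candidate, sim$weight_mode)

  prep <- cpp_scan_prepare(target$values)
  Q <- rotation_grid(fp$delta)
  keep_per_rot <- max(fp$top_n, 5L)
  pool <- vector("list", nrow(Q))
  n_pose <- 0; s1 <- 0; s2 <- 0
  n_mask <- NA_real_
  for (r in seq_len(nrow(Q))) {
    xr <- sweep(quat_rotate(Q[r, ], xyz0), 2, ctr, "+")
    mov <- cpp_splat(xr, w, mdim, morigin, vox, sigma, GAUSS_RCUT)
    mask <- (mov >= fp$mask_level * max(mov)) * 1.0
    cc <- scan_with_prep(mov, mask, prep)
    n_mask <- attr(cc, "n_mask")
    z <- atanh(pmin(1 - 1e-7, pmax(-1 + 1e-7, as.vector(cc))))
    n_pose <- n_pose + length(z); s1 <- s1 + sum(z); s2 <- s2 + sum(z * z)
    # per-rotation shortlist with greedy translation suppression
    ord <- order(cc, decreasing = TRUE)[seq_len(min(length(cc), 60L))]
    vd <- dim(cc)
    off <- cbind((ord - 1) %% vd[1],
                 ((ord - 1) %/% vd[1]) %% vd[2],
                 (ord - 1) %/% (vd[1] * vd[2]))
    sel <- integer()
    for (i in seq_along(ord)) {
      if (length(sel) >= keep_per_rot) break
      if (!length(sel) ||
          all(sqrt(rowSums(sweep(off[sel, , drop = FALSE], 2,
                                 off[i, ])^2)) * vox > nms_t))
        sel <- c(sel, i)
    }
    pool[[r]] <- data.frame(rot = r, o1 = off[sel, 1], o2 = off[sel, 2],
                            o3 = off[sel, 3], cc = cc[ord[sel]],
                            lin = ord[sel])
  }
  pool <- do.call(rbind, pool)
  pool <- pool[order(-pool$cc, pool$rot, pool$lin), , drop = FALSE]
  kept <- integer()
  for (i in seq_len(nrow(pool))) {
    if (length(kept) >= fp$top_n) break
    ok <- TRUE
    for (j in kept) {
      dt <- sqrt(sum((unlist(pool[i, c("o1", "o2", "o3")]) -
                      unlist(pool[j, c("o1", "o2", "o3")]))^2)) * vox
      dr <- quat_angle_deg(Q[pool$rot[i], ], Q[pool$rot[j], ])
      if (dt <= nms_t && dr <= fp$nms_rotation) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  pool <- pool[kept, , drop = FALSE]
  res <- data.frame(
    candidate_id = candidate_id, rank = seq_len(nrow(pool)),
    cc = pool$cc, overlap_voxels = n_mask,
    q1 = Q[pool$rot, 1], q2 = Q[pool$rot, 2], q3 = Q[pool$rot, 3],
    q4 = Q[pool$rot, 4],
    tx = target$origin[1] + pool$o1 * vox - morigin[1],
    ty = target$origin[2] + pool$o2 * vox - morigin[2],
    tz = target$origin[3] + pool$o3 * vox - morigin[3],
    stringsAsFactors = FALSE)
  if (fp$refine) {
    for (i in seq_len(nrow(res))) {
      ref <- refine_pose(candidate, target, pose_of(res[i, ]), sim,
                         step_ang = fp$delta / 2, step_trans = vox,
                         mask_level = fp$mask_level)
      res$cc[i] <- ref$cc
      res[i, c("q1", "q2", "q3", "q4")] <- as.list(ref$pose$quaternion)
      res[i, c("tx", "ty", "tz")] <- as.list(ref$pose$translation)
    }
    res <- res[order(-res$cc), , drop = FALSE]
    res$rank <- seq_len(nrow(res))
  }
  rownames(res) <- NULL
  structure(res, class = c("fit_results", "data.frame"),
            scan_moments = c(n = n_pose, mean = s1 / n_pose,
                             sd = sqrt(max(0, s2 / n_pose -
                                              (s1 / n_pose)^2))))
}

pose_of <- function(row) {
  list(quaternion = as.numeric(row[c("q1", "q2", "q3", "q4")]),
       translation = as.numeric(row[c("tx", "ty", "tz")]))
}

# Direct correlation of a posed candidate against the target: simulate on
# the target grid and take the masked Pearson correlation.
pose_cc <- function(xyz0, ctr, w, q, t, target, sigma, mask_level) {
  xp <- sweep(quat_rotate(q, xyz0), 2, ctr + t, "+")
  sim <- cpp_splat(xp, w, dim(target$values), target$origin,
                   target$voxel_size, sigma, GAUSS_RCUT)
  mask <- (sim >= mask_level * max(sim)) * 1.0
  cpp_pearson(sim, target$values, mask)
}

#' Correlation of a candidate at an arbitrary pose
#'
#' Simulates the posed candidate on the target grid and returns its masked
#' Pearson correlation — the same score [fit_domain()] assigns at integer
#' offsets, evaluated at any continuous pose.
#'
#' @param candidate an [atomic_model].
#' @param target a [density_map].
#' @param sim a [simulation_params].
#' @param pose list with `quaternion` and `translation`.
#' @param mask_level fraction-of-max level for the moving mask.
#' @return The correlation value.
#' @export
pose_correlation <- function(candidate, target, sim, pose,
                             mask_level = 0.1) {
  stopifnot(inherits(sim, "simulation_params"))
  xyz <- coords_of(candidate)
  ctr <- colMeans(xyz)
  pose_cc(sweep(xyz, 2, ctr), ctr, atom_weights(candidate, sim$weight_mode),
          pose$quaternion / sqrt(sum(pose$quaternion^2)), pose$translation,
          target, sim$resolution / GAUSS_FWHM, mask_level)
}

#' Locally refine a fitted pose
#'
#' Coordinate ascent over the six pose parameters (three incremental
#' rotations about the candidate centroid, three translations) with
#' shrinking steps, starting at `step_ang` degrees and `step_trans` Å and
#' stopping when a full sweep improves the correlation by less than `tol`
#' (or after `max_iter` sweeps). The returned correlation is never below
#' the starting one.
#'
#' @param candidate an [atomic_model].
#' @param target a [density_map].
#' @param pose list with `quaternion` and `translation`.
#' @param sim a [simulation_params].
#' @param step_ang,step_trans initial step sizes (degrees, Å).
#' @param tol convergence tolerance on the correlation.
#' @param max_iter maximum number of sweeps.
#' @param mask_level fraction-of-max level for the moving mask.
#' @return list(pose, cc, trace) where `trace` is the non-decreasing
#'   correlation after each sweep.
#' @export
refine_pose <- function(candidate, target, pose, sim, step_ang = 7.5,
                        step_trans = NULL, tol = 1e-4, max_iter = 50,
                        mask_level = 0.1) {
  stopifnot(inherits(sim, "simulation_params"))
  vox <- target$voxel_size
  if (is.null(step_trans)) step_trans <- vox
  sigma <- sim$resolution / GAUSS_FWHM
  xyz <- coords_of(candidate)
  ctr <- colMeans(xyz)
  xyz0 <- sweep(xyz, 2, ctr)
  w <- atom_weights(candidate, sim$weight_mode)
  q <- pose$quaternion / sqrt(sum(pose$quaternion^2))
  t <- pose$translation
  cc <- pose_cc(xyz0, ctr, w, q, t, target, sigma, mask_level)
  trace <- cc
  sa <- step_ang; st <- step_trans
  axes <- diag(3)
  for (it in seq_len(max_iter)) {
    cc0 <- cc
    for (a in 1:3) for (sgn in c(1, -1)) {
      qq <- quat_mul(quat_from_axis_angle(axes[a, ], sgn * sa), q)
      v <- pose_cc(xyz0, ctr, w, qq, t, target, sigma, mask_level)
      if (v > cc) { cc <- v; q <- qq }
    }
    for (a in 1:3) for (sgn in c(1, -1)) {
      tt <- t; tt[a] <- tt[a] + sgn * st
      v <- pose_cc(xyz0, ctr, w, q, tt, target, sigma, mask_level)
      if (v > cc) { cc <- v; t <- tt }
    }
    trace <- c(trace, cc)
    if (cc - cc0 < tol) {
      if (sa <= step_ang / 8 && st <= step_trans / 8) break
      sa <- sa / 2; st <- st / 2
    }
  }
  list(pose = list(quaternion = q, translation = t), cc = cc, trace = trace)
}
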