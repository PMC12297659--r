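# Candidate scoring and ranking.
#
# Global z: the best correlation standardized against the Fisher-transformed
# distribution of every correlation the scan computed for that candidate
# (its own scan null). The attached tail probability is a normal upper-tail
# heuristic, documented as uncalibrated: ranking relies on z, never on p.
# Local z: correlations of region tiles of the overlap, standardized
# against cohort regions of comparable (within +/- size_bin_width) size, so
# a region scores high only when it matches better than similarly sized
# regions across all candidate fits.

#' Scoring parameters
#'
#' @param region_edge local-region cube edge in voxels (>= 2).
#' @param v_min minimum occupied voxels for a region to be scored (>= 5).
#' @param size_bin_width relative half-width of the "comparable size" bin.
#' @param mask_level fraction-of-max level defining the overlap mask.
#' @return An object of class `score_params`.
#' @export
score_params <- function(region_edge = 8, v_min = 20, size_bin_width = 0.25,
                         mask_level = 0.1) {
  if (region_edge < 2) stop("region_edge must be >= 2", call. = FALSE)
  if (v_min < 5) stop("v_min must be >= 5", call. = FALSE)
  structure(list(region_edge = as.integer(region_edge),
                 v_min = as.integer(v_min),
                 size_bin_width = size_bin_width, mask_level = mask_level),
            class = "score_params")
}

#' Global z-score and tail probability of a best fit
#'
#' All scanned correlations are Fisher-transformed; the global z is the
#' transformed best correlation standardized by the mean and sd of that
#' distribution, and `tail_p` its normal upper-tail probability (a
#' heuristic calibration, not an exact null).
#'
#' @param pose_ccs either a numeric vector of all scanned correlations
#'   (>= 100 of them) or the `scan_moments` attribute of a
#'   [fit_domain()] result (count/mean/sd of the transformed scan).
#' @param best_cc the best correlation.
#' @return list(global_z, tail_p).
#' @export
global_scores <- function(pose_ccs, best_cc) {
  if (is.numeric(pose_ccs) && length(pose_ccs) > 3 && is.null(names(pose_ccs))) {
    if (length(pose_ccs) < 100)
      stop("need >= 100 scanned poses", call. = FALSE)
    z <- atanh(pmin(1 - 1e-7, pmax(-1 + 1e-7, pose_ccs)))
    m <- mean(z); s <- sd(z); n <- length(z)
  } else {
    n <- pose_ccs[["n"]]; m <- pose_ccs[["mean"]]; s <- pose_ccs[["sd"]]
    if (n < 100) stop("need >= 100 scanned poses", call. = FALSE)
  }
  if (!is.finite(s) || s <= 0)
    stop("degenerate scan distribution (sd = 0)", call. = FALSE)
  gz <- (atanh(min(1 - 1e-7, max(-1 + 1e-7, best_cc))) - m) / s
  list(global_z = gz, tail_p = pnorm(gz, lower.tail = FALSE))
}

# Region table of one fit: simulate the posed candidate on the target grid,
# mask the overlap, tile into cubes of region_edge voxels, and score each
# sufficiently occupied tile with a plain Pearson correlation.
region_cc_table <- function(fit_row, candidate, target, sim, sp) {
  stopifnot(inherits(sp, "score_params"))
  sigma <- sim$resolution / GAUSS_FWHM
  xyz <- coords_of(candidate)
  ctr <- colMeans(xyz)
  pose <- pose_of(fit_row)
  xp <- apply_pose(xyz, pose$quaternion, pose$translation, ctr)
  simv <- cpp_splat(xp, atom_weights(candidate, sim$weight_mode),
                    dim(target$values), target$origin, target$voxel_size,
                    sigma, GAUSS_RCUT)
  mask <- simv >= sp$mask_level * max(simv)
  d <- dim(simv)
  e <- sp$region_edge
  idx <- which(mask, arr.ind = TRUE)
  if (!nrow(idx))
    return(data.frame(region = character(), size = integer(),
                      cc = numeric()))
  block <- cbind((idx[, 1] - 1L) %/% e, (idx[, 2] - 1L) %/% e,
                 (idx[, 3] - 1L) %/% e)
  key <- paste(block[, 1], block[, 2], block[, 3], sep = ",")
  lin <- which(mask)
  out <- lapply(split(seq_along(lin), key), function(ii) {
    if (length(ii) < sp$v_min) return(NULL)
    a <- simv[lin[ii]]; b <- target$values[lin[ii]]
    cc <- if (sd(a) == 0 || sd(b) == 0) 0 else suppressWarnings(cor(a, b))
    data.frame(region = key[ii[1]], size = length(ii), cc = cc,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(region = character(), size = integer(), cc = numeric())
  rownames(out) <- NULL
  out
}

#' Local z-scores of a fit's overlap regions
#'
#' Tiles the fit's overlap mask into cubes of `region_edge` voxels, scores
#' each occupied tile by local correlation, and standardizes every region
#' against cohort regions of comparable size (within `size_bin_width`
#' relative). With a degenerate bin (sd = 0) the z is defined as 0; bins
#' with fewer than 5 members give `NA` z with `z_defined = FALSE`.
#'
#' @param fit one row of a [fit_domain()] result.
#' @param candidate the fitted [atomic_model].
#' @param target the target [density_map].
#' @param sim the [simulation_params] used for fitting.
#' @param sp a [score_params].
#' @param cohort data frame with columns `size` and `cc` pooling the
#'   regions of all kept fits of all candidates (see [cohort_regions()]);
#'   defaults to this fit's own regions.
#' @return Data frame with columns `region`, `size`, `cc`, `z`,
#'   `z_defined`.
#' @export
local_z_scores <- function(fit, candidate, target, sim, sp = score_params(),
                           cohort = NULL) {
  regions <- region_cc_table(fit, candidate, target, sim, sp)
  if (!nrow(regions))
    stop("fit has no region with >= v_min occupied voxels", call. = FALSE)
  if (is.null(cohort)) cohort <- regions[, c("size", "cc")]
  z <- numeric(nrow(regions))
  defined <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    s <- regions$size[i]
    bin <- cohort$cc[cohort$size >= s * (1 - sp$size_bin_width) &
                     cohort$size <= s * (1 + sp$size_bin_width)]
    if (length(bin) < 5) { z[i] <- NA_real_; defined[i] <- FALSE; next }
    # leave-one-out: the region must not standardize against itself, or a
    # single aberrant region inflates its own bin sd and hides
    self <- match(regions$cc[i], bin)
    if (!is.na(self) && length(bin) > 2) bin <- bin[-self]
    mu <- mean(bin); sg <- sd(bin)
    z[i] <- if (sg == 0) 0 else (regions$cc[i] - mu) / sg
    defined[i] <- TRUE
  }
  cbind(regions, z = z, z_defined = defined)
}

#' Pool region tables across fits
#'
#' @param fits a [fit_domain()] result (or several rbind-ed).
#' @param candidates named list of [atomic_model]s keyed by
#'   `candidate_id`.
#' @param target the target [density_map].
#' @param sim the [simulation_params] used for fitting.
#' @param sp a [score_params].
#' @return Data frame of all regions (columns `candidate_id`, `rank`,
#'   `region`, `size`, `cc`).
#' @export
cohort_regions <- function(fits, candidates, target, sim,
                           sp = score_params()) {
  out <- lapply(seq_len(nrow(fits)), function(i) {
    tab <- region_cc_table(fits[i, ], candidates[[fits$candidate_id[i]]],
                           target, sim, sp)
    if (nrow(tab))
      cbind(candidate_id = fits$candidate_id[i], rank = fits$rank[i], tab,
            stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Rank candidates
#'
#' Orders candidate score records by global z (descending), breaking ties
#' by best correlation, then mean local z, then candidate id, and assigns
#' ranks 1..n.
#'
#' @param scores data frame with columns `candidate_id`, `best_cc`,
#'   `global_z` and optionally `mean_local_z`, `min_local_z`, `tail_p`.
#' @return The same data frame, ordered, with a `rank` column.
#' @export
rank_candidates <- function(scores) {
  if (!nrow(scores)) stop("no candidates to rank", call. = FALSE)
  if (is.null(scores$mean_local_z)) scores$mean_local_z <- NA_real_
  mlz <- ifelse(is.na(scores$mean_local_z), -Inf, scores$mean_local_z)
  o <- order(-scores$global_z, -scores$best_cc, -mlz, scores$candidate_id)
  scores <- scores[o, , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}
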