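# Quantitative axoneme lattice analyses: repeat bookkeeping for filament
# picking, spiral-layout periodicity, axial overlap counting, bridge
# occupancy classification and C1-C2 edge distances. This module works in
# nm throughout (10 Å/nm conversion happens at module boundaries).

#' Expected unique-particle fraction of a repeat reconstruction
#'
#' Particles picked every `pick_interval` along a filament whose true
#' period is `repeat_length` fall into `repeat_length / pick_interval`
#' phase classes; only one class represents a given repeat position, so
#' ideally `pick_interval / repeat_length` of the picks contribute to the
#' long-repeat reconstruction (8-nm picks against a 32-nm repeat: 25%).
#'
#' @param pick_interval picking interval in nm.
#' @param repeat_length structural repeat in nm; `pick_interval` must
#'   divide it.
#' @return The fraction in (0, 1].
#' @export
expected_unique_fraction <- function(pick_interval, repeat_length) {
  if (pick_interval <= 0 || repeat_length <= 0)
    stop("intervals must be positive", call. = FALSE)
  if (pick_interval > repeat_length)
    stop("pick_interval must be <= repeat_length", call. = FALSE)
  r <- repeat_length / pick_interval
  if (abs(r - round(r)) > 1e-9)
    stop("pick_interval must divide repeat_length", call. = FALSE)
  pick_interval / repeat_length
}

#' Remove duplicate particles within a minimum arc separation
#'
#' Greedy per-filament sweep: the first particle of each filament is kept
#' and every subsequent particle closer than `min_sep` (along arc) to the
#' last kept one is dropped. Idempotent; this is the interval-removal step
#' applied before 16-nm and 32-nm repeat reconstructions.
#'
#' @param table a [particle_table] (sorted per its invariant).
#' @param min_sep minimum arc separation in nm.
#' @return A [particle_table] of the kept particles.
#' @export
dedup_particles <- function(table, min_sep) {
  stopifnot(inherits(table, "particle_table"))
  keep <- unlist(lapply(split(seq_len(nrow(table)), table$filament_id),
                        function(ii) {
    arcs <- table$arc_nm[ii]
    k <- logical(length(ii))
    last <- -Inf
    for (j in seq_along(ii)) {
      if (arcs[j] - last >= min_sep - 1e-9) { k[j] <- TRUE; last <- arcs[j] }
    }
    ii[k]
  }), use.names = FALSE)
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' A spiral layout pattern
#'
#' One symbol per spiral layer at fixed layer spacing, e.g. the repeating
#' `"AAAB"` layout at 8-nm layers whose period is 32 nm.
#'
#' @param layout non-empty string over a finite alphabet.
#' @param layer_spacing spacing between layers in nm.
#' @return An object of class `layout_pattern`.
#' @export
layout_pattern <- function(layout, layer_spacing) {
  if (!nzchar(layout)) stop("layout must be non-empty", call. = FALSE)
  if (layer_spacing <= 0) stop("layer spacing must be > 0", call. = FALSE)
  structure(list(layout = layout, layer_spacing = layer_spacing),
            class = "layout_pattern")
}

#' Longitudinal periodicity of a layout pattern
#'
#' Length of the minimal repeating unit of the layout string times the
#' layer spacing.
#'
#' @param lp a [layout_pattern].
#' @return Period in nm.
#' @export
pattern_period <- function(lp) {
  stopifnot(inherits(lp, "layout_pattern"))
  s <- strsplit(lp$layout, "")[[1]]
  n <- length(s)
  for (p in seq_len(n)) {
    if (n %% p == 0 && all(s == rep_len(s[seq_len(p)], n)))
      return(p * lp$layer_spacing)
  }
  n * lp$layer_spacing
}

#' Number of axially overlapping copies of a long element
#'
#' Identical elements of length `element_length` whose start points recur
#' every `spacing` cover a generic axial position with
#' `ceiling(element_length / spacing)` copies (a 33-nm element every 16 nm:
#' three copies).
#'
#' @param element_length element length in nm.
#' @param spacing start-to-start spacing in nm.
#' @return Integer copy count.
#' @export
overlap_count <- function(element_length, spacing) {
  if (element_length <= 0 || spacing <= 0)
    stop("lengths must be positive", call. = FALSE)
  as.integer(ceiling(element_length / spacing))
}

#' Occupancy-classification parameters
#'
#' @param probe_centers 2 x 3 matrix of probe sphere centres (nm, world
#'   coordinates of the subvolume frame) at the two expected connective
#'   density sites.
#' @param probe_radius probe sphere radius in nm.
#' @param theta detection threshold in background-sd units (default 3).
#' @param tubule_centers 2 x 2 matrix of tubule axis (x, y) positions (nm),
#'   axes along z, excluded from the background.
#' @param tubule_exclude_radius radial exclusion around each tubule axis
#'   (nm).
#' @param sd_floor_frac floor on the background sd used in the detection
#'   threshold, as a fraction of the subvolume maximum. Guards the
#'   degenerate noise-free background whose sd would otherwise be ~0, which
#'   makes any density tail read as "present".
#' @return An object of class `occupancy_params`.
#' @export
occupancy_params <- function(probe_centers, probe_radius = 4, theta = 3,
                             tubule_centers = NULL,
                             tubule_exclude_radius = 0,
                             sd_floor_frac = 0.01) {
  probe_centers <- as.matrix(probe_centers)
  if (nrow(probe_centers) != 2L || ncol(probe_centers) != 3L)
    stop("probe_centers must be a 2 x 3 matrix", call. = FALSE)
  if (probe_radius <= 0 || theta <= 0)
    stop("probe_radius and theta must be > 0", call. = FALSE)
  structure(list(probe_centers = probe_centers, probe_radius = probe_radius,
                 theta = theta, tubule_centers = tubule_centers,
                 tubule_exclude_radius = tubule_exclude_radius,
                 sd_floor_frac = sd_floor_frac),
            class = "occupancy_params")
}

voxel_axes <- function(map) {
  d <- dim(map$values)
  lapply(1:3, function(a) map$origin[a] + (seq_len(d[a]) - 1) * map$voxel_size)
}

#' Classify bridge-density occupancy across subvolumes
#'
#' A probe site is "present" when the mean density inside its spherical
#' mask exceeds the background mean by `theta` background standard
#' deviations; the background is the subvolume outside both probes and
#' outside the tubule exclusion cylinders. Particles are classified
#' both/one/none by the number of present probes.
#'
#' @param subvolumes list of [density_map]s (nm units).
#' @param op an [occupancy_params]; probes must lie inside every grid.
#' @return An object of class `occupancy_result`: counts and fractions per
#'   state plus the per-particle `states` vector.
#' @export
classify_occupancy <- function(subvolumes, op) {
  stopifnot(inherits(op, "occupancy_params"))
  states <- vapply(subvolumes, function(map) {
    ax <- voxel_axes(map)
    rng <- vapply(ax, range, numeric(2))
    for (k in 1:2) {
      ctr <- op$probe_centers[k, ]
      if (any(ctr - op$probe_radius < rng[1, ] - 1e-9) ||
          any(ctr + op$probe_radius > rng[2, ] + 1e-9))
        stop("probe sphere extends outside the subvolume grid",
             call. = FALSE)
    }
    d <- dim(map$values)
    X <- array(rep(ax[[1]], times = d[2] * d[3]), d)
    Y <- array(rep(rep(ax[[2]], each = d[1]), times = d[3]), d)
    Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)
    tub <- array(FALSE, d)
    if (!is.null(op$tubule_centers)) {
      for (k in seq_len(nrow(op$tubule_centers))) {
        tc <- op$tubule_centers[k, ]
        tub <- tub | ((X - tc[1])^2 + (Y - tc[2])^2 <=
                        op$tubule_exclude_radius^2)
      }
    }
    # probes exclude the tubule cylinders too: the gap is narrow and the
    # shell shoulders would otherwise leak into the probe means
    pr <- lapply(1:2, function(k) {
      ctr <- op$probe_centers[k, ]
      sph <- (X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2 <=
        op$probe_radius^2
      m <- sph & !tub
      if (!any(m))
        stop("probe mask empty after tubule exclusion", call. = FALSE)
      m
    })
    bg <- !(pr[[1]] | pr[[2]]) & !tub
    mu <- mean(map$values[bg])
    sg <- max(sd(map$values[bg]), op$sd_floor_frac * max(map$values))
    thr <- mu + op$theta * sg
    present <- vapply(pr, function(m) mean(map$values[m]) > thr, logical(1))
    c("none", "one", "both")[sum(present) + 1L]
  }, character(1))
  n <- length(states)
  counts <- c(both = sum(states == "both"), one = sum(states == "one"),
              none = sum(states == "none"))
  structure(list(counts = counts, fractions = counts / n, n = n,
                 states = states),
            class = "occupancy_result")
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> n = %d: both %.1f%%, one %.1f%%, none %.1f%%\n",
              x$n, 100 * x$fractions["both"], 100 * x$fractions["one"],
              100 * x$fractions["none"]))
  invisible(x)
}

# Fit a tubule axis near a seed point: per z-slice intensity-weighted
# centroid within a radial neighbourhood, then the principal line through
# the centroids. The neighbourhood is re-centred on the fitted axis and the
# fit repeated: a disc centred on the nominal seed crops a displaced shell
# asymmetrically and shrinks the displacement estimate toward the seed.
fit_tubule_axis <- function(map, seed_xy, neighborhood_radius, iters = 3) {
  ax <- voxel_axes(map)
  d <- dim(map$values)
  X <- matrix(rep(ax[[1]], times = d[2]), d[1], d[2])
  Y <- matrix(rep(ax[[2]], each = d[1]), d[1], d[2])
  center <- seed_xy
  for (it in seq_len(iters)) {
    sel <- (X - center[1])^2 + (Y - center[2])^2 <= neighborhood_radius^2
    cents <- matrix(NA_real_, d[3], 3)
    for (k in seq_len(d[3])) {
      w <- pmax(map$values[, , k][sel], 0)
      tw <- sum(w)
      if (tw <= 0) next
      cents[k, ] <- c(sum(w * X[sel]) / tw, sum(w * Y[sel]) / tw, ax[[3]][k])
    }
    cents <- cents[stats::complete.cases(cents), , drop = FALSE]
    if (nrow(cents) < 3)
      stop("tubule axis undefined: fewer than 3 usable slices", call. = FALSE)
    new_center <- colMeans(cents)[1:2]
    moved <- sqrt(sum((new_center - center)^2))
    center <- new_center
    if (moved < 1e-3) break
  }
  ctr <- colMeans(cents)
  v <- prcomp(cents, center = TRUE)$rotation[, 1]
  if (v[3] < 0) v <- -v
  list(point = ctr, dir = v / sqrt(sum(v^2)))
}

#' Edge distance between two tubules in a subvolume
#'
#' Fits each tubule axis as the principal line through intensity-weighted
#' slice centroids (slices perpendicular to the nominal filament axis z,
#' restricted to a radial neighbourhood of the seed) and returns the
#' inter-axis distance minus two tubule radii. The radius is supplied, not
#' estimated, which makes the "edge" definition explicit.
#'
#' @param subvolume a [density_map] (nm units).
#' @param seeds 2 x 2 or 2 x 3 matrix of per-tubule seed positions (x, y
#'   used) in nm.
#' @param tubule_radius tubule radius in nm.
#' @param neighborhood extra radial margin around `tubule_radius` defining
#'   the per-tubule neighbourhood (nm).
#' @return Edge distance in nm.
#' @export
edge_distance <- function(subvolume, seeds, tubule_radius,
                          neighborhood = 4) {
  stopifnot(inherits(subvolume, "density_map"))
  seeds <- as.matrix(seeds)
  if (nrow(seeds) != 2L) stop("need exactly 2 seed points", call. = FALSE)
  rad <- tubule_radius + neighborhood
  a1 <- fit_tubule_axis(subvolume, seeds[1, 1:2], rad)
  a2 <- fit_tubule_axis(subvolume, seeds[2, 1:2], rad)
  v <- a1$dir + a2$dir
  v <- v / sqrt(sum(v^2))
  dp <- a2$point - a1$point
  perp <- dp - sum(dp * v) * v
  sqrt(sum(perp^2)) - 2 * tubule_radius
}

#' Compare two sets of distances
#'
#' Welch's two-sample t test (two-sided) by default; `pooled = TRUE` gives
#' the classical equal-variance Student test. Degenerate equal constant
#' sets give t = 0, p = 1.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param pooled use the pooled-variance test.
#' @return list with means, sds, ns, `statistic`, `p_value`, `method`.
#' @export
compare_distance_sets <- function(a, b, pooled = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    stop("each set needs n >= 2", call. = FALSE)
  rec <- list(mean_a = mean(a), sd_a = sd(a), n_a = length(a),
              mean_b = mean(b), sd_b = sd(b), n_b = length(b))
  if (sd(a) == 0 && sd(b) == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    rec$statistic <- if (eq) 0 else Inf
    rec$p_value <- if (eq) 1 else 0
    rec$method <- "degenerate (zero variance)"
    return(rec)
  }
  tt <- t.test(a, b, var.equal = pooled)
  rec$statistic <- unname(tt$statistic)
  rec$p_value <- tt$p.value
  rec$method <- tt$method
  rec
}
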