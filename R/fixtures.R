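# Synthetic-data generators. Every generator is a pure function of its
# arguments including the seed, so downstream stages can be tested by
# parameter recovery with no deposited data.

#' Generate a backbone-only toy domain
#'
#' Traces one pseudo-atom per residue (named CA) along a parametric curve:
#' `helix_bundle` packs ~30-residue helices of markedly unequal,
#' seed-dependent lengths and tilts around an irregular polygon of axes,
#' `slab` lays antiparallel extended strands into a sheet-like zigzag, and
#' `coil` follows a momentum-smoothed random walk with a 3.8 Å step under
#' soft radial confinement. Deliberate per-seed irregularity keeps the
#' shapes asymmetric (pose recovery is otherwise ill-posed at ~8 Å, where
#' helices are nearly apolar rods) and compact enough that the rotating
#' model's bounding box fits the scene grids used throughout.
#'
#' @param kind `"helix_bundle"`, `"slab"` or `"coil"`.
#' @param n_residues number of residues (>= 5).
#' @param seed RNG seed.
#' @return An [atomic_model] with one CA atom per residue.
#' @export
make_toy_domain <- function(kind = c("helix_bundle", "slab", "coil"),
                            n_residues, seed = 1) {
  kind <- match.arg(kind)
  if (n_residues < 5) stop("n_residues must be >= 5", call. = FALSE)
  xyz <- with_seed(seed, switch(kind,
    helix_bundle = toy_helix_bundle(n_residues),
    slab = toy_slab(n_residues),
    coil = toy_coil(n_residues)))
  atomic_model(data.frame(
    element = "C", chain = "A", resno = seq_len(n_residues), resname = "ALA",
    atom = "CA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b = 0, stringsAsFactors = FALSE))
}

toy_helix_bundle <- function(n) {
  nh <- max(3L, ceiling(n / 30))         # ~30 residues (45 Å) per helix
  # markedly unequal helix lengths: real bundles are asymmetric, and a
  # near-symmetric phantom would make pose recovery ill-posed
  wt <- runif(nh, 0.7, 1.3)
  lens <- pmax(5L, as.integer(round(n * wt / sum(wt))))
  # cap the longest helix so the bundle stays compact enough for scene boxes
  cap <- as.integer(ceiling(1.15 * n / nh))
  lens <- pmin(lens, cap)
  lens[nh] <- n - sum(lens[-nh])
  if (lens[nh] < 5L) { lens[1] <- lens[1] + lens[nh] - 5L; lens[nh] <- 5L }
  if (lens[nh] > cap) {
    lens[1] <- lens[1] + lens[nh] - cap; lens[nh] <- cap
  }
  # irregular polygon of helix axis anchor points in the xy plane
  th <- 2 * pi * (seq_len(nh) - 1) / nh + rnorm(nh, sd = 0.35)
  rad <- 6.5 + rnorm(nh, sd = 1.2)
  anchors <- cbind(rad * cos(th), rad * sin(th))
  pts <- vector("list", nh)
  for (h in seq_len(nh)) {
    m <- lens[h]
    t <- seq_len(m)
    helix <- cbind(2.3 * cos(t * 100 * pi / 180),
                   2.3 * sin(t * 100 * pi / 180),
                   1.5 * t)
    if (h %% 2 == 0) helix[, 3] <- -helix[, 3]       # antiparallel packing
    tilt <- quat_from_axis_angle(rnorm(3), rnorm(1, sd = 6))
    helix <- quat_rotate(tilt, helix)
    helix[, 1] <- helix[, 1] + anchors[h, 1]
    helix[, 2] <- helix[, 2] + anchors[h, 2]
    helix[, 3] <- helix[, 3] - mean(helix[, 3]) + rnorm(1, sd = 1)
    pts[[h]] <- helix
  }
  do.call(rbind, pts)
}

toy_slab <- function(n) {
  per <- max(5L, ceiling(sqrt(n * 1.5)))
  strand <- 0L
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    j <- (i - 1L) %% per
    if (j == 0L && i > 1L) strand <- strand + 1L
    flip <- if (strand %% 2L == 0L) j else per - 1L - j  # antiparallel
    out[i, ] <- c(3.4 * flip + 0.6 * (j %% 2),
                  4.8 * strand + 1.1 * (strand %% 3 == 0),
                  1.4 * (j %% 2) + 0.3 * strand)
  }
  out + matrix(rnorm(3 * n, sd = 0.35), n, 3)
}

toy_coil <- function(n) {
  # momentum-smoothed random walk with a soft radial confinement so the
  # chain stays globular (fits compact scene boxes)
  dirs <- matrix(rnorm(3 * n), n, 3)
  v <- dirs[1, ] / sqrt(sum(dirs[1, ]^2))
  out <- matrix(0, n, 3)
  r0 <- 10                    # soft confinement radius (Å)
  for (i in 2:n) {
    p <- out[i - 1, ]
    r <- sqrt(sum(p^2))
    pull <- if (r > r0) -0.08 * (r - r0) / r * p else c(0, 0, 0)
    v <- 0.7 * v + 0.3 * dirs[i, ] / sqrt(sum(dirs[i, ]^2)) + pull
    v <- v / sqrt(sum(v^2))
    out[i, ] <- out[i - 1, ] + 3.8 * v
  }
  out
}

#' Generate a block-structured PAE matrix
#'
#' Within-block entries are drawn around `intra_pae` and between-block
#' entries around `inter_pae` (Gaussian jitter of sd `jitter_sd`, clamped
#' to `[0, max_pae]`); the diagonal is 0. This is the error structure a
#' predictor emits for a chain of internally rigid units with uncertain
#' relative placement.
#'
#' @param block_sizes integer vector of block lengths (residues), all >= 1.
#' @param intra_pae,inter_pae within/between-block mean error in Å;
#'   `intra_pae < inter_pae` required.
#' @param jitter_sd Gaussian jitter sd in Å.
#' @param seed RNG seed.
#' @param max_pae cap in Å.
#' @return A [pae_matrix] of size `sum(block_sizes)`.
#' @export
make_pae_blocks <- function(block_sizes, intra_pae, inter_pae,
                            jitter_sd = 0, seed = 1, max_pae = 31.75) {
  if (any(block_sizes < 1)) stop("block sizes must be >= 1", call. = FALSE)
  if (intra_pae >= inter_pae)
    stop("intra_pae must be < inter_pae", call. = FALSE)
  L <- sum(block_sizes)
  lab <- rep(seq_along(block_sizes), block_sizes)
  base <- matrix(inter_pae, L, L)
  same <- outer(lab, lab, "==")
  base[same] <- intra_pae
  m <- with_seed(seed, base + matrix(rnorm(L * L, sd = jitter_sd), L, L))
  m[m < 0] <- 0
  m[m > max_pae] <- max_pae
  diag(m) <- 0
  structure(pae_matrix(m, max_pae), blocks = lab)
}

#' Generate a fitting scene with a planted candidate
#'
#' Simulates the density of one candidate at a planted pose and adds white
#' noise, recording the ground truth for parameter-recovery tests. The
#' pose convention matches [fit_domain()]: a point x of the candidate maps
#' to `R (x - c) + c + t`, with c the candidate's original centroid.
#'
#' @param candidates list of [atomic_model]s (the search library).
#' @param true_index which candidate is actually in the map.
#' @param pose `NULL` for a seed-drawn random pose, or a list with
#'   `quaternion` (length 4) and `translation` (length 3, Å).
#' @param resolution,voxel simulation resolution and voxel size in Å
#'   (`resolution >= 2 * voxel`).
#' @param noise_sd_rel white-noise sd relative to the signal sd.
#' @param seed RNG seed.
#' @param dim optional integer(3): force the map dimensions (grid centred
#'   on the posed candidate); default spans the bounding box + `padding`.
#' @param padding bounding-box margin in Å when `dim` is NULL.
#' @return list(map = [density_map], truth = `scene_truth` with fields
#'   `candidate_index`, `quaternion`, `translation`, `noise_sd_rel`, `seed`).
#' @export
make_scene <- function(candidates, true_index, pose = NULL, resolution = 8,
                       voxel = 2, noise_sd_rel = 0, seed = 1, dim = NULL,
                       padding = 10) {
  if (true_index < 1 || true_index > length(candidates))
    stop("true_index out of range", call. = FALSE)
  if (resolution < 2 * voxel)
    stop("resolution must be >= 2 * voxel", call. = FALSE)
  model <- candidates[[true_index]]
  if (is.null(pose)) {
    pose_seed <- (abs(seed) %% 100000000) * 7 + 3   # decouple from noise seed
    pose <- with_seed(pose_seed, list(
      quaternion = quat_random(),
      translation = runif(3, -1.5, 1.5) * voxel))
  }
  q <- pose$quaternion / sqrt(sum(pose$quaternion^2))
  ctr <- colMeans(coords_of(model))
  posed <- model
  xyz <- sweep(quat_rotate(q, sweep(coords_of(model), 2, ctr)), 2,
               ctr + pose$translation, "+")
  posed$x <- xyz[, 1]; posed$y <- xyz[, 2]; posed$z <- xyz[, 3]
  sp <- simulation_params(resolution, voxel, padding = padding)
  grid <- NULL
  if (!is.null(dim)) {
    dim <- as.integer(dim)
    org <- colMeans(xyz) - (dim - 1) / 2 * voxel
    grid <- list(dim = dim, origin = org)
  }
  map <- simulate_map(posed, sp, grid = grid)
  map <- add_noise(map, noise_sd_rel, seed = seed)
  truth <- structure(list(candidate_index = true_index, quaternion = q,
                          translation = pose$translation,
                          noise_sd_rel = noise_sd_rel, seed = seed),
                     class = "scene_truth")
  list(map = map, truth = truth)
}

#' Generate a filament particle table with known repeat phases
#'
#' Particles are picked at fixed arc intervals along straight filaments of
#' random orientation; each particle's true phase index within the longer
#' repeat is recorded, mimicking pickers that crop at a fixed spacing over
#' a structure whose true period is a multiple of that spacing.
#'
#' @param n_filaments number of filaments.
#' @param filament_length filament length in nm (>= `repeat_length`).
#' @param pick_interval picking interval in nm; must divide `repeat_length`.
#' @param repeat_length true structural repeat in nm.
#' @param seed RNG seed.
#' @return list(table = [particle_table], phase = integer vector of true
#'   phase indices in `[0, repeat_length / pick_interval)`).
#' @export
make_filament_table <- function(n_filaments, filament_length, pick_interval,
                                repeat_length, seed = 1) {
  if (pick_interval <= 0 || repeat_length <= 0)
    stop("intervals must be positive", call. = FALSE)
  if (abs(repeat_length / pick_interval -
          round(repeat_length / pick_interval)) > 1e-9)
    stop("pick_interval must divide repeat_length", call. = FALSE)
  if (filament_length < repeat_length)
    stop("filament_length must be >= repeat_length", call. = FALSE)
  n_phase <- round(repeat_length / pick_interval)
  with_seed(seed, {
    rows <- vector("list", n_filaments)
    phases <- vector("list", n_filaments)
    for (f in seq_len(n_filaments)) {
      arc <- seq(0, filament_length - pick_interval, by = pick_interval)
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      base <- runif(3, -200, 200)
      xyz <- sweep(outer(arc, dir), 2, base, "+")
      tilt <- acos(max(-1, min(1, dir[3]))) * 180 / pi
      psi <- atan2(dir[2], dir[1]) * 180 / pi
      rows[[f]] <- data.frame(
        filament_id = sprintf("fil%03d", f), arc_nm = arc,
        x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3],
        tilt_deg = tilt, psi_deg = psi, stringsAsFactors = FALSE)
      phases[[f]] <- as.integer(round(arc / pick_interval) %% n_phase)
    }
    list(table = particle_table(do.call(rbind, rows)),
         phase = unlist(phases))
  })
}

#' Generate two-cylinder bridge phantoms
#'
#' Each subvolume holds two parallel cylindrical shells (tubule stand-ins,
#' axes along z) separated by `center_distance`, with 2, 1 or 0 connective
#' rods spanning the gap according to a per-particle state drawn from
#' `fractions`. The two rod sites sit at z = ±8 nm, the spacing of the two
#' bridge densities within one 32-nm repeat. All geometry is in nm; the
#' returned maps carry nm voxel sizes.
#'
#' @param n_particles number of subvolumes.
#' @param fractions length-3 numeric (both, one, none) summing to 1.
#' @param center_distance mean axis-to-axis tubule distance in nm.
#' @param tubule_radius tubule radius in nm (default 12.5, a 25-nm
#'   microtubule).
#' @param rod_amp rod peak amplitude relative to the shell amplitude of 1.
#' @param noise_sd_rel white-noise sd relative to the signal sd.
#' @param voxel voxel size in nm.
#' @param seed RNG seed.
#' @param box_nm cubic subvolume edge in nm.
#' @param distance_sd per-particle Gaussian sd of the centre distance (nm).
#' @return list(maps = list of [density_map], truth = `bridge_phantom_truth`
#'   with per-particle `state`, `center_distance`, the rod site z offsets,
#'   geometry and seed).
#' @export
make_bridge_phantoms <- function(n_particles, fractions = c(1, 0, 0),
                                 center_distance = 35, tubule_radius = 12.5,
                                 rod_amp = 1, noise_sd_rel = 0, voxel = 2,
                                 seed = 1, box_nm = 72, distance_sd = 0) {
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("fractions must sum to 1", call. = FALSE)
  if (center_distance <= 2 * tubule_radius)
    stop("center_distance must exceed the tubule diameter", call. = FALSE)
  shell_sd <- 1.5; rod_sd <- 2; rod_z <- c(-8, 8)
  if (center_distance + 2 * tubule_radius + 5 * shell_sd > box_nm)
    stop("geometry does not fit inside the subvolume box", call. = FALSE)
  n <- as.integer(round(box_nm / voxel))
  org <- -(n - 1) / 2 * voxel
  ax <- org + (seq_len(n) - 1) * voxel
  X <- array(rep(ax, times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax, each = n), times = n), c(n, n, n))
  Z <- array(rep(ax, each = n * n), c(n, n, n))
  states <- c("both", "one", "none")
  with_seed(seed, {
    st <- sample(states, n_particles, replace = TRUE, prob = fractions)
    dists <- center_distance + rnorm(n_particles, sd = distance_sd)
    which_rod <- sample(1:2, n_particles, replace = TRUE)
    maps <- vector("list", n_particles)
    for (p in seq_len(n_particles)) {
      d <- dists[p]
      r1 <- sqrt((X + d / 2)^2 + Y^2)
      r2 <- sqrt((X - d / 2)^2 + Y^2)
      sig <- exp(-(r1 - tubule_radius)^2 / (2 * shell_sd^2)) +
             exp(-(r2 - tubule_radius)^2 / (2 * shell_sd^2))
      rods <- switch(st[p], both = 1:2, one = which_rod[p], none = integer())
      for (k in rods) {
        between <- abs(X) <= d / 2
        sig <- sig + rod_amp * between *
          exp(-(Y^2 + (Z - rod_z[k])^2) / (2 * rod_sd^2))
      }
      if (noise_sd_rel > 0)
        sig <- sig + array(rnorm(length(sig), sd = noise_sd_rel *
                                   sd(as.vector(sig))), dim(sig))
      maps[[p]] <- density_map(sig, voxel, c(org, org, org))
    }
    truth <- structure(list(state = st, center_distance = dists,
                            rod_z = rod_z, tubule_radius = tubule_radius,
                            rod_site = which_rod, seed = seed),
                       class = "bridge_phantom_truth")
    list(maps = maps, truth = truth)
  })
}
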