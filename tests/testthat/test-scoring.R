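test_that("global scores standardize the Fisher-transformed scan", {
  expect_error(global_scores(rep(0.5, 200), 0.5), "degenerate")
  expect_error(global_scores(rnorm(50, 0, 0.1), 0.5), ">= 100")
  # a scan symmetric in Fisher space around its centre scores z = 0 there
  z <- seq(-1, 1, length.out = 201) * 0.8
  ccs <- tanh(0.2 + z)
  gs <- global_scores(ccs, tanh(0.2))
  expect_equal(gs$global_z, 0, tolerance = 1e-12)
  expect_equal(gs$tail_p, 0.5, tolerance = 1e-12)
  # moment-form input agrees with the raw vector
  zz <- atanh(pmin(1 - 1e-7, pmax(-1 + 1e-7, ccs)))
  gs2 <- global_scores(c(n = length(zz), mean = mean(zz),
                         sd = sd(zz) * sqrt(200 / 201)), tanh(0.2))
  expect_equal(gs2$global_z, 0, tolerance = 1e-9)
})

test_that("ranking orders by global z with documented tie-breaks", {
  one <- data.frame(candidate_id = "a", best_cc = 0.5, global_z = 3)
  expect_equal(rank_candidates(one)$rank, 1L)
  two <- data.frame(candidate_id = c("a", "b"), best_cc = c(0.8, 0.9),
                    global_z = c(5, 5))
  r <- rank_candidates(two)
  expect_equal(r$candidate_id, c("b", "a"))
  three <- data.frame(candidate_id = c("x", "y"), best_cc = c(0.9, 0.9),
                      global_z = c(5, 5), mean_local_z = c(0.1, 0.7))
  expect_equal(rank_candidates(three)$candidate_id[1], "y")
})

scene_with_fit <- function(seed, noise = 0) {
  mod <- make_toy_domain("helix_bundle", 80, seed)
  sp <- simulation_params(8, 2)
  sc <- make_scene(list(mod), 1, resolution = 8, voxel = 2,
                   noise_sd_rel = noise, seed = seed, dim = c(44, 44, 44))
  fit <- fit_domain(mod, sc$map, sp, fit_params(delta = 60, top_n = 2))
  list(mod = mod, sp = sp, sc = sc, fit = fit)
}

test_that("local z-scores standardize to zero mean within the cohort", {
  s <- scene_with_fit(12)
  sp_sc <- score_params(region_edge = 6, v_min = 10)
  regions <- cohort_regions(s$fit, setNames(list(s$mod, s$mod),
                                            unique(s$fit$candidate_id)),
                            s$sc$map, s$sp, sp_sc)
  expect_gt(nrow(regions), 3)
  lz <- local_z_scores(s$fit[1, ], s$mod, s$sc$map, s$sp, sp_sc,
                       cohort = regions[, c("size", "cc")])
  expect_true(all(lz$size >= 10))
  # identical cohorts (duplicated region) give z = 0 under sd = 0
  dup <- regions[rep(1, 6), c("size", "cc")]
  lz0 <- local_z_scores(s$fit[1, ], s$mod, s$sc$map, s$sp,
                        score_params(region_edge = 6, v_min = 10,
                                     size_bin_width = 1e-9),
                        cohort = dup)
  hit <- lz0$size == dup$size[1]
  expect_true(all(lz0$z[hit & lz0$z_defined] == 0))
  # sparse bins are flagged undefined, not errors
  tiny <- regions[1:2, c("size", "cc")]
  lz2 <- local_z_scores(s$fit[1, ], s$mod, s$sc$map, s$sp,
                        score_params(region_edge = 6, v_min = 10,
                                     size_bin_width = 1e-9),
                        cohort = tiny)
  expect_true(any(!lz2$z_defined))
  expect_true(all(is.na(lz2$z[!lz2$z_defined])))
})

test_that("a locally corrupted region scores the lowest local z", {
  for (seed in 1:6) {
    mod <- make_toy_domain("helix_bundle", 80, seed)
    sp <- simulation_params(8, 2)
    sc <- make_scene(list(mod), 1, resolution = 8, voxel = 2, seed = seed,
                     dim = c(44, 44, 44))
    truth_fit <- data.frame(candidate_id = "true", rank = 1L, cc = 1,
                            overlap_voxels = NA_real_,
                            q1 = sc$truth$quaternion[1],
                            q2 = sc$truth$quaternion[2],
                            q3 = sc$truth$quaternion[3],
                            q4 = sc$truth$quaternion[4],
                            tx = sc$truth$translation[1],
                            ty = sc$truth$translation[2],
                            tz = sc$truth$translation[3])
    sp_sc <- score_params(region_edge = 6, v_min = 10,
                          size_bin_width = 0.6)
    lz <- local_z_scores(truth_fit, mod, sc$map, sp, sp_sc)
    lz <- lz[lz$z_defined, ]
    expect_gte(nrow(lz), 3)
    # corrupt the largest defined region's cube with strong noise
    pick <- lz$region[which.max(lz$size)]
    blk <- as.integer(strsplit(pick, ",")[[1]])
    tgt <- sc$map
    ii <- lapply(1:3, function(a) pmin(dim(tgt$values)[a], blk[a] * 6L + 1:6))
    old <- tgt$values[ii[[1]], ii[[2]], ii[[3]]]
    set.seed(seed)
    tgt$values[ii[[1]], ii[[2]], ii[[3]]] <-
      old + rnorm(length(old), sd = 8 * sd(tgt$values))
    lz2 <- local_z_scores(truth_fit, mod, tgt, sp, sp_sc)
    lz2 <- lz2[lz2$z_defined, ]
    expect_equal(lz2$region[which.min(lz2$z)], pick)
  }
})

test_that("degrading a pose never raises its global z on noiseless scenes", {
  for (seed in c(3, 8)) {
    s <- scene_with_fit(seed)
    mom <- attr(s$fit, "scan_moments")
    at_truth <- pose_correlation(
      s$mod, s$sc$map, s$sp,
      list(quaternion = s$sc$truth$quaternion,
           translation = s$sc$truth$translation))
    for (ang in c(20, 40, 90)) {
      worse <- pose_correlation(
        s$mod, s$sc$map, s$sp,
        list(quaternion = quat_mul(quat_from_axis_angle(c(1, 0, 0), ang),
                                   s$sc$truth$quaternion),
             translation = s$sc$truth$translation + c(5, 0, 0)))
      expect_gt(global_scores(mom, at_truth)$global_z,
                global_scores(mom, worse)$global_z)
    }
  }
})
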