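test_that("rotation grid covers SO(3) and includes the identity", {
  g60 <- rotation_grid(60)
  expect_equal(g60[1, ], c(1, 0, 0, 0))
  expect_gt(nrow(rotation_grid(15)), nrow(rotation_grid(30)))
  # covering property at delta = 30 over random rotations
  set.seed(21)
  G <- rotation_grid(30)
  worst <- max(replicate(500, {
    q <- rnorm(4); q <- q / sqrt(sum(q^2))
    2 * acos(min(1, max(abs(G %*% q)))) * 180 / pi
  }))
  expect_lt(worst, 1.5 * 30)
  expect_error(rotation_grid(0), "delta")
  expect_error(rotation_grid(90), "delta")
})

test_that("translational scan equals the brute-force sliding Pearson", {
  set.seed(5)
  for (rep in 1:3) {
    tgt <- density_map(array(rnorm(16^3), c(16, 16, 16)), 2)
    mov <- density_map(array(abs(rnorm(12^3)), c(12, 12, 12)), 2)
    cc <- translational_scan(mov, tgt, mask_level = 0.3)
    oracle <- brute_pearson_scan(mov$values, tgt$values,
                                 auto_mask(mov, "fraction_of_max", 0.3))
    expect_lt(max(abs(cc - oracle)), 1e-6)
  }
})

test_that("self-match and anti-correlation are exact at the true offset", {
  mod <- make_toy_domain("coil", 30, 8)
  sp <- simulation_params(8, 2, padding = 6)
  mov <- simulate_map(mod, sp)
  md <- dim(mov$values)
  tgt <- density_map(array(0, md + c(7, 9, 11)), 2,
                     mov$origin - c(3, 4, 5) * 2)
  tgt$values[3 + 1:md[1], 4 + 1:md[2], 5 + 1:md[3]] <- mov$values
  cc <- translational_scan(mov, tgt)
  best <- which(cc == max(cc), arr.ind = TRUE)
  expect_equal(unname(best[1, ]) - 1L, c(3L, 4L, 5L))
  expect_equal(max(cc), 1.0, tolerance = 1e-6)
  neg <- density_map(-tgt$values, 2, tgt$origin)
  ccn <- translational_scan(mov, neg)
  expect_equal(ccn[4, 5, 6], -1.0, tolerance = 1e-6)
  expect_error(translational_scan(density_map(mov$values, 3), tgt),
               "resample")
})

test_that("scan correlations are invariant to affine target intensity", {
  set.seed(6)
  tgt <- density_map(array(rnorm(14^3), c(14, 14, 14)), 1)
  mov <- density_map(array(abs(rnorm(10^3)), c(10, 10, 10)), 1)
  cc1 <- translational_scan(mov, tgt)
  tgt2 <- density_map(3.7 * tgt$values + 11, 1, tgt$origin)
  cc2 <- translational_scan(mov, tgt2)
  expect_equal(as.vector(cc1), as.vector(cc2), tolerance = 1e-9)
})

test_that("self-fit recovers the identity pose with correlation 1", {
  mod <- make_toy_domain("helix_bundle", 80, 3)
  sp <- simulation_params(8, 2, padding = 10)
  tgt <- make_scene(list(mod), 1,
                    pose = list(quaternion = c(1, 0, 0, 0),
                                translation = c(0, 0, 0)),
                    resolution = 8, voxel = 2, dim = c(45, 45, 45))$map
  fit <- fit_domain(mod, tgt, sp, fit_params(delta = 30, top_n = 3))
  expect_equal(fit$cc[1], 1.0, tolerance = 1e-3)
  expect_lt(quat_angle_deg(as.numeric(fit[1, c("q1", "q2", "q3", "q4")])),
            1e-6)
  expect_lt(sqrt(sum(as.numeric(fit[1, c("tx", "ty", "tz")])^2)), 1e-9)
  expect_error(
    fit_domain(mod, density_map(array(0, c(10, 10, 10)), 2), sp,
               fit_params(delta = 60)),
    "extent")
})

test_that("noiseless scene fits recover the planted pose", {
  mods <- list(make_toy_domain("helix_bundle", 90, 1))
  sp <- simulation_params(8, 2)
  sc <- make_scene(mods, 1, resolution = 8, voxel = 2, seed = 17,
                   dim = c(48, 48, 48))
  # refine several suppression-diverse basins: at ~8 A helices are nearly
  # apolar rods, so flipped placements score well and the true basin is not
  # always the top grid pose
  fit <- fit_domain(mods[[1]], sc$map, sp,
                    fit_params(delta = 30, top_n = 6, nms_rotation = 45,
                               refine = TRUE))
  err <- fit_pose_errors(fit[1, ], sc$truth)
  expect_lt(err["rot"], 1.5 * 30)
  expect_lt(err["trans"], 2)          # one voxel
  expect_gte(fit$cc[1], 0.95)
  # a decoy of a different fold scores strictly lower
  decoy <- make_toy_domain("slab", 90, 1)
  dfit <- fit_domain(decoy, sc$map, sp, fit_params(delta = 30, top_n = 1))
  expect_lt(dfit$cc[1], fit$cc[1])
})

test_that("refinement is monotone and recovers a perturbed pose", {
  mods <- list(make_toy_domain("coil", 60, 9))
  sp <- simulation_params(8, 2)
  sc <- make_scene(mods, 1, resolution = 8, voxel = 2, seed = 31,
                   dim = c(44, 44, 44))
  truth <- sc$truth
  start <- list(
    quaternion = quat_mul(quat_from_axis_angle(c(0, 0, 1), 15),
                          truth$quaternion),
    translation = truth$translation + c(1.5, -1, 0.5))
  ref <- refine_pose(mods[[1]], sc$map, start, sp, step_ang = 7.5,
                     step_trans = 2)
  expect_true(all(diff(ref$trace) >= -1e-12))
  expect_lt(quat_angle_deg(ref$pose$quaternion, truth$quaternion), 2)
  expect_lt(sqrt(sum((ref$pose$translation - truth$translation)^2)), 1)
  # starting at the planted pose cannot get worse and barely moves
  at_truth <- refine_pose(mods[[1]], sc$map,
                          list(quaternion = truth$quaternion,
                               translation = truth$translation), sp)
  expect_gte(at_truth$cc, at_truth$trace[1])
  expect_lt(sqrt(sum((at_truth$pose$translation - truth$translation)^2)), 1)
})
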