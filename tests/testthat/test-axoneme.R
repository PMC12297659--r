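test_that("unique-particle fractions follow the pick/repeat ratio", {
  expect_equal(expected_unique_fraction(8, 32), 0.25)
  expect_equal(expected_unique_fraction(16, 16), 1.0)
  expect_equal(expected_unique_fraction(8, 16), 0.5)
  expect_error(expected_unique_fraction(7, 32), "divide")
  expect_error(expected_unique_fraction(0, 32), "positive")
  # matches the empirical phase-0 fraction of generated filament tables
  for (par in list(c(8, 32), c(8, 16), c(16, 32), c(16, 16))) {
    ft <- make_filament_table(3, 192, par[1], par[2], 5)
    expect_equal(mean(ft$phase == 0),
                 expected_unique_fraction(par[1], par[2]),
                 tolerance = 1e-12)
  }
})

test_that("duplicate removal sweeps greedily per filament and is idempotent", {
  tab <- particle_table(data.frame(
    filament_id = "f1", arc_nm = c(0, 8, 16, 24),
    x_nm = 0, y_nm = 0, z_nm = 0, tilt_deg = 0, psi_deg = 0))
  d <- dedup_particles(tab, 16)
  expect_equal(d$arc_nm, c(0, 16))
  expect_equal(as.data.frame(dedup_particles(d, 16)), as.data.frame(d))
  # jittered table vs brute-force greedy oracle
  set.seed(13)
  for (rep in 1:5) {
    arcs <- sort(runif(40, 0, 300))
    tj <- particle_table(data.frame(
      filament_id = rep(c("a", "b"), each = 20), arc_nm = arcs,
      x_nm = 0, y_nm = 0, z_nm = 0, tilt_deg = 0, psi_deg = 0))
    got <- dedup_particles(tj, 12)
    oracle <- unlist(lapply(split(seq_len(40), tj$filament_id), function(ii) {
      keep <- c(); last <- -Inf
      for (i in ii) if (tj$arc_nm[i] - last >= 12 - 1e-9) {
        keep <- c(keep, i); last <- tj$arc_nm[i]
      }
      keep
    }), use.names = FALSE)
    expect_equal(got$arc_nm, tj$arc_nm[sort(oracle)])
  }
})

test_that("layout periodicities match the spiral patterns", {
  expect_equal(pattern_period(layout_pattern("AAAB", 8)), 32)
  expect_equal(pattern_period(layout_pattern("C", 8)), 8)
  expect_equal(pattern_period(layout_pattern("ABAB", 8)), 16)
  # independent of how many copies of the minimal unit are spelled out
  for (k in 1:4)
    expect_equal(pattern_period(layout_pattern(strrep("AAB", k), 8)), 24)
})

test_that("axial overlap counts match brute-force interval coverage", {
  expect_equal(overlap_count(33, 16), 3L)
  expect_equal(overlap_count(16, 16), 1L)
  expect_equal(overlap_count(48, 16), 3L)
  # brute force: elements [k*s, k*s + L) tile the axis; the overlap count
  # is the depth of the stack where it is deepest (sampled off-boundary)
  brute <- function(L, s) {
    max(vapply(seq(0.013, s, length.out = 97), function(x)
      sum(vapply(-100:100, function(k) k * s <= x && x < k * s + L,
                 logical(1))), numeric(1)))
  }
  for (L in c(10, 16, 33, 48, 50)) for (s in c(8, 16))
    expect_equal(overlap_count(L, s), brute(L, s))
})

occupancy_op <- function(truth) {
  occupancy_params(
    probe_centers = rbind(c(0, 0, truth$rod_z[1]), c(0, 0, truth$rod_z[2])),
    probe_radius = 4, theta = 3,
    tubule_centers = rbind(c(-truth$center_distance[1] / 2, 0),
                           c(truth$center_distance[1] / 2, 0)),
    tubule_exclude_radius = truth$tubule_radius + 4)
}

test_that("occupancy classification is exact at zero noise", {
  ph <- make_bridge_phantoms(30, c(0.4, 0.4, 0.2), noise_sd_rel = 0,
                             seed = 6)
  res <- classify_occupancy(ph$maps, occupancy_op(ph$truth))
  expect_identical(res$states, ph$truth$state)
  expect_equal(sum(res$counts), 30)
  expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
  ph1 <- make_bridge_phantoms(10, c(1, 0, 0), noise_sd_rel = 0, seed = 2)
  res1 <- classify_occupancy(ph1$maps, occupancy_op(ph1$truth))
  expect_equal(unname(res1$fractions), c(1, 0, 0))
  bad <- occupancy_op(ph$truth)
  bad$probe_centers[1, ] <- c(0, 0, 40)
  expect_error(classify_occupancy(ph$maps, bad), "outside")
})

test_that("edge distance recovers the planted geometry and its invariances", {
  ph <- make_bridge_phantoms(1, c(1, 0, 0), center_distance = 35,
                             tubule_radius = 12.5, noise_sd_rel = 0,
                             seed = 3)
  seeds <- rbind(c(-17.5, 0), c(17.5, 0))
  d <- edge_distance(ph$maps[[1]], seeds, 12.5)
  expect_lt(abs(d - 10.0), 1)                # within half a voxel (2 nm)
  # rigid translation: shift the origin, shift the seeds
  m2 <- ph$maps[[1]]
  m2$origin <- m2$origin + c(5, -3, 2)
  d2 <- edge_distance(m2, seeds + cbind(c(5, 5), c(-3, -3)), 12.5)
  expect_equal(d2, d, tolerance = 1e-9)
  # global intensity scaling
  m3 <- ph$maps[[1]]
  m3$values <- m3$values * 4.2
  expect_equal(edge_distance(m3, seeds, 12.5), d, tolerance = 1e-9)
})

test_that("distance-set comparison matches the Welch formula", {
  expect_equal(compare_distance_sets(c(1, 2, 3), c(1, 2, 3))$p_value, 1,
               tolerance = 1e-12)
  r0 <- compare_distance_sets(c(2, 2), c(2, 2))
  expect_equal(r0$statistic, 0); expect_equal(r0$p_value, 1)
  set.seed(8)
  a <- rnorm(30, 10.3, 0.4); b <- rnorm(25, 10.7, 1.4)
  r <- compare_distance_sets(a, b)
  # textbook Welch statistic and Welch-Satterthwaite df
  tstat <- (mean(a) - mean(b)) / sqrt(var(a) / 30 + var(b) / 25)
  nu <- (var(a) / 30 + var(b) / 25)^2 /
    ((var(a) / 30)^2 / 29 + (var(b) / 25)^2 / 24)
  expect_equal(r$statistic, tstat, tolerance = 1e-9)
  expect_equal(r$p_value, 2 * pt(-abs(tstat), nu), tolerance = 1e-9)
  sep <- compare_distance_sets(c(0, 0, 0, 0) + rnorm(4, 0, 1e-4),
                               c(1, 1, 1, 1) + rnorm(4, 0, 1e-4))
  expect_lt(sep$p_value, 1e-6)
})
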