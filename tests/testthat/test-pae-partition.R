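test_that("symmetrization takes the element-wise minimum with zero diagonal", {
  P <- matrix(c(0, 3, 7,
                9, 0, 2,
                5, 8, 0.5), 3, 3, byrow = TRUE)
  S <- symmetrize_pae(P)
  expect_equal(S[1, 2], 3); expect_equal(S[2, 1], 3)
  expect_true(isSymmetric(S))
  expect_true(all(diag(S) == 0))
  set.seed(9)
  Q <- matrix(runif(25, 0, 30), 5, 5)
  expect_equal(symmetrize_pae(Q),
               { o <- pmin(Q, t(Q)); diag(o) <- 0; o })  # brute-force min
  sym <- (Q + t(Q)) / 2; diag(sym) <- 0
  expect_equal(symmetrize_pae(sym), sym)
})

test_that("uniformly confident PAE yields a single unit covering the chain", {
  p <- pae_matrix(matrix(0, 100, 100))
  part <- partition_model(p, partition_params(tau = 10))
  expect_length(part$units, 1L)
  expect_equal(part$units[[1]]$intervals,
               matrix(c(1, 100), 1, dimnames = list(NULL, c("start", "end"))))
  expect_length(part$flexible, 0L)
})

test_that("planted blocks are recovered exactly at zero jitter", {
  p <- make_pae_blocks(c(50, 70), 2, 25, 0, 1)
  part <- partition_model(p, partition_params(tau = 12))
  expect_length(part$units, 2L)
  expect_equal(part$units[[1]]$residues, 1:50)
  expect_equal(part$units[[2]]$residues, 51:120)
  # oracle: connected components of the thresholded graph. Weights vanish
  # exactly where S >= tau, so components are found by label propagation.
  S <- symmetrize_pae(p)
  adj <- (S < 12) & !diag(120)
  comp <- seq_len(120)
  repeat {
    new <- vapply(seq_len(120),
                  function(i) min(comp[c(i, which(adj[i, ]))]), integer(1))
    if (identical(new, comp)) break
    comp <- new
  }
  oracle <- unname(split(seq_len(120), comp))
  expect_equal(oracle, lapply(part$units, `[[`, "residues"))
})

test_that("uniformly uncertain PAE leaves every residue flexible", {
  p <- pae_matrix(matrix(30, 40, 40) - diag(30, 40))
  part <- partition_model(p, partition_params(tau = 10))
  expect_length(part$units, 0L)
  expect_equal(part$flexible, 1:40)
})

test_that("partitions are true partitions on random PAE matrices", {
  for (s in 1:12) {
    set.seed(s)
    L <- sample(30:90, 1)
    m <- matrix(runif(L * L, 0, 30), L, L)
    diag(m) <- 0
    part <- partition_model(pae_matrix(m), partition_params(tau = 15,
                                                            m_min = 5))
    all_res <- c(unlist(lapply(part$units, `[[`, "residues")), part$flexible)
    expect_equal(sort(all_res), 1:L)
    expect_equal(anyDuplicated(all_res), 0L)
    for (u in part$units) expect_gte(length(u$residues), 5L)
  }
})

test_that("partitioning is deterministic and nested in tau at zero jitter", {
  p <- make_pae_blocks(c(30, 40, 30), 2, 25, 0, 3)
  a <- partition_model(p, partition_params(tau = 12))
  b <- partition_model(p, partition_params(tau = 12))
  expect_identical(a, b)
  # decreasing tau can only split further, never merge separated units
  big <- partition_model(p, partition_params(tau = 20))
  small <- partition_model(p, partition_params(tau = 5))
  to_lab <- function(part) {
    lab <- integer(part$n_residues)
    for (i in seq_along(part$units)) lab[part$units[[i]]$residues] <- i
    lab
  }
  lb <- to_lab(big); ls <- to_lab(small)
  for (pair in combn(which(lb > 0 & ls > 0), 2, simplify = FALSE)) {
    if (lb[pair[1]] != lb[pair[2]])
      expect_true(ls[pair[1]] != ls[pair[2]])
  }
})

test_that("greedy modularity agrees with igraph fast-greedy on blocks", {
  p <- make_pae_blocks(c(40, 35, 45), 3, 22, 0.8, 11)
  part <- partition_model(p, partition_params(tau = 10, gamma = 1))
  S <- symmetrize_pae(p)
  W <- pmax(1 - S / 10, 0); diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  ref <- igraph::membership(igraph::cluster_fast_greedy(g))
  lab <- integer(120)
  for (i in seq_along(part$units)) lab[part$units[[i]]$residues] <- i
  expect_equal(mclust::adjustedRandIndex(lab, ref), 1.0)
})

test_that("unit extraction returns exactly the unit's residues", {
  mod <- make_toy_domain("coil", 120, 2)
  p <- make_pae_blocks(c(50, 70), 2, 25, 0, 1)
  part <- partition_model(p, partition_params(tau = 12))
  u1 <- extract_unit_model(mod, part$units[[1]])
  expect_equal(nrow(u1), 50L)
  expect_equal(u1$resno, 1:50)
  full <- structure(list(chain = "A",
                         intervals = cbind(start = 1, end = 120),
                         residues = 1:120), class = "rigid_unit")
  expect_equal(as.data.frame(extract_unit_model(mod, full)),
               as.data.frame(mod))
  # atom count equals the per-residue sum
  per_res <- table(mod$resno)
  expect_equal(nrow(u1), sum(per_res[as.character(1:50)]))
  bad <- structure(list(chain = "A", intervals = cbind(start = 119, end = 125),
                        residues = 119:125), class = "rigid_unit")
  expect_error(extract_unit_model(mod, bad), "absent")
})
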