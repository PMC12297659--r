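# Partitioning a predicted model into rigid units from its PAE matrix.
#
# Residues become nodes of a weighted graph with w_ij = max(0, 1 - S_ij/tau)
# where S is the element-wise-min symmetrized PAE; units are communities
# found by deterministic greedy (agglomerative) modularity maximization at
# resolution gamma with fixed node ordering, so identical inputs always
# give identical partitions. Units may be sequence-discontiguous: rigidity
# in error space does not have to be contiguous in sequence (domain inserts
# are real).

#' Partition parameters
#'
#' @param tau PAE edge threshold in Å: residue pairs with symmetrized PAE
#'   at or above `tau` share no edge. Default 10.
#' @param gamma modularity resolution; larger values favour more, smaller
#'   units. Default 1.
#' @param m_min minimum unit size in residues; smaller clusters are merged
#'   into their strongest-connected neighbour or, with no connection,
#'   declared flexible. Default 20.
#' @return An object of class `partition_params`.
#' @export
partition_params <- function(tau = 10, gamma = 1, m_min = 20) {
  if (tau <= 0 || gamma <= 0 || m_min < 1)
    stop("require tau > 0, gamma > 0, m_min >= 1", call. = FALSE)
  structure(list(tau = tau, gamma = gamma, m_min = m_min),
            class = "partition_params")
}

#' Symmetrize a PAE matrix
#'
#' Element-wise minimum of the matrix and its transpose, diagonal zeroed:
#' one confident direction is taken as sufficient evidence of mutual
#' rigidity (the optimistic convention).
#'
#' @param P a [pae_matrix] (or plain square matrix).
#' @return A symmetric matrix with zero diagonal.
#' @export
symmetrize_pae <- function(P) {
  m <- unclass(P)
  s <- pmin(m, t(m))
  diag(s) <- 0
  s
}

#' Partition a model's residues into rigid units
#'
#' @param P a [pae_matrix] for a chain of L residues.
#' @param params a [partition_params].
#' @param seed accepted for interface stability; the algorithm is fully
#'   deterministic and does not consume randomness.
#' @param chain chain id attached to the resulting units.
#' @return An object of class `partition`: list with `units` (list of
#'   `rigid_unit`s, each with `chain`, `intervals` (two-column start/end
#'   matrix, 1-based inclusive) and `residues`), and `flexible` (integer
#'   vector of residues in no unit). Units and the flexible set are
#'   disjoint and jointly cover 1..L exactly once.
#' @export
partition_model <- function(P, params = partition_params(), seed = 1,
                            chain = "A") {
  stopifnot(inherits(params, "partition_params"))
  S <- symmetrize_pae(P)
  L <- nrow(S)
  W <- pmax(1 - S / params$tau, 0)     # keeps matrix shape
  diag(W) <- 0
  labels <- greedy_modularity(W, params$gamma)
  labels <- absorb_small_clusters(labels, W, params$m_min)
  make_partition(labels, chain, L)
}

# Deterministic agglomerative modularity maximization (CNM-style) with
# resolution gamma. Ties in the best merge gain break lexicographically on
# the (smaller, larger) original cluster indices.
greedy_modularity <- function(W, gamma) {
  L <- nrow(W)
  deg <- rowSums(W)
  W2 <- sum(deg)                      # 2 * total edge weight
  if (W2 <= 0) return(seq_len(L))     # no edges: all singletons
  E <- W                              # inter-cluster weight matrix
  d <- deg                            # cluster degree sums
  lab <- seq_len(L)                   # cluster id per residue
  active <- rep(TRUE, L)
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    Esub <- E[idx, idx, drop = FALSE]
    # merge gain: e_uv / W - gamma * d_u d_v / (2 W^2), W = W2 / 2
    gain <- 2 * Esub / W2 - gamma * outer(d[idx], d[idx]) / (W2 * W2 / 2)
    gain[lower.tri(gain, diag = TRUE)] <- -Inf
    best <- max(gain)
    if (best <= 1e-15) break
    hit <- which(gain == best, arr.ind = TRUE)
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    u <- idx[hit[1, 1]]; v <- idx[hit[1, 2]]
    # merge v into u
    E[u, ] <- E[u, ] + E[v, ]
    E[, u] <- E[, u] + E[, v]
    E[u, u] <- 0
    d[u] <- d[u] + d[v]
    active[v] <- FALSE
    lab[lab == v] <- u
  }
  match(lab, sort(unique(lab)))
}

# Clusters smaller than m_min are merged into the neighbouring cluster with
# the largest total inter-cluster weight; with zero connecting weight they
# become flexible (label 0). Smallest clusters are absorbed first.
absorb_small_clusters <- function(labels, W, m_min) {
  repeat {
    ids <- setdiff(unique(labels), 0L)
    sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
    small <- ids[sizes < m_min]
    if (!length(small)) break
    tgt <- small[order(sizes[match(small, ids)], small)][1]
    members <- which(labels == tgt)
    others <- setdiff(ids, tgt)
    if (!length(others)) { labels[members] <- 0L; next }
    wsum <- vapply(others, function(o)
      sum(W[members, labels == o, drop = FALSE]), numeric(1))
    if (max(wsum) <= 0) labels[members] <- 0L
    else labels[members] <- others[order(-wsum, others)][1]
  }
  labels
}

runs_of <- function(res) {
  res <- sort(res)
  brk <- c(0, which(diff(res) != 1), length(res))
  t(vapply(seq_len(length(brk) - 1),
           function(i) c(res[brk[i] + 1], res[brk[i + 1]]), numeric(2)))
}

make_partition <- function(labels, chain, L) {
  ids <- setdiff(unique(labels), 0L)
  # report units in order of their first residue
  ids <- ids[order(vapply(ids, function(i) min(which(labels == i)), numeric(1)))]
  units <- lapply(ids, function(i) {
    res <- which(labels == i)
    iv <- runs_of(res)
    colnames(iv) <- c("start", "end")
    structure(list(chain = chain, intervals = iv, residues = res),
              class = "rigid_unit")
  })
  structure(list(units = units, flexible = which(labels == 0L), n_residues = L),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d residues, %d unit(s), %d flexible\n",
              x$n_residues, length(x$units), length(x$flexible)))
  for (i in seq_along(x$units)) {
    u <- x$units[[i]]
    iv <- apply(u$intervals, 1, function(r) sprintf("%d-%d", r[1], r[2]))
    cat(sprintf("  unit %d (chain %s, %d res): %s\n", i, u$chain,
                length(u$residues), paste(iv, collapse = ",")))
  }
  invisible(x)
}

#' Extract the atoms of one rigid unit
#'
#' @param model an [atomic_model].
#' @param unit a `rigid_unit` from [partition_model()].
#' @return An [atomic_model] restricted to the unit's residues.
#' @export
extract_unit_model <- function(model, unit) {
  stopifnot(inherits(model, "atomic_model"), inherits(unit, "rigid_unit"))
  sel <- model$chain == unit$chain & model$resno %in% unit$residues
  missing <- setdiff(unit$residues,
                     model$resno[model$chain == unit$chain])
  if (length(missing))
    stop("unit residues absent from model: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  atomic_model(as.data.frame(model)[sel, , drop = FALSE])
}
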