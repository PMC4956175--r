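# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (double loops, power sets) so they cannot share a bug
# with the vectorized implementations they check.

rand_connectome <- function(n, p, labels = paste0("A", seq_len(n))) {
  A <- matrix(stats::rbinom(n * n, 1, p), n)
  diag(A) <- 0
  connectome(A, labels)
}

rand_distance <- function(n, labels = paste0("A", seq_len(n)), scale = 10) {
  pts <- cbind(stats::runif(n), stats::runif(n)) * scale
  distance_matrix(unname(as.matrix(stats::dist(pts))), labels = labels)
}

equidistant_D <- function(n, d = 1) {
  m <- matrix(d, n, n)
  diag(m) <- 0
  distance_matrix(m, labels = paste0("A", seq_len(n)))
}

# 3-area matrix with a prescribed off-diagonal mean and max (not Euclidean,
# which the distance-matrix contract does not require)
stats_anchored_D <- function(mean_d, max_d) {
  rest <- (3 * mean_d - max_d) / 2
  stopifnot(rest > 0)
  m <- matrix(c(0, rest, rest,
                rest, 0, max_d,
                rest, max_d, 0), 3, 3)
  distance_matrix(m, labels = c("A1", "A2", "A3"))
}

# uni/bidirectional pair counts by explicit double loop
oracle_m1_m2 <- function(A) {
  n <- nrow(A)
  m1 <- 0L; m2 <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (A[i, j] == 1 && A[j, i] == 1) m2 <- m2 + 1L
    else if (A[i, j] == 1 || A[j, i] == 1) m1 <- m1 + 1L
  }
  list(M1 = m1, M2 = m2)
}

# motif class of a single 3-node digraph via igraph's triad census
# (independent C implementation; its class order matches the package's
# documented table)
oracle_motif_class <- function(A3) {
  tc <- igraph::triad_census(igraph::graph_from_adjacency_matrix(A3, mode = "directed"))
  which(tc == 1)
}

# clique census by power-set enumeration on the bidirectional skeleton
oracle_clique_census <- function(G) {
  U <- (G$A * t(G$A)) > 0
  n <- nrow(U)
  stopifnot(n <= 14)
  counts <- integer(n)
  for (mask in seq_len(2^n - 1)) {
    nodes <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    k <- length(nodes)
    ok <- TRUE
    if (k >= 2) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        if (!U[nodes[a], nodes[b]]) { ok <- FALSE; break }
        if (!ok) break
      }
    }
    if (ok) counts[k] <- counts[k] + 1L
  }
  counts[seq_len(max(which(counts > 0)))]
}

# similarity of one pair by explicit source-by-source agreement loop
oracle_similarity <- function(A, x, y) {
  n <- nrow(A)
  agree <- 0L
  for (s in seq_len(n)) {
    if ((A[s, x] > 0) == (A[s, y] > 0)) agree <- agree + 1L
  }
  kx <- sum(A[, x] > 0); ky <- sum(A[, y] > 0)
  p <- (kx / n) * (ky / n) + (1 - kx / n) * (1 - ky / n)
  agree / n - p
}

# total wire length by explicit double loop
oracle_wire <- function(A, D) {
  s <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A)))
    s <- s + A[i, j] * D[i, j]
  s
}

# planted core: two overlapping reciprocal k-cliques plus a sparse
# (reciprocity-free) periphery
planted_core_graph <- function(k = 5, n_periph = 6) {
  n <- (k + 1) + n_periph
  W <- matrix(0, n, n)
  cl1 <- 1:k
  cl2 <- 2:(k + 1)
  for (cl in list(cl1, cl2))
    for (i in cl) for (j in cl) if (i != j) W[i, j] <- 1
  # one-directional periphery links only (no reciprocal pairs outside the core)
  per <- (k + 2):n
  for (i in seq_along(per)) {
    j <- per[i]
    W[j, ((i) %% k) + 1] <- 1
  }
  connectome(W, paste0("A", seq_len(n)))
}

# mouse-scale fixture shared across tests (deterministic)
mouse_fixture <- function(seed = 101) mouse_like_species(seed = seed)
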