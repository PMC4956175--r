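test_that("graph summary matches printed density and pair-count oracles", {
  sp <- mouse_fixture()
  g <- sample_cdr(sp$D, n_edges = 719, seed = 2)
  s <- graph_summary(g)
  expect_equal(round(s$density, 2), 0.68)

  # complete bidirectional graph
  n <- 6
  K <- connectome(matrix(1, n, n) - diag(n), paste0("A", 1:n))
  sk <- graph_summary(K)
  expect_equal(sk$density, 1)
  expect_equal(sk$M1, 0)
  expect_equal(sk$M2, n * (n - 1) / 2)

  # random digraphs vs double-loop oracle, and M = M1 + 2 M2
  set.seed(10)
  for (i in 1:50) {
    G <- rand_connectome(10, stats::runif(1, 0.1, 0.9))
    s <- graph_summary(G)
    o <- oracle_m1_m2(G$A)
    expect_identical(c(s$M1, s$M2), c(o$M1, o$M2))
    expect_equal(s$M, s$M1 + 2 * s$M2)
  }
})

test_that("motif census classifies all 64 labeled 3-node digraphs correctly", {
  total_by_class <- integer(16)
  for (code in 0:63) {
    b <- as.integer(intToBits(code))[1:6]
    A <- matrix(0L, 3, 3)
    A[1, 2] <- b[1]; A[2, 1] <- b[2]
    A[1, 3] <- b[3]; A[3, 1] <- b[4]
    A[2, 3] <- b[5]; A[3, 2] <- b[6]
    cls <- oracle_motif_class(A)
    counts <- motif_census(connectome(A, paste0("A", 1:3)))$counts
    expect_equal(which(counts == 1), cls)
    total_by_class[cls] <- total_by_class[cls] + 1L
  }
  expect_equal(sum(total_by_class), 64)
})

test_that("named anchor classes: lone bidirectional pair is 3, 3-cycle is 10", {
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  expect_equal(motif_census(connectome(A, paste0("A", 1:3)))$counts[3], 1)
  C3 <- matrix(0, 3, 3); C3[1, 2] <- C3[2, 3] <- C3[3, 1] <- 1
  expect_equal(motif_census(connectome(C3, paste0("A", 1:3)))$counts[10], 1)
  expect_match(motif_class_names()[3], "bidirectional")
  expect_match(motif_class_names()[10], "cycle")
})

test_that("motif census agrees with an independent triad census on random graphs", {
  set.seed(77)
  for (i in 1:50) {
    G <- rand_connectome(8, stats::runif(1, 0.1, 0.7))
    mine <- motif_census(G)
    ref <- igraph::triad_census(igraph::graph_from_adjacency_matrix(G$A, mode = "directed"))
    expect_equal(mine$counts, as.integer(ref))
    expect_equal(sum(mine$counts), choose(8, 3))
  }
})

test_that("degree-preserving rewiring preserves degrees, edges, and not motifs", {
  sp <- mouse_fixture()
  g <- sample_edr(sp$D, 0.78, density = 0.5, seed = 4)
  din <- colSums(g$A); dout <- rowSums(g$A)
  changed <- 0L
  set.seed(15)
  for (i in 1:30) {
    r <- rewire_degree_preserving(g)
    expect_identical(colSums(r$A), din)
    expect_identical(rowSums(r$A), dout)
    expect_equal(r$M, g$M)
    expect_equal(sum(diag(r$A)), 0)
    if (!identical(r$A, g$A)) changed <- changed + 1L
  }
  expect_gt(changed, 25) # rewiring actually randomizes
  expect_error(rewire_degree_preserving(g, n_swaps = 0), "positive")

  # frozen instance: a lone 2-cycle admits no swap
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  g2 <- connectome(W, paste0("A", 1:3))
  r2 <- rewire_degree_preserving(g2, n_swaps = 10, seed = 1)
  expect_identical(r2$A, g2$A)
})

test_that("motif log-residuals: arithmetic, self-null coverage, sign stability", {
  sp <- mouse_fixture()
  g <- sample_edr(sp$D, 0.78, density = 0.68, seed = 42)

  res <- motif_log_residuals(g, n_null = 100, seed = 5)
  ok <- !res$flagged & res$data_count > 0
  # residual is the log ratio of the returned columns (arithmetic identity)
  expect_equal(res$residual[ok], log(res$data_count[ok] / res$null_mean[ok]))

  # a graph drawn from the null family sits inside its own nulls
  set.seed(6)
  within_ci <- c()
  for (t in 1:4) {
    g2 <- rewire_degree_preserving(g)
    r2 <- motif_log_residuals(g2, n_null = 150)
    ok2 <- !r2$flagged & !is.na(r2$residual)
    within_ci <- c(within_ci,
                   r2$residual[ok2] >= r2$ci_lo[ok2] & r2$residual[ok2] <= r2$ci_hi[ok2])
  }
  expect_gte(mean(within_ci), 0.9)

  # residual sign pattern stable across independent null ensembles
  r1 <- motif_log_residuals(g, n_null = 150, seed = 21)
  r2 <- motif_log_residuals(g, n_null = 150, seed = 77)
  both <- !is.na(r1$residual) & !is.na(r2$residual)
  expect_gte(sum(sign(r1$residual[both]) == sign(r2$residual[both])), 14)
})

test_that("clique census: closed forms, the near-complete core case, and the power-set oracle", {
  # bidirectional triangle
  W <- matrix(1, 3, 3) - diag(3)
  cc <- clique_census(connectome(W, paste0("A", 1:3)))
  expect_equal(unname(cc$counts), c(3L, 3L, 1L))
  expect_equal(cc$max_size, 3)

  # 12 reciprocal areas with a single missing directed link: the 12-set is
  # not a clique; two 11-cliques remain
  W <- matrix(1, 12, 12) - diag(12)
  W[1, 2] <- 0
  cc <- clique_census(connectome(W, paste0("A", 1:12)))
  expect_equal(cc$max_size, 11)
  expect_equal(unname(cc$counts[11]), 2L)

  # random graphs vs power-set enumeration
  set.seed(30)
  for (i in 1:5) {
    G <- rand_connectome(10, 0.6)
    expect_equal(unname(clique_census(G)$counts), oracle_clique_census(G))
  }

  # hereditary property and count at size 1
  sp <- mouse_fixture()
  g <- sample_edr(sp$D, 0.78, density = 0.68, seed = 13)
  cc <- clique_census(g)
  expect_equal(unname(cc$counts[1]), 33L)
  for (k in 2:cc$max_size)
    expect_gte(cc$counts[k - 1], cc$counts[k] * k / (33 - k + 1)) # weak bound
})

test_that("RMS log-ratio deviation: identities, closed form, zero handling", {
  a <- c(4, 9, 25)
  expect_equal(rms_log_ratio(a, a)$sigma, 0)
  expect_equal(rms_log_ratio(exp(1) * a, a)$sigma, 1)
  set.seed(3)
  x <- stats::runif(8, 1, 100); y <- stats::runif(8, 1, 100)
  expect_equal(rms_log_ratio(x, y)$sigma, sqrt(mean(log(x / y)^2)))
  r <- rms_log_ratio(c(1, 0, 3), c(1, 2, 3))
  expect_equal(r$n_dropped, 1)
  expect_equal(r$n_used, 2)
  # unequal lengths: missing classes are zeros
  r2 <- rms_log_ratio(c(1, 2, 3), c(1, 2))
  expect_equal(r2$n_dropped, 1)
  expect_error(rms_log_ratio(c(0, 1), c(2, 0)), "common support")
})

test_that("second eigenvalue of AA^T: closed forms and relabeling invariance", {
  n <- 5
  empty <- connectome(matrix(0, n, n), paste0("A", 1:n))
  expect_equal(second_eigenvalue(empty), 0)

  # complete digraph on 3 nodes: AA^T = J + I, eigenvalues {4, 1, 1}
  K3 <- connectome(matrix(1, 3, 3) - diag(3), paste0("A", 1:3))
  expect_equal(second_eigenvalue(K3), 1)

  set.seed(8)
  G <- rand_connectome(12, 0.4)
  perm <- sample(12)
  Gp <- connectome(G$W[perm, perm], paste0("A", 1:12))
  expect_equal(second_eigenvalue(Gp), second_eigenvalue(G), tolerance = 1e-9)
})

test_that("connection-probability GLM: signs, null behavior, and recovery", {
  sp <- mouse_fixture()
  # strong decay: negative slope
  g <- sample_edr(sp$D, 5 / 4.54, density = 0.4, seed = 9)
  fit <- connection_probability_fit(g, sp$D)
  expect_false(fit$separation)
  expect_lt(fit$beta1, 0)
  expect_lt(fit$p_value, 0.01)

  # CDR: slope compatible with zero in most seeds
  zs <- sapply(1:10, function(s) {
    gc <- sample_cdr(sp$D, density = 0.4, seed = 100 + s)
    abs(connection_probability_fit(gc, sp$D)$z)
  })
  expect_gte(sum(zs < 2), 8)

  # recovery of known logistic coefficients within 3 SE
  set.seed(55)
  b0 <- 2; b1 <- -0.5
  D <- sp$D
  p <- stats::plogis(b0 + b1 * D)
  A <- matrix(stats::rbinom(length(p), 1, as.vector(p)), nrow(p))
  diag(A) <- 0
  fit <- connection_probability_fit(connectome(A, rownames(D)), D)
  expect_lt(abs(fit$beta0 - b0), 3 * fit$se[1])
  expect_lt(abs(fit$beta1 - b1), 3 * fit$se[2])
})
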