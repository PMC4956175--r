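test_that("samplers are deterministic under a seed and hit the target density exactly", {
  sp <- mouse_fixture()
  for (fn in list(function(s) sample_edr(sp$D, 0.78, density = 0.68, seed = s),
                  function(s) sample_cdr(sp$D, density = 0.68, seed = s))) {
    g1 <- fn(11); g2 <- fn(11)
    expect_identical(g1$W, g2$W)
    expect_equal(g1$M, round(0.68 * 33 * 32))
  }
  # density exact across a range of targets (stopping rule)
  for (m in c(50, 200, 719)) {
    g <- sample_edr(sp$D, 0.78, n_edges = m, seed = m)
    expect_equal(g$M, m)
  }
  expect_error(sample_edr(sp$D, 0.78, n_edges = 33 * 32 + 1), "exceeds")
})

test_that("CDR saturates small graphs and matches binomial degree expectations", {
  D3 <- equidistant_D(3)
  g <- sample_cdr(D3, n_edges = 6, seed = 1)
  expect_equal(g$A, matrix(1L, 3, 3, dimnames = dimnames(g$A)) - diag(1L, 3))

  # expected binary in-degree (N-1) * rho over an ensemble
  set.seed(5)
  D <- rand_distance(10)
  rho <- 0.3
  deg <- replicate(1000, mean(colSums(sample_cdr(D, density = rho)$A)))
  se <- stats::sd(deg) / sqrt(length(deg))
  # the exact stopping rule makes the mean degree deterministic (se = 0)
  expect_lte(abs(mean(deg) - 9 * rho), 3 * se + 1e-9)
})

test_that("CDR edge lengths follow the interareal distance distribution q(d)", {
  sp <- mouse_fixture()
  bw <- 1
  st <- distance_stats(sp$D, binwidth = bw)
  set.seed(21)
  counts <- 0
  for (i in 1:50) {
    g <- sample_cdr(sp$D, density = 0.3)
    counts <- counts + edge_length_histogram(g, sp$D, binwidth = bw,
                                             weighted = FALSE)$counts
  }
  p_bins <- st$counts / sum(st$counts)
  keep <- p_bins > 0
  chi <- suppressWarnings(stats::chisq.test(counts[keep], p = p_bins[keep],
                                            rescale.p = TRUE))
  expect_gt(chi$p.value, 0.01)
})

test_that("the lambda -> 0 EDR limit reproduces the CDR where their laws coincide", {
  # on a fixture with exactly one pair per distance bin, uniform-bin and
  # uniform-pair sampling are the same law
  m <- matrix(0, 6, 6)
  m[upper.tri(m)] <- seq(1.25, 15.25, by = 1)
  m <- m + t(m)
  D <- distance_matrix(m, labels = paste0("A", 1:6))
  set.seed(33)
  pool_edr <- c(); pool_cdr <- c()
  for (i in 1:200) {
    ge <- sample_edr(D, lambda = 0, n_edges = 10, binwidth = 1)
    gc <- sample_cdr(D, n_edges = 10)
    pool_edr <- c(pool_edr, D[which(ge$A > 0)])
    pool_cdr <- c(pool_cdr, D[which(gc$A > 0)])
  }
  ks <- suppressWarnings(stats::ks.test(pool_edr, pool_cdr))
  expect_gt(ks$p.value, 0.01)
})

test_that("EDR multiplicity lengths recover the generating decay rate", {
  sp <- mouse_fixture()
  set.seed(8)
  counts <- NULL
  repeat {
    g <- sample_edr(sp$D, 0.78, density = 0.68)
    eh <- edge_length_histogram(g, sp$D)
    counts <- if (is.null(counts)) eh$counts else counts + eh$counts
    if (sum(counts) >= 1e5) break
  }
  fd <- fit_decay(counts = counts, binwidth = g$binwidth)
  expect_lt(abs(fd$lambda - 0.78), 0.05)
})

test_that("EDR sampler length law is memoryless within sampling error", {
  # survival of pooled multiplicity lengths: S(a+b)/S(a) ~ S(b)
  lens <- sample_axon_lengths(0.8, 2e5, d_max = 30, seed = 9)
  S <- function(t) mean(lens > t)
  a <- 1; b <- 1.5
  expect_lt(abs(S(a + b) / S(a) - S(b)), 0.01)
})

test_that("stronger decay shortens realized connections relative to the CDR", {
  sp <- mouse_fixture()
  set.seed(12)
  mean_len <- function(g) {
    sel <- which(g$W > 0)
    sum(sp$D[sel] * g$W[sel]) / sum(g$W[sel])
  }
  edr <- mean(replicate(10, mean_len(sample_edr(sp$D, 1.5, density = 0.68))))
  cdr <- mean(replicate(10, mean_len(sample_cdr(sp$D, density = 0.68))))
  expect_lt(edr, cdr)
})

test_that("EDR weights look log-normal: log weights closer to normal than raw", {
  sp <- mouse_fixture()
  g <- sample_edr(sp$D, 0.78, density = 0.68, seed = 71)
  w <- g$W[g$W > 0]
  sh_raw <- stats::shapiro.test(w)$statistic
  sh_log <- stats::shapiro.test(log(w))$statistic
  expect_gt(sh_log, sh_raw)
})

test_that("FLN view is a per-target normalization", {
  sp <- mouse_fixture()
  g <- sample_edr(sp$D, 0.78, density = 0.68, seed = 3)
  f <- fln(g)
  cs <- colSums(f)
  connected <- colSums(g$W) > 0
  expect_true(all(abs(cs[connected] - 1) < 1e-9))
  # isolated target flagged
  W <- g$W; W[, 5] <- 0
  f2 <- fln(connectome(W, g$labels))
  expect_true(g$labels[5] %in% attr(f2, "isolated_targets"))
  expect_true(all(is.na(f2[, 5])))
})
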