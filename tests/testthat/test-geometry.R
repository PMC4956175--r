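test_that("distance matrix validation rejects malformed input", {
  m <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3)
  expect_error(distance_matrix(m), "symmetric")
  m2 <- matrix(c(0, -1, 1, -1, 0, 1, 1, 1, 0), 3, 3)
  expect_error(distance_matrix(m2), "positive")
  m3 <- matrix(1, 3, 3)
  expect_error(distance_matrix(m3), "diagonal")
  expect_error(distance_matrix(matrix(c(0, 1, 1, 0), 2, 2)), "3 areas")
})

test_that("distance stats match brute-force enumeration and closed forms", {
  # equidistant areas: degenerate stats
  st <- distance_stats(equidistant_D(3, 1), binwidth = 0.5)
  expect_equal(st$mean, 1)
  expect_equal(st$max, 1)
  expect_equal(st$ratio, 1)

  # random planar points vs direct pairwise loop
  set.seed(42)
  n <- 60
  pts <- cbind(stats::runif(n, 0, 10), stats::runif(n, 0, 5))
  D <- distance_matrix(unname(as.matrix(stats::dist(pts))), labels = paste0("P", 1:n))
  st <- distance_stats(D, binwidth = 0.5)
  vals <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  expect_equal(st$mean, mean(vals))
  expect_equal(st$max, max(vals))
  expect_equal(st$n, n * (n - 1) / 2)

  # histogram is a normalized density over left-closed bins
  expect_equal(sum(st$density * st$binwidth), 1, tolerance = 1e-9)
  expect_equal(sum(st$counts), st$n)

  # invariance under relabeling
  perm <- sample(n)
  st2 <- distance_stats(distance_matrix(unname(D[perm, perm]),
                                        labels = paste0("P", 1:n)), binwidth = 0.5)
  expect_equal(st2$mean, st$mean)
  expect_equal(st2$max, st$max)
})

test_that("bin edges are left-closed, right-open", {
  # distances exactly at 1.0 must land in the [1.0, 1.5) bin, not [0.5, 1.0)
  m <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  st <- distance_stats(distance_matrix(m), binwidth = 0.5)
  expect_equal(st$counts[2], 0)      # [0.5, 1.0)
  expect_equal(st$counts[3], 2)      # [1.0, 1.5)
  expect_equal(st$counts[4], 1)      # top bin closed: the max value 2.0
})

test_that("adimensional rescaling has unit mean, preserves ratios, is idempotent", {
  set.seed(7)
  D <- rand_distance(12)
  R <- rescale_adimensional(D)
  expect_equal(mean(R[upper.tri(R)]), 1, tolerance = 1e-12)
  expect_equal(R[1, 2] / R[3, 4], D[1, 2] / D[3, 4], tolerance = 1e-12)
  R2 <- rescale_adimensional(R)
  expect_equal(unclass(R2), unclass(R), tolerance = 1e-12)
  expect_identical(attr(R, "units"), "adimensional")
})

test_that("mouse- and macaque-scale matrices map onto a common template", {
  # printed constants: mouse <d> = 4.54 mm, d_max = 10.1 mm; macaque
  # <d> = 26.35 mm, d_max = 58.2 mm; both collapse to max ~2.2 adimensional
  Dmus <- stats_anchored_D(4.54, 10.1)
  Dmac <- stats_anchored_D(26.35, 58.2)
  expect_equal(round(distance_stats(Dmus)$ratio, 2), 2.22)
  expect_equal(round(max(rescale_adimensional(Dmac)), 2), 2.21)
})

test_that("variance-ratio permutation test: identical samples give ratio 1, p 1", {
  x <- c(1.2, 0.8, 1.1, 0.9, 1.4, 0.6)
  res <- variance_ratio_permutation_test(x, x, n_perm = 99, seed = 1)
  expect_equal(res$ratio, 1)
  expect_equal(res$p_value, 1)
  expect_error(variance_ratio_permutation_test(rep(1, 5), x, n_perm = 9),
               "zero variance")
})

test_that("variance-ratio test p-values are uniform under the null", {
  set.seed(314)
  n_perm <- 99
  pvals <- replicate(500, {
    x <- stats::rnorm(25); y <- stats::rnorm(30)
    variance_ratio_permutation_test(x, y, n_perm = n_perm)$p_value
  })
  # attainable p-values are multiples of 1/(n_perm + 1)
  expect_gte(min(pvals), 1 / (n_perm + 1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # type-I error at alpha = 0.05 within a binomial band over 500 replicates
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("variance-ratio test detects the cross-species spread difference", {
  # normalized-distance spreads like the two real species (sd 0.60 vs 0.77,
  # n = 406 vs 528); permutations scaled down from 1e5 for test budget
  for (s in 1:5) {
    set.seed(1000 + s)
    x <- stats::rnorm(406, 1, 0.6)
    y <- stats::rnorm(528, 1, 0.77)
    res <- variance_ratio_permutation_test(x, y, n_perm = 1999)
    expect_lt(res$ratio, 1)
    expect_lt(res$p_value, 0.01)
  }
})
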