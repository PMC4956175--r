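#' Chance-corrected in-link similarity of one area pair
#'
#' For target areas x and y, let `n` be the number of source areas from which
#' either both or neither receive an incoming link (all N areas count as
#' potential sources, including x and y themselves; absent self-connections
#' contribute "neither receives" agreements). The index is the observed
#' agreement ratio minus its expectation under uniformly random incoming
#' connections with the same in-degrees:
#' `S = n/N - [ (k_x/N)(k_y/N) + (1 - k_x/N)(1 - k_y/N) ]`.
#'
#' @param A binary adjacency matrix oriented source -> target (or a
#'   connectome, whose `$A` is used).
#' @param x,y distinct area labels or indices.
#' @return list with `x`, `y`, `n`, `k_x`, `k_y`, `p_expected`, `S`.
#' @export
in_link_similarity <- function(A, x, y) {
  if (inherits(A, "connectome")) A <- A$A
  if (identical(x, y)) stop("x and y must differ")
  n_areas <- nrow(A)
  ax <- A[, x]; ay <- A[, y]
  n <- sum(ax == ay)
  kx <- sum(ax); ky <- sum(ay)
  p <- (kx / n_areas) * (ky / n_areas) +
    (1 - kx / n_areas) * (1 - ky / n_areas)
  list(x = x, y = y, n = n, k_x = kx, k_y = ky,
       p_expected = p, S = n / n_areas - p)
}

#' Connection-similarity profile over all area pairs
#'
#' Computes the chance-corrected similarity index for every unordered area
#' pair (N(N-1)/2 records) together with the pair separation, in the units of
#' the supplied distance matrix (physical mm or adimensional). The in-link
#' direction compares incoming source sets; `direction = "out"` applies the
#' same index to the transposed adjacency.
#'
#' @param G connectome.
#' @param D distance matrix with matching labels.
#' @param direction `"in"` (default, the cross-species comparison measure) or
#'   `"out"`.
#' @return data.frame with columns `x`, `y`, `distance`, `n`, `k_x`, `k_y`,
#'   `p_expected`, `S`.
#' @export
similarity_profile <- function(G, D, direction = c("in", "out")) {
  direction <- match.arg(direction)
  check_labels(G, D)
  A <- if (direction == "in") G$A else t(G$A)
  n_areas <- nrow(A)
  k <- colSums(A)
  # agreements: n_xy = N - k_x - k_y + 2 * (A^T A)_xy
  cp <- crossprod(A)
  pairs <- which(upper.tri(cp), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  n_agree <- n_areas - k[i] - k[j] + 2 * cp[upper.tri(cp)]
  p_exp <- (k[i] / n_areas) * (k[j] / n_areas) +
    (1 - k[i] / n_areas) * (1 - k[j] / n_areas)
  data.frame(
    x = G$labels[i], y = G$labels[j],
    distance = D[cbind(i, j)],
    n = as.integer(n_agree), k_x = as.integer(k[i]), k_y = as.integer(k[j]),
    p_expected = p_exp, S = n_agree / n_areas - p_exp,
    row.names = NULL
  )
}

#' Smoothed similarity-index density over an EDR ensemble
#'
#' Pools the (distance, similarity) points of all area pairs across an
#' ensemble of EDR model networks and returns a kernel-smoothed 2-D
#' probability density (Gaussian product kernel, Silverman-style bandwidth),
#' the model envelope against which empirical similarity clouds are judged.
#'
#' @param D distance matrix.
#' @param lambda EDR decay rate (0 for the CDR-like flat length law).
#' @param density target binary density of each realization.
#' @param n_graphs ensemble size (>= 2); 300 is the conventional choice.
#' @param binwidth sampler bin width (see [sample_edr()]).
#' @param gridsize number of grid points per axis.
#' @param seed optional master seed.
#' @return list with `x` (distance grid), `y` (similarity grid), `z` (density
#'   matrix) and `points` (the pooled data.frame).
#' @export
ensemble_similarity_density <- function(D, lambda, density, n_graphs = 300L,
                                        binwidth = NULL, gridsize = 128L,
                                        seed = NULL) {
  stopifnot(n_graphs >= 2)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_graphs)
  pts <- do.call(rbind, lapply(seq_len(n_graphs), function(r) {
    G <- sample_edr(D, lambda, density = density, binwidth = binwidth,
                    seed = seeds[r])
    sp <- similarity_profile(G, D)
    sp[, c("distance", "S")]
  }))
  dens <- MASS::kde2d(pts$distance, pts$S, n = gridsize)
  list(x = dens$x, y = dens$y, z = dens$z, points = pts)
}
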