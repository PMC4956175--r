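#' Construct and validate an interareal distance matrix
#'
#' Distances between cortical areas are measured between area barycenters and
#' stored as a symmetric matrix with a zero diagonal. The matrix may be in
#' physical units (mm) or adimensional units, i.e. rescaled by the mean
#' interareal distance so that brains of different sizes share one spatial
#' template (see [rescale_adimensional()]).
#'
#' @param d numeric N x N matrix of pairwise distances; must be symmetric with
#'   zero diagonal and strictly positive off-diagonal entries, N >= 3.
#' @param labels character vector of area names; defaults to the row names of
#'   `d` or `A1..AN`.
#' @param units `"mm"` or `"adimensional"`.
#' @return the validated matrix with dimnames set and a `units` attribute.
#' @export
distance_matrix <- function(d, labels = rownames(d), units = c("mm", "adimensional")) {
  units <- match.arg(units)
  d <- as.matrix(d)
  if (is.null(labels)) labels <- paste0("A", seq_len(nrow(d)))
  stopifnot(length(labels) == nrow(d))
  dimnames(d) <- list(labels, labels)
  attr(d, "units") <- units
  validate_distance_matrix(d)
  d
}

#' Validate a distance matrix
#'
#' @param d numeric square matrix.
#' @return `d`, invisibly; errors if invalid.
#' @export
validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || !is.numeric(d) || nrow(d) != ncol(d))
    stop("distance matrix must be a square numeric matrix")
  if (nrow(d) < 3L)
    stop("distance matrix needs at least 3 areas")
  if (any(!is.finite(d)))
    stop("distance matrix contains non-finite entries")
  if (any(abs(d - t(d)) > 0))
    stop("distance matrix is not symmetric")
  if (any(diag(d) != 0))
    stop("distance matrix diagonal must be zero")
  off <- d[upper.tri(d)]
  if (any(off <= 0))
    stop("off-diagonal distances must be strictly positive")
  invisible(d)
}

distance_units <- function(d) {
  u <- attr(d, "units")
  if (is.null(u)) "mm" else u
}

offdiag_values <- function(d) d[upper.tri(d)]

#' Distance-distribution statistics
#'
#' Computes the mean and maximum interareal distance (over the off-diagonal
#' upper triangle), their ratio, and the binned distance distribution q(d):
#' the fraction of area pairs separated by a distance in each bin, expressed
#' as a normalized density. Bins are left-closed, right-open `[k*binwidth,
#' (k+1)*binwidth)` covering `[0, d_max]` (the final bin is closed so that the
#' maximum is counted).
#'
#' @param d distance matrix (see [distance_matrix()]).
#' @param binwidth histogram bin width, same units as `d`. The conventional
#'   choices are 0.5 mm for physical matrices at mouse scale and 0.2 for
#'   adimensional matrices.
#' @return an object of class `distance_stats`: a list with `n`, `mean`,
#'   `max`, `ratio` (= max/mean), `breaks`, `counts`, `density`.
#' @export
distance_stats <- function(d, binwidth = if (distance_units(d) == "adimensional") 0.2 else 0.5) {
  validate_distance_matrix(d)
  stopifnot(binwidth > 0)
  v <- offdiag_values(d)
  dmax <- max(v)
  nb <- ceiling(dmax / binwidth)
  breaks <- seq(0, nb * binwidth, by = binwidth)
  idx <- pmin(floor(v / binwidth) + 1L, nb) # top edge closed
  counts <- tabulate(idx, nbins = nb)
  density <- counts / (length(v) * binwidth)
  structure(list(
    n = length(v), mean = mean(v), max = dmax, ratio = dmax / mean(v),
    binwidth = binwidth, breaks = breaks, counts = counts, density = density
  ), class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("distance stats over %d pairs: <d> = %.4g, d_max = %.4g, d_max/<d> = %.3g\n",
              x$n, x$mean, x$max, x$ratio))
  invisible(x)
}

#' Rescale a distance matrix onto the adimensional template
#'
#' Divides every distance by the mean interareal distance so that the rescaled
#' matrix has mean off-diagonal distance exactly 1. On this common template,
#' brains of very different physical sizes can be compared directly; the decay
#' rate transforms as gamma = lambda * <d>.
#'
#' @param d distance matrix.
#' @return rescaled distance matrix with `units = "adimensional"`.
#' @export
rescale_adimensional <- function(d) {
  validate_distance_matrix(d)
  m <- mean(offdiag_values(d))
  if (m == 0) stop("mean interareal distance is zero")
  out <- d / m
  attr(out, "units") <- "adimensional"
  out
}

#' Permutation test for the ratio of two sample variances
#'
#' Tests whether two samples of (typically mean-normalized) distances have the
#' same spread, without assuming normality. The statistic is
#' `var(x)/var(y)`. Group labels are permuted `n_perm` times and the two-sided
#' p-value is the proportion of ratios at least as extreme as the observed
#' one, where "more extreme" means below `min(r, 1/r)` or above `max(r, 1/r)`.
#' The observed ratio is included in the permutation distribution, so the
#' smallest attainable p-value is `1/(n_perm + 1)`.
#'
#' @param x,y numeric samples, each of length >= 2 with positive variance.
#' @param n_perm number of label permutations (>= 1).
#' @param seed optional RNG seed.
#' @return list with `ratio`, `p_value`, `n_perm`.
#' @export
variance_ratio_permutation_test <- function(x, y, n_perm = 10000L, seed = NULL) {
  stopifnot(length(x) >= 2, length(y) >= 2, n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 || vy == 0) stop("zero variance in one of the samples")
  r <- vx / vy
  pool <- c(x, y)
  nx <- length(x); n <- length(pool)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, nx)
    stats::var(pool[idx]) / stats::var(pool[-idx])
  }, numeric(1))
  lo <- min(r, 1 / r); hi <- max(r, 1 / r)
  all_r <- c(r, perm_r) # observed value included
  p <- mean(all_r <= lo | all_r >= hi)
  list(ratio = r, p_value = p, n_perm = n_perm)
}
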