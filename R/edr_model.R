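#' Construct a connectome object
#'
#' A connectome is a directed weighted graph over N cortical areas. The weight
#' matrix is oriented source -> target: `W[i, j]` is the weight of the
#' projection from area i to area j (for model graphs, the number of unit
#' connections accumulated on that ordered pair). The binary adjacency is
#' `A = (W > 0)`.
#'
#' @param W numeric N x N nonnegative matrix with zero diagonal.
#' @param labels area names; defaults to row names of `W`.
#' @return object of class `connectome`: list with `labels`, `W`, `A`, `N`, `M`.
#' @export
connectome <- function(W, labels = rownames(W)) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (any(W < 0) || any(!is.finite(W))) stop("weights must be finite and nonnegative")
  if (any(diag(W) != 0)) stop("self-loops are not allowed (diagonal must be zero)")
  if (is.null(labels)) labels <- paste0("A", seq_len(nrow(W)))
  dimnames(W) <- list(labels, labels)
  A <- (W > 0) * 1L
  dimnames(A) <- dimnames(W)
  structure(list(labels = labels, W = W, A = A,
                 N = nrow(W), M = sum(A)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d areas, %d directed links (density %.3f)\n",
              x$N, x$M, x$M / (x$N * (x$N - 1))))
  invisible(x)
}

#' Binary density of a connectome
#' @param G connectome.
#' @return M / (N (N - 1)).
#' @export
graph_density <- function(G) G$M / (G$N * (G$N - 1))

#' Fraction of labeled neurons (FLN) view of the weights
#'
#' Normalizes weights per target area (column), mirroring how tracer weights
#' are expressed: each incoming weight divided by the total extrinsic labeling
#' for that injected target. Columns of targets with no in-links are returned
#' as `NA` and flagged.
#'
#' @param G connectome.
#' @return N x N matrix whose non-flagged columns sum to 1; attribute
#'   `isolated_targets` lists labels of targets without in-links.
#' @export
fln <- function(G) {
  tot <- colSums(G$W)
  out <- sweep(G$W, 2, tot, "/")
  iso <- G$labels[tot == 0]
  out[, tot == 0] <- NA_real_
  attr(out, "isolated_targets") <- iso
  out
}

# Internal: shared state for binned pair sampling.
# Pairs are the unordered upper-triangle pairs of D; each is assigned to the
# left-closed bin floor(d/binwidth). Returns per-nonempty-bin pair index lists
# and the truncated-exponential bin probabilities for rate lambda (lambda = 0
# means a flat length law).
edr_bin_setup <- function(D, lambda, binwidth) {
  n <- nrow(D)
  ut <- which(upper.tri(D))
  pd <- D[ut]
  dmax <- max(pd)
  nb <- ceiling(dmax / binwidth)
  bin <- pmin(floor(pd / binwidth) + 1L, nb)
  by_bin <- split(seq_along(ut), bin)
  bins_used <- as.integer(names(by_bin))
  lo <- (bins_used - 1L) * binwidth
  hi <- bins_used * binwidth
  w <- if (lambda > 0) exp(-lambda * lo) - exp(-lambda * hi) else hi - lo
  list(ut = ut, pair_d = pd, prob = w / sum(w), n = n,
       flat = unlist(by_bin, use.names = FALSE),
       len = lengths(by_bin),
       off = cumsum(lengths(by_bin)) - lengths(by_bin))
}

# Internal core sampler. pair_draw() must return `k` unordered pair indices
# (into setup$ut). Inserts randomly oriented unit connections until the number
# of distinct ordered connected pairs reaches m_target.
sample_spatial_graph <- function(D, m_target, draw_pairs, labels) {
  n <- nrow(D)
  if (m_target > n * (n - 1)) stop("target edge count exceeds N(N-1)")
  if (m_target < 1) stop("target edge count must be >= 1")
  ids <- integer(0) # ordered-pair ids: pair_index * 2 + direction
  repeat {
    k <- max(64L, 2L * (m_target - length(unique(ids))))
    pk <- draw_pairs(k)
    dir <- sample.int(2L, k, replace = TRUE) - 1L # 1: i -> j, 0: j -> i
    new_ids <- pk * 2L + dir
    ids <- c(ids, new_ids)
    distinct <- cumsum(!duplicated(ids))
    if (distinct[length(ids)] >= m_target) {
      stop_at <- which(distinct == m_target)[1L]
      ids <- ids[seq_len(stop_at)]
      break
    }
  }
  tab <- table(ids)
  pair_idx <- as.integer(names(tab)) %/% 2L
  dir <- as.integer(names(tab)) %% 2L # 1: i -> j, 0: j -> i
  # recover (row, col) of unordered pair from upper.tri index
  ut <- which(upper.tri(matrix(0, n, n)))
  pos <- ut[pair_idx]
  j <- (pos - 1L) %/% n + 1L
  i <- (pos - 1L) %% n + 1L
  W <- matrix(0, n, n)
  src <- ifelse(dir == 1L, i, j)
  tgt <- ifelse(dir == 1L, j, i)
  W[cbind(src, tgt)] <- as.numeric(tab)
  connectome(W, labels)
}

#' Sample a random connectome from the exponential distance rule (EDR) model
#'
#' The EDR model is a maximum-entropy-style spatial random graph over a fixed
#' distance matrix: connection lengths are drawn from `p(d) = lambda *
#' exp(-lambda * d)`, the length is located in a distance bin, an unordered
#' area pair whose separation falls in that bin is chosen uniformly, and a
#' unit connection of uniformly random orientation is inserted. Draws landing
#' beyond the largest distance or in a bin containing no pairs are rejected
#' and redrawn. Repeated draws on the same ordered pair accumulate weight, so
#' edge weights are connection multiplicities (approximately log-normal when
#' `p(d)` is combined with a unimodal distance distribution). Insertion stops
#' exactly when the number of distinct ordered connected pairs reaches the
#' target, so the realized binary density equals the requested one.
#'
#' @param D distance matrix (see [distance_matrix()]).
#' @param lambda decay rate, in inverse units of `D` (>= 0; 0 gives a flat
#'   length law, the lambda -> 0 limit of the EDR).
#' @param density target binary density M / (N(N-1)); give either `density`
#'   or `n_edges`.
#' @param n_edges target number of distinct ordered connected pairs.
#' @param binwidth distance bin width used for pair lookup; defaults to
#'   `max(D)/25`, which reproduces the conventional choices (about 0.4 mm at
#'   mouse scale and a few mm at macaque scale).
#' @param seed optional RNG seed.
#' @return a [connectome()].
#' @export
sample_edr <- function(D, lambda, density = NULL, n_edges = NULL,
                       binwidth = NULL, seed = NULL) {
  validate_distance_matrix(D)
  stopifnot(lambda >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(D)
  m_target <- resolve_edges(n, density, n_edges)
  if (is.null(binwidth)) binwidth <- max(D) / 25
  stopifnot(binwidth > 0)
  setup <- edr_bin_setup(D, lambda, binwidth)
  nbins <- length(setup$len)
  draw_pairs <- function(k) {
    b <- sample.int(nbins, k, replace = TRUE, prob = setup$prob)
    within <- floor(stats::runif(k) * setup$len[b]) + 1L
    setup$flat[setup$off[b] + within]
  }
  G <- sample_spatial_graph(D, m_target, draw_pairs, rownames(D))
  G$lambda <- lambda
  G$binwidth <- binwidth
  G
}

#' Sample a random connectome from the constant distance rule (CDR) model
#'
#' The CDR is the distance-blind null: every unordered area pair is equally
#' likely to receive each unit connection, regardless of separation, so the
#' distribution of realized connection lengths simply follows the distance
#' distribution q(d). Orientation, weight accumulation and the stopping rule
#' are as in [sample_edr()].
#'
#' @inheritParams sample_edr
#' @return a [connectome()].
#' @export
sample_cdr <- function(D, density = NULL, n_edges = NULL, seed = NULL) {
  validate_distance_matrix(D)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(D)
  m_target <- resolve_edges(n, density, n_edges)
  npairs <- n * (n - 1) / 2
  draw_pairs <- function(k) sample.int(npairs, k, replace = TRUE)
  G <- sample_spatial_graph(D, m_target, draw_pairs, rownames(D))
  G$lambda <- 0
  G
}

resolve_edges <- function(n, density, n_edges) {
  if (is.null(n_edges) && is.null(density))
    stop("give either density or n_edges")
  if (is.null(n_edges)) {
    stopifnot(density > 0, density <= 1)
    n_edges <- round(density * n * (n - 1))
  }
  as.integer(n_edges)
}

#' Histogram of realized connection lengths
#'
#' Bins the lengths of a connectome's links over the distance bins used by the
#' samplers. With `weighted = TRUE` each ordered connected pair contributes
#' its weight (connection multiplicity), which is the quantity whose decay the
#' EDR describes; with `weighted = FALSE` each binary link counts once.
#'
#' @param G connectome.
#' @param D distance matrix with matching labels.
#' @param binwidth bin width; defaults to the sampler's if recorded, else
#'   `max(D)/25`.
#' @param weighted count multiplicities rather than binary links.
#' @return list with `breaks`, `mids`, `counts`.
#' @export
edge_length_histogram <- function(G, D, binwidth = NULL, weighted = TRUE) {
  check_labels(G, D)
  if (is.null(binwidth)) binwidth <- if (!is.null(G$binwidth)) G$binwidth else max(D) / 25
  dmax <- max(offdiag_values(D))
  nb <- ceiling(dmax / binwidth)
  sel <- which(G$W > 0, arr.ind = TRUE)
  dd <- D[sel]
  ww <- if (weighted) G$W[sel] else rep(1, nrow(sel))
  idx <- pmin(floor(dd / binwidth) + 1L, nb)
  counts <- vapply(seq_len(nb), function(b) sum(ww[idx == b]), numeric(1))
  breaks <- seq(0, nb * binwidth, by = binwidth)
  list(breaks = breaks, mids = breaks[-1] - binwidth / 2, counts = counts)
}

check_labels <- function(G, D) {
  if (!identical(G$labels, rownames(D)))
    stop("connectome and distance matrix labels do not match")
  invisible(TRUE)
}
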