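#' Binary summary statistics of a connectome
#'
#' Counts of nodes and directed links, binary density, the numbers of
#' unidirectionally (`M1`) and bidirectionally (`M2`) connected unordered area
#' pairs (so that `M = M1 + 2 * M2`), the second-largest eigenvalue of the
#' co-occurrence matrix `A %*% t(A)`, and the ranked in- and out-degree
#' sequences.
#'
#' @param G connectome.
#' @return object of class `graph_summary`.
#' @export
graph_summary <- function(G) {
  A <- G$A
  n <- G$N
  m <- G$M
  both <- A * t(A)
  m2 <- sum(both[upper.tri(both)])
  m1 <- m - 2L * m2
  structure(list(
    N = n, M = m, density = m / (n * (n - 1)),
    M1 = m1, M2 = m2,
    eigen2 = second_eigenvalue(G),
    in_degree = sort(colSums(A), decreasing = TRUE),
    out_degree = sort(rowSums(A), decreasing = TRUE)
  ), class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat(sprintf("N = %d, M = %d (density %.3f), M1 = %d, M2 = %d, eigen2(AA') = %.3f\n",
              x$N, x$M, x$density, x$M1, x$M2, x$eigen2))
  invisible(x)
}

# ---- 3-node motif machinery -------------------------------------------------
#
# A triple of nodes induces one of 16 directed isomorphism classes. The class
# numbering used throughout the package is fixed by the canonical table below
# (ascending arc count, mutual dyads first within equal arc count), which puts
# the lone bidirectional pair at class 3 and the oriented 3-cycle at class 10.
# Each induced subgraph on nodes (a, b, c) is encoded in 6 bits
# (ab, ba, ac, ca, bc, cb) and classified through a precomputed 64-entry
# lookup of canonical forms.

motif_code <- function(bits) as.integer(sum(bits * 2L^(0:5)))

# recompute the 6-bit code after permuting the three node roles
permute_code <- function(code, perm) {
  b <- as.integer(intToBits(code))[1:6]
  E <- matrix(0L, 3, 3)
  E[1, 2] <- b[1]; E[2, 1] <- b[2]
  E[1, 3] <- b[3]; E[3, 1] <- b[4]
  E[2, 3] <- b[5]; E[3, 2] <- b[6]
  E <- E[perm, perm]
  motif_code(c(E[1, 2], E[2, 1], E[1, 3], E[3, 1], E[2, 3], E[3, 2]))
}

canonical_motif_code <- function(code) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  min(vapply(perms, function(p) permute_code(code, p), integer(1)))
}

# representatives of the 16 classes, in package order; arcs as ordered pairs
# over nodes 1,2,3
motif_class_arcs <- list(
  list(),                                                     #  1 empty
  list(c(1, 2)),                                              #  2 single link
  list(c(1, 2), c(2, 1)),                                     #  3 lone bidirectional pair
  list(c(2, 1), c(2, 3)),                                     #  4 out-star (common driver)
  list(c(1, 2), c(3, 2)),                                     #  5 in-star (common target)
  list(c(1, 2), c(2, 3)),                                     #  6 directed path
  list(c(1, 2), c(2, 1), c(3, 1)),                            #  7 mutual pair + incoming arc
  list(c(1, 2), c(2, 1), c(1, 3)),                            #  8 mutual pair + outgoing arc
  list(c(1, 2), c(2, 3), c(1, 3)),                            #  9 transitive triangle
  list(c(1, 2), c(2, 3), c(3, 1)),                            # 10 oriented 3-cycle
  list(c(1, 2), c(2, 1), c(1, 3), c(3, 1)),                   # 11 two mutual pairs
  list(c(2, 3), c(3, 2), c(1, 2), c(1, 3)),                   # 12 mutual pair driven by third
  list(c(1, 2), c(2, 1), c(1, 3), c(2, 3)),                   # 13 mutual pair driving third
  list(c(1, 2), c(2, 1), c(2, 3), c(3, 1)),                   # 14 mutual pair + through-arc
  list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3)),          # 15 two mutual pairs + arc
  list(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))  # 16 complete (3-clique)
)

arcs_to_code <- function(arcs) {
  E <- matrix(0L, 3, 3)
  for (a in arcs) E[a[1], a[2]] <- 1L
  motif_code(c(E[1, 2], E[2, 1], E[1, 3], E[3, 1], E[2, 3], E[3, 2]))
}

# 64-entry lookup: code + 1 -> class 1..16, built once at install time
motif_lookup_table <- local({
  class_canon <- vapply(motif_class_arcs,
                        function(a) canonical_motif_code(arcs_to_code(a)), integer(1))
  stopifnot(!anyDuplicated(class_canon))
  lk <- vapply(0:63, function(code) match(canonical_motif_code(code), class_canon),
               integer(1))
  stopifnot(!anyNA(lk))
  lk
})

#' Names of the 16 directed 3-node motif classes
#' @return character vector of length 16 in package class order.
#' @export
motif_class_names <- function() {
  c("empty", "single link", "lone bidirectional pair", "out-star", "in-star",
    "directed path", "mutual pair + incoming arc", "mutual pair + outgoing arc",
    "transitive triangle", "oriented 3-cycle", "two mutual pairs",
    "mutual pair driven by third", "mutual pair driving third",
    "mutual pair + through-arc", "two mutual pairs + arc", "complete")
}

triple_cache <- new.env(parent = emptyenv())

node_triples <- function(n) {
  key <- as.character(n)
  if (is.null(triple_cache[[key]]))
    triple_cache[[key]] <- t(utils::combn(n, 3))
  triple_cache[[key]]
}

#' Census of directed 3-node motifs
#'
#' Classifies every unordered node triple into one of the 16 directed
#' isomorphism classes of 3-node digraphs. Classes are numbered so that class
#' 3 is the lone bidirectional pair and class 10 the oriented 3-cycle; see
#' [motif_class_names()] for the full table. Counts always sum to
#' `choose(N, 3)`.
#'
#' @param G connectome with N >= 3.
#' @return object of class `motif_census`: list with integer `counts` (length
#'   16) and `total`.
#' @export
motif_census <- function(G) {
  A <- G$A
  n <- G$N
  if (n < 3) stop("motif census needs at least 3 nodes")
  tr <- node_triples(n)
  i <- tr[, 1]; j <- tr[, 2]; k <- tr[, 3]
  code <- A[cbind(i, j)] + 2L * A[cbind(j, i)] +
    4L * A[cbind(i, k)] + 8L * A[cbind(k, i)] +
    16L * A[cbind(j, k)] + 32L * A[cbind(k, j)]
  counts <- tabulate(motif_lookup_table[code + 1L], nbins = 16L)
  structure(list(counts = counts, total = nrow(tr)), class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  df <- data.frame(class = 1:16, name = motif_class_names(), count = x$counts)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Degree-preserving rewiring null model
#'
#' Uniformly randomizes the binary structure of a graph while preserving every
#' node's in- and out-degree, by repeated double-edge swaps that reject
#' self-loops and duplicate edges. Weights are discarded: the null is binary.
#'
#' @param G connectome.
#' @param n_swaps number of attempted swaps (> 0); default `10 * M`.
#' @param seed optional RNG seed.
#' @return a binary [connectome()] with identical in/out degree sequences.
#' @export
rewire_degree_preserving <- function(G, n_swaps = 10 * G$M, seed = NULL) {
  if (n_swaps <= 0) stop("n_swaps must be positive")
  if (!is.null(seed)) set.seed(seed)
  g <- igraph::graph_from_adjacency_matrix(G$A, mode = "directed")
  g <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  dimnames(A) <- dimnames(G$A)
  connectome(A, G$labels)
}

#' Motif residuals against a rewiring null model
#'
#' For each of the 16 motif classes, the logarithmic residual
#' `ln(m_data / <m_null>)` of the observed count against its mean over an
#' ensemble of degree-preserving rewired graphs, with a 95% interval derived
#' from the 2.5/97.5 percentiles of the null counts. Classes whose null mean
#' is zero are flagged (`NA` residual) rather than computed.
#'
#' @param G connectome.
#' @param n_null ensemble size (>= 2).
#' @param n_swaps swap attempts per rewiring; default `10 * M`.
#' @param seed optional master seed; ensemble members use derived child seeds.
#' @return data.frame with columns `class`, `name`, `data_count`, `null_mean`,
#'   `residual`, `ci_lo`, `ci_hi`, `flagged`.
#' @export
motif_log_residuals <- function(G, n_null = 1000L, n_swaps = 10 * G$M, seed = NULL) {
  stopifnot(n_null >= 2)
  if (!is.null(seed)) set.seed(seed)
  m_data <- motif_census(G)$counts
  null_counts <- matrix(0L, n_null, 16L)
  for (r in seq_len(n_null)) {
    null_counts[r, ] <- motif_census(rewire_degree_preserving(G, n_swaps))$counts
  }
  mu <- colMeans(null_counts)
  flagged <- mu == 0
  resid <- ifelse(flagged | m_data == 0, NA_real_, log(m_data / mu))
  qs <- apply(null_counts, 2, stats::quantile, probs = c(0.025, 0.975))
  ci_lo <- ifelse(flagged, NA_real_, log(pmax(qs[1, ], 0.5) / mu))
  ci_hi <- ifelse(flagged, NA_real_, log(qs[2, ] / mu))
  data.frame(class = 1:16, name = motif_class_names(), data_count = m_data,
             null_mean = mu, residual = resid, ci_lo = ci_lo, ci_hi = ci_hi,
             flagged = flagged)
}

#' Clique census on the bidirectional skeleton
#'
#' A clique is a node set in which every pair is connected in both directions
#' (a complete subgraph of the undirected skeleton that keeps an edge only
#' where links exist in both directions). All cliques of every size are
#' counted, not only maximal ones, so the count at size 1 is N and the counts
#' obey the hereditary property of cliques.
#'
#' @param G connectome.
#' @param max_k optional cap on clique size.
#' @return object of class `clique_census`: list with `counts` (named integer
#'   vector indexed by size k) and `max_size`.
#' @export
clique_census <- function(G, max_k = NULL) {
  g <- bidirectional_skeleton(G)
  counts <- igraph::clique_size_counts(g, min = 1,
                                       max = if (is.null(max_k)) 0 else max_k)
  counts <- as.integer(counts)
  while (length(counts) > 1 && counts[length(counts)] == 0L)
    counts <- counts[-length(counts)]
  kmax <- if (any(counts > 0)) max(which(counts > 0)) else 0L
  names(counts) <- seq_along(counts)
  structure(list(counts = counts, max_size = kmax), class = "clique_census")
}

bidirectional_skeleton <- function(G) {
  U <- (G$A * t(G$A)) > 0
  igraph::graph_from_adjacency_matrix(U, mode = "undirected")
}

#' @export
print.clique_census <- function(x, ...) {
  cat("clique census (bidirectional skeleton); max clique size", x$max_size, "\n")
  print(x$counts)
  invisible(x)
}

#' Root-mean-square of log-ratios between two count vectors
#'
#' The scalar deviation used to compare motif or clique-count profiles:
#' `sigma = sqrt(mean(log(a_k / b_k)^2))` over the size classes where both
#' counts are positive. Classes where either count is zero are dropped and
#' their number is reported; vectors of unequal length are compared on the
#' overlap of their indices (missing classes count as zero).
#'
#' @param a,b nonnegative count vectors.
#' @return list with `sigma`, `n_used`, `n_dropped`.
#' @export
rms_log_ratio <- function(a, b) {
  k <- max(length(a), length(b))
  a <- c(a, rep(0, k - length(a)))
  b <- c(b, rep(0, k - length(b)))
  use <- a > 0 & b > 0
  if (!any(use)) stop("no common support between count vectors")
  lr <- log(a[use] / b[use])
  list(sigma = sqrt(mean(lr^2)), n_used = sum(use), n_dropped = sum(!use))
}

#' Second-largest eigenvalue of the co-occurrence matrix
#'
#' Eigenvalues of `A %*% t(A)` (a symmetric positive semi-definite matrix, so
#' all eigenvalues are real and nonnegative); the second largest is a global
#' measure related to the rate of spreading processes on the network.
#'
#' @param G connectome.
#' @return nonnegative scalar.
#' @export
second_eigenvalue <- function(G) {
  ev <- eigen(G$A %*% t(G$A), symmetric = TRUE, only.values = TRUE)$values
  max(ev[2], 0)
}

#' Logistic regression of connection presence on distance
#'
#' Fits a binomial GLM with logit link, one record per ordered area pair,
#' regressing the presence of a directed link on the interareal distance:
#' `logit P(link) = beta0 + beta1 * d`. Under an EDR-like network beta1 is
#' negative; under the CDR it is approximately zero.
#'
#' @param G connectome.
#' @param D distance matrix with matching labels.
#' @return list with `beta0`, `beta1`, `se`, `z`, `p_value`, `separation`
#'   (TRUE when the fit is degenerate, in which case estimates are `NA`).
#' @export
connection_probability_fit <- function(G, D) {
  check_labels(G, D)
  off <- row(G$A) != col(G$A)
  y <- G$A[off]
  d <- D[off]
  if (all(y == 0) || all(y == 1))
    return(list(beta0 = NA_real_, beta1 = NA_real_, se = c(NA_real_, NA_real_),
                z = NA_real_, p_value = NA_real_, separation = TRUE))
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ d, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged)
    return(list(beta0 = NA_real_, beta1 = NA_real_, se = c(NA_real_, NA_real_),
                z = NA_real_, p_value = NA_real_, separation = TRUE))
  s <- summary(fit)$coefficients
  list(beta0 = unname(s[1, 1]), beta1 = unname(s[2, 1]),
       se = unname(s[, 2]), z = unname(s[2, 3]), p_value = unname(s[2, 4]),
       separation = FALSE)
}
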