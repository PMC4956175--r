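#' Total wire length of a connectome layout
#'
#' `Lambda = sum_ij A_ij D_ij`: each directed link contributes the distance
#' between its endpoints. With `weighted = TRUE` the weight matrix is used
#' instead of the binary adjacency (an option not used in the standard
#' comparisons).
#'
#' @param G connectome (or a binary adjacency matrix).
#' @param D distance matrix with matching labels.
#' @param weighted use weights instead of the binary adjacency.
#' @return nonnegative scalar, in the units of `D`.
#' @export
total_wire_length <- function(G, D, weighted = FALSE) {
  A <- wiring_adjacency(G, D, weighted)
  sum(A * D)
}

wiring_adjacency <- function(G, D, weighted = FALSE) {
  if (inherits(G, "connectome")) {
    check_labels(G, D)
    if (weighted) G$W else G$A
  } else {
    stopifnot(nrow(G) == nrow(D))
    G
  }
}

#' Yoked-permutation null distribution of total wire length
#'
#' Each draw applies one random node permutation simultaneously to the rows
#' and columns of the adjacency matrix, reassigning areas to positions while
#' leaving the connectivity (and hence every topological property) unchanged,
#' and recomputes the wire length against the fixed distance matrix. A data
#' network far below this distribution is economically wired.
#'
#' @param G connectome or binary adjacency.
#' @param D distance matrix.
#' @param n_perm number of permutations (>= 1).
#' @param seed optional RNG seed.
#' @return numeric vector of `n_perm` wire lengths.
#' @export
wire_permutation_null <- function(G, D, n_perm = 1000L, seed = NULL) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  A <- wiring_adjacency(G, D)
  n <- nrow(A)
  vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    sum(A[p, p] * D)
  }, numeric(1))
}

#' Optimize area placement by simulated annealing
#'
#' Searches for a relabeling of areas onto the fixed positions that minimizes
#' the total wire length, keeping the connectivity intact. The state is a
#' node-to-position permutation initialized at the identity (the empirical
#' placement); a move swaps two positions; moves are accepted by the
#' Metropolis rule at temperature T with geometric cooling. The best-ever
#' placement is tracked, so the returned optimum never exceeds the empirical
#' wire length.
#'
#' @param G connectome or binary adjacency.
#' @param D distance matrix.
#' @param t0 initial temperature; defaults to `Lambda_data / 100`.
#' @param cooling geometric cooling factor per step, in (0, 1).
#' @param n_steps number of proposed moves.
#' @param seed optional RNG seed.
#' @return object of class `wiring_result`: list with `Lambda_data`,
#'   `Lambda_opt`, `reduction_pct`, `permutation` (position of each node),
#'   `schedule`, `trace` (best-ever wire length, thinned).
#' @export
anneal_placement <- function(G, D, t0 = NULL, cooling = 0.999, n_steps = 1e5,
                             seed = NULL) {
  if (!is.null(t0) && t0 <= 0) stop("t0 must be positive")
  if (cooling <= 0 || cooling >= 1) stop("cooling factor must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  A <- wiring_adjacency(G, D)
  n <- nrow(A)
  stopifnot(n >= 2)
  p <- seq_len(n)
  lambda_cur <- sum(A * D)
  lambda_data <- lambda_cur
  if (is.null(t0)) t0 <- lambda_data / 100
  best <- lambda_cur
  best_p <- p
  temp <- t0
  trace_every <- max(1L, floor(n_steps / 200))
  trace <- numeric(0)
  # cost of links incident to nodes a or b under placement p (a-b links counted once)
  inc_cost <- function(p, a, b) {
    sum(A[a, ] * D[p[a], p]) + sum(A[, a] * D[p, p[a]]) +
      sum(A[b, ] * D[p[b], p]) + sum(A[, b] * D[p, p[b]]) -
      A[a, b] * D[p[a], p[b]] - A[b, a] * D[p[b], p[a]]
  }
  for (step in seq_len(n_steps)) {
    ab <- sample.int(n, 2L)
    a <- ab[1L]; b <- ab[2L]
    old <- inc_cost(p, a, b)
    p2 <- p
    p2[a] <- p[b]; p2[b] <- p[a]
    new <- inc_cost(p2, a, b)
    delta <- new - old
    if (delta < 0 || stats::runif(1) < exp(-delta / temp)) {
      p <- p2
      lambda_cur <- lambda_cur + delta
      if (lambda_cur < best) {
        best <- lambda_cur
        best_p <- p
      }
    }
    temp <- temp * cooling
    if (step %% trace_every == 0L) trace <- c(trace, best)
  }
  structure(list(
    Lambda_data = lambda_data, Lambda_opt = best,
    reduction_pct = 100 * (lambda_data - best) / lambda_data,
    permutation = best_p,
    schedule = list(t0 = t0, cooling = cooling, n_steps = n_steps),
    trace = trace
  ), class = "wiring_result")
}

#' @export
print.wiring_result <- function(x, ...) {
  cat(sprintf("wire length: data %.4g, optimized %.4g (%.2f%% reduction)\n",
              x$Lambda_data, x$Lambda_opt, x$reduction_pct))
  invisible(x)
}
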