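#' Extract the clique-based core of a dense connectome
#'
#' The core is the union of all maximum-size cliques of the bidirectional
#' skeleton (ties all included); the periphery is its complement. This is the
#' construction under which, e.g., two overlapping 11-cliques yield a 12-node
#' core. The returned partition carries the directed block link counts and
#' densities (see [block_stats()]).
#'
#' @param G connectome whose bidirectional skeleton has a clique of size >= 2.
#' @return object of class `core_partition`.
#' @export
extract_core <- function(G) {
  g <- bidirectional_skeleton(G)
  mc <- igraph::largest_cliques(g)
  if (length(mc) == 0 || length(mc[[1]]) < 2)
    stop("no clique of size >= 2: core is undefined")
  core_idx <- sort(unique(unlist(lapply(mc, as.integer))))
  block_stats(G, G$labels[core_idx])
}

#' Core/periphery block link counts and densities
#'
#' Directed link counts within the core (`M_cc`), from core to periphery
#' (`M_cp`), from periphery to core (`M_pc`) and within the periphery
#' (`M_pp`); these always sum to M. Densities follow
#' `M_cc / (n_c (n_c - 1))` for the core, `M_pp / (n_p (n_p - 1))` for the
#' periphery and `(M_cp + M_pc) / (2 n_c n_p)` between blocks, reported at
#' full precision and rounded to whole percent. Empty blocks give `NA`
#' densities and are flagged.
#'
#' @param G connectome.
#' @param core character vector of core area labels (or integer indices).
#' @return object of class `core_partition`: list with `core`, `periphery`,
#'   counts `M_cc`, `M_cp`, `M_pc`, `M_pp`, `densities` (list with `core`,
#'   `periphery`, `between`), `densities_pct` (rounded), `flagged`.
#' @export
block_stats <- function(G, core) {
  if (is.numeric(core)) core <- G$labels[core]
  if (!all(core %in% G$labels)) stop("core labels not found in connectome")
  in_core <- G$labels %in% core
  A <- G$A
  M_cc <- sum(A[in_core, in_core])
  M_cp <- sum(A[in_core, !in_core])
  M_pc <- sum(A[!in_core, in_core])
  M_pp <- sum(A[!in_core, !in_core])
  n_c <- sum(in_core); n_p <- sum(!in_core)
  dens <- block_densities(n_c, n_p, M_cc, M_cp, M_pc, M_pp)
  structure(list(core = G$labels[in_core], periphery = G$labels[!in_core],
                 n_core = n_c, n_periphery = n_p,
                 M_cc = M_cc, M_cp = M_cp, M_pc = M_pc, M_pp = M_pp,
                 densities = dens$raw, densities_pct = dens$pct,
                 flagged = dens$flagged),
            class = "core_partition")
}

#' Block densities from counts and block sizes
#'
#' The same density formulas as [block_stats()], computed directly from
#' printed or tabulated counts rather than from a graph.
#'
#' @param n_core,n_periphery block sizes.
#' @param M_cc,M_cp,M_pc,M_pp directed block link counts.
#' @return list with `raw` (fractions), `pct` (rounded whole percents) and
#'   `flagged` (names of empty blocks).
#' @export
block_densities <- function(n_core, n_periphery, M_cc, M_cp, M_pc, M_pp) {
  core <- if (n_core > 1) M_cc / (n_core * (n_core - 1)) else NA_real_
  periph <- if (n_periphery > 1) M_pp / (n_periphery * (n_periphery - 1)) else NA_real_
  between <- if (n_core > 0 && n_periphery > 0)
    (M_cp + M_pc) / (2 * n_core * n_periphery) else NA_real_
  raw <- list(core = core, periphery = periph, between = between)
  pct <- lapply(raw, function(x) if (is.na(x)) NA_real_ else round(100 * x))
  flagged <- names(raw)[vapply(raw, is.na, logical(1))]
  list(raw = raw, pct = pct, flagged = flagged)
}

#' @export
print.core_partition <- function(x, ...) {
  cat(sprintf("core of %d areas / periphery of %d areas\n", x$n_core, x$n_periphery))
  cat(sprintf("  M_cc = %d, M_cp = %d, M_pc = %d, M_pp = %d\n",
              x$M_cc, x$M_cp, x$M_pc, x$M_pp))
  cat(sprintf("  densities: core %s%%, periphery %s%%, between %s%%\n",
              x$densities_pct$core, x$densities_pct$periphery, x$densities_pct$between))
  invisible(x)
}

#' Chance likelihood of a core under an Erdos-Renyi null
#'
#' Probability-style likelihood that a random directed graph on N nodes with
#' link probability p contains a specific-size core block this dense:
#' `choose(N, n_core) * choose(n_core (n_core - 1), M_cc) * p^M_cc *
#' (1 - p)^(n_core (n_core - 1) - M_cc)`. Evaluated in log space; direct
#' evaluation of the binomial coefficients would overflow.
#'
#' @param N number of nodes.
#' @param n_core core size.
#' @param M_cc directed links within the core; at most `n_core * (n_core - 1)`.
#' @param p link density, strictly between 0 and 1.
#' @param log.p return the log-likelihood instead.
#' @return numeric scalar.
#' @export
core_likelihood <- function(N, n_core, M_cc, p, log.p = FALSE) {
  slots <- n_core * (n_core - 1)
  stopifnot(p > 0, p < 1, M_cc <= slots, n_core <= N)
  ll <- lchoose(N, n_core) + lchoose(slots, M_cc) +
    M_cc * log(p) + (slots - M_cc) * log1p(-p)
  if (log.p) ll else exp(ll)
}
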