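#' Distribution of the number of ancestral lineages
#'
#' Looking backward along a branch of length `tau` (diffusion time scale), a
#' sample of `i` gene lineages coalesces down to some number `k <= i` of
#' ancestral lineages. `lineage_distribution()` is the fast approximation used
#' in the likelihood: a normal distribution with the exact mean and variance
#' of the coalescent death process, discretised on half-integer boundaries and
#' clamped to `1..i`. `tavare_lineage_distribution()` is the exact
#' alternating-series solution (numerically safe up to `i` around 25) used as
#' the test oracle.
#'
#' @param i current number of lineages (`>= 1`).
#' @param tau branch length on the diffusion time scale (`>= 0`).
#' @return a tibble with columns `k` and `prob`.
#' @examples
#' lineage_distribution(10, 0.2)
#' tavare_lineage_distribution(2, 0.3)  # P(k = 1) = 1 - exp(-0.3)
#' @export
lineage_distribution <- function(i, tau) {
  stopifnot(i >= 1, tau >= 0)
  d <- .lineage_thin_cpp(as.integer(i), tau)
  tibble(k = d$kmin + seq_along(d$probs) - 1L, prob = d$probs)
}

#' @rdname lineage_distribution
#' @export
tavare_lineage_distribution <- function(i, tau) {
  stopifnot(i >= 1, tau >= 0)
  if (i > 25)
    abort("exact alternating series is unstable for i > 25; use lineage_distribution()",
          class = "esr_lineage_error")
  i <- as.integer(i)
  if (tau == 0 || i == 1) return(tibble(k = i, prob = 1))
  probs <- vapply(seq_len(i), function(k) {
    idx <- k:i
    # log magnitudes of the alternating-series terms
    lt <- -idx * (idx - 1) * tau / 2 + log(2 * idx - 1) +
      lgamma(k + idx - 1) - lgamma(k) - lgamma(k + 1) - lgamma(idx - k + 1) +
      lgamma(i + 1) - lgamma(i - idx + 1) - (lgamma(i + idx) - lgamma(i))
    sum((-1)^(idx - k) * exp(lt))
  }, 0)
  probs[probs < 0] <- 0
  tibble(k = seq_len(i), prob = probs)
}

#' Combine daughter-lineage distributions at a node
#'
#' The number of lineages entering an internal node is the sum of the
#' independent counts arriving from its daughter branches; the distribution is
#' their discrete convolution, with support starting at the number of
#' daughters.
#'
#' @param dists a list of two or more lineage-count tibbles (columns `k`,
#'   `prob`).
#' @return a lineage-count tibble.
#' @export
combine_lineage_distributions <- function(dists) {
  if (length(dists) < 2)
    abort("need at least two distributions", class = "esr_lineage_error")
  out <- dists[[1]]
  for (d in dists[-1]) {
    r <- .lineage_convolve_cpp(min(out$k), out$prob, min(d$k), d$prob)
    out <- tibble(k = r$kmin + seq_along(r$probs) - 1L, prob = r$probs)
  }
  out
}

#' Root lineage-count distribution on a population tree
#'
#' Recursion from the leaves to the root: each leaf starts with its sample
#' size (number of genes), branches thin lineages via
#' [lineage_distribution()], nodes merge daughters by convolution, and no
#' thinning is applied above the root. The analysis uses the maximum sample
#' size per population across sites, so this is computed once per branch-
#' length vector.
#'
#' @param tree an [parse_tree()] object.
#' @param tau numeric vector of branch lengths indexed by node id (the root
#'   entry is ignored).
#' @param n integer vector of per-population lineage (gene) counts, length
#'   `tree$n_leaf`.
#' @return a lineage-count tibble for the root node.
#' @export
root_lineage_distribution <- function(tree, tau, n) {
  tree <- as_esr_tree(tree)
  stopifnot(length(tau) == tree$n_node, length(n) == tree$n_leaf)
  par0 <- ifelse(is.na(tree$parent), -1L, tree$parent - 1L)
  d <- .lineage_root_cpp(as.integer(par0), tree$n_leaf, as.numeric(tau),
                         as.integer(n))
  tibble(k = d$kmin + seq_along(d$probs) - 1L, prob = d$probs)
}

#' Probability that a site is polymorphic in the pooled sample
#'
#' Given the root allele frequency and the distribution of the number of
#' ancestral lineages at the root, the site is monomorphic exactly when all
#' root lineages carry the same allele, so
#' `P(polymorphic) = 1 - sum_k P(k) [(1 - x)^k + x^k]`. This is the term the
#' conditional likelihood divides by.
#'
#' @param x_r root allele frequency (vectorised), in `[0, 1]`.
#' @param root_dist a lineage-count tibble (from
#'   [root_lineage_distribution()]).
#' @return probabilities in `[0, 1]`; exactly 0 at `x_r` 0 or 1.
#' @export
prob_polymorphic <- function(x_r, root_dist) {
  stopifnot(all(x_r >= 0), all(x_r <= 1))
  .prob_poly_cpp(as.integer(min(root_dist$k)), root_dist$prob, as.numeric(x_r))
}
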