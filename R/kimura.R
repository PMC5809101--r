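#' Kimura's time-dependent drift transition distribution
#'
#' Under pure genetic drift, the frequency of an allele starting at `p` has,
#' after `tau = t / (2 Ne)` diffusion time units, a mixed distribution: point
#' masses at 0 (loss) and 1 (fixation) plus a continuous density on (0,1).
#' `kimura_density()` evaluates the continuous part (the classical
#' eigen-series in Gegenbauer polynomials, truncated adaptively);
#' `kimura_boundary_masses()` returns the two absorption probabilities. Below
#' `tau = 0.005` the series is replaced by a censored-Gaussian surrogate with
#' the exact drift mean and variance `p (1 - p) (1 - exp(-tau))`.
#'
#' @param p ancestral allele frequency in `[0, 1]`.
#' @param tau drift time `t / (2 Ne)`, positive.
#' @param x evaluation frequencies in (0, 1); vectorised.
#' @return `kimura_density()`: non-negative density values;
#'   `kimura_boundary_masses()`: named vector `c(lost =, fixed =)`.
#' @examples
#' kimura_density(0.3, 0.2, c(0.2, 0.5, 0.8))
#' kimura_boundary_masses(0.5, 1)
#' @export
kimura_density <- function(p, tau, x) {
  stopifnot(is.finite(p), is.finite(tau), all(is.finite(x)))
  if (tau <= 0) abort("`tau` must be > 0", class = "esr_kimura_error")
  if (p < 0 || p > 1 || any(x <= 0) || any(x >= 1))
    abort("`p` must be in [0,1] and `x` in (0,1)", class = "esr_kimura_error")
  .kimura_density_cpp(p, tau, x)
}

#' @rdname kimura_density
#' @export
kimura_boundary_masses <- function(p, tau) {
  stopifnot(is.finite(p), is.finite(tau))
  if (tau < 0 || p < 0 || p > 1)
    abort("need `tau` >= 0 and `p` in [0,1]", class = "esr_kimura_error")
  .kimura_boundary_cpp(p, tau)
}

#' Log mixed drift kernel over the closed unit interval
#'
#' Evaluation contract used by the sampler: the absorption atoms are smeared
#' uniformly over boundary strips of width `atom_width`, so the result is the
#' log of a proper density on `[0, 1]` for every `(p, tau)` and Metropolis
#' ratios between interior and absorbed states are well defined. Returns
#' `-Inf` (not an error) where the kernel has no mass (e.g. `p = 0`, `x` in
#' the interior).
#'
#' @inheritParams kimura_density
#' @param x frequencies in `[0, 1]`; vectorised.
#' @param atom_width width of the boundary strips carrying the absorption
#'   atoms; the sampler default is `1 / (2 n_max)`.
#' @export
kimura_log_kernel <- function(p, tau, x, atom_width = 0.005) {
  stopifnot(is.finite(p), is.finite(tau), all(is.finite(x)), atom_width > 0)
  if (tau <= 0) abort("`tau` must be > 0", class = "esr_kimura_error")
  .kimura_log_kernel_cpp(p, tau, x, atom_width)
}

#' Exact Wright-Fisher transition distribution (test oracle)
#'
#' Distribution of the allele frequency after `t` generations of binomial
#' resampling in a diploid population of size `N`, starting from the lattice
#' state nearest `p0`. This is the discrete process whose diffusion limit the
#' Kimura kernel approximates; it serves as ground truth in the test suite.
#'
#' @param N diploid population size (kept small; the matrix is `(2N+1)^2`).
#' @param t number of generations, `>= 0`.
#' @param p0 initial allele frequency.
#' @return a tibble with columns `x` (lattice frequencies `0, 1/(2N), ..., 1`)
#'   and `prob`.
#' @export
wright_fisher_oracle <- function(N, t, p0) {
  stopifnot(N >= 1, N <= 500, t >= 0, p0 >= 0, p0 <= 1)
  states <- 0:(2 * N) / (2 * N)
  v <- numeric(2 * N + 1)
  v[round(2 * N * p0) + 1] <- 1
  if (t > 0) {
    M <- outer(states, 0:(2 * N), function(pp, k) dbinom(k, 2 * N, pp))
    for (s in seq_len(t)) v <- as.vector(v %*% M)
  }
  tibble(x = states, prob = v)
}
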