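#' Fit branch-specific drift times and effective sex ratios
#'
#' Runs the full inference pipeline on paired autosomal and X-linked SNP
#' count tables: validation, pilot-run proposal tuning, burn-in, and
#' posterior sampling with a component-wise Metropolis-within-Gibbs sampler.
#' Latent allele frequencies at every node follow Kimura's drift diffusion
#' along each branch; root frequencies follow a Beta(mu nu, (1-mu) nu) prior
#' whose hyper-parameters are estimated per genetic system; the two branch
#' lengths of each branch, `tau_A` and `tau_X`, are updated jointly under the
#' uniform prior on the wedge `9 tau_X / 16 < tau_A < 9 tau_X / 8` implied by
#' an effective sex ratio in (0, 1); and the likelihood is conditioned on SNP
#' polymorphism through the root lineage-count distribution.
#'
#' @param counts_a,counts_x count-table tibbles (see [read_counts()]) for the
#'   autosomal and X-linked systems; they may differ in SNP number and sample
#'   sizes but must cover the same populations.
#' @param tree an [parse_tree()] object or a newick string; leaf numbering is
#'   taken from the autosomal table's column order when a string is given.
#' @param config an [esr_config()].
#' @param record_root keep the per-draw root allele frequencies (memory-heavy;
#'   used by diagnostic checks).
#' @param use_likelihood internal switch: `FALSE` samples from the prior
#'   (validation runs).
#' @param update_hyper update the root-beta hyper-parameters (`TRUE`); fix
#'   them at `init_hyper` otherwise.
#' @param init_hyper starting values `c(mu_A, nu_A, mu_X, nu_X)`.
#' @param atom_width width of the boundary strips that carry the
#'   fixation/loss atoms of the drift kernel, per system (recycled).
#'   Defaults to `1 / (20 n_max)`, well below the frequency resolution of
#'   the data: coarser strips (e.g. `1 / (2 n_max)`) measurably inflate
#'   internal branch lengths when the root frequency distribution is
#'   U-shaped, because too much near-boundary probability is lumped into
#'   the absorbed states.
#' @return an object of class `esr_fit`; see [tidy.esr_fit()],
#'   [glance.esr_fit()], [compute_dic()], [autoplot.esr_fit()].
#' @examples
#' \donttest{
#' sim <- simulate_forward("((P1,P2),P3);", tau_a = c(.1, .1, .2, .1),
#'                         J_a = 200, J_x = 200, n_genes = 50)
#' fit <- fit_esr(sim$counts_a, sim$counts_x, "((P1,P2),P3);",
#'                esr_config(n_pilot = 3, pilot_length = 100, burnin = 300,
#'                           chain_length = 600, thin = 10))
#' tidy(fit)
#' }
#' @export
fit_esr <- function(counts_a, counts_x, tree, config = esr_config(),
                    record_root = FALSE, use_likelihood = TRUE,
                    update_hyper = TRUE, init_hyper = c(0.5, 2, 0.5, 2),
                    atom_width = NULL) {
  stopifnot(inherits(config, "esr_config"))
  pops <- count_populations(counts_a)
  tree <- as_esr_tree(tree, populations = pops)
  validate_counts(counts_a, tree)
  validate_counts(counts_x, tree)
  ma <- counts_to_matrices(counts_a, tree$labels)
  mx <- counts_to_matrices(counts_x, tree$labels)

  par0 <- ifelse(is.na(tree$parent), -1L, tree$parent - 1L)
  children0 <- lapply(tree$children, function(k) as.integer(k - 1L))

  init_x <- function(m) {
    x <- matrix(0.5, tree$n_node, m$J)
    x[seq_len(tree$n_leaf), ] <- (m$y + 0.5) / pmax(m$n + 1, 1)
    for (v in (tree$n_leaf + 1):tree$n_node)
      x[v, ] <- colMeans(x[tree$children[[v]], , drop = FALSE])
    pmin(pmax(x, 1e-4), 1 - 1e-4)
  }
  tau0_a <- rep(0.1, tree$n_node)
  tau0_x <- rep(0.1 / 0.75, tree$n_node)
  atom_w <- if (is.null(atom_width))
    pmax(c(1 / (20 * max(ma$n, 2)), 1 / (20 * max(mx$n, 2))), 1e-5)
  else rep_len(atom_width, 2)

  scales <- list(x_a = rep(0.2, tree$n_node), x_x = rep(0.2, tree$n_node),
                 tau_a = rep(0.02, tree$n_node), tau_x = rep(0.02, tree$n_node),
                 mu = c(0.1, 0.1), nu = c(0.3, 0.3))
  control <- list(n_pilot = config$n_pilot, pilot_length = config$pilot_length,
                  burnin = config$burnin, chain_length = config$chain_length,
                  thin = config$thin,
                  acc_lo = config$target_acceptance[1],
                  acc_hi = config$target_acceptance[2],
                  adapt_factor = config$adapt_factor,
                  tau_min = config$tau_bounds[1], tau_max = config$tau_bounds[2],
                  condition = config$condition,
                  use_likelihood = isTRUE(use_likelihood),
                  update_hyper = isTRUE(update_hyper),
                  verbose = config$verbose,
                  record_root = isTRUE(record_root))

  set.seed(config$seed)
  t0 <- proc.time()[["elapsed"]]
  res <- .run_chain_cpp(ma$y, ma$n, mx$y, mx$n, par0, tree$n_leaf, children0,
                        init_x(ma), init_x(mx), tau0_a, tau0_x,
                        as.numeric(init_hyper), atom_w, scales, control)
  elapsed <- proc.time()[["elapsed"]] - t0

  blab <- branch_labels(tree)
  nbr <- tree$n_node - 1L
  cn <- c(paste0("tau_a_", seq_len(nbr)), paste0("tau_x_", seq_len(nbr)),
          "mu_a", "nu_a", "mu_x", "nu_x",
          "deviance_a", "deviance_x", "deviance")
  draws <- as_tibble(setNames(as.data.frame(res$draws), cn))
  draws$.draw <- seq_len(nrow(draws))

  structure(list(
    draws = draws,
    branches = tibble(branch = seq_len(nbr), label = blab,
                      parent = tree$parent[seq_len(nbr)]),
    tree = tree, config = config,
    acceptance = list(x_a = res$acc_x_a, x_x = res$acc_x_x,
                      tau = res$acc_tau[seq_len(nbr)],
                      mu = res$acc_mu, nu = res$acc_nu),
    scales = res$scales,
    xbar_a = res$xbar_a, xbar_x = res$xbar_x,
    root_draws_a = res$root_draws_a, root_draws_x = res$root_draws_x,
    data = list(y_a = ma$y, n_a = ma$n, y_x = mx$y, n_x = mx$n),
    atom_width = atom_w, elapsed = elapsed), class = "esr_fit")
}

#' @export
print.esr_fit <- function(x, ...) {
  cat(sprintf("esr_fit: %d populations, %d + %d SNPs (A + X), %d retained draws (%.1fs)\n",
              x$tree$n_leaf, ncol(x$data$y_a), ncol(x$data$y_x),
              nrow(x$draws), x$elapsed))
  print(tidy(x))
  invisible(x)
}

#' Joint log posterior density of a full model state
#'
#' Direct term-by-term evaluation of the (unnormalised) log posterior over
#' both genetic systems: binomial leaf likelihoods, Kimura log kernels along
#' every branch, root beta prior, hyper-priors (uniform for `mu`,
#' exponential(1) for `nu`), the flat joint branch-length prior on its wedge
#' support, and minus the per-site polymorphism-conditioning terms. Intended
#' for diagnostics and tests; the sampler maintains the same quantity
#' incrementally in compiled code.
#'
#' @param state a list with `x_a`, `x_x` (node-by-SNP frequency matrices),
#'   `tau_a`, `tau_x` (vectors indexed by node id, root entries ignored) and
#'   `hyper = c(mu_a, nu_a, mu_x, nu_x)`.
#' @inheritParams fit_esr
#' @param condition include the polymorphism-conditioning terms.
#' @param atom_width per-system atom widths (defaults to `1/(2 max n)`).
#' @return a single log-density value (`-Inf` if any constraint is violated).
#' @export
esr_log_posterior <- function(state, counts_a, counts_x, tree,
                              condition = TRUE, atom_width = NULL) {
  tree <- as_esr_tree(tree, count_populations(counts_a))
  ma <- counts_to_matrices(counts_a, tree$labels)
  mx <- counts_to_matrices(counts_x, tree$labels)
  if (is.null(atom_width))
    atom_width <- pmax(c(1 / (20 * max(ma$n, 2)), 1 / (20 * max(mx$n, 2))), 1e-5)
  lp <- 0
  br <- setdiff(seq_len(tree$n_node), tree$root)
  for (v in br) {
    ta <- state$tau_a[v]; tx <- state$tau_x[v]
    if (!(ta > 9 * tx / 16 && ta < 9 * tx / 8)) return(-Inf)
    if (ta < 1e-4 || ta > 10 || tx < 1e-4 || tx > 10) return(-Inf)
  }
  sys <- list(list(m = ma, x = state$x_a, tau = state$tau_a,
                   mu = state$hyper[1], nu = state$hyper[2], aw = atom_width[1]),
              list(m = mx, x = state$x_x, tau = state$tau_x,
                   mu = state$hyper[3], nu = state$hyper[4], aw = atom_width[2]))
  for (s in sys) {
    for (i in seq_len(tree$n_leaf))
      lp <- lp + sum(dbinom(s$m$y[i, ], s$m$n[i, ], s$x[i, ], log = TRUE))
    for (v in br)
      lp <- lp + sum(vapply(seq_len(s$m$J), function(j)
        kimura_log_kernel(s$x[tree$parent[v], j], s$tau[v], s$x[v, j], s$aw),
        0))
    a <- s$mu * s$nu; b <- (1 - s$mu) * s$nu
    if (s$mu <= 0 || s$mu >= 1 || s$nu <= 0) return(-Inf)
    lp <- lp + sum(dbeta(s$x[tree$root, ], a, b, log = TRUE)) - s$nu
    if (condition) {
      nmax <- apply(s$m$n, 1, max)
      rd <- root_lineage_distribution(tree, s$tau, nmax)
      xr <- pmin(pmax(s$x[tree$root, ], s$aw), 1 - s$aw)
      lp <- lp - sum(log(pmax(prob_polymorphic(xr, rd), 1e-300)))
    }
  }
  lp
}
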