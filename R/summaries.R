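#' Effective sex ratio implied by a pair of branch lengths
#'
#' Because the same branch duration `t` is scaled by each system's effective
#' size, the ratio of autosomal to X-linked drift times pins down the female
#' proportion of the effective population:
#' `xi = 2 - (9/8) tau_X / tau_A`. A balanced ESR (`xi = 0.5`) corresponds to
#' `Q = tau_A / tau_X = 0.75`.
#'
#' @param tau_a,tau_x drift times (vectorised); every pair must lie inside
#'   the wedge `9 tau_X / 16 < tau_A < 9 tau_X / 8`.
#' @return `xi` values in (0, 1).
#' @examples
#' esr_from_tau(0.1, 0.1 / 0.75)  # 0.5
#' @export
esr_from_tau <- function(tau_a, tau_x) {
  xi <- 2 - (9 / 8) * tau_x / tau_a
  if (any(xi <= 0 | xi >= 1))
    abort("(tau_a, tau_x) outside the wedge implied by 0 < xi < 1",
          class = "esr_domain_error")
  xi
}

#' Support statistic for a biased effective sex ratio
#'
#' `S = 1 - 2 |p - 0.5|`, where `p` is the fraction of posterior draws of
#' `xi` above 0.5 (draws exactly equal to 0.5 count as not greater). Values
#' near 1 indicate no departure from a balanced ESR; `S = 0.05` means 97.5%
#' of the draws fall on one side of 0.5.
#'
#' @param xi_draws numeric vector of posterior draws of the ESR.
#' @return a list with `S` and `p`.
#' @export
esr_support <- function(xi_draws) {
  if (length(xi_draws) == 0)
    abort("empty draw vector", class = "esr_domain_error")
  p <- mean(xi_draws > 0.5)
  list(S = 1 - 2 * abs(p - 0.5), p = p)
}

xi_draw_matrix <- function(fit) {
  nbr <- nrow(fit$branches)
  ta <- as.matrix(fit$draws[paste0("tau_a_", seq_len(nbr))])
  tx <- as.matrix(fit$draws[paste0("tau_x_", seq_len(nbr))])
  2 - (9 / 8) * tx / ta
}

#' Per-branch posterior summaries
#'
#' One row per branch with posterior means and 95% credible intervals for the
#' drift times, the ESR `xi` (computed per draw from the branch lengths, not
#' from the ratio of posterior means), the ratio `Q = tau_A / tau_X` of
#' posterior means, the support statistic `S`, and the fraction `p` of draws
#' with `xi > 0.5`.
#'
#' @param x an `esr_fit`.
#' @param ... unused.
#' @export
tidy.esr_fit <- function(x, ...) {
  nbr <- nrow(x$branches)
  xi <- xi_draw_matrix(x)
  ta <- as.matrix(x$draws[paste0("tau_a_", seq_len(nbr))])
  tx <- as.matrix(x$draws[paste0("tau_x_", seq_len(nbr))])
  out <- lapply(seq_len(nbr), function(b) {
    sup <- esr_support(xi[, b])
    tibble(branch = b, label = x$branches$label[b],
           tau_a_mean = mean(ta[, b]), tau_a_median = stats::median(ta[, b]),
           tau_x_mean = mean(tx[, b]), tau_x_median = stats::median(tx[, b]),
           xi_mean = mean(xi[, b]), xi_median = stats::median(xi[, b]),
           xi_q2.5 = quantile(xi[, b], 0.025, names = FALSE),
           xi_q97.5 = quantile(xi[, b], 0.975, names = FALSE),
           Q = mean(ta[, b]) / mean(tx[, b]), S = sup$S, p = sup$p)
  })
  dplyr::bind_rows(out)
}

#' One-row model summary
#'
#' Posterior means of the root-beta hyper-parameters per system, the DIC and
#' its components, and the worst proposal acceptance rate.
#'
#' @param x an `esr_fit`.
#' @param ... unused.
#' @export
glance.esr_fit <- function(x, ...) {
  d <- compute_dic(x)
  tibble(n_draws = nrow(x$draws),
         mu_a = mean(x$draws$mu_a), nu_a = mean(x$draws$nu_a),
         mu_x = mean(x$draws$mu_x), nu_x = mean(x$draws$nu_x),
         d_bar = d$d_bar, d_at_mean = d$d_at_mean, dic = d$dic,
         p_d = d$p_d, elapsed = x$elapsed)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = 2 D_bar - D(theta_bar)`: `D_bar` is the mean over retained draws of
#' the deviance `-2 [sum of binomial leaf log-likelihoods - sum of per-site
#' log polymorphism probabilities]`, recorded during sampling; `D(theta_bar)`
#' re-evaluates the same expression at the posterior means of the latent
#' frequencies and branch lengths (running means kept by the sampler).
#'
#' @param fit an `esr_fit`.
#' @return a one-row tibble with `d_bar`, `d_at_mean`, `dic` and the
#'   effective-parameter proxy `p_d = d_bar - d_at_mean`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "esr_fit"))
  d_bar <- mean(fit$draws$deviance)
  nbr <- nrow(fit$branches)
  tree <- fit$tree
  d_at <- 0
  for (sy in c("a", "x")) {
    y <- fit$data[[paste0("y_", sy)]]
    n <- fit$data[[paste0("n_", sy)]]
    xbar <- fit[[paste0("xbar_", sy)]]
    ll <- 0
    for (i in seq_len(tree$n_leaf))
      ll <- ll + sum(dbinom(y[i, ], n[i, ], pmin(pmax(xbar[i, ], 1e-12), 1 - 1e-12),
                            log = TRUE))
    if (fit$config$condition) {
      tbar <- numeric(tree$n_node)
      tbar[seq_len(nbr)] <- colMeans(as.matrix(
        fit$draws[paste0("tau_", sy, "_", seq_len(nbr))]))
      rd <- root_lineage_distribution(tree, tbar, apply(n, 1, max))
      aw <- fit$atom_width[[if (sy == "a") 1 else 2]]
      pp <- prob_polymorphic(pmin(pmax(xbar[tree$root, ], aw), 1 - aw), rd)
      ll <- ll - sum(log(pmax(pp, 1e-300)))
    }
    d_at <- d_at - 2 * ll
  }
  tibble(d_bar = d_bar, d_at_mean = d_at, dic = 2 * d_bar - d_at,
         p_d = d_bar - d_at)
}

#' Rank candidate tree topologies by DIC
#'
#' Runs one full fit per candidate topology on the same data (seeds offset
#' deterministically from `config$seed`) and returns the DIC table in
#' ascending order; the best-supported topology comes first.
#'
#' @inheritParams fit_esr
#' @param trees a character vector of newick strings (optionally named).
#' @return a tibble with one row per topology, sorted by `dic`, plus the
#'   fitted objects in the `fit` list-column.
#' @export
compare_topologies <- function(counts_a, counts_x, trees,
                               config = esr_config()) {
  stopifnot(length(trees) >= 2)
  nms <- if (!is.null(names(trees))) names(trees) else unname(trees)
  rows <- lapply(seq_along(trees), function(i) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L)
    fit <- fit_esr(counts_a, counts_x, trees[[i]], cfg)
    d <- compute_dic(fit)
    tibble(topology = nms[i], newick = unname(trees[[i]]),
           dic = d$dic, d_bar = d$d_bar, d_at_mean = d$d_at_mean,
           fit = list(fit))
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$dic)
  out$rank <- seq_len(nrow(out))
  out
}

#' Plot per-branch posterior ESR
#'
#' Posterior means with 95% credible intervals for the ESR of every branch,
#' with the balanced value 0.5 marked.
#'
#' @param object an `esr_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.esr_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$label, y = .data$xi_mean)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$xi_q2.5,
                                          ymax = .data$xi_q97.5)) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "branch", y = expression(xi ~ "(effective sex ratio)")) +
    ggplot2::theme_minimal()
}

#' Write standard result files for a fit
#'
#' Emits `chain.tsv` (retained draws), `summary.tsv` (per-branch summaries)
#' and `dic.json` into a directory.
#'
#' @param fit an `esr_fit`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_esr_results <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("chain.tsv", "summary.tsv", "dic.json"))
  readr::write_tsv(fit$draws, paths[1], progress = FALSE)
  readr::write_tsv(tidy(fit), paths[2], progress = FALSE)
  jsonlite::write_json(as.list(compute_dic(fit)), paths[3],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
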