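#' MCMC run configuration
#'
#' Defaults follow the reference analysis protocol: 20 pilot runs of 500
#' iterations to tune every proposal block into the 0.25-0.40 acceptance band,
#' a burn-in of 10,000 iterations, 20,000 sampling iterations thinned every
#' 20. Scale these down for quick exploratory runs; posterior means of the ESR
#' are already stable with much shorter chains.
#'
#' @param n_pilot number of pilot runs.
#' @param pilot_length iterations per pilot run.
#' @param burnin burn-in iterations after the pilots.
#' @param chain_length post-burn-in iterations.
#' @param thin sampling interval; `chain_length` should be a multiple.
#' @param seed integer seed driving every stochastic stage.
#' @param target_acceptance acceptance band targeted by the pilot adaptation.
#' @param tau_bounds support of the (joint, uniform) branch-length prior.
#' @param adapt_factor multiplicative scale adjustment applied after each
#'   pilot when a block is outside the acceptance band.
#' @param condition if `TRUE` (default) the likelihood is conditioned on SNP
#'   polymorphism in the pooled sample; `FALSE` gives the unconditional
#'   ("full likelihood") variant, retained for model comparison.
#' @param verbose emit progress lines to stderr.
#' @return an `esr_config` list.
#' @export
esr_config <- function(n_pilot = 20, pilot_length = 500, burnin = 10000,
                       chain_length = 20000, thin = 20, seed = 1,
                       target_acceptance = c(0.25, 0.40),
                       tau_bounds = c(1e-4, 10), adapt_factor = 1.25,
                       condition = TRUE, verbose = FALSE) {
  stopifnot(n_pilot >= 0, pilot_length > 0, burnin >= 0, chain_length > 0,
            thin > 0, chain_length >= thin,
            length(target_acceptance) == 2,
            target_acceptance[1] > 0, target_acceptance[2] < 1,
            target_acceptance[1] < target_acceptance[2],
            length(tau_bounds) == 2, tau_bounds[1] > 0,
            tau_bounds[1] < tau_bounds[2], adapt_factor > 1)
  structure(list(n_pilot = as.integer(n_pilot),
                 pilot_length = as.integer(pilot_length),
                 burnin = as.integer(burnin),
                 chain_length = as.integer(chain_length),
                 thin = as.integer(thin), seed = as.integer(seed),
                 target_acceptance = target_acceptance,
                 tau_bounds = tau_bounds, adapt_factor = adapt_factor,
                 condition = isTRUE(condition), verbose = isTRUE(verbose)),
            class = "esr_config")
}
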