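test_that("chains are exactly reproducible from the seed", {
  cts <- flat_counts(30, c("P1", "P2"), y = 3, n = 10)
  cfg <- esr_config(n_pilot = 2, pilot_length = 50, burnin = 100,
                    chain_length = 200, thin = 10, seed = 33)
  f1 <- fit_esr(cts, cts, "(P1,P2);", cfg)
  f2 <- fit_esr(cts, cts, "(P1,P2);", cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("every retained draw satisfies the wedge and the tau bounds", {
  set.seed(2)
  sim <- simulate_forward("((P1,P2),P3);", tau_a = c(0.1, 0.1, 0.2, 0.1, NA),
                          J_a = 150, J_x = 150, n_genes = 40)
  fit <- fit_esr(sim$counts_a, sim$counts_x, "((P1,P2),P3);", quick_config(4))
  for (b in 1:4) {
    ta <- fit$draws[[paste0("tau_a_", b)]]
    tx <- fit$draws[[paste0("tau_x_", b)]]
    expect_true(all(ta > 9 * tx / 16 & ta < 9 * tx / 8))
    expect_true(all(ta >= 1e-4 & ta <= 10 & tx >= 1e-4 & tx <= 10))
  }
  # pilot adaptation moved the proposal scales and landed in a sane band
  expect_false(all(fit$scales$x_a == 0.2))
  expect_true(all(fit$acceptance$tau > 0.1 & fit$acceptance$tau < 0.6))
})

test_that("with the likelihood off, the chain reproduces its priors", {
  cts <- flat_counts(4, c("P1", "P2"), y = 1, n = 10)
  cfg <- esr_config(n_pilot = 20, pilot_length = 150, burnin = 3000,
                    chain_length = 120000, thin = 30, seed = 7,
                    condition = FALSE)
  fit <- fit_esr(cts, cts, "(P1,P2);", cfg, use_likelihood = FALSE)
  d <- fit$draws
  # the wedge prior is uniform, so xi | tau_A below the box cutoff is U(0,1)
  xi <- 2 - 9 * d$tau_x_1 / (8 * d$tau_a_1)
  sub <- xi[d$tau_a_1 < 5.5]
  th <- sub[seq(1, length(sub), by = 10)]
  expect_gt(suppressWarnings(stats::ks.test(th, "punif"))$p.value, 0.01)
  expect_equal(mean(sub), 0.5, tolerance = 0.04)
  # tau explores its full support
  expect_gt(max(d$tau_a_1), 5)
  expect_lt(min(d$tau_a_1), 0.5)
  # hyper-priors: mu ~ U(0,1), nu ~ Exp(1) (moment checks; the funnel mixes
  # slowly so exact-distribution tests need far longer chains)
  expect_equal(mean(d$mu_a), 0.5, tolerance = 0.08)
  expect_equal(mean(d$nu_a), 1, tolerance = 0.2)
  expect_equal(var(d$nu_a), 1, tolerance = 0.35)
})

test_that("root frequencies reproduce a fixed beta prior without data", {
  cts <- flat_counts(10, c("P1", "P2"), y = 1, n = 10)
  cfg <- esr_config(n_pilot = 10, pilot_length = 150, burnin = 2000,
                    chain_length = 40000, thin = 40, seed = 5,
                    condition = FALSE)
  fit <- fit_esr(cts, cts, "(P1,P2);", cfg, use_likelihood = FALSE,
                 update_hyper = FALSE, init_hyper = c(0.5, 2, 0.5, 2),
                 record_root = TRUE)
  xr <- as.vector(fit$root_draws_a)  # Beta(1,1)
  # strong subsampling: the KS test needs nearly independent draws
  th <- xr[seq(1, length(xr), by = 31)]
  expect_gt(suppressWarnings(stats::ks.test(th, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(xr) - 0.5), 0.05)
  expect_lt(abs(var(xr) - 1 / 12), 0.015)
})

test_that("log posterior equals an independent term-by-term evaluation", {
  tr <- parse_tree("(P1,P2);")
  set.seed(9)
  J <- 3
  counts <- tibble::tibble(snp_id = 1:J,
                           P1_y = c(2L, 5L, 0L), P1_n = c(10L, 10L, 10L),
                           P2_y = c(3L, 9L, 4L), P2_n = c(10L, 10L, 10L))
  state <- list(x_a = rbind(c(0.2, 0.5, 0.1), c(0.3, 0.8, 0.4), c(0.25, 0.6, 0.2)),
                x_x = rbind(c(0.3, 0.4, 0.2), c(0.2, 0.7, 0.3), c(0.3, 0.5, 0.25)),
                tau_a = c(0.1, 0.15, NA), tau_x = c(0.12, 0.19, NA),
                hyper = c(0.4, 1.5, 0.6, 2.5))
  got <- esr_log_posterior(state, counts, counts, tr)

  # brute force, from first principles (x values lie outside the boundary
  # strips, so the exact atom width does not enter)
  aw <- 1 / 200
  want <- 0
  for (s in list(list(x = state$x_a, tau = state$tau_a, mu = 0.4, nu = 1.5),
                 list(x = state$x_x, tau = state$tau_x, mu = 0.6, nu = 2.5))) {
    y <- rbind(counts$P1_y, counts$P2_y); n <- rbind(counts$P1_n, counts$P2_n)
    for (i in 1:2) for (j in 1:J) {
      want <- want + dbinom(y[i, j], n[i, j], s$x[i, j], log = TRUE) +
        kimura_log_kernel(s$x[3, j], s$tau[i], s$x[i, j], aw)
    }
    a <- s$mu * s$nu; b <- (1 - s$mu) * s$nu
    want <- want + sum(dbeta(s$x[3, ], a, b, log = TRUE)) - s$nu
    rd <- root_lineage_distribution(tr, s$tau, c(10, 10))
    want <- want - sum(log(prob_polymorphic(pmin(pmax(s$x[3, ], aw), 1 - aw), rd)))
  }
  expect_equal(got, want, tolerance = 1e-10)

  # single population dominated by its binomial term at small tau
  lp1 <- esr_log_posterior(state, counts, counts, tr)
  state2 <- state
  state2$x_a[1, 1] <- 0.21
  diff_lp <- esr_log_posterior(state2, counts, counts, tr) - lp1
  dbin <- dbinom(2, 10, 0.21, log = TRUE) - dbinom(2, 10, 0.2, log = TRUE)
  dker <- kimura_log_kernel(0.25, 0.1, 0.21, 1 / 200) -
    kimura_log_kernel(0.25, 0.1, 0.2, 1 / 200)
  expect_equal(diff_lp, dbin + dker, tolerance = 1e-10)

  # outside the wedge -> -Inf
  state3 <- state
  state3$tau_a[1] <- 2 * state3$tau_x[1]
  expect_equal(esr_log_posterior(state3, counts, counts, tr), -Inf)
})

test_that("root-frequency moves include the polymorphism-conditioning ratio", {
  tr <- parse_tree("(P1,P2);")
  counts <- tibble::tibble(snp_id = 1L, P1_y = 2L, P1_n = 10L,
                           P2_y = 3L, P2_n = 10L)
  state <- list(x_a = matrix(c(0.2, 0.3, 0.25), 3, 1),
                x_x = matrix(c(0.2, 0.3, 0.25), 3, 1),
                tau_a = c(0.1, 0.15, NA), tau_x = c(0.12, 0.19, NA),
                hyper = c(0.5, 2, 0.5, 2))
  prop <- state
  prop$x_a[3, 1] <- 0.6
  d_with <- esr_log_posterior(prop, counts, counts, tr) -
    esr_log_posterior(state, counts, counts, tr)
  d_wo <- esr_log_posterior(prop, counts, counts, tr, condition = FALSE) -
    esr_log_posterior(state, counts, counts, tr, condition = FALSE)
  rd <- root_lineage_distribution(tr, state$tau_a, c(10, 10))
  cond_ratio <- log(prob_polymorphic(0.25, rd)) - log(prob_polymorphic(0.6, rd))
  expect_equal(d_with - d_wo, cond_ratio, tolerance = 1e-10)
})

test_that("a leaf sampled at fixation concentrates near one", {
  J <- 40
  counts <- tibble::tibble(snp_id = seq_len(J),
                           P1_y = rep(20L, J), P1_n = rep(20L, J),
                           P2_y = rep(2L, J), P2_n = rep(20L, J))
  fit <- fit_esr(counts, counts, "(P1,P2);", quick_config(8))
  expect_gt(mean(fit$xbar_a[1, ]), 0.9)
  expect_lt(mean(fit$xbar_a[2, ]), 0.35)
})
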