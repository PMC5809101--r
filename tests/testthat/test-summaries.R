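test_that("the ESR transform and its special points", {
  expect_equal(esr_from_tau(0.1, 2 / 15), 0.5)
  expect_equal(esr_from_tau(0.075, 0.1), 0.5)        # Q = 0.75
  # wedge endpoints
  expect_equal(esr_from_tau(0.09, 0.16 - 1e-12), 0, tolerance = 1e-9)
  expect_equal(esr_from_tau(0.09, 0.08 + 1e-12), 1, tolerance = 1e-9)
  expect_error(esr_from_tau(0.1, 0.2), class = "esr_domain_error")
  expect_error(esr_from_tau(0.1, 0.05), class = "esr_domain_error")
  # strictly decreasing in tau_X / tau_A over the wedge
  r <- seq(8 / 9 + 1e-3, 16 / 9 - 1e-3, length.out = 50)
  xi <- esr_from_tau(1, r)
  expect_true(all(diff(xi) < 0))
  # round trip through Wright's effective sizes
  es <- effective_sizes(1000, 9000)
  expect_equal(esr_from_tau(1 / (2 * es$ne_a), 1 / (2 * es$ne_x)), 0.1,
               tolerance = 1e-12)
})

test_that("the support statistic follows S = 1 - 2|p - 0.5|", {
  d <- c(rep(0.6, 975), rep(0.4, 25))
  s <- esr_support(d)
  expect_equal(s$p, 0.975)
  expect_equal(s$S, 0.05)
  expect_equal(esr_support(rep(0.7, 10))$S, 0)
  expect_equal(esr_support(c(rep(0.4, 5), rep(0.6, 5)))$S, 1)
  # ties at 0.5 count as "not greater"
  expect_equal(esr_support(c(0.5, 0.5, 0.7, 0.3))$p, 0.25)
  # invariant to monotone transforms preserving the xi > 0.5 indicator
  f <- function(x) 0.5 + (x - 0.5)^3
  expect_equal(esr_support(f(d))$S, s$S)
  expect_error(esr_support(numeric(0)), class = "esr_domain_error")
})

fake_fit <- function(ta, tx, J = 1, y = matrix(2L, 1, 1), n = matrix(10L, 1, 1),
                     dev = NULL, xbar = NULL) {
  # minimal esr_fit for summary-level tests: 2 populations, one branch pair
  tree <- parse_tree("(P1,P2);")
  nd <- length(ta)
  draws <- tibble::tibble(tau_a_1 = ta, tau_a_2 = ta, tau_x_1 = tx, tau_x_2 = tx,
                          mu_a = 0.5, nu_a = 2, mu_x = 0.5, nu_x = 2,
                          deviance_a = if (is.null(dev)) 0 else dev,
                          deviance_x = 0,
                          deviance = if (is.null(dev)) 0 else dev,
                          .draw = seq_len(nd))
  structure(list(draws = draws,
                 branches = tibble::tibble(branch = 1:2, label = c("P1", "P2"),
                                           parent = c(3L, 3L)),
                 tree = tree,
                 config = esr_config(seed = 1, condition = FALSE),
                 xbar_a = xbar %||% matrix(0.5, 3, 1),
                 xbar_x = xbar %||% matrix(0.5, 3, 1),
                 data = list(y_a = rbind(P1 = y[1, , drop = TRUE],
                                         P2 = y[1, , drop = TRUE]),
                             n_a = rbind(P1 = n[1, , drop = TRUE],
                                         P2 = n[1, , drop = TRUE]),
                             y_x = rbind(P1 = y[1, , drop = TRUE],
                                         P2 = y[1, , drop = TRUE]),
                             n_x = rbind(P1 = n[1, , drop = TRUE],
                                         P2 = n[1, , drop = TRUE])),
                 atom_width = c(0.05, 0.05), elapsed = 0),
            class = "esr_fit")
}

test_that("tidy summarises per-draw xi, not the ratio of means", {
  f <- fake_fit(ta = rep(0.1, 100), tx = rep(2 / 15, 100))
  td <- tidy(f)
  expect_equal(td$xi_mean, rep(0.5, 2))
  expect_equal(td$Q, rep(0.75, 2))
  # every draw sits at the balanced point, so all of them fall on one side
  # of 0.5 (up to floating point) and the support statistic collapses to 0
  expect_equal(td$S, rep(0, 2))

  ta <- c(rep(0.1, 50), rep(0.09, 50))
  tx <- c(rep(2 / 15, 50), rep(0.1384615), rep(0.1384615, 49))
  f2 <- fake_fit(ta = ta, tx = tx)
  td2 <- tidy(f2)
  xi <- 2 - 9 * tx / (8 * ta)
  expect_equal(td2$xi_mean[1], mean(xi))
  expect_equal(td2$p[1], mean(xi > 0.5))
})

test_that("a degenerate chain gives DIC = mean deviance (zero penalty)", {
  # one SNP, counts y = 2 of n = 10 in both populations; fix the latent state
  xbar <- matrix(c(0.2, 0.2, 0.5), 3, 1)
  # hand-computed deviance at that state (binomial terms only; conditioning off)
  d0 <- -2 * 2 * dbinom(2, 10, 0.2, log = TRUE) * 2  # two systems, two pops
  f <- fake_fit(ta = rep(0.1, 10), tx = rep(2 / 15, 10), dev = d0, xbar = xbar)
  dic <- compute_dic(f)
  expect_equal(dic$d_bar, d0)
  expect_equal(dic$d_at_mean, d0, tolerance = 1e-10)
  expect_equal(dic$dic, d0, tolerance = 1e-10)
  expect_equal(dic$p_d, 0, tolerance = 1e-10)
})

test_that("DIC with conditioning matches a hand-built evaluation", {
  xbar <- matrix(c(0.2, 0.2, 0.5), 3, 1)
  tr <- parse_tree("(P1,P2);")
  rd_a <- root_lineage_distribution(tr, c(0.1, 0.1, 0), c(10, 10))
  rd_x <- root_lineage_distribution(tr, c(2 / 15, 2 / 15, 0), c(10, 10))
  ll <- 4 * dbinom(2, 10, 0.2, log = TRUE) -
    log(prob_polymorphic(0.5, rd_a)) - log(prob_polymorphic(0.5, rd_x))
  d0 <- -2 * ll
  f <- fake_fit(ta = rep(0.1, 10), tx = rep(2 / 15, 10), dev = d0, xbar = xbar)
  f$config <- esr_config(seed = 1, condition = TRUE)
  dic <- compute_dic(f)
  expect_equal(dic$d_at_mean, d0, tolerance = 1e-10)
  expect_equal(dic$dic, d0, tolerance = 1e-10)
})

test_that("autoplot returns a ggplot of per-branch ESR", {
  f <- fake_fit(ta = runif(50, 0.09, 0.11), tx = runif(50, 0.13, 0.14))
  p <- ggplot2::autoplot(f)
  expect_s3_class(p, "ggplot")
})
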