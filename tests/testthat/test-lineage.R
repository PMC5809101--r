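test_that("lineage thinning matches the exact and simulated coalescent", {
  expect_equal(lineage_distribution(7, 0), tibble::tibble(k = 7L, prob = 1))
  expect_equal(lineage_distribution(1, 3), tibble::tibble(k = 1L, prob = 1))

  # i = 2: single coalescence at rate 1
  d2 <- lineage_distribution(2, 0.3)
  expect_equal(d2$prob[d2$k == 1], 1 - exp(-0.3), tolerance = 1e-12)

  for (cc in list(c(10, 0.2), c(25, 0.1), c(60, 0.05), c(100, 0.15))) {
    i <- cc[1]; tau <- cc[2]
    approx <- lineage_distribution(i, tau)
    set.seed(42)
    mc <- death_chain_mc(i, tau, 20000)
    emp <- tibble::tibble(k = sort(unique(mc)),
                          prob = as.numeric(table(mc)) / length(mc))
    expect_lt(lineage_tv(approx, emp), 0.03 + 3 * sqrt(0.25 / 20000) * 5)
  }
})

test_that("Tavare's exact distribution behaves as advertised", {
  t2 <- tavare_lineage_distribution(2, 0.7)
  expect_equal(t2$prob[t2$k == 1], 1 - exp(-0.7), tolerance = 1e-12)
  t3 <- tavare_lineage_distribution(3, 0.5)
  expect_equal(sum(t3$prob), 1, tolerance = 1e-12)
  expect_true(all(t3$prob >= 0))

  # i = 15 vs Monte-Carlo
  set.seed(7)
  mc <- death_chain_mc(15, 0.1, 100000)
  t15 <- tavare_lineage_distribution(15, 0.1)
  for (k in unique(mc)) {
    p_hat <- mean(mc == k)
    se <- sqrt(p_hat * (1 - p_hat) / length(mc))
    expect_lt(abs(t15$prob[t15$k == k] - p_hat), 3 * se + 1e-9)
  }
  expect_error(tavare_lineage_distribution(40, 0.1), class = "esr_lineage_error")
})

test_that("approximate thinning stays close to Tavare for i up to 25", {
  for (cc in list(c(2, 0.3), c(10, 0.2), c(18, 0.15), c(25, 0.1))) {
    tv <- lineage_tv(lineage_distribution(cc[1], cc[2]),
                     tavare_lineage_distribution(cc[1], cc[2]))
    expect_lt(tv, 0.03)
  }
})

test_that("daughter distributions combine by discrete convolution", {
  pm <- function(k) tibble::tibble(k = as.integer(k), prob = 1)
  expect_equal(combine_lineage_distributions(list(pm(3), pm(4))),
               tibble::tibble(k = 7L, prob = 1))

  half <- tibble::tibble(k = 1:2, prob = c(0.5, 0.5))
  expect_equal(combine_lineage_distributions(list(half, half)),
               tibble::tibble(k = 2:4, prob = c(0.25, 0.5, 0.25)))

  set.seed(1)
  rnd <- function() {
    p <- runif(4)
    tibble::tibble(k = 1:4, prob = p / sum(p))
  }
  ds <- list(rnd(), rnd(), rnd())
  got <- combine_lineage_distributions(ds)
  want <- convolve_brute(convolve_brute(ds[[1]], ds[[2]]), ds[[3]])
  expect_lt(lineage_tv(got, want), 1e-9)
  expect_equal(min(got$k), 3)  # support starts at the number of daughters

  expect_error(combine_lineage_distributions(list(half)), class = "esr_lineage_error")
})

test_that("root recursion composes thinning and convolution over the tree", {
  tr <- parse_tree("((P1,P2),P3);")
  # no coalescence anywhere: all sampled lineages reach the root
  d0 <- root_lineage_distribution(tr, rep(0, 5), c(4, 3, 5))
  expect_equal(d0, tibble::tibble(k = 12L, prob = 1))

  # two-leaf tree: hand-composed from exact thins
  tr2 <- parse_tree("(P1,P2);")
  tau <- c(0.2, 0.2, 0)
  got <- root_lineage_distribution(tr2, tau, c(2, 2))
  want <- convolve_brute(tavare_lineage_distribution(2, 0.2),
                         tavare_lineage_distribution(2, 0.2))
  expect_lt(lineage_tv(got, want), 1e-9)

  # ((1,2),3): mean root lineage count vs direct Monte-Carlo of the recursion
  tau3 <- c(0.1, 0.1, 0.1, 0.1, 0)
  got3 <- root_lineage_distribution(tr, tau3, c(100, 100, 100))
  set.seed(11)
  reps <- 4000
  k1 <- death_chain_mc(100, 0.1, reps)
  k2 <- death_chain_mc(100, 0.1, reps)
  k12 <- vapply(k1 + k2, function(k) death_chain_mc(k, 0.1, 1), 0)
  k3 <- death_chain_mc(100, 0.1, reps)
  ktot <- k12 + k3
  se <- sd(ktot) / sqrt(reps)
  expect_lt(abs(sum(got3$k * got3$prob) - mean(ktot)), 3 * se + 0.5)
})

test_that("polymorphism probability follows the closed forms", {
  pm <- tibble::tibble(k = 10L, prob = 1)
  expect_equal(prob_polymorphic(0, pm), 0)
  expect_equal(prob_polymorphic(1, pm), 0)
  expect_equal(prob_polymorphic(0.5, pm), 1 - 2 * 0.5^10)
  expect_equal(prob_polymorphic(0.3, pm), 1 - 0.7^10 - 0.3^10)

  # tau -> 0 limit on a tree: 1 - (1-x)^(sum n) - x^(sum n)
  tr <- parse_tree("((P1,P2),P3);")
  d0 <- root_lineage_distribution(tr, rep(1e-9, 5), c(10, 10, 10))
  x <- c(0.1, 0.5, 0.9)
  expect_equal(prob_polymorphic(x, d0), 1 - (1 - x)^30 - x^30, tolerance = 1e-5)

  # symmetry and interior maximum
  d <- root_lineage_distribution(tr, c(0.2, 0.2, 0.3, 0.1, 0), c(20, 20, 20))
  xs <- seq(0.02, 0.98, by = 0.02)
  pp <- prob_polymorphic(xs, d)
  expect_equal(pp, rev(pp), tolerance = 1e-12)
  expect_equal(xs[which.max(pp)], 0.5)
  expect_true(all(diff(pp[xs <= 0.5]) > -1e-12))
})

test_that("longer branches make pseudo-fixation more likely", {
  tr <- parse_tree("((P1,P2),P3);")
  base <- c(0.1, 0.1, 0.1, 0.1, 0)
  p0 <- prob_polymorphic(0.3, root_lineage_distribution(tr, base, c(30, 30, 30)))
  for (b in 1:4) {
    up <- base
    up[b] <- 0.5
    p1 <- prob_polymorphic(0.3, root_lineage_distribution(tr, up, c(30, 30, 30)))
    expect_lt(p1, p0)
  }
})

test_that("polymorphism probability matches forward simulation of the sampling", {
  # one population, n genes: thin to k root lineages, type them iid Bernoulli(x)
  tr2 <- parse_tree("(P1,P2);")
  tau <- c(0.25, 0.15, 0)
  n <- c(15, 10)
  x_r <- 0.3
  d <- root_lineage_distribution(tr2, tau, n)
  p_model <- prob_polymorphic(x_r, d)
  set.seed(5)
  reps <- 100000
  k <- death_chain_mc(n[1], tau[1], reps) + death_chain_mc(n[2], tau[2], reps)
  n_ref <- rbinom(reps, k, x_r)
  poly <- mean(n_ref > 0 & n_ref < k)
  se <- sqrt(poly * (1 - poly) / reps)
  expect_lt(abs(p_model - poly), 3 * se + 0.005)
})
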