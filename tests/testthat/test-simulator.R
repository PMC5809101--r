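test_that("Wright's effective sizes and the implied ESR", {
  es <- effective_sizes(500, 500)
  expect_equal(es$ne_a, 1000)
  expect_equal(es$ne_x, 750)     # the classical three-quarters ratio
  expect_equal(es$xi, 0.5)

  es2 <- effective_sizes(1000, 9000)
  expect_equal(es2$ne_a, 3600)
  expect_equal(es2$ne_x, 81e6 / 38000, tolerance = 1e-12)
  expect_equal(esr_from_tau(1 / es2$ne_a, 1 / es2$ne_x), 0.1, tolerance = 1e-12)

  expect_equal(effective_sizes(250, 750)$xi, 0.25)

  # tau pairs implied by any census always land inside the wedge
  set.seed(3)
  nf <- sample(1:20000, 200, replace = TRUE)
  nm <- sample(1:20000, 200, replace = TRUE)
  es3 <- effective_sizes(nf, nm)
  r <- es3$ne_x / es3$ne_a
  expect_true(all(r > 9 / 16 & r < 9 / 8))
  expect_equal(esr_from_tau(1 / (2 * es3$ne_a), 1 / (2 * es3$ne_x)),
               es3$xi, tolerance = 1e-9)
})

test_that("demography truth uses harmonic-mean sizes across events", {
  dem <- sim_demography("(P1,P2);", split_times = 1000,
                        n_f = c(2500, 500, 5000), n_m = c(2500, 500, 5000),
                        samples_f = 10,
                        events = tibble::tibble(node = 1L, time = 400,
                                                n_f = 500, n_m = 500))
  # branch 1: 400 generations at Ne_A 5000, then 600 at Ne_A 1000
  ne_harm <- 1000 / (400 / 5000 + 600 / 1000)
  t1 <- dem$truth[dem$truth$branch == 1, ]
  expect_equal(t1$ne_a, ne_harm)
  expect_equal(t1$tau_a, 1000 / (2 * ne_harm))
  expect_equal(t1$xi, 0.5, tolerance = 1e-12)
  expect_error(sim_demography("(P1,P2);", split_times = 0,
                              n_f = rep(10, 3), n_m = rep(10, 3)),
               class = "esr_sim_error")
})

test_that("forward simulation reproduces the drift variance law", {
  set.seed(14)
  tr <- "(P1,P2);"
  tau <- c(0.2, 0.05, NA)
  sim <- simulate_forward(tr, tau_a = tau, J_a = 6000, J_x = 300,
                          n_genes = 200, root_beta = c(5, 5))
  m <- esrtree:::counts_to_matrices(sim$counts_a)
  x1 <- m$y["P1", ] / 200
  # law of total variance with Var(x_leaf | x_r) = x_r (1 - x_r)(1 - e^-tau):
  # Var(y/n) = Var(x_r) + E[x_r(1-x_r)] (1 - e^-tau) + E[x_leaf(1-x_leaf)]/n
  v_root <- 1 / 44                                  # Beta(5,5)
  exq <- 0.25 - v_root                              # E[x_r (1 - x_r)]
  v_th <- v_root + exq * (1 - exp(-0.2)) + exq * exp(-0.2) / 200
  expect_equal(var(x1), v_th, tolerance = 0.1)
  # all emitted sites are polymorphic in the pooled sample
  tot <- colSums(m$y)
  expect_true(all(tot > 0 & tot < sum(m$n[, 1])))
})

test_that("coalescent pairwise coalescence times match Wright's sizes", {
  dem <- sim_demography("(P1,P2);", split_times = 1,
                        n_f = c(5000, 5000, 2000), n_m = c(5000, 5000, 1000),
                        samples_f = c(1, 0), samples_m = c(0, 0), mu = 1e-8)
  set.seed(21)
  tm <- simulate_coalescent(dem, J_a = 6000, J_x = 6000, genealogy_only = TRUE)
  es <- effective_sizes(2000, 1000)
  for (sys in c("a", "x")) {
    tt <- tm[[paste0("times_", sys)]]$tmrca
    want <- 2 * (if (sys == "a") es$ne_a else es$ne_x)
    expect_lt(abs(mean(tt) - want), 3 * sd(tt) / sqrt(length(tt)) + 4)
  }
})

test_that("coalescent counts are polymorphic with the right sample sizes", {
  dem <- sim_demography("((P1,P2),P3);", split_times = c(200, 400),
                        n_f = c(500, 500, 500, 500, 50000),
                        n_m = c(500, 500, 500, 500, 50000),
                        samples_f = c(10, 10, 8), samples_m = c(0, 2, 0),
                        mu = 5e-7)
  set.seed(31)
  sim <- simulate_coalescent(dem, J_a = 120, J_x = 120)
  ma <- esrtree:::counts_to_matrices(sim$counts_a)
  mx <- esrtree:::counts_to_matrices(sim$counts_x)
  expect_equal(unname(ma$n[, 1]), c(20, 24, 16))   # 2(f+m) autosomal genes
  expect_equal(unname(mx$n[, 1]), c(20, 22, 16))   # 2f + m X genes
  expect_true(all(colSums(ma$y) > 0 & colSums(ma$y) < sum(ma$n[, 1])))
  expect_true(all(colSums(mx$y) > 0 & colSums(mx$y) < sum(mx$n[, 1])))
  expect_silent(validate_counts(sim$counts_a, parse_tree("((P1,P2),P3);")))
})

test_that("discovery-panel ascertainment filters and reduces counts", {
  set.seed(41)
  sim <- simulate_forward("((P1,P2),(P3,P4));",
                          tau_a = c(0.1, 0.1, 0.1, 0.1, 0.1, 0.1, NA),
                          J_a = 800, J_x = 800, n_genes = 100)
  # no ghosts: identity
  same <- apply_ascertainment(sim$counts_a, sim$counts_x,
                              ghosts = c(P1 = 0, P3 = 0))
  expect_identical(same$counts_a, sim$counts_a)

  asc <- apply_ascertainment(sim$counts_a, sim$counts_x,
                             ghosts = c(P1 = 2, P3 = 2))
  expect_lt(nrow(asc$counts_a), nrow(sim$counts_a))
  m <- esrtree:::counts_to_matrices(asc$counts_a)
  expect_equal(unname(m$n[, 1]), c(96, 100, 96, 100))
  expect_true(all(colSums(m$y) > 0 & colSums(m$y) < colSums(m$n)))

  # a site whose panel genes are all reference cannot survive
  cts <- tibble::tibble(snp_id = 1L, P1_y = 10L, P1_n = 10L,
                        P2_y = 0L, P2_n = 10L)
  asc2 <- apply_ascertainment(cts, cts, ghosts = c(P2 = 2))
  expect_equal(nrow(asc2$counts_a), 0)
})

test_that("pseudo-replicate subsampling is exact and reproducible", {
  cts_a <- flat_counts(100, c("P1", "P2"), y = 2, n = 8)
  cts_a$snp_id <- seq_len(100)
  reps <- subsample_replicates(cts_a, cts_a, n_snps = 30, n_replicates = 4,
                               seed = 99)
  expect_length(reps, 4)
  for (r in reps) {
    expect_equal(nrow(r$counts_a), 30)
    expect_equal(anyDuplicated(r$counts_a$snp_id), 0)
  }
  reps2 <- subsample_replicates(cts_a, cts_a, n_snps = 30, n_replicates = 4,
                                seed = 99)
  expect_identical(reps, reps2)
  expect_error(subsample_replicates(cts_a, cts_a, 500, 2),
               class = "esr_sim_error")
})
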