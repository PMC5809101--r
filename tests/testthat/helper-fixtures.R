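# Shared fixtures and reduced-scale MCMC settings for the test suite.
# Everything is generated in code; chain lengths are scaled well below the
# reference protocol (20 pilots x 500, burn-in 10k, 20k iterations) so the
# whole suite stays within a CI budget -- posterior means of tau and xi are
# already stable at this scale.

quick_config <- function(seed = 1, ...) {
  esr_config(n_pilot = 4, pilot_length = 150, burnin = 700, chain_length = 1500,
             thin = 10, seed = seed, ...)
}

recovery_config <- function(seed = 1, ...) {
  esr_config(n_pilot = 6, pilot_length = 200, burnin = 1200, chain_length = 2400,
             thin = 10, seed = seed, ...)
}

# count table with constant y/n in every population (valid & polymorphic)
flat_counts <- function(J, pops, y = 1L, n = 10L) {
  tb <- tibble::tibble(snp_id = seq_len(J))
  for (p in pops) {
    tb[[paste0(p, "_y")]] <- rep(as.integer(y), J)
    tb[[paste0(p, "_n")]] <- rep(as.integer(n), J)
  }
  tb
}

# total-variation distance between two lineage-count tibbles
lineage_tv <- function(a, b) {
  m <- merge(a, b, by = "k", all = TRUE)
  m[is.na(m)] <- 0
  0.5 * sum(abs(m$prob.x - m$prob.y))
}

# exact two-distribution convolution by brute-force enumeration
convolve_brute <- function(a, b) {
  out <- list()
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    k <- a$k[i] + b$k[j]
    key <- as.character(k)
    out[[key]] <- (out[[key]] %||% 0) + a$prob[i] * b$prob[j]
  }
  ks <- as.integer(names(out))
  o <- order(ks)
  tibble::tibble(k = ks[o], prob = unlist(out)[o])
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Monte-Carlo oracle: the coalescent death chain k -> k-1 at rate k(k-1)/2
death_chain_mc <- function(i, tau, reps) {
  k <- rep(i, reps)
  t <- numeric(reps)
  alive <- rep(TRUE, reps)
  while (any(alive)) {
    idx <- which(alive)
    t[idx] <- t[idx] + stats::rexp(length(idx), k[idx] * (k[idx] - 1) / 2)
    done <- t[idx] > tau
    k[idx[!done]] <- k[idx[!done]] - 1
    alive[idx] <- !done & k[idx] > 1
  }
  k
}

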