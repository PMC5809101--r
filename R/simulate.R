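#' Wright's effective sizes for each genetic system
#'
#' With `N_f` breeding females and `N_m` breeding males per generation, the
#' autosomal and X-linked effective sizes (in diploid individuals) are
#' `Ne_A = 4 N_f N_m / (N_f + N_m)` and `Ne_X = 9 N_f N_m / (2 N_f + 4 N_m)`.
#' Their ratio lies in (9/16, 9/8) and equals 3/4 when the sexes are
#' balanced.
#'
#' @param n_f,n_m female and male census sizes (vectorised, `>= 1`).
#' @return a tibble with `n_f`, `n_m`, `ne_a`, `ne_x` and the effective sex
#'   ratio `xi = n_f / (n_f + n_m)`.
#' @examples
#' effective_sizes(500, 500)   # ne_a = 1000, ne_x = 750
#' effective_sizes(250, 750)   # xi = 0.25
#' @export
effective_sizes <- function(n_f, n_m) {
  stopifnot(all(n_f >= 1), all(n_m >= 1))
  tibble(n_f = n_f, n_m = n_m,
         ne_a = 4 * n_f * n_m / (n_f + n_m),
         ne_x = 9 * n_f * n_m / (2 * n_f + 4 * n_m),
         xi = n_f / (n_f + n_m))
}

#' Describe a sex-specific demography on a population tree
#'
#' Collects everything the generation-by-generation coalescent simulator
#' needs: the topology, split times (in generations before present; one per
#' internal node, ordered by node id), per-node female/male census sizes,
#' optional instantaneous size-change events, per-population sample
#' composition, the per-locus mutation rate, and an optional sex-specific
#' migration connection between two leaves.
#'
#' Times look backward: an event row `(node, time, n_f, n_m)` means the
#' census of that branch is `(n_f, n_m)` from `time` generations before
#' present and older, while the base `n_f[node]`, `n_m[node]` apply on the
#' recent side. The root censuses apply indefinitely past the root split.
#'
#' @param tree newick string or [parse_tree()] object.
#' @param split_times numeric vector, one entry per internal node
#'   (ids `I+1 .. r` in order); must increase along every root-ward path.
#' @param n_f,n_m per-node female/male census sizes (length `n_node`,
#'   indexed by node id).
#' @param samples_f,samples_m sampled females/males per population (scalar or
#'   length `I`). A sampled female carries 2 genes in both systems; a male
#'   carries 2 autosomal genes but 1 X.
#' @param mu per-locus per-generation mutation rate.
#' @param events optional tibble with columns `node`, `time`, `n_f`, `n_m`.
#' @param migration optional `list(pair = c("P1","P2"), m_f =, m_m =)` with
#'   per-generation sex-specific migration rates between two leaves.
#' @return an `esr_demography` object; its `truth` element gives the
#'   per-branch expected drift times (`t / (2 Ne)`, harmonic-mean `Ne` along
#'   the branch) and the implied ESR.
#' @export
sim_demography <- function(tree, split_times, n_f, n_m, samples_f = 50,
                           samples_m = 0, mu = 1.5e-7, events = NULL,
                           migration = NULL) {
  tree <- as_esr_tree(tree)
  I <- tree$n_leaf
  stopifnot(length(split_times) == tree$n_node - I,
            length(n_f) == tree$n_node, length(n_m) == tree$n_node,
            all(n_f >= 1), all(n_m >= 1), mu >= 0)
  node_time <- c(rep(0, I), as.numeric(split_times))
  for (v in seq_len(tree$n_node - 1))
    if (node_time[tree$parent[v]] <= node_time[v])
      abort("split times must strictly increase toward the root",
            class = "esr_sim_error")
  samples_f <- rep_len(samples_f, I)
  samples_m <- rep_len(samples_m, I)
  if (!is.null(events)) {
    stopifnot(all(c("node", "time", "n_f", "n_m") %in% names(events)))
    events <- dplyr::arrange(as_tibble(events), .data$node, .data$time)
  }
  if (!is.null(migration)) {
    stopifnot(length(migration$pair) == 2, all(migration$pair %in% tree$labels),
              migration$m_f >= 0, migration$m_f <= 0.5,
              migration$m_m >= 0, migration$m_m <= 0.5)
  }
  dem <- structure(list(tree = tree, node_time = node_time,
                        n_f = as.numeric(n_f), n_m = as.numeric(n_m),
                        samples_f = as.integer(samples_f),
                        samples_m = as.integer(samples_m),
                        mu = mu, events = events, migration = migration),
                   class = "esr_demography")
  dem$truth <- demography_truth(dem)
  dem
}

# piecewise census regimes per node: list of (t, n_f, n_m) vectors
node_regimes <- function(dem) {
  tree <- dem$tree
  lapply(seq_len(tree$n_node), function(v) {
    t0 <- dem$node_time[v]
    tt <- t0; nf <- dem$n_f[v]; nm <- dem$n_m[v]
    if (!is.null(dem$events)) {
      ev <- dem$events[dem$events$node == v, ]
      if (nrow(ev) > 0) {
        tt <- c(tt, ev$time); nf <- c(nf, ev$n_f); nm <- c(nm, ev$n_m)
      }
    }
    list(t = tt, n_f = nf, n_m = nm)
  })
}

# expected branch lengths: t / (2 Ne), harmonic-mean Ne along the branch
demography_truth <- function(dem) {
  tree <- dem$tree
  reg <- node_regimes(dem)
  rows <- lapply(setdiff(seq_len(tree$n_node), tree$root), function(v) {
    t0 <- dem$node_time[v]
    t1 <- dem$node_time[tree$parent[v]]
    r <- reg[[v]]
    bounds <- c(r$t[r$t >= t0 & r$t < t1], t1)
    bounds <- sort(unique(c(t0, bounds)))
    dur <- diff(bounds)
    idx <- vapply(bounds[-length(bounds)],
                  function(tm) max(which(r$t <= tm)), 0L)
    es <- effective_sizes(r$n_f[idx], r$n_m[idx])
    harm <- function(ne) sum(dur) / sum(dur / ne)
    ne_a <- harm(es$ne_a); ne_x <- harm(es$ne_x)
    tau_a <- sum(dur) / (2 * ne_a)
    tau_x <- sum(dur) / (2 * ne_x)
    tibble(branch = v,
           label = if (v <= tree$n_leaf) tree$labels[v] else paste0("node", v),
           duration = sum(dur), ne_a = ne_a, ne_x = ne_x,
           tau_a = tau_a, tau_x = tau_x, xi = 2 - 9 * tau_x / (8 * tau_a))
  })
  dplyr::bind_rows(rows)
}

#' Simulate SNP counts under the generation-by-generation coalescent
#'
#' Traces the sampled gene lineages backward one generation at a time through
#' the demography: autosomal lineages pick a female or male parent with equal
#' probability, X-linked lineages in a female do likewise while X lineages in
#' a male always pick the mother; two lineages landing in the same parental
#' gene copy coalesce. Migration moves lineages between the connected leaves
#' at the parent-sex-specific rate. Every locus is forced to carry exactly
#' one mutation (Poisson number on the realised genealogy; other outcomes are
#' rejected and redrawn), placed uniformly on the tree, with the reference
#' allele assigned at random — so every emitted site is polymorphic in the
#' pooled sample.
#'
#' @param demography an [sim_demography()] object.
#' @param J_a,J_x number of autosomal / X-linked loci to emit.
#' @param max_attempts per-locus rejection cap.
#' @param genealogy_only if `TRUE`, skip the mutation step and return the
#'   per-locus time to the most recent common ancestor and total tree length
#'   (in generations) instead of counts — used to validate the simulator
#'   against coalescent expectations.
#' @return a list with `counts_a`, `counts_x` (count-table tibbles), `truth`
#'   (the demography's expected branch lengths and ESR) and the total
#'   rejection-sampling `attempts` per system; with `genealogy_only`, tibbles
#'   `times_a`, `times_x` (columns `tmrca`, `tree_length`) instead of counts.
#' @export
simulate_coalescent <- function(demography, J_a = 5000, J_x = 5000,
                                max_attempts = 10000, genealogy_only = FALSE) {
  stopifnot(inherits(demography, "esr_demography"))
  tree <- demography$tree
  reg <- node_regimes(demography)
  par0 <- ifelse(is.na(tree$parent), -1L, tree$parent - 1L)
  mig <- demography$migration
  mig_pair <- c(-1L, -1L)
  m_f <- 0; m_m <- 0
  if (!is.null(mig)) {
    mig_pair <- as.integer(match(mig$pair, tree$labels) - 1L)
    m_f <- mig$m_f; m_m <- mig$m_m
  }
  run <- function(xlinked, J) {
    r <- .coalsim_cpp(as.integer(par0), tree$n_leaf, demography$node_time,
                      lapply(reg, `[[`, "t"), lapply(reg, `[[`, "n_f"),
                      lapply(reg, `[[`, "n_m"), demography$samples_f,
                      demography$samples_m, xlinked, as.integer(J),
                      demography$mu, mig_pair, m_f, m_m,
                      as.integer(max_attempts), isTRUE(genealogy_only))
    if (isTRUE(genealogy_only))
      return(list(times = tibble(tmrca = r$tmrca, tree_length = r$tlen),
                  attempts = r$attempts))
    nmat <- matrix(rep(r$n, J), nrow = tree$n_leaf)
    rownames(r$y) <- rownames(nmat) <- tree$labels
    list(counts = matrices_to_counts(r$y, nmat), attempts = r$attempts)
  }
  A <- run(FALSE, J_a)
  X <- run(TRUE, J_x)
  if (isTRUE(genealogy_only))
    return(list(times_a = A$times, times_x = X$times, truth = demography$truth))
  list(counts_a = A$counts, counts_x = X$counts, truth = demography$truth,
       attempts = c(a = A$attempts, x = X$attempts))
}

#' Simulate SNP counts directly under the inference model
#'
#' Model-faithful forward generator: root frequencies are Beta draws,
#' frequencies propagate along each branch by binomial Wright-Fisher
#' resampling (`2 Ne` genes per generation for `round(2 Ne tau)` generations,
#' so the realised drift time matches `tau`), leaf counts are binomial, and
#' loci monomorphic in the pooled sample are rejected and redrawn — exactly
#' the data-generating process the conditional likelihood assumes.
#'
#' @param tree newick string or [parse_tree()] object.
#' @param tau_a autosomal branch lengths, indexed by node id (root entry
#'   ignored).
#' @param tau_x X-linked branch lengths; default mirrors a balanced ESR
#'   (`tau_x = tau_a / 0.75`).
#' @param J_a,J_x number of loci per system.
#' @param n_genes sampled genes per population (scalar or length `I`); used
#'   for both systems.
#' @param root_beta shape parameters of the root frequency distribution.
#' @param ne_a,ne_x diploid effective sizes used to discretise the drift
#'   (the kernel only depends on `tau`; these set the Wright-Fisher grid).
#' @return a list with `counts_a`, `counts_x` and `truth`.
#' @export
simulate_forward <- function(tree, tau_a, tau_x = NULL, J_a = 5000,
                             J_x = 5000, n_genes = 100, root_beta = c(1, 1),
                             ne_a = 1000, ne_x = 750) {
  tree <- as_esr_tree(tree)
  stopifnot(length(tau_a) >= tree$n_node - 1)
  if (is.null(tau_x)) tau_x <- tau_a / 0.75
  n_genes <- rep_len(n_genes, tree$n_leaf)
  sim_sys <- function(tau, ne, J) {
    tgen <- round(2 * ne * tau)
    y <- matrix(0L, tree$n_leaf, 0)
    got <- 0L
    for (batch in seq_len(200)) {
      if (got >= J) break
      Jb <- min(max(ceiling((J - got) * 1.6), 200), 200000)
      x <- matrix(0, tree$n_node, Jb)
      x[tree$root, ] <- rbeta(Jb, root_beta[1], root_beta[2])
      for (v in rev(setdiff(seq_len(tree$n_node), tree$root))) {
        xx <- x[tree$parent[v], ]
        tg <- tgen[v]
        if (tg > 0) for (g in seq_len(tg)) xx <- rbinom(Jb, 2 * ne, xx) / (2 * ne)
        x[v, ] <- xx
      }
      yb <- matrix(0L, tree$n_leaf, Jb)
      for (i in seq_len(tree$n_leaf))
        yb[i, ] <- rbinom(Jb, n_genes[i], x[i, ])
      tot <- colSums(yb)
      keep <- tot > 0 & tot < sum(n_genes)
      yb <- yb[, keep, drop = FALSE]
      take <- min(ncol(yb), J - got)
      if (take > 0) y <- cbind(y, yb[, seq_len(take), drop = FALSE])
      got <- got + take
    }
    if (got < J)
      abort("could not reach the requested number of polymorphic loci",
            class = "esr_sim_error")
    rownames(y) <- tree$labels
    nmat <- matrix(rep(n_genes, J), nrow = tree$n_leaf)
    rownames(nmat) <- tree$labels
    matrices_to_counts(y, nmat)
  }
  br <- setdiff(seq_len(tree$n_node), tree$root)
  truth <- tibble(branch = br,
                  label = branch_labels(tree),
                  tau_a = tau_a[br], tau_x = tau_x[br],
                  xi = 2 - 9 * tau_x[br] / (8 * tau_a[br]))
  list(counts_a = sim_sys(tau_a, ne_a, J_a),
       counts_x = sim_sys(tau_x, ne_x, J_x), truth = truth)
}

#' Emulate discovery-panel SNP ascertainment
#'
#' Splits each panel population's sample into "ghost" individuals (used only
#' for SNP calling) and retained individuals, keeps only sites polymorphic
#' among the pooled ghost genes, and returns counts over the retained
#' individuals. Ghosts are assumed to be sampled females (2 genes in each
#' system), drawn exchangeably, so the ghost allele counts are hypergeometric
#' subsamples of the population counts.
#'
#' @param counts_a,counts_x count-table tibbles.
#' @param ghosts named integer vector: ghost diploid individuals per panel
#'   population (names are the panel membership).
#' @return a list with filtered `counts_a` and `counts_x`.
#' @export
apply_ascertainment <- function(counts_a, counts_x, ghosts) {
  if (length(ghosts) == 0 || is.null(names(ghosts)))
    abort("`ghosts` must be a named vector (panel populations)",
          class = "esr_sim_error")
  if (all(ghosts == 0)) return(list(counts_a = counts_a, counts_x = counts_x))
  one <- function(counts) {
    pops <- count_populations(counts)
    if (!all(names(ghosts) %in% pops))
      abort("panel populations must be part of the sample",
            class = "esr_sim_error")
    m <- counts_to_matrices(counts, pops)
    J <- m$J
    gy <- matrix(0L, length(ghosts), J)
    gn <- 2L * as.integer(ghosts)
    for (g in seq_along(ghosts)) {
      p <- names(ghosts)[g]
      if (any(m$n[p, ] < gn[g]))
        abort("more ghost genes than sampled genes in a panel population",
              class = "esr_sim_error")
      gy[g, ] <- rhyper(J, m$y[p, ], m$n[p, ] - m$y[p, ], gn[g])
      m$y[p, ] <- m$y[p, ] - gy[g, ]
      m$n[p, ] <- m$n[p, ] - gn[g]
    }
    tot <- colSums(gy)
    keep <- tot > 0 & tot < sum(gn)
    # retained sites must also still be polymorphic among retained genes
    keep <- keep & colSums(m$y) > 0 & colSums(m$y) < colSums(m$n)
    matrices_to_counts(m$y[, keep, drop = FALSE], m$n[, keep, drop = FALSE],
                       snp_id = m$snp_id[keep])
  }
  list(counts_a = one(counts_a), counts_x = one(counts_x))
}

#' Pseudo-replicated SNP subsamples
#'
#' Draws `n_replicates` independent subsets of `n_snps` SNPs per system
#' (without replacement within a replicate), the subsampling strategy
#' recommended for large datasets.
#'
#' @param counts_a,counts_x count-table tibbles.
#' @param n_snps SNPs per system per replicate.
#' @param n_replicates number of replicates.
#' @param seed optional seed.
#' @return a list of `n_replicates` lists, each with `counts_a`, `counts_x`.
#' @export
subsample_replicates <- function(counts_a, counts_x, n_snps, n_replicates,
                                 seed = NULL) {
  if (n_snps > nrow(counts_a) || n_snps > nrow(counts_x))
    abort("`n_snps` exceeds the number of available SNPs",
          class = "esr_sim_error")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n_replicates), function(r)
    list(counts_a = counts_a[sort(sample.int(nrow(counts_a), n_snps)), ],
         counts_x = counts_x[sort(sample.int(nrow(counts_x), n_snps)), ]))
}
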