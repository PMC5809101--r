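#' Read / write SNP allele-count tables
#'
#' A count table holds, for one genetic system (autosomal or X-linked), the
#' reference-allele count `y` and the total number of sampled genes `n` for
#' every SNP (rows) and population. The tabular layout is one `snp_id` column
#' followed by a `<pop>_y`, `<pop>_n` column pair per population, and files are
#' tab-separated.
#'
#' @param path file path of a TSV count table.
#' @return `read_counts()` returns a tibble in count-table layout.
#' @export
read_counts <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_counts(tb)
  tb
}

#' @param counts a count table tibble.
#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

count_populations <- function(counts) {
  nm <- setdiff(names(counts), "snp_id")
  ys <- sub("_y$", "", nm[grepl("_y$", nm)])
  ns <- sub("_n$", "", nm[grepl("_n$", nm)])
  if (!setequal(ys, ns) || length(ys) == 0)
    abort("count table needs matched `<pop>_y` / `<pop>_n` column pairs",
          class = "esr_counts_error")
  ys
}

# I x J integer matrices (populations in `pops` order)
counts_to_matrices <- function(counts, pops = count_populations(counts)) {
  J <- nrow(counts)
  y <- t(as.matrix(counts[paste0(pops, "_y")]))
  n <- t(as.matrix(counts[paste0(pops, "_n")]))
  storage.mode(y) <- "integer"
  storage.mode(n) <- "integer"
  dimnames(y) <- dimnames(n) <- list(pops, NULL)
  list(y = y, n = n, J = J,
       snp_id = if ("snp_id" %in% names(counts)) counts$snp_id else seq_len(J))
}

matrices_to_counts <- function(y, n, snp_id = seq_len(ncol(y))) {
  pops <- rownames(y)
  out <- tibble(snp_id = snp_id)
  for (p in pops) {
    out[[paste0(p, "_y")]] <- as.integer(y[p, ])
    out[[paste0(p, "_n")]] <- as.integer(n[p, ])
  }
  out
}

#' Validate a count table against the model's invariants
#'
#' Checks that `0 <= y <= n` everywhere and that every SNP is polymorphic in
#' the pooled sample (`0 < sum_i y_ij < sum_i n_ij`), optionally that the
#' populations match a tree's leaves. `n = 0` cells are allowed and mean the
#' population was not typed at that site.
#'
#' @param counts a count-table tibble (see [read_counts()]).
#' @param tree optional [parse_tree()] object whose leaf labels must match.
#' @return invisibly, a validation report: a list with `J`, `populations`,
#'   `max_n` (per-population maximum sample size) and `n_monomorphic`.
#'   Invariant violations raise a labelled `esr_counts_error`.
#' @export
validate_counts <- function(counts, tree = NULL) {
  pops <- count_populations(counts)
  m <- counts_to_matrices(counts, pops)
  if (!is.null(tree)) {
    tree <- as_esr_tree(tree)
    if (!setequal(pops, tree$labels))
      abort(paste0("populations in counts (", paste(pops, collapse = ","),
                   ") do not match tree leaves (",
                   paste(tree$labels, collapse = ","), ")"),
            class = "esr_counts_error")
  }
  if (any(m$n < 0) || any(m$y < 0) || any(m$y > m$n)) {
    bad <- which(colSums(m$y > m$n | m$y < 0 | m$n < 0) > 0)[1]
    abort(paste0("invalid counts (need 0 <= y <= n) at SNP ", m$snp_id[bad]),
          class = "esr_counts_error")
  }
  tot_y <- colSums(m$y)
  tot_n <- colSums(m$n)
  mono <- which(tot_y == 0 | tot_y == tot_n)
  if (length(mono) > 0)
    abort(paste0(length(mono), " site(s) not polymorphic in the pooled sample, ",
                 "first offender: SNP ", m$snp_id[mono[1]]),
          class = "esr_counts_error")
  invisible(list(J = m$J, populations = pops,
                 max_n = apply(m$n, 1, max), n_monomorphic = 0L))
}
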