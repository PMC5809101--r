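#' Parse a population tree from newick text
#'
#' Builds the rooted (possibly multifurcating) population tree on which drift
#' times and effective sex ratios are estimated. Sampled populations are the
#' leaves, numbered `1..I`; internal nodes are numbered `I+1..r` in post-order
#' (every child has a smaller id than its parent, the root is `r`). Branch
#' lengths in the newick string, if any, are ignored: the topology is fixed a
#' priori and the branch lengths are parameters of the model.
#'
#' @param newick a newick string, e.g. `"((P1,P2),P3);"`. A star tree
#'   (`"(P1,P2,P3,P4);"`) is valid.
#' @param populations optional character vector fixing the leaf numbering
#'   (typically the column order of the count tables). Must be a permutation
#'   of the leaf labels. Defaults to newick appearance order.
#' @return an object of class `esr_tree`: a list with elements `labels`
#'   (leaf labels in id order), `n_leaf`, `n_node`, `root`, `parent`
#'   (`parent[i]` is `a(i)`, `NA` for the root) and `children`.
#' @examples
#' tr <- parse_tree("((P1,P2),P3);")
#' tr$parent  # node 4 is the parent of leaves 1 and 2, node 5 the root
#' @export
parse_tree <- function(newick, populations = NULL) {
  ph <- tryCatch(ape::read.tree(text = newick),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ph)) abort("could not parse newick string", class = "esr_tree_error")
  labs <- ph$tip.label
  if (anyDuplicated(labs))
    abort(paste0("duplicate leaf labels: ",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")),
          class = "esr_tree_error")
  if (length(labs) < 2)
    abort("a population tree needs at least two leaves", class = "esr_tree_error")
  if (!is.null(populations)) {
    if (!setequal(populations, labs) || length(populations) != length(labs))
      abort("`populations` must be a permutation of the leaf labels",
            class = "esr_tree_error")
  } else {
    populations <- labs
  }
  I <- length(labs)
  n_ape <- I + ph$Nnode
  kids_of <- split(ph$edge[, 2], factor(ph$edge[, 1], levels = seq_len(n_ape)))
  deg <- lengths(kids_of)
  if (any(deg[(I + 1):n_ape] < 2))
    abort("internal nodes must have at least two children (no single-child chains)",
          class = "esr_tree_error")
  ape_root <- setdiff(ph$edge[, 1], ph$edge[, 2])[1]

  new_id <- integer(n_ape)
  next_int <- I
  assign_post <- function(a) {
    kids <- kids_of[[a]]
    if (length(kids) == 0) {
      new_id[a] <<- match(ph$tip.label[a], populations)
      return(invisible(NULL))
    }
    for (k in kids) assign_post(k)
    next_int <<- next_int + 1L
    new_id[a] <<- next_int
  }
  assign_post(ape_root)

  parent <- rep(NA_integer_, n_ape)
  for (e in seq_len(nrow(ph$edge)))
    parent[new_id[ph$edge[e, 2]]] <- new_id[ph$edge[e, 1]]
  children <- lapply(seq_len(n_ape), function(v) which(parent == v))
  structure(list(labels = populations, n_leaf = I, n_node = n_ape,
                 root = n_ape, parent = parent, children = children),
            class = "esr_tree")
}

#' Serialize a population tree back to newick
#'
#' @param tree an [parse_tree()] object.
#' @return a newick string (topology only).
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "esr_tree"))
  rec <- function(v) {
    if (v <= tree$n_leaf) return(tree$labels[v])
    paste0("(", paste(vapply(tree$children[[v]], rec, ""), collapse = ","), ")")
  }
  paste0(rec(tree$root), ";")
}

#' @export
print.esr_tree <- function(x, ...) {
  cat("Population tree:", write_newick(x), "\n")
  cat(sprintf("  %d populations (ids 1..%d), %d internal nodes (ids %d..%d, root %d)\n",
              x$n_leaf, x$n_leaf, x$n_node - x$n_leaf, x$n_leaf + 1L, x$n_node,
              x$root))
  invisible(x)
}

as_esr_tree <- function(tree, populations = NULL) {
  if (inherits(tree, "esr_tree")) return(tree)
  if (is.character(tree) && length(tree) == 1) return(parse_tree(tree, populations))
  abort("`tree` must be an esr_tree or a newick string", class = "esr_tree_error")
}

# branch label used in outputs: leaf name, or node id for internal branches
branch_labels <- function(tree) {
  ids <- setdiff(seq_len(tree$n_node), tree$root)
  vapply(ids, function(v)
    if (v <= tree$n_leaf) tree$labels[v] else paste0("node", v), "")
}
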