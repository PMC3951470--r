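#' @useDynLib ppimkl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Tree pruning: MCT, SPT and the dynamic extension (DET)
# ---------------------------------------------------------------------------

# path of child indices from root to the leaf with label `lab` (first match);
# NULL when absent
leaf_path <- function(node, lab) {
  if (is_leaf(node)) {
    if (node$label == lab) return(integer(0))
    return(NULL)
  }
  for (k in seq_along(node$children)) {
    sub <- leaf_path(node$children[[k]], lab)
    if (!is.null(sub)) return(c(k, sub))
  }
  NULL
}

subtree_at <- function(node, path) {
  for (k in path) node <- node$children[[k]]
  node
}

protein_paths <- function(parse) {
  p1 <- leaf_path(parse, "PROTEIN_1")
  p2 <- leaf_path(parse, "PROTEIN_2")
  if (is.null(p1)) stop("pruning: leaf PROTEIN_1 not found (is the instance masked?)")
  if (is.null(p2)) stop("pruning: leaf PROTEIN_2 not found (is the instance masked?)")
  list(p1 = p1, p2 = p2)
}

pruned_tree <- function(tree, strategy, provenance = NA_character_,
                        node_count_mode = "nonleaf") {
  structure(list(tree = tree, strategy = strategy,
                 node_count = count_nodes(tree, node_count_mode),
                 node_count_mode = node_count_mode,
                 provenance = provenance),
            class = "pruned_tree")
}

#' @export
print.pruned_tree <- function(x, ...) {
  cat(sprintf("<%s, %d nodes (%s)> %s\n", x$strategy, x$node_count,
              x$node_count_mode, write_ptb(x$tree)))
  invisible(x)
}

#' Minimum Complete Tree of a masked parse
#'
#' The full subtree rooted at the lowest common ancestor of the `PROTEIN_1`
#' and `PROTEIN_2` leaves.
#'
#' @param parse a masked `parse_tree` (or a masked `ppi_instance`)
#' @param node_count_mode see [count_nodes()]
#' @return a `pruned_tree` with strategy `"MCT"`
#' @export
mct <- function(parse, node_count_mode = "nonleaf") {
  prov <- NA_character_
  if (inherits(parse, "ppi_instance")) { prov <- parse$id; parse <- parse$parse }
  pp <- protein_paths(parse)
  lca_len <- 0L
  while (lca_len < length(pp$p1) && lca_len < length(pp$p2) &&
         pp$p1[lca_len + 1L] == pp$p2[lca_len + 1L]) {
    lca_len <- lca_len + 1L
  }
  pruned_tree(subtree_at(parse, pp$p1[seq_len(lca_len)]), "MCT", prov,
              node_count_mode)
}

# keep, inside `node`, only subtrees whose leaf span intersects [lo, hi]
# (0-based inclusive leaf positions relative to `node`)
prune_outside_span <- function(node, lo, hi, off = 0L) {
  if (is_leaf(node)) return(node)
  kids <- list()
  cur <- off
  for (ch in node$children) {
    w <- length(tree_leaves(ch))
    if (cur <= hi && cur + w - 1L >= lo) {
      kids[[length(kids) + 1L]] <- prune_outside_span(ch, lo, hi, cur)
    }
    cur <- cur + w
  }
  tree_node(node$label, kids)
}

#' Shortest-Path-enclosed Tree
#'
#' The MCT with every subtree removed that lies wholly outside the leaf span
#' between the two protein placeholders (span-enclosed pruning: everything
#' between the two path spines, inclusive, is kept, so e.g. a coordinating
#' `(CC and)` between the proteins survives).
#'
#' @inheritParams mct
#' @return a `pruned_tree` with strategy `"SPT"`
#' @export
spt <- function(parse, node_count_mode = "nonleaf") {
  prov <- NA_character_
  if (inherits(parse, "ppi_instance")) { prov <- parse$id; parse <- parse$parse }
  m <- mct(parse, node_count_mode)$tree
  lv <- tree_leaves(m)
  i1 <- match("PROTEIN_1", lv) - 1L
  i2 <- match("PROTEIN_2", lv) - 1L
  span <- sort(c(i1, i2))
  pruned_tree(prune_outside_span(m, span[1], span[2]), "SPT", prov,
              node_count_mode)
}

#' Dynamic Extended Tree
#'
#' The dynamic extension of the SPT. By default the SPT itself is used; when
#' the SPT has fewer than `threshold` nodes it is judged too poor in context
#' and replaced:
#' \itemize{
#'   \item if the SPT differs from the MCT, by the MCT;
#'   \item otherwise by the subtree rooted at the parent of the SPT root in
#'     the full parse (when the SPT root is already the sentence root no
#'     parent exists and the SPT is kept, with a warning).
#' }
#' Node counting defaults to labeled syntactic nodes (internal +
#' preterminal, excluding token leaves); see [count_nodes()].
#'
#' @inheritParams mct
#' @param threshold node-count threshold below which the SPT is extended
#' @return a `pruned_tree` with strategy `"DET"`; the field `$det_choice`
#'   records which of `"SPT"`, `"MCT"`, `"PARENT"` was taken
#' @export
det <- function(parse, threshold = 7L, node_count_mode = "nonleaf") {
  prov <- NA_character_
  if (inherits(parse, "ppi_instance")) { prov <- parse$id; parse <- parse$parse }
  s <- spt(parse, node_count_mode)
  m <- mct(parse, node_count_mode)
  if (s$node_count >= threshold) {
    choice <- "SPT"; tree <- s$tree
  } else if (!trees_equal(s$tree, m$tree)) {
    choice <- "MCT"; tree <- m$tree
  } else {
    pp <- protein_paths(parse)
    lca_len <- 0L
    while (lca_len < length(pp$p1) && lca_len < length(pp$p2) &&
           pp$p1[lca_len + 1L] == pp$p2[lca_len + 1L]) {
      lca_len <- lca_len + 1L
    }
    if (lca_len == 0L) {
      warning("det: SPT root is the sentence root; no parent to extend to")
      choice <- "SPT"; tree <- s$tree
    } else {
      choice <- "PARENT"
      tree <- subtree_at(parse, pp$p1[seq_len(lca_len - 1L)])
    }
  }
  out <- pruned_tree(tree, "DET", prov, node_count_mode)
  out$det_choice <- choice
  out
}

# ---------------------------------------------------------------------------
# Convolution tree kernel (Collins-Duffy)
# ---------------------------------------------------------------------------

# flatten internal nodes to production-signature strings; leaf children are
# tagged so a token can never collide with a nonterminal of the same spelling
tree_productions <- function(node, acc = NULL) {
  collect <- function(nd) {
    if (is_leaf(nd)) return(NULL)
    tags <- vapply(nd$children, function(ch) {
      if (is_leaf(ch)) paste0("t:", ch$label) else paste0("n:", ch$label)
    }, character(1))
    sig <- paste0(nd$label, " -> ", paste(tags, collapse = " "))
    sub <- lapply(nd$children, collect)
    c(list(list(sig = sig, node = nd)), unlist(sub, recursive = FALSE))
  }
  collect(node)
}

# flatten a tree for the C++ kernel against a signature dictionary
flatten_tree <- function(node, dict) {
  prods <- character(0)
  kids <- list()
  walk <- function(nd) {
    if (is_leaf(nd)) return(-1L)
    tags <- vapply(nd$children, function(ch) {
      if (is_leaf(ch)) paste0("t:", ch$label) else paste0("n:", ch$label)
    }, character(1))
    sig <- paste0(nd$label, " -> ", paste(tags, collapse = " "))
    idx <- length(prods) + 1L
    prods[[idx]] <<- sig
    kids[[idx]] <<- integer(0)
    child_ids <- integer(0)
    for (ch in nd$children) {
      ci <- walk(ch)
      if (ci >= 0L) child_ids <- c(child_ids, ci)
    }
    kids[[idx]] <<- child_ids
    idx - 1L                     # 0-based for C++
  }
  walk(node)
  ids <- match(prods, dict)
  if (anyNA(ids)) stop("internal: production missing from dictionary")
  list(prod = as.integer(ids), children = kids)
}

#' Convolution tree kernel between two parse trees
#'
#' Counts common subtree fragments, each fragment down-weighted by
#' `lambda^size` where size is its number of productions: the classic
#' recursive formulation (0 when the root productions differ; `lambda` for a
#' matching preterminal production; otherwise
#' `lambda * prod_j (1 + C(child_j, child_j'))`).
#'
#' @param t1,t2 `parse_tree` objects (or `pruned_tree`s)
#' @param lambda decay factor in (0, 1]
#' @return the (unnormalized) kernel value, a nonnegative number
#' @export
ctk <- function(t1, t2, lambda = 0.4) {
  if (inherits(t1, "pruned_tree")) t1 <- t1$tree
  if (inherits(t2, "pruned_tree")) t2 <- t2$tree
  if (!is.numeric(lambda) || lambda <= 0 || lambda > 1) {
    stop("ctk: lambda must be in (0, 1]")
  }
  sigs <- unique(c(vapply(tree_productions(t1), `[[`, character(1), "sig"),
                   vapply(tree_productions(t2), `[[`, character(1), "sig")))
  .cpp_ctk_pair(flatten_tree(t1, sigs), flatten_tree(t2, sigs), lambda)
}

#' Normalized DET tree kernel between two instances
#'
#' Prunes each instance's parse to its Dynamic Extended Tree and returns the
#' cosine-normalized convolution kernel
#' `ctk(a, b) / sqrt(ctk(a, a) * ctk(b, b))`, so `k_det(x, x) = 1`. A
#' degenerate tree with zero self-kernel yields similarity 0 with a warning.
#'
#' @param x,y masked `ppi_instance`s
#' @param lambda decay factor in (0, 1]
#' @param threshold,node_count_mode passed to [det()]
#' @return similarity in [0, 1]
#' @export
k_det <- function(x, y, lambda = 0.4, threshold = 7L,
                  node_count_mode = "nonleaf") {
  tx <- det(x, threshold, node_count_mode)$tree
  ty <- det(y, threshold, node_count_mode)$tree
  kxx <- ctk(tx, tx, lambda)
  kyy <- ctk(ty, ty, lambda)
  if (kxx <= 0 || kyy <= 0) {
    warning("k_det: degenerate tree with zero self-kernel; similarity set to 0")
    return(0)
  }
  ctk(tx, ty, lambda) / sqrt(kxx * kyy)
}

#' DET tree-kernel Gram matrix over a corpus
#'
#' @param corpus list of masked `ppi_instance`s
#' @param lambda decay factor
#' @param threshold,node_count_mode passed to [det()]
#' @return a [gram_matrix()] with unit diagonal
#' @export
gram_det <- function(corpus, lambda = 0.4, threshold = 7L,
                     node_count_mode = "nonleaf") {
  trees <- lapply(corpus, function(inst) det(inst, threshold, node_count_mode)$tree)
  sigs <- unique(unlist(lapply(trees, function(t) {
    vapply(tree_productions(t), `[[`, character(1), "sig")
  })))
  flat <- lapply(trees, flatten_tree, dict = sigs)
  K <- .cpp_ctk_gram(flat, lambda, TRUE)
  gram_matrix(K, ids = vapply(corpus, `[[`, character(1), "id"),
              kernel = "det",
              params = list(lambda = lambda, threshold = threshold,
                            node_count_mode = node_count_mode))
}
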