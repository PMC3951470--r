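#' Parse trees in Penn-Treebank bracketed notation
#'
#' A parse tree is a rooted, ordered, labeled tree represented as a nested
#' list with fields `label` (character scalar) and `children` (possibly empty
#' list of subtrees). Leaves carry the (masked) sentence tokens; preterminals
#' are the part-of-speech nodes immediately above them.
#'
#' @param label node label (nonterminal, POS tag, or token for leaves)
#' @param children list of child trees (empty for leaves)
#' @return a `parse_tree` node
#' @export
tree_node <- function(label, children = list()) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  structure(list(label = label, children = children), class = "parse_tree")
}

is_leaf <- function(node) length(node$children) == 0L

#' Read a bracketed Penn-Treebank tree string
#'
#' Accepts the usual `(LABEL child child ...)` notation with
#' whitespace-delimited tokens, e.g.
#' `"(NP (NNP PROTEIN_1) (CC and) (NNP PROTEIN_2))"`.
#'
#' @param text a single bracketed-tree string
#' @return a `parse_tree`
#' @export
parse_ptb <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    stop("parse_ptb: empty input")
  }
  # tokenize: parens and whitespace-delimited symbols, tracking offsets
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0)
  offs <- integer(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("(", ")")) {
      toks <- c(toks, ch); offs <- c(offs, i); i <- i + 1L
    } else if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !(chars[j] %in% c("(", ")")) && !grepl("^\\s$", chars[j])) j <- j + 1L
      toks <- c(toks, paste(chars[i:(j - 1L)], collapse = ""))
      offs <- c(offs, i)
      i <- j
    }
  }
  pos <- 1L
  parse_node <- function() {
    if (pos > length(toks)) stop("parse_ptb: unexpected end of input")
    if (toks[pos] != "(") {
      stop(sprintf("parse_ptb: expected '(' at character offset %d", offs[pos]))
    }
    open_off <- offs[pos]
    pos <<- pos + 1L
    if (pos > length(toks) || toks[pos] %in% c("(", ")")) {
      stop(sprintf("parse_ptb: missing node label at character offset %d", open_off))
    }
    label <- toks[pos]; pos <<- pos + 1L
    children <- list()
    repeat {
      if (pos > length(toks)) {
        stop(sprintf("parse_ptb: unbalanced parentheses, '(' at character offset %d never closed",
                     open_off))
      }
      if (toks[pos] == ")") { pos <<- pos + 1L; break }
      if (toks[pos] == "(") {
        children[[length(children) + 1L]] <- parse_node()
      } else {
        children[[length(children) + 1L]] <- tree_node(toks[pos])
        pos <<- pos + 1L
      }
    }
    tree_node(label, children)
  }
  root <- parse_node()
  if (pos <= length(toks)) {
    stop(sprintf("parse_ptb: trailing content at character offset %d", offs[pos]))
  }
  root
}

#' Write a tree back to bracketed notation
#'
#' Inverse of [parse_ptb()]: `parse_ptb(write_ptb(t))` is structurally equal
#' to `t`, and writes are bit-exact (single spaces, no trailing whitespace).
#'
#' @param tree a `parse_tree`
#' @return a single bracketed string
#' @export
write_ptb <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  paste0("(", tree$label, " ",
         paste(vapply(tree$children, write_ptb, character(1)), collapse = " "),
         ")")
}

#' Count nodes of a tree
#'
#' The dynamic-extension rule for pruned trees thresholds on tree size; what
#' counts as a "node" is configurable:
#' \describe{
#'   \item{nonleaf}{labeled syntactic nodes only, i.e. internal nodes and
#'     preterminals, excluding token leaves (default for the DET rule --
#'     this reading reproduces the published worked examples)}
#'   \item{all}{every node including token leaves}
#'   \item{leaves}{token leaves only}
#' }
#'
#' @param tree a `parse_tree`
#' @param mode one of `"all"`, `"nonleaf"`, `"leaves"`
#' @return integer node count
#' @export
count_nodes <- function(tree, mode = c("all", "nonleaf", "leaves")) {
  mode <- match.arg(mode)
  self <- switch(mode,
    all = 1L,
    nonleaf = if (is_leaf(tree)) 0L else 1L,
    leaves = if (is_leaf(tree)) 1L else 0L)
  self + sum(vapply(tree$children, count_nodes, integer(1), mode = mode))
}

#' Leaf tokens of a tree, left to right
#' @param tree a `parse_tree`
#' @return character vector of leaf labels
#' @export
tree_leaves <- function(tree) {
  if (is_leaf(tree)) return(tree$label)
  unlist(lapply(tree$children, tree_leaves), use.names = FALSE)
}

# structural equality of two trees
trees_equal <- function(a, b) {
  if (a$label != b$label) return(FALSE)
  if (length(a$children) != length(b$children)) return(FALSE)
  for (k in seq_along(a$children)) {
    if (!trees_equal(a$children[[k]], b$children[[k]])) return(FALSE)
  }
  TRUE
}

#' @export
print.parse_tree <- function(x, ...) {
  cat(write_ptb(x), "\n")
  invisible(x)
}

# deep-copy-free functional tree edit helpers ---------------------------------

# apply f to every node bottom-up; f(node) -> node or NULL (drop)
tree_filter_map <- function(node, keep, transform = identity) {
  kids <- list()
  for (ch in node$children) {
    if (keep(ch)) {
      kids[[length(kids) + 1L]] <- tree_filter_map(ch, keep, transform)
    }
  }
  transform(tree_node(node$label, kids))
}
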