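# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (enumeration, closed forms) and share no code
# with the implementation paths they check.

# --- random tree generation --------------------------------------------------

# random labeled tree with a target total node count (all nodes incl leaves)
random_tree <- function(n_nodes, labels = c("S", "NP", "VP", "PP", "NN", "DT"),
                        tokens = c("a", "b", "c", "d")) {
  stopifnot(n_nodes >= 2)
  build <- function(budget) {
    # budget = total nodes for this subtree (>= 1)
    if (budget == 1) return(tree_node(sample(tokens, 1)))
    lab <- sample(labels, 1)
    remaining <- budget - 1
    kids <- list()
    while (remaining > 0) {
      take <- sample(seq_len(remaining), 1)
      kids[[length(kids) + 1]] <- build(take)
      remaining <- remaining - take
    }
    tree_node(lab, kids)
  }
  build(n_nodes)
}

# --- brute-force convolution-kernel oracle -----------------------------------

# all subtree fragments rooted at `node`: list of c(sig, size) where size is
# the number of productions (internal nodes) in the fragment. A fragment
# includes the node's full production; each child is either cut (kept as a
# bare label) or recursively expanded.
frags_at <- function(node) {
  if (length(node$children) == 0) return(list())
  child_opts <- lapply(node$children, function(ch) {
    tag <- if (length(ch$children) == 0) paste0("t:", ch$label) else paste0("n:", ch$label)
    opts <- list(list(sig = tag, size = 0))
    for (f in frags_at(ch)) {
      opts[[length(opts) + 1]] <- list(sig = paste0("[", f$sig, "]"), size = f$size)
    }
    opts
  })
  combos <- list(list(sig = character(0), size = 0))
  for (opts in child_opts) {
    combos <- unlist(lapply(combos, function(cm) {
      lapply(opts, function(o) list(sig = c(cm$sig, o$sig), size = cm$size + o$size))
    }), recursive = FALSE)
  }
  lapply(combos, function(cm) {
    list(sig = paste0(node$label, "(", paste(cm$sig, collapse = ","), ")"),
         size = 1 + cm$size)
  })
}

all_frags <- function(tree) {
  acc <- list()
  walk <- function(nd) {
    acc[[length(acc) + 1]] <<- frags_at(nd)
    for (ch in nd$children) walk(ch)
  }
  walk(tree)
  unlist(acc, recursive = FALSE)
}

ctk_oracle <- function(t1, t2, lambda) {
  f1 <- all_frags(t1); f2 <- all_frags(t2)
  if (!length(f1) || !length(f2)) return(0)
  s1 <- vapply(f1, `[[`, character(1), "sig")
  s2 <- vapply(f2, `[[`, character(1), "sig")
  z1 <- vapply(f1, `[[`, numeric(1), "size")
  common <- intersect(s1, s2)
  total <- 0
  for (sig in common) {
    size <- z1[match(sig, s1)]
    total <- total + sum(s1 == sig) * sum(s2 == sig) * lambda^size
  }
  total
}

# --- exhaustive assignment oracle --------------------------------------------

# maximum total weight over all injections of rows into columns (or the
# transpose when there are more rows than columns), by enumerating
# permutations
matching_oracle <- function(W) {
  if (nrow(W) > ncol(W)) W <- t(W)
  m <- nrow(W); n <- ncol(W)
  if (m == 0) return(0)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(n))) {
    best <- max(best, sum(W[cbind(seq_len(m), p[seq_len(m)])]))
  }
  best
}

# --- taxonomy oracles (independent edge-list computations) -------------------

# toy 7-concept binary taxonomy used in the semantic tests:
#          r
#        /   \
#       a     b
#      / \   / \
#     a1 a2 b1 b2
toy_edges <- data.frame(
  child  = c("a", "b", "a1", "a2", "b1", "b2"),
  parent = c("r", "r", "a", "a", "b", "b"))
toy_freq <- c(r = 0, a = 10, b = 5, a1 = 40, a2 = 10, b1 = 20, b2 = 15)

# ancestors by walking the raw edge list (root first omitted bookkeeping)
oracle_ancestors <- function(edges, x) {
  out <- x
  repeat {
    p <- edges$parent[edges$child == x]
    if (!length(p)) break
    out <- c(out, p); x <- p
  }
  out
}

oracle_depth <- function(edges, x) length(oracle_ancestors(edges, x))

oracle_lcs <- function(edges, c1, c2) {
  common <- intersect(oracle_ancestors(edges, c1), oracle_ancestors(edges, c2))
  common[which.max(vapply(common, oracle_depth, numeric(1), edges = edges))]
}

oracle_li <- function(edges, c1, c2, alpha = 0.2, beta = 0.6) {
  sub <- oracle_lcs(edges, c1, c2)
  l <- (oracle_depth(edges, c1) - oracle_depth(edges, sub)) +
       (oracle_depth(edges, c2) - oracle_depth(edges, sub))
  h <- oracle_depth(edges, sub)
  exp(-alpha * l) * (exp(beta * h) - exp(-beta * h)) / (exp(beta * h) + exp(-beta * h))
}

# cumulative-frequency IC computed by explicit descendant enumeration
oracle_ic <- function(edges, freq, x) {
  concepts <- unique(c(edges$child, edges$parent))
  desc <- concepts[vapply(concepts, function(c0) x %in% oracle_ancestors(edges, c0),
                          logical(1))]
  total <- sum(freq[concepts])
  -log(sum(freq[desc]) / total)
}

oracle_lin <- function(edges, freq, c1, c2) {
  denom <- oracle_ic(edges, freq, c1) + oracle_ic(edges, freq, c2)
  if (denom <= 0) return(if (c1 == c2) 1 else 0)
  common <- intersect(oracle_ancestors(edges, c1), oracle_ancestors(edges, c2))
  2 * max(vapply(common, oracle_ic, numeric(1), edges = edges, freq = freq)) / denom
}

# --- shared fixtures ---------------------------------------------------------

toy_tax <- function() taxonomy(toy_edges, toy_freq)

# minimal hand-built instance: "<pre...> P1 <between...> P2 <post...>"
mini_instance <- function(id = "t1", pre = character(0), between = "binds",
                          post = character(0), label = 1L,
                          concepts = c(NA, NA), others = NULL) {
  tokens <- c(pre, "GeneA", between, "GeneB", post)
  p1s <- length(pre); p2s <- length(pre) + 1L + length(between)
  pt <- function(w, tag = "NN") tree_node(tag, list(tree_node(w)))
  np1 <- tree_node("NP", c(lapply(pre, pt), list(pt("GeneA", "NNP"))))
  mid <- if (length(between)) list(tree_node("VP", lapply(between, pt))) else list()
  np2 <- tree_node("NP", c(list(pt("GeneB", "NNP")), lapply(post, pt)))
  parse <- tree_node("S", c(list(np1), mid, list(np2)))
  ent <- data.frame(start = c(p1s, p2s), end = c(p1s + 1L, p2s + 1L),
                    role = c("P1", "P2"), concept_id = concepts,
                    stringsAsFactors = FALSE)
  if (!is.null(others)) ent <- rbind(ent, others)
  instance(id, "doc1", tokens, ent, parse, label)
}
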