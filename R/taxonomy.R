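#' Concept taxonomies with corpus frequencies
#'
#' A taxonomy is a rooted concept hierarchy (a stand-in for resources like
#' MeSH or WordNet) given as a child-to-parent edge list, plus optional
#' corpus frequencies from which concept probabilities and information
#' content are derived:
#' \itemize{
#'   \item `depth(c)`: edges from the root plus 1 (the root has depth 1);
#'   \item `p(c)`: cumulative frequency of `c` and all its descendants
#'     divided by the total, so `p(root) = 1`;
#'   \item `IC(c) = -log p(c)`, so `IC(root) = 0`.
#' }
#'
#' @param edges data.frame with columns `child`, `parent`
#' @param frequencies named numeric vector of nonnegative concept counts
#'   (concepts absent from the vector count 0; if the whole vector is empty
#'   every concept counts 1)
#' @return a `taxonomy` object
#' @export
taxonomy <- function(edges, frequencies = numeric(0)) {
  stopifnot(is.data.frame(edges), all(c("child", "parent") %in% names(edges)))
  edges$child <- as.character(edges$child)
  edges$parent <- as.character(edges$parent)
  concepts <- sort(unique(c(edges$child, edges$parent)))
  if (anyDuplicated(edges$child)) {
    stop("taxonomy: concept with multiple parents: ",
         edges$child[duplicated(edges$child)][1])
  }
  parent <- stats::setNames(edges$parent[match(concepts, edges$child)], concepts)
  roots <- concepts[is.na(parent)]
  if (length(roots) != 1L) {
    stop("taxonomy: expected exactly one root, found ", length(roots), ": ",
         paste(utils::head(roots, 5), collapse = ", "))
  }
  # depth by walking to the root; also detects cycles
  depth <- stats::setNames(rep(NA_integer_, length(concepts)), concepts)
  for (c0 in concepts) {
    seen <- character(0); cur <- c0; d <- 1L
    while (!is.na(parent[[cur]])) {
      if (cur %in% seen) stop("taxonomy: cycle involving concept ", cur)
      seen <- c(seen, cur)
      cur <- parent[[cur]]; d <- d + 1L
      if (d > length(concepts) + 1L) stop("taxonomy: cycle detected")
    }
    depth[[c0]] <- d
  }
  if (length(frequencies)) {
    bad <- setdiff(names(frequencies), concepts)
    if (length(bad)) stop("taxonomy: frequency for unknown concept ", bad[1])
    if (any(frequencies < 0)) stop("taxonomy: negative frequency")
  }
  freq <- stats::setNames(rep(0, length(concepts)), concepts)
  if (length(frequencies)) freq[names(frequencies)] <- frequencies
  else freq[] <- 1
  # cumulative frequency: deepest first, push onto parents
  cum <- freq
  for (c0 in concepts[order(depth[concepts], decreasing = TRUE)]) {
    if (!is.na(parent[[c0]])) cum[[parent[[c0]]]] <- cum[[parent[[c0]]]] + cum[[c0]]
  }
  total <- cum[[roots]]
  if (total <= 0) stop("taxonomy: total frequency must be positive")
  p <- cum / total
  structure(list(concepts = concepts, parent = parent, root = roots,
                 depth = depth, freq = freq, p = p, ic = -log(p)),
            class = "taxonomy")
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy: %d concepts, root '%s', max depth %d>\n",
              length(x$concepts), x$root, max(x$depth)))
  invisible(x)
}

#' Read a taxonomy from TSV files
#'
#' The edge file has two tab-separated columns `child` `parent` (no header);
#' the optional frequency file has columns `concept` `count`.
#'
#' @param edge_path path to the edge list TSV
#' @param freq_path optional path to the frequency TSV
#' @return a `taxonomy`
#' @export
read_taxonomy <- function(edge_path, freq_path = NULL) {
  ed <- utils::read.table(edge_path, sep = "\t", header = FALSE,
                          col.names = c("child", "parent"),
                          colClasses = "character", quote = "")
  freqs <- numeric(0)
  if (!is.null(freq_path)) {
    fr <- utils::read.table(freq_path, sep = "\t", header = FALSE,
                            col.names = c("concept", "count"), quote = "",
                            colClasses = c("character", "numeric"))
    freqs <- stats::setNames(fr$count, fr$concept)
  }
  taxonomy(ed, freqs)
}

#' Write taxonomy TSV files
#' @param tax a `taxonomy`
#' @param edge_path,freq_path output paths (frequency file skipped if NULL)
#' @return `edge_path`, invisibly
#' @export
write_taxonomy <- function(tax, edge_path, freq_path = NULL) {
  ch <- names(tax$parent)[!is.na(tax$parent)]
  utils::write.table(data.frame(child = ch, parent = unname(tax$parent[ch])),
                     edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(freq_path)) {
    utils::write.table(data.frame(concept = names(tax$freq),
                                  count = unname(tax$freq)),
                       freq_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(edge_path)
}

tax_check <- function(tax, ...) {
  missing <- setdiff(c(...), tax$concepts)
  if (length(missing)) stop("unknown concept: ", missing[1], call. = FALSE)
}

ancestors_of <- function(tax, c0) {
  out <- c0
  while (!is.na(tax$parent[[c0]])) { c0 <- tax$parent[[c0]]; out <- c(out, c0) }
  out
}

#' Lowest common subsumer of two concepts
#' @param tax a `taxonomy`
#' @param c1,c2 concept ids
#' @return the deepest shared ancestor (a concept id)
#' @export
lcs <- function(tax, c1, c2) {
  tax_check(tax, c1, c2)
  common <- intersect(ancestors_of(tax, c1), ancestors_of(tax, c2))
  common[which.max(tax$depth[common])]
}

#' Path-and-depth (edge-counting) concept similarity
#'
#' `exp(-alpha * l) * tanh(beta * h)` where `l` is the shortest undirected
#' path length (in edges, through the lowest common subsumer) between the
#' concepts and `h` is the depth of that subsumer (root depth 1). Identical
#' deep concepts approach 1; concepts related only through the root approach
#' 0. Defaults `alpha = 0.2`, `beta = 0.6` are the published optima of the
#' measure's authors.
#'
#' @param c1,c2 concept ids
#' @param tax a `taxonomy`
#' @param alpha path-length scale (>= 0)
#' @param beta depth scale (> 0)
#' @return similarity in [0, 1]
#' @export
li_sim <- function(c1, c2, tax, alpha = 0.2, beta = 0.6) {
  tax_check(tax, c1, c2)
  sub <- lcs(tax, c1, c2)
  l <- (tax$depth[[c1]] - tax$depth[[sub]]) + (tax$depth[[c2]] - tax$depth[[sub]])
  h <- tax$depth[[sub]]
  exp(-alpha * l) * tanh(beta * h)
}

#' Information-content (Lin) concept similarity
#'
#' `2 * IC(lcs(c1, c2)) / (IC(c1) + IC(c2))`. Equals 1 for identical
#' concepts with positive IC and 0 when the only shared subsumer is the root
#' (IC 0). When `IC(c1) + IC(c2) = 0` the value is defined as 1 if
#' `c1 == c2` and 0 otherwise.
#'
#' @inheritParams li_sim
#' @return similarity in [0, 1]
#' @export
lin_sim <- function(c1, c2, tax) {
  tax_check(tax, c1, c2)
  denom <- tax$ic[[c1]] + tax$ic[[c2]]
  if (denom <= 0) return(if (c1 == c2) 1 else 0)
  # maximum-IC shared ancestor (equals the deepest one in a tree with
  # monotone p, but IC is the quantity the measure is defined on)
  common <- intersect(ancestors_of(tax, c1), ancestors_of(tax, c2))
  2 * max(tax$ic[common]) / denom
}

#' Hybrid concept similarity
#'
#' Combines the edge-counting and information-content measures. The default
#' combiner is their arithmetic mean; `product`, `li_only` and `lin_only`
#' are available.
#'
#' @inheritParams li_sim
#' @param params a [sim_params()] list
#' @return similarity in [0, 1]
#' @export
hybrid_sim <- function(c1, c2, tax, params = sim_params()) {
  li <- li_sim(c1, c2, tax, params$alpha, params$beta)
  lin <- lin_sim(c1, c2, tax)
  switch(params$combiner,
         mean = (li + lin) / 2,
         product = li * lin,
         li_only = li,
         lin_only = lin)
}

#' Semantic-similarity parameters
#'
#' @param alpha path-length scale of the edge-counting measure (>= 0)
#' @param beta depth scale of the edge-counting measure (> 0)
#' @param combiner how the edge-counting and information-content measures are
#'   combined: `"mean"` (default), `"product"`, `"li_only"`, `"lin_only"`
#' @return a validated parameter list
#' @export
sim_params <- function(alpha = 0.2, beta = 0.6,
                       combiner = c("mean", "product", "li_only", "lin_only")) {
  stopifnot(alpha >= 0, beta > 0)
  list(alpha = alpha, beta = beta, combiner = match.arg(combiner))
}
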