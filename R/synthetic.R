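#' Synthetic-corpus generator configuration
#'
#' The generator emulates the statistical regularities the kernels exploit,
#' each behind an explicit knob so any of them can be switched off:
#' \describe{
#'   \item{keyword_signal}{probability that a positive instance carries an
#'     interaction keyword near the pair AND follows the short-span length
#'     regime (the "shorter distance, more likely interaction" regularity);
#'     at 0 positives are lexically indistinguishable from negatives}
#'   \item{taxonomy_signal}{probability that a positive pair's concepts are
#'     taxonomic siblings (vs uniformly random leaves), and that its context
#'     words are drawn from the label-associated branch of the word taxonomy}
#'   \item{distance_noise}{probability that an instance's span-length regime
#'     is resampled from the opposite class, symmetrically corrupting the
#'     distance cue}
#' }
#' With all signals at 0 the two classes are identically distributed and
#' every kernel's cross-validated AUC is ~0.5.
#'
#' @param n_instances number of instances (>= 10)
#' @param positive_rate fraction of positives in (0, 1); the positive count
#'   is an exact quota, not a Bernoulli draw
#' @param keyword_signal,taxonomy_signal,distance_noise probabilities in [0, 1]
#' @param vocab_size filler vocabulary size when no word taxonomy is supplied
#' @param doc_size instances per synthetic document (doc ids are assigned in
#'   blocks to support document-level cross-validation)
#' @param seed integer seed; generation is fully deterministic per seed
#' @return a validated `gen_config` list
#' @export
gen_config <- function(n_instances = 400L, positive_rate = 0.3,
                       keyword_signal = 0.8, taxonomy_signal = 0.8,
                       distance_noise = 0.2, vocab_size = 300L, doc_size = 5L,
                       seed = 42L) {
  stopifnot(n_instances >= 10L, positive_rate > 0, positive_rate < 1,
            keyword_signal >= 0, keyword_signal <= 1,
            taxonomy_signal >= 0, taxonomy_signal <= 1,
            distance_noise >= 0, distance_noise <= 1,
            vocab_size >= 10L, doc_size >= 1L)
  list(n_instances = as.integer(n_instances), positive_rate = positive_rate,
       keyword_signal = keyword_signal, taxonomy_signal = taxonomy_signal,
       distance_noise = distance_noise, vocab_size = as.integer(vocab_size),
       doc_size = as.integer(doc_size), seed = as.integer(seed))
}

#' Generate a toy taxonomy
#'
#' A complete rooted tree of the given depth and branching factor (so
#' `(branching^depth - 1) / (branching - 1)` concepts), with corpus
#' frequencies drawn from a seeded power law. Stands in for resources like
#' MeSH or WordNet in tests and simulations.
#'
#' @param depth tree depth (>= 2; the root alone is depth 1)
#' @param branching children per internal node (>= 2)
#' @param seed integer seed
#' @param prefix concept-id prefix
#' @return a `taxonomy`
#' @export
gen_taxonomy <- function(depth = 4L, branching = 3L, seed = 1L, prefix = "c") {
  stopifnot(depth >= 2L, branching >= 2L)
  set.seed(seed)
  root <- paste0(prefix, "0")
  edges <- data.frame(child = character(0), parent = character(0))
  level <- root
  for (d in seq_len(depth - 1L)) {
    nxt <- character(0)
    for (p in level) {
      ch <- paste0(p, ".", seq_len(branching))
      edges <- rbind(edges, data.frame(child = ch, parent = p))
      nxt <- c(nxt, ch)
    }
    level <- nxt
  }
  concepts <- c(root, edges$child)
  # power-law leaf frequencies over a random permutation of ranks
  ranks <- sample(length(concepts))
  freqs <- stats::setNames(round(1000 * ranks^-1.1) + 1, concepts)
  taxonomy(edges, freqs)
}

tax_leaves <- function(tax) setdiff(tax$concepts, unique(stats::na.omit(tax$parent)))

# leaves grouped by parent, keeping only sibling groups of >= 2
sibling_groups <- function(tax) {
  lv <- tax_leaves(tax)
  g <- split(lv, tax$parent[lv])
  g[vapply(g, length, integer(1)) >= 2L]
}

#' Generate a synthetic tagged, parsed corpus
#'
#' Sentences come from two templates with flat constituency scaffolds (no
#' parser involved; the kernels consume tree structure, not linguistic
#' truth):
#' \itemize{
#'   \item between-template: `pre* P1 between+ P2 post*`, parsed as
#'     `(S (NP ... P1) (VP between...) (NP P2 ...))`;
#'   \item conjunction-template: `pre* P1 and P2 verb-phrase`, parsed as
#'     `(S (NP (NNP P1) (CC and) (NNP P2)) (VP ...))` -- the configuration
#'     in which the shortest-path-enclosed tree is poorest and the dynamic
#'     extension recovers the predicate.
#' }
#' Labels are assigned by exact quota. Positive instances carry the
#' signal-controlled regularities described in [gen_config()]. Surface
#' protein names are random, so the lexical kernel cannot read the label off
#' the names; the taxonomy signal lives only in the concept ids.
#'
#' @param cfg a [gen_config()]
#' @param tax protein-concept `taxonomy` (e.g. from [gen_taxonomy()])
#' @param word_tax optional word `taxonomy`; when supplied, filler/context
#'   words are its leaf concepts and the taxonomy signal biases positives and
#'   negatives toward different branches
#' @param keywords interaction keywords to plant (first is used for planting)
#' @return list of `ppi_instance` (unmasked)
#' @export
gen_corpus <- function(cfg, tax, word_tax = NULL,
                       keywords = default_keywords()) {
  set.seed(cfg$seed)
  n <- cfg$n_instances
  n_pos <- round(n * cfg$positive_rate)
  labels <- sample(c(rep(1L, n_pos), rep(0L, n - n_pos)))
  leaves <- tax_leaves(tax)
  sibs <- sibling_groups(tax)
  if (is.null(word_tax)) {
    vocabA <- vocabB <- sprintf("w%02d", seq_len(cfg$vocab_size))
  } else {
    wl <- tax_leaves(word_tax)
    kids <- names(word_tax$parent)[word_tax$parent %in% word_tax$root]
    kids <- kids[!is.na(kids)]
    half <- split(kids, rep_len(1:2, length(kids)))
    under <- function(tops) wl[vapply(wl, function(w)
      any(tops %in% ancestors_of(word_tax, w)), logical(1))]
    vocabA <- under(half[[1]]); vocabB <- under(half[[2]])
    if (!length(vocabA) || !length(vocabB)) vocabA <- vocabB <- wl
  }
  draw_fillers <- function(k, lab) {
    if (k <= 0L) return(character(0))
    biased <- stats::runif(1) < cfg$taxonomy_signal
    pool <- if (!biased) c(vocabA, vocabB) else if (lab == 1L) vocabA else vocabB
    # Zipf-weighted draws: realistic lexical sparsity, so feature overlap
    # between instances is thin and lexical features generalize imperfectly
    sample(pool, k, replace = TRUE, prob = 1 / seq_along(pool))
  }
  draw_concepts <- function(lab) {
    if (lab == 1L && length(sibs) && stats::runif(1) < cfg$taxonomy_signal) {
      g <- sibs[[sample(length(sibs), 1L)]]
      sample(g, 2L)
    } else {
      sample(leaves, 2L, replace = FALSE)
    }
  }
  prot_name <- function() sprintf("PR%03d", sample(999L, 1L))
  # distractor keywords appear near negative pairs but *outside* the pruned
  # tree (in the surrounding fillers), so the window-based lexical scan is
  # fooled while the tree kernel is not; rate scales with keyword_signal so
  # the null world (all signals 0) has no keywords anywhere
  distractor_rate <- 0.5 * cfg$keyword_signal
  out <- vector("list", n)
  for (i in seq_len(n)) {
    lab <- labels[i]
    cc <- draw_concepts(lab)
    p1 <- prot_name(); p2 <- prot_name()
    conj <- stats::runif(1) < 0.35
    plant_kw <- lab == 1L && stats::runif(1) < cfg$keyword_signal
    distract <- lab == 0L && stats::runif(1) < distractor_rate
    kw <- sample(keywords, 1L)
    short_regime <- lab == 1L && stats::runif(1) < cfg$keyword_signal
    if (stats::runif(1) < cfg$distance_noise) short_regime <- !short_regime
    npre <- sample(0:3, 1L)
    npost <- sample(0:3, 1L)
    if (distract && npre + npost == 0L) npost <- 1L
    pre <- draw_fillers(npre, lab)
    post <- draw_fillers(npost, lab)
    if (distract) {
      # plant in a surrounding filler (left of P1 or right of P2)
      if (length(pre) && (stats::runif(1) < 0.5 || !length(post))) {
        pre[sample(length(pre), 1L)] <- kw
      } else {
        post[sample(length(post), 1L)] <- kw
      }
    }
    ents <- NULL
    if (conj) {
      nvp <- sample(3:8, 1L)
      vp <- draw_fillers(nvp, lab)
      kw_pos <- NA_integer_
      if (plant_kw) { kw_pos <- sample(nvp, 1L); vp[kw_pos] <- kw }
      tokens <- c(pre, p1, "and", p2, vp, post)
      p1s <- npre; p2s <- npre + 2L
      # leading fillers sit in their own sibling NP so the conjoined pair's
      # subtree is exactly the minimum complete tree (the configuration the
      # dynamic extension is designed for)
      np <- tree_node("NP", list(tree_node("NNP", list(tree_node(p1))),
                                 tree_node("CC", list(tree_node("and"))),
                                 tree_node("NNP", list(tree_node(p2)))))
      vpn <- tree_node("VP", lapply(seq_along(vp), function(k)
        tree_node(if (!is.na(kw_pos) && k == kw_pos) "VBP" else "NN",
                  list(tree_node(vp[k])))))
      kids <- list(np, vpn)
      if (length(pre)) kids <- c(list(tree_node("NP", lapply(pre, function(w)
        tree_node("NN", list(tree_node(w)))))), kids)
      if (length(post)) kids <- c(kids, list(tree_node("NP", lapply(post, function(w)
        tree_node("NN", list(tree_node(w)))))))
      parse <- tree_node("S", kids)
      ents <- data.frame(start = c(p1s, p2s), end = c(p1s + 1L, p2s + 1L),
                         role = c("P1", "P2"), concept_id = cc,
                         stringsAsFactors = FALSE)
    } else {
      nbw <- if (short_regime) 1L + stats::rpois(1L, 1.2) else 4L + stats::rpois(1L, 3)
      nbw <- min(nbw, 12L)
      bw <- draw_fillers(nbw, lab)
      kw_pos <- NA_integer_
      if (plant_kw) { kw_pos <- sample(nbw, 1L); bw[kw_pos] <- kw }
      other <- nbw >= 3L && stats::runif(1) < 0.25
      oth_pos <- NA_integer_
      if (other) {
        free <- setdiff(2:(nbw - 1L), kw_pos)
        if (length(free)) {
          oth_pos <- free[sample(length(free), 1L)]
          bw[oth_pos] <- prot_name()
        }
      }
      tokens <- c(pre, p1, bw, p2, post)
      p1s <- npre; p2s <- npre + 1L + nbw
      np1 <- tree_node("NP", c(lapply(pre, function(w) tree_node("NN", list(tree_node(w)))),
                               list(tree_node("NNP", list(tree_node(p1))))))
      vpn <- tree_node("VP", lapply(seq_along(bw), function(k) {
        tag <- if (!is.na(oth_pos) && k == oth_pos) "NNP"
               else if (!is.na(kw_pos) && k == kw_pos) "VBP" else "NN"
        tree_node(tag, list(tree_node(bw[k])))
      }))
      np2 <- tree_node("NP", c(list(tree_node("NNP", list(tree_node(p2)))),
                               lapply(post, function(w) tree_node("NN", list(tree_node(w))))))
      parse <- tree_node("S", list(np1, vpn, np2))
      ents <- data.frame(start = c(p1s, p2s), end = c(p1s + 1L, p2s + 1L),
                         role = c("P1", "P2"), concept_id = cc,
                         stringsAsFactors = FALSE)
      if (!is.na(oth_pos)) {
        os <- npre + 1L + oth_pos - 1L
        ents <- rbind(ents, data.frame(start = os, end = os + 1L, role = "OTHER",
                                       concept_id = sample(leaves, 1L),
                                       stringsAsFactors = FALSE))
      }
    }
    out[[i]] <- instance(id = sprintf("i%04d", i),
                         doc_id = sprintf("d%03d", ceiling(i / cfg$doc_size)),
                         tokens = tokens, entities = ents, parse = parse,
                         label = lab)
  }
  out
}
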