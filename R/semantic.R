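#' Protein-pair similarity
#'
#' Similarity between two candidate protein pairs, the positionally aligned
#' mean of the hybrid concept similarities:
#' `(hybrid(c11, c21) + hybrid(c12, c22)) / 2` where pair A is `(c11, c12)`
#' and pair B is `(c21, c22)` (first proteins aligned with first, second with
#' second; the pairs are sentence-ordered so positions are meaningful). A
#' protein without a resolvable taxonomy concept contributes a
#' string-identity fallback: 1 if the two surface names are equal, else 0.
#'
#' @param pairA,pairB length-2 character vectors of concept ids (or surface
#'   names when unresolvable)
#' @param tax a `taxonomy`
#' @param params a [sim_params()] list
#' @return similarity in [0, 1]
#' @export
sim_pp <- function(pairA, pairB, tax, params = sim_params()) {
  stopifnot(length(pairA) == 2L, length(pairB) == 2L)
  slot <- function(a, b) {
    if (is.na(a) || is.na(b) || !(a %in% tax$concepts) || !(b %in% tax$concepts)) {
      return(as.numeric(!is.na(a) && !is.na(b) && a == b))
    }
    hybrid_sim(a, b, tax, params)
  }
  (slot(pairA[1], pairB[1]) + slot(pairA[2], pairB[2])) / 2
}

#' Word-to-word similarity over a word taxonomy
#'
#' Information-content (Lin) similarity between the concepts two words map to
#' in a word taxonomy (a WordNet stand-in whose concept ids are the words
#' themselves). Out-of-vocabulary handling: 1 if the words are equal, 0
#' otherwise.
#'
#' @param w1,w2 lowercase words
#' @param word_taxonomy a `taxonomy` over words
#' @return similarity in [0, 1]
#' @export
word_sim <- function(w1, w2, word_taxonomy) {
  if (w1 %in% word_taxonomy$concepts && w2 %in% word_taxonomy$concepts) {
    lin_sim(w1, w2, word_taxonomy)
  } else {
    as.numeric(w1 == w2)
  }
}

#' Maximum-weight bipartite matching (Kuhn-Munkres)
#'
#' One-to-one assignment of rows to columns maximizing the total weight, via
#' the Hungarian algorithm. Each row and column is used at most once;
#' zero-weight assignments are omitted from the returned matching (they do
#' not change the total).
#'
#' @param W an m-by-n matrix of finite nonnegative weights
#' @return list with `pairs` (2-column matrix of 1-based row/column indices)
#'   and `total` (the maximum total weight)
#' @export
munkres_max_matching <- function(W) {
  if (is.null(dim(W))) W <- matrix(W, nrow = 1)
  if (!all(is.finite(W)) || any(W < 0)) {
    stop("munkres_max_matching: weights must be finite and nonnegative")
  }
  res <- .cpp_munkres(W)
  list(pairs = cbind(row = res$rows, col = res$cols), total = res$total)
}

#' Default stopword list
#'
#' A small standard English stopword list (shipped in `extdata/stopwords.txt`)
#' used when building instance contexts.
#'
#' @return character vector of lowercase stopwords
#' @export
default_stopwords <- function() {
  read_keywords(system.file("extdata", "stopwords.txt", package = "ppimkl"))
}

#' Context of an instance
#'
#' The bag of sentence words excluding protein names (placeholders and
#' tagged mention tokens) and stopwords, lowercased.
#'
#' @param inst a masked `ppi_instance`
#' @param stopwords lowercase stopword vector
#' @return character vector (possibly empty)
#' @export
context_of <- function(inst, stopwords = default_stopwords()) {
  toks <- inst$tokens
  keep <- !is_protein_token(toks)
  toks <- tolower(toks[keep])
  toks[!toks %in% stopwords & grepl("[a-z0-9]", toks)]
}

#' Context semantic similarity
#'
#' The two contexts form the sides of a complete bipartite graph whose edge
#' weights are word-to-word similarities; the similarity is the total weight
#' of the Kuhn-Munkres maximum matching, normalized by the size of the larger
#' context: `total / max(|A|, |B|)`. 0 when either context is empty;
#' symmetric; in [0, 1] since each matched weight is at most 1 and at most
#' `min(|A|, |B|)` words are matched.
#'
#' @param ctxA,ctxB character vectors (bags of context words)
#' @param word_taxonomy a `taxonomy` over words
#' @return similarity in [0, 1]
#' @export
sim_con <- function(ctxA, ctxB, word_taxonomy) {
  if (!length(ctxA) || !length(ctxB)) return(0)
  W <- outer(ctxA, ctxB, Vectorize(function(a, b) word_sim(a, b, word_taxonomy)))
  munkres_max_matching(W)$total / max(length(ctxA), length(ctxB))
}

#' Semantic kernel between two instances
#'
#' Weighted combination of protein-pair similarity and context semantic
#' similarity: `mix * sim_pp + (1 - mix) * sim_con`, default `mix = 0.5`
#' (equal contribution). `mix = 1` reduces to the protein-pair part,
#' `mix = 0` to the context part.
#'
#' @param x,y masked `ppi_instance`s carrying concept ids on P1/P2
#' @param tax concept `taxonomy` for the protein pairs
#' @param word_taxonomy word `taxonomy` for the contexts
#' @param params a [sim_params()] list
#' @param mix weight of the protein-pair part, in [0, 1]
#' @param stopwords stopword vector for context construction
#' @return similarity in [0, 1]
#' @export
k_sim <- function(x, y, tax, word_taxonomy, params = sim_params(), mix = 0.5,
                  stopwords = default_stopwords()) {
  stopifnot(mix >= 0, mix <= 1)
  spp <- sim_pp(pair_concepts(x), pair_concepts(y), tax, params)
  scon <- sim_con(context_of(x, stopwords), context_of(y, stopwords),
                  word_taxonomy)
  mix * spp + (1 - mix) * scon
}

pair_concepts <- function(inst) {
  ent <- inst$entities
  c(ent$concept_id[ent$role == "P1"], ent$concept_id[ent$role == "P2"])
}

#' Semantic-kernel Gram matrix over a corpus
#'
#' Vectorized version of [k_sim()]: hybrid concept similarities are
#' precomputed per unique concept pair, word similarities per vocabulary
#' pair, and the bipartite matchings run in compiled code.
#'
#' @param corpus list of masked `ppi_instance`s
#' @inheritParams k_sim
#' @return a [gram_matrix()] (symmetric, bounded; not necessarily positive
#'   semidefinite -- repair with [make_psd()] before SVM training)
#' @export
gram_sim <- function(corpus, tax, word_taxonomy, params = sim_params(),
                     mix = 0.5, stopwords = default_stopwords()) {
  n <- length(corpus)
  pairs <- lapply(corpus, pair_concepts)
  # protein-pair part: hybrid similarity per unique concept (or fallback) pair
  slots <- rbind(vapply(pairs, `[`, character(1), 1),
                 vapply(pairs, `[`, character(1), 2))
  uniq <- unique(stats::na.omit(as.character(slots)))
  in_tax <- uniq[uniq %in% tax$concepts]
  H <- matrix(0, length(uniq), length(uniq), dimnames = list(uniq, uniq))
  for (a in uniq) for (b in uniq) {
    H[a, b] <- if (a %in% in_tax && b %in% in_tax) {
      hybrid_sim(a, b, tax, params)
    } else as.numeric(a == b)
  }
  Spp <- matrix(0, n, n)
  s1 <- slots[1, ]; s2 <- slots[2, ]
  i1 <- match(s1, uniq); i2 <- match(s2, uniq)
  for (a in seq_len(n)) for (b in a:n) {
    v1 <- if (is.na(i1[a]) || is.na(i1[b])) 0 else H[i1[a], i1[b]]
    v2 <- if (is.na(i2[a]) || is.na(i2[b])) 0 else H[i2[a], i2[b]]
    Spp[a, b] <- Spp[b, a] <- (v1 + v2) / 2
  }
  # context part: shared vocabulary similarity matrix + compiled matchings
  ctxs <- lapply(corpus, context_of, stopwords = stopwords)
  vocab <- unique(unlist(ctxs))
  if (length(vocab)) {
    S <- matrix(0, length(vocab), length(vocab))
    inwt <- vocab %in% word_taxonomy$concepts
    for (a in seq_along(vocab)) for (b in a:length(vocab)) {
      v <- if (inwt[a] && inwt[b]) lin_sim(vocab[a], vocab[b], word_taxonomy)
           else as.numeric(vocab[a] == vocab[b])
      S[a, b] <- S[b, a] <- v
    }
    idx <- lapply(ctxs, function(ct) match(ct, vocab))
    Scon <- .cpp_context_gram(idx, S)
  } else {
    Scon <- matrix(0, n, n)
  }
  K <- mix * Spp + (1 - mix) * Scon
  gram_matrix(K, ids = vapply(corpus, `[[`, character(1), "id"),
              kernel = "sim",
              params = list(alpha = params$alpha, beta = params$beta,
                            combiner = params$combiner, mix = mix))
}
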