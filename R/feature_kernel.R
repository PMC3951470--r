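#' Default interaction keyword list
#'
#' Interaction verbs signalling a protein-protein interaction, used for the
#' interaction-term feature: the canonical triple *regulate*, *interact*,
#' *modulate* plus morphological variants. Override by supplying your own
#' lowercase vector or a keyword file (one keyword per line) to the CLI.
#'
#' @return character vector of lowercase keywords
#' @export
default_keywords <- function() {
  c("interact", "interacts", "interacted", "interacting", "interaction",
    "regulate", "regulates", "regulated", "regulating", "regulation",
    "modulate", "modulates", "modulated", "modulating", "modulation")
}

#' Read a keyword file (one lowercase keyword per line)
#' @param path file path
#' @return character vector
#' @export
read_keywords <- function(path) {
  kw <- tolower(trimws(readLines(path, warn = FALSE)))
  kw <- kw[nzchar(kw)]
  if (!length(kw)) stop("read_keywords: empty keyword list in ", path)
  kw
}

is_protein_token <- function(tok) tok %in% c("PROTEIN_1", "PROTEIN_2", "PROTEIN")

fold_case <- function(tok) ifelse(is_protein_token(tok), tok, tolower(tok))

p_spans <- function(inst) {
  ent <- inst$entities
  list(p1 = c(ent$start[ent$role == "P1"], ent$end[ent$role == "P1"]),
       p2 = c(ent$start[ent$role == "P2"], ent$end[ent$role == "P2"]))
}

#' Lexical word features of a masked instance
#'
#' Three groups of word features:
#' \describe{
#'   \item{words_in_proteins}{all words of the two protein names (original
#'     surface forms where known, placeholders otherwise)}
#'   \item{words_between}{all words strictly between the two protein names,
#'     or `"NULL"` if none}
#'   \item{words_surrounding}{up to `window` words left of the first protein
#'     plus up to `window` words right of the second, or `"NULL"` if none}
#' }
#'
#' @param inst a masked `ppi_instance`
#' @param window surrounding-context width per side (default 5)
#' @return named list of the three character vectors
#' @export
words_features <- function(inst, window = 5L) {
  stopifnot(isTRUE(inst$masked))
  sp <- p_spans(inst)
  toks <- inst$tokens
  n <- length(toks)
  in_prot <- if (!is.null(inst$protein_words) && length(inst$protein_words)) {
    tolower(inst$protein_words)
  } else {
    fold_case(c(toks[(sp$p1[1] + 1L):sp$p1[2]], toks[(sp$p2[1] + 1L):sp$p2[2]]))
  }
  between <- if (sp$p1[2] < sp$p2[1]) fold_case(toks[(sp$p1[2] + 1L):sp$p2[1]]) else character(0)
  if (!length(between)) between <- "NULL"
  left <- if (sp$p1[1] > 0L) {
    fold_case(toks[max(1L, sp$p1[1] - window + 1L):sp$p1[1]])
  } else character(0)
  right <- if (sp$p2[2] < n) {
    fold_case(toks[(sp$p2[2] + 1L):min(n, sp$p2[2] + window)])
  } else character(0)
  surrounding <- c(left, right)
  if (!length(surrounding)) surrounding <- "NULL"
  list(words_in_proteins = in_prot, words_between = between,
       words_surrounding = surrounding)
}

#' Interaction-term feature
#'
#' Scans the words between the protein pair first, then the surrounding
#' window (left of P1, then right of P2, each in sentence order), and emits
#' the first keyword found (case-insensitive). `"NULL"` when no keyword
#' appears.
#'
#' @param inst a masked `ppi_instance`
#' @param keywords lowercase keyword vector, default [default_keywords()]
#' @param window surrounding width per side
#' @return a single string
#' @export
interaction_term <- function(inst, keywords = default_keywords(), window = 5L) {
  stopifnot(isTRUE(inst$masked), length(keywords) > 0)
  sp <- p_spans(inst)
  toks <- inst$tokens
  n <- length(toks)
  between <- if (sp$p1[2] < sp$p2[1]) toks[(sp$p1[2] + 1L):sp$p2[1]] else character(0)
  left <- if (sp$p1[1] > 0L) toks[max(1L, sp$p1[1] - window + 1L):sp$p1[1]] else character(0)
  right <- if (sp$p2[2] < n) toks[(sp$p2[2] + 1L):min(n, sp$p2[2] + window)] else character(0)
  for (region in list(between, c(left, right))) {
    hit <- tolower(region)[tolower(region) %in% keywords]
    if (length(hit)) return(hit[1])
  }
  "NULL"
}

#' Distance features
#'
#' `word_num_bin` bins Word-Num, the number of non-protein words strictly
#' between the pair: `<=3 -> "1"`, `(3,6] -> "2"`, `(6,9] -> "3"`,
#' `>9 -> "4"`. `protein_count` is the number of other tagged protein
#' mentions strictly between the pair (0 if none).
#'
#' @param inst a `ppi_instance` (masked or not)
#' @return list with `word_num`, `word_num_bin`, `protein_count`
#' @export
distance_features <- function(inst) {
  sp <- p_spans(inst)
  ent <- inst$entities
  lo <- sp$p1[2]; hi <- sp$p2[1]          # between region is [lo, hi) 0-based
  others <- ent[ent$role == "OTHER", , drop = FALSE]
  n_other_between <- sum(others$start >= lo & others$end <= hi)
  n_prot_tokens <- sum(pmax(0L, pmin(others$end, hi) - pmax(others$start, lo)))
  word_num <- (hi - lo) - n_prot_tokens
  bin <- word_num_bin(word_num)
  list(word_num = word_num, word_num_bin = bin, protein_count = n_other_between)
}

#' @rdname distance_features
#' @param word_num nonnegative count of non-protein words between the pair
#' @export
word_num_bin <- function(word_num) {
  stopifnot(all(word_num >= 0))
  ifelse(word_num <= 3, "1", ifelse(word_num <= 6, "2", ifelse(word_num <= 9, "3", "4")))
}

#' Full feature vector for one instance
#'
#' Assembles the word, interaction-term and distance features into a named
#' sparse binary vector (feature strings namespaced by group).
#'
#' @inheritParams interaction_term
#' @return a `ppi_features` object with `$groups` and `$features`
#' @export
feature_vector <- function(inst, keywords = default_keywords(), window = 5L) {
  wf <- words_features(inst, window)
  it <- interaction_term(inst, keywords, window)
  df <- distance_features(inst)
  groups <- c(wf, list(interaction_term = it,
                       word_num_bin = df$word_num_bin,
                       protein_count = as.character(df$protein_count)))
  feats <- unique(c(paste0("pn=", groups$words_in_proteins),
                    paste0("bw=", groups$words_between),
                    paste0("sr=", groups$words_surrounding),
                    paste0("it=", groups$interaction_term),
                    paste0("bin=", groups$word_num_bin),
                    paste0("pc=", groups$protein_count)))
  structure(list(groups = groups, features = feats), class = "ppi_features")
}

#' Feature-based kernel between two feature vectors
#'
#' Cosine similarity of the one-hot (binary) encodings:
#' `|x intersect y| / sqrt(|x| * |y|)`. Symmetric, in [0, 1], and 1 on
#' identical non-empty vectors; the Gram matrix is positive semidefinite.
#'
#' @param x,y `ppi_features` objects from the same schema
#' @return similarity in [0, 1]
#' @export
k_fea <- function(x, y) {
  fx <- x$features; fy <- y$features
  if (!length(fx) || !length(fy)) stop("k_fea: empty feature vector")
  length(intersect(fx, fy)) / sqrt(length(fx) * length(fy))
}

#' Feature-kernel Gram matrix over a corpus
#'
#' @param corpus list of masked `ppi_instance`s
#' @inheritParams interaction_term
#' @return a [gram_matrix()] with unit diagonal
#' @export
gram_fea <- function(corpus, keywords = default_keywords(), window = 5L) {
  fvs <- lapply(corpus, feature_vector, keywords = keywords, window = window)
  all_feats <- unique(unlist(lapply(fvs, `[[`, "features")))
  i <- rep(seq_along(fvs), vapply(fvs, function(f) length(f$features), integer(1)))
  j <- match(unlist(lapply(fvs, `[[`, "features")), all_feats)
  M <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(fvs), length(all_feats)))
  nrm <- sqrt(Matrix::rowSums(M^2))
  K <- as.matrix(Matrix::tcrossprod(M / nrm))
  diag(K) <- 1
  gram_matrix(K, ids = vapply(corpus, `[[`, character(1), "id"),
              kernel = "fea", params = list(window = window))
}
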