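#' Candidate-pair instances
#'
#' An instance is one candidate protein pair in one sentence: the tokens, the
#' tagged entity mentions, a constituency parse whose leaves equal the tokens,
#' and a binary interaction label. Entity spans are 0-based half-open
#' `[start, end)` over tokens. Exactly one mention has role `P1` and one `P2`
#' (P1 precedes P2 in the sentence; the relation is undirected); any number of
#' further mentions have role `OTHER`.
#'
#' @param id instance identifier (unique within a corpus)
#' @param doc_id document identifier (used for document-level CV splits)
#' @param tokens character vector of sentence tokens
#' @param entities data.frame with columns `start`, `end`, `role`,
#'   `concept_id` (NA when the mention has no taxonomy concept)
#' @param parse a `parse_tree` whose leaves equal `tokens`
#' @param label 1 (positive, interacting) or 0 (negative)
#' @return a validated `ppi_instance`
#' @export
instance <- function(id, doc_id, tokens, entities, parse, label) {
  inst <- structure(
    list(id = as.character(id), doc_id = as.character(doc_id),
         tokens = as.character(tokens), entities = entities, parse = parse,
         label = as.integer(label), masked = FALSE, protein_words = NULL),
    class = "ppi_instance")
  validate_instance(inst)
  inst
}

#' Validate an instance against the data-model invariants
#'
#' Checks token integrity, entity-span sanity (one P1, one P2, P1 before P2,
#' non-overlapping), that the label is binary, and that the parse leaves equal
#' the tokens.
#'
#' @param inst a `ppi_instance`
#' @return the instance, invisibly; stops with an informative error otherwise
#' @export
validate_instance <- function(inst) {
  id <- inst$id
  fail <- function(msg) stop(sprintf("instance '%s': %s", id, msg), call. = FALSE)
  if (!length(inst$tokens) || any(!nzchar(inst$tokens)) || anyNA(inst$tokens)) {
    fail("tokens must be non-empty strings")
  }
  ent <- inst$entities
  if (!is.data.frame(ent) || !all(c("start", "end", "role") %in% names(ent))) {
    fail("entities must be a data.frame with start, end, role")
  }
  if (!"concept_id" %in% names(ent)) ent$concept_id <- NA_character_
  if (sum(ent$role == "P1") != 1L || sum(ent$role == "P2") != 1L) {
    fail("exactly one P1 and one P2 mention required")
  }
  if (!all(ent$role %in% c("P1", "P2", "OTHER"))) fail("entity roles must be P1/P2/OTHER")
  n <- length(inst$tokens)
  if (any(ent$start < 0L) || any(ent$end > n) || any(ent$start >= ent$end)) {
    fail("entity spans must satisfy 0 <= start < end <= sentence length")
  }
  p1 <- ent[ent$role == "P1", ]; p2 <- ent[ent$role == "P2", ]
  if (!(p1$end <= p2$start || p2$end <= p1$start)) fail("P1 and P2 spans overlap")
  if (p1$start >= p2$start) fail("P1 span must precede P2 span")
  if (!inst$label %in% c(0L, 1L)) fail("label must be binary")
  lv <- tree_leaves(inst$parse)
  if (length(lv) != n || any(lv != inst$tokens)) {
    fail("parse leaves do not equal sentence tokens")
  }
  invisible(inst)
}

#' @export
print.ppi_instance <- function(x, ...) {
  cat(sprintf("<ppi_instance %s doc=%s label=%d%s>\n  %s\n", x$id, x$doc_id,
              x$label, if (x$masked) " masked" else "",
              paste(x$tokens, collapse = " ")))
  invisible(x)
}

CORPUS_FORMAT_VERSION <- "1.0"

#' Read a JSONL corpus
#'
#' One JSON object per line with fields `id`, `doc_id`, `tokens`,
#' `entities` (list of `{start, end, role, concept_id}` with 0-based half-open
#' spans), `parse` (a bracketed Penn-Treebank string) and `label`
#' (`"positive"`/`"negative"`). Every record is validated; a record violating
#' an invariant aborts the read with an error naming the record.
#'
#' @param path file path
#' @param format only `"jsonl"` is supported
#' @return list of `ppi_instance`
#' @export
read_corpus <- function(path, format = "jsonl") {
  format <- match.arg(format, "jsonl")
  if (!file.exists(path)) stop("read_corpus: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[[k]], simplifyDataFrame = FALSE)
    rid <- if (!is.null(rec$id)) rec$id else sprintf("<line %d>", k)
    if (is.null(rec$parse)) stop(sprintf("record '%s': missing parse", rid), call. = FALSE)
    ent <- do.call(rbind, lapply(rec$entities, function(e) {
      data.frame(start = as.integer(e$start), end = as.integer(e$end),
                 role = as.character(e$role),
                 concept_id = if (is.null(e$concept_id)) NA_character_ else as.character(e$concept_id),
                 stringsAsFactors = FALSE)
    }))
    lab <- switch(as.character(rec$label),
                  positive = 1L, negative = 0L, `1` = 1L, `0` = 0L,
                  stop(sprintf("record '%s': bad label '%s'", rid, rec$label), call. = FALSE))
    inst <- instance(rid, rec$doc_id, unlist(rec$tokens), ent,
                     parse_ptb(rec$parse), lab)
    out[[k]] <- inst
  }
  message(sprintf("read_corpus: %d instances from %s", length(out), path))
  out
}

#' Write a corpus as JSONL
#'
#' Deterministic field order and formatting, so identical corpora produce
#' byte-identical files.
#'
#' @param corpus list of `ppi_instance`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(inst) {
    ents <- lapply(seq_len(nrow(inst$entities)), function(i) {
      e <- inst$entities[i, ]
      x <- list(start = e$start, end = e$end, role = e$role)
      if (!is.na(e$concept_id)) x$concept_id <- e$concept_id
      x
    })
    jsonlite::toJSON(
      list(format_version = CORPUS_FORMAT_VERSION, id = inst$id,
           doc_id = inst$doc_id, tokens = inst$tokens, entities = ents,
           parse = write_ptb(inst$parse),
           label = if (inst$label == 1L) "positive" else "negative"),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# find, within `node`, the lowest node whose leaf span is exactly [lo, hi)
# (0-based, relative to node's own leaves starting at `off`); returns a new
# tree with that node replaced by replacement(node), or NULL if no exact cover
replace_span_node <- function(node, lo, hi, off, replacement) {
  nlv <- length(tree_leaves(node))
  if (off == lo && off + nlv == hi) {
    # recurse first: prefer the lowest covering node
    if (!is_leaf(node) && length(node$children) == 1L) {
      sub <- replace_span_node(node$children[[1]], lo, hi, off, replacement)
      if (!is.null(sub)) return(tree_node(node$label, list(sub)))
    }
    return(replacement(node))
  }
  if (is_leaf(node)) return(NULL)
  cur <- off
  for (k in seq_along(node$children)) {
    ch <- node$children[[k]]
    w <- length(tree_leaves(ch))
    if (cur <= lo && hi <= cur + w) {
      sub <- replace_span_node(ch, lo, hi, cur, replacement)
      if (is.null(sub)) return(NULL)
      kids <- node$children
      kids[[k]] <- sub
      return(tree_node(node$label, kids))
    }
    cur <- cur + w
  }
  NULL
}

# delete leaves with 0-based indices in `drop`; prune nodes left childless
drop_leaves <- function(node, drop, off = 0L) {
  if (is_leaf(node)) {
    if (off %in% drop) return(NULL)
    return(node)
  }
  kids <- list()
  cur <- off
  for (ch in node$children) {
    w <- length(tree_leaves(ch))
    sub <- drop_leaves(ch, drop, cur)
    if (!is.null(sub)) kids[[length(kids) + 1L]] <- sub
    cur <- cur + w
  }
  if (!length(kids)) return(NULL)
  tree_node(node$label, kids)
}

#' Mask protein mentions
#'
#' Replaces the tokens of the focus pair by the placeholders `PROTEIN_1` and
#' `PROTEIN_2` and every other tagged protein mention by `PROTEIN`, in both
#' the token sequence and the parse tree. A multi-token mention collapses to a
#' single leaf under its lowest dominating node; if no node covers the span
#' exactly, the leftmost leaf is replaced and the rest deleted, with a
#' warning. The original surface words of P1 and P2 are retained in
#' `$protein_words` for the lexical features. Masking is idempotent.
#'
#' @param inst a `ppi_instance`
#' @return the masked instance
#' @export
mask_proteins <- function(inst) {
  if (isTRUE(inst$masked)) return(inst)
  ent <- inst$entities
  placeholder <- function(role) switch(role, P1 = "PROTEIN_1", P2 = "PROTEIN_2", "PROTEIN")
  pw <- c(inst$tokens[(ent$start[ent$role == "P1"] + 1L):ent$end[ent$role == "P1"]],
          inst$tokens[(ent$start[ent$role == "P2"] + 1L):ent$end[ent$role == "P2"]])
  ord <- order(ent$start, decreasing = TRUE)   # right-to-left: spans stay valid
  tokens <- inst$tokens
  tree <- inst$parse
  new_ent <- ent
  for (i in ord) {
    lo <- ent$start[i]; hi <- ent$end[i]
    ph <- placeholder(ent$role[i])
    rep_fun <- function(node) {
      if (is_leaf(node)) tree_node(ph)
      else if (hi - lo == 1L) {
        # single-token span covered by its preterminal: keep the POS label
        tree_node(node$label, list(tree_node(ph)))
      } else {
        tree_node(node$label, list(tree_node(ph)))
      }
    }
    new_tree <- replace_span_node(tree, lo, hi, 0L, rep_fun)
    if (is.null(new_tree)) {
      warning(sprintf("instance '%s': span [%d,%d) not covered by one subtree; %s",
                      inst$id, lo, hi, "replacing leftmost leaf and dropping the rest"))
      new_tree <- replace_span_node(tree, lo, lo + 1L, 0L,
                                    function(node) if (is_leaf(node)) tree_node(ph)
                                                   else tree_node(node$label, list(tree_node(ph))))
      if (hi - lo > 1L) new_tree <- drop_leaves(new_tree, seq.int(lo + 1L, hi - 1L))
    }
    tree <- new_tree
    tokens <- append(tokens[-seq.int(lo + 1L, hi)], ph, after = lo)
    shift <- (hi - lo) - 1L
    later <- new_ent$start >= hi
    new_ent$start[later] <- new_ent$start[later] - shift
    new_ent$end[later] <- new_ent$end[later] - shift
    new_ent$start[i] <- lo
    new_ent$end[i] <- lo + 1L
  }
  out <- inst
  out$tokens <- tokens
  out$entities <- new_ent
  out$parse <- tree
  out$masked <- TRUE
  out$protein_words <- pw
  validate_instance(out)
  out
}
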