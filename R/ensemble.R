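#' Gram matrices with provenance
#'
#' A symmetric instance-by-instance kernel matrix tagged with the ordered
#' instance ids, the kernel name and its parameters.
#'
#' @param K numeric matrix (symmetric within 1e-9)
#' @param ids character vector of unique instance ids, one per row
#' @param kernel kernel name (e.g. `"fea"`, `"det"`, `"sim"`, `"ensemble"`)
#' @param params named list of the kernel parameters used
#' @return a `gram_matrix`
#' @export
gram_matrix <- function(K, ids, kernel = "custom", params = list()) {
  K <- as.matrix(K)
  stopifnot(nrow(K) == ncol(K), length(ids) == nrow(K))
  if (anyDuplicated(ids)) stop("gram_matrix: duplicate instance ids")
  if (max(abs(K - t(K))) > 1e-9) stop("gram_matrix: matrix not symmetric")
  K <- (K + t(K)) / 2
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, ids = as.character(ids), kernel = kernel,
                 params = params), class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("<gram_matrix %s: %d x %d, params: %s>\n", x$kernel,
              nrow(x$K), ncol(x$K),
              paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Write / read a Gram matrix as TSV
#'
#' Tab-separated with the instance ids as header and first column; writes are
#' deterministic (fixed 17 significant digits) so identical matrices are
#' byte-identical on disk.
#'
#' @param g a `gram_matrix`
#' @param path file path
#' @return `path` (write) or a `gram_matrix` (read)
#' @export
write_gram <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("id", g$ids), collapse = "\t"), con)
  for (i in seq_along(g$ids)) {
    writeLines(paste(c(g$ids[i], sprintf("%.17g", g$K[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_gram
#' @export
read_gram <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           row.names = 1)
  gram_matrix(as.matrix(tab), ids = rownames(tab), kernel = "file",
              params = list(path = path))
}

#' Linear ensemble of kernels
#'
#' The weighted sum of the input Gram matrices (equal weights by default,
#' matching the plain multiple-kernel setting; weighted combinations are a
#' config knob), renormalized to unit diagonal:
#' `K'[i,j] = S[i,j] / sqrt(S[i,i] * S[j,j])`.
#'
#' @param grams list of `gram_matrix` objects over the same instances in the
#'   same order
#' @param weights nonnegative weights, default equal
#' @return a `gram_matrix` named `"ensemble"`
#' @export
ensemble <- function(grams, weights = NULL) {
  stopifnot(length(grams) >= 1)
  ids <- grams[[1]]$ids
  for (g in grams[-1]) {
    if (!identical(g$ids, ids)) {
      d <- which(g$ids != ids)[1]
      stop(sprintf("ensemble: instance-id mismatch at position %d ('%s' vs '%s')",
                   d, ids[d], g$ids[d]))
    }
  }
  if (is.null(weights)) weights <- rep(1, length(grams))
  stopifnot(length(weights) == length(grams), all(weights >= 0), sum(weights) > 0)
  S <- Reduce(`+`, Map(function(g, w) w * g$K, grams, weights))
  d <- diag(S)
  if (any(d <= 0)) stop("ensemble: nonpositive self-similarity; cannot renormalize")
  K <- S / sqrt(outer(d, d))
  diag(K) <- 1
  gram_matrix(K, ids, kernel = "ensemble",
              params = list(kernels = paste(vapply(grams, `[[`, character(1), "kernel"),
                                            collapse = "+"),
                            weights = paste(weights, collapse = ",")))
}

#' Repair a Gram matrix to positive semidefiniteness
#'
#' Similarity matrices (notably the semantic kernel) need not be Mercer
#' kernels. If the minimum eigenvalue is below `-tol`, negative eigenvalues
#' are clipped to zero and the matrix reconstructed (the nearest PSD matrix
#' in Frobenius norm among spectral clippings); a matrix already PSD within
#' tolerance is returned unchanged.
#'
#' @param g a `gram_matrix` (or plain symmetric matrix)
#' @param tol nonnegative tolerance on the minimum eigenvalue
#' @return object of the same type, PSD within `tol`
#' @export
make_psd <- function(g, tol = 1e-8) {
  K <- if (inherits(g, "gram_matrix")) g$K else as.matrix(g)
  if (max(abs(K - t(K))) > 1e-6) stop("make_psd: matrix not symmetric")
  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  if (min(e$values) >= -tol) return(g)
  v <- pmax(e$values, 0)
  K2 <- e$vectors %*% (v * t(e$vectors))
  K2 <- (K2 + t(K2)) / 2
  if (inherits(g, "gram_matrix")) {
    out <- gram_matrix(K2, g$ids, g$kernel, c(g$params, list(psd_repaired = TRUE)))
    out
  } else K2
}

# ---------------------------------------------------------------------------
# SVM with precomputed kernel
# ---------------------------------------------------------------------------

#' Train a C-SVM on a precomputed kernel
#'
#' Solves the soft-margin C-SVC dual with a deterministic SMO solver.
#' Training is fully reproducible for fixed inputs.
#'
#' @param G training `gram_matrix` (PSD; run [make_psd()] first if needed)
#' @param labels binary labels (0/1) in the order of `G$ids`
#' @param C soft-margin cost (> 0), default 1
#' @param tol KKT tolerance
#' @return an `svm_model` (support coefficients `alpha`, bias `b`, labels)
#' @export
svm_train <- function(G, labels, C = 1, tol = 1e-3) {
  K <- if (inherits(G, "gram_matrix")) G$K else as.matrix(G)
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), length(labels) == nrow(K), C > 0)
  if (length(unique(labels)) < 2L) stop("svm_train: single-class training set")
  y <- ifelse(labels == 1L, 1, -1)
  fit <- .cpp_smo_train(K, y, C, tol, 10L)
  structure(list(alpha = fit$alpha, b = fit$b, y = y, C = C,
                 n = length(y), iterations = fit$iterations),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf("<svm_model: n=%d, SV=%d, C=%g>\n", x$n, sum(x$alpha > 1e-8), x$C))
  invisible(x)
}

#' Decision scores for new instances
#'
#' @param model an `svm_model`
#' @param K_test_rows matrix of kernel values, test instances in rows and the
#'   training instances (in training order) in columns
#' @return numeric decision values (positive means predicted interaction)
#' @export
svm_predict <- function(model, K_test_rows) {
  K_test_rows <- matrix(K_test_rows, ncol = model$n)
  as.numeric(K_test_rows %*% (model$alpha * model$y) + model$b)
}

# ---------------------------------------------------------------------------
# Evaluation: P/R/F, ROC, AUC, cross-validation
# ---------------------------------------------------------------------------

#' ROC curve and AUC
#'
#' ROC points by sweeping a threshold over the scores (ties grouped), AUC by
#' trapezoidal integration -- equal, with the half-credit tie convention, to
#' the Mann-Whitney statistic `U / (n+ * n-)`.
#'
#' @param scores numeric decision scores (higher = more positive)
#' @param labels binary labels (0/1)
#' @return list with `roc` (data.frame of FPR, TPR) and `auc`
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop("roc_auc: need at least one positive and one negative")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # group tied scores so ties move diagonally (half-credit)
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)
  roc <- data.frame(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Precision, recall and F-score from confusion counts
#' @param tp,fp,fn true-positive, false-positive, false-negative counts
#' @return list with `precision`, `recall`, `f` (0 when undefined)
#' @export
prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f = f)
}

# deterministic fold assignment; document-level keeps all instances of one
# doc_id in the same fold
make_folds <- function(corpus, folds, split = c("document", "instance"), seed = 1L) {
  split <- match.arg(split)
  n <- length(corpus)
  rng <- local({ set.seed(seed); NULL })
  if (split == "document") {
    docs <- vapply(corpus, `[[`, character(1), "doc_id")
    ud <- unique(docs)
    if (length(ud) < folds) {
      stop(sprintf("cross_validate: %d documents < %d folds", length(ud), folds))
    }
    set.seed(seed)
    ud <- sample(ud)
    fold_of_doc <- stats::setNames(rep_len(seq_len(folds), length(ud)), ud)
    unname(fold_of_doc[docs])
  } else {
    if (n < folds) stop("cross_validate: fewer instances than folds")
    set.seed(seed)
    rep_len(seq_len(folds), n)[sample(n)]
  }
}

#' Cross-validated evaluation of a kernel configuration
#'
#' k-fold cross-validation of the precomputed-kernel SVM over one or more
#' Gram matrices (combined with [ensemble()] and repaired with [make_psd()]).
#' Splitting is by document by default, so sibling candidate pairs from one
#' abstract never straddle a train/test boundary; instance-level splitting is
#' available. Deterministic for a fixed seed.
#'
#' @param grams a `gram_matrix` or list of them (same instance order)
#' @param labels binary labels (0/1) in instance order
#' @param corpus list of `ppi_instance` (for doc ids); may be NULL with
#'   `split = "instance"`
#' @param folds number of folds (default 10)
#' @param split `"document"` or `"instance"`
#' @param seed fold-shuffling seed (the only randomness)
#' @param C SVM cost
#' @param weights optional ensemble weights
#' @return an `eval_report`: pooled and per-fold precision/recall/F, ROC
#'   points, AUC and confusion counts
#' @export
cross_validate <- function(grams, labels, corpus = NULL, folds = 10L,
                           split = c("document", "instance"), seed = 1L, C = 1,
                           weights = NULL) {
  split <- match.arg(split)
  if (inherits(grams, "gram_matrix")) grams <- list(grams)
  G <- if (length(grams) > 1L) ensemble(grams, weights) else grams[[1]]
  G <- make_psd(G)
  K <- G$K
  labels <- as.integer(labels)
  n <- nrow(K)
  stopifnot(length(labels) == n)
  if (split == "document" && is.null(corpus)) {
    stop("cross_validate: document split needs the corpus for doc ids")
  }
  fold_id <- if (split == "document") make_folds(corpus, folds, "document", seed)
             else make_folds(seq_len(n), folds, "instance", seed)
  scores <- numeric(n)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    te <- which(fold_id == f); tr <- which(fold_id != f)
    model <- svm_train(gram_matrix(K[tr, tr, drop = FALSE], G$ids[tr]),
                       labels[tr], C = C)
    sc <- svm_predict(model, K[te, tr, drop = FALSE])
    scores[te] <- sc
    pred <- as.integer(sc > 0)
    tp <- sum(pred == 1L & labels[te] == 1L)
    fp <- sum(pred == 1L & labels[te] == 0L)
    fn <- sum(pred == 0L & labels[te] == 1L)
    tn <- sum(pred == 0L & labels[te] == 0L)
    per_fold[[f]] <- c(fold = f, n = length(te), tp = tp, fp = fp, fn = fn, tn = tn,
                       unlist(prf(tp, fp, fn)))
  }
  fold_tab <- as.data.frame(do.call(rbind, per_fold))
  tp <- sum(fold_tab$tp); fp <- sum(fold_tab$fp)
  fn <- sum(fold_tab$fn); tn <- sum(fold_tab$tn)
  pooled <- prf(tp, fp, fn)
  ra <- roc_auc(scores, labels)
  structure(list(kernel = G$kernel, params = G$params, folds = folds,
                 split = split, seed = seed, C = C,
                 confusion = c(tp = tp, fp = fp, fn = fn, tn = tn),
                 precision = pooled$precision, recall = pooled$recall,
                 f = pooled$f, auc = ra$auc, roc = ra$roc,
                 per_fold = fold_tab, scores = scores, fold_id = fold_id),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report %s: %d-fold %s CV>\n", x$kernel, x$folds, x$split))
  cat(sprintf("  P = %.4f  R = %.4f  F = %.4f  AUC = %.4f\n",
              x$precision, x$recall, x$f, x$auc))
  cat(sprintf("  confusion: TP=%d FP=%d FN=%d TN=%d\n", x$confusion["tp"],
              x$confusion["fp"], x$confusion["fn"], x$confusion["tn"]))
  invisible(x)
}

#' Serialize an evaluation report as JSON
#' @param report an `eval_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  out <- list(kernel = report$kernel, params = report$params,
              folds = report$folds, split = report$split, seed = report$seed,
              C = report$C, confusion = as.list(report$confusion),
              precision = report$precision, recall = report$recall,
              f = report$f, auc = report$auc,
              per_fold = report$per_fold, roc = report$roc)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
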