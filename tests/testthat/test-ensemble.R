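random_psd_gram <- function(n, seed, ids = sprintf("i%02d", seq_len(n))) {
  set.seed(seed)
  A <- matrix(stats::rnorm(n * n), n)
  S <- crossprod(A) / n
  d <- sqrt(diag(S))
  K <- S / outer(d, d)
  diag(K) <- 1
  gram_matrix(K, ids = ids, kernel = paste0("rnd", seed))
}

test_that("ensemble is the renormalized weighted sum", {
  g1 <- random_psd_gram(8, 1)
  # single input, weight 1: unchanged
  expect_equal(ensemble(list(g1))$K, g1$K, tolerance = 1e-12)
  # two identical inputs, equal weights: unchanged after renormalization
  expect_equal(ensemble(list(g1, g1))$K, g1$K, tolerance = 1e-12)

  g2 <- random_psd_gram(8, 2); g3 <- random_psd_gram(8, 3)
  w <- c(0.5, 1, 2)
  E <- ensemble(list(g1, g2, g3), w)
  S <- 0.5 * g1$K + 1 * g2$K + 2 * g3$K
  expected <- S / sqrt(outer(diag(S), diag(S)))   # element-wise oracle
  expect_equal(E$K, expected, tolerance = 1e-12)
  expect_equal(unname(diag(E$K)), rep(1, 8))
  # PSD is preserved under nonnegative combination
  expect_gte(min(eigen(E$K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)

  bad <- random_psd_gram(8, 4, ids = sprintf("x%02d", 1:8))
  expect_error(ensemble(list(g1, bad)), "mismatch at position 1")
})

test_that("make_psd clips negative eigenvalues and keeps PSD inputs intact", {
  g <- random_psd_gram(10, 5)
  expect_identical(make_psd(g), g)   # fast path: untouched object

  set.seed(6)
  A <- matrix(stats::rnorm(100), 10); A <- (A + t(A)) / 2   # indefinite
  expect_lt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), 0)
  R <- make_psd(A, tol = 1e-8)
  expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  # eigen-decomposition oracle: clipping reconstruction
  e <- eigen(A, symmetric = TRUE)
  oracle <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  expect_equal(R, (oracle + t(oracle)) / 2, tolerance = 1e-10)
  expect_error(make_psd(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("the SVM solves small problems exactly", {
  # analytic 2-support-vector problem: alpha1 = alpha2 =
  # min(C, 2 / (K11 + K22 - 2 K12)), b from the margin conditions
  K <- matrix(c(1, 0.2, 0.2, 1), 2)
  labels <- c(1L, 0L)
  model <- svm_train(gram_matrix(K, c("p", "n")), labels, C = 10)
  a_star <- min(10, 2 / (1 + 1 - 2 * 0.2))
  expect_equal(model$alpha, c(a_star, a_star), tolerance = 1e-3)
  f <- svm_predict(model, K)
  expect_equal(f, c(1, -1), tolerance = 1e-2)   # both on the margin

  # linearly separable toy Gram: perfect training accuracy
  set.seed(8)
  X <- rbind(matrix(stats::rnorm(20, 3), 10), matrix(stats::rnorm(20, -3), 10))
  Klin <- X %*% t(X)
  lab <- rep(c(1L, 0L), each = 10)
  m2 <- svm_train(gram_matrix(Klin / max(Klin), sprintf("s%02d", 1:20)), lab, C = 100)
  sc <- svm_predict(m2, Klin / max(Klin))
  expect_equal(as.integer(sc > 0), lab)

  # duplicated instances get identical scores (determinism)
  Kdup <- Klin[c(1:20, 1), c(1:20, 1)] / max(Klin)
  sc2 <- svm_predict(m2, Kdup[21, 1:20, drop = FALSE])
  expect_equal(sc2, sc[1], tolerance = 1e-12)

  expect_error(svm_train(gram_matrix(K, c("a", "b")), c(1L, 1L)), "single-class")
})

test_that("roc_auc matches the pairwise-comparison oracle", {
  expect_equal(roc_auc(c(3, 2, 1, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(1, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "positive and")

  set.seed(9)
  for (k in 1:20) {
    n <- sample(10:40, 1)
    lab <- c(1L, 0L, sample(0:1, n - 2, replace = TRUE))
    sc <- round(stats::rnorm(n), 1)            # rounding forces ties
    auc <- roc_auc(sc, lab)$auc
    sp <- sc[lab == 1]; sn <- sc[lab == 0]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(auc, mean(cmp), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(sc), lab)$auc, auc, tolerance = 1e-12)
  }
})

test_that("prf satisfies the harmonic-mean identity", {
  r <- prf(tp = 30, fp = 10, fn = 20)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$f, 2 * r$precision * r$recall / (r$precision + r$recall))
  expect_equal(prf(0, 0, 0)$f, 0)
})

test_that("cross-validation conserves counts and respects document splits", {
  tax <- gen_taxonomy(3, 2, seed = 31)
  wtax <- gen_taxonomy(3, 3, seed = 32, prefix = "w")
  corpus <- gen_corpus(gen_config(n_instances = 80, seed = 31), tax, wtax)
  masked <- lapply(corpus, mask_proteins)
  labels <- vapply(corpus, `[[`, integer(1), "label")
  G <- gram_fea(masked)
  rep <- cross_validate(G, labels, corpus, folds = 5, seed = 7)
  # fold sizes sum to the corpus size; confusion counts are conserved
  expect_equal(sum(rep$per_fold$n), 80)
  expect_equal(sum(rep$per_fold$tp + rep$per_fold$fp +
                   rep$per_fold$fn + rep$per_fold$tn), 80)
  expect_equal(unname(rep$confusion["tp"] + rep$confusion["fn"]), sum(labels))
  # no document straddles a fold boundary
  docs <- vapply(corpus, `[[`, character(1), "doc_id")
  expect_true(all(tapply(rep$fold_id, docs, function(f) length(unique(f))) == 1))
  # determinism
  rep2 <- cross_validate(G, labels, corpus, folds = 5, seed = 7)
  expect_identical(rep$scores, rep2$scores)
  expect_identical(rep$f, rep2$f)
  # all-positive prediction analytics: R = 1, P = prevalence
  n_te <- 30
  pr <- prf(tp = sum(labels[1:n_te]), fp = n_te - sum(labels[1:n_te]), fn = 0)
  expect_equal(pr$recall, 1)
  expect_equal(pr$precision, mean(labels[1:n_te]))
  expect_error(cross_validate(G, labels, corpus, folds = 100), "documents")
})

test_that("gram matrices round-trip through TSV", {
  g <- random_psd_gram(6, 12)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_gram(g, p)
  back <- read_gram(p)
  expect_equal(back$K, g$K, tolerance = 1e-15)
  expect_identical(back$ids, g$ids)
  # writes are deterministic
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_gram(g, p2)
  expect_identical(readLines(p), readLines(p2))
})
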