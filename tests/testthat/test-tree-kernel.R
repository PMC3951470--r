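# the published worked examples
FIG2_FULL <- paste0("(S (NP (NNP PROTEIN_1) (CC and) (NNP PROTEIN_2)) ",
                    "(VP (VBP interact) (PP (IN with) (NP (DT each) (JJ other)))))")
FIG2_SPT <- "(NP (NNP PROTEIN_1) (CC and) (NNP PROTEIN_2))"

test_that("MCT is the LCA-rooted subtree and contains the enclosed leaves", {
  # LCA at the root: MCT is the whole tree
  full <- parse_ptb(FIG2_FULL)
  wide <- parse_ptb("(S (NP (NNP PROTEIN_1)) (VP (VBZ binds)) (NP (NNP PROTEIN_2)))")
  expect_identical(write_ptb(mct(wide)$tree), write_ptb(wide))
  # LCA below the root: MCT is the NP
  expect_identical(write_ptb(mct(full)$tree), FIG2_SPT)
  expect_error(mct(parse_ptb("(S (NNP PROTEIN_1))")), "PROTEIN_2")

  # property: MCT contains both protein leaves and every leaf between them
  set.seed(11)
  tax <- gen_taxonomy(3, 2, seed = 11)
  corpus <- gen_corpus(gen_config(n_instances = 30, seed = 11), tax)
  for (inst in corpus) {
    m <- mask_proteins(inst)
    lv <- tree_leaves(m$parse)
    i1 <- match("PROTEIN_1", lv); i2 <- match("PROTEIN_2", lv)
    mlv <- tree_leaves(mct(m)$tree)
    expect_true(all(lv[i1:i2] %in% mlv))
  }
})

test_that("SPT matches the published pruning and is contained in the MCT", {
  full <- parse_ptb(FIG2_FULL)
  expect_identical(write_ptb(spt(full)$tree), FIG2_SPT)

  # siblings with nothing else: SPT = MCT
  sib <- parse_ptb("(S (DT the) (NP (NNP PROTEIN_1) (NNP PROTEIN_2)))")
  expect_identical(write_ptb(spt(sib)$tree), "(NP (NNP PROTEIN_1) (NNP PROTEIN_2))")
  expect_identical(write_ptb(spt(sib)$tree), write_ptb(mct(sib)$tree))

  # material outside the pair span is pruned, inside is kept
  mixed <- parse_ptb(paste0("(S (NP (DT the) (NNP PROTEIN_1) (NN complex)) ",
                            "(VP (VBZ binds) (NP (NNP PROTEIN_2) (NN promoter))))"))
  s <- spt(mixed)$tree
  expect_identical(write_ptb(s),
    "(S (NP (NNP PROTEIN_1) (NN complex)) (VP (VBZ binds) (NP (NNP PROTEIN_2))))")

  # property: SPT node multiset is a subset of MCT's
  tax <- gen_taxonomy(3, 2, seed = 13)
  corpus <- gen_corpus(gen_config(n_instances = 30, seed = 13), tax)
  for (inst in corpus) {
    m <- mask_proteins(inst)
    expect_lte(spt(m)$node_count, mct(m)$node_count)
    expect_lte(count_nodes(spt(m)$tree, "all"), count_nodes(mct(m)$tree, "all"))
  }
})

test_that("DET reproduces the published dynamic extension", {
  full <- parse_ptb(FIG2_FULL)
  d <- det(full)
  expect_equal(d$det_choice, "PARENT")
  expect_identical(write_ptb(d$tree), FIG2_FULL)

  # a large SPT stays the SPT
  big <- parse_ptb(paste0("(S (NP (NNP PROTEIN_1)) (VP (VBZ binds) (PP (IN to) ",
                          "(NP (DT the) (NN promoter)))) (NP (NNP PROTEIN_2)))"))
  db <- det(big)
  expect_equal(db$det_choice, "SPT")
  expect_identical(write_ptb(db$tree), write_ptb(spt(big)$tree))

  # small SPT != MCT: extended to MCT
  s1 <- parse_ptb(paste0("(S (NP (DT The) (NN PROTEIN_1) (NN PROTEIN_2) (NN complex)) ",
                         "(VP (VBZ suggests)))"))
  ds <- det(s1)
  expect_equal(ds$det_choice, "MCT")
  expect_identical(write_ptb(ds$tree),
                   "(NP (DT The) (NN PROTEIN_1) (NN PROTEIN_2) (NN complex))")

  # SPT root = sentence root with a small SPT: nothing to extend to
  tiny <- parse_ptb("(NP (NNP PROTEIN_1) (NNP PROTEIN_2))")
  expect_warning(dt <- det(tiny), "no parent")
  expect_equal(dt$det_choice, "SPT")

  # trichotomy on generated corpora: choice fully determined by size and
  # the SPT/MCT comparison
  tax <- gen_taxonomy(3, 2, seed = 17)
  corpus <- gen_corpus(gen_config(n_instances = 40, seed = 17), tax)
  for (inst in corpus) {
    m <- mask_proteins(inst)
    d <- det(m)
    s <- spt(m); mc <- mct(m)
    if (s$node_count >= 7) {
      expect_equal(d$det_choice, "SPT")
    } else if (!identical(write_ptb(s$tree), write_ptb(mc$tree))) {
      expect_equal(d$det_choice, "MCT")
    } else {
      expect_true(d$det_choice %in% c("PARENT", "SPT"))
    }
  }
})

test_that("node-count mode is configurable in the DET rule", {
  full <- parse_ptb(FIG2_FULL)
  # counting token leaves as nodes the SPT has exactly 7 -> no extension
  expect_equal(det(full, node_count_mode = "all")$det_choice, "SPT")
  expect_equal(det(full, node_count_mode = "leaves")$det_choice, "PARENT")
  expect_equal(det(full, threshold = 5, node_count_mode = "nonleaf")$det_choice, "PARENT")
  expect_equal(det(full, threshold = 4, node_count_mode = "nonleaf")$det_choice, "SPT")
})

test_that("ctk equals the brute-force fragment enumeration on small trees", {
  # trivial anchors
  pre <- parse_ptb("(NNP PROTEIN_1)")
  expect_equal(ctk(pre, pre, 1), 1)
  expect_equal(ctk(parse_ptb("(A (B x))"), parse_ptb("(C (D y))"), 0.4), 0)
  expect_error(ctk(pre, pre, 0), "lambda")
  expect_error(ctk(pre, pre, 1.5), "lambda")

  set.seed(29)
  for (k in 1:200) {
    t1 <- random_tree(sample(3:8, 1), labels = c("S", "NP", "VP"),
                      tokens = c("a", "b"))
    t2 <- random_tree(sample(3:8, 1), labels = c("S", "NP", "VP"),
                      tokens = c("a", "b"))
    for (lam in c(0.4, 1.0)) {
      expect_equal(ctk(t1, t2, lam), ctk_oracle(t1, t2, lam), tolerance = 1e-10)
    }
    expect_equal(ctk(t1, t2, 0.4), ctk(t2, t1, 0.4))
  }
})

test_that("ctk is monotone under shared-subtree growth", {
  base1 <- parse_ptb("(S (NP (NNP PROTEIN_1)) (NP (NNP PROTEIN_2)))")
  base2 <- parse_ptb("(S (NP (NNP PROTEIN_1)) (VP (VBZ binds)) (NP (NNP PROTEIN_2)))")
  shared <- tree_node("PP", list(tree_node("IN", list(tree_node("with")))))
  grow <- function(t) tree_node(t$label, c(t$children, list(shared)))
  expect_gte(ctk(grow(base1), grow(base2), 0.4), ctk(base1, base2, 0.4))
})

test_that("k_det is normalized and the Gram is consistent and PSD", {
  tax <- gen_taxonomy(3, 2, seed = 19)
  corpus <- gen_corpus(gen_config(n_instances = 25, seed = 19), tax)
  masked <- lapply(corpus, mask_proteins)
  expect_equal(k_det(masked[[1]], masked[[1]]), 1)
  v <- k_det(masked[[1]], masked[[2]])
  expect_gte(v, 0); expect_lte(v, 1)

  G <- gram_det(masked)
  expect_equal(unname(diag(G$K)), rep(1, 25))
  expect_equal(max(abs(G$K - t(G$K))), 0)
  expect_gte(min(eigen(G$K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  for (idx in list(c(1, 2), c(3, 20), c(10, 25))) {
    expect_equal(G$K[idx[1], idx[2]], k_det(masked[[idx[1]]], masked[[idx[2]]]),
                 tolerance = 1e-12)
  }
  # hand-built pair checked against the enumeration oracle with normalizers
  ta <- det(parse_ptb("(S (NP (NNP PROTEIN_1) (NNP PROTEIN_2)) (VP (VBZ binds)))"))$tree
  tb <- det(parse_ptb("(S (NP (NNP PROTEIN_1) (NNP PROTEIN_2)) (VP (VBZ acts)))"))$tree
  expected <- ctk_oracle(ta, tb, 0.4) /
    sqrt(ctk_oracle(ta, ta, 0.4) * ctk_oracle(tb, tb, 0.4))
  got <- ctk(ta, tb, 0.4) / sqrt(ctk(ta, ta, 0.4) * ctk(tb, tb, 0.4))
  expect_equal(got, expected, tolerance = 1e-10)
})
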