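test_that("taxonomy construction validates structure and computes p/IC", {
  tax <- toy_tax()
  expect_equal(tax$root, "r")
  expect_equal(unname(tax$p[["r"]]), 1)
  expect_equal(unname(tax$ic[["r"]]), 0)
  expect_equal(unname(tax$depth[c("r", "a", "a1")]), c(1, 2, 3))
  # p monotone non-increasing from root to leaves
  for (c0 in tax$concepts) {
    p <- tax$parent[[c0]]
    if (!is.na(p)) expect_lte(tax$p[[c0]], tax$p[[p]])
  }
  # cumulative probability agrees with the explicit oracle
  for (c0 in tax$concepts) {
    expect_equal(unname(tax$ic[[c0]]), oracle_ic(toy_edges, toy_freq, c0),
                 tolerance = 1e-12)
  }
  # structural errors
  expect_error(taxonomy(data.frame(child = c("a", "b"), parent = c("r", "q"))),
               "one root")
  expect_error(taxonomy(data.frame(child = c("a", "b", "a"),
                                   parent = c("r", "r", "b"))),
               "multiple parents")
  expect_error(taxonomy(toy_edges, c(zz = 3)), "unknown concept")
})

test_that("taxonomy TSV files round-trip", {
  tax <- gen_taxonomy(3, 3, seed = 4)
  ep <- withr::local_tempfile(fileext = ".tsv")
  fp <- withr::local_tempfile(fileext = ".tsv")
  write_taxonomy(tax, ep, fp)
  back <- read_taxonomy(ep, fp)
  expect_equal(back$concepts, tax$concepts)
  expect_equal(back$p, tax$p)
  expect_equal(back$depth, tax$depth)
})

test_that("li_sim matches the oracle and is monotone in path and depth", {
  tax <- toy_tax()
  for (c1 in tax$concepts) for (c2 in tax$concepts) {
    expect_equal(li_sim(c1, c2, tax), oracle_li(toy_edges, c1, c2),
                 tolerance = 1e-12)
    expect_equal(li_sim(c1, c2, tax), li_sim(c2, c1, tax))
    expect_gte(li_sim(c1, c2, tax), 0)
    expect_lte(li_sim(c1, c2, tax), 1)
  }
  # identical concepts: l = 0 gives tanh(beta * depth)
  expect_equal(li_sim("a1", "a1", tax), tanh(0.6 * 3), tolerance = 1e-12)
  # fixed subsumer depth, growing path length decreases the similarity
  expect_gt(li_sim("a", "a", tax), li_sim("a1", "a", tax))
  expect_gt(li_sim("a1", "a", tax), li_sim("a1", "a2", tax))
  # fixed path length, deeper subsumer increases it
  expect_gt(li_sim("a1", "a2", tax), li_sim("a", "b", tax))
  expect_error(li_sim("a1", "nope", tax), "nope")
})

test_that("lin_sim matches the IC oracle with the stated conventions", {
  tax <- toy_tax()
  for (c1 in tax$concepts) for (c2 in tax$concepts) {
    expect_equal(lin_sim(c1, c2, tax), oracle_lin(toy_edges, toy_freq, c1, c2),
                 tolerance = 1e-12)
    expect_equal(lin_sim(c1, c2, tax), lin_sim(c2, c1, tax))
  }
  expect_equal(lin_sim("a1", "a1", tax), 1)          # identity with IC > 0
  expect_equal(lin_sim("a1", "b2", tax), 0)          # root-only subsumer
  expect_equal(lin_sim("r", "r", tax), 1)            # IC-sum-zero convention
  expect_equal(lin_sim("r", "a", tax), 0)
})

test_that("hybrid_sim applies the configured combiner", {
  tax <- toy_tax()
  for (c1 in c("a1", "b1")) for (c2 in c("a2", "b2")) {
    li <- li_sim(c1, c2, tax); lin <- lin_sim(c1, c2, tax)
    expect_equal(hybrid_sim(c1, c2, tax, sim_params()), (li + lin) / 2)
    expect_equal(hybrid_sim(c1, c2, tax, sim_params(combiner = "product")), li * lin)
    expect_equal(hybrid_sim(c1, c2, tax, sim_params(combiner = "li_only")), li)
    expect_equal(hybrid_sim(c1, c2, tax, sim_params(combiner = "lin_only")), lin)
  }
})

test_that("sim_pp averages positionally aligned hybrid similarities", {
  tax <- toy_tax()
  pairs <- list(c("a1", "b1"), c("a2", "b2"), c("a1", "a2"))
  M <- outer(seq_along(pairs), seq_along(pairs), Vectorize(function(i, j) {
    sim_pp(pairs[[i]], pairs[[j]], tax)
  }))
  expect_equal(M, t(M))
  for (i in seq_along(pairs)) for (j in seq_along(pairs)) {
    expected <- (hybrid_sim(pairs[[i]][1], pairs[[j]][1], tax) +
                 hybrid_sim(pairs[[i]][2], pairs[[j]][2], tax)) / 2
    expect_equal(M[i, j], expected, tolerance = 1e-12)
  }
  # identical pair of deep concepts is 1 (both slots self-similar at 1 under
  # the information-content component and tanh saturation ignored by mean)
  expect_equal(sim_pp(c("a1", "a1"), c("a1", "a1"), tax,
                      sim_params(combiner = "lin_only")), 1)
  # unresolvable concepts fall back to string identity
  expect_equal(sim_pp(c("XX", "a1"), c("XX", "a1"), tax,
                      sim_params(combiner = "lin_only")), 1)
  # fallback slot contributes 0; the resolvable slot keeps its hybrid value
  expect_equal(sim_pp(c("XX", "a1"), c("YY", "b2"), tax),
               hybrid_sim("a1", "b2", tax) / 2, tolerance = 1e-12)
})

test_that("munkres matching equals the exhaustive permutation oracle", {
  expect_equal(munkres_max_matching(matrix(0.7, 1, 1))$total, 0.7)
  diag3 <- diag(c(3, 2, 1))
  res <- munkres_max_matching(diag3)
  expect_equal(res$total, 6)
  expect_equal(res$pairs[order(res$pairs[, 1]), "col"], c(1, 2, 3))
  empty <- munkres_max_matching(matrix(numeric(0), 0, 0))
  expect_equal(empty$total, 0)
  expect_error(munkres_max_matching(matrix(c(1, -1), 1, 2)), "nonnegative")

  set.seed(37)
  for (k in 1:100) {
    m <- sample(1:6, 1); n <- sample(1:6, 1)
    W <- matrix(round(stats::runif(m * n), 3), m, n)
    res <- munkres_max_matching(W)
    expect_equal(res$total, matching_oracle(W), tolerance = 1e-9)
    # one-to-one
    expect_false(anyDuplicated(res$pairs[, "row"]) > 0)
    expect_false(anyDuplicated(res$pairs[, "col"]) > 0)
    expect_equal(res$total, sum(W[res$pairs]), tolerance = 1e-12)
  }
})

test_that("sim_con normalizes the maximum matching by the larger context", {
  wtax <- toy_tax()
  expect_equal(sim_con(c("a1", "b1", "a2"), c("a1", "b1", "a2"), wtax), 1)
  expect_equal(sim_con(character(0), c("a1"), wtax), 0)
  expect_equal(sim_con(c("a1"), character(0), wtax), 0)
  # 3-vs-3 toy contexts against the permutation oracle
  ctxA <- c("a1", "a2", "zz")          # zz is out of vocabulary
  ctxB <- c("a1", "b1", "zz")
  W <- outer(ctxA, ctxB, Vectorize(function(x, y) word_sim(x, y, wtax)))
  expect_equal(sim_con(ctxA, ctxB, wtax), matching_oracle(W) / 3,
               tolerance = 1e-12)
  expect_equal(sim_con(ctxA, ctxB, wtax), sim_con(ctxB, ctxA, wtax))
  # unbalanced contexts: normalizer is the larger size
  expect_equal(sim_con(c("a1"), c("a1", "b1", "b2", "zz"), wtax),
               matching_oracle(outer(c("a1"), c("a1", "b1", "b2", "zz"),
                                     Vectorize(function(x, y) word_sim(x, y, wtax)))) / 4)
})

test_that("word_sim handles vocabulary and OOV cases", {
  wtax <- toy_tax()
  expect_equal(word_sim("a1", "a1", wtax), 1)
  expect_equal(word_sim("qq", "qq", wtax), 1)
  expect_equal(word_sim("qq", "zz", wtax), 0)
  expect_equal(word_sim("a1", "b2", wtax), lin_sim("a1", "b2", wtax))
})

test_that("k_sim mixes sim_pp and sim_con with boundary reductions", {
  tax <- gen_taxonomy(3, 2, seed = 23, prefix = "c")
  wtax <- gen_taxonomy(3, 3, seed = 24, prefix = "w")
  corpus <- gen_corpus(gen_config(n_instances = 12, seed = 23), tax, wtax)
  masked <- lapply(corpus, mask_proteins)
  x <- masked[[1]]; y <- masked[[2]]
  spp <- sim_pp(ppimkl:::pair_concepts(x), ppimkl:::pair_concepts(y), tax)
  scon <- sim_con(context_of(x), context_of(y), wtax)
  expect_equal(k_sim(x, y, tax, wtax, mix = 1), spp)
  expect_equal(k_sim(x, y, tax, wtax, mix = 0), scon)
  expect_equal(k_sim(x, y, tax, wtax, mix = 0.5), (spp + scon) / 2)
  expect_equal(k_sim(x, y, tax, wtax), k_sim(y, x, tax, wtax))

  # Gram assembly matches the scalar combination of the two parts
  G <- gram_sim(masked, tax, wtax, mix = 0.5)
  for (idx in list(c(1, 2), c(3, 7), c(5, 12))) {
    expect_equal(G$K[idx[1], idx[2]],
                 k_sim(masked[[idx[1]]], masked[[idx[2]]], tax, wtax),
                 tolerance = 1e-10)
  }
  expect_equal(max(abs(G$K - t(G$K))), 0)
  expect_true(all(G$K >= 0 & G$K <= 1))
})
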