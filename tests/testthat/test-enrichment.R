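test_that("hypergeometric tail matches exhaustive draw enumeration on small universes", {
  # literal enumeration of every C(N, n) draw
  cases <- list(c(2, 5, 4, 20), c(0, 5, 4, 20), c(3, 3, 3, 10),
                c(1, 6, 2, 12), c(4, 4, 6, 11))
  for (cs in cases) {
    expect_equal(hypergeom_upper_tail(cs[1], cs[2], cs[3], cs[4]),
                 hyper_tail_enum(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  expect_equal(hypergeom_upper_tail(2, 5, 4, 20), 0.24871, tolerance = 1e-5)
  # maximal overlap equals the point mass of min(n, K)
  expect_equal(hypergeom_upper_tail(3, 3, 5, 10), hyper_tail_enum(3, 3, 5, 10),
               tolerance = 1e-12)
  # k = 0 covers the whole support
  expect_identical(hypergeom_upper_tail(0, 7, 3, 15), 1)
  expect_error(hypergeom_upper_tail(5, 3, 4, 10), class = "lnctrans_invalid_input")
})

test_that("the hypergeometric pmf sums to one over its support", {
  set.seed(99)
  for (i in 1:200) {
    N <- sample(5:200, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    support <- max(0, n + K - N):min(n, K)
    pmf <- sum(choose(K, support) * choose(N - K, n - support)) / choose(N, n)
    expect_equal(pmf, 1, tolerance = 1e-12)
    # and our tail at the support minimum is exactly 1
    expect_equal(hypergeom_upper_tail(max(0, n + K - N), K, n, N), 1,
                 tolerance = 1e-12)
  }
})

test_that("fold enrichment is the (k/n)/(K/N) ratio", {
  expect_equal(fold_enrichment(1, 5, 4, 20), 1)     # k/n == K/N
  expect_equal(fold_enrichment(2, 5, 4, 20), 2)
  expect_equal(fold_enrichment(6, 10, 6, 10), 1)    # saturated
  expect_equal(fold_enrichment(0, 5, 4, 20), 0)
  expect_error(fold_enrichment(0, 0, 4, 20), class = "lnctrans_invalid_input")
})

test_that("a perfectly overlapping set dominates the enrichment ranking", {
  gs <- tiny_collection()
  res <- enrich(c("E", "F", "G", "H"), gs)
  expect_equal(res$set_id[1], "S3")
  expect_equal(res$k[res$set_id == "S3"], 4L)
  expect_true(res$p_value[1] == min(res$p_value))
  expect_true(res$significant[1])
  expect_error(enrich("ZZZ", gs), class = "lnctrans_empty_query")
})

test_that("BH q-values are order-invariant and universe pruning only acts through N", {
  gs <- tiny_collection()
  res <- enrich(c("A", "C", "E"), gs)
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  # dropping a universe gene outside query and sets changes p only through N
  gs2 <- gene_set_collection(gs$sets, universe = setdiff(gs$universe, "L"))
  res2 <- enrich(c("A", "C", "E"), gs2)
  for (sid in res$set_id) {
    a <- res[res$set_id == sid, ]
    b <- res2[res2$set_id == sid, ]
    expect_equal(b$p_value,
                 hyper_tail_direct(b$k, b$K, b$n, b$N), tolerance = 1e-12)
    expect_equal(a$k, b$k)
    expect_equal(a$N - 1L, b$N)
  }
})

test_that("null queries attain their exact discrete type-I rate", {
  # hypergeometric p-values are discrete, so the attained level at p < 0.05 is
  # P(p < 0.05) under the null, not 0.05 itself; compare the simulated rate to
  # that exact level within a binomial 99% band.
  universe <- sprintf("U%03d", 1:500)
  gs <- gene_set_collection(list(S1 = universe[1:50], S2 = universe[51:80]),
                            universe = universe)
  n_query <- 20
  alpha_star <- vapply(gs$sets, function(s) {
    K <- length(s)
    ks <- 0:min(n_query, K)
    tails <- vapply(ks, hyper_tail_direct, numeric(1), K = K, n = n_query, N = 500)
    pmf <- choose(K, ks) * choose(500 - K, n_query - ks) / choose(500, n_query)
    sum(pmf[tails < 0.05])
  }, numeric(1))
  set.seed(2024)
  hits <- c(S1 = 0, S2 = 0)
  n_sim <- 200
  for (i in 1:n_sim) {
    res <- enrich(sample(universe, n_query), gs)
    hits <- hits + (res$p_value[match(names(hits), res$set_id)] < 0.05)
  }
  for (sid in names(hits)) {
    band <- 2.576 * sqrt(alpha_star[sid] * (1 - alpha_star[sid]) / n_sim)
    expect_lt(abs(hits[[sid]] / n_sim - alpha_star[[sid]]), band + 1e-9)
  }
})

test_that("lncRNA annotation is enrichment of its co-expressed set", {
  gs <- tiny_collection()
  edges <- data.frame(lncrna_id = c("L1", "L1", "L1", "L2"),
                      mrna_id = c("E", "F", "G", "Q"),
                      r = c(0.9, 0.8, 0.85, 0.95),
                      p_value = c(0.01, 0.02, 0.015, 0.001), n = 6)
  ann <- annotate_lncrna("L1", edges, gs)
  expect_equal(ann$set_id[1], "S3")
  expect_true(ann$significant[1])
  # lncRNA with no edges: empty annotation with a message
  expect_message(none <- annotate_lncrna("L9", edges, gs), "no co-expressed")
  expect_equal(nrow(none), 0)
  # a single co-expressed gene outside all sets cannot be significant
  gs_plus <- gene_set_collection(gs$sets, universe = c(gs$universe, "Q"))
  lonely <- annotate_lncrna("L2", edges, gs_plus)
  expect_false(any(lonely$significant))
})

test_that("planted lncRNAs are annotated with their TF's regulon across seeds", {
  hits <- 0
  for (s in 1:20) {
    ds <- generate_dataset(recovery_config(seed = 700 + s))
    edges <- coexpression_pairs(ds$lncrna, ds$mrna)
    ann <- annotate_lncrna("LNC001", edges, ds$regulons,
                           universe = rownames(ds$mrna$values))
    row <- ann[ann$set_id == "TF01", ]
    if (nrow(row) == 1 && row$significant) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of 20 seeds
})
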