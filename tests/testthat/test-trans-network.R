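make_edges <- function(lnc, mrnas, r = 0.9, p = 0.01) {
  data.frame(lncrna_id = lnc, mrna_id = mrnas, r = r, p_value = p, n = 6)
}

test_that("a lncRNA matching one regulon ranks that TF first", {
  universe <- sprintf("g%02d", 1:20)
  regs <- gene_set_collection(list(TF1 = universe[1:5], TF2 = universe[6:10]),
                              universe = universe)
  edges <- make_edges("L1", universe[1:5])
  pairs <- score_pairs(edges, regs, universe)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$tf_id[1], "TF1")
  expect_lt(pairs$p_value[1], pairs$p_value[2])
  # hypergeometric counts as documented
  expect_equal(pairs$k[1], 5L)
  expect_equal(pairs$n[1], 5L)
  expect_equal(pairs$K[1], 5L)
  expect_equal(pairs$N[1], 20L)
})

test_that("pair p-values equal the enumeration oracle on a 20-gene universe", {
  universe <- sprintf("g%02d", 1:20)
  regs <- gene_set_collection(list(TF1 = universe[1:6], TF2 = universe[5:12]),
                              universe = universe)
  edges <- rbind(make_edges("L1", universe[c(1, 2, 7, 13)]),
                 make_edges("L2", universe[c(5, 6, 8)]))
  pairs <- score_pairs(edges, regs, universe)
  for (i in seq_len(nrow(pairs))) {
    expect_equal(pairs$p_value[i],
                 hyper_tail_enum(pairs$k[i], pairs$K[i], pairs$n[i], pairs$N[i]),
                 tolerance = 1e-12)
  }
  # a lncRNA with no co-expressed genes contributes no pairs
  expect_false("L3" %in% score_pairs(rbind(edges), regs, universe)$lncrna_id)
  expect_error(score_pairs(edges, regs, character(0)),
               class = "lnctrans_invalid_input")
})

test_that("tier selection is a deterministic head of the full ranking", {
  set.seed(6)
  n <- 150
  pairs <- data.frame(
    lncrna_id = sprintf("L%03d", sample(n)), tf_id = sprintf("T%03d", sample(n)),
    k = 1L, n = 10L, K = 10L, N = 100L,
    p_value = runif(n), fold_enrichment = runif(n, 0, 5)
  )
  tiers <- select_pairs(pairs)
  expect_equal(nrow(tiers$pair_tier), 100)
  expect_equal(nrow(tiers$triad_tier), 10)
  full_sort <- pairs[order(pairs$p_value, -pairs$fold_enrichment,
                           pairs$lncrna_id, pairs$tf_id, method = "radix"), ]
  expect_equal(tiers$pair_tier$p_value, head(full_sort$p_value, 100))
  expect_identical(tiers$triad_tier$lncrna_id, head(full_sort$lncrna_id, 10))

  # fewer pairs than the limits: both tiers keep everything
  tiers_small <- select_pairs(head(pairs, 5))
  expect_equal(nrow(tiers_small$pair_tier), 5)
  expect_equal(nrow(tiers_small$triad_tier), 5)

  # exact ties break lexicographically and reproducibly
  tied <- data.frame(lncrna_id = c("LB", "LA"), tf_id = c("T1", "T1"),
                     k = 1L, n = 5L, K = 5L, N = 50L,
                     p_value = 0.2, fold_enrichment = 2)
  expect_equal(select_pairs(tied)$pair_tier$lncrna_id, c("LA", "LB"))
})

test_that("triads are the regulon/co-expression intersection, optionally DE-filtered", {
  universe <- sprintf("g%02d", 1:20)
  regs <- gene_set_collection(list(TF1 = universe[1:6]), universe = universe)
  edges <- make_edges("L1", universe[c(1, 2, 3, 10)])
  pairs <- score_pairs(edges, regs, universe)
  triads <- build_triads(pairs, edges, regs)
  expect_setequal(triads$target_id, universe[1:3])
  expect_true(all(triads$pair_p == pairs$p_value[1]))
  # triad targets never exceed the pair overlap k
  expect_lte(nrow(triads), pairs$k[1])

  filtered <- build_triads(pairs, edges, regs, de_mrnas = universe[2])
  expect_identical(filtered$target_id, universe[2])
  expect_message(dropped <- build_triads(pairs, edges, regs, de_mrnas = "none"),
                 "dropped")
  expect_equal(nrow(dropped), 0)
  expect_error(build_triads(data.frame(lncrna_id = "L1", tf_id = "NOPE",
                                       p_value = 0.1),
                            edges, regs),
               class = "lnctrans_invalid_input")
})

test_that("network assembly emits 1 + t + t edges per triad and dedups nodes", {
  triads <- data.frame(lncrna_id = "L1", tf_id = "TF1",
                       target_id = c("G1", "G2", "G3"),
                       r = c(0.9, -0.8, 0.85), pair_p = 0.001)
  net <- assemble_network(triads)
  expect_equal(nrow(net$edges), 7)  # 1 lncRNA-TF + 3 regulates + 3 lncRNA-target
  expect_equal(sum(net$edges$interaction == "regulates"), 3)
  expect_equal(nrow(net$nodes), 5)

  # two triads sharing a TF emit the TF node once
  triads2 <- rbind(triads,
                   data.frame(lncrna_id = "L2", tf_id = "TF1", target_id = "G4",
                              r = 0.75, pair_p = 0.002))
  net2 <- assemble_network(triads2)
  expect_equal(sum(net2$nodes$id == "TF1"), 1)

  # a gene that is both TF and target keeps type TF
  triads3 <- rbind(triads,
                   data.frame(lncrna_id = "L1", tf_id = "G1", target_id = "G9",
                              r = 0.7, pair_p = 0.003))
  expect_message(net3 <- assemble_network(triads3), "both TF and target")
  expect_equal(net3$nodes$type[net3$nodes$id == "G1"], "TF")

  empty <- assemble_network(triads[0, ])
  expect_equal(nrow(empty$nodes), 0)
  expect_equal(nrow(empty$edges), 0)
})

test_that("the audit traces every exported edge to its evidence", {
  universe <- sprintf("g%02d", 1:20)
  regs <- gene_set_collection(list(TF1 = universe[1:6]), universe = universe)
  edges <- make_edges("L1", universe[1:3])
  pairs <- score_pairs(edges, regs, universe)
  triads <- build_triads(pairs, edges, regs)
  net <- assemble_network(triads)
  expect_true(audit_network(net, edges, regs))

  forged <- net
  forged$nodes <- rbind(forged$nodes, data.frame(id = "gX", type = "target"))
  forged$edges <- rbind(forged$edges,
                        data.frame(source = "TF1", target = "gX",
                                   interaction = "regulates", score = NA_real_))
  expect_error(audit_network(forged, edges, regs),
               class = "lnctrans_audit_failure")
})
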