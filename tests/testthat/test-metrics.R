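# Confusion matrix, target ranking, significant counts, specificity profiles.

# build an enrichment_result directly from (term, p_raw, p_adj) triples
result_from <- function(term_id, p_raw, p_adj = p_raw, label = "t") {
  enrichment_result(data.frame(term_id = term_id, p_raw = p_raw,
                               p_adj = p_adj, stringsAsFactors = FALSE),
                    label = label)
}

test_that("count_significant uses a strict threshold", {
  r <- result_from(paste0("T", 1:5), c(0.001, 0.01, 0.02, 0.1, 0.9),
                   c(0.01, 0.04, 0.05, 0.2, 1.0))
  expect_equal(count_significant(r), 2L)   # 0.05 is NOT significant
  expect_equal(count_significant(r, use_adjusted = FALSE), 3L)
  expect_equal(count_significant(result_from(character(0), numeric(0))), 0L)
  expect_equal(count_significant(result_from("T1", 1, 1)), 0L)
})

test_that("the two-chain example spans all five confusion classes", {
  g <- two_chain_graph()
  tg <- "A4"
  # hand-derived Wang similarities to the target A4
  expect_equal(wang_similarity(g, "A3", "A4"), 5.3136 / 6.3136,
               tolerance = 1e-12)                          # ~0.842, high
  expect_equal(wang_similarity(g, "A2", "A4"), 4.0016 / 5.8016,
               tolerance = 1e-12)                          # ~0.690, mid
  expect_equal(wang_similarity(g, "A1", "A4"), 2.7216 / 5.1616,
               tolerance = 1e-12)                          # ~0.527, mid
  expect_equal(wang_similarity(g, "B3", "A4"), 0.9216 / 6.3136,
               tolerance = 1e-12)                          # ~0.146, low
  sig <- 0.01; ns <- 0.5
  r <- result_from(c("A4", "A3", "B4", "B3", "A1", "A2"),
                   c(sig,  ns,   sig,  ns,   sig,  ns))
  cm <- confusion_matrix(r, tg, g)
  expect_equal(cm$tp, 1L)   # A4: sim 1, significant
  expect_equal(cm$fn, 1L)   # A3: sim >= 0.7, not significant
  expect_equal(cm$fp, 1L)   # B4: sim < 0.3, significant
  expect_equal(cm$tn, 1L)   # B3: sim < 0.3, not significant
  expect_equal(cm$n_excluded_mid_ss, 2L)   # A1, A2 in [0.3, 0.7)
  expect_equal(cm$accuracy, 0.5)
  expect_equal(cm$fpr, 0.5)
})

test_that("degenerate confusion matrices use explicit undefined markers", {
  g <- two_chain_graph()
  # result = exactly the targets, all significant
  r <- result_from(c("A4", "B4"), c(0.001, 0.002))
  cm <- confusion_matrix(r, c("A4", "B4"), g)
  expect_equal(cm$tp, 2L)
  expect_equal(cm$fp + cm$fn + cm$tn, 0L)
  expect_equal(cm$accuracy, 1)
  expect_true(is.na(cm$fpr))
  # unrelated branch only, none significant
  r2 <- result_from(c("B3", "B4"), c(0.5, 0.6))
  cm2 <- confusion_matrix(r2, "A4", g)
  expect_equal(cm2$tn, 2L)
  expect_equal(cm2$accuracy, 1)
  expect_equal(cm2$fpr, 0)
  expect_error(confusion_matrix(r2, character(), g), "empty target")
})

test_that("widening the exclusion band never adds classified records", {
  s <- synth_fixture()
  tg <- pick_branch_targets(s$graph, s$annset)
  b <- make_target_lists(s$annset, s$graph, tg, sizes = 50, seed = 5)
  r <- run_ora(b$gene_lists[[1]], s$annset, s$graph)
  base <- confusion_matrix(r, tg, s$graph)
  tighter <- confusion_matrix(r, tg, s$graph, hi = 0.8, lo = 0.2)
  n_base <- base$tp + base$fn + base$fp + base$tn
  n_tight <- tighter$tp + tighter$fn + tighter$fp + tighter$tn
  expect_lte(n_tight, n_base)
  expect_equal(n_tight + tighter$n_excluded_mid_ss,
               n_base + base$n_excluded_mid_ss)
})

test_that("target ranks and medians follow the even-count rule", {
  terms <- sprintf("T%02d", 1:20)
  p <- seq(0.001, 0.02, length.out = 20)
  r <- result_from(terms, p)
  tr <- target_report(r, c("T02", "T05", "T09"), alpha = 0.05)
  expect_equal(tr$n_identified, 3L)
  expect_equal(tr$median_rank, 5)
  tr4 <- target_report(r, c("T01", "T04", "T08", "T20"))
  expect_equal(tr4$median_rank, 6.0)   # mean of 4 and 8
  # nothing significant -> undefined marker
  r_ns <- result_from(terms, rep(0.9, 20))
  tr0 <- target_report(r_ns, c("T01", "T02"))
  expect_equal(tr0$n_identified, 0L)
  expect_true(is.na(tr0$median_rank))
})

test_that("ranks ignore appended worse records and support rank-within-significant", {
  terms <- sprintf("T%02d", 1:10)
  r <- result_from(terms, seq(0.001, 0.01, length.out = 10))
  tr <- target_report(r, c("T03", "T07"))
  r_more <- result_from(c(terms, "X1", "X2"),
                        c(seq(0.001, 0.01, length.out = 10), 0.6, 0.7))
  tr_more <- target_report(r_more, c("T03", "T07"))
  expect_equal(tr_more$ranks, tr$ranks)
  # rank within significant records only
  r_mix <- result_from(c("A", "B", "C"), c(0.001, 0.2, 0.01),
                       c(0.003, 0.6, 0.03))
  tr_sig <- target_report(r_mix, "C", rank_within = "significant")
  expect_equal(unname(tr_sig$ranks["C"]), 2)
  tr_all <- target_report(r_mix, "C")
  expect_equal(unname(tr_all$ranks["C"]), 2)  # same here: B not significant
})

test_that("specificity profiles take the top significant records in order", {
  s <- synth_fixture()
  g <- s$graph; a <- s$annset
  tg <- pick_branch_targets(g, a)
  b <- make_target_lists(a, g, tg, sizes = 50, seed = 5)
  r <- run_ora(b$gene_lists[[1]], a, g)
  sp20 <- specificity_profile(r, a, g, k = 20)
  # independent sort-and-slice recomputation
  sig <- r[r$p_adj < 0.05, ]
  sig <- sig[order(sig$p_adj, sig$p_raw, sig$term_id), ]
  top <- utils::head(sig, 20)
  sizes <- vapply(top$term_id, function(t) annotation_size(a, t), integer(1))
  depths <- term_depth(g, top$term_id)
  expect_equal(sp20$n_used, nrow(top))
  expect_equal(sp20$median_annotation_size, stats::median(sizes))
  expect_equal(sp20$mean_annotation_size, mean(sizes))
  expect_equal(sp20$median_depth, stats::median(depths))
  expect_equal(sp20$mean_depth, mean(depths))
  # k = 100 profile covers a superset of the k = 20 records
  sp100 <- specificity_profile(r, a, g, k = 100)
  expect_gte(sp100$n_used, sp20$n_used)
  # zero significant records -> empty-profile marker
  r0 <- result_from("T1", 0.9)
  r0$term_id <- g$terms$term_id[1]
  sp0 <- specificity_profile(r0, a, g, k = 20)
  expect_equal(sp0$n_used, 0L)
  expect_true(is.na(sp0$median_depth))
})

test_that("profile medians and means reduce correctly on tiny examples", {
  g <- ontology_graph(make_terms(c("R", "A", "B", "C")),
                      make_edges(c("A", "R"), c("B", "A"), c("C", "B")))
  a <- annotation_set(data.frame(gene_id = c("g1", "g2", "g3"),
                                 term_id = c("C", "C", "B")), g)
  r <- result_from(c("A", "B", "C"), c(0.001, 0.002, 0.003))
  sp <- specificity_profile(r, a, g, k = 3)
  expect_equal(sp$median_depth, 2)         # depths 1, 2, 3
  expect_equal(sp$mean_depth, 2)
  expect_equal(sp$median_annotation_size, 3)  # sizes A=3, B=3, C=2
  expect_equal(sp$mean_annotation_size, mean(c(3, 3, 2)))
})

test_that("evaluate_results assembles one row per result", {
  s <- synth_fixture()
  tg <- pick_branch_targets(s$graph, s$annset)
  b <- make_target_lists(s$annset, s$graph, tg, sizes = 50, seed = 5)
  r <- run_ora(b$gene_lists[[1]], s$annset, s$graph)
  df <- evaluate_results(list(planted = r), tg, s$annset, s$graph)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("n_significant", "accuracy", "fpr", "median_rank",
                    "median_size_top20", "mean_depth_top100") %in% names(df)))
  df2 <- evaluate_results(list(planted = r), NULL, s$annset, s$graph)
  expect_false("accuracy" %in% names(df2))
  expect_true("median_size_top20" %in% names(df2))
})
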