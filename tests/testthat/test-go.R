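chain_obo <- function() {
  c("format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: biological_process", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: biological_process", "is_a: GO:0000002 ! mid", "",
    "[Term]", "id: GO:0000009", "name: gone", "is_obsolete: true", "")
}

test_that("OBO parsing builds levels, drops obsoletes and closes
          ancestors", {
  tf <- withr::local_tempfile(lines = chain_obo(), fileext = ".obo")
  g <- load_obo(tf)
  expect_equal(nrow(g$terms), 3)
  expect_false("GO:0000009" %in% g$terms$id)
  lv <- stats::setNames(g$terms$level, g$terms$id)
  expect_equal(lv[["GO:0000001"]], 0L)
  expect_equal(lv[["GO:0000002"]], 1L)
  expect_equal(lv[["GO:0000003"]], 2L)
  expect_setequal(go_ancestors(g, "GO:0000003"),
                  c("GO:0000002", "GO:0000001"))
  # ancestors equal the brute-force edge closure on the toy DAG
  cfg <- simulation_config(seed = 71, length = 10000L)
  feats <- simulate_features(cfg)
  gg <- feats$graph
  closure <- function(id) {
    seen <- character(0); frontier <- id
    repeat {
      nxt <- setdiff(unique(unlist(gg$parents[frontier])), seen)
      if (!length(nxt)) return(seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
  }
  for (id in sample(gg$terms$id, 10))
    expect_setequal(go_ancestors(gg, id), closure(id))
  # cycles are refused
  cyc <- c("[Term]", "id: GO:1", "is_a: GO:2", "",
           "[Term]", "id: GO:2", "is_a: GO:1", "")
  tf2 <- withr::local_tempfile(lines = cyc, fileext = ".obo")
  expect_error(load_obo(tf2), "cycle")
})

test_that("annotation propagation follows the true-path rule", {
  tf <- withr::local_tempfile(lines = chain_obo(), fileext = ".obo")
  g <- load_obo(tf)
  ann <- list(g1 = "GO:0000003", g2 = "GO:0000002", g3 = "GO:0000001")
  tg <- propagate_annotation(g, ann)
  expect_setequal(tg[["GO:0000003"]], "g1")
  expect_setequal(tg[["GO:0000002"]], c("g1", "g2"))
  expect_setequal(tg[["GO:0000001"]], c("g1", "g2", "g3"))
  # restriction to a universe subset
  tg2 <- propagate_annotation(g, ann, genes = c("g1", "g3"))
  expect_setequal(tg2[["GO:0000001"]], c("g1", "g3"))
})

test_that("the BUSCO universe filter equals its boolean oracle", {
  summ <- data.frame(
    busco_id = sprintf("b%02d", 1:8),
    status = c(rep("Complete", 6), "Fragmented", "Missing"),
    snp_density = c(0.02, 0.005, 0.02, 0.02, NA, 0.01, 0.05, 0.05),
    mean_depth_f1 = c(3, 3, 1.9, 3, 3, 2, 3, 3),
    mean_depth_f2 = c(3, 3, 3, 1.0, 3, 2, 3, 3))
  u <- build_universe(summ)
  expect_setequal(u, c("b01", "b06"))  # b06: thresholds are inclusive
  oracle <- with(summ, status == "Complete" & !is.na(snp_density) &
                 snp_density >= 0.01 & mean_depth_f1 >= 2 &
                 mean_depth_f2 >= 2)
  expect_setequal(u, summ$busco_id[oracle])
})

test_that("top-percentile study sets follow the quantile convention", {
  summ <- data.frame(busco_id = sprintf("b%03d", 1:100),
                     status = "Complete", mean_rs = seq(0.01, 1, 0.01))
  u <- summ$busco_id
  top <- select_top_set(summ, u, "rs", 99)
  expect_true(length(top) %in% 1:2)        # type-7 on 100 distinct values
  expect_true("b100" %in% top)
  # degenerate ties: everything at the threshold qualifies
  summ$mean_rs <- 0.5
  expect_setequal(select_top_set(summ, u, "rs", 99), u)
  # a BUSCO may sit in both top sets
  summ$mean_rs <- seq(0.01, 1, 0.01)
  summ$mean_fst <- seq(0.01, 1, 0.01)
  expect_true(all(select_top_set(summ, u, "rs", 99) %in%
                  select_top_set(summ, u, "fst", 99)))
})

test_that("without eliminations the test is the classic hypergeometric", {
  tf <- withr::local_tempfile(lines = chain_obo(), fileext = ".obo")
  g <- load_obo(tf)
  genes <- sprintf("g%02d", 1:20)
  ann <- c(stats::setNames(as.list(rep("GO:0000003", 5)), genes[1:5]),
           stats::setNames(as.list(rep("GO:0000002", 5)), genes[6:10]),
           stats::setNames(as.list(rep("GO:0000001", 10)), genes[11:20]))
  study <- genes[1:5]
  res <- elim_fisher(g, ann, study, genes, min_node_size = 5,
                     elim_alpha = 0)
  # worked closed form: all 5 of the term's genes in a study of 5 from 20
  expect_equal(res$p[res$term == "GO:0000003"], 1 / choose(20, 5),
               tolerance = 1e-7 / 6.45e-5)
  # every term equals a direct phyper computation
  tg <- propagate_annotation(g, ann, genes)
  for (i in seq_len(nrow(res))) {
    K <- length(tg[[res$term[i]]])
    k <- length(intersect(tg[[res$term[i]]], study))
    expect_equal(res$p[i],
                 stats::phyper(k - 1, K, 20 - K, 5, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # a term annotating the whole universe cannot be enriched
  expect_equal(res$p[res$term == "GO:0000001"], 1)
  expect_error(elim_fisher(g, ann, c(study, "zz"), genes),
               "configuration error")
})

test_that("elimination reproduces the hand-traced three-term example", {
  # leaf annotates g1..g6; mid adds g7..g10; root covers all 20.
  # study = g1..g6. Hand trace: leaf p = 1/C(20,6) < 0.01 eliminates its
  # genes from mid and root; mid then has 4 effective genes, 0 in study,
  # p = 1; root p = 1. Without elim, mid p = C(10,6)/C(20,6).
  tf <- withr::local_tempfile(lines = chain_obo(), fileext = ".obo")
  g <- load_obo(tf)
  genes <- sprintf("g%02d", 1:20)
  ann <- c(stats::setNames(as.list(rep("GO:0000003", 6)), genes[1:6]),
           stats::setNames(as.list(rep("GO:0000002", 4)), genes[7:10]),
           stats::setNames(as.list(rep("GO:0000001", 10)), genes[11:20]))
  study <- genes[1:6]
  res <- elim_fisher(g, ann, study, genes, min_node_size = 4,
                     elim_alpha = 0.01)
  expect_equal(res$p[res$term == "GO:0000003"], 1 / choose(20, 6),
               tolerance = 1e-12)
  expect_equal(res$eliminated[res$term == "GO:0000002"], 6)
  expect_equal(res$p[res$term == "GO:0000002"], 1, tolerance = 1e-12)
  expect_equal(res$p[res$term == "GO:0000001"], 1, tolerance = 1e-12)
  classic <- elim_fisher(g, ann, study, genes, min_node_size = 4,
                         elim_alpha = 0)
  expect_equal(classic$p[classic$term == "GO:0000002"],
               choose(10, 6) / choose(20, 6), tolerance = 1e-12)
  # elim never increases the annotated count
  expect_true(all(res$annotated == classic$annotated))
  # min_node_size prunes small terms
  small <- elim_fisher(g, ann, study, genes, min_node_size = 7)
  expect_false("GO:0000003" %in% small$term)
})

test_that("top-k reporting ranks by p, study count, then id", {
  res <- data.frame(term = c("GO:3", "GO:2", "GO:1", "GO:4"),
                    name = "x", annotated = c(10, 10, 10, 5),
                    significant = c(2, 5, 5, 1),
                    p = c(0.5, 0.01, 0.01, 0.2), eliminated = 0,
                    members = "")
  top <- report_top(res, k = 10)
  expect_equal(top$term, c("GO:1", "GO:2", "GO:4", "GO:3"))
  expect_equal(nrow(report_top(res, k = 2)), 2)
})
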