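test_that("hit loading handles the TSV dialect, PSL arithmetic and
          min_block", {
  tsv <- c("query\tqstart\tqend\ttarget\ttstart\ttend\tstrand",
           "q1\t0\t4000\tT1\t100\t4100\t+",
           "q1\t5000\t6000\tT2\t0\t1000\t-")
  tf <- withr::local_tempfile(lines = tsv, fileext = ".tsv")
  h <- load_hits(tf)
  expect_equal(nrow(h), 2)
  expect_equal(h$length, c(4000L, 1000L))
  expect_equal(nrow(load_hits(tf, min_block = 2000)), 1)
  # PSL: 21 columns; aligned length = matches + mismatches + repmatches
  psl <- paste(c(950, 40, 10, 0, 0, 0, 0, 0, "+", "q1", 2000, 100, 1100,
                 "T1", 50000, 30000, 31000, 1, 1000, 100, 30000),
               collapse = "\t")
  tf2 <- withr::local_tempfile(lines = psl, fileext = ".psl")
  hp <- load_hits(tf2)
  expect_equal(hp$qstart, 100L)
  expect_equal(hp$qend, 1100L)
  expect_equal(hp$tstart, 30000L)
  expect_equal(hp$length, 1000L)
  expect_equal(hp$strand, "+")
  # empty file -> empty list
  tf3 <- withr::local_tempfile(lines = "query\tqstart\tqend\ttarget\ttstart\ttend\tstrand")
  expect_equal(nrow(load_hits(tf3)), 0)
  tf4 <- withr::local_tempfile(lines = "a\tb")
  expect_error(load_hits(tf4), "format error")
})

test_that("primary-target assignment applies the coverage-share rules", {
  qlen <- c(q1 = 10000L, q2 = 10000L, q3 = 10000L)
  hits <- data.frame(
    query = c("q1", "q1", "q1", "q2", "q3", "q3"),
    qstart = c(0L, 2000L, 5000L, 0L, 0L, 5000L),
    qend = c(3000L, 4000L, 6000L, 3000L, 4000L, 9000L),
    target = c("T1", "T1", "T2", "T1", "T1", "T2"),
    tstart = 0L, tend = 1L, strand = "+",
    length = c(3000L, 2000L, 1000L, 3000L, 4000L, 4000L))
  asn <- assign_primary_targets(hits, qlen)
  # q1: union on T1 = [0,4000) = 0.40 > 0.33 and > 0.10 on T2 -> anchored
  expect_equal(asn$decision[asn$query == "q1"], "anchored")
  expect_equal(asn$target[asn$query == "q1"], "T1")
  expect_equal(asn$covered_frac[asn$query == "q1"], 0.40)
  # q2: 30% best coverage -> unassigned
  expect_equal(asn$decision[asn$query == "q2"], "unassigned")
  # q3: exact tie between targets -> unassigned
  expect_equal(asn$decision[asn$query == "q3"], "unassigned")
  # overlapping hits are not double-counted
  over <- data.frame(query = "q1", qstart = c(0L, 1000L),
                     qend = c(3000L, 3500L), target = "T1", tstart = 0L,
                     tend = 1L, strand = "+", length = c(3000L, 2500L))
  a2 <- assign_primary_targets(over, qlen["q1"])
  expect_equal(a2$covered_frac, 0.35)
  # only the top_k longest queries are considered
  a3 <- assign_primary_targets(hits, qlen, top_k = 1)
  expect_equal(nrow(a3), 1)
})

test_that("plans order by weighted target position and majority strand", {
  qlen <- c(qa = 1000L, qb = 1000L, qc = 500L)
  hits <- data.frame(
    query = c("qa", "qb", "qb", "qc"),
    qstart = c(0L, 0L, 500L, 0L),
    qend = c(900L, 450L, 950L, 400L),
    target = "T", tstart = c(5000000L, 900000L, 1100000L, 2000000L),
    tend = c(5000900L, 900450L, 1100450L, 2000400L),
    strand = c("+", "-", "-", "+"),
    length = c(900L, 450L, 450L, 400L))
  asn <- assign_primary_targets(hits, qlen, min_frac = 0.33)
  plan <- build_anchor_plan(asn, hits, qlen)
  g <- plan$groups$T
  expect_equal(g$query, c("qb", "qc", "qa"))  # ~1.0 Mb < 2.0 Mb < 5.0 Mb
  expect_equal(g$orientation, c("-", "+", "+"))
  expect_equal(plan$unplaced, character(0))
})

test_that("emission writes exact gaps, a valid AGP and a faithful
          liftover", {
  seqs <- Biostrings::DNAStringSet(c(s1 = strrep("ACGT", 250),
                                     s2 = strrep("GGCC", 250),
                                     lone = "ACGTACGTAA"))
  plan <- structure(list(
    groups = list(T1 = data.frame(query = c("s1", "s2"),
                                  orientation = c("+", "-"),
                                  position = c(1, 2))),
    unplaced = "lone", gap_size = 100L), class = "anchor_plan")
  agp <- withr::local_tempfile(fileext = ".agp")
  fa <- withr::local_tempfile(fileext = ".fa")
  lift <- withr::local_tempfile(fileext = ".tsv")
  mega <- emit_anchor_plan(plan, seqs, agp, fa, lift)
  # 2 x 1000 bp + one 100 bp gap
  expect_equal(length(mega[["mscaf_T1"]]), 2100L)
  s <- as.character(mega[["mscaf_T1"]])
  runs <- rle(strsplit(s, "")[[1]] == "N")
  expect_equal(runs$lengths[runs$values], 100L)
  # single-scaffold objects get no gap rows
  agp_lines <- readLines(agp)
  lone_rows <- grep("^lone", agp_lines, value = TRUE)
  expect_length(lone_rows, 1)
  expect_false(grepl("\tU\t", lone_rows))
  # independent AGP -> FASTA reconstruction is byte-identical
  rec <- reconstruct_from_agp(agp, seqs)
  written <- Biostrings::readDNAStringSet(fa)
  for (nm in names(written))
    expect_identical(rec[[nm]], as.character(written[[nm]]))
  # liftover maps old coordinates onto the mega-scaffold
  lf <- utils::read.table(lift, sep = "\t", comment.char = "#")
  s2row <- lf[lf$V1 == "s2", ]
  expect_equal(s2row$V5, 1100)  # after s1 (1000) + gap (100)
  expect_equal(s2row$V7, "-")
  expect_error(emit_anchor_plan(plan, seqs[1:2], agp), "lone")
})

test_that("a shattered genome is reassembled exactly", {
  set.seed(81)
  genome <- c(chrZ = paste(sample(c("A", "C", "G", "T"), 60000,
                                  replace = TRUE), collapse = ""))
  fr <- fragment_assembly(genome, 30, seed = 6)
  expect_length(fr$fragments, 30)
  # determinism
  fr2 <- fragment_assembly(genome, 30, seed = 6)
  expect_identical(as.character(fr$fragments), as.character(fr2$fragments))
  asn <- assign_primary_targets(fr$hits, fr$query_lengths)
  plan <- build_anchor_plan(asn, fr$hits, fr$query_lengths)
  ord <- plan$groups$chrZ
  tru <- fr$truth[order(fr$truth$order_index), ]
  expect_equal(ord$query, tru$query)
  expect_equal(ord$orientation, tru$strand)
  mega <- emit_anchor_plan(plan, fr$fragments)
  expect_identical(gsub("N", "", as.character(mega[[1]])), genome[["chrZ"]])
  # base multiset conservation (reverse-complement aware by construction)
  expect_identical(sort(table(strsplit(gsub("N", "",
                                            as.character(mega[[1]])),
                                       "")[[1]])),
                   sort(table(strsplit(genome[["chrZ"]], "")[[1]])))
})
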