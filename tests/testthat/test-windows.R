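test_that("window tiling follows the width/step arithmetic", {
  w <- make_windows(c(chr = 100000L), 50000L, 25000L)
  expect_equal(w$start, c(0L, 25000L, 50000L, 75000L))
  expect_equal(w$end, c(50000L, 75000L, 100000L, 100000L))
  expect_equal(w$truncated, c(FALSE, FALSE, FALSE, TRUE))
  # width == step tiles without overlap
  t <- make_windows(c(chr = 10000L), 2000L, 2000L)
  expect_equal(t$start, seq(0L, 8000L, by = 2000L))
  # sequence shorter than the width -> single truncated window
  s <- make_windows(c(chr = 700L), 1000L, 500L)
  expect_equal(nrow(s), 2)
  expect_true(all(s$truncated))
  expect_error(make_windows(c(chr = 10L), 100L, 200L))
})

random_fixture <- function(seed, L = 5000L) {
  set.seed(seed)
  rs_pos <- sort(sample(0:(L - 1), 800))
  rs <- data.frame(seqname = "chr", pos = rs_pos,
                   rs = rnorm(800, 0.05, 0.02))
  fst_pos <- sort(sample(0:(L - 1), 400))
  fst <- data.frame(seqname = "chr", pos = fst_pos,
                    fst = runif(400, -0.2, 1), defined = TRUE)
  fst$defined[sample(400, 40)] <- FALSE
  fst$fst[!fst$defined] <- NA
  snp_sites <- data.frame(seqname = "chr",
                          pos = sort(sample(0:(L - 1), 300)))
  depth_all <- structure(list(chr = sample(0:11, L, TRUE)),
                         class = "depth_track")
  fam <- list(f1 = structure(list(chr = sample(0:4, L, TRUE)),
                             class = "depth_track"),
              f2 = structure(list(chr = sample(0:6, L, TRUE)),
                             class = "depth_track"))
  list(rs = rs, fst = fst, snps = snp_sites, depth_all = depth_all,
       fam = fam, L = L)
}

test_that("window aggregation equals brute-force interval intersection", {
  fx <- random_fixture(61)
  win <- make_windows(c(chr = fx$L), 700L, 300L)
  agg <- aggregate_windows(win, rs = fx$rs, fst = fx$fst, snps = fx$snps,
                           depth_all = fx$depth_all,
                           depth_families = fx$fam)
  def <- fx$fst[fx$fst$defined, ]
  for (i in seq_len(nrow(agg))) {
    row <- agg[i, ]
    expect_equal(row$mean_rs, brute_mean_in(row, fx$rs$pos, fx$rs$rs),
                 tolerance = 1e-12)
    expect_equal(row$mean_fst, brute_mean_in(row, def$pos, def$fst),
                 tolerance = 1e-12)
    expect_equal(row$n_snps,
                 sum(fx$snps$pos >= row$start & fx$snps$pos < row$end))
    expect_equal(row$snp_density, row$n_snps / (row$end - row$start))
    idx <- seq.int(row$start + 1L, row$end)
    expect_equal(row$mean_depth_all, mean(fx$depth_all$chr[idx]),
                 tolerance = 1e-12)
    expect_equal(row$frac_cov_all, mean(fx$depth_all$chr[idx] >= 4),
                 tolerance = 1e-12)
    expect_equal(row$frac_cov_f1, mean(fx$fam$f1$chr[idx] >= 2),
                 tolerance = 1e-12)
    expect_equal(row$mean_depth_f2, mean(fx$fam$f2$chr[idx]),
                 tolerance = 1e-12)
  }
  # uniform RS value gives that value in every covered window
  flat <- fx$rs; flat$rs <- 0.3
  agg2 <- aggregate_windows(win, rs = flat)
  expect_equal(agg2$mean_rs[agg2$n_rs > 0],
               rep(0.3, sum(agg2$n_rs > 0)), tolerance = 1e-12)
})

test_that("the eligibility filter equals its boolean oracle and is strict
          on density", {
  fx <- random_fixture(62)
  win <- make_windows(c(chr = fx$L), 500L, 500L)
  agg <- aggregate_windows(win, snps = fx$snps, depth_families = fx$fam)
  kept <- filter_windows(agg, 0.5, 0.01)
  oracle <- agg[!is.na(agg$frac_cov_f1) & agg$frac_cov_f1 >= 0.5 &
                agg$frac_cov_f2 >= 0.5 & agg$snp_density > 0.01, ]
  expect_equal(kept$start, oracle$start)
  # idempotent
  expect_equal(nrow(filter_windows(kept, 0.5, 0.01)), nrow(kept))
  # density exactly at the threshold is excluded
  agg$snp_density[] <- 0.01
  agg$frac_cov_f1[] <- 1; agg$frac_cov_f2[] <- 1
  expect_equal(nrow(filter_windows(agg, 0.5, 0.01)), 0)
  # a family entirely absent excludes the window
  agg$snp_density[] <- 0.05
  agg$frac_cov_f2[] <- 0
  expect_equal(nrow(filter_windows(agg, 0.5, 0.01)), 0)
})

test_that("percentile peaks merge as constructed and respect the count
          bound", {
  # flat landscape: no window strictly above the threshold
  win <- make_windows(c(chr = 200000L), 10000L, 5000L)
  win$mean_rs <- 0.5
  class(win) <- c("window_summary", class(win))
  pk0 <- suppressWarnings(call_outlier_peaks(win, "rs", 99.99))
  expect_equal(nrow(pk0), 0)
  # one spiked region -> exactly one merged peak covering the spike
  win$mean_rs <- 0.05
  spike <- win$start >= 100000 & win$start < 110000
  win$mean_rs[spike] <- 0.9
  pk1 <- suppressWarnings(call_outlier_peaks(win, "rs", 95))
  expect_equal(nrow(pk1), 1)
  expect_true(pk1$start <= 100000 && pk1$end >= 110000)
  expect_equal(pk1$peak_value, 0.9)
  # two overlapping-window spikes merge; distant spikes stay separate
  win$mean_rs <- 0.05
  win$mean_rs[win$start %in% c(50000, 55000)] <- 0.9   # adjacent windows
  win$mean_rs[win$start == 150000] <- 0.8
  pk2 <- suppressWarnings(call_outlier_peaks(win, "rs", 90))
  expect_equal(nrow(pk2), 2)
  expect_equal(pk2$n_windows, c(2L, 1L))
  # count above the 99.99th percentile is <= 0.01% + 1 of eligible
  set.seed(8)
  win$mean_rs <- rnorm(nrow(win))
  pk3 <- suppressWarnings(call_outlier_peaks(win, "rs", 99.99))
  expect_lte(sum(pk3$n_windows), nrow(win) * 1e-4 + 1)
})

test_that("peak annotation equals brute-force gene intersection", {
  genes <- data.frame(seqname = "chr",
                      start = c(100L, 500L, 900L, 2000L),
                      end = c(300L, 800L, 1500L, 2500L),
                      gene_id = c("gA", "gB", "gC", "gD"))
  peaks <- data.frame(seqname = "chr", start = c(0L, 250L, 1600L),
                      end = c(50L, 1000L, 1900L))
  ann <- annotate_peaks(peaks, genes)
  expect_equal(ann$genes, c("", "gA,gB,gC", ""))
  expect_equal(ann$n_genes, c(0L, 3L, 0L))
  set.seed(63)
  rg <- data.frame(seqname = "chr", start = sample(0:5000, 50))
  rg$end <- rg$start + sample(50:500, 50, TRUE)
  rg$gene_id <- sprintf("g%02d", 1:50)
  rp <- data.frame(seqname = "chr", start = sample(0:5000, 20))
  rp$end <- rp$start + sample(100:800, 20, TRUE)
  out <- annotate_peaks(rp, rg)
  for (i in seq_len(nrow(out))) {
    hit <- rg$start < rp$end[i] & rg$end > rp$start[i]
    expect_equal(out$n_genes[i], sum(hit))
  }
})

test_that("BUSCO tables round-trip and aggregate per interval", {
  busco <- data.frame(
    busco_id = c("b1", "b2", "b3", "b4", "b4"),
    status = c("Complete", "Missing", "Fragmented", "Duplicated",
               "Duplicated"),
    seqname = c("chr", NA, "chr", "chr", "chr"),
    start = c(100L, NA, 900L, 2000L, 3000L),
    end = c(600L, NA, 1400L, 2500L, 3500L), stringsAsFactors = FALSE)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_busco_table(busco, tf)
  back <- read_busco_table(tf)
  expect_equal(back$busco_id, busco$busco_id)
  expect_equal(back$status, busco$status)
  expect_equal(back$start, busco$start)
  expect_equal(back$duplicated, busco$status == "Duplicated")
  fx <- random_fixture(64)
  agg <- aggregate_buscos(back, rs = fx$rs, snps = fx$snps,
                          depth_families = fx$fam)
  # Missing BUSCOs yield no row; duplicated copies are both present
  expect_equal(nrow(agg), 4)
  expect_false("b2" %in% agg$busco_id)
  expect_equal(sum(agg$busco_id == "b4"), 2)
  expect_true(all(agg$duplicated[agg$busco_id == "b4"]))
  i <- which(agg$busco_id == "b1")
  expect_equal(agg$mean_rs[i],
               brute_mean_in(list(start = 100L, end = 600L), fx$rs$pos,
                             fx$rs$rs), tolerance = 1e-12)
  # malformed rows are skipped with a warning
  tf2 <- withr::local_tempfile(
    lines = c("# header", "b9\tComplete\tchr\tnot_a_number\t5"))
  expect_warning(read_busco_table(tf2), "malformed")
})
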