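# Stage orchestration: each stage reads its declared input files from the
# run directory, writes its outputs there, and appends a manifest record
# (JSON-lines) with parameter values and input/output checksums, so any
# stage can be re-run standalone and reruns are verifiably identical.

#' Default run configuration
#'
#' Parameter defaults follow the published scan design: broad 50 kb / 25 kb
#' and fine 10 kb / 5 kb sliding windows, GERP minimum coverage 3, 5,000
#' neutral windows of 1 kb at alignment depth >= n_species - 1, the
#' 2-genomes-per-family / 50% / 1% SNP-density window filter, outlier
#' percentile 99.99, BUSCO top-set percentile 99, elim min_node_size 5,
#' anchoring top-k 45 with the 33% coverage rule and 100-bp N gaps.
#'
#' @param outdir run directory for all artifacts.
#' @param seed integer seed for every stochastic stage.
#' @param ... overrides for any default parameter.
#' @return validated list of class `run_config`.
#' @export
default_run_config <- function(outdir = "pinnscan_run", seed = 1L, ...) {
  cfg <- list(
    outdir = outdir, seed = as.integer(seed),
    # synthetic inputs
    sim_length = 200000L, block_size = 5000L, n_genes = 40L,
    n_fragments = 30L,
    # neutral tree
    neutral_n = 5000L, neutral_length = 1000L, min_depth = NA_integer_,
    # gerp / fst
    gerp_min_coverage = 3L, r_max = 5,
    # windows
    broad_width = 50000L, broad_step = 25000L,
    fine_width = 10000L, fine_step = 5000L,
    target_all = 4L, target_family = 2L,
    min_family_frac = 0.5, min_snp_density = 0.01,
    peak_percentile = 99.99,
    # enrichment
    busco_percentile = 99, min_node_size = 5L, elim_alpha = 0.01,
    # anchoring
    top_k = 45L, min_frac = 0.33, gap_size = 100L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    config_error("unknown parameter(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_run_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

validate_run_config <- function(cfg) {
  chk <- function(ok, what) if (!ok) config_error("invalid ", what)
  chk(cfg$sim_length >= 1000, "sim_length (>= 1000)")
  chk(cfg$neutral_n >= 1 && cfg$neutral_length >= 1, "neutral window parameters")
  chk(cfg$gerp_min_coverage >= 2, "gerp_min_coverage (>= 2)")
  chk(cfg$broad_width >= cfg$broad_step && cfg$broad_step > 0,
      "broad window parameters")
  chk(cfg$fine_width >= cfg$fine_step && cfg$fine_step > 0,
      "fine window parameters")
  chk(cfg$min_family_frac >= 0 && cfg$min_family_frac <= 1,
      "min_family_frac")
  chk(cfg$peak_percentile > 0 && cfg$peak_percentile < 100,
      "peak_percentile")
  chk(cfg$busco_percentile > 0 && cfg$busco_percentile < 100,
      "busco_percentile")
  chk(cfg$min_node_size >= 1, "min_node_size")
  chk(cfg$elim_alpha >= 0 && cfg$elim_alpha <= 1, "elim_alpha")
  chk(cfg$top_k >= 1, "top_k")
  chk(cfg$min_frac > 0 && cfg$min_frac < 1, "min_frac")
  chk(cfg$gap_size >= 1, "gap_size")
  invisible(cfg)
}

run_path <- function(cfg, name) file.path(cfg$outdir, name)

require_artifact <- function(cfg, name, producer) {
  p <- run_path(cfg, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s': run stage '%s' first", name,
                 producer), call. = FALSE)
  p
}

manifest_append <- function(cfg, stage, params, inputs, outputs) {
  rec <- list(stage = stage, seed = cfg$seed, params = params,
              inputs = as.list(tools::md5sum(inputs)),
              outputs = as.list(tools::md5sum(outputs)))
  line <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  cat(line, "\n", sep = "", file = run_path(cfg, "manifest.jsonl"),
      append = TRUE)
  invisible(rec)
}

pipeline_clades <- function() {
  fam <- PINNIPED_CLADES
  list(map = clade_map(names(fam)[fam == "otariids"],
                       names(fam)[fam == "phocids"],
                       names(fam)[fam == "excluded"]),
       families = list(otariids = names(fam)[fam == "otariids"],
                       phocids = names(fam)[fam == "phocids"]))
}

#' Run one pipeline stage
#'
#' Stages: `simulate`, `anchor`, `neutral-tree`, `gerp`, `snps`, `fst`,
#' `windows`, `peaks`, `enrich`, `all` (runs everything in order). Each
#' stage requires the artifacts of its upstream stages in `cfg$outdir` and
#' appends a manifest record.
#'
#' @param stage stage name.
#' @param cfg a `run_config` from [default_run_config()].
#' @return invisibly, the named list of artifact paths the stage wrote.
#' @export
run_stage <- function(stage, cfg) {
  stopifnot(inherits(cfg, "run_config"))
  stages <- c("simulate", "anchor", "neutral-tree", "gerp", "snps", "fst",
              "windows", "peaks", "enrich")
  if (identical(stage, "all")) {
    for (s in stages) run_stage(s, cfg)
    return(invisible(NULL))
  }
  if (!stage %in% stages)
    config_error("unknown stage '", stage, "'")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  fn <- switch(stage, "simulate" = stage_simulate,
               "anchor" = stage_anchor, "neutral-tree" = stage_neutral,
               "gerp" = stage_gerp, "snps" = stage_snps,
               "fst" = stage_fst, "windows" = stage_windows,
               "peaks" = stage_peaks, "enrich" = stage_enrich)
  fn(cfg)
}

#' Run the full pipeline
#' @param cfg a `run_config`.
#' @export
run_pipeline <- function(cfg) run_stage("all", cfg)

stage_simulate <- function(cfg) {
  sc <- simulation_config(seed = cfg$seed, length = cfg$sim_length,
                          block_size = cfg$block_size,
                          n_genes = cfg$n_genes)
  sim <- simulate_alignment(sc)
  feats <- simulate_features(sc, sim$truth, dir = cfg$outdir)
  maf <- run_path(cfg, "alignment.maf")
  write_maf(sim$alignment, maf)
  truth_tsv <- run_path(cfg, "truth_sites.tsv")
  utils::write.table(data.frame(seqname = names(sc$seqname) %||% sc$seqname,
                                pos = seq_along(sim$truth$site_class) - 1L,
                                class = sim$truth$site_class),
                     truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  topo <- run_path(cfg, "topology.nwk")
  writeLines(write_newick(sim$truth$tree), topo)
  # reference genome FASTA (for the anchoring fixture)
  cols <- ref_columns(sim$alignment)
  refseq <- paste(cols$bases[sim$alignment$reference, ], collapse = "")
  fa <- run_path(cfg, "target_genome.fa")
  x <- Biostrings::DNAStringSet(refseq)
  names(x) <- sc$seqname
  Biostrings::writeXStringSet(x, fa, width = 80L)
  outs <- c(maf, truth_tsv, topo, fa, unlist(feats$files))
  manifest_append(cfg, "simulate",
                  cfg[c("seed", "sim_length", "block_size", "n_genes")],
                  character(0), outs)
  invisible(outs)
}

stage_anchor <- function(cfg) {
  fa <- require_artifact(cfg, "target_genome.fa", "simulate")
  genome <- Biostrings::readDNAStringSet(fa)
  fr <- fragment_assembly(genome, cfg$n_fragments, seed = cfg$seed + 1L)
  frag_fa <- run_path(cfg, "fragments.fa")
  Biostrings::writeXStringSet(fr$fragments, frag_fa, width = 80L)
  hits_tsv <- run_path(cfg, "hits.tsv")
  write_hits(fr$hits, hits_tsv)
  hits <- load_hits(hits_tsv)
  asn <- assign_primary_targets(hits, fr$query_lengths,
                                top_k = cfg$top_k, min_frac = cfg$min_frac)
  plan <- build_anchor_plan(asn, hits, fr$query_lengths,
                            gap_size = cfg$gap_size)
  agp <- run_path(cfg, "anchored.agp")
  mega_fa <- run_path(cfg, "anchored.fa")
  lift <- run_path(cfg, "liftover.tsv")
  emit_anchor_plan(plan, fr$fragments, agp = agp, fasta = mega_fa,
                   liftover = lift)
  outs <- c(frag_fa, hits_tsv, agp, mega_fa, lift)
  manifest_append(cfg, "anchor",
                  cfg[c("n_fragments", "top_k", "min_frac", "gap_size")],
                  fa, outs)
  invisible(outs)
}

stage_neutral <- function(cfg) {
  maf <- require_artifact(cfg, "alignment.maf", "simulate")
  gff <- require_artifact(cfg, "genes.gff3", "simulate")
  topo <- require_artifact(cfg, "topology.nwk", "simulate")
  aln <- read_maf(maf)
  depth <- depth_track(aln)
  coding <- read_coding_intervals(gff)
  min_depth <- if (is.na(cfg$min_depth)) length(aln$species_names) - 1L
               else cfg$min_depth
  regions <- eligible_regions(depth, coding, min_depth)
  sample <- sample_windows(regions, n = cfg$neutral_n,
                           length = cfg$neutral_length,
                           seed = cfg$seed + 2L)
  bed <- run_path(cfg, "neutral_windows.bed")
  write_bed(sample, bed)
  mat <- extract_concat_alignment(aln, sample)
  concat_fa <- run_path(cfg, "neutral_concat.fa")
  write_alignment_fasta(mat, concat_fa)
  topology <- parse_newick(readLines(topo))
  fitted <- fit_branch_lengths(topology, mat)
  nwk <- run_path(cfg, "neutral_tree.nwk")
  writeLines(write_newick(fitted), nwk)
  outs <- c(bed, concat_fa, nwk)
  manifest_append(cfg, "neutral-tree",
                  c(cfg[c("neutral_n", "neutral_length")],
                    list(min_depth = min_depth)),
                  c(maf, gff, topo), outs)
  invisible(outs)
}

stage_gerp <- function(cfg) {
  maf <- require_artifact(cfg, "alignment.maf", "simulate")
  nwk <- require_artifact(cfg, "neutral_tree.nwk", "neutral-tree")
  aln <- read_maf(maf)
  tree <- parse_newick(readLines(nwk))
  rs <- score_alignment(aln, tree, min_coverage = cfg$gerp_min_coverage,
                        r_max = cfg$r_max)
  tsv <- run_path(cfg, "rs_track.tsv")
  write_rs_track(rs, tsv, bedgraph = run_path(cfg, "rs_track.bedgraph"))
  manifest_append(cfg, "gerp",
                  cfg[c("gerp_min_coverage", "r_max")], c(maf, nwk),
                  c(tsv, run_path(cfg, "rs_track.bedgraph")))
  invisible(tsv)
}

stage_snps <- function(cfg) {
  maf <- require_artifact(cfg, "alignment.maf", "simulate")
  aln <- read_maf(maf)
  snps <- extract_snps(aln)
  vcf <- run_path(cfg, "snps.vcf")
  write_vcf(snps, vcf, contig_sizes = aln$chrom_sizes)
  manifest_append(cfg, "snps", list(), maf, vcf)
  invisible(vcf)
}

stage_fst <- function(cfg) {
  maf <- require_artifact(cfg, "alignment.maf", "simulate")
  require_artifact(cfg, "snps.vcf", "snps")
  aln <- read_maf(maf)
  snps <- extract_snps(aln)
  cl <- pipeline_clades()
  fst <- fst_scan(snps, cl$map)
  tsv <- run_path(cfg, "fst.tsv")
  write_fst_table(fst, tsv)
  manifest_append(cfg, "fst", list(), maf, tsv)
  invisible(tsv)
}

read_rs_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

stage_windows <- function(cfg) {
  maf <- require_artifact(cfg, "alignment.maf", "simulate")
  rs_tsv <- require_artifact(cfg, "rs_track.tsv", "gerp")
  fst_tsv <- require_artifact(cfg, "fst.tsv", "fst")
  busco_tsv <- require_artifact(cfg, "busco_full_table.tsv", "simulate")
  aln <- read_maf(maf)
  rs <- read_rs_tsv(rs_tsv)
  fst <- read_rs_tsv(fst_tsv)
  snps <- extract_snps(aln)
  cl <- pipeline_clades()
  depth_all <- depth_track(aln)
  depth_fam <- lapply(cl$families, function(sp)
    depth_track(aln, intersect(sp, aln$species_names)))
  outs <- character(0)
  for (set in c("broad", "fine")) {
    win <- make_windows(aln$chrom_sizes, cfg[[paste0(set, "_width")]],
                        cfg[[paste0(set, "_step")]])
    agg <- aggregate_windows(win, rs = rs, fst = fst, snps = snps,
                             depth_all = depth_all,
                             depth_families = depth_fam,
                             target_all = cfg$target_all,
                             target_family = cfg$target_family)
    p <- run_path(cfg, paste0("windows_", set, ".tsv"))
    utils::write.table(agg, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outs <- c(outs, p)
  }
  busco <- read_busco_table(busco_tsv)
  bagg <- aggregate_buscos(busco, rs = rs, fst = fst, snps = snps,
                           depth_all = depth_all,
                           depth_families = depth_fam,
                           target_all = cfg$target_all,
                           target_family = cfg$target_family)
  p <- run_path(cfg, "busco_summaries.tsv")
  utils::write.table(bagg, p, sep = "\t", quote = FALSE, row.names = FALSE)
  outs <- c(outs, p)
  manifest_append(cfg, "windows",
                  cfg[c("broad_width", "broad_step", "fine_width",
                        "fine_step", "target_all", "target_family")],
                  c(maf, rs_tsv, fst_tsv, busco_tsv), outs)
  invisible(outs)
}

stage_peaks <- function(cfg) {
  win_tsv <- require_artifact(cfg, "windows_broad.tsv", "windows")
  gff <- require_artifact(cfg, "genes.gff3", "simulate")
  agg <- read_rs_tsv(win_tsv)
  eligible <- filter_windows(agg, cfg$min_family_frac, cfg$min_snp_density)
  genes <- read_genes(gff)
  outs <- character(0)
  for (metric in c("rs", "fst")) {
    pk <- suppressWarnings(
      call_outlier_peaks(eligible, metric, cfg$peak_percentile))
    pk <- annotate_peaks(pk, genes)
    p <- run_path(cfg, paste0("peaks_", metric, ".tsv"))
    utils::write.table(pk, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, p)
  }
  manifest_append(cfg, "peaks",
                  cfg[c("min_family_frac", "min_snp_density",
                        "peak_percentile")],
                  c(win_tsv, gff), outs)
  invisible(outs)
}

stage_enrich <- function(cfg) {
  busco_tsv <- require_artifact(cfg, "busco_summaries.tsv", "windows")
  obo <- require_artifact(cfg, "ontology.obo", "simulate")
  map_tsv <- require_artifact(cfg, "go_mapping.tsv", "simulate")
  summ <- read_rs_tsv(busco_tsv)
  graph <- load_obo(obo)
  annotation <- read_go_mapping(map_tsv)
  universe <- build_universe(summ, min_snp_density = cfg$min_snp_density)
  outs <- character(0)
  for (metric in c("rs", "fst")) {
    study <- select_top_set(summ, universe, metric, cfg$busco_percentile)
    res <- elim_fisher(graph, annotation, study, universe,
                       min_node_size = cfg$min_node_size,
                       elim_alpha = cfg$elim_alpha)
    top <- report_top(res, 10)
    p <- run_path(cfg, paste0("go_top_", metric, ".tsv"))
    utils::write.table(top, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outs <- c(outs, p)
  }
  manifest_append(cfg, "enrich",
                  cfg[c("busco_percentile", "min_node_size", "elim_alpha")],
                  c(busco_tsv, obo, map_tsv), outs)
  invisible(outs)
}
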