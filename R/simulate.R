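# Synthetic data generator: every input the scan pipeline consumes, with
# truth tables. Sequences evolve site-independently along a known tree
# under JC69 with a per-site rate multiplier (< 1 inside conserved blocks);
# family-diagnostic sites are forced (not evolved) to clade-fixed states;
# missingness is block-level species dropout emulating unaligned regions.
# Everything is byte-deterministic under the config seed.

#' Default 11-taxon pinniped-like study tree (newick)
#'
#' Fixed topology with branch lengths in substitutions/site totalling 0.086,
#' the cumulative neutral branch length scale of the pinniped alignment:
#' four otariids, six phocids, and the walrus between them.
#' @export
PINNIPED_TREE <- paste0(
  "((((Arctocephalus_gazella:0.004,Callorhinus_ursinus:0.004):0.002,",
  "(Zalophus_californianus:0.004,Eumetopias_jubatus:0.004):0.002):0.006,",
  "Odobenus_rosmarus:0.012):0.004,",
  "(((Phoca_vitulina:0.003,Halichoerus_grypus:0.003):0.004,",
  "(Leptonychotes_weddellii:0.005,(Mirounga_angustirostris:0.001,",
  "Mirounga_leonina:0.001):0.004):0.002):0.003,",
  "Neomonachus_schauinslandi:0.012):0.006);")

#' Default family labels for the study taxa
#'
#' Maps each species of [PINNIPED_TREE] to `"otariids"`, `"phocids"` or
#' `"excluded"` (the walrus, left out of the family contrast).
#' @export
PINNIPED_CLADES <- c(
  Arctocephalus_gazella = "otariids", Callorhinus_ursinus = "otariids",
  Zalophus_californianus = "otariids", Eumetopias_jubatus = "otariids",
  Odobenus_rosmarus = "excluded",
  Phoca_vitulina = "phocids", Halichoerus_grypus = "phocids",
  Leptonychotes_weddellii = "phocids",
  Mirounga_angustirostris = "phocids", Mirounga_leonina = "phocids",
  Neomonachus_schauinslandi = "phocids")

#' Simulation configuration
#'
#' Defaults emulate the 11-taxon pinniped alignment: a fixed topology with
#' branch lengths totalling 0.086 substitutions/site, the Antarctic fur
#' seal as reference, two families (otariids vs phocids) with the walrus
#' excluded from the contrast, conserved blocks at a reduced substitution
#' rate, a small fraction of clade-fixed differentiated sites, and
#' block-level species dropout.
#'
#' @param seed mandatory integer RNG seed.
#' @param length reference sequence length (bp).
#' @param tree newick string or [ape::phylo]; defaults to the pinniped-like
#'   11-taxon tree.
#' @param clades named character vector species -> family label or
#'   `"excluded"`.
#' @param reference reference species (must be a tree leaf).
#' @param seqname reference sequence name.
#' @param conserved_blocks `data.frame(start, end, multiplier)` or `"auto"`
#'   (5% of the sequence in 5 blocks at multiplier 0.1).
#' @param differentiated_sites integer 0-based positions or `"auto"`
#'   (fraction `diff_fraction` of positions, uniform).
#' @param diff_fraction fraction of positions forced to clade-fixed
#'   differences under `"auto"` (default 0.001).
#' @param missingness named list species -> `data.frame(start, end)` of
#'   dropout intervals, or `"auto"` (each non-reference species loses
#'   `miss_fraction` of the sequence in contiguous chunks).
#' @param miss_fraction dropout fraction per non-reference species under
#'   `"auto"` (default 0.08).
#' @param block_size MAF block tiling size (bp).
#' @param n_genes,gene_length gene models for the feature fixtures.
#' @param n_go_terms toy GO DAG size (>= 3 levels).
#' @param go_direct_terms direct GO annotations per BUSCO.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed, length = 200000L,
                              tree = PINNIPED_TREE,
                              clades = PINNIPED_CLADES,
                              reference = "Arctocephalus_gazella",
                              seqname = "scaf_1",
                              conserved_blocks = "auto",
                              differentiated_sites = "auto",
                              diff_fraction = 0.001,
                              missingness = "auto",
                              miss_fraction = 0.08,
                              block_size = 5000L,
                              n_genes = 40L, gene_length = 2000L,
                              n_go_terms = 40L, go_direct_terms = 3L) {
  if (missing(seed)) config_error("simulation seed is mandatory")
  if (is.character(tree)) tree <- parse_newick(tree)
  stopifnot(length >= 1, reference %in% tree$tip.label)
  if (!all(names(clades) %in% tree$tip.label))
    config_error("clade species must be tree leaves")
  if (is.data.frame(conserved_blocks)) {
    if (any(conserved_blocks$multiplier <= 0))
      config_error("rate multipliers must be > 0")
    if (any(conserved_blocks$end > length))
      config_error("conserved block outside sequence")
  }
  if (is.numeric(differentiated_sites) &&
      any(differentiated_sites >= length))
    config_error("differentiated site outside sequence")
  structure(list(seed = as.integer(seed), length = as.integer(length),
                 tree = tree, clades = clades, reference = reference,
                 seqname = seqname, conserved_blocks = conserved_blocks,
                 differentiated_sites = differentiated_sites,
                 diff_fraction = diff_fraction, missingness = missingness,
                 miss_fraction = miss_fraction,
                 block_size = as.integer(block_size),
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 n_go_terms = as.integer(n_go_terms),
                 go_direct_terms = as.integer(go_direct_terms)),
            class = "simulation_config")
}

# evolve integer base states (1..4) along the tree under JC69 with a
# per-site rate multiplier vector; returns leaf states matrix (tips x L)
evolve_jc <- function(tree, rates) {
  L <- length(rates)
  tr <- stats::reorder(tree, "cladewise")  # edges in preorder
  ntip <- length(tr$tip.label)
  edge <- tr$edge; elen <- tr$edge.length
  states <- vector("list", ntip + tr$Nnode)
  uses <- tabulate(edge[, 1], nbins = ntip + tr$Nnode)
  root <- ntip + 1L
  states[[root]] <- sample.int(4L, L, replace = TRUE)
  leaves <- matrix(0L, ntip, L, dimnames = list(tr$tip.label, NULL))
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    p_change <- 0.75 * (1 - exp(-4 / 3 * elen[e] * rates))
    x <- states[[par]]
    hit <- stats::runif(L) < p_change
    if (any(hit)) {
      # JC: conditional on change, the new base is uniform on the other 3
      shift <- sample.int(3L, L, replace = TRUE)
      x[hit] <- ((x[hit] - 1L + shift[hit]) %% 4L) + 1L
    }
    uses[par] <- uses[par] - 1L
    if (uses[par] == 0L && par > ntip) states[par] <- list(NULL)
    if (ch <= ntip) leaves[ch, ] <- x else states[[ch]] <- x
  }
  leaves
}

#' Simulate a reference-anchored multi-species alignment with truth
#'
#' @param config a `simulation_config`.
#' @return list: `alignment` (a `genome_alignment`), `truth` (list with
#'   `site_class` — `neutral`/`conserved`/`differentiated` per position —
#'   `rates`, `diff_positions`, `diff_alleles`, `missingness`, `tree`,
#'   `clades`).
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$length
  tree <- config$tree
  cons <- config$conserved_blocks
  if (identical(cons, "auto")) {
    bl <- max(1L, as.integer(0.01 * L))
    starts <- as.integer(seq(0.1, 0.9, length.out = 5) * L)
    cons <- data.frame(start = starts, end = pmin(starts + bl, L),
                       multiplier = 0.1)
  }
  rates <- rep(1, L)
  for (i in seq_len(nrow(cons)))
    rates[seq.int(cons$start[i] + 1L, cons$end[i])] <- cons$multiplier[i]
  with_seed(config$seed, {
    leaves <- evolve_jc(tree, rates)
    diff_pos <- config$differentiated_sites
    if (identical(diff_pos, "auto")) {
      n_diff <- round(config$diff_fraction * L)
      diff_pos <- sort(sample.int(L, n_diff) - 1L)
    } else diff_pos <- sort(unique(as.integer(diff_pos)))
    fam <- setdiff(unique(config$clades), "excluded")
    a_sp <- names(config$clades)[config$clades == fam[1]]
    b_sp <- names(config$clades)[config$clades == fam[2]]
    diff_a <- diff_b <- integer(0)
    if (length(diff_pos)) {
      diff_a <- sample.int(4L, length(diff_pos), replace = TRUE)
      diff_b <- ((diff_a - 1L + sample.int(3L, length(diff_pos),
                                           replace = TRUE)) %% 4L) + 1L
      leaves[a_sp, diff_pos + 1L] <-
        matrix(diff_a, length(a_sp), length(diff_pos), byrow = TRUE)
      leaves[b_sp, diff_pos + 1L] <-
        matrix(diff_b, length(b_sp), length(diff_pos), byrow = TRUE)
    }
    miss <- config$missingness
    if (identical(miss, "auto")) {
      miss <- list()
      others <- setdiff(tree$tip.label, config$reference)
      n_chunk <- max(1L, as.integer(ceiling(L / 50000)))
      chunk <- as.integer(config$miss_fraction * L / n_chunk)
      if (chunk > 0)
        for (sp in others) {
          st <- sort(sample.int(L - chunk, n_chunk))
          miss[[sp]] <- data.frame(start = st - 1L,
                                   end = pmin(st - 1L + chunk, L))
        }
    }
    miss <- miss %||% list()
  })
  if (config$reference %in% names(miss))
    config_error("reference species cannot have missingness")
  # block tiling: boundaries at block_size multiples and dropout edges
  brk <- sort(unique(c(seq.int(0L, L, by = config$block_size), L,
                       unlist(lapply(miss, function(d) c(d$start, d$end))))))
  brk <- brk[brk >= 0L & brk <= L]
  chars <- c("A", "C", "G", "T")
  blocks <- list()
  for (i in seq_len(length(brk) - 1L)) {
    s <- brk[i]; e <- brk[i + 1L]
    if (e <= s) next
    present <- tree$tip.label
    for (sp in names(miss)) {
      d <- miss[[sp]]
      if (any(d$start <= s & d$end >= e)) present <- setdiff(present, sp)
    }
    present <- c(config$reference, setdiff(present, config$reference))
    texts <- vapply(present, function(sp)
      paste(chars[leaves[sp, seq.int(s + 1L, e)]], collapse = ""), "")
    blocks[[length(blocks) + 1L]] <-
      data.frame(species = present, seqname = config$seqname, start = s,
                 size = e - s, strand = "+", src_size = L,
                 text = unname(texts), stringsAsFactors = FALSE)
  }
  aln <- genome_alignment(blocks, config$reference,
                          chrom_sizes = stats::setNames(L, config$seqname))
  site_class <- rep("neutral", L)
  for (i in seq_len(nrow(cons)))
    site_class[seq.int(cons$start[i] + 1L, cons$end[i])] <- "conserved"
  site_class[diff_pos + 1L] <- "differentiated"
  list(alignment = aln,
       truth = list(site_class = site_class, rates = rates,
                    diff_positions = diff_pos,
                    diff_alleles = data.frame(pos = diff_pos,
                                              allele_a = chars[diff_a],
                                              allele_b = chars[diff_b]),
                    missingness = miss, conserved_blocks = cons,
                    tree = tree, clades = config$clades))
}

#' Simulate annotation fixtures: genes, BUSCOs, toy GO DAG and mapping
#'
#' Gene models are non-overlapping; most BUSCOs are Complete with a few
#' Duplicated/Fragmented/Missing. The toy GO DAG has 4 levels under one
#' biological_process root; two designated terms preferentially annotate
#' BUSCOs overlapping conserved or differentiated regions so that true
#' enrichment is known.
#'
#' @param config a `simulation_config`.
#' @param truth truth list from [simulate_alignment()] (used to target the
#'   enriched annotations); may be `NULL` for annotation-independent
#'   fixtures.
#' @param dir directory to write `genes.gff3`, `busco_full_table.tsv`,
#'   `ontology.obo`, `go_mapping.tsv` into; `NULL` writes nothing.
#' @return list: `genes`, `busco`, `graph` (a `go_graph`), `mapping`,
#'   `enriched_terms`, `files`.
#' @export
simulate_features <- function(config, truth = NULL, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$length; n <- config$n_genes
  out <- with_seed(config$seed + 1L, {
    glen <- min(config$gene_length, max(1L, L %/% (2L * max(n, 1L))))
    pitch <- L / max(n, 1L)
    starts <- as.integer(floor((seq_len(n) - 1L) * pitch +
                               stats::runif(n, 0, pitch - glen)))
    genes <- data.frame(seqname = config$seqname, start = starts,
                        end = starts + glen,
                        gene_id = sprintf("gene_%03d", seq_len(n)),
                        stringsAsFactors = FALSE)
    # CDS = middle 60% of each gene
    cds <- data.frame(seqname = config$seqname,
                      start = genes$start + as.integer(0.2 * glen),
                      end = genes$start + as.integer(0.8 * glen),
                      gene_id = genes$gene_id, stringsAsFactors = FALSE)
    status <- rep("Complete", n)
    if (n >= 10L) {
      status[sample.int(n, max(1L, n %/% 20L))] <- "Missing"
      status[sample.int(n, max(1L, n %/% 20L))] <- "Fragmented"
      dup <- sample(which(status == "Complete"), 1L)
      status[dup] <- "Duplicated"
    }
    busco <- data.frame(busco_id = sprintf("busco_%04d", seq_len(n)),
                        status = status, seqname = config$seqname,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
    busco$seqname[busco$status == "Missing"] <- NA
    busco$start[busco$status == "Missing"] <- NA
    busco$end[busco$status == "Missing"] <- NA
    # toy GO DAG: root -> k1 -> k2 -> leaves (4 levels, one namespace)
    nt <- max(config$n_go_terms, 8L)
    ids <- sprintf("GO:%07d", seq_len(nt))
    parents <- vector("list", nt); names(parents) <- ids
    k1 <- 2L:min(4L, nt)
    k2 <- setdiff(seq_len(min(nt %/% 2L, nt)), c(1L, k1))
    k3 <- setdiff(seq_len(nt), c(1L, k1, k2))
    parents[[ids[1]]] <- character(0)
    for (i in k1) parents[[ids[i]]] <- ids[1]
    for (i in k2) parents[[ids[i]]] <- ids[sample(k1, 1L)]
    for (i in k3) parents[[ids[i]]] <- ids[sample(k2, 1L)]
    leaves_lvl <- ids[k3]
    # truth-linked BUSCOs: overlap a conserved block or lie near
    # differentiated sites
    linked_cons <- linked_diff <- rep(FALSE, n)
    if (!is.null(truth)) {
      cb <- truth$conserved_blocks
      for (i in seq_len(nrow(cb)))
        linked_cons <- linked_cons | (genes$start < cb$end[i] &
                                      genes$end > cb$start[i])
      if (length(truth$diff_positions))
        linked_diff <- vapply(seq_len(n), function(i)
          any(truth$diff_positions >= genes$start[i] &
              truth$diff_positions < genes$end[i]), TRUE)
    }
    enriched <- c(conserved = leaves_lvl[1],
                  differentiated = leaves_lvl[2])
    mapping <- vector("list", n); names(mapping) <- busco$busco_id
    pool <- setdiff(leaves_lvl, enriched)
    for (i in seq_len(n)) {
      terms <- sample(pool, min(config$go_direct_terms, length(pool)))
      if (linked_cons[i] && stats::runif(1) < 0.9)
        terms <- c(terms, enriched[["conserved"]])
      if (linked_diff[i] && stats::runif(1) < 0.9)
        terms <- c(terms, enriched[["differentiated"]])
      mapping[[i]] <- unique(terms)
    }
    list(genes = genes, cds = cds, busco = busco, parents = parents,
         ids = ids, mapping = mapping, enriched = enriched)
  })
  obo <- character(0)
  for (id in out$ids) {
    obo <- c(obo, "[Term]", paste0("id: ", id),
             paste0("name: toy term ", sub("GO:", "", id)),
             "namespace: biological_process",
             paste0("is_a: ", out$parents[[id]], " ! parent"), "")
  }
  obo <- c("format-version: 1.2", "", obo)
  files <- list()
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files$gff3 <- file.path(dir, "genes.gff3")
    write_gff3(out$genes, out$cds, files$gff3)
    files$busco <- file.path(dir, "busco_full_table.tsv")
    write_busco_table(out$busco, files$busco)
    files$obo <- file.path(dir, "ontology.obo")
    writeLines(obo, files$obo)
    files$mapping <- file.path(dir, "go_mapping.tsv")
    writeLines(sprintf("%s\t%s", names(out$mapping),
                       vapply(out$mapping, paste, "", collapse = ",")),
               files$mapping)
  }
  graph <- load_obo_text(obo)
  list(genes = out$genes, cds = out$cds, busco = out$busco, graph = graph,
       mapping = out$mapping, enriched_terms = out$enriched, files = files)
}

# parse OBO given as lines (shared with load_obo)
load_obo_text <- function(lines) {
  tf <- tempfile(fileext = ".obo")
  writeLines(lines, tf)
  on.exit(unlink(tf))
  load_obo(tf)
}

#' Write gene + CDS models as GFF3
#' @param genes,cds data frames with `seqname`, `start`, `end`, `gene_id`.
#' @param path output file.
#' @export
write_gff3 <- function(genes, cds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    writeLines(sprintf("%s\tpinnscan\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       genes$seqname[i], genes$start[i] + 1L, genes$end[i],
                       genes$gene_id[i]), con)
    ci <- which(cds$gene_id == genes$gene_id[i])
    if (length(ci))
      writeLines(sprintf("%s\tpinnscan\tCDS\t%d\t%d\t.\t+\t0\tID=cds_%s;Parent=%s",
                         cds$seqname[ci], cds$start[ci] + 1L, cds$end[ci],
                         cds$gene_id[ci], cds$gene_id[ci]), con)
  }
  invisible(path)
}

#' Write a BUSCO-style full table
#' @param busco data frame (`busco_id`, `status`, `seqname`, `start`,
#'   `end`), 0-based half-open coordinates.
#' @param path output file.
#' @export
write_busco_table <- function(busco, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# BUSCO version is: 5.4.7",
               "# Busco id\tStatus\tSequence\tGene Start\tGene End\tStrand\tScore\tLength"),
             con)
  for (i in seq_len(nrow(busco))) {
    if (is.na(busco$seqname[i]) || busco$status[i] == "Missing")
      writeLines(sprintf("%s\tMissing", busco$busco_id[i]), con)
    else
      writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t+\t%.1f\t%d",
                         busco$busco_id[i], busco$status[i],
                         busco$seqname[i], busco$start[i] + 1L,
                         busco$end[i], 100.0,
                         busco$end[i] - busco$start[i]), con)
  }
  invisible(path)
}

#' Shatter a genome into fragments with exact self-hits (anchoring fixture)
#'
#' Cuts each input sequence at random breakpoints, reverse-complements a
#' random subset of fragments, and emits exact alignment hits of every
#' fragment against its source, plus the true order/orientation.
#'
#' @param genome named character vector or [Biostrings::DNAStringSet].
#' @param n_fragments total number of fragments (>= 2).
#' @param seed integer RNG seed.
#' @param prop_reversed expected proportion of reverse-complemented
#'   fragments (default 0.3).
#' @return list: `fragments` ([Biostrings::DNAStringSet]), `hits`
#'   (`alignment_hits`), `truth` (`query`, `target`, `order_index`,
#'   `tstart`, `tend`, `strand`), `query_lengths`.
#' @export
fragment_assembly <- function(genome, n_fragments, seed,
                              prop_reversed = 0.3) {
  if (n_fragments < 2) config_error("need at least 2 fragments")
  seqs <- if (methods::is(genome, "DNAStringSet")) as.character(genome)
          else unlist(genome)
  if (is.null(names(seqs))) names(seqs) <- paste0("target_", seq_along(seqs))
  lens <- nchar(seqs)
  if (any(lens < 2 * n_fragments))
    config_error("sequences too short for ", n_fragments, " fragments")
  # distribute fragments across sequences proportionally to length
  nf <- pmax(1L, round(n_fragments * lens / sum(lens)))
  while (sum(nf) != n_fragments) {
    i <- which.max(lens / nf)
    nf[i] <- nf[i] + sign(n_fragments - sum(nf))
  }
  frag_seq <- character(0); hits <- list(); truth <- list()
  with_seed(seed, {
    fi <- 0L
    for (si in seq_along(seqs)) {
      L <- lens[si]
      k <- nf[si]
      brk <- if (k > 1) sort(sample(seq.int(2L, L - 2L, by = 2L), k - 1L))
             else integer(0)
      bounds <- c(0L, brk, L)
      for (j in seq_len(k)) {
        fi <- fi + 1L
        s <- bounds[j]; e <- bounds[j + 1L]
        nm <- sprintf("frag_%03d", fi)
        piece <- substr(seqs[si], s + 1L, e)
        flip <- stats::runif(1) < prop_reversed
        if (flip)
          piece <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(piece)))
        frag_seq[nm] <- piece
        hits[[fi]] <- data.frame(query = nm, qstart = 0L,
                                 qend = e - s, target = names(seqs)[si],
                                 tstart = s, tend = e,
                                 strand = if (flip) "-" else "+",
                                 length = e - s, stringsAsFactors = FALSE)
        truth[[fi]] <- data.frame(query = nm, target = names(seqs)[si],
                                  order_index = j, tstart = s, tend = e,
                                  strand = if (flip) "-" else "+",
                                  stringsAsFactors = FALSE)
      }
    }
  })
  hits <- do.call(rbind, hits)
  class(hits) <- c("alignment_hits", "data.frame")
  list(fragments = Biostrings::DNAStringSet(frag_seq), hits = hits,
       truth = do.call(rbind, truth),
       query_lengths = stats::setNames(nchar(frag_seq), names(frag_seq)))
}

#' Write alignment hits as TSV
#' @param hits an `alignment_hits` data frame.
#' @param path output file.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
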