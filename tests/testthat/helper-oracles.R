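# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (enumeration, per-position scans) so they check the
# fast implementations from the outside.

# exhaustive-enumeration column likelihood for small trees: sums the joint
# probability over every assignment of internal-node states
enum_loglik <- function(tree, column, model = jc69(), rate = 1) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  states <- match(toupper(column), c("A", "C", "G", "T"))[
    match(tr$tip.label, names(column))]
  internal <- (ntip + 1):nn
  Ps <- lapply(seq_len(nrow(tr$edge)), function(e)
    transition_matrix(model, rate * tr$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internal))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    s <- integer(nn)
    s[seq_len(ntip)] <- states
    s[internal] <- grid[g, ]
    pr <- model$freqs[s[ntip + 1L]]  # root at the model's stationary freqs
    for (e in seq_len(nrow(tr$edge))) {
      b <- s[tr$edge[e, 2]]
      if (is.na(b)) next  # absent leaf: marginalized, row sums to 1
      pr <- pr * Ps[[e]][s[tr$edge[e, 1]], b]
    }
    total <- total + pr
  }
  log(total)
}

# total length of the induced subtree on a taxon set: an edge contributes
# iff it separates two retained leaves (checked via tip descendants)
subtree_length_oracle <- function(tree, taxa) {
  ntip <- length(tree$tip.label)
  keep <- match(taxa, tree$tip.label)
  desc_tips <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  total <- 0
  for (e in seq_len(nrow(tree$edge))) {
    below <- desc_tips(tree$edge[e, 2])
    k <- sum(keep %in% below)
    if (k > 0 && k < length(keep)) total <- total + tree$edge.length[e]
  }
  total
}

# single-block alignment from a named character vector of gapped texts;
# the first entry is the reference
make_toy_alignment <- function(texts, start = 0L, seqname = "chr",
                               src_size = 1000L) {
  sizes <- nchar(gsub("-", "", texts))
  block <- data.frame(species = names(texts), seqname = seqname,
                      start = start, size = sizes, strand = "+",
                      src_size = src_size, text = unname(toupper(texts)),
                      stringsAsFactors = FALSE)
  genome_alignment(list(block), names(texts)[1],
                   chrom_sizes = stats::setNames(src_size, seqname))
}

# a small neutral simulation on an arbitrary tree with no extra structure
neutral_sim <- function(tree, length, seed, block_size = 5000L) {
  tips <- tree$tip.label
  cl <- stats::setNames(rep(c("a", "b"), length.out = length(tips)), tips)
  cfg <- simulation_config(seed = seed, length = length, tree = tree,
                           clades = cl, reference = tips[1],
                           conserved_blocks = data.frame(
                             start = integer(0), end = integer(0),
                             multiplier = numeric(0)),
                           differentiated_sites = integer(0),
                           missingness = list(), block_size = block_size)
  simulate_alignment(cfg)
}

# brute-force per-interval aggregation of a sparse (pos, value) track
brute_mean_in <- function(iv_row, pos, value) {
  inside <- pos >= iv_row$start & pos < iv_row$end
  if (!any(inside)) NA_real_ else mean(value[inside])
}

# reconstruct mega-scaffold sequences from an AGP file + component FASTA;
# written independently of emit_anchor_plan
reconstruct_from_agp <- function(agp_path, components) {
  lines <- readLines(agp_path)
  lines <- lines[!grepl("^#", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  objs <- list()
  for (x in f) {
    obj <- x[1]
    if (x[5] == "U") {
      piece <- strrep("N", as.integer(x[6]))
    } else {
      s <- as.character(components[[x[6]]])
      s <- substr(s, as.integer(x[7]), as.integer(x[8]))
      if (x[9] == "-")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      piece <- s
    }
    objs[[obj]] <- paste0(objs[[obj]] %||% "", piece)
  }
  objs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
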