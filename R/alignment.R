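# Reference-anchored multi-species alignments (MAF). A genome_alignment
# holds ordered alignment blocks anchored to one reference genome; all
# coordinates are 0-based half-open on the + strand of the reference.
# Non-reference rows on the - strand are reverse-complemented into reference
# orientation at parse time. 'N' and '-' both mean "species absent" at a
# column: neither carries state information for scoring.

#' Construct a genome alignment
#'
#' @param blocks list of alignment blocks, each a `data.frame` with columns
#'   `species`, `seqname`, `start`, `size`, `strand`, `src_size`, `text`;
#'   the reference row must come first in each block.
#' @param reference name of the reference species.
#' @param chrom_sizes named integer vector of reference sequence lengths;
#'   inferred from the reference rows when `NULL`.
#' @return an object of class `genome_alignment`.
#' @export
genome_alignment <- function(blocks, reference, chrom_sizes = NULL) {
  if (length(blocks)) {
    ref_sq <- vapply(blocks, function(b) b$seqname[1], "")
    ref_st <- vapply(blocks, function(b) b$start[1], 0L)
    o <- order(ref_sq, ref_st)
    blocks <- blocks[o]
    ref_sq <- ref_sq[o]; ref_st <- ref_st[o]
    ref_en <- ref_st + vapply(blocks, function(b) b$size[1], 0L)
    for (b in blocks) {
      if (b$species[1] != reference)
        config_error("block does not start with reference species '",
                     reference, "'")
      if (b$strand[1] != "+")
        stop("reference row must be on the + strand")
    }
    same <- ref_sq[-1] == ref_sq[-length(ref_sq)]
    if (any(same & ref_st[-1] < ref_en[-length(ref_en)]))
      stop("alignment blocks overlap in reference coordinates")
  }
  species <- unique(unlist(lapply(blocks, function(b) b$species)))
  species <- c(reference, setdiff(species, reference))
  if (is.null(chrom_sizes)) {
    cs <- integer()
    for (b in blocks) cs[b$seqname[1]] <- b$src_size[1]
    chrom_sizes <- cs
  }
  structure(list(species_names = species, reference = reference,
                 blocks = blocks, chrom_sizes = chrom_sizes),
            class = "genome_alignment")
}

#' @export
print.genome_alignment <- function(x, ...) {
  cat(sprintf("genome_alignment: %d species, %d blocks, reference '%s'\n",
              length(x$species_names), length(x$blocks), x$reference))
  cat(sprintf("  reference sequences: %s\n",
              paste(sprintf("%s (%d bp)", names(x$chrom_sizes),
                            x$chrom_sizes), collapse = ", ")))
  invisible(x)
}

REVCOMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

revcomp_text <- function(text) {
  chars <- rev(strsplit(text, "", fixed = TRUE)[[1]])
  paste(REVCOMP[chars], collapse = "")
}

#' Read a MAF alignment
#'
#' Parses a multiple alignment format file whose blocks all start with the
#' same reference species (`src` fields are `species.seqname`). Sequence is
#' case-folded to upper case; rows on the `-` strand are reverse-complemented
#' into + orientation; duplicated species rows within a block keep the first
#' occurrence with a warning.
#'
#' @param path MAF file.
#' @param reference_species reference species name; inferred from the first
#'   row of the first block when `NULL`.
#' @return a `genome_alignment`.
#' @export
read_maf <- function(path, reference_species = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  starts <- grep("^a", lines)
  blocks <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (bi in seq_along(starts)) {
    chunk <- lines[seq(bounds[bi] + 1L, bounds[bi + 1L] - 1L)]
    srows <- chunk[grepl("^s\\s", chunk)]
    if (!length(srows)) next
    f <- strsplit(trimws(srows), "\\s+")
    bad <- vapply(f, length, 0L) != 7L
    if (any(bad))
      stop(sprintf("MAF parse error in block %d: malformed 's' line", bi))
    src <- vapply(f, `[`, "", 2L)
    species <- sub("\\..*$", "", src)
    seqname <- ifelse(grepl(".", src, fixed = TRUE),
                      sub("^[^.]*\\.", "", src), src)
    start <- as.integer(vapply(f, `[`, "", 3L))
    size <- as.integer(vapply(f, `[`, "", 4L))
    strand <- vapply(f, `[`, "", 5L)
    src_size <- as.integer(vapply(f, `[`, "", 6L))
    text <- toupper(vapply(f, `[`, "", 7L))
    if (length(unique(nchar(text))) != 1L)
      stop(sprintf("MAF parse error in block %d: row text lengths differ", bi))
    ungapped <- nchar(gsub("-", "", text, fixed = TRUE))
    if (any(ungapped != size))
      stop(sprintf("MAF parse error in block %d: size does not match text", bi))
    if (any(grepl("[^ACGTN-]", text)))
      stop(sprintf("MAF parse error in block %d: invalid characters", bi))
    if (anyDuplicated(species)) {
      warning(sprintf("block %d: duplicated species row(s) %s; keeping first",
                      bi, paste(unique(species[duplicated(species)]),
                                collapse = ", ")))
      keep <- !duplicated(species)
      species <- species[keep]; seqname <- seqname[keep]
      start <- start[keep]; size <- size[keep]; strand <- strand[keep]
      src_size <- src_size[keep]; text <- text[keep]
    }
    # normalize - strand rows to + orientation
    neg <- strand == "-"
    if (any(neg)) {
      text[neg] <- vapply(text[neg], revcomp_text, "")
      start[neg] <- src_size[neg] - start[neg] - size[neg]
      strand[neg] <- "+"
    }
    blocks[[bi]] <- data.frame(species = species, seqname = seqname,
                               start = start, size = size, strand = strand,
                               src_size = src_size, text = text,
                               stringsAsFactors = FALSE)
  }
  blocks <- blocks[!vapply(blocks, is.null, TRUE)]
  if (!length(blocks)) {
    if (is.null(reference_species))
      config_error("empty MAF and no reference_species given")
    return(genome_alignment(list(), reference_species,
                            chrom_sizes = integer()))
  }
  ref <- reference_species %||% blocks[[1]]$species[1]
  seen <- unique(unlist(lapply(blocks, function(b) b$species)))
  if (!ref %in% seen)
    config_error("reference species '", ref, "' not present in MAF")
  genome_alignment(blocks, ref)
}

#' Write a MAF alignment
#'
#' Inverse of [read_maf()]: emits one `a` paragraph per block with all rows
#' on the + strand. Reading the result back reproduces every
#' (species, position, base) triple; repeated writes are byte-identical.
#'
#' @param aln a `genome_alignment`.
#' @param path output file.
#' @export
write_maf <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  writeLines("", con)
  for (b in aln$blocks) {
    writeLines("a", con)
    writeLines(sprintf("s %s.%s %d %d %s %d %s", b$species, b$seqname,
                       b$start, b$size, b$strand, b$src_size, b$text), con)
    writeLines("", con)
  }
  invisible(path)
}

# Expand one block into per-reference-position columns. Returns NULL for an
# all-gap reference, else list(pos = 0-based positions, bases = species x n
# character matrix with NA for '-'/'N'). Insertion columns (reference gap)
# are dropped.
block_columns <- function(block) {
  mat <- do.call(rbind, strsplit(block$text, "", fixed = TRUE))
  rownames(mat) <- block$species
  keep <- mat[1L, ] != "-"
  if (!any(keep)) return(NULL)
  bases <- mat[, keep, drop = FALSE]
  bases[bases == "-" | bases == "N"] <- NA_character_
  pos <- block$start[1L] + seq_len(sum(keep)) - 1L
  list(seqname = block$seqname[1L], pos = pos, bases = bases)
}

#' Extract reference-anchored alignment columns
#'
#' One column per reference position covered by a block, ascending; columns
#' that are insertions relative to the reference are skipped, and species
#' with a gap or `N` are absent (`NA`) from the column.
#'
#' @param aln a `genome_alignment`.
#' @param seqname restrict to one reference sequence (default: all).
#' @param start,end 0-based half-open restriction within `seqname`.
#' @return list with `seqname` (character), `pos` (0-based integer) and
#'   `bases` (full species x position character matrix, `NA` = absent).
#' @export
ref_columns <- function(aln, seqname = NULL, start = NULL, end = NULL) {
  if (!is.null(seqname)) {
    if (!seqname %in% names(aln$chrom_sizes))
      stop("range error: unknown reference sequence '", seqname, "'")
    L <- aln$chrom_sizes[[seqname]]
    start <- start %||% 0L
    end <- end %||% L
    if (start < 0L || end > L || start > end)
      stop("range error: [", start, ",", end, ") outside reference ",
           seqname, " of length ", L)
  }
  sq_out <- character(); pos_out <- integer(); mats <- list()
  for (b in aln$blocks) {
    if (!is.null(seqname) &&
        (b$seqname[1] != seqname || b$start[1] >= end ||
         b$start[1] + b$size[1] <= start)) next
    bc <- block_columns(b)
    if (is.null(bc)) next
    keep <- rep(TRUE, length(bc$pos))
    if (!is.null(seqname)) keep <- bc$pos >= start & bc$pos < end
    if (!any(keep)) next
    full <- matrix(NA_character_, length(aln$species_names), sum(keep),
                   dimnames = list(aln$species_names, NULL))
    full[rownames(bc$bases), ] <- bc$bases[, keep, drop = FALSE]
    sq_out <- c(sq_out, rep(bc$seqname, sum(keep)))
    pos_out <- c(pos_out, bc$pos[keep])
    mats[[length(mats) + 1L]] <- full
  }
  bases <- if (length(mats)) do.call(cbind, mats)
           else matrix(NA_character_, length(aln$species_names), 0,
                       dimnames = list(aln$species_names, NULL))
  o <- order(sq_out, pos_out)
  list(seqname = sq_out[o], pos = pos_out[o],
       bases = bases[, o, drop = FALSE])
}

#' Per-position alignment depth
#'
#' Counts, at every reference position, the species (optionally restricted
#' to a subset) present with an informative base; the reference assembly
#' itself counts where included. Positions outside any alignment block have
#' depth 1 when the subset contains the reference (the reference sequence
#' exists everywhere), else 0.
#'
#' @param aln a `genome_alignment`.
#' @param species_subset character vector of species (default: all).
#' @return object of class `depth_track`: named list of integer vectors, one
#'   per reference sequence, position i = 0-based coordinate i - 1.
#' @export
depth_track <- function(aln, species_subset = NULL) {
  subset <- species_subset %||% aln$species_names
  unknown <- setdiff(subset, aln$species_names)
  if (length(unknown))
    config_error("unknown species: ", paste(unknown, collapse = ", "))
  base_val <- if (aln$reference %in% subset) 1L else 0L
  track <- lapply(aln$chrom_sizes, function(L) rep(base_val, L))
  for (b in aln$blocks) {
    bc <- block_columns(b)
    if (is.null(bc)) next
    rows <- intersect(rownames(bc$bases), subset)
    cnt <- if (length(rows))
      colSums(!is.na(bc$bases[rows, , drop = FALSE])) else
      rep(0L, length(bc$pos))
    track[[bc$seqname]][bc$pos + 1L] <- as.integer(cnt)
  }
  structure(track, species_subset = subset, reference = aln$reference,
            class = "depth_track")
}

#' Export a depth track as BedGraph
#' @param depth a `depth_track`.
#' @param path output file.
#' @export
write_depth_bedgraph <- function(depth, path) {
  write_bedgraph(unclass(depth), path, track_name = "alignment_depth")
}
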