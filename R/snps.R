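# Haploid SNP extraction from alignment columns and Hudson-type FST between
# two clades. Each aligned genome contributes a single haploid allele call
# per site; the walrus-style outgroup can be excluded from the clade
# contrast via the clade map.

#' Extract haploid SNPs from a genome alignment
#'
#' One record per reference position where at least one aligned species
#' carries a base different from the reference base. Species absent from the
#' column (gap or `N`) are recorded as missing; sites with more than one
#' alternate allele are flagged multiallelic. Alternate alleles are ordered
#' by descending call count, ties alphabetically.
#'
#' @param aln a `genome_alignment`.
#' @return object of class `snp_table`: list with `sites` (data.frame:
#'   `seqname`, `pos` 0-based, `ref`, `alt` comma-separated, `biallelic`)
#'   and `geno` (species x site integer matrix: 0 = ref, k = k-th alternate,
#'   `NA` = missing).
#' @export
extract_snps <- function(aln) {
  species <- aln$species_names
  sites <- list(); genos <- list()
  for (b in aln$blocks) {
    bc <- block_columns(b)
    if (is.null(bc)) next
    full <- matrix(NA_character_, length(species), ncol(bc$bases),
                   dimnames = list(species, NULL))
    full[rownames(bc$bases), ] <- bc$bases
    refb <- full[aln$reference, ]
    diffs <- full != refb[col(full)]
    is_var <- !is.na(refb) & colSums(diffs, na.rm = TRUE) > 0
    if (!any(is_var)) next
    idx <- which(is_var)
    ref <- refb[idx]
    alt <- character(length(idx)); bi <- logical(length(idx))
    g <- matrix(NA_integer_, length(species), length(idx),
                dimnames = list(species, NULL))
    for (j in seq_along(idx)) {
      col <- full[, idx[j]]
      called <- !is.na(col)
      alts <- col[called & col != ref[j]]
      lv <- unique(alts)
      if (length(lv) > 1L) {
        tab <- table(alts)
        # stable order: count desc, then letter
        lv <- names(tab)[order(-as.integer(tab), names(tab))]
      }
      alt[j] <- paste(lv, collapse = ",")
      bi[j] <- length(lv) == 1L
      g[called, j] <- match(col[called], c(ref[j], lv)) - 1L
    }
    sites[[length(sites) + 1L]] <-
      data.frame(seqname = bc$seqname, pos = bc$pos[idx], ref = ref,
                 alt = alt, biallelic = bi, stringsAsFactors = FALSE)
    genos[[length(genos) + 1L]] <- g
  }
  sites_df <- if (length(sites)) do.call(rbind, sites) else
    data.frame(seqname = character(), pos = integer(), ref = character(),
               alt = character(), biallelic = logical())
  geno <- if (length(genos)) do.call(cbind, genos) else
    matrix(NA_integer_, length(species), 0, dimnames = list(species, NULL))
  o <- order(sites_df$seqname, sites_df$pos)
  sites_df <- sites_df[o, , drop = FALSE]
  rownames(sites_df) <- NULL
  structure(list(sites = sites_df, geno = geno[, o, drop = FALSE],
                 reference = aln$reference),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d sites (%d biallelic), %d samples\n",
              nrow(x$sites), sum(x$sites$biallelic), nrow(x$geno)))
  invisible(x)
}

#' Write haploid SNP calls as VCF 4.2
#'
#' One haploid genotype per species sample (`0`, `1`, ... or `.`); positions
#' are converted to 1-based.
#'
#' @param snps a `snp_table`.
#' @param path output file.
#' @param sample_order character vector of species column order (default:
#'   genotype-matrix order).
#' @param contig_sizes optional named vector for `##contig` header lines.
#' @export
write_vcf <- function(snps, path, sample_order = NULL,
                      contig_sizes = NULL) {
  samples <- sample_order %||% rownames(snps$geno)
  stopifnot(all(samples %in% rownames(snps$geno)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=pinnscan_haploid_alignment_calls",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Haploid genotype">'),
             con)
  if (!is.null(contig_sizes))
    writeLines(sprintf("##contig=<ID=%s,length=%d>", names(contig_sizes),
                       contig_sizes), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"), con)
  if (nrow(snps$sites)) {
    g <- snps$geno[samples, , drop = FALSE]
    gt <- matrix(as.character(g), nrow = nrow(g))
    gt[is.na(gt)] <- "."
    body <- paste(snps$sites$seqname, snps$sites$pos + 1L, ".",
                  snps$sites$ref, snps$sites$alt, ".", "PASS", ".", "GT",
                  sep = "\t")
    body <- paste(body, apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}

#' Hudson-type FST for one biallelic site (haploid samples)
#'
#' With clade sample sizes `n1`, `n2` and alternate-allele frequencies
#' `p1`, `p2`:
#' \deqn{num = (p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
#' \deqn{den = p_1(1-p_2) + p_2(1-p_1)}
#' and `fst = num/den`, undefined (`NA`) when the denominator is 0.
#'
#' @param n1,n2 numbers of non-missing haploid calls per clade (>= 2).
#' @param p1,p2 alternate-allele frequencies per clade.
#' @return one-row `data.frame`: `n1`, `n2`, `p1`, `p2`, `numerator`,
#'   `denominator`, `fst`, `defined`.
#' @export
site_fst <- function(n1, n2, p1, p2) {
  stopifnot(n1 >= 2, n2 >= 2, p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(n1 = n1, n2 = n2, p1 = p1, p2 = p2, numerator = num,
             denominator = den,
             fst = ifelse(den == 0, NA_real_, num / den),
             defined = den != 0)
}

#' Build a clade map for the two-family contrast
#' @param group1,group2 character vectors of species per clade (>= 2 each).
#' @param excluded species ignored by the contrast (e.g. the walrus).
#' @return named character vector species -> label, class `clade_map`.
#' @export
clade_map <- function(group1, group2, excluded = character()) {
  if (length(group1) < 2 || length(group2) < 2)
    config_error("each clade needs at least 2 species")
  if (length(intersect(group1, group2)))
    config_error("clades overlap")
  structure(c(stats::setNames(rep("group1", length(group1)), group1),
              stats::setNames(rep("group2", length(group2)), group2),
              stats::setNames(rep("excluded", length(excluded)), excluded)),
            class = "clade_map")
}

#' Per-site FST scan between two clades
#'
#' Applies [site_fst()] to every biallelic SNP with at least 2 non-missing
#' calls in each clade; multiallelic and under-called sites are skipped and
#' counted. The allele frequency is that of the alternate allele.
#'
#' @param snps a `snp_table`.
#' @param clades a `clade_map`; species absent from the map are ignored.
#' @return `data.frame` of class `fst_table` (`seqname`, `pos`, `n1`, `n2`,
#'   `p1`, `p2`, `numerator`, `denominator`, `fst`, `defined`) with
#'   attribute `skipped` = named counts (`multiallelic`, `undercalled`).
#' @export
fst_scan <- function(snps, clades) {
  g1 <- names(clades)[clades == "group1"]
  g2 <- names(clades)[clades == "group2"]
  g1 <- intersect(g1, rownames(snps$geno))
  g2 <- intersect(g2, rownames(snps$geno))
  if (length(g1) < 2 || length(g2) < 2)
    config_error("each clade needs at least 2 species present in the table")
  bi <- snps$sites$biallelic
  G1 <- snps$geno[g1, , drop = FALSE]
  G2 <- snps$geno[g2, , drop = FALSE]
  n1 <- colSums(!is.na(G1)); n2 <- colSums(!is.na(G2))
  callable <- n1 >= 2 & n2 >= 2
  keep <- bi & callable
  skipped <- c(multiallelic = sum(!bi),
               undercalled = sum(bi & !callable))
  p1 <- colSums(G1 == 1L, na.rm = TRUE)[keep] / n1[keep]
  p2 <- colSums(G2 == 1L, na.rm = TRUE)[keep] / n2[keep]
  rec <- site_fst_vec(n1[keep], n2[keep], p1, p2)
  out <- cbind(data.frame(seqname = snps$sites$seqname[keep],
                          pos = snps$sites$pos[keep],
                          stringsAsFactors = FALSE), rec)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  attr(out, "clade_sizes") <- c(group1 = length(g1), group2 = length(g2))
  class(out) <- c("fst_table", "data.frame")
  out
}

# vectorized body of site_fst without per-call validation
site_fst_vec <- function(n1, n2, p1, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  data.frame(n1 = n1, n2 = n2, p1 = p1, p2 = p2, numerator = num,
             denominator = den,
             fst = ifelse(den == 0, NA_real_, num / den),
             defined = den != 0)
}

#' Write a per-site FST table as TSV
#' @param fst an `fst_table`.
#' @param path output file.
#' @export
write_fst_table <- function(fst, path) {
  utils::write.table(fst, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
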