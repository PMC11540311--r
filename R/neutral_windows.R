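# Selection of putatively neutral windows: non-coding, high-coverage 1-kb
# windows sampled genome-wide, whose concatenated alignment is the input for
# neutral branch-length fitting.

#' Coding intervals from a GFF3 or BED file
#'
#' GFF3: CDS features are extracted and merged. BED: all records are used.
#'
#' @param path GFF3 (`.gff`/`.gff3`) or BED file.
#' @param feature GFF3 feature type to extract (default `"CDS"`).
#' @return an `interval_set` (0-based half-open, merged).
#' @export
read_coding_intervals <- function(path, feature = "CDS") {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == feature]
    interval_set(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  } else {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    interval_set(d[[1]], d[[2]], d[[3]])
  }
}

#' Regions eligible for neutral-window sampling
#'
#' Maximal intervals where the alignment depth meets `min_depth` at every
#' position and that do not overlap any coding interval. With 11 genomes the
#' default (`n_species - 1`) allows at most one genome to be missing.
#'
#' @param depth a `depth_track`.
#' @param coding an `interval_set` of coding intervals (may be empty).
#' @param min_depth minimum alignment depth; default = number of species in
#'   the depth track's subset minus one.
#' @return an `interval_set` of eligible regions.
#' @export
eligible_regions <- function(depth, coding = interval_set(),
                             min_depth = NULL) {
  min_depth <- min_depth %||%
    (length(attr(depth, "species_subset")) - 1L)
  sq <- character(); st <- integer(); en <- integer()
  for (s in names(depth)) {
    ok <- depth[[s]] >= min_depth
    cd <- coding[coding$seqname == s, , drop = FALSE]
    for (i in seq_len(nrow(cd)))
      ok[seq.int(cd$start[i] + 1L, cd$end[i])] <- FALSE
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    sq <- c(sq, rep(s, sum(keep)))
    st <- c(st, starts[keep]); en <- c(en, ends[keep])
  }
  interval_set(sq, st, en, merge = FALSE)
}

#' Sample fixed-length non-overlapping windows from eligible regions
#'
#' Windows are drawn one at a time, uniformly over all currently admissible
#' start positions. A start is admissible when taking it still leaves enough
#' capacity (in the greedy packing sense) to place the remaining windows, so
#' the sampler always succeeds when `n` windows fit at all — in the tight
#' case where the eligible length is exactly `n * length` it returns the
#' unique tiling.
#'
#' @param regions an `interval_set` of eligible regions.
#' @param n number of windows (default 5000).
#' @param length window length in bp (default 1000).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return an `interval_set`-like data frame of `n` windows with attributes
#'   `seed`, `n`, `window_length`; class `window_sample`.
#' @export
sample_windows <- function(regions, n = 5000, length = 1000, seed) {
  stopifnot(n >= 1, length >= 1)
  w <- as.integer(length)
  reg <- regions[regions$end - regions$start >= w, , drop = FALSE]
  cap <- sum((reg$end - reg$start) %/% w)
  if (cap < n)
    stop(sprintf(paste0("insufficient eligible sequence: requested %d ",
                        "windows of %d bp but at most %d fit"), n, w, cap))
  sq <- reg$seqname; a <- reg$start; b <- reg$end
  out_sq <- character(n); out_st <- integer(n)
  with_seed(seed, {
    remaining <- n
    repeat {
      L <- b - a
      cvec <- L %/% w            # per-region capacity
      Rvec <- L %% w
      slack <- sum(cvec) - remaining
      # admissible starts: offset x with x %% w <= R loses 1 capacity unit,
      # others lose 2; the latter are admissible only when slack >= 1
      n1 <- cvec * (Rvec + 1L)
      n2 <- (L - w + 1L) - n1
      adm <- if (slack >= 1L) n1 + n2 else n1
      j <- sample.int(length(adm), 1L, prob = adm)
      if (slack >= 1L) {
        x <- sample.int(L[j] - w + 1L, 1L) - 1L
      } else {
        q <- sample.int(cvec[j], 1L) - 1L
        r <- sample.int(Rvec[j] + 1L, 1L) - 1L
        x <- q * w + r
      }
      s <- a[j] + x
      out_sq[n - remaining + 1L] <- sq[j]
      out_st[n - remaining + 1L] <- s
      remaining <- remaining - 1L
      if (remaining == 0L) break
      # split region j around the placed window
      new_a <- c(a[-j], a[j], s + w)
      new_b <- c(b[-j], s, b[j])
      new_sq <- c(sq[-j], sq[j], sq[j])
      keep <- (new_b - new_a) >= w
      a <- new_a[keep]; b <- new_b[keep]; sq <- new_sq[keep]
      if (!sum((b - a) %/% w))
        stop("internal error: sampler ran out of capacity")
    }
  })
  res <- interval_set(out_sq, out_st, out_st + w, merge = FALSE)
  attr(res, "seed") <- seed
  attr(res, "n") <- n
  attr(res, "window_length") <- w
  class(res) <- c("window_sample", class(res))
  res
}

#' Concatenated multi-species alignment over sampled windows
#'
#' Stacks the reference-anchored columns of every window (in window order)
#' into one ungapped-reference alignment matrix; positions where a species
#' is absent are written as `N`.
#'
#' @param aln a `genome_alignment`.
#' @param sample a `window_sample` (or any `interval_set`).
#' @return character matrix, species x concatenated positions.
#' @export
extract_concat_alignment <- function(aln, sample) {
  mats <- vector("list", nrow(sample))
  for (i in seq_len(nrow(sample))) {
    cols <- ref_columns(aln, sample$seqname[i], sample$start[i],
                        sample$end[i])
    width <- sample$end[i] - sample$start[i]
    m <- matrix("N", length(aln$species_names), width,
                dimnames = list(aln$species_names, NULL))
    if (length(cols$pos)) {
      o <- cols$pos - sample$start[i] + 1L
      got <- cols$bases
      got[is.na(got)] <- "N"
      m[, o] <- got
    }
    mats[[i]] <- m
  }
  do.call(cbind, mats)
}

#' Write a species x sites alignment matrix as multi-FASTA
#' @param mat character matrix with species rownames.
#' @param path output file.
#' @export
write_alignment_fasta <- function(mat, path) {
  seqs <- apply(mat, 1L, paste, collapse = "")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- rownames(mat)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write an interval set (or window sample) as BED
#' @param x an `interval_set`.
#' @param path output file.
#' @export
write_bed <- function(x, path) {
  writeLines(sprintf("%s\t%d\t%d", x$seqname, x$start, x$end), path)
  invisible(path)
}
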