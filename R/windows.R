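# Sliding-window and BUSCO-interval aggregation of RS / FST / coverage,
# the coverage + SNP-density eligibility filters, and percentile outlier
# peak calling.

#' Sliding windows over reference sequences
#'
#' Windows start at 0, `step`, `2*step`, ...; a final truncated window is
#' emitted when the sequence end falls mid-window (flagged via `truncated`).
#'
#' @param chrom_sizes named integer vector of sequence lengths.
#' @param width window width in bp.
#' @param step increment in bp; `width >= step > 0`.
#' @return `data.frame`: `seqname`, `start`, `end`, `truncated`.
#' @export
make_windows <- function(chrom_sizes, width, step = width) {
  stopifnot(width >= step, step > 0)
  out <- lapply(names(chrom_sizes), function(sq) {
    L <- chrom_sizes[[sq]]
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    starts <- starts[starts < L]
    ends <- pmin(starts + width, L)
    data.frame(seqname = sq, start = as.integer(starts),
               end = as.integer(ends), truncated = ends - starts < width,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# --- aggregation core -----------------------------------------------------

# count and sum of a sparse (pos, value) track within [start, end) intervals
sparse_window_stats <- function(iv, seqname, pos, value = NULL) {
  n <- numeric(nrow(iv)); s <- numeric(nrow(iv))
  for (sq in unique(iv$seqname)) {
    rows <- which(iv$seqname == sq)
    sel <- which(seqname == sq)
    p <- pos[sel]
    o <- order(p); p <- p[o]
    cs <- if (!is.null(value)) cumsum(value[sel][o])
    lo <- findInterval(iv$start[rows] - 1L, p)
    hi <- findInterval(iv$end[rows] - 1L, p)
    n[rows] <- hi - lo
    if (!is.null(value))
      s[rows] <- ifelse(hi > 0, cs[pmax(hi, 1L)], 0) -
        ifelse(lo > 0, cs[pmax(lo, 1L)], 0)
  }
  list(count = n, sum = s)
}

# per-interval mean of a dense per-position track, and fraction >= threshold
dense_window_stats <- function(iv, track, threshold = NULL) {
  m <- numeric(nrow(iv)); f <- numeric(nrow(iv))
  for (sq in unique(iv$seqname)) {
    rows <- which(iv$seqname == sq)
    v <- track[[sq]]
    if (is.null(v)) { m[rows] <- NA; f[rows] <- NA; next }
    cs <- c(0, cumsum(as.numeric(v)))
    width <- iv$end[rows] - iv$start[rows]
    m[rows] <- (cs[iv$end[rows] + 1L] - cs[iv$start[rows] + 1L]) / width
    if (!is.null(threshold)) {
      ci <- c(0, cumsum(as.numeric(v >= threshold)))
      f[rows] <- (ci[iv$end[rows] + 1L] - ci[iv$start[rows] + 1L]) / width
    }
  }
  list(mean = m, frac = f)
}

aggregate_intervals <- function(iv, rs = NULL, fst = NULL, snps = NULL,
                                depth_all = NULL, depth_families = NULL,
                                target_all = 4, target_family = 2) {
  out <- iv
  out$width <- iv$end - iv$start
  if (!is.null(rs)) {
    st <- sparse_window_stats(iv, rs$seqname, rs$pos, rs$rs)
    out$n_rs <- st$count
    out$mean_rs <- ifelse(st$count > 0, st$sum / st$count, NA_real_)
  }
  if (!is.null(fst)) {
    def <- fst[fst$defined & !is.na(fst$fst), , drop = FALSE]
    st <- sparse_window_stats(iv, def$seqname, def$pos, def$fst)
    out$n_fst <- st$count
    out$mean_fst <- ifelse(st$count > 0, st$sum / st$count, NA_real_)
  }
  if (!is.null(snps)) {
    sites <- if (inherits(snps, "snp_table")) snps$sites else snps
    st <- sparse_window_stats(iv, sites$seqname, sites$pos)
    out$n_snps <- st$count
    out$snp_density <- st$count / out$width
  }
  if (!is.null(depth_all)) {
    st <- dense_window_stats(iv, depth_all, target_all)
    out$mean_depth_all <- st$mean
    out$frac_cov_all <- st$frac
  }
  for (fam in names(depth_families %||% list())) {
    st <- dense_window_stats(iv, depth_families[[fam]], target_family)
    out[[paste0("mean_depth_", fam)]] <- st$mean
    out[[paste0("frac_cov_", fam)]] <- st$frac
  }
  out
}

#' Aggregate score tracks within windows
#'
#' Per window: mean RS over records inside, mean FST over defined values,
#' SNP count and density, mean alignment depth, and the fraction of
#' positions meeting the coverage targets (>= `target_all` species overall,
#' >= `target_family` members within each family).
#'
#' @param windows output of [make_windows()] (or any interval data frame).
#' @param rs an `rs_track` (optional).
#' @param fst an `fst_table` (optional).
#' @param snps a `snp_table` or its `sites` data frame (optional).
#' @param depth_all a `depth_track` over all species (optional).
#' @param depth_families named list of per-family `depth_track`s (optional).
#' @param target_all,target_family coverage targets (defaults 4 and 2).
#' @return `data.frame` of class `window_summary`.
#' @export
aggregate_windows <- function(windows, rs = NULL, fst = NULL, snps = NULL,
                              depth_all = NULL, depth_families = NULL,
                              target_all = 4, target_family = 2) {
  out <- aggregate_intervals(windows, rs, fst, snps, depth_all,
                             depth_families, target_all, target_family)
  attr(out, "families") <- names(depth_families %||% list())
  class(out) <- c("window_summary", "data.frame")
  out
}

#' Eligibility filter for outlier analysis
#'
#' Keeps windows covered by at least `target_family` genomes per family for
#' at least `min_family_frac` of their positions (both families) and with a
#' SNP density strictly exceeding `min_snp_density`.
#'
#' @param summaries a `window_summary` with family coverage fractions.
#' @param min_family_frac minimum fraction of positions meeting the family
#'   coverage target (default 0.5).
#' @param min_snp_density SNP-density threshold, exclusive (default 0.01).
#' @return the eligible subset (same class).
#' @export
filter_windows <- function(summaries, min_family_frac = 0.5,
                           min_snp_density = 0.01) {
  fam_cols <- grep("^frac_cov_", names(summaries), value = TRUE)
  fam_cols <- setdiff(fam_cols, "frac_cov_all")
  if (!length(fam_cols))
    config_error("summaries lack per-family coverage fractions")
  keep <- rep(TRUE, nrow(summaries))
  for (fc in fam_cols)
    keep <- keep & !is.na(summaries[[fc]]) &
      summaries[[fc]] >= min_family_frac
  keep <- keep & !is.na(summaries$snp_density) &
    summaries$snp_density > min_snp_density
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percentile outlier peaks
#'
#' The threshold is the stated percentile (type-7 linear-interpolation
#' quantile) of the chosen metric over the supplied (eligible) windows;
#' windows strictly above it are merged into peaks when their intervals
#' overlap or are book-ended.
#'
#' @param summaries eligible `window_summary` rows.
#' @param metric `"rs"` or `"fst"` (uses `mean_rs` / `mean_fst`).
#' @param percentile percentile in (0, 100), default 99.99.
#' @return `data.frame` of class `outlier_peaks` (`seqname`, `start`, `end`,
#'   `peak_value`, `n_windows`) with attribute `threshold`.
#' @export
call_outlier_peaks <- function(summaries, metric = c("rs", "fst"),
                               percentile = 99.99) {
  metric <- match.arg(metric)
  colname <- paste0("mean_", metric)
  v <- summaries[[colname]]
  ok <- !is.na(v)
  if (sum(ok) < 100)
    warning("fewer than 100 eligible windows; percentile threshold unstable")
  thr <- stats::quantile(v[ok], percentile / 100, type = 7, names = FALSE)
  sel <- which(ok & v > thr)
  if (!length(sel)) {
    out <- data.frame(seqname = character(), start = integer(),
                      end = integer(), peak_value = numeric(),
                      n_windows = integer())
  } else {
    gr <- GenomicRanges::GRanges(summaries$seqname[sel],
                                 IRanges::IRanges(summaries$start[sel] + 1L,
                                                  summaries$end[sel]))
    red <- GenomicRanges::reduce(gr)
    hits <- GenomicRanges::findOverlaps(gr, red)
    pk <- S4Vectors::subjectHits(hits)
    peak_val <- tapply(v[sel][S4Vectors::queryHits(hits)], pk, max)
    nwin <- tapply(pk, pk, length)
    out <- data.frame(seqname = as.character(GenomicRanges::seqnames(red)),
                      start = GenomicRanges::start(red) - 1L,
                      end = GenomicRanges::end(red),
                      peak_value = as.numeric(peak_val),
                      n_windows = as.integer(nwin),
                      stringsAsFactors = FALSE)
    o <- order(out$seqname, out$start)
    out <- out[o, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- thr
  attr(out, "metric") <- metric
  attr(out, "percentile") <- percentile
  class(out) <- c("outlier_peaks", "data.frame")
  out
}

#' Read gene models from a GFF3 file
#' @param path GFF3 file.
#' @param feature feature type (default `"gene"`).
#' @return `data.frame`: `seqname`, `start` (0-based), `end`, `gene_id`.
#' @export
read_genes <- function(path, feature = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature]
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  data.frame(seqname = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr), gene_id = id,
             stringsAsFactors = FALSE)
}

#' Annotate peaks with overlapping genes
#'
#' @param peaks an `outlier_peaks` data frame.
#' @param genes gene data frame from [read_genes()].
#' @return `peaks` with a `genes` column (comma-separated identifiers in
#'   coordinate order; empty string when intergenic) and `n_genes`.
#' @export
annotate_peaks <- function(peaks, genes) {
  gl <- character(nrow(peaks)); ng <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    hit <- genes$seqname == peaks$seqname[i] &
      genes$start < peaks$end[i] & genes$end > peaks$start[i]
    ids <- genes$gene_id[hit][order(genes$start[hit])]
    gl[i] <- paste(ids, collapse = ",")
    ng[i] <- length(ids)
  }
  peaks$genes <- gl
  peaks$n_genes <- ng
  peaks
}

#' Read a BUSCO full table
#'
#' Parses the tab-separated `full_table.tsv` produced by BUSCO (comment
#' lines starting with `#`). Coordinates are converted to 0-based half-open.
#' Malformed rows are skipped with a warning.
#'
#' @param path BUSCO full-table TSV.
#' @return `data.frame`: `busco_id`, `status`, `seqname`, `start`, `end`,
#'   `duplicated` (status Duplicated).
#' @export
read_busco_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(f))
  for (i in seq_along(f)) {
    x <- f[[i]]
    if (length(x) < 2) { warning("skipping malformed BUSCO row ", i); next }
    status <- x[2]
    if (status == "Missing" || length(x) < 5) {
      rows[[i]] <- data.frame(busco_id = x[1], status = status,
                              seqname = NA_character_, start = NA_integer_,
                              end = NA_integer_, stringsAsFactors = FALSE)
      next
    }
    st <- suppressWarnings(as.integer(x[4])); en <- suppressWarnings(as.integer(x[5]))
    if (is.na(st) || is.na(en)) { warning("skipping malformed BUSCO row ", i); next }
    rows[[i]] <- data.frame(busco_id = x[1], status = status,
                            seqname = x[3], start = st - 1L, end = en,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  out$duplicated <- out$status == "Duplicated"
  out
}

#' Aggregate score tracks within BUSCO intervals
#'
#' Same statistics as [aggregate_windows()], over the interval of every
#' BUSCO with coordinates (statuses Complete, Duplicated, Fragmented);
#' Missing BUSCOs yield no row. Duplicated copies are summarized separately
#' and flagged.
#'
#' @param busco output of [read_busco_table()].
#' @inheritParams aggregate_windows
#' @return `data.frame` of class `busco_summary`.
#' @export
aggregate_buscos <- function(busco, rs = NULL, fst = NULL, snps = NULL,
                             depth_all = NULL, depth_families = NULL,
                             target_all = 4, target_family = 2) {
  b <- busco[!is.na(busco$start), , drop = FALSE]
  iv <- data.frame(seqname = b$seqname, start = b$start, end = b$end,
                   stringsAsFactors = FALSE)
  out <- aggregate_intervals(iv, rs, fst, snps, depth_all, depth_families,
                             target_all, target_family)
  out <- cbind(data.frame(busco_id = b$busco_id, status = b$status,
                          duplicated = b$duplicated,
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  attr(out, "families") <- names(depth_families %||% list())
  class(out) <- c("busco_summary", "data.frame")
  out
}
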