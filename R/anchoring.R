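# Synteny-based anchoring of assembly scaffolds onto a target assembly:
# per-query primary-target assignment by aligned-coverage share, grouping,
# ordering and orientation within each target, and concatenation into
# mega-scaffolds joined by 100-bp N gaps (AGP 2.1 + FASTA + liftover).

#' Load tabular alignment hits
#'
#' Accepts PSL (21+ columns, as emitted by last/blat) or a generic TSV with
#' columns `query`, `qstart`, `qend`, `target`, `tstart`, `tend`, `strand`
#' (and optional `length`). Query coordinates are 0-based half-open on the
#' + strand of the query, with the aligned strand recorded.
#'
#' @param path hits file.
#' @param min_block drop hits with aligned length below this (bp).
#' @param format `"auto"` (by extension / column sniffing), `"psl"` or
#'   `"tsv"`.
#' @return `data.frame` of class `alignment_hits`: `query`, `qstart`,
#'   `qend`, `target`, `tstart`, `tend`, `strand`, `length`.
#' @export
load_hits <- function(path, min_block = 0, format = c("auto", "psl", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "psl") "psl" else "tsv"
  if (format == "psl") {
    lines <- readLines(path)
    lines <- lines[!grepl("^(psLayout|match|-|\\s*$)", lines)]
    f <- strsplit(lines, "\t", fixed = TRUE)
    if (length(f) && any(vapply(f, length, 0L) < 21))
      stop("format error: PSL rows need at least 21 columns")
    get <- function(i) vapply(f, `[`, "", i)
    hits <- data.frame(query = get(10), qstart = as.integer(get(12)),
                       qend = as.integer(get(13)), target = get(14),
                       tstart = as.integer(get(16)),
                       tend = as.integer(get(17)),
                       strand = substr(get(9), 1, 1),
                       length = as.integer(get(1)) + as.integer(get(2)) +
                         as.integer(get(3)),
                       stringsAsFactors = FALSE)
  } else {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    need <- c("query", "qstart", "qend", "target", "tstart", "tend",
              "strand")
    if (!all(need %in% names(d)))
      stop("format error: TSV hits need columns ",
           paste(need, collapse = ", "))
    if (is.null(d$length)) d$length <- d$qend - d$qstart
    hits <- d[, c(need, "length")]
  }
  if (nrow(hits) && (any(hits$qstart < 0) || any(hits$qend <= hits$qstart)))
    stop("format error: invalid hit coordinates")
  hits <- hits[hits$length >= min_block, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("alignment_hits", "data.frame")
  hits
}

#' Assign each large query scaffold a primary target
#'
#' Only the `top_k` longest queries are considered. Per query and target,
#' coverage is the union of the query intervals aligned to that target
#' divided by the query length; a query is anchored when its best target's
#' coverage strictly exceeds `min_frac` and strictly exceeds every other
#' target's coverage (ties leave the query unassigned).
#'
#' @param hits an `alignment_hits` data frame.
#' @param query_lengths named integer vector of query scaffold lengths.
#' @param top_k number of largest queries considered (default 45).
#' @param min_frac minimum covered fraction of the query (default 0.33).
#' @return `data.frame`: `query`, `target`, `covered_frac`, `decision`
#'   (`anchored`/`unassigned`), one row per considered query.
#' @export
assign_primary_targets <- function(hits, query_lengths, top_k = 45,
                                   min_frac = 0.33) {
  missing <- setdiff(unique(hits$query), names(query_lengths))
  if (length(missing))
    config_error("no length for query scaffold(s): ",
                 paste(missing, collapse = ", "))
  o <- order(-query_lengths, names(query_lengths))
  considered <- names(query_lengths)[utils::head(o, top_k)]
  rows <- lapply(considered, function(q) {
    h <- hits[hits$query == q, , drop = FALSE]
    if (!nrow(h))
      return(data.frame(query = q, target = NA_character_,
                        covered_frac = 0, decision = "unassigned",
                        stringsAsFactors = FALSE))
    cov <- vapply(split(h, h$target), function(ht) {
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(ht$qstart + 1L, ht$qend))))
    }, 0L) / query_lengths[[q]]
    best <- which.max(cov)
    strict_best <- sum(cov == max(cov)) == 1L
    anchored <- strict_best && cov[best] > min_frac
    data.frame(query = q,
               target = if (anchored) names(cov)[best] else NA_character_,
               covered_frac = unname(cov[best]),
               decision = if (anchored) "anchored" else "unassigned",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Order and orient anchored scaffolds into an anchor plan
#'
#' Within each target group, queries are ordered by the length-weighted
#' mean target coordinate of their hits to the primary target (ties broken
#' by query name); orientation is the strand carrying the majority of the
#' aligned length (ties +). Queries not anchored are carried over
#' unchanged.
#'
#' @param assignments output of [assign_primary_targets()].
#' @param hits the `alignment_hits` used for assignment.
#' @param query_lengths named integer vector of all query scaffold lengths.
#' @param gap_size N-gap length between placements (default 100).
#' @return object of class `anchor_plan`: list with `groups` (named list of
#'   data.frames `query`, `orientation`, `position`), `unplaced` (character)
#'   and `gap_size`.
#' @export
build_anchor_plan <- function(assignments, hits, query_lengths,
                              gap_size = 100L) {
  anchored <- assignments[assignments$decision == "anchored", , drop = FALSE]
  if (!nrow(anchored)) stop("no anchored query scaffolds")
  rows <- lapply(seq_len(nrow(anchored)), function(i) {
    q <- anchored$query[i]; tg <- anchored$target[i]
    h <- hits[hits$query == q & hits$target == tg, , drop = FALSE]
    w <- h$length
    posn <- sum((h$tstart + h$tend) / 2 * w) / sum(w)
    fwd <- sum(w[h$strand == "+"]); rev <- sum(w[h$strand == "-"])
    data.frame(target = tg, query = q,
               orientation = if (rev > fwd) "-" else "+",
               position = posn, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  groups <- lapply(split(df, df$target), function(d) {
    d <- d[order(d$position, d$query), c("query", "orientation", "position")]
    rownames(d) <- NULL
    d
  })
  unplaced <- setdiff(names(query_lengths), df$query)
  structure(list(groups = groups, unplaced = unplaced,
                 gap_size = as.integer(gap_size)),
            class = "anchor_plan")
}

#' @export
print.anchor_plan <- function(x, ...) {
  cat(sprintf("anchor_plan: %d mega-scaffolds (%d placed scaffolds), %d unplaced\n",
              length(x$groups), sum(vapply(x$groups, nrow, 0L)),
              length(x$unplaced)))
  invisible(x)
}

#' Emit mega-scaffolds: AGP 2.1, FASTA and liftover table
#'
#' Placed scaffolds are concatenated per target group in plan order,
#' reverse-complemented where orientation is `-`, and joined by `gap_size`
#' N bases (AGP gap rows: `U`, scaffold, yes, align_genus). Unplaced
#' scaffolds are carried over unchanged as their own objects. The liftover
#' table maps original scaffold coordinates (0-based half-open) to
#' mega-scaffold coordinates.
#'
#' @param plan an `anchor_plan`.
#' @param scaffold_fasta path to the query-scaffold FASTA or a
#'   [Biostrings::DNAStringSet].
#' @param agp,fasta,liftover output paths (any may be `NULL` to skip).
#' @param object_prefix prefix for mega-scaffold names.
#' @return invisibly, the mega-scaffold [Biostrings::DNAStringSet].
#' @export
emit_anchor_plan <- function(plan, scaffold_fasta, agp = NULL, fasta = NULL,
                             liftover = NULL, object_prefix = "mscaf_") {
  seqs <- if (methods::is(scaffold_fasta, "DNAStringSet")) scaffold_fasta
          else Biostrings::readDNAStringSet(scaffold_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  placed <- unlist(lapply(plan$groups, function(g) g$query))
  missing <- setdiff(c(placed, plan$unplaced), names(seqs))
  if (length(missing))
    stop("scaffold(s) missing from FASTA: ", paste(missing, collapse = ", "))
  gap <- plan$gap_size
  agp_rows <- list(); lift_rows <- list(); out_seqs <- list()
  add_agp <- function(...) agp_rows[[length(agp_rows) + 1L]] <<- paste(...,
                                                                sep = "\t")
  for (tg in sort(names(plan$groups))) {
    g <- plan$groups[[tg]]
    obj <- paste0(object_prefix, tg)
    parts <- character(nrow(g)); at <- 0L; part_no <- 0L
    for (i in seq_len(nrow(g))) {
      q <- g$query[i]
      s <- as.character(seqs[[q]])
      len <- nchar(s)
      if (i > 1L) {
        part_no <- part_no + 1L
        add_agp(obj, at + 1L, at + gap, part_no, "U", gap, "scaffold",
                "yes", "align_genus")
        at <- at + gap
      }
      part_no <- part_no + 1L
      add_agp(obj, at + 1L, at + len, part_no, "W", q, 1L, len,
              g$orientation[i])
      lift_rows[[length(lift_rows) + 1L]] <-
        sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s", q, 0L, len, obj, at,
                at + len, g$orientation[i])
      if (g$orientation[i] == "-")
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      parts[i] <- s
      at <- at + len
    }
    out_seqs[[obj]] <- paste(parts, collapse = strrep("N", gap))
  }
  for (q in plan$unplaced) {
    len <- length(seqs[[q]])
    add_agp(q, 1L, len, 1L, "W", q, 1L, len, "+")
    lift_rows[[length(lift_rows) + 1L]] <-
      sprintf("%s\t%d\t%d\t%s\t%d\t%d\t%s", q, 0L, len, q, 0L, len, "+")
    out_seqs[[q]] <- as.character(seqs[[q]])
  }
  mega <- Biostrings::DNAStringSet(unlist(out_seqs))
  if (!is.null(agp))
    writeLines(c("##agp-version\t2.1", unlist(agp_rows)), agp)
  if (!is.null(fasta))
    Biostrings::writeXStringSet(mega, fasta, width = 80L)
  if (!is.null(liftover))
    writeLines(c(paste0("# pinnscan liftover; ordering/orientation by ",
                        "deterministic weighted-coordinate heuristic"),
                 "# old_name\told_start\told_end\tnew_name\tnew_start\tnew_end\tstrand",
                 unlist(lift_rows)), liftover)
  invisible(mega)
}
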