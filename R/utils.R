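# Internal helpers shared across modules. All coordinates are 0-based,
# half-open [start, end); 1-based coordinates appear only in the VCF and AGP
# writers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Construct a normalized interval set
#'
#' An interval set is a data frame of half-open, 0-based intervals
#' (`seqname`, `start`, `end`), sorted and with overlapping or book-ended
#' intervals on the same sequence merged.
#'
#' @param seqname character vector of sequence names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param merge merge overlapping/adjacent intervals (default `TRUE`).
#' @return a `data.frame` with class `interval_set`.
#' @export
interval_set <- function(seqname = character(), start = integer(),
                         end = integer(), merge = TRUE) {
  df <- data.frame(seqname = as.character(seqname),
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start < 0L) || any(df$end <= df$start))
      stop("invalid interval: need 0 <= start < end")
    df <- df[order(df$seqname, df$start, df$end), , drop = FALSE]
    if (merge) {
      parts <- lapply(split(df, df$seqname), function(d) {
        ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
        data.frame(seqname = d$seqname[1L], start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir), stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, parts)
      df <- df[order(df$seqname, df$start), , drop = FALSE]
    }
    rownames(df) <- NULL
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

#' Total length (bp) of an interval set
#' @param x an `interval_set`.
#' @return integer number of bases covered.
#' @export
interval_length <- function(x) sum(x$end - x$start)

# interval set -> GRanges (1-based internally for IRanges machinery)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(df$seqname,
                         IRanges::IRanges(df$start + 1L, df$end))
}

#' Read a two-column chromosome-sizes TSV (name, length)
#' @param path file path.
#' @return named integer vector of sequence lengths.
#' @export
read_chrom_sizes <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("seqname", "size"),
                         colClasses = c("character", "integer"))
  stats::setNames(d$size, d$seqname)
}

#' Write a per-position track as BedGraph
#'
#' Consecutive positions with equal values are collapsed into one record.
#'
#' @param values named list of numeric vectors, one per sequence, giving the
#'   value at every position (position i is 0-based coordinate i - 1).
#' @param path output file.
#' @param track_name name written in the track header line.
#' @export
write_bedgraph <- function(values, path, track_name = "track") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  for (sq in names(values)) {
    v <- values[[sq]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- !is.na(r$values)
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", sq, starts[keep], ends[keep],
                         r$values[keep]), con)
  }
  invisible(path)
}

# stop() with a consistent configuration-error prefix
config_error <- function(...) stop("configuration error: ", ..., call. = FALSE)
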