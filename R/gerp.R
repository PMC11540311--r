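# GERP rejected-substitution scoring. At each reference position with
# sufficient species coverage, the neutral tree is projected onto the
# present species; the projected total branch length T is the expected
# number of substitutions under neutrality, an ML rate multiplier r-hat is
# estimated for the column, and the RS score is T * (1 - r-hat) = expected
# minus observed substitutions. Positive RS = constraint (rejected
# substitutions), negative RS = acceleration; the total neutral tree length
# is the upper bound of attainable RS.

#' ML substitution-rate multiplier for one column
#'
#' Maximizes the pruning log-likelihood of the column over a rate multiplier
#' `r` applied to all branch lengths of the tree projected onto the present
#' species, by 1-D bounded search on `[0, r_max]`.
#'
#' @param tree neutral tree ([ape::phylo]).
#' @param column named character vector species -> base, at least 2 species.
#' @param model a `subst_model`.
#' @param r_max upper bound for the rate multiplier (default 5).
#' @param tol convergence tolerance of the 1-D search.
#' @return the rate estimate, with attribute `at_bound` (`TRUE` when the
#'   estimate sits at `r_max`).
#' @export
estimate_column_rate <- function(tree, column, model = jc69(), r_max = 5,
                                 tol = 1e-6) {
  column <- column[!is.na(column) & column != "N" & column != "-"]
  if (length(column) < 2)
    stop("estimate_column_rate: need at least 2 present species")
  sub <- prune_to_taxa(tree, names(column))
  rate_hat_pruned(sub, column, model, r_max, tol)
}

# Rate estimation given the already-projected tree.
rate_hat_pruned <- function(sub, column, model, r_max = 5, tol = 1e-6) {
  # identical observed bases: likelihood is maximized at the r = 0 boundary
  if (length(unique(column)) == 1L)
    return(structure(0, at_bound = FALSE))
  prep <- prep_tree(sub)
  pat <- matrix(encode_bases(column), ncol = 1,
                dimnames = list(names(column), NULL))
  f <- function(r) loglik_patterns(prep, model, pat, rate = r)
  opt <- stats::optimize(f, c(0, r_max), maximum = TRUE, tol = tol)
  cand <- c(opt$maximum, 0, r_max)
  vals <- c(opt$objective, f(0), f(r_max))
  best <- which.max(vals)
  r <- cand[best]
  structure(r, at_bound = r >= r_max - 10 * tol)
}

#' RS score for one alignment column
#'
#' @param tree neutral tree.
#' @param column named character vector species -> base (`NA`/`N` = absent).
#' @param model a `subst_model`.
#' @param min_coverage minimum number of present species (default 3).
#' @param r_max rate-multiplier cap passed to [estimate_column_rate()].
#' @return a one-row `data.frame` (`n_species`, `t_projected`, `observed`,
#'   `rs`, `at_bound`) or `NULL` when coverage is below `min_coverage`.
#' @export
score_column <- function(tree, column, model = jc69(), min_coverage = 3,
                         r_max = 5) {
  column <- column[!is.na(column) & column != "N" & column != "-"]
  if (length(column) < min_coverage) return(NULL)
  sub <- prune_to_taxa(tree, names(column))
  tproj <- total_length(sub)
  r <- rate_hat_pruned(sub, column, model, r_max)
  data.frame(n_species = length(column), t_projected = tproj,
             observed = as.numeric(r) * tproj,
             rs = tproj * (1 - as.numeric(r)),
             at_bound = isTRUE(attr(r, "at_bound")))
}

#' GERP RS score track over a whole alignment
#'
#' Streams over alignment blocks and scores every reference position with at
#' least `min_coverage` present species. Computation is memoized on the
#' (present-species set, base pattern) pair, which makes genome-scale scans
#' cheap: the vast majority of columns repeat a small set of patterns.
#'
#' @param aln a `genome_alignment`.
#' @param tree neutral tree; its leaves must cover the alignment species.
#' @param model a `subst_model`.
#' @param min_coverage minimum species per column (default 3).
#' @param r_max rate-multiplier cap.
#' @return `data.frame` of class `rs_track` with columns `seqname`, `pos`,
#'   `n_species`, `t_projected`, `observed`, `rs`, `at_bound`; attribute
#'   `tree_length` = total neutral tree length.
#' @export
score_alignment <- function(aln, tree, model = jc69(), min_coverage = 3,
                            r_max = 5) {
  offenders <- setdiff(aln$species_names, tree$tip.label)
  if (length(offenders))
    config_error("alignment species missing from tree: ",
                 paste(offenders, collapse = ", "))
  species <- aln$species_names
  subtree_cache <- new.env(parent = emptyenv())
  pattern_cache <- new.env(parent = emptyenv())
  res <- vector("list", length(aln$blocks))
  for (bi in seq_along(aln$blocks)) {
    bc <- block_columns(aln$blocks[[bi]])
    if (is.null(bc)) next
    full <- matrix(NA_character_, length(species), ncol(bc$bases),
                   dimnames = list(species, NULL))
    full[rownames(bc$bases), ] <- bc$bases
    present <- !is.na(full)
    nsp <- colSums(present)
    ok <- nsp >= min_coverage
    if (!any(ok)) next
    codes <- matrix(encode_bases(full), nrow = nrow(full))
    codes[is.na(codes)] <- 0L
    key <- do.call(paste0, as.data.frame(t(codes)))
    ok_idx <- which(ok)
    uniq <- key[ok_idx][!duplicated(key[ok_idx])]
    rep_idx <- ok_idx[!duplicated(key[ok_idx])]
    vals <- matrix(NA_real_, length(uniq), 4L)
    for (u in seq_along(uniq)) {
      hit <- pattern_cache[[uniq[u]]]
      if (is.null(hit)) {
        col <- full[, rep_idx[u]]
        col <- col[!is.na(col)]
        skey <- paste(names(col), collapse = ",")
        sub <- subtree_cache[[skey]]
        if (is.null(sub)) {
          sub <- prune_to_taxa(tree, names(col))
          subtree_cache[[skey]] <- sub
        }
        tproj <- total_length(sub)
        r <- rate_hat_pruned(sub, col, model, r_max)
        hit <- c(tproj, as.numeric(r) * tproj,
                 tproj * (1 - as.numeric(r)),
                 as.numeric(isTRUE(attr(r, "at_bound"))))
        pattern_cache[[uniq[u]]] <- hit
      }
      vals[u, ] <- hit
    }
    grp <- match(key, uniq)
    tp <- vals[grp, 1L]; ob <- vals[grp, 2L]; rs <- vals[grp, 3L]
    bd <- !is.na(grp) & vals[grp, 4L] > 0
    res[[bi]] <- data.frame(seqname = bc$seqname, pos = bc$pos,
                            n_species = nsp, t_projected = tp,
                            observed = ob, rs = rs, at_bound = bd,
                            stringsAsFactors = FALSE)[ok, , drop = FALSE]
  }
  out <- do.call(rbind, res[!vapply(res, is.null, TRUE)])
  if (is.null(out))
    out <- data.frame(seqname = character(), pos = integer(),
                      n_species = integer(), t_projected = numeric(),
                      observed = numeric(), rs = numeric(),
                      at_bound = logical())
  out <- out[order(out$seqname, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tree_length") <- total_length(tree)
  attr(out, "min_coverage") <- min_coverage
  class(out) <- c("rs_track", "data.frame")
  out
}

#' Export an RS track as TSV (and optionally BedGraph)
#' @param track an `rs_track`.
#' @param path TSV output path.
#' @param bedgraph optional BedGraph output path for the RS values.
#' @export
write_rs_track <- function(track, path, bedgraph = NULL) {
  utils::write.table(track, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bedgraph)) {
    con <- file(bedgraph, "w")
    writeLines("track type=bedGraph name=\"gerp_rs\"", con)
    writeLines(sprintf("%s\t%d\t%d\t%g", track$seqname, track$pos,
                       track$pos + 1L, track$rs), con)
    close(con)
  }
  invisible(path)
}
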