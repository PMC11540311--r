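# Tree handling and likelihood machinery. Trees are ape "phylo" objects with
# named tips and branch lengths in substitutions/site. The likelihood engine
# is Felsenstein's pruning algorithm vectorized over site patterns.

#' Parse a newick string into a rooted tree
#'
#' Thin validation layer over [ape::read.tree()]. Missing branch lengths are
#' set to 0 and flagged via the `"had_missing_lengths"` attribute.
#'
#' @param text newick string (must end in `;`).
#' @return an [ape::phylo] tree.
#' @export
parse_newick <- function(text) {
  if (length(grep("\\(", gsub("[^(]", "", text))) >= 0) {
    n_open <- nchar(gsub("[^(]", "", text))
    n_close <- nchar(gsub("[^)]", "", text))
    if (n_open != n_close) stop("newick parse error: unbalanced parentheses")
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("newick parse error: ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("newick parse error: could not read tree")
  if (anyDuplicated(tr$tip.label))
    stop("newick parse error: duplicate leaf label '",
         tr$tip.label[duplicated(tr$tip.label)][1], "'")
  had_missing <- is.null(tr$edge.length) || anyNA(tr$edge.length)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0)) stop("newick parse error: negative branch length")
  attr(tr, "had_missing_lengths") <- had_missing
  tr
}

#' Serialize a tree to newick
#' @param tree an [ape::phylo] tree.
#' @return newick string with 10 significant digits on branch lengths.
#' @export
write_newick <- function(tree) {
  old <- options(digits = 10)
  on.exit(options(old))
  ape::write.tree(tree, digits = 10)
}

#' Total branch length of a tree (substitutions/site)
#' @param tree an [ape::phylo] tree.
#' @export
total_length <- function(tree) {
  if (is.null(tree$edge.length)) 0 else sum(tree$edge.length)
}

#' Project a tree onto a taxon subset
#'
#' Induced subtree on `taxa`: dropped lineages are removed and degree-2
#' internal nodes are collapsed with their branch lengths summed, so the
#' total length equals the length of the union of paths connecting the
#' retained leaves.
#'
#' @param tree an [ape::phylo] tree.
#' @param taxa character vector of leaf names, at least 2, all present.
#' @return the pruned [ape::phylo] tree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) < 2) stop("prune_to_taxa: need at least 2 taxa")
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    config_error("taxa not in tree: ", paste(missing, collapse = ", "))
  if (setequal(taxa, tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

# --- pruning engine -------------------------------------------------------

# Precompute a postorder edge walk. Returns list(edge, lengths, ntip, nnode,
# root, tips) with edges ordered child-before-parent.
prep_tree <- function(tree) {
  tr <- stats::reorder(tree, "postorder")
  list(edge = tr$edge, lengths = tr$edge.length,
       ntip = length(tr$tip.label), nnode = tr$Nnode,
       root = length(tr$tip.label) + 1L, tips = tr$tip.label)
}

# Core likelihood: patterns is an (ntaxa x npat) integer matrix of base codes
# 1..4 with NA = missing (marginalized as a vector of ones). Rows named by
# taxon. Returns per-pattern log-likelihoods (length npat).
loglik_patterns <- function(prep, model, patterns, rate = 1,
                            lengths = NULL) {
  if (is.null(lengths)) lengths <- prep$lengths
  npat <- ncol(patterns)
  nnodes <- prep$ntip + prep$nnode
  # conditional likelihoods: list of 4 x npat matrices
  L <- vector("list", nnodes)
  idx <- match(prep$tips, rownames(patterns))
  for (i in seq_len(prep$ntip)) {
    M <- matrix(0, 4, npat)
    b <- if (is.na(idx[i])) rep(NA_integer_, npat) else patterns[idx[i], ]
    miss <- is.na(b)
    if (any(miss)) M[, miss] <- 1
    if (any(!miss)) M[cbind(b[!miss], which(!miss))] <- 1
    L[[i]] <- M
  }
  for (e in seq_len(nrow(prep$edge))) {
    parent <- prep$edge[e, 1L]
    child <- prep$edge[e, 2L]
    P <- transition_matrix(model, rate * lengths[e])
    contrib <- P %*% L[[child]]
    L[[parent]] <- if (is.null(L[[parent]])) contrib else L[[parent]] * contrib
  }
  lik <- colSums(model$freqs * L[[prep$root]])
  log(lik)
}

#' Log-likelihood of one alignment column
#'
#' Felsenstein pruning with the model's stationary frequencies at the root.
#' Tree leaves absent from `column` are marginalized (contribute a vector of
#' ones); `N` bases count as absent.
#'
#' @param tree an [ape::phylo] tree.
#' @param column named character vector, species -> base (`A/C/G/T`).
#' @param model a `subst_model` (default [jc69()]).
#' @param rate positive rate multiplier applied to all branch lengths.
#' @return the column log-likelihood (natural log).
#' @export
column_log_likelihood <- function(tree, column, model = jc69(), rate = 1) {
  stopifnot(rate >= 0)
  sp <- names(column)
  if (is.null(sp) || !length(sp)) stop("column must be a named base vector")
  unknown <- setdiff(sp, tree$tip.label)
  if (length(unknown))
    config_error("column species not in tree: ", paste(unknown, collapse = ", "))
  pat <- matrix(encode_bases(column), ncol = 1,
                dimnames = list(sp, NULL))
  prep <- prep_tree(tree)
  as.numeric(loglik_patterns(prep, model, pat, rate = rate))
}

# Compress a species x sites character matrix into unique patterns + weights.
# Returns list(patterns = ntaxa x npat integer matrix, weights).
compress_patterns <- function(mat) {
  codes <- matrix(encode_bases(mat), nrow = nrow(mat),
                  dimnames = list(rownames(mat), NULL))
  key <- do.call(paste, c(as.data.frame(t(codes)), sep = "."))
  first <- !duplicated(key)
  patterns <- codes[, first, drop = FALSE]
  weights <- as.numeric(table(factor(key, levels = key[first])))
  list(patterns = patterns, weights = weights)
}

#' Fit branch lengths by maximum likelihood on a fixed topology
#'
#' Coordinate-wise optimization: each branch in turn is optimized by 1-D
#' bounded search ([stats::optimize()]) on `[0, 10]` substitutions/site,
#' sweeping until the total log-likelihood improves by less than `tol`
#' (relative) or `max_sweeps` is reached. The topology is never changed and
#' sites with missing taxa are marginalized. Deterministic: all lengths start
#' at 0.05.
#'
#' @param topology an [ape::phylo] tree (branch lengths ignored).
#' @param alignment species x sites character matrix, named list/vector of
#'   equal-length sequence strings, or a [Biostrings::DNAStringSet].
#' @param model a `subst_model`.
#' @param tol relative convergence tolerance on the log-likelihood.
#' @param max_sweeps maximum number of passes over all branches.
#' @return the topology with fitted `edge.length`; attributes `logLik` and
#'   `converged`.
#' @export
fit_branch_lengths <- function(topology, alignment, model = jc69(),
                               tol = 1e-6, max_sweeps = 100) {
  mat <- as_alignment_matrix(alignment)
  common <- intersect(topology$tip.label, rownames(mat))
  if (length(common) < 2)
    config_error("alignment and topology share fewer than 2 taxa")
  if (ncol(mat) < 100)
    stop("fit_branch_lengths: need at least 100 alignment columns")
  tree <- if (setequal(common, topology$tip.label)) topology
          else prune_to_taxa(topology, common)
  cp <- compress_patterns(mat[tree$tip.label, , drop = FALSE])
  prep <- prep_tree(tree)
  lens <- rep(0.05, nrow(prep$edge))
  ll_total <- function(l) sum(cp$weights *
                              loglik_patterns(prep, model, cp$patterns,
                                              lengths = l))
  ll <- ll_total(lens)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    for (e in seq_along(lens)) {
      f <- function(x) { l2 <- lens; l2[e] <- x; ll_total(l2) }
      opt <- stats::optimize(f, c(0, 10), maximum = TRUE, tol = 1e-8)
      # candidate set includes the boundary at 0 (optimize avoids endpoints)
      cand <- c(opt$maximum, 0, lens[e])
      vals <- c(opt$objective, f(0), ll)
      best <- which.max(vals)
      if (vals[best] > ll) { lens[e] <- cand[best]; ll <- vals[best] }
    }
    new_ll <- ll_total(lens)
    if (sweep > 1 && (new_ll - ll_prev) <= tol * abs(ll_prev)) {
      converged <- TRUE; ll <- new_ll; break
    }
    ll_prev <- new_ll
    ll <- new_ll
  }
  if (!converged)
    warning("fit_branch_lengths: not converged after ", max_sweeps,
            " sweeps; returning last iterate")
  # map postorder edge lengths back onto the original edge ordering
  fitted <- tree
  po <- stats::reorder(tree, "postorder")
  key_po <- paste(po$edge[, 1], po$edge[, 2])
  key_or <- paste(fitted$edge[, 1], fitted$edge[, 2])
  fitted$edge.length <- lens[match(key_or, key_po)]
  attr(fitted, "logLik") <- ll
  attr(fitted, "converged") <- converged
  fitted
}

# Coerce the accepted alignment representations to a character matrix
# (rows = species, cols = sites).
as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    if (is.null(rownames(alignment))) stop("alignment matrix needs rownames")
    return(toupper(alignment))
  }
  if (methods::is(alignment, "DNAStringSet")) {
    seqs <- as.character(alignment)
  } else if (is.list(alignment) || is.character(alignment)) {
    seqs <- unlist(alignment)
  } else stop("unsupported alignment representation")
  if (is.null(names(seqs))) stop("alignment sequences must be named")
  n <- unique(nchar(seqs))
  if (length(n) != 1) stop("alignment sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  mat
}
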