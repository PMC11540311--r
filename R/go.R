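# Gene Ontology handling and the elim Fisher enrichment test. The ontology
# is reduced to its is_a DAG; annotations are propagated to all ancestors
# ("true path rule"); terms are then tested bottom-up, with the genes of
# significant descendants removed from ancestor counts so nested terms do
# not inherit their children's signal.

#' Load an OBO 1.2 ontology as an is_a DAG
#'
#' Only `is_a` edges are kept; obsolete terms are dropped. Levels are the
#' longest is-a path from a root (root = 0).
#'
#' @param path OBO file.
#' @return object of class `go_graph`: list with `terms` (data.frame `id`,
#'   `name`, `namespace`, `level`) and `parents` (named list id -> parent
#'   ids).
#' @export
load_obo <- function(path) {
  lines <- readLines(path)
  term_starts <- grep("^\\[Term\\]$", lines)
  other_stanza <- grep("^\\[(?!Term\\])", lines, perl = TRUE)
  bounds <- sort(c(term_starts, other_stanza, length(lines) + 1L))
  ids <- names <- ns <- character(0)
  parents <- list()
  for (s in term_starts) {
    e <- min(bounds[bounds > s]) - 1L
    chunk <- lines[s:e]
    get1 <- function(tag) {
      m <- grep(paste0("^", tag, ": "), chunk, value = TRUE)
      if (length(m)) sub(paste0("^", tag, ": "), "", m[1]) else NA_character_
    }
    if (any(grepl("^is_obsolete: true", chunk))) next
    id <- get1("id")
    if (is.na(id)) next
    isa <- grep("^is_a: ", chunk, value = TRUE)
    isa <- sub("^is_a: ", "", isa)
    isa <- trimws(sub("!.*$", "", isa))
    ids <- c(ids, id)
    names <- c(names, get1("name"))
    ns <- c(ns, get1("namespace"))
    parents[[id]] <- isa
  }
  # drop edges to dropped (obsolete/absent) terms
  parents <- lapply(parents, function(p) intersect(p, ids))
  # cycle check + longest-path levels by iterative relaxation
  level <- stats::setNames(rep(0L, length(ids)), ids)
  for (iter in seq_len(length(ids) + 1L)) {
    changed <- FALSE
    for (id in ids) {
      p <- parents[[id]]
      if (length(p)) {
        l <- max(level[p]) + 1L
        if (l > level[id]) { level[id] <- l; changed <- TRUE }
      }
    }
    if (!changed) break
    if (iter > length(ids)) stop("OBO format error: cycle in is_a graph")
  }
  structure(list(terms = data.frame(id = ids, name = names, namespace = ns,
                                    level = as.integer(level),
                                    stringsAsFactors = FALSE),
                 parents = parents),
            class = "go_graph")
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("go_graph: %d terms, %d levels, namespaces: %s\n",
              nrow(x$terms), max(x$terms$level) + 1L,
              paste(unique(stats::na.omit(x$terms$namespace)),
                    collapse = ", ")))
  invisible(x)
}

#' All ancestors of a term (excluding itself)
#' @param graph a `go_graph`.
#' @param id term identifier.
#' @return character vector of ancestor term ids.
#' @export
go_ancestors <- function(graph, id) {
  out <- character(0)
  frontier <- graph$parents[[id]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(graph$parents[frontier])), out)
  }
  out
}

#' Read a gene -> GO mapping TSV
#'
#' Two tab-separated columns: gene (BUSCO) id and a comma-separated list of
#' GO term ids.
#'
#' @param path mapping file.
#' @return named list gene id -> character vector of term ids.
#' @export
read_go_mapping <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("gene", "terms"),
                         colClasses = "character", quote = "")
  stats::setNames(strsplit(d$terms, ","), d$gene)
}

#' Propagate annotations up the DAG
#'
#' Maps each term to the set of genes annotated to it or to any descendant
#' (true-path rule), restricted to `genes`.
#'
#' @param graph a `go_graph`.
#' @param annotation named list gene -> directly annotated term ids.
#' @param genes restrict to these gene ids (default: all annotated genes).
#' @return named list term id -> character vector of gene ids.
#' @export
propagate_annotation <- function(graph, annotation, genes = NULL) {
  genes <- genes %||% names(annotation)
  term_genes <- new.env(parent = emptyenv())
  for (g in intersect(genes, names(annotation))) {
    direct <- intersect(annotation[[g]], graph$terms$id)
    all_terms <- unique(c(direct,
                          unlist(lapply(direct, go_ancestors,
                                        graph = graph))))
    for (t in all_terms)
      term_genes[[t]] <- c(term_genes[[t]], g)
  }
  out <- as.list(term_genes)
  lapply(out, unique)
}

#' BUSCO universe for enrichment testing
#'
#' Complete BUSCOs whose interval has a mean alignment coverage of at least
#' `min_family_depth` genomes for both families and a SNP density of at
#' least `min_snp_density` (1 SNP per 100 bp by default).
#'
#' @param busco_summaries a `busco_summary` from [aggregate_buscos()].
#' @param min_family_depth minimum mean family depth (default 2).
#' @param min_snp_density minimum SNP density, inclusive (default 0.01).
#' @return character vector of BUSCO ids.
#' @export
build_universe <- function(busco_summaries, min_family_depth = 2,
                           min_snp_density = 0.01) {
  fam_cols <- setdiff(grep("^mean_depth_", names(busco_summaries),
                           value = TRUE), "mean_depth_all")
  if (!length(fam_cols))
    config_error("busco summaries lack per-family depth columns")
  keep <- busco_summaries$status == "Complete"
  for (fc in fam_cols)
    keep <- keep & !is.na(busco_summaries[[fc]]) &
      busco_summaries[[fc]] >= min_family_depth
  keep <- keep & !is.na(busco_summaries$snp_density) &
    busco_summaries$snp_density >= min_snp_density
  unique(busco_summaries$busco_id[keep])
}

#' Top-percentile study set
#'
#' BUSCOs whose metric is at or above the given percentile (type-7
#' quantile) of the universe's values.
#'
#' @param busco_summaries a `busco_summary`.
#' @param universe BUSCO ids forming the universe.
#' @param metric `"rs"` or `"fst"`.
#' @param percentile percentile of the universe distribution (default 99).
#' @return character vector of BUSCO ids (the study set).
#' @export
select_top_set <- function(busco_summaries, universe,
                           metric = c("rs", "fst"), percentile = 99) {
  metric <- match.arg(metric)
  colname <- paste0("mean_", metric)
  rows <- busco_summaries[busco_summaries$busco_id %in% universe, ,
                          drop = FALSE]
  v <- tapply(rows[[colname]], rows$busco_id, mean, na.rm = TRUE)
  v <- v[!is.na(v)]
  if (!length(v)) return(character(0))
  thr <- stats::quantile(v, percentile / 100, type = 7, names = FALSE)
  names(v)[v >= thr]
}

#' elim Fisher GO enrichment
#'
#' Terms (restricted to one namespace) with at least `min_node_size`
#' annotated universe genes are tested from the deepest level upward with a
#' one-sided Fisher exact test (hypergeometric upper tail) for
#' over-representation in the study set. When a term's p-value falls below
#' `elim_alpha`, its annotated genes are eliminated from all ancestor
#' terms' counts before those are tested. With `elim_alpha = 0` the
#' procedure reduces to the classic per-term Fisher test.
#'
#' @param graph a `go_graph`.
#' @param annotation named list gene -> direct term ids.
#' @param study study gene ids (must be a subset of `universe`).
#' @param universe universe gene ids.
#' @param min_node_size minimum annotated universe genes per term
#'   (default 5).
#' @param elim_alpha significance cutoff that triggers elimination
#'   (default 0.01).
#' @param namespace restrict to this namespace (default
#'   `"biological_process"`); `NULL` = all.
#' @return `data.frame` of class `enrichment_result`: `term`, `name`,
#'   `annotated`, `significant`, `p`, `eliminated`, `members`.
#' @export
elim_fisher <- function(graph, annotation, study, universe,
                        min_node_size = 5, elim_alpha = 0.01,
                        namespace = "biological_process") {
  if (length(setdiff(study, universe)))
    config_error("study set is not a subset of the universe")
  term_genes <- propagate_annotation(graph, annotation, universe)
  terms <- graph$terms
  if (!is.null(namespace))
    terms <- terms[!is.na(terms$namespace) &
                   terms$namespace == namespace, , drop = FALSE]
  terms <- terms[terms$id %in% names(term_genes), , drop = FALSE]
  sizes <- vapply(term_genes[terms$id], length, 0L)
  terms <- terms[sizes >= min_node_size, , drop = FALSE]
  if (!nrow(terms))
    return(structure(data.frame(term = character(), name = character(),
                                annotated = integer(),
                                significant = integer(), p = numeric(),
                                eliminated = integer(),
                                members = character()),
                     class = c("enrichment_result", "data.frame")))
  # deepest first; ties by id for determinism
  terms <- terms[order(-terms$level, terms$id), , drop = FALSE]
  N <- length(unique(universe)); n_study <- length(unique(study))
  eliminated <- stats::setNames(vector("list", nrow(terms)), terms$id)
  res <- vector("list", nrow(terms))
  for (i in seq_len(nrow(terms))) {
    id <- terms$id[i]
    ann <- term_genes[[id]]
    elim <- eliminated[[id]]
    eff <- setdiff(ann, elim)
    K <- length(eff)
    k <- length(intersect(eff, study))
    p <- stats::phyper(k - 1, K, N - K, n_study, lower.tail = FALSE)
    res[[i]] <- data.frame(term = id, name = terms$name[i],
                           annotated = length(ann),
                           significant = length(intersect(ann, study)),
                           p = p, eliminated = length(intersect(elim, ann)),
                           members = paste(sort(intersect(ann, study)),
                                           collapse = ","),
                           stringsAsFactors = FALSE)
    if (p < elim_alpha) {
      for (anc in go_ancestors(graph, id))
        if (anc %in% names(eliminated))
          eliminated[[anc]] <- union(eliminated[[anc]], ann)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "universe_size") <- N
  attr(out, "study_size") <- n_study
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Top-k enrichment results
#'
#' Lowest p first; ties broken by larger study count, then term id.
#'
#' @param results an `enrichment_result`.
#' @param k number of terms to report (default 10).
#' @return the ranked head of `results`.
#' @export
report_top <- function(results, k = 10) {
  o <- order(results$p, -results$significant, results$term)
  out <- results[utils::head(o, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}
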