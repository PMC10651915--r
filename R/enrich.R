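#' Parse a gene annotation table into a gene -> term mapping
#'
#' @param annotation data frame with gene_id and a semicolon-joined
#'   term column.
#' @param terms_col name of the term column (default "go_ids").
#' @return named list mapping gene_id to a character vector of terms.
#' @export
annotation_terms <- function(annotation, terms_col = "go_ids") {
  stopifnot("gene_id" %in% names(annotation),
            terms_col %in% names(annotation))
  if (anyDuplicated(annotation$gene_id)) stopf("duplicate gene ids")
  terms <- strsplit(as.character(annotation[[terms_col]]), ";",
                    fixed = TRUE)
  terms <- lapply(terms, function(t) t[nzchar(t)])
  names(terms) <- annotation$gene_id
  terms
}

## ancestors (excluding the term itself) for every term in a parent map
term_ancestors <- function(dag) {
  stopifnot(all(c("child", "parent") %in% names(dag)))
  g <- igraph::graph_from_data_frame(dag[, c("child", "parent")])
  if (!igraph::is_dag(g)) stopf("term parent map contains a cycle")
  parents <- split(as.character(dag$parent), as.character(dag$child))
  anc <- function(term) {
    seen <- character(0)
    frontier <- parents[[term]] %||% character(0)
    while (length(frontier)) {
      seen <- union(seen, frontier)
      frontier <- unique(unlist(lapply(frontier,
                                       function(t) parents[[t]]),
                                use.names = FALSE))
      frontier <- setdiff(frontier, seen)
    }
    seen
  }
  all_terms <- unique(c(dag$child, dag$parent))
  stats::setNames(lapply(all_terms, anc), all_terms)
}

#' Hypergeometric term over-representation analysis
#'
#' For each term annotating at least one study gene, the upper-tail
#' hypergeometric probability of observing at least the study count is
#' computed against the annotated population, followed by
#' Benjamini-Hochberg adjustment over all tested terms. With
#' \code{propagate = TRUE} (ontology-style) a gene annotated to a term
#' also counts for all of the term's ancestors in \code{dag}; flat
#' category schemes should leave propagation off.
#'
#' @param study character vector of study gene ids (must be a subset
#'   of the population).
#' @param annotation annotation data frame (see
#'   \code{\link{annotation_terms}}).
#' @param population character vector of population gene ids; default
#'   is every annotated gene.
#' @param terms_col term column to use.
#' @param propagate propagate annotations up the term DAG.
#' @param dag parent map data frame (child, parent); required when
#'   \code{propagate} is TRUE.
#' @return data frame: term_id, study_count, study_size, pop_count,
#'   pop_size, p, q, sorted by p.
#' @export
hypergeom_enrich <- function(study, annotation,
                             population = annotation$gene_id,
                             terms_col = "go_ids", propagate = FALSE,
                             dag = NULL) {
  study <- unique(as.character(study))
  population <- unique(as.character(population))
  if (!all(study %in% population))
    stopf("study gene(s) absent from population: %s",
          paste(utils::head(setdiff(study, population)), collapse = ", "))
  terms <- annotation_terms(annotation, terms_col)
  terms <- terms[intersect(names(terms), population)]
  if (propagate) {
    if (is.null(dag)) stopf("propagation requires a term DAG")
    anc <- term_ancestors(dag)
    terms <- lapply(terms, function(t)
      unique(c(t, unlist(anc[intersect(t, names(anc))],
                         use.names = FALSE))))
  }
  gene_of_term <- split(rep(names(terms), lengths(terms)),
                        unlist(terms, use.names = FALSE))
  pop_size <- length(population)
  study_size <- length(study)
  rows <- lapply(names(gene_of_term), function(tm) {
    genes <- gene_of_term[[tm]]
    k <- sum(study %in% genes)
    if (k == 0) return(NULL)
    K <- length(unique(genes))
    p <- stats::phyper(k - 1, K, pop_size - K, study_size,
                       lower.tail = FALSE)
    data.frame(term_id = tm, study_count = k, study_size = study_size,
               pop_count = K, pop_size = pop_size, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(0), study_count = integer(0),
                      study_size = integer(0), pop_count = integer(0),
                      pop_size = integer(0), p = numeric(0),
                      q = numeric(0)))
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcriptome-proteome intersection network
#'
#' Merges two enrichment result sets over the same term universe into
#' a term graph: a term is a node when its enrichment p-value is <=
#' alpha in at least one dataset, with membership \code{"both"},
#' \code{"transcriptome_only"} or \code{"proteome_only"}; node size is
#' the sum of the study counts ("cluster frequencies") across the two
#' datasets. Edges are the parent-child links of the term DAG
#' restricted to included nodes.
#'
#' @param enrich_t,enrich_p enrichment tables from
#'   \code{\link{hypergeom_enrich}} for the transcriptome and the
#'   proteome.
#' @param dag optional parent map (child, parent); must be acyclic.
#' @param alpha inclusion level (default 0.05).
#' @return an \code{igraph} graph with vertex attributes
#'   \code{membership} and \code{size}.
#' @export
intersect_networks <- function(enrich_t, enrich_p, dag = NULL,
                               alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must be in (0,1)")
  sig_t <- enrich_t$term_id[enrich_t$p <= alpha]
  sig_p <- enrich_p$term_id[enrich_p$p <= alpha]
  nodes <- union(sig_t, sig_p)
  membership <- ifelse(nodes %in% sig_t & nodes %in% sig_p, "both",
                       ifelse(nodes %in% sig_t, "transcriptome_only",
                              "proteome_only"))
  count_in <- function(tbl, term) {
    i <- match(term, tbl$term_id)
    ifelse(is.na(i), 0L, tbl$study_count[i])
  }
  size <- count_in(enrich_t, nodes) + count_in(enrich_p, nodes)
  edges <- data.frame(from = character(0), to = character(0))
  if (!is.null(dag) && nrow(dag) > 0) {
    term_ancestors(dag)  # validates acyclicity
    keep <- dag$child %in% nodes & dag$parent %in% nodes
    edges <- data.frame(from = as.character(dag$child[keep]),
                        to = as.character(dag$parent[keep]))
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = nodes, membership = membership,
                          size = size))
  g
}

#' Export an intersection network
#'
#' @param graph result of \code{\link{intersect_networks}}.
#' @param graphml_path optional path for a GraphML export.
#' @param nodes_path,edges_path optional paths for node/edge TSVs.
#' @return invisibly, the graph.
#' @export
write_network <- function(graph, graphml_path = NULL, nodes_path = NULL,
                          edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(nodes_path)) {
    v <- igraph::as_data_frame(graph, what = "vertices")
    names(v)[names(v) == "name"] <- "term_id"
    write_tsv(v, nodes_path)
  }
  if (!is.null(edges_path))
    write_tsv(igraph::as_data_frame(graph, what = "edges"), edges_path)
  invisible(graph)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Used e.g. for testing whether secreted genes are enriched in one
#' regulatory family. No continuity correction by default; Yates
#' correction available via \code{yates = TRUE}.
#'
#' @param table 2x2 matrix of nonnegative counts with positive
#'   margins.
#' @param yates apply the continuity correction.
#' @return list with \code{chi2}, \code{p} (upper tail, df = 1) and
#'   the input \code{table}.
#' @export
contingency_chi2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stopf("need a 2x2 table")
  if (any(table < 0)) stopf("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("zero margin in contingency table")
  ht <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value),
       table = table)
}
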