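#' Assign significant pathways to functional categories
#'
#' Two modes.  With a mapping file (curated labels, the reference mode):
#' assignments are copied and unmapped significant pathways are labelled
#' `"unassigned"`.  Without one, an automated surrogate groups pathways by
#' single-linkage clustering on the Jaccard similarity of their
#' changed-gene sets; clusters are merged while similarity is at least
#' `jaccard_threshold`, and each cluster is labelled by the name of its
#' largest member pathway (ties broken alphabetically).  The provenance
#' of every assignment is recorded.
#'
#' @param result an [run_enrichment()] result with at least one
#'   significant pathway.
#' @param mapping optional data.frame with columns `pathway_id`,
#'   `category` (curated labels); ids absent from the significant set
#'   trigger a warning.
#' @param jaccard_threshold similarity at or above which two pathways
#'   (or clusters, via single linkage) are merged (default 0.3).
#' @return data.frame of class `category_assignment`: `pathway_id`,
#'   `category`, `provenance` (`"manual_config"` or `"overlap_cluster"`).
#' @export
assign_categories <- function(result, mapping = NULL,
                              jaccard_threshold = 0.3) {
  stopifnot(inherits(result, "enrichment_result"))
  sig <- result$pathway_id[result$significant]
  if (length(sig) == 0L) stop("no significant pathways to assign")
  if (!is.null(mapping)) {
    stopifnot(is.data.frame(mapping),
              all(c("pathway_id", "category") %in% names(mapping)))
    unknown <- setdiff(mapping$pathway_id, result$pathway_id)
    if (length(unknown))
      warning("mapping references unknown pathway ids: ",
              paste(unknown, collapse = ", "))
    cat_of <- stats::setNames(as.character(mapping$category),
                              mapping$pathway_id)
    category <- ifelse(sig %in% names(cat_of), unname(cat_of[sig]),
                       "unassigned")
    prov <- "manual_config"
  } else {
    sets <- attr(result, "changed_genes")[sig]
    category <- .jaccard_single_linkage(sets, jaccard_threshold,
                                        sizes = result$n[result$significant])
    prov <- "overlap_cluster"
  }
  out <- data.frame(pathway_id = sig, category = category,
                    provenance = prov, stringsAsFactors = FALSE)
  class(out) <- c("category_assignment", "data.frame")
  out
}

# single-linkage clustering of gene sets at a Jaccard similarity
# threshold; labels each cluster by its largest pathway's name
.jaccard_single_linkage <- function(sets, threshold, sizes = NULL) {
  K <- length(sets)
  if (is.null(sizes)) sizes <- lengths(sets)
  if (K == 1L) return(names(sets))
  jac <- matrix(0, K, K)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      u <- length(union(sets[[i]], sets[[j]]))
      jac[i, j] <- jac[j, i] <-
        if (u == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - jac), method = "single")
  # merge while similarity >= threshold, i.e. distance <= 1 - threshold
  cl <- stats::cutree(hc, h = 1 - threshold)
  labels <- vapply(split(seq_len(K), cl), function(idx) {
    nm <- names(sets)[idx]
    nm[order(-sizes[idx], nm)][1]
  }, character(1))
  unname(labels[as.character(cl)])
}

#' Build the gene-category cluster network
#'
#' Bipartite-derived graph linking differentially expressed genes to the
#' functional categories whose significant pathways contain them.  A gene
#' enters the network iff `|logFC| > display_cutoff` and it is a changed
#' gene of at least one significant pathway.  Gene nodes carry their
#' `logFC`, a direction (`"up"`/`"down"`) and `n_clusters`, the number of
#' categories they connect to (the node-size attribute of the standard
#' rendering); categories without any retained gene are dropped.
#'
#' @param assignment a [assign_categories()] result.
#' @param result the [run_enrichment()] result the assignment came from.
#' @param gene_stats named numeric vector mapping gene id to logFC; must
#'   cover all changed genes of the significant pathways.
#' @param display_cutoff strict cutoff on `|logFC|` (default 0.58).
#' @return list of class `cluster_network`: `graph` (an
#'   \pkg{igraph} bipartite graph), `genes` (data.frame `gene_id`,
#'   `logFC`, `direction`, `n_clusters`), `edges` (data.frame `gene_id`,
#'   `category`), `categories` (character vector).
#' @export
build_network <- function(assignment, result, gene_stats,
                          display_cutoff = 0.58) {
  stopifnot(inherits(assignment, "category_assignment"),
            inherits(result, "enrichment_result"))
  ch_sets <- attr(result, "changed_genes")
  edges <- NULL
  for (i in seq_len(nrow(assignment))) {
    pid <- assignment$pathway_id[i]
    genes <- ch_sets[[pid]]
    if (length(genes))
      edges <- rbind(edges, data.frame(gene_id = genes,
                                       category = assignment$category[i],
                                       stringsAsFactors = FALSE))
  }
  if (is.null(edges)) edges <- data.frame(gene_id = character(0),
                                          category = character(0),
                                          stringsAsFactors = FALSE)
  missing <- setdiff(unique(edges$gene_id), names(gene_stats))
  if (length(missing))
    stop("gene_stats does not cover changed genes: ",
         paste(utils::head(missing, 5), collapse = ", "))
  keep <- abs(gene_stats[edges$gene_id]) > display_cutoff
  edges <- unique(edges[keep, , drop = FALSE])
  edges <- edges[order(edges$gene_id, edges$category), , drop = FALSE]
  rownames(edges) <- NULL

  gene_ids <- sort(unique(edges$gene_id))
  n_cl <- if (length(gene_ids))
    as.integer(table(edges$gene_id)[gene_ids]) else integer(0)
  genes <- data.frame(
    gene_id = gene_ids,
    logFC = unname(gene_stats[gene_ids]),
    direction = ifelse(gene_stats[gene_ids] > 0, "up", "down"),
    n_clusters = n_cl,
    stringsAsFactors = FALSE)
  categories <- sort(unique(edges$category))

  g <- igraph::make_empty_graph(directed = FALSE)
  if (nrow(genes) > 0) {
    verts <- data.frame(
      name = c(genes$gene_id, categories),
      type = c(rep(FALSE, nrow(genes)), rep(TRUE, length(categories))),
      logFC = c(genes$logFC, rep(NA_real_, length(categories))),
      direction = c(genes$direction, rep(NA_character_,
                                         length(categories))),
      n_clusters = c(genes$n_clusters, rep(NA_integer_,
                                           length(categories))),
      stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = verts)
  }
  structure(list(graph = g, genes = genes, edges = edges,
                 categories = categories,
                 display_cutoff = display_cutoff),
            class = "cluster_network")
}

#' @export
print.cluster_network <- function(x, ...) {
  cat(sprintf(
    "cluster_network: %d genes x %d categories, %d edges (|logFC| > %g)\n",
    nrow(x$genes), length(x$categories), nrow(x$edges), x$display_cutoff))
  invisible(x)
}

#' Table of genes shared between functional clusters
#'
#' Summarizes the network by gene: how many categories each gene belongs
#' to and which, keeping genes in at least `min_clusters` categories.
#' Rows are sorted by cluster count descending, then gene id; category
#' lists are alphabetical.
#'
#' @param network a [build_network()] result.
#' @param min_clusters minimum number of categories (default 2).
#' @return data.frame `gene_id`, `n_clusters`, `categories`
#'   (comma-separated).
#' @export
shared_gene_table <- function(network, min_clusters = 2L) {
  stopifnot(inherits(network, "cluster_network"))
  g <- network$genes
  g <- g[g$n_clusters >= min_clusters, , drop = FALSE]
  cats <- vapply(g$gene_id, function(id)
    paste(sort(network$edges$category[network$edges$gene_id == id]),
          collapse = ", "), character(1))
  out <- data.frame(gene_id = g$gene_id, n_clusters = g$n_clusters,
                    categories = unname(cats), stringsAsFactors = FALSE)
  out <- out[order(-out$n_clusters, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a cluster network to GraphML and/or SIF
#'
#' GraphML preserves the node attributes (logFC, direction, n_clusters,
#' bipartite type); SIF carries the topology only, one
#' `category <TAB> contains <TAB> gene` line per edge.  Colors and sizes
#' are emitted as numeric/string attributes, not rendered.
#'
#' @param network a [build_network()] result.
#' @param graphml optional GraphML output path.
#' @param sif optional SIF output path.
#' @return invisible list of the written paths.
#' @export
export_network <- function(network, graphml = NULL, sif = NULL) {
  stopifnot(inherits(network, "cluster_network"))
  if (!is.null(graphml))
    igraph::write_graph(network$graph, graphml, format = "graphml")
  if (!is.null(sif)) {
    lines <- sprintf("%s\tcontains\t%s", network$edges$category,
                     network$edges$gene_id)
    writeLines(lines, sif)
  }
  invisible(list(graphml = graphml, sif = sif))
}
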