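#' Pathway collection
#'
#' A set of named gene sets, typically merged from one or more GMT files
#' (e.g. WikiPathways, KEGG and Reactome exports combined for larger
#' pathway coverage).
#'
#' @param gene_sets named list of character vectors (pathway id -> genes);
#'   duplicate genes within a set are collapsed; empty sets are rejected.
#' @param descriptions optional character vector of per-pathway
#'   descriptions (GMT second field).
#' @param source optional single source tag (e.g. the database name).
#' @return list of class `pathway_collection` with elements `gene_sets`,
#'   `descriptions`, `source`.
#' @export
pathway_collection <- function(gene_sets, descriptions = NULL,
                               source = NA_character_) {
  if (!is.list(gene_sets) || is.null(names(gene_sets)) ||
      anyDuplicated(names(gene_sets)))
    stop("gene_sets must be a uniquely named list")
  gene_sets <- lapply(gene_sets, function(g) unique(as.character(g)))
  if (any(lengths(gene_sets) == 0L))
    stop("empty gene sets are not allowed: ",
         paste(names(gene_sets)[lengths(gene_sets) == 0L], collapse = ", "))
  if (is.null(descriptions)) descriptions <- rep("", length(gene_sets))
  if (length(descriptions) != length(gene_sets))
    stop("descriptions must match the number of gene sets")
  structure(list(gene_sets = gene_sets,
                 descriptions = stats::setNames(as.character(descriptions),
                                                names(gene_sets)),
                 source = source),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("pathway_collection: %d pathways, %d unique genes%s\n",
              length(x$gene_sets), length(unique(unlist(x$gene_sets))),
              if (is.na(x$source)) "" else paste0(" [", x$source, "]")))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$gene_sets)

#' Read a GMT gene-set file
#'
#' Standard GMT: one pathway per tab-separated line --- name, description,
#' then member genes.  Duplicate genes within a line are collapsed; lines
#' with fewer than 3 fields raise an error naming the line number.
#'
#' @param path path of the GMT file.
#' @param source optional source tag stored on the collection.
#' @return a [pathway_collection()].
#' @export
read_gmt <- function(path, source = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(pathway_collection(stats::setNames(list(), character(0)),
                              character(0), source))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  ids <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- ids
  pathway_collection(sets, desc, source)
}

#' Write a pathway collection as GMT
#'
#' @param collection a [pathway_collection()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "pathway_collection"))
  lines <- vapply(names(collection$gene_sets), function(id) {
    paste(c(id, collection$descriptions[[id]],
            collection$gene_sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge pathway collections into one
#'
#' Combines several collections (e.g. one per source database) into a
#' single collection for a joint overrepresentation run.  On a pathway-id
#' collision the source tag is prepended (`source:id`) to keep ids unique.
#'
#' @param ... `pathway_collection` objects.
#' @return a merged [pathway_collection()].
#' @export
merge_collections <- function(...) {
  cols <- list(...)
  if (length(cols) == 1L && is.list(cols[[1]]) &&
      !inherits(cols[[1]], "pathway_collection"))
    cols <- cols[[1]]
  stopifnot(all(vapply(cols, inherits, logical(1), "pathway_collection")))
  if (length(cols) == 1L) return(cols[[1]])
  sets <- list()
  desc <- character(0)
  for (cl in cols) {
    ids <- names(cl$gene_sets)
    clash <- ids %in% names(sets)
    ids[clash] <- paste(ifelse(is.na(cl$source), "merged", cl$source),
                        ids[clash], sep = ":")
    if (anyDuplicated(c(names(sets), ids)))
      stop("pathway ids still collide after source tagging")
    add <- cl$gene_sets
    names(add) <- ids
    sets <- c(sets, add)
    desc <- c(desc, stats::setNames(unname(cl$descriptions), ids))
  }
  pathway_collection(sets, desc, NA_character_)
}
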