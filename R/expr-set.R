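#' Expression set: probe-by-sample log2 intensity matrix plus sample metadata
#'
#' The basic container of the per-study preprocessing stages, in the style
#' of a limma expression matrix with a `targets` frame.  Values are log2
#' intensities; rows are probes, columns are samples.
#'
#' @param exprs numeric matrix, probes x samples, with unique non-empty
#'   rownames (probe ids) and colnames (sample ids).
#' @param metadata data.frame with one row per sample and columns
#'   `sample_id`, `individual`, `condition` (`"treated"` or `"control"`)
#'   and `replicate`.  Row order must match the matrix columns.
#' @return An object of class `expr_set`: a list with elements `exprs`
#'   and `metadata`.
#' @examples
#' m <- matrix(rnorm(8), 2, 4,
#'   dimnames = list(c("p1", "p2"), paste0("s", 1:4)))
#' md <- data.frame(
#'   sample_id = paste0("s", 1:4),
#'   individual = c("i1", "i1", "i2", "i2"),
#'   condition = c("treated", "control", "treated", "control"),
#'   replicate = 1L)
#' es <- expr_set(m, md)
#' @export
expr_set <- function(exprs, metadata) {
  if (!is.matrix(exprs) || !is.numeric(exprs))
    stop("'exprs' must be a numeric matrix")
  if (is.null(rownames(exprs)) || anyDuplicated(rownames(exprs)))
    stop("'exprs' must have unique probe rownames")
  if (is.null(colnames(exprs)) || anyDuplicated(colnames(exprs)))
    stop("'exprs' must have unique sample colnames")
  need <- c("sample_id", "individual", "condition", "replicate")
  if (!is.data.frame(metadata) || !all(need %in% names(metadata)))
    stop("'metadata' must contain columns: ", paste(need, collapse = ", "))
  if (nrow(metadata) != ncol(exprs) ||
      !identical(as.character(metadata$sample_id), colnames(exprs)))
    stop("metadata sample_id must match exprs colnames in order")
  bad <- setdiff(unique(metadata$condition), c("treated", "control"))
  if (length(bad))
    stop("unknown condition labels: ", paste(bad, collapse = ", "))
  structure(list(exprs = exprs, metadata = metadata), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf(
    "expr_set: %d probes x %d samples (%d individuals; %d treated, %d control)\n",
    nrow(x$exprs), ncol(x$exprs),
    length(unique(x$metadata$individual)),
    sum(x$metadata$condition == "treated"),
    sum(x$metadata$condition == "control")))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$exprs)

#' Read / write an expression set as a pair of TSV files
#'
#' The expression file has a `probe_id` key column followed by one column
#' per sample; the metadata file has columns `sample_id`, `individual`,
#' `condition`, `replicate`.  Lines starting with `#` are ignored.
#'
#' @param expr_path path of the probe x sample intensity TSV.
#' @param metadata_path path of the sample metadata TSV.
#' @return `read_expression_tsv` returns an [expr_set()];
#'   `write_expression_tsv` returns the expression file path, invisibly.
#' @export
read_expression_tsv <- function(expr_path, metadata_path) {
  ex <- read_tsv(expr_path, check.names = FALSE)
  md <- read_tsv(metadata_path)
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex[[1]]
  md$sample_id <- as.character(md$sample_id)
  expr_set(m, md)
}

#' @param es an [expr_set()].
#' @param header_lines optional character vector of `#`-prefixed
#'   provenance lines written atop both files.
#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(es, expr_path, metadata_path,
                                 header_lines = NULL) {
  stopifnot(inherits(es, "expr_set"))
  df <- data.frame(probe_id = rownames(es$exprs), es$exprs,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, expr_path, header_lines)
  write_tsv(es$metadata, metadata_path, header_lines)
  invisible(expr_path)
}
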