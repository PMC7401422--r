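#' Weighted-average log2 fold change across studies
#'
#' Combines per-study log2 fold changes with weights `-log10(p_i)`:
#' `sum(logFC_i * -log10(p_i)) / sum(-log10(p_i))`.  Studies with strong
#' evidence therefore dominate the cross-study estimate.  If every weight
#' is zero (all p-values equal 1) the unweighted arithmetic mean is
#' returned as a documented fallback so the gene is not dropped.
#'
#' @param logfcs numeric vector of per-study log2 fold changes.
#' @param pvalues numeric vector of per-study p-values in (0, 1], same
#'   length as `logfcs`.
#' @param size_weights optional positive multipliers (e.g. the number of
#'   individuals per study) applied on top of the `-log10 p` weights.
#' @return The weighted average (scalar).
#' @examples
#' weighted_logfc(c(1, 0), c(0.001, 0.1))  # (3*1 + 1*0)/(3+1) = 0.75
#' @export
weighted_logfc <- function(logfcs, pvalues, size_weights = NULL) {
  .check_lfc_p(logfcs, pvalues)
  w <- neglog10(pvalues)
  if (!is.null(size_weights)) {
    if (length(size_weights) != length(w) || any(size_weights <= 0))
      stop("size_weights must be positive and match length")
    w <- w * size_weights
  }
  if (sum(w) == 0) return(mean(logfcs))
  sum(logfcs * w) / sum(w)
}

#' Weighted-average p-value across studies
#'
#' The cross-study evidence weight is the mean of `-log10(p_i)` over the
#' studies measuring the gene; back-transforming gives
#' `combined_p = 10^(-average_weight)`, the geometric mean of the input
#' p-values.  An average weight of 4.33 thus corresponds to a combined
#' p-value of about 5e-5.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return list with `average_weight` and `combined_p`.
#' @examples
#' weighted_pvalue(c(0.001, 0.1))  # average_weight 2, combined_p 0.01
#' @export
weighted_pvalue <- function(pvalues) {
  .check_lfc_p(rep(0, length(pvalues)), pvalues)
  w <- mean(neglog10(pvalues))
  list(average_weight = w, combined_p = 10^(-w))
}

.check_lfc_p <- function(logfcs, pvalues) {
  if (length(logfcs) == 0L || length(logfcs) != length(pvalues))
    stop("logfcs and pvalues must be non-empty and of equal length")
  if (any(!is.finite(logfcs))) stop("logFC values must be finite")
  if (any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  invisible(TRUE)
}

#' Configuration of the cross-study integration
#'
#' @param k_min a gene must have been measured in at least `k_min` studies
#'   to enter the integrated result (default 4).
#' @param n_total nominal number of studies (default 5); `k_min` must not
#'   exceed it.
#' @param logfc_cutoff differential-expression cutoff on
#'   `|weighted_logFC|` (default 0.58, about a 1.5-fold change on the
#'   original scale); strict inequality.
#' @param p_cutoff differential-expression cutoff on the combined p-value
#'   (default 0.05); strict inequality.
#' @param size_weighted logical; additionally weight each study's logFC by
#'   its number of individuals (off by default: the plain `-log10 p`
#'   weighting is the reference behaviour).
#' @return list of class `integration_config`.
#' @export
integration_config <- function(k_min = 4L, n_total = 5L,
                               logfc_cutoff = 0.58, p_cutoff = 0.05,
                               size_weighted = FALSE) {
  cfg <- list(k_min = as.integer(k_min), n_total = as.integer(n_total),
              logfc_cutoff = as.numeric(logfc_cutoff),
              p_cutoff = as.numeric(p_cutoff),
              size_weighted = isTRUE(size_weighted))
  if (cfg$k_min < 1L || cfg$k_min > cfg$n_total)
    stop("k_min must satisfy 1 <= k_min <= n_total")
  if (cfg$logfc_cutoff <= 0 || cfg$p_cutoff <= 0)
    stop("cutoffs must be positive")
  structure(cfg, class = "integration_config")
}

#' Integrate per-study gene statistics into cross-study summaries
#'
#' Merges deduplicated per-study records by gene id, removes genes
#' measured in fewer than `k_min` studies, and computes for each remaining
#' gene the weighted-average log2 fold change, the average evidence
#' weight (mean `-log10 p`), and its back-transformed combined p-value.
#' A gene is called differentially expressed when
#' `|weighted_logFC| > logfc_cutoff` and `combined_p < p_cutoff`, both
#' strict.
#'
#' @param stats data.frame of per-study per-gene records with columns
#'   `study_id`, `gene_id`, `logFC`, `p_value` and optionally
#'   `n_individuals` (required when `cfg$size_weighted`); at most one
#'   record per (study, gene) pair.
#' @param cfg an [integration_config()].
#' @return data.frame of class `integrated_genes`, one row per surviving
#'   gene: `gene_id`, `n_studies_measured`, `weighted_logFC`,
#'   `average_weight`, `combined_p`, `weight_fallback` (TRUE when all
#'   study weights were zero and the unweighted mean was used),
#'   `is_differentially_expressed`.  Sorted by gene id; the config is in
#'   attribute `config`.
#' @export
integrate_studies <- function(stats, cfg = integration_config()) {
  stopifnot(is.data.frame(stats), inherits(cfg, "integration_config"))
  need <- c("study_id", "gene_id", "logFC", "p_value")
  if (!all(need %in% names(stats)))
    stop("stats must contain columns: ", paste(need, collapse = ", "))
  key <- paste(stats$study_id, stats$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- stats[duplicated(key), c("study_id", "gene_id")]
    stop("duplicate (study, gene) pairs; deduplicate first: ",
         paste(utils::head(paste(dup$study_id, dup$gene_id, sep = "/"), 3),
               collapse = ", "))
  }
  .check_lfc_p(stats$logFC, stats$p_value)
  if (cfg$size_weighted && !("n_individuals" %in% names(stats)))
    stop("size_weighted integration needs an n_individuals column")

  parts <- split(stats, stats$gene_id)
  n_meas <- vapply(parts, nrow, integer(1))
  parts <- parts[n_meas >= cfg$k_min]
  if (length(parts) == 0L)
    warning("no gene measured in >= ", cfg$k_min, " studies")
  rows <- lapply(parts, function(df) {
    sw <- if (cfg$size_weighted) df$n_individuals else NULL
    wl <- weighted_logfc(df$logFC, df$p_value, sw)
    wp <- weighted_pvalue(df$p_value)
    data.frame(gene_id = df$gene_id[1],
               n_studies_measured = nrow(df),
               weighted_logFC = wl,
               average_weight = wp$average_weight,
               combined_p = wp$combined_p,
               weight_fallback = all(neglog10(df$p_value) == 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), n_studies_measured = integer(0),
                      weighted_logFC = numeric(0), average_weight = numeric(0),
                      combined_p = numeric(0), weight_fallback = logical(0),
                      stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out$is_differentially_expressed <-
    abs(out$weighted_logFC) > cfg$logfc_cutoff &
    out$combined_p < cfg$p_cutoff
  attr(out, "config") <- cfg
  class(out) <- c("integrated_genes", "data.frame")
  out
}

#' @export
print.integrated_genes <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf(
    "integrated_genes: %d genes (k_min=%d), %d differentially expressed (|logFC|>%g & p<%g)\n",
    nrow(x), cfg$k_min, sum(x$is_differentially_expressed),
    cfg$logfc_cutoff, cfg$p_cutoff))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.integrated_genes <- function(object, ...) {
  cfg <- attr(object, "config")
  res <- list(
    n_genes = nrow(object),
    n_de = sum(object$is_differentially_expressed),
    n_up = sum(object$is_differentially_expressed &
                 object$weighted_logFC > 0),
    n_down = sum(object$is_differentially_expressed &
                   object$weighted_logFC < 0),
    n_fallback = sum(object$weight_fallback),
    config = cfg)
  class(res) <- "summary.integrated_genes"
  res
}

#' @export
print.summary.integrated_genes <- function(x, ...) {
  cat(sprintf(
    "%d integrated genes; %d DE (%d up, %d down); %d weight fallbacks\n",
    x$n_genes, x$n_de, x$n_up, x$n_down, x$n_fallback))
  invisible(x)
}

#' Volcano plot of an integrated result
#'
#' @param x an `integrated_genes` object.
#' @param ... passed to [plot()].
#' @export
plot.integrated_genes <- function(x, ...) {
  cfg <- attr(x, "config")
  col <- ifelse(x$is_differentially_expressed, "red3", "grey50")
  plot(x$weighted_logFC, x$average_weight, col = col, pch = 20,
       xlab = "weighted log2 fold change",
       ylab = "average weight (-log10 p)", ...)
  graphics::abline(v = c(-1, 1) * cfg$logfc_cutoff, lty = 2)
  graphics::abline(h = -log10(cfg$p_cutoff), lty = 2)
  invisible(x)
}
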