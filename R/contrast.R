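#' Responder vs nonresponder fold-change contrast
#'
#' From a table of mean abundances (FPKM scale) per gene --- responders
#' treated (`A`) and control (`B`), nonresponders treated (`C`) and
#' control (`D`) --- computes the pseudocounted log2 fold changes
#' `logFC_R = log2((A+1)/(B+1))` and `logFC_NR = log2((C+1)/(D+1))`, their
#' difference (the responder-specific contrast) and their mean (the
#' overall treatment effect).  The +1 pseudocount keeps every quantity
#' finite for any non-negative abundance.
#'
#' @param table data.frame with columns `gene_id`, `A`, `B`, `C`, `D`;
#'   abundances must be finite and non-negative.
#' @param pseudocount the additive pseudocount; fixed at 1 by the
#'   definition of the contrast, exposed only for expert use.
#' @return data.frame of class `responder_contrast`, one row per input
#'   gene in input order: `gene_id`, `A`, `B`, `C`, `D`, `logFC_R`,
#'   `logFC_NR`, `diff_R_minus_NR`, `mean_effect`.
#' @examples
#' contrast_table(data.frame(gene_id = "g", A = 3, B = 1, C = 0, D = 0))
#' @export
contrast_table <- function(table, pseudocount = 1) {
  stopifnot(is.data.frame(table))
  need <- c("gene_id", "A", "B", "C", "D")
  if (!all(need %in% names(table)))
    stop("table must contain columns: ", paste(need, collapse = ", "))
  for (col in c("A", "B", "C", "D")) {
    v <- table[[col]]
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf("negative or non-finite abundance: gene %s, column %s",
                   table$gene_id[bad[1]], col))
  }
  pc <- pseudocount
  lr <- log2((table$A + pc) / (table$B + pc))
  ln <- log2((table$C + pc) / (table$D + pc))
  out <- data.frame(gene_id = table$gene_id,
                    A = table$A, B = table$B, C = table$C, D = table$D,
                    logFC_R = lr, logFC_NR = ln,
                    diff_R_minus_NR = lr - ln,
                    mean_effect = (lr + ln) / 2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("responder_contrast", "data.frame")
  out
}

#' Call changed genes from a responder contrast by fold-change cutoff only
#'
#' For summary-level abundance data no p-values are available, so changed
#' genes are defined purely by an absolute log2 fold-change cutoff on
#' either the responder-minus-nonresponder difference (`which = "diff"`)
#' or the overall treatment effect (`which = "mean"`).  Inequalities are
#' strict, so a value exactly at the cutoff is called unchanged.
#'
#' @param records a `responder_contrast` from [contrast_table()].
#' @param which `"diff"` (responder-specific contrast) or `"mean"`
#'   (overall treatment effect).
#' @param logfc_cutoff positive cutoff (default 0.58, about 1.5-fold).
#' @return list with character vectors `up` (value > cutoff) and `down`
#'   (value < -cutoff); the sets are disjoint.
#' @export
call_changed_genes <- function(records, which = c("diff", "mean"),
                               logfc_cutoff = 0.58) {
  stopifnot(inherits(records, "responder_contrast"))
  which <- match.arg(which)
  if (logfc_cutoff <= 0) stop("logfc_cutoff must be positive")
  v <- if (which == "diff") records$diff_R_minus_NR else records$mean_effect
  list(up = records$gene_id[v > logfc_cutoff],
       down = records$gene_id[v < -logfc_cutoff])
}

#' @export
print.responder_contrast <- function(x, ...) {
  cat(sprintf("responder_contrast: %d genes\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
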