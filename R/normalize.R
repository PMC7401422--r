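#' Quantile-normalize an expression set
#'
#' Forces every sample (column) onto the same empirical distribution: each
#' column's values are replaced by the mean of the column-sorted values at
#' the corresponding rank, with ties receiving the mean of the rank-means
#' they span.  Delegates to [limma::normalizeQuantiles()] with averaged
#' ties; row and column labels are preserved.
#'
#' @param es an [expr_set()] with at least 2 probes and 2 samples.
#' @return The normalized [expr_set()].
#' @export
quantile_normalize <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  m <- es$exprs
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("quantile normalization needs >= 2 probes and >= 2 samples")
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    bad <- utils::head(bad, 5)
    stop("non-finite values at: ",
         paste(sprintf("(%s, %s)", rownames(m)[bad[, 1]],
                       colnames(m)[bad[, 2]]), collapse = ", "))
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  expr_set(out, es$metadata)
}

#' Flag low-quality samples by median inter-sample correlation
#'
#' An automated surrogate for curated quality control of array data: for
#' each sample, the median Pearson correlation against all other samples
#' is computed; samples falling below `min_median_correlation` are
#' flagged.  Per-sample signal median and IQR are reported alongside.
#' Constant-valued samples (zero variance, correlation undefined) are
#' flagged with an explicit reason.  Flagging never deletes: dropping is a
#' separate, auditable step (see `drop_flagged`).
#'
#' @param es an [expr_set()] with at least 3 samples.
#' @param min_median_correlation flag threshold (default 0.8); samples
#'   with median correlation strictly below it are flagged.
#' @return A data.frame of class `qc_report` with columns `sample_id`,
#'   `median_correlation`, `signal_median`, `signal_iqr`, `flagged`,
#'   `reason`; the threshold is stored in attribute `flag_threshold`.
#' @export
qc_flag_samples <- function(es, min_median_correlation = 0.8) {
  stopifnot(inherits(es, "expr_set"))
  m <- es$exprs
  if (ncol(m) < 3L) stop("QC needs >= 3 samples")
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  diag(cc) <- NA
  med_cor <- apply(cc, 2, stats::median, na.rm = TRUE)
  med_cor[sds == 0] <- NA_real_
  flagged <- !is.na(med_cor) & med_cor < min_median_correlation
  reason <- ifelse(sds == 0, "zero variance",
                   ifelse(flagged, "low median correlation", ""))
  flagged <- flagged | sds == 0
  rep <- data.frame(
    sample_id = colnames(m),
    median_correlation = unname(med_cor),
    signal_median = unname(apply(m, 2, stats::median)),
    signal_iqr = unname(apply(m, 2, stats::IQR)),
    flagged = unname(flagged),
    reason = unname(reason),
    stringsAsFactors = FALSE)
  attr(rep, "flag_threshold") <- min_median_correlation
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d samples, %d flagged (threshold %.3g)\n",
              nrow(x), sum(x$flagged), attr(x, "flag_threshold")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Drop the samples a QC report flagged
#'
#' @param es an [expr_set()].
#' @param report a `qc_report` from [qc_flag_samples()].
#' @return The [expr_set()] without the flagged samples.
#' @export
drop_flagged <- function(es, report) {
  stopifnot(inherits(es, "expr_set"), inherits(report, "qc_report"))
  keep <- !(colnames(es$exprs) %in% report$sample_id[report$flagged])
  if (sum(keep) < 2L) stop("dropping flagged samples leaves < 2 samples")
  expr_set(es$exprs[, keep, drop = FALSE], es$metadata[keep, , drop = FALSE])
}
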