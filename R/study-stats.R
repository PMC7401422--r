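#' Average within-individual replicates
#'
#' Collapses replicate samples so every individual contributes one column
#' per condition, giving each individual the same weight in the downstream
#' statistics.  Individuals observed in only one condition are excluded
#' from the result with a warning (they cannot inform a treated-vs-control
#' comparison).
#'
#' @param es an [expr_set()] whose metadata identifies `individual`,
#'   `condition` and `replicate`.
#' @return An [expr_set()] with one column per (individual, condition),
#'   each value the arithmetic mean of that individual's replicates.
#' @export
average_replicates <- function(es) {
  stopifnot(inherits(es, "expr_set"))
  md <- es$metadata
  key <- paste(md$individual, md$condition, sep = ".")
  groups <- split(seq_len(ncol(es$exprs)), key)
  # preserve first-appearance order of the groups
  groups <- groups[unique(key)]
  m <- vapply(groups, function(j)
    rowMeans(es$exprs[, j, drop = FALSE]), numeric(nrow(es$exprs)))
  m <- matrix(m, nrow = nrow(es$exprs),
              dimnames = list(rownames(es$exprs), names(groups)))
  ind <- vapply(groups, function(j) md$individual[j[1]], character(1))
  cond <- vapply(groups, function(j) md$condition[j[1]], character(1))
  has_both <- tapply(cond, ind, function(x)
    all(c("treated", "control") %in% x))
  unpaired <- names(has_both)[!has_both]
  if (length(unpaired)) {
    warning("individuals without both conditions excluded: ",
            paste(unpaired, collapse = ", "))
    keep <- !(ind %in% unpaired)
    m <- m[, keep, drop = FALSE]
    ind <- ind[keep]
    cond <- cond[keep]
  }
  if (ncol(m) == 0L) stop("no individual has both conditions")
  expr_set(m, data.frame(sample_id = colnames(m), individual = unname(ind),
                         condition = unname(cond), replicate = 1L,
                         stringsAsFactors = FALSE))
}

# limma-style inversion of the trigamma function by Newton iteration
.trigamma_inverse <- function(x) {
  y <- numeric(length(x))
  hi <- x > 1e7
  lo <- x < 1e-6
  mid <- !hi & !lo
  y[hi] <- 1 / sqrt(x[hi])
  y[lo] <- 1 / x[lo]
  if (any(mid)) {
    z <- x[mid]
    g <- 0.5 + 1 / z
    for (i in 1:50) {
      tri <- trigamma(g)
      dif <- tri * (1 - tri / z) / psigamma(g, deriv = 2)
      g <- g + dif
      if (max(-dif / g) < 1e-8) break
    }
    y[mid] <- g
  }
  y
}

# moment-matching fit of a scaled F prior to sample variances: under
# s2 ~ s0^2 * F(d, d0), log(s2) has closed-form mean/variance in terms of
# digamma/trigamma; invert those moments to estimate (d0, s0^2)
.fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 3L) return(list(df_prior = 0, s2_prior = NA_real_))
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

.row_var <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Per-probe differential statistics between treated and control samples
#'
#' For each probe: the log2 fold change (mean treated minus mean control),
#' a two-sample pooled-variance t statistic, and a two-sided p-value.
#' With `moderate = TRUE` the per-probe variances are shrunk towards a
#' common prior by empirical-Bayes moderation: the prior degrees of
#' freedom and variance are estimated by moment matching on the
#' distribution of log sample variances, and the posterior variance is
#' `(d0*s0^2 + d*s^2) / (d0 + d)` with `d0 + d` total degrees of freedom.
#' This stabilizes inference in the very small studies typical of this
#' domain (1--6 individuals).
#'
#' Probes with no residual degrees of freedom (or fewer than 2 when
#' moderation is off) receive `p_value = 1` and an explanatory flag rather
#' than NaN.  p-values are clamped at 1e-300 so downstream -log10 weights
#' stay finite.
#'
#' @param es an [expr_set()], normally after [average_replicates()].
#' @param moderate logical; apply empirical-Bayes variance moderation.
#' @return data.frame with columns `probe_id`, `logFC`, `mean_expr`, `t`,
#'   `p_value`, `df`, `flag`.  The estimated prior (`df_prior`,
#'   `s2_prior`) is attached as attribute `variance_prior` when
#'   moderation is on.
#' @export
differential_stats <- function(es, moderate = TRUE) {
  stopifnot(inherits(es, "expr_set"))
  cond <- es$metadata$condition
  tr <- es$exprs[, cond == "treated", drop = FALSE]
  ct <- es$exprs[, cond == "control", drop = FALSE]
  n1 <- ncol(tr)
  n2 <- ncol(ct)
  if (n1 < 1L || n2 < 1L)
    stop("need >= 1 treated and >= 1 control sample")
  logfc <- rowMeans(tr) - rowMeans(ct)
  d <- n1 + n2 - 2L
  v1 <- .row_var(tr)
  v2 <- .row_var(ct)
  s2 <- if (d > 0) {
    ((if (n1 > 1) (n1 - 1) * v1 else 0) +
     (if (n2 > 1) (n2 - 1) * v2 else 0)) / d
  } else {
    rep(NA_real_, nrow(es$exprs))
  }

  flag <- rep("", nrow(es$exprs))
  tstat <- rep(NA_real_, nrow(es$exprs))
  pval <- rep(1, nrow(es$exprs))
  df_tot <- rep(as.numeric(d), nrow(es$exprs))
  prior <- NULL

  if (d == 0L) {
    flag[] <- "no_residual_df"
  } else if (d < 2L && !moderate) {
    flag[] <- "low_df"
  } else {
    s2_used <- s2
    if (moderate) {
      prior <- .fit_variance_prior(s2, d)
      if (prior$df_prior > 0 && is.finite(prior$s2_prior)) {
        s2_used <- if (is.infinite(prior$df_prior)) {
          rep(prior$s2_prior, length(s2))
        } else {
          (prior$df_prior * prior$s2_prior + d * s2) / (prior$df_prior + d)
        }
        df_tot[] <- d + prior$df_prior
      } else if (d < 2L) {
        flag[] <- "low_df"
      }
    }
    if (!all(flag == "low_df")) {
      se <- sqrt(s2_used * (1 / n1 + 1 / n2))
      tstat <- logfc / se
      zero_var <- se == 0
      tstat[zero_var & logfc == 0] <- 0
      flag[zero_var] <- "zero_variance"
      pval <- 2 * stats::pt(-abs(tstat), df = pmin(df_tot, 1e6))
      pval <- clamp_p(pval)
      pval[is.na(tstat)] <- 1
    }
  }

  out <- data.frame(
    probe_id = rownames(es$exprs),
    logFC = unname(logfc),
    mean_expr = unname(rowMeans(cbind(tr, ct))),
    t = unname(tstat),
    p_value = unname(pval),
    df = unname(df_tot),
    flag = flag,
    stringsAsFactors = FALSE)
  if (moderate && !is.null(prior)) attr(out, "variance_prior") <- prior
  out
}

#' Map probes to genes and deduplicate to one record per gene
#'
#' Converts probe-level statistics to gene level.  When several probes map
#' to one gene, the record maximizing `|logFC * (-log10 p)|` is kept, as
#' this represents the largest change jointly in effect size and evidence;
#' exact score ties are broken by the lexicographically smallest probe id.
#' Unmapped probes are counted and reported, never silently dropped.
#'
#' @param stats per-probe statistics from [differential_stats()].
#' @param probe_map data.frame with columns `probe_id`, `gene_id`
#'   (many-to-one and one-to-many both allowed).
#' @param study_id study label stamped on every record.
#' @param n_individuals number of individuals behind the statistics
#'   (stored for optional study-size weighting at integration).
#' @return data.frame of per-gene records: `study_id`, `gene_id`,
#'   `probe_id`, `logFC`, `p_value`, `mean_expr`, `t`, `n_individuals`,
#'   `dedup_score`; the number of unmapped probes is in attribute
#'   `n_unmapped`.
#' @export
map_and_deduplicate <- function(stats, probe_map, study_id = "study",
                                n_individuals = NA_integer_) {
  stopifnot(is.data.frame(stats), is.data.frame(probe_map))
  unmapped <- setdiff(stats$probe_id, probe_map$probe_id)
  if (length(unmapped))
    message(length(unmapped), " probe(s) without gene mapping dropped")
  merged <- merge(stats, probe_map, by = "probe_id")
  if (nrow(merged) == 0L) {
    out <- data.frame(study_id = character(0), gene_id = character(0),
                      probe_id = character(0), logFC = numeric(0),
                      p_value = numeric(0), mean_expr = numeric(0),
                      t = numeric(0), n_individuals = integer(0),
                      dedup_score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "n_unmapped") <- length(unmapped)
    return(out)
  }
  merged$dedup_score <- abs(merged$logFC * neglog10(merged$p_value))
  # highest score first; ties -> smallest probe_id
  merged <- merged[order(merged$gene_id, -merged$dedup_score,
                         merged$probe_id), ]
  keep <- !duplicated(merged$gene_id)
  out <- merged[keep, ]
  out <- data.frame(study_id = study_id, gene_id = out$gene_id,
                    probe_id = out$probe_id, logFC = out$logFC,
                    p_value = out$p_value, mean_expr = out$mean_expr,
                    t = out$t, n_individuals = as.integer(n_individuals),
                    dedup_score = out$dedup_score,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- length(unmapped)
  out
}

#' Run the whole per-study stage on one expression set
#'
#' Convenience wrapper: quantile normalization, QC flagging (optionally
#' dropping flagged samples), replicate averaging, differential
#' statistics, and probe-to-gene deduplication.
#'
#' @inheritParams differential_stats
#' @inheritParams map_and_deduplicate
#' @param qc_min_correlation threshold for [qc_flag_samples()].
#' @param drop logical; drop flagged samples before statistics.
#' @return list with `gene_stats` (see [map_and_deduplicate()]) and
#'   `qc` (the [qc_flag_samples()] report, or NULL for < 3 samples).
#' @export
study_pipeline <- function(es, probe_map, study_id = "study",
                           moderate = TRUE, qc_min_correlation = 0.8,
                           drop = TRUE) {
  es <- quantile_normalize(es)
  qc <- NULL
  if (ncol(es$exprs) >= 3L) {
    qc <- qc_flag_samples(es, qc_min_correlation)
    if (drop && any(qc$flagged)) es <- drop_flagged(es, qc)
  }
  es <- average_replicates(es)
  st <- differential_stats(es, moderate = moderate)
  n_ind <- length(unique(es$metadata$individual))
  list(gene_stats = map_and_deduplicate(st, probe_map, study_id, n_ind),
       qc = qc)
}
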