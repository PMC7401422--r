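#' Overrepresentation Z-score with finite-population variance
#'
#' Standardized excess of changed genes in a pathway.  With `N` genes
#' measured, `R` of them changed, `n` pathway genes among the measured,
#' and `r` changed pathway genes, the null expectation of `r` is `n*R/N`
#' and its variance the hypergeometric one, giving
#' `z = (r - n*R/N) / sqrt(n * (R/N) * (1 - R/N) * (1 - (n-1)/(N-1)))`.
#' When the variance term is zero (no changed genes, all genes changed,
#' or the pathway spans the whole universe) the score is defined as 0.
#'
#' @param N number of measured genes (universe size), >= 2.
#' @param R number of changed genes in the universe.
#' @param n number of pathway genes in the universe, > 0.
#' @param r number of changed pathway genes.
#' @return The Z-score (vectorized over equal-length inputs).
#' @examples
#' zscore(100, 10, 10, 5)  # ~ 4.42
#' @export
zscore <- function(N, R, n, r) {
  if (any(N < 2)) stop("N must be >= 2")
  if (any(n <= 0 | n > N)) stop("need 0 < n <= N")
  if (any(R < 0 | R > N)) stop("need 0 <= R <= N")
  if (any(r < 0 | r > pmin(n, R))) stop("need 0 <= r <= min(n, R)")
  p <- R / N
  v <- n * p * (1 - p) * (1 - (n - 1) / (N - 1))
  z <- rep(0, length(v + N + R + n + r))
  ok <- v > 0
  z[ok] <- ((r - n * p) / sqrt(v))[ok]
  z
}

# pathway-by-universe membership indicator matrix
.membership_matrix <- function(collection, universe) {
  K <- length(collection$gene_sets)
  M <- matrix(0, nrow = K, ncol = length(universe),
              dimnames = list(names(collection$gene_sets), universe))
  for (k in seq_len(K)) {
    M[k, universe %in% collection$gene_sets[[k]]] <- 1
  }
  M
}

#' Permutation p-values for pathway overrepresentation
#'
#' Permutes the changed-gene labels across the measured universe,
#' preserving the total number of changed genes `R` and every pathway
#' size `n`, and counts how often the permuted Z-score reaches the
#' observed one.  Because Z is monotone increasing in `r` for fixed
#' `(N, R, n)`, this equals counting permutations with `r* >= r`.
#' Add-one smoothing, `(1 + #exceedances) / (n_perm + 1)`, keeps the
#' p-value strictly positive.  The test is one-sided
#' (overrepresentation).
#'
#' @param universe character vector of measured genes.
#' @param changed character vector of changed genes, a subset of
#'   `universe`.
#' @param collection a [pathway_collection()]; pathways with no gene in
#'   the universe are excluded with a warning.
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @return named numeric vector of permuted p-values per pathway.
#' @export
permutation_pvalues <- function(universe, changed, collection,
                                n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(collection, "pathway_collection"), n_perm >= 1L)
  universe <- unique(as.character(universe))
  changed <- unique(as.character(changed))
  out <- setdiff(changed, universe)
  if (length(out))
    stop("changed genes outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  M <- .membership_matrix(collection, universe)
  n_in <- rowSums(M)
  if (any(n_in == 0)) {
    warning("pathways with no gene in the universe excluded: ",
            paste(names(n_in)[n_in == 0], collapse = ", "))
    M <- M[n_in > 0, , drop = FALSE]
  }
  Np <- length(universe)
  R <- length(changed)
  obs <- as.numeric(M %*% as.numeric(universe %in% changed))
  set.seed(seed)
  perm <- matrix(0, nrow = Np, ncol = n_perm)
  for (b in seq_len(n_perm)) perm[sample.int(Np, R), b] <- 1
  rstar <- M %*% perm
  exceed <- rowSums(rstar >= obs)
  stats::setNames((1 + exceed) / (n_perm + 1), rownames(M))
}

#' Pathway overrepresentation analysis
#'
#' Tests every pathway of a collection for overrepresentation of changed
#' genes against the measured universe.  Per pathway it reports the
#' counts (`N`, `R`, `n`, `r`), the finite-population [zscore()], the
#' label-permutation p-value, a Benjamini-Hochberg adjusted column (for
#' transparency only), and the three-part significance call:
#' `z >= z_cutoff` AND `permuted_p < p_cutoff` AND `r > min_changed`
#' (defaults 1.96, 0.05 and 3; all as stated, i.e. at least 4 changed
#' genes are required).
#'
#' @inheritParams permutation_pvalues
#' @param z_cutoff Z-score threshold (inclusive; default 1.96).
#' @param p_cutoff permuted p-value threshold (strict; default 0.05).
#' @param min_changed minimum changed genes, strict `r > min_changed`
#'   (default 3).
#' @return data.frame of class `enrichment_result`, sorted by Z
#'   descending: `pathway_id`, `N`, `R`, `n`, `r`, `z_score`,
#'   `permuted_p`, `p_bh`, `significant`.  The changed genes per pathway
#'   are in attribute `changed_genes` (named list); the universe and
#'   changed sets in attributes `universe` and `changed`.
#' @export
run_enrichment <- function(changed, universe, collection,
                           n_perm = 1000L, seed = 1L,
                           z_cutoff = 1.96, p_cutoff = 0.05,
                           min_changed = 3L) {
  stopifnot(inherits(collection, "pathway_collection"))
  universe <- unique(as.character(universe))
  changed <- unique(as.character(changed))
  out <- setdiff(changed, universe)
  if (length(out))
    stop("changed genes outside the universe: ",
         paste(utils::head(out, 5), collapse = ", "))
  pp <- suppressWarnings(
    permutation_pvalues(universe, changed, collection, n_perm, seed))
  keep_ids <- names(pp)
  sets <- collection$gene_sets[keep_ids]
  if (length(keep_ids) < length(collection$gene_sets))
    warning("pathways with no gene in the universe excluded: ",
            paste(setdiff(names(collection$gene_sets), keep_ids),
                  collapse = ", "))
  Np <- length(universe)
  R <- length(changed)
  n <- vapply(sets, function(g) sum(g %in% universe), numeric(1))
  ch_sets <- lapply(sets, function(g) intersect(g, changed))
  r <- lengths(ch_sets)
  z <- zscore(rep(Np, length(n)), rep(R, length(n)), n, r)
  res <- data.frame(pathway_id = keep_ids,
                    N = Np, R = R, n = as.integer(n), r = as.integer(r),
                    z_score = z,
                    permuted_p = unname(pp),
                    p_bh = unname(stats::p.adjust(pp, method = "BH")),
                    stringsAsFactors = FALSE)
  res$significant <- res$z_score >= z_cutoff &
    res$permuted_p < p_cutoff & res$r > min_changed
  res <- res[order(-res$z_score, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "changed_genes") <- ch_sets
  attr(res, "universe") <- universe
  attr(res, "changed") <- changed
  attr(res, "thresholds") <- list(z_cutoff = z_cutoff, p_cutoff = p_cutoff,
                                  min_changed = min_changed,
                                  n_perm = n_perm, seed = seed)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat(sprintf(
    "enrichment_result: %d pathways, %d significant (z>=%.3g, p<%.3g, r>%d; %d permutations)\n",
    nrow(x), sum(x$significant), th$z_cutoff, th$p_cutoff,
    th$min_changed, th$n_perm))
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE,
                   digits = 4)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.enrichment_result <- function(object, ...) {
  cat(sprintf("universe %d genes, %d changed; %d/%d pathways significant\n",
              object$N[1], object$R[1], sum(object$significant),
              nrow(object)))
  invisible(object)
}
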