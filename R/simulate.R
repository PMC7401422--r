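#' Configuration of the synthetic multi-study simulation
#'
#' Describes the study structure the generator emulates: a handful of small
#' microarray studies of trabecular-meshwork cells treated with a
#' corticosteroid versus control, with 1--6 individuals per study, optional
#' within-individual replicates, partially overlapping gene coverage,
#' multi-probe genes, and a differential-expression signal concentrated in
#' designated pathways.  All expression values are log2 intensities and all
#' noise is additive Gaussian on that scale.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_studies number of studies.
#' @param individuals_per_study integer vector of length `n_studies`.
#' @param replicates_per_individual replicates per (individual, condition).
#' @param coverage_fraction_range length-2 numeric in (0,1]; each study
#'   measures a uniformly drawn fraction of the gene universe in this range.
#' @param multiprobe_fraction fraction of covered genes carried by two
#'   probes instead of one (probes share the gene effect plus a fixed
#'   probe-level offset).
#' @param n_pathways number of gene sets in the simulated collection.
#' @param pathway_size_range length-2 integer; minimum must be >= 4 so the
#'   ">3 changed genes" significance rule is reachable.
#' @param enriched_pathway_ids pathway ids carrying concentrated signal;
#'   defaults to the first three pathways.
#' @param de_fraction_background fraction of non-enriched-pathway genes that
#'   are differentially expressed.
#' @param de_fraction_enriched fraction of each enriched pathway's genes
#'   that are differentially expressed.
#' @param effect_size_log2 absolute treated-minus-control shift (log2 units)
#'   of differentially expressed genes; sign is random per gene.
#' @param noise_sd_log2 per-measurement Gaussian noise SD (log2 units).
#' @param responder_effect_log2 responder-specific shift (log2 units) used
#'   by [simulate_responder_table()].
#' @param seed master seed; per-study substreams are derived at fixed
#'   offsets so adding a study never perturbs earlier studies.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_studies()], [simulate_responder_table()]
#' @export
sim_config <- function(n_genes = 1000L,
                       n_studies = 5L,
                       individuals_per_study = c(1L, 2L, 5L, 3L, 6L),
                       replicates_per_individual = 1L,
                       coverage_fraction_range = c(0.85, 1),
                       multiprobe_fraction = 0.2,
                       n_pathways = 25L,
                       pathway_size_range = c(10L, 40L),
                       enriched_pathway_ids = NULL,
                       de_fraction_background = 0.05,
                       de_fraction_enriched = 0.6,
                       effect_size_log2 = 1.0,
                       noise_sd_log2 = 0.3,
                       responder_effect_log2 = 1.5,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_studies = as.integer(n_studies),
    individuals_per_study = as.integer(individuals_per_study),
    replicates_per_individual = as.integer(replicates_per_individual),
    coverage_fraction_range = as.numeric(coverage_fraction_range),
    multiprobe_fraction = as.numeric(multiprobe_fraction),
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    enriched_pathway_ids = enriched_pathway_ids,
    de_fraction_background = as.numeric(de_fraction_background),
    de_fraction_enriched = as.numeric(de_fraction_enriched),
    effect_size_log2 = as.numeric(effect_size_log2),
    noise_sd_log2 = as.numeric(noise_sd_log2),
    responder_effect_log2 = as.numeric(responder_effect_log2),
    seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_studies < 1L)
    stop("n_genes and n_studies must be positive")
  if (length(cfg$individuals_per_study) != cfg$n_studies)
    stop("individuals_per_study must have length n_studies")
  if (any(cfg$individuals_per_study < 1L) || cfg$replicates_per_individual < 1L)
    stop("individuals and replicates counts must be >= 1")
  cr <- cfg$coverage_fraction_range
  if (length(cr) != 2L || any(cr <= 0) || any(cr > 1) || cr[1] > cr[2])
    stop("coverage_fraction_range must be an increasing pair in (0, 1]")
  for (f in c("multiprobe_fraction", "de_fraction_background",
              "de_fraction_enriched")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  pr <- cfg$pathway_size_range
  if (length(pr) != 2L || pr[1] < 4L || pr[1] > pr[2])
    stop("pathway_size_range must be an increasing pair with minimum >= 4")
  if (pr[2] > cfg$n_genes) stop("pathway_size_range exceeds gene universe")
  if (cfg$effect_size_log2 < 0 || cfg$noise_sd_log2 < 0)
    stop("effect_size_log2 and noise_sd_log2 must be non-negative")
  if (is.null(cfg$enriched_pathway_ids))
    cfg$enriched_pathway_ids <-
      sprintf("PW%03d", seq_len(min(3L, cfg$n_pathways)))
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "sim_config: %d genes, %d studies (individuals: %s), seed %d\n",
    x$n_genes, x$n_studies,
    paste(x$individuals_per_study, collapse = ","), x$seed))
  cat(sprintf(
    "  effect %.2f log2, noise %.2f log2, DE %.0f%% background / %.0f%% in %s\n",
    x$effect_size_log2, x$noise_sd_log2, 100 * x$de_fraction_background,
    100 * x$de_fraction_enriched,
    paste(x$enriched_pathway_ids, collapse = ",")))
  invisible(x)
}

# expected genes surviving a measured-in->=4-studies filter, at the most
# optimistic coverage; < 1 means the design is infeasible
.expected_k_of_n <- function(cfg, k = 4L) {
  k <- min(k, cfg$n_studies)
  p_hi <- cfg$coverage_fraction_range[2]
  cfg$n_genes * stats::pbinom(k - 1L, cfg$n_studies, p_hi, lower.tail = FALSE)
}

#' Simulate multi-study expression data with planted pathway signal
#'
#' Generates one probe-level log2 intensity matrix per study (with sample
#' metadata), a probe-to-gene map, a pathway collection, and the ground
#' truth of planted effects.  Differentially expressed genes are shifted by
#' their true log2 fold change in treated samples only; probes of a
#' multi-probe gene share the gene effect plus an independent probe-level
#' offset, so probe deduplication has real work to do.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_studies` with elements:
#' \describe{
#'   \item{studies}{named list of [expr_set()] objects, one per study.}
#'   \item{probe_map}{data.frame `probe_id`, `gene_id`.}
#'   \item{pathways}{a [pathway_collection()].}
#'   \item{truth}{list of class `ground_truth`: `de_gene_ids`,
#'     `true_log2fc` (named vector over DE genes),
#'     `enriched_pathway_ids`, `responder_specific_gene_ids` (filled by
#'     [simulate_responder_table()]).}
#'   \item{config}{the input config.}
#' }
#' @export
# deterministic gene universe, pathway collection and planted DE signal;
# shared by simulate_studies and simulate_responder_table so the
# responder-specific genes can coincide with the cross-study signal
.simulate_universe <- function(cfg) {
  set.seed(cfg$seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                  cfg$n_pathways, replace = TRUE)
  pw_ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  pw_sets <- lapply(sizes, function(k) sort(sample(genes, k)))
  names(pw_sets) <- pw_ids
  missing_pw <- setdiff(cfg$enriched_pathway_ids, pw_ids)
  if (length(missing_pw))
    stop("enriched_pathway_ids not in collection: ",
         paste(missing_pw, collapse = ", "))
  # planted differential expression: concentrated in enriched pathways,
  # sparse in the background
  de <- character(0)
  for (pid in cfg$enriched_pathway_ids) {
    g <- pw_sets[[pid]]
    de <- union(de, sample(g, ceiling(cfg$de_fraction_enriched * length(g))))
  }
  bg <- setdiff(genes, unlist(pw_sets[cfg$enriched_pathway_ids]))
  n_bg <- round(cfg$de_fraction_background * length(bg))
  if (n_bg > 0) de <- union(de, sample(bg, n_bg))
  de <- sort(de)
  true_lfc <- stats::setNames(
    sample(c(-1, 1), length(de), replace = TRUE) * cfg$effect_size_log2, de)
  list(genes = genes, pw_sets = pw_sets, de = de, true_lfc = true_lfc)
}

simulate_studies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (.expected_k_of_n(config) < 1)
    stop("infeasible design: coverage too low for any gene to be ",
         "measured in >= 4 studies")
  cfg <- config
  uni <- .simulate_universe(cfg)
  genes <- uni$genes
  pw_sets <- uni$pw_sets
  de <- uni$de
  true_lfc <- uni$true_lfc
  collection <- pathway_collection(
    pw_sets, descriptions = rep("simulated", cfg$n_pathways),
    source = "sim")

  # gene baselines and probe layout shared across studies
  baseline <- stats::setNames(stats::rnorm(cfg$n_genes, 7, 1.5), genes)
  n_multi <- round(cfg$multiprobe_fraction * cfg$n_genes)
  multi <- if (n_multi > 0) sample(genes, n_multi) else character(0)
  map_gene <- c(genes, multi)
  ord <- order(map_gene)
  map_gene <- map_gene[ord]
  probe_ids <- sprintf("PR%06d", seq_along(map_gene))
  probe_map <- data.frame(probe_id = probe_ids, gene_id = map_gene,
                          stringsAsFactors = FALSE)
  probe_offset <- stats::setNames(
    stats::rnorm(length(probe_ids), 0, 0.3), probe_ids)

  studies <- vector("list", cfg$n_studies)
  names(studies) <- sprintf("study%d", seq_len(cfg$n_studies))
  for (s in seq_len(cfg$n_studies)) {
    # fixed-offset substream: adding a study leaves earlier ones untouched
    set.seed(cfg$seed + 97L * s)
    cov <- stats::runif(1, cfg$coverage_fraction_range[1],
                        cfg$coverage_fraction_range[2])
    g_s <- sort(sample(genes, max(1L, round(cov * cfg$n_genes))))
    keep <- probe_map$gene_id %in% g_s
    pr_s <- probe_map$probe_id[keep]
    gn_s <- probe_map$gene_id[keep]

    n_ind <- cfg$individuals_per_study[s]
    reps <- cfg$replicates_per_individual
    md <- expand.grid(replicate = seq_len(reps),
                      condition = c("treated", "control"),
                      individual = sprintf("ind%d", seq_len(n_ind)),
                      stringsAsFactors = FALSE)[, 3:1]
    md$sample_id <- sprintf("%s_%s_%s_r%d", names(studies)[s],
                            md$individual, md$condition, md$replicate)
    md <- md[, c("sample_id", "individual", "condition", "replicate")]

    shift <- numeric(length(gn_s))
    is_de <- gn_s %in% de
    shift[is_de] <- unname(true_lfc[gn_s[is_de]])
    base <- baseline[gn_s] + probe_offset[pr_s]
    m <- matrix(0, nrow = length(pr_s), ncol = nrow(md),
                dimnames = list(pr_s, md$sample_id))
    for (j in seq_len(nrow(md))) {
      mu <- base + if (md$condition[j] == "treated") shift else 0
      m[, j] <- mu + stats::rnorm(length(mu), 0, cfg$noise_sd_log2)
    }
    studies[[s]] <- expr_set(m, md)
  }

  truth <- structure(
    list(de_gene_ids = de, true_log2fc = true_lfc,
         enriched_pathway_ids = cfg$enriched_pathway_ids,
         responder_specific_gene_ids = character(0)),
    class = "ground_truth")
  structure(list(studies = studies, probe_map = probe_map,
                 pathways = collection, truth = truth, config = cfg),
            class = "sim_studies")
}

#' @export
print.sim_studies <- function(x, ...) {
  cat(sprintf("sim_studies: %d studies, %d probes / %d genes, %d DE genes\n",
              length(x$studies), nrow(x$probe_map),
              x$config$n_genes, length(x$truth$de_gene_ids)))
  invisible(x)
}

#' Simulate a responder / nonresponder mean-abundance table
#'
#' Emulates a summary-level RNA-seq result: per gene, the mean abundance
#' (FPKM scale) of responders treated (`A`) and control (`B`) and of
#' nonresponders treated (`C`) and control (`D`).  Responder-specific genes
#' receive a `responder_effect_log2` shift on the pseudocounted log2 scale
#' in `A` only, so their `(A+1)/(B+1)` ratio reflects
#' `2^responder_effect_log2` while `(C+1)/(D+1)` stays near 1.  Noise is
#' Gaussian on the `log2(x+1)` scale; abundances are clamped at 0.
#'
#' By default the responder-specific genes are the same genes carrying the
#' planted cross-study signal (signed by each gene's true log2 fold
#' change), so the pathway concentration of the signal is shared between
#' the two analyses as it would be for a common underlying biology.
#' Passing `n_responder_genes` instead plants a flat
#' `+responder_effect_log2` effect on that many randomly drawn genes.
#'
#' @param config a [sim_config()]; uses `responder_effect_log2`,
#'   `noise_sd_log2`, `n_genes` and `seed`.
#' @param n_responder_genes optional number of randomly placed
#'   responder-specific genes; `NULL` (default) reuses the planted DE
#'   genes of [simulate_studies()].
#' @param baseline optional numeric vector (length `n_genes`) of noiseless
#'   control abundances; by default log-normal around ~20 FPKM.
#' @return list with `table` (data.frame `gene_id`, `A`, `B`, `C`, `D`)
#'   and `truth` (`ground_truth` with `responder_specific_gene_ids` and
#'   per-gene signed `responder_effect_log2`).
#' @export
simulate_responder_table <- function(config, n_responder_genes = NULL,
                                     baseline = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  if (is.null(n_responder_genes)) {
    uni <- .simulate_universe(cfg)
    resp <- uni$de
    eff_of <- sign(uni$true_lfc) * abs(cfg$responder_effect_log2)
  } else {
    set.seed(cfg$seed + 3163L)
    resp <- sort(sample(genes, min(n_responder_genes, cfg$n_genes)))
    eff_of <- stats::setNames(rep(cfg$responder_effect_log2,
                                  length(resp)), resp)
  }
  set.seed(cfg$seed + 7919L)
  if (is.null(baseline)) {
    baseline <- stats::rlnorm(cfg$n_genes, meanlog = 3, sdlog = 1)
  } else if (length(baseline) != cfg$n_genes || any(baseline < 0)) {
    stop("baseline must be non-negative and of length n_genes")
  }
  eff <- numeric(cfg$n_genes)
  eff[match(resp, genes)] <- unname(eff_of[resp])

  lg <- function(x) log2(x + 1)
  noisy <- function(mu_log) pmax(2^(mu_log +
    stats::rnorm(length(mu_log), 0, cfg$noise_sd_log2)) - 1, 0)
  B <- noisy(lg(baseline))
  D <- noisy(lg(baseline))
  A <- noisy(lg(B) + eff)
  C <- noisy(lg(D))

  truth <- structure(
    list(de_gene_ids = character(0), true_log2fc = numeric(0),
         enriched_pathway_ids = character(0),
         responder_specific_gene_ids = resp,
         responder_effect_log2 = eff_of),
    class = "ground_truth")
  list(table = data.frame(gene_id = genes, A = A, B = B, C = C, D = D,
                          stringsAsFactors = FALSE),
       truth = truth)
}

#' Write the artifacts of a simulation to a directory
#'
#' Emits per-study expression and metadata TSVs, the probe map TSV, the
#' pathway collection as GMT, and a ground-truth TSV.
#'
#' @param sim a `sim_studies` object.
#' @param dir output directory (created if absent).
#' @param header_lines optional provenance lines for the TSVs.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir, header_lines = NULL) {
  stopifnot(inherits(sim, "sim_studies"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sim$studies)) {
    write_expression_tsv(sim$studies[[nm]],
                         file.path(dir, paste0(nm, "_expression.tsv")),
                         file.path(dir, paste0(nm, "_metadata.tsv")),
                         header_lines)
  }
  write_tsv(sim$probe_map, file.path(dir, "probe_map.tsv"), header_lines)
  write_gmt(sim$pathways, file.path(dir, "pathways.gmt"))
  tr <- sim$truth
  truth_df <- data.frame(
    gene_id = tr$de_gene_ids,
    true_log2fc = unname(tr$true_log2fc[tr$de_gene_ids]),
    stringsAsFactors = FALSE)
  write_tsv(truth_df, file.path(dir, "ground_truth.tsv"), header_lines)
  invisible(dir)
}
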