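#' Run the full analysis end to end on synthetic data
#'
#' Chains every stage on data from the synthetic generator: per-study
#' quantile normalization, QC flagging, replicate averaging, differential
#' statistics, probe-to-gene deduplication, cross-study integration,
#' pathway overrepresentation on the integrated (human-style) result, the
#' responder/nonresponder contrast with its own overrepresentation run,
#' category assignment, and the shared-gene cluster network.  All output
#' files are TSV/GMT/GraphML/SIF with a `#` provenance header (package
#' version, seed, config hash) and fixed 6-significant-digit numeric
#' formatting, so a rerun with the same seed is byte-identical.
#'
#' @param out_dir output directory (created if absent).
#' @param sim a [sim_config()] describing the synthetic inputs.
#' @param integration an [integration_config()].
#' @param n_perm permutations for the overrepresentation tests.
#' @param seed seed for the permutation stage (the generator uses
#'   `sim$seed`).
#' @param display_cutoff network display cutoff on `|logFC|`.
#' @param qc_min_correlation QC flag threshold.
#' @param drop_flagged drop QC-flagged samples before statistics.
#' @param category_mapping optional curated `pathway_id`/`category`
#'   data.frame for [assign_categories()].
#' @return invisible list with the in-memory stage results:
#'   `sim`, `study_stats`, `integrated`, `enrichment_integrated`,
#'   `contrast`, `enrichment_contrast`, `assignment`, `network`,
#'   `shared_genes`, `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         sim = sim_config(),
                         integration = integration_config(),
                         n_perm = 1000L,
                         seed = 1L,
                         display_cutoff = 0.58,
                         qc_min_correlation = 0.8,
                         drop_flagged = TRUE,
                         category_mapping = NULL) {
  stopifnot(inherits(sim, "sim_config"),
            inherits(integration, "integration_config"))
  if (integration$k_min > sim$n_studies)
    stop("k_min (", integration$k_min, ") exceeds the number of studies (",
         sim$n_studies, ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance_header(seed, list(sim = unclass(sim),
                                      integration = unclass(integration),
                                      n_perm = n_perm,
                                      display_cutoff = display_cutoff))

  data <- simulate_studies(sim)
  write_simulation(data, file.path(out_dir, "input"), hdr)

  per_study <- vector("list", length(data$studies))
  names(per_study) <- names(data$studies)
  qc_rows <- NULL
  for (nm in names(data$studies)) {
    res <- study_pipeline(data$studies[[nm]], data$probe_map, study_id = nm,
                          qc_min_correlation = qc_min_correlation,
                          drop = drop_flagged)
    per_study[[nm]] <- res$gene_stats
    if (!is.null(res$qc))
      qc_rows <- rbind(qc_rows, cbind(study_id = nm,
                                      as.data.frame(res$qc)))
    write_tsv(res$gene_stats,
              file.path(out_dir, paste0(nm, "_gene_stats.tsv")), hdr)
  }
  if (!is.null(qc_rows))
    write_tsv(qc_rows, file.path(out_dir, "qc_report.tsv"), hdr)

  all_stats <- do.call(rbind, c(per_study, list(make.row.names = FALSE)))
  integrated <- integrate_studies(all_stats, integration)
  write_tsv(as.data.frame(integrated),
            file.path(out_dir, "integrated_genes.tsv"), hdr)

  universe_h <- integrated$gene_id
  changed_h <- integrated$gene_id[integrated$is_differentially_expressed]
  enr_h <- run_enrichment(changed_h, universe_h, data$pathways,
                          n_perm = n_perm, seed = seed)
  write_tsv(as.data.frame(enr_h),
            file.path(out_dir, "enrichment_integrated.tsv"), hdr)

  resp <- simulate_responder_table(sim)
  contr <- contrast_table(resp$table)
  write_tsv(as.data.frame(contr), file.path(out_dir, "contrast.tsv"), hdr)
  ch <- call_changed_genes(contr, "diff", integration$logfc_cutoff)
  enr_b <- run_enrichment(c(ch$up, ch$down), contr$gene_id, data$pathways,
                          n_perm = n_perm, seed = seed)
  write_tsv(as.data.frame(enr_b),
            file.path(out_dir, "enrichment_contrast.tsv"), hdr)

  # pathway-level cross-dataset presence/absence overview
  presence <- data.frame(
    pathway_id = sort(unique(c(enr_h$pathway_id, enr_b$pathway_id))),
    stringsAsFactors = FALSE)
  presence$integrated <- as.integer(presence$pathway_id %in%
    enr_h$pathway_id[enr_h$significant])
  presence$contrast <- as.integer(presence$pathway_id %in%
    enr_b$pathway_id[enr_b$significant])
  write_tsv(presence, file.path(out_dir, "pathway_presence.tsv"), hdr)

  assignment <- NULL
  network <- NULL
  shared <- NULL
  if (any(enr_b$significant)) {
    assignment <- assign_categories(enr_b, category_mapping)
    write_tsv(assignment, file.path(out_dir, "categories.tsv"), hdr)
    lfc <- stats::setNames(contr$diff_R_minus_NR, contr$gene_id)
    network <- build_network(assignment, enr_b, lfc, display_cutoff)
    export_network(network,
                   graphml = file.path(out_dir, "network.graphml"),
                   sif = file.path(out_dir, "network.sif"))
    shared <- shared_gene_table(network, min_clusters = 2L)
    write_tsv(shared, file.path(out_dir, "shared_genes.tsv"), hdr)
  }

  invisible(list(sim = data, study_stats = all_stats,
                 integrated = integrated,
                 enrichment_integrated = enr_h,
                 contrast = contr, enrichment_contrast = enr_b,
                 assignment = assignment, network = network,
                 shared_genes = shared, out_dir = out_dir))
}
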