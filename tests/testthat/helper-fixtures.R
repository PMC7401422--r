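# small in-code fixtures shared across test files

# expression set with explicit values: probes x samples
make_es <- function(values, individuals, conditions,
                    replicates = rep(1L, length(individuals)),
                    probe_ids = NULL) {
  if (!is.matrix(values))
    values <- matrix(values, ncol = length(individuals))
  if (is.null(probe_ids)) probe_ids <- sprintf("p%d", seq_len(nrow(values)))
  sample_ids <- sprintf("s%d", seq_along(individuals))
  m <- matrix(values, nrow = length(probe_ids),
              dimnames = list(probe_ids, sample_ids))
  expr_set(m, data.frame(sample_id = sample_ids, individual = individuals,
                         condition = conditions, replicate = replicates,
                         stringsAsFactors = FALSE))
}

# balanced two-group expression set from per-group matrices
make_two_group_es <- function(treated, control) {
  n1 <- ncol(treated)
  n2 <- ncol(control)
  make_es(cbind(treated, control),
          individuals = c(sprintf("t%d", 1:n1), sprintf("c%d", 1:n2)),
          conditions = c(rep("treated", n1), rep("control", n2)))
}

# tiny pathway collection from a named list
make_collection <- function(sets, source = NA_character_) {
  pathway_collection(sets, source = source)
}

# per-study gene-stat rows in the integrate_studies input format
make_stat_rows <- function(study_id, gene_id, logFC, p_value,
                           n_individuals = 3L) {
  data.frame(study_id = study_id, gene_id = gene_id, logFC = logFC,
             p_value = p_value, n_individuals = n_individuals,
             stringsAsFactors = FALSE)
}
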