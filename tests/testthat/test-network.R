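# build a ready-made enrichment result carrying given changed-gene sets,
# all significant, for exercising the clustering/network stage
fake_enrichment <- function(changed_sets, universe, n = NULL) {
  ids <- names(changed_sets)
  if (is.null(n)) n <- lengths(changed_sets) + 2L
  res <- data.frame(pathway_id = ids, N = length(universe),
                    R = length(unique(unlist(changed_sets))),
                    n = as.integer(n), r = lengths(changed_sets),
                    z_score = rev(seq_along(ids)) + 2,
                    permuted_p = 0.001, p_bh = 0.01,
                    significant = TRUE, stringsAsFactors = FALSE)
  attr(res, "changed_genes") <- changed_sets
  attr(res, "universe") <- universe
  attr(res, "changed") <- unique(unlist(changed_sets))
  attr(res, "thresholds") <- list(z_cutoff = 1.96, p_cutoff = 0.05,
                                  min_changed = 3L, n_perm = 0L, seed = 0L)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

test_that("identical changed-gene sets cluster together, disjoint ones apart", {
  u <- sprintf("G%d", 1:50)
  res <- fake_enrichment(list(Pa = c("G1", "G2", "G3", "G4"),
                              Pb = c("G1", "G2", "G3", "G4"),
                              Pc = c("G10", "G11", "G12", "G13")), u)
  asg <- assign_categories(res)
  expect_identical(asg$category[1], asg$category[2])
  expect_false(asg$category[3] == asg$category[1])
  expect_identical(unique(asg$provenance), "overlap_cluster")
})

test_that("overlap clustering equals an exhaustive single-linkage oracle", {
  u <- sprintf("G%d", 1:100)
  sets <- list(P1 = sprintf("G%d", 1:10),
               P2 = sprintf("G%d", 6:14),    # J(P1,P2) = 5/14 > 0.3
               P3 = sprintf("G%d", 13:20),   # J(P2,P3) = 2/15 < 0.3
               P4 = sprintf("G%d", 14:21),   # J(P3,P4) = 7/9  > 0.3
               P5 = sprintf("G%d", 40:47))
  res <- fake_enrichment(sets, u)
  asg <- assign_categories(res, jaccard_threshold = 0.3)
  # brute-force transitive closure over pairwise Jaccard >= 0.3
  jac <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  K <- length(sets)
  adj <- outer(1:K, 1:K, Vectorize(function(i, j)
    jac(sets[[i]], sets[[j]]) >= 0.3))
  reach <- adj
  for (k in 1:K) reach <- reach | (reach[, k] %o% reach[k, ] > 0)
  comp <- match(apply(reach, 1, paste, collapse = ""),
                unique(apply(reach, 1, paste, collapse = "")))
  got <- match(asg$category, unique(asg$category))
  expect_equal(comp[match(asg$pathway_id, names(sets))], got)
})

test_that("a curated mapping overrides clustering and labels stragglers", {
  u <- sprintf("G%d", 1:30)
  res <- fake_enrichment(list(Pa = c("G1", "G2", "G3", "G4"),
                              Pb = c("G5", "G6", "G7", "G8")), u)
  map <- data.frame(pathway_id = c("Pa", "Pz"),
                    category = c("ECM", "ghost"),
                    stringsAsFactors = FALSE)
  expect_warning(asg <- assign_categories(res, map), "Pz")
  expect_identical(asg$category[asg$pathway_id == "Pa"], "ECM")
  expect_identical(asg$category[asg$pathway_id == "Pb"], "unassigned")
  expect_identical(unique(asg$provenance), "manual_config")
})

test_that("a gene spanning six categories gets n_clusters 6 and tops the table", {
  # the hub gene joins the changed set of one significant pathway in each
  # of six functional categories
  u <- c("FN1", sprintf("G%d", 1:60))
  cats <- c("Inflammation", "ECM", "senescence", "focal adhesion",
            "oxidative stress", "glucose metabolism")
  sets <- lapply(seq_along(cats), function(i)
    c("FN1", sprintf("G%d", (i * 5 - 4):(i * 5))))
  names(sets) <- sprintf("P%d", seq_along(cats))
  res <- fake_enrichment(sets, u)
  asg <- data.frame(pathway_id = names(sets), category = cats,
                    provenance = "manual_config", stringsAsFactors = FALSE)
  class(asg) <- c("category_assignment", "data.frame")
  lfc <- setNames(c(-1.2, rnorm(60, 0, 2)), u)
  net <- build_network(asg, res, lfc, display_cutoff = 0.58)
  expect_equal(net$genes$n_clusters[net$genes$gene_id == "FN1"], 6)
  expect_identical(net$genes$direction[net$genes$gene_id == "FN1"], "down")
  tab <- shared_gene_table(net, min_clusters = 2)
  expect_identical(tab$gene_id[1], "FN1")
  expect_equal(tab$n_clusters[1], 6)
  expect_identical(tab$categories[1],
                   paste(sort(cats), collapse = ", "))
})

test_that("the display cutoff filters genes strictly and monotonically", {
  u <- c("A", "B", "C", "D")
  res <- fake_enrichment(list(P1 = c("A", "B", "C", "D")), u)
  asg <- assign_categories(res)
  lfc <- c(A = 0.5, B = 0.59, C = -2, D = 0.58)
  net <- build_network(asg, res, lfc, display_cutoff = 0.58)
  expect_setequal(net$genes$gene_id, c("B", "C"))  # 0.5 and 0.58 excluded
  # raising the cutoff never adds nodes
  net_hi <- build_network(asg, res, lfc, display_cutoff = 1)
  expect_true(all(net_hi$genes$gene_id %in% net$genes$gene_id))
})

test_that("an empty significant set yields an empty network", {
  u <- sprintf("G%d", 1:10)
  res <- fake_enrichment(list(P1 = c("G1", "G2", "G3", "G4")), u)
  res$significant <- FALSE
  expect_error(assign_categories(res), "no significant")
  # empty edges path through build_network
  asg <- data.frame(pathway_id = character(0), category = character(0),
                    provenance = character(0), stringsAsFactors = FALSE)
  class(asg) <- c("category_assignment", "data.frame")
  net <- build_network(asg, res, c(G1 = 1), display_cutoff = 0.58)
  expect_equal(nrow(net$genes), 0)
  expect_equal(igraph::vcount(net$graph), 0)
})

test_that("edge bookkeeping: degrees sum to edge count; order invariance", {
  set.seed(50)
  u <- sprintf("G%d", 1:40)
  sets <- list(P1 = sample(u, 8), P2 = sample(u, 8), P3 = sample(u, 8))
  res <- fake_enrichment(sets, u)
  asg <- assign_categories(res, jaccard_threshold = 0.99)
  lfc <- setNames(rnorm(40, 0, 2), u)
  net <- build_network(asg, res, lfc)
  expect_equal(sum(net$genes$n_clusters), nrow(net$edges))
  # category nodes never isolated
  expect_true(all(net$categories %in% net$edges$category))
  # permuting pathway order changes nothing
  res2 <- fake_enrichment(sets[c(3, 1, 2)], u)
  asg2 <- assign_categories(res2, jaccard_threshold = 0.99)
  net2 <- build_network(asg2, res2, lfc)
  expect_equal(net2$edges, net$edges)
  expect_equal(net2$genes, net$genes)
})

test_that("gene stats must cover every changed network gene", {
  u <- c("A", "B", "C", "D", "E")
  res <- fake_enrichment(list(P1 = c("A", "B", "C", "D")), u)
  asg <- assign_categories(res)
  expect_error(build_network(asg, res, c(A = 1, B = 1), 0.58), "C")
})

test_that("GraphML and SIF exports are written and readable", {
  u <- sprintf("G%d", 1:20)
  res <- fake_enrichment(list(P1 = sprintf("G%d", 1:6),
                              P2 = sprintf("G%d", 4:9)), u)
  asg <- assign_categories(res, jaccard_threshold = 0.9)
  lfc <- setNames(rep(c(2, -2), 10), u)
  net <- build_network(asg, res, lfc)
  gml <- tempfile(fileext = ".graphml")
  sif <- tempfile(fileext = ".sif")
  export_network(net, graphml = gml, sif = sif)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), igraph::vcount(net$graph))
  expect_setequal(igraph::vertex_attr(g, "direction",
                                      igraph::V(g)$type == FALSE),
                  c("up", "down"))
  lines <- readLines(sif)
  expect_length(lines, nrow(net$edges))
  expect_true(all(grepl("\tcontains\t", lines)))
})
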