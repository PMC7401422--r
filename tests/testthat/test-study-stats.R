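test_that("replicate averaging equals brute-force per-cell means", {
  # 2 probes, 3 individuals x 3 replicates, both conditions
  set.seed(10)
  ind <- rep(sprintf("i%d", 1:3), each = 6)
  cond <- rep(rep(c("treated", "control"), each = 3), 3)
  repl <- rep(1:3, 6)
  m <- matrix(rnorm(2 * 18), 2, 18)
  es <- make_es(m, ind, cond, repl)
  out <- average_replicates(es)
  expect_equal(ncol(out$exprs), 6)
  for (i in unique(ind)) for (cn in c("treated", "control")) {
    cols <- which(ind == i & cond == cn)
    expect_equal(unname(out$exprs[, paste(i, cn, sep = ".")]),
                 unname(rowMeans(m[, cols])))
  }
  # trivial case: replicate values (1, 3) average to 2
  es2 <- make_es(c(1, 3), c("i1", "i1"), c("treated", "treated"), 1:2)
  # add a control so the individual survives
  es2 <- make_es(c(1, 3, 5), c("i1", "i1", "i1"),
                 c("treated", "treated", "control"), c(1L, 2L, 1L))
  out2 <- average_replicates(es2)
  expect_equal(unname(out2$exprs[1, "i1.treated"]), 2)
})

test_that("no replicates leaves the matrix unchanged", {
  set.seed(11)
  es <- make_es(matrix(rnorm(8), 2, 4), c("i1", "i1", "i2", "i2"),
                rep(c("treated", "control"), 2))
  out <- average_replicates(es)
  expect_equal(unname(out$exprs), unname(es$exprs))
})

test_that("individuals missing a condition are excluded with a warning", {
  es <- make_es(matrix(1:6, 1, 6),
                c("i1", "i1", "i2", "i2", "i3", "i3"),
                c("treated", "control", "treated", "control",
                  "treated", "treated"), c(1L, 1L, 1L, 1L, 1L, 2L))
  expect_warning(out <- average_replicates(es), "i3")
  expect_false(any(grepl("^i3", colnames(out$exprs))))
})

test_that("unmoderated t equals the textbook pooled-variance oracle", {
  set.seed(12)
  tr <- matrix(rnorm(50 * 4, 1), 50, 4)
  ct <- matrix(rnorm(50 * 3), 50, 3)
  es <- make_two_group_es(tr, ct)
  st <- differential_stats(es, moderate = FALSE)
  for (k in c(1, 17, 50)) {
    s2 <- (3 * var(tr[k, ]) + 2 * var(ct[k, ])) / 5
    t_oracle <- (mean(tr[k, ]) - mean(ct[k, ])) /
      sqrt(s2 * (1 / 4 + 1 / 3))
    expect_equal(st$t[k], t_oracle)
    expect_equal(st$p_value[k], 2 * pt(-abs(t_oracle), 5))
    expect_equal(st$logFC[k], mean(tr[k, ]) - mean(ct[k, ]))
  }
})

test_that("noiseless groups give exact logFC and zero variance", {
  es <- make_two_group_es(matrix(2, 1, 2), matrix(1, 1, 2))
  st <- differential_stats(es, moderate = FALSE)
  expect_equal(st$logFC, 1)
  expect_identical(st$flag, "zero_variance")
  expect_gt(st$p_value, 0)  # clamped, never 0 or NaN
})

test_that("1-vs-1 designs emit p = 1 with a flag, never NaN", {
  es <- make_two_group_es(matrix(c(2, 3), 2, 1), matrix(c(1, 1), 2, 1))
  st <- differential_stats(es, moderate = FALSE)
  expect_equal(st$p_value, c(1, 1))
  expect_identical(st$flag, c("no_residual_df", "no_residual_df"))
  expect_equal(st$logFC, c(1, 2))
  st_m <- differential_stats(es, moderate = TRUE)
  expect_equal(st_m$p_value, c(1, 1))
})

test_that("null simulation yields uniform p-values", {
  # Kolmogorov-Smirnov statistic against U(0,1) below the 1% critical
  # value in nearly all seeds
  crit <- 1.628 / sqrt(800)  # asymptotic 1% point
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    es <- make_two_group_es(matrix(rnorm(800 * 3), 800, 3),
                            matrix(rnorm(800 * 3), 800, 3))
    st <- differential_stats(es, moderate = FALSE)
    as.numeric(ks.test(st$p_value, "punif")$statistic) < crit
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("moderated statistics agree with an independent empirical-Bayes oracle", {
  skip_if_not_installed("limma")
  set.seed(13)
  tr <- matrix(rnorm(300 * 3, 0, sqrt(rchisq(300, 4) / 4)), 300, 3)
  ct <- matrix(rnorm(300 * 3, 0, sqrt(rchisq(300, 4) / 4)), 300, 3)
  es <- make_two_group_es(tr, ct)
  st <- differential_stats(es, moderate = TRUE)
  design <- cbind(1, rep(c(1, 0), each = 3))
  fit <- limma::eBayes(limma::lmFit(cbind(tr, ct), design))
  expect_equal(st$t, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(st$p_value, unname(fit$p.value[, 2]), tolerance = 1e-6)
  prior <- attr(st, "variance_prior")
  expect_equal(prior$df_prior, fit$df.prior, tolerance = 1e-6)
  expect_equal(prior$s2_prior, fit$s2.prior, tolerance = 1e-6)
})

test_that("swapping condition labels negates logFC and preserves p", {
  set.seed(14)
  tr <- matrix(rnorm(40 * 3, 0.5), 40, 3)
  ct <- matrix(rnorm(40 * 3), 40, 3)
  a <- differential_stats(make_two_group_es(tr, ct), moderate = FALSE)
  b <- differential_stats(make_two_group_es(ct, tr), moderate = FALSE)
  expect_equal(a$logFC, -b$logFC)
  expect_equal(a$p_value, b$p_value)
})

test_that("deduplication keeps the record with the highest |logFC * -log10 p|", {
  st <- data.frame(probe_id = c("pB", "pA"),
                   logFC = c(1.0, 0.5), p_value = c(0.1, 0.001),
                   mean_expr = c(5, 6), t = c(2, 4), df = c(4, 4),
                   flag = "", stringsAsFactors = FALSE)
  map <- data.frame(probe_id = c("pA", "pB"), gene_id = "g1",
                    stringsAsFactors = FALSE)
  out <- map_and_deduplicate(st, map, "s1", 3L)
  # scores: 1.0 vs 1.5 -> the (0.5, 0.001) record wins
  expect_equal(nrow(out), 1)
  expect_identical(out$probe_id, "pA")
  expect_equal(out$logFC, 0.5)
  # selection never alters the kept values
  expect_equal(out$p_value, 0.001)
})

test_that("single-probe genes pass through and ties break lexicographically", {
  st <- data.frame(probe_id = c("p1", "p3", "p2"),
                   logFC = c(0.3, 1, 1), p_value = c(0.2, 0.01, 0.01),
                   mean_expr = 0, t = 0, df = 4, flag = "",
                   stringsAsFactors = FALSE)
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene_id = c("gA", "gB", "gB"),
                    stringsAsFactors = FALSE)
  out <- map_and_deduplicate(st, map, "s1")
  expect_equal(out$probe_id[out$gene_id == "gA"], "p1")
  expect_equal(out$probe_id[out$gene_id == "gB"], "p2")  # exact tie -> smallest id
})

test_that("unmapped probes are counted, and kept scores dominate discarded ones", {
  set.seed(15)
  n <- 60
  st <- data.frame(probe_id = sprintf("p%03d", 1:n),
                   logFC = rnorm(n), p_value = runif(n),
                   mean_expr = 0, t = 0, df = 4, flag = "",
                   stringsAsFactors = FALSE)
  map <- data.frame(probe_id = sprintf("p%03d", 1:50),
                    gene_id = sprintf("g%d", rep(1:10, 5)),
                    stringsAsFactors = FALSE)
  expect_message(out <- map_and_deduplicate(st, map, "s1"), "10 probe")
  expect_equal(attr(out, "n_unmapped"), 10)
  expect_equal(nrow(out), 10)
  merged <- merge(st, map, by = "probe_id")
  merged$score <- abs(merged$logFC * -log10(merged$p_value))
  for (g in unique(out$gene_id)) {
    expect_gte(out$dedup_score[out$gene_id == g] + 1e-12,
               max(merged$score[merged$gene_id == g]))
  }
})
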