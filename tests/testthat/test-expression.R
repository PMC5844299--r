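mk_join <- function(n = 40, seed = 61) {
  set.seed(seed)
  g <- data.frame(gene_id = sprintf("g%03d", 1:n),
                  exon_ratio = runif(n),
                  n_exon_mcpg = rbinom(n, 5, 0.4))
  g$class <- ifelse(g$exon_ratio > 0.1, "methylated", "nonmethylated")
  f <- data.frame(gene_id = g$gene_id, fpkm = 10^rnorm(n, 1, 0.5))
  list(g = g, f = f)
}

test_that("join keeps both-side bookkeeping and bins ratios", {
  d <- mk_join()
  d$g <- rbind(d$g, data.frame(gene_id = "only_meth", exon_ratio = 0.2,
                               n_exon_mcpg = 1, class = "methylated"))
  d$f <- rbind(d$f, data.frame(gene_id = "only_expr", fpkm = 3))
  j <- join_expression(d$g, d$f)
  expect_equal(attr(j, "methylation_only"), "only_meth")
  expect_equal(attr(j, "expression_only"), "only_expr")
  expect_equal(nrow(j), 40)
  # bins partition [0, 1]
  expect_false(anyNA(j$methylation_bin))
  j2 <- join_expression(data.frame(gene_id = c("a", "b"),
                                   exon_ratio = c(0.95, 1)),
                        data.frame(gene_id = c("a", "b"), fpkm = c(1, 2)))
  expect_equal(as.character(unique(j2$methylation_bin)), "[0.9,1.0]")
})

test_that("Spearman correlation hits 1 for monotone coupling", {
  g <- data.frame(gene_id = sprintf("g%02d", 1:20),
                  exon_ratio = seq(0.01, 0.96, length.out = 20))
  f <- data.frame(gene_id = g$gene_id, fpkm = exp(g$exon_ratio))
  j <- join_expression(g, f)
  ct <- correlate_methylation_expression(j)
  expect_equal(unname(ct$estimate), 1)
  # invariant under monotone transform of fpkm
  f2 <- f; f2$fpkm <- f$fpkm^3
  ct2 <- correlate_methylation_expression(join_expression(g, f2))
  expect_equal(unname(ct2$estimate), unname(ct$estimate))
})

test_that("shuffled expression decorrelates", {
  set.seed(62)
  d <- mk_join(n = 300)
  d$f$fpkm <- sample(d$f$fpkm)
  j <- join_expression(d$g, d$f)
  ct <- correlate_methylation_expression(j)
  expect_lt(abs(unname(ct$estimate)), 0.15)
})

test_that("class comparison reports medians and needs both classes", {
  d <- mk_join(n = 100, seed = 63)
  j <- join_expression(d$g, d$f)
  cmp <- compare_class_expression(j)
  expect_equal(cmp$median_methylated,
               median(j$fpkm[j$class == "methylated"]))
  expect_s3_class(cmp$test, "htest")

  j1 <- j[c(which(j$class == "methylated")[1],
            which(j$class == "nonmethylated")[1]), ]
  expect_error(compare_class_expression(j1), "at least 2")
})

test_that("zero-expression overlap fractions behave at the edges", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"),
                  exon_ratio = c(0, 0.5, 0, 0.2),
                  n_exon_mcpg = c(0, 3, 0, 1))
  f <- data.frame(gene_id = g$gene_id, fpkm = c(0, 10, 0, 2))
  z <- zero_expression_overlap(join_expression(g, f))
  expect_equal(z$n_silent, 2)
  expect_equal(z$frac_silent_zero_meth, 1)
  expect_equal(z$frac_all_zero_meth, 0.5)

  f2 <- f; f2$fpkm <- c(1, 10, 3, 2)   # nothing silent
  z2 <- zero_expression_overlap(join_expression(g, f2))
  expect_true(is.na(z2$frac_silent_zero_meth))

  g3 <- g; g3$n_exon_mcpg <- c(2, 3, 1, 1)   # everything methylated
  z3 <- zero_expression_overlap(join_expression(g3, f))
  expect_equal(z3$frac_all_zero_meth, 0)
})

test_that("binned profile keeps empty bins and tracks medians", {
  g <- data.frame(gene_id = c("a", "b", "c"),
                  exon_ratio = c(0.05, 0.07, 0.95))
  f <- data.frame(gene_id = g$gene_id, fpkm = c(1, 100, 1000))
  prof <- binned_expression_profile(join_expression(g, f))
  expect_equal(nrow(prof), 10)
  expect_equal(prof$n[prof$bin == "[0.0,0.1)"], 2)
  expect_equal(prof$median_log_expr[prof$bin == "[0.0,0.1)"], 1)
  expect_equal(prof$n[prof$bin == "[0.5,0.6)"], 0)
  expect_true(is.na(prof$median_log_expr[prof$bin == "[0.5,0.6)"]))
})

test_that("simulated coupling flows through to the joined statistics", {
  sim <- tiny_sim(seed = 64, n_genes = 150, contig_length = 400000L)
  cr <- simulate_counts(sim, contexts = "CpG")
  calls <- call_sites(cr, error_rate = 0.01)
  r <- compute_ratios(assign_sites(calls, sim$models), calls)
  cls <- classify_genes(r)
  gm <- merge(r$genes, cls[, c("gene_id", "class")], by = "gene_id")
  j <- join_expression(gm, simulate_expression(sim))
  ct <- correlate_methylation_expression(j)
  expect_gt(unname(ct$estimate), 0.2)
  expect_lt(ct$p.value, 0.01)
  cmp <- compare_class_expression(j)
  expect_gt(cmp$median_methylated, cmp$median_nonmethylated)
  z <- zero_expression_overlap(j)
  expect_gt(z$frac_silent_zero_meth, z$frac_all_zero_meth)
})
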