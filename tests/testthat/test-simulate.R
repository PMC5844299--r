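test_that("identical seed gives byte-identical simulations", {
  cfg <- sim_config(seed = 3, n_genes = 30, n_contigs = 1L,
                    contig_length = 160000L)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth$sites, s2$truth$sites)
  expect_identical(simulate_counts(s1, contexts = "CpG"),
                   simulate_counts(s2, contexts = "CpG"))
  expect_identical(simulate_expression(s1), simulate_expression(s2))
})

test_that("gene placement fails gracefully on a too-small contig", {
  expect_error(simulate_genome(sim_config(seed = 1, n_genes = 100,
                                          n_contigs = 1L,
                                          contig_length = 20000L)),
               "contig_length")
})

test_that("deamination lowers CpG O/E only in the methylated class", {
  cfg0 <- sim_config(seed = 7, n_genes = 80, n_contigs = 2L,
                     contig_length = 240000L, deamination_strength = 0)
  s0 <- simulate_genome(cfg0)
  oe0 <- gene_cpg_oe(s0$genome, s0$models)
  d0 <- merge(oe0, s0$truth$genes, by = "gene_id")
  diff0 <- mean(d0$cpg_oe[d0$class == 1]) - mean(d0$cpg_oe[d0$class == 0])
  expect_lt(abs(diff0), 0.12)   # no depletion applied

  cfg1 <- sim_config(seed = 7, n_genes = 80, n_contigs = 2L,
                     contig_length = 240000L, deamination_strength = 0.3)
  s1 <- simulate_genome(cfg1)
  oe1 <- gene_cpg_oe(s1$genome, s1$models)
  d1 <- merge(oe1, s1$truth$genes, by = "gene_id")
  expect_lt(mean(d1$cpg_oe[d1$class == 1]),
            mean(d1$cpg_oe[d1$class == 0]) - 0.1)
})

test_that("count simulation respects the binomial observation model", {
  sim <- tiny_sim(seed = 5, n_genes = 20, contig_length = 80000L)

  # error_rate 0 and m = 0 -> no methylated reads anywhere
  sim0 <- sim
  sim0$truth$sites$m <- 0
  sim0$config$error_rate <- 0
  cr0 <- simulate_counts(sim0, contexts = "CpG")
  expect_true(all(cr0$n_meth == 0))

  # m = 1 -> no unmethylated reads
  sim1 <- sim
  sim1$truth$sites$m <- 1
  cr1 <- simulate_counts(sim1, contexts = "CpG")
  expect_true(all(cr1$n_unmeth == 0))

  # m = 0, error 0.01, high coverage: pooled rate within 3 binomial SD
  sim2 <- sim
  sim2$truth$sites$m <- 0
  sim2$config$error_rate <- 0.01
  sim2$config$mean_coverage <- 1000
  cr2 <- simulate_counts(sim2, contexts = "CpG")
  tot <- sum(cr2$n_meth + cr2$n_unmeth)
  rate <- sum(cr2$n_meth) / tot
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / tot))
})

test_that("cytosine report has consistent context and trinucleotide", {
  sim <- tiny_sim(seed = 6, n_genes = 10, contig_length = 50000L)
  cr <- simulate_counts(sim, contexts = "all")
  expect_true(all(cr$context %in% c("CpG", "CHG", "CHH")))
  # CpG rows must carry a CG-starting trinucleotide
  cpg <- cr[cr$context == "CpG", ]
  expect_true(all(substr(cpg$trinucleotide, 1, 2) == "CG"))
  # non-CpG rows never start with CG
  non <- cr[cr$context != "CpG", ]
  expect_true(all(substr(non$trinucleotide, 1, 2) != "CG"))
  # pooled non-CpG methylation reflects only the conversion error
  err <- estimate_error_rate(cr)
  expect_lt(abs(err - sim$config$error_rate), 0.003)
})

test_that("expression coupling drives the class difference", {
  sim <- tiny_sim(seed = 8, n_genes = 200, contig_length = 500000L)
  ex <- simulate_expression(sim)
  d <- merge(ex, sim$truth$genes, by = "gene_id")
  expect_gt(median(d$fpkm[d$class == 1]), median(d$fpkm[d$class == 0]))

  sim0 <- sim
  sim0$config$expression_coupling <- 0
  ex0 <- simulate_expression(sim0)
  d0 <- merge(ex0, sim0$truth$genes, by = "gene_id")
  # no coupling: medians of the expressed genes close on the log scale
  expect_lt(abs(log10(median(d0$fpkm[d0$class == 1])) -
                log10(median(d0$fpkm[d0$class == 0 & d0$fpkm > 0]))), 0.35)
  # silencing only affects the nonmethylated class
  expect_true(all(d0$fpkm[d0$class == 1] > 0))
  expect_gt(sum(d0$fpkm == 0), 0)
})

test_that("amplicon panels emit one table per sample and plant the diff", {
  sites <- data.frame(chrom = "scaf", pos = 1:12 * 100L,
                      base_meth = rep(0.5, 12))
  pan <- simulate_amplicon_panel(sites, planted_diff = 0.2,
                                 n_per_group = 8, coverage = 500, seed = 2)
  expect_length(pan$samples, 16)
  expect_equal(sum(pan$labels$group == "long"), 8)
  expect_equal(pan$truth$mean_long - pan$truth$mean_short, rep(0.2, 12))

  expect_error(simulate_amplicon_panel(
    data.frame(chrom = "s", pos = 1L, base_meth = 0.95),
    planted_diff = 0.2), "outside")
})

test_that("a planted Table-1-sized difference is recovered with power", {
  # 0.323 difference, 8 vs 8 samples, 500x coverage
  sites <- data.frame(chrom = "s", pos = 1L, base_meth = 0.4865)
  hits <- 0
  for (rep in 1:30) {
    pan <- simulate_amplicon_panel(sites, planted_diff = 0.323,
                                   n_per_group = 8, coverage = 500,
                                   seed = 100 + rep)
    fr <- amplicon_site_fractions(pan$samples, min_reads = 10)
    st <- amplicon_compare_groups(fr, pan$labels)
    if (st$p_value[1] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 30, 0.9)
})
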