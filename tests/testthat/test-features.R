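fixture_models <- function() {
  gene_models(
    genes = data.frame(gene_id = c("gp", "gm"), chrom = "c1",
                       strand = c("+", "-"),
                       start = c(3000L, 10000L), end = c(3900L, 11000L)),
    exons = data.frame(gene_id = c("gp", "gp", "gm"),
                       start = c(3000L, 3600L, 10000L),
                       end = c(3300L, 3900L, 11000L)))
}

fake_calls <- function(pos, meth = rep(TRUE, length(pos))) {
  data.frame(chrom = "c1", pos = pos, strand = "+",
             n_meth = ifelse(meth, 5L, 0L), n_total = 10L,
             level = ifelse(meth, 0.5, 0),
             p_raw = ifelse(meth, 1e-8, 1), p_adj = ifelse(meth, 1e-8, 1),
             is_methylated = meth)
}

test_that("sites are assigned to exon, intron and upstream features", {
  m <- fixture_models()
  calls <- fake_calls(c(3150L, 3450L, 2500L, 10500L, 11400L))
  a <- assign_sites(calls, m, seqlengths = c(c1 = 20000L))
  feat_of <- function(p, g) a$feature[a$site == which(calls$pos == p) &
                                        a$gene_id == g]
  expect_equal(feat_of(3150L, "gp"), "exon")
  expect_equal(feat_of(3450L, "gp"), "intron")
  expect_equal(feat_of(2500L, "gp"), "upstream2kb")
  expect_equal(feat_of(10500L, "gm"), "exon")
  # 400 bp past the 3' end in genome coords = 5' upstream of a minus gene
  expect_equal(feat_of(11400L, "gm"), "upstream2kb")
})

test_that("assignment matches a brute-force interval scan", {
  sim <- tiny_sim(seed = 13, n_genes = 25, contig_length = 90000L)
  sl <- setNames(Biostrings::width(sim$genome), names(sim$genome))
  set.seed(14)
  pos <- sort(sample(90000L, 150))
  calls <- data.frame(chrom = names(sim$genome)[1], pos = pos,
                      strand = "+", is_methylated = TRUE)
  a <- assign_sites(calls, sim$models, seqlengths = sl)
  for (i in sample(seq_along(pos), 40)) {
    bf <- brute_force_feature(pos[i], names(sim$genome)[1], sim$models,
                              seqlengths = sl)
    got <- a[a$site == i, c("gene_id", "feature")]
    expect_setequal(paste(got$gene_id, got$feature),
                    paste(bf$gene_id, bf$feature))
  }
})

test_that("ratios count methylated over detected CpGs per feature", {
  m <- fixture_models()
  calls <- fake_calls(c(3100L, 3150L, 3650L, 3700L),
                      meth = c(TRUE, TRUE, FALSE, FALSE))
  r <- compute_ratios(assign_sites(calls, m), calls)
  g <- r$genes[r$genes$gene_id == "gp", ]
  expect_equal(g$exon_ratio, 0.5)       # 2 methylated of 4 exonic CpGs
  expect_equal(g$n_exon_cpg, 4)
  expect_true(is.na(g$intron_ratio))    # no detected intronic CpGs
  expect_true(g$has_any_mcpg)

  none <- compute_ratios(assign_sites(
    fake_calls(c(3100L, 3650L), meth = c(FALSE, FALSE)), m),
    fake_calls(c(3100L, 3650L), meth = c(FALSE, FALSE)))
  expect_equal(none$genes$exon_ratio, 0)
  expect_false(any(none$genes$has_any_mcpg))
})

test_that("within a gene every genic CpG is exon xor intron", {
  sim <- tiny_sim(seed = 15, n_genes = 30, contig_length = 100000L)
  cr <- simulate_counts(sim, contexts = "CpG")
  calls <- call_sites(cr, error_rate = 0.01)
  a <- assign_sites(calls, sim$models)
  genic <- a[a$feature %in% c("exon", "intron"), ]
  expect_false(any(duplicated(paste(genic$site, genic$gene_id))))
  # counts per gene add up
  per_gene <- table(genic$gene_id)
  per_feat <- table(genic$gene_id, genic$feature)
  expect_equal(as.vector(per_feat[, "exon"] + per_feat[, "intron"]),
               as.vector(per_gene))
})

test_that("feature percentages are weighted means of per-gene counts", {
  sim <- tiny_sim(seed = 16, n_genes = 30, contig_length = 100000L)
  cr <- simulate_counts(sim, contexts = "CpG")
  calls <- call_sites(cr, error_rate = 0.01)
  a <- assign_sites(calls, sim$models)
  r <- compute_ratios(a, calls)
  a$meth <- calls$is_methylated[a$site]
  for (f in r$features$feature) {
    sub <- a[a$feature == f, ]
    expect_equal(r$features$pct_mC[r$features$feature == f],
                 100 * sum(sub$meth) / nrow(sub))
  }
})

test_that("classification uses a strict 10% exon-ratio cutoff", {
  g <- data.frame(gene_id = c("a", "b", "c", "d"),
                  exon_ratio = c(0.11, 0.10, 0, NA))
  cl <- classify_genes(g)
  expect_equal(cl$class[cl$gene_id == "a"], "methylated")
  expect_equal(cl$class[cl$gene_id == "b"], "nonmethylated")  # not > 0.10
  expect_equal(attr(cl, "n_undefined"), 1)
  expect_false("d" %in% cl$gene_id)
})
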