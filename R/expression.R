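#' Join gene-level methylation with an expression table
#'
#' Inner-joins per-gene methylation (exon ratio, class, per-gene mCpG
#' flag) with TMM-normalised FPKM values and bins the exon ratio into
#' ten 10%-wide bins (`[0, 0.1), ..., [0.9, 1]`, top edge closed). Genes
#' present in only one of the two tables are not silently dropped: their
#' ids are carried in the `methylation_only` / `expression_only`
#' attributes.
#'
#' @param gene_meth Per-gene methylation: needs `gene_id`, `exon_ratio`,
#'   and optionally `class` (from [classify_genes()]) and `has_any_mcpg`
#'   or `n_exon_mcpg` (from [compute_ratios()]).
#' @param fpkm Expression table: `gene_id`, `fpkm` (TMM-normalised FPKM,
#'   >= 0).
#' @return `data.frame` of class `expr_join`: `gene_id`, `exon_ratio`,
#'   `class` (if available), `fpkm`, `log_expr` (log10 FPKM, `NA` for
#'   FPKM = 0), `methylation_bin`.
#' @export
join_expression <- function(gene_meth, fpkm) {
  stopifnot(all(c("gene_id", "exon_ratio") %in% names(gene_meth)),
            all(c("gene_id", "fpkm") %in% names(fpkm)))
  if (any(fpkm$fpkm < 0)) stop("FPKM values must be non-negative")
  j <- merge(gene_meth, fpkm, by = "gene_id")
  j$log_expr <- ifelse(j$fpkm > 0, log10(j$fpkm), NA_real_)
  j$methylation_bin <- cut(j$exon_ratio,
                           breaks = seq(0, 1, by = 0.1),
                           include.lowest = TRUE, right = FALSE,
                           labels = sprintf("[%.1f,%.1f)",
                                            seq(0, 0.9, 0.1),
                                            seq(0.1, 1, 0.1)))
  # the top bin is closed: [0.9, 1.0]
  levels(j$methylation_bin)[10] <- "[0.9,1.0]"
  j$methylation_bin[j$exon_ratio == 1] <- "[0.9,1.0]"
  attr(j, "methylation_only") <-
    setdiff(gene_meth$gene_id, fpkm$gene_id)
  attr(j, "expression_only") <-
    setdiff(fpkm$gene_id, gene_meth$gene_id)
  class(j) <- c("expr_join", "data.frame")
  j
}

#' Spearman correlation of gene-body methylation and expression
#'
#' Rank correlation of exon methylation ratio against FPKM (ties by
#' midranks); robust to the nonlinearity of the
#' methylation-expression relationship.
#'
#' @param join Output of [join_expression()].
#' @return `htest` object from [stats::cor.test()].
#' @export
correlate_methylation_expression <- function(join) {
  j <- join[!is.na(join$exon_ratio) & !is.na(join$fpkm), , drop = FALSE]
  if (nrow(j) < 10) stop("need at least 10 joined genes")
  if (length(unique(j$exon_ratio)) < 2 || length(unique(j$fpkm)) < 2) {
    stop("constant column: correlation undefined")
  }
  suppressWarnings(cor.test(j$exon_ratio, j$fpkm, method = "spearman"))
}

#' Compare expression between methylated and nonmethylated genes
#'
#' Rank-based comparison of FPKM between the two gene classes. The
#' default is the two-independent-sample rank-sum (Mann-Whitney) test,
#' the natural design for two disjoint gene classes; a signed-rank
#' variant on a trimmed paired ranking is also available for
#' completeness (`test = "signedrank"` pairs the sorted values of the
#' two classes, which is only meaningful as a descriptive device).
#'
#' @param join Output of [join_expression()] (needs a `class` column).
#' @param test `"ranksum"` (default) or `"signedrank"`.
#' @return List: `test` (htest), `median_methylated`,
#'   `median_nonmethylated`, `n_methylated`, `n_nonmethylated`.
#' @export
compare_class_expression <- function(join, test = c("ranksum",
                                                    "signedrank")) {
  test <- match.arg(test)
  stopifnot("class" %in% names(join))
  m <- join$fpkm[join$class == "methylated"]
  u <- join$fpkm[join$class == "nonmethylated"]
  if (length(m) < 2 || length(u) < 2) {
    stop("each class needs at least 2 genes")
  }
  ht <- if (test == "ranksum") {
    suppressWarnings(wilcox.test(m, u))
  } else {
    k <- min(length(m), length(u))
    suppressWarnings(wilcox.test(sort(m)[seq_len(k)],
                                 sort(u)[seq_len(k)], paired = TRUE))
  }
  list(test = ht, median_methylated = median(m),
       median_nonmethylated = median(u),
       n_methylated = length(m), n_nonmethylated = length(u))
}

#' Overlap of silent genes with unmethylated genes
#'
#' Reports (a) among genes with FPKM = 0, the fraction with zero
#' methylated exonic CpGs, and (b) the same fraction over all joined
#' genes; sparse methylomes show a large excess of (a) over (b).
#'
#' @param join Output of [join_expression()]; needs `n_exon_mcpg` or
#'   `has_any_mcpg` to define "zero exonic methylation" (preference:
#'   `n_exon_mcpg == 0`, else exon_ratio == 0).
#' @return `data.frame`: `n_silent`, `frac_silent_zero_meth` (`NA` if no
#'   silent genes), `frac_all_zero_meth`.
#' @export
zero_expression_overlap <- function(join) {
  zero_meth <- if ("n_exon_mcpg" %in% names(join)) {
    join$n_exon_mcpg == 0
  } else {
    join$exon_ratio == 0
  }
  silent <- join$fpkm == 0
  data.frame(
    n_silent = sum(silent),
    frac_silent_zero_meth = if (any(silent)) mean(zero_meth[silent])
                            else NA_real_,
    frac_all_zero_meth = mean(zero_meth))
}

#' Expression profile across exon-methylation bins
#'
#' For each 10%-wide exon-ratio bin: gene count, median and quartiles of
#' log10 expression (FPKM = 0 genes are excluded from the log-scale
#' summaries; empty bins are retained with `n = 0`).
#'
#' @param join Output of [join_expression()].
#' @return `data.frame`: `bin`, `n`, `n_expressed`, `median_log_expr`,
#'   `q1_log_expr`, `q3_log_expr`.
#' @export
binned_expression_profile <- function(join) {
  bins <- levels(join$methylation_bin)
  rows <- lapply(bins, function(b) {
    sub <- join[!is.na(join$methylation_bin) &
                  join$methylation_bin == b, , drop = FALSE]
    le <- sub$log_expr[!is.na(sub$log_expr)]
    data.frame(bin = b, n = nrow(sub), n_expressed = length(le),
               median_log_expr = if (length(le)) median(le) else NA_real_,
               q1_log_expr = if (length(le)) unname(quantile(le, 0.25))
                             else NA_real_,
               q3_log_expr = if (length(le)) unname(quantile(le, 0.75))
                             else NA_real_,
               stringsAsFactors = FALSE)
  })
  .rbind_all(rows)
}
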