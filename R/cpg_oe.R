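#' CpG observed/expected ratio of a nucleotide sequence
#'
#' `CpG O/E = (count(CG) * L) / (count(C) * count(G))`, the observed CpG
#' dinucleotide count relative to its expectation under independent base
#' composition. Methylated cytosines deaminate to thymine over
#' evolutionary time, so low CpG O/E marks historically methylated
#' sequence. `N` bases are excluded from the mono-nucleotide counts and
#' from the length `L`.
#'
#' @param sequence Character string or `Biostrings::DNAString`.
#' @return The CpG O/E value, or `NA` when `count(C) * count(G) == 0`
#'   (undefined).
#' @examples
#' compute_cpg_oe("CGCG")  # (2 * 4) / (2 * 2) = 2
#' @export
compute_cpg_oe <- function(sequence) {
  s <- toupper(as.character(sequence))
  if (nchar(s) < 2) stop("sequence must have length >= 2")
  v <- strsplit(s, "")[[1]]
  n_c <- sum(v == "C")
  n_g <- sum(v == "G")
  L <- sum(v != "N")
  n_cg <- sum(v[-length(v)] == "C" & v[-1] == "G")
  if (n_c == 0 || n_g == 0) return(NA_real_)
  (n_cg * L) / (n_c * n_g)
}

#' Per-gene CpG observed/expected ratios
#'
#' Computes [compute_cpg_oe()] on each gene's sequence: the full genomic
#' gene span (exons + introns, default) or the concatenated exons.
#' Counts are taken on the annotated strand; CpG O/E is invariant under
#' reverse complement, so the reported strand does not affect the value.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param models A [gene_models] object.
#' @param region `"gene"` (span) or `"exons"` (concatenated exons).
#' @return `data.frame`: `gene_id`, `cpg_oe`, `length`, `n_cpg`, `n_c`,
#'   `n_g`.
#' @export
gene_cpg_oe <- function(genome, models, region = c("gene", "exons")) {
  region <- match.arg(region)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  seq_of <- function(chrom, start, end) {
    as.character(Biostrings::subseq(genome[[chrom]], start, end))
  }
  rows <- lapply(seq_len(nrow(g)), function(i) {
    s <- if (region == "gene") {
      seq_of(g$chrom[i], g$start[i], g$end[i])
    } else {
      e <- models$exons[models$exons$gene_id == g$gene_id[i], , drop = FALSE]
      paste(vapply(seq_len(nrow(e)),
                   function(j) seq_of(g$chrom[i], e$start[j], e$end[j]),
                   character(1)), collapse = "")
    }
    if (g$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    v <- strsplit(s, "")[[1]]
    data.frame(gene_id = g$gene_id[i],
               cpg_oe = compute_cpg_oe(s),
               length = sum(v != "N"),
               n_cpg = sum(v[-length(v)] == "C" & v[-1] == "G"),
               n_c = sum(v == "C"), n_g = sum(v == "G"),
               stringsAsFactors = FALSE)
  })
  .rbind_all(rows)
}

#' Compare CpG O/E between methylation classes
#'
#' Reports per-class means of CpG O/E, a variance-ratio F statistic with
#' `(n1 - 1, n2 - 1)` degrees of freedom, a Welch two-sample mean
#' comparison, and the Spearman correlation between exon methylation
#' ratio and CpG O/E (expected negative: depletion tracks methylation).
#'
#' @param oe Output of [gene_cpg_oe()].
#' @param classes Output of [classify_genes()].
#' @return List of class `cpg_oe_comparison`: `mean_methylated`,
#'   `mean_nonmethylated`, `f_statistic`, `df`, `f_p_value`, `t_test`
#'   (htest), `spearman` (htest or NULL if exon ratios unavailable),
#'   `n_methylated`, `n_nonmethylated`.
#' @export
compare_oe_classes <- function(oe, classes) {
  j <- merge(oe, classes, by = "gene_id")
  j <- j[!is.na(j$cpg_oe), , drop = FALSE]
  m <- j$cpg_oe[j$class == "methylated"]
  u <- j$cpg_oe[j$class == "nonmethylated"]
  if (length(m) < 2 || length(u) < 2) {
    stop("each class needs at least 2 genes with defined CpG O/E")
  }
  f <- var(m) / var(u)
  df <- c(length(m) - 1, length(u) - 1)
  f_p <- 2 * min(pf(f, df[1], df[2]), pf(f, df[1], df[2],
                                         lower.tail = FALSE))
  sp <- suppressWarnings(
    cor.test(j$exon_ratio, j$cpg_oe, method = "spearman"))
  structure(list(mean_methylated = mean(m), mean_nonmethylated = mean(u),
                 f_statistic = f, df = df, f_p_value = f_p,
                 t_test = t.test(m, u), spearman = sp,
                 n_methylated = length(m), n_nonmethylated = length(u)),
            class = "cpg_oe_comparison")
}

#' @export
print.cpg_oe_comparison <- function(x, ...) {
  cat(sprintf(
    "CpG O/E by class: methylated %.3f (n=%d), nonmethylated %.3f (n=%d)\n",
    x$mean_methylated, x$n_methylated, x$mean_nonmethylated,
    x$n_nonmethylated))
  cat(sprintf("variance ratio F(%d,%d) = %.3f, p = %.3g\n",
              x$df[1], x$df[2], x$f_statistic, x$f_p_value))
  cat(sprintf("Welch t = %.3f, p = %.3g; Spearman rho = %.3f\n",
              x$t_test$statistic, x$t_test$p.value,
              x$spearman$estimate))
  invisible(x)
}
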