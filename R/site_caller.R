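#' Estimate the bisulfite non-conversion error rate
#'
#' In insect genomes methylation is essentially confined to CpG context,
#' so reads reporting methylation at CHG/CHH cytosines measure failed
#' bisulfite conversion. The pooled rate
#' `sum(n_meth) / sum(n_meth + n_unmeth)` over non-CpG sites estimates the
#' error probability used as the binomial null in [call_sites()].
#'
#' @param records Cytosine report `data.frame` (see
#'   [read_cytosine_report()]).
#' @param mode `"non_cpg"` to pool non-CpG sites, `"fixed"` to pass
#'   through `value`.
#' @param value Error rate used in `"fixed"` mode.
#' @return Error rate in `[0, 1]`.
#' @export
estimate_error_rate <- function(records, mode = c("non_cpg", "fixed"),
                                value = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(value) || value <= 0 || value >= 1) {
      stop("fixed mode requires a value in (0, 1)")
    }
    return(value)
  }
  non <- records[records$context %in% c("CHG", "CHH"), , drop = FALSE]
  tot <- sum(non$n_meth) + sum(non$n_unmeth)
  if (nrow(non) == 0 || tot == 0) {
    stop("no covered non-CpG records; supply mode = \"fixed\" with a value")
  }
  sum(non$n_meth) / tot
}

#' Call per-site CpG methylation with a binomial test
#'
#' A site with `n_meth` of `n_total` reads reporting methylation is tested
#' against the null that all methylated reads arise from bisulfite
#' non-conversion: the one-sided upper-tail probability
#' `P[X >= n_meth]`, `X ~ Binomial(n_total, error_rate)`. Sites with fewer
#' than `min_reads` total reads are excluded before testing, so the
#' Benjamini-Hochberg family consists of tested sites only. A site is
#' called methylated when its adjusted p-value is below `alpha`.
#'
#' @param records Cytosine report `data.frame`; only `CpG`-context rows
#'   are tested (other contexts are dropped).
#' @param error_rate Binomial null probability in (0, 1); see
#'   [estimate_error_rate()].
#' @param min_reads Minimum total reads for a site to enter testing
#'   (default 2).
#' @param alpha Adjusted-p threshold for calling (default 0.05).
#' @return `data.frame` of class `site_calls`: `chrom`, `pos`, `strand`,
#'   `n_meth`, `n_total`, `level` (`n_meth / n_total`), `p_raw`, `p_adj`,
#'   `is_methylated`.
#' @export
call_sites <- function(records, error_rate = 0.01, min_reads = 2,
                       alpha = 0.05) {
  if (error_rate <= 0 || error_rate >= 1) {
    stop("error_rate must lie strictly between 0 and 1")
  }
  stopifnot(min_reads >= 1)
  r <- records
  if ("context" %in% names(r)) r <- r[r$context == "CpG", , drop = FALSE]
  n_total <- r$n_meth + r$n_unmeth
  keep <- n_total >= min_reads
  r <- r[keep, , drop = FALSE]
  n_total <- n_total[keep]
  p_raw <- pbinom(r$n_meth - 1, n_total, error_rate, lower.tail = FALSE)
  p_adj <- bh_adjust(p_raw)
  out <- data.frame(chrom = r$chrom, pos = r$pos, strand = r$strand,
                    n_meth = r$n_meth, n_total = n_total,
                    level = ifelse(n_total > 0, r$n_meth / n_total, NA_real_),
                    p_raw = p_raw, p_adj = p_adj,
                    is_methylated = p_adj < alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_calls", "data.frame")
  out
}

#' Summarise site calls against the genomic CpG universe
#'
#' @param calls Output of [call_sites()].
#' @param genome_cpg_total Total number of CpG cytosines in the genome
#'   (e.g. `nrow(enumerate_genome_cpgs(genome))`).
#' @return One-row `data.frame`: `n_detected`, `n_methylated`,
#'   `pct_of_genomic` (methylated as % of all genomic CpGs),
#'   `pct_of_detected` (methylated as % of detected CpGs),
#'   `mean_coverage`.
#' @examples
#' # the headline arithmetic of a sparse methylome: ~169,911 methylated
#' # sites against 19.7 million genomic and 14.5 million detected CpGs
#' calls <- data.frame(n_total = 1, is_methylated = TRUE)
#' summarize_calls(calls[rep(1, 10), ], genome_cpg_total = 1000)
#' @export
summarize_calls <- function(calls, genome_cpg_total) {
  stopifnot(genome_cpg_total > 0)
  n_detected <- nrow(calls)
  n_methylated <- sum(calls$is_methylated)
  data.frame(
    n_detected = n_detected,
    n_methylated = n_methylated,
    pct_of_genomic = 100 * n_methylated / genome_cpg_total,
    pct_of_detected = if (n_detected > 0) 100 * n_methylated / n_detected
                      else 0,
    mean_coverage = if (n_detected > 0) mean(calls$n_total) else NA_real_)
}
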