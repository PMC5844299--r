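#' Assign called CpG sites to gene features
#'
#' Each site is assigned, per gene, to one of three feature classes:
#' `exon` (inside any exon of the gene), `intron` (inside the gene span
#' but not in an exon; exon takes precedence), or `upstream2kb` (inside
#' the strand-aware 2 kb window 5' of the gene start). A site may be
#' assigned to several genes; it is counted in each.
#'
#' @param calls Site calls from [call_sites()] (needs `chrom`, `pos`).
#' @param models A [gene_models] object.
#' @param seqlengths Optional contig lengths for clipping upstream
#'   windows.
#' @param upstream_width Upstream window width (default 2000).
#' @return `data.frame` with one row per (site, gene, feature):
#'   `site` (row index into `calls`), `gene_id`, `feature`.
#' @export
assign_sites <- function(calls, models, seqlengths = NULL,
                         upstream_width = 2000) {
  stopifnot(inherits(models, "gene_models"))
  site_gr <- GenomicRanges::GRanges(calls$chrom,
                                    IRanges::IRanges(calls$pos, calls$pos))

  overlap_pairs <- function(tab) {
    if (nrow(tab) == 0) {
      return(data.frame(site = integer(), gene_id = character(),
                        stringsAsFactors = FALSE))
    }
    gr <- GenomicRanges::GRanges(tab$chrom,
                                 IRanges::IRanges(tab$start, tab$end))
    h <- GenomicRanges::findOverlaps(site_gr, gr)
    data.frame(site = S4Vectors::queryHits(h),
               gene_id = tab$gene_id[S4Vectors::subjectHits(h)],
               stringsAsFactors = FALSE)
  }

  ex <- models$exons
  ex$chrom <- models$genes$chrom[match(ex$gene_id, models$genes$gene_id)]
  exon_hits <- unique(overlap_pairs(ex))
  gene_hits <- overlap_pairs(models$genes)
  up_hits <- overlap_pairs(gene_upstream(models, seqlengths,
                                         upstream_width))

  key <- function(d) paste(d$site, d$gene_id)
  intron_hits <- gene_hits[!key(gene_hits) %in% key(exon_hits), ,
                           drop = FALSE]
  out <- rbind(
    if (nrow(exon_hits)) cbind(exon_hits, feature = "exon"),
    if (nrow(intron_hits)) cbind(intron_hits, feature = "intron"),
    if (nrow(up_hits)) cbind(up_hits, feature = "upstream2kb"))
  if (is.null(out)) {
    out <- data.frame(site = integer(), gene_id = character(),
                      feature = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Per-gene and per-feature methylation ratios
#'
#' The methylation ratio (mCpG/CpG) of a gene feature is the number of
#' CpG sites called methylated divided by the number of CpG sites
#' detected in that feature. Genes without detected CpGs in a feature get
#' `NA` (undefined), never silently 0. Genome-wide percentages per
#' feature class (`pct_mC`) aggregate counts over all genes.
#'
#' @param assignment Output of [assign_sites()].
#' @param calls The site calls the assignment refers to.
#' @return A list of class `feature_methylation`: `genes` (per gene:
#'   `gene_id`, `exon_ratio`, `intron_ratio`, `upstream_ratio`,
#'   `n_exon_cpg`, `n_exon_mcpg`, `has_any_mcpg`), and `features`
#'   (per feature class: `feature`, `n_cpg_detected`, `n_cpg_methylated`,
#'   `pct_mC`).
#' @export
compute_ratios <- function(assignment, calls) {
  a <- assignment
  a$meth <- calls$is_methylated[a$site]
  dt <- data.table::as.data.table(a)
  per <- dt[, list(n = .N, k = sum(meth)), by = c("gene_id", "feature")]

  wide <- function(feat, col) {
    sub <- per[per$feature == feat, ]
    setNames(sub[[col]], sub$gene_id)
  }
  gene_ids <- sort(unique(per$gene_id))
  ratio_of <- function(feat) {
    n <- wide(feat, "n")[gene_ids]
    k <- wide(feat, "k")[gene_ids]
    ifelse(!is.na(n) & n > 0, k / n, NA_real_)
  }
  n_ex <- wide("exon", "n")[gene_ids]
  k_ex <- wide("exon", "k")[gene_ids]
  tot_k <- tapply(per$k, per$gene_id, sum)[gene_ids]
  genes <- data.frame(
    gene_id = gene_ids,
    exon_ratio = ratio_of("exon"),
    intron_ratio = ratio_of("intron"),
    upstream_ratio = ratio_of("upstream2kb"),
    n_exon_cpg = ifelse(is.na(n_ex), 0L, n_ex),
    n_exon_mcpg = ifelse(is.na(k_ex), 0L, k_ex),
    has_any_mcpg = !is.na(tot_k) & tot_k > 0,
    stringsAsFactors = FALSE, row.names = NULL)

  feats <- dt[, list(n_cpg_detected = .N, n_cpg_methylated = sum(meth)),
              by = "feature"]
  feats$pct_mC <- 100 * feats$n_cpg_methylated / feats$n_cpg_detected
  data.table::setDF(feats)

  structure(list(genes = genes, features = feats),
            class = "feature_methylation")
}

#' @export
print.feature_methylation <- function(x, ...) {
  cat("feature_methylation:", nrow(x$genes), "genes\n")
  print(x$features)
  invisible(x)
}

#' Classify genes as methylated or nonmethylated
#'
#' A gene is methylated when its exon methylation ratio strictly exceeds
#' `threshold` (default 0.10, i.e. the "> 10%" rule). Genes with an
#' undefined exon ratio (no detected exonic CpGs) are excluded; their
#' count is carried in the `n_undefined` attribute.
#'
#' @param ratios A `feature_methylation` object from [compute_ratios()],
#'   or its `genes` data.frame.
#' @param threshold Exon-ratio cutoff (strict inequality).
#' @return `data.frame` with `gene_id`, `exon_ratio`, `class`
#'   (`"methylated"` / `"nonmethylated"`); attribute `n_undefined`.
#' @export
classify_genes <- function(ratios, threshold = 0.10) {
  g <- if (inherits(ratios, "feature_methylation")) ratios$genes else ratios
  undef <- is.na(g$exon_ratio)
  out <- data.frame(gene_id = g$gene_id[!undef],
                    exon_ratio = g$exon_ratio[!undef],
                    class = ifelse(g$exon_ratio[!undef] > threshold,
                                   "methylated", "nonmethylated"),
                    stringsAsFactors = FALSE)
  attr(out, "n_undefined") <- sum(undef)
  out
}
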