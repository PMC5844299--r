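#' Read a per-cytosine bisulfite count table (cytosine-report dialect)
#'
#' Reads the 7-column tab-separated per-cytosine report produced by
#' bisulfite-alignment post-processing (chromosome, 1-based position,
#' strand, count of reads supporting methylation, count supporting
#' non-methylation, context, trinucleotide). Counts encode methylation
#' because bisulfite converts unmethylated cytosines to thymine while
#' methylated cytosines are protected.
#'
#' @param path Path to the tab-separated report (no header).
#' @param context Optional context filter: keep only rows whose context
#'   matches (e.g. `"CpG"`). Default keeps all contexts.
#' @return A `data.frame` with columns `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_unmeth`, `context`, `trinucleotide`.
#' @examples
#' tf <- tempfile()
#' writeLines("scaf1\t10\t+\t5\t5\tCpG\tCGA", tf)
#' read_cytosine_report(tf)
#' @export
read_cytosine_report <- function(path, context = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), n_meth = integer(),
                      n_unmeth = integer(), context = character(),
                      trinucleotide = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 3, 6, 7)),
                          fill = TRUE, data.table = TRUE)
  if (nrow(dt) == 0) return(empty)
  if (ncol(dt) != 7) {
    stop("cytosine report must have 7 tab-separated columns, found ",
         ncol(dt))
  }
  data.table::setnames(dt, c("chrom", "pos", "strand", "n_meth",
                             "n_unmeth", "context", "trinucleotide"))
  bad <- which(!is.finite(dt$pos) | !is.finite(dt$n_meth) |
                 !is.finite(dt$n_unmeth))
  if (length(bad)) stop("malformed line ", bad[1], ": non-numeric field")
  bad <- which(dt$n_meth < 0 | dt$n_unmeth < 0)
  if (length(bad)) stop("malformed line ", bad[1], ": negative count")
  bad <- which(dt$pos < 1)
  if (length(bad)) stop("malformed line ", bad[1], ": position < 1")
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) stop("malformed line ", bad[1], ": strand must be + or -")
  if (!is.null(context)) {
    keep_ctx <- dt[["context"]] %in% context
    dt <- dt[keep_ctx, ]
  }
  data.table::setDF(dt)
  dt
}

#' Gene models: genes with exon structure
#'
#' Lightweight container for gene annotations: a `genes` table (one row per
#' gene: `gene_id`, `chrom`, `strand`, `start`, `end`; 1-based inclusive)
#' and an `exons` table (`gene_id`, `start`, `end`). Exons are sorted and
#' overlapping exons within a gene are merged (with a warning), so introns
#' are well-defined as within-gene gaps between exons.
#'
#' @param genes `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`.
#' @param exons `data.frame` with columns `gene_id`, `start`, `end`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  genes <- genes[order(genes$chrom, genes$start), , drop = FALSE]
  orphan <- !exons$gene_id %in% genes$gene_id
  if (any(orphan)) {
    warning(sum(orphan), " exon(s) without a parent gene; skipped")
    exons <- exons[!orphan, , drop = FALSE]
  }
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  # merge overlapping/adjacent-overlapping exons within each gene
  merged <- lapply(split(exons, exons$gene_id), function(e) {
    if (nrow(e) <= 1) return(e)
    ir <- IRanges::IRanges(e$start, e$end)
    red <- IRanges::reduce(ir)
    if (length(red) < nrow(e)) {
      warning("overlapping exons merged in gene ", e$gene_id[1])
    }
    data.frame(gene_id = e$gene_id[1], start = IRanges::start(red),
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  exons <- .rbind_all(merged)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
  }
  # exons must lie within their gene span
  gidx <- match(exons$gene_id, genes$gene_id)
  if (any(exons$start < genes$start[gidx] | exons$end > genes$end[gidx])) {
    stop("exon outside gene span")
  }
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      length(unique(x$genes$chrom)), "sequence(s)\n")
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Imports `gene` and `exon` features; exons are linked to genes through
#' their `Parent` attribute (one level of mRNA/transcript indirection is
#' resolved if present). Coordinates are kept 1-based inclusive as in GFF3.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models] object.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- if ("ID" %in% names(meta)) as.character(meta$ID) else
    rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr)[is_gene]),
    strand = as.character(GenomicRanges::strand(gr)[is_gene]),
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE)

  # resolve one level of indirection (exon -> mRNA -> gene)
  parent_of <- setNames(
    vapply(meta$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
           character(1)),
    ids)
  is_exon <- type == "exon"
  ex_parent <- vapply(meta$Parent[is_exon],
                      function(p) if (length(p)) p[[1]] else NA_character_,
                      character(1))
  resolved <- ifelse(ex_parent %in% genes$gene_id, ex_parent,
                     unname(parent_of[ex_parent]))
  exons <- data.frame(
    gene_id = resolved,
    start = GenomicRanges::start(gr)[is_exon],
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE)
  drop <- is.na(exons$gene_id)
  if (any(drop)) {
    warning(sum(drop), " exon(s) without a resolvable parent gene; skipped")
    exons <- exons[!drop, , drop = FALSE]
  }
  gene_models(genes, exons)
}

#' Intron intervals of gene models
#'
#' Introns are the within-gene gaps between sorted, merged exons.
#'
#' @param models A [gene_models] object.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive); zero rows for genes without introns.
#' @export
gene_introns <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  out <- lapply(split(ex, ex$gene_id), function(e) {
    if (nrow(e) <= 1) return(NULL)
    e <- e[order(e$start), ]
    data.frame(gene_id = e$gene_id[1],
               start = e$end[-nrow(e)] + 1L,
               end = e$start[-1] - 1L, stringsAsFactors = FALSE)
  })
  out <- .rbind_all(out)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- out[out$end >= out$start, , drop = FALSE]
  out$chrom <- models$genes$chrom[match(out$gene_id, models$genes$gene_id)]
  out[, c("gene_id", "chrom", "start", "end")]
}

#' Upstream (putative promoter) windows of gene models
#'
#' The window covers up to `width` bp 5' of the annotated gene start (used
#' as a proxy for the transcription start site), respecting strand, and is
#' clipped at contig boundaries.
#'
#' @param models A [gene_models] object.
#' @param seqlengths Optional named vector of contig lengths, used to clip
#'   windows of minus-strand genes at the contig end.
#' @param width Window width in bp (default 2000).
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`;
#'   genes whose window is empty (gene starts at a contig edge) are
#'   omitted.
#' @export
gene_upstream <- function(models, seqlengths = NULL, width = 2000) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  plus <- g$strand != "-"
  start <- ifelse(plus, pmax(1L, g$start - width), g$end + 1L)
  end <- ifelse(plus, g$start - 1L, g$end + width)
  if (!is.null(seqlengths)) {
    lim <- unname(seqlengths[g$chrom])
    end <- ifelse(plus, end, pmin(end, lim))
  }
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  out[out$end >= out$start, , drop = FALSE]
}

#' Enumerate all CpG cytosines of a genome
#'
#' Each CG dinucleotide contributes two strand-symmetric cytosines: the
#' plus-strand cytosine at the C position and the minus-strand cytosine at
#' the G position. Positions involving ambiguity codes are not matched.
#'
#' @param genome A `Biostrings::DNAStringSet` or path to a FASTA file.
#' @return `data.frame` with columns `chrom`, `pos` (1-based), `strand`.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = "ACGT"))
#' enumerate_genome_cpgs(genome)
#' @export
enumerate_genome_cpgs <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  stopifnot(methods::is(genome, "DNAStringSet"))
  hits <- Biostrings::vmatchPattern("CG", genome, fixed = TRUE)
  out <- lapply(seq_along(genome), function(i) {
    s <- BiocGenerics::start(hits[[i]])
    if (length(s) == 0) return(NULL)
    data.frame(chrom = names(genome)[i],
               pos = as.integer(rbind(s, s + 1L)),
               strand = rep(c("+", "-"), length(s)),
               stringsAsFactors = FALSE)
  })
  out <- .rbind_all(out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), stringsAsFactors = FALSE)
  }
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Write site calls as BED6
#'
#' Converts 1-based site positions to BED's 0-based half-open convention.
#' Columns: chrom, start, end, name (`chrom:pos`), score (methylation
#' level scaled to 0-1000 and rounded), strand.
#'
#' @param calls `data.frame` with columns `chrom`, `pos`, `strand`, `level`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_bed <- function(calls, path) {
  stopifnot(all(c("chrom", "pos", "strand", "level") %in% names(calls)))
  if (nrow(calls) == 0) {
    file.create(path)
    return(invisible(path))
  }
  bed <- data.frame(chrom = calls$chrom,
                    start = calls$pos - 1L,
                    end = calls$pos,
                    name = paste0(calls$chrom, ":", calls$pos),
                    score = as.integer(round(1000 * calls$level)),
                    strand = calls$strand, stringsAsFactors = FALSE)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read site calls back from BED6
#'
#' Inverse of [write_site_bed()]: restores 1-based positions and the
#' methylation level from the scaled score.
#'
#' @param path Path to a BED6 file written by [write_site_bed()].
#' @return `data.frame` with columns `chrom`, `pos`, `strand`, `level`.
#' @export
read_site_bed <- function(path) {
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), level = numeric(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  bed <- data.table::fread(path, header = FALSE, sep = "\t",
                           data.table = FALSE)
  if (nrow(bed) == 0) return(empty)
  data.frame(chrom = as.character(bed[[1]]), pos = bed[[3]],
             strand = as.character(bed[[6]]), level = bed[[5]] / 1000,
             stringsAsFactors = FALSE)
}
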