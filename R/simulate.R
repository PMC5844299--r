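#' Configuration for the synthetic methylome generator
#'
#' Collects every tunable of the generator with defaults chosen to mirror
#' the structure of a sparse, bimodal insect methylome: two overlapping
#' classes of lowly and highly methylated genes, binomially sampled read
#' counts with a ~1% bisulfite non-conversion error, sequencing depth
#' around 28x, CpG depletion in historically methylated genes, and
#' expression positively coupled to methylation class.
#'
#' @param seed RNG seed; identical configuration and seed give identical
#'   output.
#' @param n_contigs,contig_length Number and length (bp) of contigs.
#' @param gc_fraction Genomic GC content.
#' @param n_genes Number of genes, placed without overlap.
#' @param frac_methylated_genes Probability that a gene belongs to the
#'   highly methylated class.
#' @param beta_low,beta_high Beta parameters (length-2) for per-site true
#'   methylation fractions in the low and high class.
#' @param frac_low_sites_methylated Fraction of low-class (and intronic)
#'   sites that carry any methylation at all; the rest are exactly 0.
#'   Keeps the low class's asymptotic mCpG/CpG ratio below the 10%%
#'   classification cutoff and reproduces the large share of genes with
#'   no detectable methylation.
#' @param mean_coverage,nb_size Negative-binomial read depth: mean and
#'   dispersion (size) parameter.
#' @param error_rate Bisulfite non-conversion probability: the chance an
#'   unmethylated cytosine reads as methylated.
#' @param background_meth True methylation fraction at CpG sites outside
#'   genes (intergenic background).
#' @param deamination_strength Per-CpG probability of a CG -> TG/CA
#'   substitution in highly methylated genes, emulating deamination of
#'   methyl-cytosine over evolutionary time so that CpG depletion emerges
#'   from the sequence itself.
#' @param expression_coupling Additive log10-expression offset of the
#'   methylated class.
#' @param baseline_log_expr,sd_log_expr Baseline and spread (sd) of
#'   log10 FPKM.
#' @param frac_silent_nonmeth Fraction of nonmethylated-class genes set to
#'   FPKM = 0 (not expressed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_contigs = 4L,
                       contig_length = 600000L,
                       gc_fraction = 0.42,
                       n_genes = 400L,
                       frac_methylated_genes = 0.3,
                       beta_low = c(0.5, 20),
                       beta_high = c(8, 2),
                       frac_low_sites_methylated = 0.08,
                       mean_coverage = 28,
                       nb_size = 5,
                       error_rate = 0.01,
                       background_meth = 0.002,
                       deamination_strength = 0.2,
                       expression_coupling = 0.8,
                       baseline_log_expr = 0.7,
                       sd_log_expr = 0.5,
                       frac_silent_nonmeth = 0.10) {
  cfg <- list(seed = seed, n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              frac_methylated_genes = frac_methylated_genes,
              beta_low = beta_low, beta_high = beta_high,
              frac_low_sites_methylated = frac_low_sites_methylated,
              mean_coverage = mean_coverage, nb_size = nb_size,
              error_rate = error_rate, background_meth = background_meth,
              deamination_strength = deamination_strength,
              expression_coupling = expression_coupling,
              baseline_log_expr = baseline_log_expr,
              sd_log_expr = sd_log_expr,
              frac_silent_nonmeth = frac_silent_nonmeth)
  probs <- c(cfg$gc_fraction, cfg$frac_methylated_genes, cfg$error_rate,
             cfg$background_meth, cfg$deamination_strength,
             cfg$frac_silent_nonmeth, cfg$frac_low_sites_methylated)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate a genome with annotated genes and a true methylation state
#'
#' Generates random contigs at the configured GC content, places genes
#' with 2-6 exons without overlap, erodes CG dinucleotides inside highly
#' methylated genes (`deamination_strength`), and draws a true methylation
#' fraction for every CpG cytosine of the final sequence: exonic sites of
#' highly methylated genes from `beta_high`, other genic sites from
#' `beta_low`, intergenic sites at `background_meth`. Methylation is
#' therefore exon-biased, as observed in insect methylomes.
#'
#' @param config A [sim_config] object.
#' @return A list of class `meth_sim`: `genome` (DNAStringSet), `models`
#'   ([gene_models]), `truth` (list with per-gene `genes`: `gene_id`,
#'   `class`; and per-site `sites`: `chrom`, `pos`, `strand`, `m`,
#'   `gene_id`, `feature`), and `config`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- config$gc_fraction
  base_probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)

  contigs <- lapply(seq_len(config$n_contigs), function(i) {
    sample(names(base_probs), config$contig_length, replace = TRUE,
           prob = base_probs)
  })
  names(contigs) <- sprintf("contig_%02d", seq_len(config$n_contigs))

  # gene structures
  n <- config$n_genes
  classes <- rbinom(n, 1, config$frac_methylated_genes)
  genes <- vector("list", n)
  exons <- vector("list", n)
  cursor <- rep(1L, config$n_contigs)
  for (g in seq_len(n)) {
    ctg <- ((g - 1) %% config$n_contigs) + 1L
    n_ex <- sample(2:6, 1)
    ex_len <- sample(150:450, n_ex, replace = TRUE)
    in_len <- if (n_ex > 1) sample(80:400, n_ex - 1, replace = TRUE) else
      integer(0)
    gap <- sample(500:3000, 1)
    start <- cursor[ctg] + gap
    ex_start <- start + c(0L, cumsum(ex_len[-n_ex] + in_len))
    ex_end <- ex_start + ex_len - 1L
    end <- ex_end[n_ex]
    if (end > config$contig_length) {
      stop("genes do not fit on contigs; increase contig_length")
    }
    cursor[ctg] <- end
    gid <- sprintf("gene_%04d", g)
    genes[[g]] <- data.frame(gene_id = gid, chrom = names(contigs)[ctg],
                             strand = sample(c("+", "-"), 1),
                             start = start, end = end,
                             class = classes[g], stringsAsFactors = FALSE)
    exons[[g]] <- data.frame(gene_id = gid, start = ex_start, end = ex_end,
                             stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  exons <- do.call(rbind, exons)

  # deaminate CGs in highly methylated genes: CG -> TG or CG -> CA
  if (config$deamination_strength > 0) {
    for (g in which(genes$class == 1)) {
      ctg <- genes$chrom[g]
      seqv <- contigs[[ctg]]
      span <- genes$start[g]:genes$end[g]
      isC <- seqv[span[-length(span)]] == "C" & seqv[span[-1]] == "G"
      hit <- span[which(isC)]
      hit <- hit[runif(length(hit)) < config$deamination_strength]
      if (length(hit)) {
        to_t <- runif(length(hit)) < 0.5
        seqv[hit[to_t]] <- "T"                 # CG -> TG
        seqv[hit[!to_t] + 1L] <- "A"           # CG -> CA
        contigs[[ctg]] <- seqv
      }
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(contigs, paste0,
                                            character(1), collapse = ""))
  models <- gene_models(genes[, c("gene_id", "chrom", "strand", "start",
                                  "end")], exons)

  # true methylation fraction per CpG cytosine of the final sequence
  sites <- enumerate_genome_cpgs(genome)
  feat <- .locate_sites(sites, models)
  m <- rep(config$background_meth, nrow(sites))
  cls <- setNames(genes$class, genes$gene_id)
  genic <- !is.na(feat$gene_id)
  high_ex <- genic & feat$feature == "exon" & cls[feat$gene_id] == 1
  low <- genic & !high_ex
  m[high_ex] <- rbeta(sum(high_ex), config$beta_high[1], config$beta_high[2])
  n_low <- sum(low)
  m[low] <- ifelse(runif(n_low) < config$frac_low_sites_methylated,
                   rbeta(n_low, config$beta_low[1], config$beta_low[2]), 0)
  truth_sites <- cbind(sites, m = m, gene_id = feat$gene_id,
                       feature = feat$feature, stringsAsFactors = FALSE)

  structure(list(genome = genome, models = models,
                 truth = list(genes = genes[, c("gene_id", "class")],
                              sites = truth_sites),
                 config = config),
            class = "meth_sim")
}

# first (exon > intron > intergenic) feature of each site; upstream windows
# are not distinguished here because the true state only depends on genic
# context
.locate_sites <- function(sites, models) {
  site_gr <- GenomicRanges::GRanges(sites$chrom,
                                    IRanges::IRanges(sites$pos, sites$pos))
  ex <- models$exons
  gchrom <- models$genes$chrom[match(ex$gene_id, models$genes$gene_id)]
  ex_gr <- GenomicRanges::GRanges(gchrom, IRanges::IRanges(ex$start, ex$end))
  g_gr <- GenomicRanges::GRanges(models$genes$chrom,
                                 IRanges::IRanges(models$genes$start,
                                                  models$genes$end))
  gene_id <- rep(NA_character_, nrow(sites))
  feature <- rep(NA_character_, nrow(sites))
  hg <- GenomicRanges::findOverlaps(site_gr, g_gr, select = "first")
  ing <- !is.na(hg)
  gene_id[ing] <- models$genes$gene_id[hg[ing]]
  feature[ing] <- "intron"
  hx <- GenomicRanges::findOverlaps(site_gr, ex_gr, select = "first")
  inx <- !is.na(hx)
  gene_id[inx] <- ex$gene_id[hx[inx]]
  feature[inx] <- "exon"
  data.frame(gene_id = gene_id, feature = feature, stringsAsFactors = FALSE)
}

#' Simulate a per-cytosine bisulfite count table from a true state
#'
#' Per cytosine, coverage is drawn from a negative binomial and the
#' methylated read count from `Binomial(coverage, m + (1 - m) * error)`,
#' where `m` is the site's true methylation fraction and `error` the
#' bisulfite non-conversion rate; inappropriate conversion of methylated
#' cytosines is taken as absent. Non-CpG cytosines are truly unmethylated
#' (`m = 0`), as in insect genomes.
#'
#' @param sim A `meth_sim` object from [simulate_genome()].
#' @param contexts `"all"` for a full cytosine report (CpG + CHG + CHH) or
#'   `"CpG"` for CpG rows only.
#' @param seed RNG seed (default: `config$seed + 1`).
#' @return `data.frame` in cytosine-report layout (see
#'   [read_cytosine_report()]).
#' @export
simulate_counts <- function(sim, contexts = c("all", "CpG"), seed = NULL) {
  stopifnot(inherits(sim, "meth_sim"))
  contexts <- match.arg(contexts)
  if (is.null(seed)) seed <- sim$config$seed + 1L
  set.seed(seed)
  cfg <- sim$config

  cpg <- sim$truth$sites
  tab <- data.frame(chrom = cpg$chrom, pos = cpg$pos, strand = cpg$strand,
                    m = cpg$m, context = "CpG", stringsAsFactors = FALSE)
  if (contexts == "all") {
    other <- .non_cpg_cytosines(sim$genome)
    if (nrow(other)) {
      other$m <- 0
      tab <- rbind(tab, other[, c("chrom", "pos", "strand", "m", "context")])
    }
    tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  }
  ncov <- nrow(tab)
  cov <- rnbinom(ncov, mu = cfg$mean_coverage, size = cfg$nb_size)
  p <- tab$m + (1 - tab$m) * cfg$error_rate
  n_meth <- rbinom(ncov, cov, p)
  data.frame(chrom = tab$chrom, pos = tab$pos, strand = tab$strand,
             n_meth = n_meth, n_unmeth = cov - n_meth,
             context = tab$context,
             trinucleotide = .trinucleotide(sim$genome, tab$chrom, tab$pos,
                                            tab$strand),
             stringsAsFactors = FALSE)
}

# all cytosines outside CpG context, both strands, with CHG/CHH labels
.non_cpg_cytosines <- function(genome) {
  out <- lapply(seq_along(genome), function(i) {
    s <- strsplit(as.character(genome[[i]]), "")[[1]]
    L <- length(s)
    plus <- which(s == "C")
    minus <- which(s == "G")
    nxt <- function(pos, off, strand) {
      # strand-aware downstream base
      p <- if (strand == "+") pos + off else pos - off
      b <- rep("N", length(pos))
      ok <- p >= 1 & p <= L
      b[ok] <- s[p[ok]]
      if (strand == "-") b[ok] <- chartr("ACGT", "TGCA", b[ok])
      b
    }
    ctx <- function(pos, strand) {
      b1 <- nxt(pos, 1L, strand); b2 <- nxt(pos, 2L, strand)
      ifelse(b1 == "G", "CpG", ifelse(b2 == "G", "CHG", "CHH"))
    }
    cp <- ctx(plus, "+"); cm <- ctx(minus, "-")
    rbind(
      data.frame(chrom = names(genome)[i], pos = plus, strand = "+",
                 context = cp, stringsAsFactors = FALSE)[cp != "CpG", ],
      data.frame(chrom = names(genome)[i], pos = minus, strand = "-",
                 context = cm, stringsAsFactors = FALSE)[cm != "CpG", ])
  })
  .rbind_all(out)
}

.trinucleotide <- function(genome, chrom, pos, strand) {
  out <- character(length(pos))
  seqs <- lapply(as.character(genome), function(s) strsplit(s, "")[[1]])
  base_at <- function(v, p) {
    b <- rep("N", length(p))
    ok <- p >= 1 & p <= length(v)
    b[ok] <- v[p[ok]]
    b
  }
  for (ch in unique(chrom)) {
    v <- seqs[[ch]]
    sel <- which(chrom == ch)
    p <- pos[sel]
    plus <- strand[sel] == "+"
    tri <- character(length(sel))
    ip <- sel[plus]; pp <- p[plus]
    tri[plus] <- paste0(base_at(v, pp), base_at(v, pp + 1L),
                        base_at(v, pp + 2L))
    im <- p[!plus]
    tri[!plus] <- chartr("ACGT", "TGCA",
                         paste0(base_at(v, im), base_at(v, im - 1L),
                                base_at(v, im - 2L)))
    out[sel] <- tri
  }
  out
}

#' Simulate a TMM-normalised FPKM expression table
#'
#' Log10 expression is `baseline + coupling * [gene is methylated] +
#' Gaussian noise`; a configurable fraction of nonmethylated-class genes
#' is silenced (FPKM = 0), emulating the enrichment of unexpressed genes
#' among genes without methylation.
#'
#' @param sim A `meth_sim` object.
#' @param seed RNG seed (default: `config$seed + 2`).
#' @return `data.frame` with columns `gene_id`, `fpkm`.
#' @export
simulate_expression <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "meth_sim"))
  if (is.null(seed)) seed <- sim$config$seed + 2L
  set.seed(seed)
  cfg <- sim$config
  g <- sim$truth$genes
  log_expr <- cfg$baseline_log_expr + cfg$expression_coupling * g$class +
    rnorm(nrow(g), 0, cfg$sd_log_expr)
  fpkm <- 10^log_expr
  nonmeth <- which(g$class == 0)
  silent <- sample(nonmeth, round(cfg$frac_silent_nonmeth * length(nonmeth)))
  fpkm[silent] <- 0
  data.frame(gene_id = g$gene_id, fpkm = fpkm, stringsAsFactors = FALSE)
}

#' Simulate a two-group targeted bisulfite amplicon panel
#'
#' Per site, the two phenotype groups have true methylation fractions
#' `base_meth -/+ planted_diff / 2` (so the group difference equals
#' `planted_diff`, long minus short); per sample and site, methylated read
#' counts are binomial at the observed probability `m + (1 - m) * error`.
#'
#' @param sites `data.frame` with columns `chrom`, `pos`, `base_meth` and
#'   optionally `gene_id`.
#' @param planted_diff Per-site true group difference (recycled).
#' @param n_per_group Samples per phenotype group.
#' @param coverage Read depth per site and sample.
#' @param error_rate Bisulfite non-conversion rate.
#' @param seed RNG seed.
#' @return List with `samples` (named list of per-sample `data.frame`s:
#'   `chrom`, `pos`, `n_meth`, `n_unmeth`), `labels` (`sample`, `group`)
#'   and `truth` (`chrom`, `pos`, `mean_long`, `mean_short`).
#' @export
simulate_amplicon_panel <- function(sites, planted_diff = 0,
                                    n_per_group = 8, coverage = 500,
                                    error_rate = 0.01, seed = 1L) {
  stopifnot(all(c("chrom", "pos", "base_meth") %in% names(sites)))
  set.seed(seed)
  ns <- nrow(sites)
  diff <- rep_len(planted_diff, ns)
  m_long <- sites$base_meth + diff / 2
  m_short <- sites$base_meth - diff / 2
  if (any(m_long < 0 | m_long > 1 | m_short < 0 | m_short > 1)) {
    stop("planted difference drives a group mean outside [0, 1]")
  }
  groups <- rep(c("long", "short"), each = n_per_group)
  sample_ids <- sprintf("%s_%02d", groups, c(seq_len(n_per_group),
                                             seq_len(n_per_group)))
  samples <- lapply(seq_along(sample_ids), function(i) {
    m <- if (groups[i] == "long") m_long else m_short
    p <- m + (1 - m) * error_rate
    n_meth <- rbinom(ns, coverage, p)
    data.frame(chrom = sites$chrom, pos = sites$pos, n_meth = n_meth,
               n_unmeth = coverage - n_meth, stringsAsFactors = FALSE)
  })
  names(samples) <- sample_ids
  list(samples = samples,
       labels = data.frame(sample = sample_ids, group = groups,
                           stringsAsFactors = FALSE),
       truth = data.frame(chrom = sites$chrom, pos = sites$pos,
                          mean_long = m_long, mean_short = m_short,
                          stringsAsFactors = FALSE))
}
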