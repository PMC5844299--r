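#' Per-site fractional methylation across amplicon samples
#'
#' Builds the sites x samples matrix of fractional methylation
#' (mCpG/CpG per site: methylated reads over total reads). A site is
#' retained when at least one sample covers it with `min_reads` reads;
#' samples below `min_reads` at a retained site contribute `NA`.
#'
#' @param samples Named list of per-sample count tables (`chrom`, `pos`,
#'   `n_meth`, `n_unmeth`), all over the same site coordinate space.
#' @param min_reads Per-sample coverage threshold (default 10).
#' @return List of class `amplicon_fractions`: `fractions` (matrix,
#'   rownames `chrom:pos`), `sites` (`chrom`, `pos`), `n_dropped`
#'   (sites failing the coverage rule in every sample).
#' @export
amplicon_site_fractions <- function(samples, min_reads = 10) {
  stopifnot(is.list(samples), length(samples) >= 1)
  key <- function(d) paste0(d$chrom, ":", d$pos)
  k0 <- key(samples[[1]])
  for (s in samples[-1]) {
    if (!identical(key(s), k0)) {
      stop("inconsistent site coordinates across samples")
    }
  }
  frac <- sapply(samples, function(d) {
    tot <- d$n_meth + d$n_unmeth
    ifelse(tot >= min_reads, d$n_meth / tot, NA_real_)
  })
  frac <- matrix(frac, nrow = length(k0),
                 dimnames = list(k0, names(samples)))
  covered <- rowSums(!is.na(frac)) >= 1
  structure(list(fractions = frac[covered, , drop = FALSE],
                 sites = data.frame(chrom = samples[[1]]$chrom[covered],
                                    pos = samples[[1]]$pos[covered],
                                    stringsAsFactors = FALSE),
                 n_dropped = sum(!covered)),
            class = "amplicon_fractions")
}

#' Two-group comparison of amplicon methylation
#'
#' Per retained site: group means of per-sample fractional methylation,
#' their difference (`long` minus `short`), and a two-sample Student
#' t-test (equal variances by default, Welch via `var_equal = FALSE`).
#' Sites with fewer than 2 non-missing samples in either group are
#' flagged (`tested = FALSE`) and get `NA` statistics. No
#' multiple-testing adjustment is applied to the reported p-values; a
#' BH-adjusted column is emitted alongside for transparency.
#'
#' @param fractions An `amplicon_fractions` object (or a plain matrix of
#'   per-sample fractions with sample columns).
#' @param labels `data.frame` with `sample`, `group`; groups must be
#'   `"long"` and `"short"`.
#' @param var_equal Use the pooled-variance Student t-test (default).
#' @return `data.frame` sorted by `|meth_diff|` descending: `chrom`,
#'   `pos`, `mean_long`, `mean_short`, `meth_diff`, `t_statistic`,
#'   `p_value`, `p_bh`, `n_long`, `n_short`, `tested`.
#' @export
amplicon_compare_groups <- function(fractions, labels, var_equal = TRUE) {
  if (inherits(fractions, "amplicon_fractions")) {
    mat <- fractions$fractions
    sites <- fractions$sites
  } else {
    mat <- fractions
    parts <- strsplit(rownames(mat), ":", fixed = TRUE)
    sites <- data.frame(chrom = vapply(parts, `[`, "", 1),
                        pos = as.integer(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("sample", "group") %in% names(labels)),
            all(labels$group %in% c("long", "short")))
  grp <- setNames(labels$group, labels$sample)[colnames(mat)]
  if (anyNA(grp)) stop("every sample column needs a group label")
  long_cols <- grp == "long"

  rows <- lapply(seq_len(nrow(mat)), function(i) {
    xl <- mat[i, long_cols]; xl <- xl[!is.na(xl)]
    xs <- mat[i, !long_cols]; xs <- xs[!is.na(xs)]
    ok <- length(xl) >= 2 && length(xs) >= 2
    tt <- if (ok && (var(xl) > 0 || var(xs) > 0)) {
      t.test(xl, xs, var.equal = var_equal)
    } else NULL
    data.frame(chrom = sites$chrom[i], pos = sites$pos[i],
               mean_long = if (length(xl)) mean(xl) else NA_real_,
               mean_short = if (length(xs)) mean(xs) else NA_real_,
               meth_diff = if (length(xl) && length(xs))
                 mean(xl) - mean(xs) else NA_real_,
               t_statistic = if (!is.null(tt)) unname(tt$statistic)
                             else if (ok) 0 else NA_real_,
               p_value = if (!is.null(tt)) tt$p.value
                         else if (ok) 1 else NA_real_,
               n_long = length(xl), n_short = length(xs),
               tested = ok, stringsAsFactors = FALSE)
  })
  out <- .rbind_all(rows)
  out$p_bh <- NA_real_
  out$p_bh[out$tested] <- bh_adjust(out$p_value[out$tested])
  out[order(-abs(out$meth_diff)), , drop = FALSE]
}

#' Concordance of amplicon and whole-genome methylation estimates
#'
#' Least-squares fit of per-site mean amplicon methylation on the WGBS
#' methylation level at the same sites; a strong positive relationship
#' validates the targeted assay against the genome-wide one.
#'
#' @param amplicon_means Per-site mean fractional methylation over all
#'   amplicon samples.
#' @param wgbs_levels Matched per-site WGBS methylation levels.
#' @return List: `r_squared`, `slope`, `intercept`, `p_value`, `n`;
#'   `slope_negative` flags an anti-correlated fit.
#' @export
concordance_wgbs <- function(amplicon_means, wgbs_levels) {
  ok <- !is.na(amplicon_means) & !is.na(wgbs_levels)
  x <- wgbs_levels[ok]; y <- amplicon_means[ok]
  if (length(x) < 3) stop("need at least 3 shared sites")
  fit <- lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  p <- if (s$sigma == 0 || nrow(s$coefficients) < 2 ||
           is.na(s$coefficients[2, 4])) 0 else s$coefficients[2, 4]
  list(r_squared = s$r.squared,
       slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       p_value = p, n = length(x),
       slope_negative = unname(coef(fit)[2]) < 0)
}
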