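#' Hartigan's dip statistic
#'
#' The dip of a sample is the sup-norm distance between its empirical CDF
#' and the closest unimodal CDF (convex below the mode, concave above,
#' with an atom allowed at the mode). It measures departure from
#' unimodality: an equispaced (perfectly flat) sample of size `n` attains
#' the minimum `1/(2n)`, and a balanced two-point mixture attains the
#' maximum 0.25.
#'
#' The statistic is computed exactly by bisection on the fit distance:
#' a candidate distance is feasible when, for some mode placement on the
#' tied-value-reduced empirical CDF, a convex chain fits the band below
#' the mode (greatest-convex-minorant feasibility), a concave chain fits
#' it above (least-concave-majorant), and the two sides are compatible
#' at the mode -- the convex side's minimal attainable value, forced up
#' by convex extrapolation, must not exceed the concave side's maximal
#' start value; both extremes are tracked exactly as convex polygons of
#' achievable (slope, value) states.
#'
#' @param x Numeric sample, `n >= 4`.
#' @return The dip statistic in `[0, 0.25]`.
#' @examples
#' dip_statistic(seq_len(8) / 8)        # 1 / 16
#' dip_statistic(c(0, 0, 0, 1, 1, 1))   # 0.25
#' @export
dip_statistic <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x must not contain NA")
  if (length(x) < 4) stop("need at least 4 observations")
  .dip_cpp(sort(x))
}

#' Dip test of unimodality (Monte-Carlo null)
#'
#' Tests the null of unimodality by comparing the observed dip to dips of
#' uniform(0, 1) samples of the same size (the conventional reference
#' null). The p-value uses the plus-one correction
#' `(1 + #{dip_boot >= dip_obs}) / (n_boot + 1)`.
#'
#' @param x Numeric sample, `n >= 4`.
#' @param n_boot Number of Monte-Carlo null samples (>= 100).
#' @param seed Optional RNG seed for reproducibility.
#' @return List of class `dip_test`: `statistic`, `p_value`, `n`,
#'   `n_boot`, `seed`.
#' @export
dip_test <- function(x, n_boot = 2000, seed = NULL) {
  stopifnot(n_boot >= 100)
  d <- dip_statistic(x)
  n <- length(x)
  if (!is.null(seed)) set.seed(seed)
  boots <- vapply(seq_len(n_boot),
                  function(i) .dip_cpp(sort(runif(n))), numeric(1))
  p <- (1 + sum(boots >= d)) / (n_boot + 1)
  structure(list(statistic = d, p_value = p, n = n, n_boot = n_boot,
                 seed = seed), class = "dip_test")
}

#' @export
print.dip_test <- function(x, ...) {
  cat(sprintf("Hartigan dip test: D = %.5f, n = %d, MC p = %.4g (%d draws)\n",
              x$statistic, x$n, x$p_value, x$n_boot))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: for raw p-values sorted
#' ascending, `p_adj_(i) = min_{j >= i} ( n * p_(j) / j )`, capped at 1
#' and mapped back to the input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(n * p[o] / seq_len(n))))
  pmin(adj, 1)[order(o)]
}

#' Fisher-exact term enrichment
#'
#' One-sided (enrichment) Fisher exact test per term on the 2x2 table
#' of target/non-target vs annotated/not-annotated genes, with
#' Benjamini-Hochberg adjustment across terms.
#'
#' @param target_genes Character vector of target gene ids (must be a
#'   subset of `background_genes`).
#' @param background_genes Character vector of all gene ids in the
#'   reference set.
#' @param gene2term `data.frame` with columns `gene_id`, `term`; genes
#'   outside the background are ignored.
#' @param fdr_alpha FDR threshold for the `enriched` flag.
#' @return `data.frame`: `term`, `a` (target with term), `b` (non-target
#'   with term), `c` (target without term), `d` (non-target without
#'   term), `odds_ratio`, `p_fisher`, `fdr`, `enriched`.
#' @export
fisher_enrichment <- function(target_genes, background_genes, gene2term,
                              fdr_alpha = 0.05) {
  if (length(target_genes) == 0) stop("empty target set")
  target_genes <- unique(target_genes)
  background_genes <- unique(background_genes)
  if (!all(target_genes %in% background_genes)) {
    stop("target genes must be a subset of the background")
  }
  g2t <- gene2term[gene2term$gene_id %in% background_genes, , drop = FALSE]
  n_t <- length(target_genes)
  n_b <- length(background_genes)
  terms <- sort(unique(g2t$term))
  rows <- lapply(terms, function(tm) {
    with_term <- unique(g2t$gene_id[g2t$term == tm])
    a <- sum(with_term %in% target_genes)
    b <- length(with_term) - a
    cc <- n_t - a
    d <- (n_b - n_t) - b
    ft <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                      alternative = "greater")
    data.frame(term = tm, a = a, b = b, c = cc, d = d,
               odds_ratio = unname(ft$estimate), p_fisher = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- .rbind_all(rows)
  out$fdr <- bh_adjust(out$p_fisher)
  out$enriched <- out$fdr < fdr_alpha
  out[order(out$p_fisher), , drop = FALSE]
}
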