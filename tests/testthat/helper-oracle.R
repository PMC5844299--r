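# Independent oracles used across tests.

# Exact dip oracle: minimum over mode placements of an LP fit of a
# piecewise-linear convex-then-concave CDF within the sup-norm band
# (boot::simplex).  Mode either at a distinct value (atom) or inside a
# gap, optimised by golden section (the objective is quasiconvex in the
# mode position).  Independent of the package's hull/DP implementation.
dip_lp_oracle <- function(x) {
  x <- sort(x); n <- length(x)
  u <- unique(x)
  LO <- cumsum(tabulate(match(x, u))) / n
  HI <- c(0, LO[-length(LO)])
  U <- length(u)
  if (U == 1) return(0)

  solve_placement <- function(pu, loB, hiB, nl) {
    P <- length(pu); nv <- P + 1; eps <- nv
    rows1 <- list(); rhs1 <- c(); rows2 <- list(); rhs2 <- c()
    add1 <- function(r, b) { rows1[[length(rows1) + 1]] <<- r
                             rhs1 <<- c(rhs1, b) }
    add2 <- function(r, b) { rows2[[length(rows2) + 1]] <<- r
                             rhs2 <<- c(rhs2, b) }
    for (p in seq_len(P)) {
      r <- rep(0, nv); r[p] <- 1; r[eps] <- -1; add1(r, hiB[p])
      r <- rep(0, nv); r[p] <- 1; r[eps] <-  1; add2(r, loB[p])
    }
    for (p in seq_len(P - 1)) {
      r <- rep(0, nv); r[p + 1] <- 1; r[p] <- -1; add2(r, 0)
    }
    r <- rep(0, nv); r[P] <- 1; add1(r, 1)
    for (t in 2:(P - 1)) {
      d1 <- pu[t] - pu[t - 1]; d2 <- pu[t + 1] - pu[t]
      if (d1 <= 0 || d2 <= 0) next
      r <- rep(0, nv); r[t + 1] <- d1; r[t] <- -(d1 + d2); r[t - 1] <- d2
      if (t + 1 <= nl) add2(r, 0)          # convex part
      if (t - 1 >= nl) add1(r, 0)          # concave part
    }
    a <- c(rep(0, nv - 1), 1)
    s <- tryCatch(
      boot::simplex(a = a, A1 = do.call(rbind, rows1), b1 = rhs1,
                    A2 = do.call(rbind, rows2), b2 = rhs2,
                    maxi = FALSE, n.iter = 500 * nv),
      error = function(e) NULL)
    if (is.null(s) || s$solved != 1) return(NA_real_)
    s$value
  }

  vals <- c()
  for (M in seq_len(U)) {
    pu  <- c(u[seq_len(M - 1)], u[M], u[M], if (M < U) u[(M + 1):U])
    loB <- c(LO[seq_len(M - 1)], HI[M], LO[M], if (M < U) LO[(M + 1):U])
    hiB <- c(HI[seq_len(M - 1)], HI[M], LO[M], if (M < U) HI[(M + 1):U])
    vals <- c(vals, solve_placement(pu, loB, hiB, nl = M))
  }
  if (U >= 2) for (j in seq_len(U - 1)) {
    gap_val <- function(m) {
      pu  <- c(u[seq_len(j)], m, m, u[(j + 1):U])
      loB <- c(LO[seq_len(j)], LO[j], LO[j], LO[(j + 1):U])
      hiB <- c(HI[seq_len(j)], LO[j], LO[j], HI[(j + 1):U])
      solve_placement(pu, loB, hiB, nl = j + 1)
    }
    marg <- 1e-5 * (u[j + 1] - u[j])
    a <- u[j] + marg; b <- u[j + 1] - marg; phi <- (sqrt(5) - 1) / 2
    c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
    f1 <- gap_val(c1); f2 <- gap_val(c2)
    bestg <- suppressWarnings(min(f1, f2, na.rm = TRUE))
    for (it in 1:60) {
      if (is.na(f1) || is.na(f2)) break
      if (f1 <= f2) {
        b <- c2; c2 <- c1; f2 <- f1
        c1 <- b - phi * (b - a); f1 <- gap_val(c1)
      } else {
        a <- c1; c1 <- c2; f1 <- f2
        c2 <- a + phi * (b - a); f2 <- gap_val(c2)
      }
      bestg <- suppressWarnings(min(bestg, f1, f2, na.rm = TRUE))
      if (abs(b - a) < 1e-13) break
    }
    vals <- c(vals, bestg)
  }
  min(vals, na.rm = TRUE)
}

# Brute-force interval membership: which genes/features cover position p.
brute_force_feature <- function(pos, chrom, models, seqlengths = NULL,
                                width = 2000) {
  hits <- list()
  for (i in seq_len(nrow(models$genes))) {
    g <- models$genes[i, ]
    if (g$chrom != chrom) next
    ex <- models$exons[models$exons$gene_id == g$gene_id, , drop = FALSE]
    in_exon <- any(pos >= ex$start & pos <= ex$end)
    if (in_exon) {
      hits[[length(hits) + 1]] <- c(g$gene_id, "exon")
    } else if (pos >= g$start && pos <= g$end) {
      hits[[length(hits) + 1]] <- c(g$gene_id, "intron")
    }
    if (g$strand != "-") {
      us <- max(1, g$start - width); ue <- g$start - 1
    } else {
      us <- g$end + 1
      ue <- g$end + width
      if (!is.null(seqlengths)) ue <- min(ue, seqlengths[[g$chrom]])
    }
    if (ue >= us && pos >= us && pos <= ue) {
      hits[[length(hits) + 1]] <- c(g$gene_id, "upstream2kb")
    }
  }
  if (!length(hits)) {
    return(data.frame(gene_id = character(), feature = character()))
  }
  m <- do.call(rbind, hits)
  data.frame(gene_id = m[, 1], feature = m[, 2], stringsAsFactors = FALSE)
}

# Small shared simulation for fast tests (one genome per test run).
tiny_sim <- function(seed = 11, n_genes = 60, contig_length = 250000L) {
  simulate_genome(sim_config(seed = seed, n_genes = n_genes,
                             n_contigs = 2L,
                             contig_length = contig_length))
}
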