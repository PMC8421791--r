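# Shared fixtures and independent oracles for the suite. Oracles here are
# deliberately naive (enumeration / direct formulas), independent of the
# package's computational paths.

# single-chromosome layout with markers at given cM (bp spaced 1 Mb)
one_chr_layout <- function(cm, len_cm = max(cm, 1), len_bp = 1e6 * (length(cm) + 1),
                           snp_bp = NULL, qtl = NULL) {
  chroms <- data.frame(chrom = "chr1", length_bp = len_bp, length_cm = len_cm)
  markers <- data.frame(name = paste0("m", seq_along(cm)), chrom = "chr1",
                        bp = 1e6 * seq_along(cm))
  # explicit marker cM only when no SNPs share the chromosome (mixing
  # declared and interpolated positions would break monotonicity)
  if (is.null(snp_bp)) markers$cm <- cm
  snps <- if (is.null(snp_bp)) NULL else data.frame(chrom = "chr1", bp = snp_bp)
  genome_layout(chroms, markers = markers, snps = snps, qtl = qtl)
}

# cross_data straight from genotype code vectors (one per marker)
make_cross <- function(..., chrom = "chr1", pheno = NULL) {
  cols <- list(...)
  geno <- do.call(cbind, cols)
  markers <- data.frame(name = paste0("m", seq_along(cols)), chrom = chrom,
                        bp = 1e6 * seq_along(cols))
  cross_data(geno, markers, pheno = pheno)
}

# textbook Pearson chi-square, written directly
oracle_chi2_gof <- function(obs, ratio) {
  exp <- sum(obs) * ratio / sum(ratio)
  sum((obs - exp)^2 / exp)
}

# exhaustive minimum-crossover count: try every chromatid assignment of
# the het markers and count switches directly
oracle_min_crossovers <- function(geno) {
  g <- geno[geno != "-"]
  if (length(g) < 2) return(0L)
  options <- lapply(g, function(code) switch(code,
    A = list(c(0L, 0L)), B = list(c(1L, 1L)),
    H = list(c(0L, 1L), c(1L, 0L))))
  best <- Inf
  idx <- rep(1L, length(g))
  repeat {
    states <- mapply(function(opts, i) opts[[i]], options, idx, SIMPLIFY = FALSE)
    switches <- 0L
    for (k in 2:length(states))
      switches <- switches + sum(states[[k]] != states[[k - 1]])
    best <- min(best, switches)
    # advance the mixed-radix counter
    pos <- 1L
    while (pos <= length(g)) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= length(options[[pos]])) break
      idx[pos] <- 1L
      pos <- pos + 1L
    }
    if (pos > length(g)) break
  }
  as.integer(best)
}

# F2 two-locus genotype-class probabilities by direct enumeration of
# gamete pairs (independent of the package's implementation)
oracle_two_locus_probs <- function(r) {
  haps <- list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  hp <- c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  p <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    d1 <- haps[[i]][1] + haps[[j]][1]
    d2 <- haps[[i]][2] + haps[[j]][2]
    p[d1 + 1, d2 + 1] <- p[d1 + 1, d2 + 1] + hp[i] * hp[j]
  }
  p
}

# dense grid-search MLE of r over the same two-locus likelihood
oracle_grid_rf <- function(counts, grid = seq(1e-4, 0.5, by = 1e-4)) {
  ll <- vapply(grid, function(r) {
    p <- oracle_two_locus_probs(r)
    sum(counts[p > 0] * log(p[p > 0]))
  }, numeric(1))
  grid[which.max(ll)]
}

# simulate a two-locus F2 count table at true recombination fraction r
sim_two_locus_counts <- function(r, n) {
  p <- oracle_two_locus_probs(r)
  counts <- stats::rmultinom(1, n, as.vector(p))
  matrix(counts, 3, 3)
}
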