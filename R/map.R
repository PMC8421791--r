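#' Kosambi map function and its inverse
#'
#' Converts a recombination fraction r to Kosambi genetic distance,
#' d = (1/4) ln((1+2r)/(1-2r)) Morgans (returned in cM), and back via
#' r = (1/2) tanh(2d).
#'
#' @param r recombination fraction(s), 0 <= r < 0.5.
#' @return `kosambi_cm()`: distance in centimorgans.
#' @export
kosambi_cm <- function(r) {
  if (any(is.na(r)) || any(r < 0)) stop("r must lie in [0, 0.5)")
  if (any(r >= 0.5)) stop("r >= 0.5 corresponds to infinite map distance")
  100 * 0.25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_cm
#' @param cm genetic distance(s) in centimorgans, >= 0.
#' @return `kosambi_r()`: recombination fraction.
#' @export
kosambi_r <- function(cm) {
  if (any(is.na(cm)) || any(cm < 0)) stop("cM must be >= 0")
  0.5 * tanh(2 * cm / 100)
}

# 3x3 matrix of F2 two-locus genotype-class probabilities at
# recombination fraction r; rows/cols indexed by Gigi-allele dosage 0/1/2
# at locus 1/2. Gamete haplotype probs: parental (1-r)/2, recombinant r/2.
f2_two_locus_probs <- function(r) {
  g <- c(pp = (1 - r) / 2, pq = r / 2, qp = r / 2, qq = (1 - r) / 2)
  hap <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))  # alleles at the two loci
  probs <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    a <- hap[i, 1] + hap[j, 1]
    b <- hap[i, 2] + hap[j, 2]
    probs[a + 1, b + 1] <- probs[a + 1, b + 1] + g[i] * g[j]
  }
  probs
}

# log-likelihood of a 3x3 two-locus count table at recombination fraction r
f2_two_locus_loglik <- function(counts, r) {
  p <- f2_two_locus_probs(r)
  sum(counts[p > 0] * log(p[p > 0]))
}

#' Estimate the recombination fraction between two F2 markers
#'
#' Maximum-likelihood estimate of r from the 3x3 table of two-locus
#' genotype classes, by EM over expected recombinant-gamete counts. The
#' double heterozygote class is a mixture of two-parental and
#' two-recombinant gamete configurations (phase is unobserved); all other
#' classes have a determined recombinant count. Also reports the linkage
#' LOD, log10 L(r-hat) - log10 L(1/2).
#'
#' @param cross a `cross_data` object (see [read_cross()]).
#' @param markerA,markerB marker names.
#' @param tol EM convergence tolerance on r.
#' @return list with `r` (clipped to \[1e-6, 0.5\]), `lod`, `n` (complete
#'   pairs used) and `counts` (the 3x3 table, Gigi dosage 0/1/2).
#' @export
estimate_rf <- function(cross, markerA, markerB, tol = 1e-10) {
  g1 <- genotype_dosage(cross, markerA)
  g2 <- genotype_dosage(cross, markerB)
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 10) stop("fewer than 10 individuals typed at both markers")
  counts <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  est <- estimate_rf_counts(unclass(counts), tol = tol)
  est$counts <- counts
  est
}

# EM on a 3x3 count table; exported workhorse so count tables can be
# analysed directly
#' @rdname estimate_rf
#' @param counts 3x3 matrix of two-locus genotype counts (dosage 0/1/2).
#' @export
estimate_rf_counts <- function(counts, tol = 1e-10) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  n <- sum(counts)
  # recombinant gametes determined by class, except the double het
  det_rec <- matrix(c(0, 1, 2,
                      1, NA, 1,
                      2, 1, 0), nrow = 3, byrow = TRUE)
  n_dh <- counts[2, 2]
  fixed_rec <- sum(counts * ifelse(is.na(det_rec), 0, det_rec))
  r <- 0.25
  for (iter in 1:1000) {
    # P(double het is the two-recombinant configuration)
    w <- r^2 / (r^2 + (1 - r)^2)
    r_new <- (fixed_rec + 2 * w * n_dh) / (2 * n)
    r_new <- min(max(r_new, 1e-6), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  lod <- (f2_two_locus_loglik(counts, r) -
            f2_two_locus_loglik(counts, 0.5)) / log(10)
  list(r = r, lod = max(0, lod), n = n)
}

#' Build a genetic map from adjacent-marker recombination fractions
#'
#' For each chromosome, estimates r between consecutive markers (physical
#' order; no de novo ordering) with [estimate_rf()] and accumulates
#' Kosambi cM positions from the first marker.
#'
#' @param cross a `cross_data`.
#' @return data.frame with `name`, `chrom`, `bp`, `r_next` (r to the next
#'   marker, `NA` for the last of a chromosome), `lod_next`, and `cm`
#'   (cumulative Kosambi position within chromosome).
#' @export
build_genetic_map <- function(cross) {
  mk <- cross$markers
  out <- mk[, c("name", "chrom", "bp")]
  out$r_next <- NA_real_
  out$lod_next <- NA_real_
  out$cm <- NA_real_
  for (cc in unique(mk$chrom)) {
    i <- which(mk$chrom == cc)
    cm <- 0
    out$cm[i[1]] <- 0
    if (length(i) > 1) for (k in seq_len(length(i) - 1)) {
      est <- estimate_rf(cross, mk$name[i[k]], mk$name[i[k + 1]])
      out$r_next[i[k]] <- est$r
      out$lod_next[i[k]] <- est$lod
      cm <- cm + kosambi_cm(min(est$r, 0.5 - 1e-9))
      out$cm[i[k + 1]] <- cm
    }
  }
  out
}
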