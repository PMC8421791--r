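#' Mendelian segregation chi-square test
#'
#' Pearson goodness-of-fit of observed F2 genotype counts (maize hom,
#' het, Gigi hom) against an expected ratio, 1:2:1 by default; df = 2.
#'
#' @param counts numeric vector `(n_A, n_H, n_B)` of non-negative counts.
#' @param ratio expected class ratio (default `c(1, 2, 1)`).
#' @return list of class `seg_test` with `counts`, `expected`,
#'   `statistic`, `df`, `p_value`.
#' @export
seg_distortion_chi2 <- function(counts, ratio = c(1, 2, 1)) {
  if (length(counts) != length(ratio)) stop("counts and ratio lengths differ")
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("total count must be > 0")
  # p-values are asymptotic; small expected counts warn uninformatively
  ht <- suppressWarnings(stats::chisq.test(counts, p = ratio / sum(ratio)))
  structure(list(counts = counts, expected = unname(ht$expected),
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value)),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, ...) {
  cat(sprintf("chi2 = %.3f, df = %.0f, p = %.4g (counts %s)\n",
              x$statistic, x$df, x$p_value, paste(x$counts, collapse = "/")))
  invisible(x)
}

#' Per-marker genotype counts and segregation tests
#'
#' Tabulates A/H/B/missing per marker and applies
#' [seg_distortion_chi2()] to each -- the standard segregation-distortion
#' screen run before QTL scanning.
#'
#' @param cross a `cross_data`.
#' @return data.frame with `marker`, `chrom`, `n_A`, `n_H`, `n_B`,
#'   `missing`, `chi2`, `p_value`.
#' @export
geno_table <- function(cross) {
  stopifnot(inherits(cross, "cross_data"))
  res <- lapply(seq_len(ncol(cross$geno)), function(j) {
    g <- cross$geno[, j]
    counts <- c(sum(g == "A"), sum(g == "H"), sum(g == "B"))
    st <- if (sum(counts) > 0) seg_distortion_chi2(counts) else
      list(statistic = NA_real_, p_value = NA_real_)
    data.frame(marker = cross$markers$name[j], chrom = cross$markers$chrom[j],
               n_A = counts[1], n_H = counts[2], n_B = counts[3],
               missing = sum(g == "-"),
               chi2 = st$statistic, p_value = st$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Two-locus linkage chi-square test
#'
#' Pearson test of independence on the 3x3 genotype contingency table of
#' two markers, after dropping empty rows/columns; used to check that two
#' QTL regions segregate independently (no linkage disequilibrium that
#' could create spurious trait associations).
#'
#' @param cross a `cross_data`.
#' @param markerA,markerB marker names.
#' @return list of class `seg_test` with the contingency `table`,
#'   `statistic`, `df`, `p_value`.
#' @export
two_locus_linkage_chi2 <- function(cross, markerA, markerB) {
  g1 <- genotype_dosage(cross, markerA)
  g2 <- genotype_dosage(cross, markerB)
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 20) stop("fewer than 20 individuals typed at both markers")
  tab <- table(factor(g1[ok], levels = 0:2), factor(g2[ok], levels = 0:2))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("degenerate contingency table: fewer than two non-empty classes")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(counts = tab, table = tab,
                 statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = unname(ht$p.value)),
            class = "seg_test")
}
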