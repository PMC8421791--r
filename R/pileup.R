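#' Sequencing depth model for pooled bulks
#'
#' @param lambda mean read depth per SNP per bulk (Poisson; > 0).
#' @param epsilon per-read sequencing error rate, in \[0, 0.05\].
#' @param parent_lambda mean depth for the parent sample.
#' @return An object of class `depth_model`.
#' @export
depth_model <- function(lambda = 50, epsilon = 0, parent_lambda = lambda) {
  if (lambda <= 0 || parent_lambda <= 0) stop("mean depth must be > 0")
  if (epsilon < 0 || epsilon > 0.05) stop("epsilon must lie in [0, 0.05]")
  structure(list(lambda = lambda, epsilon = epsilon,
                 parent_lambda = parent_lambda),
            class = "depth_model")
}

#' Simulate pooled sequencing read counts over the bulks
#'
#' At each SNP locus the true Gigi-allele frequency in a bulk is the
#' fraction of Gigi alleles among its pooled individuals. Read depth is
#' Poisson(`lambda`) and the Gigi-supporting read count is binomial with
#' success probability `f(1-eps) + (1-f)eps`. The Gigi parent is emitted
#' as a homozygous-ALT call (the maize line is the reference) with depth
#' at least 3 and GQ 99, so that the standard parent-side filters pass by
#' construction; bulk GQ is an idealised phred-scaled likelihood ratio
#' `min(99, round(10 * DP * log10(2)))`, which reaches the 99 cap from 33
#' reads up.
#'
#' @param sim an `f2_sim`.
#' @param bulk1,bulk2 integer indices of bulk members (from [form_bulks()]).
#' @param depth a [depth_model()].
#' @param seed optional integer seed.
#' @return data.frame of class `bulk_pileup`: one row per SNP locus with
#'   `chrom`, `pos`, `ref`, `alt`, parent fields (`parent_gt`, `parent_dp`,
#'   `parent_gq`) and per-bulk `ad1`, `dp1`, `gq1`, `ad2`, `dp2`, `gq2`.
#' @export
simulate_bulk_pileup <- function(sim, bulk1, bulk2, depth = depth_model(),
                                 seed = NULL) {
  stopifnot(inherits(sim, "f2_sim"), inherits(depth, "depth_model"))
  if (length(bulk1) == 0 || length(bulk2) == 0) stop("empty bulk")
  if (!is.null(seed)) set.seed(seed)
  loci <- sim$layout$loci
  is_snp <- loci$type == "snp"
  if (!any(is_snp)) stop("layout declares no SNP loci")
  snp <- loci[is_snp, , drop = FALSE]
  m <- nrow(snp)

  draw_bulk <- function(ids) {
    f <- colSums(sim$geno[ids, is_snp, drop = FALSE]) / (2 * length(ids))
    dp <- stats::rpois(m, depth$lambda)
    p <- f * (1 - depth$epsilon) + (1 - f) * depth$epsilon
    ad <- stats::rbinom(m, dp, p)
    list(ad = ad, dp = dp, gq = pmin(99L, as.integer(round(10 * dp * log10(2)))))
  }
  b1 <- draw_bulk(bulk1)
  b2 <- draw_bulk(bulk2)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))

  structure(data.frame(
    chrom = snp$chrom, pos = snp$bp, ref = ref, alt = unname(alt),
    parent_gt = "1/1",
    parent_dp = pmax(3L, stats::rpois(m, depth$parent_lambda)),
    parent_gq = 99L,
    ad1 = b1$ad, dp1 = b1$dp, gq1 = b1$gq,
    ad2 = b2$ad, dp2 = b2$dp, gq2 = b2$gq,
    stringsAsFactors = FALSE),
    class = c("bulk_pileup", "data.frame"))
}

#' Write a parent + two-bulk pileup as a VCF v4.2 file
#'
#' Emits one biallelic SNP per record with FORMAT `GT:AD:DP:GQ` and
#' samples ordered parent, bulk1, bulk2. Bulk genotype calls are a naive
#' threshold on the alt-read fraction (they are not used downstream; the
#' analysis consumes AD/DP/GQ). The output round-trips losslessly through
#' [read_bulk_vcf()].
#'
#' @param pileup a [simulate_bulk_pileup()] result (rows sorted by
#'   chromosome then position; unsorted input is an error).
#' @param path output file path.
#' @param parent,bulk1,bulk2 sample names for the header.
#' @param contigs optional data.frame (`chrom`, `length_bp`) for contig
#'   header lines; taken from the pileup extent if omitted.
#' @return `path`, invisibly.
#' @export
write_bulk_vcf <- function(pileup, path, parent = "Gigi", bulk1 = "RG",
                           bulk2 = "NRG", contigs = NULL) {
  stopifnot(is.data.frame(pileup))
  chrom_order <- unique(pileup$chrom)
  o <- order(match(pileup$chrom, chrom_order), pileup$pos)
  if (nrow(pileup) > 0 && any(o != seq_len(nrow(pileup))))
    stop("pileup records must be sorted by (chrom, pos)")

  if (is.null(contigs) && nrow(pileup) > 0) {
    len <- tapply(pileup$pos, pileup$chrom, max)
    contigs <- data.frame(chrom = names(len), length_bp = as.numeric(len))
    contigs <- contigs[match(chrom_order, contigs$chrom), ]
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=regqtl",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", contigs$chrom, as.integer(contigs$length_bp)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", parent, bulk1, bulk2, sep = "\t"))

  body <- character(0)
  if (nrow(pileup) > 0) {
    naive_gt <- function(ad, dp) {
      frac <- ifelse(dp > 0, ad / dp, NA_real_)
      ifelse(is.na(frac), "./.",
             ifelse(frac < 0.25, "0/0", ifelse(frac > 0.75, "1/1", "0/1")))
    }
    fmt <- function(gt, ad_ref, ad_alt, dp, gq)
      sprintf("%s:%d,%d:%d:%d", gt, ad_ref, ad_alt, dp, gq)
    parent_col <- fmt(pileup$parent_gt, 0L, pileup$parent_dp,
                      pileup$parent_dp, pileup$parent_gq)
    b1_col <- fmt(naive_gt(pileup$ad1, pileup$dp1),
                  pileup$dp1 - pileup$ad1, pileup$ad1, pileup$dp1, pileup$gq1)
    b2_col <- fmt(naive_gt(pileup$ad2, pileup$dp2),
                  pileup$dp2 - pileup$ad2, pileup$ad2, pileup$dp2, pileup$gq2)
    body <- paste(pileup$chrom, as.integer(pileup$pos), ".", pileup$ref,
                  pileup$alt, ".", "PASS", ".", "GT:AD:DP:GQ",
                  parent_col, b1_col, b2_col, sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Export marker genotypes and phenotypes as a cross table
#'
#' Tab-separated dialect: a header row of column names (`id`, marker
#' names, phenotype columns), a second row giving each marker's
#' chromosome, a third giving its bp position (`-` for non-marker
#' columns), then one row per individual with genotype codes `A` (maize
#' hom), `H` (het), `B` (Gigi hom), `-` (missing), the binary regrowth
#' calls per time point and the tiller count.
#'
#' @param sim an `f2_sim` (phenotypes optional).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cross_tsv <- function(sim, path) {
  stopifnot(inherits(sim, "f2_sim"))
  loci <- sim$layout$loci
  mk <- which(loci$type == "marker")
  if (length(mk) == 0) stop("layout declares no marker loci")
  codes <- c("A", "H", "B")[sim$geno[, mk, drop = FALSE] + 1L]
  geno <- matrix(codes, nrow = nrow(sim$geno))

  pheno <- sim$pheno
  pheno_names <- if (is.null(pheno)) character(0) else names(pheno)
  header <- c("id", loci$name[mk], pheno_names)
  chrom_row <- c("chrom", loci$chrom[mk], rep("-", length(pheno_names)))
  pos_row <- c("pos", format(loci$bp[mk], scientific = FALSE, trim = TRUE),
               rep("-", length(pheno_names)))

  pheno_cols <- if (is.null(pheno)) NULL else {
    pm <- as.matrix(pheno)
    pm[is.na(pm)] <- "-"
    pm
  }
  rows <- cbind(sim$id, geno, pheno_cols)
  lines <- c(paste(header, collapse = "\t"),
             paste(chrom_row, collapse = "\t"),
             paste(pos_row, collapse = "\t"),
             apply(rows, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
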