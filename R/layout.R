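#' Define a synthetic genome layout for F2 simulation
#'
#' A `genome_layout` holds the physical and genetic skeleton on which F2
#' populations are simulated: chromosome sizes, codominant marker loci,
#' SNP loci interrogated by pooled sequencing, and the trait loci (QTL)
#' themselves. Genetic (cM) positions of loci are taken as given when
#' supplied, otherwise interpolated from physical position assuming a
#' uniform recombination rate along each chromosome.
#'
#' @param chromosomes data.frame with columns `chrom` (id), `length_bp`
#'   (physical length, base pairs) and `length_cm` (genetic length,
#'   centimorgans, >= 0).
#' @param markers data.frame with columns `name`, `chrom`, `bp` and
#'   optionally `cm`; codominant marker loci scored on individuals.
#' @param snps data.frame with columns `chrom`, `bp`; loci observed only
#'   through pooled sequencing. May be `NULL`.
#' @param qtl data.frame with columns `name`, `chrom`, `bp`, `role`
#'   (one of `"early"`, `"late"`, `"tiller"`) and optionally `cm`.
#'   May be `NULL` for a neutral genome.
#'
#' @return An object of class `genome_layout`: the validated inputs plus
#'   `$loci`, a single table of all loci (markers, SNPs, QTL) with columns
#'   `name`, `chrom`, `bp`, `cm`, `type`, sorted by (chrom, bp).
#' @export
genome_layout <- function(chromosomes, markers = NULL, snps = NULL, qtl = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("chrom", "length_bp", "length_cm") %in% names(chromosomes)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome ids")
  if (any(chromosomes$length_bp <= 0)) stop("chromosome physical length must be > 0")
  if (any(chromosomes$length_cm < 0)) stop("chromosome genetic length must be >= 0")

  as_loci <- function(df, type, need_name = TRUE) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df <- as.data.frame(df)
    if (!need_name && is.null(df$name))
      df$name <- paste0(type, "_", df$chrom, "_", df$bp)
    stopifnot(all(c("name", "chrom", "bp") %in% names(df)))
    data.frame(name = as.character(df$name), chrom = as.character(df$chrom),
               bp = as.numeric(df$bp),
               cm = if ("cm" %in% names(df)) as.numeric(df$cm) else NA_real_,
               type = type,
               role = if ("role" %in% names(df)) as.character(df$role) else NA_character_,
               stringsAsFactors = FALSE)
  }
  loci <- rbind(as_loci(markers, "marker"),
                as_loci(snps, "snp", need_name = FALSE),
                as_loci(qtl, "qtl"))
  if (is.null(loci) || nrow(loci) == 0) stop("layout declares no loci")
  if (!all(loci$chrom %in% chromosomes$chrom))
    stop("locus on undeclared chromosome: ",
         paste(unique(setdiff(loci$chrom, chromosomes$chrom)), collapse = ", "))
  bad_role <- loci$type == "qtl" & !loci$role %in% c("early", "late", "tiller")
  if (any(bad_role)) stop("QTL role must be one of early/late/tiller")
  if (any(loci$bp < 1)) stop("bp positions must be >= 1")

  # interpolate missing cM from bp under a uniform cM/bp rate per chromosome
  idx <- match(loci$chrom, chromosomes$chrom)
  rate <- chromosomes$length_cm[idx] / chromosomes$length_bp[idx]
  loci$cm <- ifelse(is.na(loci$cm), loci$bp * rate, loci$cm)

  loci <- loci[order(match(loci$chrom, chromosomes$chrom), loci$bp), , drop = FALSE]
  rownames(loci) <- NULL
  for (cc in unique(loci$chrom)) {
    sub <- loci[loci$chrom == cc, ]
    if (anyDuplicated(sub$bp)) stop("bp positions must be strictly increasing within ", cc)
    if (is.unsorted(sub$cm)) stop("cM positions must be non-decreasing within ", cc)
  }
  if (anyDuplicated(loci$name)) stop("duplicated locus names")

  structure(list(chromosomes = chromosomes, loci = loci),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x$chromosomes), "chromosomes,",
      sum(x$loci$type == "marker"), "markers,",
      sum(x$loci$type == "snp"), "SNPs,",
      sum(x$loci$type == "qtl"), "QTL\n")
  invisible(x)
}

#' Default synthetic genome for regrowth QTL studies
#'
#' A scaled-down stand-in for the maize physical map: ten 50-Mb chromosomes
#' of 75 cM each, 2,000 sequencing SNPs evenly spaced genome-wide (one per
#' 250 kb, i.e. four per 1-Mb bin), 22 codominant markers on the three
#' chromosomes carrying trait loci, and up to three QTL: an early-acting
#' regrowth locus on chromosome 2, a late-acting regrowth locus on
#' chromosome 8, and a tiller-number locus on chromosome 3.
#'
#' @param n_snps total number of sequencing SNP loci, spread evenly.
#' @param qtl_roles character subset of `c("early", "late", "tiller")`
#'   selecting which trait loci exist.
#' @return A [genome_layout()].
#' @export
default_layout <- function(n_snps = 2000, qtl_roles = c("early", "late", "tiller")) {
  chroms <- data.frame(chrom = paste0("chr", 1:10),
                       length_bp = rep(50e6, 10),
                       length_cm = rep(75, 10))
  per_chr <- ceiling(n_snps / 10)
  snps <- do.call(rbind, lapply(chroms$chrom, function(cc) {
    # offset by a prime so sparse grids never collide with marker/QTL bp
    data.frame(chrom = cc,
               bp = round(seq(125e3, 50e6 - 125e3, length.out = per_chr)) + 137)
  }))
  marker_bp <- function(chrom, positions)
    data.frame(name = paste0(chrom, "_m", seq_along(positions)),
               chrom = chrom, bp = positions)
  markers <- rbind(
    marker_bp("chr2", seq(5e6, 47e6, by = 6e6)),    # 8 markers spanning the early QTL
    marker_bp("chr7", seq(4e6, 46e6, by = 7e6)),    # 7 markers, neutral chromosome
    marker_bp("chr8", seq(5e6, 47e6, by = 7e6)))    # 7 markers spanning the late QTL
  qtl <- data.frame(name = c("early_qtl", "late_qtl", "tiller_qtl"),
                    chrom = c("chr2", "chr8", "chr3"),
                    bp = c(23.4e6, 26.6e6, 30.2e6),
                    role = c("early", "late", "tiller"))
  qtl <- qtl[qtl$role %in% qtl_roles, , drop = FALSE]
  if (nrow(qtl) == 0) qtl <- NULL
  genome_layout(chroms, markers = markers, snps = snps, qtl = qtl)
}
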