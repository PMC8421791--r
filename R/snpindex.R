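#' Read a parent + two-bulk VCF into variant records
#'
#' Parses a VCF v4.2 containing the donor parent and the two
#' phenotype-selected bulks, keeping one record per biallelic SNP line.
#' Multiallelic and non-SNP (indel/symbolic) lines are skipped and
#' counted. Missing FORMAT values become `NA`.
#'
#' @param path VCF file (plain text or gzipped; parsed with vcfR).
#' @param parent,bulk1,bulk2 sample names as they appear in the VCF
#'   header; `bulk1` is the phenotype-selected bulk (e.g. regrown or
#'   high-tiller), `bulk2` its opposite.
#' @return data.frame of class `bulk_variants` with columns `chrom`,
#'   `pos`, `ref`, `alt`, `parent_gt`, `parent_dp`, `parent_gq`, `ad1`,
#'   `dp1`, `gq1`, `ad2`, `dp2`, `gq2`; attribute `skipped` counts the
#'   lines dropped as `multiallelic` or `non_snp`.
#' @export
read_bulk_vcf <- function(path, parent = "Gigi", bulk1 = "RG", bulk2 = "NRG") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  for (s in c(parent, bulk1, bulk2))
    if (!s %in% samples) stop("sample missing from VCF header: ", s)

  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0) {
    out <- empty_bulk_variants()
    attr(out, "skipped") <- c(multiallelic = 0L, non_snp = 0L)
    return(out)
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  snp <- !multi & nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  keep <- which(snp)

  get_fmt <- function(elem, numeric = TRUE) {
    m <- vcfR::extract.gt(v, element = elem, as.numeric = numeric)
    m[keep, , drop = FALSE]
  }
  gt <- get_fmt("GT", numeric = FALSE)
  dp <- get_fmt("DP")
  gq <- get_fmt("GQ")
  ad <- vcfR::extract.gt(v, element = "AD")[keep, , drop = FALSE]
  ad_alt <- apply(ad, 2L, function(x) {
    alt <- suppressWarnings(as.numeric(vapply(strsplit(x, ",", fixed = TRUE),
                                              function(p) if (length(p) >= 2) p[2] else NA_character_,
                                              character(1))))
    alt
  })
  if (length(keep) == 1) ad_alt <- matrix(ad_alt, nrow = 1, dimnames = list(NULL, colnames(ad)))

  out <- data.frame(
    chrom = fix$CHROM[keep], pos = as.numeric(fix$POS[keep]),
    ref = fix$REF[keep], alt = fix$ALT[keep],
    parent_gt = unname(gt[, parent]),
    parent_dp = unname(dp[, parent]),
    parent_gq = unname(gq[, parent]),
    ad1 = unname(ad_alt[, bulk1]), dp1 = unname(dp[, bulk1]), gq1 = unname(gq[, bulk1]),
    ad2 = unname(ad_alt[, bulk2]), dp2 = unname(dp[, bulk2]), gq2 = unname(gq[, bulk2]),
    stringsAsFactors = FALSE)
  class(out) <- c("bulk_variants", "data.frame")
  attr(out, "skipped") <- c(multiallelic = sum(multi),
                            non_snp = sum(!multi & !snp))
  out
}

empty_bulk_variants <- function() {
  out <- data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
                    alt = character(0), parent_gt = character(0),
                    parent_dp = numeric(0), parent_gq = numeric(0),
                    ad1 = numeric(0), dp1 = numeric(0), gq1 = numeric(0),
                    ad2 = numeric(0), dp2 = numeric(0), gq2 = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("bulk_variants", "data.frame")
  out
}

#' SNP filter criteria for QTL-seq
#'
#' The standard filters applied before SNP-index computation: the donor
#' parent must be called homozygous for the ALT allele with a minimum
#' read depth, and both bulks must reach a minimum genotype quality.
#'
#' @param parent_min_dp minimum parent read depth (default 3).
#' @param bulk_min_gq minimum phred genotype quality in each bulk
#'   (default 99).
#' @param require_parent_hom_alt require a homozygous-ALT parent call.
#' @return An object of class `filter_criteria`.
#' @export
filter_criteria <- function(parent_min_dp = 3, bulk_min_gq = 99,
                            require_parent_hom_alt = TRUE) {
  if (parent_min_dp < 0 || bulk_min_gq < 0) stop("thresholds must be >= 0")
  structure(list(parent_min_dp = parent_min_dp, bulk_min_gq = bulk_min_gq,
                 require_parent_hom_alt = isTRUE(require_parent_hom_alt)),
            class = "filter_criteria")
}

#' Filter variant records before SNP-index computation
#'
#' A record is kept iff the parent call is homozygous-ALT (when required),
#' the parent depth reaches `parent_min_dp`, and genotype quality reaches
#' `bulk_min_gq` in *both* bulks. Absent fields fail their rule. Rejected
#' records are partitioned by the first rule they fail, in the order
#' parent genotype, parent depth, bulk GQ.
#'
#' @param records a `bulk_variants` data.frame.
#' @param criteria a [filter_criteria()].
#' @return list with `kept` (the surviving records) and `rejected`
#'   (named counts `parent_genotype`, `parent_depth`, `bulk_gq`).
#' @export
filter_variants <- function(records, criteria = filter_criteria()) {
  stopifnot(is.data.frame(records), inherits(criteria, "filter_criteria"))
  hom_alt <- !is.na(records$parent_gt) & records$parent_gt %in% c("1/1", "1|1")
  ok_gt <- if (criteria$require_parent_hom_alt) hom_alt else rep(TRUE, nrow(records))
  ok_dp <- !is.na(records$parent_dp) & records$parent_dp >= criteria$parent_min_dp
  ok_gq <- !is.na(records$gq1) & !is.na(records$gq2) &
    records$gq1 >= criteria$bulk_min_gq & records$gq2 >= criteria$bulk_min_gq

  first_fail <- ifelse(!ok_gt, "parent_genotype",
                ifelse(!ok_dp, "parent_depth",
                ifelse(!ok_gq, "bulk_gq", "kept")))
  kept <- records[first_fail == "kept", , drop = FALSE]
  class(kept) <- class(records)
  rejected <- c(parent_genotype = sum(first_fail == "parent_genotype"),
                parent_depth = sum(first_fail == "parent_depth"),
                bulk_gq = sum(first_fail == "bulk_gq"))
  list(kept = kept, rejected = rejected)
}

#' SNP-index: fraction of reads carrying the donor allele
#'
#' `AD/DP` for a bulk: the fraction of reads at the SNP supporting the
#' ALT (Gigi) allele. After the parent-homozygous filter the ALT allele
#' is the donor-parent allele, so the SNP-index is the donor allele
#' frequency in the pool as seen by the sequencer.
#'
#' @param ad alt-supporting read count(s).
#' @param dp total read depth(s); must be > 0.
#' @return Numeric in \[0, 1\].
#' @export
snp_index <- function(ad, dp) {
  if (any(is.na(dp)) || any(dp <= 0)) stop("snp_index undefined for DP <= 0")
  if (any(ad < 0 | ad > dp)) stop("need 0 <= AD <= DP")
  ad / dp
}

#' Per-SNP SNP-index and delta SNP-index for both bulks
#'
#' Computes `AD/DP` in each bulk and their difference (bulk1 - bulk2;
#' i.e. selected minus unselected, RG - NRG or HT - LT). Records with
#' zero depth in either bulk are undefined and dropped with a count --
#' coding them 0 would bias the delta.
#'
#' @param records a filtered `bulk_variants` data.frame.
#' @return data.frame of class `snp_index_table` with columns `chrom`,
#'   `pos`, `index1`, `index2`, `delta`; attribute `dropped_zero_depth`
#'   counts the excluded records.
#' @export
delta_snp_index <- function(records) {
  stopifnot(is.data.frame(records))
  ok <- !is.na(records$dp1) & !is.na(records$dp2) &
    records$dp1 > 0 & records$dp2 > 0 &
    !is.na(records$ad1) & !is.na(records$ad2)
  r <- records[ok, , drop = FALSE]
  out <- data.frame(chrom = r$chrom, pos = r$pos,
                    index1 = snp_index(r$ad1, r$dp1),
                    index2 = snp_index(r$ad2, r$dp2),
                    stringsAsFactors = FALSE)
  out$delta <- out$index1 - out$index2
  class(out) <- c("snp_index_table", "data.frame")
  attr(out, "dropped_zero_depth") <- sum(!ok)
  out
}

#' Mean SNP-index per genomic bin
#'
#' Divides each chromosome into fixed-size bins (default 1 Mb) on 1-based
#' coordinates -- bin k covers \[k*B + 1, (k+1)*B\], so position B belongs
#' to the first bin -- and reports the unweighted arithmetic mean
#' SNP-index of each bulk and mean delta over the SNPs in each bin. Bins
#' containing no SNPs are omitted.
#'
#' @param idx a [delta_snp_index()] table.
#' @param bin_size bin width in bp (> 0; default 1e6).
#' @return data.frame with `chrom`, `bin_start`, `bin_end`, `n_snps`,
#'   `index1`, `index2`, `delta`.
#' @export
bin_snp_index <- function(idx, bin_size = 1e6) {
  stopifnot(is.data.frame(idx))
  if (length(bin_size) != 1 || is.na(bin_size) || bin_size <= 0)
    stop("bin_size must be > 0")
  if (nrow(idx) == 0)
    return(data.frame(chrom = character(0), bin_start = numeric(0),
                      bin_end = numeric(0), n_snps = integer(0),
                      index1 = numeric(0), index2 = numeric(0),
                      delta = numeric(0)))
  bin <- floor((idx$pos - 1) / bin_size)
  key <- paste(idx$chrom, bin, sep = "\r")
  agg <- function(x) tapply(x, key, mean)
  n <- tapply(idx$pos, key, length)
  first <- !duplicated(key)
  ord_key <- key[first][order(match(idx$chrom[first], unique(idx$chrom)),
                              bin[first])]
  out <- data.frame(
    chrom = sub("\r.*$", "", ord_key),
    bin_start = as.numeric(sub("^.*\r", "", ord_key)) * bin_size + 1,
    n_snps = as.integer(n[ord_key]),
    index1 = as.numeric(agg(idx$index1)[ord_key]),
    index2 = as.numeric(agg(idx$index2)[ord_key]),
    delta = as.numeric(agg(idx$delta)[ord_key]),
    stringsAsFactors = FALSE)
  out$bin_end <- out$bin_start + bin_size - 1
  out[, c("chrom", "bin_start", "bin_end", "n_snps", "index1", "index2", "delta")]
}
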