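# SNP filters, SNP-index arithmetic, delta and binning

make_records <- function(parent_gt = "1/1", parent_dp = 30, gq1 = 99, gq2 = 99,
                         ad1 = 5, dp1 = 10, ad2 = 5, dp2 = 10,
                         chrom = "chr1", pos = NULL) {
  n <- max(lengths(list(parent_gt, parent_dp, gq1, gq2, ad1, dp1, ad2, dp2)))
  if (is.null(pos)) pos <- seq_len(n) * 100
  out <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                    parent_gt = parent_gt, parent_dp = parent_dp,
                    parent_gq = 99, ad1 = ad1, dp1 = dp1, gq1 = gq1,
                    ad2 = ad2, dp2 = dp2, gq2 = gq2,
                    stringsAsFactors = FALSE)
  class(out) <- c("bulk_variants", "data.frame")
  out
}

test_that("multiallelic and non-SNP lines are skipped with counts", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"q\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "Gigi", "RG", "NRG", sep = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD:DP:GQ\t1/1:0,9:9:99\t0/1:5,5:10:99\t0/0:9,1:10:99",
    "chr1\t200\t.\tA\tT,G\t.\tPASS\t.\tGT:AD:DP:GQ\t1/1:0,9,0:9:99\t0/1:5,5,0:10:99\t0/0:9,1,0:10:99",
    "chr1\t300\t.\tAT\tA\t.\tPASS\t.\tGT:AD:DP:GQ\t1/1:0,9:9:99\t0/1:5,5:10:99\t0/0:9,1:10:99"),
    path)
  rec <- read_bulk_vcf(path)
  expect_equal(nrow(rec), 1)
  expect_equal(unname(attr(rec, "skipped")["multiallelic"]), 1L)
  expect_equal(unname(attr(rec, "skipped")["non_snp"]), 1L)
  expect_error(read_bulk_vcf(path, bulk1 = "HT"), "sample missing")
})

test_that("filters keep exactly the records passing every rule", {
  # enumerate pass/fail combinations of the three rules
  rec <- make_records(
    parent_gt = c("1/1", "1/1", "0/1", "1/1", "0/0", "1/1", "./.", "1/1", "1/1", "1/1"),
    parent_dp = c(30,     2,    30,    3,    30,    30,    30,    30,   50,   30),
    gq1       = c(99,    99,    99,   99,    99,    98,   99,    99,   99,   99),
    gq2       = c(99,    99,    99,   99,    99,    99,   99,    45,   99,   99))
  flt <- filter_variants(rec, filter_criteria())
  expect_equal(nrow(flt$kept), 4)  # rows 1, 4, 9, 10 pass every rule
  expect_equal(sum(flt$rejected) + nrow(flt$kept), nrow(rec))
  expect_equal(unname(flt$rejected["parent_genotype"]), 3L)  # 0/1, 0/0, ./.
  expect_equal(unname(flt$rejected["parent_depth"]), 1L)
  expect_equal(unname(flt$rejected["bulk_gq"]), 2L)
})

test_that("boundary thresholds behave as specified", {
  rec <- make_records(parent_dp = c(2, 3), gq1 = c(99, 99))
  flt <- filter_variants(rec)
  expect_equal(nrow(flt$kept), 1)          # DP=2 rejected, DP=3 kept
  rec2 <- make_records(parent_gt = "0/1", parent_dp = 30)
  expect_equal(nrow(filter_variants(rec2)$kept), 0)  # het parent rejected
})

test_that("filtering is idempotent and partitions the input", {
  set.seed(9)
  rec <- make_records(parent_gt = sample(c("1/1", "0/1"), 50, TRUE),
                      parent_dp = sample(0:10, 50, TRUE),
                      gq1 = sample(c(99, 80), 50, TRUE),
                      gq2 = sample(c(99, 80), 50, TRUE))
  f1 <- filter_variants(rec)
  f2 <- filter_variants(f1$kept)
  expect_equal(nrow(f2$kept), nrow(f1$kept))
  expect_equal(unname(sum(f2$rejected)), 0)
  expect_equal(nrow(f1$kept) + sum(f1$rejected), nrow(rec))
})

test_that("snp_index is AD/DP with guarded degenerate input", {
  expect_equal(snp_index(5, 10), 0.5)
  expect_equal(snp_index(37, 37), 1.0)
  expect_equal(snp_index(0, 12), 0.0)
  expect_error(snp_index(0, 0), "DP <= 0")
  expect_error(snp_index(5, 4), "AD <= DP")
})

test_that("delta is selected-minus-unselected with zero-depth records dropped", {
  rec <- make_records(ad1 = c(10, 5, 40, 3), dp1 = c(10, 10, 60, 10),
                      ad2 = c(0, 5, 3, 2), dp2 = c(10, 10, 30, 0))
  idx <- delta_snp_index(rec)
  expect_equal(nrow(idx), 3)
  expect_equal(attr(idx, "dropped_zero_depth"), 1L)
  expect_equal(idx$delta[1], 1.0)
  expect_equal(idx$delta[2], 0.0)
  expect_equal(idx$delta[3], 2 / 3 - 0.1, tolerance = 1e-12)
  expect_true(all(idx$index1 >= 0 & idx$index1 <= 1))
  expect_true(all(idx$delta >= -1 & idx$delta <= 1))
})

test_that("bin means are unweighted and use 1-based right-closed bins", {
  rec <- make_records(ad1 = c(4, 6), dp1 = 10, ad2 = 0, dp2 = 10,
                      pos = c(10, 20))
  bins <- bin_snp_index(delta_snp_index(rec))
  expect_equal(nrow(bins), 1)
  expect_equal(bins$index1, 0.5)
  expect_equal(bins$bin_start, 1)
  expect_equal(bins$bin_end, 1e6)

  rec2 <- make_records(ad1 = c(5, 5), dp1 = 10, ad2 = 0, dp2 = 10,
                       pos = c(1e6, 1e6 + 1))
  bins2 <- bin_snp_index(delta_snp_index(rec2))
  expect_equal(bins2$bin_start, c(1, 1e6 + 1))  # pos 1e6 in bin 1, 1e6+1 in bin 2

  # arithmetic series 0.01..1.00 in one bin
  rec3 <- make_records(ad1 = 1:100, dp1 = 100, ad2 = 0, dp2 = 100,
                       pos = 1000 + 1:100)
  bins3 <- bin_snp_index(delta_snp_index(rec3))
  expect_equal(bins3$index1, 0.505)
  expect_equal(bins3$n_snps, 100L)
  expect_error(bin_snp_index(delta_snp_index(rec3), bin_size = 0), "bin_size")
})

test_that("bin means lie within the range of their member SNPs", {
  set.seed(13)
  rec <- make_records(ad1 = sample(0:20, 200, TRUE), dp1 = 20,
                      ad2 = sample(0:20, 200, TRUE), dp2 = 20,
                      pos = sort(sample(1:5e6, 200)))
  idx <- delta_snp_index(rec)
  bins <- bin_snp_index(idx)
  for (k in seq_len(nrow(bins))) {
    members <- idx[idx$pos >= bins$bin_start[k] & idx$pos <= bins$bin_end[k], ]
    expect_gte(bins$delta[k], min(members$delta))
    expect_lte(bins$delta[k], max(members$delta))
  }
  expect_equal(sum(bins$n_snps), nrow(idx))
})
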