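# Meiosis, F2 genotype structure, phenotype model, bulk selection

test_that("a 0-cM chromosome transmits one parental haplotype intact", {
  lay <- one_chr_layout(cm = c(0, 0, 0), len_cm = 0)
  set.seed(1)
  picks <- replicate(400, {
    g <- simulate_gamete(lay)
    expect_true(all(g == g[1]))  # no recombination possible
    g[1]
  })
  # chosen with probability 1/2
  expect_gt(mean(picks), 0.5 - 3 * sqrt(0.25 / 400))
  expect_lt(mean(picks), 0.5 + 3 * sqrt(0.25 / 400))
})

test_that("recombinant fraction at 25 cM matches the no-interference map function", {
  lay <- one_chr_layout(cm = c(0, 25), len_cm = 25)
  set.seed(42)
  n <- 20000
  gam <- regqtl:::sim_f1_gametes(lay, n)
  rec <- mean(gam[, 1] != gam[, 2])
  expected <- (1 - exp(-0.5)) / 2  # Haldane at 25 cM = 0.19673
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rec - expected), 3 * se)
})

test_that("mean crossover count on a 100-cM chromosome is one Morgan", {
  lay <- one_chr_layout(cm = seq(0, 100, by = 1), len_cm = 100)
  # count chromatid switches along a dense locus grid as a crossover proxy
  set.seed(7)
  n <- 20000
  gam <- regqtl:::sim_f1_gametes(lay, n)
  switches <- rowSums(gam[, -1] != gam[, -ncol(gam)])
  expect_lt(abs(mean(switches) - 1), 3 * sqrt(1 / n))  # Poisson(1) se
})

test_that("simulate_gamete validates its inputs", {
  lay <- one_chr_layout(cm = c(0, 10))
  lay2 <- lay
  lay2$chromosomes <- rbind(lay2$chromosomes,
                            data.frame(chrom = "chr2", length_bp = 1e6, length_cm = 10))
  expect_error(simulate_gamete(lay2), "zero loci")
  expect_error(simulate_f2(lay, 0), "n must be")
})

test_that("F2 genotypes segregate 1:2:1 and assort independently when unlinked", {
  lay <- genome_layout(
    data.frame(chrom = c("chr1", "chr2"), length_bp = 1e6, length_cm = 50),
    markers = data.frame(name = c("m1", "m2"), chrom = c("chr1", "chr2"),
                         bp = c(5e5, 5e5)))
  sim <- simulate_f2(lay, 10000, seed = 11)
  counts <- table(factor(sim$geno[, 1], levels = 0:2))
  expect_gt(stats::chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 0.001)
  # two unlinked markers: independence
  tab <- table(sim$geno[, 1], sim$geno[, 2])
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
})

test_that("simulate_f2 is reproducible under a fixed seed", {
  lay <- default_layout(n_snps = 100)
  a <- simulate_f2(lay, 50, seed = 99)
  b <- simulate_f2(lay, 50, seed = 99)
  expect_identical(a$geno, b$geno)
})

test_that("full-penetrance dominance regrows 3/4 of the F2", {
  lay <- one_chr_layout(cm = c(0, 10), len_cm = 10,
                        qtl = data.frame(name = "q", chrom = "chr1",
                                         bp = 1.5e6, role = "early"))
  sim <- simulate_f2(lay, 10000, seed = 21)
  sim <- assign_phenotypes(sim, penetrance_full("early"), seed = 22)
  frac <- mean(sim$pheno$regrow_1)
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(frac - 0.75), 3 * se)
})

test_that("constant penetrance gives a genotype-independent binomial trait", {
  lay <- one_chr_layout(cm = c(0, 10), len_cm = 10,
                        qtl = data.frame(name = "q", chrom = "chr1",
                                         bp = 1.5e6, role = "early"))
  p <- 0.3
  pen <- penetrance_table(matrix(p, nrow = 4, ncol = 1,
                                 dimnames = list(c("00", "10", "01", "11"), NULL)))
  sim <- simulate_f2(lay, 10000, seed = 31)
  sim <- assign_phenotypes(sim, pen, seed = 32)
  y <- sim$pheno$regrow_1
  expect_lt(abs(mean(y) - p), 3 * sqrt(p * (1 - p) / 10000))
  qg <- sim$geno[, lay$loci$type == "qtl"]
  tab <- table(factor(qg, levels = 0:2), y)
  expect_gt(suppressWarnings(stats::chisq.test(tab)$p.value), 0.001)
})

test_that("two-QTL penetrance reproduces the enumerated regrown fraction", {
  # oracle: enumerate the (1:2:1) x (1:2:1) two-locus genotype classes
  pen_vals <- c("00" = 0.0, "10" = 0.6, "01" = 0.2, "11" = 0.9)
  probs <- c(0.25, 0.5, 0.25)
  expected <- 0
  for (i in 0:2) for (j in 0:2) {
    cls <- paste0(as.integer(i >= 1), as.integer(j >= 1))
    expected <- expected + probs[i + 1] * probs[j + 1] * pen_vals[cls]
  }
  expect_equal(unname(expected), 0.65625)  # frozen from the enumeration

  lay <- genome_layout(
    data.frame(chrom = c("chr1", "chr2"), length_bp = 2e6, length_cm = 10),
    markers = data.frame(name = c("m1", "m2"), chrom = c("chr1", "chr2"), bp = 5e5),
    qtl = data.frame(name = c("q1", "q2"), chrom = c("chr1", "chr2"),
                     bp = 1e6, role = c("early", "late")))
  pen <- penetrance_table(matrix(pen_vals, ncol = 1,
                                 dimnames = list(names(pen_vals), NULL)))
  sim <- simulate_f2(lay, 10000, seed = 41)
  sim <- assign_phenotypes(sim, pen, seed = 42)
  frac <- mean(sim$pheno$regrow_1)
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(frac - expected), 3 * se)
})

test_that("regrowth time series never resurrects", {
  lay <- default_layout(n_snps = 50)
  sim <- simulate_f2(lay, 500, seed = 51)
  sim <- assign_phenotypes(sim, penetrance_greenhouse(), seed = 52)
  regrow <- as.matrix(sim$pheno[, grep("^regrow_", names(sim$pheno))])
  diffs <- t(apply(regrow, 1, diff))
  expect_true(all(diffs <= 0))
})

test_that("penetrance tables are validated", {
  expect_error(penetrance_table(matrix(0.5, 4, 1,
    dimnames = list(c("00", "10", "01", "12"), NULL))), "00/10/01/11")
  expect_error(penetrance_table(matrix(c(0.5, 0.5, 0.5, 1.2), 4, 1,
    dimnames = list(c("00", "10", "01", "11"), NULL))), "\\[0, 1\\]")
})

test_that("bulk selection samples exactly the qualifying individuals", {
  lay <- default_layout(n_snps = 50)
  sim <- simulate_f2(lay, 496, seed = 61)
  sim <- assign_phenotypes(sim, penetrance_full("early"), seed = 62)
  ids <- form_bulks(sim, bulk_spec(90, "regrowth", regrown = 1), seed = 63)
  expect_length(ids, 90)
  expect_true(all(sim$pheno$regrow_1[ids] == 1))

  ht <- form_bulks(sim, bulk_spec(26, "tiller", tiller_range = c(9, 15)), seed = 64)
  expect_length(ht, 26)
  expect_true(all(sim$pheno$tillers[ht] >= 9 & sim$pheno$tillers[ht] <= 15))

  expect_error(bulk_spec(0), "size must be > 0")
  expect_error(form_bulks(sim, bulk_spec(1e6, "regrowth"), seed = 65), "short by")
})
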