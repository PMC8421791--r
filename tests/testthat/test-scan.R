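# Binary-trait LOD scan and permutation thresholds

test_that("the six-individual worked example gives LOD 1.659 in closed form", {
  cr <- make_cross(c("A", "A", "H", "H", "B", "B"),
                   pheno = data.frame(regrow_t1 = c(1, 1, 1, 1, 0, 0)))
  res <- scan_binary(cr, "regrow_t1")
  # independent direct-likelihood oracle: class MLEs are (1, 1, 0),
  # alternative log-lik 0; null penetrance 4/6
  l_null <- 4 * log(2 / 3) + 2 * log(1 / 3)
  expect_equal(res$lod, -l_null / log(10), tolerance = 1e-10)
  expect_equal(round(res$lod, 3), 1.659)
  expect_equal(c(res$pi_A, res$pi_H, res$pi_B), c(1, 1, 0))
})

test_that("a constant phenotype yields all-zero LOD with a warning", {
  cr <- make_cross(sample(c("A", "H", "B"), 30, TRUE),
                   pheno = data.frame(regrow_t1 = rep(1, 30)))
  expect_warning(res <- scan_binary(cr, "regrow_t1"), "constant")
  expect_true(all(res$lod == 0))
  expect_warning(thr <- permutation_threshold(cr, "regrow_t1", n_perm = 120, seed = 1),
                 "constant")
  expect_equal(thr$threshold, 0)
})

test_that("LOD is invariant to swapping the A/B allele labels and never negative", {
  set.seed(5)
  g <- sample(c("A", "H", "B"), 120, TRUE, prob = c(1, 2, 1) / 4)
  y <- rbinom(120, 1, ifelse(g == "A", 0.2, 0.6))
  cr <- make_cross(g, pheno = data.frame(regrow_t1 = y))
  swapped <- chartr("AB", "BA", g)
  cr2 <- make_cross(swapped, pheno = data.frame(regrow_t1 = y))
  r1 <- scan_binary(cr, "regrow_t1")
  r2 <- scan_binary(cr2, "regrow_t1")
  expect_equal(r1$lod, r2$lod, tolerance = 1e-10)
  expect_equal(r1$pi_A, r2$pi_B)
  expect_gte(min(r1$lod), 0)
})

test_that("EM equals the complete-data MLE when no genotypes are missing", {
  lay <- default_layout(n_snps = 20)
  sim <- simulate_f2(lay, 150, seed = 8)
  sim <- assign_phenotypes(sim, penetrance_greenhouse(), seed = 9)
  cr <- as_cross_data(sim)
  em <- scan_binary(cr, "regrow_january", missing_mode = "em")
  cc <- scan_binary(cr, "regrow_january", missing_mode = "complete-cases")
  expect_equal(em$lod, cc$lod, tolerance = 1e-8)
})

test_that("EM with missing genotypes uses flanking information sensibly", {
  set.seed(12)
  lay <- one_chr_layout(cm = c(0, 5, 10))
  sim <- simulate_f2(lay, 400, seed = 13)
  cr <- as_cross_data(sim)
  y <- as.integer(cr$geno[, 2] != "A")  # trait defined by the middle marker
  cr$pheno <- data.frame(regrow_t1 = y)
  full <- scan_binary(cr, "regrow_t1")$lod[2]
  # hide the middle marker for a third of individuals
  hide <- sample(400, 133)
  cr$geno[hide, 2] <- "-"
  em <- scan_binary(cr, "regrow_t1", missing_mode = "em")$lod[2]
  cc <- scan_binary(cr, "regrow_t1", missing_mode = "complete-cases")$lod[2]
  # flanking markers at 5 cM carry most of the hidden genotype information,
  # so the EM LOD should sit well above the complete-cases LOD
  expect_gt(em, cc)
  expect_gt(em, 0.85 * full)
  expect_lt(em, 1.05 * full)
})

test_that("permutation threshold is order-free and reproducible", {
  lay <- default_layout(n_snps = 20)
  sim <- simulate_f2(lay, 120, seed = 15)
  sim <- assign_phenotypes(sim, penetrance_greenhouse(), seed = 16)
  cr <- as_cross_data(sim)
  t1 <- permutation_threshold(cr, "regrow_january", n_perm = 200, seed = 7)
  # shuffle marker order: the genome-wide max is unchanged
  perm <- sample(ncol(cr$geno))
  cr_shuf <- cross_data(cr$geno[, perm][, order(perm)],
                        cr$markers, pheno = cr$pheno, id = cr$id)
  t2 <- permutation_threshold(cr_shuf, "regrow_january", n_perm = 200, seed = 7)
  expect_equal(t1$threshold, t2$threshold)
  expect_error(permutation_threshold(cr, "regrow_january", n_perm = 1),
               "at least 2")
  expect_warning(permutation_threshold(cr, "regrow_january", n_perm = 50, seed = 2),
                 "fewer than 100")
})

test_that("scans recover the early and late QTL at their nearest markers", {
  # recovery positive control: early trait peaks near the chr2 QTL,
  # late trait near the chr8 QTL, both above their permutation thresholds
  lay <- default_layout(n_snps = 20)
  hits_early <- 0; hits_late <- 0
  near_early <- 0; near_late <- 0
  n_rep <- 20
  for (b in seq_len(n_rep)) {
    sim <- simulate_f2(lay, 300, seed = 100 + b)
    sim <- assign_phenotypes(sim, penetrance_greenhouse(), seed = 200 + b)
    cr <- as_cross_data(sim)
    early <- scan_binary(cr, "regrow_january")
    late <- scan_binary(cr, "regrow_may")
    thr_e <- permutation_threshold(cr, "regrow_january", n_perm = 200,
                                   seed = 300 + b)$threshold
    thr_l <- permutation_threshold(cr, "regrow_may", n_perm = 200,
                                   seed = 400 + b)$threshold
    pk_e <- early[which.max(early$lod), ]
    pk_l <- late[which.max(late$lod), ]
    hits_early <- hits_early + (max(early$lod) > thr_e)
    hits_late <- hits_late + (max(late$lod) > thr_l)
    # "near" = the marker nearest the QTL or one of its immediate
    # neighbours (tightly linked markers share the peak expectation)
    near_early <- near_early + (pk_e$chrom == "chr2" && abs(pk_e$bp - 23.4e6) <= 8e6)
    near_late <- near_late + (pk_l$chrom == "chr8" && abs(pk_l$bp - 26.6e6) <= 8e6)
  }
  expect_gte(hits_early / n_rep, 0.9)
  expect_gte(hits_late / n_rep, 0.9)
  expect_gte(near_early / n_rep, 0.9)
  expect_gte(near_late / n_rep, 0.9)
})
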