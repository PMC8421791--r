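#' Minimum crossover count consistent with a genotype vector
#'
#' Genotype codes at ordered markers do not reveal phase, so the number of
#' recombination events is not directly observable. This computes the
#' minimum total number of chromatid switches consistent with the
#' observed codes, by dynamic programming over the four ordered chromatid
#' states (het markers admit two phases), skipping missing markers.
#' Used as a parsimony-based data-quality score: F2 individuals with
#' implausibly many apparent crossovers are typically mislabelled or
#' contaminated samples.
#'
#' @param geno character vector of codes `A`/`H`/`B`/`-` at markers
#'   ordered by map position within one chromosome.
#' @return Non-negative integer; 0 for vectors with < 2 informative
#'   markers.
#' @export
count_min_crossovers_chr <- function(geno) {
  g <- geno[geno != "-" & !is.na(geno)]
  if (length(g) < 2) return(0L)
  # ordered chromatid states: (A,A) (A,B) (B,A) (B,B) coded by alleles
  states <- rbind(c(0L, 0L), c(0L, 1L), c(1L, 0L), c(1L, 1L))
  allowed <- list(A = 1L, H = c(2L, 3L), B = 4L)
  cost <- rep(Inf, 4)
  cost[allowed[[g[1]]]] <- 0
  for (k in 2:length(g)) {
    new_cost <- rep(Inf, 4)
    for (s in allowed[[g[k]]]) {
      trans <- abs(states[, 1] - states[s, 1]) + abs(states[, 2] - states[s, 2])
      new_cost[s] <- min(cost + trans)
    }
    cost <- new_cost
  }
  as.integer(min(cost))
}

#' Minimum crossover counts for every individual in a cross
#'
#' Sums the per-chromosome minimum crossover counts
#' ([count_min_crossovers_chr()]) over all chromosomes.
#'
#' @param cross a `cross_data`.
#' @return Integer vector, one count per individual.
#' @export
count_min_crossovers <- function(cross) {
  stopifnot(inherits(cross, "cross_data"))
  chroms <- unique(cross$markers$chrom)
  total <- integer(nrow(cross$geno))
  for (cc in chroms) {
    idx <- which(cross$markers$chrom == cc)
    if (length(idx) < 2) next
    sub <- cross$geno[, idx, drop = FALSE]
    total <- total + apply(sub, 1L, count_min_crossovers_chr)
  }
  total
}

#' Remove poorly genotyped and implausibly recombinant individuals
#'
#' Standard F2 quality control: first drop individuals typed at fewer
#' than `min_markers` markers, then drop those whose minimum-crossover
#' parsimony count exceeds `max_crossovers`.
#'
#' @param cross a `cross_data`.
#' @param min_markers minimum number of non-missing marker genotypes.
#' @param max_crossovers maximum tolerated minimum-crossover count.
#' @return list with `cross` (the filtered data), `removed_few_markers`
#'   and `removed_many_crossovers` (ids removed by each rule).
#' @export
filter_individuals <- function(cross, min_markers = 11, max_crossovers = 7) {
  stopifnot(inherits(cross, "cross_data"), min_markers >= 0, max_crossovers >= 0)
  n_typed <- rowSums(cross$geno != "-")
  drop1 <- n_typed < min_markers
  keep1 <- subset_cross(cross, !drop1)
  if (nrow(keep1$geno) == 0) stop("all individuals removed by the filters")
  xo <- count_min_crossovers(keep1)
  drop2 <- xo > max_crossovers
  out <- subset_cross(keep1, !drop2)
  if (nrow(out$geno) == 0) stop("all individuals removed by the filters")
  list(cross = out,
       removed_few_markers = cross$id[drop1],
       removed_many_crossovers = keep1$id[drop2])
}

subset_cross <- function(cross, keep) {
  cross$geno <- cross$geno[keep, , drop = FALSE]
  cross$id <- cross$id[keep]
  if (!is.null(cross$pheno)) cross$pheno <- cross$pheno[keep, , drop = FALSE]
  cross
}
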