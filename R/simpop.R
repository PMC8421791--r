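#' Simulate one gamete from a parent by meiosis without interference
#'
#' Crossover counts per chromosome are Poisson with mean equal to the
#' genetic length in Morgans and crossover positions are uniform on the
#' genetic map (no interference; Haldane-consistent). The returned gamete
#' is a mosaic of the parent's two haplotypes.
#'
#' @param layout a [genome_layout()].
#' @param parent list with elements `h1`, `h2`: integer vectors of allele
#'   origin (0 = maize, 1 = Gigi) over `layout$loci` rows. Default is the
#'   fully heterozygous F1.
#' @return Integer vector of alleles (0/1) over `layout$loci` rows.
#' @export
simulate_gamete <- function(layout, parent = f1_parent(layout)) {
  loci <- layout$loci
  for (cc in layout$chromosomes$chrom)
    if (!any(loci$chrom == cc)) stop("chromosome with zero loci: ", cc)
  stopifnot(length(parent$h1) == nrow(loci), length(parent$h2) == nrow(loci))
  out <- integer(nrow(loci))
  for (k in seq_len(nrow(layout$chromosomes))) {
    cc <- layout$chromosomes$chrom[k]
    idx <- which(loci$chrom == cc)
    len_cm <- layout$chromosomes$length_cm[k]
    chromatid <- chromatid_path(loci$cm[idx], len_cm)
    out[idx] <- ifelse(chromatid == 0L, parent$h1[idx], parent$h2[idx])
  }
  out
}

#' @rdname simulate_gamete
#' @param layout a [genome_layout()].
#' @return `f1_parent()`: the heterozygous F1 of the maize x Gigi cross,
#'   as a two-haplotype list (`h1` all maize, `h2` all Gigi).
#' @export
f1_parent <- function(layout) {
  n <- nrow(layout$loci)
  list(h1 = integer(n), h2 = rep(1L, n))
}

# chromatid index (0/1) at each cM position after Poisson crossovers,
# starting from a random chromatid
chromatid_path <- function(cm, len_cm) {
  start <- sample.int(2L, 1L) - 1L
  n_xo <- stats::rpois(1L, len_cm / 100)
  if (n_xo == 0L) return(rep(start, length(cm)))
  xo <- sort(stats::runif(n_xo, 0, len_cm))
  (start + findInterval(cm, xo, left.open = TRUE)) %% 2L
}

# n F1 gametes as an n x L allele matrix (fast path used by simulate_f2)
sim_f1_gametes <- function(layout, n) {
  loci <- layout$loci
  out <- matrix(0L, nrow = n, ncol = nrow(loci))
  for (k in seq_len(nrow(layout$chromosomes))) {
    cc <- layout$chromosomes$chrom[k]
    idx <- which(loci$chrom == cc)
    if (length(idx) == 0) stop("chromosome with zero loci: ", cc)
    cm <- loci$cm[idx]
    len_cm <- layout$chromosomes$length_cm[k]
    starts <- sample.int(2L, n, replace = TRUE) - 1L
    n_xo <- stats::rpois(n, len_cm / 100)
    for (g in seq_len(n)) {
      if (n_xo[g] == 0L) {
        out[g, idx] <- starts[g]
      } else {
        xo <- sort(stats::runif(n_xo[g], 0, len_cm))
        out[g, idx] <- (starts[g] + findInterval(cm, xo, left.open = TRUE)) %% 2L
      }
    }
  }
  out
}

#' Simulate an F2 intercross population
#'
#' Each F2 individual is formed from two independent gametes of a single
#' fully heterozygous F1 (all F1s of an inbred x clonal-parent cross are
#' genetically equivalent at biallelic loci). Genotypes are recorded at
#' every locus in the layout.
#'
#' @param layout a [genome_layout()].
#' @param n number of individuals (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `f2_sim`: list with `layout`, haplotype
#'   matrices `h1`/`h2` (n x loci, 0 = maize / 1 = Gigi allele), `geno`
#'   (Gigi-allele dosage 0/1/2 per locus), `id`, and `pheno` (`NULL` until
#'   [assign_phenotypes()] is called).
#' @export
simulate_f2 <- function(layout, n, seed = NULL) {
  if (!inherits(layout, "genome_layout")) stop("layout must be a genome_layout")
  if (length(n) != 1 || is.na(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  h1 <- sim_f1_gametes(layout, n)
  h2 <- sim_f1_gametes(layout, n)
  structure(list(layout = layout, h1 = h1, h2 = h2, geno = h1 + h2,
                 id = paste0("F2_", seq_len(n)), pheno = NULL),
            class = "f2_sim")
}

#' @export
print.f2_sim <- function(x, ...) {
  cat("f2_sim:", nrow(x$geno), "individuals x", ncol(x$geno), "loci;",
      if (is.null(x$pheno)) "no phenotypes\n" else
        paste0(ncol(x$pheno) - 1, " regrowth time points + tillers\n"))
  invisible(x)
}

#' Assign regrowth and tiller phenotypes to a simulated F2 population
#'
#' Regrowth at each time point is Bernoulli with probability given by the
#' [penetrance_table()] entry for the individual's carrier status at the
#' early and late QTL (carrier = at least one Gigi allele; dominance).
#' Time points are coupled through a single latent uniform draw per
#' individual compared against the running minimum of its penetrance
#' profile, so a plant that has stopped regrowing never resurrects and the
#' regrowth series is non-increasing in time. Tiller counts are Poisson
#' with a rate depending on the genotype at the tiller QTL (if declared).
#'
#' @param sim an [simulate_f2()] result.
#' @param pen a [penetrance_table()].
#' @param tiller_rates Poisson mean tiller number per genotype at the
#'   tiller QTL, named `A` (maize hom), `H`, `B` (Gigi hom).
#' @param seed optional integer seed.
#' @return `sim` with `$pheno`: data.frame of `regrow_<timepoint>` columns
#'   (0/1) and `tillers` (integer, `NA` if no tiller QTL in the layout).
#' @export
assign_phenotypes <- function(sim, pen, tiller_rates = c(A = 1, H = 4, B = 10),
                              seed = NULL) {
  stopifnot(inherits(sim, "f2_sim"), inherits(pen, "penetrance_table"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sim$geno)
  loci <- sim$layout$loci

  carrier_at <- function(role) {
    i <- which(loci$type == "qtl" & loci$role == role)
    if (length(i) == 0) return(rep(0L, n))       # locus absent: nobody carries
    if (length(i) > 1) stop("multiple QTL with role ", role)
    as.integer(sim$geno[, i] >= 1L)
  }
  cls <- paste0(carrier_at("early"), carrier_at("late"))
  profile <- unclass(pen)[cls, , drop = FALSE]          # n x T
  # running minimum forbids resurrection whatever the table's shape
  if (ncol(profile) > 1L) profile <- t(apply(profile, 1L, cummin))
  u <- stats::runif(n)
  regrow <- matrix(as.integer(u < profile), nrow = n)
  colnames(regrow) <- paste0("regrow_", colnames(pen))

  it <- which(loci$type == "qtl" & loci$role == "tiller")
  tillers <- if (length(it) == 1) {
    rate <- unname(tiller_rates[c("A", "H", "B")][sim$geno[, it] + 1L])
    stats::rpois(n, rate)
  } else rep(NA_integer_, n)

  sim$pheno <- data.frame(regrow, tillers = tillers)
  sim
}

#' Specify a phenotype-selected sequencing bulk
#'
#' @param size number of individuals to pool (> 0).
#' @param phenotype `"regrowth"` (select on the binary regrowth call at
#'   one time point) or `"tiller"` (select on a tiller-count range).
#' @param time time point index for regrowth selection.
#' @param regrown required regrowth value (1 = regrown, 0 = non-regrown).
#' @param tiller_range length-2 inclusive range of tiller counts, e.g.
#'   `c(0, 2)` for a low-tiller bulk or `c(9, 15)` for a high-tiller bulk.
#' @return An object of class `bulk_spec`.
#' @export
bulk_spec <- function(size, phenotype = c("regrowth", "tiller"), time = 1,
                      regrown = 1, tiller_range = NULL) {
  phenotype <- match.arg(phenotype)
  if (length(size) != 1 || is.na(size) || size <= 0) stop("bulk size must be > 0")
  if (phenotype == "tiller" &&
      (length(tiller_range) != 2 || tiller_range[1] > tiller_range[2]))
    stop("tiller selection needs an increasing length-2 tiller_range")
  structure(list(size = as.integer(size), phenotype = phenotype,
                 time = as.integer(time), regrown = as.integer(regrown),
                 tiller_range = tiller_range),
            class = "bulk_spec")
}

#' Draw a phenotype-selected bulk from a simulated population
#'
#' Uniform random sample without replacement of exactly `spec$size`
#' individuals satisfying the selection predicate.
#'
#' @param sim an `f2_sim` with phenotypes assigned.
#' @param spec a [bulk_spec()].
#' @param seed optional integer seed.
#' @return Integer vector of selected individual indices.
#' @export
form_bulks <- function(sim, spec, seed = NULL) {
  stopifnot(inherits(sim, "f2_sim"), inherits(spec, "bulk_spec"))
  if (is.null(sim$pheno)) stop("phenotypes not assigned; call assign_phenotypes() first")
  if (!is.null(seed)) set.seed(seed)
  qualifying <- if (spec$phenotype == "regrowth") {
    col <- paste0("regrow_", colnames_or_index(sim$pheno, spec$time))
    which(sim$pheno[[col]] == spec$regrown)
  } else {
    which(sim$pheno$tillers >= spec$tiller_range[1] &
          sim$pheno$tillers <= spec$tiller_range[2])
  }
  if (length(qualifying) < spec$size)
    stop(sprintf("bulk of %d requested but only %d individuals qualify (short by %d)",
                 spec$size, length(qualifying), spec$size - length(qualifying)))
  sort(sample(qualifying, spec$size))
}

colnames_or_index <- function(pheno, time) {
  nm <- sub("^regrow_", "", grep("^regrow_", names(pheno), value = TRUE))
  if (time < 1 || time > length(nm)) stop("no such time point: ", time)
  nm[time]
}
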