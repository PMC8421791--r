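#' Single-marker binary-trait QTL scan by maximum likelihood
#'
#' At each marker the alternative model gives each genotype class its own
#' penetrance, P(y = 1 | class g) = pi_g for g in A/H/B, against a null
#' of a single shared penetrance; LOD is the base-10 log likelihood
#' ratio. With complete genotypes the MLEs are the class-wise and overall
#' phenotype means and the LOD is closed-form. Individuals missing the
#' marker genotype are handled by EM over genotype-class probabilities
#' conditioned on the nearest typed flanking markers of the same
#' chromosome (recombination fractions from Kosambi map distances, 1:2:1
#' prior when no flank is typed), or excluded entirely in
#' `"complete-cases"` mode.
#'
#' @param cross a `cross_data` with phenotypes.
#' @param phenotype name of a binary phenotype column (e.g.
#'   `"regrow_january"`) or its `regrow_*` time-point index.
#' @param missing_mode `"em"` (default) or `"complete-cases"`.
#' @param map optional [build_genetic_map()] result; computed on the fly
#'   when needed and omitted.
#' @param tol EM convergence tolerance on the log-likelihood.
#' @param max_iter EM iteration cap.
#' @return data.frame of class `scan_result` with one row per marker:
#'   `marker`, `chrom`, `bp`, `lod`, fitted penetrances `pi_A`, `pi_H`,
#'   `pi_B`, and `n` (phenotyped individuals used).
#' @export
scan_binary <- function(cross, phenotype, missing_mode = c("em", "complete-cases"),
                        map = NULL, tol = 1e-8, max_iter = 1000) {
  missing_mode <- match.arg(missing_mode)
  stopifnot(inherits(cross, "cross_data"))
  y_all <- get_phenotype(cross, phenotype)

  keep <- !is.na(y_all)
  y <- y_all[keep]
  geno <- cross$geno[keep, , drop = FALSE]
  if (length(y) == 0) stop("phenotype entirely missing")
  constant <- length(unique(y)) == 1
  if (constant)
    warning("phenotype is constant; all LOD scores are 0")
  if (!constant && (sum(y == 1) < 1 || sum(y == 0) < 1))
    stop("need at least one case and one control")

  mk <- cross$markers
  any_missing <- any(geno == "-")
  if (missing_mode == "em" && any_missing && is.null(map)) {
    sub <- cross; sub$geno <- geno; sub$id <- cross$id[keep]
    sub$pheno <- NULL
    map <- tryCatch(build_genetic_map(sub), error = function(e) NULL)
  }

  out <- mk[, c("name", "chrom", "bp")]
  names(out)[1] <- "marker"
  out$lod <- 0; out$pi_A <- NA_real_; out$pi_H <- NA_real_; out$pi_B <- NA_real_
  out$n <- NA_integer_

  for (j in seq_len(nrow(mk))) {
    g <- unname(c(A = 0L, H = 1L, B = 2L, `-` = NA_integer_)[geno[, j]])
    if (constant) {
      pis <- rep(unique(y), 3)
      out[j, c("lod", "pi_A", "pi_H", "pi_B", "n")] <-
        c(0, pis, sum(!is.na(g)))
      next
    }
    if (missing_mode == "complete-cases" || !anyNA(g)) {
      ok <- !is.na(g)
      fit <- binary_lod_complete(g[ok], y[ok])
    } else {
      prior <- genotype_prior(geno, j, mk, map)
      # typed individuals get an indicator prior
      typed <- !is.na(g)
      prior[typed, ] <- 0
      prior[cbind(which(typed), g[typed] + 1L)] <- 1
      fit <- binary_lod_em(prior, y, tol = tol, max_iter = max_iter)
    }
    out[j, c("lod", "pi_A", "pi_H", "pi_B", "n")] <-
      c(fit$lod, fit$pi, fit$n)
  }
  class(out) <- c("scan_result", "data.frame")
  out
}

get_phenotype <- function(cross, phenotype) {
  if (is.null(cross$pheno)) stop("cross has no phenotypes")
  if (is.numeric(phenotype)) {
    cols <- grep("^regrow_", names(cross$pheno), value = TRUE)
    if (phenotype < 1 || phenotype > length(cols))
      stop("no such regrowth time point: ", phenotype)
    phenotype <- cols[phenotype]
  }
  if (!phenotype %in% names(cross$pheno)) stop("no such phenotype: ", phenotype)
  y <- cross$pheno[[phenotype]]
  if (!all(y %in% c(0, 1, NA))) stop("phenotype is not binary")
  y
}

# closed-form complete-data LOD at one marker
binary_lod_complete <- function(g, y) {
  n <- length(y)
  pi_g <- vapply(0:2, function(k) {
    yk <- y[g == k]
    if (length(yk) == 0) NA_real_ else mean(yk)
  }, numeric(1))
  pi0 <- mean(y)
  ll <- function(p, yy) {
    p <- pmin(pmax(p, 0), 1)
    sum(log(ifelse(yy == 1, p, 1 - p)))
  }
  l_alt <- sum(vapply(0:2, function(k) {
    yk <- y[g == k]
    if (length(yk) == 0) 0 else ll(rep(pi_g[k + 1], length(yk)), yk)
  }, numeric(1)))
  l_null <- ll(rep(pi0, n), y)
  list(lod = max(0, (l_alt - l_null) / log(10)), pi = pi_g, n = n)
}

# EM fit of class penetrances with per-individual genotype priors
binary_lod_em <- function(prior, y, tol = 1e-8, max_iter = 1000) {
  n <- length(y)
  pi_g <- rep(mean(y), 3) + c(-0.05, 0, 0.05)
  pi_g <- pmin(pmax(pi_g, 1e-6), 1 - 1e-6)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- outer(y, pi_g, function(yy, p) ifelse(yy == 1, p, 1 - p))
    joint <- prior * dens
    lik <- rowSums(joint)
    ll <- sum(log(lik))
    w <- joint / lik
    pi_g <- colSums(w * y) / colSums(w)
    pi_g[is.nan(pi_g)] <- mean(y)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  pi0 <- mean(y)
  l_null <- sum(log(ifelse(y == 1, pi0, 1 - pi0)))
  list(lod = max(0, (ll - l_null) / log(10)), pi = pi_g, n = n)
}

# genotype transition matrix between two F2 loci at recombination
# fraction r (per-gamete switch probability r, gametes independent)
f2_geno_transition <- function(r) {
  rbind(c((1 - r)^2, 2 * r * (1 - r), r^2),
        c(r * (1 - r), (1 - r)^2 + r^2, r * (1 - r)),
        c(r^2, 2 * r * (1 - r), (1 - r)^2))
}

# class-probability prior at marker j for every individual, conditioning
# on the nearest typed flanking markers (map gives cM; NULL map falls
# back to the 1:2:1 prior for untyped individuals)
genotype_prior <- function(geno, j, mk, map) {
  n <- nrow(geno)
  prior <- matrix(rep(c(0.25, 0.5, 0.25), each = n), nrow = n)
  cm <- if (!is.null(map)) map$cm[match(mk$name, map$name)] else NULL
  if (is.null(cm) || anyNA(cm)) return(prior)
  chrom_j <- mk$chrom[j]
  same <- which(mk$chrom == chrom_j)
  for (i in seq_len(n)) {
    if (geno[i, j] != "-") next
    typed <- same[geno[i, same] != "-"]
    left <- typed[typed < j]
    right <- typed[typed > j]
    left <- if (length(left)) max(left) else NA
    right <- if (length(right)) min(right) else NA
    p <- c(0.25, 0.5, 0.25)
    if (!is.na(left)) {
      r1 <- kosambi_r(abs(cm[j] - cm[left]))
      gl <- c(A = 1L, H = 2L, B = 3L)[geno[i, left]]
      p <- f2_geno_transition(r1)[gl, ]
    }
    if (!is.na(right)) {
      r2 <- kosambi_r(abs(cm[right] - cm[j]))
      gr <- c(A = 1L, H = 2L, B = 3L)[geno[i, right]]
      p <- p * f2_geno_transition(r2)[, gr]
    }
    prior[i, ] <- p / sum(p)
  }
  prior
}

#' Genome-wide permutation threshold for a binary scan
#'
#' Permutes the phenotype vector across individuals (genotypes fixed,
#' preserving the marker correlation structure) and records the
#' genome-wide maximum LOD of each permuted scan; the threshold is the
#' empirical `1 - alpha` quantile (linear interpolation between order
#' statistics) of those maxima.
#'
#' @inheritParams scan_binary
#' @param n_perm number of permutations (>= 2; < 100 draws a warning).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed integer seed for the permutation stream (recorded).
#' @return list of class `perm_threshold`: `threshold`, `alpha`,
#'   `n_perm`, `seed`, and `max_lods` (the permutation maxima).
#' @export
permutation_threshold <- function(cross, phenotype, n_perm = 1000,
                                  alpha = 0.05, seed = 1,
                                  missing_mode = c("em", "complete-cases"),
                                  map = NULL) {
  missing_mode <- match.arg(missing_mode)
  if (n_perm < 2) stop("need at least 2 permutations")
  if (n_perm < 100) warning("fewer than 100 permutations; threshold is unstable")
  y_all <- get_phenotype(cross, phenotype)
  keep <- !is.na(y_all)
  y <- y_all[keep]
  geno <- cross$geno[keep, , drop = FALSE]
  set.seed(seed)

  if (length(unique(y)) == 1) {
    warning("phenotype is constant; threshold is 0")
    return(structure(list(threshold = 0, alpha = alpha, n_perm = n_perm,
                          seed = seed, max_lods = rep(0, n_perm)),
                     class = "perm_threshold"))
  }

  if (!any(geno == "-")) {
    # complete data: closed-form class-mean LOD, vectorised across
    # markers and permutations through class indicator cross-products
    max_lods <- perm_max_lods_complete(geno, y, n_perm)
  } else {
    sub <- cross
    sub$geno <- geno
    sub$id <- cross$id[keep]
    max_lods <- vapply(seq_len(n_perm), function(b) {
      sub$pheno <- stats::setNames(data.frame(sample(y)), "perm")
      max(scan_binary(sub, "perm", missing_mode = missing_mode, map = map)$lod)
    }, numeric(1))
  }
  structure(list(threshold = unname(stats::quantile(max_lods, 1 - alpha, type = 7)),
                 alpha = alpha, n_perm = n_perm, seed = seed,
                 max_lods = max_lods),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("genome-wide LOD threshold %.3f (alpha %.3g, %d permutations, seed %d)\n",
              x$threshold, x$alpha, x$n_perm, x$seed))
  invisible(x)
}

# permutation maxima with complete genotypes: for each marker the class
# totals of a permuted 0/1 phenotype determine the LOD in closed form
perm_max_lods_complete <- function(geno, y, n_perm) {
  n <- length(y)
  n1 <- sum(y)
  perm <- matrix(0, nrow = n, ncol = n_perm)
  for (b in seq_len(n_perm)) perm[, b] <- sample(y)
  xlogx <- function(x) ifelse(x > 0, x * log(x), 0)
  l_null <- xlogx(n1) + xlogx(n - n1) - xlogx(n)  # n1*log(p)+... collapsed
  max_lods <- rep(0, n_perm)
  for (j in seq_len(ncol(geno))) {
    ind <- outer(geno[, j], c("A", "H", "B"), "==") * 1  # n x 3
    n_g <- colSums(ind)
    k_g <- t(ind) %*% perm                                # 3 x n_perm cases per class
    l_alt <- xlogx(k_g) + xlogx(n_g - k_g) - xlogx(n_g)   # recycled n_g per column
    lod <- (colSums(l_alt) - l_null) / log(10)
    max_lods <- pmax(max_lods, lod)
  }
  pmax(max_lods, 0)
}
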