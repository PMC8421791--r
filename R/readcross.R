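#' Construct an F2 cross-data object
#'
#' @param geno character matrix (individuals x markers) of genotype codes
#'   `A` (maize hom), `H` (het), `B` (Gigi hom), `-` (missing).
#' @param markers data.frame with `name`, `chrom`, `bp` (ordered by bp
#'   within chromosome).
#' @param pheno data.frame of phenotypes: `regrow_*` columns with values
#'   0/1/`NA`, optional `tillers`.
#' @param id individual identifiers.
#' @return An object of class `cross_data`.
#' @export
cross_data <- function(geno, markers, pheno = NULL, id = NULL) {
  geno <- as.matrix(geno)
  markers <- as.data.frame(markers)
  stopifnot(all(c("name", "chrom", "bp") %in% names(markers)),
            ncol(geno) == nrow(markers))
  if (!all(geno %in% c("A", "H", "B", "-")))
    stop("genotype codes restricted to A/H/B/-")
  if (anyDuplicated(markers$name)) stop("duplicated marker names")
  for (cc in unique(markers$chrom)) {
    bp <- markers$bp[markers$chrom == cc]
    if (is.unsorted(bp, strictly = TRUE))
      stop("marker bp positions not strictly increasing on ", cc)
  }
  if (is.null(id)) id <- paste0("F2_", seq_len(nrow(geno)))
  colnames(geno) <- markers$name
  if (!is.null(pheno)) {
    pheno <- as.data.frame(pheno)
    stopifnot(nrow(pheno) == nrow(geno))
    for (col in grep("^regrow_", names(pheno), value = TRUE))
      if (!all(pheno[[col]] %in% c(0, 1, NA)))
        stop("regrowth phenotypes must be 0/1/missing")
  }
  structure(list(geno = geno, markers = markers, pheno = pheno, id = id),
            class = "cross_data")
}

#' @export
print.cross_data <- function(x, ...) {
  cat("cross_data:", nrow(x$geno), "individuals x", ncol(x$geno), "markers on",
      length(unique(x$markers$chrom)), "chromosome(s);",
      if (is.null(x$pheno)) "no phenotypes\n" else
        paste(length(grep("^regrow_", names(x$pheno))), "regrowth time point(s)\n"))
  invisible(x)
}

# Gigi-allele dosage (0/1/2, NA for missing) at one marker
genotype_dosage <- function(cross, marker) {
  if (!marker %in% colnames(cross$geno)) stop("no such marker: ", marker)
  g <- cross$geno[, marker]
  unname(c(A = 0L, H = 1L, B = 2L, `-` = NA_integer_)[g])
}

#' Read a cross table written by [write_cross_tsv()]
#'
#' Parses the tab-separated cross-table dialect: a name header, a
#' chromosome row, a position row, then one row per individual with
#' genotype codes and phenotype columns. Unknown genotype symbols are an
#' error naming the offending row and column; `-` codes missing.
#'
#' @param path file path.
#' @return A [cross_data()].
#' @export
read_cross <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) stop("cross table needs header, chrom and pos rows")
  split_row <- function(x) strsplit(x, "\t", fixed = TRUE)[[1]]
  header <- split_row(lines[1])
  chrom_row <- split_row(lines[2])
  pos_row <- split_row(lines[3])
  stopifnot(header[1] == "id", chrom_row[1] == "chrom", pos_row[1] == "pos")

  is_marker <- chrom_row != "-" & seq_along(header) > 1
  mk_idx <- which(is_marker)
  ph_idx <- setdiff(seq_along(header)[-1], mk_idx)
  markers <- data.frame(name = header[mk_idx], chrom = chrom_row[mk_idx],
                        bp = as.numeric(pos_row[mk_idx]),
                        stringsAsFactors = FALSE)

  body <- lines[-(1:3)]
  cells <- t(vapply(body, split_row, character(length(header)), USE.NAMES = FALSE))
  id <- cells[, 1]
  geno <- cells[, mk_idx, drop = FALSE]
  bad <- which(matrix(!(geno %in% c("A", "H", "B", "-")), nrow(geno)),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("unknown genotype symbol %s for individual %s at marker %s",
                 geno[bad[1, 1], bad[1, 2]], id[bad[1, 1]],
                 markers$name[bad[1, 2]]))

  pheno <- NULL
  if (length(ph_idx) > 0) {
    pheno <- as.data.frame(cells[, ph_idx, drop = FALSE],
                           stringsAsFactors = FALSE)
    names(pheno) <- header[ph_idx]
    pheno[] <- lapply(pheno, function(x) suppressWarnings(as.numeric(ifelse(x == "-", NA, x))))
  }
  cross_data(geno, markers, pheno = pheno, id = id)
}

#' Extract a marker cross from a simulated population
#'
#' @param sim an `f2_sim`.
#' @return A [cross_data()] with the simulated marker genotypes and any
#'   assigned phenotypes.
#' @export
as_cross_data <- function(sim) {
  stopifnot(inherits(sim, "f2_sim"))
  loci <- sim$layout$loci
  mk <- which(loci$type == "marker")
  if (length(mk) == 0) stop("layout declares no marker loci")
  geno <- matrix(c("A", "H", "B")[sim$geno[, mk, drop = FALSE] + 1L],
                 nrow = nrow(sim$geno))
  cross_data(geno, loci[mk, c("name", "chrom", "bp")],
             pheno = sim$pheno, id = sim$id)
}
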