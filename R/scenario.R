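#' Simulate a complete QTL-seq + marker-scan scenario to disk
#'
#' End-to-end study emulation: simulate an F2 population on a genome
#' layout, assign phenotypes, draw the phenotype-selected bulks, simulate
#' pooled sequencing, and write a VCF, a cross table and a plain-text
#' truth file (QTL positions, penetrances, bulk membership) for recovery
#' tests. The default mirrors the motivating study's design: 496
#' individuals, a 90-plant selected and 30-plant unselected bulk, ~2,000
#' SNPs on 10 chromosomes at 50x pooled depth.
#'
#' @param dir output directory (created if absent).
#' @param layout a [genome_layout()].
#' @param n population size.
#' @param pen a [penetrance_table()].
#' @param bulk1,bulk2 [bulk_spec()]s for the selected and unselected bulk.
#' @param depth a [depth_model()].
#' @param seed integer seed; all downstream draws derive from it.
#' @return list with `sim`, `bulk1`, `bulk2`, `pileup` and the written
#'   `paths` (vcf, cross, truth).
#' @export
sim_scenario <- function(dir, layout = default_layout(), n = 496,
                         pen = penetrance_full("early"),
                         bulk1 = bulk_spec(90, "regrowth", time = 1, regrown = 1),
                         bulk2 = bulk_spec(30, "regrowth", time = 1, regrown = 0),
                         depth = depth_model(lambda = 50, epsilon = 0),
                         seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_f2(layout, n, seed = seed)
  sim <- assign_phenotypes(sim, pen, seed = seed + 1L)
  ids1 <- form_bulks(sim, bulk1, seed = seed + 2L)
  ids2 <- form_bulks(sim, bulk2, seed = seed + 3L)
  pileup <- simulate_bulk_pileup(sim, ids1, ids2, depth = depth, seed = seed + 4L)

  paths <- list(vcf = file.path(dir, "bulks.vcf"),
                cross = file.path(dir, "cross.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_bulk_vcf(pileup, paths$vcf,
                 contigs = data.frame(chrom = layout$chromosomes$chrom,
                                      length_bp = layout$chromosomes$length_bp))
  write_cross_tsv(sim, paths$cross)

  qtl <- layout$loci[layout$loci$type == "qtl", , drop = FALSE]
  truth <- c(
    sprintf("n_individuals\t%d", n),
    sprintf("seed\t%d", seed),
    sprintf("bulk1_size\t%d", bulk1$size),
    sprintf("bulk2_size\t%d", bulk2$size),
    sprintf("bulk1_ids\t%s", paste(ids1, collapse = ",")),
    sprintf("bulk2_ids\t%s", paste(ids2, collapse = ",")),
    sprintf("qtl\t%s:%s:%s:%s", qtl$name, qtl$chrom,
            format(qtl$bp, scientific = FALSE, trim = TRUE), qtl$role),
    sprintf("penetrance_%s\t%s", rownames(unclass(pen)),
            apply(unclass(pen), 1L, paste, collapse = ",")))
  writeLines(truth, paths$truth)
  list(sim = sim, bulk1 = ids1, bulk2 = ids2, pileup = pileup, paths = paths)
}

#' Run the QTL-seq stage on a parent + two-bulk VCF
#'
#' Chains [read_bulk_vcf()], [filter_variants()], [delta_snp_index()] and
#' [bin_snp_index()], optionally writing the per-SNP and per-bin tables
#' as TSV.
#'
#' @param vcf path to the VCF.
#' @param parent,bulk1,bulk2 sample names (bulk1 = selected bulk; the
#'   delta is bulk1 - bulk2).
#' @param criteria a [filter_criteria()].
#' @param bin_size bin width in bp.
#' @param out_dir optional directory for `snp_index.tsv` and
#'   `bin_index.tsv`.
#' @return list with `snps` (per-SNP index table), `bins` (per-bin
#'   summary), `rejected` (filter rejection counts), `skipped` (reader
#'   skip counts), `dropped_zero_depth`.
#' @export
run_snpindex <- function(vcf, parent = "Gigi", bulk1 = "RG", bulk2 = "NRG",
                         criteria = filter_criteria(), bin_size = 1e6,
                         out_dir = NULL) {
  records <- read_bulk_vcf(vcf, parent = parent, bulk1 = bulk1, bulk2 = bulk2)
  flt <- filter_variants(records, criteria)
  idx <- delta_snp_index(flt$kept)
  bins <- bin_snp_index(idx, bin_size = bin_size)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(idx, file.path(out_dir, "snp_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bins, file.path(out_dir, "bin_index.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(snps = idx, bins = bins, rejected = flt$rejected,
       skipped = attr(records, "skipped"),
       dropped_zero_depth = attr(idx, "dropped_zero_depth"))
}

#' Run the marker-based QTL scan stage on a cross table
#'
#' Chains [read_cross()], [filter_individuals()], [geno_table()],
#' [build_genetic_map()], and per-time-point [scan_binary()] +
#' [permutation_threshold()] (each time point gets its own threshold).
#'
#' @param cross a `cross_data` or path to a cross-table TSV.
#' @param min_markers,max_crossovers individual filters
#'   ([filter_individuals()]).
#' @param n_perm,alpha,seed permutation-threshold settings.
#' @param missing_mode `"em"` or `"complete-cases"`.
#' @param out_dir optional directory for `scan.tsv`, `segregation.tsv`
#'   and `map.tsv`.
#' @return list with `scan` (marker x time-point LOD table with
#'   thresholds), `thresholds`, `segregation` ([geno_table()] result),
#'   `map`, `filtered` (removed ids) and the filtered `cross`.
#' @export
run_scan <- function(cross, min_markers = 11, max_crossovers = 7,
                     n_perm = 1000, alpha = 0.05, seed = 1,
                     missing_mode = c("em", "complete-cases"),
                     out_dir = NULL) {
  missing_mode <- match.arg(missing_mode)
  if (is.character(cross)) cross <- read_cross(cross)
  flt <- filter_individuals(cross, min_markers = min_markers,
                            max_crossovers = max_crossovers)
  cr <- flt$cross
  seg <- geno_table(cr)
  map <- build_genetic_map(cr)

  time_cols <- grep("^regrow_", names(cr$pheno), value = TRUE)
  if (length(time_cols) == 0) stop("cross has no regrowth phenotypes")
  scan <- map[, c("name", "chrom", "bp", "cm")]
  names(scan)[1] <- "marker"
  thresholds <- numeric(0)
  for (k in seq_along(time_cols)) {
    col <- time_cols[k]
    y <- cr$pheno[[col]]
    if (all(is.na(y)) ) stop("phenotype entirely missing: ", col)
    res <- scan_binary(cr, col, missing_mode = missing_mode)
    thr <- permutation_threshold(cr, col, n_perm = n_perm, alpha = alpha,
                                 seed = seed + k, missing_mode = missing_mode)
    scan[[paste0("lod_", sub("^regrow_", "", col))]] <- res$lod
    thresholds[sub("^regrow_", "", col)] <- thr$threshold
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    scan_out <- scan
    for (nm in names(thresholds))
      scan_out[[paste0("threshold_", nm)]] <- thresholds[[nm]]
    utils::write.table(scan_out, file.path(out_dir, "scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(seg, file.path(out_dir, "segregation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(map, file.path(out_dir, "map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(scan = scan, thresholds = thresholds, segregation = seg, map = map,
       filtered = flt[c("removed_few_markers", "removed_many_crossovers")],
       cross = cr)
}
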