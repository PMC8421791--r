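#' Regrowth rate from regrown / non-regrown counts
#'
#' `100 * RG / (RG + NRG)`, rounded half-up to one decimal place to match
#' the convention of published regrowth tables.
#'
#' @param rg,nrg non-negative counts of regrown and non-regrown plants.
#' @return Percentage to one decimal place.
#' @export
regrowth_rate <- function(rg, nrg) {
  if (any(is.na(c(rg, nrg))) || any(c(rg, nrg) < 0)) stop("counts must be non-negative")
  if (any(rg + nrg <= 0)) stop("total count must be > 0")
  floor(100 * rg / (rg + nrg) * 10 + 0.5) / 10
}

#' Packaged observation tables from the motivating regrowth study
#'
#' Transcriptions of the observed count tables from the Z. diploperennis
#' x maize F2 regrowth study that motivates this package: greenhouse
#' regrowth counts for the 2018 QTL-seq population, marker genotype
#' counts among its regrown plants, the four-date 2019 greenhouse
#' regrowth counts for both mapping populations, and marker genotype
#' counts from the 2019 field planting. The `*_printed` columns carry the
#' statistics as originally printed, for cross-checking recomputation.
#'
#' @param name one of `"greenhouse2018_regrowth"`,
#'   `"greenhouse2018_markers"`, `"greenhouse2019_regrowth"`,
#'   `"field2019_markers"`.
#' @return data.frame.
#' @export
study_table <- function(name = c("greenhouse2018_regrowth",
                                 "greenhouse2018_markers",
                                 "greenhouse2019_regrowth",
                                 "field2019_markers")) {
  name <- match.arg(name)
  file <- c(greenhouse2018_regrowth = "greenhouse2018_regrowth_counts.tsv",
            greenhouse2018_markers = "greenhouse2018_marker_counts.tsv",
            greenhouse2019_regrowth = "greenhouse2019_regrowth_counts.tsv",
            field2019_markers = "field2019_marker_counts.tsv")[[name]]
  path <- system.file("extdata", file, package = "regqtl", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
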