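#' Penetrance table for the two-locus regrowth model
#'
#' Perennial regrowth is modelled as a binary trait controlled by up to two
#' dominant QTL with incomplete penetrance: an early-acting locus and a
#' late-acting locus. An individual is a *carrier* at a locus if it has at
#' least one allele from the perennial (Z. diploperennis) parent. The table
#' gives P(regrown at time point t) for each of the four carrier-status
#' combinations.
#'
#' @param probs numeric matrix with 4 rows named `"00"`, `"10"`, `"01"`,
#'   `"11"` (carrier status at the early locus, then the late locus) and one
#'   column per time point; all entries in \[0, 1\].
#' @return An object of class `penetrance_table`.
#' @export
penetrance_table <- function(probs) {
  probs <- as.matrix(probs)
  if (is.null(rownames(probs))) stop("rows must be named 00/10/01/11")
  need <- c("00", "10", "01", "11")
  if (!setequal(rownames(probs), need)) stop("rows must be exactly 00/10/01/11")
  probs <- probs[need, , drop = FALSE]
  if (ncol(probs) < 1) stop("at least one time point required")
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("penetrance entries must lie in [0, 1] and be complete")
  if (is.null(colnames(probs))) colnames(probs) <- as.character(seq_len(ncol(probs)))
  structure(probs, class = c("penetrance_table", "matrix"))
}

#' Fully penetrant single-locus dominance
#'
#' Carriers at the chosen locus always regrow, non-carriers never do —
#' the idealised selection regime under which the bulk-segregant signal at
#' the QTL is exactly 2/3 vs 0 Gigi-allele frequency.
#'
#' @param locus `"early"` or `"late"`: which QTL drives the trait.
#' @param n_time number of (identical) time points.
#' @return A [penetrance_table()].
#' @export
penetrance_full <- function(locus = c("early", "late"), n_time = 1) {
  locus <- match.arg(locus)
  carrier <- if (locus == "early") c("10", "11") else c("01", "11")
  probs <- matrix(0, nrow = 4, ncol = n_time,
                  dimnames = list(c("00", "10", "01", "11"), NULL))
  probs[carrier, ] <- 1
  penetrance_table(probs)
}

#' Greenhouse-like incomplete penetrance over four scoring dates
#'
#' A two-locus table emulating the pattern seen in greenhouse F2 trials:
#' regrowth is common early in the season and declines as plants senesce;
#' the early locus drives the initiation of regrowth (strong effect at the
#' first scorings, negligible by the last), while the late locus sustains
#' regrowth through the season. Population-level regrowth under Mendelian
#' (3/4 carrier) frequencies is ~46% at the first time point falling to
#' ~23% at the last.
#'
#' @return A [penetrance_table()] with four time points.
#' @export
penetrance_greenhouse <- function() {
  penetrance_table(matrix(
    c(0.05, 0.04, 0.03, 0.02,   # 00: background regrowth, fading
      0.50, 0.35, 0.15, 0.05,   # 10: early carrier only: initiates, not sustained
      0.30, 0.30, 0.29, 0.28,   # 01: late carrier only: sustained
      0.55, 0.45, 0.37, 0.30),  # 11: both
    nrow = 4, byrow = TRUE,
    dimnames = list(c("00", "10", "01", "11"),
                    c("january", "february", "march", "may"))))
}
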