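---
title: "Methods: mapping perennial-regrowth QTL in F2 intercrosses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping perennial-regrowth QTL in F2 intercrosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regqtl)
```

## The biological setting and the statistical model

*Zea diploperennis* is a perennial wild relative of maize: after flowering
and senescence it regrows from dormant basal tiller buds. In F2 populations
from a maize inbred × *Z. diploperennis* cross, regrowth segregates as a
binary trait — scored as presence of green leaves on young tillers at one
or more dates — under the control of a small number of dominant QTL with
incomplete penetrance. Two features of the trait shape everything in this
package:

* **Dominance with incomplete penetrance.** A carrier (one or two donor
  alleles) regrows with some probability below 1; a non-carrier regrows
  rarely if at all. Observable consequences: an excess of heterozygotes
  among regrown plants relative to 1:2:1, and an expected donor-allele
  frequency of 2/3 among regrown carriers (1 hom : 2 het) versus 0 among
  non-regrown plants when penetrance is complete.
* **Temporal structure.** One locus acts early (initiation of regrowth)
  and one late (continuation): scans of regrowth scored at successive
  dates move their peak from the early to the late locus.

`regqtl` implements the two standard mapping routes for such populations —
QTL-seq on pooled bulks, and single-marker binary-trait scans on
individually genotyped plants — and a forward simulator that produces data
with precisely the generative structure the analyses assume.

## The simulator (what it emulates, and what it does not)

**Meiosis.** Gametes are produced with *no crossover interference*: per
chromosome the crossover count is Poisson with mean equal to the genetic
length in Morgans and positions are uniform on the cM scale
(Haldane-consistent). The mapping stage nevertheless reports Kosambi
distances, as mapping studies in maize conventionally do; the slight
mismatch between the interference-free generative model and the
interference-allowing map function is standard practice and immaterial at
the marker densities used here. All F1s of an inbred × clonal-parent cross
are genetically identical at biallelic loci, so the population is simulated
as a single fully heterozygous F1 selfed, even though real populations
intermate several sibling F1s.

**Phenotypes.** A `penetrance_table()` gives P(regrown at date *t*) for
each of the four carrier-status combinations at the early and late QTL.
Dates are coupled through a *single latent uniform draw* per individual
compared against the running minimum of its penetrance profile: a plant
whose regrowth has ended never resurrects, matching the field observation
that early regrowth does not guarantee continued regrowth while forbidding
0→1 transitions in time. Tiller counts are Poisson with a genotype-
dependent rate at a tiller-number QTL (defaults 1 / 4 / 10 for maize-hom /
het / donor-hom; chosen so that the 0–2 and 9–15 tiller selection windows
used for low/high-tiller bulks are both well populated in a ~500-plant
population).

**Pooled sequencing.** At each SNP the true donor-allele frequency *f* in a
bulk is the realised fraction among the pooled individuals' chromosomes;
depth is Poisson(λ, default 50) and the donor-supporting read count is
Binomial(DP, f(1−ε) + (1−f)ε) with sequencing error ε (default 0, capped at
0.05). The donor parent is written as a homozygous-ALT call with DP ≥ 3 and
GQ 99 so the parent-side filters pass by construction — the simulator's job
is to exercise the index arithmetic, not to model GATK's caller. Bulk GQ is
an idealised phred-scaled likelihood ratio, min(99, round(10·DP·log10 2)),
which reaches the 99 cap from 33 reads; at the default depth ≥ 95% of
records pass the GQ ≥ 99 filter, so filter attrition is realistic but not
rate-limiting.

**The default genome** (`default_layout()`) is a deliberately scaled-down
stand-in for the maize physical map: 10 chromosomes × 50 Mb / 75 cM, 2,000
SNPs evenly spaced (four per 1-Mb bin), 22 codominant markers on the three
chromosomes carrying trait loci, QTL mid-chromosome on the chromosome-2 and
chromosome-8 analogues. Bin occupancy, marker spacing (6–7 Mb ≈ 9–10 cM)
and total map length are chosen so that every analysis behaves as it would
on the real map while simulations complete in seconds. The default
*scenario* (`sim_scenario()`) mirrors the motivating study design: 496 F2
plants, a 90-plant selected and 30-plant unselected bulk, 50× pooled depth.

**What passing tests do not show.** The simulator draws biallelic SNPs with
clean AD/DP counts; it does not model mapping bias, indels, multiallelic
sites, duplicated regions, family structure among intermated F1s, or G×E
variation in penetrance. Recovery of simulated QTL therefore validates the
statistics, not robustness to artefacts of real short-read data.

## QTL-seq stage: filters, index, binning

Records are kept iff the parent call is homozygous-ALT **and** parent
DP ≥ 3 **and** GQ ≥ 99 in both bulks; rejected records are partitioned by
the first failed rule so the attrition is auditable. SNP-index is AD/DP per
bulk; Δ is selected-minus-unselected. Numerical choices worth stating:

* **Zero depth.** A record with DP = 0 in either bulk has an undefined
  index and is dropped (with a count), never coded 0 — silently coding 0/0
  as 0 would bias Δ toward ±1 near coverage gaps.
* **Bins** are disjoint 1-Mb windows on 1-based coordinates: bin *k*
  covers [k·10⁶ + 1, (k+1)·10⁶], so position 10⁶ belongs to the first bin.
  Bin means are unweighted across SNPs (not depth-weighted) and empty bins
  are omitted.
* **Sampling noise floor.** The bulk's allelic composition is shared by
  every SNP in a bin, so binning averages away read noise but *not*
  bulk-composition noise: with 90/30 bulks a distal bin's Δ has standard
  deviation ≈ √(1/(8·90) + 1/(8·30)) ≈ 0.075. Distal bins should therefore
  be judged by their mean (≈ 0), not by a per-bin bound.
* The high/low-tiller analysis reuses the stage unchanged with
  bulk1 = HT, bulk2 = LT.

## Marker stage: map, filters, scan, thresholds

**Map.** Recombination fractions between adjacent markers (physical order;
no de novo ordering, since genetic and physical order agree in these
populations) are estimated by EM on the 3×3 two-locus genotype table. All
classes except the double heterozygote determine their recombinant-gamete
count; the double heterozygote is a phase mixture resolved in the E-step by
weight r²/(r² + (1−r)²). The estimate is clipped to [10⁻⁶, 0.5] and
verified in tests against a dense grid search of the same likelihood.
Cumulative positions use the Kosambi function d = ¼ ln((1+2r)/(1−2r)),
inverse r = ½ tanh(2d).

**Individual filters.** Individuals typed at fewer than a minimum number of
markers (default 11) are removed first; then individuals whose
*minimum-crossover parsimony count* exceeds a cap (default 7). Because
genotype codes hide phase, the count is defined as the minimum number of
chromatid switches over the four ordered chromatid states consistent with
the codes (dynamic programming, missing markers skipped, summed over
chromosomes) — a reproducible, oracle-checkable definition of "apparent
crossovers".

**Scan.** At each marker the alternative model gives each genotype class
its own penetrance π_A, π_H, π_B against a single-π null;
LOD = (ℓ_alt − ℓ_null)/ln 10, clipped at 0. With complete genotypes the
MLEs are class-wise means and the LOD is closed-form. Missing genotypes are
handled by EM over class probabilities conditioned on the nearest typed
flanking markers of the same chromosome (genotype-level Markov transitions
at the Kosambi-inverted map distances; 1:2:1 prior when no flank is
typed), iterated to |Δℓ| < 10⁻⁸ with a 1,000-iteration cap. A
`"complete-cases"` mode drops untyped individuals instead. This flanking
conditioning is a two-point approximation to a full multipoint hidden
Markov treatment; with the marker densities and missingness here the two
agree closely, but small LOD differences against multipoint implementations
are expected. A constant phenotype yields all-zero LOD with a warning
rather than an error.

**Thresholds.** The phenotype vector is permuted jointly across individuals
(genotypes fixed, preserving marker correlation) and the threshold is the
empirical 95th percentile — quantile type 7, linear interpolation between
order statistics — of the per-permutation genome-wide maximum LOD, with the
seed recorded. Each scoring date is scanned and thresholded independently.
P-values elsewhere are unadjusted; the permutation maximum is the only
multiplicity control, as is conventional for single-population scans.

## Segregation statistics

`seg_distortion_chi2()` is the Pearson 1:2:1 goodness-of-fit (df 2) used
both as a pre-scan distortion screen and to test for donor-allele
enrichment among regrown plants; `two_locus_linkage_chi2()` is the standard
3×3 independence test (df 4 after dropping empty rows/columns) used to
confirm that the early and late QTL segregate independently. Both delegate
to `stats::chisq.test` (asymptotic p-values; small-count warnings are
suppressed as uninformative for these table sizes). Published tables of
this kind occasionally carry χ² values that do not recompute from their
printed counts (transcription slips); the packaged `study_table()` fixtures
therefore keep the printed statistics in separate `*_printed` columns and
all recomputation is done from the counts.

## Problem sizes and verification

The test suite and the acceptance script verify, among others: Mendelian
1:2:1 and independent assortment at n = 10,000; the closed-form 2/3 vs 0
bulk signal on the 496-plant default scenario over five seeds; genome-wide
type-I error of the permutation threshold on 50 null crosses (n = 200, 11
markers, 200 permutations each); EM-vs-grid agreement on simulated marker
pairs to 5×10⁻⁴; crossover parsimony against exhaustive phase enumeration
for all genotype vectors up to length 6; and Kosambi round-trips to 10⁻¹⁰.
These sizes give three-standard-error resolution on every stochastic check
while keeping the full suite under a minute.

## Known limitations

* Single-marker association only: no interval mapping between markers, no
  multiple-QTL or covariate models, no effect-size decomposition.
* The two-point flanking approximation for missing genotypes (above).
* The simulator's idealisations (above); in particular, simulated GQ is a
  depth proxy, so GQ-filter attrition patterns of real joint calling are
  not reproduced.
* Penetrance tables are treated as fixed parameters; no uncertainty in the
  trait model is propagated.
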