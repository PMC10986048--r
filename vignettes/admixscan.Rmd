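---
title: "Methods: windowed genome scans for admixed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed genome scans for admixed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`admixscan` analyses a four-population design: a target population `B`
suspected to be of hybrid origin, panels of its two candidate ancestor
populations `EU` and `AS`, and an outgroup `O` used to polarize derived
alleles. This vignette documents the models behind each stage, the
parameters that matter, what the built-in simulator does and does not
emulate, and the numerical conventions, so that results can be read with
the right caveats.

## Coordinates and containers

Every interval in the package — windows, bins, tracts, calls — is 0-based
half-open (`[start, end)`, the BED convention). VCF positions are 1-based
on disk and converted on read; BED files interchange bit-exactly. The
central container is a `genotype_matrix`: haplotype alleles coded 0/1/NA
at biallelic SNPs, two haplotype columns per diploid sample, one
population label per sample. Missing genotypes are never imputed; every
statistic declares its own site-inclusion rule instead.

Windows are anchored at position 0 on each chromosome. With step < size,
full windows are laid while they fit and one truncated terminal window is
appended only if coverage would otherwise not reach the chromosome end;
with step = size the windows partition the chromosome exactly. Anchoring
and terminal handling are conventions (no anchoring rule is standard in
the field); both are implemented in one place (`make_windows`) so they
are at least reproducible conventions.

## Site frequencies and polarization

Allele counts use only called alleles. Sites are unusable for a
statistic when any involved population has fewer than `min_alleles`
(default 2) called alleles. For D and f_d, the ancestral allele is the
outgroup's major allele, and sites where the derived allele exceeds
frequency 0.1 in the outgroup (or the outgroup is uncalled) are excluded
— a guard against misdirected polarization. The 0.1 cutoff is exposed as
`outgroup_max_derived`.

## Patterson's D and the block jackknife

With derived-allele frequencies `p1, p2, p3, pO` for the quartet
((P1,P2),P3,O),

```
ABBA = (1-p1) p2 p3 (1-pO)      BABA = p1 (1-p2) p3 (1-pO)
D    = sum(BABA - ABBA) / sum(BABA + ABBA)
```

This is the qpDstat orientation: significantly negative D means gene
flow between P2 and P3 (the donor-into-target direction when P2 is the
admixed breed and P3 the donor candidate). Frequency-weighted site
patterns are used rather than single sampled haplotypes; this matches
population-mode D and reduces variance.

The Z score comes from a weighted delete-one block jackknife over
contiguous blocks, weighted by informative-site counts. The default
block size is 5 Mb — conventional for whole-genome data, where linkage
decays well below that scale. On the simulated benchmark cohorts the
package uses 50-kb blocks instead: the simulator draws sites
independently given the planted structure, so blocks are valid at any
size above the SNP spacing, and smaller blocks buy more jackknife
resolution on a 20-Mb genome (400 blocks rather than 4). Degeneracies
are loud: fewer than two non-empty blocks is an error, and zero
jackknife variance yields `Z = NA` with a warning, never a silently huge
number.

## Windowed f_d

f_d follows the dynamic-donor formulation: the observed ABBA−BABA excess
in a window divided by the excess expected if the donor frequency were
fully transferred, with the donor chosen per site as whichever of P2/P3
has the higher derived frequency. Windows are non-overlapping 50 kb by
default with a 100-informative-site floor. The clamping rules are:
window D < 0, or window D > 0 with raw f_d > 1, gives f_d = 0, so
reported values lie in [0, 1]. Note the window D used here is the
ABBA−BABA orientation (positive for donor-into-target flow), which is
the orientation those clamping rules presuppose; the genome-wide D above
deliberately reports the opposite, qpDstat, orientation. The `> 1` clamp
carries a 1e-9 floating-point guard so that a complete-replacement tract,
whose raw f_d is exactly 1 up to rounding, is not zeroed.

Candidate introgression regions are the top `fd_quantile` (default 5%)
of non-missing f_d windows, merged with gap 0 and intersected with the
high-donor-ancestry windows. No absolute f_d cutoff exists in the
literature this mirrors; a top-tail convention is used throughout and the
quantile is config-exposed.

## Weir–Cockerham Fst, d_xy and PBS

Fst is Weir & Cockerham's (1984) estimator: per-site variance components
a (among populations) and a+b+c (total) are accumulated over a window
and combined as a ratio of sums — the "weighted" estimator reported by
VCFtools. Negative window values are retained. Sites need two called
diploids per population.

d_xy is the mean per-site cross-population haplotype difference
`p_x(1-p_y) + (1-p_x)p_y`, summed over usable sites and divided either by
the usable-site count (default) or by window length (`per_bp`). The
frequency formula equals exhaustive enumeration over haplotype pairs
exactly, which the tests verify. The per-used-site default is a choice:
divergence per SNP site, insensitive to SNP density; `per_bp` is offered
because neither denominator is universal.

PBS transforms pairwise Fst into branch lengths `T = -log(1 - Fst)`
(natural log by default, the original formulation; the base is exposed
as `log_base`) and combines `PBS = (T_BY + T_BO - T_YO)/2` on 50-kb
windows sliding by 2 kb. Fst is clamped at `1 - 1e-12` so T stays
finite; negative Fst legitimately gives negative T (observed PBS minima
below zero are expected). The sweep call takes the empirical top 5%
(ties pass, `>=`), drops windows with any bp overlap with the
introgression call — "coincided with introgression" is read in its
strictest any-overlap sense — and merges the rest with gap 0. The
fraction of the genome covered by the merged set is reported, making
explicit how a 5%-of-windows scan can cover a different fraction of the
genome once overlapping sliding windows merge.

## rIBD

The genome is cut into 10-kb bins. Per bin, `cIBD` counts
cross-population *sample pairs* with any IBD segment overlapping the bin
(a pair counts once per bin however many haplotype combinations match),
`tIBD = n_B × n_other` is the total number of pairs, `nIBD = cIBD/tIBD`,
and `rIBD = nIBD_EU − nIBD_AS`. Counting pairs rather than haplotype
combinations is what keeps nIBD in [0, 1] with that tIBD. ZrIBD
standardizes rIBD by its mean and s.d. over *all* genome bins, zeros
included — the far-right-tail threshold only makes sense against the
full genome-wide distribution. Candidate ancestor-shared regions are
bins with `ZrIBD > 2` and `nIBD_EU > 0.80`, intersected with the
high-EU-ancestry windows and merged. A segment contributes to every bin
it overlaps by at least 1 bp.

The built-in `naive_ibd` detector reports maximal runs of exact
haplotype identity above a minimum span (default 100 kb) — a stand-in
for HMM-based IBD callers that is exact on simulated data (where
identity means descent) and deliberately naive on real data.

## Local ancestry

The package consumes a site × haplotype 0/1 label matrix from any
external local-ancestry tool, or produces one with `naive_paint`: per
50-kb chunk, each target haplotype is labelled by the panel containing
its minimum-Hamming-distance haplotype; exact ties are unassigned.
Window ancestry is the fraction of assigned (site × haplotype) cells
labelled 1 — allele-level averaging, not per-haplotype majorities.
Top/bottom tails take `ceiling(tail × n)` windows each, ties broken by
genomic order for determinism.

The painter's background behaviour matters for interpretation: when the
target is genuinely equidistant from both panels, chunk assignments are
near-coin-flips that are *correlated across haplotypes within a chunk*
(all target haplotypes face the same panel configuration), so the
background window-ancestry distribution is wide. True donor tracts
(exact haplotype copies) are still assigned essentially perfectly. This
is why the benchmark analyses gate f_d calls with an ancestry tail set
to twice the planted tract fraction — the naive painter needs that
head-room, where a production LAI tool would not.

## Gene-tree census and the ILS null

Each 4-taxon newick tree is classified by unrooting and finding the
outgroup's cherry partner: partner AS means topology I ((B,EU) cherry,
concordant with the species tree), partner EU means II (B with AS),
partner B means III. Polytomies are unresolved and excluded from
counts. Genes with ten or fewer SNPs are removed before counting
(`min_snps = 11`).

Under pure incomplete lineage sorting the two discordant topologies are
equally frequent, so `(n_II, n_III)` is tested against 50:50 by a 1-df
χ². The ILS ratio test calibrates the species-tree internal branch from
the concordant fraction, `t̂ = -ln(1.5 (1 - n_I/total))` (valid only for
concordance in (1/3, 1); outside it the calibration errors), simulates
`n_reps` censuses of the same size from the multispecies-coalescent law
`P(discordant class) = (1/3)e^{-t̂}`, and compares the observed
`n_III/n_II` to the simulated ratio distribution. Both a one-sample t
test (as commonly reported) and a two-sided empirical tail probability
with the add-one correction `2·min((1+#≤)/(R+1), (1+#≥)/(R+1))` are
returned; the empirical p is the defensible one when the simulated ratio
distribution is skewed, and it is what the calibration tests check for
uniformity.

## The simulator: what it emulates, what it does not

`simulate_cohort` draws, per site, an ancestral derived-allele frequency
uniform on (0.05, 0.95), then per-population frequencies from a
Balding–Nichols beta with that mean and a per-population drift parameter
F. Defaults are F = 0.15 for the three ingroup populations, chosen so
that pairwise Weir–Cockerham Fst between simulated populations is ≈0.15,
the differentiation typical of distinct pig breeds (and of the motivating
system). The outgroup is drawn around a small derived mean (0.02) with
its own F, making it a near-monomorphic carrier of the ancestral allele
so that outgroup-major polarization is essentially always correct.
Haplotypes are binomial draws; phasing is exact by construction.

Planted structure:

* **Introgression tracts** replace a fraction f of B haplotypes with
  copies of donor haplotypes, sampled without replacement while the
  panel allows — full replacement then reproduces the donor panel's
  frequencies exactly, which is what makes f_d ≈ 1 the right expectation
  for an f = 1 tract.
* **Sweep tracts** shift B's frequency by δ toward the locally major
  allele before sampling, truncated to [0, 1]. Sweep and introgression
  tracts may not overlap (the downstream pipeline treats the classes as
  exclusive, so the generator rejects contradictory truth).
* **IBD tracts** fix one shared EU ancestor haplotype on both
  chromosomes of every designated sample, so designated pairs are
  literally identical over the tract and bin-level nIBD approaches 1 —
  the regime the nIBD > 0.80 filter is designed for.

Sites are independent given the planted structure: there is no
background linkage disequilibrium, no recombination map, no mutation
model, and no sequencing error. Consequences for interpretation: the
planted tracts carry perfect haplotype structure while the background
carries none, so tract recovery here is an upper bound on real-data
performance; jackknife blocks can be small without violating
independence; and `naive_ibd`'s zero false-positive rate is a property
of the independence, not of the detector. Passing recovery tests
demonstrates the statistical machinery is correct and correctly wired,
not that these thresholds transfer to any particular real genome.

All randomness flows from the single seed in the config; the same seed
reproduces the cohort — and the VCF bytes — exactly.

## Benchmark study conditions

Two standard cohorts (`benchmark_config`) are used by the tests and the
acceptance script:

* *null*: 2 chromosomes × 5 Mb, 1 SNP/kb, 20+20+20 ingroup and 6
  outgroup samples, no tracts. Used for calibration: across 200 such
  cohorts the jackknife |Z| > 1.96 rate must sit within the binomial 95%
  band around 5%.
* *recovery*: 2 chromosomes × 10 Mb, 1 SNP/200 bp (so a 50-kb window
  holds ≈200 usable sites, comfortably above f_d's 100-site floor),
  30+30+30+6 samples. Planted: eight 250-kb introgression tracts
  (f = 0.8, 10% of the genome), two 500-kb sweeps (δ = 0.4, 5% of the
  genome, matching the scan's top-5% convention), two 200-kb IBD tracts
  shared by all B×EU pairs. All classes disjoint.

On the recovery cohort the candidate fraction for introgression calling
is set equal to the planted fraction (f_d quantile 0.10) — with 10% of
the genome truly introgressed, a 5% cutoff could never recall more than
half the truth by construction — and the ancestry gate is set to twice
that (0.20) to absorb the naive painter's background noise discussed
above. The sweep and IBD analyses run at the field defaults (top 5%,
ZrIBD > 2, nIBD > 0.80, bottom-5% ancestry tail). These sizes keep the
full test suite and the acceptance script within a few minutes on one
CPU while leaving every per-window site count in the regime the
estimators assume.

## Numerical conventions and degenerate inputs

* Quantile ties: threshold comparisons are `>=` (ties pass); ranking
  ties are broken by genomic order (earlier window wins).
* Fst windows with zero usable sites, f_d windows under the site floor,
  and ancestry windows with no assigned cells are `NA`, never 0.
* `ZrIBD` with zero genome-wide variance (no segments anywhere) is an
  error, as is a D statistic with fewer than two jackknife blocks.
* `merge_regions` is idempotent; `intersect_regions` operates on merged
  inputs; `covered_bp` counts union bp, so recall/precision arithmetic
  is well defined even for overlapping calls.

## Known limitations

The naive painter and naive IBD detector are desk-scale stand-ins, not
replacements for LAI and HMM-IBD tools; their outputs are accepted in
the same formats so real tool output can be dropped in. The simulator's
lack of background LD means window statistics have lower variance than
on real genomes at equal site counts. d_xy's window size and denominator,
the f_d candidate quantile, and the jackknife block size have no single
field-standard value; all are config-exposed and their defaults recorded
here.
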