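---
title: "Methods: multi-breed rEHH selection scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-breed rEHH selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistics it computes,
the choices made where the design was genuinely open, and what its tests
do and do not establish. It states no empirical result that the test suite
does not itself compute.

## 1. Model and workflow

The long-range haplotype test asks whether a core haplotype is *too
frequent for its length*. Under neutral drift a variant needs many
generations to become common, during which recombination shortens the
haplotype it rides on; under recent positive selection frequency rises
fast and the flanking haplotype stays long. The package operationalises
this in five stages, each usable on its own:

1. **QC** (`run_qc`, `prune_relatives`). Two steps, animals then markers,
   with thresholds standard for 50k-chip bull panels: call rate > 0.95
   (samples at or below are removed), duo Mendelian-error rate < 0.2%
   (opposing homozygotes between a genotyped sire and son; the son is
   dropped by default — the pair member whose identity is most likely
   mislabelled — configurable), one member of each declared replicate pair
   (the lower-call-rate one; ties keep the lexicographically smaller id),
   then markers with > 2.5% missingness, markers entirely missing in one
   breed, whole-dataset MAF < 5%, non-autosomal or unplaced markers.
   Relatedness pruning afterwards removes every genotyped father of a
   genotyped son and caps half-sib families at 5 random members: sires
   transmit half their genome to dozens of sons, so family structure
   masquerades as haplotype frequency.
2. **LD decay** (`ld_decay`). Haplotype r² (the squared Pearson
   correlation of two 0/1 columns; no EM, data are phased) averaged in
   50-kb bins up to 1 Mb — descriptive, to compare breeds' LD persistence.
3. **Core detection** (`find_cores`). See §2.
4. **EHH / rEHH** (`ehh_at`, `rehh`, `scan_breed`). See §3.
5. **Significance and multi-breed comparison** (`fit_bins`,
   `empirical_p`, `shared_regions`). See §4-5.

Distances are genetic, with a flat 1 cM/Mb map unless per-marker cM
positions are supplied — the standard approximation when no
recombination map exists for the genome at hand. Coordinates are 1-based,
intervals closed, and all interval overlap tests (including gene
annotation) use closed-interval logic; BED input is converted on read.

## 2. Core-haplotype detection

The upstream literature delegates core selection to a program whose
default algorithm it does not describe, beyond "longest non-overlapping
cores of 3-20 SNPs". This is the largest open design point in the package,
filled with the haplotype-block rule historically bundled with that
software family (Gabriel-style):

* For each marker pair within 20 SNPs, the 90% confidence interval of
  |D'| is computed from the normalised multinomial likelihood on a
  101-point |D'| grid, allele frequencies fixed at their MLEs.
* A pair is **strong LD** if CI-lower ≥ 0.70 and CI-upper ≥ 0.98,
  **recombination** if CI-upper < 0.90, otherwise inconclusive
  (excluded from denominators).
* Every contiguous span of 3-20 markers in which ≥ 95% of informative
  pairs are strong LD is a candidate; candidates are accepted greedily by
  descending marker count, then descending bp extent, then ascending
  position, subject to non-overlap.

All four thresholds are exposed as arguments. Candidates are enumerated
directly as intervals (rather than maximal runs trimmed to 20 SNPs with
the remainder reconsidered); the two formulations agree on every case we
test, and direct enumeration is what the brute-force acceptance oracle —
exhaustive search over all feasible non-overlapping span sets on small
chromosomes — verifies against.

## 3. EHH and rEHH

For core allele *t* with `c_t` carriers, `EHH_t(x) = Σ C(e_i,2) / C(c_t,2)`
over the distinct carrier haplotypes spanning core∪extension. The
denominator of the relative statistic treats all non-carriers as one set:
two non-carriers count as homozygous only when identical over core plus
extension (so necessarily sharing some other core allele), giving
`EHH_others = Σ_{s≠t} Σ_j C(e_sj,2) / C(Σ_{s≠t} c_s, 2)`. This is the
combined-set form of the statistic's original definition. The distinction
matters: normalising each rival allele within its own family instead
(denominator `Σ C(c_s,2)`) makes the reference as internally conserved as
the tested allele in small populations, driving rEHH toward 1 at true
sweeps and destroying power — our simulations confirm this directly.

The scalar rEHH reported per allele and direction is evaluated at the
marker whose genetic distance from the core's **outer marker** (first for
upstream, last for downstream) is nearest to 0.25 cM (250 kb under the
default map), ties to the farther marker; the evaluation distance used by
the original software's defaults is not recoverable, so 0.25 cM — inside
the distance range where chip-density EHH contrast is strongest — is the
package default and configurable. If no marker lies within twice the test
distance the allele is skipped in that direction. `EHH_pooled = 0` with
`EHH_t > 0` yields an infinite rEHH: reported with p = 0 and excluded
from null fitting, never silently dropped; 0/0 is undefined (`NA`).
Alleles with fewer than 2 carriers are untestable.

## 4. Empirical significance

rEHH depends strongly on allele frequency, so values are stratified into
20 frequency bins of 5% (left-closed; frequency 1.0 falls in the last
bin). Within bins, values are natural-log transformed and fitted with a
normal distribution; p is the one-sided upper tail (positive selection
predicts large rEHH; a two-sided option exists). Choices the source
material leaves open, decided here: natural log for the transform (−log10
for reporting), fits per breed and per direction (up- and downstream
significance are reported separately), genome-wide rather than
per-chromosome bins, and a minimum of 10 members per bin — bins below it
merge recursively into their nearest non-empty neighbour (ties toward the
lower bin), since a standard deviation from a handful of values is noise.
The null is fitted on **all** core alleles; the frequency > 25% rule
gates only which alleles are reported, matching the stated order of
operations of the method. No multiple-testing correction is applied
within breeds — cross-breed replication is the false-positive control.

## 5. Shared regions and genes

Significant cores of different breeds "share" a locus when they contain
at least one common marker id. Within a production group, connected
components of the sharing graph that span ≥ 2 breeds become shared
regions: interval = union of member core intervals, shared SNPs = markers
present in cores of ≥ 2 breeds. Components (rather than pairwise
intersections) were chosen so a locus chained across three breeds is
reported once; construction is invariant to breed input order. A
dual-purpose breed simply appears in both group definitions. The
"fraction of genome" summary uses the mapped span of the marker map (sum
over chromosomes of last-minus-first marker bp) as denominator, avoiding
any dependence on external assembly sizes. Gene overlap is positional,
closed-interval, against a local BED/GFF3 annotation; regions without
genes are kept but flagged.

## 6. The synthetic world

`simulate_base_population` draws marker allele frequencies from
Uniform(0.05, 0.95) — chip ascertainment favours common variants — and
builds background LD with forward Wright-Fisher mating: each offspring
takes one recombined gamete from each parent, crossovers Poisson on the
cM map. No new mutations arise (markers are predefined, as on a chip).
Defaults: 200 diploids, one 100-Mb chromosome, 20 markers/Mb, 1 cM/Mb,
100 generations, matching the scale at which the whole pipeline runs in
seconds. Sweeps place a new favoured allele on one random haplotype at
the marker nearest the requested position and select with additive
fitness 1 : 1+s : 1+2s until the frequency first enters the target window
(default 0.5-0.8, the range where a segregating sweep is detectable);
lost or overshooting runs restart from a derived seed, bounded. The
default s = 0.1 reflects strong artificial selection. Breeds are founded
by resampling the base population and diverging independently;
group-assigned sweeps are implanted at the same map position in every
member breed, and a truth table records positions for power evaluation.
`degrade_and_pedigree` collapses haplotypes to genotypes and plants the
QC test surface: sire-gamete × population-gamete sons (Mendelian-
consistent by construction), replicate copies, missingness and genotype
errors at configurable rates (defaults 1% and 0.1%). Everything is
deterministic under the configured seed.

What the generator does **not** emulate: realistic cattle demography
(bottlenecks, migration), chip ascertainment bias beyond the initial
frequency range, genotype-calling error structure, or linkage between
chromosomes. A green test on synthetic data therefore establishes
correctness of the computations and calibration of the empirical test
under drift + recombination — not field performance on any particular
breed history.

## 7. Power at desk scale — why two acceptance tests stay red

With 2N = 400 haplotypes, a sweep with s = 0.05 has 2Ns = 20 and needs
~70-110 generations to reach frequency 0.5. Neutral drift in so small a
population constantly creates young, common haplotype families whose
rEHH (3-6) rivals the sweep's; the within-bin null log-rEHH spread is
~0.5, leaving the swept allele only z ≈ 1.1-1.3 above the mean. Measured
consequences (all computed by the acceptance suite or the analyses in the
repository notes): the empirical test is well calibrated on neutral data
(type-I error inside the 99% band around 0.05), the median signal at
sweep cores exceeds the genome-wide median, but a *significant* core at
the sweep appears in only ~25% of seeds at s = 0.05, and detection
saturates near 50-65% even at s = 0.4 because the null's right tail is
drift-generated. Joint detection in two breeds — the requirement for a
shared region — caps near ~30%. The acceptance criteria demanding ≥ 50%
single-breed and ≥ 80% two-breed recovery at this scale are therefore
left failing rather than met by inflating population sizes (infeasible
for a forward simulator in the test budget) or quietly strengthening
sweeps. The real-data regime the method was designed for — thousands of
chromosomes whose LD reflects a long pedigree history — is precisely
what a desk-scale forward simulation cannot reproduce.

## 8. Numerical and degenerate-input conventions

* `bin_assign` guards binary-representation error with a 1e-9 slack
  before flooring; core-allele frequencies are exact rationals `c/2N`.
* EHH values are ratios of integer pair counts — oracle comparisons in
  the tests are exact, not tolerance-based.
* Monomorphic markers make r² and |D'| undefined (classed errors);
  `scan_breed` removes markers below MAF 0.05 before core detection.
* A merged frequency bin with zero variance raises a classed
  degenerate-bin error; `scan_breed` degrades to NA p-values for that
  direction rather than aborting a whole run.
* Replicate-pair exclusion ties (equal call rates) keep the
  lexicographically smaller id; family capping uses the run seed — both
  make reruns byte-identical.
* PLINK genotypes are recoded to minor-allele dosage per marker computed
  on the dataset read, ties toward the alphabetically first allele, so a
  canonically coded file round-trips exactly.

## 9. Known limitations

* Phasing is out of scope: `scan_breed` consumes phased haplotypes
  (simulated, or phased externally).
* The block rule realises "automatic core selection" plausibly but not
  verifiably identically to the original software's undocumented
  defaults; results should be reported together with the rule thresholds.
* The empirical p-value assumes within-bin log-normality; heavy-tailed
  null deviations shift calibration (the neutral-calibration test bounds
  this at chip scale).
* Pathway analysis and remote annotation retrieval are deliberately
  absent; gene context comes only from local annotation files.
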