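---
title: "Selection-signature scans for altitude-contrast designs: models and methods"
author: "altiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Populations that colonize contrasting environments — here the motivating
case is cattle herded above 3,000 m against lowland relatives — accumulate
locally adaptive alleles.  Recent positive selection leaves three
complementary footprints in phased genome data:

* unusually long haplotypes around an allele that rose quickly
  (within-population haplotype statistics: EHH, iHS);
* allele-frequency change in one population that is too sharp and too
  spatially coherent to be drift (cross-population composite likelihood,
  XP-CLR);
* lineage-specific divergence on one branch of a three-population tree
  (the population branch statistic, PBS, from pairwise FST).

`altiscan` implements all three scans, the windowed FST and nucleotide
diversity tracks and LD-block summaries used to characterize candidate
loci, and the windowing / outlier-calling / merging / intersection /
gene-annotation bookkeeping that turns per-SNP statistics into candidate
gene lists.  A compiled forward Wright–Fisher simulator generates phased
three-population data with a known sweep, so every stage is testable
end-to-end with no external data.

# Data model

A `HaplotypePanel` holds a haplotype × site 0/1 matrix for one chromosome
with 1-based physical positions, ref/alt alleles, per-site ancestral
polarity (0 = ref ancestral, 1 = alt ancestral, `NA` = unknown) and a
sample → population map; rows 2k−1 and 2k are the phased haplotypes of
diploid k.  Panels come from phased VCF (`readVcfPanel()`; biallelic SNPs
with fully called, phased genotypes only; `AA` INFO tag honoured) or from
the simulator.

All windows, candidate regions and gene intervals are 0-based half-open
`[start, end)` while sites keep their 1-based VCF positions.  The single
conversion point is `bedRanges()`: position *p* lies in `[a, b)` iff
`a < p ≤ b`, which is containment in the 1-based closed `GRanges`
`[a+1, b]`.  Every overlap computation goes through `GRanges`, so the
boundary rule cannot drift between modules.

When no ancestral information is present, `polarizePanel()` offers
ref-is-ancestral (default, logged — this is a common but biased fallback),
outgroup-major-allele, or skip.  Simulated panels are polarized exactly,
because the simulator tracks every derived mutation.

# The simulator

`simulateSweep()` runs a discrete-generation haploid Wright–Fisher model
forward in time: an ancestral population of `N_anc` haploids evolves a
burn-in of `10 × N_anc` generations (configurable) to approach
mutation–drift equilibrium; an outgroup branch splits `t_out_split`
generations before present; the remaining lineage splits into the
highland and lowland populations at `t_hilo_split`.  Each offspring
haplotype draws two parents (selection weights `1 + s` per carrier of the
beneficial allele), recombines at `Poisson(rho · L)` uniform breakpoints
and adds `Poisson(mu · L)` new mutations on distinct integer base pairs
(infinite sites).  An optional hard sweep injects a single beneficial copy
into the highland branch at `t_start`; with
`condition_on_establishment = TRUE` the state at `t_start` is restored and
the copy re-injected whenever the allele is lost, up to `retry_cap`
attempts.  All randomness flows from R's global RNG, so a seed fixes the
output byte-for-byte.

Two bookkeeping choices matter for interpretation.  Mutations that fix in
*every* population are periodically removed (they are invisible as SNPs);
and position uniqueness is enforced against currently segregating or
locally fixed sites, so a position whose mutation was lost everywhere can
be reused — at desk scale the cumulative mutation supply exceeds the
region length, making global-history uniqueness impossible.  Sampled
panels contain the sites segregating in the pooled sample.

## Reference study conditions

The paperless defaults (`simConfig()`) are chosen for testability at desk
scale, not demographic realism: 1 Mb region, `N = 1000` haploids per
population, `mu = rho = 1e-7` per bp per generation (π ≈ 2Nμ = 2×10⁻⁴ —
a scaled-down coalescent; the *ratio* of mutation to recombination is
kept at 1), highland/lowland split 200 generations ago, outgroup 600,
sweep `s = 0.05` starting 180 generations ago at the region centre.
Under conditioning on establishment the logistic trajectory brings the
beneficial allele to ≈0.95–1.0 by sampling time — a sweep near fixation,
which is the regime the three scans are aimed at.  Ten diploids per
population mirror the per-population sampling scale of the motivating
design; calibration and localization analyses sample 30 diploids per
altitude-class branch because the within-class haplotype scan in such
designs pools the class's populations (≈30 animals per class), and
haplotype statistics need that many chromosomes to resolve high-frequency
sweeps.

What the simulator does *not* emulate: diploid dominance, gene
conversion, variable recombination and mutation maps, background
selection, gene flow after the splits, and the deep zebu–taurine
admixture structure of real cattle.  Passing tests therefore demonstrate
the statistical machinery on clean hard-sweep genealogies, not
performance on real admixed genomes.

# Haplotype statistics

For a core allele class at site `c`, EHH at marker `x` is the probability
that two randomly chosen carrier haplotypes are identical at every site
from `c` to `x` inclusive: `Σ_h C(n_h,2) / C(n_c,2)` over the distinct
extended haplotypes.  It is computed outward marker-by-marker by partition
refinement, so monotone non-increase holds exactly.

iHH is the trapezoidal integral of EHH over physical distance (bp·EHH
units; no genetic map is used), each side integrated from the core to the
*first marker below the cutoff* (default 0.05) with that final sub-cutoff
trapezoid included, sides summed.  Three guards apply:

* **Border truncation.** If the chromosome ends before EHH drops below
  the cutoff the site is flagged; the default policy discards such sites
  from the scan (`borderPolicy = "keep"` integrates to the border
  instead).  On short simulated regions discarding removes low-carrier
  classes whose EHH cannot decay, which is the conservative choice: the
  kept-truncated alternative floods the scan with spurious extremes from
  under-integrated sites.
* **Gap rule.** If adjacent markers are more than `maxGap` (default
  200 kb) apart, integration stops and the site is flagged, preventing
  sparse-region artifacts.
* **Carrier minimum.** Classes with fewer than two carriers are undefined.

`uniHS = ln(iHH_ancestral / iHH_derived)` is standardized within
equal-width derived-allele-frequency bins on `[mafMin, 1 − mafMin]`
(default width 0.025, edge ties to the lower bin):
`iHS = (uniHS − bin mean)/bin sd`, and
`piHS = −log10(2·Φ(−|iHS|))` maps the standardized score through the
two-sided normal tail onto a −log10 p scale, the scale on which
genome-scale scans threshold at `piHS ≥ 6` (p < 10⁻⁶); a relaxed
`p < 10⁻⁵` style cutoff is exposed as a parameter rather than hard-coded,
since published analyses use both.  Bins with fewer than two scored sites
— or whose sites are perfect-LD duplicates with zero variance — carry no
score and are flagged; erroring there would make small-region scans
unusable.  Bin width 0.025 was kept after measuring that wider bins mix
frequency-dependent means and *reduce* sweep localization.

# XP-CLR

Per site, the object population's derived count `k` of `n` is binomial
with frequency `p2` drawn from a drift distribution around the reference
frequency `p1`: Normal(`p1`, `ω·p1(1−p1)`) truncated to `[0,1]`, escaped
mass placed as point masses on the boundaries.  The drift scale ω is a
method-of-moments estimate over sites (`estimateOmega()`), floored at a
small positive constant.

Under a sweep the lineage escapes the swept background with probability
`c` and keeps its pre-sweep frequency; otherwise it descends from the
single swept haplotype, whose allele is derived with probability `p2`.
Given pre-sweep `p2`, the sampling frequency is `c·p2 + (1−c)` with
probability `p2` and `c·p2` with probability `1−p2`; at `c = 1` the sweep
model reduces *exactly* to the neutral one.  The escape probability at
physical distance `d` from the putative sweep site (window centre) is
`c(d) = 1 − (2N s̃)^(−r·d/s̃)` with a fixed 1 cM/Mb map (`r = 1e-8`/bp)
and `2N = 10⁴`; the grid is 10 log-spaced intensities `s̃ ∈ [1e-4, 0.1]`.

Numerics: a 512-point midpoint quadrature on (0,1) plus the two boundary
masses, with the interior weights renormalized to the non-escaped mass so
the site distribution stays proper when σ approaches the grid resolution.
Because the low end of the s̃ grid degenerates (at `2N s̃ ≤ 1` the
parameterization collapses to complete hitchhiking), the neutral model is
included explicitly in the maximization: the window score
`2·(max_s̃ ℓ_sweep − ℓ_neutral)` is floored at 0, which is also the
nesting bound.  SNPs within a window whose reference-panel r² exceeds
0.95 share weight (1/m over the connected component of the r² > 0.95
graph), controlling composite-likelihood inflation from redundant sites;
windows with fewer than `minSnps` (default 10) usable SNPs score `NA`.

# FST, PBS and nucleotide diversity

Two per-site FST estimators are provided.  Hudson (Bhatia et al. form):
`num = (p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)`,
`den = p1(1−p2) + p2(1−p1)` — well behaved at small, unequal sample
sizes.  Weir–Cockerham (default, mirroring the vcftools convention of the
motivating analyses): the 1984 variance components in their two-population
haploid form.  Windowed values are the ratio of summed numerators to
summed denominators ("ratio of averages"); empty windows are `NA`, never
zero.  Per-site ratios are reported unclamped.

PBS clamps each FST to `[0, 1−1e-9]`, transforms to branch lengths
`T = −ln(1−FST)`, and reports the focal branch
`(T_S,L1 + T_S,L2 − T_L1,L2)/2`.  The rotation identity
`PBS_A + PBS_B = T_AB` holds algebraically and is tested exactly.  PBS is
computed on 10 kb / 5 kb windows — windowed rather than per-site FST,
matching how ≥0.2-style window thresholds are applied — restricted in
pipeline mode to the candidate regions found by iHS and XP-CLR, with a
genome-wide mode for calibration.

Nucleotide diversity per site is the unbiased heterozygosity
`2p(1−p)·n/(n−1)`; a window's π is the sum over its SNPs divided by the
window length in bp, so invariant positions dilute π through the
denominator exactly as in vcftools' windowed output.

# Windows, outliers, regions, genes

`makeWindows()` builds half-open sliding windows (default 100 kb size,
50 kb step) with `start + size ≤ L`.  `summarizeTrack()` reduces a
per-SNP track per window (`max`, `mean`, `count_above(t)`); empty windows
are `NA`.  `callOutliers()` keeps windows `≥ v` (threshold rule) or the
`⌈q·M⌉` highest non-NA windows (top-fraction rule) with deterministic
tie-breaking (value desc, chrom, start), excluding windows with fewer
than `min_snps` SNPs first.  `mergeRegions()` unions overlapping or
book-ended windows into candidate regions carrying the method label and
peak value; `intersectRegions()` intersects region sets by base-pair
overlap or by annotated gene-name sets; `annotateGenes()` assigns a gene
iff it overlaps a region by ≥1 bp under the half-open convention.

Genome-scale analyses call iHS outlier windows through a per-SNP
`piHS ≥ 6` threshold and take the top 0.5% of XP-CLR windows.  On
10³-SNP simulated panels the normal-tail threshold is unreachable (the
largest attainable |z| in a few hundred sites is ≈3), so the package's
desk-scale intersection analyses use the top-decile windows of each scan
with the fixed windowed `PBS ≥ 0.2` rule; the pipeline defaults keep the
genome-scale thresholds and expose all of them as configuration.

# LD blocks

`ldMatrix()` computes `D = p_AB − p_A·p_B`,
`r² = D²/(p_A(1−p_A)p_B(1−p_B))` and `D′ = |D|/D_max` from phased
haplotypes directly (inputs are phased by contract, so no genotype-EM is
needed).  `ldBlocks()` calls solid-spine blocks: maximal runs of
consecutive sites each in strong LD (`r² ≥ 0.5` by default) with both the
first and last site of the run — deterministic and adequate for
heatmap-contrast use; the Gabriel confidence-interval method is a
deliberate non-goal.  `meanR2()` summarizes LD level within a distance
bound, the statistic used to contrast the swept against the neutral
class at candidate loci.

# Pipeline

`runPipeline()` executes the full order — load or simulate, polarize,
iHS scan of the focal group, XP-CLR focal-vs-reference, outlier windows,
merged regions, windowed PBS over the candidates, three-way intersection,
gene annotation, FST/π/LD tracks at the final candidates — and writes a
JSON manifest listing every artifact with parameters, seed and md5
checksums.  Stage outputs are pure functions of (inputs, config): rerun
with the same config and seed is byte-identical, which the test suite
checks by md5.  Any stage error aborts with the stage name and leaves a
partial manifest with a note.

# Problem sizes used by the test suite

The suite exercises the stochastic claims at sizes chosen to keep a full
run comfortable on one core: oracle-equivalence checks on ≥1000 random
small instances per estimator; drift calibration on twenty 10 kb
two-population replicates (N = 500, split 50 generations, where mean
Hudson FST is compared to `1 − exp(−t/N)`); standardization
self-consistency on a 4 Mb neutral panmictic run with >5000 scored SNPs;
and twenty sweep plus twenty neutral replicates of the 1 Mb
three-population design for localization, PBS exceedance and the
three-way intersection.  These sizes are the package's reference
conditions and are restated in the acceptance script.

One calibration detail: the site-frequency-spectrum check compares the
aggregate unfolded spectrum against the neutral 1/i law with a
chi-square test, which assumes independent sites.  Tightly linked sites
share a genealogy and inflate the statistic regardless of the true
spectrum, so the SFS calibration runs use a recombination rate high
enough (2×10⁻⁵ /bp/gen at N = 500) that sites decorrelate within about
a hundred base pairs.

# Known limitations

* Haploid genic selection approximates genic (semidominant) diploid
  selection; dominance is out of scope.
* The iHS scan integrates over physical distance; no genetic-map input.
* XP-CLR uses a constant recombination map and no soft-sweep haplotype
  model.
* The ref-is-ancestral fallback biases iHS where the reference allele is
  actually derived; prefer an outgroup policy or AA tags on real data.
* On regions much shorter than a chromosome the border-discard rule
  removes a band of sites near a strong sweep (their EHH cannot decay
  within the region); localization there rests on flanking hitchhikers,
  and the peak |iHS| can sit at the sweep's shoulder rather than its
  core — visible in the simulated acceptance checks.
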