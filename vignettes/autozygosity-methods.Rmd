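---
title: "Autozygosity, inbreeding and selection scans: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity, inbreeding and selection scans: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

rohscan characterizes autozygosity — homozygosity where an individual's two
alleles are identical by descent (IBD) from a common ancestor — in diploid
SNP genotype panels, and connects it to inbreeding, demography and
selection. This vignette is the package's own account of the models it
implements, the parameters that matter, and the design decisions taken where
the methodology left room.

## Runs of homozygosity

A run of homozygosity (ROH) is a contiguous stretch where the two inherited
haplotypes are identical. Since an IBD segment descending from an ancestor
`G` generations back has expected genetic length `1/(2G)` Morgan
(`expected_roh_length()`), segment length dates the inbreeding: at ~1 cM/Mb,
segments over 10 Mb point to the last ~5 generations, while 1–5 Mb segments
reach back up to ~50 generations. This is also why a 1 Mb minimum length is
the conventional floor — shorter homozygous stretches are dominated by
ancient LD rather than inbreeding.

`call_roh()` implements the classical sliding-window scan:

1. every 50-SNP window is scored *homozygous* if it carries at most 1
   heterozygous and 5 missing calls (the allowances absorb genotyping error);
2. a SNP is ROH-eligible if at least 5% of the windows containing it are
   homozygous — SNPs near chromosome ends are judged on the windows that
   physically exist, a deterministic edge rule we document rather than
   guess another tool's internals;
3. maximal runs of eligible SNPs, split at inter-SNP gaps over 1000 kb,
   become candidates with endpoints at the first/last eligible SNP;
4. candidates survive if they hold ≥ 100 SNPs, span ≥ 1 Mb, and average
   ≤ 50 kb per SNP.

All eight knobs live in `roh_params()`. Because the windowed logic is easy
to get subtly wrong, the package ships `call_roh_exact()`, a brute-force
re-evaluation of the same definition (every window of every SNP re-counted
explicitly, run construction written independently); the test suite demands
exact segment-set equality between the two on a hundred seeded datasets.
Heterozygous calls *can* end up inside an emitted segment — that is the
point of the window allowance.

## Inbreeding coefficients

Eight per-individual coefficients are computed and cross-compared with
Pearson correlations (`inbreeding_table()`, `inbreeding_correlations()`):

* **F_PED** (`f_ped()`): the kinship of the parents, by the recursive
  tabular method (`kinship(a,a) = (1+F(a))/2`, unknown parents contribute
  0). Memoized recursion is exact and fast at pedigree scale; a
  path-counting oracle backs it in the tests.
* **F_ROH** (`f_roh()`): `L_ROH / L_auto`, the fraction of the mapped
  autosome length covered by the individual's ROH, overall and within the
  1–5 / 5–10 / >10 Mb classes. The overall value is computed as the sum of
  the class values, so additivity is exact by construction. `L_auto`
  defaults to the summed chromosome spans of the map but should be
  overridden with the assembly's covered length when known — it is the
  denominator of every F_ROH and must be explicit.
* **F_SNP1–3** (`f_snp()`): marker-by-marker estimators based on the
  variance of additive genotypes, the excess of homozygosity, and the
  correlation of uniting gametes, with allele frequencies taken from the
  current sample (hence negative values are legitimate). Monomorphic SNPs
  are excluded (their `h = 2p(1-p)` is zero); each sample's mean runs over
  its own non-missing calls.

Under Hardy–Weinberg sampling all three SNP estimators are unbiased around
zero, which the suite verifies at n = 500, m = 5000 (tolerance ±0.01). On
planted-autozygosity data, F_SNP2 and F_SNP3 — both driven directly by
homozygosity — track F_ROH nearly interchangeably (correlations within
0.01 of each other) and far better than F_SNP1. Empirical sequence data
tends to separate them further (F_SNP2 ahead), an effect of skewed allele
frequency spectra and residual genotyping error that the deliberately clean
generator does not emulate; the tests therefore pin the robust pattern
(F_SNP2 ≫ F_SNP1, F_SNP2 ≈ F_SNP3) rather than a strict ranking.

## ROH islands and cold-spots

Per-SNP ROH incidence (`snp_roh_incidence()`) counts, for every marker, the
individuals with a ROH spanning it. Regions where an exceptional share of
the population is autozygous — ROH islands — are candidate footprints of
selection. `detect_islands()` keeps the top 0.5% of SNPs by incidence; the
threshold is the `ceiling(0.005 m)`-th largest proportion with ties kept,
a deterministic convention that never degenerates on heavily tied tracks.
Island SNPs merge only under strict map adjacency — no bridging across a
single sub-threshold SNP — because published island lists include 3-SNP,
90 bp regions that bridging would have destroyed. Cold-spots
(`detect_coldspots()`) are the mirror image: maximal runs of SNPs never
inside any individual's ROH, candidate regions of high recombination or
balancing selection.

## EHH, iHS and the significance threshold

For a core SNP, the extended haplotype homozygosity `EHH(x)` is the
probability that two random carrier haplotypes of one core allele are
identical from the core through position `x`; it starts at 1 and decays by
haplotype-class splitting (`ehh()`). Integrating each allele's curve over
genetic distance gives iHH, and `ihs_raw = ln(iHH_ancestral / iHH_derived)`
— strongly negative when the derived allele sits on unusually long
haplotypes, the signature of a recent sweep.

Raw scores depend on allele frequency, so `ihs_scan()` standardizes within
derived-allele-frequency bins (width 0.05 by default) to mean 0, sd 1;
bins with fewer than two usable SNPs borrow the nearest populated bin's
moments. The two-sided normal p-value is reported as
`p_ihs = -log10(1 - 2|Φ(iHS) - 0.5|)`, and `significance_threshold(0.005)`
returns the conventional |iHS| > 2.81 cutoff that matches a top-0.5%
selection under normality. Numerical choices, all exposed as arguments:
EHH truncation at 0.05; trapezoid integration through the first sub-cutoff
point; SNPs whose EHH reaches a chromosome end before the cutoff are
flagged and excluded by default; genetic distance is physical distance at
1 cM/Mb unless overridden. Ancestral alleles come from the map's `anc`
column; without one the major allele is used as ancestral with a loud
warning — a common approximation that halves power at swept loci where the
derived allele is frequent.

## LD decay and effective population size

Pairwise LD is the composite (genotype-correlation) r² — the squared
Pearson correlation of 0/1/2 counts across samples — which needs no
phasing and matches standard practice for unphased panels (`ld_r2()`).
The finite-sample bias of r² under no linkage is removed by subtracting
`1/(βn)` (β = 2 for unphased genotypes; `r2_adjust()`), and pairs are
binned by physical distance (`bin_ld()`, default 50 log-spaced bins over
50 kb–10 Mb; the binning is a reporting choice, not an inference).

`ne_trajectory()` inverts Sved's drift–recombination expectation
`E[r²adj] = 1/(α + 4 N_e c)` per bin: `N_e = (1/r²adj − α)/(4c)`, dated at
`t = 1/(2c)` generations ago, with α = 1 (drift only) or 2/2.2 (mutation
corrections). The recombination fraction for a distance comes from a
selectable mapping — Haldane `c = (1−e^{−2d})/2` by default, Sved &
Feldman `c = d/(1+2d)`, or linear — because the literature's formula line
is ambiguous about whether the mapping or the raw distance enters the time
axis; the flag makes either reading reproducible. The inversion is exact:
bins constructed from the expectation at any planted `(N, c, α)` return
`N` to machine precision, which doubles as the round-trip test.

## The synthetic-data generator

Every stage is validated against simulated data with known ground truth;
none of it requires downloads.

* `sample_founders()` draws founder haplotypes with per-SNP allele
  frequencies uniform on [0.05, 0.5] and LD from a first-order copying
  process: each haplotype keeps its previous allele with probability ρ,
  else redraws at the site frequency. ρ defaults to 0.9, giving adjacent
  r² ≈ 0.3 at the default 13.6 kb marker spacing, decaying over a few
  hundred kb — the scale seen in livestock panels. This is *not* a
  coalescent: it has no demography, no mutation, no recombination
  hotspots, and its background produces ~2% of the genome in genuine
  ≥ 1 Mb homozygous runs, which the ROH caller rightly reports and tests
  must account for.
* `gene_drop()` pushes founder haplotypes down a pedigree under the
  Haldane model (Poisson crossovers at 1 cM/Mb, no interference),
  tracking the founder origin of every segment; true autozygous tracts
  are the runs where an individual's gametes share an origin. Classical
  expectations anchor it: selfed offspring average `f_true = 1/2`,
  full-sib offspring `1/4`, matching `f_ped()` on the same pedigrees.
* `plant_roh()` gives direct control for calibration: tracts with
  exponential lengths (mean 4.11 Mb by default, a realistic sequence-data
  ROH mean) are placed without overlap until a target autozygous fraction
  is reached, the final tract capped at the remaining target so the
  realized fraction lands on the request instead of overshooting by a
  full mean length (the inspection paradox). Within tracts the second
  haplotype is overwritten by the first, preserving allele frequencies
  approximately.
* `plant_sweep()` and `plant_shared_tract()` create ground truth for the
  selection machinery (a hard-sweep core shared by carrier haplotypes;
  one homozygous window shared by a chosen fraction of individuals).
* `inject_noise()` adds missingness and hom→het error at the call level.

What passing tests show — and what they do not: recovery, calibration and
oracle results under this generator demonstrate the *algorithms* are
implemented correctly and are well-calibrated under exchangeable, cleanly
phased, error-free conditions. They do not certify performance on real
sequence data, where allele-frequency spectra are skewed, phasing is
inferred, error is structured, and recombination varies along the genome.

## Problem sizes and reproducibility

Simulation-backed checks run at desk scale, chosen to finish in minutes
while leaving no estimator data-starved: oracle equivalence on one hundred
50-individual × 5,000-SNP datasets; recovery on three 50-individual
populations over 150 Mb of genome; 500 gene-dropping replicates for the
selfing expectation; ≥ 5,000 usable SNPs for null iHS calibration. Every
stochastic function takes an explicit `seed` and restores the caller's RNG
state, so pipelines (`run_pipeline()`) are byte-reproducible from a config
file and a single seed.

## Known limitations

* The ROH caller follows the windowed definition as specified here;
  other implementations' undocumented edge trimming may differ at segment
  boundaries on real data.
* The copying-process LD model cannot answer demographic questions — the
  Ne stage is validated by algebraic round-trip, not by coalescent truth.
* iHS requires phased input; the package never phases genotypes.
* `l_auto_bp` is a user responsibility when maps cover less than the
  assembly; all F_ROH values scale with it.
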