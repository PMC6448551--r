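# Pipeline output dictionary

Columns of every TSV written by `run_pipeline()` into the output directory.
Coordinates are 1-based inclusive bp unless a file is BED (0-based half-open).

## qc_log.tsv
| column | meaning |
|---|---|
| rule | QC rule: `maf`, `call_rate`, `chromosome`, or the final `kept` row |
| n_fail / n_pass | variants failing / passing that rule in isolation |

## sample_call_rate.tsv
| sample | sample id | | call_rate | fraction of variants genotyped in the sample |

## roh_segments.tsv (one row per ROH segment)
| column | meaning |
|---|---|
| sample, chrom | carrier and chromosome |
| start_bp, end_bp | first and last ROH-eligible SNP position |
| n_snps | eligible SNPs in the segment |
| length_kb | `end_bp - start_bp + 1` in kb |
| length_class | 1-5 Mb / 5-10 Mb / >10 Mb |

## roh_class_summary.tsv
| column | meaning |
|---|---|
| length_class | class label (plus a `Total` row) |
| n, percent | segment count and percent of the total count |
| mean_length_mb, sd_length_mb | class length statistics (Mb) |
| coverage_pct | class length summed over individuals / (n_samples x L_auto), % |

## inbreeding.tsv (one row per sample)
`f_ped` (pedigree), `f_roh_1_5`, `f_roh_5_10`, `f_roh_gt10`, `f_roh_all`
(ROH length fractions of L_auto), `f_snp1`-`f_snp3` (SNP-by-SNP estimators).

## inbreeding_correlations.tsv
Pairwise Pearson correlation matrix of the coefficient columns above.

## roh_incidence.tsv (one row per QC-passing SNP)
`chrom`, `pos_bp`, `id`, `count` (individuals with a ROH spanning the SNP),
`proportion` (= count / n_samples).

## roh_islands.tsv
`chrom`, `start_bp`, `end_bp`, `length_bp`, `mean_abs_ihs` (filled when the
iHS stage runs), `n_snps` (island SNPs in the run).

## roh_coldspots.tsv
`chrom`, `start_bp`, `end_bp`, `n_snps`, `span_bp` — maximal zero-incidence
runs, longest first.

## ihs.tsv (one row per scanned SNP)
`chrom`, `pos_bp`, `id`, `freq_derived`, `ihh_a`, `ihh_d` (integrated EHH in
Morgans for ancestral/derived allele), `ihs_raw` (= ln(iHH_A/iHH_D)),
`ihs_std` (frequency-bin standardized), `p_ihs` (-log10 two-sided normal p),
`flag` (`ok`, `truncated`, `zero_ihh`, `skipped_freq`, `few_carriers`).

## ld_bins.tsv
`dist_lo`, `dist_hi`, `dist_mid` (bin edges/midpoint, bp), `n_pairs`,
`mean_r2` (composite r²), `mean_r2adj` (sample-size adjusted), `c_t`
(recombination fraction at the midpoint).

## ne_trajectory.tsv
`t` (generations ago, = 1/(2c)), `ne` (effective size), `c_t`,
`mean_r2adj`, `n_pairs`, `flag` (`ok`, `boundary`, `nonpositive_r2adj`).

BED exports (`roh_segments.bed`, `roh_islands.bed`) are BED3.
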