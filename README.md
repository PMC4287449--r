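# dynachip

Analysis of dynamic transcription-factor (TF) binding from two-colour
ChIP-chip tiling arrays, end to end: from replicate probe-level log2
IP/mock ratios to called binding peaks, per-gene occupancy trajectories,
dynamic occupancy clusters, activation/repression calls, a palindromic
cis-regulatory motif, TF-to-general-factor co-binding geometry,
functional enrichment, and growth-phenotype scores.

The package targets the experimental design of a dynamic oxidative-stress
study in a GC-rich archaeon: a genome tiled every 30 bp in triplicate,
IP/mock ratios collected at 0, 10, 20 and 60 minutes after peroxide
addition in several biological replicates, matched expression time
courses for the parent strain and a regulator knockout, external binding
site tables for TFIIB (Tfb) paralogs, and plate-reader growth curves.

## The models at the core

* **Peak calling** is sparse nonnegative deconvolution: probe signal is
  modelled as a superposition of a peak-normalized kernel
  (`kernel(0) = 1`, Gaussian with scale `width`), fitted by greedy
  forward selection on a sub-probe grid with joint nonnegative
  least-squares refits. Significance is a residual bootstrap of the
  maximum single-peak amplitude: `p = (1 + #[null >= a]) / (1 + n_boot)`.
* **Gene evidence** combines peak p-values with Fisher's method
  (`X = -2 Σ log p ~ χ²(2k)`), assigns peaks to genes whose translation
  start lies within 250 bp, zeroes time points that fail `p < 0.05`, and
  propagates retained profiles to operon members.
* **Dynamics and regulation**: complete-linkage clustering on
  `1 − Spearman` cut at k = 4; the GE-ChIP statistic `Cs` is the Spearman
  correlation of a gene's occupancy and expression trajectories —
  `Cs ≥ 0.6` activated, `Cs ≤ −0.6` repressed; parent-vs-knockout shifts
  are tested by Student's t-test.
* **Motif discovery** is an any-number-of-repeats EM over both strands
  with a GC-aware background, deterministic word seeding, overlap
  suppression and column-shift refinement; significance is a paired
  Wilcoxon signed-rank test against per-window mononucleotide shuffles.
* **Co-binding geometry**: signed RosR-to-Tfb distance (negative = the
  sequence-specific site upstream), Spearman distance-activity
  association in 50-bp windows stepped every 5 bp with a 10,000-fold
  permutation null, and hypergeometric enrichment/overlap tests.
* **Growth**: rates are slopes of log2(OD600) in the detected log phase
  (doublings/hour); stress ratios divide stressed by unstressed rates.

A synthetic-data module generates every input with planted ground truth
(peak centers and amplitudes per time point, dynamic archetypes,
regulation signs, motif implants, Tfb distances, growth rates), so the
whole pipeline is benchmarked against truth in the test suite. See the
methods vignette (`vignettes/dynachip-methods.Rmd`) for models,
assumptions and design decisions.

## A worked example

```r
library(dynachip)

config <- synthetic_config(genome_length = 120000, n_genes = 80,
                           n_planted_sites = 30, n_bio_replicates = 2,
                           n_probe_replicates = 2, seed = 5)
res <- run_pipeline(config, mode = "synthetic",
                    params = list(n_boot = 150, n_resample = 500))
print(res)
```

```
<dynachip pipeline run> synthetic mode, seed 5
  peaks: 396  genes retained: 30
  truth recovery:
    peak_recall                      1
    peak_center_error_median_bp      2
    peak_precision                   0.9839
    gene_recall                      1
    cluster_purity                   0.8667
    regulation_recall                1
    mean_abs_cs_parent               0.8415
    mean_abs_cs_knockout             0.4962
    motif_consensus_match            1
    motif_wilcoxon_p                 7.276e-11
    motif_mean_abs_dist_bp           33.52
    distance_activity_cs             -0.6136
    distance_activity_p              0.001996
    distance_peak_cutoff_bp          100
    tfb_distance_mode_bp             75
    growth_rate_max_rel_error        0.03645
```

Reading the report: every planted binding event at detectable amplitude
was re-called with a median center error of 2 bp and near-perfect
precision; all planted target genes were recovered; occupancy clusters
match the planted archetypes at 0.87 purity at this noise level; every
planted activation/repression sign was recovered from the
binding-expression correlation (parent `|Cs|` ~ 0.84 versus ~ 0.50 in the
decoupled knockout -- the 4-point null level, not 0); the implanted 20-bp
palindrome was recovered exactly (consensus match 1) with shuffle-test
p ~ 7e-11 (the mean occurrence-to-start distance of 34 bp mixes the
planted 18-bp implants with a few secondary matches); signed Tfb distance
anticorrelates with regulatory activity (Cs ~ -0.61 at the permutation
floor p ~ 0.002) with the |distance| mode in the planted 70-75 bp bin;
and growth rates were recovered within 4 %.

Individual stages are ordinary tibble-in/tibble-out functions
(`normalize_arrays()`, `call_peaks_timecourse()`,
`build_binding_profiles()`, `cluster_profiles()`, `ge_chip_correlate()`,
`discover_motif()`, `detect_cobinding()`, `fit_growth_rate()`, ...), with
`tidy()`/`glance()` methods for fitted objects and `plot_*()` /
`autoplot()` helpers for the standard displays. A thin command-line
wrapper lives at `inst/scripts/dynachip`
(`dynachip run --config pipeline.yaml --mode synthetic --out results/`).

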