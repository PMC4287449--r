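---
title: "Methods: dynamic TF occupancy analysis with dynachip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic TF occupancy analysis with dynachip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

dynachip analyses dynamic transcription-factor (TF) binding measured by
two-colour ChIP-chip on a high-resolution tiling array: a GC-rich archaeal
genome tiled every 30 bp, hybridized with IP against mock-treated control,
sampled before oxidative stress and at three times after peroxide addition
(0, 10, 20, 60 min). The pipeline turns replicate probe-level log2 IP/mock
ratios into called binding peaks, per-gene occupancy trajectories, dynamic
occupancy clusters, activation/repression calls from binding-expression
correlation, a palindromic cis-regulatory motif, the geometry of co-binding
with general transcription factor (Tfb/TFIIB) paralogs, functional
enrichment, and growth-phenotype scores.

Every stage can be exercised against planted ground truth: the
synthetic-data module generates all the inputs the pipeline consumes with
known peak positions, dynamics, regulation signs, motif implants, Tfb
distances and growth rates.

# Probe normalization

Two stages, in fixed order.

**Within array.** A degree-1 loess of the log ratio against a predictor is
fitted and subtracted. When a per-probe total-intensity channel is present
its rank is the predictor; synthetic data carry no intensity channel, so
genomic probe order is used instead. Observation weights are the
reciprocal of a kernel-density estimate of the predictor, which
down-weights densely populated stretches of the predictor axis. The span
(default 0.3) is exposed; with ~3000-5000 probes the trend window is far
wider than a binding peak (~10 probes), so peaks are not absorbed into the
trend.

**Across arrays.** Quantile normalization maps every array onto the mean
of the per-array order statistics; tied values receive the mean of their
target quantiles (this keeps the map rank-preserving, and makes the
operation exactly idempotent on tie-free data). By default the quantile
step pools only the replicate arrays *within* each time point. This is a
deliberate choice: occupancy genuinely changes between time points in a
dynamic experiment, and forcing a single distribution onto all conditions
redistributes enrichment across time points. The effect is negligible when
bound probes are a tiny fraction of the array, but on a compact synthetic
genome (where planted peaks can cover >5 % of probes) pooling measurably
reorders within-trajectory amplitudes. `normalize_arrays(quantile_scope =
"all")` restores full pooling. Dye-swapped arrays are sign-flipped before
either stage.

# Peak calling

A binding event appears on the tiling array as a kernel-shaped enrichment
profile. The kernel is parametric — Gaussian by default, with
`kernel(0) = 1`, scale `width` (the Gaussian standard deviation is
`width/2`; default width 150 bp) and truncation half-width `support`
(default `3 * width`).

Deconvolution is sparse and nonnegative: candidate centers live on a grid
three times finer than the probe spacing; greedy forward selection
repeatedly adds the candidate whose single-peak fit most reduces the
residual sum of squares (computed in one pass per grid phase by
cross-correlating the residuals with the kernel), then refits all selected
amplitudes jointly by nonnegative least squares. Selection stops when the
best incremental amplitude falls below `min_amplitude` (default 0.5 log2
units) or `max_peaks` is reached. Noiseless planted peaks are recovered at
grid resolution with amplitude error below 1e-6.

Significance is by residual bootstrap: model residuals are resampled with
replacement onto the probe grid `n_boot` times; the null statistic is the
maximum nonnegative single-peak amplitude over the grid; each peak's
p-value is `(1 + #[null >= amplitude]) / (1 + n_boot)`. The add-one form
keeps p-values away from zero and monotone in amplitude; under pure-noise
signals the resulting p-values are verifiably super-uniform. Each
(replicon, replicate, time point) array is processed independently, with a
per-array seed derived from the run seed.

# Peak-to-gene assignment and occupancy profiles

A peak is assigned to every non-redundant gene whose translation start is
within 250 bp (inclusive, either side) of the peak center — archaeal
transcripts are commonly leaderless, so peaks may sit atop the start
codon, and one intergenic peak may serve two divergently transcribed
genes.

Evidence combines in two stages, both using Fisher's combined probability
test (`X = -2 * sum(log p)` against chi-square with 2k degrees of
freedom): first across replicates within a binding locus (peaks whose
centers lie within 100 bp single-linkage), then across loci of the same
gene; intensities are averaged at each stage. A gene is retained when its
composite p-value beats `alpha = 0.05` at one or more time points; time
points that fail are set to zero intensity, which encodes "no binding
detected" in the trajectory itself. Retained genes propagate their profile
unchanged to other members of the same operon (the best-evidence retained
gene of an operon acts as the source). The order replicates-then-loci is a
package decision (the two-stage combination is symmetric in the evidence
it sees; the alternative order is a one-line change and is noted as
configurable).

# Dynamics and integration with expression

Occupancy trajectories are clustered with complete-linkage agglomeration
on the dissimilarity `1 - Spearman`, cut at `k = 4`. Four is the number of
archetypal stress responses the generator plants (bound-then-lost;
lost-then-restored; gained-under-stress; variable), and matches the number
of dynamic patterns such time courses typically exhibit; `k` is exposed.
Cluster numbers are matched to archetypes by exhaustively assigning
scaled cluster means to scaled archetype templates (4! = 24 assignments,
minimum total squared distance).

The GE-ChIP statistic `Cs` is the Spearman rank correlation between a
gene's occupancy vector and its replicate-averaged expression vector on
the shared time grid, computed separately for the parent and the
regulator-knockout genotype. With four time points and no ties `Cs` lives
on the lattice {-1, -0.8, ..., 0.8, 1}. Genes with `Cs >= 0.6` are called
activated, `Cs <= -0.6` repressed (both thresholds inclusive), otherwise
unclassified. Constant profiles have no rank ordering: their `Cs` is NA
and they are excluded (flagged) rather than coerced to zero. The
parent-versus-knockout shift of `Cs` within the activated (or repressed)
class is tested with Student's t-test, unpaired equal-variance by default
(a paired variant is available since the gene sets are matched).

Note an honest property of the 4-point statistic: under independence the
*mean absolute* Spearman correlation at n = 4 is ~0.45-0.5, not 0.
"Knockout correlations trend toward 0" therefore means the signed values
center on zero and `|Cs|` collapses to the permutation-null level, far
below the coupled parent's ~0.9 — which is what the tests assert.

# Motif discovery

Search windows are 250 bp either side of each binding locus. The model is
a two-component mixture over every fixed-width subsequence of the windows
on both strands: a position weight matrix (PWM) versus a mononucleotide
background estimated from the windows themselves (strand-symmetrized).
A uniform background would be wrong at 67 % G+C. The prior admits any
number of sites per window.

Expectation-maximization is seeded deterministically from enumerated
7-mers ranked by Poisson surprise (observed count against its
composition-expected count — a plain ratio would promote rare AT-rich
words that appear twice by chance), each tried at every offset inside the
motif window; the best few one-step starts are run to convergence.

Two refinements matter for palindromic, internally repetitive motifs:

* **Overlap suppression.** Within each window only the locally maximal
  responsibility inside one motif width (across both strands, compared in
  forward coordinates) survives each E-step. Without this the
  any-number-of-repeats model blends phase-shifted alignments of the
  repeat unit into a smeared PWM. Ties among saturated responsibilities
  break on the site's own sequence content, so results are invariant to
  window order and to reverse-complementing the input.
* **Shift refinement.** After convergence the claimed site set is
  realigned by a small global offset (±5 bp), keeping the phase with the
  highest background-relative information content — the classic column
  shifting move. A residual one-off-phase solution remains possible for a
  zero-entropy implant whose flanking base happens to co-vary with the
  selected sites; this is a known limitation and shows up as a shifted
  consensus in a small fraction of seeds.

The mixture log-likelihood is evaluated each iteration and the run stops
as soon as it fails to improve, so the recorded objective trace is
non-decreasing by construction. Consensus rendering writes `n` for
columns whose maximal base probability is below 0.5. Motif significance
is a paired, one-sided Wilcoxon signed-rank test of per-window best
log-odds scores against per-window mononucleotide-shuffled copies; for 15
or fewer non-zero differences the signed-rank tail is enumerated exactly
(ties in |difference| make the asymptotic approximation inaccurate
exactly where small-sample exactness matters). Genome scanning reports
occurrences above a log-odds threshold with the signed distance from the
occurrence midpoint to the nearest translation start (upstream negative).
Palindromicity is the fraction of positions whose base complements the
mirrored position (strings; `n` matches anything) or the mean mirrored
shared probability mass (PWMs).

# Co-binding geometry

A gene is co-bound when a sequence-specific site and a Tfb site each lie
within 250 bp of its translation start and within 250 bp of each other.
The signed RosR-to-Tfb distance is negative when the sequence-specific
site is upstream of the Tfb site in the gene's orientation.

The distance-activity analysis slides a 50-bp window in 5-bp steps over
|distance| up to 250 bp; within each window it computes Spearman's
correlation between signed distance and the gene's GE-ChIP activity and
an empirical permutation p-value (activities permuted within the window,
`(1 + #[|Cs_perm| >= |Cs|]) / (1 + n_resample)`, two-sided on |Cs|). A
reference series replaces the actual activities with draws from a normal
distribution with the same mean, standard deviation and count — a
sanity curve, not the significance null. One caveat is inherent to the
empirical p: windows with enough sign-consistent pairs all saturate at
the add-one floor `1/(1 + n_resample)`, so under a uniformly planted
effect the -log10 p series attains its maximum over a plateau that
contains the planted distance mode rather than at a unique interior
point; reports therefore quote the plateau midpoint alongside the
|distance| histogram mode.

Enrichment and overlap questions (functional categories of bound genes,
agreement with an externally predicted target list) use the upper-tail
hypergeometric test against the genome-wide background; category tables
report unadjusted p-values with optional Benjamini-Hochberg adjustment.

# Growth phenotypes

Growth rates are the least-squares slope of log2(OD600) against time
during the detected log phase, in doublings per hour. Detection is the
longest contiguous window of at least 5 samples reaching R² >= 0.95 with
a positive slope, after excluding samples above 70 % of the curve maximum
(the approach to stationary phase bends the curve while still passing a
loose linearity check, biasing slopes downward; a literal "best R²"
window rule instead picks short, luckily-linear noise stretches). Both
thresholds are arguments. Stress ratios divide each stressed replicate's
rate by the matched unstressed replicate of the same strain; strain
differences in ratio are tested with a two-sample t-test.

# The synthetic study and what it does (not) emulate

The generator plants, per replicon: non-overlapping genes (600-1200 bp)
with strands, operons and translation starts; a random sequence at 67 %
G+C; binding sites within 250 bp of translation starts, mutually
separated by two kernel widths; per-site dynamic archetypes in
proportions 88:90:29:45 (the relative sizes of the four occupancy
clusters such stress time courses produce); base amplitudes uniform on
[1.5, 2.5] log2 units against probe noise of sd 0.5 — signal-to-noise 4
at the detection floor; expression that is a signed, standardized
monotone transform of occupancy in the parent (sign +1 activated, -1
repressed) and pure noise in the knockout; a 20-bp imperfect palindrome
implanted in a configurable fraction of promoters with its midpoint 18 bp
upstream of the start codon, sampled from a PWM with 0.9 consensus-base
probability by default; one to three Tfb sites per planted site at
|distance| mode 70 bp (sd 15), signed so activation pairs with the
sequence-specific site upstream; and OD600 curves `OD0 * 2^(rate t)` with
a plateau and 5 % multiplicative noise, sampled every 30 min, for a
parent and a stress-sensitive mutant at 0/5/6 mM peroxide.

Deliberately *not* emulated: dye bias and spatial array artifacts
(normalization is still exercised, but not against these specific
failure modes), sequence-dependent probe affinity, autocorrelated or
heavy-tailed probe noise, transcription-to-binding time lags, and probe
cross-hybridization. Passing the recovery tests shows the pipeline's
inferential machinery is correct under its stated noise model, not that
real arrays meet that model.

Default problem sizes (a 150-kb replicon, 100 genes, 40 sites, 3x3
replicate arrays, 4 time points) were chosen so a full synthetic run
completes in a few minutes on one core while keeping >100 probes per
planted site; tests use the same machinery at reduced sizes.

# Numerical choices and determinism

All randomness in a pipeline run derives from one seed; each stage's seed
is a fixed function of it, so stages are independently reproducible, and
two runs with the same configuration produce byte-identical outputs and
manifests. Fisher combination clamps p = 0 to the smallest double with a
warning. Bootstrap and permutation p-values use add-one estimators.
Greedy tie-breaks are deterministic everywhere (first maximal candidate in
deconvolution; lowest member index in clustering via the standard
agglomeration order; content keys in motif suppression). Quantile
normalization averages tied target quantiles. Peaks with zero refitted
amplitude are dropped.

# Known limitations

* The deconvolution assumes a homogeneous, known kernel family;
  widths are not learned per peak (a mismatched simulation kernel is
  supported for robustness testing).
* Edge probes within one kernel support of a replicon end have truncated
  candidate coverage.
* Motif discovery at zero entropy can lock onto a one-base-shifted phase
  for some seeds (see above).
* The distance-activity permutation p floors at `1/(1 + n_resample)`,
  limiting resolution between strongly associated windows.
* Operon propagation assumes operon membership is given; it does not
  infer transcription units.
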