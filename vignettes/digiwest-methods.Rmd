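---
title: "Methods: bead-based digital western quantification and tumor classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bead-based digital western quantification and tumor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the pipeline computes

DigiWest is a bead-based digital western blot: size-separated, blotted and
biotinylated proteins are eluted from 96 membrane strips onto color-coded
beads, so each antibody readout is a 96-point fluorescence trace over a
calibrated molecular-weight axis. This package implements the complete
analysis chain for a five-class tumor tissue-of-origin study on such data:

1. **Simulation** of paired fresh-frozen (FF) / formalin-fixed
   paraffin-embedded (FFPE) cohorts with planted ground truth
   (`generate_cohort()`, `generate_validation_cohort()`);
2. **Quantification** of traces into analyte signals: peak detection,
   local-background-subtracted area integration, molecular-weight band
   assembly (`detect_peaks()`, `quantify_peak()`, `build_signal_matrix()`);
3. **Antibody selection** by FF/FFPE concordance: detection filtering,
   per-signal Pearson correlation with Benjamini–Hochberg (BH) correction,
   best-signal retention, shift and artifact exclusions
   (`correlate_ff_ffpe()`, `select_panel()`);
4. **Descriptive statistics**: average-linkage clustering on
   correlation distance, pairwise pooled-sd t-tests
   (`hierarchical_cluster()`, `pairwise_ttests()`);
5. **Classification**: RBF-kernel SVM with repeated nested
   cross-validation, class-merging re-scores, a final model and
   independent-cohort prediction with calibrated class probabilities
   (`nested_cv()`, `train_final()`, `predict_cohort()`).

The `analysis/` scripts run these stages in order on the default synthetic
study; `run_pipeline()` composes them in one call with a manifest.

## The generative model

Every tunable lives in `cohort_config()`. The latent abundance of antibody
$a$ in sample $s$ is, on the log2 scale,

$$\log_2 A(s,a) = b_a + \delta_a[\mathrm{type}(s)] + u_s + \varepsilon_{sa},$$

with a per-antibody baseline $b_a \sim N(9, 1.4^2)$ (so amplitudes span
roughly 60–4000 RFU), a planted tumor-type effect $\delta_a$, a per-sample
random effect $u_s \sim N(0, 0.75^2)$ and residual noise
$\varepsilon_{sa} \sim N(0, 0.8^2)$. A trace is the baseline level (30 RFU)
plus Gaussian bands in strip index (sd 2 strips) centred at the strip
nearest the antibody's expected molecular weight times its shift factor,
plus i.i.d. noise (sd 12 RFU), clipped at zero. Strips — not kilodaltons —
are the physical sampling unit, which is why the band shape is Gaussian in
strip index.

**FFPE degradation.** Concordant antibodies (a third of the panel by
default, mirroring the roughly one-third survival rate of real
fixation-tolerant epitopes) reuse the FF latent abundance, multiplied by a
per-antibody attenuation factor drawn uniformly from 0.25–0.8 and blurred
by extra $N(0, 0.45^2)$ log2 noise. Non-concordant antibodies redraw their
FFPE abundance independently with no tumor-type structure: fixation
destroyed the epitope, so whatever the antibody binds in FFPE material is
unrelated to the FF signal. Under these defaults the selected panel is
detected in about 23.6 of 25 FF samples versus 21.2 of 25 FFPE samples,
with uniformly lower FFPE intensities — the qualitative regime the method
is designed for. No quantitative attenuation distribution is available for
real material, so these values were fixed once from that regime and are not
revisited per experiment.

**Marker geometry.** Forty percent of antibodies carry a planted effect of
$N(2.5, 0.5^2)$ log2 units. Effects follow tumor lineage: 55% mark a
single type, and the rest mark the squamous pair (HNSC+LUSC), the lung
pair (LUSC+LUAD) or the adenocarcinoma triple (LUAD+COAD+PAAD). Closely
related classes are therefore separable by fewer antibodies than distant
ones, so FFPE noise erodes exactly the distinctions (LUSC vs LUAD above
all) that are hardest in real cohorts.

**Cross-reaction artifact.** Every HNSC sample carries an additive band at
a per-sample uniform position in 47–53 kDa — the secondary-antibody
cross-reaction — with independent amplitudes per preservation, stronger in
FF (350 vs 120 RFU times log-normal jitter). Because the band appears in
both preservations of the same tumors, any antibody whose specific band can
merge with it acquires a spurious FF/FFPE correlation; this is why the
selection stage excludes, a priori, all antibodies whose expected molecular
weight falls within the artifact window widened by the band-merge distance
(`crossreaction_excludes()`, ±18%). With a log-uniform molecular-weight
panel this removes ~45–50 of 300 antibodies — proportionally more than a
real panel would lose, since real target weights are not uniform around
50 kDa.

**Seeding.** One global seed expands into per-(sample, antibody) substreams
through a stable polynomial hash (`substream_seed()`), so any entity's
numbers are independent of generation order and cohorts are byte-identical
across reruns.

## Quantification choices

* Molecular weight is calibrated log-linearly in strip index through ladder
  anchors, decreasing with strip index (gel-top convention); the default
  axis spans 250 down to 10 kDa.
* Peaks are strict local maxima, extended to their nearest flanking minima;
  apexes closer than 3 strips merge into the higher one. Noise is estimated
  as `mad(diff(trace))/sqrt(2)`, and peaks must reach a signal-to-noise of
  3 above the local background. These thresholds are exposed because the
  underlying instrument software does not document its merging rules; ours
  are a documented choice, not a reconstruction.
* The local background is a linear bridge between the intensities at the
  peak bounds; the area is the sum of intensities above the bridge, clipped
  at zero. This makes areas exactly invariant to additive offsets and
  exactly linear in trace scale — both properties are tested.
* Peaks are grouped across samples into molecular-weight bands by 1-D
  single linkage (a gap wider than 3 strips starts a new band); each band
  becomes one signal row, so antibodies with several bands contribute
  several analytes. Signals are ranked per antibody by closeness to the
  expected molecular weight.
* A signal counts as detected in a sample when its background-subtracted
  area exceeds the detection floor (400 RFU·strips by default). A band
  shifted more than 20% from the expected weight is flagged; the tolerance
  is inclusive at exactly 20%.

## Selection choices

Correlations use complete pairs only (samples detected in both
preservations), since Pearson's r is undefined with missing values; signals
with fewer than 3 complete pairs or zero variance are reported untested.
Significance is assessed with `cor.test` two-sided p-values, BH-adjusted
across all tested signals (the family could also be antibodies; signals is
the default and configurable). Per antibody, only the signal with the
highest correlation survives, ties broken by smaller shift and then signal
id for determinism. Shift-flagged and manually QC-flagged signals are then
dropped; unclear-peak flags are an input, not auto-inferred.

## Statistics choices

Clustering uses distance $1 - r$ between sample profiles
(pairwise-complete) with average linkage; zero-variance profiles get the
maximal distance 2 with a warning. Leaf order is deterministic:
smaller subtree first, ties by smallest leaf label. Pairwise t-tests pool
the standard deviation across all tumor types (the default of the standard
`pairwise.t.test`), dropping groups with fewer than two non-missing values
— a one-observation group has no within-group variance and would poison the
pooled estimate. BH correction is applied per tumor-type pair across the
panel (one family per heatmap row); a global family is available via
`bh_scope = "global"` since the choice is genuinely open.

## Classification choices

The kernel is $k(x,y) = \exp(-\sigma\|x-y\|^2)$ with $\sigma$ multiplying
the squared distance, so grid values like $10^{-4}$ are meaningful on
~75-dimensional standardized profiles. Grids are $C \in 10^{0..3}$ and
$\sigma \in 0.01\times10^{-3..3}$; the engine is libsvm via e1071, whose
`gamma` uses the same convention. The nested design is five outer folds
repeated ten times with four inner folds repeated five times; with five
samples per class and five outer folds, every fold holds exactly one sample
per class. Imputation (missing signals to the training minimum minus one
log2 unit by default) and per-feature standardization are fitted inside
each training split only — never on held-out samples — and the test suite
audits this through an instrumented access log. Hyperparameter ties go to
the smallest $C$, then the smallest $\sigma$ (prefer the least complex
model, deterministically). Overall accuracy is sample-weighted; its spread
is the standard deviation across the ten outer repeats.

Class probabilities come from per-pair Platt sigmoids fitted on the
training decision values by regularized maximum likelihood and combined by
pairwise coupling (the same coupling scheme libsvm uses). Fitting the
sigmoids directly on training decision values — rather than on internal
cross-validated values — keeps the whole model deterministic under the
package seed; on small, well-separated training sets such sigmoids are
steep and probabilities saturate, which is why the predicted label is
always the SVM vote and the probability vector is reported alongside.
Merging classes (e.g. both lung carcinomas into one organ class) re-scores
the averaged contingency matrix by summing rows and columns; per-repeat
matrices are not retained, so a merged report has no repeat-wise spread.

## Problem sizes used by the tests

The packaged checks run the full study geometry — 300 antibodies, 25 paired
samples, 25 validation samples — for simulation, quantification and
selection (ten replicate seeds), and the published nested-CV design for the
headline accuracy runs in `scripts/acceptance.R`. The repeated regime
checks in the test suite (separability, label permutation, FF vs FFPE,
validation drift) use two outer repeats and one inner repeat over the full
hyperparameter grid: the regime these checks probe is a property of the
data-generating process, not of the repeat count, and the reduced design
keeps ten-replicate checks at a few minutes. The global-null calibration
uses twenty 150-antibody cohorts for the same reason.

## What passing tests do and do not show

The generator reproduces the structural features the pipeline exercises:
paired design, FFPE attenuation and drop-out, multiple and shifted bands,
a cross-reacting artifact band, lineage-structured markers. It does not
model electrophoresis physics, blotting or bead chemistry, antibody
cross-reactivity beyond the single artifact, batch effects, or tumor-cell
content dilution. Recovery results on synthetic cohorts therefore validate
the statistical machinery — not the wet-lab performance of any antibody
panel. Real-data counts (e.g. how many antibodies survive selection) will
differ because real molecular weights, abundances and fixation effects are
not uniform.

## Known limitations

* Peak bounds stop at the first flanking minimum; heavily overlapping bands
  are merged rather than deconvolved (deconvolution is out of scope).
* Plateau apexes (exactly equal neighbouring intensities) are not detected
  as peaks; with continuous noise this has probability zero.
* The a-priori artifact exclusion is driven by expected molecular weight;
  an antibody whose *observed* band drifts into the artifact window from a
  distant expected weight is instead caught by the shift filter.
* `merge_class_report()` recomputes accuracies from the averaged matrix;
  repeat-level spread is unavailable after merging.
* Probability calibration on perfectly separated small training sets is
  saturated; probabilities are then informative only near class boundaries.
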