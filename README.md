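# digiwest

Tumor tissue-of-origin classification from bead-based digital western blot
(DigiWest) profiles, as a tested end-to-end pipeline.

DigiWest size-separates proteins on a gel, blots and biotinylates them, then
cuts each lane into 96 membrane strips whose eluates bind color-coded beads —
so each antibody × sample measurement is a 96-point fluorescence trace over a
calibrated molecular-weight axis. Routine pathology archives tissue as
formalin-fixed, paraffin-embedded (FFPE) blocks, but fixation cross-links
proteins and destroys many epitopes; a classifier that is to run on clinical
material must therefore be built on the antibodies whose signals survive
fixation. This package implements that workflow for five carcinoma types
(HNSC, LUSC, LUAD, COAD, PAAD):

1. **Trace quantification** — peak detection on each trace, area integration
   above a local linear background, molecular-weight band assembly, with a
   ±20% band-shift flag against each antibody's expected weight.
2. **Antibody selection** — a-priori exclusion of the 47–53 kDa
   secondary-antibody cross-reaction window, a detection filter (≥ 4 samples
   or a full tumor type), per-signal Pearson correlation between log2
   fresh-frozen and FFPE signals across paired tumors, Benjamini–Hochberg
   correction (panel kept at *p*-BH < 0.05), best-signal retention per
   antibody.
3. **Descriptive statistics** — average-linkage clustering of samples on the
   distance `1 − r`, pairwise pooled-sd t-tests between tumor types per
   antibody with per-pair BH correction.
4. **Classification** — RBF-kernel SVM, `k(x,y) = exp(−σ‖x−y‖²)`, tuned over
   `C ∈ 10^{0..3}` and `σ ∈ 0.01·10^{−3..3}` by nested cross-validation
   (5-fold outer × 10 repeats, 4-fold inner × 5 repeats), averaged
   contingency matrices, organ-level class merging, a final FFPE model and
   independent-cohort prediction with pairwise-coupled Platt probabilities.

Because no patient-level DigiWest dataset is public, the package ships a
first-class synthetic cohort generator (`generate_cohort()`) that emulates
the study design — 25 paired FF/FFPE primary tumors (five per type), an
independent 25-sample FFPE validation cohort, ~300 antibodies of which a
planted subset is fixation-concordant, FFPE signal attenuation and drop-out,
shifted and secondary bands, and the HNSC cross-reaction artifact — with full
ground truth for every planted property.

## Worked example

The numbered scripts under `analysis/` run the whole study as a narrated
workflow and write every table under `results/`; everything they call is an
exported package function (`run_pipeline()` composes the same stages in one
call):

```sh
Rscript analysis/01_simulate.R    # traces, metadata, ground truth
Rscript analysis/02_quantify.R    # signal matrices (TSV + JSON sidecar)
Rscript analysis/03_select.R      # concordance screen, volcano table
Rscript analysis/04_stats.R       # clustering (Newick), pairwise t-tests
Rscript analysis/05_classify.R    # nested CV, final model, validation
```

With the default seed (17) the drivers print:

```
seed 17: 25 paired samples + 25 validation samples, 300 antibodies
planted concordant antibodies: 100
ff: 587 signals from 300 antibodies; 59.2% of entries detected
ffpe: 569 signals from 300 antibodies; 49.6% of entries detected
a-priori cross-reaction exclusions: 52 antibodies
detectable in >= 4 samples or a full tumor type: 287 antibodies
<dw_selection>
  239 antibodies -> 234 tested -> 81 significant -> 75 kept
  dispositions: kept=75, not_detected=5, not_significant=153, shifted=6
...
ff nested CV: 88.8% overall accuracy (sd 3.2% over 10 repeats)
ffpe nested CV: 79.2% overall accuracy (sd 3.7% over 10 repeats)
<dw_svm_model> C = 1000, sigma = 0.0001, 75 features, 5 classes (CV accuracy 84.4%)
validation cohort: 84% accuracy (21 of 25)
```

Reading these numbers: of 300 antibodies, 75 survive the concordance screen
(the planted truth contains 100 concordant ones, some of which fall in the
excluded cross-reaction window or below the FFPE detection floor);
fresh-frozen profiles classify better than FFPE under the planted
attenuation and noise (88.8% vs 79.2%); and the final model trained on all
25 FFPE samples generalizes to the independent cohort (84%). The
`results/` tables carry the underlying contingency matrices, per-pair
p-value tables, the volcano table and per-sample class probabilities.

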