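# msnetvar

Spatiotemporal variability of microstate-segmented dynamic EEG brain
networks, with a fixed-classifier comparison harness and group statistics.

## The problem

Resting-state EEG alternates among a small number of quasi-stable scalp
topographies — *microstates*, canonically labeled A–D — each lasting tens of
milliseconds. Dynamic functional-connectivity analyses usually chop the
recording into arbitrary fixed sliding windows; segmenting at microstate
boundaries instead yields windows that each correspond to one transient,
physiologically meaningful brain state. `msnetvar` implements that idea end
to end for people studying disease-related changes in brain-network
dynamics (the motivating application is early Parkinson's disease vs.
healthy controls):

1. **Preprocessing** — zero-phase 2–20 Hz FIR band-pass, common average
   reference (`bandpass_fir()`, `average_reference()`); EDF and delimited
   matrix I/O (`read_recording()`, `write_recording()`).
2. **Microstate segmentation** — global field power
   `GFP(t) = sqrt( (1/n) Σ_i [u_i(t) − ū(t)]² )`, peak-map extraction,
   polarity-invariant modified K-means clustering into k = 4 template maps,
   canonical A–D ordering, and backfitting by maximal absolute spatial
   correlation (`compute_gfp()`, `fit_microstates()`, `backfit()`).
3. **Connectivity** — instantaneous phase by the analytic signal, and the
   phase lag index per window
   `PLI_ij = | ⟨ sign( sin(φ_i(t) − φ_j(t)) ) ⟩ |`,
   an index in [0, 1] that ignores zero-lag (volume-conduction) coupling.
   Network sequences come in three schemes (`build_networks()`): fixed
   sliding windows (SN), microstate windows (MN), and microstate windows
   split by class (MCN).
4. **Variability statistics** — per channel i over a sequence of v networks
   (`temporal_variability()`, `spatial_variability()`, `variability_profile()`):
   - temporal: `T_i = 1 − (1/(v(v−1))) Σ_{p≠q} corr(F_p(i,:), F_q(i,:))`
     — instability of channel i's whole connection profile across windows;
   - spatial: `S_i = 1 − (1/((n−1)(n−2))) Σ_{j≠h; j,h≠i} corr(F_s(i,j), F_s(i,h))`
     — desynchronization among the time courses of channel i's individual
     connections (for 19 channels the normalizer is 1/(18×17)).
5. **Classification & statistics** — linear-SVM repeated stratified
   cross-validation over the three feature sets (`cross_validate()`,
   5 folds × 10 repeats = 50 trials; accuracy, sensitivity, specificity,
   F1, AUC), channel-wise pooled t-tests with Benjamini–Hochberg FDR and
   direction/tier flags (`topographic_group_map()`,
   `whole_brain_comparison()`), and Spearman correlations with clinical
   scores (`clinical_correlation_map()`).
6. **Synthetic data** — `generate_recording()` / `generate_cohort()` build
   recordings with known microstate sequences and switchable per-class
   phase-coupling patterns, so every stage is testable without clinical
   data and group effects can be injected with known direction.

## Worked example

```r
library(msnetvar)

# a small synthetic two-group cohort: patients switch class-B coupling
# patterns twice as fast and class-C patterns half as fast as controls
ctrl <- synth_config(duration = 30)
pat  <- synth_config(duration = 30,
                     group_effects = list(switching = c(B = 2, C = 0.5)))
coh  <- generate_cohort(ctrl, pat, n_control = 10, n_patient = 10, seed = 1)

res <- cohort_variability(coh$recordings, schemes = "MCN", band = NULL,
                          n_init = 5, min_window = 10)
whole_brain_comparison(res$profiles$MCN, statistic = "temporal")
```

prints (t is control minus patient, so a negative t means the patient group
is higher):

```
  statistic class mean_control sd_control mean_patient sd_patient      t       p  p_adj   tier
1  temporal     A        0.776     0.0750        0.734     0.0834  1.158 0.26193 0.3492     ns
2  temporal     B        0.721     0.0821        0.818     0.0574 -3.038 0.00708 0.0283 p<0.05
3  temporal     C        0.781     0.0377        0.695     0.1170  2.224 0.03922 0.0784     ns
4  temporal     D        0.741     0.1344        0.765     0.0808 -0.477 0.63904 0.6390     ns
```

The injected effects are recovered with the right signs: class-B temporal
variability is higher in patients (negative t, FDR-significant), class-C
lower (positive t), and the uninjected classes A and D stay null; a 10+10
cohort of 30-second recordings is deliberately small, so class C here shows
the right direction without clearing the FDR threshold. Feeding the
same profiles to `build_feature_table()` + `cross_validate()` compares the
SN / MN / MCN schemes with the identical SVM protocol.

A thin CLI wraps the same functions for shell use:
`exec/msnetvar simulate|build-networks|variability|classify --help`.

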