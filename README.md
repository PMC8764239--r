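# tinnconn

Connectivity-feature analysis and classification of resting-state EEG for
objective recognition of tinnitus laterality.

## The problem

Chronic subjective tinnitus has no objective clinical test: diagnosis rests
on questionnaires and audiometry. Resting-state EEG offers a candidate
biomarker — tinnitus is associated with abnormal oscillatory coupling
between auditory cortical areas, and the *pattern* of that coupling differs
with the perceived location of the tinnitus (left ear, right ear, or both).
`tinnconn` implements the full analysis chain for testing that idea: from
multichannel EEG over the left and right auditory cortex (12 electrodes of
the 10–20 system: FT7, FC5, C5, T7, TP7, CP5 and FC6, FT8, C6, T8, CP6,
TP8) to per-epoch functional-connectivity features, cross-validated
classification of four groups (healthy / bilateral / left-sided /
right-sided), and group-level statistics on the connectivity matrices.

Because clinical recordings cannot be redistributed, the package ships a
first-class synthetic-data generator whose class-conditional connectivity
structure is controlled knob by knob, so every stage of the pipeline is
testable end to end without any download.

## The statistics at the core

For two channel signals \(x_i, x_k\) over an epoch of \(T\) samples, with
instantaneous phases \(\varphi_i^t\) (angle of the analytic signal) and
band-limited analytic signals \(Z_i(t)\):

* **PLV** (phase-locking value):
  \(\mathrm{PLV} = \bigl|\tfrac1T\sum_t e^{j(\varphi_i^t-\varphi_k^t)}\bigr|
  \in [0,1]\) — 1 for a constant phase relation, 0 for none.
* **PLI** (phase lag index):
  \(\mathrm{PLI} = \bigl|\tfrac1T\sum_t \operatorname{sgn}
  \operatorname{Im}(Z_i(t) Z_k(t)^*)\bigr| \in [0,1]\) — consistent
  *non-zero* lag; insensitive to zero-lag (volume-conduction) coupling.
* **PCC** (Pearson correlation):
  \(\tfrac1T\sum_t (x_i^t-\mu_i)(x_k^t-\mu_k) / (\sigma_i\sigma_k)
  \in [-1,1]\).
* **TE** (transfer entropy), histogram plug-in estimate in bits:
  \(\mathrm{TE}(i\to k) = \sum p(x_i^t, x_k^t, x_k^{t+1})
  \log_2 \frac{p(x_k^{t+1}\mid x_i^t, x_k^t)}{p(x_k^{t+1}\mid x_k^t)}\)
  over equal-width amplitude bins — a *directed* measure.

Per epoch, an undirected measure on 12 channels gives a 66-length feature
vector (the upper triangle); TE gives 132 directed entries. Comparison
features: per-band mean/SD of the six EEG rhythms (δ 1–3.5, θ 4–7.5,
α 8–12, β 12.5–30, low-γ 30.5–48, high-γ 52–90 Hz; 144 values) and Welch
band power (72 values). Classifiers: linear SVM under leave-one-out and
stratified 10-fold CV, a two-hidden-layer (200/200) MLP trained with Adam,
and a CNN-LSTM stack — all implemented in-package. Group analysis:
per-channel-pair Welch-*t* difference maps, one-way ANOVA /
Kruskal–Wallis over repeated evaluations, and channel clustering by
classical MDS of the connectivity matrix (the "multidimensional cluster
statistics" view).

## Worked example

```r
library(tinnconn)

# simulate four groups (healthy / bilateral / left / right), 200 s each
cfg <- sim_config(sampling_rate = 250, duration = 200,
                  recordings_per_class = 1, seed = 7)
ds  <- make_labeled_dataset(cfg, build_class_templates("default"))
length(ds$epochs)
#> [1] 80

# per-epoch Pearson-correlation connectivity, flattened to 66 features
feats <- extract_features(ds$epochs, "pcc")
dim(feats$x)
#> [1] 80 66

# cross-validated classifiers, 3 repeats
res <- repeated_evaluation(feats$x, feats$labels, feature_name = "pcc",
                           classifiers = c("svm_10cv", "mlp"),
                           n_repeats = 3, seed = 7)
results_table(res)
#>   feature classifier mean_accuracy sd_accuracy mean_time_s n_repeats n_train n_validation
#> 1     pcc   svm_10cv      99.16667   0.7216878   0.1213333         3      72            8
#> 2     pcc        mlp      94.44444   2.4056261   0.1493333         3      56           24
```

The four synthetic classes are nearly perfectly separable from 66
correlation values per 10-s epoch: the class templates differ in which
channel pairs are coupled, and PCC reads that structure directly. Chance
level would be 25 %.

```r
# channel clustering of the healthy group's mean PLV matrix
healthy <- ds$epochs[feats$labels == "healthy"]
mats <- lapply(healthy, connectivity_matrix, measure = "plv")
mean_plv <- Reduce(`+`, lapply(mats, unclass)) / length(mats)
cluster_channels(mds_embed(mean_plv), threshold_fraction = 0.35)$cluster
#> FT7 FC5  C5  T7 TP7 CP5 FC6 FT8  C6  T8 CP6 TP8
#>   1   2   2   3   2   4   2   1   2   3   4   2
```

The healthy template couples the three homologous interhemispheric pairs
FT7–FT8, T7–T8 and CP5–CP6; the clustering recovers exactly those pairs
(ids 1, 3 and 4) against the background cluster (id 2) of uncoupled
channels.

## Command line

```sh
Rscript inst/cli/tinnconn run      --config cfg.json --out run_dir
Rscript inst/cli/tinnconn simulate --out sim_dir --edf
Rscript inst/cli/tinnconn classify --features pcc,plv --models svm_10cv,mlp \
                                   --repeats 10 --seed 1 --out run_dir
```

Exit codes: 0 ok, 2 input error, 3 configuration error.

## Layout

* `R/` — simulation, preprocessing, connectivity estimators, features,
  classifiers, group statistics, pipeline.
* `src/` — Rcpp dual-coordinate-descent solver for the linear SVM.
* `tests/testthat/` — unit, property and acceptance tests (independent
  brute-force oracles live in `helper-tinnconn.R`).
* `vignettes/tinnconn-methods.Rmd` — the methods notes: generative model,
  estimator conventions, numerical choices, limitations.
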