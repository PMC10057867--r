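# pollenoptics

Automatic airborne-pollen monitoring with a low-cost optical particle
counter: simulation and analysis pipeline.

Manual pollen monitoring (Hirst-type traps read under a microscope) delivers
species counts with a delay of days. An alternative is an airflow cytometer
that records, for every particle crossing a laser beam, the light scattered
onto four photodiodes at 15°, 60°, 125° and 160°, as counts in 19 intensity
bins per channel every 10 s. The forward channel sizes the particle through
a power-law calibration `F = a·d^b` (5–100 µm); the three side/back
("speciation") channels are sensitive to shape, surface and absorbance.
This package implements the full discrimination analysis for such an
instrument, together with a synthetic session generator that stands in for
laboratory measurement campaigns:

* **Sizing stage** — local-outlier-factor (LOF) filtering of contaminated
  frames (parameters tuned by silhouette grid search), oversampling of
  frames into cumulative size distributions (≥ 20 particles per occupied
  bin), row normalisation, Hopkins clustering-tendency test, cluster-count
  voting over ten internal validity indices, agglomerative hierarchical
  clustering (Euclidean, complete linkage) and a PCA view.
* **Speciation stage** — for a reference intensity F1 on the sizing
  channel, each speciation channel's curve of counts per logarithmic
  intensity interval is inverted for the intensity F_c carrying the same
  number concentration, `(dN/dF1)·F1 = (dN/dFc)·Fc`; the speciation index
  is `S_c = F1/F_c` and the 6-element optical signature is
  `(S2, S3, S4, S2/S3, S2/S4, S3/S4)`.
* **Classification stage** — per size cluster, one-vs-one logistic
  regression on log-transformed standardised signatures, with per-pair
  decision thresholds tuned to maximise F1 on inner folds, evaluated by
  repeated stratified 10-fold cross-validation (per-class recall and
  confusion matrices).

The synthetic generator emulates measurement sessions for 12 pollen taxa
(lognormal grain sizes at the supplier diameters, species-specific channel
gains, Poisson counting noise) plus droplets, carbonaceous particles and
two mineral dusts, with ambient/aggregate/debris contamination and a
fraction of grossly contaminated frames.

## Worked example

```r
library(pollenoptics)

cfg  <- instrument_config()                   # 4 channels, 19 bins, 5-100 um
prof <- builtin_profiles()                    # 12 pollens + 4 aerosol classes
ses  <- simulate_session(prof[["Olea euopaea"]], contamination_model(),
                         n_frames = 240, cfg = cfg, seed = 11)

v <- session_size_distribution(ses, cfg, mode = "volume")
modal_diameter(v)
#> [1] 26.17943
```

The volume distribution of a contaminated Olea session is bimodal: the
primary mode at 26.2 µm (the bin containing the 25 µm grain diameter) and a
secondary mode near 40 µm produced by pollen aggregates. LOF filtering
removes the grossly contaminated frames and shrinks the aggregate peak.

The full campaign is a sequence of four scripts (set `POLLEN_SEED` to vary
the seed; intermediate tables land under `results/`):

```sh
Rscript analysis/01_simulate_sessions.R   # 16 sessions, frame CSVs
Rscript analysis/02_size_clustering.R     # LOF, 360 x 19 dataset, clusters
Rscript analysis/03_optical_signatures.R  # signature tables
Rscript analysis/04_classification.R      # per-cluster OvO classification
```

Stage 2 prints, for the default seed:

```
Hopkins statistic (mean of 20 draws): 0.993  -- strongly clustered
validity-index vote: k = 7 (votes: 2:2 3:0 4:0 5:0 6:0 7:5 8:3)
k = 3 majority clusters:
  cluster 1 (20-30 um): Alnus glutinosa, Ambrosia artemisiifolia, ...
  cluster 2 (39-45 um): Anthoxanthum odoratum, Festuca pratensis
  cluster 3 (14-14 um): Parietaria officinalis
```

A Hopkins statistic of 0.99 means the cumulative size distributions are
strongly clustered rather than spatially random. The species-to-cluster
assignment is monotone in grain diameter (small / medium / large). Note the
index vote resolves more clusters on synthetic data than the three coarse
size classes seen in laboratory data; the k = 3 cut is reported alongside
as the laboratory reference (see the methods vignette).

Stage 4 prints per-cluster recall, e.g. for the large-size cluster:

```
cluster 2 recall (5x10-fold CV):
  Anthoxanthum odoratum      100.0%
  Festuca pratensis          100.0%
  mineral_concrete           100.0%
```

Under the default generator settings the class signatures are well
separated and recalls saturate; the median indices line up with the
planted optics (e.g. droplets, optically transparent, show a median
S3 of 6.9 ≈ 1/g3 — far outside the pollen range of 1.0–2.2).

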