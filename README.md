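# ivmmotility

Motility analysis for two-photon intravital microscopy (2P-IVM) recordings
of T cells in tumor-invaded tissue — for imaging labs that already have
cell tracks (e.g. Imaris exports) and want reproducible, scriptable answers
to three questions: *how motile is each cell*, *what behavior is it
performing*, and *where in the tumor is the motility concentrated*.

The package implements:

* **Per-track motility statistics.** For a track with positions
  $p_1,\dots,p_n$ at uniform interval $\Delta t$: duration, path length
  $L=\sum_i\lVert p_{i+1}-p_i\rVert$, displacement
  $D=\lVert p_n-p_1\rVert$, mean speed $L/T$, max instantaneous speed,
  straightness $D/L$, speed variation (SD of instantaneous speeds) and
  arrest coefficient (fraction of steps below 2 µm/min). Tracks shorter
  than 5 frames are excluded. Mann–Whitney / t-test comparisons between
  conditions.
* **Behavioral action recognition.** Tracks → 8-point sliding-window
  tracklets → four features per tracklet (mean speed, net displacement,
  directionality, arrest coefficient) → cohort-standardized multivariate
  series → dynamic-time-warping cross-distance matrix → 2-D UMAP
  (precomputed distances) → k-means (k = 5) → deterministic rule mapping
  cluster profiles to the five actions *flowing, directed, patrolling,
  focused patrolling, arrested* → per-condition cluster percentages.
* **Pixel motility over tumor bands.** Dense pyramidal Lucas–Kanade
  optical flow on the timelapse, time-averaged per-pixel magnitude
  min–max-normalized to [0, 1], quantified over concentric equidistant
  bands (default 40 µm) obtained by progressive Euclidean erosion of the
  tumor mask, from periphery (band I) to core.
* **Synthetic ground truth.** A two-state persistent-random-walk simulator
  for the five behavioral archetypes plus a Gaussian-blob timelapse
  renderer and disk tumor masks, used to validate the whole pipeline
  against known labels.

See `vignettes/motility-analysis.Rmd` for the model details and design
decisions.

## Worked example

```r
library(ivmmotility)

co  <- simulate_cohort(n_per_archetype = 40, seed = 42, condition = "untreated")
act <- recognize_actions(co$tracks, seed = 42)
act$profiles
#>   cluster_id mean_speed displacement directionality arrest_coefficient
#> 1          0       8.58       59.228          0.986             0.0535
#> 2          1      15.74      104.137          0.945             0.0113
#> 3          2       0.13        0.658          0.524             0.9946
#> 4          3       1.45        4.955          0.527             0.5762
#> 5          4       4.15       13.828          0.492             0.1935
act$labels
#>                    0                    1                    2
#>           "directed"            "flowing"           "arrested"
#>                    3                    4
#> "focused_patrolling"         "patrolling"
```

Cluster 1 — fastest (15.7 µm/min mean tracklet speed), highly directional,
almost never arrested — is labeled *flowing*; cluster 2, with arrest
coefficient 0.99 and sub-µm displacements, is *arrested*; the remaining
clusters rank into *directed*, *patrolling* and *focused patrolling* by
their composite motility. Against the generator's ground truth the
confusion is 199/200 on the diagonal:

```r
truth <- co$true_labels[match(act$assignments$track_id,
                              vapply(co$tracks, function(t) t$track_id, ""))]
table(predicted = act$assignments$label, truth = truth)
#>                     truth
#> predicted            arrested directed flowing focused_patrolling patrolling
#>   arrested                 40        0       0                  1          0
#>   directed                  0       40       0                  0          0
#>   flowing                  0        0      40                  0          0
#>   focused_patrolling        0        0       0                 39          0
#>   patrolling               0        0       0                  0         40
```

Single-track metrics:

```r
compute_metrics(co$tracks[[1]])
#>      track_id condition n_points duration_s length_um displacement_um
#> 1 flowing_001 untreated       40       2340       587             512
#>   mean_speed_um_min max_speed_um_min straightness speed_variation_um_min
#> 1              15.1             21.8        0.872                   3.46
#>   arrest_coefficient
#> 1             0.0256
```

The full pipeline — filtering, metrics, action recognition and (with a
timelapse + mask) band motility — runs from one call or from the shell:

```r
cfg <- run_config(seed = 1)
run_pipeline(cfg, "tracks.csv", "run_out",
             images_path = "seq.tif", mask_path = "mask.tif")
write_report("run_out")
```

```sh
Rscript inst/scripts/motility-pipeline.R --tracks tracks.csv --out run_out --report
```

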