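# anemowhisk

Quantitative analysis of whisker-mediated wind sensing (anemotaxis) in
rodents, for sensory neurophysiologists and behavioral biologists
working with whisker tracking, follicle morphometry, cortical
recordings and turning-behavior assays.

Facial whiskers differ sharply in their sensitivity to airflow: under
weak wind, a small set of whiskers — above all the long supra-orbital
(lSO) above the eye — shows large tip displacement, while most pad
whiskers barely move. `anemowhisk` implements the full analysis chain
used to characterize such specialization, plus a seeded synthetic-data
generator so every step can be validated end to end with known ground
truth.

## What it computes

- **Kinematics.** Tip displacement from pose-tracking tables
  (DeepLabCut CSV dialect) as the distance to the coordinate-wise
  median position, d_t = sqrt((X − x_t)² + (Y − y_t)²); per-whisker
  summaries (mean ± SEM or median ± IQR) and rank order; tie-corrected
  Kruskal–Wallis omnibus with Dunn or Tukey post hoc; high/low wind
  displacement ratios tested against 1 (signed-rank); ex vivo bending
  angles at 75% of arc length; wind-trace rise times.
- **Morphometrics.** Length/base-diameter ratios, ring-wulst aperture
  angles (largest polar gap about the shaft center), Pearson
  correlations, fold change against the lSO reference, and a
  permutation test comparing the mean within-group variance of six
  spatial arrangements of the pad against a 10,000-shuffle null
  (exhaustive enumeration on small instances).
- **Ephys.** Peri-stimulus spike counts in half-open 1-s bins (−4…+4 s
  around wind onset), baseline z-scoring, Poisson-GLM classification of
  each post-onset second as excited/inhibited/none, percentages of
  responsive units over time, 2-SD max-bin response latency, and
  plug-in mutual information I(R;S) = Σ_r Σ_s P(r)P(s|r) log₂
  (P(s|r)/P(s)) between capped spike counts and the binary wind
  stimulus, normalized by a baseline bias floor and tested against 1.
- **Behavior.** Direction-bias χ² on toward vs away turn counts, Fisher
  exact comparison of toward-rates between stimulus strengths, and
  per-animal Mann–Whitney / Wilcoxon comparisons for trimming and
  follicle-blockade designs — with exact small-sample rank tests that
  stay exact under ties.

## Worked example

```r
library(anemowhisk)

# a synthetic tracking session at the default study conditions
cfg   <- sim_config(seed = 42)
trajs <- gen_whisker_trajectories(cfg, wind_speed = 0.5)  # 0.5 m/s
ds    <- lapply(trajs, displacement_series)
head(summarize_displacement(ds, mode = "mean_sem"), 5)
#>   whisker_id    n    center       spread rank
#> 1        lSO 6000 0.3733548 0.0025406189    1
#> 2         A1 6000 0.1891909 0.0012706862    2
#> 3      alpha 6000 0.1884111 0.0012813307    3
#> 4       beta 6000 0.1866049 0.0012578510    4
#> 5      delta 6000 0.1009008 0.0006720059    5

compare_whiskers(ds, posthoc = "dunn")
#> Kruskal-Wallis: H(25, 156000) = 85193.8, p = <2e-16
#> Post hoc: dunn (pairwise p-value matrix in $posthoc)
```

The lSO tip moves most (0.37 cm mean displacement, rank 1), trailed by
the other wind-responsive whiskers (A1, α, β), and the omnibus test
confirms the whiskers differ; the Dunn matrix then shows lSO separating
from non-responsive whiskers such as E3 (p ≈ 0).

Behavioral contingency analysis works directly from counts — here, 31
toward-turns vs 7 away-turns under hand-flap stimulation:

```r
res <- direction_bias_test(counts = c(31, 7))
cat("chi2 =", round(res$chi_sq, 2), " p =", signif(res$p, 3), "\n")
#> chi2 = 15.16  p = 9.89e-05
```

a strong bias toward the airflow source. Morphometry follows the same
pattern of small composable functions:

```r
m  <- gen_morphology_table(cfg)
ct <- correlate(m$length_mm, m$diameter_um)
cat("r =", round(ct$r, 2), " n =", ct$n, "\n")
#> r = 0.73  n = 104
```

i.e. longer whiskers are thicker — except the deliberately thin lSO,
which carries the extreme length/diameter ratio
(`fold_change_vs_reference`, `select_optimal_arrangement` continue the
analysis). `run_pipeline(run_config(seed = 1))` executes all four
stages on a fully synthetic study and writes tidy CSVs plus a report.

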