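# gaitclust

Clustering multi-joint stance-phase gait kinematics in spastic diplegic
cerebral palsy, with repeatability-based selection of the number of clusters
and time-resolved mapping of each cluster's deviations from
normally-developing (ND) kinematics.

## Who this is for

Clinical movement-analysis groups and gait-biomechanics researchers who have
per-participant joint-angle trajectories (hip sagittal/coronal/transverse,
knee sagittal, ankle sagittal over stance) and want to (a) find subgroups of
patients with similar multi-joint gait patterns without reducing the
waveforms to discrete features first, (b) justify *how many* subgroups the
data support, and (c) describe each subgroup's deviations from reference
kinematics as signed intervals of the stance phase.

## The method

Each participant's channels are time-normalized to 101 points (0–100%
stance), averaged across gait repetitions, z-standardized per channel, and
concatenated in a fixed order into a 505-feature vector; the cohort forms a
matrix **M** (n × 505). **M** is clustered with Lloyd k-means (Forgy seeding,
50 restarts, minimum-SSE selection) for k = 2–5, repeated R = 10 times.
Cluster quality is the mean silhouette

        s(i) = (b(i) − a(i)) / max{a(i), b(i)}

computed with squared Euclidean distances; allocation repeatability is the
percentage of participant-by-repetition allocations that agree with each
participant's modal aligned label across the 10 repetitions. The chosen k is
the largest k with repeatability above a threshold (default 95%).

Each final cluster is then compared channel-by-channel against an augmented
ND reference (4 mean waveforms × offsets {−1, −0.5, 0, +0.5, +1}·SD = 20
curves per channel) using a pointwise two-sample t field SPM{t}. The
family-wise critical threshold comes from 1D random field theory: residual
smoothness (FWHM) is estimated from normalized residual gradients and the
threshold solves the expected-Euler-characteristic equation at alpha 0.05
(two-tailed). Maximal runs with |t| above threshold become the reported
deviation intervals, labelled with clinical directions (flexion, abduction,
internal rotation, dorsiflexion, ...).

Because no clinical recordings are distributed, the package includes a
synthetic cohort generator with four kinematic archetypes (sustained
abduction/external rotation; jump-like; sagittal-only; crouch-like), known
ground-truth labels, graded membership and smooth correlated noise, so the
entire pipeline is testable end to end.

## Worked example

```r
library(gaitclust)

cohort <- generate_cohort(seed = 1)      # 37 participants, archetypes 5/12/12/8
result <- run_gait_pipeline(cohort, config = pipeline_config(master_seed = 1))
result$selection
```

```
Cluster selection report
| k | mean s | SD s | repeatability % | switching participants |
|---|--------|------|-----------------|------------------------|
| 2 | 0.407 | 0.177 | 100.0 | 0 |
| 3 | 0.295 | 0.240 | 100.0 | 0 |
| 4 | 0.334 | 0.171 | 100.0 | 0 |
| 5 | 0.291 | 0.189 | 93.2 | 9 |

Chosen k: 4
```

k = 2–4 allocate identically in every repetition; k = 5 drops below the 95%
repeatability threshold (9 of 37 participants switch allocation between
repetitions), so the rule keeps the largest stable solution, k = 4. The
deviation report then lists, per cluster and channel, the significant % stance
intervals and their clinical direction:

```r
head(result$deviation_report$table, 5)
#>   cluster        channel direction start_pct end_pct
#> 1       1   hip_sagittal   flexion        68      95
#> 2       1   hip_sagittal   flexion        98     100
#> 3       1    hip_coronal adduction         6      15
#> 4       1    hip_coronal adduction        17      18
#> 5       1    hip_coronal abduction        42      55
```

e.g. cluster 1 walks with significantly increased hip flexion late in stance
(an extension deficit) and moves from adduction in loading response to
abduction in midstance. Against the generator's ground truth:

```r
ev <- evaluate_recovery(result, cohort)
#> adjusted Rand index vs ground truth: 0.926
#> mean deviation-interval Jaccard:     0.836
```

`plot_silhouette_panels()`, `plot_boundary_effect()` and
`plot_cluster_kinematics()` (ggplot2) render the matching figures, and
`inst/cli/gaitclust` exposes `simulate` / `run` / `plot` / `report`
subcommands for shell use.

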