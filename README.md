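# fcclean

Benchmarking data-driven artifact removal for resting-state fMRI
functional connectivity, on simulated two-group cohorts with known ground
truth.

## The problem

Resting-state BOLD timeseries mix neural network signal with structured
noise: head-motion effects at brain boundaries, CSF pulsation, white-matter
drift, vascular signal along the dural sinuses, scanner drift. Cleanup
strategies differ in what they remove — and in a clinical comparison the
question is whether a real group difference survives and becomes detectable.
The benchmark planted here mirrors a well-replicated clinical finding:
reduced posterior default-mode-network (DMN) connectivity in Alzheimer's
disease, at realistic sample sizes (20 controls vs 21 patients, 160 volumes
at TR = 2.5 s).

`fcclean` simulates such cohorts (networks, artifacts, a multiplicative
posterior-DMN deficit `dmn_deficit = 0.6` for patients, per-subject
gray-matter-volume covariate), then compares five datasets per subject:

| cleanup     | definition |
|-------------|------------|
| `none`      | common preprocessing only (5 mm FWHM smoothing, 0.01 Hz high-pass) |
| `motreg`    | OLS removal of 24 motion parameters (6 rigid-body + derivatives + squares) |
| `mwcreg`    | 24 motion parameters + mean WM and CSF signals |
| `comp_soft` | spatial ICA; full motion removal; *unique* variance of noise components removed |
| `comp_agg`  | spatial ICA; *full* variance of motion + noise components removed |

Evaluation follows the standard battery: temporal SNR (`temporal_snr`),
voxelwise fluctuation suppression
`%dSTD = 100 * SD_t(uncleaned − cleaned) / SD_t(uncleaned)`
(`delta_std_map`, with group exceedance maps), within-group consistency of
FC maps (`consistency_map`), and between-group inference — posterior-ROI
pooled-variance t-tests and a voxelwise Freedman–Lane permutation GLM with
gray-matter-volume covariate and cluster-extent correction
(`permutation_group_glm`, `cluster_correct`). Connectivity is mapped by
PCC-seed correlation with Fisher r-to-z (`seed_fc_zmap`) and by
template-based dual regression (`dual_regression`).

## Worked example

```r
library(fcclean)

# reduced spatial scale (full anatomy proportions, T = 120) for a quick run;
# sim_config() gives the full-scale defaults
rc <- run_config(sim = smoke_config(grid_shape = c(14L, 16L, 12L),
                                    n_volumes = 120L, random_seed = 1),
                 n_perm = 199, seed = 1)
bench <- run_full_benchmark(rc)
print(bench)
```

```
<fc_benchmark> 41 subjects, 5 cleanups x 2 FC methods
# A tibble: 10 × 4
   fc_method cleanup        t            p
   <chr>     <chr>      <dbl>        <dbl>
 1 seed      none       0.428 0.671
 2 dualreg   none       0.194 0.847
 3 seed      motreg    -0.345 0.732
 4 dualreg   motreg    -0.194 0.847
 5 seed      mwcreg    -0.595 0.555
 6 dualreg   mwcreg    -0.960 0.343
 7 seed      comp_soft  6.74  0.0000000492
 8 dualreg   comp_soft  5.59  0.00000191
 9 seed      comp_agg   6.14  0.000000328
10 dualreg   comp_agg   5.81  0.000000937
```

Each row is the HC-vs-AD comparison of the mean DMN connectivity statistic
in the posterior (PCC/precuneus) ROI: with uncleaned or regression-only
data the planted deficit is invisible at n = 20/21 (|t| < 1, p ≫ 0.05);
after ICA-based cleanup it is strongly detected (p < 2e-6). The voxelwise
permutation comparison agrees — `glance(bench$comparisons[["dualreg.comp_agg"]])`
reports a significant cluster at corrected p = 0.005 with 199 permutations.
`tidy(bench)`
returns the full table with group means/SDs, `autoplot(bench)` boxplots the
median temporal SNR per cleanup, `plot_consistency(bench)` shows the
across-subject variability of the FC maps, and
`tidy(bench$comparisons[["dualreg.comp_agg"]])` gives the
permutation-corrected cluster table of the voxelwise comparison.

A thin command-line wrapper is installed at
`inst/scripts/run_benchmark.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/run_benchmark.R", package="fcclean"))')" \
  --config run.yaml --out results/
```

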