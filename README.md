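# petr1

Voxel-wise kinetic modelling of dynamic PET with the simplified reference
tissue model, and the statistics needed to ask how *repeatable* the resulting
parameter is.

## The problem

The relative tracer delivery rate R1 = K1/K1′ — the ratio of the
plasma-to-tissue influx of a target region to that of a reference tissue —
can be computed from the early kinetics of a standard dynamic amyloid scan
(e.g. [11C]PiB with cerebellar grey matter as reference) and serves as a
proxy of relative cerebral blood flow. Before R1 can be used to track disease
progression or treatment response, its intrinsic test-retest precision must
be known: how different would two R1 maps of the same subject, scanned twice
in the same week, be? `petr1` implements the full analysis chain for that
question:

1. **Parametric imaging.** The simplified reference tissue model (SRTM)
   describes a target time-activity curve as

   C_T(t) = R1·C_R(t) + (k2 − R1·k2a)·C_R(t) ⊗ e^(−k2a·t),

   with k2a = k2/(1 + BP_ND). The voxel-wise fit uses the basis-function
   linearisation: for each candidate k2a on a log-spaced grid the model is
   linear and solved in closed form; the grid point with minimal residual sum
   of squares wins. A first pass (receptor parametric mapping, RPM) estimates
   all three parameters per voxel; the reference efflux k2′ = k2/R1 is then
   coupled across the brain as the median over voxels with BP_ND > 0.05, and
   a second one-parameter pass (SRTM2) re-estimates R1 with k2′ fixed.
2. **Regional extraction.** Grey-matter VOIs are superimposed on the R1 map;
   a global cortical composite is the volume-weighted average over all
   target regions.
3. **Test-retest statistics.** Percent test-retest variability
   TRT% = |T − R| / (0.5·|T + R|) · 100 per subject and region; a linear
   mixed-effects regression of retest on test (random intercept per subject,
   amyloid status as covariate) with its marginal R²; Bland-Altman bias and
   limits of agreement in percent of the pair mean; and an exact,
   tie-aware Mann-Whitney U comparison of diagnostic groups.
4. **Synthetic phantoms.** Because clinical test-retest data cannot be
   shipped, the package generates ground-truth-known cohorts (a plasma-like
   input through one-tissue reference kinetics, SRTM voxel kinetics,
   count-statistics frame noise, paired scans with per-region R1 jitter) so
   that every stage of the pipeline is testable end to end.

## Worked example: one voxel

```r
library(petr1)
sch <- default_schedule()            # 23 frames, 90 min
ref <- generate_reference_tac(sch)   # noise-free cerebellar-like curve
tgt <- srtm_forward(ref, R1 = 0.85, k2 = 0.1275, bp_nd = 0.4)
fit <- srtm_fit(tgt, srtm_basis(ref), method = "rpm")
fit
#> RPM basis-function fit
#>     R1     k2    k2a  BP_ND
#> 0.8520 0.1250 0.0891 0.4026
#> RSS: 0.00366
```

R1 is recovered to about 0.2 % of truth; the residual RSS reflects only the
quantisation of the k2a grid (the generating k2a falls between grid points).
`plot(fit)` overlays data, fit and reference curve.

## Worked example: full synthetic cohort

```r
cfg <- pipeline_config(out_dir = "run", seed = 5)
report <- run_pipeline(cfg)
report
#> Test-retest report over 12 subjects, 22 regions
#>   global composite TRT: 0.44 % (regional range 0.80-2.23 %)
#>   LME slope 0.982 [0.951, 1.014], marginal R^2 0.969
#>   Bland-Altman bias -0.03 +/- 1.62 %
#>   volume-TRT trend: R^2 0.106, p 0.139 (negative slope)
#>   CU vs AD composite R1 (test): p = 0.004329
```

Reading the report: every region repeats to within a few percent; the
regression of retest on test R1 has a slope indistinguishable from 1 with a
high fixed-effects R²; the Bland-Altman bias is negligible against its
limits of agreement; smaller regions tend to repeat worse (negative volume
trend); and the cognitively unimpaired and AD-dementia groups are separated
in composite R1. Maps (`r1.nii.gz`, `k2a.nii.gz`, `bpnd.nii.gz`,
`validity.nii.gz`), regional tables, the report JSON/TSV and plots are
written under `out_dir`.

A thin command-line wrapper with verbs `simulate`, `fit`, `extract`,
`stats` and `run-all` lives at `inst/cli/petr1.R`:

```sh
Rscript inst/cli/petr1.R run-all --out run --seed 5
```

## Design notes

See the methods vignette (`vignettes/r1-test-retest.Rmd`) for the model
assumptions, the noise model, default parameter choices and their
rationale, numerical details of the analytic convolution, and known
limitations of the phantom cohort.
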