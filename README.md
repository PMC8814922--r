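# brightpath

Image-based planning tools for transcranial magnetic stimulation (TMS)
treatment of depression: connectivity-guided target selection from
resting-state fMRI, neuronavigation coil-pose geometry, BOLD motion
quality control, MEGA-PRESS edited-spectroscopy preprocessing, and the
trial power calculations that justify the design — all backed by
synthetic fixtures with known ground truth.

## The problem

Standard repetitive TMS (rTMS) for depression stimulates the left
dorsolateral prefrontal cortex at the scalp position F3. A
connectivity-guided alternative (cgiTBS) instead stimulates the voxel of
the left middle frontal gyrus (lMFG) that is most strongly *driven* by
the right anterior insula (rAI), on the hypothesis that the
insula-to-prefrontal effective-connectivity path carries the treatment
effect. Turning that idea into a coil position on a specific head
requires a chain of well-defined computations, each of which this package
implements and tests:

1. **Target selection.** With seed series $x_t$ (mean over a 6 mm rAI
   sphere) and voxel series $y_t$, both standardized, fit

   $$ y_t = c + a\,y_{t-1} + b\,x_{t-1} + \varepsilon_t $$

   by OLS; the path coefficient $b$, standardized across the search
   region into a z-map, measures first-order Granger causality. The
   target is the peak voxel of the suprathreshold (z > 1.96)
   26-connected cluster containing the global maximum. The search region
   is the lMFG mask intersected with the suprathreshold part of the
   resting-state component best matching a left central-executive
   network template; the series are nuisance-regressed (eroded WM/CSF
   means) and high-pass filtered (0.01 Hz) first.

2. **Coil pose.** Brain targets become poses in a nasion–left–right
   (NLR) fiducial frame: origin at the projection of the nasion onto the
   preauricular line, fitted by the Kabsch rigid algorithm. At the scalp
   vertex nearest the target, the coil z-axis is the outward mesh
   normal, and the coil y-axis is the tangent vector whose *projection
   onto the NLR xy-plane* makes exactly 45° with the midsagittal axis.
   Rotations are exported as unit quaternions $(w, x, y, z)$.

3. **Quality control.** Framewise displacement (Power's convention,
   rotations on a 50 mm sphere): any frame > 3 mm or run mean > 1 mm
   aborts planning.

4. **Spectroscopy.** MEGA-PRESS ON/OFF series are eddy-current
   corrected, frequency-and-phase aligned by spectral registration,
   outlier-rejected, averaged, and differenced, with absorption-mode
   water-linewidth (< 13 Hz) and NAA SNR gates.

5. **Power.** The trial's repeated-follow-up ANCOVA power and the
   Fisher-z correlation power for the mechanistic hypotheses, in closed
   form with Monte-Carlo cross-checks.

## Running the tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "brightpath", load_package = "installed")'
```

or, during development, `Rscript -e 'devtools::test()'`. The suite
includes `tests/testthat/test-acceptance.R`, one test per acceptance
criterion (power reproduction with Monte-Carlo oracles, 1,000-pose coil
geometry, rigid-motion invariance, 100-run planted-target recovery, QC
rules, MRS accuracy, projection contract).

## Worked example

```r
library(brightpath)

fx <- make_var_bold(seed = 42)                 # planted causal voxel at (7, 16, 11)
hf <- make_head_fixture("sphere", radius = 80) # head mesh with analytic fiducials

plan <- run_cgitbs_pipeline(
  bold = fx$bold, components = fx$components, template = fx$template,
  lmfg_mask = fx$lmfg, rai_mask = fx$rai,
  wm_mask = fx$wm, csf_mask = fx$csf, head = hf$mesh)
plan
#> <target_plan cgiTBS>
#> <brain_target cgiTBS> voxel (7, 16, 11), world (18, 45, 30) mm, peak z = 4.548
#> <coil_pose> scalp vertex (24.72, 64.72, 40.00) mm, quaternion ( 0.8292603, -0.4986888,  0.0361873, -0.2496543)

export_plan(plan, "plan.json")   # versioned JSON with config hash + provenance

round(100 * power_mean_followups(trial_design(266)), 1)
#> [1] 89.3
round(required_correlation(111, 0.90), 2)
#> [1] 0.27
```

A command-line interface covering the same pipelines
(`power`, `qc`, `pose`, `target`, `mrs`, `fixtures`; exit codes 0 ok,
2 QC failure, 3 input error) is installed at
`system.file("cli", "brightpath.R", package = "brightpath")`.

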