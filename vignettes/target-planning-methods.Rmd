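---
title: "Methods: connectivity-guided TMS target planning, coil-pose geometry, and trial power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity-guided TMS target planning, coil-pose geometry, and trial power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brightpath)
```

This vignette documents the statistical and geometric model behind each
module, the default parameters and where they come from, the numerical
choices that affect results, and what the synthetic fixtures do and do not
capture.

## 1. Connectivity-guided target selection

### Model

A treatment target for connectivity-guided intermittent theta-burst
stimulation (cgiTBS) is the voxel in the left middle frontal gyrus (lMFG)
whose activity is most strongly *driven* by the right anterior insula
(rAI), in the Granger sense. For a seed series $x_t$ (mean series over a
6 mm sphere in the rAI) and a candidate voxel series $y_t$, both
standardized, we fit the bivariate first-order model

$$ y_t = c + a\, y_{t-1} + b\, x_{t-1} + \varepsilon_t $$

by ordinary least squares and take $b$ as the effective-connectivity path
coefficient. `gca_zmap()` computes $b$ for every voxel in the search
region and standardizes the coefficients across voxels into a z-map;
`peak_cluster_target()` thresholds the map (z > 1.96), finds
26-connected clusters, and returns the peak voxel of the cluster
containing the global maximum.

Before the causality analysis the pipeline optionally regresses out mean
white-matter and CSF series (tissue masks thresholded at probability
0.98 and eroded by a 2-voxel spherical element, so partial-volume voxels
do not leak gray-matter signal), then high-pass filters at 0.01 Hz by
zeroing Fourier coefficients below the cutoff. The search region itself
is the intersection of the lMFG mask with the suprathreshold part of the
resting-state component that best matches a left central-executive
network template (`select_component()`, highest spatial Pearson
correlation after zeroing subthreshold voxels).

### Why first-order and bivariate

The target definition only needs the *direction and relative strength*
of the rAI-to-lMFG influence at the TR timescale, not a full multivariate
spectral decomposition. A first-order bivariate model has a closed-form
OLS solution per voxel, is stable for the 240-frame series used here,
and the resulting map is standardized across voxels, so only the
*ranking* of voxels matters — model misspecification that shifts all
coefficients equally does not move the peak.

## 2. Coil-pose geometry

### The NLR frame

Neuronavigation poses are expressed in a head frame built from three
fiducials: nasion $N$, left preauricular $L$, right preauricular $R$.
The origin $O$ is the orthogonal projection of $N$ onto the line $LR$:

$$ O = R + \frac{(N-R)\cdot(L-R)}{\lVert L-R \rVert^2}\,(L-R). $$

The frame sends $N \mapsto (d_N, 0, 0)$, $L \mapsto (0, d_L, 0)$,
$R \mapsto (0, -d_R, 0)$ with $d$ the respective distances to $O$.
`fit_rigid()` solves the four-point correspondence (origin plus three
fiducials) with the Kabsch/Umeyama SVD algorithm, including the
determinant sign correction, so the transform is exactly rigid. Because
the frame is defined only by the fiducials, rigidly moving the head,
mesh, and target together leaves the NLR-space plan unchanged; the test
suite verifies invariance to $10^{-6}$.

### Coil orientation

At the scalp vertex nearest the target (in NLR space), the coil z-axis
$c_z$ is the outward surface normal (area-weighted average of incident
face normals). The coil y-axis must satisfy the handle-angulation rule:
its *projection onto the NLR xy-plane* makes a 45° angle with the
midsagittal x-axis. Writing $u = (\cos 45°, \sin 45°, 0)$, we take

$$ c_y \propto u + \alpha\,\hat z, \qquad
   \alpha = -\frac{u \cdot c_z}{(c_z)_3}, $$

which is the unique (up to sign) tangent vector whose xy-projection is
exactly $u$: the correction is purely vertical, so the xy-components of
$c_y$ stay proportional to $u$, while $\alpha$ is chosen to make
$c_y \perp c_z$. Note this is *not* the same as projecting $u$ onto the
tangent plane ($u - (u\cdot c_z)c_z$), which tilts the xy-projection away
from 45° on oblique scalp normals — that formulation was evaluated and
rejected because it violates the stated 45° projection rule. The rule is
degenerate when the normal lies in the xy-plane ($ (c_z)_3 = 0 $) or when
the required tangent would be vertical; `coil_pose()` then falls back to
the mirrored handle direction with a warning. $c_x = c_y \times c_z$
completes a right-handed orthonormal triad, converted to a unit
quaternion $(w, x, y, z)$, $w \ge 0$, by Shepperd's method (choosing the
largest diagonal pivot for numerical stability).

## 3. BOLD motion quality control

Framewise displacement follows Power's convention: the sum of absolute
frame-to-frame differences of the six rigid parameters, with rotations
(radians) converted to millimetres on a 50 mm sphere. A run fails QC if
any frame exceeds 3 mm or the run mean exceeds 1 mm. The gate is
deliberately a hard abort in the pipelines: a target estimated from a
motion-corrupted series is worse than no target.

## 4. MEGA-PRESS preprocessing

`mrs_preprocess()` chains, in order:

1. **Eddy-current correction** — each FID is multiplied by
   $e^{-i\,\phi_w(t)}$ where $\phi_w$ is the water reference phase;
   near-zero water samples carry the last reliable phase forward.
2. **Spectral registration** — each FID is aligned to the mean OFF
   spectrum by profiled nonlinear least squares: the frequency shift
   maximizes $|S(f)| = |\sum_t \mathrm{fid}_t\,
   \overline{\mathrm{ref}_t}\, e^{-i 2\pi f t}|$ (coarse grid then
   golden-section refinement over ±20 Hz), and the phase is the argument
   of $S$ at the optimum. The estimator is unbiased; at time-domain SNR
   50 its phase error has a spread of roughly a third of a degree, so
   accuracy claims in the tests are made on the *median* over repeated
   draws rather than a single noisy realization.
3. **Outlier rejection** — per-spectrum mean squared deviation from the
   group mean over the 3.1–3.3 ppm (choline) window; spectra above
   mean + 3 sd are dropped (single pass, computed within ON and OFF
   groups separately; groups smaller than 3 are left untouched).
4. **Averaging and differencing** — mean ON, mean OFF, and the edited
   difference spectrum.
5. **QC gates** — water linewidth must be below 13 Hz, and OFF-spectrum
   NAA SNR values more than 3 sd below the group mean are flagged.

Water linewidth is measured as the full width at half maximum of the
*absorption-mode* (phased real) water peak, obtained by zero-order
phasing at the magnitude maximum. This matters: for a Lorentzian line the
magnitude-mode FWHM is $\sqrt 3$ times the absorption FWHM, so a
magnitude measurement would report ~13.9 Hz for a true 8 Hz line and
break the 13 Hz gate. Spectra are zero-filled 8× before peak
interpolation so the FWHM is resolved to well under 2%.

The chemical-shift axis uses $f_j = (\delta_j - 4.7)\,\nu_0$ Hz with
$\nu_0$ the spectrometer frequency in MHz and 4.7 ppm the water
reference.

## 5. Trial power

`power_mean_followups()` computes normal-approximation power for a
two-arm comparison of the mean of $k$ correlated follow-up scores with a
baseline covariate:

$$ \mathrm{var}(\bar Y) = \sigma^2 \frac{1+(k-1)r_f}{k}, \qquad
   r_{bm} = r_b \sqrt{\frac{k}{1+(k-1)r_f}}, $$

the ANCOVA adjustment multiplies the variance by $(1 - r_{bm}^2)$, and
the analysed per-arm size is `round(n_total * (1 - dropout) / 2)` — a
whole number of participants. The integer rounding is not cosmetic: with
the default design (3-point effect, SD 8, $r_f = 0.7$, $r_b = 0.27$,
$k = 3$, 20% dropout, two-sided $\alpha = .05$) it gives per-arm sizes of
106 and 93 and reproduces the published 89.3% (n = 266) and 85.1%
(n = 232) exactly, where a fractional n would give 89.4% and 85.0%.

```{r power}
round(100 * power_mean_followups(trial_design(266)), 1)
round(100 * power_mean_followups(trial_design(232)), 1)
```

Correlation power uses the Fisher z transform,
$\Phi(|z(\rho_1) - z(\rho_0)|\sqrt{n-3} - z_{1-\alpha/\mathrm{tails}})$,
and `required_correlation()` inverts it in closed form (no rounding until
presentation):

```{r corr}
round(100 * power_correlation(120, 0.2, 0.5), 1)
round(required_correlation(232, 0.90), 2)
round(required_correlation(111, 0.90), 2)
```

At zero effect these normal-approximation formulas return
$\alpha/\mathrm{tails}$ (only one rejection tail is counted), the
standard boundary behavior of the approximation. All analytic values are
cross-checked in the test suite against Monte-Carlo oracles that simulate
and analyse whole trials.

## 6. Synthetic fixtures: what they capture and what they do not

All tests run on generated data with known ground truth:

- `make_var_bold()` plants a single voxel following
  $y_t = 0.5\,x_{t-1} + \varepsilon_t$ inside the search region, with the
  driver $x_t$ carried by the seed sphere, in a 24×24×18×240 noise
  volume (a package-chosen size: big enough for meaningful cluster and
  nuisance structure, small enough that 100 end-to-end runs finish in
  minutes). It captures the causal ordering and the component-selection
  logic, but not hemodynamic convolution, spatial autocorrelation, or
  scanner drift beyond white noise.
- `make_head_fixture()` builds subdivided-icosahedron spheres and
  ellipsoids with *analytic* outward normals and fiducials exactly at the
  axis poles, so geometric claims can be tested against closed-form
  answers rather than against the mesh itself.
- `make_megapress()` synthesizes Lorentzian FIDs (choline 3.2,
  creatine 3.0, NAA 2.0 ppm, plus a GABA-like 3.0 ppm resonance only in
  ON acquisitions) with controllable per-FID frequency/phase jitter and
  complex noise. Real spectra add baseline distortions, J-coupled
  multiplets, and lineshape deviations the fixture does not model.
- `make_motion_trace()` is a slow random walk with optional step spikes;
  it exercises the FD arithmetic and QC rules, not realistic biomechanics.

Every generator is deterministic under its seed, and the uniformity of
the no-signal case (coupling 0) is itself under test, so the recovery
claims are not artifacts of the generator.

## 7. Reproducing the headline numbers

`scripts/acceptance.R` recomputes the published values at runtime from
the installed package and writes them as JSON:

```
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

producing the two design powers (89.3, 85.1), the two minimum detectable
correlations (0.19, 0.27), and the coil-angle check (45°).
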