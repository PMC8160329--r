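---
title: "Methods: neurovascular coupling metrics and the radial oxygen model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neurovascular coupling metrics and the radial oxygen model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nvcoxy)
```

nvcoxy quantifies how well local blood supply tracks neuronal energy
demand in brain microvasculature, and what the resulting capillary
oxygen levels mean for tissue metabolism. It covers three layers:
extraction of vascular and neuronal signals from two-photon imaging
(line-scan kymographs, XY movies, 3-D stacks), event-based
neurovascular-coupling statistics from those signals and from combined
laser-doppler/haemoglobin-spectroscopy ("oxy-CBF probe") recordings, and
a radial oxygen diffusion--consumption model that converts measured
blood oxygenation and capillary spacing into tissue oxygen profiles.
Because raw in vivo recordings of this kind are rarely shareable, every
input modality has a seeded synthetic generator with known ground
truth; the test suite exercises each estimator against that truth.

## Line-scan velocimetry, flux and haematocrit

A line-scan kymograph stores successive laser sweeps along a capillary
as image rows, so a red blood cell (RBC) moving at velocity $v$ casts a
dark shadow on the bright dye-filled lumen whose slope is
$v\,\Delta t_{\mathrm{line}}/\mathrm{px}$ columns per line.
`estimate_velocity()` finds that slope per 40 ms block (blocks share
10 ms by default, i.e. a 30 ms stride; both are arguments, since either
reading of a "10 ms overlap" is defensible) by maximizing the variance
of the image projected along candidate stripe directions. Projection is
by bilinear sampling along the candidate lines at half-pixel and
half-line steps; continuous resampling matters, because accumulating
raw pixels into bins resonates at integer slopes and biases the
estimate. Candidate slopes are spaced at 5 % relative steps (the
variance peak has a roughly constant relative width), refined by
golden-section search. A block whose best-direction variance is less
than 1.2 times the median over directions carries no directional
information and is flagged low quality.

`count_flux()` binarizes the along-vessel segment with Otsu's threshold
(one threshold per recording), averages the central columns into a
single time trace, and counts each connected dark epoch as one RBC in
the 250 ms window containing its onset, so no cell is counted twice
across window boundaries. `estimate_hematocrit()` reports the dark
fraction of the binarized segment per 40 ms block — the fraction of the
scanned lumen occupied by RBCs.

Vessel diameter, from the across-vessel segment of a line scan or per
frame of an XY movie, is the full width at half maximum (FWHM) of the
lumen intensity profile. The baseline is the 5th percentile of the
profile; the peak is located on a 3-point median-filtered profile
(single-pixel specks cannot become the peak) and its height taken from
a parabolic fit through the raw samples, which avoids the downward bias
that a robust percentile gives narrow peaks; half-maximum crossings are
linearly interpolated for sub-pixel precision. For movies,
`frame_diameter_trace()` segments the lumen (threshold at half the 95th
percentile intensity), thins it to a 2-D skeleton, and measures FWHM
profiles perpendicular to the local axis at every other skeleton pixel,
each profile averaged over a five-pixel running window along the
vessel.

## Vascular morphometry in 3-D

`skeletonize_volume()` reduces the binarized vasculature (Gaussian
smoothing, $\sigma$ = 1 voxel, then Otsu, for grey-scale stacks) to a
one-voxel centerline by distance-ordered homotopic erosion: voxels are
deleted in order of increasing Euclidean distance from the background,
skipping any deletion that would change topology (simple-point test,
26/6-connectivity) or remove a curve endpoint. Ordering ties are broken
by a fixed hash of the voxel index rather than scan order — scan-order
ties let the erosion front run down a tube and swallow it. Voxels
outside the stack count as vessel, since a capillary at the border
continues beyond the imaged field; this keeps centerlines of crossing
vessels from being eroded back from the faces. The exact Euclidean
distance transform is computed with the separable lower-envelope
algorithm in compiled code.

Vessel radius at each skeleton point is the distance-map value there
(distance from centerline to the nearest background voxel), and
diameter-by-depth profiles bin twice that radius in 10 µm half-open
depth bins below the first image plane. Capillary density is total
centerline length over imaged volume (m/mm³). Length is measured by
walking each skeleton branch and summing chords over every fifth voxel:
the thinned line jitters at voxel scale, and voxel-to-voxel summation
inflates length by up to ~10 %, while 5-voxel chords recover straight
tubes to well under the 5 % accuracy the recovery tests require.

`tissue_distance_distribution()` histograms the exact distance of every
tissue voxel to the nearest vessel over five non-overlapping 100 µm
substacks (seeded uniform placement with restarts; the substack count,
edge and 1 µm bin width are arguments, the bin width because no
published convention exists) and reports the 50th–95th centile
distances, the geometric input of the oxygen model.

## Events, responses and coupling indices

Calcium traces are first normalized across the recording,
$\Delta F/F = (F - F_{\min})/(F_{\max} - F_{\min})$; putative events
are local maxima of this trace above 10 % of the maximum (applied to
the level, with a separate minimum prominence of 0.05 and 1 s
separation; both are arguments). Each putative peak is re-expressed
relative to its own 5 s baseline, $(F - F_0)/|F_0|$, over a −5 to
+10 s window, and kept only if it exceeds the baseline mean by more
than two baseline standard deviations. Windows that would be clipped by
the recording edges are dropped rather than padded. Note that min-max
normalization is scale-free: on a recording containing nothing but
noise these rules still fire at a small chance rate, which is precisely
what the shuffled null measures; real transients dominate the
normalized range and suppress noise peaks below the 10 % level.

A vessel responds to an event if its diameter, baseline-normalized the
same way, exceeds the baseline mean by more than one standard deviation
for a contiguous run longer than 0.5 s within 5 s after the event.
`shuffled_null()` repeats this classification after randomly permuting
the diameter trace over (by default) 100 iterations, estimating the
chance response rate (a seeded circular-shift variant is available; the
unrestricted permutation is the default because the original procedure
used a random-permutation routine). The single-vessel coupling index is
the dilation peak divided by the triggering calcium peak.

Probe recordings add derived channels
$\mathrm{Hbt} = \mathrm{HbO} + \mathrm{Hbr}$,
$\mathrm{SO_2} = \mathrm{HbO}/\mathrm{Hbt}$, and
$\mathrm{CMRO_2}(t) = \mathrm{CBF}(t)\,\mathrm{Hbr}(t)/\mathrm{Hbt}(t)$,
computed samplewise at 40 Hz. Rest is defined as locomotion below
0.25 cm/s with no stimulus, padded by 1 s around bouts (both
parameters exposed; "immobile and in the dark" fixes no numbers).
Metabolic events are CMRO₂ peaks detected by the same code path as
calcium events, with the same 5 s preceding baseline and 2-SD rule; the
regional coupling index is the Hbt excursion within 5 s divided by the
CMRO₂ peak. The source descriptions disagree about this ratio's
orientation (one passage divides the other way), so the direction is an
argument; the default, blood-volume change per unit metabolic change,
matches the single-vessel dilation-per-calcium convention.

## The radial oxygen model

Oxygen transport from a capillary of radius $r_c$ = 2.5 µm into the
surrounding tissue is modelled in cylindrical geometry with
Michaelis–Menten consumption by oxidative phosphorylation:

$$\frac{\partial C}{\partial t} = \frac{1}{r}\frac{\partial}{\partial r}
\left(r D \frac{\partial C}{\partial r}\right)
- \frac{V_{\max} C}{C + K_m},$$

with $D = 9.24\times10^{-8}$ m²/min (brain, 37 °C), $K_m$ = 1 µM (the
literature value is printed with a length unit in places; it is evidently
a concentration), $V_{\max}$ of 0.5–3 mM/min spanning reported brain
oxygen consumption rates, a Dirichlet boundary at the capillary edge,
and zero flux at $r_{\max}$, the midpoint between capillaries. Across a
200 nm wall adjacent to the lumen, $D$ is reduced by 40 % (basement
membrane barrier). The capillary boundary concentration comes from
measured blood oxygen saturation through the mouse haemoglobin
dissociation curve ($\mathrm{sO_2} = p^h/(p^h + P50^h)$, $h$ = 2.59,
$P50$ = 40.2 mmHg) and Henry's law at body temperature
($k_H = 1.3\times10^{-5}$ mol m⁻³ Pa⁻¹ at the reference temperature,
rescaled by $\exp[1500\,\mathrm{K}\,(1/T - 1/T_0)]$ with $T$ = 310.15 K;
$T_0$ is set to 298.15 K and exposed, since "standard temperature" is
not pinned down). Since the plasma between RBCs, not the RBC interior,
equilibrates with tissue, the inter-RBC concentration (14 µM
hippocampus, 21 µM visual cortex) is the physiological boundary value;
the RBC-derived values (42/60 µM) serve as an upper-bound check.

The discretization is a conservative finite volume on $[r_c, r_{\max}]$:
400 cells by default plus ≤50 nm cells across the wall, harmonic-mean
face diffusivities, with a face aligned to the wall edge. Steady states
are found by damped Picard iteration on the linearized sink (a
tridiagonal solve per iteration, converging to $10^{-12}$ in tens of
iterations); transient solutions use stiff method-of-lines integration
(`deSolve::ode.1D`) from $C(r) = 0$, and the two routes agree to four
figures (tested). Every accepted steady solve satisfies the mass
balance — capillary-wall influx equals integrated consumption — to
better than 0.5 %, and the solver matches the Krogh zero-order closed
form in the $K_m \to 0$, no-wall limit to under 1 %.

Reported quantities are the "midpoint" oxygen concentration and
consumption fraction $\mathrm{VO_2}/V_{\max} = C/(C + K_m)$ at
$r_{\max}$, i.e. in the tissue furthest from a vessel. The source
geometry is ambiguous about whether the domain extends to the
tissue-distance centile or to the full capillary separation (twice the
centile); $r_{\max}$ is therefore always an explicit input. The printed
median separation of 14.4 µm used *as the domain extent* reproduces the
printed far-boundary value of ≈37 µM for the 42 µM/3 mM-per-min upper
bound case, so the separation convention is used where a printed
geometry is needed. Where the centile geometry is not printed at all,
`calibrate_rmax()` bisects $r_{\max}$ (to 0.05 µm, over 1–100 µm) so a
stated consumption fraction is met at a reference $V_{\max}$, exploiting
the monotone decrease of the midpoint fraction with $r_{\max}$;
perturbing $V_{\max}$ or the boundary concentration at fixed calibrated
geometry then reproduces the reported sensitivity, e.g. ~31 % of
$V_{\max}$ at 3 mM/min in hippocampus after calibrating 59 % at
2 mM/min, and 90 % after calibrating 93 % in cortex. One printed pair is
not internally consistent with this machinery: calibrating 60 % at
14 µM and raising the boundary to 18 µM yields ≈76 %, not the reported
70 %, under any single geometry; the package reports the computed
value. `centile_sweep()` solves one steady profile per capillary
spacing, and `inhibition_fractions()` converts the sweep plus a
tissue-distance distribution into the fraction of tissue whose
consumption is inhibited by at least a threshold: tissue at the $p$-th
centile distance experiences the midpoint conditions of capillaries
spaced at twice that centile, so the inhibited fraction is one minus
the centile at which the (monotone) inhibition curve crosses the
threshold.

## What the synthetic data does and does not emulate

The generators implement the forward models the estimators invert: RBC
shadows as anti-aliased periodic stripes of exactly the requested
velocity, flux and dark fraction (the three are linked — haematocrit
equals stripe width times flux over velocity); vessels as anti-aliased
tubes under a Gaussian PSF (σ 0.4 µm) with additive Gaussian noise;
calcium transients as single-exponential kernels (τ 0.4 s,
indicator-like); random vascular networks as non-overlapping chords at
a target centerline density of ~1 m/mm³ (brain-like); probe sessions as
coupled multiplicative deflections in which the derived CMRO₂ has
exactly the requested fractional peak and the Hbt excursion per unit
CMRO₂ is the requested gain, with an alpha-function kernel peaking at
1 s. Network chords avoid running along a stack face (a face-hugging
vessel is only half imaged and has no recoverable centerline) and do
not share lumens.

They do not emulate photon statistics, motion artefacts, scan-path
curvature, optical sectioning anisotropy, RBC shape, vessel tortuosity
or pulsatility. Passing recovery tests therefore demonstrates the
estimators invert their stated image-formation models at realistic
geometry, sampling and noise, not robustness to every artefact of real
microscopy — motion registration, in particular, is assumed done
upstream.

## Numerical choices and test problem sizes

Degenerate inputs are handled explicitly: constant traces cannot be
min-max normalized (error); constant kymograph segments skip Otsu and
count as bright; baseline means at machine zero drop the event with a
warning; empty histogram depth bins are missing, not zero; windows
clipped at recording edges drop their events. Ties in peak detection
break toward the earlier peak. Bisection brackets and tolerances, grid
resolutions, and every block length, threshold and padding mentioned
above are function arguments with the stated defaults.

The test suite runs volumes of 60–90 voxels per side at 1 µm, 100
single-block kymographs for the velocity sweep, and minutes-long 40 Hz
probe sessions; these sizes put every estimator in its asymptotic
regime while keeping the full suite to a few minutes. The acceptance
script solves the radial model at its default 400-cell grid, where the
answers are grid-converged to well below reporting precision.

## Known limitations

Single-vessel scan paths only (no multi-vessel line scans); the movie
diameter extraction assumes one vessel per field; skeleton length
slightly undercounts closed loops (spanning-tree walk); the oxygen
model is single-capillary radial — no capillary network heterogeneity,
no erythrocyte-associated transients, no intravascular longitudinal
gradients; laser-doppler units are relative, so CMRO₂ and the regional
coupling index are unitless ratios, not absolute rates.
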