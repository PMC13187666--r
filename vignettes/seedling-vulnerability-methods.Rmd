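---
title: "Methods: acoustic and optical vulnerability analysis of seedling drydowns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic and optical vulnerability analysis of seedling drydowns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedlingvc)
```

## The problem

Drought kills tree seedlings largely through xylem embolism: under tension,
gas is aspirated through pit membranes into water-filled conduits
(air seeding), and conductance is progressively lost as the water potential
$\Psi$ falls. Seedlings are too small for the standard hydraulic (flow-based)
vulnerability techniques, so two indirect techniques are used on
bench-dehydrating plants:

* **Acoustic emission (AE)**: each cavitation event emits an ultrasonic hit
  (recorded above a 35 dB threshold). Because late-drydown records are
  contaminated by non-embolism sources (wood micro-fractures, tissue
  dehydration) and therefore never plateau, cumulative AE counts cannot be
  normalized into a curve. Instead the activity (signals min⁻¹, 1-min bins)
  is smoothed and the $\Psi$ at the **main activity peak**, $\Psi_{AEmax}$,
  is taken as the 50%-embolism proxy.
* **Optical visualization (OV)**: the exposed xylem is imaged every 150 s;
  an embolizing conduit changes local intensity between consecutive frames.
  Successive-frame differencing, thresholding and connected-component
  labeling yield embolized pixel clusters; the cumulative embolized area
  $A_{cum}$ is normalized by the total at the end of the record,
  $\mathrm{percent} = A_{cum}/A_{max}\times 100$, and fitted against $\Psi$
  with a two-parameter Weibull curve
  $$F(\Psi) = 1 - \exp\!\left[-\left(|\Psi|/\lambda\right)^{k}\right],$$
  from which $\Psi_{OV12}$, $\Psi_{OV50}$, $\Psi_{OV88}$ are read as
  quantiles $-\lambda(-\ln(1-p))^{1/k}$.

Both branches need $\Psi(t)$: discrete pressure-chamber readings on
sacrificed proxy plants (2–3 per timepoint) are averaged per timepoint and
linearly interpolated.

The package also computes the anatomy metrics used to interpret
cross-technique discrepancies — conduit diameters from lumen areas (circle
model for vessels, square for tracheids), the hydraulic diameter
$d_h = \sum d^5 / \sum d^4$, wall reinforcement $(t/b)^2$ over pairs with
span within $d_h \pm 1\,\mu m$, 1-µm diameter-class histograms — and a
comparison layer ($\Delta\Psi_{OV50-AEmax}$, one-way ANOVA with Tukey
letters after Shapiro/Levene checks, CI-overlap calls, Pearson
correlations).

## The synthetic drydown world

No public dataset accompanies this type of experiment, so every stage is
validated against a simulator with known ground truth
(`synthetic_config()`, `drydown_truth()`):

* **Thresholds**: per-conduit air-seeding tensions $T \sim
  \mathrm{Weibull}(k, \lambda)$, embolism at $\Psi = -T$. Defaults
  $\lambda = 3.54$ MPa, $k = 5.86$ (a resistant-conifer-like curve). Using
  the same family the fitter assumes makes recovery tests self-consistent;
  that is a deliberate choice, and it means green recovery tests do not
  establish robustness to curve-family misspecification.
* **Trajectory**: monotone piecewise-linear $\Psi(t)$ from −0.2 MPa to
  −7 MPa over 20 h (the bench-drydown maximum). −7 MPa terminates beyond
  effectively all thresholds so records are complete.
* **AE stream**: one hit per conduit at its threshold-crossing time, plus
  an inhomogeneous-Poisson nuisance process with rate
  $\propto e^{k_n (t - t_0)}$ starting at 70% of the record (default end
  rate 0; tests use a few hits min⁻¹). The source literature only states
  that emissions "do not plateau", so these parameters are uncalibrated
  placeholders, exposed in the config. Amplitudes are truncated-normal
  above 35 dB and carried but unused (the analysis counts hits).
* **OV stack**: conduits are disks on a uniform background, laid out on a
  jittered grid whose cells are wide enough that rendered disks can never
  touch (so connected components map 1:1 to conduits); at the embolism time
  a disk steps by +40 intensity units; i.i.d. Gaussian pixel noise
  (sd 1) is added per frame at 2 µm px⁻¹. Conduits whose disk covers no
  pixel center are invisible by construction — the sub-resolution
  detection limit. A point mass (default 14%, the small-conduit fraction
  reported for *Sorbus aucuparia*) of 0.5–1.5 µm conduits sits below that
  limit. The renderer deliberately omits periderm, focus and drift
  effects: it is the minimal model that exhibits the detection-limit bias.
* **Coupling switch**: whether small conduits are more embolism-resistant
  (the pit-area hypothesis) is exactly that — a hypothesis — so the
  simulator exposes it as `coupling = "none" | "shift" | "rank"` rather
  than baking it in. `"shift"` moves small-class thresholds 1.5 MPa more
  negative.
* **Determinism**: one master seed is split into fixed named substreams
  (population, thresholds, nuisance, image noise, pressure-chamber
  sampling), so identical configs give byte-identical datasets.

## Estimators and numerical choices

* **Timeline**: readings within a grouping tolerance (default 60 s) are
  averaged per timepoint before interpolation; non-monotone knots are kept
  as measured but flagged. Extrapolation defaults to clamping with a
  warning; the protocol never evaluates outside the measured range.
* **Savitzky–Golay**: window and order are not reported in the source
  protocols. The package default is 31 bins, order 3 — reasonable for real
  records with thousands of hits. Interior points use central convolution
  weights; the edges are filled by evaluating the polynomial fitted to the
  first/last full window. Smoothed rates are floored at 0. The main peak is
  the global maximum of the smoothed rate; exact plateaus break toward the
  more negative $\Psi$; secondary local maxima are reported as diagnostics
  (seedlings show genuine early peaks from primary xylem).
* **Peak recovery and bandwidth**: under a constant drying rate,
  $\Psi_{AEmax}$ estimates the **mode** of the threshold distribution,
  $-\lambda((k-1)/k)^{1/k}$, not its median (they differ by ~0.1 MPa at
  the default shape). Mode estimation from $n$ events is an intrinsically
  slow ($n^{-1/7}$) problem: at 2000 conduits the argmax of a lightly
  smoothed series scatters by ±0.2 MPa and is biased toward the flatter
  (less negative) flank. Recovery tests therefore use a wide window
  (301 bins ≈ 0.29 MPa of $\Psi$ at the default drying rate; 501 bins for
  the 800-conduit bias experiment) and average over 6 simulated
  individuals, mirroring the 6–8 plants per species of the real protocol.
  Results are insensitive to ±10 bins around these windows.
* **OV detection**: the published protocol leaves pixel-level parameters
  open; defaults are threshold = 3× the robust noise sd of the first
  difference map (MAD about zero of the absolute differences, scaled by
  $1/\Phi^{-1}(3/4)$ — difference maps are folded, so the usual MAD about
  the median underestimates), minimum cluster 4 px, 8-connectivity, no
  pre-blur. A running union mask ensures each pixel counts once.
  Event $\Psi$ is assigned at the frame-pair midpoint (events are known
  only to a 150 s window). $A_{max}$ is the cumulative area at the end of
  the record; no extrapolation.
* **Weibull fitting**: unweighted least squares on the fraction scale, with
  `optim` (Nelder–Mead polished by BFGS) on $(\log\lambda, \log k)$.
  Starting values come from the closed-form two-quantile solver applied to
  the empirical 12%/88% crossings, which keeps near-step leaf curves
  (shape ≈ 68) stable. Confidence intervals: case-resampling bootstrap
  percentile intervals (default B = 1000) or residual-sum-of-squares
  profiling with the $\chi^2_1$ likelihood-ratio cut; for noise-free data
  the profiled RSS floor makes intervals collapse to the point estimate
  rather than dividing by zero. Points are pooled per organ before
  fitting (per-individual fitting is available through repeated calls);
  the source protocol does not state which pooling it used.
* **Two-quantile solver**: through $(\Psi_a, p_a)$, $(\Psi_b, p_b)$,
  $k = \ln[\ln(1-p_b)/\ln(1-p_a)] / \ln(|\Psi_b|/|\Psi_a|)$ and $\lambda$
  from either constraint. This inverts published
  $(\Psi_{12}, \Psi_{50}, \Psi_{88})$ triplets for consistency checks; all
  five published hypocotyl/leaf cases round-trip to 2 decimals. The one
  excluded case in the acceptance battery sits on a 0.005-rounding
  boundary after 2-dp propagation.
* **Statistics**: Levene is implemented in its Brown–Forsythe form (ANOVA
  on absolute deviations from group medians). Tukey letters are the
  maximal cliques of the non-significance graph, so two groups share a
  letter iff their pairwise test is non-significant. CI comparison uses
  strict disjointness (touching endpoints = "same"); the overlap rule is
  not defined by the source, and disjointness is the conservative choice.
  Correlations over fewer than 5 paired observations warn: a 4-species
  trait–threshold correlation is descriptive only.

## What a green test establishes — and what it does not

The detection-bias experiment reproduces the *mechanism* of the
cross-technique discrepancy: with 14% sub-resolution conduits 1.5 MPa more
resistant than the visible population, the OV-fitted $\Psi_{50}$ comes out
less negative than $\Psi_{AEmax}$ on the same simulated plant (positive
$\Delta\Psi_{OV50-AEmax}$, here ~+0.1 MPa). It does not reproduce the
magnitude observed on real *S. aucuparia* (+2.5 MPa), which would require
stronger coupling and/or optical effects (overshadowing by large vessels,
field-of-view limits) that the renderer intentionally omits. Likewise,
published per-species $\Psi_{AEmax}$, anatomy tables and p-values depend on
raw data that are not public; they are covered only by property-based
surfaces (consistency identities, recovery from known truth, conservation
laws).

## Known limitations

* No deconvolution of embolism vs non-embolism AE sources; the nuisance
  robustness property holds only while nuisance activity stays below the
  embolism peak rate.
* No image registration: a drifting sample would generate spurious events.
* The simulator's conduit layout forbids overlap, so it cannot emulate
  overshadowing of small conduits by large vessels.
* Bootstrap coverage is verified at the default noise model (i.i.d.
  Gaussian on fractions); autocorrelated residuals from real cumulative
  curves will under-cover.
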