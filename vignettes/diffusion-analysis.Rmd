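---
title: "Estimating receptor surface diffusion from single-molecule tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating receptor surface diffusion from single-molecule tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptdiffusion)
```

## The problem

Single-particle tracking follows individual fluorescently labeled
membrane receptors (e.g. AMPA-type glutamate receptors) across video
frames and summarizes each trajectory by a diffusion coefficient D. Two
nuisance effects make the naive MSD slope biased on the short tracks that
live-cell experiments produce: *static localization noise* — the
finite-photon jitter of each fitted position, sd σ, which inflates
apparent displacements — and *motion blur* — the averaging of the true
position over the camera exposure, which deflates them and correlates
consecutive displacement steps. This package implements the
maximum-likelihood estimator that models both effects explicitly, plus
the up- and downstream steps a complete receptor-mobility study needs.

## The displacement covariance model

For a track sampled at frame interval $\Delta t$, the per-axis
displacement vector is multivariate Gaussian with symmetric tridiagonal
Toeplitz covariance

$$\Sigma_{ij} = \begin{cases}
2D\Delta t - 2(2DR\Delta t - \sigma^2) & i = j\\
2DR\Delta t - \sigma^2 & i = j \pm 1\\
0 & \text{otherwise,}
\end{cases}$$

where $R$ is the motion-blur coefficient,
$R = \frac1T\int_0^T S(t)(1-S(t))\,dt$ for cumulative shutter function
$S$; continuous illumination gives $R = 1/6$
(`motion_blur_coefficient()` evaluates arbitrary shutter profiles by
quadrature). The per-track log-likelihood, in the convention that drops
the constant $-N\log 2\pi$ (it cannot move the maximizer; absolute
log-likelihood values are reported in this convention),

$$L = -\log|\Sigma| - \tfrac12 \Delta x^\top \Sigma^{-1}\Delta x
      - \tfrac12 \Delta y^\top \Sigma^{-1}\Delta y,$$

is evaluated in $O(N)$ by an $LDL^\top$ factorization of the tridiagonal
matrix (C++ inner loop; never a dense inverse). For $D > 0$,
$\sigma^2 \ge 0$ and $R \le 1/4$ the matrix is always positive definite
($a + 2b = 2D\Delta t$, $a - 2b = 2D\Delta t(1-4R) + 4\sigma^2$). A
circulant approximation — eigenvalues $a + 2b\cos(2\pi k/N)$, quadratic
forms via the FFT — is provided as `loglik_circulant()`; on 512-step
tracks it agrees with the exact likelihood to well under 1% and is the
cheaper option for very long tracks.

## Fitting

`fit_mle()` maximizes $L$ over $(\log D, s)$ with $\sigma^2 = s^2$, so
$\sigma^2 = 0$ is attainable; bounds are $D \in [10^{-6}, 10]$ μm²/s and
$\sigma^2 \le 0.25$ μm². Five Nelder–Mead starts are used: one from the
closed-form covariance-based estimator (CVE),

$$\hat D_{\mathrm{CVE}} = \frac{\overline{\Delta^2} +
  2\overline{\Delta_k\Delta_{k+1}}}{2\Delta t},\qquad
  \hat\sigma^2_{\mathrm{CVE}} = R\,\overline{\Delta^2} +
  (2R-1)\,\overline{\Delta_k\Delta_{k+1}},$$

plus a log-spaced D grid. Ties below $10^{-6}$ in $L$ resolve toward the
smaller D. Noise-dominated tracks (negative CVE diffusion signature) end
up pinned at the lower D bound and are flagged, not dropped. The CVE is
also the independent cross-check: on $10^4$-step tracks the two
estimators agree to a fraction of a percent.

Quality control follows the σ-based rule: with $\mu_\sigma$ the mean
$\hat\sigma$ over a group's converged fits, estimates outside
$[0.1\mu_\sigma, 1.9\mu_\sigma]$ — i.e. beyond ±90% of the group mean,
read arithmetically — are excluded in a single pass (the mean is not
recomputed; a percentile-band reading of the same rule would behave
differently and is noted as an alternative). One caveat the validation
surfaced: on 29-step tracks where motion strongly dominates noise
(D = 0.1 μm²/s, σ = 20 nm), about 16% of tracks place the σ MLE exactly
on the zero boundary — these are true likelihood maxima, verified against
dense likelihood-grid evaluation — so the band excludes ~20% of that
extreme condition while all milder conditions retain ≥ 93%.

## MSD analysis and motion classification

`msd_curve()` evaluates the overlapping-pair MSD exactly,
$\mathrm{MSD}(m\Delta T) = \frac{1}{N-m}\sum_i
 (x_{i+m}-x_i)^2 + (y_{i+m}-y_i)^2$, with `max_lag` defaulting to half
the track (longer lags average too few pairs). `fit_msd_linear()` gives
the conventional slope D with an intercept that absorbs the
$4\sigma^2 - 8RD\Delta t$ offset.

Motion classification fits a line $4Dt$ and a saturating corral model
$A(1 - e^{-4Dt/A})$. Because the saturating model nests the line, a pure
residual comparison mislabels many genuinely Brownian tracks — the
correlated wiggles of a single-track MSD look like curvature — so a curve
is called confined only when (i) the saturating fit beats the line by
more than 5% of RSS *and* (ii) the observation window spans at least 3
confinement times $A/(4D_c)$, i.e. the plateau is demonstrably reached.
On 300-frame simulated tracks (D = 0.1 μm²/s, 0.4 μm corral) this
labels ≥ 98% of each class correctly; on 100-frame tracks the classes
genuinely overlap and both sub-model scores are reported so users can
re-threshold. The confinement geometry is a reflecting square corral —
the simplest model with a closed-form plateau of $L^2/3$ for a side-$L$
square.

## What the simulator emulates

`simulate_trajectory()` builds motion blur mechanistically: within each
exposure the molecule takes `n_substeps` Brownian sub-steps (sampled at
sub-step midpoints) and the camera records their average, then
localization noise is added. The estimator is therefore tested against
physics, not against its own covariance model; with one sub-step the
observation is a point sample (R = 0) and with the default 50 sub-steps
the empirical displacement covariance matches the R = 1/6 model to within
sampling error. Dark gaps (frame interval > exposure) are simulated but
unobserved, so timing ambiguities between sampling interval and exposure
can be explored without hard-coding either. Defaults mirror the
video-rate study conditions: Δt = exposure = 33 ms, pixel 0.16 μm,
σ = 20–30 nm, D in the 0.02–0.25 μm²/s range of membrane receptors,
30-frame tracks, 400 trajectories per recording.

The movie renderer integrates a symmetric Gaussian PSF over pixels with
Poisson shot noise and Gaussian read noise; the STORM generator draws
cluster centers uniformly (optionally with a minimum separation), members
as isotropic 3D Gaussians around them — z reflected into the ±300 nm
detectable band — and uniform background. Not emulated: EMCCD gain
statistics, astigmatic PSF shapes, dye photophysics beyond one-step
bleaching, and receptor interactions; passing tests therefore validate
the estimators under their stated model, not every property of real
recordings.

## Downstream rules

Filters follow fixed published-style rules, each logged: tracks shorter
than 15 frames are excluded, as are tracks containing a single-frame step
over 1 μm (the automated stand-in for manual artifact screening — an
approximation, flagged as such in the exclusion log). STORM localizations
keep z ∈ [−300, 300] nm (closed band) and a configurable photon minimum;
molecules are DBSCAN clusters with ≥ 3 points within 100 nm (the point
itself counts; border points attach to their nearest core so the result
is order-invariant), clustered in 3D by default with a lateral-only
option. A trajectory is synaptic if at least one frame falls in a
synaptic mask pixel; dwell time is total inside-time per synaptic track
(per-visit durations are also emitted so either convention can be
summarized). Mask projection supports both maximum (default) and average
intensity, with the binarization threshold exposed as configuration.
Group statistics use the Kolmogorov–Smirnov test (asymptotic two-sided),
Mann–Whitney U (exact for small tie-free samples), Kruskal–Wallis with
tie correction followed by Dunn's z with Holm adjustment (Bonferroni and
unadjusted available), and percent-of-vehicle normalization whose SEM
deliberately ignores vehicle-mean uncertainty, matching the usual
plotting convention.

## Numerical choices and problem sizes

Run configuration lives in one YAML file per analysis so every threshold
is reproducible from the file plus a seed; identical config and seed give
byte-identical outputs. Quadrature for the blur coefficient uses a
200,000-interval Simpson rule (~1e-9 for smooth shutters). The linker
solves each frame-pair assignment exactly (shortest augmenting path) with
links gated at `max_step`; gap closing defaults to 0 frames. Validation
problem sizes were chosen to keep the full suite in the minutes range on
one core: 10⁵-step tracks for moment checks, 500-track ensembles per
condition for recovery, and 100 replicate two-condition experiments
(400 + 400 tracks) for the power and type-I study, which detects a 55%
slowdown at p < 0.001 in every replicate while the null rejects at ~3–5%.

## Known limitations

Per-trajectory likelihoods assume a single constant D per track — no
state switching, drift, or anomalous exponents. The σ-QC band's
arithmetic reading and the single-pass group mean follow the method as
described; iterating the exclusion would shift the band slightly.
DBSCAN's O(n²) neighbor search is comfortable to ~10⁴ localizations per
ROI but not for whole-field millions. The linker is globally optimal per
frame pair, not over whole tracks (no multi-hypothesis smoothing).
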