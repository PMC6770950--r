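---
title: "Monitoring milk renneting from time-resolved NIR spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring milk renneting from time-resolved NIR spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rennetpat)
```

## The problem

Enzymatic coagulation (renneting) is the critical step of cheese making:
chymosin cleaves kappa-casein, destabilized micelles aggregate, and a gel
network forms. A failed coagulation — too little rennet, a cold vat, too
little calcium — costs yield and quality, and is traditionally caught late,
by eye or by off-line rheology. In-line FT-NIR probes see the process as it
happens: absorbance spectra collected once per minute over a 30-minute run
carry both chemical and scattering signatures of the sol-gel transition.

`rennetpat` implements the full analysis chain that turns such spectra into
process knowledge and real-time fault alarms:

1. preprocessing — spectral-range reduction and the standard normal variate
   (SNV) transform;
2. rank analysis by PCA/SVD;
3. SIMPLISMA pure-spectrum selection for non-random starting estimates;
4. multivariate curve resolution by alternating least squares (MCR-ALS)
   under non-negativity and unimodality constraints;
5. kinetic interpretation — the sol-gel transition time from the resolved
   transition-phase profile, compared against sigmoid-fitted rheology;
6. PCA-based multivariate statistical process control (MSPC) with
   Hotelling's T² and Q statistics.

Because raw renneting spectra of this kind are not publicly deposited, the
package ships a synthetic-data generator that produces batches with exactly
the statistical structure the analysis assumes. All quantitative claims the
package makes are claims about this simulator plus pipeline, checked in the
test suite; qualitative behaviour mirrors what is reported for real milk.

## The bilinear model and its constraints

A batch is a matrix $D$ ($M = 30$ spectra $\times$ $N = 1730$ wavenumbers,
12,500–5,824 cm$^{-1}$). Curve resolution assumes

$$D = C\,S^{\mathsf T} + E,$$

with $F = 3$ components: concentration profiles $C$ ($M \times F$) describing
how the liquid, transition, and gel phases wax and wane, spectral profiles
$S^{\mathsf T}$ ($F \times N$), and residuals $E$. The alternating
least-squares loop repeats

* $C \leftarrow \arg\min \lVert D - C S^{\mathsf T}\rVert^2$ subject to
  $C \ge 0$ (row-wise active-set NNLS), then a unimodality projection of each
  concentration column (pool-adjacent-violators on each side of the peak,
  peak at the current argmax, ties to the earlier time);
* $S^{\mathsf T} \leftarrow \arg\min \lVert D - C S^{\mathsf T}\rVert^2$,
  each spectral profile rescaled to unit length with the inverse scale
  absorbed into $C$ (the product is invariant; tested to $10^{-10}$),

monitoring the lack of fit
$\mathrm{LOF}(\%) = 100\sqrt{\sum e_{ij}^2 / \sum d_{ij}^2}$ after every full
cycle. Iteration stops when the relative LOF change drops below 0.1%
(`lof_rel_tol = 0.1`, `tol_mode = "relative"`; an absolute-difference mode is
available), or at `max_iterations = 50`. Five consecutive LOF increases abort
with a diagnostic error; increases below numerical noise ($10^{-9}$ relative,
or LOF under $10^{-8}$) are ignored, since near-exact fits jitter at machine
precision.

Spectra are *not* constrained non-negative by default: the fitted data are
usually SNV-transformed, and SNV output is legitimately negative
(`mcr_config(nonneg_s = TRUE)` turns it on for raw-absorbance fits if
desired).

One behaviour worth knowing: on *exactly* bilinear (noiseless) data the LOF
decays geometrically toward zero, so the relative stopping rule never
triggers and the fit runs to the iteration cap with `converged = FALSE` and
an LOF orders of magnitude below practical relevance. On noisy data the LOF
plateaus at the noise floor and the rule stops the loop after roughly a
dozen iterations. The absolute mode converges in both situations.

## What the generator emulates — and what it does not

`kinetic_params()` + `make_concentration_profiles()` build the three phase
profiles from two logistic sigmoids with common time scale `steepness`
(default 1 min), centred `pulse_width/2` (default 2.5 min) before and after
`transition_time` (default 7 min). The transition pulse is the *difference*
of the two sigmoids, so:

* the pulse peaks exactly at `transition_time` (the downstream peak-time
  extraction has a known truth);
* at default amplitude the three phases sum to one at every time — mass
  balance closure. This is what makes noiseless simulated data rank 3
  uncentered and rank 2 after column centering, the relationship
  `select_rank()` checks. SNV's per-row scaling perturbs closure (the third
  centered singular value rises to a few percent of the first), so the exact
  rank-drop property is asserted on raw noiseless matrices.

The defaults make the aggregation phase genuinely absent in the first
minutes of a run, as enzymatic proteolysis precedes visible aggregation.
This matters beyond realism: if the transition pulse is still substantial at
$t = 1$, the constraint set (non-negativity + unimodality only) no longer
pins the bilinear factorization, and ALS legitimately returns a rotated
solution. Identifiability of the truth is a precondition for the recovery
tests, not something the algorithm can supply by itself.

Spectral profiles are sums of Gaussian bands with component-specific
amplitudes around the three diagnostic positions of coagulating milk —
6,900 cm$^{-1}$ (water O–H), 8,600 and 10,800 cm$^{-1}$ (lipid C–H) — plus
seeded jitter; rows are checked for linear independence. Noise is additive
i.i.d. Gaussian with `noise_sd = 0.003` absorbance units, which puts fitted
residual SDs in the range reported for well-fit renneting spectra (below
0.0067). The corresponding simulated LOF is about 1%; real instruments with
stronger signal power report a few tenths of a percent. Explicitly *not*
simulated: multiplicative scatter, baseline drift, wavelength-correlated
noise, detector saturation, or any mechanistic temperature/pH/fat model —
`kinetics_from_conditions()` is an illustrative monotone mapping (warmer,
more acidic, leaner milk coagulates faster) chosen to spread transition
times over roughly 5–17 minutes, nothing more. Passing tests therefore
validate the algorithms under the stated statistical assumptions; they do
not certify performance on real milk.

Fault archetypes (`apply_fault()`) scale the kinetic parameters; the rules
are part of the generator's contract, stated in the function documentation.
All three archetypes delay the transition (by ≥ 2 min at severity 0.5 under
default kinetics) and weaken the final gel, since under-renneted, cold, and
calcium-starved milk all set poorly.

## Initialization and component identity

`select_pure_spectra()` runs the SIMPLISMA recursion over rows (spectra), so
the selections are directly usable as starting spectral estimates: purity
$s_i / (m_i + \alpha\,\max_j m_j)$ with offset $\alpha = 0.01$, weighted from
the second round by the Gram determinant of the unit-normalized candidate
plus already-selected rows. On renneting batches the three selections land
at the start (liquid milk), near the transition, and at the end (set gel).
Two numerical notes: on standardized rows (e.g. SNV output) every row mean
is zero and the purity denominator degenerates — it is floored at a tiny
positive value, leaving the determinant weight to drive selection, which is
exactly the sensible behaviour there; and duplicates of selected spectra
have determinant zero, so they can never be selected twice.

Because MCR component order is arbitrary, the "transition" component is
identified operationally in `transition_time()`: the column whose peak is
interior and stands highest above its endpoint values, ties to the earliest
interior peak. The discrete peak is refined by a three-point parabola, which
is how fractional transition times (e.g. 7.3 min) arise from a 1-minute
acquisition grid. If no interior-peaked column exists the boundary time is
returned with a warning flag rather than a fabricated refinement.

## Rheology and critical times

Elastic-modulus time-curing curves follow
$G'(t) = a / (1 + \exp(-(t - b)/c))$; `fit_sigmoid()` estimates $(a, b, c)$
by Levenberg–Marquardt with data-driven starts ($a$ from the maximum, $b$
from the half-maximum crossing, $c$ from the inter-quartile rise time over
$\log 9$). The first derivative peaks at $b$; the second derivative's
maximum and minimum sit at $b \mp c\,\ln(2+\sqrt3)$. The acceleration time
$AT_{G'} = b - c\,\ln(2+\sqrt3)$ marks the onset of fast gelation and is the
rheological counterpart of the spectroscopic transition time CP2. On the
bundled reference table of fifteen batches the two correlate at $r = 0.96$
($p < 0.001$), with CP2 always leading — the spectroscopic probe feels the
sol-gel transition a few minutes before the bulk rheometer does. The paired
simulator reproduces that lead by construction
(`run_renneting_demo()` couples the rheological midpoint to the spectral
transition time plus a positive lag).

## Control charts

`build_control_chart()` trains on the concentration-profile rows of
in-control batches (each observation = the $F$ concentration values at one
time point; eigenvalues from the sample covariance, $n-1$ denominator).
Limits at confidence $1-\alpha$ (default 99%):

* T² (retained space): $\frac{K(n-1)(n+1)}{n(n-K)} F_{K,\,n-K,\,1-\alpha}$ —
  the small-sample limit for future observations; a $\chi^2_K$ limit is
  available via `t2_method = "chisq"`. On 10,000 fresh in-control draws from
  the training distribution the empirical false-alarm rate at 99% is close
  to 1% (tested within 0.5–2%).
* Q (residual space): Jackson–Mudholkar from the discarded eigenvalues, with
  a moment-matched $g\chi^2_h$ fallback when the exponent degenerates and a
  flagged zero limit when no residual variance exists ($K = F$).

Two monitoring choices deserve their rationale:

* **K = 2 of 3.** The in-control observations trace a curve whose two
  in-plane modes carry almost all variance (PC1 alone about 78%, echoing the
  ~80% figure familiar from renneting studies). Retaining only PC1 leaves
  the second trajectory mode in the residual space, inflating the Q limit by
  orders of magnitude and blinding the chart; retaining both in-plane modes
  leaves the mass-balance-violation direction — precisely where coagulation
  faults manifest — as the residual space. Highly correlated concentration
  variables make a lone-PC T² insufficient, which is the same observation
  that motivates consulting the Q chart at all.
* **Raw absorbance for the monitoring fit.** SNV removes each spectrum's
  intensity scale. In a strictly bilinear simulator a weakened gel *is* an
  intensity suppression: after SNV the faulty rows become proportional to
  in-control ones and the signature vanishes identically. The monitoring
  arm therefore fits its augmented model (one shared $S^{\mathsf T}$ across
  the in-control replicates and fault batches, unimodality enforced within
  each batch segment) to range-reduced raw absorbance, while the kinetics
  arm keeps SNV — there only the peak position is used, which SNV shifts
  negligibly. With real scatter-dominated spectra the balance may differ;
  both preprocessing routes are exported.

Performance is reported per chart (T², Q, and the either-flag rule) by
pooling time points: sensitivity over fault-batch points, specificity over
in-control points, with empty denominators reported as `NA` rather than
invented rates. Under the default study conditions (severity 0.5 faults)
every fault batch is first flagged within the opening minutes of the run
and over 90% of its points are Q-flagged, while the held-out in-control
replicate stays essentially in control — the simulator's counterpart of
high-sensitivity, high-specificity Q monitoring with early T²/Q alarms.

## Numerical choices and degenerate inputs

* SNV uses the sample ($n-1$) standard deviation; constant rows are
  rejected (division by zero), as are all-zero matrices in the LOF.
* Range reduction is a closed interval on wavenumber values, not indices.
* Rank selection uses a singular-value ratio threshold (default $10^{-3}$)
  in place of subjective score/loading inspection; it is exposed as a
  parameter and reported alongside the centered/uncentered pair.
* The unimodality projection is idempotent and, for the argmax peak rule,
  matches an exhaustive quadratic-program search on short vectors (tested);
  the NNLS step matches brute-force active-set enumeration on toy systems.
* PCA loadings are sign-fixed (largest-magnitude element positive) so score
  plots reproduce across SVD implementations.
* All simulation functions take explicit seeds and restore the caller's RNG
  state; `run_renneting_demo()` derives every stage seed deterministically
  from one root seed and logs it.

## Problem sizes used in the shipped checks

The test suite and the acceptance script work at the study's native scale —
30 × 1730 single batches and 180 × 1730 augmented sets — for the headline
fits, with 5 seeds for fit diagnostics and fault detection, 10 batches for
recovery, 100 random draws for the critical-time comparison, and 10,000
points for chart calibration; structural unit tests use coarser wavenumber
grids (a few hundred points) where the spectral resolution is irrelevant.

## Known limitations

* The simulator is linear and noise-homoscedastic; no scatter, drift, or
  saturation. Conclusions about SNV's role in monitoring are conditional on
  that.
* The condition-to-kinetics mapping is illustrative; no claim is made about
  real temperature/pH/fat effect sizes.
* Time-pooled MSPC cannot, by construction, flag a pure time delay whose
  states all lie on the in-control path; detection relies on faults leaving
  the in-control state manifold, which the fault archetypes do.
* Rotational ambiguity is handled by constraints plus informed
  initialization, not by explicit feasible-band analysis; profile sets
  without near-zero tails may resolve only up to a rotation.
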