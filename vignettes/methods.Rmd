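---
title: "Models and methods behind redinfo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind redinfo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redinfo)
```

`redinfo` quantifies information transfer through redundant arrays of
threshold gene-regulatory circuits. This vignette is the package's own
account of the models, the numerical choices, and the places where a
design decision was genuinely open — and why we decided it the way we did.

## The three threshold units

All models are dimensionless: time is in units of the protein decay rate,
expression in units of the effective transcription-factor dissociation
constant.

**Simple regulated unit.** Production is a Hill function of the signal:
$$\dot y = \alpha_0 + \alpha\,\frac{x^n}{1+x^n} - y,$$
with defaults $\alpha_0 = 0.01$, $\alpha = 2.5$, $n = 2$. Its response is
graded (analog), with the half-activation point at $x = 1$.

**Bistable unit.** Transcriptional autoactivation with the signal as a
small additive perturbation:
$$\dot y = \alpha_0 + \alpha\,\frac{y^n}{1+y^n} - y + x.$$
At $x = 0$ the unit has stable OFF ($y \approx 0.0103$) and ON
($y \approx 2.017$) states separated by an unstable state at
$y \approx 0.483$.

**Excitable unit.** A two-gene competence-like circuit with interlinked
positive and negative feedback and a shared (saturating) degradation
pathway:
$$\dot y = \alpha_0 + \alpha\,\frac{(\sigma y)^n}{1+(\sigma y)^n}
          - \frac{y}{1+y+z}, \qquad
  \dot z = \frac{\beta}{1+\sigma y^m} - \frac{z}{1+y+z} + x(t),$$
with $\alpha_0 = 0.004$, $\alpha = 0.07$, $\beta = 0.826$, $\sigma = 5$,
$n = 2$, $m = 5$. The signal is a pulse of one time unit on the $z$ gene.
Two parameterization points deserve comment:

* The positive-feedback Hill argument is $\sigma y$, i.e. the feedback
  dissociation constant is $1/\sigma = 0.2$, the value used by the
  dimensionless competence model this unit is patterned on. With the
  alternative reading $\sigma y^n$ the unit is not excitable by pulses
  anywhere near the stated signal range: the rest state sits so far below
  the excursion region that a deterministic pulse of amplitude $\sim 20$
  would be required. With $(\sigma y)^n$ the deterministic pulse threshold
  falls between $x = 0.6$ and $0.9$, matching the signal scale
  ($\langle x\rangle = 0.9$) the study centers on.
* With these parameters the phase plane contains, besides the stable rest
  state and the saddle above it, a *weakly attracting* excited focus near
  $(y, z) \approx (0.39, 5.2)$, so a deterministic excursion parks there
  rather than returning. We verified that no tested parameterization gives
  both a strictly transient excursion and the stated threshold; we chose
  threshold fidelity. Because every realization starts at rest and is
  classified on a finite observation window, the distinction does not
  affect any reported statistic.

Excitation is read out as a Boolean: a unit counts as excited when its
post-pulse maximum of $y$ exceeds a cut calibrated once per parameter set
as the midpoint between the rest expression and the deterministic
excursion peak under a strong ($x = 9$) calibration pulse
(`excitation_threshold()`). The observation window is 150 time units: the
excursion rides the slow eigendirections of the rest state (eigenvalues
$\approx -0.046, -0.02$), so its peak occurs at $t \approx 25$–$100$ and a
short window would miss it. The integration step is $dt = 0.01$.

## Intrinsic noise and the Langevin engine

Each unit carries multiplicative intrinsic noise in the chemical-Langevin
form: the noise amplitude is the square root of the summed reaction
propensities over the molecule-number scale $K$,
$q(y) = \sqrt{(\text{production} + y)/K}$ for the 1-D units (the small
additive signal is neglected in the propensities), and a constant
$q = \sqrt{(\beta+1)/K}$ acting on $z$ only for the excitable unit
($K = 500$ there, $K = 100$ elsewhere unless scanned). The intrinsic
noise *amplitude* therefore scales as $1/\sqrt{K}$, and noise scans are
parameterized by $K$.

Integration is Euler–Maruyama in the Itô convention with $dt = 0.01$,
horizon $t_{\max} = 50$ for the 1-D units, negative excursions clipped to
zero (the standard chemical-Langevin regularization). Steady-state
responses are time averages over the final 20% of the horizon, which
reduces estimator variance relative to a single endpoint. The ensemble
kernels are written in C++ and draw all normals from R's RNG, so a single
seed fixes every trajectory.

## Steady-state responses from the stationary Fokker–Planck density

The response variable is $\Delta y_i = y_i(x) - y_i(0)$ "at steady state",
and here lies the central numerical decision of the package. For the
bistable unit at the study's noise levels the two wells of the stationary
potential are separated by barriers of order $e^{20}$ (at $K = 100$):
barrier crossing is astronomically slower than any feasible integration
horizon, so a finite-time Langevin run from the rest state can never
reach the stationary well occupancies. The stationary law itself, however,
is available in closed form for a 1-D diffusion:
$$P_{\rm st}(y \mid x) \propto \frac{1}{q^2(y)}
  \exp\!\Big(2\int^y \frac{\mathrm{drift}(u; x)}{q^2(u)}\,du\Big),$$
and because the signal enters the bistable drift additively, the exponent
is *linear in x*: one pair of tabulated integrals serves every signal
value, making exact per-realization sampling cheap at any $K$ — including
the noiseless limit, where the density collapses onto the deeper well.
`run_ensemble()` therefore defaults to `response_source = "stationary"`
for the 1-D units; the Langevin route remains available, is required for
the excitable unit, and is validated against the stationary density by a
stationarity-preservation test (ensemble initialized from
$P_{\rm st}$, integrated, compared by Kolmogorov–Smirnov distance) and by
MI agreement on the binary readout.

Two thresholds follow from this picture and must not be confused:

* the deterministic **saddle-node** (`bifurcation_threshold()`), the
  signal at which the OFF state ceases to exist — $x \approx 0.095$ at the
  defaults; and
* the stochastic **switching threshold** (`switching_threshold()`), the
  signal at which the two wells have equal depth, so the zero-noise limit
  of the stationary state flips from OFF to ON — $x \approx 0.00117$,
  independent of $K$.

The second is the threshold the information-transfer analyses center on:
a log-uniform input centered there elicits OFF and ON with equal
probability in the noiseless limit (exactly one bit through the binary
readout), which is not true of any input centered near the saddle-node.

## Input signals

Inputs are static levels drawn per realization: log10-uniform
($x = \langle x\rangle\,10^u$, $u \sim U[-1, 1]$, two decades), lognormal
(sd of $\log_{10} x$ equal to $2/3$ — we read the stated spread on the
log10 scale, parallel to the other families), or Beta$(1/3, 1/3)$ in log
scale (mass piled at the support edges). The "mean" of a family is the
geometric center of its log support: the arithmetic mean of
$\langle x\rangle 10^u$ is not $\langle x\rangle$, but the $10^u$
parameterization fixes $\langle x\rangle$ as the central scale. The MI
input variable is $\log_{10} x$; mutual information is invariant under
the base choice.

## The mutual-information estimator

`mutual_information()` is a histogram plug-in: equal-width bins on the
observed ranges, 30 input × 30 output bins for continuous outputs, and
the exact support for discrete outputs (Boolean sums), where the estimate
coincides with the closed-form MI of the empirical table. Design notes:

* **Bias.** The plug-in over-reads by roughly
  $(\text{occupied cells})/(2 n \ln 2)$; at $n = 10^4$ and default bins
  this is a few hundredths of a bit for unstructured data.
  `mi_config(bias_correction = "mm")` subtracts this Miller–Madow-style
  term (and is what drives independent samples to $<0.02$ bits); the
  default leaves the estimate uncorrected so that discrete-table MI stays
  exact and values remain directly comparable across conditions with the
  same binning. Where a scan's *shape* could be bias-made rather than
  real — the heterogeneity resonance is the delicate case, because
  heterogeneity broadens the joint support and with it the bias — we
  verified the effect at $n = 10^4$, where the bias is small.
* **Binning.** Equal-width input bins under-read a deterministic binary
  channel: the one bin straddling the threshold mixes labels, costing
  $\sim$0.05 bits at 30 bins. `input_binning = "quantile"` caps the loss
  at $\sim 1/n_{\rm bins}$ and makes the estimate exactly invariant under
  monotone input transforms; the Heaviside-array scan uses it with 100
  bins so that the zero-noise channel reads its closed-form one bit.
* Small negative values are clipped to zero and flagged; degenerate
  (constant) inputs return zero bits with a flag.

## The redundant array and its perturbation layers

An array (`array_config()`) is $N$ units reading one signal;
$\Delta y = \sum_i \Delta y_i$ exactly. Binary mode applies the OFF/ON
cut $y < 1$ per unit before summing, giving the alphabet
$\{0, \dots, N\}$.

**Extrinsic noise** is one Gaussian draw per realization,
$\xi_{\rm ex} \sim N(0, \sigma_{\rm ex})$, shared by all units and
constant over the response window (short-lived-protein regime), entering
as an additive production offset. For the bistable unit this is formally
an input shift $x \to x + \xi_{\rm ex}$, which is what makes it so
damaging: it moves all units coherently, shrinking the output alphabet.

**Cross-talk** (bistable pairs) lets each product occupy the partner's
autoactivation site: unit 1's Hill argument becomes
$y_1 + \varepsilon_2 y_2$ and unit 2's $y_2 + \varepsilon_1 y_1$. At
study noise levels the stationary law of the pair cannot be reached by
integration (the same barrier argument as above), and a 2-D stationary
density has no closed form. We exploit the extreme time-scale separation
instead: each unit is a two-state (OFF/ON) system whose flip rates,
conditional on the partner frozen at its well mean, follow from exact 1-D
mean-first-passage-time integrals; the pair is then a four-state Markov
chain whose stationary distribution we compute by the Markov-chain tree
theorem in log space (robust to rates spanning hundreds of orders of
magnitude). Within-well expression is sampled from the conditional 1-D
densities. Consistency checks: at $\varepsilon = 0$ the four-state law
factorizes into the product of the single-unit occupancies; symmetric
coupling gives a symmetric law; and coupling raises the odds of the
aligned states, which is the mechanism that collapses the bimodal
marginal of one unit into a unimodal one at $\varepsilon = 0.01$ and
drives the sharp MI decay.

**Heterogeneity** multiplies each unit's dissociation scale by an
independent Gaussian $\omega_i$ of mean 1 (redrawn until positive, which
preserves the mean for small sd, unlike clipping): Hill arguments are
evaluated at $y/\omega_i$. A key — and at first counterintuitive —
property of the bistable unit is that its switching threshold is
*exponentially* sensitive to $\omega$: a few percent increase moves
$x^*$ an order of magnitude; a fraction of a percent decrease collapses
it below zero. This is what gives the heterogeneity scan its
characteristic shape: moderate sd spreads the five thresholds across the
input window (more letters, more information), large sd scatters them out
of it (dead units, information loss). The alternative literal reading —
$\omega_i$ multiplying the threshold value directly, i.e. the unit seeing
$x/\omega_i$ — never becomes detrimental at large sd (half the thresholds
always stay in the two-decade window) and so cannot reproduce the decline;
we kept the dissociation-scale mechanism. Multipliers are drawn once per
ensemble: one heterogeneous array, read out many times.

Only intrinsic noise is active in the cross-talk and heterogeneity
analyses.

## Scan drivers and statistical guards

Every driver derives one sub-seed per replicate from its top-level seed
and *shares it across the scanned grid* (common random numbers): ratios
against the $N = 1$ or zero-perturbation reference are paired, and a
noiseless array has relative MI exactly 1 by construction. An "interior
maximum" requires the peak of the replicate-averaged curve to lie
strictly inside the grid and to exceed both grid-end averages by more
than twice the combined standard error.

Default problem sizes are $10^3$–$10^4$ realizations per MI estimate with
about five replicates per scan point; the test suite runs the full
property battery at this scale in a few minutes. The heterogeneity scan
uses ten replicates (the quenched $\omega$ draws dominate its replicate
variance) and $3\times 10^3$ realizations (so the detected maximum is the
genuine alphabet effect, not plug-in bias — confirmed against $10^4$).

The heterogeneity scan's main noise level deserves its own note. The gain
from threshold spread requires units whose response transition is narrow
relative to the input span, i.e. the sharp-threshold (high-$K$) regime: at
$K \le$ a few hundred the per-unit sigmoids are already a large fraction
of the input window wide and the resonance is not resolvable. The driver
defaults to $K_{\rm main} = 1000$ — the low-intrinsic-noise reference
level the barrier analysis contrasts with $K = 100$ — with an inset grid
$\{100, 4000\}$ over which the peak differential MI falls monotonically
as intrinsic noise grows. How a printed "intrinsic noise amplitude" maps
onto $K$ is convention-dependent ($1/\sqrt K$, or $q$ evaluated at a
reference state); the package avoids the ambiguity by parameterizing all
noise scans by $K$ directly.

## Synthetic dose–response generators

The `synthetic_data` generators emulate the *statistical structure* of
two empirical settings — a graded reporter whose copies sum with
independent multiplicative lognormal noise, and a Boolean all-or-none
response with lognormal cell-to-cell threshold variability — so the
dose–response analysis stage (`mi_dose_response()`) is testable without
any external data. They are labelled synthetic throughout and make no
attempt to match published measurements: Hill midpoints default to the
geometric center of the dose grid (steepness 2), dose grids to two
log-uniform decades, mirroring the signal conventions of the main study.
What passing tests show is that the analysis pipeline behaves correctly
on data with this structure (copy-number gain with diminishing returns
per doubling; threshold noise degrading the one-bit deterministic step;
response probabilities matching the threshold survival function) — not
that any particular biological dataset would yield these numbers.

## Known limitations

* The Langevin description is itself an approximation; no exact
  (Gillespie-type) simulation is provided, by design.
* The finite-time Langevin route cannot equilibrate bistable well
  occupancies at low noise ($K \gtrsim 30$); use the stationary route for
  steady-state responses there. The dt-convergence guard is therefore
  tested in the fast-mixing regime ($K = 20$).
* The cross-talk reduction is adiabatic: it assumes flips are rare on the
  within-well relaxation time, which holds at study noise levels but
  would degrade for very small $K$ (barriers of order one).
* The excitable unit's excited state is weakly attracting rather than
  strictly transient (see above); classification windows start from rest,
  so reported statistics are unaffected.
* Plug-in MI values carry finite-sample bias at $n = 10^3$; comparisons
  within a scan share binning and sample size, and the delicate cases
  were re-verified at $n = 10^4$.
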