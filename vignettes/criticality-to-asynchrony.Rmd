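---
title: "From criticality to asynchrony in a binary E/I network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From criticality to asynchrony in a binary E/I network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(critasync)
```

## The model

`critasync` simulates and analyses a recurrent network of $N$ probabilistic
binary neurons, a fraction $\alpha$ of them inhibitory. The connectivity
matrix $J$ has entry $J_{ji}$ for the synapse from presynaptic neuron $i$ to
postsynaptic neuron $j$; each directed pair is connected independently with
probability $p$, excitatory weights are drawn uniformly on $[0, w]$ and
inhibitory weights uniformly on $[-gw, 0]$, where $g$ is the I/E weight
ratio. Self-connections are excluded (the diagonal is zero); at $p = 0.2$
this has a negligible spectral effect, and it reflects the reading that each
neuron connects to *other* neurons. The first $(1-\alpha)N$ indices are
excitatory, which keeps the E/I input decomposition a simple column split.

The state $s_i(t) \in \{0, 1\}$ updates synchronously: the recurrent firing
probability is the clamped synaptic input,
$$p_i(t) = \sigma(I_i(t)), \qquad I_i(t) = \sum_j J_{ij} s_j(t-1),$$
with $\sigma(x) = \min(\max(x, 0), 1)$, and an external Bernoulli drive
$p_{ext}$ is applied independently afterwards, so a neuron fires with
probability $1 - (1 - \sigma(I_i))(1 - p_{ext})$. The two-stage
probabilistic-OR combination is the literal reading of "apply $p_i$, then
apply $p_{ext}$ independently"; it preserves $p_{ext}$ as a marginal extra
drive and is idempotent where $\sigma(I_i) = 1$. The default
$p_{ext} = 0.005/N$ delivers one externally driven spike per 200 steps
across the whole network — deliberately weak, because strong external drive
washes out critical fluctuations.

## Parameters

| parameter | meaning | default | units |
|---|---|---|---|
| `N` | neurons | 1000 | count |
| `p` | connection probability | 0.2 | — |
| `alpha` | inhibitory fraction | 0.2 | — |
| `w` | excitatory weight scale (max weight) | set by the boundary | probability/spike |
| `g` | I/E weight ratio | scanned | — |
| `p_ext` | external firing probability | 0.005/N | per neuron per step |
| `steps` | run length | 2×10⁵ (scans) | steps |
| `burn_in` | discarded steps | 10⁴ | steps |
| `initial_active` | initially active neurons | 10 | count |

Run length, burn-in and the initial condition are simulation choices, not
model constants: 2×10⁵ post-burn-in steps give a few thousand avalanches per
realization at either end of the boundary, enough for stable $\kappa$ and
maximum-likelihood exponent estimates at desk scale, while a single
realization simulates in seconds. All are configurable through
`sim_config()`.

## Eigenvalue theory and the critical boundary

The ensemble spectrum of $J$ is a disc of radius
$R = \sqrt{N[(1-\alpha)\sigma_E^2 + \alpha\sigma_I^2]}$ (element variances
$\sigma_E^2 = (p/3 - p^2/4)w^2$, $\sigma_I^2 = (p/3 - p^2/4)(gw)^2$, zeros
included) plus one real outlier
$\lambda_b = \tfrac{w}{2}Np(1-\alpha) - \tfrac{gw}{2}Np\alpha$ set by the
net mean drive. `eigen_theory()` returns both and
$\lambda_{max} = \max(\lambda_b, R)$. Which one dominates depends only on
$g$: setting $\lambda_b = R$ and squaring yields a quadratic in $g$ whose
physically admissible root (the one with $\lambda_b \ge 0$) is the
crossover, about 3.34 at $N = 1000$ and exactly $(1-\alpha)/\alpha = 4$ as
$N \to \infty$. Squaring introduces a companion root on the
$\lambda_b < 0$ side, which is discarded. Because the published one-line
form of this root is easy to mistranscribe, `crossover_ratio()` implements
the closed form *and* an independent bisection of $\lambda_b(g) = R(g)$, and
the test suite asserts their agreement to $10^{-9}$.

`boundary_weight()` inverts $\lambda_{max} = 1$ in closed form: the outlier
branch $w^* = 1/[\tfrac{Np}{2}((1-\alpha) - g\alpha)]$ below the crossover
and the bulk branch
$w^* = 1/\sqrt{N(p/3 - p^2/4)((1-\alpha) + \alpha g^2)}$ at and above it
(the two coincide at the crossover; the bulk branch is used from there on).

The theory is leading-order in $N$. At $N = 1000$ the sampled outlier at
$g = 0$ matches $\lambda_b$ to well under 10% over realizations, but in the
disc-dominated regime ($g = 4$) the measured largest modulus exceeds $R = 1$
by about 10–30% per realization — a bulk-edge finite-size effect compounded
by the non-normal rank-one mean structure, whose zero trace removes the mean
outlier but not its interaction with fluctuations. This quenched spread
matters downstream: realizations at $g = 4$ differ visibly in stationary
rate (and therefore in avalanche statistics) even though the ensemble
$\lambda_{max}$ is exactly 1. The tests therefore pin the 10% band at
$g = 0$ and assert the qualitative spectral geometry (no dominant outlier)
at $g = 4$.

## Branching function, critical range, avalanche threshold

The branching function $\Lambda(S) = E[S(t+1) \mid S(t) = S]/S$ measures
one-step propagation. `branching_empirical()` imposes $S(1) = k/N$ by
activating $k$ uniformly chosen neurons and samples one recurrent step
(external drive excluded — the branching function measures recurrent
propagation), returning per-point standard errors from the trial spread;
one forward step is *sampled* rather than averaged in probability, so the
error bars reflect the model's own firing noise. `branching_semianalytic()`
evaluates the ensemble prediction
$$\Lambda(S) = \frac{1}{S}\sum_{n_E}\sum_{n_I} P(n_E)\,P(n_I)\,
\sigma\!\left(\tfrac{w}{2}n_E - \tfrac{gw}{2}n_I\right)$$
with $n_E \sim \mathrm{Pois}(Np(1-\alpha)S)$,
$n_I \sim \mathrm{Pois}(Np\alpha S)$. The sums start at $n = 0$ (the
zero-count terms carry Poisson mass, though $\sigma(0) = 0$ contributes
nothing) and truncate where the tail mass falls below $10^{-12}$.

The semi-analytic form replaces each synapse by its *average* weight. This
is exact wherever $\sigma$ acts linearly — on the weak-synapse boundary
$\Lambda(S) = \lambda_b = 1$ identically at small $S$ — but it discards the
weight-variance contribution $w^2/12$ per synapse to the drive spread. Where
the transfer is rectified around zero mean drive (the strong-synapse
boundary), $E[\sigma(X)]$ scales with the drive standard deviation, and the
true branching function runs a factor $\approx \sqrt{4/3} \approx 1.15$
above the average-weight prediction. The package keeps both estimators and
treats the empirical one as ground truth for the dynamics; consistency
checks between them are expected to hold tightly only in the weak-synapse
regime.

The critical range $\rho = S_2 - S_1$ (activities where $\Lambda$ crosses
1.05 and 0.95, linearly interpolated; with multiple crossings, the
largest-$S$ 1.05 crossing and the first 0.95 crossing beyond it, matching
the descending geometry of the curves) quantifies how wide an activity band
stays near criticality. Flat curves that never reach 1.05 fall back to
$S_1 = \min S$; if 0.95 is never crossed, $S_2$ is the largest grid $S$ with
$\Lambda \ge 0.95$. Both fallbacks are flagged.

The avalanche threshold is the activity $S^\dagger$ where
$\Lambda(S^\dagger) = 1.01$, taken from the semi-analytic (noise-free)
curve. An exactly critical curve never attains 1.01, and the package then
falls back to the single-neuron level $S^\dagger = 1/N$ — the classical
threshold for avalanche detection at criticality — with a flag. This
fallback is what operates on the whole weak-synapse boundary.

## Avalanches, $\kappa$, and exponent fits

`detect_avalanches()` reads "exceeds a threshold" strictly on integer
counts: an avalanche is a maximal run of steps with more than
`threshold` active neurons; duration is the run length, size the total
spike count in the run, and runs touching either end of the record are
discarded as incomplete.

$\kappa_\epsilon$ compares the empirical CDF $F$ (right-continuous,
$P(X \le \beta)$) with a continuous reference power law of exponent
$-\epsilon$ truncated to the observed $[\min, \max]$, at 10 log-spaced
points including both endpoints:
$\kappa_\epsilon = 1 + \tfrac{1}{10}\sum_i [F^{NA}(\beta_i) - F(\beta_i)]$.
Truncating the reference to the observed support makes $\kappa$ scale-free;
this is the standard construction of the statistic in the avalanche
literature. $\epsilon = 1.5$ is used for sizes and $1.7$ for durations, the
best-fit exponents of the critical ($g = 0$) networks.

`fit_power_law()` is a zeta-normalized discrete maximum-likelihood fit with
a curvature-based standard error; no goodness-of-fit machinery is attached.
The `x_min` argument defaults to 1, but the analysis drivers pass
`x_min = min(sample)` for avalanche sizes: with a strict count threshold
$\theta$, every size is at least $\theta + 1$, and a zeta model whose
support starts at 1 would be forced to explain the missing small sizes by
deflating the exponent (at $g = 0$ the pooled size exponent reads 1.34 with
`x_min = 1` and 1.50 with the support-matched cutoff). Durations start at 1
and are unaffected. `rpowerlaw_discrete()` provides an exact rejection
sampler for the zeta distribution used in parameter-recovery tests, so the
generator and the estimator share no code.

## E/I balance, correlograms, irregularity

The input decomposition splits $I_i = I^E_i + I^I_i$ by coupling sign. The
E/I tension
$T_i = 1 - \langle I_i\rangle / (\langle I^E_i\rangle + \langle|I^I_i|\rangle)$
is 0 without inhibition and 1 under exact mean cancellation; time averages
are plain averages over the post-burn-in window, quiescent steps included.
Because the input is linear in the presynaptic state and each stream has
constant sign, the per-neuron time averages reduce to
$\langle I^E_i \rangle = (J^+\bar{s})_i$ with $\bar{s}$ the mean activity
vector — so the network tension is computed from spike counts alone, with no
stored input series; the test suite checks this identity against the full
decomposition on small runs.

The area-based definition of the asynchrony index leaves the correlogram
estimator open, so the package makes a standard, bounded, scale-free choice:
input series are reconstructed for a random subset of neurons (default 60)
over a window (default 5000 steps), standardized over the window, and lagged
products are averaged over a random sample of 2000 ordered pairs at lags
$-20 \ldots 20$; the E and I correlograms pair E-inputs with E-inputs and
I-inputs with I-inputs. Standardizing once over the window (rather than per
lag segment) differs from per-segment Pearson by $O(\mathrm{lag}/W)$.
Areas are plain sums over the 41 lags — negative lobes legitimately
subtract — and the asynchrony index is
$\eta = 1 - A_{Total}/[(A_{EE} + A_{II})/2]$. Since the estimator details
are a package choice, absolute $\eta$ values may sit on a smooth monotone
transform of any other implementation's; the meaningful, tested content is
the ordering (near 0 at $g = 1$, rising sharply beyond $g = 2$, above 0.9
at $g = 4$) and the identities $\eta = 0$ when the total area equals the
mean single-stream area and $\eta = 1$ when total-input correlations vanish.

ISI statistics are computed in discrete steps; $CV_i = sd/mean$ of the
inter-spike intervals, and neurons with fewer than 3 spikes are excluded
from the population mean and counted. Bernoulli firing at low rate gives
geometric ISIs with $CV \approx 1$; bursty critical firing gives $CV > 1$.

## Sweeps, seeding, reproducibility

`run_phase_diagram()` and `run_boundary_scan()` drive the full stack over
$(g, w)$ grids and along the $\lambda_{max} = 1$ line. One master seed
spawns per-cell child seeds through `child_seed()`, a fixed affine
congruence modulo $2^{31}-1$, so any single cell can be re-run in isolation
and a rerun of a whole sweep is byte-identical. A connectivity draw is one
quenched realization; re-drawing under a new child seed is a new
realization, and scans default to 5 realizations per boundary point. Runs
with no avalanches or no spiking neurons produce `NA` plus a QC flag, never
silent zeros. Simulation state is binary throughout, rasters are stored as
event lists, and every artifact (connectivity, raster, curves, catalogs)
round-trips through plain-text formats with JSON sidecars carrying the
generating parameters and seeds; a dense binary container was deliberately
not added, since the triplet text round-trips exactly and keeps artifacts
diffable.

## What the simulations do and do not show

All inputs are generated by the model itself; there is no external data.
The synthetic conditions emulate the study design — Erdős–Rényi topology at
$p = 0.2$, uniform weight distributions, fixed weak external drive — under
which the documented continuum from synchronous/critical to asynchronous
dynamics emerges. Passing tests therefore validate the implementation of
this model family, not claims about cortical tissue: real networks have
structured topology, weight heterogeneity beyond uniform, conductance
dynamics, and refractoriness, all outside scope.

Two quantitative caveats recur in the test surface and are worth stating
plainly. First, the average-weight semi-analytic branching function is
biased low by up to $\sqrt{4/3}$ in the strong-synapse regime (see above),
so empirical/semi-analytic consistency at 3 standard errors holds on the
weak-synapse boundary but not at $g = 4$; the avalanche threshold derived
from it at $g = 4$ is correspondingly lower than a threshold derived from
the measured branching function would be. Second, quenched realization
variance at $g = 4$ is substantial (the finite-$N$ spectral radius
fluctuates 5–30% above 1), so the avalanche deviation statistic
$\kappa$ at $g = 4$ averages near 0.9 rather than 0.8 under these
conditions with 5 realizations, while the tension ($\approx 1$), ISI CV
($\approx 0.95$) and asynchrony ordering reproduce cleanly. Both effects
are properties of the stated pipeline, stable under longer runs, and
documented rather than tuned away.

## Problem sizes used

Scans and acceptance analyses use $N = 1000$, 2×10⁵ post-burn-in steps and
5 realizations per condition; branching curves use 200 trials per grid
point; correlograms use 60 neurons, 5000-step windows and 2000 ordered
pairs. These sizes were chosen so the complete analysis of one boundary
point takes seconds and the full reported set a few minutes, while keeping
standard errors on the headline statistics well inside the tolerances of
interest.
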