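---
title: "Models and methods behind wmprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wmprior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`wmprior` models how delayed estimates of a circular stimulus feature
are degraded and biased, and how those biases can be *learned* from the
statistics of the environment. This vignette is the package's own
account of the models, their assumptions, the tunable parameters, and
the numerical and design choices that were genuinely open.

## The particle model

The remembered estimate is a particle on the ring `[-pi, pi)`:

    dtheta = -U'(theta) dt + sigma dW(t)

with `sigma` in rad s^-1/2 (default 0.05) over a delay `T_delay`
(default 5 s), integrated by Euler-Maruyama at `dt` = 10 ms. Positions
are kept continuous during integration; the 1-degree state
discretization enters only at readout (histograms, likelihood bins).
Snapping positions to bins during integration would inject spurious
quantization noise into the SDE, so it is deliberately avoided.

Parametric landscapes use `U = -(A_p/n) cos(n (theta - theta_off))`.
Two printed conventions for the amplitude exist (with and without the
`1/n`); the per-well scaling is the default because it makes the drift
equal `-A_p sin(n (theta - theta_off))`, exactly the drift term of the
fitted heterogeneous response models; the plain scaling is available
via `scaling = "plain"`. The offset enters as `sin(n (theta -
theta_off))`: the fitted offset domain `[0, pi/2]` then covers exactly
one period at `n = 4`, which is the only reading under which that
domain is a non-redundant parameterization.

## Stationary densities, posteriors, and learning

The Fokker-Planck equation `p_t = (U' p)_theta + (sigma^2/2)
p_thetatheta` has the Boltzmann stationary state `p ~ exp(-2
U/sigma^2)`. For weak heterogeneity this links a posterior `L = 1/(2
pi) + l(theta)` to a landscape `U ~ -sigma^2 pi l(theta)`
(`posterior_to_landscape`), accurate to second order in the amplitude
of `l`.

Sequential learning updates the landscape after each trial,

    U_N = ((N-1) U_{N-1} + h - s f_vM(theta - theta_N; beta)) / N,

a symmetric running average of inverted von Mises kernels, hence
exactly permutation-invariant in the stimulus history. The kernel is
the *normalized* von Mises density by default: with the defaults
(`s = 5`, `beta = 8`) an unnormalized `exp(beta cos)` kernel would have
depth ~3000 and dwarf every other term, while constant shifts are
gauge-irrelevant to the dynamics; the unnormalized variant is kept
behind `normalize = FALSE`. In the long run the landscape converges to
`h - s (P_env * f_vM)` (`longrun_landscape`): for an exp-cosine prior
with `m` peaks this is a mode-`m` cosine with wells at the prior peaks,
because the von Mises kernel has positive Fourier coefficients at every
mode.

Defaults for the learning rule (`beta = 8`, `s = 5`, `h = 0.25`) and
the particle (`sigma = 0.05`, `A_p = 1`, `n = 4`, `T_delay = 5`) are
the study's standard parameter set.

### A note on drift-dominated defaults

At those standard values the drift is ~100 times stronger than
diffusion: wells trap completely (barrier ~400 in units of
`sigma^2/2`), a target started near a saddle rolls all the way to a
well, and an environment-matched landscape *raises* the prior-averaged
distortion under a broad exp-cosine prior (the quantization error
exceeds the diffusion it prevents). The matched-landscape efficiency
advantage at these values appears when the stimulus distribution
concentrates targets within roughly the diffusion width of the wells —
e.g. the task's biased distribution of four 20-degree arcs — and that
is the distribution the efficiency comparison uses. In
diffusion-competitive regimes (e.g. `sigma = 0.3`, `A_p = 0.05`, used
for the stationarity checks) wells also reduce effective diffusion in
the classical way.

## Fokker-Planck numerics

Space is discretized by a conservative finite-volume scheme with
exponentially fitted (Scharfetter-Gummel / Chang-Cooper) interface
fluxes; this makes the *discrete* stationary state exactly Boltzmann at
any drift strength and preserves positivity. Time stepping is backward
Euler, whose step matrix is an M-matrix: unconditionally stable,
mass-conserving to round-off, positivity-preserving, and sharing the
exact stationary state, so long horizons use proportionally larger
steps (capped at 20 000 steps) instead of sub-stepping against a CFL
limit. The one-step matrix is reused across steps (sparse LU), and
`fp_kernel` exponentiates it to return the full transition matrix —
every conditional response distribution at once.

Wells can be sharper than the 1-degree output grid (stationary width
`sigma / sqrt(2 U'')`, e.g. 1 degree at `sigma = 0.05`, `A_p = 1`,
`n = 4`), so conditionals are solved on an automatically refined
subgrid (~3 fine bins per stationary width, odd refinement factor so
fine bins sit symmetrically inside each output bin) and aggregated.
Likelihoods are conditional bin masses divided by the bin width,
floored at 1e-12 to keep log-likelihood ratios finite. Delta initial
conditions put all mass in one bin, matching the 1-degree readout
convention.

## The synthetic task

`make_session` emulates the two-item delayed-estimation protocol: per
trial a target and distractor are drawn independently; each item is
biased with probability 0.5, in which case it comes from one of four
20-degree arcs (uniform within the arc — the simplest reading of
"peaks spanning 20 degrees", taken as *full* width) centered at the
subject's randomly assigned offset plus multiples of 90 degrees;
otherwise it is uniform. 100 short (0.5 s) and 100 long (4 s) trials
are interleaved in random order. The cued item is by convention the
`target` column; none of the models use cue identity beyond the
target/distractor roles, and swap errors are not modeled (the response
models never produce them). What passing tests on these synthetic
subjects shows is that the *pipeline* recovers known generators under
the task's stimulus statistics; they cannot show anything about
sequential effects, lapses, or motor noise in real data, which the
generator does not emulate.

## Model fitting

Eight response models are fitted per subject and delay class: Flat
(sigma), StaticHet (sigma, A_p, n; wells at the assigned offset),
OffsetHet (+ free offset in [0, pi/2]), DualHet (two cosine components,
5 parameters), and four learning variants (sigma, beta, s; target-only
vs target+distractor kernels; flat vs population-bias 4-well initial
landscape `-cos(4(theta - pop_offset))`). Parameters are drawn
uniformly from bounded domains (sigma [0.01, 0.2], amplitudes
[0.1, 2], well numbers integer 1-12 — wells must be whole — offset
[0, pi/2], beta and s [1, 10]). Scoring is the mean squared
shortest-arc error (rad^2) between simulated and observed responses;
5-fold cross-validation holds out a random 20% of trials per fold
(uniform without replacement, seeded), picks the best training-set
parameter draw, and records its held-out MSE; the model with the lowest
mean held-out MSE wins, ties broken toward fewer free parameters.
For learning models the landscape evolves in chronological order using
only *training* stimuli that precede the simulated trial; a trial's own
stimuli never influence its own response. Default search sizes are 100
parameter sets x 100 replicates; the recovery experiments in the tests
and acceptance script use 25 x 25 with 50 trials per delay class,
which keeps a three-model comparison under ~15 s per subject while
still recovering the generating class.

`trial_llr` compares a learning against a fixed model trial by trial
using the exact PDE likelihoods, with the learning landscape evolved by
the full stimulus history before each trial.

## The neural field model

Activity `u(x, t)` on the ring obeys

    du = [-u + int w(x - y) (1 + h(y)) H(u(y) - kappa) dy] dt
         + eps u dW(x, t) + I(x, t) dt

with `w(d) = exp(-d^2) - A_inh exp(-d^2/sigma_inh^2)`, presynaptic
heterogeneity `h` (fixed `A_n cos(n x)` or the learned modulation
`s(y, t)`), a transient Gaussian cue, and multiplicative noise obtained
by filtering space-time white noise with `eps exp(-|d|)` (cell
increments carry `sqrt(dx dt)`, so the per-site variance is `dt int
F^2`, independent of the discretization). The bump's half-width `a`
solves the classical threshold condition `int_0^{2a} w = kappa`; the
centroid (argmax, ties broken by the circular mean of tied bins) is the
reported estimate.

**Spatial units.** The printed parameter table is only self-consistent
if all spatial numbers are in simulation length units on a ring of
circumference 36 (equivalently, one unit = 10 degrees of feature
space; `36 / 0.036 = 1000` grid points exactly). That is the default
(`ring_units = 36`): the stable bump half-width is then ~1.5 units
(15 degrees), narrow against the 90-degree well spacing, and
potentiated locations attract the bump — the behavior the model's
asymptotics and its figures describe. Reading the same numbers in
radians (`ring_units = 2*pi`) gives an 86-degree half-width bump that
is *repelled* by potentiated sites (the mode-4 component of so wide a
bump is negative); the option is kept because it is the other literal
reading, but it inverts the model's intended phenomenology.

**Plasticity.** Once per trial, at the end of the cue, the modulation
profile is updated. The default is the retention reading

    s <- gamma_s s + beta_s (1 - gamma_s) u(., t_inp),

an exponential moving average of `beta_s u` with a weak `1 - gamma_s`
(1%) decay per trial — consistent with "weak decay", with a fixed point
`beta_s E[u]` of amplitude comparable to the fixed heterogeneity, and
with a long-run profile proportional to the prior convolved with the
bump shape (mode-m, aligned, since the imprinted profile has positive
Fourier coefficients). Applying the printed increment
`beta_s u - gamma_s s` literally retains only 1% of the profile per
trial and can never accumulate the prior's structure; it is available
as `rule = "literal"`.

**Reduction.** Projecting perturbations onto the adjoint nullspace of
the linearized bump operator gives the drift
`U'(pos) = alpha int_{-a}^{a} [w(y - a) - w(a + y)] h(y + pos) dy` with
`alpha = 1/(2 (w(2a) - w(0)))`; with this orientation the predicted
drift matches the sign of the simulated centroid velocity at every
probe. For single-mode heterogeneity the integral evaluates exactly
mode by mode (`drift_fourier`). The narrow-bump limit was re-derived:
Taylor expansion of the integrand gives
`U' -> -(4/3) alpha a^4 w''(0) h'` (a trapezoidal end-point evaluation
of the same integral has the right proportionality `U ~ -h` but
overestimates the constant threefold), and the implementation uses the
Taylor form, which matches direct quadrature to ~2% at `a = 0.1`
kernel units.

**Known limitation.** At the table's noise strength the bump's argmax
jitter (a mean-reverting shape fluctuation, s.d. ~4 degrees)
dominates the true positional diffusion predicted by the reduction
(~0.002 units^2/s), so centroid variance saturates within ~1 s rather
than growing linearly over the 10 s delay, and the fixed-heterogeneity
network's drift cost exceeds its pinning benefit: those two field-level
orderings are not reproduced at these parameter values. All learning
results are — dominant mode, phase alignment, correlation with the
matched profile, decreasing session distortion, and re-adaptation
after an environment shift. The two failing acceptance checks assert
the orderings anyway and are retained deliberately rather than
re-tuned.

## Problem sizes

Unit tests run in ~20 s (Monte-Carlo sizes 1e4-1e5, 200-2000 replicates
per target). The acceptance checks use the study's own sizes where
stated — 1e5 simulations per conditional, N_boot = 200-1000, a 2000 s
stationarity run, 300-trial field sessions, 10-seed recovery at
25 parameter sets x 25 replicates — and the acceptance script scales
the recovery experiment to 6 seeds per generator. All randomness
derives from a single seed through a documented per-component
derivation, so every run is bit-for-bit reproducible.
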