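# wmprior

Attractor models of how learned environmental priors bias working-memory
delayed estimates.

In a delayed-estimation task an observer briefly sees a stimulus whose
feature value θ lives on a ring (a color angle, an orientation), retains
it over a delay, and reports it on a continuous scale. Reports drift and
diffuse over the delay, and they are systematically biased toward
*common* feature values. `wmprior` implements a family of models in which
the remembered estimate evolves as a particle on an energy landscape,

    dθ(t) = -U'(θ(t)) dt + σ dW(t),

where wells of U(θ) are attractors of the memory. The landscape can be

- **flat** (pure diffusion),
- **static heterogeneous**, U(θ) = -(A_p/n) cos(n(θ - θ_off)), with `n`
  wells of amplitude `A_p` aligned to the environment, or
- **learned from experience**: after each trial the landscape is updated
  with an inverted von Mises kernel at the observed stimulus,
  U_N = ((N-1) U_{N-1} + h - s f_vM(θ - θ_N; β)) / N, which is the
  energy-landscape form of sequential Bayesian updating of a stimulus
  prior. In the long run U_∞ ∝ -(P_env * f_vM), a mode-m cosine with
  wells at the prior's peaks.

Around this core the package provides:

- the **Fokker–Planck** propagation of the position density
  ∂_t p = ∂_θ[U' p] + (σ²/2) ∂²_θ p (exponentially fitted finite
  volumes, exact discrete Boltzmann stationary state), giving exact
  conditional/marginal response distributions and response likelihoods;
- **distortion** metrics d̄(θ) = E[1 - cos(θ - θ')] and their
  prior-weighted total, with percentile-bootstrap variability;
- a stochastic **neural field** model u(x,t) with lateral-inhibitory
  connectivity, Heaviside firing, multiplicative spatially correlated
  noise, presynaptic plasticity that learns the stimulus distribution,
  and the asymptotic reduction of its bump dynamics to the particle
  model (numeric, Fourier-mode, and narrow-bump forms);
- a **synthetic task generator** emulating the two-item protocol
  (biased 4-peak stimulus distribution with a random per-subject offset,
  short 0.5 s and long 4 s delays, 100 trials each);
- a cross-validated **model-fitting pipeline**: eight response models
  (flat / three fixed-heterogeneous / four learning variants), random
  parameter search on bounded domains, 5-fold cross-validation scored by
  mean squared circular error, model selection, and trial-by-trial
  learning-vs-fixed log-likelihood ratios from the PDE likelihoods.

## Worked example

Generate a synthetic subject whose responses come from a learning model,
then fit and compare model classes:

```r
library(wmprior)

sess <- make_session(assigned_offset = deg2rad(20),
                     n_short = 50, n_long = 50, seed = 2)
subj <- synthetic_subject("StaticHet",
                          list(sigma = 0.05, A_p = 1, n = 4),
                          sess, seed = 102,
                          assigned_offset = deg2rad(20))

fit <- wm_fit(subj,
              models = wm_models(c("Flat", "StaticHet",
                                   "LearnTargetFlatPrior")),
              delay_classes = "long",
              k_sets = 25, n_rep = 25, seed = 202)
print(fit)
#> Cross-validated working-memory response model fit
#> Subject: synthetic
#>   long  delay: StaticHet (fixed-heterogeneous), mean test MSE 0.0004 rad^2
coef(fit)
#>     sigma       A_p         n
#> 0.0141557 1.4009772 4.0000000
```

The winner is the generating model class, with the correct well number
n = 4 (the amplitude is only loosely identified once wells trap the
particle, and the best random draw's σ sits below the generating 0.05 —
held-out MSE of 4e-4 rad² is about a 1° circular error, the
within-well spread at these settings). A quick look at the science
itself:

```r
# distortion is lower at a common (attractor) target than a rare one
ls4 <- landscape("cosine", A_p = 1, n = 4)
pp  <- particle_params(sigma = 0.05, T_delay = 5, seed = 4)
r   <- simulate_responses(ls4, c(0, pi/4), pp, n_rep = 2000)
colMeans(1 - cos(sweep(r, 2, c(0, pi/4))))
#> [1] 0.0001649968 0.2927534856    # attractor vs saddle
```

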