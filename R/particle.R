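#' Particle (drift-diffusion) simulation parameters
#'
#' Defaults mirror the standard particle-model parameterization: noise
#' amplitude sigma = 0.05 rad s^-1/2, delay 5 s, Euler-Maruyama step 10 ms.
#'
#' @param sigma noise amplitude (>= 0), rad s^-1/2.
#' @param T_delay delay duration, seconds (>= 0).
#' @param dt integration step, seconds (> 0).
#' @param seed optional integer seed.
#' @return an object of class `particle_params`.
#' @export
particle_params <- function(sigma = 0.05, T_delay = 5, dt = 0.01,
                            seed = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  if (T_delay < 0) stop("T_delay must be >= 0")
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = sigma, T_delay = T_delay, dt = dt, seed = seed),
            class = "particle_params")
}

#' Simulate one particle trajectory on the ring
#'
#' Euler-Maruyama integration of
#' `d theta = -U'(theta) dt + sigma dW`:
#' `theta_{k+1} = wrap(theta_k - U'(theta_k) dt + sigma sqrt(dt) xi_k)`.
#' Positions are kept continuous during integration; the 1-degree
#' discretization of the state space is applied only when positions are
#' histogrammed or read out.
#'
#' @param spec a [landscape].
#' @param theta0 initial position, radians.
#' @param params a [particle_params].
#' @return list with `times` (seconds) and `positions` (radians, wrapped);
#'   the first position is `theta0`.
#' @examples
#' tr <- simulate_trajectory(landscape("flat"), 0,
#'                           particle_params(sigma = 0, T_delay = 1))
#' all(tr$positions == 0)
#' @export
simulate_trajectory <- function(spec, theta0, params = particle_params()) {
  n_steps <- round(params$T_delay / params$dt)
  pos <- numeric(n_steps + 1)
  pos[1] <- wrap_angle(theta0)
  with_seed(params$seed, {
    noise <- if (params$sigma > 0 && n_steps > 0)
      params$sigma * sqrt(params$dt) * rnorm(n_steps) else numeric(n_steps)
    th <- pos[1]
    for (k in seq_len(n_steps)) {
      th <- wrap_angle(th - landscape_gradient(spec, th) * params$dt +
                         noise[k])
      pos[k + 1] <- th
    }
  })
  list(times = seq(0, by = params$dt, length.out = n_steps + 1),
       positions = pos)
}

# translate a landscape into the compiled kernel's drift description
em_drift_args <- function(spec) {
  dummy <- matrix(0, 1, 360)
  switch(spec$kind,
    flat = list(mode = 0L, par = 0, rows = dummy),
    cosine = list(
      mode = 1L,
      par = c(if (spec$scaling == "per_well") spec$A_p
              else spec$A_p * spec$n, spec$n, spec$theta_off),
      rows = dummy),
    dual = list(mode = 2L,
                par = c(spec$A1, spec$n1, spec$A2, spec$n2,
                        spec$theta_off),
                rows = dummy),
    gridded = list(mode = 3L, par = 0,
                   rows = matrix(gridded_gradient(spec), 1)))
}

# vectorized Euler-Maruyama endpoint simulation (compiled kernel)
em_endpoints <- function(spec, theta0, sigma, dt, n_steps) {
  a <- em_drift_args(spec)
  em_sim_cpp(wrap_angle(theta0), integer(length(theta0)), a$mode, a$par,
             a$rows, sigma, dt, as.integer(n_steps))
}

#' Simulate end-of-delay responses for a set of targets
#'
#' For each target, `n_rep` independent particles are initialized at the
#' target and integrated for the delay; the end positions are the model's
#' responses. Per-target random streams are derived deterministically from
#' `params$seed` and the target index, so results are reproducible and
#' stable under re-ordering of work.
#'
#' @param spec a [landscape].
#' @param targets vector of target angles, radians.
#' @param params a [particle_params].
#' @param n_rep replicates per target (>= 1).
#' @return a matrix of responses with `n_rep` rows and one column per
#'   target (radians in \[-pi, pi)).
#' @export
simulate_responses <- function(spec, targets, params = particle_params(),
                               n_rep = 100L) {
  if (length(targets) == 0) stop("targets must be non-empty")
  if (n_rep < 1) stop("n_rep must be >= 1")
  n_steps <- round(params$T_delay / params$dt)
  out <- matrix(NA_real_, nrow = n_rep, ncol = length(targets))
  for (i in seq_along(targets)) {
    out[, i] <- with_seed(derive_seed(params$seed, i),
      em_endpoints(spec, rep(targets[i], n_rep), params$sigma,
                   params$dt, n_steps))
  }
  out
}
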