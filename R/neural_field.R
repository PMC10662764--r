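#' Neural field model parameters
#'
#' Parameters of the stochastic neural field
#' `du = [-u + int w(x - y) (1 + h(y)) f(u(y)) dy] dt + eps u dW + I dt`
#' on a ring of preferred feature values, with a Heaviside firing
#' nonlinearity `f(u) = H(u - kappa)`, a local-excitation /
#' broad-inhibition kernel
#' `w(d) = exp(-d^2) - A_inh exp(-d^2 / sigma_inh^2)`, spatially
#' correlated multiplicative noise with filter `eps * exp(-|d|)`, and a
#' transient Gaussian cue input of strength `I0` and width `sigma_inp`
#' lasting `t_inp` seconds.
#'
#' Spatial unit convention: kernel distances, `sigma_inp`, the noise
#' filter and `dx` are all expressed in simulation length units on a ring
#' of circumference `ring_units` (default 36, i.e. one unit = 10 degrees
#' of feature space, giving `36 / 0.036 = 1000` grid points). With these
#' units the stable bump half-width is about 1.5 units (15 degrees),
#' narrow relative to the 90-degree spacing of a 4-mode heterogeneity, so
#' potentiated locations attract the bump. Positions exchanged with the
#' rest of the package (targets, centroids, heterogeneity phase) are ring
#' angles in radians; the conversion factor is `2 * pi / ring_units`.
#' Setting `ring_units = 2 * pi` makes the length unit one radian of
#' feature space, in which case the same kernel supports a much wider
#' bump (half-width ~86 degrees) that is repelled by potentiated sites.
#'
#' @param A_inh inhibition strength. @param sigma_inh inhibitory spread.
#' @param A_n fixed-heterogeneity amplitude. @param n heterogeneity modes
#'   (per ring). @param kappa firing threshold. @param epsilon noise
#'   strength. @param I0 input strength. @param t_inp input duration, s.
#' @param sigma_inp input width (length units). @param T_delay delay, s.
#' @param dt time step, s. @param dx space step, length units.
#' @param beta_s presynaptic potentiation strength.
#' @param gamma_s depression factor in (0, 1).
#' @param ring_units ring circumference in length units.
#' @param seed optional seed.
#' @return object of class `field_params`, including `n_x`, the unit grid
#'   `y_grid` and the ring-angle grid `x_grid` (radians).
#' @export
field_params <- function(A_inh = 0.35, sigma_inh = 3, A_n = 0.4, n = 4L,
                         kappa = 0.1, epsilon = 0.5, I0 = 1, t_inp = 0.5,
                         sigma_inp = 1, T_delay = 10, dt = 0.1,
                         dx = 0.036, beta_s = 0.8, gamma_s = 0.99,
                         ring_units = 36, seed = NULL) {
  if (gamma_s <= 0 || gamma_s >= 1) stop("gamma_s must be in (0, 1)")
  n_x <- round(ring_units / dx)
  dx <- ring_units / n_x
  y_grid <- -ring_units / 2 + (seq_len(n_x) - 1) * dx
  structure(list(A_inh = A_inh, sigma_inh = sigma_inh, A_n = A_n,
                 n = as.integer(n), kappa = kappa, epsilon = epsilon,
                 I0 = I0, t_inp = t_inp, sigma_inp = sigma_inp,
                 T_delay = T_delay, dt = dt, dx = dx, n_x = n_x,
                 ring_units = ring_units, y_grid = y_grid,
                 x_grid = y_grid * 2 * pi / ring_units,
                 beta_s = beta_s, gamma_s = gamma_s, seed = seed),
            class = "field_params")
}

# wrap a distance onto [-C/2, C/2)
wrap_units <- function(d, C) ((d + C / 2) %% C) - C / 2

#' Synaptic weight kernel
#'
#' Distance-dependent connectivity combining local excitation and broad
#' inhibition; distances are circular, in simulation length units.
#'
#' @param params a [field_params].
#' @param delta circular distance(s), length units.
#' @return synaptic weight(s).
#' @export
weight_kernel <- function(params, delta) {
  d <- wrap_units(delta, params$ring_units)
  exp(-d^2) - params$A_inh * exp(-d^2 / params$sigma_inh^2)
}

# antiderivative W(z) = int_0^z w by fine quadrature + spline
kernel_antideriv <- function(params, z) {
  zmax <- params$ring_units / 2
  zg <- seq(0, zmax, length.out = 4097)
  wg <- weight_kernel(params, zg)
  Wg <- c(0, cumsum((wg[-1] + wg[-length(wg)]) / 2 * diff(zg)))
  stats::spline(zg, Wg, xout = pmin(abs(z), zmax))$y * sign(z)
}

#' Stationary bump half-width (Amari construction)
#'
#' With a Heaviside nonlinearity and no noise or heterogeneity, a bump of
#' half-width `a` satisfies the threshold condition `B(a) = kappa` where
#' `B(a) = int_0^{2a} w(z) dz` is the recurrent drive at the bump edge.
#' The wider root with `w(2a) < 0` (drive decreasing in width) is the
#' stable bump; `NULL` is returned if no such root exists.
#'
#' @param params a [field_params].
#' @return list with `a` (half-width, length units), `a_rad` (radians of
#'   feature space) and `edge_slope` (`w(2a)`, negative at a stable
#'   root), or `NULL` if no bump exists.
#' @export
bump_halfwidth <- function(params) {
  fcond <- function(a) kernel_antideriv(params, 2 * a) - params$kappa
  amax <- params$ring_units / 4 - 1e-3
  as <- seq(1e-3, amax, length.out = 1024)
  fv <- vapply(as, fcond, numeric(1))
  roots <- c()
  for (i in seq_len(length(as) - 1))
    if (fv[i] * fv[i + 1] < 0)
      roots <- c(roots,
                 stats::uniroot(fcond, c(as[i], as[i + 1]),
                                tol = 1e-12)$root)
  if (!length(roots)) return(NULL)
  stable <- roots[weight_kernel(params, 2 * roots) < 0]
  if (!length(stable)) return(NULL)
  a <- max(stable)
  list(a = a, a_rad = a * 2 * pi / params$ring_units,
       edge_slope = weight_kernel(params, 2 * a))
}

#' @rdname bump_halfwidth
#' @param x positions, length units.
#' @param a bump half-width, length units.
#' @return `bump_profile` returns the noise-free bump activity
#'   `U(x) = int_{x-a}^{x+a} w(z) dz`.
#' @export
bump_profile <- function(params, x, a) {
  kernel_antideriv(params, x + a) - kernel_antideriv(params, x - a)
}

# precomputed dense operators for the discretized field
field_ops <- function(params) {
  D <- outer(params$y_grid, params$y_grid,
             function(a, b) wrap_units(a - b, params$ring_units))
  # noise filter applied to space-time white noise: each cell's increment
  # has variance dx * dt, so the filter matrix carries sqrt(dx) and the
  # filtered increment variance per site is dt * int F^2 dy, independent
  # of the discretization
  list(W = weight_kernel(params, D) * params$dx,
       NF = params$epsilon * exp(-abs(D)) * sqrt(params$dx))
}

# circular argmax (ring angle) with ties broken by the circular mean of
# tied bins
field_centroid <- function(u, x_grid) {
  m <- max(u)
  tied <- which(u >= m - 1e-12)
  if (length(tied) == 1L) return(x_grid[tied])
  atan2(mean(sin(x_grid[tied])), mean(cos(x_grid[tied])))
}

#' Simulate one delay-period trial of the neural field
#'
#' Euler-Maruyama integration of the discretized field with Riemann-sum
#' convolution. The cue input is on for `t < t_inp`; the delay runs to
#' `t_inp + T_delay`. Heterogeneity enters presynaptically as a
#' `(1 + h(y))` scaling of outgoing weights; `h` is either the fixed ring
#' profile `A_n cos(n theta)`, a learned modulation profile `s_mod`, or
#' absent. Multiplicative noise is generated by filtering iid Gaussian
#' increments with `eps * exp(-|d|)`. Independent replicates are
#' integrated in parallel as columns.
#'
#' @param params a [field_params].
#' @param x_targ target position(s), ring angle in radians (recycled
#'   across replicates).
#' @param heterogeneity `"none"`, `"fixed"`, or `"learned"`.
#' @param s_mod modulation profile for `heterogeneity = "learned"`.
#' @param n_rep number of independent replicates.
#' @param seed optional seed.
#' @param record_centroid record the centroid at every step.
#' @param ops precomputed [field_ops] (internal reuse across trials).
#' @return list with `x_grid` (radians), `u` (final activity,
#'   `n_x x n_rep`), `u_stim` (activity at the end of the cue),
#'   `centroid` (matrix `[n_steps+1 x n_rep]` if recorded), `times`, and
#'   `response` (end-of-delay centroid per replicate, radians).
#' @export
simulate_field_trial <- function(params, x_targ,
                                 heterogeneity = c("none", "fixed",
                                                   "learned"),
                                 s_mod = NULL, n_rep = 1L, seed = NULL,
                                 record_centroid = TRUE, ops = NULL) {
  heterogeneity <- match.arg(heterogeneity)
  nx <- params$n_x
  xg <- params$x_grid
  h <- switch(heterogeneity,
              none = rep(0, nx),
              fixed = params$A_n * cos(params$n * xg),
              learned = {
                if (is.null(s_mod) || length(s_mod) != nx)
                  stop("learned heterogeneity needs s_mod of length n_x")
                s_mod
              })
  if (is.null(ops)) ops <- field_ops(params)
  x_targ <- rep_len(x_targ, n_rep)
  targ_units <- x_targ * params$ring_units / (2 * pi)
  Imat <- params$I0 *
    exp(-outer(params$y_grid, targ_units,
               function(a, b) wrap_units(a - b, params$ring_units))^2 /
          (2 * params$sigma_inp^2))
  n_inp <- round(params$t_inp / params$dt)
  n_del <- round(params$T_delay / params$dt)
  n_steps <- n_inp + n_del
  u <- matrix(0, nx, n_rep)
  u_stim <- NULL
  cent <- if (record_centroid) matrix(NA_real_, n_steps + 1, n_rep)
  sqdt <- sqrt(params$dt)
  with_seed(seed, {
    if (record_centroid)
      cent[1, ] <- apply(u, 2, field_centroid, x_grid = xg)
    for (k in seq_len(n_steps)) {
      f <- (u >= params$kappa) * 1
      drive <- ops$W %*% ((1 + h) * f)
      du <- (-u + drive) * params$dt
      if (k <= n_inp) du <- du + Imat * params$dt
      if (params$epsilon > 0)
        du <- du + u * (ops$NF %*% matrix(rnorm(nx * n_rep), nx)) * sqdt
      u <- u + du
      if (max(abs(u)) > 1e3)
        stop("neural field activity blew up (|u| > 1e3) at t = ",
             k * params$dt)
      if (k == n_inp) u_stim <- u
      if (record_centroid)
        cent[k + 1, ] <- apply(u, 2, field_centroid, x_grid = xg)
    }
  })
  response <- apply(u, 2, field_centroid, x_grid = xg)
  list(x_grid = xg, u = u, u_stim = u_stim,
       centroid = if (record_centroid) cent else response,
       times = seq(0, by = params$dt, length.out = n_steps + 1),
       response = response)
}

#' Presynaptic plasticity update
#'
#' Once per trial, at stimulation time, the presynaptic modulation
#' profile is potentiated by the activity profile and depressed toward
#' zero. With the default `"retention"` reading the update is an
#' exponential moving average,
#' `s <- gamma_s * s + beta_s * (1 - gamma_s) * u`,
#' i.e. a weak `(1 - gamma_s)` decay per trial of what has not been
#' re-stimulated, settling at amplitude `beta_s * E[u]`. The `"literal"`
#' reading applies the increment `beta_s * u - gamma_s * s` exactly as
#' stated, which retains only a `(1 - gamma_s)` fraction of the previous
#' profile on every trial.
#'
#' @param s_mod current modulation profile.
#' @param u_stim activity profile at the stimulation time.
#' @param params a [field_params].
#' @param rule `"retention"` (default) or `"literal"`.
#' @return updated modulation profile.
#' @export
plasticity_update <- function(s_mod, u_stim, params,
                              rule = c("retention", "literal")) {
  rule <- match.arg(rule)
  if (length(s_mod) != length(u_stim))
    stop("s_mod and u_stim must be on the same grid")
  if (rule == "retention")
    params$gamma_s * s_mod +
      params$beta_s * (1 - params$gamma_s) * u_stim
  else
    (1 - params$gamma_s) * s_mod + params$beta_s * u_stim
}

#' Run an experience-dependent learning session of the neural field
#'
#' Targets are sampled from the environmental prior; each trial encodes
#' the target, holds it over the delay, reads out the centroid as the
#' response, and applies the presynaptic plasticity update using the
#' activity at stimulation time. Returns the evolving modulation profile
#' and the per-trial distortion trace.
#'
#' @param params a [field_params].
#' @param prior an [env_prior] supplying targets.
#' @param n_trials number of trials (>= 1).
#' @param seed optional seed.
#' @param rule plasticity rule, see [plasticity_update].
#' @param s_init optional initial modulation profile (default zero).
#' @param keep_trace keep the per-trial modulation profiles (rows of
#'   `s_trace`); disable to save memory on long sessions.
#' @return list with `s_mod` (final profile), `s_trace`, `targets`,
#'   `responses`, `distortion` (per-trial `1 - cos` error) and
#'   `running_distortion` (running mean).
#' @export
run_field_session <- function(params, prior, n_trials, seed = NULL,
                              rule = c("retention", "literal"),
                              s_init = NULL, keep_trace = FALSE) {
  rule <- match.arg(rule)
  if (n_trials < 1) stop("n_trials must be >= 1")
  s_mod <- if (is.null(s_init)) rep(0, params$n_x) else s_init
  targets <- sample_stimuli(prior, n_trials, seed = derive_seed(seed, 0L))
  dist <- numeric(n_trials)
  resp <- numeric(n_trials)
  s_trace <- if (keep_trace) matrix(NA_real_, n_trials, params$n_x)
  ops <- field_ops(params)
  for (t in seq_len(n_trials)) {
    tr <- simulate_field_trial(params, targets[t],
                               heterogeneity = "learned", s_mod = s_mod,
                               n_rep = 1L, seed = derive_seed(seed, t),
                               record_centroid = FALSE, ops = ops)
    resp[t] <- tr$response
    dist[t] <- 1 - cos(tr$response - targets[t])
    s_mod <- plasticity_update(s_mod, tr$u_stim[, 1], params, rule = rule)
    if (keep_trace) s_trace[t, ] <- s_mod
  }
  list(s_mod = s_mod, s_trace = s_trace, targets = targets,
       responses = resp, distortion = dist,
       running_distortion = cumsum(dist) / seq_len(n_trials))
}

#' Numeric drift of the bump-position reduction
#'
#' To first order, the bump position obeys a drift-diffusion equation
#' whose drift derives from the weight heterogeneity:
#' `U'(pos) = alpha * int_{-a}^{a} [w(y - a) - w(a + y)] h(y + pos) dy`,
#' with `alpha = 1 / (2 (w(2a) - w(0)))` from projecting onto the adjoint
#' nullspace of the linearized bump operator. The integral is evaluated
#' in kernel length units and the gradient converted to ring radians, so
#' `-dU` is directly comparable to the measured centroid velocity in
#' rad/s.
#'
#' @param params a [field_params].
#' @param h_fun heterogeneity profile: a function of ring angle
#'   (radians), e.g. `function(th) 0.4 * cos(4 * th)`.
#' @param a bump half-width in length units (default from
#'   [bump_halfwidth]).
#' @param theta ring angles (radians) at which to evaluate the drift.
#' @param n_quad quadrature points.
#' @return list with `theta`, `dU` (energy gradient, rad/s), `U`
#'   (integrated energy, mean-removed) and `alpha`.
#' @export
reduction_drift <- function(params, h_fun, a = NULL,
                            theta = ring_grid()$centers,
                            n_quad = 2001L) {
  if (is.null(a)) a <- bump_halfwidth(params)$a
  alpha <- 1 / (2 * (weight_kernel(params, 2 * a) -
                       weight_kernel(params, 0)))
  to_rad <- 2 * pi / params$ring_units
  y <- seq(-a, a, length.out = n_quad)
  wts <- rep(2 * a / (n_quad - 1), n_quad)
  wts[c(1, n_quad)] <- wts[1] / 2                    # trapezoid
  wdiff <- weight_kernel(params, y - a) - weight_kernel(params, a + y)
  dU <- vapply(theta, function(th)
    alpha * sum(wts * wdiff * h_fun(y * to_rad + th)), numeric(1)) * to_rad
  h <- if (length(theta) > 1) diff(theta[1:2]) else 1
  U <- cumsum(dU) * h
  list(theta = theta, dU = dU, U = U - mean(U), alpha = alpha)
}

# Fourier cosine coefficients of the (even, wrapped) kernel on the unit
# ring: w(d) = w_0 + sum_k w_k cos(k * d * 2 pi / C)
kernel_fourier <- function(params, k_max = 80L) {
  C <- params$ring_units
  zg <- seq(-C / 2, C / 2, length.out = 16385)[-1]
  wg <- weight_kernel(params, zg)
  dz <- zg[2] - zg[1]
  om <- 2 * pi / C
  w0 <- sum(wg) * dz / C
  wk <- vapply(seq_len(k_max),
               function(k) sum(wg * cos(k * om * zg)) * dz * 2 / C,
               numeric(1))
  c(w0, wk)
}

#' Dominant-Fourier-mode approximation of the reduction drift
#'
#' For heterogeneity dominated by a single even ring mode,
#' `h ~ b_m cos(m theta)`, the reduction integral evaluates mode by mode:
#' `U'(pos) = 2 alpha_m sin(m pos)` and
#' `U(pos) = -(2 alpha_m / m) cos(m pos)`, with
#' `alpha_m = -alpha b_m sum_k w_k sin(k om a) I_km`, where `om` is the
#' ring mode spacing `2 pi / ring_units`, `w_k` are the kernel's ring
#' Fourier coefficients, and
#' `I_km = int_{-a}^{a} sin(k om y) sin(m om y) dy`.
#'
#' @param params a [field_params].
#' @param b_m amplitude of the dominant cosine mode of the heterogeneity.
#' @param m the dominant ring mode.
#' @param a bump half-width in length units (default from
#'   [bump_halfwidth]).
#' @param k_max number of kernel Fourier modes summed.
#' @return list with `alpha_m`, and functions `dU(theta)`, `U(theta)` of
#'   ring angle (radians), on the same scale as [reduction_drift].
#' @export
drift_fourier <- function(params, b_m, m, a = NULL, k_max = 80L) {
  if (is.null(a)) a <- bump_halfwidth(params)$a
  alpha <- 1 / (2 * (weight_kernel(params, 2 * a) -
                       weight_kernel(params, 0)))
  om <- 2 * pi / params$ring_units
  wk <- kernel_fourier(params, k_max)[-1]
  ks <- seq_len(k_max)
  I_km <- ifelse(ks == m,
                 a - sin(2 * m * om * a) / (2 * m * om),
                 sin((ks - m) * om * a) / ((ks - m) * om) -
                   sin((ks + m) * om * a) / ((ks + m) * om))
  alpha_m <- -alpha * b_m * sum(wk * sin(ks * om * a) * I_km) * om
  list(alpha_m = alpha_m,
       dU = function(theta) 2 * alpha_m * sin(m * theta),
       U = function(theta) -(2 * alpha_m / m) * cos(m * theta))
}

#' Narrow-bump approximation of the reduction drift
#'
#' When the bump is narrow relative to both the kernel length scale and
#' the heterogeneity wavelength, Taylor expansion of the reduction
#' integrand (`w(y-a) - w(y+a) ~ -2 a w''(0) y` and
#' `h(y + pos) ~ h(pos) + y h'(pos)`) collapses the integral to
#' `U(pos) ~ -(4/3) alpha a^4 w''(0) h(pos)`: the energy landscape is
#' proportional to the negative of the heterogeneity profile, so
#' potentiated locations attract the bump. (A trapezoidal end-point
#' evaluation of the same integral gives the same proportionality with a
#' three-fold larger constant; the Taylor limit is the one that matches
#' the numeric integral as a -> 0.) A warning attribute is attached when
#' the regime is violated (`a_rad * m > 1` or `a > 0.5` kernel units).
#'
#' @param params a [field_params].
#' @param h_fun heterogeneity profile function of ring angle (radians).
#' @param a bump half-width, length units.
#' @param m heterogeneity ring mode used for the regime check.
#' @return list with function `U(theta)` (ring radians, same scale as
#'   [reduction_drift]), `coef` (the constant multiplying `-h`), and
#'   `regime_ok`.
#' @export
drift_narrowbump <- function(params, h_fun, a, m = params$n) {
  alpha <- 1 / (2 * (weight_kernel(params, 2 * a) -
                       weight_kernel(params, 0)))
  w2_0 <- -2 * (1 - params$A_inh / params$sigma_inh^2)
  to_rad <- 2 * pi / params$ring_units
  # two powers of the unit->radian factor: one from h'(ring angle), one
  # from expressing the gradient per radian of bump position
  coef <- (4 / 3) * alpha * a^4 * w2_0 * to_rad^2
  a_rad <- a * to_rad
  regime_ok <- (a_rad * m) <= 1 && a <= 0.5
  out <- list(U = function(theta) -coef * h_fun(theta), coef = coef,
              regime_ok = regime_ok)
  if (!regime_ok)
    attr(out, "warning") <-
      "bump half-width not small relative to heterogeneity wavelength"
  out
}
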