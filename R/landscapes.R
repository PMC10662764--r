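#' Energy landscapes on the ring
#'
#' The remembered estimate drifts down the gradient of a scalar potential
#' U(theta); wells (minima) are attractors of the memory and, when aligned
#' with the peaks of the environmental prior, stabilize common feature
#' values. Parametric kinds:
#' \describe{
#'   \item{`flat`}{U = 0 (homogeneous; pure diffusion).}
#'   \item{`cosine`}{U = -(A_p/n) cos(n (theta - theta_off)), so the drift
#'     is -U' = -A_p sin(n (theta - theta_off)). With `scaling = "plain"`
#'     the 1/n factor is omitted: U = -A_p cos(n (theta - theta_off)).}
#'   \item{`dual`}{superposition of two cosine components with amplitudes
#'     A1, A2 and well numbers n1, n2 sharing one offset; drift
#'     -A1 sin(n1(theta-off)) - A2 sin(n2(theta-off)).}
#'   \item{`gridded`}{arbitrary per-bin energies; gradients by centered
#'     periodic finite differences.}
#' }
#' The `cosine` convention with the 1/n factor is the default because it
#' makes the drift amplitude equal A_p regardless of well number, matching
#' the drift term of the fitted heterogeneous response models.
#'
#' @param kind one of `"flat"`, `"cosine"`, `"dual"`, `"gridded"`.
#' @param A_p well amplitude (>= 0) for the cosine kind.
#' @param n number of wells (positive integer) for the cosine kind.
#' @param theta_off circular offset of the wells, radians.
#' @param A1,A2,n1,n2 components of the dual kind.
#' @param values per-bin energies for the gridded kind (length = grid bins).
#' @param grid the [ring_grid] a gridded landscape lives on.
#' @param scaling `"per_well"` (amplitude divided by n, default) or
#'   `"plain"`.
#' @return an object of class `landscape`.
#' @examples
#' ls4 <- landscape("cosine", A_p = 1, n = 4)
#' eval_landscape(ls4, theta = 0)        # -0.25
#' landscape_gradient(ls4, pi / 8)       # 1 = A_p sin(pi/2)
#' @export
landscape <- function(kind = c("flat", "cosine", "dual", "gridded"),
                      A_p = 1, n = 4L, theta_off = 0,
                      A1 = 1, A2 = 0, n1 = 4L, n2 = 8L,
                      values = NULL, grid = ring_grid(),
                      scaling = c("per_well", "plain")) {
  kind <- match.arg(kind)
  scaling <- match.arg(scaling)
  if (kind == "cosine" && A_p < 0) stop("A_p must be >= 0")
  if (kind == "gridded") {
    if (is.null(values)) stop("gridded landscape needs values")
    if (length(values) != grid$n_bins)
      stop("values length must equal grid$n_bins")
  }
  structure(list(kind = kind, A_p = A_p, n = as.integer(n),
                 theta_off = wrap_angle(theta_off),
                 A1 = A1, A2 = A2, n1 = as.integer(n1), n2 = as.integer(n2),
                 values = values, grid = grid, scaling = scaling),
            class = "landscape")
}

#' @rdname landscape
#' @param spec a `landscape`.
#' @param theta angles (radians) at which to evaluate; defaults to the
#'   centers of `grid`.
#' @return `eval_landscape` returns per-angle energies.
#' @export
eval_landscape <- function(spec, theta = NULL, grid = ring_grid()) {
  if (!inherits(spec, "landscape")) stop("spec must be a landscape")
  if (is.null(theta)) theta <- grid$centers
  switch(spec$kind,
    flat = rep(0, length(theta)),
    cosine = {
      sc <- if (spec$scaling == "per_well") spec$A_p / spec$n else spec$A_p
      -sc * cos(spec$n * (theta - spec$theta_off))
    },
    dual = {
      -(spec$A1 / spec$n1) * cos(spec$n1 * (theta - spec$theta_off)) -
        (spec$A2 / spec$n2) * cos(spec$n2 * (theta - spec$theta_off))
    },
    gridded = {
      # periodic linear interpolation between bin centers
      g <- spec$grid
      h <- g$bin_width
      pos <- (wrap_angle(theta) + pi) / h
      i0 <- floor(pos)
      frac <- pos - i0
      i0 <- (as.integer(i0) %% g$n_bins) + 1L
      i1 <- (i0 %% g$n_bins) + 1L
      (1 - frac) * spec$values[i0] + frac * spec$values[i1]
    })
}

#' @rdname landscape
#' @return `landscape_gradient` returns dU/dtheta at `theta` (closed form
#'   for parametric kinds, centered periodic finite differences for the
#'   gridded kind).
#' @export
landscape_gradient <- function(spec, theta) {
  switch(spec$kind,
    flat = rep(0, length(theta)),
    cosine = {
      sc <- if (spec$scaling == "per_well") spec$A_p else spec$A_p * spec$n
      sc * sin(spec$n * (theta - spec$theta_off))
    },
    dual = {
      spec$A1 * sin(spec$n1 * (theta - spec$theta_off)) +
        spec$A2 * sin(spec$n2 * (theta - spec$theta_off))
    },
    gridded = {
      gvals <- gridded_gradient(spec)
      gvals[ring_bin(theta, spec$grid)]
    })
}

# centered periodic finite-difference gradient of a gridded landscape
gridded_gradient <- function(spec) {
  v <- spec$values
  n <- length(v)
  (v[c(2:n, 1)] - v[c(n, 1:(n - 1))]) / (2 * spec$grid$bin_width)
}

# per-bin gradient values on an arbitrary grid, exact for parametric kinds
gradient_on_grid <- function(spec, grid = ring_grid()) {
  if (spec$kind == "gridded") {
    if (identical(grid$n_bins, spec$grid$n_bins)) return(gridded_gradient(spec))
    g <- gridded_gradient(spec)
    idx <- ring_bin(grid$centers, spec$grid)
    return(g[idx])
  }
  landscape_gradient(spec, grid$centers)
}

#' Stationary (Boltzmann) density of a particle in a landscape
#'
#' In the long-time limit the position density of the drift-diffusion
#' process equals `p(theta) = chi * exp(-2 U(theta) / sigma^2)` with `chi`
#' a normalization constant.
#'
#' @param spec a [landscape].
#' @param sigma diffusion (noise) amplitude, rad s^-1/2 (> 0).
#' @param grid a [ring_grid].
#' @return a `density_grid` of per-bin probabilities.
#' @export
stationary_density <- function(spec, sigma, grid = ring_grid()) {
  if (sigma <= 0) stop("sigma must be > 0")
  u <- eval_landscape(spec, grid$centers, grid)
  w <- exp(-2 * (u - min(u)) / sigma^2)
  density_grid(w / sum(w), grid)
}

#' Landscape implied by a posterior over feature values
#'
#' For a weakly non-uniform posterior `L(theta) = 1/(2*pi) + l(theta)` (with
#' l integrating to zero), the energy landscape whose stationary density
#' matches L is, to linear order, proportional to `-l(theta)`; the constant
#' of proportionality is `sigma^2 * pi` from linearizing the Boltzmann
#' relation.
#'
#' @param l_variation per-bin deviation of the posterior density from
#'   uniform (must integrate to ~0).
#' @param sigma diffusion amplitude (> 0).
#' @param grid the [ring_grid] `l_variation` is defined on.
#' @return a gridded [landscape].
#' @export
posterior_to_landscape <- function(l_variation, sigma, grid = ring_grid()) {
  if (length(l_variation) != grid$n_bins)
    stop("l_variation length must equal grid$n_bins")
  if (abs(sum(l_variation) * grid$bin_width) > 1e-8 *
        max(1, max(abs(l_variation))))
    stop("l_variation must integrate to zero")
  u <- -sigma^2 * pi * l_variation
  landscape("gridded", values = u - mean(u), grid = grid)
}

#' Sequential experience-dependent landscape learning
#'
#' After each trial the observer's running estimate of the prior is merged
#' with a von Mises likelihood centered at that trial's stimulus, which in
#' energy-landscape form is the additive update
#' `U_N = ((N-1) U_{N-1} + h - s * f_vM(theta - theta_N; beta)) / N`,
#' with `f_vM` the normalized von Mises density
#' `exp(beta cos d) / (2 pi I0(beta))`, `s` a depth scale, `h` a constant
#' shift, and `beta` the concentration (inverse width). The update is a
#' symmetric running average, so it is invariant to permuting the stimulus
#' history. With `normalize = FALSE` the raw kernel `exp(beta cos d)` is
#' used instead of the normalized density.
#'
#' @param grid a [ring_grid].
#' @param U0 optional initial landscape (a [landscape] or per-bin values);
#'   default flat.
#' @param beta von Mises concentration (> 0); default 8.
#' @param s kernel depth scale (> 0); default 5.
#' @param h constant shift; default 0.25.
#' @param normalize logical; use the normalized von Mises density (default).
#' @return a `learning_state`: list with `N`, `U_est` (per-bin energies),
#'   `beta`, `s`, `h`, `grid`.
#' @examples
#' st <- learning_state()
#' st <- learning_update(st, 0)
#' st$N  # 1
#' @export
learning_state <- function(grid = ring_grid(), U0 = NULL,
                           beta = 8, s = 5, h = 0.25, normalize = TRUE) {
  if (beta <= 0 || s <= 0) stop("beta and s must be > 0")
  u <- if (is.null(U0)) rep(0, grid$n_bins)
       else if (inherits(U0, "landscape")) eval_landscape(U0, grid$centers, grid)
       else if (length(U0) == grid$n_bins) as.numeric(U0)
       else stop("U0 must be a landscape or per-bin values")
  structure(list(N = 0L, U_est = u, beta = beta, s = s, h = h,
                 normalize = normalize, grid = grid),
            class = "learning_state")
}

# von Mises kernel used by the learning rule
vm_kernel <- function(delta, beta, normalize = TRUE) {
  k <- exp(beta * cos(delta))
  if (normalize) k / (2 * pi * besselI(beta, 0, expon.scaled = FALSE)) else k
}

#' @rdname learning_state
#' @param state a `learning_state`.
#' @param theta_N observed stimulus value(s) on this trial, radians. With
#'   several values (e.g. target and distractor) one full kernel per value
#'   is added within the same trial count.
#' @return `learning_update` returns the updated `learning_state` with `N`
#'   incremented by one.
#' @export
learning_update <- function(state, theta_N) {
  if (!inherits(state, "learning_state")) stop("state must be a learning_state")
  N <- state$N + 1L
  kern <- rep(0, state$grid$n_bins)
  for (th in theta_N)
    kern <- kern + vm_kernel(state$grid$centers - th, state$beta,
                             state$normalize)
  state$U_est <- ((N - 1) * state$U_est + state$h - state$s * kern) / N
  state$N <- N
  state
}

#' @rdname learning_state
#' @param sigma diffusion amplitude used to map energies to a density.
#' @return `learned_prior_estimate` returns the prior estimate implied by
#'   the current landscape, `p propto exp(-2 U / sigma^2)`, as a
#'   `density_grid`.
#' @export
learned_prior_estimate <- function(state, sigma = 0.05) {
  stationary_density(landscape("gridded", values = state$U_est,
                               grid = state$grid),
                     sigma, state$grid)
}

#' Long-run limit of the learned landscape
#'
#' As the number of observed trials grows, the learned landscape converges
#' to `h` minus `s` times the circular convolution of the environmental
#' prior with the von Mises likelihood kernel; for an exp-cosine prior with
#' m peaks this is a pure mode-m cosine with wells at the prior peaks.
#'
#' @param prior an [env_prior].
#' @param beta von Mises concentration of the likelihood kernel.
#' @param s,h depth scale and shift (defaults as in [learning_state]).
#' @param normalize use the normalized von Mises kernel (default TRUE).
#' @param grid a [ring_grid].
#' @param demean remove the circular mean of the result (default TRUE).
#' @return a gridded [landscape].
#' @export
longrun_landscape <- function(prior, beta = 8, s = 5, h = 0.25,
                              normalize = TRUE, grid = ring_grid(),
                              demean = TRUE) {
  p <- env_pdf(prior, grid$centers)            # density values
  k <- vm_kernel(grid$centers, beta, normalize)
  n <- grid$n_bins
  # circular convolution (P_env * f_vM)(theta) via FFT
  conv <- Re(fft(fft(p) * fft(k), inverse = TRUE)) / n * grid$bin_width
  # fft convolution is indexed from the first grid point (-pi); recenter so
  # lag zero sits at each bin
  shift <- ring_bin(0, grid) - 1L
  conv <- conv[((seq_len(n) - 1L + shift) %% n) + 1L]
  u <- h - s * conv
  if (demean) u <- u - mean(u)
  landscape("gridded", values = u, grid = grid)
}

#' Landscape import/export as two-column CSV (theta_deg, U)
#' @param spec a [landscape]; evaluated on `grid` if parametric.
#' @param path file path.
#' @param grid a [ring_grid].
#' @export
write_landscape <- function(spec, path, grid = ring_grid()) {
  u <- eval_landscape(spec, grid$centers, grid)
  utils::write.csv(data.frame(theta_deg = rad2deg(grid$centers), U = u),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape
#' @export
read_landscape <- function(path) {
  x <- utils::read.csv(path)
  if (!all(c("theta_deg", "U") %in% names(x)))
    stop("expected columns theta_deg, U")
  grid <- ring_grid(nrow(x))
  ord <- order(wrap_angle(deg2rad(x$theta_deg)))
  landscape("gridded", values = x$U[ord], grid = grid)
}
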