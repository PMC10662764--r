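#' Probability mass on the ring
#'
#' Container for per-bin probability mass (position densities, conditional
#' and marginal response distributions). Mass must be nonnegative and sum
#' to one; small numerical deviations are renormalized, larger ones are an
#' error.
#'
#' @param mass per-bin probabilities.
#' @param grid the [ring_grid] the mass lives on.
#' @return an object of class `density_grid` with elements `grid` and
#'   `mass`.
#' @export
density_grid <- function(mass, grid = ring_grid()) {
  if (length(mass) != grid$n_bins)
    stop("mass length must equal grid$n_bins")
  if (any(mass < -1e-10)) stop("mass must be nonnegative")
  mass <- pmax(mass, 0)
  s <- sum(mass)
  if (abs(s - 1) > 1e-6) stop("mass must sum to 1 (got ", format(s), ")")
  structure(list(grid = grid, mass = mass / s), class = "density_grid")
}

# one-bin delta density
delta_density <- function(theta, grid = ring_grid()) {
  m <- rep(0, grid$n_bins)
  m[ring_bin(theta, grid)] <- 1
  density_grid(m, grid)
}

# Chang-Cooper / Scharfetter-Gummel generator of the Fokker-Planck
# equation  dp/dt = d/dtheta [U' p] + (sigma^2/2) d2p/dtheta2  on the ring.
# The exponentially fitted interface fluxes make the discrete stationary
# state exactly Boltzmann (p_{i+1}/p_i = exp(-2 dU / sigma^2)) and keep the
# scheme positivity-preserving for any drift strength.
fp_generator <- function(spec, sigma, grid = ring_grid()) {
  if (sigma <= 0) stop("sigma must be > 0")
  n <- grid$n_bins
  h <- grid$bin_width
  D <- sigma^2 / 2
  u <- eval_landscape(spec, grid$centers, grid)
  up <- u[c(2:n, 1)]
  w <- -(up - u) / D                       # v*h/D at interface i+1/2
  bern <- function(x) ifelse(abs(x) < 1e-12, 1 - x / 2, x / expm1(x))
  bp <- bern(w)                            # multiplies p_{i+1}
  bm <- bern(-w)                           # multiplies p_i
  r <- D / h^2
  # dp_i/dt = r * (bm[i-1] p_{i-1} - (bp[i-1]+bm[i]) p_i + bp[i] p_{i+1})
  i_all <- seq_len(n)
  im1 <- c(n, 1:(n - 1))
  Matrix::sparseMatrix(
    i = c(i_all, i_all, i_all),
    j = c(i_all, im1, c(2:n, 1)),
    x = r * c(-(bp[im1] + bm), bm[im1], bp),
    dims = c(n, n))
}

# number of backward-Euler steps for horizon T (dt close to dt_target,
# capped so very long horizons stay tractable; the stationary state is a
# fixed point of the step operator at any dt)
fp_nsteps <- function(T, dt_target = 0.01, max_steps = 20000L) {
  if (T <= 0) return(0L)
  min(max(ceiling(T / dt_target), 1L), max_steps)
}

#' Propagate a position density through the delay (Fokker-Planck)
#'
#' Solves `dp/dt = d/dtheta[U'(theta) p] + (sigma^2/2) d^2 p/dtheta^2` with
#' periodic boundary, using an exponentially fitted (Scharfetter-Gummel)
#' finite-volume discretization in space and implicit (backward Euler)
#' steps in time. Mass is conserved exactly and the scheme is
#' positivity-preserving at any drift strength and step size, so long
#' horizons are integrated with proportionally larger steps instead of
#' blowing up.
#'
#' @param spec a [landscape].
#' @param sigma noise amplitude (> 0).
#' @param p0 initial density: a `density_grid`, a per-bin mass vector, or a
#'   single angle (treated as a one-bin delta).
#' @param T delay duration, seconds (>= 0).
#' @param grid a [ring_grid] (ignored when `p0` carries its own grid).
#' @param dt_target nominal time step, seconds.
#' @return a `density_grid` after time `T`.
#' @export
fp_propagate <- function(spec, sigma, p0, T, grid = ring_grid(),
                         dt_target = 0.01) {
  if (T < 0) stop("T must be >= 0")
  if (inherits(p0, "density_grid")) {
    grid <- p0$grid
    p <- p0$mass
  } else if (length(p0) == 1L) {
    p <- delta_density(p0, grid)$mass
  } else {
    p <- density_grid(p0, grid)$mass
  }
  n_steps <- fp_nsteps(T, dt_target)
  if (n_steps == 0L) return(density_grid(p, grid))
  dt <- T / n_steps
  L <- fp_generator(spec, sigma, grid)
  A <- Matrix::Diagonal(grid$n_bins) - dt * L
  fa <- Matrix::lu(A)
  for (k in seq_len(n_steps)) p <- as.numeric(Matrix::solve(fa, p))
  density_grid(pmax(p, 0) / sum(pmax(p, 0)), grid)
}

#' Full transition kernel of the delay-period dynamics
#'
#' Returns the matrix `K` with `K[i, j] = P(end in bin i | start in bin j)`
#' after delay `T`, computed column-exactly by propagating the identity
#' through the backward-Euler steps. Columns are the conditional response
#' distributions for every possible target bin at once.
#'
#' @inheritParams fp_propagate
#' @return an `n_bins x n_bins` column-stochastic matrix.
#' @export
fp_kernel <- function(spec, sigma, T, grid = ring_grid(), dt_target = 0.01) {
  n <- grid$n_bins
  n_steps <- fp_nsteps(T, dt_target)
  P <- diag(n)
  if (n_steps == 0L) return(P)
  dt <- T / n_steps
  L <- fp_generator(spec, sigma, grid)
  A <- Matrix::Diagonal(n) - dt * L
  fa <- Matrix::lu(A)
  # one-step matrix, then fast exponentiation
  M <- as.matrix(Matrix::solve(fa, diag(n)))
  out <- NULL
  e <- n_steps
  B <- M
  while (e > 0) {
    if (e %% 2 == 1) out <- if (is.null(out)) B else B %*% out
    e <- e %/% 2
    if (e > 0) B <- B %*% B
  }
  out <- pmax(out, 0)
  sweep(out, 2, colSums(out), "/")
}

# pick an odd subgrid refinement so the sharpest stationary width
# sigma/sqrt(2 max U'') is resolved by ~3 bins; odd factors keep the fine
# bins symmetric inside each output bin so aggregation is unbiased
fp_refine_auto <- function(spec, sigma, grid) {
  u2max <- switch(spec$kind,
    flat = 0,
    cosine = (if (spec$scaling == "per_well") spec$A_p * spec$n
              else spec$A_p * spec$n^2),
    dual = spec$A1 * spec$n1 + spec$A2 * spec$n2,
    gridded = {
      g <- gridded_gradient(spec)
      n <- length(g)
      max(abs((g[c(2:n, 1)] - g[c(n, 1:(n - 1))]) /
                (2 * spec$grid$bin_width)))
    })
  if (u2max <= 0) return(1L)
  sd_min <- sigma / sqrt(2 * u2max)
  r <- ceiling(grid$bin_width / (sd_min / 3))
  if (r %% 2 == 0) r <- r + 1
  as.integer(min(max(r, 1), 15))
}

#' Conditional response distribution P(theta' | theta)
#'
#' Distribution of the reported value after the delay, given the target.
#' `method = "pde"` propagates a one-bin delta with [fp_propagate] on an
#' automatically refined subgrid (so that strongly attracting wells whose
#' stationary width is below one output bin are still resolved) and
#' aggregates back to the output grid; `method = "mc"` histograms
#' [simulate_responses] endpoints.
#'
#' @param spec a [landscape].
#' @param sigma noise amplitude (> 0).
#' @param target target angle, radians.
#' @param T delay, seconds.
#' @param method `"pde"` or `"mc"`.
#' @param grid output [ring_grid].
#' @param n_sim Monte Carlo replicates (mc method).
#' @param seed seed for the mc method.
#' @param refine pde subgrid refinement factor (odd integer); `NULL`
#'   (default) chooses automatically.
#' @param dt integration step for either method.
#' @return a `density_grid` over response bins.
#' @export
conditional_response_dist <- function(spec, sigma, target, T,
                                      method = c("pde", "mc"),
                                      grid = ring_grid(), n_sim = 1e5,
                                      seed = NULL, refine = NULL,
                                      dt = 0.01) {
  method <- match.arg(method)
  if (method == "mc") {
    pp <- particle_params(sigma = sigma, T_delay = T, dt = dt, seed = seed)
    resp <- simulate_responses(spec, target, pp, n_rep = as.integer(n_sim))
    cnt <- tabulate(ring_bin(resp, grid), nbins = grid$n_bins)
    return(density_grid(cnt / sum(cnt), grid))
  }
  if (is.null(refine)) refine <- fp_refine_auto(spec, sigma, grid)
  fine <- ring_grid(grid$n_bins * refine)
  # represent a gridded landscape exactly on the finer grid by resampling
  spec_f <- if (spec$kind == "gridded" && refine > 1L)
    landscape("gridded",
              values = eval_landscape(spec, fine$centers),
              grid = fine) else spec
  pf <- fp_propagate(spec_f, sigma, target, T, fine, dt_target = dt)
  if (refine == 1L) return(pf)
  idx <- ring_bin(fine$centers, grid)
  mass <- as.numeric(rowsum(pf$mass, idx)[as.character(seq_len(grid$n_bins)), 1])
  density_grid(mass, grid)
}

#' Marginal response distribution under an environmental prior
#'
#' `P_resp(theta') = sum_theta P(theta'|theta) P_env(theta) h`, the
#' prior-weighted average of the conditional response distributions.
#'
#' @inheritParams conditional_response_dist
#' @param prior an [env_prior].
#' @return a `density_grid`.
#' @export
marginal_response_dist <- function(spec, sigma, prior, T,
                                   grid = ring_grid(), dt = 0.01) {
  K <- fp_kernel(spec, sigma, T, grid, dt_target = dt)
  w <- env_density(prior, grid)$mass
  density_grid(as.numeric(K %*% w), grid)
}

#' Exact response likelihood under a particle model
#'
#' Density (per radian) of observing `response` given the target, the
#' landscape and the delay, evaluated from the PDE conditional response
#' distribution. Likelihoods are floored at 1e-12 to keep log-likelihood
#' ratios finite.
#'
#' @inheritParams conditional_response_dist
#' @param response observed response angle(s), radians.
#' @return likelihood density value(s), strictly positive.
#' @export
response_likelihood <- function(spec, sigma, target, T, response,
                                grid = ring_grid(), refine = NULL,
                                dt = 0.01) {
  cond <- conditional_response_dist(spec, sigma, target, T, method = "pde",
                                    grid = grid, refine = refine, dt = dt)
  dens <- cond$mass[ring_bin(response, grid)] / grid$bin_width
  pmax(dens, 1e-12)
}
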