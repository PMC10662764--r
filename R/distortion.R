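#' Mean distortion of a conditional response distribution
#'
#' Distortion of a response theta' to a target theta is `1 - cos(theta -
#' theta')`, a circular squared-error surrogate bounded in \[0, 2\]. The
#' mean distortion at a target is its expectation under the conditional
#' response distribution.
#'
#' @param cond a `density_grid` giving P(theta' | target).
#' @param target the target angle, radians.
#' @return scalar mean distortion in \[0, 2\].
#' @export
mean_distortion <- function(cond, target) {
  if (!inherits(cond, "density_grid")) stop("cond must be a density_grid")
  sum(cond$mass * (1 - cos(target - cond$grid$centers)))
}

#' Per-target distortion profile from simulated responses
#'
#' Simulates `n_sim` responses per target bin and computes the mean
#' distortion per bin.
#'
#' @param spec a [landscape].
#' @param sigma noise amplitude.
#' @param T delay, seconds.
#' @param targets target angles (radians); default every grid bin center.
#' @param n_sim replicates per target.
#' @param seed optional seed.
#' @param dt integration step.
#' @return data.frame with `target` (radians) and `d_mean`.
#' @export
distortion_profile <- function(spec, sigma, T, targets = NULL,
                               n_sim = 1e4, seed = NULL, dt = 0.01) {
  if (is.null(targets)) targets <- ring_grid()$centers
  pp <- particle_params(sigma = sigma, T_delay = T, dt = dt, seed = seed)
  resp <- simulate_responses(spec, targets, pp, n_rep = as.integer(n_sim))
  d <- colMeans(1 - cos(sweep(resp, 2, targets, "-")))
  data.frame(target = targets, d_mean = d)
}

#' Total mean distortion under an environmental prior
#'
#' `d_tot = E[1 - cos(response - target)]` with targets drawn from the
#' environmental prior: the prior-weighted average of the per-target mean
#' distortion. `method = "mc"` samples targets and simulates particles;
#' `method = "pde"` computes the double sum from the transition kernel.
#'
#' @param spec a [landscape].
#' @param sigma noise amplitude.
#' @param prior an [env_prior].
#' @param T delay, seconds.
#' @param n_sim Monte Carlo sample size (mc method).
#' @param seed optional seed.
#' @param method `"mc"` or `"pde"`.
#' @param dt integration step.
#' @param grid grid for the pde method.
#' @return scalar total mean distortion.
#' @export
total_mean_distortion <- function(spec, sigma, prior, T, n_sim = 1e4,
                                  seed = NULL, method = c("mc", "pde"),
                                  dt = 0.01, grid = ring_grid()) {
  method <- match.arg(method)
  if (method == "pde") {
    K <- fp_kernel(spec, sigma, T, grid, dt_target = dt)
    w <- env_density(prior, grid)$mass
    dmat <- 1 - cos(outer(grid$centers, grid$centers, "-"))  # [resp, targ]
    return(as.numeric(colSums(dmat * K) %*% w))
  }
  if (sigma == 0 && spec$kind == "flat") return(0)
  targets <- sample_stimuli(prior, n_sim, seed = derive_seed(seed, 1L))
  n_steps <- round(T / dt)
  ends <- with_seed(derive_seed(seed, 2L),
                    em_endpoints(spec, targets, sigma, dt, n_steps))
  mean(1 - cos(ends - targets))
}

#' Bootstrap variability of the per-bin distortion
#'
#' Resamples responses with replacement within each target bin and
#' recomputes the per-bin mean distortion, giving percentile-bootstrap
#' means and standard deviations. Bins with no responses are flagged
#' missing (NA), never zero.
#'
#' @param target vector of target angles, radians (one per response).
#' @param response vector of response angles, radians.
#' @param n_boot number of bootstrap resamples.
#' @param seed optional seed.
#' @param grid a [ring_grid] defining the target bins.
#' @return data.frame with one row per non-empty target bin: `target`
#'   (bin center), `n`, `d_mean` (bootstrap mean), `d_sd` (bootstrap SD),
#'   `d_plugin` (plug-in estimate).
#' @export
bootstrap_distortion <- function(target, response, n_boot = 1000L,
                                 seed = NULL, grid = ring_grid()) {
  if (length(target) != length(response))
    stop("target and response must have equal length")
  bins <- ring_bin(target, grid)
  err <- 1 - cos(response - target)
  out <- with_seed(seed, {
    do.call(rbind, lapply(sort(unique(bins)), function(b) {
      e <- err[bins == b]
      n <- length(e)
      if (n < 2) {
        bm <- if (n == 1) e else NA_real_
        return(data.frame(target = grid$centers[b], n = n,
                          d_mean = bm, d_sd = NA_real_,
                          d_plugin = bm))
      }
      bm <- vapply(seq_len(n_boot), function(i)
        mean(e[sample.int(n, n, replace = TRUE)]), numeric(1))
      data.frame(target = grid$centers[b], n = n,
                 d_mean = mean(bm), d_sd = stats::sd(bm),
                 d_plugin = mean(e))
    }))
  })
  out
}
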