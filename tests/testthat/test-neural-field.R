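# small field configuration for fast structural tests: coarser grid and
# shorter delay than the analysis defaults, same kernel shape
fast_field <- function(T_delay = 2, ...) {
  # dx chosen so a 90-degree rotation is an integer number of grid cells
  field_params(dx = 0.18, T_delay = T_delay, ...)
}

test_that("weight kernel combines local excitation and broad inhibition", {
  fp <- field_params()
  expect_equal(weight_kernel(fp, 0), 1 - 0.35)
  expect_equal(weight_kernel(fp, 1.3), weight_kernel(fp, -1.3))
  expect_lt(abs(weight_kernel(fp, 8)), 1e-3)
  expect_lt(weight_kernel(fp, 2.5), 0)       # lateral inhibition
})

test_that("Amari bump half-width solves the threshold condition", {
  fp <- field_params()
  bh <- bump_halfwidth(fp)
  expect_lt(abs(bump_profile(fp, bh$a, bh$a) - fp$kappa), 1e-8)
  expect_lt(bh$edge_slope, 0)                # stable root
  # threshold above the maximal drive: no bump
  expect_null(bump_halfwidth(field_params(kappa = 0.6)))
  # noise-free simulated bump converges to the predicted width
  fp0 <- field_params(epsilon = 0, T_delay = 3)
  tr <- simulate_field_trial(fp0, 0, "none", record_centroid = FALSE)
  a_sim <- sum(tr$u[, 1] > fp0$kappa) * fp0$dx / 2
  expect_lt(abs(a_sim - bh$a), 2 * fp0$dx)
})

test_that("continuous attractor: no drift without noise or heterogeneity", {
  fp0 <- fast_field(epsilon = 0)
  tr <- simulate_field_trial(fp0, deg2rad(30), "none")
  i0 <- round(fp0$t_inp / fp0$dt) + 1
  cents <- tr$centroid[i0:nrow(tr$centroid), 1]
  expect_true(all(abs(circ_diff(cents, cents[1])) < 1e-12))
  expect_lt(abs(circ_diff(tr$response, deg2rad(30))),
            fp0$dx * 2 * pi / fp0$ring_units)
})

test_that("fixed 4-mode heterogeneity attracts bumps toward its peaks", {
  fp0 <- fast_field(epsilon = 0, T_delay = 6)
  tr <- simulate_field_trial(fp0, deg2rad(30), "fixed",
                             record_centroid = FALSE)
  expect_lt(abs(tr$response), deg2rad(15))   # moved toward 0 from 30 deg
  # rotational equivariance: rotating target and heterogeneity by one
  # heterogeneity period rotates the response exactly
  tr2 <- simulate_field_trial(fp0, deg2rad(30 + 90), "fixed",
                              record_centroid = FALSE)
  expect_equal(wrap_angle(tr2$response - pi / 2), tr$response,
               tolerance = 1e-9)
})

test_that("plasticity updates follow their scalar recursions", {
  fp <- field_params()
  z <- rep(0, 5)
  expect_equal(plasticity_update(z, z, fp), z)
  # constant activity: geometric approach to the fixed point
  u <- rep(1, 5)
  s_r <- z; s_l <- z
  for (k in 1:50) {
    s_r <- plasticity_update(s_r, u, fp, "retention")
    s_l <- plasticity_update(s_l, u, fp, "literal")
  }
  gam <- fp$gamma_s; bet <- fp$beta_s
  expect_equal(s_r, rep(bet * (1 - gam^50), 5), tolerance = 1e-12)
  expect_equal(s_l, rep(bet * (1 - (1 - gam)^50) / gam, 5),
               tolerance = 1e-12)
  expect_error(plasticity_update(z, rep(0, 4), fp), "same grid")
  expect_error(field_params(gamma_s = 1), "gamma_s")
})

test_that("repeated stimulation at one location potentiates it", {
  fp <- fast_field(epsilon = 0, T_delay = 1)
  s <- rep(0, fp$n_x)
  ops <- wmprior:::field_ops(fp)
  for (k in 1:5) {
    tr <- simulate_field_trial(fp, deg2rad(60), "learned", s_mod = s,
                               record_centroid = FALSE, ops = ops)
    s <- plasticity_update(s, tr$u_stim[, 1], fp)
  }
  expect_lt(abs(circ_diff(fp$x_grid[which.max(s)], deg2rad(60))),
            deg2rad(10))
})

test_that("the reduction drift matches symmetry requirements and the
           simulated bump motion", {
  fp0 <- field_params(epsilon = 0)
  bh <- bump_halfwidth(fp0)
  # constant heterogeneity: no drift (odd integrand)
  rc <- reduction_drift(fp0, function(th) rep(1, length(th)), a = bh$a,
                        theta = seq(-3, 3, by = 0.5))
  expect_lt(max(abs(rc$dU)), 1e-10)
  # mode-4 heterogeneity: drift vanishes at multiples of pi/4
  r4 <- reduction_drift(fp0, function(th) 0.4 * cos(4 * th), a = bh$a,
                        theta = c(0, pi / 4, pi / 2, -pi / 4))
  expect_lt(max(abs(r4$dU)), 1e-9)
  # sign agreement with measured centroid velocity at probes
  probes <- deg2rad(c(-30, -15, 15, 30))
  vel <- vapply(probes, function(x0) {
    tr <- simulate_field_trial(fp0, x0, "fixed")
    i0 <- round(fp0$t_inp / fp0$dt) + 1
    wrap_angle(tr$centroid[i0 + 20, 1] - tr$centroid[i0, 1]) /
      (20 * fp0$dt)
  }, numeric(1))
  pred <- -reduction_drift(fp0, function(th) 0.4 * cos(4 * th),
                           a = bh$a, theta = probes)$dU
  expect_true(all(sign(vel) == sign(pred)))
})

test_that("Fourier and narrow-bump approximations bracket the numeric
           drift in their regimes", {
  fp <- field_params()
  bh <- bump_halfwidth(fp)
  thg <- seq(-pi, pi, length.out = 181)
  num <- reduction_drift(fp, function(th) 0.4 * cos(4 * th), a = bh$a,
                         theta = thg)
  fo <- drift_fourier(fp, 0.4, 4, a = bh$a)
  expect_lt(max(abs(fo$dU(thg) - num$dU)) / max(abs(num$dU)), 0.1)
  expect_equal(fo$dU(pi / 8), 2 * fo$alpha_m, tolerance = 1e-12)
  # b_m = 0: no heterogeneity contribution
  expect_equal(drift_fourier(fp, 0, 4, a = bh$a)$alpha_m, 0)
  # narrow-bump regime: half-width small against both the kernel length
  # scale and the heterogeneity wavelength
  a_nb <- 0.2
  num_nb <- reduction_drift(fp, function(th) 0.4 * cos(4 * th), a = a_nb,
                            theta = thg)
  nb <- drift_narrowbump(fp, function(th) 0.4 * cos(4 * th), a = a_nb)
  dU_nb <- 0.4 * 4 * nb$coef * sin(4 * thg)   # -coef * h'(theta)
  expect_lt(max(abs(dU_nb - num_nb$dU)) / max(abs(num_nb$dU)), 0.2)
  expect_true(nb$regime_ok)
  # the same check in a field whose length unit is one ring radian, at
  # one tenth of the heterogeneity wavelength
  fpr <- field_params(ring_units = 2 * pi)
  a_r <- 0.1 * (2 * pi / 4)
  num_r <- reduction_drift(fpr, function(th) 0.4 * cos(4 * th), a = a_r,
                           theta = thg)
  nb_r <- drift_narrowbump(fpr, function(th) 0.4 * cos(4 * th), a = a_r)
  expect_lt(max(abs(0.4 * 4 * nb_r$coef * sin(4 * thg) - num_r$dU)) /
              max(abs(num_r$dU)), 0.2)
  # flat heterogeneity: flat landscape; attractors sit at h maxima
  expect_equal(nb$U(0), -nb$coef * 0.4)
  expect_gt(nb$coef, 0)                      # U minimal where h maximal
  nb_wide <- drift_narrowbump(fp, function(th) 0.4 * cos(4 * th),
                              a = bump_halfwidth(fp)$a)
  expect_false(nb_wide$regime_ok)
})
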