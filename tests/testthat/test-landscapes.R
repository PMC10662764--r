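test_that("landscape evaluation follows the stated conventions", {
  g <- ring_grid()
  expect_equal(eval_landscape(landscape("flat"), g$centers), rep(0, 360))
  ls4 <- landscape("cosine", A_p = 1, n = 4)
  expect_equal(eval_landscape(ls4, 0), -0.25)          # -(A_p/n) cos(0)
  expect_equal(eval_landscape(landscape("cosine", A_p = 1, n = 4,
                                        scaling = "plain"), 0), -1)
  # minima at theta_off + 2 pi k / n
  u <- eval_landscape(landscape("cosine", A_p = 1, n = 4,
                                theta_off = deg2rad(10)), g$centers)
  mins <- g$centers[which(u <= min(u) + 1e-12)]
  expect_true(all(abs(wrap_angle(4 * (mins - deg2rad(10)))) < 1e-9))
  expect_error(landscape("gridded", values = 1:10, grid = g), "length")
})

test_that("gradients match closed forms and finite differences", {
  g <- ring_grid()
  ls4 <- landscape("cosine", A_p = 1, n = 4)
  expect_equal(landscape_gradient(ls4, 0), 0)
  expect_equal(landscape_gradient(ls4, pi / 8), 1)     # A_p sin(pi/2)
  # gridded encoding of the same landscape reproduces the gradient
  lg <- landscape("gridded", values = eval_landscape(ls4, g$centers),
                  grid = g)
  expect_equal(landscape_gradient(lg, g$centers),
               landscape_gradient(ls4, g$centers), tolerance = 1e-3)
  # parametric gradient equals centered finite differences of evaluation
  u <- eval_landscape(ls4, g$centers)
  fd <- (u[c(2:360, 1)] - u[c(360, 1:359)]) / (2 * g$bin_width)
  expect_equal(landscape_gradient(ls4, g$centers), fd, tolerance = 1e-3)
  # gauge invariance: adding a constant leaves the gradient unchanged
  lg2 <- landscape("gridded", values = lg$values + 3.7, grid = g)
  expect_equal(landscape_gradient(lg2, g$centers),
               landscape_gradient(lg, g$centers))
  # dual drift is the sum of the two components
  ld <- landscape("dual", A1 = 0.5, A2 = 0.3, n1 = 4, n2 = 8)
  th <- seq(-3, 3, by = 0.1)
  expect_equal(landscape_gradient(ld, th),
               0.5 * sin(4 * th) + 0.3 * sin(8 * th))
})

test_that("stationary density is Boltzmann and satisfies detailed balance", {
  g <- ring_grid()
  expect_equal(stationary_density(landscape("flat"), 0.1, g)$mass,
               rep(1 / 360, 360), tolerance = 1e-12)
  ls4 <- landscape("cosine", A_p = 0.05, n = 4)
  sigma <- 0.3
  p <- stationary_density(ls4, sigma, g)
  ref <- exp((2 * 0.05 / (4 * sigma^2)) * cos(4 * g$centers))
  expect_equal(p$mass, ref / sum(ref), tolerance = 1e-12)
  # zero probability flux J = -U' p - (sigma^2/2) p' at every bin
  # (five-point stencil so the derivative error stays below the bound)
  dens <- p$mass / g$bin_width
  sh <- function(v, k) v[((seq_along(v) - 1 + k) %% length(v)) + 1]
  dp <- (-sh(dens, 2) + 8 * sh(dens, 1) - 8 * sh(dens, -1) +
           sh(dens, -2)) / (12 * g$bin_width)
  J <- -landscape_gradient(ls4, g$centers) * dens - sigma^2 / 2 * dp
  expect_true(all(abs(J) < 1e-6))
  expect_error(stationary_density(ls4, 0), "sigma")
})

test_that("posterior-to-landscape linearization round-trips", {
  g <- ring_grid()
  sigma <- 0.05
  l0 <- posterior_to_landscape(rep(0, 360), sigma, g)
  expect_equal(l0$values, rep(0, 360))
  eps <- 0.01
  l <- eps * cos(4 * g$centers)
  spec <- posterior_to_landscape(l, sigma, g)
  expect_equal(cor(spec$values, -cos(4 * g$centers)), 1, tolerance = 1e-9)
  post <- stationary_density(spec, sigma, g)
  target <- (1 / (2 * pi) + l) * g$bin_width
  expect_lt(max(abs(post$mass / g$bin_width - target / g$bin_width)),
            1e-3)
  expect_error(posterior_to_landscape(l + 1, sigma, g), "zero")
})

test_that("sequential learning matches its unrolled closed form", {
  g <- ring_grid()
  st <- learning_state(g, beta = 8, s = 5, h = 0.25)
  st1 <- learning_update(st, deg2rad(30))
  fvm <- exp(8 * cos(g$centers - deg2rad(30))) / (2 * pi * besselI(8, 0))
  expect_equal(st1$U_est, 0.25 - 5 * fvm, tolerance = 1e-12)
  expect_identical(st1$N, 1L)
  # unrolled-recursion oracle for N <= 20: U_N = mean_j (h - s f(.-th_j))
  set.seed(11)
  ths <- runif(20, -pi, pi)
  stN <- Reduce(learning_update, ths, accumulate = FALSE, init = st)
  oracle <- rowMeans(vapply(ths, function(t0)
    0.25 - 5 * exp(8 * cos(g$centers - t0)) / (2 * pi * besselI(8, 0)),
    numeric(360)))
  expect_equal(stN$U_est, oracle, tolerance = 1e-10)
  # permutation invariance of the stimulus history
  stP <- Reduce(learning_update, sample(ths), init = st)
  expect_equal(stP$U_est, stN$U_est, tolerance = 1e-10)
  expect_error(learning_state(beta = 0), "beta")
  # implied prior estimate is the Boltzmann transform of U_est
  pe <- learned_prior_estimate(stN, sigma = 0.05)
  expect_equal(pe$mass,
               stationary_density(landscape("gridded",
                                            values = stN$U_est,
                                            grid = g), 0.05, g)$mass)
})

test_that("long-run landscape is the prior convolved with the kernel", {
  g <- ring_grid()
  lr0 <- longrun_landscape(env_prior("uniform"))
  expect_lt(max(abs(lr0$values)), 1e-10)
  pr <- env_prior("exp_cosine", A = 1, m = 4)
  lr <- longrun_landscape(pr, beta = 8, s = 5, h = 0.25)
  # direct O(n^2) convolution oracle
  pv <- env_density(pr, g)$mass / g$bin_width
  kv <- exp(8 * cos(g$centers)) / (2 * pi * besselI(8, 0))
  conv <- vapply(seq_len(360), function(i)
    sum(pv * kv[((i - seq_len(360)) %% 360) + 1]) * g$bin_width,
    numeric(1))
  u_oracle <- 0.25 - 5 * conv
  expect_equal(lr$values, u_oracle - mean(u_oracle), tolerance = 1e-9)
  # minima at the prior peaks, within one bin
  amin <- g$centers[which.min(lr$values)]
  expect_lt(abs(wrap_angle(4 * amin)) / 4, g$bin_width + 1e-12)
  # dominant Fourier mode is the prior's mode
  amp <- Mod(fft(lr$values))[2:13]
  expect_identical(which.max(amp), 4L)
  # empirical limit: averaged sequential updates converge to it
  x <- sample_stimuli(pr, 5000, seed = 3)
  st <- Reduce(learning_update, x, init = learning_state(g))
  expect_gt(cor(st$U_est, lr$values), 0.95)
})

test_that("landscapes round-trip through CSV", {
  ls4 <- landscape("cosine", A_p = 1, n = 4)
  f <- tempfile(fileext = ".csv")
  write_landscape(ls4, f)
  back <- read_landscape(f)
  expect_equal(back$values, eval_landscape(ls4, ring_grid()$centers),
               tolerance = 1e-9)
  unlink(f)
})
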