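test_that("the model zoo has the documented free parameters and bounds", {
  mods <- wm_models()
  expect_identical(names(mods),
                   c("Flat", "StaticHet", "OffsetHet", "DualHet",
                     "LearnTargetFlatPrior", "LearnTargetHetPrior",
                     "LearnTDFlatPrior", "LearnTDHetPrior"))
  expect_identical(vapply(mods, `[[`, 0L, "n_free") |> unname(),
                   c(1L, 3L, 4L, 5L, 3L, 3L, 3L, 3L))
  expect_identical(mods$StaticHet$bounds$sigma, c(0.01, 0.2))
  expect_identical(mods$StaticHet$bounds$A_p, c(0.1, 2))
  expect_identical(mods$StaticHet$bounds$n, c(1L, 12L))
  expect_identical(mods$OffsetHet$bounds$theta_off, c(0, pi / 2))
  expect_identical(mods$LearnTargetFlatPrior$bounds$beta, c(1, 10))
  expect_identical(mods$LearnTargetFlatPrior$bounds$s, c(1, 10))
  expect_error(wm_models("NotAModel"), "unknown model")
})

test_that("parameter sampling respects the bounded domains", {
  sf <- sample_parameter_sets(wm_models("Flat")[[1]], 200, seed = 1)
  expect_identical(names(sf), "sigma")
  expect_true(all(sf$sigma >= 0.01 & sf$sigma <= 0.2))
  sh <- sample_parameter_sets(wm_models("StaticHet")[[1]], 200, seed = 2)
  expect_true(all(sh$n == round(sh$n) & sh$n >= 1 & sh$n <= 12))
  expect_true(all(sh$A_p >= 0.1 & sh$A_p <= 2))
  s1 <- sample_parameter_sets(wm_models("Flat")[[1]], 1, seed = 10)
  s2 <- sample_parameter_sets(wm_models("Flat")[[1]], 1, seed = 11)
  expect_false(identical(s1, s2))
})

test_that("model response simulation dispatches the right drift", {
  sess <- make_session(0.3, n_short = 5, n_long = 5, seed = 1)
  # near-zero noise flat model reproduces the targets
  sim <- simulate_model_responses(wm_models("Flat")[[1]],
                                  list(sigma = 1e-9), sess, n_rep = 2,
                                  seed = 2)
  expect_equal(as.numeric(sim[1, ]), sess$target, tolerance = 1e-6)
  # StaticHet: a target at the assigned offset sits on an attractor
  simh <- simulate_model_responses(
    wm_models("StaticHet")[[1]], list(sigma = 0, A_p = 1, n = 4),
    transform(sess, target = 0.3), n_rep = 1, seed = 3,
    assigned_offset = 0.3)
  expect_equal(as.numeric(simh), rep(0.3, 10), tolerance = 1e-9)
  expect_error(wm_models("Flat")[[1]] |>
                 simulate_model_responses(list(sigma = 0.05),
                                          sess[0, ], n_rep = 1))
})

test_that("learning models develop wells at frequently seen targets", {
  # feed many trials at theta = 0; the learned drift then pulls a probe
  # at +10 degrees back toward 0 (negative drift = -U' < 0)
  trials <- data.frame(trial_index = 1:40, delay_class = "long",
                       delay_s = 4, target = 0, distractor = pi / 2)
  G <- wmprior:::learning_gradient_rows(
    wm_models("LearnTargetFlatPrior")[[1]],
    list(sigma = 0.05, beta = 8, s = 5), trials, rep(TRUE, 40))
  g_late <- G[40, ]
  probe <- ring_bin(deg2rad(10))
  expect_gt(g_late[probe], 0)   # drift -U' points toward 0
  expect_lt(g_late[ring_bin(deg2rad(-10))], 0)
  # first trial starts from the flat initial landscape
  expect_true(all(G[1, ] == 0))
})

test_that("mse_score is the mean squared shortest-arc error", {
  expect_identical(mse_score(matrix(c(1, 2), 1), c(1, 2)), 0)
  expect_equal(mse_score(matrix(pi, 1), 0), pi^2)
  # wrap handling: 350 vs -10 degrees differ by 0 after wrapping
  expect_lt(mse_score(matrix(deg2rad(170), 1), deg2rad(-170)),
            deg2rad(21)^2)
  set.seed(4)
  obs <- rnorm(2000, sd = 0.1)
  expect_equal(mse_score(matrix(0, 1, 2000), obs), 0.01,
               tolerance = 0.05)
  expect_error(mse_score(matrix(0, 1, 3), c(1, 2)), "match")
})

test_that("cross-validation partitions trials and recovers a noiseless
           flat subject", {
  sess <- make_session(0.1, n_short = 10, n_long = 20, seed = 5)
  subj <- synthetic_subject("Flat", list(sigma = 0), sess, seed = 6)
  fit <- crossval_fit(subj, wm_models("Flat")[[1]], "long", k_sets = 15,
                      n_rep = 10, seed = 7)
  sets <- sample_parameter_sets(wm_models("Flat")[[1]], 15,
                                wmprior:::derive_seed(7, 1L))
  # each fold picks the smallest sampled sigma (responses equal targets)
  for (f in fit$folds)
    expect_equal(f$best_params$sigma, min(sets$sigma))
  expect_lt(fit$mean_test_mse, 3 * min(sets$sigma)^2 * 4)
  expect_error(crossval_fit(subj, wm_models("Flat")[[1]], "long",
                            folds = 50L), "at least")
})

test_that("model selection minimizes held-out MSE with parsimony ties", {
  fake <- function(name, mse) {
    structure(list(model = wm_models(name)[[1]], delay_class = "long",
                   folds = list(list(best_params = list(sigma = 0.05),
                                     train_mse = mse, test_mse = mse)),
                   mean_test_mse = mse), class = "wm_cvfit")
  }
  sel <- select_model(list(fake("Flat", 0.3), fake("StaticHet", 0.1)))
  expect_identical(sel$model_name, "StaticHet")
  expect_identical(sel$class, "fixed-heterogeneous")
  tie <- select_model(list(fake("DualHet", 0.2), fake("Flat", 0.2)))
  expect_identical(tie$model_name, "Flat")  # fewer free parameters
  expect_identical(select_model(list(fake("LearnTargetFlatPrior",
                                          0.1)))$class, "learning")
})

test_that("MSE is invariant to a global rotation of the task", {
  rot <- deg2rad(57)
  sess <- make_session(0.2, n_short = 5, n_long = 10, seed = 8)
  sess_r <- transform(sess, target = wrap_angle(target + rot),
                      distractor = wrap_angle(distractor + rot))
  m <- wm_models("StaticHet")[[1]]
  par <- list(sigma = 0.05, A_p = 1, n = 4)
  s1 <- simulate_model_responses(m, par, sess, n_rep = 20, seed = 9,
                                 assigned_offset = 0.2)
  s2 <- simulate_model_responses(m, par, sess_r, n_rep = 20, seed = 9,
                                 assigned_offset = wrap_angle(0.2 + rot))
  obs <- sess$target
  expect_equal(mse_score(s1, obs),
               mse_score(s2, wrap_angle(obs + rot)), tolerance = 1e-10)
})

test_that("wm_fit returns a classed object with methods", {
  sess <- make_session(0.1, n_short = 8, n_long = 8, seed = 12)
  subj <- synthetic_subject("Flat", list(sigma = 0.05), sess, seed = 13)
  fit <- wm_fit(subj, models = wm_models(c("Flat", "StaticHet")),
                delay_classes = "long", k_sets = 4, n_rep = 4, seed = 14)
  expect_s3_class(fit, "wm_fit")
  expect_output(print(fit), "delay")
  tab <- summary(fit)
  expect_identical(nrow(tab), 2L)
  expect_identical(sum(tab$selected), 1L)
  cf <- coef(fit)
  expect_true("sigma" %in% names(cf))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims$long), c(3L, 8L))
})

test_that("trial LLR vanishes for equivalent models and favors the
           generator class", {
  sess <- make_session(0, n_short = 0, n_long = 12, seed = 15)
  subj <- synthetic_subject("Flat", list(sigma = 0.05), sess, seed = 16)
  # learning model with negligible kernel depth is the flat model
  llr0 <- trial_llr(subj, wm_models("LearnTargetFlatPrior")[[1]],
                    list(sigma = 0.05, beta = 1, s = 1e-9),
                    wm_models("Flat")[[1]], list(sigma = 0.05),
                    delay_class = "long", refine = 1)
  expect_lt(max(abs(llr0$llr)), 1e-6)
  expect_equal(llr0$cum_llr, cumsum(llr0$llr))
})
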