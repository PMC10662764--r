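#' The particle-model zoo for fitting behavioral responses
#'
#' Eight response models, in three classes:
#' \describe{
#'   \item{flat}{`Flat` - pure diffusion, 1 free parameter (sigma).}
#'   \item{fixed}{`StaticHet` (sigma, A_p, n; wells at the subject's
#'     assigned environmental offset), `OffsetHet` (adds a free offset
#'     theta_off in \[0, pi/2\]), `DualHet` (two cosine components, 5 free
#'     parameters, wells at the assigned offset).}
#'   \item{learning}{`LearnTargetFlatPrior`, `LearnTargetHetPrior`,
#'     `LearnTDFlatPrior`, `LearnTDHetPrior` - the landscape is updated
#'     after every trial by subtracting a scaled von Mises kernel at the
#'     target (Target) or at both target and distractor (TD); free
#'     parameters sigma, beta (kernel concentration) and s (kernel depth);
#'     the initial landscape is flat (FlatPrior) or a 4-well landscape
#'     `-cos(4 (theta - pop_offset))` at the population-bias offset
#'     (HetPrior).}
#' }
#' Free parameters are drawn uniformly from bounded domains:
#' sigma in \[0.01, 0.2\], amplitudes in \[0.1, 2\], well numbers integer in
#' \[1, 12\], free offset in \[0, pi/2\], beta in \[1, 10\], s in \[1, 10\].
#'
#' @param names optional subset of model names to return.
#' @return named list of `wm_model` objects (fields `name`, `class`,
#'   `bounds`, `n_free`, `learn_items`, `het_prior`).
#' @export
wm_models <- function(names = NULL) {
  b_sigma <- c(0.01, 0.2); b_amp <- c(0.1, 2); b_n <- c(1L, 12L)
  b_off <- c(0, pi / 2); b_beta <- c(1, 10); b_s <- c(1, 10)
  mk <- function(name, class, bounds, learn_items = NULL,
                 het_prior = FALSE) {
    structure(list(name = name, class = class, bounds = bounds,
                   n_free = length(bounds), learn_items = learn_items,
                   het_prior = het_prior), class = "wm_model")
  }
  mods <- list(
    Flat = mk("Flat", "flat", list(sigma = b_sigma)),
    StaticHet = mk("StaticHet", "fixed",
                   list(sigma = b_sigma, A_p = b_amp, n = b_n)),
    OffsetHet = mk("OffsetHet", "fixed",
                   list(sigma = b_sigma, A_p = b_amp, n = b_n,
                        theta_off = b_off)),
    DualHet = mk("DualHet", "fixed",
                 list(sigma = b_sigma, A1 = b_amp, A2 = b_amp,
                      n1 = b_n, n2 = b_n)),
    LearnTargetFlatPrior = mk("LearnTargetFlatPrior", "learning",
      list(sigma = b_sigma, beta = b_beta, s = b_s), "target", FALSE),
    LearnTargetHetPrior = mk("LearnTargetHetPrior", "learning",
      list(sigma = b_sigma, beta = b_beta, s = b_s), "target", TRUE),
    LearnTDFlatPrior = mk("LearnTDFlatPrior", "learning",
      list(sigma = b_sigma, beta = b_beta, s = b_s), "both", FALSE),
    LearnTDHetPrior = mk("LearnTDHetPrior", "learning",
      list(sigma = b_sigma, beta = b_beta, s = b_s), "both", TRUE))
  if (!is.null(names)) {
    bad <- setdiff(names, names(mods))
    if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
    mods <- mods[names]
  }
  mods
}

#' Sample random parameter sets for a model
#'
#' Each free parameter is drawn uniformly from its bounded domain
#' (integer-valued well numbers uniformly on the integer range).
#'
#' @param model a `wm_model` from [wm_models].
#' @param k number of parameter sets.
#' @param seed optional seed.
#' @return data.frame with `k` rows, one column per free parameter.
#' @export
sample_parameter_sets <- function(model, k, seed = NULL) {
  if (k < 1) stop("k must be >= 1")
  with_seed(seed, {
    cols <- lapply(model$bounds, function(b) {
      if (is.integer(b)) sample(seq.int(b[1], b[2]), k, replace = TRUE)
      else runif(k, b[1], b[2])
    })
    as.data.frame(cols)
  })
}

# landscape of a fixed-class model (NULL context offset -> 0)
fixed_model_landscape <- function(model, params, assigned_offset = 0) {
  switch(model$name,
    Flat = landscape("flat"),
    StaticHet = landscape("cosine", A_p = params$A_p, n = params$n,
                          theta_off = assigned_offset),
    OffsetHet = landscape("cosine", A_p = params$A_p, n = params$n,
                          theta_off = params$theta_off),
    DualHet = landscape("dual", A1 = params$A1, A2 = params$A2,
                        n1 = params$n1, n2 = params$n2,
                        theta_off = assigned_offset),
    stop("not a fixed-class model: ", model$name))
}

# initial learning state of a learning-class model
learning_initial_state <- function(model, params, pop_offset = 0,
                                   grid = ring_grid(), h = 0.25) {
  U0 <- if (model$het_prior)
    landscape("cosine", A_p = 1, n = 4L, theta_off = pop_offset,
              scaling = "plain")
  else NULL
  learning_state(grid = grid, U0 = U0, beta = params$beta, s = params$s,
                 h = h)
}

# per-trial gridded gradient matrix [n_trials x n_bins] for a learning
# model: row t is the drift landscape in force DURING trial t (i.e. after
# updates from all earlier trials with update_mask TRUE)
learning_gradient_rows <- function(model, params, trials, update_mask,
                                   pop_offset = 0, grid = ring_grid()) {
  st <- learning_initial_state(model, params, pop_offset, grid)
  n_t <- nrow(trials)
  G <- matrix(0, n_t, grid$n_bins)
  for (t in seq_len(n_t)) {
    G[t, ] <- gridded_gradient(landscape("gridded", values = st$U_est,
                                         grid = grid))
    if (update_mask[t]) {
      obs <- if (identical(model$learn_items, "both"))
        c(trials$target[t], trials$distractor[t]) else trials$target[t]
      st <- learning_update(st, obs)
    }
  }
  G
}

# vectorized response simulation for one delay-duration group of trials.
# gradient_rows: NULL (flat), a single per-bin gradient vector (fixed
# landscape), or a [n_trials x n_bins] matrix (learning; row per trial).
sim_trials_em <- function(targets, gradient_rows, sigma, T, dt, n_rep,
                          grid = ring_grid(), drift = NULL) {
  n_t <- length(targets)
  n_steps <- as.integer(round(T / dt))
  th <- rep(targets, each = n_rep)
  tr <- rep(seq_len(n_t) - 1L, each = n_rep)
  if (!is.null(drift)) {
    mode <- drift$mode; par <- drift$par; rows <- drift$rows
  } else if (is.null(gradient_rows)) {
    mode <- 0L; par <- 0; rows <- matrix(0, 1, grid$n_bins)
  } else if (is.matrix(gradient_rows)) {
    mode <- 4L; par <- 0; rows <- gradient_rows
  } else {
    mode <- 3L; par <- 0; rows <- matrix(gradient_rows, 1)
  }
  ends <- em_sim_cpp(wrap_angle(th), tr, mode, par, rows, sigma, dt,
                     n_steps)
  matrix(ends, nrow = n_rep)
}

#' Simulate model responses for a set of trials
#'
#' Dispatches the named model's drift to the Euler-Maruyama particle
#' simulation, one column per trial. Learning models evolve their landscape
#' across trials in chronological order: the response on trial t is
#' simulated under the landscape learned from the stimuli of earlier trials
#' (optionally restricted by `update_mask`, e.g. to training trials during
#' cross-validation); a trial's own stimuli never influence its own
#' response.
#'
#' @param model a `wm_model`.
#' @param params named list/one-row data.frame of parameter values.
#' @param trials data.frame with columns `target`, `distractor`, `delay_s`
#'   (radians/seconds), in chronological order.
#' @param n_rep simulated replicates per trial.
#' @param seed optional seed.
#' @param assigned_offset the subject's assigned environmental offset
#'   (StaticHet/DualHet wells).
#' @param pop_offset population-bias offset for HetPrior learning models.
#' @param update_mask logical vector, one per trial: whether that trial's
#'   stimuli update the learning landscape (default all TRUE).
#' @param dt integration step, seconds.
#' @param grid a [ring_grid] for gridded learning landscapes.
#' @return matrix `[n_rep x n_trials]` of simulated responses (radians).
#' @export
simulate_model_responses <- function(model, params, trials, n_rep = 100L,
                                     seed = NULL, assigned_offset = 0,
                                     pop_offset = 0, update_mask = NULL,
                                     dt = 0.01, grid = ring_grid()) {
  if (!inherits(model, "wm_model")) stop("model must be a wm_model")
  params <- as.list(params)
  n_t <- nrow(trials)
  if (n_t == 0) stop("trials must be non-empty")
  if (is.null(update_mask)) update_mask <- rep(TRUE, n_t)
  if (model$class == "learning") {
    gradient_rows <- learning_gradient_rows(model, params, trials,
                                            update_mask, pop_offset, grid)
    drift <- NULL
  } else {
    # parametric models use the exact closed-form drift
    gradient_rows <- NULL
    drift <- em_drift_args(fixed_model_landscape(model, params,
                                                 assigned_offset))
  }
  out <- matrix(NA_real_, n_rep, n_t)
  with_seed(seed, {
    for (T in unique(trials$delay_s)) {
      sel <- which(trials$delay_s == T)
      gr <- if (is.matrix(gradient_rows)) gradient_rows[sel, , drop = FALSE]
      out[, sel] <- sim_trials_em(trials$target[sel], gr, params$sigma,
                                  T, dt, n_rep, grid, drift = drift)
    }
  })
  out
}

#' Mean squared circular error between simulated and observed responses
#'
#' Squared shortest-arc difference in radians, averaged over replicates and
#' trials.
#'
#' @param sim matrix `[n_rep x n_trials]` of simulated responses.
#' @param obs vector of observed responses, one per trial.
#' @return scalar MSE (rad^2).
#' @export
mse_score <- function(sim, obs) {
  if (!is.matrix(sim)) sim <- matrix(sim, nrow = 1)
  if (ncol(sim) != length(obs))
    stop("sim columns must match length of obs")
  mean(circ_diff(sim, rep(obs, each = nrow(sim)))^2)
}

#' Generate a synthetic subject from a known response model
#'
#' Simulates one response per trial of a session under the named model
#' (learning models update their landscape trial-by-trial over the whole
#' session, in order), producing a subject dataset whose generating model
#' and parameters are recorded in `generator_truth` for recovery studies.
#'
#' @param model_name one of the names in [wm_models].
#' @param params named list of parameter values for that model.
#' @param session trial table from [make_session].
#' @param seed optional seed.
#' @param assigned_offset,pop_offset context offsets (radians).
#' @param subject_id identifier string.
#' @param dt integration step.
#' @return a `wm_subject`: list with `subject_id`, `assigned_offset`,
#'   `trials`, `responses`, `generator_truth`.
#' @export
synthetic_subject <- function(model_name, params, session, seed = NULL,
                              assigned_offset = 0, pop_offset = 0,
                              subject_id = "synthetic", dt = 0.01) {
  model <- wm_models(model_name)[[1]]
  ord <- order(session$trial_index)
  trials <- session[ord, , drop = FALSE]
  sim <- simulate_model_responses(model, params, trials, n_rep = 1L,
                                  seed = seed,
                                  assigned_offset = assigned_offset,
                                  pop_offset = pop_offset, dt = dt)
  responses <- numeric(nrow(session))
  responses[ord] <- as.numeric(sim)
  structure(list(subject_id = subject_id,
                 assigned_offset = wrap_angle(assigned_offset),
                 trials = session, responses = responses,
                 generator_truth = list(model = model_name,
                                        params = as.list(params),
                                        pop_offset = pop_offset,
                                        seed = seed)),
            class = "wm_subject")
}
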