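#' Cross-validated random-search fit of one model to one subject
#'
#' Five-fold cross-validation over the trials of one delay class: in each
#' fold a unique ~20% of trials is held out; `k_sets` random parameter sets
#' are scored on the training trials by the mean squared circular error
#' between `n_rep` simulated responses per trial and the subject's
#' responses; the best training set is then scored on the held-out trials.
#' For learning models the landscape is evolved, in chronological order,
#' using only training-trial stimuli that precede the simulated trial.
#'
#' @param subject a `wm_subject`.
#' @param model a `wm_model` from [wm_models].
#' @param delay_class `"short"` or `"long"`.
#' @param k_sets number of random parameter sets.
#' @param n_rep simulated replicates per trial.
#' @param folds number of cross-validation folds.
#' @param seed optional seed (controls parameter draws, fold assignment
#'   and simulation noise).
#' @param pop_offset population-bias offset for HetPrior learning models.
#' @param dt integration step.
#' @return a `wm_cvfit`: list with `model`, `delay_class`, `fold` results
#'   (best params, train/test MSE per fold) and `mean_test_mse`.
#' @export
crossval_fit <- function(subject, model, delay_class = "long",
                         k_sets = 100L, n_rep = 100L, folds = 5L,
                         seed = NULL, pop_offset = 0, dt = 0.01) {
  sel <- which(subject$trials$delay_class == delay_class)
  if (length(sel) < folds)
    stop("need at least ", folds, " trials in delay class ", delay_class)
  ord <- sel[order(subject$trials$trial_index[sel])]
  trials <- subject$trials[ord, , drop = FALSE]
  obs <- subject$responses[ord]
  n_t <- nrow(trials)
  sets <- sample_parameter_sets(model, k_sets, derive_seed(seed, 1L))
  fold_id <- with_seed(derive_seed(seed, 2L),
                       sample(rep(seq_len(folds), length.out = n_t)))
  fold_res <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- fold_id != f
    train_mse <- test_mse <- numeric(k_sets)
    for (j in seq_len(k_sets)) {
      sim <- simulate_model_responses(
        model, sets[j, , drop = FALSE], trials, n_rep = n_rep,
        seed = derive_seed(seed, 100L + f * k_sets + j),
        assigned_offset = subject$assigned_offset,
        pop_offset = pop_offset, update_mask = train, dt = dt)
      train_mse[j] <- mse_score(sim[, train, drop = FALSE], obs[train])
      test_mse[j] <- mse_score(sim[, !train, drop = FALSE], obs[!train])
    }
    best <- which.min(train_mse)
    fold_res[[f]] <- list(best_params = as.list(sets[best, , drop = FALSE]),
                          train_mse = train_mse[best],
                          test_mse = test_mse[best])
  }
  structure(list(model = model, delay_class = delay_class,
                 folds = fold_res,
                 mean_test_mse = mean(vapply(fold_res, `[[`, 0,
                                             "test_mse")),
                 k_sets = k_sets, n_rep = n_rep),
            class = "wm_cvfit")
}

#' Select the winning model from a set of cross-validated fits
#'
#' The model with the lowest mean held-out MSE wins; exact ties are broken
#' toward the model with fewer free parameters (parsimony).
#'
#' @param fits list of `wm_cvfit` objects for the same subject and delay
#'   class.
#' @return list with `model_name`, `class` (one of "flat",
#'   "fixed-heterogeneous", "learning"), `mean_test_mse`, and `best_params`
#'   (from the winning model's best fold).
#' @export
select_model <- function(fits) {
  mse <- vapply(fits, `[[`, 0, "mean_test_mse")
  nf <- vapply(fits, function(f) f$model$n_free, 0)
  ord <- order(mse, nf)
  win <- fits[[ord[1]]]
  cls <- switch(win$model$class, flat = "flat",
                fixed = "fixed-heterogeneous", learning = "learning")
  best_fold <- which.min(vapply(win$folds, `[[`, 0, "test_mse"))
  list(model_name = win$model$name, class = cls,
       mean_test_mse = win$mean_test_mse,
       best_params = win$folds[[best_fold]]$best_params)
}

#' Fit the model zoo to a subject's responses
#'
#' The top-level fitting interface: cross-validates every model in
#' `models` on each requested delay class and selects the winner per
#' delay class by mean held-out MSE.
#'
#' @param subject a `wm_subject` ([synthetic_subject] or [read_trials]).
#' @param models list of `wm_model`s (default all eight).
#' @param delay_classes delay classes to fit (default both).
#' @inheritParams crossval_fit
#' @return an object of class `wm_fit` with elements `subject_id`,
#'   `fits` (per delay class, per model), `selection` (per delay class)
#'   and the run settings; methods: [print.wm_fit], [summary.wm_fit],
#'   [coef.wm_fit], [simulate.wm_fit].
#' @examples
#' \donttest{
#' sess <- make_session(n_short = 10, n_long = 10, seed = 1)
#' subj <- synthetic_subject("Flat", list(sigma = 0.05), sess, seed = 2)
#' fit <- wm_fit(subj, models = wm_models(c("Flat", "StaticHet")),
#'               delay_classes = "long", k_sets = 5, n_rep = 5, seed = 3)
#' print(fit)
#' }
#' @export
wm_fit <- function(subject, models = wm_models(),
                   delay_classes = c("short", "long"), k_sets = 100L,
                   n_rep = 100L, folds = 5L, seed = NULL, pop_offset = 0,
                   dt = 0.01) {
  if (!inherits(subject, "wm_subject") &&
      !all(c("trials", "responses") %in% names(subject)))
    stop("subject must be a wm_subject")
  fits <- list()
  selection <- list()
  for (dc in delay_classes) {
    fits[[dc]] <- lapply(seq_along(models), function(i)
      crossval_fit(subject, models[[i]], dc, k_sets = k_sets,
                   n_rep = n_rep, folds = folds,
                   seed = derive_seed(seed, i), pop_offset = pop_offset,
                   dt = dt))
    names(fits[[dc]]) <- vapply(models, `[[`, "", "name")
    selection[[dc]] <- select_model(fits[[dc]])
  }
  structure(list(subject_id = subject$subject_id, fits = fits,
                 selection = selection, models = models,
                 settings = list(k_sets = k_sets, n_rep = n_rep,
                                 folds = folds, seed = seed,
                                 pop_offset = pop_offset, dt = dt),
                 subject = subject),
            class = "wm_fit")
}

#' @rdname wm_fit
#' @param x,object a `wm_fit`.
#' @param ... unused.
#' @export
print.wm_fit <- function(x, ...) {
  cat("Cross-validated working-memory response model fit\n")
  cat("Subject:", x$subject_id, "\n")
  for (dc in names(x$selection)) {
    s <- x$selection[[dc]]
    cat(sprintf("  %-5s delay: %s (%s), mean test MSE %.4f rad^2\n",
                dc, s$model_name, s$class, s$mean_test_mse))
  }
  invisible(x)
}

#' @rdname wm_fit
#' @export
summary.wm_fit <- function(object, ...) {
  rows <- do.call(rbind, lapply(names(object$fits), function(dc)
    do.call(rbind, lapply(object$fits[[dc]], function(f)
      data.frame(delay_class = dc, model = f$model$name,
                 class = f$model$class, n_free = f$model$n_free,
                 mean_test_mse = f$mean_test_mse,
                 selected = FALSE)))))
  for (dc in names(object$selection))
    rows$selected[rows$delay_class == dc &
                    rows$model == object$selection[[dc]]$model_name] <- TRUE
  rownames(rows) <- NULL
  rows
}

#' @rdname wm_fit
#' @param delay_class which delay class's winning parameters to return.
#' @export
coef.wm_fit <- function(object, delay_class = NULL, ...) {
  dcs <- if (is.null(delay_class)) names(object$selection) else delay_class
  out <- lapply(dcs, function(dc)
    unlist(object$selection[[dc]]$best_params))
  names(out) <- dcs
  if (length(out) == 1L) out[[1]] else out
}

#' @rdname wm_fit
#' @param nsim simulated replicates per trial.
#' @param seed optional seed.
#' @export
simulate.wm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  subj <- object$subject
  out <- list()
  for (dc in names(object$selection)) {
    s <- object$selection[[dc]]
    model <- wm_models(s$model_name)[[1]]
    sel <- which(subj$trials$delay_class == dc)
    trials <- subj$trials[sel[order(subj$trials$trial_index[sel])], ,
                          drop = FALSE]
    out[[dc]] <- simulate_model_responses(
      model, s$best_params, trials, n_rep = nsim, seed = seed,
      assigned_offset = subj$assigned_offset,
      pop_offset = object$settings$pop_offset, dt = object$settings$dt)
  }
  out
}

#' Trial-by-trial log-likelihood ratio: learning vs fixed landscape
#'
#' For each trial (one delay class, chronological order) the exact PDE
#' response likelihood is computed under (a) a learning model whose
#' landscape has been evolved by the full stimulus history up to that
#' trial and (b) a fixed-landscape model, and their log ratio is
#' accumulated. A positive cumulative ratio is evidence that the subject's
#' responses track an experience-dependent landscape.
#'
#' @param subject a `wm_subject`.
#' @param learn_model,learn_params a learning-class `wm_model` and its
#'   parameter list.
#' @param fixed_model,fixed_params a flat/fixed-class `wm_model` and its
#'   parameter list.
#' @param delay_class which delay class to analyze.
#' @param pop_offset population-bias offset for HetPrior learning models.
#' @param grid output [ring_grid].
#' @param refine PDE subgrid refinement (NULL = automatic).
#' @param dt PDE time step.
#' @return data.frame with per-trial `ll_learn`, `ll_fixed`, `llr` and
#'   `cum_llr`.
#' @export
trial_llr <- function(subject, learn_model, learn_params, fixed_model,
                      fixed_params, delay_class = "long", pop_offset = 0,
                      grid = ring_grid(), refine = NULL, dt = 0.01) {
  stopifnot(learn_model$class == "learning",
            fixed_model$class %in% c("flat", "fixed"))
  learn_params <- as.list(learn_params)
  fixed_params <- as.list(fixed_params)
  sel <- which(subject$trials$delay_class == delay_class)
  sel <- sel[order(subject$trials$trial_index[sel])]
  trials <- subject$trials[sel, , drop = FALSE]
  obs <- subject$responses[sel]
  T <- trials$delay_s[1]
  fspec <- fixed_model_landscape(fixed_model, fixed_params,
                                 subject$assigned_offset)
  st <- learning_initial_state(learn_model, learn_params, pop_offset, grid)
  n_t <- nrow(trials)
  ll_l <- ll_f <- numeric(n_t)
  for (t in seq_len(n_t)) {
    lspec <- landscape("gridded", values = st$U_est, grid = grid)
    ll_l[t] <- log(response_likelihood(lspec, learn_params$sigma,
                                       trials$target[t], T, obs[t],
                                       grid = grid, refine = refine,
                                       dt = dt))
    ll_f[t] <- log(response_likelihood(fspec, fixed_params$sigma,
                                       trials$target[t], T, obs[t],
                                       grid = grid, refine = refine,
                                       dt = dt))
    stims <- if (identical(learn_model$learn_items, "both"))
      c(trials$target[t], trials$distractor[t]) else trials$target[t]
    st <- learning_update(st, stims)
  }
  data.frame(trial_index = trials$trial_index, ll_learn = ll_l,
             ll_fixed = ll_f, llr = ll_l - ll_f,
             cum_llr = cumsum(ll_l - ll_f))
}
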