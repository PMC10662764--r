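#' Load a run configuration
#'
#' Reads a YAML or JSON configuration for [run_command]. Unknown top-level
#' keys are an error (strict schema); absent blocks fall back to the
#' package defaults (the standard particle parameters sigma = 0.05,
#' A_p = 1, n = 4, T_delay = 5, beta = 8, h = 0.25, s = 5; the neural
#' field defaults of [field_params]; fitting defaults k_sets = 100,
#' n_rep = 100, folds = 5). Angles in configuration files are degrees.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `wm_config` list with blocks `seed`, `out_dir`, `session`,
#'   `model`, `particle`, `fitting`, `distortion`, `llr`, `data`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (is.null(cfg)) cfg <- list()
  known <- c("seed", "out_dir", "session", "model", "particle", "fitting",
             "distortion", "llr", "data")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    seed = 1L, out_dir = ".",
    session = list(assigned_offset_deg = 0, n_short = 100L,
                   n_long = 100L, p_biased = 0.5, arc_width_deg = 20),
    model = list(name = "StaticHet",
                 params = list(sigma = 0.05, A_p = 1, n = 4),
                 pop_offset_deg = 0),
    particle = list(sigma = 0.05, A_p = 1, n = 4, T_delay = 5,
                    beta = 8, h = 0.25, s = 5, dt = 0.01),
    fitting = list(models = "all", k_sets = 100L, n_rep = 100L,
                   folds = 5L, delay_classes = c("short", "long")),
    distortion = list(sigma = 0.05, T = 5, n_sim = 10000L,
                      prior = list(form = "exp_cosine", A = 1, m = 4,
                                   offset_deg = 0)),
    llr = list(learn_model = "LearnTargetFlatPrior",
               learn_params = list(sigma = 0.05, beta = 8, s = 5),
               fixed_model = "Flat",
               fixed_params = list(sigma = 0.05),
               delay_class = "long"),
    data = NULL)
  out <- defaults
  for (k in names(cfg)) {
    out[[k]] <- if (is.list(defaults[[k]]) && is.list(cfg[[k]]))
      utils::modifyList(defaults[[k]], cfg[[k]]) else cfg[[k]]
  }
  structure(out, class = "wm_config")
}

# write the reproducibility manifest next to a command's outputs
write_manifest <- function(out_dir, command, config, outputs, t0) {
  man <- list(command = command,
              seed = config$seed,
              config = unclass(config),
              outputs = outputs,
              package_version =
                as.character(utils::packageVersion("wmprior")),
              elapsed_s = as.numeric(difftime(Sys.time(), t0,
                                              units = "secs")))
  path <- file.path(out_dir, paste0("manifest-", command, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

#' Run a package command from a configuration
#'
#' Deterministic command runner tying the modules together; every run
#' writes its outputs plus a JSON manifest (seed, resolved configuration,
#' package version, wall time) so fixed-seed runs reproduce bit-for-bit.
#'
#' Commands:
#' \describe{
#'   \item{gen-synthetic}{generate a synthetic session and subject under
#'     `model`, write `trials.csv`.}
#'   \item{simulate}{simulate `model` responses for a generated session,
#'     write `responses.csv`.}
#'   \item{fit-subjects}{fit the model zoo to the trial table at
#'     `config$data` (CSV schema of [write_trials]), write
#'     `fit_results.json`.}
#'   \item{distortion}{total mean distortion of the configured particle
#'     model under the configured prior, write `distortion.json`.}
#'   \item{llr}{trial-by-trial learning-vs-fixed log-likelihood ratios
#'     for the subject at `config$data`, write `llr.csv`.}
#' }
#'
#' @param config a `wm_config` from [load_config] (or a compatible list).
#' @param command one of the commands above.
#' @param out_dir output directory (created if needed); defaults to
#'   `config$out_dir`.
#' @return (invisibly) named list of output file paths, including the
#'   manifest.
#' @export
run_command <- function(config,
                        command = c("gen-synthetic", "simulate",
                                    "fit-subjects", "distortion", "llr"),
                        out_dir = NULL) {
  command <- match.arg(command)
  if (!inherits(config, "wm_config")) config <- structure(config,
                                                          class = "wm_config")
  if (is.null(out_dir)) out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  seed <- config$seed
  outputs <- list()
  ses_cfg <- config$session
  make_ses <- function()
    make_session(deg2rad(ses_cfg$assigned_offset_deg), ses_cfg$n_short,
                 ses_cfg$n_long, ses_cfg$p_biased,
                 deg2rad(ses_cfg$arc_width_deg),
                 seed = derive_seed(seed, 1L))
  if (command %in% c("gen-synthetic", "simulate")) {
    session <- make_ses()
    subj <- synthetic_subject(
      config$model$name, config$model$params, session,
      seed = derive_seed(seed, 2L),
      assigned_offset = deg2rad(ses_cfg$assigned_offset_deg),
      pop_offset = deg2rad(config$model$pop_offset_deg %||% 0))
    f <- file.path(out_dir,
                   if (command == "gen-synthetic") "trials.csv"
                   else "responses.csv")
    write_trials(subj, f)
    outputs$trials <- f
  } else if (command == "fit-subjects") {
    if (is.null(config$data)) stop("fit-subjects requires config$data")
    subj <- read_trials(config$data)
    fit_cfg <- config$fitting
    models <- if (identical(fit_cfg$models, "all")) wm_models()
              else wm_models(fit_cfg$models)
    fit <- wm_fit(subj, models = models,
                  delay_classes = fit_cfg$delay_classes,
                  k_sets = fit_cfg$k_sets, n_rep = fit_cfg$n_rep,
                  folds = fit_cfg$folds, seed = derive_seed(seed, 3L),
                  pop_offset = deg2rad(config$model$pop_offset_deg %||% 0))
    f <- file.path(out_dir, "fit_results.json")
    res <- list(subject_id = fit$subject_id,
                selection = fit$selection,
                table = summary(fit))
    jsonlite::write_json(res, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    outputs$fit_results <- f
  } else if (command == "distortion") {
    d_cfg <- config$distortion
    p_cfg <- config$particle
    spec <- landscape("cosine", A_p = p_cfg$A_p, n = p_cfg$n)
    prior <- env_prior(d_cfg$prior$form, A = d_cfg$prior$A,
                       m = d_cfg$prior$m,
                       offset = deg2rad(d_cfg$prior$offset_deg %||% 0))
    dt_mc <- total_mean_distortion(spec, d_cfg$sigma, prior, d_cfg$T,
                                   n_sim = d_cfg$n_sim,
                                   seed = derive_seed(seed, 4L))
    f <- file.path(out_dir, "distortion.json")
    jsonlite::write_json(list(d_tot = dt_mc, n_sim = d_cfg$n_sim), f,
                         auto_unbox = TRUE, digits = NA)
    outputs$distortion <- f
  } else if (command == "llr") {
    if (is.null(config$data)) stop("llr requires config$data")
    subj <- read_trials(config$data)
    l_cfg <- config$llr
    res <- trial_llr(subj,
                     wm_models(l_cfg$learn_model)[[1]],
                     l_cfg$learn_params,
                     wm_models(l_cfg$fixed_model)[[1]],
                     l_cfg$fixed_params,
                     delay_class = l_cfg$delay_class,
                     pop_offset = deg2rad(config$model$pop_offset_deg %||% 0))
    f <- file.path(out_dir, "llr.csv")
    utils::write.csv(res, f, row.names = FALSE, quote = FALSE)
    outputs$llr <- f
  }
  outputs$manifest <- write_manifest(out_dir, command, config, outputs, t0)
  invisible(outputs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
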