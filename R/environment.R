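#' Environmental priors over circular feature values
#'
#' Constructs the distribution from which stimulus feature values (e.g.
#' colors on a ring) are drawn. Three forms are supported:
#' \describe{
#'   \item{`exp_cosine`}{periodic density proportional to
#'     `exp(A * cos(m * (theta - offset)))`, with peaks at common feature
#'     values; `A = 0` recovers the uniform distribution.}
#'   \item{`peaked_arcs`}{the task-style distribution: with probability
#'     `p_biased` an item is drawn uniformly from one of `m` equispaced arcs
#'     of full width `arc_width` centered at `offset + 2*pi*k/m`, otherwise
#'     uniformly on the ring.}
#'   \item{`uniform`}{uniform on the ring.}
#' }
#'
#' @param form one of `"exp_cosine"`, `"peaked_arcs"`, `"uniform"`.
#' @param A amplitude of the exp-cosine modulation (>= 0).
#' @param m number of peaks (positive integer).
#' @param offset circular offset of the peaks, radians.
#' @param p_biased probability that a draw comes from the biased arcs
#'   (peaked_arcs form only).
#' @param arc_width full arc width in radians (peaked_arcs form only);
#'   must lie in (0, pi/2) so arcs do not overlap at m = 4.
#' @return an object of class `env_prior`.
#' @examples
#' pr <- env_prior("exp_cosine", A = 1, m = 4)
#' d <- env_density(pr)
#' sum(d$mass)  # 1
#' @export
env_prior <- function(form = c("exp_cosine", "peaked_arcs", "uniform"),
                      A = 1, m = 4L, offset = 0,
                      p_biased = 0.5, arc_width = deg2rad(20)) {
  form <- match.arg(form)
  if (A < 0) stop("A must be >= 0")
  m <- as.integer(m)
  if (m < 1L) stop("m must be a positive integer")
  if (form == "peaked_arcs") {
    if (arc_width <= 0 || arc_width >= pi / 2)
      stop("arc_width must be in (0, pi/2)")
    if (p_biased < 0 || p_biased > 1) stop("p_biased must be in [0, 1]")
  }
  structure(list(form = form, A = A, m = m, offset = wrap_angle(offset),
                 p_biased = p_biased, arc_width = arc_width),
            class = "env_prior")
}

# continuous density of an env_prior, vectorized over theta
env_pdf <- function(prior, theta) {
  theta <- wrap_angle(theta)
  switch(prior$form,
    uniform = rep(1 / (2 * pi), length(theta)),
    exp_cosine = {
      z <- 2 * pi * besselI(prior$A, 0)
      exp(prior$A * cos(prior$m * (theta - prior$offset))) / z
    },
    peaked_arcs = {
      d <- abs(circ_diff(prior$m * theta, prior$m * prior$offset)) / prior$m
      on_arc <- d <= prior$arc_width / 2
      base <- (1 - prior$p_biased) / (2 * pi)
      base + ifelse(on_arc, prior$p_biased / (prior$m * prior$arc_width), 0)
    },
    stop("unknown prior form"))
}

#' Evaluate an environmental prior on a ring grid
#'
#' @param prior an [env_prior].
#' @param grid a [ring_grid].
#' @return a `density_grid`: list with `grid` and per-bin probability `mass`
#'   summing to 1 (bin-integrated density).
#' @export
env_density <- function(prior, grid = ring_grid()) {
  if (!inherits(prior, "env_prior")) stop("prior must be an env_prior")
  mass <- env_pdf(prior, grid$centers) * grid$bin_width
  density_grid(mass / sum(mass), grid)
}

#' Sample stimulus feature values from an environmental prior
#'
#' Rejection sampling for the exp-cosine form; direct mixture sampling for
#' the peaked-arcs form. Reproducible under a fixed seed.
#'
#' @inheritParams env_density
#' @param n number of draws (>= 1).
#' @param seed optional integer seed.
#' @return numeric vector of n angles in \[-pi, pi).
#' @export
sample_stimuli <- function(prior, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  with_seed(seed, {
    switch(prior$form,
      uniform = runif(n, -pi, pi),
      peaked_arcs = {
        biased <- runif(n) < prior$p_biased
        out <- runif(n, -pi, pi)
        nb <- sum(biased)
        if (nb > 0) {
          peak <- sample.int(prior$m, nb, replace = TRUE) - 1L
          ctr <- prior$offset + 2 * pi * peak / prior$m
          out[biased] <- wrap_angle(
            ctr + runif(nb, -prior$arc_width / 2, prior$arc_width / 2))
        }
        out
      },
      exp_cosine = {
        out <- numeric(0)
        while (length(out) < n) {
          k <- max(2L * (n - length(out)), 32L)
          cand <- runif(k, -pi, pi)
          acc <- runif(k) < exp(prior$A *
            (cos(prior$m * (cand - prior$offset)) - 1))
          out <- c(out, cand[acc])
        }
        out[seq_len(n)]
      })
  })
}

#' Generate a synthetic delayed-estimation session
#'
#' Emulates the two-item task protocol: on each trial a target and a
#' distractor color are drawn independently; each item has probability
#' `p_biased` of coming from a biased distribution made of `4` equispaced
#' arcs of full width `arc_width` centered at `assigned_offset + k * 90`
#' degrees, and is otherwise uniform. Half the trials use a short delay
#' (0.5 s) and half a long delay (4 s); trial order is randomized.
#'
#' @param assigned_offset the subject's randomly assigned offset of the
#'   biased peaks, radians (one period of the 4-peak distribution is
#'   \[0, pi/2)).
#' @param n_short,n_long number of short- and long-delay trials.
#' @param p_biased per-item probability of a biased draw.
#' @param arc_width full arc width, radians (default 20 degrees).
#' @param seed optional integer seed.
#' @return a data.frame with one row per trial: `trial_index`, `delay_class`
#'   ("short"/"long"), `delay_s`, `target`, `distractor` (radians),
#'   `biased_target`, `biased_distractor` (logical).
#' @export
make_session <- function(assigned_offset = 0, n_short = 100L, n_long = 100L,
                         p_biased = 0.5, arc_width = deg2rad(20),
                         seed = NULL) {
  if (arc_width <= 0 || arc_width >= pi / 2)
    stop("arc_width must be in (0, pi/2) radians")
  n <- n_short + n_long
  if (n < 1) stop("session must contain at least one trial")
  prior <- env_prior("peaked_arcs", m = 4L, offset = assigned_offset,
                     p_biased = p_biased, arc_width = arc_width)
  with_seed(seed, {
    draw_items <- function(k) {
      biased <- runif(k) < p_biased
      val <- runif(k, -pi, pi)
      nb <- sum(biased)
      if (nb > 0) {
        peak <- sample.int(4L, nb, replace = TRUE) - 1L
        ctr <- assigned_offset + peak * pi / 2
        val[biased] <- wrap_angle(ctr + runif(nb, -arc_width / 2,
                                              arc_width / 2))
      }
      list(val = val, biased = biased)
    }
    tg <- draw_items(n)
    ds <- draw_items(n)
    delay_class <- sample(rep(c("short", "long"), c(n_short, n_long)))
    data.frame(
      trial_index = seq_len(n),
      delay_class = delay_class,
      delay_s = ifelse(delay_class == "short", 0.5, 4.0),
      target = tg$val, distractor = ds$val,
      biased_target = tg$biased, biased_distractor = ds$biased,
      stringsAsFactors = FALSE)
  })
}

#' Read and write trial/response tables
#'
#' Trial tables are exchanged as plain CSV with angles in degrees in
#' \[-180, 180): columns `subject_id`, `trial_index`, `delay_class`,
#' `delay_s`, `target_deg`, `distractor_deg`, `response_deg`,
#' `assigned_offset_deg`. Internally all angles are radians.
#'
#' @param subject a `wm_subject` (see [synthetic_subject]).
#' @param path file path.
#' @export
write_trials <- function(subject, path) {
  tr <- subject$trials
  out <- data.frame(
    subject_id = subject$subject_id,
    trial_index = tr$trial_index,
    delay_class = tr$delay_class,
    delay_s = tr$delay_s,
    target_deg = rad2deg(tr$target),
    distractor_deg = rad2deg(tr$distractor),
    response_deg = rad2deg(subject$responses),
    assigned_offset_deg = rad2deg(subject$assigned_offset))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @return `read_trials` returns a `wm_subject` list: `subject_id`,
#'   `assigned_offset`, `trials` (data.frame, radians), `responses`.
#' @export
read_trials <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "delay_class", "delay_s",
            "target_deg", "distractor_deg", "response_deg",
            "assigned_offset_deg")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  trials <- data.frame(
    trial_index = x$trial_index,
    delay_class = x$delay_class,
    delay_s = x$delay_s,
    target = wrap_angle(deg2rad(x$target_deg)),
    distractor = wrap_angle(deg2rad(x$distractor_deg)),
    stringsAsFactors = FALSE)
  structure(list(subject_id = x$subject_id[1],
                 assigned_offset = wrap_angle(deg2rad(x$assigned_offset_deg[1])),
                 trials = trials,
                 responses = wrap_angle(deg2rad(x$response_deg)),
                 generator_truth = NULL),
            class = "wm_subject")
}
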