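#' Two-state persistent-random-walk simulator of villus lymphocytes
#'
#' Cells switch between an *arrested* state (isotropic positional jitter) and
#' a *patrolling* state (a persistent run at `v_run` whose heading diffuses)
#' according to a two-state Markov chain at fine time resolution, inside a
#' reflecting villus-scale box. All cells of a simulated field share a
#' sinusoidal XY tissue drift; trajectories are then sampled at the imaging
#' frame interval and perturbed by localization noise, emulating intravital
#' acquisition. Stop-and-go dynamics at sub-frame resolution are what let a
#' single model family reproduce both "spot" and "wavy" cohorts.
#'
#' @name synthetic_tracks
NULL

#' Generative parameters of one motility regime
#'
#' @param name regime label.
#' @param p_AP per-fine-step probability of switching arrested -> patrolling.
#' @param p_PA per-fine-step probability of switching patrolling -> arrested.
#' @param v_run run speed while patrolling, um/min.
#' @param sigma_arrest s.d. of isotropic XY jitter per fine step while
#'   arrested, um.
#' @param sigma_turn s.d. of the heading increment per fine step while
#'   patrolling, radians.
#' @param sigma_z s.d. of axial jitter per fine step, um.
#' @param drift_amp amplitude of the shared sinusoidal tissue-drift velocity,
#'   um/min.
#' @param drift_period drift period, minutes.
#' @param confinement half-widths of the reflecting box, um (x, y, z);
#'   `Inf` disables confinement on an axis.
#' @return list of class `regime_params`. The stationary arrested-state
#'   occupancy is `p_PA / (p_AP + p_PA)` when both probabilities are positive.
#' @export
regime_params <- function(name = "custom", p_AP = 0.01, p_PA = 0.1,
                          v_run = 5, sigma_arrest = 0.1, sigma_turn = 0.5,
                          sigma_z = 0.05, drift_amp = 1, drift_period = 5,
                          confinement = c(75, 25, 25)) {
  if (p_AP < 0 || p_AP > 1 || p_PA < 0 || p_PA > 1)
    vt_stop("bad_regime", "transition probabilities must lie in [0, 1]")
  if (v_run < 0 || sigma_arrest < 0 || sigma_turn < 0 || sigma_z < 0 ||
      drift_amp < 0 || drift_period <= 0 || any(confinement <= 0))
    vt_stop("bad_regime", "speeds, jitters and confinement must be non-negative")
  if (length(confinement) != 3L)
    vt_stop("bad_regime", "confinement must give 3 half-widths (x, y, z)")
  structure(list(name = name, p_AP = p_AP, p_PA = p_PA, v_run = v_run,
                 sigma_arrest = sigma_arrest, sigma_turn = sigma_turn,
                 sigma_z = sigma_z, drift_amp = drift_amp,
                 drift_period = drift_period, confinement = confinement),
            class = "regime_params")
}

#' Simulation configuration
#'
#' @param n_tracks number of cells to simulate.
#' @param duration movie duration, minutes.
#' @param fine_step integration step of the motility model, minutes; must
#'   divide `frame_interval`.
#' @param frame_interval imaging frame interval, minutes; must divide
#'   `duration`, with at least 10 frames per movie.
#' @param localization_sigma per-coordinate localization noise s.d., um.
#' @param seed RNG seed for the whole simulated field.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_tracks = 500, duration = 30, fine_step = 0.1,
                       frame_interval = 1.0, localization_sigma = 0.3,
                       seed = 20220823) {
  K <- frame_interval / fine_step
  if (abs(K - round(K)) > 1e-9)
    vt_stop("bad_sim_config", "frame_interval must be an integer multiple of fine_step")
  Fn <- duration / frame_interval
  if (abs(Fn - round(Fn)) > 1e-9)
    vt_stop("bad_sim_config", "duration must be an integer multiple of frame_interval")
  if (duration < 10 * frame_interval)
    vt_stop("bad_sim_config", "duration must span at least 10 frames")
  if (localization_sigma < 0)
    vt_stop("bad_sim_config", "localization_sigma must be non-negative")
  structure(list(n_tracks = as.integer(n_tracks), duration = duration,
                 fine_step = fine_step, frame_interval = frame_interval,
                 localization_sigma = localization_sigma, seed = seed),
            class = "sim_config")
}

# reflect an unconstrained coordinate into [-h, h] (triangle-wave folding,
# equivalent to sequential reflection of a piecewise-linear path)
.fold <- function(u, h) {
  if (!is.finite(h)) return(u)
  L <- 2 * h
  y <- (u + h) %% (2 * L)
  y <- ifelse(y > L, 2 * L - y, y)
  y - h
}

# Core field simulation. Regime parameters are supplied per fine step (each a
# vector of length M) so a time course is just a step change in the vectors.
# Consumes a fixed number of RNG draws independent of parameter values, so
# paired designs (e.g. with/without drift) stay aligned draw-for-draw.
.simulate_field <- function(par, conf, drift_amp, drift_period, cfg) {
  n <- cfg$n_tracks
  dt <- cfg$fine_step
  K <- as.integer(round(cfg$frame_interval / dt))
  Fn <- as.integer(round(cfg$duration / cfg$frame_interval))
  M <- Fn * K
  # shared field drift (phase, direction) -- drawn even when amplitude is 0
  phi <- stats::runif(1, 0, 2 * pi)
  alpha <- stats::runif(1, 0, 2 * pi)
  # initial positions uniform in the confinement box
  h <- conf
  u0 <- matrix(stats::runif(3 * n, -1, 1), nrow = n)
  x <- if (is.finite(h[1])) u0[, 1] * h[1] else rep(0, n)
  y <- if (is.finite(h[2])) u0[, 2] * h[2] else rep(0, n)
  z <- if (is.finite(h[3])) u0[, 3] * h[3] else rep(0, n)
  # initial state from the stationary distribution of the chain at t = 1
  psum <- par$p_AP[1] + par$p_PA[1]
  piA <- if (psum > 0) par$p_PA[1] / psum else 1
  patrolling <- stats::runif(n) >= piA
  theta <- stats::runif(n, 0, 2 * pi)
  X <- Y <- Z <- matrix(NA_real_, nrow = n, ncol = Fn + 1L)
  X[, 1] <- x; Y[, 1] <- y; Z[, 1] <- z
  arrested_steps <- numeric(n)
  for (t in seq_len(M)) {
    if (t > 1L) {
      u <- stats::runif(n)
      patrolling <- ifelse(patrolling, u >= par$p_PA[t], u < par$p_AP[t])
    }
    theta <- theta + stats::rnorm(n) * par$sigma_turn[t] * patrolling
    jx <- stats::rnorm(n); jy <- stats::rnorm(n); jz <- stats::rnorm(n)
    run <- par$v_run[t] * dt
    x <- x + ifelse(patrolling, run * cos(theta), par$sigma_arrest[t] * jx)
    y <- y + ifelse(patrolling, run * sin(theta), par$sigma_arrest[t] * jy)
    z <- z + par$sigma_z[t] * jz
    arrested_steps <- arrested_steps + !patrolling
    if (t %% K == 0L) {
      f <- t %/% K + 1L
      X[, f] <- x; Y[, f] <- y; Z[, f] <- z
    }
  }
  X <- .fold(X, h[1]); Y <- .fold(Y, h[2]); Z <- .fold(Z, h[3])
  # shared tissue drift: displacement integral of a sinusoidal velocity
  t_frames <- (0:Fn) * cfg$frame_interval
  D <- drift_amp * drift_period / (2 * pi) *
    (cos(phi) - cos(2 * pi * t_frames / drift_period + phi))
  X <- sweep(X, 2L, D * cos(alpha), `+`)
  Y <- sweep(Y, 2L, D * sin(alpha), `+`)
  # localization noise, per frame and coordinate
  s <- cfg$localization_sigma
  X <- X + matrix(stats::rnorm(length(X)), nrow = n) * s
  Y <- Y + matrix(stats::rnorm(length(Y)), nrow = n) * s
  Z <- Z + matrix(stats::rnorm(length(Z)), nrow = n) * s
  list(X = X, Y = Y, Z = Z, t = t_frames,
       arrested_fraction = arrested_steps / M,
       drift = data.frame(frame = 0:Fn,
                          dx = D * cos(alpha), dy = D * sin(alpha)))
}

.const_par <- function(r, M) {
  list(p_AP = rep(r$p_AP, M), p_PA = rep(r$p_PA, M),
       v_run = rep(r$v_run, M), sigma_arrest = rep(r$sigma_arrest, M),
       sigma_turn = rep(r$sigma_turn, M), sigma_z = rep(r$sigma_z, M))
}

.field_to_trackset <- function(field, cfg, condition, cell_class) {
  n <- nrow(field$X)
  tracks <- lapply(seq_len(n), function(i) {
    track(sprintf("%s_%04d", condition, i),
          data.frame(t = field$t, x = field$X[i, ], y = field$Y[i, ],
                     z = field$Z[i, ]),
          frame_interval = cfg$frame_interval,
          cell_class = cell_class, condition = condition)
  })
  ts <- track_set(tracks, condition = condition,
                  acquisition = acquisition_params(
                    frame_interval = cfg$frame_interval,
                    localization_sigma = max(cfg$localization_sigma, 1e-12)))
  attr(ts, "arrested_fraction") <- field$arrested_fraction
  attr(ts, "true_drift") <- field$drift
  ts
}

#' Simulate one track
#'
#' @param regime a [regime_params()] object or preset name (see
#'   [regime_table()]).
#' @param cfg a [sim_config()]; `n_tracks` is ignored (one track).
#' @param seed RNG seed; defaults to the config seed.
#' @return a [track()] with an `arrested_fraction` attribute giving the
#'   realized fraction of fine steps spent arrested.
#' @export
simulate_track <- function(regime, cfg = sim_config(), seed = cfg$seed) {
  regime <- .resolve_regime(regime)
  cfg$n_tracks <- 1L
  ts <- with_seed(seed, {
    M <- as.integer(round(cfg$duration / cfg$fine_step))
    field <- .simulate_field(.const_par(regime, M), regime$confinement,
                             regime$drift_amp, regime$drift_period, cfg)
    .field_to_trackset(field, cfg, regime$name, "synthetic")
  })
  tr <- ts$tracks[[1]]
  attr(tr, "arrested_fraction") <- attr(ts, "arrested_fraction")[1]
  tr
}

#' Simulate a cohort of tracks under one regime
#'
#' All cells share one simulated field (and hence one tissue-drift
#' realization). Deterministic for a fixed seed.
#'
#' @param regime a [regime_params()] object or preset name.
#' @param cfg a [sim_config()].
#' @return a [track_set()] with attributes `arrested_fraction` (per track,
#'   realized fine-step state occupancy) and `true_drift` (the injected
#'   cumulative drift, for validating drift correction).
#' @export
simulate_cohort <- function(regime, cfg = sim_config()) {
  regime <- .resolve_regime(regime)
  if (cfg$n_tracks == 0L)
    return(track_set(list(), condition = regime$name,
                     acquisition = acquisition_params(frame_interval = cfg$frame_interval)))
  with_seed(cfg$seed, {
    M <- as.integer(round(cfg$duration / cfg$fine_step))
    field <- .simulate_field(.const_par(regime, M), regime$confinement,
                             regime$drift_amp, regime$drift_period, cfg)
    .field_to_trackset(field, cfg, regime$name, "synthetic")
  })
}

#' Simulate a treatment time course
#'
#' Every cell follows `regime_before` until `switch_time` minutes and
#' `regime_after` thereafter, with state, heading and position continuous at
#' the switch -- the design of an injection-during-imaging experiment.
#' Confinement and drift parameters are taken from `regime_before`.
#'
#' @param regime_before,regime_after [regime_params()] objects or preset names.
#' @param switch_time minutes from movie start; must lie within the duration.
#' @param cfg a [sim_config()].
#' @return a [track_set()]; the condition label is
#'   `"<before>_to_<after>"` and the switch time is stored in the
#'   `event_time` attribute.
#' @export
simulate_timecourse <- function(regime_before, regime_after, switch_time,
                                cfg = sim_config()) {
  rb <- .resolve_regime(regime_before)
  ra <- .resolve_regime(regime_after)
  if (switch_time < 0 || switch_time > cfg$duration)
    vt_stop("bad_switch_time", "switch_time %g outside the movie duration [0, %g]",
            switch_time, cfg$duration)
  with_seed(cfg$seed, {
    M <- as.integer(round(cfg$duration / cfg$fine_step))
    t_mid <- (seq_len(M) - 0.5) * cfg$fine_step
    before <- t_mid < switch_time
    mix <- function(a, b) ifelse(before, a, b)
    par <- list(p_AP = mix(rb$p_AP, ra$p_AP), p_PA = mix(rb$p_PA, ra$p_PA),
                v_run = mix(rb$v_run, ra$v_run),
                sigma_arrest = mix(rb$sigma_arrest, ra$sigma_arrest),
                sigma_turn = mix(rb$sigma_turn, ra$sigma_turn),
                sigma_z = mix(rb$sigma_z, ra$sigma_z))
    field <- .simulate_field(par, rb$confinement, rb$drift_amp,
                             rb$drift_period, cfg)
    ts <- .field_to_trackset(field, cfg, sprintf("%s_to_%s", rb$name, ra$name),
                             "synthetic")
    attr(ts, "event_time") <- switch_time
    ts
  })
}
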