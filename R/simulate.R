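#' Minimum-jerk displacement profile
#'
#' Normalized minimum-jerk position profile
#' \eqn{s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5} on \eqn{\tau \in [0,1]}.
#' Its peak speed over a movement of extent `D` and duration `T` is
#' `1.875 * D / T`, attained at the midpoint.
#'
#' @param tau numeric vector in \[0, 1\] (values outside are clamped).
#' @return numeric vector of normalized displacements in \[0, 1\].
#' @export
min_jerk_s <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Single minimum-jerk movement as a kinematic stream
#'
#' Convenience constructor used throughout the tests: one straight
#' minimum-jerk reach of given extent and duration, sampled uniformly,
#' with constant orientation.
#'
#' @param extent_mm movement extent in mm.
#' @param duration_s movement duration in seconds.
#' @param rate_hz sampling rate in Hz.
#' @param direction length-3 direction vector (normalized internally).
#' @param lead_s,trail_s stationary padding before and after the
#'   movement, seconds.
#' @return A [kinematic_stream].
#' @export
min_jerk_stream <- function(extent_mm, duration_s, rate_hz = 50,
                            direction = c(1, 0, 0),
                            lead_s = 0, trail_s = 0) {
  total <- lead_s + duration_s + trail_s
  n <- round(total * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  tau <- (t - lead_s) / duration_s
  s <- extent_mm * min_jerk_s(tau)
  d <- direction / sqrt(sum(direction^2))
  pos <- outer(s, d)
  quat <- matrix(rep(c(1, 0, 0, 0), n), ncol = 4, byrow = TRUE)
  kinematic_stream(t, pos, quat)
}

#' Simulate an instrument trajectory from a skill profile
#'
#' Builds tip motion as a superposition of straight minimum-jerk
#' submovements whose onsets form a Poisson process (at
#' `submovement_rate` per second) outside randomly placed pauses, plus
#' additive Gaussian tremor.  Orientation advances about a slowly
#' drifting axis with angular increment proportional to the translation
#' at each step (`rotation_gain_rad_per_mm`), so angular path length is
#' correlated with, but not identical to, linear path length.
#'
#' Identical `seed` and arguments reproduce the stream bit-for-bit; no
#' global random state is touched.
#'
#' @param profile a [skill_profile].
#' @param duration_s task duration in seconds (> 0).
#' @param rate_hz sampling rate in Hz (> 0); robotic recorders log at 50.
#' @param seed integer seed.
#' @return A [kinematic_stream] with `round(duration_s * rate_hz)` samples.
#' @export
simulate_trajectory <- function(profile, duration_s, rate_hz = 50, seed = 1L) {
  stopifnot(inherits(profile, "skill_profile"))
  if (!is.numeric(duration_s) || duration_s <= 0) stop("`duration_s` must be > 0")
  if (!is.numeric(rate_hz) || rate_hz <= 0) stop("`rate_hz` must be > 0")
  n <- round(duration_s * rate_hz)
  if (n < 2L) stop("`duration_s * rate_hz` must give at least 2 samples")
  t <- (seq_len(n) - 1) / rate_hz

  withr_seed(seed, {
    pauses <- draw_pauses(profile, duration_s)
    in_pause <- rep(FALSE, n)
    if (nrow(pauses)) {
      for (j in seq_len(nrow(pauses))) {
        in_pause <- in_pause | (t >= pauses$start[j] & t < pauses$end[j])
      }
    }

    # submovement onsets: Poisson over the full task, thinned to non-pause time
    n_cand <- rpois(1L, profile$submovement_rate * duration_s)
    onsets <- sort(runif(n_cand, 0, duration_s))
    if (nrow(pauses)) {
      keep <- !vapply(onsets, function(o) {
        any(o >= pauses$start & o < pauses$end)
      }, logical(1))
      onsets <- onsets[keep]
    }
    k <- length(onsets)
    disp <- matrix(0, n, 3)
    if (k > 0L) {
      d0 <- profile$submovement_duration_s
      durs <- runif(k, 0.65 * d0, 1.35 * d0)
      amps <- rgamma(k, shape = 4,
                     scale = profile$submovement_amplitude_mm / 4)
      dirs <- unit_sphere_sample(k)
      for (j in seq_len(k)) {
        tau <- (t - onsets[j]) / durs[j]
        disp <- disp + outer(amps[j] * min_jerk_s(tau), dirs[j, ])
      }
    }
    if (profile$tremor_sd_mm > 0) {
      disp <- disp + matrix(rnorm(3 * n, sd = profile$tremor_sd_mm), n, 3)
    }

    # orientation: rotation about a drifting axis, angle tied to translation
    step_mm <- sqrt(rowSums((disp[-1, , drop = FALSE] -
                             disp[-n, , drop = FALSE])^2))
    axis <- unit_sphere_sample(1L)[1, ]
    quat <- matrix(0, n, 4)
    quat[1, ] <- c(1, 0, 0, 0)
    drift <- matrix(rnorm(3 * (n - 1), sd = 0.02), n - 1, 3)
    for (kk in seq_len(n - 1)) {
      axis <- axis + drift[kk, ]
      axis <- axis / sqrt(sum(axis^2))
      dq <- quat_from_axis_angle(axis,
                                 profile$rotation_gain_rad_per_mm * step_mm[kk])
      q <- quat_multiply(dq, quat[kk, ])
      quat[kk + 1, ] <- q / sqrt(sum(q^2))
    }
    kinematic_stream(t, disp, quat)
  })
}

draw_pauses <- function(profile, duration_s) {
  n_pause <- rpois(1L, profile$pause_rate_per_min * duration_s / 60)
  if (n_pause == 0L) {
    return(data.frame(start = numeric(), end = numeric()))
  }
  start <- sort(runif(n_pause, 0, duration_s))
  len <- rexp(n_pause, rate = 1 / max(profile$pause_mean_s, 1e-9))
  data.frame(start = start, end = pmin(start + len, duration_s))
}

#' Simulate a console event stream
#'
#' Clutch presses form a Poisson process at `clutch_rate_per_min`.
#' Energy application is an alternating renewal process with exponential
#' on/off sojourns whose stationary on-fraction equals `energy_duty`;
#' the initial state is drawn from the stationary distribution so the
#' expected energized fraction equals the duty over any horizon.  A
#' burst still on at `duration_s` is closed there so the on/off
#' alternation invariant always holds.
#'
#' @param profile a [skill_profile].
#' @param duration_s task duration in seconds (> 0).
#' @param seed integer seed.
#' @param mean_burst_s mean duration of one energized burst, seconds.
#' @return An [event_stream].
#' @export
simulate_events <- function(profile, duration_s, seed = 1L, mean_burst_s = 3) {
  stopifnot(inherits(profile, "skill_profile"))
  if (!is.numeric(duration_s) || duration_s <= 0) stop("`duration_s` must be > 0")
  duty <- profile$energy_duty
  if (duty < 0 || duty > 1) stop("`energy_duty` must be in [0, 1]")

  withr_seed(seed, {
    t <- numeric(); kind <- character()

    n_clutch <- rpois(1L, profile$clutch_rate_per_min * duration_s / 60)
    if (n_clutch > 0L) {
      t <- c(t, sort(runif(n_clutch, 0, duration_s)))
      kind <- c(kind, rep("clutch", n_clutch))
    }

    if (duty > 0 && duty < 1) {
      mean_off <- mean_burst_s * (1 - duty) / duty
      now <- 0
      on <- runif(1L) < duty  # stationary initial state (memoryless sojourns)
      if (on) { t <- c(t, 0); kind <- c(kind, "energy_on") }
      while (now < duration_s) {
        soj <- rexp(1L, rate = 1 / (if (on) mean_burst_s else mean_off))
        now <- now + soj
        if (now >= duration_s) break
        on <- !on
        t <- c(t, now)
        kind <- c(kind, if (on) "energy_on" else "energy_off")
      }
      if (on) { t <- c(t, duration_s); kind <- c(kind, "energy_off") }
    } else if (duty == 1) {
      t <- c(t, 0, duration_s); kind <- c(kind, "energy_on", "energy_off")
    }
    event_stream(t, kind)
  })
}

#' Simulate a dichotomous Rasch response matrix
#'
#' Entry (n, i) is Bernoulli with success probability
#' \eqn{\exp(\theta_n - \delta_i) / (1 + \exp(\theta_n - \delta_i))}.
#'
#' @param abilities numeric vector of person abilities (logits).
#' @param difficulties numeric vector of item difficulties (logits).
#' @param seed integer seed.
#' @return An integer matrix `length(abilities)` x `length(difficulties)`
#'   with dimnames `person<n>` / `item<i>`.
#' @export
simulate_response_matrix <- function(abilities, difficulties, seed = 1L) {
  if (length(abilities) == 0L) stop("`abilities` must be non-empty")
  if (length(difficulties) == 0L) stop("`difficulties` must be non-empty")
  withr_seed(seed, {
    p <- plogis(outer(abilities, difficulties, `-`))
    x <- matrix(rbinom(length(p), 1L, p), nrow = length(abilities))
    dimnames(x) <- list(paste0("person", seq_along(abilities)),
                        paste0("item", seq_along(difficulties)))
    x
  })
}

# run code under a local RNG seed without touching the caller's state
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
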