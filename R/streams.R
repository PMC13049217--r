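#' Kinematic stream of instrument tip pose
#'
#' A validated container for one instrument's tip trajectory: time stamps,
#' 3D position in millimetres, and unit-quaternion orientation
#' (scalar-first \code{(qw, qx, qy, qz)} convention).
#'
#' @param t numeric vector of time stamps in seconds, strictly increasing.
#' @param pos numeric matrix, `length(t)` x 3, tip position in mm.
#' @param quat numeric matrix, `length(t)` x 4, unit quaternions
#'   (scalar first).  Each row must have unit norm within `1e-9`.
#' @return An object of class `kinematic_stream`: a list with elements
#'   `t`, `pos`, `quat`.
#' @examples
#' s <- kinematic_stream(
#'   t = c(0, 0.02, 0.04),
#'   pos = rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)),
#'   quat = matrix(rep(c(1, 0, 0, 0), 3), ncol = 4, byrow = TRUE)
#' )
#' linear_path_length(s)
#' @export
kinematic_stream <- function(t, pos, quat) {
  t <- as.numeric(t)
  pos <- as.matrix(pos)
  quat <- as.matrix(quat)
  if (ncol(pos) != 3L) stop("`pos` must have 3 columns (x, y, z in mm)")
  if (ncol(quat) != 4L) stop("`quat` must have 4 columns (qw, qx, qy, qz)")
  n <- length(t)
  if (nrow(pos) != n || nrow(quat) != n) {
    stop("`t`, `pos` and `quat` must have equal length")
  }
  if (n >= 2L && any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  norms <- sqrt(rowSums(quat^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop("quaternions must have unit norm within 1e-9")
  }
  structure(list(t = t, pos = pos, quat = quat), class = "kinematic_stream")
}

#' @export
print.kinematic_stream <- function(x, ...) {
  dur <- if (length(x$t) >= 2) diff(range(x$t)) else 0
  cat(sprintf("<kinematic_stream> %d samples over %.2f s\n", length(x$t), dur))
  invisible(x)
}

#' Console event stream
#'
#' Timestamped console events: energy pedal on/off and clutch presses.
#' Energy events must strictly alternate starting with `energy_on`.
#'
#' @param t numeric vector of event times in seconds, non-decreasing.
#' @param kind character vector, each one of `"energy_on"`, `"energy_off"`,
#'   `"clutch"`.
#' @return An object of class `event_stream`: a data.frame with columns
#'   `t` and `kind`.
#' @examples
#' ev <- event_stream(c(1, 3, 5), c("energy_on", "energy_off", "clutch"))
#' clutch_count(ev)
#' @export
event_stream <- function(t = numeric(), kind = character()) {
  t <- as.numeric(t)
  kind <- as.character(kind)
  if (length(t) != length(kind)) stop("`t` and `kind` must have equal length")
  ok <- kind %in% c("energy_on", "energy_off", "clutch")
  if (!all(ok)) {
    stop("unknown event kind: ", paste(unique(kind[!ok]), collapse = ", "))
  }
  o <- order(t)
  t <- t[o]; kind <- kind[o]
  if (length(t) >= 2L && any(diff(t) < 0)) stop("event times must be non-decreasing")
  check_energy_alternation(kind)
  structure(data.frame(t = t, kind = kind, stringsAsFactors = FALSE),
            class = c("event_stream", "data.frame"))
}

# energy_on / energy_off must strictly alternate, starting with energy_on;
# a trailing unmatched energy_on is rejected at construction so that
# downstream interval pairing is always well defined.
check_energy_alternation <- function(kind) {
  en <- kind[kind != "clutch"]
  if (length(en) == 0L) return(invisible(TRUE))
  expected <- rep(c("energy_on", "energy_off"), length.out = length(en))
  if (!identical(en, expected)) {
    stop("energy events must strictly alternate energy_on/energy_off, ",
         "starting with energy_on")
  }
  if (length(en) %% 2L != 0L) stop("unmatched energy_on: missing energy_off")
  invisible(TRUE)
}

#' Skill profile for the trajectory and event simulators
#'
#' Parameterizes the expert-versus-trainee contrast the OPIs must detect.
#' Defaults describe a mid-level trainee; see [expert_profile()] and
#' [novice_profile()] for the endpoints used in tests.
#'
#' @param submovement_rate submovements per second of active (non-pause)
#'   time; more submovements mean a jerkier, longer path.
#' @param submovement_amplitude_mm mean spatial extent of one submovement.
#' @param submovement_duration_s mean duration of one submovement;
#'   individual durations are drawn uniformly within +/-35%.  Experts
#'   produce long flowing strokes, novices short jerky ones — this is
#'   what lets a novice rack up more speed peaks *and* more idle time
#'   inside the same task duration.
#' @param tremor_sd_mm standard deviation of additive Gaussian positional
#'   noise per 50 Hz sample (mm).  Note the finite-difference speed
#'   floor this implies (about `113 * tremor_sd_mm` mm/s at 50 Hz):
#'   values above ~0.008 mm keep the smoothed speed permanently over a
#'   1 mm/s idle threshold.  Robotic tip positions are servo-filtered,
#'   so realistic values are a few micrometres.
#' @param pause_rate_per_min expected number of idle pauses per minute.
#' @param pause_mean_s mean pause duration (exponential), seconds.
#' @param energy_duty target fraction of active time with energy applied,
#'   in \[0, 1\].
#' @param clutch_rate_per_min expected clutch presses per minute.
#' @param rotation_gain_rad_per_mm wrist rotation per unit tip
#'   translation (rad/mm).
#' @return An object of class `skill_profile` (a named list).
#' @export
skill_profile <- function(submovement_rate = 1.5,
                          submovement_amplitude_mm = 20,
                          submovement_duration_s = 0.65,
                          tremor_sd_mm = 0.004,
                          pause_rate_per_min = 4,
                          pause_mean_s = 1.5,
                          energy_duty = 0.2,
                          clutch_rate_per_min = 3,
                          rotation_gain_rad_per_mm = 0.02) {
  p <- list(submovement_rate = submovement_rate,
            submovement_amplitude_mm = submovement_amplitude_mm,
            submovement_duration_s = submovement_duration_s,
            tremor_sd_mm = tremor_sd_mm,
            pause_rate_per_min = pause_rate_per_min,
            pause_mean_s = pause_mean_s,
            energy_duty = energy_duty,
            clutch_rate_per_min = clutch_rate_per_min,
            rotation_gain_rad_per_mm = rotation_gain_rad_per_mm)
  nonneg <- c("submovement_rate", "submovement_amplitude_mm",
              "submovement_duration_s", "tremor_sd_mm",
              "pause_rate_per_min", "pause_mean_s", "clutch_rate_per_min",
              "rotation_gain_rad_per_mm")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0) {
      stop("`", nm, "` must be a single non-negative number")
    }
  }
  if (energy_duty < 0 || energy_duty > 1) stop("`energy_duty` must be in [0, 1]")
  structure(p, class = "skill_profile")
}

#' @rdname skill_profile
#' @details `expert_profile()` makes few, long, flowing strokes with no
#'   tremor, pauses rarely, and uses energy and clutch sparingly;
#'   `novice_profile()` makes many short jerky submovements with tremor,
#'   pauses often and long, and leans on the console harder.
#' @export
expert_profile <- function() {
  skill_profile(submovement_rate = 1.4, submovement_amplitude_mm = 15,
                submovement_duration_s = 1.7, tremor_sd_mm = 0,
                pause_rate_per_min = 2, pause_mean_s = 1,
                energy_duty = 0.15, clutch_rate_per_min = 2,
                rotation_gain_rad_per_mm = 0.015)
}

#' @rdname skill_profile
#' @export
novice_profile <- function() {
  skill_profile(submovement_rate = 3, submovement_amplitude_mm = 25,
                submovement_duration_s = 0.3, tremor_sd_mm = 0.006,
                pause_rate_per_min = 8, pause_mean_s = 3,
                energy_duty = 0.35, clutch_rate_per_min = 8,
                rotation_gain_rad_per_mm = 0.03)
}

# ---- quaternion helpers (scalar-first) --------------------------------

quat_multiply <- function(a, b) {
  # Hamilton product a * b, both length-4 scalar-first
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < .Machine$double.eps) return(c(1, 0, 0, 0))
  c(cos(angle / 2), sin(angle / 2) * axis / n)
}

unit_sphere_sample <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}
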