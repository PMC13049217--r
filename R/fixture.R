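#' Synthetic study cohort with known gating structure
#'
#' Builds a cohort mirroring the published study counts: 65 scored
#' trainees over two training cohorts (35 + 30) and 7 expert attendings.
#' Video failure modes follow the printed per-cohort tallies — 15
#' bleeding (8 + 7), 4 poor tissue handling (2019 only), 3 lost tension
#' (2 + 1), 43 clean — so the gate fires for exactly 22 trainees.
#' Bleeding zeroes one of items 2-4 (assigned round-robin per record,
#' since the published counts do not identify the item per subject),
#' poor tissue handling zeroes item 5, lost tension item 6.  Subgroup
#' (self-reported sex) labels are assigned in the 2023 cohort only: 13
#' female, 17 male.
#'
#' Clean trainees are split between near-expert ("within-norms") and
#' degraded ("beyond-norms") skill profiles by `beyond_norm_fraction`;
#' experts all use [expert_profile()].  Kinematic and event streams are
#' simulated per subject with seeds derived from `seed`.
#'
#' @param seed integer master seed.
#' @param duration_s simulated task duration per subject (s).
#' @param rate_hz kinematic sampling rate (Hz).
#' @param beyond_norm_fraction fraction of clean trainees given a
#'   degraded skill profile.
#' @param streams if `FALSE`, skip trajectory/event simulation and
#'   return only the roster and video outcomes (fast path for scoring
#'   tests).
#' @return A list of class `cohort_fixture` with `subjects` (roster
#'   data.frame), `video` (outcomes data.frame for the 65 trainees),
#'   `streams`, `events` (named lists over all subjects, or `NULL`),
#'   and `profiles`.
#' @export
make_cohort_fixture <- function(seed = 1L, duration_s = 60, rate_hz = 50,
                                beyond_norm_fraction = 0.5, streams = TRUE) {
  counts <- list(
    `2019` = c(bleeding = 8L, poor_tissue_handling = 4L, lost_tension = 2L,
               none = 21L),
    `2023` = c(bleeding = 7L, poor_tissue_handling = 0L, lost_tension = 1L,
               none = 22L))

  rows <- list(); k <- 0L
  for (cohort in names(counts)) {
    for (mode in names(counts[[cohort]])) {
      for (j in seq_len(counts[[cohort]][[mode]])) {
        k <- k + 1L
        rows[[k]] <- data.frame(subject_id = sprintf("T%03d", k),
                                role = "trainee", cohort = cohort,
                                failure_mode = mode)
      }
    }
  }
  subjects <- do.call(rbind, rows)
  experts <- data.frame(subject_id = sprintf("E%03d", 1:7), role = "expert",
                        cohort = "expert", failure_mode = "none")
  subjects <- rbind(subjects, experts)

  # subgroup labels: 2023 cohort only, 13 female / 17 male (assignment
  # interleaved across failure modes so both labels appear among clean
  # and gated trainees)
  subjects$group <- NA_character_
  i23 <- which(subjects$cohort == "2023")
  lab <- c(rep(c("female", "male"), 13L), rep("male", length(i23) - 26L))
  subjects$group[i23] <- lab

  # video items: the failing item per mode; bleeding rotates over items 2-4
  trainees <- subjects[subjects$role == "trainee", , drop = FALSE]
  video <- data.frame(subject_id = trainees$subject_id,
                      item1 = 1L, item2 = 1L, item3 = 1L,
                      item4 = 1L, item5 = 1L, item6 = 1L,
                      failure_mode = trainees$failure_mode,
                      group = trainees$group,
                      stringsAsFactors = FALSE)
  bl <- which(video$failure_mode == "bleeding")
  for (j in seq_along(bl)) {
    video[[paste0("item", 2L + (j - 1L) %% 3L)]][bl[j]] <- 0L
  }
  video$item5[video$failure_mode == "poor_tissue_handling"] <- 0L
  video$item6[video$failure_mode == "lost_tension"] <- 0L

  # skill profile per subject
  clean <- which(trainees$failure_mode == "none")
  n_beyond <- round(beyond_norm_fraction * length(clean))
  profiles <- vector("list", nrow(subjects))
  names(profiles) <- subjects$subject_id
  beyond_ids <- withr_seed(seed, sample(clean, n_beyond))
  for (i in seq_len(nrow(subjects))) {
    profiles[[i]] <-
      if (subjects$role[i] == "expert") expert_profile()
      else if (subjects$failure_mode[i] != "none") novice_profile()
      else if (i %in% beyond_ids) novice_profile()
      else within_norm_profile()
  }

  out <- list(subjects = subjects, video = video, profiles = profiles,
              streams = NULL, events = NULL)
  if (streams) {
    st <- vector("list", nrow(subjects)); ev <- vector("list", nrow(subjects))
    names(st) <- names(ev) <- subjects$subject_id
    for (i in seq_len(nrow(subjects))) {
      si <- derive_seed(seed, i)
      st[[i]] <- simulate_trajectory(profiles[[i]], duration_s, rate_hz,
                                     seed = si)
      ev[[i]] <- simulate_events(profiles[[i]], duration_s, seed = si + 1L)
    }
    out$streams <- st
    out$events <- ev
  }
  structure(out, class = "cohort_fixture")
}

# near-expert trainee: same motion economy as the experts (a trainee
# "within norms" performs, by definition, like the expert population)
# with a trace of tremor; sampling noise still lets individual OPIs
# fall outside the 2-SD band occasionally
within_norm_profile <- function() {
  skill_profile(submovement_rate = 1.35, submovement_amplitude_mm = 15,
                submovement_duration_s = 1.6, tremor_sd_mm = 0.002,
                pause_rate_per_min = 2, pause_mean_s = 1.1,
                energy_duty = 0.16, clutch_rate_per_min = 2,
                rotation_gain_rad_per_mm = 0.015)
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

#' @export
print.cohort_fixture <- function(x, ...) {
  cat(sprintf("<cohort_fixture> %d trainees + %d experts; failure modes:\n",
              sum(x$subjects$role == "trainee"),
              sum(x$subjects$role == "expert")))
  print(table(x$video$failure_mode))
  invisible(x)
}

#' Extract the OPI table for a fixture cohort
#'
#' Runs [extract_opis()] over every subject's simulated stream.
#'
#' @param fixture a [make_cohort_fixture()] result built with
#'   `streams = TRUE`.
#' @param config an [opi_config].
#' @return data.frame with `subject_id`, `role`, and the six OPI columns.
#' @export
fixture_opi_table <- function(fixture, config = opi_config()) {
  if (is.null(fixture$streams)) stop("fixture was built without streams")
  ids <- fixture$subjects$subject_id
  tab <- do.call(rbind, lapply(ids, function(id) {
    extract_opis(fixture$streams[[id]], fixture$events[[id]], config)
  }))
  cbind(data.frame(subject_id = ids, role = fixture$subjects$role),
        as.data.frame(tab))
}
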