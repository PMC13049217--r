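#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: simulation scale,
#' signal-processing settings, rubric conventions, Rasch estimation
#' controls and fit bounds.  Defaults reproduce the package's stated
#' conventions; everything is echoed into the run summary so each run
#' is self-describing.
#'
#' @param out_dir output directory for CSV/JSON artifacts.
#' @param seed master seed for the simulated cohort.
#' @param duration_s,rate_hz simulated task length and sampling rate.
#' @param beyond_norm_fraction see [make_cohort_fixture()].
#' @param opi an [opi_config].
#' @param rubric a [rubric_config].
#' @param sided OPI threshold sidedness (see [score_opi_item()]).
#' @param level_rule level assignment rule (see [assign_level()]).
#' @param n_quadrature,tol,max_iter Rasch estimation controls.
#' @param fit_lower,fit_upper infit acceptance band.
#' @param gated_as_missing treat gate-forced zeros as structurally
#'   missing in the calibration (sensitivity mode) instead of observed
#'   zeros (default, matching how gated rubrics are scored in practice).
#' @param write_streams also write one kinematics/events CSV per subject.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("opirasch_run_"),
                            seed = 1L, duration_s = 60, rate_hz = 50,
                            beyond_norm_fraction = 0.5,
                            opi = opi_config(), rubric = rubric_config(),
                            sided = "two", level_rule = "cumulative",
                            n_quadrature = 41L, tol = 1e-5, max_iter = 500L,
                            fit_lower = 0.7, fit_upper = 1.3,
                            gated_as_missing = FALSE,
                            write_streams = FALSE) {
  stopifnot(fit_lower < fit_upper, n_quadrature >= 3, tol > 0, max_iter >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full assessment pipeline
#'
#' simulate -> extract OPIs -> fit expert norms -> score the gated
#' rubric -> Rasch calibration (difficulties, EAP/WLE abilities,
#' reliabilities, infit/outfit) -> validity suite (Wright map, banding,
#' construct-alignment rho, biserial, subgroup fairness).  All tabular
#' artifacts are written under `config$out_dir`, together with a
#' structured `summary.json` and a one-line-per-stage log; identical
#' config and seed give byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage log lines on the console.
#' @return Invisibly, a list with all intermediate objects (`fixture`,
#'   `opis`, `norms`, `irm`, `fit`, `eap`, `wle`, `fitstats`,
#'   `wright`, `banding`, `rho`, `biserial`, `fairness`, `summary`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  stage <- function(name, fmt, ...) {
    line <- sprintf("[%s] %s", name, sprintf(fmt, ...))
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  stage("config", "seed=%d duration_s=%g rate_hz=%g level_rule=%s sided=%s",
        config$seed, config$duration_s, config$rate_hz, config$level_rule,
        config$sided)

  fixture <- run_stage("simulate", make_cohort_fixture(
    seed = config$seed, duration_s = config$duration_s,
    rate_hz = config$rate_hz,
    beyond_norm_fraction = config$beyond_norm_fraction))
  stage("simulate", "%d trainees, %d experts",
        sum(fixture$subjects$role == "trainee"),
        sum(fixture$subjects$role == "expert"))
  if (config$write_streams) {
    kdir <- file.path(config$out_dir, "kinematics")
    edir <- file.path(config$out_dir, "events")
    dir.create(kdir, showWarnings = FALSE); dir.create(edir, showWarnings = FALSE)
    for (id in fixture$subjects$subject_id) {
      write_kinematics_csv(fixture$streams[[id]],
                           file.path(kdir, paste0(id, ".csv")))
      write_events_csv(fixture$events[[id]],
                       file.path(edir, paste0(id, ".csv")))
    }
  }
  write_outcomes_csv(fixture$video, file.path(config$out_dir, "outcomes.csv"))

  opis <- run_stage("extract", fixture_opi_table(fixture, config$opi))
  data.table::fwrite(opis, file.path(config$out_dir, "opis.csv"))
  stage("extract", "OPI table: %d rows x %d metrics", nrow(opis),
        length(opi_metric_names()))

  norms <- run_stage("norms", fit_expert_norms(
    opis[opis$role == "expert", , drop = FALSE]))
  data.table::fwrite(as.data.frame(norms), file.path(config$out_dir, "norms.csv"))
  stage("norms", "fitted on %d experts", attr(norms, "n_experts"))

  irm <- run_stage("score", score_cohort(
    opis[opis$role == "trainee", c("subject_id", opi_metric_names())],
    fixture$video, norms, config$rubric,
    sided = config$sided, level_rule = config$level_rule))
  write_scores_csv(irm, file.path(config$out_dir, "scores.csv"))
  n_gated <- sum(!is.na(irm$gated_from))
  stage("score", "%d subjects scored; %d gated; %d passed all video items",
        nrow(irm$scores), n_gated, nrow(irm$scores) - n_gated)

  cal_irm <- irm
  if (config$gated_as_missing) cal_irm <- gated_to_missing(irm)
  fit <- run_stage("calibrate", fit_rasch_mml(
    cal_irm, n_quadrature = config$n_quadrature,
    tol = config$tol, max_iter = config$max_iter))
  eap <- eap_scores(fit, cal_irm)
  wle <- wle_scores(fit, cal_irm)
  fitstats <- flag_fit(infit_outfit(fit, cal_irm),
                       config$fit_lower, config$fit_upper)
  data.table::fwrite(
    data.frame(item = fit$item_names, delta = as.vector(fit$delta),
               delta_se = as.vector(fit$delta_se),
               infit = fitstats$infit_mnsq, outfit = fitstats$outfit_mnsq,
               flag = fitstats$flag),
    file.path(config$out_dir, "calibration.csv"))
  data.table::fwrite(
    data.frame(subject_id = irm$subject_ids, theta_eap = eap$theta_eap,
               psd_eap = eap$psd_eap, theta_wle = wle$theta_wle,
               se_wle = wle$se_wle),
    file.path(config$out_dir, "persons.csv"))
  rel_eap <- eap_reliability(eap)
  rel_wle <- wle_reliability(wle)
  stage("calibrate", "%d/%d items included; EAP rel %.3f; WLE rel %.3f",
        sum(fit$included), length(fit$included), rel_eap, rel_wle)

  wright <- run_stage("validate", build_wright_map(
    fit, config$rubric, person_locations = wle$theta_wle))
  banding <- banding_check(wright)
  rho <- construct_alignment_rho(config$rubric$level_of_item, fit$delta)
  biserial <- item_ability_biserial(irm, wle$theta_wle,
                                    levels = irm$level)
  fairness <- tryCatch(
    fairness_dif(irm, n_quadrature = config$n_quadrature,
                 tol = config$tol, max_iter = config$max_iter),
    error = function(e) {
      stage("validate", "fairness skipped: %s", conditionMessage(e))
      NULL
    })
  data.table::fwrite(biserial$item,
                     file.path(config$out_dir, "biserial_items.csv"))
  if (!is.null(fairness)) {
    data.table::fwrite(fairness$items,
                       file.path(config$out_dir, "fairness_items.csv"))
  }
  stage("validate", "rho=%.3f banded=%s fairness_r=%s", rho, banding$banded,
        if (is.null(fairness)) "NA" else sprintf("%.3f", fairness$pearson_r))

  summary <- list(
    config = list(seed = config$seed, duration_s = config$duration_s,
                  rate_hz = config$rate_hz, sided = config$sided,
                  level_rule = config$level_rule,
                  beyond_norm_fraction = config$beyond_norm_fraction,
                  gated_as_missing = config$gated_as_missing,
                  n_quadrature = config$n_quadrature,
                  fit_bounds = c(config$fit_lower, config$fit_upper)),
    versions = list(opirasch = as.character(utils::packageVersion("opirasch")),
                    r = as.character(getRversion())),
    n_scored = nrow(irm$scores),
    n_gated = n_gated,
    n_pass_all_video = nrow(irm$scores) - n_gated,
    level_counts = as.list(table(irm$level)),
    eap_reliability = rel_eap,
    wle_reliability = rel_wle,
    construct_alignment_rho = rho,
    banded = banding$banded,
    fairness_r = if (is.null(fairness)) NA else fairness$pearson_r,
    flagged_items = fitstats$item[!is.na(fitstats$flag) & fitstats$flag != "ok"])
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("done", "artifacts in %s", config$out_dir)

  invisible(list(fixture = fixture, opis = opis, norms = norms, irm = irm,
                 fit = fit, eap = eap, wle = wle, fitstats = fitstats,
                 wright = wright, banding = banding, rho = rho,
                 biserial = biserial, fairness = fairness, summary = summary))
}

#' Convert gate-forced zeros to structural missing
#'
#' Sensitivity mode for the calibration: every response at or after the
#' position where the gate fired becomes `NA` instead of an observed 0
#' (the gate item itself stays an observed 0, since it was actually
#' rated).
#'
#' @param irm an `item_response_matrix` with `gated_from` provenance.
#' @return A copy with post-gate responses set to `NA`.
#' @export
gated_to_missing <- function(irm) {
  stopifnot(inherits(irm, "item_response_matrix"))
  sc <- irm$scores
  for (n in seq_len(nrow(sc))) {
    g <- irm$gated_from[n]
    if (!is.na(g) && g < ncol(sc)) sc[n, (g + 1L):ncol(sc)] <- NA_integer_
  }
  irm$scores <- sc
  irm
}

#' Command-line entry point
#'
#' Subcommands: `run` (end-to-end pipeline) and `simulate` (write the
#' fixture cohort CSVs only).  Options: `--out <dir>`, `--seed <int>`,
#' `--duration <s>`, `--level-rule cumulative|count`, `--write-streams`.
#' Exits non-zero with a stage-tagged message on failure.
#'
#' @param args character vector of command-line arguments (defaults to
#'   the process's trailing arguments).
#' @return Exit status, invisibly (0 on success).
#' @export
opirasch_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: opirasch <run|simulate> [--out DIR] [--seed N] [--duration S]\n",
    "                [--level-rule cumulative|count] [--write-streams]\n")
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat(usage)
    return(invisible(0L))
  }
  cmd <- args[1]; args <- args[-1]
  status <- tryCatch({
    opt <- list(out = "opirasch_out", seed = 1L, duration = 60,
                level_rule = "cumulative", write_streams = FALSE)
    i <- 1L
    while (i <= length(args)) {
      a <- args[i]
      take <- function() { i <<- i + 1L; args[i] }
      switch(a,
             "--out" = { opt$out <- take() },
             "--seed" = { opt$seed <- as.integer(take()) },
             "--duration" = { opt$duration <- as.numeric(take()) },
             "--level-rule" = { opt$level_rule <- take() },
             "--write-streams" = { opt$write_streams <- TRUE },
             stop("unknown argument: ", a))
      i <- i + 1L
    }
    if (cmd == "run") {
      cfg <- pipeline_config(out_dir = opt$out, seed = opt$seed,
                             duration_s = opt$duration,
                             level_rule = opt$level_rule,
                             write_streams = opt$write_streams)
      run_pipeline(cfg)
      0L
    } else if (cmd == "simulate") {
      fx <- make_cohort_fixture(seed = opt$seed, duration_s = opt$duration)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      write_outcomes_csv(fx$video, file.path(opt$out, "outcomes.csv"))
      kdir <- file.path(opt$out, "kinematics")
      edir <- file.path(opt$out, "events")
      dir.create(kdir, showWarnings = FALSE)
      dir.create(edir, showWarnings = FALSE)
      for (id in fx$subjects$subject_id) {
        write_kinematics_csv(fx$streams[[id]], file.path(kdir, paste0(id, ".csv")))
        write_events_csv(fx$events[[id]], file.path(edir, paste0(id, ".csv")))
      }
      0L
    } else {
      cat(usage)
      1L
    }
  }, error = function(e) {
    message(conditionMessage(e))
    1L
  })
  invisible(status)
}
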