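#' Fit expert OPI norms
#'
#' Per-OPI sample mean and standard deviation (n - 1 denominator) over
#' the expert performances, with the two-sided credit interval
#' `[mean - 2*sd, mean + 2*sd]`.  A trainee receives credit for an OPI
#' item when their value falls inside this interval.
#'
#' @param expert_opis a data.frame of expert OPI values, one row per
#'   expert, containing the columns of [opi_metric_names()] (extra
#'   columns such as `subject_id` are ignored).
#' @param n_sd number of standard deviations defining the credit band.
#' @return An object of class `expert_norms`: a data.frame with one row
#'   per OPI and columns `opi`, `mean`, `sd`, `lower`, `upper`, plus an
#'   `n_experts` attribute.
#' @examples
#' e <- data.frame(speed_peaks = c(90, 100, 110))
#' fit_expert_norms(e)   # mean 100, sd 10, interval [80, 120]
#' @export
fit_expert_norms <- function(expert_opis, n_sd = 2) {
  expert_opis <- as.data.frame(expert_opis)
  metrics <- intersect(opi_metric_names(), names(expert_opis))
  if (!length(metrics)) stop("no OPI columns found in `expert_opis`")
  if (nrow(expert_opis) < 2L) stop("need at least 2 expert performances")
  out <- do.call(rbind, lapply(metrics, function(m) {
    v <- expert_opis[[m]]
    mu <- mean(v); s <- sd(v)
    data.frame(opi = m, mean = mu, sd = s,
               lower = mu - n_sd * s, upper = mu + n_sd * s)
  }))
  rownames(out) <- NULL
  attr(out, "n_experts") <- nrow(expert_opis)
  attr(out, "n_sd") <- n_sd
  class(out) <- c("expert_norms", "data.frame")
  out
}

#' Score one OPI value against the expert norm
#'
#' Returns 1 when the value lies within the norm interval (boundary
#' inclusive), else 0.  `sided = "lower"` / `"upper"` give one-sided
#' variants (credit when value <= upper, resp. >= lower) for count-like
#' OPIs where only one tail is poor performance; the symmetric two-sided
#' rule is the default.
#'
#' @param value numeric OPI value(s).
#' @param norm one row of an [fit_expert_norms()] result (or any list
#'   with `lower` and `upper`).
#' @param sided `"two"` (default), `"lower"` or `"upper"`.
#' @return Integer 0/1, vectorized over `value`.
#' @export
score_opi_item <- function(value, norm, sided = c("two", "lower", "upper")) {
  sided <- match.arg(sided)
  ok <- switch(sided,
               two = value >= norm$lower & value <= norm$upper,
               lower = value <= norm$upper,
               upper = value >= norm$lower)
  as.integer(ok)
}

#' Rubric configuration for the twelve-item gated assessment
#'
#' Twelve dichotomous items in four consecutive levels of three items:
#' completion (1-3), safety (4-6), economy of motion (7-9) and optimized
#' performance (10-12).  Items 1-6 are video-based and gate: the first 0
#' among them zeroes every later item.  Items 7-9 map to the economy
#' OPI categories (energy usage, clutching, instrument movement) and
#' items 10-12 to the optimized-performance categories (wrist
#' articulation, smoothness, instrument active time).
#'
#' @param opi_items named character vector mapping item names
#'   (`item7`..`item12`) to OPI metric columns; override to re-map.
#' @return An object of class `rubric_config`.
#' @export
rubric_config <- function(opi_items = c(
    item7 = "energy_proportion",      # energy usage
    item8 = "clutch_count",           # clutching / console events
    item9 = "linear_path_length_mm",  # instrument movement
    item10 = "angular_path_length_rad", # wrist articulation
    item11 = "speed_peaks",             # smoothness
    item12 = "idle_time_s")) {          # instrument active time
  if (!identical(sort(names(opi_items)), sort(paste0("item", 7:12)))) {
    stop("`opi_items` must name exactly item7..item12")
  }
  if (anyDuplicated(opi_items) || !all(opi_items %in% opi_metric_names())) {
    stop("each OPI metric must map to exactly one item")
  }
  structure(list(
    items = paste0("item", 1:12),
    gate_items = paste0("item", 1:6),
    opi_items = opi_items,
    levels = c("completion", "safety", "economy", "optimized"),
    level_of_item = rep(c("completion", "safety", "economy", "optimized"),
                        each = 3L)
  ), class = "rubric_config")
}

#' Apply the safety gate to a raw item vector
#'
#' Video items 1-6 are a gateway: at the first 0 among them, scoring
#' stops and every remaining item (including the OPI items) is forced to
#' 0.  A 0 on items 7-12 does not gate.
#'
#' @param raw integer vector of 12 raw 0/1 scores, or a matrix with 12
#'   columns (one row per person).
#' @param rubric a [rubric_config].
#' @return For a vector: list with `final` (length-12 integer) and
#'   `gated_from` (item index at which the gate fired, or `NA`).  For a
#'   matrix: list with `final` (matrix) and `gated_from` (vector).
#' @export
apply_gate <- function(raw, rubric = rubric_config()) {
  if (is.matrix(raw) || is.data.frame(raw)) {
    raw <- as.matrix(raw)
    res <- apply(raw, 1L, function(r) apply_gate_one(as.integer(r)),
                 simplify = FALSE)
    final <- do.call(rbind, lapply(res, `[[`, "final"))
    dimnames(final) <- dimnames(raw)
    return(list(final = final,
                gated_from = unname(vapply(res, `[[`, numeric(1),
                                           "gated_from"))))
  }
  apply_gate_one(as.integer(raw))
}

apply_gate_one <- function(raw) {
  if (length(raw) != 12L) stop("raw item vector must have length 12")
  if (!all(raw %in% c(0L, 1L))) stop("raw scores must be 0 or 1")
  fail <- which(raw[1:6] == 0L)
  if (length(fail)) {
    g <- fail[1]
    final <- raw
    final[g:12] <- 0L
    list(final = final, gated_from = g)
  } else {
    list(final = raw, gated_from = NA_real_)
  }
}

#' Assign the competency level from a gated item vector
#'
#' Default cumulative rule: the assigned level is the highest level all
#' of whose items, and all lower levels' items, are passed; failing any
#' completion item (1-3) gives `below_completion`.  The alternative
#' `"count"` rule assigns by total score (>= 3, 6, 9, 12 passed items
#' for completion, safety, economy, optimized); the field does not fix a
#' single convention, so the rule is explicit.
#'
#' @param final gated integer vector of 12 scores, or a matrix.
#' @param rubric a [rubric_config].
#' @param rule `"cumulative"` (default) or `"count"`.
#' @return Factor with levels `below_completion`, `completion`,
#'   `safety`, `economy`, `optimized`.
#' @export
assign_level <- function(final, rubric = rubric_config(),
                         rule = c("cumulative", "count")) {
  rule <- match.arg(rule)
  lv <- c("below_completion", rubric$levels)
  if (is.matrix(final) || is.data.frame(final)) {
    final <- as.matrix(final)
    out <- apply(final, 1L, function(r) assign_level_one(as.integer(r), rule))
    return(factor(out, levels = lv))
  }
  factor(assign_level_one(as.integer(final), rule), levels = lv)
}

assign_level_one <- function(final, rule) {
  if (length(final) != 12L) stop("item vector must have length 12")
  if (rule == "count") {
    s <- sum(final)
    return(c("below_completion", "completion", "safety", "economy",
             "optimized")[1 + findInterval(s, c(3, 6, 9, 12))])
  }
  triples <- vapply(0:3, function(l) all(final[(3 * l + 1):(3 * l + 3)] == 1L),
                    logical(1))
  full <- which(!triples)
  if (!length(full)) return("optimized")
  if (full[1] == 1L) return("below_completion")
  c("completion", "safety", "economy")[full[1] - 1L]
}

#' Score a cohort: OPIs + video outcomes -> gated response matrix
#'
#' For each subject, items 1-6 come from the video outcomes, items 7-12
#' from [score_opi_item()] applied to the mapped OPI metric against the
#' expert norms; the gate is then applied and the competency level
#' assigned.
#'
#' @param opis data.frame with `subject_id` and the six OPI columns.
#' @param video data.frame with `subject_id` and `item1`..`item6`
#'   (0/1); optional columns `failure_mode` and `group` are carried
#'   through.
#' @param norms an [fit_expert_norms()] result.
#' @param rubric a [rubric_config].
#' @param sided threshold sidedness, passed to [score_opi_item()].
#' @param level_rule passed to [assign_level()].
#' @return An object of class `item_response_matrix`: a list with
#'   `scores` (persons x 12 integer matrix), `subject_ids`,
#'   `gated_from`, `level`, and `group` (or `NULL`).
#' @export
score_cohort <- function(opis, video, norms, rubric = rubric_config(),
                         sided = "two", level_rule = "cumulative") {
  opis <- as.data.frame(opis)
  video <- as.data.frame(video)
  if (!"subject_id" %in% names(opis) || !"subject_id" %in% names(video)) {
    stop("both `opis` and `video` need a `subject_id` column")
  }
  if (!setequal(opis$subject_id, video$subject_id) ||
      anyDuplicated(opis$subject_id) || anyDuplicated(video$subject_id)) {
    stop("subject ids do not align between OPI table and video outcomes")
  }
  opis <- opis[match(video$subject_id, opis$subject_id), , drop = FALSE]

  raw <- matrix(0L, nrow(video), 12L,
                dimnames = list(video$subject_id, paste0("item", 1:12)))
  for (i in 1:6) raw[, i] <- as.integer(video[[paste0("item", i)]])
  for (it in names(rubric$opi_items)) {
    metric <- rubric$opi_items[[it]]
    norm <- norms[norms$opi == metric, ]
    if (nrow(norm) != 1L) stop("no fitted norm for OPI `", metric, "`")
    raw[, it] <- score_opi_item(opis[[metric]], norm, sided = sided)
  }
  g <- apply_gate(raw, rubric)
  structure(list(scores = g$final,
                 subject_ids = video$subject_id,
                 gated_from = g$gated_from,
                 level = assign_level(g$final, rubric, rule = level_rule),
                 group = if ("group" %in% names(video)) video$group else NULL),
            class = "item_response_matrix")
}

#' @export
print.item_response_matrix <- function(x, ...) {
  cat(sprintf("<item_response_matrix> %d persons x %d items; %d gated\n",
              nrow(x$scores), ncol(x$scores), sum(!is.na(x$gated_from))))
  print(table(level = x$level))
  invisible(x)
}

#' Coerce a bare 0/1 matrix to an item response matrix
#'
#' Used to feed simulated matrices from [simulate_response_matrix()]
#' into the calibration functions.
#'
#' @param scores persons x items 0/1 matrix.
#' @param group optional subgroup label per person.
#' @return An `item_response_matrix`.
#' @export
as_item_response_matrix <- function(scores, group = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "integer"
  if (!all(scores %in% c(0L, 1L, NA))) stop("scores must be 0/1 (or NA)")
  ids <- rownames(scores)
  if (is.null(ids)) ids <- paste0("person", seq_len(nrow(scores)))
  structure(list(scores = scores, subject_ids = ids,
                 gated_from = rep(NA_real_, nrow(scores)),
                 level = NULL, group = group),
            class = "item_response_matrix")
}
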