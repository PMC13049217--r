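# CSV schemas shared by the pipeline stages.  All files are UTF-8 with
# '.' decimal separator; headers must match the schema exactly.
# Validation errors name the offending row and column.

KINEMATICS_COLS <- c("t", "x_mm", "y_mm", "z_mm", "qw", "qx", "qy", "qz")
EVENTS_COLS <- c("t", "kind")
OUTCOMES_COLS <- c("subject_id", paste0("item", 1:6), "failure_mode", "group")
SCORES_COLS <- c("subject_id", paste0("item", 1:12), "gated_from", "level",
                 "group")

check_schema <- function(df, cols, path) {
  if (!identical(names(df)[seq_along(cols)], cols) || ncol(df) != length(cols)) {
    stop("schema error in ", path, ": expected columns [",
         paste(cols, collapse = ", "), "], got [",
         paste(names(df), collapse = ", "), "]")
  }
  invisible(TRUE)
}

#' Read and write the pipeline CSV schemas
#'
#' Four schemas: kinematics (`t, x_mm, y_mm, z_mm, qw, qx, qy, qz`),
#' events (`t, kind`), video outcomes (`subject_id, item1..item6,
#' failure_mode, group`) and the score matrix (`subject_id,
#' item1..item12, gated_from, level, group`).  Writing then reading a
#' stream reproduces it within 1e-9 and preserves row order.
#'
#' @param path file path.
#' @param stream,events,outcomes,irm the object to write.
#' @return Readers return the validated object; writers return the path
#'   invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_kinematics_csv <- function(stream, path) {
  stopifnot(inherits(stream, "kinematic_stream"))
  df <- data.table::data.table(
    t = stream$t,
    x_mm = stream$pos[, 1], y_mm = stream$pos[, 2], z_mm = stream$pos[, 3],
    qw = stream$quat[, 1], qx = stream$quat[, 2],
    qy = stream$quat[, 3], qz = stream$quat[, 4])
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_kinematics_csv <- function(path) {
  df <- data.table::fread(path, colClasses = "numeric", data.table = FALSE)
  check_schema(df, KINEMATICS_COLS, path)
  bad <- which(diff(df$t) <= 0)
  if (length(bad)) {
    stop("schema error in ", path, ": non-monotone time at row ", bad[1] + 1L,
         " column t")
  }
  q <- as.matrix(df[, c("qw", "qx", "qy", "qz")])
  q <- q / sqrt(rowSums(q^2)) # re-normalize away text round-off
  kinematic_stream(df$t, as.matrix(df[, c("x_mm", "y_mm", "z_mm")]), q)
}

#' @rdname pipeline_io
#' @export
write_events_csv <- function(events, path) {
  stopifnot(inherits(events, "event_stream"))
  data.table::fwrite(data.table::as.data.table(unclass(events)[EVENTS_COLS]),
                     path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_events_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE,
                          colClasses = list(numeric = "t", character = "kind"))
  if (nrow(df) == 0L) return(event_stream())
  check_schema(df, EVENTS_COLS, path)
  tryCatch(event_stream(df$t, df$kind),
           error = function(e) stop("schema error in ", path, ": ",
                                    conditionMessage(e)))
}

#' @rdname pipeline_io
#' @export
write_outcomes_csv <- function(outcomes, path) {
  df <- as.data.frame(outcomes)[, OUTCOMES_COLS]
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_outcomes_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  check_schema(df, OUTCOMES_COLS, path)
  for (i in 1:6) {
    col <- paste0("item", i)
    bad <- which(!df[[col]] %in% c(0L, 1L))
    if (length(bad)) {
      stop("schema error in ", path, ": non-binary score at row ", bad[1],
           " column ", col)
    }
  }
  df
}

#' @rdname pipeline_io
#' @export
write_scores_csv <- function(irm, path) {
  stopifnot(inherits(irm, "item_response_matrix"))
  df <- data.frame(subject_id = irm$subject_ids, irm$scores,
                   gated_from = irm$gated_from,
                   level = as.character(irm$level),
                   group = if (is.null(irm$group)) NA_character_ else irm$group,
                   row.names = NULL)
  data.table::fwrite(df, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_scores_csv <- function(path) {
  df <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  check_schema(df, SCORES_COLS, path)
  items <- paste0("item", 1:12)
  for (col in items) {
    bad <- which(!df[[col]] %in% c(0L, 1L))
    if (length(bad)) {
      stop("schema error in ", path, ": non-binary score at row ", bad[1],
           " column ", col)
    }
  }
  scores <- as.matrix(df[, items])
  storage.mode(scores) <- "integer"
  rownames(scores) <- df$subject_id
  structure(list(scores = scores, subject_ids = df$subject_id,
                 gated_from = df$gated_from,
                 level = factor(df$level,
                                levels = c("below_completion", "completion",
                                           "safety", "economy", "optimized")),
                 group = df$group),
            class = "item_response_matrix")
}
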