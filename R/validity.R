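#' Inter-rater percent agreement and Cohen's kappa
#'
#' For paired dichotomous ratings: agreement is
#' `100 * matches / total`; kappa is `(p_o - p_e) / (1 - p_e)` with the
#' chance agreement `p_e` from the product of marginal proportions.
#' When a rater is constant, `p_e` reflects that margin and kappa is 0
#' unless `p_e = 1` (both raters constant and equal), which is
#' undefined.
#'
#' @param r1,r2 equal-length vectors of 0/1 ratings.
#' @return `percent_agreement`: percentage in \[0, 100\];
#'   `cohens_kappa`: coefficient in \[-1, 1\].
#' @export
percent_agreement <- function(r1, r2) {
  check_ratings(r1, r2)
  100 * mean(r1 == r2)
}

#' @rdname percent_agreement
#' @export
cohens_kappa <- function(r1, r2) {
  check_ratings(r1, r2)
  po <- mean(r1 == r2)
  p1 <- mean(r1 == 1); p2 <- mean(r2 == 1)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    if (po == 1 && (p1 %in% c(0, 1))) return(0) # constant rater convention
    stop("kappa undefined: chance agreement is 1")
  }
  (po - pe) / (1 - pe)
}

check_ratings <- function(r1, r2) {
  if (!length(r1)) stop("ratings must be non-empty")
  if (length(r1) != length(r2)) stop("ratings must have equal length")
  if (!all(c(r1, r2) %in% c(0, 1))) stop("ratings must be 0/1")
  invisible(TRUE)
}

#' Item-ability point-biserial correlations and level ability summary
#'
#' Per item: the point-biserial correlation between the 0/1 item column
#' and person ability (the classic biserial correction
#' `r_pb * sqrt(p*q) / dnorm(qnorm(p))` is available by flag).  Per
#' level (when the matrix carries level assignments): the mean ability
#' of persons assigned to each level and whether mean ability is
#' strictly increasing with level.
#'
#' @param matrix an `item_response_matrix` or 0/1 matrix.
#' @param abilities person abilities aligned with the rows.
#' @param levels optional per-person level factor (defaults to
#'   `matrix$level` when present).
#' @param biserial_correction apply the classic biserial correction.
#' @return List with `item` (item, prop_correct, correlation) and
#'   `level` (level, n, mean_ability, plus attribute
#'   `ordered_by_ability`), the latter `NULL` when no levels are known.
#' @export
item_ability_biserial <- function(matrix, abilities, levels = NULL,
                                  biserial_correction = FALSE) {
  X <- response_matrix_of(matrix)
  if (length(abilities) != nrow(X)) stop("abilities must align with persons")
  if (is.null(levels) && inherits(matrix, "item_response_matrix")) {
    levels <- matrix$level
  }
  item_names <- colnames(X)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(ncol(X)))
  cors <- vapply(seq_len(ncol(X)), function(i) {
    x <- X[, i]
    if (var(x, na.rm = TRUE) == 0 || is.na(var(x, na.rm = TRUE))) {
      warning("item ", item_names[i], " has zero variance; correlation NA")
      return(NA_real_)
    }
    r <- cor(x, abilities, use = "complete.obs")
    if (biserial_correction) {
      p <- mean(x, na.rm = TRUE)
      r <- r * sqrt(p * (1 - p)) / dnorm(qnorm(p))
    }
    r
  }, numeric(1))
  item <- data.frame(item = item_names,
                     prop_correct = colMeans(X, na.rm = TRUE),
                     correlation = cors, row.names = NULL)
  level <- NULL
  if (!is.null(levels)) {
    lv <- levels[!is.na(levels)]
    ab <- abilities[!is.na(levels)]
    agg <- tapply(ab, droplevels(as.factor(lv)), mean)
    level <- data.frame(level = names(agg), n = as.vector(table(droplevels(as.factor(lv)))),
                        mean_ability = as.vector(agg), row.names = NULL)
    attr(level, "ordered_by_ability") <- !is.unsorted(level$mean_ability,
                                                      strictly = TRUE)
  }
  list(item = item, level = level)
}

#' Construct-alignment Spearman correlation
#'
#' Spearman rank correlation (average ranks for ties) between each
#' item's construct-level rank and its fitted difficulty.  With 12
#' items in 4 tied triples against untied, perfectly level-ordered
#' difficulties the coefficient is 0.972, not 1: tied level ranks cap
#' the attainable value.
#'
#' @param item_levels level rank per item: a numeric rank, an ordered
#'   factor (its level order is used), or a character vector (ranked by
#'   first appearance, lowest level first).
#' @param delta item difficulties (logits); non-finite entries dropped
#'   pairwise.
#' @return Spearman's rho, or `NA` (with a warning) when difficulties
#'   are constant.
#' @export
construct_alignment_rho <- function(item_levels, delta) {
  lv <- if (is.factor(item_levels)) {
    as.numeric(item_levels)
  } else if (is.character(item_levels)) {
    match(item_levels, unique(item_levels))
  } else {
    as.numeric(item_levels)
  }
  if (length(lv) != length(delta)) stop("`item_levels` must align with `delta`")
  keep <- is.finite(delta)
  lv <- lv[keep]; delta <- delta[keep]
  if (length(lv) < 3L) stop("need at least 3 items with finite difficulty")
  if (var(delta) == 0) {
    warning("constant difficulties: rho undefined")
    return(NA_real_)
  }
  cor(lv, delta, method = "spearman")
}

#' Build a Wright map and check level banding
#'
#' Pairs person ability locations with item difficulty locations on the
#' shared logit scale and summarizes item difficulty per construct
#' level.  `banding_check` reports whether level mean difficulties are
#' strictly increasing and whether the difficulty ranges of consecutive
#' levels overlap (banding = ordered means with non-overlapping ranges).
#'
#' @param fit a [fit_rasch_mml()] result.
#' @param rubric a [rubric_config()] supplying item-level labels, a
#'   factor of level labels per item (its level order defines the
#'   construct order), or a character vector (construct order taken as
#'   first appearance).
#' @param person_locations person abilities to display (e.g. WLE).
#' @return `build_wright_map`: object of class `wright_map` with
#'   `person_locations`, `items` (item, level, location) and
#'   `level_summaries`.  `banding_check`: list with `means_increasing`,
#'   `overlaps` (data.frame per consecutive level pair) and `banded`.
#' @export
build_wright_map <- function(fit, rubric = rubric_config(),
                             person_locations = numeric()) {
  labels <- if (inherits(rubric, "rubric_config")) rubric$level_of_item else rubric
  if (length(labels) != length(fit$delta)) {
    stop("rubric level labels must align with fitted items")
  }
  level_order <- if (is.factor(labels)) levels(droplevels(labels))
                 else unique(as.character(labels))
  labels <- as.character(labels)
  items <- data.frame(item = fit$item_names, level = labels,
                      location = as.vector(fit$delta), row.names = NULL)
  fin <- items[is.finite(items$location), , drop = FALSE]
  lsum <- do.call(rbind, lapply(level_order, function(l) {
    d <- fin$location[fin$level == l]
    data.frame(level = l, n_items = length(d),
               mean = if (length(d)) mean(d) else NA_real_,
               min = if (length(d)) min(d) else NA_real_,
               max = if (length(d)) max(d) else NA_real_)
  }))
  structure(list(person_locations = person_locations, items = items,
                 level_summaries = lsum),
            class = "wright_map")
}

#' @rdname build_wright_map
#' @param map a `wright_map`.
#' @export
banding_check <- function(map) {
  ls <- map$level_summaries
  ls <- ls[!is.na(ls$mean), , drop = FALSE]
  means_increasing <- !is.unsorted(ls$mean, strictly = TRUE)
  overlaps <- NULL
  if (nrow(ls) >= 2L) {
    overlaps <- do.call(rbind, lapply(seq_len(nrow(ls) - 1L), function(j) {
      data.frame(lower_level = ls$level[j], upper_level = ls$level[j + 1L],
                 overlap = ls$max[j] >= ls$min[j + 1L])
    }))
  }
  list(means_increasing = means_increasing, overlaps = overlaps,
       banded = means_increasing && (is.null(overlaps) || !any(overlaps$overlap)))
}

#' Subgroup fairness via per-group difficulty refits
#'
#' Refits item difficulties separately in two subgroups (each anchored
#' by the latent-mean-zero convention), mean-centers the two difficulty
#' vectors over the common item subset to remove scale-origin
#' artifacts, and reports their Pearson correlation together with
#' per-item 95% Wald confidence-interval overlap.  Items without
#' response variance in either group are dropped from the subset with a
#' logged reason (a constant column identifies no finite difficulty).
#'
#' @param matrix an `item_response_matrix` with a `group` field, or a
#'   0/1 matrix (then `groups` is required).
#' @param groups per-person subgroup labels (exactly 2 distinct
#'   non-missing values used).
#' @param item_subset item names (or indices) to analyze; defaults to
#'   all items.
#' @param conf_level confidence level for the Wald intervals.
#' @param ... passed to [fit_rasch_mml()].
#' @return Object of class `fairness_result`: list with `items`
#'   (data.frame: item, per-group centered difficulty, SE, CI bounds,
#'   `ci_overlap`), `pearson_r`, `groups`, `dropped` (named reasons).
#' @export
fairness_dif <- function(matrix, groups = NULL, item_subset = NULL,
                         conf_level = 0.95, ...) {
  X <- response_matrix_of(matrix)
  if (is.null(groups) && inherits(matrix, "item_response_matrix")) {
    groups <- matrix$group
  }
  if (is.null(groups)) stop("`groups` is required")
  if (length(groups) != nrow(X)) stop("`groups` must align with persons")
  keep <- !is.na(groups)
  X <- X[keep, , drop = FALSE]; groups <- groups[keep]
  gl <- sort(unique(as.character(groups)))
  if (length(gl) != 2L) stop("exactly 2 subgroups are required, got ", length(gl))
  if (min(table(groups)) < 2L) stop("both groups need at least 2 persons")
  item_names <- colnames(X)
  if (is.null(item_names)) item_names <- colnames(X) <- paste0("item", seq_len(ncol(X)))
  subset <- if (is.null(item_subset)) item_names
            else if (is.numeric(item_subset)) item_names[item_subset]
            else item_subset

  dropped <- character(0)
  for (g in gl) {
    pg <- colMeans(X[groups == g, subset, drop = FALSE], na.rm = TRUE)
    bad <- subset[pg <= 0 | pg >= 1 | is.nan(pg)]
    for (b in bad) {
      dropped[b] <- paste0("no response variance in group ", g)
    }
  }
  subset <- setdiff(subset, names(dropped))
  if (length(subset) < 2L) {
    stop("degenerate group: fewer than 2 items with variance in both groups")
  }

  fits <- lapply(gl, function(g) {
    fit_rasch_mml(X[groups == g, subset, drop = FALSE], ...)
  })
  z <- qnorm(1 - (1 - conf_level) / 2)
  d <- lapply(fits, function(f) f$delta[subset] - mean(f$delta[subset]))
  se <- lapply(fits, function(f) f$delta_se[subset])
  items <- data.frame(
    item = subset,
    delta_a = d[[1]], se_a = se[[1]],
    lo_a = d[[1]] - z * se[[1]], hi_a = d[[1]] + z * se[[1]],
    delta_b = d[[2]], se_b = se[[2]],
    lo_b = d[[2]] - z * se[[2]], hi_b = d[[2]] + z * se[[2]],
    row.names = NULL)
  items$ci_overlap <- items$lo_a <= items$hi_b & items$lo_b <= items$hi_a
  structure(list(items = items,
                 pearson_r = cor(d[[1]], d[[2]]),
                 groups = setNames(gl, c("a", "b")),
                 dropped = dropped),
            class = "fairness_result")
}

#' @export
print.fairness_result <- function(x, ...) {
  cat(sprintf("<fairness_result> groups %s vs %s over %d items: r = %.3f; %d CI non-overlaps\n",
              x$groups[["a"]], x$groups[["b"]], nrow(x$items), x$pearson_r,
              sum(!x$items$ci_overlap)))
  if (length(x$dropped)) {
    cat("dropped:", paste(names(x$dropped), collapse = ", "), "\n")
  }
  invisible(x)
}
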