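test_that("percent agreement and kappa match hand formulas", {
  r <- rbinom(40, 1, 0.5)
  expect_equal(percent_agreement(r, r), 100)
  expect_equal(cohens_kappa(c(r, 0, 1), c(r, 0, 1)), 1)

  # 2x2 table: both-1 = 50, both-0 = 41, disagreements 5 and 4
  r1 <- c(rep(1, 50), rep(0, 41), rep(1, 5), rep(0, 4))
  r2 <- c(rep(1, 50), rep(0, 41), rep(0, 5), rep(1, 4))
  expect_equal(percent_agreement(r1, r2), 91)
  p1 <- 55 / 100; p2 <- 54 / 100
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  expect_equal(cohens_kappa(r1, r2), (0.91 - pe) / (1 - pe))

  # one rater constant: no chance-corrected information
  expect_equal(cohens_kappa(rep(1, 20), rbinom(20, 1, 0.5)), 0)
  expect_error(percent_agreement(numeric(), numeric()), "non-empty")
  expect_error(percent_agreement(c(0, 1), c(0, 1, 1)), "equal length")
  expect_error(cohens_kappa(c(0, 2), c(0, 1)), "0/1")
})

test_that("kappa never exceeds the agreement proportion rescaled", {
  set.seed(30)
  for (i in 1:25) {
    r1 <- rbinom(50, 1, runif(1, 0.2, 0.8))
    r2 <- ifelse(rbinom(50, 1, 0.8) == 1, r1, 1 - r1)
    po <- percent_agreement(r1, r2) / 100
    k <- tryCatch(cohens_kappa(r1, r2), error = function(e) NA)
    if (!is.na(k)) expect_lte(k, po + 1e-12)
  }
})

test_that("item-ability biserial separates informative from null items", {
  set.seed(31)
  n <- 2000
  theta <- rnorm(n)
  top_half <- as.integer(theta > median(theta))
  coin <- rbinom(n, 1, 0.5)
  rasch_item <- rbinom(n, 1, plogis(theta))
  X <- cbind(split = top_half, coin = coin, rasch = rasch_item)
  res <- item_ability_biserial(X, theta)
  expect_equal(res$item$item[which.max(res$item$correlation)], "split")
  expect_gt(res$item$correlation[res$item$item == "split"], 0.7)
  expect_lt(abs(res$item$correlation[res$item$item == "coin"]), 0.05)

  expect_warning(item_ability_biserial(cbind(z = rep(1L, 10)), rnorm(10)),
                 "zero variance")
})

test_that("mean ability increases across levels on a level-ordered cohort", {
  set.seed(32)
  theta <- sort(rnorm(120, sd = 2))
  lev <- rep(c("below_completion", "completion", "safety", "economy",
               "optimized"), each = 24)
  X <- cbind(i1 = rbinom(120, 1, plogis(theta)),
             i2 = rbinom(120, 1, plogis(theta - 0.5)))
  res <- item_ability_biserial(X, theta,
                               levels = factor(lev, levels = unique(lev)))
  expect_true(attr(res$level, "ordered_by_ability"))
})

test_that("construct alignment rho: tied-triple closed form and antisymmetry", {
  levels4 <- rep(1:4, each = 3)
  delta <- seq(-3, 3, length.out = 12)
  rho <- construct_alignment_rho(levels4, delta)
  # exact tie-corrected value for 4 tied triples vs untied difficulties
  lr <- rank(levels4); dr <- rank(delta)
  exact <- sum((lr - mean(lr)) * (dr - mean(dr))) /
    sqrt(sum((lr - mean(lr))^2) * sum((dr - mean(dr))^2))
  expect_equal(rho, exact, tolerance = 1e-12)
  expect_equal(rho, 0.972, tolerance = 5e-4)
  expect_equal(construct_alignment_rho(levels4, rev(delta)), -rho,
               tolerance = 1e-12)

  # character labels rank by first appearance, not alphabetically
  labs <- rep(c("completion", "safety", "economy", "optimized"), each = 3)
  expect_equal(construct_alignment_rho(labs, delta), rho, tolerance = 1e-12)

  expect_warning(r0 <- construct_alignment_rho(levels4, rep(1, 12)),
                 "constant")
  expect_true(is.na(r0))
})

test_that("random difficulty permutations center rho at zero", {
  set.seed(33)
  levels4 <- rep(1:4, each = 3)
  delta <- seq(-3, 3, length.out = 12)
  rhos <- vapply(1:10000, function(i) {
    suppressWarnings(construct_alignment_rho(levels4, sample(delta)))
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.02)
})

test_that("wright map banding detects ordered bands and overlaps", {
  fake_fit <- function(delta) {
    structure(list(delta = setNames(delta, paste0("item", 1:12)),
                   item_names = paste0("item", 1:12)),
              class = "rasch_fit")
  }
  banded <- c(-3, -2.8, -2.6, -1, -0.8, -0.6, 1, 1.2, 1.4, 3, 3.2, 3.4)
  wm <- build_wright_map(fake_fit(banded))
  bc <- banding_check(wm)
  expect_true(bc$means_increasing)
  expect_true(bc$banded)
  expect_false(any(bc$overlaps$overlap))

  # order-correct for any permutation of item input order
  set.seed(34)
  perm <- sample(12)
  fit_p <- fake_fit(banded)
  fit_p$delta <- fit_p$delta[perm]
  fit_p$item_names <- fit_p$item_names[perm]
  rub <- rubric_config()
  wm_p <- build_wright_map(fit_p, factor(rub$level_of_item[perm],
                                         levels = rub$levels))
  expect_true(banding_check(wm_p)$banded)

  shuffled <- fake_fit(banded[c(10, 2, 3, 4, 5, 6, 7, 8, 9, 1, 11, 12)])
  expect_false(banding_check(build_wright_map(shuffled))$banded)
})

test_that("fairness on literally identical groups returns r = 1", {
  X <- simulate_response_matrix(rnorm(80), seq(-1, 1, length.out = 6),
                                seed = 40)
  XX <- rbind(X, X)
  groups <- rep(c("a", "b"), each = 80)
  res <- fairness_dif(XX, groups)
  expect_equal(res$pearson_r, 1)
  expect_true(all(res$items$ci_overlap))
  # permuting the labels of equal groups changes nothing
  res2 <- fairness_dif(XX[c(81:160, 1:80), ], groups)
  expect_equal(res2$items$delta_a, res$items$delta_a)
})

test_that("fairness drops zero-variance items with a reason", {
  X <- simulate_response_matrix(rnorm(60), c(-1, 0, 1), seed = 41)
  colnames(X) <- c("i1", "i2", "i3")
  X[1:30, "i1"] <- 1L   # group a constant on i1
  res <- fairness_dif(X, rep(c("a", "b"), each = 30))
  expect_false("i1" %in% res$items$item)
  expect_match(res$dropped[["i1"]], "no response variance in group a")
  expect_error(fairness_dif(X, rep("a", 60)), "2 subgroups")
})
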