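test_that("marginal likelihood matches brute-force integration on a toy", {
  set.seed(3)
  X <- simulate_response_matrix(rnorm(5), c(-1, 0, 1), seed = 14)
  for (sd in c(0.8, 1, 1.7)) {
    d <- c(-0.6, 0.2, 1.1)
    expect_equal(rasch_marginal_loglik(X, d, sd),
                 brute_marginal_loglik(X, d, sd), tolerance = 1e-6)
  }
})

test_that("column-swapped identical items get equal difficulties", {
  set.seed(4)
  x1 <- rbinom(80, 1, plogis(rnorm(80)))
  X <- cbind(a = x1, b = x1, c = rbinom(80, 1, 0.5))
  fit <- fit_rasch_mml(X)
  expect_equal(unname(fit$delta["a"]), unname(fit$delta["b"]),
               tolerance = 1e-4)
})

test_that("EM increases the marginal likelihood and beats the truth", {
  delta <- c(-1, 0, 1)
  X <- simulate_response_matrix(rnorm(150), delta, seed = 15)
  fit <- fit_rasch_mml(X)
  expect_true(fit$converged)
  expect_true(all(diff(fit$ll_trace) > -1e-8))
  ll_true <- rasch_marginal_loglik(X, delta, 1, n_quadrature = fit$n_quadrature)
  expect_gte(fit$log_likelihood, ll_true - 1e-9)
})

test_that("degenerate items are flagged and degenerate data error", {
  X <- cbind(a = c(1, 1, 1, 1), b = c(0, 0, 0, 0), c = c(1, 0, 1, 0),
             d = c(0, 1, 1, 0))
  # 4 persons cannot pin down the latent sd; convergence is not the point
  fit <- suppressWarnings(fit_rasch_mml(X))
  expect_identical(unname(fit$delta[c("a", "b")]), c(-Inf, Inf))
  expect_identical(unname(fit$included), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(fit_rasch_mml(cbind(c(1, 1), c(0, 0))), "degenerate")
})

test_that("EAP scores shrink, are pattern-determined, and finite", {
  X <- simulate_response_matrix(rnorm(60), seq(-1.5, 1.5, length.out = 8),
                                seed = 16)
  X[1, ] <- 0L; X[2, ] <- 0L; X[3, ] <- 1L
  fit <- fit_rasch_mml(X)
  eap <- eap_scores(fit, X)
  expect_true(all(is.finite(eap$theta_eap)))
  expect_lt(eap$theta_eap[1], fit$latent_mean)   # zero score below the mean
  expect_equal(eap$theta_eap[1], eap$theta_eap[2])  # identical patterns
  expect_gt(eap$theta_eap[3], max(eap$theta_eap[c(1, 2)]))
})

test_that("WLE matches the grid oracle and respects sufficiency", {
  delta <- seq(-2, 2, length.out = 12)
  X <- simulate_response_matrix(rnorm(40), delta, seed = 17)
  fit <- fit_rasch_mml(X, latent_sd = 1)
  wle <- wle_scores(fit, X)
  d <- fit$delta[fit$included]
  for (n in c(1, 7, 23)) {
    expect_equal(wle$theta_wle[n], brute_wle(X[n, fit$included], d),
                 tolerance = 1e-4)
  }
  # sufficiency: equal raw scores => equal estimates (exhaustive)
  raw <- rowSums(X)
  for (r in unique(raw)) {
    expect_lt(diff(range(wle$theta_wle[raw == r])), 1e-10)
  }
  # 6 of 12 on an all-zero-difficulty test sits at zero
  X0 <- rbind(rep(c(0, 1), 6), rep(c(1, 0), 6), c(rep(1, 3), rep(0, 9)),
              rep(1, 12))
  f0 <- suppressWarnings(fit_rasch_mml(rbind(X0, 1 - X0), latent_sd = 1,
                                       max_iter = 1))
  f0$delta[] <- 0
  w0 <- wle_scores(f0, X0)
  expect_equal(w0$theta_wle[1], 0, tolerance = 1e-8)
  expect_equal(w0$theta_wle[2], 0, tolerance = 1e-8)
  # perfect score: finite and above every mixed score
  expect_true(is.finite(w0$theta_wle[4]))
  expect_gt(w0$theta_wle[4], max(w0$theta_wle[1:3]))
})

test_that("reliabilities behave at the edges and rise with latent spread", {
  identical_eap <- data.frame(theta_eap = rep(0.4, 10), psd_eap = rep(0.5, 10))
  expect_equal(eap_reliability(identical_eap), 0)
  expect_error(eap_reliability(identical_eap[1, , drop = FALSE]), "2 persons")

  delta <- seq(-2, 2, length.out = 12)
  rel <- vapply(c(0.5, 2), function(s) {
    Xs <- simulate_response_matrix(rnorm(800, sd = s), delta, seed = 18)
    f <- fit_rasch_mml(Xs)
    eap_reliability(eap_scores(f, Xs))
  }, numeric(1))
  expect_gt(rel[2], rel[1])
})

test_that("infit/outfit flag misfitting items and flag_fit applies bounds", {
  delta <- seq(-1.5, 1.5, length.out = 9)
  X <- simulate_response_matrix(rnorm(600), delta, seed = 19)
  set.seed(20)
  noise <- rbinom(600, 1, 0.5)
  Xn <- cbind(X, noise = noise)
  fit <- fit_rasch_mml(Xn)
  fs <- infit_outfit(fit, Xn)
  expect_gt(fs$outfit_mnsq[fs$item == "noise"],
            max(fs$outfit_mnsq[fs$item != "noise"]))
  expect_true(all(fs$infit_mnsq > 0))

  flagged <- flag_fit(data.frame(item = c("a", "b", "c"),
                                 infit_mnsq = c(1.0, 0.69, 1.31),
                                 outfit_mnsq = 1))
  expect_equal(flagged$flag, c("ok", "low", "high"))
  fig <- flag_fit(data.frame(item = "b", infit_mnsq = 0.72, outfit_mnsq = 1),
                  lower = 0.75, upper = 1.33)
  expect_equal(fig$flag, "low")
  expect_error(flag_fit(flagged, lower = 1.3, upper = 0.7), "below")
})

test_that("gate-forced zeros depress infit below 1", {
  # simulate a clean Rasch matrix, then impose the deterministic gate
  delta <- seq(-2, 2, length.out = 12)
  X <- simulate_response_matrix(rnorm(400), delta, seed = 21)
  gated <- t(apply(X, 1, function(r) apply_gate(r)$final))
  colnames(gated) <- colnames(X)
  fit <- fit_rasch_mml(gated)
  # near-deterministic post-gate cells sit below the information floor
  fs <- suppressWarnings(infit_outfit(fit, gated))
  early <- fs$infit_mnsq[fs$item %in% paste0("item", 2:6)]
  expect_true(all(early[is.finite(early)] < 1))
})

test_that("translation identification: probabilities invariant to a shift", {
  X <- simulate_response_matrix(rnorm(30), c(-1, 0, 1), seed = 22)
  d <- c(-0.5, 0.1, 0.9)
  # shifting difficulties and the latent mean together leaves person
  # likelihoods unchanged; with the mean fixed at 0 the fit is unique
  ll1 <- rasch_marginal_loglik(X, d, 1)
  gh <- gauss_hermite(41)
  shift <- 0.7
  theta_q <- sqrt(2) * 1 * gh$nodes + shift
  logw <- log(gh$weights) - 0.5 * log(pi)
  eta <- outer(theta_q, d + shift, `-`)
  lp <- -log1p(exp(-eta)); l1p <- -log1p(exp(eta))
  ll_nq <- X %*% t(lp) + (1 - X) %*% t(l1p)
  lse <- sweep(ll_nq, 2, logw, `+`)
  m <- apply(lse, 1, max)
  ll2 <- sum(m + log(rowSums(exp(lse - m))))
  expect_equal(ll1, ll2, tolerance = 1e-9)
})
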