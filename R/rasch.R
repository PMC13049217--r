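# Dichotomous Rasch model, marginal maximum likelihood via EM over
# Gauss-Hermite quadrature.  Identification: latent mean fixed at 0,
# latent SD estimated, item difficulties free.

#' Gauss-Hermite quadrature nodes and weights
#'
#' Golub-Welsch nodes/weights for \eqn{\int e^{-x^2} f(x) dx}; used with
#' the change of variable \eqn{\theta = \sqrt{2}\sigma x} to integrate
#' against a Normal(0, sigma^2) latent density.
#'
#' @param n number of nodes.
#' @return List with `nodes` and `weights`.
#' @export
gauss_hermite <- function(n) {
  if (n < 1L) stop("`n` must be >= 1")
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * (e$vectors[1, ord])^2)
}

response_matrix_of <- function(matrix) {
  if (inherits(matrix, "item_response_matrix")) matrix$scores else as.matrix(matrix)
}

# log-likelihood of each person at each quadrature ability;
# X may contain NA (structural missing); M marks observed cells.
person_node_loglik <- function(X, theta_q, delta) {
  M <- !is.na(X)
  X0 <- X; X0[!M] <- 0L
  eta <- outer(theta_q, delta, `-`)       # Q x I
  logP <- -log1p(exp(-eta))
  log1mP <- -log1p(exp(eta))
  X0 %*% t(logP) + (M - X0) %*% t(log1mP) # n x Q
}

#' Marginal log-likelihood of a Rasch model
#'
#' Integrates each person's response likelihood over a Normal(0,
#' `latent_sd`^2) ability distribution with Gauss-Hermite quadrature and
#' sums the logs.  Exposed so that fitted likelihoods can be compared
#' against independent numerical integration.
#'
#' @param matrix an `item_response_matrix` or 0/1 matrix.
#' @param delta item difficulties (finite; items must match columns).
#' @param latent_sd latent ability standard deviation.
#' @param n_quadrature number of Gauss-Hermite nodes.
#' @return Scalar marginal log-likelihood.
#' @export
rasch_marginal_loglik <- function(matrix, delta, latent_sd,
                                  n_quadrature = 41L) {
  X <- response_matrix_of(matrix)
  if (length(delta) != ncol(X)) stop("`delta` must match the item count")
  gh <- gauss_hermite(n_quadrature)
  theta_q <- sqrt(2) * latent_sd * gh$nodes
  logw <- log(gh$weights) - 0.5 * log(pi)
  ll_nq <- person_node_loglik(X, theta_q, delta)
  lse <- sweep(ll_nq, 2L, logw, `+`)
  m <- apply(lse, 1L, max)
  sum(m + log(rowSums(exp(lse - m))))
}

#' Fit the dichotomous Rasch model by marginal maximum likelihood
#'
#' EM with Gauss-Hermite quadrature over a normal latent distribution.
#' The latent mean is fixed at 0 for identification; the latent SD is
#' estimated (or fixed via `latent_sd`).  Items answered identically by
#' everyone (all 0 or all 1) carry no information about a finite
#' difficulty: they are flagged, reported with `-Inf`/`Inf`, and
#' excluded from the likelihood.
#'
#' @param matrix an `item_response_matrix` (see [score_cohort()],
#'   [as_item_response_matrix()]) or a persons x items 0/1 matrix.
#'   `NA` entries are treated as structurally missing.
#' @param n_quadrature Gauss-Hermite nodes (default 41).
#' @param tol EM convergence tolerance on the largest absolute parameter
#'   change (default 1e-5).
#' @param max_iter maximum EM iterations (default 500).
#' @param latent_sd if non-`NULL`, fix the latent SD instead of
#'   estimating it.
#' @param sd_max upper bound on the estimated latent SD.  Near-Guttman
#'   response patterns (e.g. from hard gating) push the marginal
#'   likelihood towards an unbounded latent variance; the cap keeps the
#'   fit finite, and hitting it is reported via `sd_capped`.
#' @return An object of class `rasch_fit`: list with `delta`,
#'   `delta_se`, `included` (items with mixed responses), `latent_mean`
#'   (0), `latent_sd`, `log_likelihood`, `ll_trace`, `converged`,
#'   `n_iter`, `n_quadrature`, `item_names`, `n_persons`.
#' @export
fit_rasch_mml <- function(matrix, n_quadrature = 41L, tol = 1e-5,
                          max_iter = 500L, latent_sd = NULL, sd_max = 10) {
  X <- response_matrix_of(matrix)
  storage.mode(X) <- "double"
  if (nrow(X) < 2L || ncol(X) < 2L) stop("need at least 2 persons and 2 items")
  if (!all(X %in% c(0, 1) | is.na(X))) stop("responses must be 0/1 or NA")
  item_names <- colnames(X)
  if (is.null(item_names)) item_names <- paste0("item", seq_len(ncol(X)))

  p_i <- colMeans(X, na.rm = TRUE)
  included <- p_i > 0 & p_i < 1 & !is.nan(p_i)
  if (sum(included) < 2L) {
    stop("degenerate data: fewer than 2 items with mixed responses")
  }
  Xi <- X[, included, drop = FALSE]
  M <- !is.na(Xi)
  X0 <- Xi; X0[!M] <- 0

  gh <- gauss_hermite(n_quadrature)
  logw <- log(gh$weights) - 0.5 * log(pi)

  delta <- qlogis(1 - pmin(pmax(colMeans(Xi, na.rm = TRUE), 0.02), 0.98))
  sigma <- if (is.null(latent_sd)) 1 else latent_sd
  estimate_sd <- is.null(latent_sd)
  r_i <- colSums(X0)

  ll_trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    theta_q <- sqrt(2) * sigma * gh$nodes
    ll_nq <- person_node_loglik(Xi, theta_q, delta)
    lse <- sweep(ll_nq, 2L, logw, `+`)
    mmax <- apply(lse, 1L, max)
    wexp <- exp(lse - mmax)
    denom <- rowSums(wexp)
    ll <- sum(mmax + log(denom))
    ll_trace <- c(ll_trace, ll)
    post <- wexp / denom                       # n x Q

    # M-step: item difficulties (Newton on expected complete-data score)
    f_qi <- t(post) %*% M                      # Q x I expected exposure
    r_qi <- t(post) %*% X0                     # Q x I expected score
    new_delta <- delta
    for (inner in 1:5) {
      P <- plogis(outer(theta_q, new_delta, `-`))
      W <- P * (1 - P)
      g <- colSums(f_qi * P) - r_i
      h <- colSums(f_qi * W)
      step <- g / pmax(h, 1e-12)
      step[!is.finite(step)] <- 0
      step <- pmin(pmax(step, -2), 2)
      new_delta <- new_delta + step
      if (max(abs(step)) < tol / 10) break
    }
    new_sigma <- sigma
    if (estimate_sd) {
      new_sigma <- sqrt(sum(post %*% theta_q^2) / nrow(Xi))
      new_sigma <- min(max(new_sigma, 1e-3), sd_max)
    }
    change <- max(abs(new_delta - delta), abs(new_sigma - sigma))
    delta <- new_delta
    sigma <- new_sigma
    if (change < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  if (!converged) warning("Rasch EM did not converge in ", max_iter,
                          " iterations")

  theta_q <- sqrt(2) * sigma * gh$nodes
  ll_nq <- person_node_loglik(Xi, theta_q, delta)
  lse <- sweep(ll_nq, 2L, logw, `+`)
  mmax <- apply(lse, 1L, max)
  wexp <- exp(lse - mmax)
  post <- wexp / rowSums(wexp)
  ll <- sum(mmax + log(rowSums(wexp)))
  P <- plogis(outer(theta_q, delta, `-`))
  info <- colSums((t(post) %*% M) * P * (1 - P))

  full_delta <- rep(NA_real_, ncol(X))
  full_delta[included] <- delta
  full_delta[!included & p_i >= 1] <- -Inf  # everyone passed: trivially easy
  full_delta[!included & p_i <= 0] <- Inf
  full_se <- rep(NA_real_, ncol(X))
  full_se[included] <- 1 / sqrt(pmax(info, 1e-12))
  names(full_delta) <- names(full_se) <- item_names

  structure(list(delta = full_delta, delta_se = full_se,
                 included = setNames(included, item_names),
                 latent_mean = 0, latent_sd = sigma,
                 log_likelihood = ll, ll_trace = ll_trace,
                 converged = converged, n_iter = it,
                 sd_capped = estimate_sd && sigma >= sd_max - 1e-9,
                 n_quadrature = n_quadrature,
                 item_names = item_names, n_persons = nrow(X)),
            class = "rasch_fit")
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf(paste0("<rasch_fit> %d persons, %d/%d items included; ",
                     "latent sd %.3f; logLik %.2f; %s in %d iterations\n"),
              x$n_persons, sum(x$included), length(x$included),
              x$latent_sd, x$log_likelihood,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' EAP person ability estimates
#'
#' Posterior mean and SD of ability for each person under the fitted
#' normal prior, evaluated on the quadrature grid.  Finite for perfect
#' and zero scores (the proper prior shrinks them inward).
#'
#' @param fit a [fit_rasch_mml()] result.
#' @param matrix the response matrix the fit was computed on.
#' @return data.frame with `theta_eap` and `psd_eap`, one row per person.
#' @export
eap_scores <- function(fit, matrix) {
  X <- response_matrix_of(matrix)[, fit$included, drop = FALSE]
  gh <- gauss_hermite(fit$n_quadrature)
  theta_q <- sqrt(2) * fit$latent_sd * gh$nodes
  logw <- log(gh$weights) - 0.5 * log(pi)
  ll_nq <- person_node_loglik(X, theta_q, fit$delta[fit$included])
  lse <- sweep(ll_nq, 2L, logw, `+`)
  mmax <- apply(lse, 1L, max)
  post <- exp(lse - mmax)
  post <- post / rowSums(post)
  mu <- as.vector(post %*% theta_q)
  m2 <- as.vector(post %*% theta_q^2)
  data.frame(theta_eap = mu, psd_eap = sqrt(pmax(m2 - mu^2, 0)))
}

#' Warm weighted-likelihood (WLE) person ability estimates
#'
#' Solves \eqn{r - \sum_i P_i(\theta) + J(\theta)/(2 I(\theta)) = 0}
#' where \eqn{I = \sum_i W_i} is the test information and
#' \eqn{J = \sum_i W_i (1 - 2 P_i)}; the bias-correction term keeps the
#' estimate finite at perfect and zero raw scores.  `se_wle` is
#' \eqn{1/\sqrt{I(\hat\theta)}}.  Under the Rasch model the raw score is
#' sufficient, so persons with equal scores (and equal missingness
#' patterns) receive equal estimates.
#'
#' @param fit a [fit_rasch_mml()] result.
#' @param matrix the response matrix the fit was computed on.
#' @param bound search interval half-width in logits.
#' @return data.frame with `theta_wle` and `se_wle`, one row per person.
#' @export
wle_scores <- function(fit, matrix, bound = 15) {
  X <- response_matrix_of(matrix)[, fit$included, drop = FALSE]
  est <- wle_estimate(X, fit$delta[fit$included], bound = bound)
  data.frame(theta_wle = est[, 1], se_wle = est[, 2], row.names = NULL)
}

# Warm WLE per response row for a fixed difficulty vector; rows cached
# by (observed-item pattern, raw score) since the raw score is
# sufficient under the Rasch model
wle_estimate <- function(X, delta, bound = 15) {
  obs_key <- apply(!is.na(X), 1L, function(m) paste(which(m), collapse = ","))
  raw <- rowSums(X, na.rm = TRUE)
  key <- paste(obs_key, raw, sep = "|")
  uk <- !duplicated(key)
  cache <- new.env(parent = emptyenv())
  for (idx in which(uk)) {
    m <- !is.na(X[idx, ])
    d <- delta[m]
    r <- raw[idx]
    f <- function(th) {
      P <- plogis(th - d)
      W <- P * (1 - P)
      I <- sum(W)
      J <- sum(W * (1 - 2 * P))
      r - sum(P) + J / (2 * max(I, 1e-12))
    }
    root <- uniroot(f, lower = -bound, upper = bound, tol = 1e-10,
                    extendInt = "downX")$root
    P <- plogis(root - d)
    se <- 1 / sqrt(max(sum(P * (1 - P)), 1e-12))
    assign(key[idx], c(root, se), envir = cache)
  }
  t(vapply(key, function(k) get(k, envir = cache), numeric(2)))
}

#' EAP and WLE reliability coefficients
#'
#' `eap_reliability`: \eqn{\mathrm{var}(\hat\theta_{EAP}) /
#' (\mathrm{var}(\hat\theta_{EAP}) + \overline{PSD^2})}.
#' `wle_reliability`: \eqn{1 - \overline{SE^2} /
#' \mathrm{var}(\hat\theta_{WLE})}.  Both clipped to \[0, 1\].
#'
#' Zero estimate variance (all persons sharing one response pattern)
#' means no true-score variance and reliability 0; reliability is
#' undefined only for fewer than 2 persons.
#'
#' @param eap data.frame from [eap_scores()].
#' @param wle data.frame from [wle_scores()].
#' @return Scalar reliability in \[0, 1\].
#' @export
eap_reliability <- function(eap) {
  if (nrow(eap) < 2L) stop("undefined reliability: need at least 2 persons")
  v <- var(eap$theta_eap)
  if (v == 0) return(0)
  min(max(v / (v + mean(eap$psd_eap^2)), 0), 1)
}

#' @rdname eap_reliability
#' @export
wle_reliability <- function(wle) {
  if (nrow(wle) < 2L) stop("undefined reliability: need at least 2 persons")
  v <- var(wle$theta_wle)
  if (v == 0) return(0)
  min(max(1 - mean(wle$se_wle^2) / v, 0), 1)
}

#' Infit and outfit mean-square item fit statistics
#'
#' With \eqn{E_{ni} = P(1 | \hat\theta_n, \delta_i)} and
#' \eqn{W_{ni} = E_{ni}(1 - E_{ni})}: outfit is the unweighted mean of
#' squared standardized residuals \eqn{(x - E)^2 / W}; infit is the
#' information-weighted version \eqn{\sum (x - E)^2 / \sum W}.  Values
#' near 1 are model-conforming; gated items (deterministic zeros after
#' a gate) depress residual variance and show infit below 1.
#'
#' The default `method = "posterior"` takes the expectation of the
#' squared residuals over each person's posterior ability distribution
#' (the usual choice with marginal estimation): conditioning instead on
#' a point estimate fitted to the same responses deflates the mean
#' squares by roughly one part per test length, while conditioning on a
#' leave-one-out estimate inflates them by the estimate's noise.  Point
#' conditioning on WLE or EAP estimates remains available for
#' comparability with joint-estimation software.
#'
#' @param fit a [fit_rasch_mml()] result.
#' @param matrix the response matrix.
#' @param method `"posterior"` (default), `"wle"` or `"eap"`.
#' @param w_floor variance floor applied inside the standardized
#'   residual to keep extreme-ability cells finite; cells below the
#'   floor under point conditioning are excluded with a warning.
#' @return data.frame with `item`, `infit_mnsq`, `outfit_mnsq`
#'   (`NA` for excluded items).
#' @export
infit_outfit <- function(fit, matrix, method = c("posterior", "wle", "eap"),
                         w_floor = 1e-10) {
  method <- match.arg(method)
  X <- response_matrix_of(matrix)
  inc <- fit$included
  delta <- fit$delta[inc]
  Xi <- X[, inc, drop = FALSE]
  obs <- !is.na(Xi)

  if (method == "posterior") {
    gh <- gauss_hermite(fit$n_quadrature)
    theta_q <- sqrt(2) * fit$latent_sd * gh$nodes
    logw <- log(gh$weights) - 0.5 * log(pi)
    ll_nq <- person_node_loglik(Xi, theta_q, delta)
    lse <- sweep(ll_nq, 2L, logw, `+`)
    post <- exp(lse - apply(lse, 1L, max))
    post <- post / rowSums(post)
    P <- plogis(outer(theta_q, delta, `-`))        # Q x I
    W <- pmax(P * (1 - P), w_floor)
    X0 <- Xi; X0[!obs] <- 0
    # E_post[(x - P)^2] = x (1 - 2 E[P]) + E[P^2], x binary
    A <- post %*% P
    B <- post %*% P^2
    num_sq <- (X0 * (1 - 2 * A) + B) * obs
    Aw <- post %*% ((1 - 2 * P) / W)
    Bw <- post %*% (P^2 / W)
    z2 <- (X0 * Aw + Bw) * obs
    ew <- (post %*% (P * (1 - P))) * obs
    outfit <- colSums(z2) / pmax(colSums(obs), 1)
    infit <- colSums(num_sq) / pmax(colSums(ew), 1e-12)
  } else {
    th <- if (method == "wle") wle_scores(fit, matrix)$theta_wle
          else eap_scores(fit, matrix)$theta_eap
    E <- plogis(outer(th, delta, `-`))
    W <- E * (1 - E)
    R2 <- (Xi - E)^2
    low <- W < w_floor & obs
    if (any(low)) {
      warning(sum(low), " cells below the information floor excluded from fit")
      obs <- obs & !low
    }
    R2[!obs] <- 0; Wm <- W; Wm[!obs] <- 0
    outfit <- colSums(R2 / pmax(W, w_floor) * obs) / pmax(colSums(obs), 1)
    infit <- colSums(R2 * obs) / pmax(colSums(Wm), 1e-12)
  }
  out <- data.frame(item = fit$item_names,
                    infit_mnsq = NA_real_, outfit_mnsq = NA_real_)
  out$infit_mnsq[inc] <- infit
  out$outfit_mnsq[inc] <- outfit
  out
}

#' Flag items whose infit leaves the acceptance band
#'
#' Mean-square fit in roughly \[0.7, 1.3\] is conventionally read as
#' productive measurement; an alternative figure convention of
#' \[0.75, 1.33\] can be set via the bounds.
#'
#' @param fitstats data.frame from [infit_outfit()].
#' @param lower,upper acceptance band for infit (defaults 0.7 and 1.3).
#' @return The input with a `flag` column: `"ok"`, `"low"`, `"high"` or
#'   `NA` for excluded items.
#' @export
flag_fit <- function(fitstats, lower = 0.7, upper = 1.3) {
  if (lower >= upper) stop("`lower` must be below `upper`")
  f <- ifelse(is.na(fitstats$infit_mnsq), NA_character_,
       ifelse(fitstats$infit_mnsq < lower, "low",
       ifelse(fitstats$infit_mnsq > upper, "high", "ok")))
  fitstats$flag <- f
  fitstats
}
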