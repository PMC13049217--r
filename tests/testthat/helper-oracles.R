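# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: brute-force scans, adaptive quadrature,
# grid search.

# marginal Rasch log-likelihood by adaptive numerical integration
brute_marginal_loglik <- function(X, delta, latent_sd) {
  sum(vapply(seq_len(nrow(X)), function(n) {
    f <- function(th) {
      p <- plogis(outer(th, delta, `-`))
      lik <- apply(p, 1, function(pr) {
        prod(ifelse(X[n, ] == 1, pr, 1 - pr))
      })
      lik * dnorm(th, 0, latent_sd)
    }
    log(integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-14)$value)
  }, numeric(1)))
}

# brute-force strict local maxima scan (no prominence logic)
brute_local_maxima <- function(x) {
  n <- length(x)
  which(vapply(seq_len(n), function(i) {
    i > 1 && i < n && x[i] > x[i - 1] && x[i] > x[i + 1]
  }, logical(1)))
}

# brute-force idle time: scan maximal sub-threshold interval runs
brute_idle_time <- function(speed, dt, threshold, min_dwell) {
  total <- 0; run <- 0
  for (k in seq_along(speed)) {
    if (speed[k] < threshold) {
      run <- run + dt[k]
    } else {
      if (run >= min_dwell) total <- total + run
      run <- 0
    }
  }
  if (run >= min_dwell) total <- total + run
  total
}

# grid maximizer of Warm's weighted likelihood for one response vector
brute_wle <- function(x, delta, grid = seq(-8, 8, by = 1e-4)) {
  obj <- vapply(grid, function(th) {
    p <- plogis(th - delta)
    I <- sum(p * (1 - p))
    sum(ifelse(x == 1, log(p), log(1 - p))) + 0.5 * log(I)
  }, numeric(1))
  grid[which.max(obj)]
}

# stream helpers -------------------------------------------------------

identity_quat <- function(n) matrix(rep(c(1, 0, 0, 0), n), ncol = 4,
                                    byrow = TRUE)

# two (or more) well-separated minimum-jerk submovements along one axis
multi_submovement_stream <- function(n_sub, extent_mm = 50, move_s = 1,
                                     gap_s = 2, rate_hz = 50) {
  total <- n_sub * move_s + (n_sub + 1) * gap_s
  n <- round(total * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  x <- numeric(n)
  for (j in seq_len(n_sub)) {
    onset <- j * gap_s + (j - 1) * move_s
    x <- x + extent_mm * opirasch::min_jerk_s((t - onset) / move_s)
  }
  kinematic_stream(t, cbind(x, 0, 0), identity_quat(n))
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# standard-normal abilities under a local seed
withr_local_theta <- function(n, seed) {
  set.seed(seed)
  rnorm(n)
}
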