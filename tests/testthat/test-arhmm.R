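test_that("parameter validation names the violated invariant", {
  p <- toy_arhmm()
  expect_silent(validate_arhmm(p))
  bad <- p; bad$pi <- c(0.7, 0.7)
  expect_error(validate_arhmm(bad), "pi")
  bad <- p; bad$A[1, ] <- c(0.5, 0.6)
  expect_error(validate_arhmm(bad), "sum to 1")
  expect_error(
    arhmm_params(pi = c(1), A = matrix(1), c = matrix(0),
                 Phi = list(matrix(0)), sigma2 = matrix(0),
                 mu0 = matrix(0), sigma02 = matrix(1)),
    "variances"
  )
})

test_that("simulation respects absorbing states and transition rates", {
  A <- benchmark_transition_matrix()
  p <- arhmm_params(
    pi = c(1, 0, 0, 0, 0), A = A,
    c = matrix(0, 5, 1), Phi = rep(list(matrix(0)), 5),
    sigma2 = matrix(1, 5, 1), mu0 = matrix(1:5, 5, 1),
    sigma02 = matrix(1, 5, 1)
  )
  d <- simulate_arhmm(p, 300, 12, seed = 5)
  states <- t(vapply(d, `[[`, integer(12), "states"))
  expect_true(all(states[, 1] == 1))
  # absorbing: once in state 4 or 5, never leave
  for (k in 4:5) {
    hits <- which(states == k, arr.ind = TRUE)
    for (r in unique(hits[, 1])) {
      t0 <- min(hits[hits[, 1] == r, 2])
      expect_true(all(states[r, t0:12] == states[r, t0]))
    }
  }
  # same seed, same draw
  d2 <- simulate_arhmm(p, 300, 12, seed = 5)
  expect_identical(d, d2)
})

test_that("near-zero noise with no autoregression pins emissions at the intercept", {
  p <- arhmm_params(
    pi = c(0.5, 0.5), A = matrix(0.5, 2, 2),
    c = matrix(c(-3, 7), 2, 1), Phi = rep(list(matrix(0)), 2),
    sigma2 = matrix(1e-12, 2, 1), mu0 = matrix(c(-3, 7), 2, 1),
    sigma02 = matrix(1e-12, 2, 1)
  )
  d <- simulate_arhmm(p, 5, 8, seed = 1)
  for (s in d) {
    expect_equal(drop(s$X), c(-3, 7)[s$states], tolerance = 1e-4)
  }
})

test_that("forward log-likelihood equals exhaustive path enumeration", {
  set.seed(11)
  for (K in 2:3) {
    for (Tn in c(4, 6)) {
      d <- 2
      A <- matrix(rgamma(K * K, 2), K); A <- A / rowSums(A)
      pi <- rgamma(K, 2); pi <- pi / sum(pi)
      p <- arhmm_params(
        pi = pi, A = A,
        c = matrix(rnorm(K * d), K), Phi = replicate(K, matrix(rnorm(d * d, 0, 0.2), d), simplify = FALSE),
        sigma2 = matrix(runif(K * d, 0.5, 2), K),
        mu0 = matrix(rnorm(K * d, 0, 2), K),
        sigma02 = matrix(runif(K * d, 0.5, 2), K)
      )
      X <- matrix(rnorm(Tn * d), Tn)
      expect_equal(arhmm_loglik(p, list(X)), enumerate_loglik(p, X),
                   tolerance = 1e-8)
    }
  }
})

test_that("single-state likelihood is the closed-form AR(1) density sum", {
  phi <- matrix(0.4)
  p <- arhmm_params(pi = 1, A = matrix(1), c = matrix(1.5),
                    Phi = list(phi), sigma2 = matrix(0.8),
                    mu0 = matrix(0.5), sigma02 = matrix(1.2))
  set.seed(3)
  X <- matrix(rnorm(10), 10)
  closed <- dnorm(X[1], 0.5, sqrt(1.2), log = TRUE) +
    sum(dnorm(X[-1], 1.5 + 0.4 * X[-10], sqrt(0.8), log = TRUE))
  expect_equal(arhmm_loglik(p, list(X)), closed, tolerance = 1e-10)
  # independence across sequences: duplicating the data doubles it
  expect_equal(arhmm_loglik(p, list(X, X)), 2 * closed, tolerance = 1e-10)
})

test_that("EM recovers a well-separated two-state model", {
  truth <- toy_arhmm(sep = 5, sd = 0.5, phi = 0.2)
  d <- simulate_arhmm(truth, 200, 20, seed = 11)
  fit <- suppressWarnings(em_fit(d, K = 2, n_restarts = 3, seed = 5))
  # states come back ordered by first mean component, matching the truth
  expect_lt(max(abs(fit$params$A - truth$A)), 0.05)
  expect_lt(max(abs(fit$params$mu0 - truth$mu0)), 0.3)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # the fit improves on the model it started from
  expect_gte(fit$loglik, fit$loglik_trace[1])
})

test_that("single-state EM equals the ordinary least-squares AR(1) fit", {
  truth <- arhmm_params(pi = 1, A = matrix(1), c = matrix(c(1, -1), 1),
                        Phi = list(matrix(c(0.5, 0.1, -0.2, 0.3), 2)),
                        sigma2 = matrix(c(0.5, 0.8), 1),
                        mu0 = matrix(0, 1, 2), sigma02 = matrix(1, 1, 2))
  d <- simulate_arhmm(truth, 30, 25, seed = 9)
  fit <- suppressWarnings(em_fit(d, K = 1, n_restarts = 1, seed = 1))
  # pooled OLS of x_t on (1, x_{t-1}), per output dimension
  Z <- do.call(rbind, lapply(d, function(s) cbind(1, s$X[-nrow(s$X), ])))
  Y <- do.call(rbind, lapply(d, function(s) s$X[-1, , drop = FALSE]))
  beta <- solve(crossprod(Z), crossprod(Z, Y))
  expect_equal(drop(fit$params$c), unname(beta[1, ]), tolerance = 1e-6)
  expect_equal(unname(fit$params$Phi[[1]]), unname(t(beta[-1, ])),
               tolerance = 1e-6)
})

test_that("row-stochasticity survives every EM iteration", {
  truth <- toy_arhmm(sep = 3, sd = 1)
  d <- simulate_arhmm(truth, 40, 10, seed = 21)
  fit <- suppressWarnings(em_fit(d, K = 2, n_restarts = 2, seed = 3))
  expect_equal(rowSums(fit$params$A), c(1, 1), tolerance = 1e-9)
  expect_equal(sum(fit$params$pi), 1, tolerance = 1e-9)
})

test_that("Viterbi decoding is optimal and degenerate cases are forced", {
  # K = 1: constant path
  p1 <- arhmm_params(pi = 1, A = matrix(1), c = matrix(0),
                     Phi = list(matrix(0)), sigma2 = matrix(1),
                     mu0 = matrix(0), sigma02 = matrix(1))
  expect_equal(arhmm_decode(p1, matrix(rnorm(6))), rep(1, 6))

  # near-disjoint emissions: decoded path equals the true path
  truth <- toy_arhmm(sep = 8, sd = 0.3)
  d <- simulate_arhmm(truth, 10, 12, seed = 31)
  for (s in d) expect_equal(arhmm_decode(truth, s$X), s$states)

  # beats 1,000 random paths
  truth2 <- toy_arhmm(sep = 2, sd = 1)
  d2 <- simulate_arhmm(truth2, 1, 8, seed = 41)
  vit <- arhmm_decode(truth2, d2[[1]]$X)
  lp_vit <- path_logprob(truth2, d2[[1]]$X, vit)
  set.seed(1)
  for (i in 1:1000) {
    z <- sample(1:2, 8, replace = TRUE)
    expect_gte(lp_vit, path_logprob(truth2, d2[[1]]$X, z) - 1e-10)
  }
})

test_that("state statistics are responsibility-weighted means", {
  # single state: plain feature means
  p1 <- arhmm_params(pi = 1, A = matrix(1), c = matrix(c(0, 0), 1),
                     Phi = list(diag(0, 2)), sigma2 = matrix(1, 1, 2),
                     mu0 = matrix(0, 1, 2), sigma02 = matrix(1, 1, 2))
  set.seed(2)
  X <- matrix(rnorm(40), 20)
  st <- expected_state_statistics(p1, list(X))
  expect_equal(drop(st), colMeans(X), tolerance = 1e-10, ignore_attr = TRUE)

  # convexity: weighted means stay inside the observed range
  truth <- toy_arhmm(sep = 4, sd = 1)
  d <- simulate_arhmm(truth, 20, 10, seed = 51)
  st2 <- expected_state_statistics(truth, d)
  allX <- do.call(rbind, lapply(d, `[[`, "X"))
  for (j in 1:2) {
    expect_true(all(st2[, j] >= min(allX[, j]) & st2[, j] <= max(allX[, j])))
  }

  # near-zero noise: per-state means sit at the AR(1) fixed point
  fix <- arhmm_params(pi = 1, A = matrix(1), c = matrix(2),
                      Phi = list(matrix(0.5)), sigma2 = matrix(1e-10),
                      mu0 = matrix(4), sigma02 = matrix(1e-10))
  dfix <- simulate_arhmm(fix, 1, 400, seed = 61)
  stfix <- expected_state_statistics(fix, dfix)
  expect_equal(drop(stfix), 2 / (1 - 0.5), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("simulate -> fit -> simulate preserves the transition structure", {
  truth <- toy_arhmm(sep = 5, sd = 0.5)
  d <- simulate_arhmm(truth, 150, 15, seed = 71)
  fit <- suppressWarnings(em_fit(d, K = 2, n_restarts = 2, seed = 7))
  d2 <- simulate_arhmm(fit$params, 150, 15, seed = 72)
  emp <- function(data) {
    tr <- do.call(rbind, lapply(data, function(s) {
      cbind(s$states[-length(s$states)], s$states[-1])
    }))
    prop.table(table(factor(tr[, 1], 1:2), factor(tr[, 2], 1:2)), 1)
  }
  expect_lt(max(abs(emp(d) - emp(d2))), 0.05)
})

test_that("parameters survive the JSON round trip", {
  p <- toy_arhmm(sep = 3.21, sd = 0.77, phi = 0.13)
  path <- file.path(tempdir(), "arhmm.json")
  arhmm_params_to_json(p, path)
  q <- arhmm_params_from_json(path)
  for (nm in c("pi", "A", "c", "sigma2", "mu0", "sigma02")) {
    expect_equal(unname(as.matrix(q[[nm]])), unname(as.matrix(p[[nm]])),
                 tolerance = 1e-12)
  }
  expect_equal(lapply(q$Phi, unname), lapply(p$Phi, unname),
               tolerance = 1e-12)
})
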