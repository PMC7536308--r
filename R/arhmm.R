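#' Autoregressive hidden Markov model parameters
#'
#' An order-1 autoregressive Gaussian HMM: the hidden state follows a
#' Markov chain with initial distribution `pi` and transition matrix `A`;
#' the first observation of a sequence is drawn from a diagonal Gaussian
#' `N(mu0_k, sigma02_k)` and every later observation from
#' `N(c_k + Phi_k x_{t-1}, sigma2_k)`, all conditioned on the current
#' state `k`.
#'
#' @param pi initial state distribution (length `K`, sums to 1).
#' @param A `K x K` row-stochastic transition matrix.
#' @param c `K x d` matrix of per-state AR intercepts.
#' @param Phi list of `K` `d x d` AR coefficient matrices.
#' @param sigma2 `K x d` matrix of per-state diagonal noise variances
#'   (AR step), all positive.
#' @param mu0 `K x d` matrix of initial-step emission means.
#' @param sigma02 `K x d` matrix of initial-step variances, all positive.
#' @return an `arhmm_params` object.
#' @export
arhmm_params <- function(pi, A, c, Phi, sigma2, mu0, sigma02) {
  p <- structure(
    list(K = length(pi), d = ncol(as.matrix(c)), pi = as.numeric(pi),
         A = as.matrix(A), c = as.matrix(c), Phi = Phi,
         sigma2 = as.matrix(sigma2), mu0 = as.matrix(mu0),
         sigma02 = as.matrix(sigma02)),
    class = "arhmm_params"
  )
  validate_arhmm(p)
  p
}

#' Validate AR-HMM parameters
#'
#' @param p an `arhmm_params` object.
#' @return invisibly `TRUE`; otherwise an error naming the violated
#'   invariant.
#' @export
validate_arhmm <- function(p) {
  K <- p$K; d <- p$d
  if (abs(sum(p$pi) - 1) > 1e-9) stopf("arhmm: pi must sum to 1")
  if (any(p$pi < 0)) stopf("arhmm: pi must be non-negative")
  if (!all(dim(p$A) == c(K, K))) stopf("arhmm: A must be %d x %d", K, K)
  if (any(abs(rowSums(p$A) - 1) > 1e-9)) stopf("arhmm: rows of A must sum to 1")
  if (any(p$A < 0)) stopf("arhmm: A must be non-negative")
  for (nm in c("c", "sigma2", "mu0", "sigma02")) {
    if (!all(dim(p[[nm]]) == c(K, d))) stopf("arhmm: %s must be %d x %d", nm, K, d)
  }
  if (length(p$Phi) != K || !all(vapply(p$Phi, function(m) all(dim(as.matrix(m)) == c(d, d)), logical(1)))) {
    stopf("arhmm: Phi must be a list of %d %d x %d matrices", K, d, d)
  }
  if (any(p$sigma2 <= 0) || any(p$sigma02 <= 0)) {
    stopf("arhmm: variances must be > 0")
  }
  invisible(TRUE)
}

#' @export
print.arhmm_params <- function(x, ...) {
  cat(sprintf("arhmm_params: K = %d states, d = %d observed variables\n",
              x$K, x$d))
  cat("  transition matrix:\n")
  print(round(x$A, 3))
  invisible(x)
}

#' State-sequence data container
#'
#' @param seqs list of sequences; each either a numeric matrix (rows =
#'   time steps) or a list with elements `X` (matrix) and optional
#'   `states` (true hidden states, simulation only).
#' @return a `state_sequences` object.
#' @export
state_sequences <- function(seqs) {
  out <- lapply(seqs, function(s) {
    if (is.matrix(s) || is.data.frame(s)) list(X = as.matrix(s), states = NULL)
    else list(X = as.matrix(s$X), states = s$states)
  })
  d <- unique(vapply(out, function(s) ncol(s$X), integer(1)))
  if (length(d) != 1) stopf("state_sequences: sequences differ in dimension")
  if (any(vapply(out, function(s) nrow(s$X), integer(1)) < 1)) {
    stopf("state_sequences: sequences must have length >= 1")
  }
  structure(out, class = "state_sequences")
}

#' @export
print.state_sequences <- function(x, ...) {
  lens <- vapply(x, function(s) nrow(s$X), integer(1))
  cat(sprintf("state_sequences: %d sequences, lengths %d..%d, %d variables%s\n",
              length(x), min(lens), max(lens), ncol(x[[1]]$X),
              if (!is.null(x[[1]]$states)) " (true states attached)" else ""))
  invisible(x)
}

as_state_sequences <- function(data) {
  if (inherits(data, "state_sequences")) data else state_sequences(data)
}

#' Simulate sequences from an AR-HMM
#'
#' @param params an `arhmm_params` object.
#' @param n_sequences number of independent sequences.
#' @param length length of each sequence.
#' @param seed integer seed; the caller's RNG state is untouched.
#' @return a `state_sequences` object with true states attached.
#' @export
simulate_arhmm <- function(params, n_sequences, length, seed = 1L) {
  validate_arhmm(params)
  K <- params$K; d <- params$d
  with_local_seed(seed, {
    seqs <- lapply(seq_len(n_sequences), function(s) {
      z <- integer(length)
      X <- matrix(0, length, d)
      z[1] <- sample.int(K, 1, prob = params$pi)
      X[1, ] <- rnorm(d, params$mu0[z[1], ], sqrt(params$sigma02[z[1], ]))
      for (t in seq_len(length)[-1]) {
        z[t] <- sample.int(K, 1, prob = params$A[z[t - 1], ])
        mu <- params$c[z[t], ] + as.numeric(params$Phi[[z[t]]] %*% X[t - 1, ])
        X[t, ] <- rnorm(d, mu, sqrt(params$sigma2[z[t], ]))
      }
      list(X = X, states = z)
    })
    state_sequences(seqs)
  })
}

# Log emission matrix (T x K) for one sequence under the AR(1) model.
arhmm_log_emissions <- function(params, X) {
  Tn <- nrow(X); K <- params$K; d <- params$d
  logB <- matrix(0, Tn, K)
  for (k in seq_len(K)) {
    logB[1, k] <- sum(stats::dnorm(X[1, ], params$mu0[k, ],
                                   sqrt(params$sigma02[k, ]), log = TRUE))
    if (Tn > 1) {
      pred <- X[-Tn, , drop = FALSE] %*% t(as.matrix(params$Phi[[k]]))
      pred <- sweep(pred, 2, params$c[k, ], `+`)
      resid <- X[-1, , drop = FALSE] - pred
      lg <- sweep(-0.5 * sweep(resid^2, 2, params$sigma2[k, ], `/`), 2,
                  0.5 * log(2 * pi * params$sigma2[k, ]), `-`)
      logB[-1, k] <- rowSums(lg)
    }
  }
  logB
}

# Scaled forward-backward for one sequence. Returns log-likelihood,
# smoothed state probabilities gamma (T x K) and the summed transition
# responsibilities xi (K x K).
arhmm_forward_backward <- function(params, X) {
  Tn <- nrow(X); K <- params$K
  logB <- arhmm_log_emissions(params, X)
  shift <- apply(logB, 1, max)
  B <- exp(logB - shift)
  A <- params$A
  alpha <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  a <- params$pi * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- as.numeric(crossprod(A, alpha[t - 1, ])) * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  loglik <- sum(log(cvec)) + sum(shift)
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      beta[t, ] <- as.numeric(A %*% (B[t + 1, ] * beta[t + 1, ])) / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi <- matrix(0, K, K)
  if (Tn > 1) {
    for (t in 2:Tn) {
      x <- (alpha[t - 1, ] %o% (B[t, ] * beta[t, ])) * A
      xi <- xi + x / sum(x)
    }
  }
  list(loglik = loglik, gamma = gamma, xi = xi)
}

#' Exact log-likelihood of sequences under an AR-HMM
#'
#' Computed with the scaled forward recursion, summed over independent
#' sequences. On a chain this is exact inference (identical to junction
#' tree message passing).
#'
#' @param params an `arhmm_params` object.
#' @param data a `state_sequences` object or list of sequence matrices.
#' @return the total log-likelihood.
#' @export
arhmm_loglik <- function(params, data) {
  validate_arhmm(params)
  data <- as_state_sequences(data)
  sum(vapply(data, function(s) {
    arhmm_forward_backward(params, s$X)$loglik
  }, numeric(1)))
}

#' Fit an AR-HMM by expectation-maximisation
#'
#' E-step: scaled forward-backward responsibilities. M-step: closed form —
#' responsibility-weighted least squares for the per-state AR intercepts
#' and coefficient matrices, weighted moments for the variances, initial
#' distribution and transition matrix. Several random restarts are run
#' (k-means on the pooled observations initialises state means; the
#' transition matrix starts sticky at `0.8 I + 0.2/K`) and the restart
#' with the best final log-likelihood wins. States are relabelled by
#' ascending first component of the initial-step mean for identifiability.
#'
#' @param data a `state_sequences` object or list of sequence matrices.
#' @param K number of hidden states (default 5).
#' @param max_iter maximum EM iterations per restart.
#' @param tol stop when the log-likelihood gain drops below this.
#' @param n_restarts random restarts (default 5).
#' @param seed integer seed controlling initialisation.
#' @return list with `params` (fitted `arhmm_params`), `loglik_trace`
#'   (non-decreasing), `loglik` (final value), `n_iter` and `restart`
#'   (index of the winning restart).
#' @export
em_fit <- function(data, K = 5, max_iter = 100, tol = 1e-6,
                   n_restarts = 5, seed = 1L) {
  data <- as_state_sequences(data)
  d <- ncol(data[[1]]$X)
  all_obs <- do.call(rbind, lapply(data, function(s) s$X))
  if (nrow(all_obs) < K * (d + 2)) {
    stopf("em_fit: need at least %d observations for K = %d", K * (d + 2), K)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- with_local_seed(seed + r - 1, {
      km <- suppressWarnings(kmeans(all_obs, centers = K, nstart = 3,
                                    iter.max = 50))
      km$centers
    })
    pooled_var <- pmax(apply(all_obs, 2, stats::var), 1e-4)
    p <- arhmm_params(
      pi = rep(1 / K, K),
      A = matrix(0.2 / K, K, K) + diag(0.8, K),
      c = init,
      Phi = rep(list(matrix(0, d, d)), K),
      sigma2 = matrix(pooled_var, K, d, byrow = TRUE),
      mu0 = init,
      sigma02 = matrix(pooled_var, K, d, byrow = TRUE)
    )
    fit <- tryCatch(
      em_run(data, p, max_iter = max_iter, tol = tol),
      error = function(e) e
    )
    if (inherits(fit, "error") || fit$degenerate) {
      warning(sprintf("em_fit: restart %d discarded (%s)", r,
                      if (inherits(fit, "error")) conditionMessage(fit)
                      else "empty state"))
      next
    }
    if (is.null(best) || fit$loglik > best$loglik) {
      best <- fit
      best$restart <- r
    }
  }
  if (is.null(best)) stopf("em_fit: every restart failed")
  best$params <- relabel_states(best$params)
  best[c("params", "loglik_trace", "loglik", "n_iter", "restart")]
}

# One EM run from given starting parameters.
em_run <- function(data, p, max_iter, tol) {
  K <- p$K; d <- p$d
  trace <- numeric(0)
  degenerate <- FALSE
  for (iter in seq_len(max_iter)) {
    loglik <- 0
    g1_sum <- numeric(K); g1_x <- matrix(0, K, d); g1_xx <- matrix(0, K, d)
    xi_sum <- matrix(0, K, K)
    S_zz <- rep(list(matrix(0, d + 1, d + 1)), K)
    S_zy <- rep(list(matrix(0, d + 1, d)), K)
    S_yy <- matrix(0, K, d)
    W <- numeric(K)
    max_gamma <- numeric(K)
    for (s in data) {
      X <- s$X; Tn <- nrow(X)
      fb <- arhmm_forward_backward(p, X)
      loglik <- loglik + fb$loglik
      gamma <- fb$gamma
      max_gamma <- pmax(max_gamma, apply(gamma, 2, max))
      g1_sum <- g1_sum + gamma[1, ]
      g1_x <- g1_x + gamma[1, ] %o% X[1, ]
      g1_xx <- g1_xx + gamma[1, ] %o% (X[1, ]^2)
      xi_sum <- xi_sum + fb$xi
      if (Tn > 1) {
        Z <- cbind(1, X[-Tn, , drop = FALSE])
        Y <- X[-1, , drop = FALSE]
        for (k in seq_len(K)) {
          w <- gamma[-1, k]
          Zw <- Z * w
          S_zz[[k]] <- S_zz[[k]] + crossprod(Zw, Z)
          S_zy[[k]] <- S_zy[[k]] + crossprod(Zw, Y)
          S_yy[k, ] <- S_yy[k, ] + colSums(w * Y^2)
          W[k] <- W[k] + sum(w)
        }
      }
    }
    trace <- c(trace, loglik)
    if (any(max_gamma < 1e-6)) {
      degenerate <- TRUE
      break
    }
    # M-step
    p$pi <- g1_sum / sum(g1_sum)
    rs <- rowSums(xi_sum)
    for (k in seq_len(K)) {
      if (rs[k] > 1e-12) p$A[k, ] <- xi_sum[k, ] / rs[k]
    }
    for (k in seq_len(K)) {
      if (g1_sum[k] > 1e-8) {
        p$mu0[k, ] <- g1_x[k, ] / g1_sum[k]
        p$sigma02[k, ] <- pmax(g1_xx[k, ] / g1_sum[k] - p$mu0[k, ]^2, 1e-6)
      }
      if (W[k] > 1e-8) {
        beta <- solve(S_zz[[k]] + diag(1e-8, d + 1), S_zy[[k]])
        p$c[k, ] <- beta[1, ]
        p$Phi[[k]] <- t(beta[-1, , drop = FALSE])
        rss <- S_yy[k, ] - 2 * colSums(beta * S_zy[[k]]) +
          diag(t(beta) %*% S_zz[[k]] %*% beta)
        p$sigma2[k, ] <- pmax(rss / W[k], 1e-6)
      }
    }
    if (iter > 1 && trace[iter] - trace[iter - 1] < tol) break
  }
  list(params = p, loglik_trace = trace, loglik = trace[length(trace)],
       n_iter = length(trace), degenerate = degenerate)
}

# Relabel states by ascending first component of the initial-step mean.
relabel_states <- function(p) {
  perm <- order(p$mu0[, 1])
  arhmm_params(
    pi = p$pi[perm], A = p$A[perm, perm, drop = FALSE],
    c = p$c[perm, , drop = FALSE], Phi = p$Phi[perm],
    sigma2 = p$sigma2[perm, , drop = FALSE],
    mu0 = p$mu0[perm, , drop = FALSE],
    sigma02 = p$sigma02[perm, , drop = FALSE]
  )
}

#' Most probable state path (Viterbi)
#'
#' @param params an `arhmm_params` object.
#' @param sequence numeric matrix (rows = time steps) or a sequence entry
#'   of a `state_sequences` object.
#' @return integer vector of decoded states; ties resolve to the lower
#'   state index.
#' @export
arhmm_decode <- function(params, sequence) {
  validate_arhmm(params)
  X <- if (is.list(sequence)) as.matrix(sequence$X) else as.matrix(sequence)
  Tn <- nrow(X); K <- params$K
  logB <- arhmm_log_emissions(params, X)
  logA <- log(params$A)
  delta <- log(params$pi) + logB[1, ]
  psi <- matrix(0L, Tn, K)
  if (Tn > 1) {
    for (t in 2:Tn) {
      cand <- delta + logA  # K x K: previous state in rows
      best_prev <- apply(cand, 2, which.max)
      delta <- cand[cbind(best_prev, seq_len(K))] + logB[t, ]
      psi[t, ] <- best_prev
    }
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta)
  if (Tn > 1) {
    for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  }
  path
}

#' Responsibility-weighted per-state feature means
#'
#' Soft state-membership (smoothed responsibilities) is used to weight
#' every observation, giving the expected value of each observed variable
#' in each hidden state — the state-summary table of a fitted model.
#'
#' @param params a fitted `arhmm_params` object.
#' @param data a `state_sequences` object or list of sequence matrices.
#' @return `K x d` matrix of weighted means (rows = states).
#' @export
expected_state_statistics <- function(params, data) {
  validate_arhmm(params)
  data <- as_state_sequences(data)
  K <- params$K; d <- params$d
  num <- matrix(0, K, d); den <- numeric(K)
  for (s in data) {
    fb <- arhmm_forward_backward(params, s$X)
    num <- num + crossprod(fb$gamma, s$X)
    den <- den + colSums(fb$gamma)
  }
  out <- num / den
  rownames(out) <- paste0("state_", seq_len(K))
  colnames(out) <- colnames(data[[1]]$X)
  out
}

#' Serialise AR-HMM parameters to JSON
#'
#' Field names and shapes are explicit; [arhmm_params_from_json()] reads
#' the file back into an identical object.
#'
#' @param params an `arhmm_params` object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
arhmm_params_to_json <- function(params, path) {
  obj <- list(
    K = params$K, d = params$d, pi = params$pi, A = params$A,
    c = params$c, Phi = params$Phi, sigma2 = params$sigma2,
    mu0 = params$mu0, sigma02 = params$sigma02
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read AR-HMM parameters from JSON
#' @param path file written by [arhmm_params_to_json()].
#' @return an `arhmm_params` object.
#' @export
arhmm_params_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arhmm_params(
    pi = obj$pi, A = obj$A, c = obj$c,
    Phi = if (is.array(obj$Phi) && length(dim(obj$Phi)) == 3) {
      lapply(seq_len(dim(obj$Phi)[1]), function(k) obj$Phi[k, , , drop = TRUE])
    } else if (is.list(obj$Phi)) {
      lapply(obj$Phi, as.matrix)
    } else {
      list(as.matrix(obj$Phi))
    },
    sigma2 = obj$sigma2, mu0 = obj$mu0, sigma02 = obj$sigma02
  )
}
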