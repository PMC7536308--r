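# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately brute-force / closed-form and shares no
# code with the implementation paths it checks.

# A bare network with singleton nodes and an explicit edge list, shaped
# like a mapper_graph (shared sets are dummy singletons; only the edge
# structure matters for community/MST tests).
graph_from_edges <- function(n, u, v) {
  ed <- data.frame(u = as.integer(u), v = as.integer(v))
  ed$shared <- as.list(seq_len(nrow(ed)))
  structure(
    list(nodes = as.list(seq_len(n)), node_bin = seq_len(n), edges = ed,
         attrs = list(), n_rows = n),
    class = "mapper_graph"
  )
}

# Erdos-Renyi style random test graph (upper-triangle coin flips).
random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n) < p, n)
  m[lower.tri(m, diag = TRUE)] <- FALSE
  idx <- which(m, arr.ind = TRUE)
  graph_from_edges(n, idx[, 1], idx[, 2])
}

# Exhaustive modularity maximum by enumerating every set partition of the
# nodes (restricted growth strings). Feasible for n <= 10.
enumerate_max_modularity <- function(graph) {
  n <- length(graph$nodes)
  u <- graph$edges$u; v <- graph$edges$v
  m <- length(u)
  deg <- tabulate(c(u, v), nbins = n)
  qof <- function(memb) {
    d_c <- tapply(deg, memb, sum)
    sum(memb[u] == memb[v]) / m - sum((d_c / (2 * m))^2)
  }
  best <- -Inf
  best_part <- NULL
  a <- integer(n)  # restricted growth string
  recurse <- function(i, maxlab) {
    if (i > n) {
      q <- qof(a[1:n])
      if (q > best) {
        best <<- q
        best_part <<- a[1:n]
      }
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1)) {
      a[i] <<- lab
      recurse(i + 1, max(maxlab, lab))
    }
  }
  recurse(1, 0)
  list(modularity = best, membership = best_part)
}

# Exhaustive minimum spanning tree weight: try every (n-1)-subset of
# edges, keep acyclic spanning ones. Feasible for small graphs.
enumerate_mst_weight <- function(n, u, v, w) {
  conn_comp <- function(uu, vv) {
    lab <- seq_len(n)
    repeat {
      changed <- FALSE
      for (e in seq_along(uu)) {
        a <- lab[uu[e]]; b <- lab[vv[e]]
        if (a != b) {
          lab[lab == max(a, b)] <- min(a, b)
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    lab
  }
  comp_all <- conn_comp(u, v)
  n_comp <- length(unique(comp_all))
  k <- n - n_comp  # forest edge count
  if (k == 0) return(0)
  # k edges reach n_comp components only if every edge merges two
  # components, so the component-count test alone certifies a spanning
  # forest.
  best <- Inf
  for (sel in utils::combn(length(u), k, simplify = FALSE)) {
    lab <- conn_comp(u[sel], v[sel])
    if (length(unique(lab)) == n_comp) best <- min(best, sum(w[sel]))
  }
  best
}

# Exact HMM sequence likelihood by summing over every hidden state path.
enumerate_loglik <- function(params, X) {
  K <- params$K; Tn <- nrow(X)
  logB <- phenotraj:::arhmm_log_emissions(params, X)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lps <- apply(paths, 1, function(z) {
    lp <- log(params$pi[z[1]]) + logB[1, z[1]]
    if (Tn > 1) {
      for (t in 2:Tn) lp <- lp + log(params$A[z[t - 1], z[t]]) + logB[t, z[t]]
    }
    lp
  })
  mx <- max(lps)
  mx + log(sum(exp(lps - mx)))
}

# Log-probability of one specific state path (for Viterbi optimality).
path_logprob <- function(params, X, z) {
  logB <- phenotraj:::arhmm_log_emissions(params, X)
  lp <- log(params$pi[z[1]]) + logB[1, z[1]]
  if (nrow(X) > 1) {
    for (t in 2:nrow(X)) lp <- lp + log(params$A[z[t - 1], z[t]]) + logB[t, z[t]]
  }
  lp
}

# Small deterministic two-state AR-HMM used in several tests.
toy_arhmm <- function(sep = 5, sd = 0.5, phi = 0.2) {
  arhmm_params(
    pi = c(0.5, 0.5),
    A = matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE),
    c = matrix(c(0, 0, sep, sep), 2, byrow = TRUE) * (1 - phi),
    Phi = rep(list(diag(phi, 2)), 2),
    sigma2 = matrix(sd^2, 2, 2),
    mu0 = matrix(c(0, 0, sep, sep), 2, byrow = TRUE),
    sigma02 = matrix(sd^2, 2, 2)
  )
}

# Tiny cohort CSV on disk; returns the path.
write_cohort_csv <- function(n_subjects, seed, dir = tempdir()) {
  tab <- suppressMessages(generate_mosaic_like_cohort(n_subjects, seed = seed))
  path <- file.path(dir, sprintf("cohort_%d_%d.csv", n_subjects, seed))
  write_observations(tab, path)
  path
}

cohort_schema <- function() {
  default_schema(c("age", "smoking", "hba1c", "bmi", "sbp", "totchol",
                   "trigl"))
}
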