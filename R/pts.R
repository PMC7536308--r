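#' Generate one bootstrapped pseudo-time-series
#'
#' Draws a uniform subsample of encounters without replacement, builds the
#' complete weighted graph over the subsample under the chosen metric,
#' takes its minimum spanning tree (deterministic tie-breaks), draws a
#' start uniformly among the sampled label-0 rows (no staging event) and
#' an end among the label-1 rows, and returns the unique start-to-end path
#' in the tree. The path orders cross-sectional encounters from a
#' disease-free state to a diseased one — a pseudo-time-series.
#'
#' @param table an `observation_table` (feature columns are used as-is;
#'   normalise first if desired).
#' @param metric distance metric, `"cosine"` (default) or `"euclidean"`.
#' @param sample_size subsample size; default `min(200, nrow(table))`.
#' @param rng_seed integer seed; the caller's RNG state is untouched.
#' @param max_retries resamples allowed when a draw misses a label class.
#' @return a `pseudo_time_series`: list with `row_indices` (ordered row
#'   ids; first has label 0, last label 1), `start_label`, `end_label`,
#'   `sample` (the drawn row ids) and `seed`.
#' @export
generate_single_pts <- function(table, metric = c("cosine", "euclidean"),
                                sample_size = NULL, rng_seed = 1L,
                                max_retries = 20L) {
  metric <- match.arg(metric)
  n <- nrow(table)
  if (is.null(sample_size)) sample_size <- min(200L, n)
  if (sample_size > n) stopf("generate_single_pts: sample_size exceeds table size")
  if (sample_size < 2) stopf("generate_single_pts: sample_size must be >= 2")
  X <- feature_matrix(table)
  with_local_seed(rng_seed, {
    rows <- NULL
    for (try in seq_len(max_retries)) {
      cand <- sort(sample.int(n, sample_size))
      if (any(table$label[cand] == 0L) && any(table$label[cand] == 1L)) {
        rows <- cand
        break
      }
    }
    if (is.null(rows)) {
      stopf("generate_single_pts: no subsample with both label classes after %d tries",
            max_retries)
    }
    D <- pairwise_distance(X[rows, , drop = FALSE], metric)
    m <- length(rows)
    pairs <- combn(m, 2)
    u <- pairs[1, ]; v <- pairs[2, ]
    w <- D[cbind(u, v)]
    picked <- kruskal_edges(m, u, v, w, early_stop_n = m - 1L)
    adj <- forest_adjacency(m, u[picked], v[picked])
    lab <- table$label[rows]
    starts <- which(lab == 0L)
    ends <- which(lab == 1L)
    start <- starts[sample.int(length(starts), 1)]
    end <- ends[sample.int(length(ends), 1)]
    path <- tree_path(adj, start, end)
    structure(
      list(row_indices = rows[path], start_label = 0L, end_label = 1L,
           sample = rows, seed = as.integer(rng_seed)),
      class = "pseudo_time_series"
    )
  })
}

#' @export
print.pseudo_time_series <- function(x, ...) {
  cat(sprintf("pseudo_time_series: %d steps (rows %d .. %d), sample of %d, seed %d\n",
              length(x$row_indices), x$row_indices[1],
              x$row_indices[length(x$row_indices)], length(x$sample), x$seed))
  invisible(x)
}

#' Generate an ensemble of pseudo-time-series
#'
#' Repeats the resampling procedure `B` times with per-iteration seeds
#' `base_seed + i`, `i = 0 .. B-1`, so `B = 1` reproduces
#' [generate_single_pts()] at `base_seed` and the whole ensemble is
#' reproducible from `base_seed` alone. Iterations whose resamples
#' exhaust the retry budget are skipped and counted.
#'
#' @inheritParams generate_single_pts
#' @param B number of series (default 1000).
#' @param base_seed integer base seed.
#' @return a `pts_ensemble`: list of `pseudo_time_series` with attributes
#'   `base_seed`, `seeds` and `n_failed`.
#' @export
generate_pts_ensemble <- function(table, metric = c("cosine", "euclidean"),
                                  sample_size = NULL, B = 1000L,
                                  base_seed = 1L) {
  metric <- match.arg(metric)
  if (B < 1) stopf("generate_pts_ensemble: B must be >= 1")
  out <- vector("list", B)
  seeds <- base_seed + seq_len(B) - 1L
  failed <- 0L
  for (i in seq_len(B)) {
    res <- tryCatch(
      generate_single_pts(table, metric, sample_size, rng_seed = seeds[i]),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- failed + 1L
      out[[i]] <- NULL
    } else {
      out[[i]] <- res
    }
  }
  out <- Filter(Negate(is.null), out)
  if (length(out) == 0) {
    stopf("generate_pts_ensemble: all %d iterations failed", B)
  }
  if (failed > 0) {
    pt_log("pts", sprintf("%d of %d iterations skipped (label class missing)",
                          failed, B))
  }
  pt_log("pts", sprintf("generated %d pseudo-time-series (base seed %d)",
                        length(out), base_seed))
  structure(out, class = "pts_ensemble", base_seed = base_seed,
            seeds = seeds, n_failed = failed)
}

#' Export a pseudo-time-series ensemble
#'
#' Writes one CSV with columns `series_id`, `step`, `row_index` and, when
#' `manifest_path` is given, a JSON manifest with the base seed and
#' per-iteration seeds.
#'
#' @param ensemble a `pts_ensemble`.
#' @param path CSV output path.
#' @param manifest_path optional JSON manifest path.
#' @return invisibly, `path`.
#' @export
write_pts_csv <- function(ensemble, path, manifest_path = NULL) {
  rows <- do.call(rbind, lapply(seq_along(ensemble), function(i) {
    idx <- ensemble[[i]]$row_indices
    data.frame(series_id = i, step = seq_along(idx), row_index = idx)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(
      list(base_seed = attr(ensemble, "base_seed"),
           seeds = attr(ensemble, "seeds"),
           n_series = length(ensemble),
           n_failed = attr(ensemble, "n_failed")),
      manifest_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Convert a pseudo-time-series ensemble to model sequences
#'
#' Each series becomes one observation sequence (the feature vectors of
#' its rows, in path order), ready for [em_fit()].
#'
#' @param ensemble a `pts_ensemble`.
#' @param table the `observation_table` the series index into.
#' @return a `state_sequences` object (no true states).
#' @export
pts_to_sequences <- function(ensemble, table) {
  X <- feature_matrix(table)
  seqs <- lapply(ensemble, function(s) {
    list(X = X[s$row_indices, , drop = FALSE], states = NULL)
  })
  structure(seqs, class = "state_sequences")
}
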