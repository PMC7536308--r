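#' Construct an observation table
#'
#' An observation table holds one row per clinical encounter: a subject
#' identifier, time since the subject's first visit in days, a binary
#' disease-stage label (1 = the staging event, e.g. a microvascular
#' complication, is present) and a fixed-order vector of clinical features.
#' Rows are sorted by `(subject_id, time_days)` and receive stable 1-based
#' row ids that all downstream member sets refer to.
#'
#' @param subject_id character or factor, one entry per encounter.
#' @param time_days non-negative numeric, days since the subject's first
#'   visit; each subject's earliest encounter must sit at 0.
#' @param label integer in \{0, 1\}.
#' @param features data frame or matrix of numeric features (one column per
#'   feature, named).
#' @return an `observation_table`: a data frame with columns `row_id`,
#'   `subject_id`, `time_days`, `label` and one column per feature, plus a
#'   `feature_names` attribute.
#' @export
observation_table <- function(subject_id, time_days, label, features) {
  features <- as.data.frame(features)
  n <- length(subject_id)
  if (nrow(features) != n || length(time_days) != n || length(label) != n) {
    stopf("observation_table: all inputs must describe the same %d rows", n)
  }
  if (is.null(names(features)) || any(!nzchar(names(features)))) {
    stopf("observation_table: features must be named")
  }
  time_days <- as.numeric(time_days)
  label <- as.integer(label)
  if (any(!is.finite(time_days)) || any(time_days < 0)) {
    stopf("observation_table: time_days must be finite and >= 0")
  }
  if (!all(label %in% c(0L, 1L))) {
    stopf("observation_table: label must be 0 or 1")
  }
  tab <- data.frame(
    subject_id = as.character(subject_id),
    time_days = time_days,
    label = label,
    features,
    stringsAsFactors = FALSE,
    check.names = FALSE
  )
  ord <- order(tab$subject_id, tab$time_days)
  tab <- tab[ord, , drop = FALSE]
  first_time <- tapply(tab$time_days, tab$subject_id, min)
  if (any(first_time != 0)) {
    stopf(
      "observation_table: first encounter of subject(s) %s is not at time 0",
      paste(names(first_time)[first_time != 0][1:min(3, sum(first_time != 0))],
            collapse = ", ")
    )
  }
  tab <- cbind(row_id = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  attr(tab, "feature_names") <- names(features)
  class(tab) <- c("observation_table", "data.frame")
  tab
}

#' Feature names of an observation table
#' @param table an `observation_table`.
#' @return character vector of feature names, in column order.
#' @export
feature_names <- function(table) attr(table, "feature_names")

#' Feature matrix of an observation table
#' @param table an `observation_table`.
#' @return numeric matrix, one row per encounter, columns in feature order.
#' @export
feature_matrix <- function(table) {
  as.matrix(table[, feature_names(table), drop = FALSE])
}

#' @export
print.observation_table <- function(x, ...) {
  cat(sprintf(
    "observation_table: %d encounters, %d subjects, %d features (%s)\n",
    nrow(x), length(unique(x$subject_id)), length(feature_names(x)),
    paste(feature_names(x), collapse = ", ")
  ))
  cat(sprintf(
    "  label prevalence: %.3f; follow-up span: %.0f days\n",
    mean(x$label), max(x$time_days)
  ))
  invisible(x)
}

#' Load encounters from a CSV file
#'
#' Reads a header CSV and maps its columns to the observation-table schema.
#' Rows with any missing feature value are dropped (and counted in the log);
#' rows are sorted by `(subject, time)` before row ids are assigned, so the
#' ids are stable regardless of the file's row order. Duplicate
#' `(subject, time)` rows are retained and logged.
#'
#' @param path CSV file path.
#' @param schema named list with entries `subject_col`, `time_col`,
#'   `label_col` and `feature_cols` (character vector).
#' @return an [observation_table].
#' @export
load_observations <- function(path, schema) {
  required <- c("subject_col", "time_col", "label_col", "feature_cols")
  missing_keys <- setdiff(required, names(schema))
  if (length(missing_keys) > 0) {
    stopf("load_observations: schema lacks key(s): %s",
          paste(missing_keys, collapse = ", "))
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(schema$subject_col, schema$time_col, schema$label_col,
              schema$feature_cols)
  absent <- setdiff(needed, names(raw))
  if (length(absent) > 0) {
    stopf("load_observations: column(s) missing from %s: %s",
          path, paste(absent, collapse = ", "))
  }
  feats <- raw[, schema$feature_cols, drop = FALSE]
  for (cn in names(feats)) {
    col <- feats[[cn]]
    if (!is.numeric(col)) {
      parsed <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(parsed) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad) > 0) {
        stopf("load_observations: non-numeric value in feature '%s' at data row %d",
              cn, bad[1])
      }
      feats[[cn]] <- parsed
    }
  }
  complete <- stats::complete.cases(feats)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    pt_log("load", sprintf("dropped %d row(s) with missing feature values",
                           n_dropped))
  }
  keep <- which(complete)
  tab <- observation_table(
    subject_id = raw[[schema$subject_col]][keep],
    time_days = raw[[schema$time_col]][keep],
    label = raw[[schema$label_col]][keep],
    features = feats[keep, , drop = FALSE]
  )
  dup <- duplicated(tab[, c("subject_id", "time_days")])
  if (any(dup)) {
    pt_log("load", sprintf("retained %d duplicate (subject, time) row(s)",
                           sum(dup)))
  }
  pt_log("load", sprintf("%s: %d encounters, %d subjects, %d features",
                         path, nrow(tab), length(unique(tab$subject_id)),
                         length(feature_names(tab))))
  tab
}

#' Write an observation table to CSV
#'
#' Inverse of [load_observations()] with the identity schema: columns are
#' written as `subject_id`, `time_days`, `label` and the feature names.
#'
#' @param table an `observation_table`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_observations <- function(table, path) {
  out <- as.data.frame(table)[, c("subject_id", "time_days", "label",
                                  feature_names(table)), drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Identity schema for files written by [write_observations()]
#' @param feature_cols character vector of feature column names.
#' @return a schema list for [load_observations()].
#' @export
default_schema <- function(feature_cols) {
  list(subject_col = "subject_id", time_col = "time_days",
       label_col = "label", feature_cols = feature_cols)
}

#' Normalise features to a symmetric -1..+1 scale
#'
#' Each feature is rescaled by `x' = 2 (x - min) / (max - min) - 1`, so its
#' observed minimum maps to -1 and maximum to +1. Binary 0/1 features
#' (e.g. smoking habit) fall out of the same formula as \{-1, +1\}.
#' Constant features cannot be rescaled and are passed through at 0.
#' When a previously computed `spec` is supplied it is applied unchanged;
#' out-of-range inputs then map outside `[-1, 1]`, which is permitted.
#'
#' @param table an `observation_table`.
#' @param spec optional normalisation spec from a previous call.
#' @return list with elements `table` (normalised copy) and `spec`
#'   (a `normalization_spec`: per-feature `min`, `max`, `method`).
#' @export
normalize_features <- function(table, spec = NULL) {
  fn <- feature_names(table)
  X <- feature_matrix(table)
  if (is.null(spec)) {
    spec <- list(
      min = apply(X, 2, min),
      max = apply(X, 2, max),
      method = "minmax-symmetric"
    )
    class(spec) <- "normalization_spec"
    const <- spec$max == spec$min
    if (any(const)) {
      pt_log("normalize", sprintf("constant feature(s) passed through at 0: %s",
                                  paste(fn[const], collapse = ", ")))
    }
  }
  if (any(spec$max < spec$min)) stopf("normalize_features: max < min in spec")
  out <- table
  for (j in seq_along(fn)) {
    rng <- spec$max[j] - spec$min[j]
    out[[fn[j]]] <- if (rng == 0) {
      rep(0, nrow(table))
    } else {
      2 * (X[, j] - spec$min[j]) / rng - 1
    }
  }
  pt_log("normalize", sprintf("%d features rescaled to [-1, 1]", length(fn)))
  list(table = out, spec = spec)
}

#' Undo a -1..+1 normalisation
#'
#' @param table a normalised `observation_table`.
#' @param spec the `normalization_spec` used to normalise it.
#' @return an `observation_table` on the original scale; constant features
#'   are restored to their recorded constant value.
#' @export
denormalize_features <- function(table, spec) {
  fn <- feature_names(table)
  out <- table
  for (j in seq_along(fn)) {
    rng <- spec$max[j] - spec$min[j]
    out[[fn[j]]] <- if (rng == 0) {
      rep(spec$min[j], nrow(table))
    } else {
      (table[[fn[j]]] + 1) / 2 * rng + spec$min[j]
    }
  }
  out
}

#' Collapse consecutive duplicates in a node sequence
#'
#' A subject may stay in the same network node over several consecutive
#' follow-ups; mined trajectories record only the sequence of nodes, so
#' runs of the same node are collapsed to a single occurrence.
#' Non-consecutive repeats are retained and relative order is preserved.
#'
#' @param seq vector of node ids (possibly empty).
#' @return the compressed vector.
#' @examples
#' compress_sequence(c(41, 41, 42, 42, 42, 41)) # 41 42 41
#' @export
compress_sequence <- function(seq) {
  if (length(seq) == 0) return(seq)
  seq[c(TRUE, seq[-1] != seq[-length(seq)])]
}
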