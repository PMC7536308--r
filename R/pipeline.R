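#' Read a flat key-value run configuration
#'
#' Plain text, one `key = value` pair per line; `#` starts a comment.
#' `feature_cols` may be a comma-separated list. Values that parse as
#' numbers are converted.
#'
#' @param path config file path.
#' @return named list of settings.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stopf("read_run_config: malformed line '%s'", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (grepl(",", val)) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    }
    num <- suppressWarnings(as.numeric(val))
    if (length(num) == length(val) && !anyNA(num)) val <- num
    cfg[[key]] <- val
  }
  cfg
}

default_run_config <- function() {
  list(
    subject_col = "subject_id", time_col = "time_days", label_col = "label",
    metric = "cosine", lens_pair = "svd+linf",
    intervals = 7, gain = 0.6, clusters_per_bin = 8,
    weight_mode = "time",
    pts_sample_size = 200, pts_B = 1000, pts_seed = 17,
    arhmm_K = 5, arhmm_restarts = 5, arhmm_max_iter = 100, arhmm_tol = 1e-4,
    seed = 1
  )
}

#' Run the full temporal-phenotyping pipeline
#'
#' Executes the topology arm — normalise, build the network, detect
#' communities, extract time-weighted spanning-tree trajectories, map
#' encounters to nodes and assign subjects — and the pseudo-time arm —
#' bootstrap a pseudo-time-series ensemble and fit the AR-HMM. All
#' artifacts (graph JSON/GraphML, trajectory JSON, assignment CSV,
#' pseudo-time-series CSV, fitted model JSON) and a manifest with every
#' seed and parameter are written to `out_dir`. A stage failure
#' propagates with the stage name and leaves a `FAILED` marker next to
#' any partial outputs.
#'
#' @param config named list (see [read_run_config()]) or a config file
#'   path. Required keys: `input` (CSV path), `feature_cols`, `out_dir`.
#' @return invisibly, a list with the main in-memory results (`graph`,
#'   `partition`, `mined`, `assignments`, `pts`, `arhmm`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  for (key in c("input", "feature_cols", "out_dir")) {
    if (is.null(cfg[[key]])) stopf("run_pipeline: config lacks required key '%s'", key)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  failed_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(failed_marker)) file.remove(failed_marker)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0(name, ": ", conditionMessage(e)), failed_marker)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  table <- stage("load", load_observations(cfg$input, list(
    subject_col = cfg$subject_col, time_col = cfg$time_col,
    label_col = cfg$label_col, feature_cols = cfg$feature_cols
  )))
  norm <- stage("normalize", normalize_features(table))
  ntab <- norm$table
  X <- feature_matrix(ntab)

  mcfg <- mapper_config(metric = cfg$metric, lens_pair = cfg$lens_pair,
                        num_intervals = cfg$intervals, gain = cfg$gain,
                        clusters_per_bin = cfg$clusters_per_bin,
                        random_seed = cfg$seed)
  graph <- stage("mapper", build_mapper(X, mcfg))
  graph <- enrich_nodes(graph, ntab$time_days, "mean", name = "mean_time")
  partition <- stage("communities", optimal_communities(graph))
  graph$attrs$community_id <- partition$membership

  mined <- stage("trajectories", mine_trajectories(
    graph, time = ntab$time_days, first = ntab$time_days == 0,
    weights = if (identical(cfg$weight_mode, "index")) "index" else "time",
    partition = partition))
  weights <- if (identical(cfg$weight_mode, "index")) index_weights(graph) else
    edge_time_weights(graph, ntab$time_days)
  individuals <- stage("assignment",
                       map_observations_to_nodes(graph, ntab, graph$D))
  assignments <- stage("assignment", assign_subjects(individuals, mined))

  write_mapper_json(graph, file.path(cfg$out_dir, "graph.json"))
  write_mapper_graphml(graph, file.path(cfg$out_dir, "graph.graphml"),
                       weights = weights)
  write_trajectories_json(mined, assignments,
                          file.path(cfg$out_dir, "trajectories.json"),
                          csv_path = file.path(cfg$out_dir, "assignments.csv"))

  pts <- stage("pts", generate_pts_ensemble(
    ntab, metric = cfg$metric,
    sample_size = min(cfg$pts_sample_size, nrow(ntab)),
    B = cfg$pts_B, base_seed = cfg$pts_seed))
  write_pts_csv(pts, file.path(cfg$out_dir, "pts.csv"),
                manifest_path = file.path(cfg$out_dir, "pts_manifest.json"))
  fit <- stage("arhmm", em_fit(pts_to_sequences(pts, ntab), K = cfg$arhmm_K,
                               max_iter = cfg$arhmm_max_iter,
                               tol = cfg$arhmm_tol,
                               n_restarts = cfg$arhmm_restarts,
                               seed = cfg$seed))
  arhmm_params_to_json(fit$params, file.path(cfg$out_dir, "arhmm.json"))

  manifest <- cfg
  manifest$n_rows <- nrow(table)
  manifest$n_subjects <- length(unique(table$subject_id))
  manifest$n_nodes <- n_nodes(graph)
  manifest$n_edges <- nrow(graph$edges)
  manifest$n_trajectories <- length(mined)
  manifest$modularity <- partition$modularity
  manifest$arhmm_loglik <- fit$loglik
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  pt_log("pipeline", sprintf("completed; artifacts in %s", cfg$out_dir))
  invisible(list(graph = graph, partition = partition, mined = mined,
                 assignments = assignments, pts = pts, arhmm = fit))
}
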