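#' Pipeline logging
#'
#' One line per pipeline stage, written to stderr and, when
#' `options(phenotraj.log_file = )` is set, appended to that file.
#'
#' @param stage short stage tag.
#' @param ... message parts, concatenated with `paste0()`.
#' @return invisibly, the formatted line.
#' @keywords internal
pt_log <- function(stage, ...) {
  line <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(line)
  log_file <- getOption("phenotraj.log_file", NULL)
  if (!is.null(log_file)) cat(line, "\n", file = log_file, append = TRUE)
  invisible(line)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic argmax: first index attaining the maximum.
which_max_first <- function(x) which.max(x)

stopf <- function(...) stop(sprintf(...), call. = FALSE)
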