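#' Pairwise distance matrix
#'
#' Cosine distance `d(i, j) = 1 - x_i . x_j / (|x_i| |x_j|)` or Euclidean
#' distance between the rows of a feature matrix.
#'
#' @param X numeric matrix, one row per observation.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return symmetric matrix with zero diagonal.
#' @export
pairwise_distance <- function(X, metric = c("cosine", "euclidean")) {
  metric <- match.arg(metric)
  X <- as.matrix(X)
  if (metric == "euclidean") {
    D <- as.matrix(dist(X, method = "euclidean"))
  } else {
    nrm <- sqrt(rowSums(X^2))
    zero <- which(nrm == 0)
    if (length(zero) > 0) {
      stopf("pairwise_distance: zero-norm row(s) under cosine metric: %s",
            paste(zero[1:min(5, length(zero))], collapse = ", "))
    }
    S <- tcrossprod(X / nrm)
    D <- 1 - pmin(pmax(S, -1), 1)
    D[D < 0] <- 0
  }
  diag(D) <- 0
  dimnames(D) <- NULL
  D
}

#' L-infinity centrality lens
#'
#' Assigns to each point its distance to the point most distant from it:
#' the row maximum of the distance matrix. Points on the data's outskirts
#' get large values, central points small ones.
#'
#' @param D symmetric distance matrix.
#' @return numeric vector, one value per row; 0 for a single point.
#' @export
lens_linf_centrality <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) == 1) return(0)
  apply(D, 1, max)
}

#' First-singular-vector lens
#'
#' Projects each observation onto the first right singular vector of the
#' (by default column-centred) feature matrix — the direction of largest
#' variance. The vector's sign is fixed so that its largest-magnitude
#' component is positive, making the orientation reproducible.
#'
#' @param X numeric matrix, one row per observation.
#' @param center centre columns before the decomposition (default `TRUE`).
#' @return numeric vector of projections, one per row.
#' @export
lens_svd <- function(X, center = TRUE) {
  X <- as.matrix(X)
  Xc <- if (center) scale(X, center = TRUE, scale = FALSE) else X
  if (all(abs(Xc) < .Machine$double.eps * 100)) {
    warning("lens_svd: all rows identical after centring; lens is all-zero")
    return(rep(0, nrow(X)))
  }
  sv <- svd(Xc, nu = 0, nv = 1)
  v1 <- sv$v[, 1]
  if (v1[which.max(abs(v1))] < 0) v1 <- -v1
  drop(Xc %*% v1)
}
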