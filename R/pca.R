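#' Mean-center the columns of a matrix
#'
#' @param x Numeric matrix (n x p), finite entries.
#' @return List with `centered` (same shape, each column mean 0) and `means`
#'   (length-p column means).
#' @export
center_columns <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("matrix must be numeric and finite")
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("matrix must have at least one row and one column")
  means <- colMeans(x)
  list(centered = sweep(x, 2L, means, "-"), means = means)
}

#' Principal component scores via covariance eigendecomposition
#'
#' Computes PC scores of the rows of `x` as projections of the column-centered
#' matrix onto the leading eigenvectors of the sample covariance matrix
#' (divisor `n - 1`). Variables are *not* scaled to unit variance: on MFI
#' data the magnitude of the signal is itself informative, so covariance PCA
#' rather than correlation PCA is used throughout.
#'
#' The decomposition is deterministic: components are ordered by descending
#' eigenvalue and each component's loading vector is oriented so that its
#' entry of largest absolute value is non-negative (ties broken by lowest
#' variable index). When `p > n` the eigendecomposition is carried out on the
#' n x n Gram matrix, which has the same non-zero spectrum. Components whose
#' eigenvalue is numerically zero get all-zero scores; if the whole matrix
#' has (numerically) zero variance the result is flagged degenerate with
#' zero scores and zero explained fractions.
#'
#' @param x Numeric matrix, n >= 2 rows (observations) by p columns
#'   (variables); finite entries.
#' @param n_components Number of components, `1 <= n_components <= min(n-1, p)`.
#' @return An object of class `sab_scores`: list with `observation_ids`,
#'   `scores` (n x n_components, columns `PC1..PCk`), `explained_fraction`,
#'   `n_components`, `degenerate`, `total_variance`, `column_means`.
#' @export
pca_scores <- function(x, n_components = 2L) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("matrix must be numeric and finite")
  n <- nrow(x); p <- ncol(x)
  if (n < 2L) stop("insufficient observations: PCA needs at least 2 rows")
  n_components <- as.integer(n_components)
  if (is.na(n_components) || n_components < 1L || n_components > min(n - 1L, p))
    stop(sprintf("n_components must be in [1, %d]", min(n - 1L, p)))
  ctr <- center_columns(x)
  xc <- ctr$centered
  total <- sum(xc * xc) / (n - 1)
  k <- n_components
  scale_ref <- max(1, max(abs(x)))^2
  degenerate <- total <= 1e-24 * scale_ref
  scores <- matrix(0, n, k)
  lambda <- rep(0, k)
  if (!degenerate) {
    tol <- total * 1e-12
    if (p <= n) {
      eg <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
      lambda <- pmax(eg$values[seq_len(k)], 0)
      for (j in seq_len(k)) {
        if (lambda[j] > tol) {
          v <- eg$vectors[, j]
          if (v[which.max(abs(v))] < 0) v <- -v
          scores[, j] <- xc %*% v
        }
      }
    } else {
      eg <- eigen(tcrossprod(xc) / (n - 1), symmetric = TRUE)
      lambda <- pmax(eg$values[seq_len(k)], 0)
      for (j in seq_len(k)) {
        if (lambda[j] > tol) {
          u <- eg$vectors[, j]
          # unit loading vector in variable space, for the sign convention
          v <- drop(crossprod(xc, u)) / sqrt(lambda[j] * (n - 1))
          s <- if (v[which.max(abs(v))] < 0) -1 else 1
          scores[, j] <- s * u * sqrt(lambda[j] * (n - 1))
        }
      }
    }
  }
  obs_ids <- rownames(x) %||% as.character(seq_len(n))
  dimnames(scores) <- list(obs_ids, paste0("PC", seq_len(k)))
  structure(
    list(observation_ids = obs_ids,
         scores = scores,
         explained_fraction = if (degenerate) rep(0, k) else lambda / total,
         n_components = k,
         degenerate = degenerate,
         total_variance = total,
         column_means = ctr$means),
    class = "sab_scores")
}

#' @export
print.sab_scores <- function(x, ...) {
  cat(sprintf("<sab_scores> %d observations x %d components%s\n",
              nrow(x$scores), x$n_components,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  if (!x$degenerate)
    cat("explained variance fractions:",
        paste(sprintf("%.3f", x$explained_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Euclidean distance between two score rows
#'
#' @param a,b Numeric vectors of equal length (>= 1), finite.
#' @return The l2 distance, a non-negative scalar.
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop("score rows must have the same length")
  if (length(a) < 1L) stop("score rows must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("score rows must be finite")
  sqrt(sum((a - b)^2))
}

#' Export PC scores as a table
#'
#' @param scores A `sab_scores` object.
#' @return Data frame with `observation_id` and one column per component.
#' @export
scores_table <- function(scores) {
  stopifnot(inherits(scores, "sab_scores"))
  data.frame(observation_id = scores$observation_ids,
             as.data.frame(scores$scores, row.names = NULL),
             stringsAsFactors = FALSE, check.names = FALSE)
}
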