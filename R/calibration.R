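#' ROC curve, AUC and optimal threshold for distance ratios
#'
#' Builds the ROC over labelled distance-ratio values. The AUC is computed
#' through the Mann-Whitney identity, `P(pos > neg) + 0.5 P(pos = neg)` over
#' all positive/negative pairs. Candidate thresholds are the midpoints
#' between adjacent distinct pooled scores plus `-Inf`/`+Inf` endpoints; at a
#' threshold `t`, sensitivity is the fraction of positives `>= t` and
#' specificity the fraction of negatives `< t` (matching the inclusive
#' flagging rule). The optimal threshold maximizes Youden's
#' `J = sensitivity + specificity - 1`; ties go to the larger threshold
#' (fewer flags).
#'
#' Infinite scores (the degenerate-history sentinel) are mapped to a value
#' above all finite scores before the curve is built.
#'
#' @param neg Distance ratios of the negative class (no clinically relevant
#'   change).
#' @param pos Distance ratios of the positive class (known pattern change).
#' @return An object of class `sab_roc`: list with `points` (data frame
#'   `threshold, sensitivity, specificity`), `auc`, `optimal_threshold` and
#'   `youden_j_at_optimum`.
#' @export
roc_auc <- function(neg, pos) {
  neg <- as.numeric(neg); pos <- as.numeric(pos)
  if (length(neg) == 0L || length(pos) == 0L)
    stop("both score lists must be non-empty")
  if (any(is.na(neg)) || any(is.na(pos)))
    stop("scores must not contain NA")
  finite <- c(neg[is.finite(neg)], pos[is.finite(pos)])
  cap <- if (length(finite) > 0L) max(finite) + 1 else 1
  neg[is.infinite(neg)] <- cap
  pos[is.infinite(pos)] <- cap
  # Mann-Whitney identity via midranks of the pooled sample
  pooled <- c(neg, pos)
  r <- rank(pooled)
  n_neg <- length(neg); n_pos <- length(pos)
  auc <- (sum(r[(n_neg + 1L):(n_neg + n_pos)]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  s <- sort(unique(pooled))
  thresholds <- c(-Inf, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- max(which(j == max(j)))  # ties -> larger threshold
  structure(
    list(points = data.frame(threshold = thresholds, sensitivity = sens,
                             specificity = spec),
         auc = auc,
         optimal_threshold = thresholds[best],
         youden_j_at_optimum = j[best]),
    class = "sab_roc")
}

#' @export
print.sab_roc <- function(x, ...) {
  cat(sprintf("<sab_roc> AUC = %.4f; optimal threshold = %.4g (Youden J = %.3f)\n",
              x$auc, x$optimal_threshold, x$youden_j_at_optimum))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midranks for ties. The two-sided p-value is
#' exact by enumeration of all group labelings when `length(a) * length(b)
#' <= max_exact` and there are no ties, and otherwise uses the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Non-empty numeric vectors.
#' @param max_exact Largest `n_a * n_b` for which the exact enumeration is
#'   used (default 400).
#' @return List with `U` (for sample `a`), `p_value` and `method`
#'   (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(a, b, max_exact = 400L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0L
  if (!has_ties && n_a * n_b <= max_exact) {
    # enumerate all C(n_a + n_b, n_a) assignments of ranks to group a
    combos <- combn(n_a + n_b, n_a)
    u_all <- colSums(matrix(r[combos], nrow = n_a)) - n_a * (n_a + 1) / 2
    mid <- n_a * n_b / 2
    p <- mean(abs(u_all - mid) >= abs(u - mid) - 1e-9)
    return(list(U = u, p_value = p, method = "exact"))
  }
  n <- n_a + n_b
  mu <- n_a * n_b / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0)
    return(list(U = u, p_value = 1, method = "normal_approx"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(U = u, p_value = min(1, 2 * pnorm(-abs(z))), method = "normal_approx")
}

#' Paired t-test with degenerate-difference handling
#'
#' Thin wrapper around [stats::t.test()] on the paired differences. When the
#' differences have zero variance the test statistic is undefined; the result
#' is then flagged degenerate instead of erroring.
#'
#' @param a,b Numeric vectors of equal length >= 2, paired in order.
#' @return List with `t`, `df`, `p_value` and `degenerate`.
#' @export
paired_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("paired samples must have equal length")
  if (length(a) < 2L) stop("paired test needs at least 2 pairs")
  d <- a - b
  if (sd(d) == 0)
    return(list(t = NA_real_, df = length(d) - 1L, p_value = NA_real_,
                degenerate = TRUE))
  res <- t.test(a, b, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, degenerate = FALSE)
}
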