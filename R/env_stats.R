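# Association statistics linking abundances to environmental variables
# and station groups: Spearman rank correlation with permutation (or
# exhaustive) p-values, and Welch's unequal-variance t-test.

#' Construct a statistical test result
#' @param method Method tag.
#' @param estimate Statistic value.
#' @param p_value Two-sided p-value in \[0, 1\].
#' @param n Sample count.
#' @param ... Further fields stored on the result.
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(method, estimate, p_value, n, ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, estimate = unname(estimate),
                 p_value = unname(p_value), n = n, ...),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g, n = %d\n",
              x$method, x$estimate, x$p_value, x$n))
  invisible(x)
}

# All permutations of 1..n as a matrix (n! rows); desk scale, n <= 7.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    m <- sub
    m[m >= k] <- m[m >= k] + 1L
    cbind(rep.int(k, nrow(m)), m, deparse.level = 0)
  }))
}

#' Spearman rank correlation with permutation p-value
#'
#' The correlation is computed on mid-ranks (average ranks for ties).
#' The two-sided p-value is obtained by permuting one vector: exhaustively
#' over all n! permutations when `exact` (default for n <= 7), otherwise
#' by `n_perm` random permutations with the add-one correction,
#' reproducible for a fixed seed. Station counts in transect surveys are
#' small, which is why a permutation null is used rather than the
#' large-sample approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither constant.
#' @param n_perm Number of random permutations (default 10000).
#' @param seed RNG seed for the random-permutation path.
#' @param exact Force (or forbid) exhaustive enumeration; `NULL` chooses
#'   exhaustive for n <= 7.
#' @return A [stat_result()] with the rank correlation as `estimate`.
#' @examples
#' spearman_test(1:6, (1:6)^3)$estimate
#' @export
spearman_test <- function(x, y, n_perm = 10000L, seed = NULL, exact = NULL) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L)
    stop("at least three paired observations are required")
  if (anyNA(x) || anyNA(y))
    stop("missing values are not supported")
  if (var(x) == 0 || var(y) == 0)
    stop("rank correlation is undefined for a constant vector")
  rho <- cor(x, y, method = "spearman")
  if (is.null(exact)) exact <- n <= 7L
  rx <- rank(x)
  ry <- rank(y)
  if (exact) {
    perm <- .permutations(n)
    rhos <- apply(perm, 1L, function(idx) cor(rx, ry[idx]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "spearman_exact"
  } else {
    n_perm <- .check_count(n_perm, "n_perm", min = 1L)
    if (!is.null(seed)) set.seed(seed)
    rhos <- replicate(n_perm, cor(rx, sample(ry)))
    p <- (1 + sum(abs(rhos) >= abs(rho) - 1e-12)) / (n_perm + 1)
    method <- "spearman_permutation"
  }
  stat_result(method, estimate = rho, p_value = p, n = n)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch t-test (Welch-Satterthwaite degrees of freedom) for a
#' difference in group means; chosen over the pooled-variance test
#' because oceanic station groups rarely share a variance.
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 values; at
#'   least one group must have nonzero variance.
#' @return A [stat_result()] with the t statistic as `estimate` and the
#'   Welch degrees of freedom in `df`.
#' @examples
#' welch_t(c(1, 2, 3), c(1, 2, 3))$p_value
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least two values")
  if (anyNA(group_a) || anyNA(group_b))
    stop("missing values are not supported")
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(stat_result("welch_t", estimate = 0, p_value = 1,
                         n = length(group_a) + length(group_b),
                         df = NA_real_))
    stop("both groups are constant; the Welch statistic is undefined")
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  stat_result("welch_t", estimate = tt$statistic, p_value = tt$p.value,
              n = length(group_a) + length(group_b),
              df = unname(tt$parameter))
}
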