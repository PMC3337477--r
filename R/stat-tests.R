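## Statistical primitives used by the extension and DMR callers. These are
## thin wrappers over the base-R tests that make degenerate inputs total:
## the callers run over thousands of windows, many with zero variance, and
## must always get a usable p-value back.

test_result <- function(statistic, df, p, degenerate = FALSE) {
  list(statistic = statistic, df = df, p = p, degenerate = degenerate)
}

#' Two-sample Student t-test (pooled variance)
#'
#' Two-sided equal-variance t-test with `df = nA + nB - 2`. Degenerate
#' inputs are mapped to definite p-values so filtering pipelines stay
#' total: a group with fewer than 2 values gives `p = 1`; both groups
#' constant gives `p = 1` if the constants agree and `p = 0` otherwise.
#'
#' @param group_a,group_b numeric vectors.
#' @return List with `statistic`, `df`, `p`, `degenerate`.
#' @export
student_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2)
    return(test_result(NA_real_, NA_real_, 1, degenerate = TRUE))
  pooled <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (pooled == 0) {
    p <- if (mean(group_a) == mean(group_b)) 1 else 0
    return(test_result(if (p == 1) 0 else Inf, na + nb - 2, p,
                       degenerate = TRUE))
  }
  fit <- t.test(group_a, group_b, var.equal = TRUE)
  test_result(unname(fit$statistic), unname(fit$parameter), fit$p.value)
}

#' Kruskal-Wallis rank-sum test
#'
#' H statistic with the midrank tie correction; p-value from the
#' chi-square approximation with `k - 1` degrees of freedom, or from a
#' Monte-Carlo permutation of group labels when `method = "permutation"`.
#' All observations identical gives `H = 0`, `p = 1`.
#'
#' @param groups list of numeric vectors (>= 2 groups, total N >= 3).
#' @param method `"chisq"` (default) or `"permutation"`.
#' @param n_perm permutations for `method = "permutation"`.
#' @return List with `statistic`, `df`, `p`, `degenerate`.
#' @export
kruskal_wallis <- function(groups, method = c("chisq", "permutation"),
                           n_perm = 2000) {
  method <- match.arg(method)
  stopifnot(length(groups) >= 2)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  stopifnot(length(x) >= 3)
  if (length(unique(x)) == 1L)
    return(test_result(0, length(groups) - 1, 1, degenerate = TRUE))
  fit <- kruskal.test(x, g)
  h <- unname(fit$statistic)
  if (method == "chisq")
    return(test_result(h, unname(fit$parameter), fit$p.value))
  exceed <- vapply(seq_len(n_perm), function(i) {
    unname(kruskal.test(x, sample(g))$statistic) >= h
  }, logical(1))
  test_result(h, unname(fit$parameter), (1 + sum(exceed)) / (n_perm + 1))
}

#' Fisher's combination of independent p-values
#'
#' `X^2 = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2k` degrees of freedom. Zero p-values are clamped to the smallest
#' positive double with a warning.
#'
#' @param pvals p-values in (0, 1]; must be non-empty.
#' @return List with `statistic` (X^2), `df`, `p`.
#' @export
fisher_combine <- function(pvals) {
  if (length(pvals) == 0L) stop("fisher_combine: empty p-value list")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (any(pvals == 0)) {
    warning("zero p-value(s) clamped for Fisher combination")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  x2 <- -2 * sum(log(pvals))
  k <- length(pvals)
  test_result(x2, 2 * k, pchisq(x2, df = 2 * k, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment; input order preserved.
#'
#' @param pvals p-values in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}
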