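## Rank-based tests: Mann-Whitney U, Kruskal-Wallis with Dunn post-hoc,
## and the Shapiro-Wilk gate used to choose rank-based over parametric
## comparisons. Conventions (W offset, tie and continuity corrections,
## adjustment method) are always recorded in the returned object.

## Null distribution of the U statistic (no ties): P(U = u) for
## u = 0..na*nb, by counting size-na subsets of ranks 1..N with each
## rank-sum (dynamic programme over ranks).
.uDistribution <- function(na, nb) {
  N <- na + nb
  maxsum <- sum((N - na + 1):N)
  ## counts[k + 1, s + 1] = number of size-k subsets of ranks seen so far
  ## with rank-sum s
  counts <- matrix(0, nrow = na + 1L, ncol = maxsum + 1L)
  counts[1L, 1L] <- 1
  for (r in seq_len(N)) {
    kmax <- min(r, na)
    for (k in kmax:1) {
      s <- seq(0L, maxsum - r)
      counts[k + 1L, s + r + 1L] <- counts[k + 1L, s + r + 1L] +
        counts[k, s + 1L]
    }
  }
  offset <- na * (na + 1L) / 2L
  sums <- counts[na + 1L, ]
  u <- seq(0L, na * nb)
  p <- sums[u + offset + 1L]
  p / sum(p)
}

#' Mann-Whitney U test for two samples
#'
#' Rank-based two-sample location test. The statistic `W` follows the
#' rank-sum-minus-offset convention: the sum of (mid)ranks of `a` in the
#' pooled sample minus `n_a (n_a + 1) / 2`, so `W` ranges over
#' `0..n_a n_b` with null mean `n_a n_b / 2`. The two-sided p-value is
#' exact (enumeration of the null permutation distribution) when
#' `n_a + n_b <= 12` and there are no ties, otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' The convention and corrections applied are recorded in the result.
#'
#' @param a,b Numeric samples, each non-empty.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`, default) the
#'   exact path. The exact path requires tie-free data.
#' @param continuity Apply the continuity correction on the normal path
#'   (default `TRUE`).
#' @return An object of class `htest` with `statistic` (`W`), `p.value`,
#'   sample sizes in `parameter`, and `method` recording the path taken.
#'   When both samples are identical constants the result carries
#'   `p.value = 1` and a degenerate-data note.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # W = 0, exact p = 1/3
#' @export
mannWhitneyU <- function(a, b, exact = NULL, continuity = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 1L, length(b) >= 1L,
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  W <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(pooled)
  has_ties <- any(ties > 1L)
  if (is.null(exact)) exact <- (N <= 12L) && !has_ties
  if (exact && has_ties) {
    warning("exact path unavailable with ties; using normal approximation")
    exact <- FALSE
  }
  mu <- na * nb / 2
  degenerate <- length(ties) == 1L
  if (degenerate) {
    method <- "Mann-Whitney U (degenerate: all values identical)"
    p <- 1
    note <- "degenerate data: all values identical across both samples"
  } else if (exact) {
    probs <- .uDistribution(na, nb)
    u <- seq(0L, na * nb)
    p <- min(1, sum(probs[abs(u - mu) >= abs(W - mu) - 1e-9]))
    method <- "Mann-Whitney U (exact enumeration)"
    note <- "W = rank sum of sample a minus n_a(n_a+1)/2; two-sided"
  } else {
    tiecorr <- sum(ties^3 - ties)
    sigma2 <- na * nb / 12 * ((N + 1) - tiecorr / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
      method <- "Mann-Whitney U (degenerate: zero variance)"
      note <- "degenerate data"
    } else {
      cc <- if (continuity) 0.5 else 0
      z <- (W - mu - sign(W - mu) * cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- sprintf(
        "Mann-Whitney U (normal approximation, tie correction%s)",
        if (continuity) ", continuity correction" else "")
      note <- "W = rank sum of sample a minus n_a(n_a+1)/2; two-sided"
    }
  }
  structure(list(
    statistic = c(W = W),
    parameter = c(n_a = na, n_b = nb),
    p.value = p,
    method = method,
    alternative = "two.sided",
    data.name = "a vs b",
    tie_correction = has_ties && !exact && !degenerate,
    exact = isTRUE(exact) && !degenerate,
    note = note
  ), class = "htest")
}

#' Kruskal-Wallis rank test for several samples
#'
#' Tests the equality of location across k groups using pooled midranks.
#' The statistic H carries the standard tie correction and is referred to a
#' chi-squared distribution with k - 1 degrees of freedom.
#'
#' @param values Numeric vector of observations, or a list of numeric
#'   group vectors (then `groups` is ignored).
#' @param groups Group labels parallel to `values`.
#' @return `htest` with `statistic` (H), `parameter` (df), `p.value`.
#' @examples
#' kruskalWallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))  # H = 7.2
#' @export
kruskalWallis <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(length(values) == length(groups), all(is.finite(values)))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(g) == 0L)) stop("empty group", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  Rj <- tapply(r, g, sum)
  nj <- tabulate(g)
  H <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr <= 0) {
    H <- 0; p <- 1
  } else {
    H <- H / corr
    p <- pchisq(H, df = nlevels(g) - 1L, lower.tail = FALSE)
  }
  structure(list(
    statistic = c(H = H),
    parameter = c(df = nlevels(g) - 1L),
    p.value = p,
    method = "Kruskal-Wallis rank test (tie-corrected)",
    data.name = "values by groups",
    group_sizes = nj,
    tie_correction = any(ties > 1L)
  ), class = "htest")
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Pairwise z tests on mean pooled midranks following a Kruskal-Wallis
#' test, with the standard tie correction in the variance. Raw p-values
#' are adjusted for multiple comparisons; the adjustment method is
#' recorded in the output (default Bonferroni).
#'
#' @inheritParams kruskalWallis
#' @param method Adjustment: `"bonferroni"` (default), `"holm"` or
#'   `"none"`.
#' @return data.frame with one row per pair: `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adj`, plus attribute `adjustment`.
#' @export
dunnPosthoc <- function(values, groups = NULL,
                        method = c("bonferroni", "holm", "none")) {
  method <- match.arg(method)
  if (is.list(values)) {
    nm <- names(values)
    if (is.null(nm)) nm <- as.character(seq_along(values))
    groups <- rep(nm, lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(g) == 0L)) stop("empty group", call. = FALSE)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, g, mean)
  nj <- tabulate(g)
  names(nj) <- levels(g)
  ties <- table(values)
  tiesum <- sum(ties^3 - ties)
  pairs <- combn(levels(g), 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    ga <- pairs[1L, i]; gb <- pairs[2L, i]
    se2 <- (N * (N + 1) / 12 - tiesum / (12 * (N - 1))) *
      (1 / nj[[ga]] + 1 / nj[[gb]])
    z[i] <- if (se2 > 0) (rbar[[ga]] - rbar[[gb]]) / sqrt(se2) else 0
    p_raw[i] <- min(1, 2 * pnorm(-abs(z[i])))
  }
  out <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                    z = z, p_raw = p_raw,
                    p_adj = p.adjust(p_raw, method = method),
                    stringsAsFactors = FALSE)
  attr(out, "adjustment") <- method
  out
}

#' Shapiro-Wilk normality screen
#'
#' Normality gate used to decide between parametric and rank-based
#' comparisons in reports: Shapiro-Wilk W and p-value (Royston's
#' algorithm, via [stats::shapiro.test()]), with explicit range and
#' degeneracy checks.
#'
#' @param values Numeric vector, `3 <= n <= 5000`, not all equal.
#' @return `htest` from [stats::shapiro.test()].
#' @export
normalityScreen <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("normality screen requires 3 <= n <= 5000 finite values",
         call. = FALSE)
  if (diff(range(values)) == 0)
    stop("normality screen undefined for constant input", call. = FALSE)
  shapiro.test(values)
}
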