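# From-scratch nonparametric tests shared by every downstream module.
#
# All two-group and signed-rank tests use the same two-sided exact
# convention: the p-value is the null probability of an outcome at least
# as extreme as the observed one in |statistic - null mean|. Midranks are
# used wherever ties occur and large-sample variances carry the usual tie
# corrections.

#' Construct a test result record
#'
#' Uniform container returned by every hypothesis test in the package.
#'
#' @param statistic test statistic (U, W, H, Q, odds ratio or r).
#' @param p_value two-sided p-value in \[0, 1\].
#' @param method short label naming the test.
#' @param n_per_group integer vector of group sizes.
#' @param exact logical; `TRUE` when the p-value comes from full
#'   enumeration rather than a large-sample approximation.
#' @param degenerate logical; `TRUE` when the input carried no usable
#'   information (e.g. all paired differences zero) and the defined
#'   fallback `p = 1` was returned.
#'
#' @return An object of class `chemo_test`.
#' @keywords internal
new_test_result <- function(statistic, p_value, method, n_per_group,
                            exact, degenerate = FALSE) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1 + 1e-12))
  structure(
    list(
      statistic = as.numeric(statistic),
      p_value = min(as.numeric(p_value), 1),
      method = method,
      n_per_group = as.integer(n_per_group),
      exact = isTRUE(exact),
      degenerate = isTRUE(degenerate)
    ),
    class = "chemo_test"
  )
}

#' @export
print.chemo_test <- function(x, ...) {
  cat(x$method, "\n")
  cat("  statistic =", format(x$statistic), "  p =", format.pval(x$p_value),
      if (x$exact) "(exact)" else "(approximate)", "\n")
  cat("  n =", paste(x$n_per_group, collapse = ", "),
      if (x$degenerate) " [degenerate input]" else "", "\n")
  invisible(x)
}

#' @export
as.data.frame.chemo_test <- function(x, ...) {
  data.frame(
    method = x$method,
    statistic = x$statistic,
    p = x$p_value,
    exact = x$exact,
    degenerate = x$degenerate,
    n = paste(x$n_per_group, collapse = "/"),
    stringsAsFactors = FALSE
  )
}

#' Two-sided exact Fisher test for a 2x2 table
#'
#' Enumerates every table compatible with the observed margins and sums
#' the hypergeometric probabilities of those no more probable than the
#' observed table (relative tolerance 1e-12), the standard two-sided
#' definition. The statistic is the sample odds ratio `a*d / (b*c)`,
#' `Inf` when `b*c == 0` and the numerator is positive.
#'
#' @param a,b,c,d nonnegative integer cell counts; rows are the two
#'   strata (e.g. HPV-negative / HPV-positive), columns the two outcomes
#'   (induced / not induced).
#'
#' @return A `chemo_test` with the odds ratio and exact two-sided p.
#' @examples
#' fisher_exact_2x2(7, 1, 0, 3)  # p = 8/330, rounds to 0.02
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("all four cells must be nonnegative integers")
  if (sum(cells) == 0)
    stop("all four cells are zero: no table to test")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  odds <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  new_test_result(odds, min(p, 1), "Fisher exact test (2x2)",
                  c(r1, r2), exact = TRUE)
}

# Enumerate the exact two-sided Mann-Whitney p-value: all C(N, n)
# assignments of the pooled midranks to group 1, extremeness measured as
# |U - nm/2|.
.mw_exact_p <- function(ranks, n, u_obs) {
  N <- length(ranks)
  mu <- n * (N - n) / 2
  sums <- utils::combn(N, n, FUN = function(idx) sum(ranks[idx]))
  us <- sums - n * (n + 1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Two-sided test for a location difference between two unpaired groups.
#' Exact by complete enumeration of group assignments when the data are
#' untied and small enough; otherwise a normal approximation with
#' midranks, tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y numeric vectors, each nonempty.
#' @param exact_threshold use enumeration when both groups are at most
#'   this size (default 8). Enumeration is also used for unbalanced
#'   designs whenever `choose(n + m, min(n, m)) <= 20000` and there are
#'   no ties, so e.g. a 3-vs-13 comparison is exact.
#'
#' @return A `chemo_test`; the statistic is U for the first group.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact p = 2/6
#' @export
mann_whitney <- function(x, y, exact_threshold = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be nonempty")
  if (anyNA(c(x, y))) stop("missing values are not allowed")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  ties <- anyDuplicated(pooled) > 0
  small <- (n <= exact_threshold && m <= exact_threshold) ||
    choose(N, min(n, m)) <= 20000
  if (!ties && small) {
    p <- .mw_exact_p(r, n, u_obs)
    return(new_test_result(u_obs, p, "Mann-Whitney U test", c(n, m),
                           exact = TRUE))
  }
  tt <- table(pooled)
  tie_term <- sum(tt^3 - tt) / (N * (N - 1))
  sigma2 <- (n * m / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) {
    return(new_test_result(u_obs, 1, "Mann-Whitney U test", c(n, m),
                           exact = FALSE, degenerate = TRUE))
  }
  z <- max(0, abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-z))
  new_test_result(u_obs, p, "Mann-Whitney U test", c(n, m), exact = FALSE)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' before ranking; magnitude ties take midranks. Exact by enumeration of
#' all 2^n sign patterns when at most `exact_threshold` nonzero
#' differences remain, otherwise a tie-corrected normal approximation
#' with continuity correction. When every difference is zero the test is
#' degenerate and returns `p = 1` with the degenerate flag set (not an
#' error), so batch screens do not abort.
#'
#' @param paired_a,paired_b numeric vectors of equal length >= 2.
#' @param exact_threshold largest number of nonzero differences for
#'   which the 2^n enumeration is used (default 12).
#'
#' @return A `chemo_test`; the statistic is W, the positive-rank sum.
#' @examples
#' wilcoxon_signed_rank(6:10, rep(5, 5))  # diffs 1..5, exact p = 2/32
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b, exact_threshold = 12) {
  a <- as.numeric(paired_a); b <- as.numeric(paired_b)
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  if (anyNA(c(a, b))) stop("missing values are not allowed")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(new_test_result(0, 1, "Wilcoxon signed-rank test", length(a),
                           exact = TRUE, degenerate = TRUE))
  }
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_threshold) {
    # all sign patterns; each magnitude keeps its midrank
    patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- patterns %*% r
    p <- mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
    return(new_test_result(w_obs, p, "Wilcoxon signed-rank test", length(a),
                           exact = TRUE))
  }
  tt <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tt^3 - tt) / 48
  if (sigma2 <= 0) {
    return(new_test_result(w_obs, 1, "Wilcoxon signed-rank test", length(a),
                           exact = FALSE, degenerate = TRUE))
  }
  z <- max(0, abs(w_obs - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-z))
  new_test_result(w_obs, p, "Wilcoxon signed-rank test", length(a),
                  exact = FALSE)
}

#' Kruskal-Wallis rank test for k unpaired groups
#'
#' Tie-corrected H statistic referred to a chi-square distribution with
#' k - 1 degrees of freedom. When every observation is identical the
#' tie correction degenerates and the defined result `H = 0, p = 1` is
#' returned with the degenerate flag.
#'
#' @param groups list of numeric vectors, at least 2, each nonempty.
#'
#' @return A `chemo_test` with statistic H.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of at least 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must be nonempty")
  x <- unlist(groups, use.names = FALSE)
  if (anyNA(x)) stop("missing values are not allowed")
  g <- rep(seq_along(groups), sizes)
  N <- length(x)
  r <- rank(x)
  H0 <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / sizes) - 3 * (N + 1)
  tt <- table(x)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  if (C <= 0) {
    return(new_test_result(0, 1, "Kruskal-Wallis test", sizes,
                           exact = FALSE, degenerate = TRUE))
  }
  H <- H0 / C
  p <- stats::pchisq(H, df = length(groups) - 1, lower.tail = FALSE)
  new_test_result(H, p, "Kruskal-Wallis test", sizes, exact = FALSE)
}

#' Friedman rank test for k paired conditions
#'
#' Within-subject midranks, tie-corrected Q, chi-square reference with
#' k - 1 degrees of freedom. For small designs (`n * k` at most
#' `exact_bound`) the p-value is exact over all (k!)^n within-row
#' rearrangements of the observed midranks, with extremeness measured by
#' Q itself (large Q = extreme). Identical values in every row give the
#' defined degenerate result `Q = 0, p = 1`.
#'
#' @param blocks numeric matrix, rows = subjects, columns = conditions;
#'   no missing cells.
#' @param exact_bound enumerate when `nrow * ncol <= exact_bound`
#'   (default 12).
#'
#' @return A `chemo_test` with statistic Q.
#' @export
friedman <- function(blocks, exact_bound = 12) {
  blocks <- as.matrix(blocks)
  if (anyNA(blocks)) stop("missing cells are not allowed")
  n <- nrow(blocks); k <- ncol(blocks)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 conditions")
  R <- t(apply(blocks, 1, rank))
  q_of <- function(Rm) 12 / (n * k * (k + 1)) * sum(colSums(Rm)^2) -
    3 * n * (k + 1)
  Q0 <- q_of(R)
  tie_sum <- sum(apply(blocks, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  }))
  C <- 1 - tie_sum / (n * k * (k^2 - 1))
  if (C <= 0) {
    return(new_test_result(0, 1, "Friedman test", rep(n, k),
                           exact = FALSE, degenerate = TRUE))
  }
  Q <- Q0 / C
  if (n * k <= exact_bound) {
    # all within-row permutations of each row's midranks; the tie
    # correction is permutation-invariant so comparing Q0 suffices
    col_sums <- matrix(0, nrow = 1, ncol = k)
    for (i in seq_len(n)) {
      perms <- .permutations(R[i, ])
      idx_prev <- rep(seq_len(nrow(col_sums)), each = nrow(perms))
      idx_new <- rep(seq_len(nrow(perms)), times = nrow(col_sums))
      col_sums <- col_sums[idx_prev, , drop = FALSE] +
        perms[idx_new, , drop = FALSE]
    }
    qs <- 12 / (n * k * (k + 1)) * rowSums(col_sums^2) - 3 * n * (k + 1)
    p <- mean(qs >= Q0 - 1e-9)
    return(new_test_result(Q, p, "Friedman test", rep(n, k), exact = TRUE))
  }
  p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  new_test_result(Q, p, "Friedman test", rep(n, k), exact = FALSE)
}

# All distinct orderings of a (possibly tied) numeric vector.
.permutations <- function(v) {
  k <- length(v)
  if (k == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(k)) {
    rest <- .permutations(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  unique(out)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Rank-based z comparisons following a Kruskal-Wallis (unpaired) or
#' Friedman (paired) omnibus test. Each two-sided p is multiplied by the
#' number of comparisons actually requested (Bonferroni-within-Dunn) and
#' capped at 1; pass all pairs to get the conventional all-pairs family.
#'
#' @param groups for `paired = FALSE`, a named list of numeric vectors;
#'   for `paired = TRUE`, a numeric matrix with subjects in rows and
#'   named condition columns.
#' @param comparisons list of length-2 character vectors naming the
#'   groups/conditions to compare; default all pairs.
#' @param paired logical; `TRUE` for the Friedman-rank analogue.
#'
#' @return data.frame with columns group1, group2, z, p_unadjusted,
#'   p_adjusted.
#' @export
dunn_posthoc <- function(groups, comparisons = NULL, paired = FALSE) {
  if (paired) {
    blocks <- as.matrix(groups)
    nms <- colnames(blocks)
    if (is.null(nms)) nms <- paste0("g", seq_len(ncol(blocks)))
    n <- nrow(blocks); k <- ncol(blocks)
    R <- t(apply(blocks, 1, rank))
    mean_rank <- colMeans(R)
    names(mean_rank) <- nms
    se_of <- function(i, j) sqrt(k * (k + 1) / (6 * n))
    sizes <- stats::setNames(rep(n, k), nms)
  } else {
    if (!is.list(groups)) stop("groups must be a list for unpaired Dunn")
    nms <- names(groups)
    if (is.null(nms)) nms <- paste0("g", seq_along(groups))
    names(groups) <- nms
    x <- unlist(groups, use.names = FALSE)
    g <- rep(nms, lengths(groups))
    N <- length(x)
    r <- rank(x)
    mean_rank <- tapply(r, factor(g, levels = nms), mean)
    sizes <- lengths(groups)
    tt <- table(x)
    tie_term <- sum(tt^3 - tt) / (12 * (N - 1))
    se_of <- function(i, j) {
      sqrt((N * (N + 1) / 12 - tie_term) * (1 / sizes[[i]] + 1 / sizes[[j]]))
    }
  }
  if (is.null(comparisons))
    comparisons <- utils::combn(nms, 2, simplify = FALSE)
  bad <- !vapply(comparisons, function(cp) all(cp %in% nms), logical(1))
  if (any(bad)) stop("comparison names an unknown group")
  m <- length(comparisons)
  rows <- lapply(comparisons, function(cp) {
    se <- se_of(cp[1], cp[2])
    z <- if (se > 0) (mean_rank[[cp[1]]] - mean_rank[[cp[2]]]) / se else 0
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = cp[1], group2 = cp[2], z = z,
               p_unadjusted = p, p_adjusted = min(1, p * m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pearson correlation with t-distribution p-value
#'
#' `r` with a two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` on
#' n - 2 degrees of freedom. Zero variance in either variable yields a
#' defined degenerate result (`r = NA`, `p = NA`, flag set) rather than
#' an error.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#'
#' @return A `chemo_test`; the statistic is r.
#' @export
pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (anyNA(c(x, y))) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(new_test_result(NA_real_, NA_real_, "Pearson correlation", n,
                           exact = FALSE, degenerate = TRUE))
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * stats::sd(x) * stats::sd(y))
  r <- max(-1, min(1, r))
  if (abs(r) == 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_test_result(r, p, "Pearson correlation", n, exact = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, mapped back to the input order.
#' Tied p-values share a q and the output never drops below the input.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#'
#' @return An object of class `chemo_fdr`: list with `p_values` and
#'   `q_values` in the input order.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))$q_values  # all 0.04
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("all p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) {
    return(structure(list(p_values = numeric(0), q_values = numeric(0)),
                     class = "chemo_fdr"))
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  # multiplier m/j computed first so j = m gives exactly 1 and q >= p
  # holds in floating point as well as in exact arithmetic
  q <- pmin(1, cummin((m / seq(m, 1)) * p[o]))[ro]
  structure(list(p_values = p, q_values = q), class = "chemo_fdr")
}
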