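# The nonparametric testing battery: Jarque-Bera normality gate,
# Mann-Whitney U for two groups, Kruskal-Wallis with Dunn's
# post-hoc z tests (Bonferroni), and Friedman with pairwise Wilcoxon
# signed-rank (Bonferroni) for repeated measures. Mid-ranks are used
# everywhere for ties; all adjusted p values are capped at 1.

test_result <- function(comparison, statistic, value, p_raw, p_adjusted, n) {
  data.frame(comparison = comparison, statistic = statistic,
             value = as.numeric(value), p_raw = p_raw,
             p_adjusted = p_adjusted, n = n, row.names = NULL)
}

#' Jarque-Bera normality gate
#'
#' Decides between a parametric and nonparametric analysis track from
#' sample skewness S and kurtosis K: `JB = n (S^2/6 + (K-3)^2/24)`,
#' referred to a chi-square distribution with 2 df. Rejection at `alpha`
#' (or a degenerate constant sample) routes to "nonparametric". The gate
#' is informational: the pipeline's tests are nonparametric throughout.
#'
#' @param x Numeric sample of length at least 8.
#' @param alpha Significance level (default 0.05).
#' @return List with `decision` ("parametric"/"nonparametric"),
#'   `statistic` and `p_value`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("normality_gate: need at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0)
    return(list(decision = "nonparametric", statistic = Inf, p_value = 0))
  S <- mean((x - m)^3) / m2^1.5
  K <- mean((x - m)^4) / m2^2
  jb <- n * (S^2 / 6 + (K - 3)^2 / 24)
  p <- stats::pchisq(jb, df = 2, lower.tail = FALSE)
  list(decision = if (p < alpha) "nonparametric" else "parametric",
       statistic = jb, p_value = p)
}

#' Two-group Mann-Whitney U test
#'
#' Two-sided Mann-Whitney U; the exact p value is used when
#' `min(n, m) <= 8` and there are no ties, the normal approximation
#' with tie correction (and continuity correction) otherwise.
#'
#' @param a,b Non-empty numeric samples.
#' @param comparison Label stored in the result.
#' @return A one-row test-result data frame (`statistic = "U"`;
#'   `p_adjusted` equals `p_raw` for a single comparison).
#' @export
two_group_test <- function(a, b, comparison = "a vs b") {
  if (!length(a) || !length(b)) stop("two_group_test: empty group")
  exact <- min(length(a), length(b)) <= 8 && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  test_result(comparison, "U", unname(wt$statistic), wt$p.value, wt$p.value,
              sprintf("%d/%d", length(a), length(b)))
}

#' Kruskal-Wallis with Dunn-Bonferroni post hocs
#'
#' Tie-corrected Kruskal-Wallis H over three or more groups, followed by
#' Dunn's pairwise z tests on mean ranks with the standard tie
#' correction; each pairwise p is Bonferroni-adjusted by the number of
#' pairs (capped at 1).
#'
#' @param groups Named list of at least three non-empty numeric vectors.
#' @return Test-result data frame: one `H` row for the omnibus test and
#'   one `z_Dunn` row per pair.
#' @export
multi_group_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 3)
    stop("multi_group_test: need at least three groups ",
         "(use two_group_test for two)")
  if (any(!lengths(groups))) stop("multi_group_test: empty group")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  g <- rep(seq_along(groups), ns)
  rk <- rank(unlist(groups))          # mid-ranks
  Ri <- tapply(rk, g, mean)
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(seq_along(groups), 2)
  npairs <- ncol(pairs)
  out <- test_result("omnibus", "H", unname(kw$statistic), kw$p.value,
                     NA_real_, paste(ns, collapse = "/"))
  for (p in seq_len(npairs)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[i] + 1 / ns[j]))
    z <- (Ri[i] - Ri[j]) / se
    praw <- 2 * stats::pnorm(-abs(z))
    out <- rbind(out, test_result(
      paste(names(groups)[i], "vs", names(groups)[j]), "z_Dunn", z,
      praw, min(1, praw * npairs), sprintf("%d/%d", ns[i], ns[j])))
  }
  out
}

# exact two-sided signed-rank p by full 2^n sign enumeration on
# mid-ranks of |d| (handles ties, unlike the closed-form tables);
# zero differences are dropped beforehand
exact_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (!n) return(list(W = 0, p = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  sums <- 0
  for (x in r) sums <- c(sums, sums + x)   # all 2^n values of W+
  M <- n * (n + 1) / 2
  p <- min(1, 2 * min(mean(sums >= W), mean(sums <= W)))
  list(W = W, p = p)
}

#' Friedman test with pairwise Wilcoxon-Bonferroni post hocs
#'
#' Friedman chi-square over a complete subjects x conditions matrix,
#' followed by pairwise two-sided Wilcoxon signed-rank tests between
#' conditions, Bonferroni-adjusted over all condition pairs. For up to
#' 16 non-zero paired differences the signed-rank p is computed by exact
#' sign enumeration (valid under ties); larger samples use the normal
#' approximation.
#'
#' @param m Numeric matrix, subjects in rows (>= 3), conditions in
#'   columns (>= 2), no missing cells.
#' @return Test-result data frame: one `chi2_Friedman` row and one `W`
#'   row per condition pair.
#' @export
repeated_measures_test <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("repeated_measures_test: missing cells")
  if (ncol(m) < 2 || nrow(m) < 3)
    stop("repeated_measures_test: need >= 3 subjects and >= 2 conditions")
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  fr <- stats::friedman.test(m)
  fr_stat <- unname(fr$statistic)
  fr_p <- fr$p.value
  if (is.nan(fr_stat)) {              # fully tied rows: no evidence at all
    fr_stat <- 0
    fr_p <- 1
  }
  out <- test_result("omnibus", "chi2_Friedman", fr_stat, fr_p,
                     NA_real_, nrow(m))
  pairs <- utils::combn(seq_len(ncol(m)), 2)
  npairs <- ncol(pairs)
  for (p in seq_len(npairs)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    d <- m[, j] - m[, i]
    if (sum(d != 0) <= 16) {
      ex <- exact_signed_rank_p(d)
      W <- ex$W; praw <- ex$p
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(m[, j], m[, i], paired = TRUE, exact = FALSE))
      W <- unname(wt$statistic); praw <- wt$p.value
    }
    out <- rbind(out, test_result(
      paste(colnames(m)[j], "vs", colnames(m)[i]), "W", W,
      praw, min(1, praw * npairs), nrow(m)))
  }
  out
}
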