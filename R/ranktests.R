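# Nonparametric rank statistics used to compare regional age sets and
# proxy series: Mann-Whitney U, Kruskal-Wallis H, Spearman rank correlation.
# Ties are handled with mid-ranks throughout.

new_rank_test <- function(statistic_name, statistic, n_per_group, p_value,
                          method) {
  structure(list(statistic_name = statistic_name,
                 statistic = statistic,
                 n_per_group = n_per_group,
                 p_value = p_value,
                 method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s = %.4f (n = %s), p = %.4g [%s]\n", x$statistic_name,
              x$statistic, paste(x$n_per_group, collapse = ", "),
              x$p_value, x$method))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' `U` counts the pairs `(x, y)` with `x > y`, counting ties as 1/2. The
#' two-sided p-value is exact (from the null permutation distribution of U)
#' when `min(n1, n2) <= 8` and there are no ties across the pooled sample;
#' otherwise a tie-corrected normal approximation is used. The `method`
#' field records which branch was taken.
#'
#' @param a,b numeric vectors (for example per-date calibrated median ages
#'   of two regions). Both must be nonempty.
#' @return A `rank_test` with `statistic_name = "U"`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("empty input: both groups must contain at least one value")
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  rk <- rank(pooled)  # mid-ranks
  r1 <- sum(rk[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2  # equals #{x > y} with ties as 1/2
  ties <- any(duplicated(pooled))
  if (min(n1, n2) <= 8 && !ties) {
    # exact two-sided p from the null distribution of U
    p <- min(1, 2 * min(stats::pwilcox(u, n1, n2),
                        stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)))
    method <- "exact"
  } else {
    t_tab <- table(pooled)
    tie_term <- sum(t_tab^3 - t_tab) / (n * (n - 1))
    sd_u <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- (u - n1 * n2 / 2) / sd_u
    p <- 2 * stats::pnorm(-abs(z))
    method <- "approximate"
  }
  new_rank_test("U", u, c(n1, n2), p, method)
}

#' Kruskal-Wallis H test
#'
#' Rank-based comparison of two or more groups:
#' `H = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)` with mid-rank ties
#' and the usual tie correction; p from the chi-square distribution with
#' `k - 1` degrees of freedom. Delegates to [stats::kruskal.test()].
#'
#' @param groups list of numeric vectors, each nonempty, at least two.
#' @return A `rank_test` with `statistic_name = "H"`.
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 4.571
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("need at least two groups")
  }
  if (any(vapply(groups, length, 0L) == 0L)) {
    stop("empty input: every group must contain at least one value")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  kt <- stats::kruskal.test(x, g)
  new_rank_test("H", unname(kt$statistic),
                vapply(groups, length, 0L), kt$p.value,
                "chi-square approximation")
}

#' Spearman rank correlation
#'
#' Pearson correlation of the mid-ranks of `x` and `y`; two-sided p-value
#' from the t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors of equal length `>= 3`.
#' @return A `rank_test` with `statistic_name = "r_s"`.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) {
    stop("pairing error: x and y must have equal length")
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("undefined correlation: constant input")
  }
  rs <- stats::cor(rank(x), rank(y))
  if (abs(rs) >= 1) {
    p <- 0
  } else {
    tstat <- rs * sqrt((n - 2) / (1 - rs^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  new_rank_test("r_s", rs, n, p, "t approximation")
}
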