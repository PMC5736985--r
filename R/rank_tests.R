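# Nonparametric rank tests used by the expansion screen.
#
# Gene counts are small integers with heavy ties, so the Mann-Whitney test is
# computed exactly by default: the null distribution of U is taken over all
# choose(n1 + n2, n1) equally likely assignments of the pooled observations to
# the two groups, with midranks shared across ties. The enumeration is done
# with a subset-sum dynamic program over doubled midranks (doubling makes the
# rank sums integral), which is equivalent to full enumeration but runs in
# polynomial time, so exactness is affordable well past the default n <= 20
# switchover.

new_rank_test <- function(statistic, p_value, method, tie_corrected,
                          group_sizes, name) {
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         tie_corrected = tie_corrected, group_sizes = group_sizes,
         name = name),
    class = "pep_rank_test"
  )
}

#' @export
print.pep_rank_test <- function(x, ...) {
  cat(x$name, " (", x$method, if (x$tie_corrected) ", tie-corrected" else "",
      ")\n", sep = "")
  cat("  statistic = ", format(x$statistic), ", p = ", format(x$p_value),
      ", n = ", paste(x$group_sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' @method tidy pep_rank_test
#' @export
tidy.pep_rank_test <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, method = x$method,
         tie_corrected = x$tie_corrected,
         n = sum(x$group_sizes))
}

# Distribution of the sum of doubled midranks over all subsets of size n1,
# as counts indexed by achievable sums. Returns list(sums, counts).
rank_sum_distribution <- function(double_ranks, n1) {
  total <- sum(double_ranks)
  # f[k + 1, s + 1] = number of subsets of size k with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  f[1, 1] <- 1
  for (d in double_ranks) {
    kmax <- n1
    for (k in kmax:1) {
      if (d + 1 <= total + 1) {
        idx <- 1:(total + 1 - d)
        f[k + 1, idx + d] <- f[k + 1, idx + d] + f[k, idx]
      }
    }
  }
  sums <- which(f[n1 + 1, ] > 0) - 1
  list(sums = sums, counts = f[n1 + 1, sums + 1])
}

#' Mann-Whitney U test with exact enumeration p-value
#'
#' Two-sided Mann-Whitney U comparing two groups of counts. The statistic is
#' computed from midranks, so ties are handled without breaking them. With
#' `method = "exact"` (the default resolution of `"auto"` when
#' `n1 + n2 <= 20`), the p-value is the fraction of all
#' `choose(n1 + n2, n1)` assignments of the pooled values whose
#' `min(U, n1 * n2 - U)` is at most the observed minimum — a two-sided
#' extremity probability that needs no doubling and stays exact under ties.
#' Otherwise a normal approximation with tie correction (and optional
#' continuity correction) is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param continuity apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @return a `pep_rank_test` object; `statistic` is U for group `a`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4, 5))   # U = 0, exact p = 0.2
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal"),
                           continuity = TRUE) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  if (anyNA(c(a, b))) abort("missing values are not supported")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)                       # midranks
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(new_rank_test(n1 * n2 / 2, 1, "exact_enumeration", TRUE,
                         c(n1, n2), "Mann-Whitney U"))
  }
  use_exact <- method == "exact" || (method == "auto" && n <= 20)
  if (use_exact) {
    dr <- as.integer(round(2 * r))
    dist <- rank_sum_distribution(dr, n1)
    u_all <- dist$sums / 2 - n1 * (n1 + 1) / 2
    m_all <- pmin(u_all, n1 * n2 - u_all)
    m_obs <- min(u, n1 * n2 - u)
    p <- sum(dist$counts[m_all <= m_obs + 1e-9]) / sum(dist$counts)
    return(new_rank_test(u, p, "exact_enumeration", TRUE, c(n1, n2),
                         "Mann-Whitney U"))
  }
  # normal approximation with tie correction
  t_tab <- table(pooled)
  tie_term <- sum(t_tab^3 - t_tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  mu <- n1 * n2 / 2
  cc <- if (continuity) 0.5 else 0
  dev <- abs(u - mu)
  z <- max(dev - cc, 0) / sqrt(sigma2)
  p <- min(1, 2 * pnorm(-z))
  new_rank_test(u, p, "normal_approx", tie_term > 0, c(n1, n2),
                "Mann-Whitney U")
}

#' Kruskal-Wallis rank test with tie correction
#'
#' H is computed from midranks and divided by the tie-correction factor
#' `1 - sum(t^3 - t) / (N^3 - N)`; the p-value comes from the chi-square
#' distribution with `k - 1` degrees of freedom. If every pooled value is
#' tied, `H = 0` and `p = 1`.
#'
#' @param groups list of >= 2 non-empty numeric vectors.
#' @return a `pep_rank_test` object; `statistic` is tie-corrected H.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))   # H = 32/7
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("kruskal_wallis needs a list of at least 2 groups")
  }
  sizes <- lengths(groups)
  if (any(sizes == 0)) abort("every group must be non-empty")
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank(pooled)
  g <- rep(seq_along(groups), sizes)
  if (length(unique(pooled)) == 1) {
    return(new_rank_test(0, 1, "chisq_approx", TRUE, as.integer(sizes),
                         "Kruskal-Wallis"))
  }
  rbar <- tapply(r, g, mean)
  h <- 12 / (n * (n + 1)) * sum(sizes * rbar^2) - 3 * (n + 1)
  t_tab <- table(pooled)
  corr <- 1 - sum(t_tab^3 - t_tab) / (n^3 - n)
  h <- h / corr
  p <- pchisq(h, df = length(groups) - 1, lower.tail = FALSE)
  new_rank_test(h, p, "chisq_approx", TRUE, as.integer(sizes),
                "Kruskal-Wallis")
}
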