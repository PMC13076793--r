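# Rank-based group comparison implemented from the formulas:
# Kruskal-Wallis omnibus test with tie correction, Dunn's pairwise post hoc
# z-tests with Bonferroni correction, and significance-tier labels.

as_group_data <- function(data) {
  if (is.data.frame(data)) {
    stop_if(!all(c("group", "value") %in% names(data)),
            "data frame input needs columns 'group' and 'value'")
    data <- split(data$value, data$group)
  }
  stop_if(!is.list(data) || length(data) < 2, "need >= 2 groups")
  stop_if(any(!vapply(data, length, integer(1))), "every group needs >= 1 value")
  lapply(data, as.numeric)
}

# pooled mid-ranks, per-group sizes and mean ranks, tie counts
rank_summary <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  r <- rank(x)  # mid-ranks
  ties <- table(x)
  list(n = lengths(groups), N = length(x),
       rbar = tapply(r, g, mean),
       tie_term = sum(ties^3 - ties))
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus test over k groups on pooled mid-ranks:
#' `H = 12 / (N (N + 1)) * sum n_i (rbar_i - (N + 1) / 2)^2`, divided by the
#' tie correction `1 - sum(t^3 - t) / (N^3 - N)`; p from the chi-square
#' approximation with k - 1 degrees of freedom. Fully tied data give
#' `H = 0, p = 1` (not an error).
#'
#' @param data Named list of numeric vectors, or a data frame with `group`
#'   and `value` columns.
#' @return List: `H`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(data) {
  groups <- as_group_data(data)
  rs <- rank_summary(groups)
  N <- rs$N
  stop_if(N < 3, "need total N >= 3")
  h0 <- 12 / (N * (N + 1)) * sum(rs$n * (rs$rbar - (N + 1) / 2)^2)
  corr <- 1 - rs$tie_term / (N^3 - N)
  if (corr <= 0) return(list(H = 0, p_value = 1, df = length(groups) - 1L))
  H <- h0 / corr
  list(H = H, p_value = pchisq(H, length(groups) - 1L, lower.tail = FALSE),
       df = length(groups) - 1L)
}

#' Significance tier label
#'
#' The usual figure-caption convention: `****` p < 0.0001, `***` p < 0.001,
#' `**` p < 0.01, `*` p < 0.05, otherwise `ns`.
#'
#' @param p P-value(s).
#' @return Character vector of tier labels.
#' @export
significance_tier <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}

#' Dunn's post hoc test with Bonferroni correction
#'
#' Pairwise z-statistics on pooled mid-ranks,
#' `z_ij = (rbar_i - rbar_j) / sqrt((N (N + 1) / 12 -
#' sum(t^3 - t) / (12 (N - 1))) (1 / n_i + 1 / n_j))`,
#' two-sided normal p-values, Bonferroni-adjusted over all k (k - 1) / 2
#' pairs, with significance-tier labels.
#'
#' @inheritParams kruskal_wallis
#' @return A `test_report`: the omnibus [kruskal_wallis()] result plus a
#'   `pairwise` data frame (`group1`, `group2`, `z`, `p_raw`, `p_adj`,
#'   `tier`).
#' @export
dunn_posthoc <- function(data) {
  groups <- as_group_data(data)
  kw <- kruskal_wallis(data)
  rs <- rank_summary(groups)
  N <- rs$N
  k <- length(groups)
  var_term <- N * (N + 1) / 12 - rs$tie_term / (12 * (N - 1))
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  z <- p_raw <- numeric(m)
  for (c_ in seq_len(m)) {
    i <- pairs[1, c_]
    j <- pairs[2, c_]
    se <- sqrt(var_term * (1 / rs$n[i] + 1 / rs$n[j]))
    z[c_] <- if (se > 0) (rs$rbar[i] - rs$rbar[j]) / se else 0
    p_raw[c_] <- 2 * pnorm(-abs(z[c_]))
  }
  p_adj <- pmin(1, p_raw * m)
  nm <- names(groups) %||% as.character(seq_len(k))
  pw <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                   z = z, p_raw = p_raw, p_adj = p_adj,
                   tier = significance_tier(p_adj))
  structure(list(kruskal = kw, pairwise = pw, n_comparisons = m),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
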