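#' Significance stars
#'
#' Maps a p-value to the conventional star annotation used on peri-event
#' panels: `n.s.` (p >= 0.05), `*` (< 0.05), `**` (< 0.01), `***` (< 0.001).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of annotations.
#' @export
stars_from_p <- function(p) {
  cut(p, breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("***", "**", "*", "n.s."), right = FALSE) |>
    as.character()
}

# Subset-sum count vector: number of sign assignments reaching each doubled
# rank sum 0..S. Returns counts (doubles; exact for n <= ~50).
signed_rank_null_counts <- function(ranks2) {
  s_max <- sum(ranks2)
  v <- numeric(s_max + 1)
  v[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), v[seq_len(s_max + 1 - r)])
    v <- v + shifted
  }
  v
}

#' Wilcoxon signed-rank test with exact tied-rank null
#'
#' Paired two-sided signed-rank test. Zero differences are dropped before
#' ranking; tied absolute differences receive mid-ranks. For `n` non-zero
#' pairs up to `exact_limit` the null distribution of the positive-rank sum
#' is computed exactly by dynamic programming over all `2^n` sign
#' assignments (valid under ties); above it a normal approximation with
#' continuity and tie correction is used.
#'
#' @param x Numeric vector: paired differences, or first member of each pair
#'   when `y` is given.
#' @param y Optional second member of each pair (`x - y` is tested).
#' @param exact_limit Maximum `n` for the exact null (default 25).
#' @return List with `statistic` (positive-rank sum W), `p_value`
#'   (two-sided), `n` (non-zero pairs), `method` (`"exact"` or `"normal"`),
#'   and `trend` (`"greater"`, `"less"` or `"none"`: the sign of W relative
#'   to its null mean).
#' @export
#' @examples
#' signed_rank_test(c(1, 2, 3, 4, 5, 6))$p_value  # 2/64
signed_rank_test <- function(x, y = NULL, exact_limit = 25) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  null_mean <- n * (n + 1) / 4
  if (n == 0) {
    return(list(statistic = 0, p_value = 1, n = 0L, method = "exact",
                trend = "none"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  trend <- if (w > null_mean) "greater" else if (w < null_mean) "less"
           else "none"
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    counts <- signed_rank_null_counts(r2)
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[seq(w2 + 1, length(counts))]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - null_mean - 0.5 * sign(w - null_mean)) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n = as.integer(n), method = method,
       trend = trend)
}

# Count, for each doubled-rank sum s, the subsets of size m with that sum.
# Returns a (m+1) x (S+1) matrix of counts.
rank_sum_null_counts <- function(ranks2, m) {
  s_max <- sum(ranks2)
  f <- matrix(0, nrow = m + 1, ncol = s_max + 1)
  f[1, 1] <- 1
  for (r in ranks2) {
    for (k in seq(m, 1)) {
      row <- f[k, seq_len(s_max + 1 - r)]
      f[k + 1, seq(r + 1, s_max + 1)] <-
        f[k + 1, seq(r + 1, s_max + 1)] + row
    }
  }
  f
}

#' Wilcoxon rank-sum test with exact tied-rank null
#'
#' Two-sample rank-sum test on independent groups, with mid-ranks for ties.
#' For combined sample sizes up to `exact_limit` the null distribution of the
#' first group's rank sum is computed exactly by dynamic programming over all
#' size-`n_x` subsets of the observed (possibly tied) ranks; above it a
#' normal approximation with tie correction and continuity correction is
#' used and the standardized `z` is reported.
#'
#' @param x,y Numeric vectors for the two groups.
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or
#'   `"less"`.
#' @param exact_limit Maximum combined size for the exact null (default 30).
#' @return List with `statistic` (rank sum of `x`), `p_value`, `n_x`, `n_y`,
#'   `method`, and `z` (normal path only, `NA` otherwise).
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p_value # 1/20
rank_sum_test <- function(x, y, alternative = c("two.sided", "greater",
                                                "less"),
                          exact_limit = 30) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y); n <- nx + ny
  if (nx == 0 || ny == 0) {
    abort("Both groups must be non-empty.", class = "flydom_stats_error")
  }
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    f <- rank_sum_null_counts(r2, nx)
    counts <- f[nx + 1, ]
    total <- choose(n, nx)
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[seq(w2 + 1, length(counts))]) / total
    p <- switch(alternative,
                two.sided = min(1, 2 * min(p_le, p_ge)),
                greater = p_ge,
                less = p_le)
    list(statistic = w, p_value = p, n_x = nx, n_y = ny, method = "exact",
         z = NA_real_)
  } else {
    mu <- nx * (n + 1) / 2
    ties <- table(r)
    sigma2 <- nx * ny / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    cc <- switch(alternative, two.sided = 0.5 * sign(w - mu), greater = 0.5,
                 less = -0.5)
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- switch(alternative,
                two.sided = min(1, 2 * pnorm(-abs(z))),
                greater = pnorm(z, lower.tail = FALSE),
                less = pnorm(z))
    list(statistic = w, p_value = p, n_x = nx, n_y = ny, method = "normal",
         z = z)
  }
}

#' Exact sign test for paired designs
#'
#' Drops zero differences and applies an exact binomial test of the number
#' of positive differences against probability one half.
#'
#' @inheritParams signed_rank_test
#' @param alternative Passed to [stats::binom.test()].
#' @return List with `n_positive`, `n`, `p_value`.
#' @export
sign_test <- function(x, y = NULL, alternative = "two.sided") {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d) & d != 0]
  if (length(d) == 0) {
    return(list(n_positive = 0L, n = 0L, p_value = 1))
  }
  bt <- binom.test(sum(d > 0), length(d), p = 0.5,
                   alternative = alternative)
  list(n_positive = sum(d > 0), n = length(d), p_value = bt$p.value)
}
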