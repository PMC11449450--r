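#' Group summary statistics
#' @param mean Group mean.
#' @param sd Group standard deviation (>= 0).
#' @param n Group size (integer >= 2).
#' @return An object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  stopifnot(is.finite(mean), is.finite(sd), sd >= 0, n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Independent Student t-test with pooled variance, computed directly from
#' printed group means, standard deviations and sizes:
#' `t = (m_a - m_b) / sqrt(s_p^2 (1/n_a + 1/n_b))` with
#' `s_p^2 = ((n_a - 1) s_a^2 + (n_b - 1) s_b^2) / (n_a + n_b - 2)` and
#' `df = n_a + n_b - 2`; the p-value is two-tailed.
#'
#' @param a,b [group_summary()] objects (or lists with `mean`, `sd`, `n`).
#' @return A list of class `ttest_result` with `t`, `df`, `p`.
#' @examples
#' ttest_from_summary(group_summary(9124, 4174, 4),
#'                    group_summary(4030, 1633, 4))  # t = 2.273, df = 6
#' @export
ttest_from_summary <- function(a, b) {
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 <= 0) {
    if (a$mean == b$mean) {
      stop("t undefined: both sds zero and means equal", call. = FALSE)
    }
    t <- sign(a$mean - b$mean) * Inf
  } else {
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  }
  df <- a$n + b$n - 2L
  structure(list(t = t, df = df, p = 2 * stats::pt(-abs(t), df)),
            class = "ttest_result")
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, two-tailed p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}

#' Pooled-variance two-sample t-test from raw samples
#'
#' Identical to [ttest_from_summary()] applied to the samples' means, sds
#' and sizes.
#'
#' @param x,y Numeric sample vectors, each of length >= 2.
#' @return A `ttest_result`.
#' @export
ttest_from_samples <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  ttest_from_summary(group_summary(mean(x), stats::sd(x), length(x)),
                     group_summary(mean(y), stats::sd(y), length(y)))
}

#' Permutation-based comparison of two sets of normalized-cycle curves
#'
#' Pointwise two-sample pooled t statistics are computed along the
#' normalized cycle, and the family-wise threshold is the (1 - alpha)
#' quantile of the null distribution of the maximum absolute t over the
#' cycle under group-label permutations (exhaustive enumeration when the
#' total number of group assignments is below 20,000, otherwise `n_perm`
#' random permutations seeded by `seed`). Significant clusters are the
#' maximal grid intervals where |t| exceeds the threshold. This targets the
#' same inference as one-dimensional statistical parametric mapping but
#' replaces the random-field threshold with a max-statistic permutation
#' threshold.
#'
#' @param group_a,group_b Numeric matrices, one curve per row, columns on a
#'   common normalized-cycle grid; at least 3 curves per group.
#' @param n_perm Number of random permutations when enumeration is
#'   infeasible (default 10,000).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Integer seed for the permutation draw (ignored when
#'   enumeration is exhaustive).
#' @param grid Percent positions of the columns (default 0-100 evenly).
#' @return An object of class `curve_comparison` with `t_curve`,
#'   `threshold`, `clusters` (data frame of `start_pct`, `end_pct`,
#'   `max_abs_t`), `p_value` (for the global maximum), `n_permutations`,
#'   `exhaustive`, `seed`, `grid`.
#' @export
compare_curves <- function(group_a, group_b, n_perm = 10000, alpha = 0.05,
                           seed = NULL, grid = NULL) {
  A <- as.matrix(group_a)
  B <- as.matrix(group_b)
  if (ncol(A) != ncol(B)) {
    stop("curves must share a common grid", call. = FALSE)
  }
  n1 <- nrow(A); n2 <- nrow(B)
  if (n1 < 3L || n2 < 3L) {
    stop("need at least 3 curves per group", call. = FALSE)
  }
  g <- ncol(A)
  if (is.null(grid)) grid <- seq(0, 100, length.out = g)
  X <- rbind(A, B)
  N <- n1 + n2
  total <- choose(N, n1)
  exhaustive <- total < 20000
  combos <- if (exhaustive) {
    utils::combn(N, n1)
  } else {
    if (!is.null(seed)) set.seed(seed)
    cbind(seq_len(n1),
          replicate(n_perm - 1L, sort(sample.int(N, n1))))
  }
  # put the observed labelling first
  obs <- seq_len(n1)
  is_obs <- colSums(combos == obs) == n1
  if (any(is_obs)) {
    combos <- cbind(obs, combos[, !is_obs, drop = FALSE])
  } else {
    combos <- cbind(obs, combos)
  }
  M <- ncol(combos)
  # indicator matrix (M x N) of group-1 membership per permutation
  P <- matrix(0, M, N)
  P[cbind(rep(seq_len(M), each = n1), as.vector(combos))] <- 1
  X2 <- X^2
  S1 <- P %*% X                 # M x g sums of group 1
  Q1 <- P %*% X2
  Stot <- matrix(colSums(X), M, g, byrow = TRUE)
  Qtot <- matrix(colSums(X2), M, g, byrow = TRUE)
  m1 <- S1 / n1
  m2 <- (Stot - S1) / n2
  ss1 <- pmax(0, Q1 - S1^2 / n1)
  ss2 <- pmax(0, (Qtot - Q1) - (Stot - S1)^2 / n2)
  sp2 <- (ss1 + ss2) / (N - 2)
  denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tmat <- (m1 - m2) / denom
  tmat[denom == 0 & (m1 - m2) == 0] <- 0
  maxs <- apply(abs(tmat), 1, max)
  t_obs <- tmat[1, ]
  thr <- sort(maxs)[ceiling((1 - alpha) * M)]
  sig <- abs(t_obs) > thr
  clusters <- data.frame(start_pct = numeric(0), end_pct = numeric(0),
                         max_abs_t = numeric(0))
  if (any(sig)) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    kk <- which(r$values)
    clusters <- data.frame(
      start_pct = grid[starts[kk]],
      end_pct = grid[ends[kk]],
      max_abs_t = vapply(kk, function(k) {
        max(abs(t_obs[starts[k]:ends[k]]))
      }, numeric(1)))
  }
  structure(list(t_curve = t_obs, threshold = thr, clusters = clusters,
                 p_value = mean(maxs >= max(abs(t_obs))),
                 n_permutations = M, exhaustive = exhaustive,
                 seed = seed, grid = grid, alpha = alpha),
            class = "curve_comparison")
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf(
    "<curve_comparison> max|t| = %.2f, threshold = %.2f (alpha %.2f, %d %s permutations)\n",
    max(abs(x$t_curve)), x$threshold, x$alpha, x$n_permutations,
    if (x$exhaustive) "exhaustive" else "random"))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %.1f-%.1f%% (max|t| %.2f)\n",
                  x$clusters$start_pct[i], x$clusters$end_pct[i],
                  x$clusters$max_abs_t[i]))
    }
  } else {
    cat("  no significant clusters\n")
  }
  invisible(x)
}
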