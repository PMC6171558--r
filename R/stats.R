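#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether values are symmetric about `mu`. Values equal to `mu` are
#' dropped (standard convention); the statistic V is the sum of ranks of the
#' positive deviations. The exact null distribution is used for n <= 25
#' without ties, otherwise the normal approximation with continuity
#' correction.
#'
#' @param values Numeric vector.
#' @param mu Reference value (default 0).
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @return A list of class `"ftcd_test"`: `test`, `statistic`, `p`,
#'   `alternative`, `n` (after dropping zeros), `note`.
#' @export
signed_rank_one_sample <- function(values, mu = 0,
                                   alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  alt <- sub("_", ".", alternative)
  d <- as.numeric(values) - mu
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(list(test = "wilcoxon_signed_rank", statistic = NA_real_,
                          p = NA_real_, alternative = alternative, n = 0L,
                          note = "degenerate: all values equal mu"),
                     class = "ftcd_test"))
  ties <- anyDuplicated(abs(d)) > 0L
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = alt,
                       exact = (n <= 25L && !ties), correct = TRUE)
  )
  structure(list(test = "wilcoxon_signed_rank",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 alternative = alternative, n = n,
                 note = if (ties) "ties present; normal approximation" else ""),
            class = "ftcd_test")
}

#' Paired Wilcoxon signed-rank test
#'
#' One-sample signed-rank test on the pairwise differences `x - y`.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param alternative One of `"two_sided"`, `"greater"`, `"less"`.
#' @return An `"ftcd_test"` list; `n` counts the nonzero differences.
#' @export
signed_rank_paired <- function(x, y,
                               alternative = c("two_sided", "greater", "less")) {
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  out <- signed_rank_one_sample(as.numeric(x) - as.numeric(y), 0,
                                match.arg(alternative))
  out$test <- "wilcoxon_signed_rank_paired"
  out
}

#' @export
print.ftcd_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %.4g (%s, n = %d)\n",
              x$test, x$statistic, x$p, x$alternative, x$n))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Spearman correlation with a bootstrapped confidence interval
#'
#' Rank correlation (average ranks for ties) with a seeded nonparametric
#' percentile bootstrap over pairs; an analytic Fisher-z interval is
#' reported alongside.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param cfg An [ftcd_config()] supplying `bootstrap_n`, `ci_level` and
#'   `rng_seed`.
#' @return List: `rho`, `ci_low`, `ci_high` (bootstrap percentile),
#'   `ci_fisher_low`, `ci_fisher_high`, `n`, `bootstrap_n`.
#' @export
spearman_ci <- function(x, y, cfg = ftcd_config()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 4L) stop("at least 4 pairs are required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rho undefined for a constant input vector", call. = FALSE)
  rho <- stats::cor(x, y, method = "spearman")
  set.seed(cfg$rng_seed)
  boot <- vapply(seq_len(cfg$bootstrap_n), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
    stats::cor(x[i], y[i], method = "spearman")
  }, numeric(1))
  alpha <- 1 - cfg$ci_level
  ci <- stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
                        na.rm = TRUE, names = FALSE)
  z <- atanh(min(max(rho, -1 + 1e-12), 1 - 1e-12))
  se <- 1.06 / sqrt(n - 3)  # Fieller-Hartley-Pearson se for Spearman's rho
  zq <- stats::qnorm(1 - alpha / 2)
  list(rho = rho, ci_low = ci[1], ci_high = ci[2],
       ci_fisher_low = tanh(z - zq * se), ci_fisher_high = tanh(z + zq * se),
       n = n, bootstrap_n = cfg$bootstrap_n)
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @return An `"ftcd_test"` list with the W statistic.
#' @export
normality_check <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3L || n > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  sw <- stats::shapiro.test(values)
  structure(list(test = "shapiro_wilk", statistic = unname(sw$statistic),
                 p = sw$p.value, alternative = "two_sided", n = n, note = ""),
            class = "ftcd_test")
}
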