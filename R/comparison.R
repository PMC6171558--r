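#' @title Comparison-task subtraction
#' @description Three ways of referencing the sentence-generation laterality
#'   index against the list-generation comparison task: subtracting the two
#'   LIs, subtracting the difference waves before peak finding, and
#'   subtracting the POI means.
#' @name subtraction-methods
NULL

#' Subtraction method A: difference of laterality indices
#'
#' @param li_sg,li_lg Laterality indices for the sentence and list task.
#' @return `li_sg - li_lg`.
#' @rdname subtraction-methods
#' @export
subtract_li <- function(li_sg, li_lg) {
  stopifnot(is.finite(li_sg), is.finite(li_lg))
  li_sg - li_lg
}

#' Subtraction method B: subtract the difference waves, then find the peak
#'
#' The list-task L-R wave is subtracted from the sentence-task wave sample
#' by sample, and the usual peak procedure is applied to the result.
#'
#' @param dw_sg,dw_lg `"ftcd_diffwave"` objects on the same time grid.
#' @param cfg An [ftcd_config()].
#' @return List with `li` and `latency`.
#' @rdname subtraction-methods
#' @export
subtract_difference_waves <- function(dw_sg, dw_lg, cfg = ftcd_config()) {
  stopifnot(inherits(dw_sg, "ftcd_diffwave"), inherits(dw_lg, "ftcd_diffwave"))
  if (length(dw_sg$time_s) != length(dw_lg$time_s) ||
      any(dw_sg$time_s != dw_lg$time_s))
    stop("difference waves are on mismatched time grids", call. = FALSE)
  d <- dw_sg
  d$values <- dw_sg$values - dw_lg$values
  lat <- find_peak(d, cfg)
  list(li = li_peak(d, lat, cfg), latency = lat)
}

#' Subtraction method C: difference of POI means
#'
#' @rdname subtraction-methods
#' @export
subtract_poi_means <- function(dw_sg, dw_lg, cfg = ftcd_config()) {
  stopifnot(inherits(dw_sg, "ftcd_diffwave"), inherits(dw_lg, "ftcd_diffwave"))
  if (length(dw_sg$time_s) != length(dw_lg$time_s) ||
      any(dw_sg$time_s != dw_lg$time_s))
    stop("difference waves are on mismatched time grids", call. = FALSE)
  li_mean_poi(dw_sg, cfg) - li_mean_poi(dw_lg, cfg)
}

#' Bland-Altman agreement analysis with predetermined limits
#'
#' Computes pairwise differences `x - y`, their mean and sd, the limits of
#' agreement `mean +/- 1.96 sd`, and the t confidence interval of the mean
#' difference. The primary equivalence rule: the two measures are judged
#' equivalent when the *mean* difference lies within the predetermined
#' limits; the fraction of individual differences inside those limits is
#' also reported so the stricter point-wise rule can be applied.
#'
#' @param x,y Paired per-participant values (equal length, n >= 3).
#' @param cfg An [ftcd_config()] supplying `predetermined_loa` and
#'   `ci_level`.
#' @return An object of class `"ftcd_blandaltman"`.
#' @export
bland_altman <- function(x, y, cfg = ftcd_config()) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must be paired vectors of equal length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("at least 3 pairs are required", call. = FALSE)
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  loa <- m + c(-1.96, 1.96) * s
  half <- stats::qt(1 - (1 - cfg$ci_level) / 2, n - 1) * s / sqrt(n)
  lim <- cfg$predetermined_loa
  structure(list(
    n = n, mean_diff = m, sd_diff = s,
    loa_low = loa[1], loa_high = loa[2],
    ci_mean_low = m - half, ci_mean_high = m + half,
    predetermined = lim,
    prop_within = mean(d >= lim[1] & d <= lim[2]),
    verdict = if (m >= lim[1] && m <= lim[2]) "equivalent" else "not_equivalent"
  ), class = "ftcd_blandaltman")
}

#' @export
print.ftcd_blandaltman <- function(x, ...) {
  cat("Bland-Altman agreement analysis\n")
  cat(sprintf("  n = %d; mean difference %.3f (sd %.3f), 95%% CI [%.3f, %.3f]\n",
              x$n, x$mean_diff, x$sd_diff, x$ci_mean_low, x$ci_mean_high))
  cat(sprintf("  limits of agreement [%.3f, %.3f]; predetermined [%g, %g]\n",
              x$loa_low, x$loa_high, x$predetermined[1], x$predetermined[2]))
  cat(sprintf("  %.0f%% of differences within predetermined limits; verdict: %s\n",
              100 * x$prop_within, x$verdict))
  invisible(x)
}
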