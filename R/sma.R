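#' Standardized major axis (SMA) regression
#'
#' The symmetric line-fitting standard for trait allometry: slope =
#' sign(r) * s_y / s_x, intercept = mean(y) - slope * mean(x). Because the
#' SMA slope magnitude does not shrink with r, significance is the
#' two-tailed test of r = 0 (t = r sqrt((n - 2) / (1 - r^2)), n - 2 df),
#' not a test of the slope.
#'
#' @param x,y numeric vectors (n >= 3, finite, nonzero variance).
#' @return object of class \code{sma_fit}: slope, intercept, r, r_squared,
#'   p_value, n, through_origin = FALSE.
#' @export
sma_fit <- function(x, y) {
  check_xy(x, y, min_n = 3)
  n <- length(x)
  r <- stats::cor(x, y)
  slope <- sign_or_pos(r) * stats::sd(y) / stats::sd(x)
  structure(list(slope = slope, intercept = mean(y) - slope * mean(x),
                 r = r, r_squared = r^2, p_value = cor_p(r, df = n - 2),
                 n = n, through_origin = FALSE),
            class = "sma_fit")
}

#' Through-origin SMA regression for independent contrasts
#'
#' Contrast regressions pass through the origin, and the x contrasts are
#' positivized first (each contrast pair's signs flipped so x >= 0, which
#' leaves products and squares unchanged). Uncentred moments give
#' r = sum(xy) / sqrt(sum(x^2) sum(y^2)) and slope =
#' sign(r) sqrt(sum(y^2) / sum(x^2)); the test of r uses n - 1 df.
#'
#' @param xc,yc standardized contrasts from the same tree, in the same node
#'   order (n >= 3).
#' @return object of class \code{sma_fit} with \code{intercept = NA} and
#'   \code{through_origin = TRUE}.
#' @export
sma_fit_origin <- function(xc, yc) {
  if (inherits(xc, "contrast_set")) xc <- xc$contrasts
  if (inherits(yc, "contrast_set")) yc <- yc$contrasts
  if (length(xc) != length(yc))
    stop("contrast vectors have different lengths")
  check_xy(xc, yc, min_n = 3, allow_constant = TRUE)
  flip <- xc < 0
  xc[flip] <- -xc[flip]
  yc[flip] <- -yc[flip]
  sxx <- sum(xc^2); syy <- sum(yc^2)
  if (sxx == 0 || syy == 0)
    stop("degenerate input: contrasts are all zero")
  n <- length(xc)
  r <- sum(xc * yc) / sqrt(sxx * syy)
  structure(list(slope = sign_or_pos(r) * sqrt(syy / sxx),
                 intercept = NA_real_, r = r, r_squared = r^2,
                 p_value = cor_p(r, df = n - 1), n = n,
                 through_origin = TRUE),
            class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit%s: n = %d\n",
              if (x$through_origin) " (through origin)" else "", x$n))
  cat(sprintf("  slope = %.4f%s, r = %.4f, r2 = %.4f, p = %.4g\n", x$slope,
              if (is.na(x$intercept)) ""
              else sprintf(", intercept = %.4f", x$intercept),
              x$r, x$r_squared, x$p_value))
  invisible(x)
}

#' Pearson correlation with two-tailed test
#'
#' Requires n >= 4 because a Fisher-z variance 1/(n - 3) must exist for the
#' correlation to enter the site-level meta-analysis.
#'
#' @param x,y numeric vectors.
#' @return list with \code{r}, \code{p_value}, \code{n}.
#' @export
pearson_r <- function(x, y) {
  check_xy(x, y, min_n = 4)
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Wilcoxon signed-rank test for paired environment differences
#'
#' Differences are field minus greenhouse per species. Zero differences are
#' dropped (classic Wilcoxon); ties get average ranks; W is the sum of the
#' positive-difference ranks. For n <= 25 the two-tailed p-value is exact,
#' from the full sign-flip distribution of W (computed by dynamic
#' programming over the doubled ranks, which also covers ties); above 25 a
#' normal approximation with continuity and tie corrections is used.
#'
#' @param greenhouse,field paired species values.
#' @return object of class \code{paired_comparison}: differences, W,
#'   p_value, n_used, n_zero_dropped, median_difference, direction
#'   (sign of the median difference), method.
#' @export
wilcoxon_signed_rank <- function(greenhouse, field) {
  stopifnot(length(greenhouse) == length(field))
  ok <- stats::complete.cases(greenhouse, field)
  d <- (field - greenhouse)[ok]
  zero <- d == 0
  if (all(zero)) stop("no signal: all paired differences are zero")
  d <- d[!zero]
  n <- length(d)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= 25) {
    p <- wsr_exact_p(rk, W)
    method <- "exact"
  } else {
    p <- wsr_normal_p(rk, W)
    method <- "normal approximation"
  }
  structure(list(differences = d, W = W, p_value = p, n_used = n,
                 n_zero_dropped = sum(zero),
                 median_difference = stats::median(d),
                 direction = sign(stats::median(d)), method = method),
            class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W = %g, p = %.4g, n = %d",
              x$method, x$W, x$p_value, x$n_used))
  if (x$n_zero_dropped > 0)
    cat(sprintf(" (%d zero differences dropped)", x$n_zero_dropped))
  cat(sprintf("\n  median difference %.4g (%s)\n", x$median_difference,
              if (x$direction > 0) "field higher"
              else if (x$direction < 0) "field lower" else "no shift"))
  invisible(x)
}

# exact two-tailed p for the signed-rank statistic, ties included:
# counts of 2W over all 2^n sign patterns via subset-sum convolution on the
# doubled ranks (integers even with average ranks of .5)
wsr_exact_p <- function(ranks, W) {
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  counts <- numeric(total + 1)   # counts[k+1] = #patterns with 2W == k
  counts[1] <- 1
  for (si in s) {
    shifted <- c(rep(0, si), counts[seq_len(total + 1 - si)])
    counts <- counts + shifted
  }
  w2 <- as.integer(round(2 * W))
  p_le <- sum(counts[seq_len(w2 + 1)]) / 2^length(s)
  p_ge <- sum(counts[(w2 + 1):(total + 1)]) / 2^length(s)
  min(1, 2 * min(p_le, p_ge))
}

wsr_normal_p <- function(ranks, W) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  tie_tab <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

check_xy <- function(x, y, min_n, allow_constant = FALSE) {
  if (length(x) != length(y)) stop("x and y have different lengths")
  if (length(x) < min_n)
    stop("insufficient data: need at least ", min_n, " pairs")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input")
  if (!allow_constant && (stats::sd(x) == 0 || stats::sd(y) == 0))
    stop("degenerate input: zero variance")
  invisible(TRUE)
}

sign_or_pos <- function(r) if (r == 0) 1 else sign(r)

cor_p <- function(r, df) {
  if (abs(r) >= 1) return(0)
  t <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(t), df)
}
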