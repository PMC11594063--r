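# Resampling-based comparison of two surface-potential samples.
#
# Each iteration draws a fixed number of points from each sample and runs
# three two-sample tests: Welch's t (difference of means), Kolmogorov-
# Smirnov (maximum ECDF difference), and the two-sample Anderson-Darling
# test (tail-weighted ECDF discrepancy; Scholz-Stephens k-sample statistic,
# midrank version). Fixing the per-draw size keeps significance from being
# manufactured by simply measuring the surface at more points or more time
# frames. Per-iteration p-values are aggregated by their median (default) or
# by Fisher's combination. The effect size is the median potential shift,
# computed on the full samples.

# Scholz-Stephens asymptotic critical values of the standardized k-sample
# Anderson-Darling statistic: tm(alpha) = b0 + b1/sqrt(m) + b2/m, m = k - 1.
.ad_table <- data.frame(
  alpha = c(0.25, 0.10, 0.05, 0.025, 0.01),
  b0 = c(0.675, 1.281, 1.645, 1.960, 2.326),
  b1 = c(-0.245, 0.250, 0.678, 1.149, 1.822),
  b2 = c(-0.105, -0.305, -0.362, -0.391, -0.396)
)

# logit-scale interpolation of the published table (m = 1 for two samples);
# monotone spline inside the tabulated range, tangent extrapolation outside.
# Values below the table's smallest p are extrapolated on the log/logit
# scale, never clipped: silent capping would hide exactly the strongest
# surface changes this method chases.
ad_pvalue <- function(tstat, m = 1) {
  crit <- .ad_table$b0 + .ad_table$b1 / sqrt(m) + .ad_table$b2 / m
  lg <- log(.ad_table$alpha / (1 - .ad_table$alpha))
  sf <- stats::splinefun(crit, lg, method = "hyman")
  t_lo <- crit[1]
  t_hi <- crit[length(crit)]
  slope_lo <- sf(t_lo, deriv = 1)
  slope_hi <- sf(t_hi, deriv = 1)
  eval1 <- function(tt) {
    if (!is.finite(tt)) return(if (tt > 0) 0 else 1)
    if (tt < t_lo) {
      g <- lg[1] + slope_lo * (tt - t_lo)
    } else if (tt > t_hi) {
      g <- lg[length(lg)] + slope_hi * (tt - t_hi)
    } else {
      g <- sf(tt)
    }
    1 / (1 + exp(-g))
  }
  p <- vapply(tstat, eval1, 0)
  attr(p, "extrapolated") <- tstat < t_lo | tstat > t_hi
  p
}

# asymptotic two-sample Kolmogorov p-value: lambda = sqrt(nm/(n+m)) * D,
# Kolmogorov distribution evaluated by whichever series converges fast
ks_asymptotic_p <- function(D, n, m) {
  lam <- sqrt(n * m / (n + m)) * D
  p1 <- function(l) {
    if (l < 1e-3) return(1)
    if (l < 1) {
      # theta-function form, accurate for small lambda
      j <- 1:20
      cdf <- sqrt(2 * pi) / l * sum(exp(-(2 * j - 1)^2 * pi^2 / (8 * l^2)))
      return(max(0, min(1, 1 - cdf)))
    }
    j <- 1:100
    max(0, min(1, 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * l^2))))
  }
  vapply(lam, p1, 0)
}

welch_p <- function(tstat, df) {
  ifelse(is.finite(tstat), 2 * pt(-abs(tstat), df),
         ifelse(is.na(tstat), NA_real_, 0))
}

#' Two-sample test p-value
#'
#' One of three two-sample tests on the raw samples: Welch's unequal-variance
#' t (two-sided), Kolmogorov-Smirnov (asymptotic), or the two-sample
#' Anderson-Darling test (Scholz-Stephens midrank statistic with p from the
#' published asymptotic interpolation, extrapolated -- not clipped -- beyond
#' its range; the attribute `extrapolated` flags that case). All three are
#' invariant to exchanging `x` and `y`. Two identical constant samples give
#' p = 1 by convention.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @param test `"t"`, `"ks"`, or `"ad"`.
#' @return The p-value in `[0, 1]`.
#' @export
two_sample_p <- function(x, y, test = c("t", "ks", "ad")) {
  test <- match.arg(test)
  if (length(x) < 2 || length(y) < 2) stop("each sample must have size >= 2")
  constant <- length(unique(c(x, y))) == 1L
  if (constant) {
    p <- 1
    if (test == "ad") attr(p, "extrapolated") <- FALSE
    return(p)
  }
  s <- cpp_two_sample_stats(x, y)
  switch(test,
    t = {
      if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) 1
      else welch_p(s[["t"]], s[["df"]])
    },
    ks = ks_asymptotic_p(s[["ksD"]], length(x), length(y)),
    ad = ad_pvalue(s[["T"]])
  )
}

#' Significance at a threshold
#'
#' Strict inequality: p-values equal to `alpha` are not significant.
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param alpha Threshold (default 0.01).
#' @return Logical.
#' @export
is_significant <- function(p, alpha = 0.01) {
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  as.vector(p) < alpha
}

#' Resampling configuration
#'
#' @param n_points Points drawn from each sample per iteration (default 100).
#' @param n_iterations Number of resampling iterations (default 1000).
#' @param alpha Significance threshold (default 0.01).
#' @param seed RNG seed; every draw is reproducible given it.
#' @param aggregation How to collapse per-iteration p-values: `"median_p"`
#'   (median across iterations; calibrated under the null) or `"fisher"`
#'   (Fisher's combination, reported with a caveat since iterations reuse
#'   the same underlying samples and are not independent).
#' @param with_replacement Draw with replacement (default TRUE; keeps the
#'   procedure valid when a local region has fewer vertices than
#'   `n_points`).
#' @return A list of class `resampling_config`.
#' @export
resampling_config <- function(n_points = 100, n_iterations = 1000,
                              alpha = 0.01, seed = 1,
                              aggregation = c("median_p", "fisher"),
                              with_replacement = TRUE) {
  aggregation <- match.arg(aggregation)
  stopifnot(n_points >= 2, n_iterations >= 1, alpha > 0, alpha < 1)
  structure(
    list(n_points = as.integer(n_points),
         n_iterations = as.integer(n_iterations), alpha = alpha,
         seed = as.integer(seed), aggregation = aggregation,
         with_replacement = isTRUE(with_replacement)),
    class = "resampling_config"
  )
}

#' Resampled comparison of two potential samples
#'
#' Runs `n_iterations` resampling iterations, each drawing `n_points` values
#' from the wild-type and variant samples and computing all three test
#' p-values, then aggregates per the configuration. The median potential
#' shift (variant minus wild-type) is computed on the full samples, not on
#' resamples. Deterministic given the seed.
#'
#' @param wt_values,mut_values Full potential samples (kBT/ec).
#' @param cfg A [resampling_config()].
#' @return A `comparison_result`: aggregated `p_T`, `p_KS`, `p_AD`, the
#'   3 x n_iterations `per_iteration_p` matrix, `median_shift`, `median_wt`,
#'   `median_mut`, sample sizes, notes, and the configuration echo.
#' @export
resampled_comparison <- function(wt_values, mut_values,
                                 cfg = resampling_config()) {
  stopifnot(inherits(cfg, "resampling_config"))
  n_wt <- length(wt_values)
  n_mut <- length(mut_values)
  if (!cfg$with_replacement &&
      (cfg$n_points > n_wt || cfg$n_points > n_mut)) {
    stop("n_points exceeds a sample size and with_replacement = FALSE")
  }
  if (n_wt < 2 || n_mut < 2) stop("each sample must have size >= 2")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  ni <- cfg$n_iterations
  np <- cfg$n_points
  ix <- if (cfg$with_replacement) {
    matrix(sample.int(n_wt, ni * np, replace = TRUE), nrow = ni)
  } else {
    t(vapply(seq_len(ni), function(i) sample.int(n_wt, np), integer(np)))
  }
  iy <- if (cfg$with_replacement) {
    matrix(sample.int(n_mut, ni * np, replace = TRUE), nrow = ni)
  } else {
    t(vapply(seq_len(ni), function(i) sample.int(n_mut, np), integer(np)))
  }

  stats_mat <- cpp_resample_kernel(wt_values, mut_values, ix, iy)
  p_t <- welch_p(stats_mat[, 1], stats_mat[, 2])
  p_ks <- ks_asymptotic_p(stats_mat[, 3], np, np)
  p_ad_full <- ad_pvalue(stats_mat[, 4])
  extrap <- attr(p_ad_full, "extrapolated")
  p_ad <- as.vector(p_ad_full)
  # degenerate draws (both subsamples constant and equal) carry no evidence
  p_t[is.na(p_t)] <- 1

  per_iteration_p <- rbind(t = p_t, ks = p_ks, ad = p_ad)

  agg <- function(p) {
    if (cfg$aggregation == "median_p") median(p)
    else pchisq(-2 * sum(log(pmax(p, 1e-320))), df = 2 * length(p),
                lower.tail = FALSE)
  }
  notes <- character(0)
  if (cfg$aggregation == "fisher") {
    notes <- c(notes, paste(
      "Fisher combination treats iterations as independent, but resampling",
      "iterations reuse the same underlying samples; combined p-values are",
      "anti-conservative."))
  }
  if (any(extrap)) {
    notes <- c(notes,
               "some AD p-values extrapolated beyond the asymptotic table")
  }
  structure(
    list(
      p_T = agg(p_t), p_KS = agg(p_ks), p_AD = agg(p_ad),
      per_iteration_p = per_iteration_p,
      ad_extrapolated = any(extrap),
      median_wt = median(wt_values), median_mut = median(mut_values),
      median_shift = median(mut_values) - median(wt_values),
      n_wt = n_wt, n_mut = n_mut,
      notes = notes, config = cfg
    ),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "<comparison_result> n_wt=%d n_mut=%d  median shift %+.4f kBT/ec\n",
    x$n_wt, x$n_mut, x$median_shift))
  cat(sprintf("  p_T  = %s\n  p_KS = %s\n  p_AD = %s   [%s aggregation]\n",
              format_pvalue(x$p_T), format_pvalue(x$p_KS),
              format_pvalue(x$p_AD), x$config$aggregation))
  invisible(x)
}

# paper-table style: 3 significant digits scientific; underflow as a string
format_pvalue <- function(p) {
  ifelse(!is.finite(p) | p < 1e-300,
         "<1e-300",
         formatC(p, format = "e", digits = 2))
}
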