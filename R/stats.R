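# Estimation statistics for unpaired two-group comparisons: mean
# differences with BCa bootstrap confidence intervals, permutation
# p-values, and Welch's t as a convenience check.

check_group <- function(x, name) {
  x <- as.numeric(x)
  if (length(x) < 2L || any(!is.finite(x)))
    stop(sprintf("group '%s' needs >= 2 finite values", name))
  x
}

#' Unpaired mean difference
#'
#' Orientation convention: `a` is the control/reference group and `b` the
#' comparison group, so the effect is `mean(b) - mean(a)`.
#'
#' @param a,b numeric vectors.
#' @return `mean(b) - mean(a)`.
#' @export
mean_difference <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty group")
  mean(b) - mean(a)
}

#' BCa bootstrap confidence interval for the unpaired mean difference
#'
#' Each group is resampled with replacement independently `n_boot` times.
#' The bias-correction constant z0 is the normal quantile of the fraction
#' of bootstrap statistics strictly below the observed difference; the
#' acceleration constant comes from a jackknife over the pooled
#' leave-one-out differences. When z0 is infinite (all bootstrap statistics
#' on one side of the estimate) or the jackknife variance is zero, the
#' interval falls back to the plain percentile interval and this is
#' recorded in the result.
#'
#' @param a,b numeric vectors, each with >= 2 finite values.
#' @param n_boot bootstrap resamples (default 5000, the published
#'   convention).
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @param seed integer RNG seed; identical seed gives an identical
#'   interval.
#' @return List with `ci_low`, `ci_high`, `estimate`, `n_boot`, `alpha`,
#'   `method` (`"bca"` or `"percentile"`) and `seed`.
#' @export
bca_ci <- function(a, b, n_boot = 5000L, alpha = 0.05, seed = 1L) {
  a <- check_group(a, "a"); b <- check_group(b, "b")
  obs <- mean_difference(a, b)
  boots <- with_seed(seed, {
    ia <- matrix(sample.int(length(a), n_boot * length(a), replace = TRUE),
                 nrow = n_boot)
    ib <- matrix(sample.int(length(b), n_boot * length(b), replace = TRUE),
                 nrow = n_boot)
    rowMeans(matrix(b[ib], nrow = n_boot)) -
      rowMeans(matrix(a[ia], nrow = n_boot))
  })
  # jackknife over the pooled leave-one-out differences
  jk <- c(vapply(seq_along(a), function(i) mean(b) - mean(a[-i]), 0),
          vapply(seq_along(b), function(i) mean(b[-i]) - mean(a), 0))
  jbar <- mean(jk)
  num <- sum((jbar - jk)^3)
  den <- 6 * sum((jbar - jk)^2)^1.5
  z0 <- stats::qnorm(mean(boots < obs))
  method <- "bca"
  if (!is.finite(z0) || den == 0) {
    method <- "percentile"
    probs <- c(alpha / 2, 1 - alpha / 2)
  } else {
    acc <- num / den
    zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
    probs <- stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
  }
  ci <- unname(stats::quantile(boots, probs, type = 7))
  list(ci_low = ci[1], ci_high = ci[2], estimate = obs,
       n_boot = as.integer(n_boot), alpha = alpha, method = method,
       seed = as.integer(seed))
}

#' Two-sided permutation test for a difference in means
#'
#' Pooled values are randomly relabeled at the observed group sizes;
#' permutations whose absolute mean difference is at least the observed
#' absolute difference count as extreme. The Monte-Carlo estimate uses the
#' add-one convention `p = (b + 1) / (n_perm + 1)`, so p is never exactly
#' zero. With `exhaustive = TRUE` all distinct splits are enumerated and
#' the exact extreme fraction is returned (feasible for small groups).
#'
#' @param a,b numeric vectors, each with >= 2 values.
#' @param n_perm random relabelings (default 5000).
#' @param seed integer RNG seed.
#' @param exhaustive enumerate all `choose(na + nb, na)` splits instead of
#'   sampling.
#' @return List with `p`, `observed`, `n_perm` (or the number of splits),
#'   `mode` and `seed`.
#' @export
permutation_p <- function(a, b, n_perm = 5000L, seed = 1L,
                          exhaustive = FALSE) {
  a <- check_group(a, "a"); b <- check_group(b, "b")
  obs <- abs(mean_difference(a, b))
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  tot <- sum(pool)
  # |mean(b*) - mean(a*)| from the sum of the permuted a-group
  absdiff_from_sa <- function(sa)
    abs((tot - sa) / (n - na) - sa / na)
  if (exhaustive) {
    splits <- utils::combn(n, na)
    d <- apply(splits, 2, function(ix) absdiff_from_sa(sum(pool[ix])))
    n_extreme <- sum(d >= obs - 1e-12)
    return(list(p = n_extreme / ncol(splits), observed = obs,
                n_perm = ncol(splits), mode = "exhaustive", seed = NA_integer_))
  }
  d <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    absdiff_from_sa(sum(pool[sample.int(n, na)])), 0))
  b_extreme <- sum(d >= obs - 1e-12)
  list(p = (b_extreme + 1) / (n_perm + 1), observed = obs,
       n_perm = as.integer(n_perm), mode = "monte-carlo",
       seed = as.integer(seed))
}

#' Welch's two-sample t test
#'
#' Direct evaluation of the Welch statistic and Welch-Satterthwaite degrees
#' of freedom, with a two-sided p from the t distribution. Provided as a
#' conventional-significance companion to the estimation statistics.
#'
#' @param a,b numeric vectors, each >= 2 values; at least one group must
#'   have nonzero variance.
#' @return List with `t`, `df`, `p`. The sign convention matches
#'   [mean_difference()]: `t > 0` when `mean(b) > mean(a)`.
#' @export
welch_t <- function(a, b) {
  a <- check_group(a, "a"); b <- check_group(b, "b")
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    stop("both groups have zero variance")
  }
  t <- (mean(b) - mean(a)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Full effect-size summary for one comparison
#'
#' Bundles the unpaired mean difference, its BCa 95% interval, the
#' permutation p-value and Welch's t into the row format used by the
#' reporting stage.
#'
#' @param a,b numeric vectors (control, comparison).
#' @param n_boot,n_perm resample counts (defaults 5000).
#' @param alpha interval level (default 0.05).
#' @param seed integer RNG seed; the bootstrap and permutation streams are
#'   derived from it deterministically.
#' @param name comparison label.
#' @return A one-row data.frame of class `effect_size`.
#' @export
effect_size <- function(a, b, n_boot = 5000L, n_perm = 5000L, alpha = 0.05,
                        seed = 1L, name = "b_vs_a") {
  ci <- bca_ci(a, b, n_boot = n_boot, alpha = alpha, seed = seed)
  pp <- permutation_p(a, b, n_perm = n_perm, seed = seed + 1L)
  wt <- welch_t(a, b)
  out <- data.frame(comparison = name, n_a = length(a), n_b = length(b),
                    mean_diff = ci$estimate, ci_low = ci$ci_low,
                    ci_high = ci$ci_high, ci_method = ci$method,
                    perm_p = pp$p, welch_t = wt$t, welch_df = wt$df,
                    welch_p = wt$p, n_boot = ci$n_boot, n_perm = pp$n_perm,
                    alpha = alpha, seed = as.integer(seed),
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_size", class(out))
  out
}
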