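#' Construct a variance-components object directly
#'
#' Builds a `varcomp` object from known between- and within-donor variances,
#' e.g. published component estimates or generator truths, so that the
#' reference-interval machinery can be driven without refitting.
#'
#' @param sigma2_between,sigma2_within Non-negative variances (same units).
#' @param n Total number of samples the components refer to.
#' @param k Number of donors.
#' @param center Optional grand mean on the analysis scale.
#' @param method Label recorded in the object.
#' @return An object of class `varcomp`.
#' @examples
#' varcomp(1.47, 1.49, n = 240, k = 40)
#' @export
varcomp <- function(sigma2_between, sigma2_within, n, k, center = NA_real_,
                    method = "supplied") {
  if (sigma2_between < 0 || sigma2_within < 0) {
    ctvar_abort("Variance components must be non-negative.", "config")
  }
  if (n < k || k < 1) ctvar_abort("Need n >= k >= 1.", "config")
  total <- sigma2_between + sigma2_within
  structure(
    list(
      sigma2_between = sigma2_between,
      sigma2_within = sigma2_within,
      sigma2_total = total,
      icc = if (total > 0) sigma2_between / total else 0,
      percent_between = if (total > 0) 100 * sigma2_between / total else 0,
      percent_within = if (total > 0) 100 * sigma2_within / total else 100,
      method = method,
      n_used = as.integer(n),
      k_used = as.integer(k),
      center = center
    ),
    class = "varcomp"
  )
}

# shared entry: pull value/donor columns, drop NA, validate grouping
varcomp_prepare <- function(data, value, donor) {
  y <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ donor }}))
  keep <- !is.na(y)
  y <- y[keep]
  g <- g[keep]
  if (length(y) == 0) ctvar_abort("No non-missing observations.", "data")
  n_i <- table(g)
  if (length(n_i) < 2) {
    ctvar_abort("Variance decomposition needs observations from >= 2 donors.",
                "data")
  }
  if (all(n_i < 2)) {
    ctvar_abort(
      "Within-donor variance is unidentifiable: every donor has one observation.",
      "data")
  }
  list(y = y, g = g, n_i = as.vector(n_i))
}

#' One-way random-effects variance components by method-of-moments ANOVA
#'
#' Fits the model `y_ij = mu + b_i + e_ij`, `b_i ~ N(0, sigma2_between)`,
#' `e_ij ~ N(0, sigma2_within)`, by equating mean squares: `sigma2_within =
#' MSW`; `sigma2_between = max(0, (MSB - MSW) / m0)` with the unbalanced
#' coefficient `m0 = (N - sum(n_i^2)/N) / (k - 1)` (which reduces to the
#' common visit count for balanced designs). A negative moment estimate of
#' the between component is truncated to zero. Missing values are dropped
#' listwise; donors left with no observations do not count towards `k`.
#'
#' @param data A data frame with one row per sample.
#' @param value Column holding the response (e.g. `delta_ct` or a log2
#'   enzyme level), tidy-eval.
#' @param donor Column identifying the donor, tidy-eval.
#' @return A `varcomp` object; see [tidy.varcomp()] and [glance.varcomp()].
#' @examples
#' d <- tibble::tibble(donor = rep(1:3, each = 2), y = c(0, 0, 1, 1, 4, 4))
#' fit_anova(d, y, donor)
#' @export
fit_anova <- function(data, value, donor) {
  pp <- varcomp_prepare(data, {{ value }}, {{ donor }})
  y <- pp$y; g <- pp$g; n_i <- pp$n_i
  n <- length(y); k <- length(n_i)
  means <- tapply(y, g, mean)
  grand <- mean(y)
  ssw <- sum((y - means[g])^2)
  ssb <- sum(n_i * (sort_by_name(means, g) - grand)^2)
  msw <- ssw / (n - k)
  msb <- ssb / (k - 1)
  m0 <- (n - sum(n_i^2) / n) / (k - 1)
  varcomp(max(0, (msb - msw) / m0), msw, n = n, k = k, center = grand,
          method = "anova")
}

# tapply returns means in sorted-name order; align n_i (from table, same
# sorted order) with them
sort_by_name <- function(means, g) means[sort(unique(g))]

#' One-way random-effects variance components by REML
#'
#' Maximizes the restricted likelihood of the Gaussian one-way
#' random-intercept model by one-dimensional search over the variance ratio
#' `lambda = sigma2_between / sigma2_within`, profiling out `sigma2_within`
#' in closed form. With `w_i = n_i / (1 + n_i * lambda)` and GLS mean
#' `mu(lambda) = sum(w_i * ybar_i) / sum(w_i)`, the profiled -2 restricted
#' log-likelihood is, up to a constant,
#' `(N - 1) * log Q + sum(log(1 + n_i * lambda)) + log(sum(w_i))` where
#' `Q = SS_within + sum(w_i * (ybar_i - mu)^2)`; then
#' `sigma2_within = Q / (N - 1)`. The boundary `lambda = 0` is always
#' compared with the interior optimum, so datasets whose between-group mean
#' square falls below the within mean square return a zero between
#' component. On balanced designs with an interior solution REML coincides
#' with the ANOVA estimator.
#'
#' @inheritParams fit_anova
#' @param tol Convergence tolerance of the one-dimensional search, on the
#'   lambda scale.
#' @param lambda_max Upper bound of the search interval for the variance
#'   ratio.
#' @return A `varcomp` object with `method = "reml"`.
#' @export
fit_reml <- function(data, value, donor, tol = 1e-10, lambda_max = 1e6) {
  pp <- varcomp_prepare(data, {{ value }}, {{ donor }})
  y <- pp$y; g <- pp$g; n_i <- pp$n_i
  n <- length(y); k <- length(n_i)
  means <- sort_by_name(tapply(y, g, mean), g)
  ssw <- sum((y - tapply(y, g, mean)[g])^2)

  q_of <- function(lambda) {
    w <- n_i / (1 + n_i * lambda)
    mu <- sum(w * means) / sum(w)
    list(q = ssw + sum(w * (means - mu)^2), w = w, mu = mu)
  }
  neg2rll <- function(lambda) {
    qq <- q_of(lambda)
    (n - 1) * log(qq$q) + sum(log1p(n_i * lambda)) + log(sum(qq$w))
  }
  opt <- optimize(neg2rll, interval = c(0, lambda_max), tol = tol)
  lambda <- if (neg2rll(0) <= opt$objective) 0 else opt$minimum
  if (lambda > 0.99 * lambda_max) {
    ctvar_abort(
      "REML search hit the upper bound of the variance-ratio interval.",
      "numeric")
  }
  qq <- q_of(lambda)
  s2w <- qq$q / (n - 1)
  varcomp(lambda * s2w, s2w, n = n, k = k, center = mean(y), method = "reml")
}

#' Per-component summary of a variance decomposition
#'
#' @param vc A `varcomp` object.
#' @return A tibble with one row per component (between, within, total):
#'   `component`, `std_dev`, `variance`, `percent`.
#' @export
summarize_components <- function(vc) {
  stopifnot(inherits(vc, "varcomp"))
  tibble(
    component = c("between", "within", "total"),
    std_dev = sqrt(c(vc$sigma2_between, vc$sigma2_within, vc$sigma2_total)),
    variance = c(vc$sigma2_between, vc$sigma2_within, vc$sigma2_total),
    percent = c(vc$percent_between, vc$percent_within, 100)
  )
}

#' @rdname summarize_components
#' @param x A `varcomp` object.
#' @param ... Unused.
#' @export
tidy.varcomp <- function(x, ...) summarize_components(x)

#' One-row summary of a variance decomposition
#'
#' @param x A `varcomp` object.
#' @param ... Unused.
#' @return A one-row tibble with the components, ICC, percentage split,
#'   method and sample/donor counts.
#' @export
glance.varcomp <- function(x, ...) {
  tibble(
    sigma2_between = x$sigma2_between,
    sigma2_within = x$sigma2_within,
    sigma2_total = x$sigma2_total,
    icc = x$icc,
    percent_between = x$percent_between,
    percent_within = x$percent_within,
    method = x$method,
    n_used = x$n_used,
    k_used = x$k_used
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "One-way variance components (%s): n = %d samples, k = %d donors\n",
    x$method, x$n_used, x$k_used))
  cat(sprintf("  between %.4g  within %.4g  total %.4g  (ICC %.3f)\n",
              x$sigma2_between, x$sigma2_within, x$sigma2_total, x$icc))
  invisible(x)
}
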