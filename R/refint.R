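#' Study design descriptor
#'
#' Records the clustered sampling design: `k` donors each contributing a
#' number of visits. Used to derive the design effect and effective sample
#' size for reference intervals.
#'
#' @param k Number of donors (>= 2).
#' @param visits Visits per donor: a single count for balanced designs or a
#'   length-`k` vector.
#' @return A list of class `study_design` with `k`, `n_i`, `n` (total
#'   samples) and `m_bar` (mean cluster size).
#' @examples
#' study_design(40, 6)  # 240 samples, mean cluster size 6
#' @export
study_design <- function(k, visits) {
  if (k < 2) ctvar_abort("A study design needs k >= 2 donors.", "config")
  n_i <- if (length(visits) == 1) rep(visits, k) else visits
  if (length(n_i) != k || any(n_i < 1)) {
    ctvar_abort("`visits` must be a scalar or a length-k vector of counts >= 1.",
                "config")
  }
  n <- sum(n_i)
  structure(list(k = as.integer(k), n_i = as.integer(n_i), n = as.integer(n),
                 m_bar = n / k),
            class = "study_design")
}

as_study_design <- function(design) {
  if (inherits(design, "study_design")) return(design)
  ctvar_abort("`design` must be a study_design object.", "config")
}

#' Effective sample size under clustering
#'
#' Repeated measures on the same donor are correlated (intraclass
#' correlation `icc`), so `n` clustered samples carry less information than
#' `n` independent ones. The Kish design effect for (mean) cluster size
#' `m_bar = n / k` is `D = 1 + (m_bar - 1) * icc`, and the effective sample
#' size is `n / D`: it equals `n` for independent data (`icc = 0`) and falls
#' to `k` when all within-donor measurements are perfectly correlated
#' (`icc = 1`).
#'
#' @param n Total number of samples.
#' @param k Number of donors.
#' @param icc Intraclass correlation in \[0, 1\].
#' @return The (real-valued) effective sample size.
#' @examples
#' effective_sample_size(240, 40, 0)  # 240
#' effective_sample_size(240, 40, 1)  # 40
#' @export
effective_sample_size <- function(n, k, icc) {
  if (!(n >= k && k >= 1)) ctvar_abort("Need n >= k >= 1.", "config")
  if (is.na(icc) || icc < 0 || icc > 1) {
    ctvar_abort("`icc` must lie in [0, 1].", "config")
  }
  m_bar <- n / k
  n / (1 + (m_bar - 1) * icc)
}

# scalar primitive: fold span of a 2-sided interval with the given SD
# policy "fixed_2sd": 2^(4 sd); "t_df": 2^(2 t sd) at the supplied df
fold_from_sd <- function(sd, policy, df = NULL, coverage = 0.95) {
  if (sd == 0) return(1)
  switch(policy,
    fixed_2sd = 2^(4 * sd),
    t_df = {
      if (is.null(df) || df <= 0) ctvar_abort("t policy needs df > 0.", "config")
      2^(2 * qt(1 - (1 - coverage) / 2, df) * sd)
    },
    ctvar_abort(paste0("Unknown fold policy: ", policy), "config")
  )
}

#' Total 95% reference interval from variance components
#'
#' Builds the interval expected to contain `coverage` of the population of
#' single measurements, centred on the mean delta-Ct and using the model
#' total SD `sqrt(sigma2_between + sigma2_within)`. Because the samples are
#' clustered within donors, the t multiplier uses degrees of freedom derived
#' from the effective sample size: `df = n_eff - 1` with
#' `n_eff = effective_sample_size(n, k, icc)`. The df is kept continuous
#' (not floored); `qt()` accepts real df and flooring would discretely
#' widen intervals.
#'
#' Bounds are reported on the delta-Ct scale and mapped to relative
#' expression via `2^(-dCt)`; the fold-change span is `2^(upper - lower)`,
#' which equals the ratio of the relative-expression bounds.
#'
#' @param vc A `varcomp` object.
#' @param design A [study_design()]. Defaults to the design recorded in the
#'   fit (`n_used` donors-by-samples with equal cluster sizes inferred from
#'   `n_used / k_used`).
#' @param center Interval centre (mean delta-Ct). Defaults to the grand mean
#'   stored in `vc`.
#' @param coverage Two-sided coverage, default 0.95.
#' @return A one-row tibble of class `ref_interval`: `center`, `lower`,
#'   `upper`, `width`, `coverage`, `df`, `multiplier`, `fold_change`,
#'   `rel_expr_center`, `rel_expr_lower`, `rel_expr_upper`.
#' @examples
#' vc <- varcomp(1.47, 1.49, n = 240, k = 40)
#' total_reference_interval(vc, study_design(40, 6), center = 3.6)
#' @export
total_reference_interval <- function(vc, design = NULL, center = NULL,
                                     coverage = 0.95) {
  stopifnot(inherits(vc, "varcomp"))
  if (!(coverage > 0 && coverage < 1)) {
    ctvar_abort("`coverage` must be in (0, 1).", "config")
  }
  if (is.null(design)) {
    design <- study_design(vc$k_used, vc$n_used / vc$k_used)
  }
  design <- as_study_design(design)
  if (is.null(center)) center <- vc$center
  sd_tot <- sqrt(vc$sigma2_total)
  n_eff <- effective_sample_size(design$n, design$k, vc$icc)
  df <- n_eff - 1
  if (df <= 0) ctvar_abort("Effective sample size gives df <= 0.", "config")
  mult <- qt(1 - (1 - coverage) / 2, df)
  lower <- center - mult * sd_tot
  upper <- center + mult * sd_tot
  out <- tibble(
    center = center, lower = lower, upper = upper, width = upper - lower,
    coverage = coverage, df = df, multiplier = mult,
    fold_change = 2^(upper - lower),
    rel_expr_center = 2^(-center),
    rel_expr_lower = 2^(-upper),
    rel_expr_upper = 2^(-lower)
  )
  class(out) <- c("ref_interval", class(out))
  out
}

#' Fold-change range of a single variance component
#'
#' Expresses the spread attributable to one component (between-donor,
#' within-donor, or total) as a fold change of relative expression, under a
#' selectable policy:
#' \describe{
#'   \item{`t_component_df`}{`2^(2 * t * SD)` with the t quantile at the
#'     component's own degrees of freedom — `k - 1` for the between
#'     component, `n - k` for within. For the total component this policy
#'     falls back to the effective-sample-size df, since the total has no
#'     single ANOVA stratum. Default for miRNA delta-Ct tables.}
#'   \item{`fixed_2sd`}{`2^(4 * SD)`, i.e. mean +/- 2 SD on the log2 scale.
#'     Conventional for clinical-chemistry analytes.}
#'   \item{`t_effective_n`}{`2^(2 * t * SD)` with df = effective n - 1, the
#'     same multiplier as [total_reference_interval()].}
#' }
#'
#' @param vc A `varcomp` object.
#' @param component `"between"`, `"within"` or `"total"`.
#' @param design A [study_design()]; defaults as in
#'   [total_reference_interval()].
#' @param policy Fold policy; see Details.
#' @param coverage Coverage for the t policies.
#' @return A single fold change (>= 1).
#' @examples
#' vc <- varcomp(1.47, 1.49, n = 240, k = 40)
#' component_fold_range(vc, "within")   # t at df = 200
#' @export
component_fold_range <- function(vc, component = c("between", "within", "total"),
                                 design = NULL,
                                 policy = c("t_component_df", "fixed_2sd",
                                            "t_effective_n"),
                                 coverage = 0.95) {
  stopifnot(inherits(vc, "varcomp"))
  component <- tryCatch(match.arg(component),
                        error = function(e) ctvar_abort(
                          "Unknown component tag.", "config"))
  policy <- match.arg(policy)
  if (is.null(design)) design <- study_design(vc$k_used, vc$n_used / vc$k_used)
  design <- as_study_design(design)
  sd_c <- sqrt(switch(component,
                      between = vc$sigma2_between,
                      within = vc$sigma2_within,
                      total = vc$sigma2_total))
  if (policy == "fixed_2sd") return(fold_from_sd(sd_c, "fixed_2sd"))
  df <- switch(policy,
    t_component_df = switch(component,
      between = design$k - 1,
      within = design$n - design$k,
      total = effective_sample_size(design$n, design$k, vc$icc) - 1),
    t_effective_n = effective_sample_size(design$n, design$k, vc$icc) - 1
  )
  fold_from_sd(sd_c, "t_df", df = df, coverage = coverage)
}
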