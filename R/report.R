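#' Study-level analysis configuration
#'
#' @param qc A [qc_config()].
#' @param panel_size,candidate_completeness Passed to
#'   [select_normalizer_panel()].
#' @param spike_in_assay Assay id of the exogenous control, or `NULL` to
#'   skip the spike-in scheme.
#' @param schemes Normalization schemes to run: subset of
#'   `c("panel", "spike_in")`.
#' @param coverage Two-sided reference-interval coverage.
#' @param mirna_fold_policy Fold-range policy for miRNA component rows; see
#'   [component_fold_range()].
#' @param enzyme_fold_policy Fold-range policy for enzyme component rows.
#' @param correlate_assay Assay whose expression is correlated with enzyme
#'   levels, or `NULL` to skip.
#' @return A list of class `study_config`.
#' @export
study_config <- function(qc = qc_config(), panel_size = 5,
                         candidate_completeness = 0.99,
                         spike_in_assay = NULL,
                         schemes = c("panel", "spike_in"),
                         coverage = 0.95,
                         mirna_fold_policy = "t_component_df",
                         enzyme_fold_policy = "fixed_2sd",
                         correlate_assay = NULL) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  if ("spike_in" %in% schemes && is.null(spike_in_assay)) {
    ctvar_abort("Spike-in scheme requested but `spike_in_assay` is NULL.",
                "config")
  }
  structure(
    list(qc = qc, panel_size = panel_size,
         candidate_completeness = candidate_completeness,
         spike_in_assay = spike_in_assay, schemes = schemes,
         coverage = coverage,
         mirna_fold_policy = mirna_fold_policy,
         enzyme_fold_policy = enzyme_fold_policy,
         correlate_assay = correlate_assay),
    class = "study_config"
  )
}

# fit one assay's delta-Ct and assemble the per-assay report row
analyse_one_assay <- function(d, scheme, coverage, policy) {
  vc <- fit_anova(d, .data$delta_ct, .data$donor_id)
  n_i <- d |>
    dplyr::filter(!is.na(.data$delta_ct)) |>
    dplyr::count(.data$donor_id)
  design <- study_design(nrow(n_i), n_i$n)
  ri <- total_reference_interval(vc, design, coverage = coverage)
  tibble(
    n = vc$n_used, k = vc$k_used,
    mean_dct = vc$center,
    rel_expr = 2^(-vc$center),
    sigma2_between = vc$sigma2_between,
    sigma2_within = vc$sigma2_within,
    sigma2_total = vc$sigma2_total,
    icc = vc$icc,
    percent_between = vc$percent_between,
    percent_within = vc$percent_within,
    lower_dct = ri$lower, upper_dct = ri$upper,
    rel_expr_lower = ri$rel_expr_lower, rel_expr_upper = ri$rel_expr_upper,
    fold_total = ri$fold_change,
    fold_between = component_fold_range(vc, "between", design, policy,
                                        coverage),
    fold_within = component_fold_range(vc, "within", design, policy, coverage)
  )
}

#' Run the full cohort analysis
#'
#' Orchestrates the pipeline on a replicate-level Ct table: replicate QC and
#' aggregation, assay completeness filtering, normalizer-panel selection,
#' delta-Ct under the configured schemes, a one-way random-effects variance
#' decomposition per assay per scheme, and 95% reference intervals with
#' component fold ranges. If per-sample enzyme columns (`ALT`, `AST`, ...)
#' are present in `metadata`, they are analysed on the log2 scale through
#' the same variance-component and interval machinery with the enzyme fold
#' policy, and (when `correlate_assay` is set) correlated with the focal
#' assay's expression.
#'
#' @param data Replicate tibble as from [read_replicate_table()] or
#'   [simulate_study()].
#' @param metadata Optional per-sample metadata tibble (`donor_id`,
#'   `visit_index`, donor covariates, enzyme columns).
#' @param config A [study_config()].
#' @return A list of class `study_report` with `assays` (tidy per-assay,
#'   per-scheme results), `enzymes`, `correlations`, `panel`,
#'   `completeness`, `config`.
#' @export
run_study <- function(data, metadata = NULL, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(metadata)) {
    extra <- setdiff(unique(data$donor_id), unique(metadata$donor_id))
    if (length(extra) > 0) {
      ctvar_abort(paste0("Donors absent from metadata: ",
                         paste(extra, collapse = ", ")), "data")
    }
  }
  mat <- qc_replicates(data, config$qc)
  mat <- filter_assay_completeness(mat, config$qc)
  completeness <- attr(mat, "completeness_report")

  panel <- NULL
  deltas <- list()
  if ("panel" %in% config$schemes) {
    panel <- select_normalizer_panel(mat, config$panel_size,
                                     config$candidate_completeness)
    deltas$panel <- delta_ct(mat, panel, "panel")
  }
  if ("spike_in" %in% config$schemes) {
    deltas$spike_in <- delta_ct(mat, config$spike_in_assay, "spike_in")
  }

  assay_rows <- purrr::imap(deltas, function(d, scheme) {
    d |>
      dplyr::filter(!.data$is_spike_in) |>
      dplyr::group_by(.data$assay_id) |>
      dplyr::group_modify(~ analyse_one_assay(.x, scheme, config$coverage,
                                              config$mirna_fold_policy)) |>
      dplyr::ungroup() |>
      dplyr::mutate(scheme = scheme, .after = "assay_id")
  })
  assays <- dplyr::bind_rows(assay_rows)

  enzymes <- NULL
  correlations <- NULL
  if (!is.null(metadata)) {
    enzyme_cols <- setdiff(names(metadata),
                           c("donor_id", "visit_index", "sex",
                             "ethnicity_group", "age"))
    enzyme_cols <- enzyme_cols[vapply(metadata[enzyme_cols], is.numeric,
                                      TRUE)]
    if (length(enzyme_cols) > 0) {
      enzymes <- purrr::map_dfr(enzyme_cols, function(e) {
        d <- metadata |>
          dplyr::transmute(.data$donor_id, .data$visit_index,
                           value = log2(.data[[e]])) |>
          dplyr::filter(!is.na(.data$value))
        vc <- fit_anova(d, .data$value, .data$donor_id)
        td <- summarize_components(vc)
        td$fold <- vapply(td$component, function(comp) {
          component_fold_range(vc, comp, policy = config$enzyme_fold_policy,
                               coverage = config$coverage)
        }, 0, USE.NAMES = FALSE)
        dplyr::mutate(td, enzyme = e, .before = 1)
      })
      if (!is.null(config$correlate_assay)) {
        correlations <- purrr::imap_dfr(deltas, function(d, scheme) {
          correlate_with_enzymes(d, config$correlate_assay, metadata,
                                 enzyme_cols) |>
            dplyr::mutate(scheme = scheme, .before = 1)
        })
      }
    }
  }

  structure(
    list(assays = assays, enzymes = enzymes, correlations = correlations,
         panel = panel, completeness = completeness, config = config),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Cohort study report\n")
  cat("  assays analysed:", dplyr::n_distinct(x$assays$assay_id),
      "| schemes:", paste(unique(x$assays$scheme), collapse = ", "), "\n")
  if (!is.null(x$panel)) {
    cat("  normalizer panel:", paste(x$panel$assay_ids, collapse = ", "), "\n")
  }
  if (!is.null(x$enzymes)) {
    cat("  enzymes:", paste(unique(x$enzymes$enzyme), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reference intervals within donor strata
#'
#' Re-runs the variance decomposition and total reference interval within
#' each donor-level stratum of an already-normalized delta-Ct table (the
#' normalizer panel stays fixed at the cohort level). Strata never split a
#' donor's visits. Strata with fewer than 2 donors are skipped with a
#' warning. The ratio of fold spans between strata quantifies differential
#' variability.
#'
#' @param delta Delta-Ct tibble from [delta_ct()].
#' @param metadata Tibble with `donor_id` and the stratifying covariate
#'   (one value per donor).
#' @param stratify_by Name of the stratifying column in `metadata` (string).
#' @param assay Optional assay id(s) to restrict to; default all.
#' @param coverage Interval coverage.
#' @return A list: `intervals` (tibble per assay x stratum with components
#'   and fold span) and `fold_ratio` (per assay, max/min fold across
#'   strata).
#' @export
stratified_intervals <- function(delta, metadata, stratify_by,
                                 assay = NULL, coverage = 0.95) {
  if (!stratify_by %in% names(metadata)) {
    ctvar_abort(paste0("Column not in metadata: ", stratify_by), "config")
  }
  strata_map <- metadata |>
    dplyr::distinct(.data$donor_id, stratum = .data[[stratify_by]])
  if (anyNA(strata_map$stratum) ||
      nrow(strata_map) != dplyr::n_distinct(strata_map$donor_id)) {
    ctvar_abort("Stratification must assign one stratum per donor.", "data")
  }
  d <- delta |> dplyr::filter(!.data$is_spike_in)
  if (!is.null(assay)) d <- dplyr::filter(d, .data$assay_id %in% assay)
  d <- dplyr::inner_join(d, strata_map, by = "donor_id")

  sizes <- d |> dplyr::distinct(.data$stratum, .data$donor_id) |>
    dplyr::count(.data$stratum)
  small <- sizes$stratum[sizes$n < 2]
  if (length(small) > 0) {
    warn(paste0("Skipping stratum with < 2 donors: ",
                paste(small, collapse = ", ")))
    d <- dplyr::filter(d, !.data$stratum %in% small)
  }
  intervals <- d |>
    dplyr::group_by(.data$assay_id, .data$stratum) |>
    dplyr::group_modify(~ analyse_one_assay(.x, "panel", coverage,
                                            "t_component_df")) |>
    dplyr::ungroup()
  fold_ratio <- intervals |>
    dplyr::group_by(.data$assay_id) |>
    dplyr::summarise(fold_ratio = max(.data$fold_total) / min(.data$fold_total),
                     .groups = "drop")
  list(intervals = intervals, fold_ratio = fold_ratio)
}

#' Correlate an assay's expression with enzyme levels
#'
#' Pearson correlation between the assay's log2 relative expression
#' (`-delta_ct`, so larger means more expressed) and log2 enzyme level,
#' pairwise complete over samples.
#'
#' @param delta Delta-Ct tibble from [delta_ct()].
#' @param assay Assay id to correlate.
#' @param metadata Per-sample tibble with `donor_id`, `visit_index` and
#'   numeric enzyme columns.
#' @param enzymes Character vector of enzyme column names; defaults to all
#'   numeric non-identifier columns.
#' @return A tibble: `enzyme`, `r`, `n`.
#' @export
correlate_with_enzymes <- function(delta, assay, metadata, enzymes = NULL) {
  if (is.null(enzymes)) {
    enzymes <- setdiff(names(metadata),
                       c("donor_id", "visit_index", "sex", "ethnicity_group",
                         "age"))
    enzymes <- enzymes[vapply(metadata[enzymes], is.numeric, TRUE)]
  }
  d <- delta |>
    dplyr::filter(.data$assay_id == assay) |>
    dplyr::inner_join(metadata, by = c("donor_id", "visit_index"))
  purrr::map_dfr(enzymes, function(e) {
    x <- -d$delta_ct
    y <- log2(d[[e]])
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      ctvar_abort("Need >= 3 paired observations for a correlation.", "data")
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      ctvar_abort("Correlation undefined: a variable has zero variance.",
                  "data")
    }
    tibble(enzyme = e, r = cor(x[ok], y[ok]), n = sum(ok))
  })
}

#' Write report tables as TSV
#'
#' Emits the per-assay results, enzyme table, correlations, completeness
#' report and panel provenance of a [run_study()] report as tab-separated
#' files.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  emit <- function(tbl, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(tbl, p)
    paths <<- c(paths, p)
  }
  emit(report$assays, "assay_results")
  emit(report$completeness, "assay_completeness")
  if (!is.null(report$panel)) {
    emit(tibble(assay_id = report$panel$assay_ids,
                stability = unname(report$panel$stability)),
         "normalizer_panel")
  }
  if (!is.null(report$enzymes)) emit(report$enzymes, "enzyme_results")
  if (!is.null(report$correlations)) emit(report$correlations, "correlations")
  invisible(paths)
}
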