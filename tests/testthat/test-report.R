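make_report_inputs <- function(seed = 101, ...) {
  # clean small studies: degradation rates are exercised in the ingest and
  # simulator tests, not here
  sim <- simulate_study(simulation_config(seed = seed, missing_rate = 0,
                                          out_of_range_rate = 0, ...))
  cfg <- study_config(spike_in_assay = "spike-in-control",
                      correlate_assay = "miR-122")
  list(sim = sim, cfg = cfg)
}

test_that("run_study produces one row per retained assay per scheme", {
  inp <- make_report_inputs(k = 15, m = 4, replicates = 2)
  rep <- run_study(inp$sim$ct, inp$sim$metadata, inp$cfg)
  expect_s3_class(rep, "study_report")
  n_assays <- dplyr::n_distinct(rep$assays$assay_id)
  expect_equal(nrow(rep$assays), 2 * n_assays)
  expect_setequal(unique(rep$assays$scheme), c("panel", "spike_in"))
  # analytes only: the spike-in never appears as a reported assay
  expect_false("spike-in-control" %in% rep$assays$assay_id)
  # every reported assay passed completeness
  comp <- rep$completeness
  expect_true(all(rep$assays$assay_id %in% comp$assay_id[comp$retained]))
  # derived columns are internally consistent
  expect_equal(rep$assays$percent_between + rep$assays$percent_within,
               rep(100, nrow(rep$assays)))
  expect_equal(rep$assays$fold_total,
               2^(rep$assays$upper_dct - rep$assays$lower_dct),
               tolerance = 1e-9)
  # enzymes analysed on log2 scale with the 2-SD fold policy
  expect_setequal(unique(rep$enzymes$enzyme), c("ALT", "AST"))
  alt_tot <- rep$enzymes[rep$enzymes$enzyme == "ALT" &
                           rep$enzymes$component == "total", ]
  expect_equal(alt_tot$fold, 2^(4 * alt_tot$std_dev), tolerance = 1e-9)
  # correlations reported per scheme and enzyme
  expect_equal(nrow(rep$correlations), 4)
})

test_that("identical inputs give byte-identical report tables", {
  inp <- make_report_inputs(k = 8, m = 3, replicates = 2)
  r1 <- run_study(inp$sim$ct, inp$sim$metadata, inp$cfg)
  r2 <- run_study(inp$sim$ct, inp$sim$metadata, inp$cfg)
  expect_identical(r1$assays, r2$assays)
  expect_identical(r1$enzymes, r2$enzymes)
  expect_identical(r1$correlations, r2$correlations)
})

test_that("an incomplete assay is absent from results but present in QC provenance", {
  inp <- make_report_inputs(k = 12, m = 4, replicates = 2)
  ct <- inp$sim$ct
  # knock one assay below 95% completeness: remove it from 7% of samples
  samples <- ct |> dplyr::distinct(donor_id, visit_index)
  drop <- samples[seq_len(ceiling(0.07 * nrow(samples))), ]
  ct_damaged <- ct |>
    dplyr::anti_join(dplyr::mutate(drop, assay_id = "miR-375"),
                     by = c("donor_id", "visit_index", "assay_id"))
  rep <- run_study(ct_damaged, inp$sim$metadata, inp$cfg)
  expect_false("miR-375" %in% rep$assays$assay_id)
  comp_row <- rep$completeness[rep$completeness$assay_id == "miR-375", ]
  expect_equal(nrow(comp_row), 1)
  expect_false(comp_row$retained)
})

test_that("donors missing from metadata are a data error", {
  inp <- make_report_inputs(k = 6, m = 3, replicates = 2)
  meta_short <- dplyr::filter(inp$sim$metadata, donor_id != "D01")
  expect_error(run_study(inp$sim$ct, meta_short, inp$cfg),
               class = "ctvar_error_data", regexp = "D01")
})

test_that("report tables write as TSV", {
  inp <- make_report_inputs(k = 8, m = 3, replicates = 2)
  rep <- run_study(inp$sim$ct, inp$sim$metadata, inp$cfg)
  dir <- withr::local_tempdir()
  paths <- write_study_report(rep, dir)
  expect_true(all(file.exists(paths)))
  back <- readr::read_tsv(file.path(dir, "assay_results.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), nrow(rep$assays))
})

test_that("a single stratum reproduces the unstratified analysis exactly", {
  inp <- make_report_inputs(k = 10, m = 4, replicates = 2)
  mat <- filter_assay_completeness(qc_replicates(inp$sim$ct), qc_config())
  panel <- select_normalizer_panel(mat)
  d <- delta_ct(mat, panel, "panel")
  meta1 <- dplyr::mutate(inp$sim$metadata, group = "all")
  strat <- stratified_intervals(d, meta1, "group", assay = "miR-122")
  whole <- d |>
    dplyr::filter(assay_id == "miR-122") |>
    fit_anova(delta_ct, donor_id)
  expect_equal(strat$intervals$sigma2_between, whole$sigma2_between,
               tolerance = 1e-12)
  expect_equal(strat$intervals$fold_total,
               total_reference_interval(whole)$fold_change,
               tolerance = 1e-12)
  expect_equal(strat$fold_ratio$fold_ratio, 1)
})

test_that("strata with inflated generator variance show a larger fold span", {
  # Non-Caucasian donors simulated at 4x the biological variance
  sim <- simulate_study(simulation_config(k = 40, m = 6, replicates = 2,
                                          ethnicity_variance_ratio = 4,
                                          missing_rate = 0,
                                          out_of_range_rate = 0, seed = 401))
  mat <- filter_assay_completeness(qc_replicates(sim$ct), qc_config())
  panel <- select_normalizer_panel(mat)
  d <- delta_ct(mat, panel, "panel")
  strat <- stratified_intervals(d, sim$metadata, "ethnicity_group",
                                assay = "miR-122")
  iv <- strat$intervals
  expect_equal(nrow(iv), 2)
  hi <- iv$fold_total[iv$stratum == "Non-Caucasian"]
  lo <- iv$fold_total[iv$stratum == "Caucasian"]
  expect_gt(hi, lo)
  # 4x the variance doubles the interval width in dCt, i.e. squares the
  # fold span; with estimation noise the realized ratio should land well
  # above 1 and bracket the analytic expectation lo^(2)-ish loosely
  expect_gt(strat$fold_ratio$fold_ratio, 2)
})

test_that("exchangeable strata give fold ratios near one", {
  sim <- simulate_study(simulation_config(k = 40, m = 6, replicates = 2,
                                          ethnicity_variance_ratio = 1,
                                          missing_rate = 0,
                                          out_of_range_rate = 0, seed = 402))
  mat <- filter_assay_completeness(qc_replicates(sim$ct), qc_config())
  panel <- select_normalizer_panel(mat)
  d <- delta_ct(mat, panel, "panel")
  strat <- stratified_intervals(d, sim$metadata, "ethnicity_group",
                                assay = "miR-122")
  expect_lt(strat$fold_ratio$fold_ratio, 3)
  # a stratum with < 2 donors is skipped with a warning
  meta_bad <- sim$metadata |>
    dplyr::mutate(ethnicity_group = ifelse(donor_id == "D01", "solo",
                                           "rest"))
  expect_warning(
    s2 <- stratified_intervals(d, meta_bad, "ethnicity_group",
                               assay = "miR-122"),
    regexp = "solo")
  expect_equal(unique(s2$intervals$stratum), "rest")
})

test_that("enzyme correlations behave at their analytic limits", {
  # exact linear relationship: r = 1
  d <- tibble::tibble(donor_id = rep("D1", 10), visit_index = 1:10,
                      assay_id = "A", is_spike_in = FALSE,
                      delta_ct = seq(-2, 2.5, by = 0.5))
  meta <- tibble::tibble(donor_id = "D1", visit_index = 1:10,
                         ALT = 2^(-d$delta_ct))
  out <- correlate_with_enzymes(d, "A", meta)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$n, 10)
  # independence: |r| < 2/sqrt(n) most of the time
  set.seed(73)
  n <- 240
  d2 <- tibble::tibble(donor_id = sprintf("D%03d", 1:n), visit_index = 1,
                       assay_id = "A", is_spike_in = FALSE,
                       delta_ct = rnorm(n))
  meta2 <- tibble::tibble(donor_id = d2$donor_id, visit_index = 1,
                          ALT = 2^rnorm(n))
  r0 <- correlate_with_enzymes(d2, "A", meta2)$r
  expect_lt(abs(r0), 3 / sqrt(n))
  # a target correlation of 0.5 is recovered within its Fisher-z error
  rho <- 0.5
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  d3 <- dplyr::mutate(d2, delta_ct = -x)
  meta3 <- tibble::tibble(donor_id = d2$donor_id, visit_index = 1,
                          ALT = 2^y)
  r1 <- correlate_with_enzymes(d3, "A", meta3)$r
  z_se <- 1 / sqrt(n - 3)
  expect_lt(abs(atanh(r1) - atanh(rho)), 2.5 * z_se)
  # degenerate inputs raise classed errors
  expect_error(correlate_with_enzymes(d[1:2, ], "A", meta),
               class = "ctvar_error_data")
  meta_const <- dplyr::mutate(meta, ALT = 3)
  expect_error(correlate_with_enzymes(d, "A", meta_const),
               class = "ctvar_error_data", regexp = "zero variance")
})

test_that("report plots build without error", {
  inp <- make_report_inputs(k = 8, m = 3, replicates = 2)
  rep <- run_study(inp$sim$ct, inp$sim$metadata, inp$cfg)
  p1 <- plot_reference_intervals(rep)
  p2 <- autoplot(rep, type = "components")
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
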