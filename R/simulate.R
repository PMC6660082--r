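#' Default per-assay simulation truths
#'
#' Reads the bundled table of per-assay generator parameters: mean Ct and
#' between-/within-donor variance components for a panel of abundant serum
#' miRNAs spanning the variance regimes seen in longitudinal healthy-donor
#' cohorts — five tightly co-moving low-variance assays suitable as an
#' endogenous normalizer panel, mid-variance assays, and a high-variance
#' liver-enriched marker.
#'
#' @return A tibble: `assay_id`, `mu_ct`, `sigma2_between`, `sigma2_within`.
#' @export
default_assay_truths <- function() {
  path <- system.file("extdata", "default_assay_truths.csv", package = "ctvar")
  readr::read_csv(path, show_col_types = FALSE)
}

#' Simulation configuration
#'
#' Defines a synthetic longitudinal qRT-PCR study. The generator draws, for
#' assay a, donor d, visit v and technical replicate r,
#' `Ct = mu_a + s(d, v) + b(a, d) + w(a, d, v) + e(a, d, v, r)` with
#' independent Gaussian terms: donor effect `b ~ N(0, sigma2_between_a)`,
#' visit deviation `w ~ N(0, sigma2_within_a)`, a per-sample handling shift
#' `s ~ N(0, sigma_sample_shift^2)` shared by every assay in that sample
#' (including the spike-in channel), and replicate noise
#' `e ~ N(0, sigma_tech^2)`. The spike-in channel carries the shift and the
#' replicate noise but no biological components: it mimics an exogenous
#' control added at fixed copy number, which reflects sample processing
#' only.
#'
#' Degradation of the data is injected per replicate: with probability
#' `missing_rate` the Ct is set missing, and with probability
#' `out_of_range_rate` it is replaced by a uniform draw on (25, 30] —
#' a late, QC-failing threshold crossing, the common qPCR failure mode.
#'
#' @param k Number of donors.
#' @param m Visits per donor.
#' @param replicates Technical replicates per (sample, assay).
#' @param assays Tibble with columns `assay_id`, `mu_ct`, `sigma2_between`,
#'   `sigma2_within`; defaults to [default_assay_truths()].
#' @param sigma_sample_shift SD (cycles) of the shared per-sample handling
#'   shift.
#' @param sigma_tech SD (cycles) of replicate noise.
#' @param spike_in Named numeric `c(mu = ..)` for the exogenous channel, or
#'   `NULL` for no spike-in.
#' @param spike_in_id Assay id used for the spike-in channel.
#' @param missing_rate,out_of_range_rate Per-replicate degradation rates in
#'   \[0, 1).
#' @param enzyme_params Tibble `enzyme`, `log2_mean`, `sigma2_between`,
#'   `sigma2_within` for per-sample clinical-chemistry analytes, or `NULL`.
#' @param ethnicity_variance_ratio Multiplier applied to both biological
#'   variance components (on the variance scale) for donors in the
#'   "Non-Caucasian" stratum; 1 means exchangeable strata.
#' @param seed Integer seed; all draws are reproducible from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(k = 40, m = 6, replicates = 4,
                              assays = default_assay_truths(),
                              sigma_sample_shift = 0.5,
                              sigma_tech = 0.15,
                              spike_in = c(mu = 12.8),
                              spike_in_id = "spike-in-control",
                              missing_rate = 0.01,
                              out_of_range_rate = 0.02,
                              enzyme_params = default_enzyme_truths(),
                              ethnicity_variance_ratio = 1,
                              seed = 1L) {
  if (k < 2 || m < 1 || replicates < 1) {
    ctvar_abort("Need k >= 2, m >= 1, replicates >= 1.", "config")
  }
  req <- c("assay_id", "mu_ct", "sigma2_between", "sigma2_within")
  if (!all(req %in% names(assays))) {
    ctvar_abort("`assays` must have assay_id, mu_ct, sigma2_between, sigma2_within.",
                "config")
  }
  if (any(assays$sigma2_between < 0) || any(assays$sigma2_within < 0) ||
      sigma_sample_shift < 0 || sigma_tech < 0) {
    ctvar_abort("All variances must be non-negative.", "config")
  }
  for (r in c(missing_rate, out_of_range_rate)) {
    if (r < 0 || r >= 1) ctvar_abort("Rates must lie in [0, 1).", "config")
  }
  if (ethnicity_variance_ratio <= 0) {
    ctvar_abort("`ethnicity_variance_ratio` must be positive.", "config")
  }
  structure(
    list(k = as.integer(k), m = as.integer(m),
         replicates = as.integer(replicates),
         assays = as_tibble(assays),
         sigma_sample_shift = sigma_sample_shift, sigma_tech = sigma_tech,
         spike_in = spike_in, spike_in_id = spike_in_id,
         missing_rate = missing_rate, out_of_range_rate = out_of_range_rate,
         enzyme_params = enzyme_params,
         ethnicity_variance_ratio = ethnicity_variance_ratio,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Default enzyme simulation truths
#'
#' Log2-scale means and variance components for two transaminases with the
#' contrast typical of healthy cohorts: ALT dominated by between-donor
#' variation, AST split roughly evenly.
#'
#' @return A tibble: `enzyme`, `log2_mean`, `sigma2_between`, `sigma2_within`.
#' @export
default_enzyme_truths <- function() {
  tibble(
    enzyme = c("ALT", "AST"),
    log2_mean = c(log2(20), log2(22)),
    sigma2_between = c(0.28, 0.06),
    sigma2_within = c(0.06, 0.07)
  )
}

#' Simulate a longitudinal qRT-PCR study
#'
#' Draws a replicate-level Ct table under the one-way random-effects model
#' described in [simulation_config()], together with donor metadata
#' (sex, ethnicity, age, and per-sample enzyme levels when `enzyme_params`
#' is configured) and the realized ground truth needed for parameter-recovery
#' checks.
#'
#' @param cfg A [simulation_config()].
#' @return A list of class `sim_study` with elements `ct` (replicate tibble
#'   in the format of [read_replicate_table()]), `metadata` (per-sample
#'   tibble: donor, visit, sex, ethnicity_group, age, one column per
#'   enzyme), and `truth` (list: the assay truth table, realized donor
#'   effects and sample shifts, the seed).
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  k <- cfg$k; m <- cfg$m; reps <- cfg$replicates
  donors <- sprintf("D%02d", seq_len(k))
  assays <- cfg$assays
  p <- nrow(assays)

  # donor-level metadata: alternate ethnicity so strata are balanced
  ethnicity <- rep(c("Caucasian", "Non-Caucasian"), length.out = k)
  donor_meta <- tibble(
    donor_id = donors,
    sex = sample(c("F", "M"), k, replace = TRUE),
    ethnicity_group = ethnicity,
    age = sample(29:62, k, replace = TRUE)
  )
  sd_mult <- ifelse(ethnicity == "Non-Caucasian",
                    sqrt(cfg$ethnicity_variance_ratio), 1)

  # shared per-sample handling shift, one per (donor, visit); all stochastic
  # terms are drawn as standard normals and scaled, so the realized
  # structure is identical across configurations that differ only in
  # variance magnitudes (a zero-SD rnorm would skip the RNG stream)
  shifts <- matrix(rnorm(k * m), k, m, dimnames = list(donors, NULL)) *
    cfg$sigma_sample_shift
  # biological terms per assay
  b <- matrix(rnorm(p * k), p, k) * sqrt(assays$sigma2_between) *
    rep(sd_mult, each = p)
  w <- array(rnorm(p * k * m), c(p, k, m)) *
    sqrt(assays$sigma2_within) * rep(rep(sd_mult, each = p), m)

  grid <- tidyr::expand_grid(
    assay_idx = seq_len(p),
    donor_idx = seq_len(k),
    visit_index = seq_len(m),
    replicate_index = seq_len(reps)
  )
  ct <- assays$mu_ct[grid$assay_idx] +
    shifts[cbind(grid$donor_idx, grid$visit_index)] +
    b[cbind(grid$assay_idx, grid$donor_idx)] +
    w[cbind(grid$assay_idx, grid$donor_idx, grid$visit_index)] +
    rnorm(nrow(grid)) * cfg$sigma_tech
  tbl <- tibble(
    donor_id = donors[grid$donor_idx],
    visit_index = grid$visit_index,
    assay_id = assays$assay_id[grid$assay_idx],
    replicate_index = grid$replicate_index,
    ct = ct,
    is_spike_in = FALSE
  )

  if (!is.null(cfg$spike_in)) {
    sgrid <- tidyr::expand_grid(donor_idx = seq_len(k),
                                visit_index = seq_len(m),
                                replicate_index = seq_len(reps))
    sct <- cfg$spike_in[["mu"]] +
      shifts[cbind(sgrid$donor_idx, sgrid$visit_index)] +
      rnorm(nrow(sgrid)) * cfg$sigma_tech
    tbl <- dplyr::bind_rows(tbl, tibble(
      donor_id = donors[sgrid$donor_idx],
      visit_index = sgrid$visit_index,
      assay_id = cfg$spike_in_id,
      replicate_index = sgrid$replicate_index,
      ct = sct,
      is_spike_in = TRUE
    ))
  }

  # degradation: out-of-range replacement, then missingness
  n_row <- nrow(tbl)
  oor <- runif(n_row) < cfg$out_of_range_rate
  tbl$ct[oor] <- runif(sum(oor), 25, 30)
  miss <- runif(n_row) < cfg$missing_rate
  tbl$ct[miss] <- NA_real_

  metadata <- tidyr::expand_grid(donor_id = donors, visit_index = seq_len(m)) |>
    dplyr::left_join(donor_meta, by = "donor_id")
  if (!is.null(cfg$enzyme_params)) {
    enz <- simulate_enzyme_values(cfg, donors)
    metadata <- dplyr::left_join(metadata, enz,
                                 by = c("donor_id", "visit_index"))
  }

  structure(
    list(
      ct = dplyr::arrange(tbl, .data$donor_id, .data$visit_index,
                          .data$assay_id, .data$replicate_index),
      metadata = metadata,
      truth = list(assays = assays, donor_effects = b, sample_shifts = shifts,
                   n_out_of_range = sum(oor & !miss), n_missing = sum(miss),
                   seed = cfg$seed)
    ),
    class = "sim_study"
  )
}

# enzyme draws on the log2 scale, wide per-sample columns on the U/L scale
simulate_enzyme_values <- function(cfg, donors) {
  k <- length(donors); m <- cfg$m
  ep <- cfg$enzyme_params
  out <- tidyr::expand_grid(donor_id = donors, visit_index = seq_len(cfg$m))
  for (i in seq_len(nrow(ep))) {
    bd <- rnorm(k) * sqrt(ep$sigma2_between[i])
    wv <- matrix(rnorm(k * m), k, m) * sqrt(ep$sigma2_within[i])
    log2_val <- ep$log2_mean[i] + bd[match(out$donor_id, donors)] +
      wv[cbind(match(out$donor_id, donors), out$visit_index)]
    out[[ep$enzyme[i]]] <- 2^log2_val
  }
  out
}

#' Simulate per-sample enzyme levels alone
#'
#' Draws the configured clinical-chemistry analytes under the same one-way
#' random-effects model as the Ct generator (on the log2 scale) and reports
#' them long, on both scales.
#'
#' @param cfg A [simulation_config()] with non-`NULL` `enzyme_params`.
#' @return A tibble: `donor_id`, `visit_index`, `enzyme`, `value`
#'   (natural scale), `log2_value`.
#' @export
simulate_enzymes <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (is.null(cfg$enzyme_params)) {
    ctvar_abort("`enzyme_params` is NULL in this configuration.", "config")
  }
  set.seed(cfg$seed)
  donors <- sprintf("D%02d", seq_len(cfg$k))
  simulate_enzyme_values(cfg, donors) |>
    tidyr::pivot_longer(-c("donor_id", "visit_index"),
                        names_to = "enzyme", values_to = "value") |>
    dplyr::mutate(log2_value = log2(.data$value))
}

#' Fixture generator for normalizer-panel selection
#'
#' Builds a replicate table in which a designated "stable" assay subset
#' shares a per-sample shift with small independent noise, while an
#' "unstable" subset fluctuates independently with larger noise. The stable
#' subset is then recoverable by [select_normalizer_panel()] (and by
#' brute-force subset search, which tests use as an oracle).
#'
#' @param n_stable,n_unstable Sizes of the two subsets.
#' @param k,m Donors and visits.
#' @param shift_sd SD of the shared per-sample shift.
#' @param stable_sd,unstable_sd Independent noise SDs of the two subsets.
#' @param panel_size Size of the panel the caller intends to select; must
#'   not exceed `n_stable`.
#' @param seed Integer seed.
#' @return A replicate tibble (single replicate per cell, all values inside
#'   the QC window).
#' @export
make_panel_fixture <- function(n_stable = 5, n_unstable = 10, k = 12, m = 4,
                               shift_sd = 1, stable_sd = 0.05,
                               unstable_sd = 1, panel_size = 5, seed = 1L) {
  if (n_stable < panel_size) {
    ctvar_abort("Stable subset smaller than the requested panel size.", "config")
  }
  set.seed(seed)
  stable_ids <- sprintf("stable-%02d", seq_len(n_stable))
  unstable_ids <- sprintf("unstable-%02d", seq_len(n_unstable))
  donors <- sprintf("D%02d", seq_len(k))
  samples <- tidyr::expand_grid(donor_id = donors, visit_index = seq_len(m))
  n_s <- nrow(samples)
  shift <- rnorm(n_s) * shift_sd
  rows <- list()
  for (a in seq_along(stable_ids)) {
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      samples, assay_id = stable_ids[a], replicate_index = 1L,
      ct = 14 + a / 2 + shift + rnorm(n_s, 0, stable_sd))
  }
  for (a in seq_along(unstable_ids)) {
    rows[[length(rows) + 1L]] <- dplyr::mutate(
      samples, assay_id = unstable_ids[a], replicate_index = 1L,
      ct = 15 + a / 4 + rnorm(n_s, 0, unstable_sd))
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(is_spike_in = FALSE) |>
    dplyr::relocate("donor_id", "visit_index", "assay_id", "replicate_index",
                    "ct", "is_spike_in")
  validate_replicate_table(out)
  out
}
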