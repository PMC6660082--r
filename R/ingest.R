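#' Quality-control configuration for replicate-level Ct data
#'
#' Bundles the thresholds used when collapsing technical replicates to
#' per-sample mean Ct values and when filtering assays on completeness.
#'
#' A replicate passes QC when its Ct is present and falls inside
#' `[ct_min, ct_max]`. Instrument exports in this field commonly flag a well
#' as failed when the threshold crossing is implausibly early or never
#' reached within the cycling protocol, hence the default window of 4 to 25
#' cycles. Whether a Ct sitting exactly on a boundary passes is
#' instrument-convention dependent; `inclusive_bounds = TRUE` (the default)
#' treats Ct = 4 and Ct = 25 as passing, `FALSE` fails them.
#'
#' @param ct_min,ct_max Ct window in cycles; replicates outside it fail QC.
#' @param min_replicates Minimum number of passing technical replicates a
#'   (sample, assay) cell needs before its mean Ct is reported.
#' @param completeness_threshold Minimum fraction of samples in which an
#'   assay must have a reportable mean Ct to be retained for analysis.
#' @param inclusive_bounds Logical; are the window boundaries passing?
#'
#' @return A list of class `qc_config`.
#' @examples
#' qc_config()
#' qc_config(ct_max = 28, min_replicates = 3)
#' @export
qc_config <- function(ct_min = 4, ct_max = 25, min_replicates = 2,
                      completeness_threshold = 0.95, inclusive_bounds = TRUE) {
  if (!(ct_min > 0 && ct_min < ct_max)) {
    ctvar_abort("`ct_min` must satisfy 0 < ct_min < ct_max.", "config")
  }
  if (min_replicates < 1) ctvar_abort("`min_replicates` must be >= 1.", "config")
  if (!(completeness_threshold > 0 && completeness_threshold <= 1)) {
    ctvar_abort("`completeness_threshold` must be in (0, 1].", "config")
  }
  structure(
    list(
      ct_min = ct_min, ct_max = ct_max,
      min_replicates = as.integer(min_replicates),
      completeness_threshold = completeness_threshold,
      inclusive_bounds = isTRUE(inclusive_bounds)
    ),
    class = "qc_config"
  )
}

#' Read a long-format replicate-level Ct table
#'
#' Reads a CSV/TSV export with one row per technical replicate and returns a
#' tidy replicate table with the columns `donor_id`, `visit_index`,
#' `assay_id`, `replicate_index`, `ct` and `is_spike_in`. Blank or
#' unparseable Ct fields become `NA` (the record is kept, not dropped).
#'
#' @param path Path to a delimited text file.
#' @param col_map Named character vector mapping the canonical names
#'   (`donor`, `visit`, `assay`, `replicate`, `ct`) to the column names used
#'   in the file.
#' @param spike_in_assay Assay id of the exogenous spike-in control, or
#'   `NULL` if none is present.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.tsv`/`.txt` are tab, anything else comma).
#'
#' @return A tibble of replicate records, one row per well.
#' @export
read_replicate_table <- function(path,
                                 col_map = c(donor = "donor_id",
                                             visit = "visit_index",
                                             assay = "assay_id",
                                             replicate = "replicate_index",
                                             ct = "ct"),
                                 spike_in_assay = NULL,
                                 delim = NULL) {
  if (!file.exists(path)) ctvar_abort(paste0("File not found: ", path), "config")
  needed <- c("donor", "visit", "assay", "replicate", "ct")
  if (!all(needed %in% names(col_map))) {
    ctvar_abort("`col_map` must name donor, visit, assay, replicate and ct columns.",
                "config")
  }
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(unname(col_map[needed]), names(raw))
  if (length(missing_cols) > 0) {
    ctvar_abort(paste0("Mandatory column(s) absent from file: ",
                       paste(missing_cols, collapse = ", ")), "config")
  }
  out <- tibble(
    donor_id = as.character(raw[[col_map[["donor"]]]]),
    visit_index = as.integer(raw[[col_map[["visit"]]]]),
    assay_id = as.character(raw[[col_map[["assay"]]]]),
    replicate_index = as.integer(raw[[col_map[["replicate"]]]]),
    ct = suppressWarnings(as.numeric(raw[[col_map[["ct"]]]]))
  )
  validate_replicate_table(out)
  out$is_spike_in <- out$assay_id %in% spike_in_assay
  out
}

#' Read a wide assay-by-sample Ct matrix
#'
#' Convenience reader for array-style exports where rows are assays and
#' columns are samples named `<donor><sep><visit>`. Each cell holds a single
#' Ct, so the resulting replicate table has `replicate_index = 1` throughout.
#'
#' @param path Delimited text file; first column holds assay ids.
#' @param sep Separator between donor and visit in the sample column names.
#' @inheritParams read_replicate_table
#' @return A tibble of replicate records.
#' @export
read_ct_matrix <- function(path, sep = "_", spike_in_assay = NULL, delim = NULL) {
  if (!file.exists(path)) ctvar_abort(paste0("File not found: ", path), "config")
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  assay_col <- names(raw)[1]
  long <- tidyr::pivot_longer(raw, -dplyr::all_of(assay_col),
                              names_to = "sample", values_to = "ct")
  parts <- strsplit(long$sample, sep, fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) {
    ctvar_abort(paste0("Sample column name(s) not of the form donor", sep,
                       "visit: ", paste(unique(long$sample[bad]), collapse = ", ")),
                "config")
  }
  out <- tibble(
    donor_id = vapply(parts, function(p) paste(head(p, -1), collapse = sep), ""),
    visit_index = as.integer(vapply(parts, function(p) p[length(p)], "")),
    assay_id = as.character(long[[assay_col]]),
    replicate_index = 1L,
    ct = suppressWarnings(as.numeric(long$ct))
  )
  validate_replicate_table(out)
  out$is_spike_in <- out$assay_id %in% spike_in_assay
  out
}

# key uniqueness + positivity; shared by both readers and the simulator
validate_replicate_table <- function(tbl) {
  key <- paste(tbl$donor_id, tbl$visit_index, tbl$assay_id, tbl$replicate_index,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- tbl[which(dup)[1], ]
    ctvar_abort(sprintf(
      "Duplicate replicate key: donor %s, visit %s, assay %s, replicate %s",
      first$donor_id, first$visit_index, first$assay_id, first$replicate_index),
      "data")
  }
  bad_ct <- !is.na(tbl$ct) & (!is.finite(tbl$ct) | tbl$ct <= 0)
  if (any(bad_ct)) {
    ctvar_abort("Ct values must be finite and > 0 when present.", "data")
  }
  invisible(tbl)
}

#' Collapse technical replicates to per-sample mean Ct
#'
#' Applies replicate-level QC and aggregates: a replicate passes when its Ct
#' is present and inside the configured window; a (sample, assay) cell gets a
#' mean Ct when at least `min_replicates` replicates pass, and is missing
#' otherwise. Every cell of the sample-by-assay grid is represented, so
#' downstream completeness accounting sees failed cells explicitly.
#'
#' @param data Replicate table as returned by [read_replicate_table()] or
#'   [simulate_study()].
#' @param config A [qc_config()].
#'
#' @return A tibble with one row per (donor, visit, assay): columns
#'   `donor_id`, `visit_index`, `assay_id`, `is_spike_in`, `n_passing`,
#'   `mean_ct`.
#' @export
qc_replicates <- function(data, config = qc_config()) {
  if (nrow(data) == 0) ctvar_abort("Replicate table is empty.", "data")
  pass <- if (config$inclusive_bounds) {
    !is.na(data$ct) & data$ct >= config$ct_min & data$ct <= config$ct_max
  } else {
    !is.na(data$ct) & data$ct > config$ct_min & data$ct < config$ct_max
  }
  spike_flag <- if ("is_spike_in" %in% names(data)) data$is_spike_in else FALSE
  agg <- data |>
    dplyr::mutate(.pass = pass, is_spike_in = spike_flag) |>
    dplyr::group_by(.data$donor_id, .data$visit_index, .data$assay_id,
                    .data$is_spike_in) |>
    dplyr::summarise(
      n_passing = sum(.data$.pass),
      mean_ct = if (sum(.data$.pass) >= config$min_replicates) {
        mean(.data$ct[.data$.pass])
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  # complete the sample x assay grid: samples or assays entirely absent from
  # some combination appear as zero-passing missing cells
  assay_flags <- dplyr::distinct(agg, .data$assay_id, .data$is_spike_in)
  agg |>
    dplyr::select(-"is_spike_in") |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(c("donor_id", "visit_index"))),
      assay_id = sort(unique(data$assay_id)),
      fill = list(n_passing = 0L, mean_ct = NA_real_)
    ) |>
    dplyr::left_join(assay_flags, by = "assay_id") |>
    dplyr::mutate(is_spike_in = dplyr::coalesce(.data$is_spike_in, FALSE)) |>
    dplyr::relocate("is_spike_in", .after = "assay_id") |>
    dplyr::arrange(.data$donor_id, .data$visit_index, .data$assay_id)
}

#' Per-assay completeness report
#'
#' For each assay, counts the samples with a reportable mean Ct and flags
#' whether the assay meets the completeness threshold. The spike-in control
#' is always marked retained: it is the normalizer, not an analyte.
#'
#' @param data Mean-Ct tibble from [qc_replicates()].
#' @param config A [qc_config()].
#' @return A tibble: `assay_id`, `is_spike_in`, `n_present`, `n_total`,
#'   `fraction`, `retained`.
#' @export
assay_completeness <- function(data, config = qc_config()) {
  n_samples <- dplyr::n_distinct(paste(data$donor_id, data$visit_index, sep = "\r"))
  if (n_samples == 0) ctvar_abort("No samples present.", "data")
  data |>
    dplyr::group_by(.data$assay_id, .data$is_spike_in) |>
    dplyr::summarise(n_present = sum(!is.na(.data$mean_ct)), .groups = "drop") |>
    dplyr::mutate(
      n_total = n_samples,
      fraction = .data$n_present / .data$n_total,
      retained = .data$fraction >= config$completeness_threshold | .data$is_spike_in
    ) |>
    dplyr::arrange(.data$assay_id)
}

#' Drop assays that fail the completeness threshold
#'
#' Restricts the mean-Ct table to assays measured in at least
#' `completeness_threshold` of the samples (plus the spike-in, which is
#' always kept). Samples are never dropped here — only assays. The full
#' per-assay report is attached as the `"completeness_report"` attribute.
#'
#' @inheritParams assay_completeness
#' @return The filtered mean-Ct tibble.
#' @seealso [assay_completeness()] for the report alone.
#' @export
filter_assay_completeness <- function(data, config = qc_config()) {
  report <- assay_completeness(data, config)
  keep <- report$assay_id[report$retained]
  out <- dplyr::filter(data, .data$assay_id %in% keep)
  attr(out, "completeness_report") <- report
  out
}
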