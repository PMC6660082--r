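#' Select an endogenous normalizer panel by iterative stability elimination
#'
#' Chooses a small set of assays whose Ct values move together across
#' samples, in the spirit of adaptive reference-gene selection for
#' circulating miRNA panels. The algorithm is the classic pairwise-variation
#' scheme: for candidate assays i and j let `v(i, j)` be the standard
#' deviation across samples of the per-sample difference `Ct_i - Ct_j`; the
#' stability of assay i is `M_i = mean_{j != i} v(i, j)`. The assay with the
#' largest `M_i` is removed and all scores recomputed, until `panel_size`
#' assays remain. Because `v(i, j)` is invariant to any per-sample shift
#' shared by both assays, the procedure favours assays tracking the common
#' sample-handling signal rather than assays that are merely flat.
#'
#' Candidates are the non-spike-in assays with completeness at least
#' `candidate_completeness`; stability is computed over pairwise-complete
#' samples. Ties in `M_i` are broken by removing the lexicographically last
#' assay id, so a fully tied field leaves the lexicographically first
#' `panel_size` ids as the panel.
#'
#' @param data Mean-Ct tibble from [qc_replicates()] (optionally already
#'   completeness-filtered).
#' @param panel_size Number of assays to retain in the panel.
#' @param candidate_completeness Minimum completeness for an assay to enter
#'   the candidate pool.
#'
#' @return An object of class `normalizer_panel`: a list with `assay_ids`
#'   (the selected panel, in assay-id order), `stability` (final `M_i` for
#'   the panel members), `mean_pairwise_correlation` (mean Pearson
#'   correlation of Ct across samples among panel members — a diagnostic of
#'   how much shared sample-level signal the panel carries), and
#'   `elimination` (tibble recording the removal order).
#' @export
select_normalizer_panel <- function(data, panel_size = 5,
                                    candidate_completeness = 0.99) {
  report <- assay_completeness(data, qc_config(completeness_threshold = candidate_completeness))
  candidates <- report$assay_id[!report$is_spike_in &
                                  report$fraction >= candidate_completeness]
  if (length(candidates) < panel_size) {
    ctvar_abort(sprintf(
      "Only %d candidate assays at completeness >= %g; panel of %d requested.",
      length(candidates), candidate_completeness, panel_size), "config")
  }
  wide <- data |>
    dplyr::filter(.data$assay_id %in% candidates) |>
    tidyr::pivot_wider(id_cols = c("donor_id", "visit_index"),
                       names_from = "assay_id", values_from = "mean_ct")
  mat <- as.matrix(wide[, candidates, drop = FALSE])

  pairwise_v <- function(m) {
    p <- ncol(m)
    v <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(p)) {
      for (j in seq_len(p)) {
        if (i != j) v[i, j] <- sd(m[, i] - m[, j], na.rm = TRUE)
      }
    }
    v
  }

  remaining <- sort(candidates)
  elim <- list()
  step <- 0L
  while (length(remaining) > panel_size) {
    step <- step + 1L
    v <- pairwise_v(mat[, remaining, drop = FALSE])
    m_score <- rowMeans(v, na.rm = TRUE)
    worst <- max(m_score)
    # among ties remove the lexicographically last id
    tied <- names(m_score)[m_score >= worst - 1e-12]
    drop_id <- tied[length(tied)]
    elim[[step]] <- tibble(step = step, assay_id = drop_id,
                           stability = m_score[[drop_id]])
    remaining <- setdiff(remaining, drop_id)
  }
  v_final <- pairwise_v(mat[, remaining, drop = FALSE])
  m_final <- rowMeans(v_final, na.rm = TRUE)
  cors <- suppressWarnings(stats::cor(mat[, remaining, drop = FALSE],
                                      use = "pairwise.complete.obs"))
  mean_cor <- mean(cors[upper.tri(cors)])
  if (is.na(mean_cor) || mean_cor < 0.2) {
    warn(paste0(
      "Mean pairwise correlation among panel members is ",
      if (is.na(mean_cor)) "undefined" else sprintf("%.2f", mean_cor),
      "; the panel carries little shared sample-level signal."))
  }
  structure(
    list(
      assay_ids = remaining,
      stability = m_final[remaining],
      mean_pairwise_correlation = mean_cor,
      elimination = if (length(elim)) dplyr::bind_rows(elim) else
        tibble(step = integer(), assay_id = character(), stability = double())
    ),
    class = "normalizer_panel"
  )
}

#' @export
print.normalizer_panel <- function(x, ...) {
  cat("Normalizer panel (", length(x$assay_ids), " assays)\n", sep = "")
  cat("  ", paste(x$assay_ids, collapse = ", "), "\n", sep = "")
  cat(sprintf("  mean pairwise correlation: %.3f\n", x$mean_pairwise_correlation))
  invisible(x)
}

#' Normalize Ct values to delta-Ct
#'
#' Computes per-sample normalized Ct under one of two schemes:
#' \describe{
#'   \item{`panel`}{`dCt(s, a) = Ct(s, a) - mean(Ct(s, panel members))`.
#'     A sample missing any panel member yields missing dCt for every assay
#'     in that sample, keeping the reference definition uniform.}
#'   \item{`spike_in`}{`dCt(s, a) = Ct(s, a) - Ct(s, spike-in assay)`. The
#'     spike-in normalized to itself is identically 0.}
#' }
#'
#' @param data Mean-Ct tibble from [qc_replicates()].
#' @param reference A `normalizer_panel` (or character vector of assay ids)
#'   for the panel scheme; a single assay id for the spike-in scheme.
#' @param scheme `"panel"` or `"spike_in"`.
#'
#' @return A tibble `donor_id`, `visit_index`, `assay_id`, `is_spike_in`,
#'   `delta_ct`, with attributes `scheme` and `reference_description`.
#' @export
delta_ct <- function(data, reference, scheme = c("panel", "spike_in")) {
  scheme <- tryCatch(match.arg(scheme),
                     error = function(e) ctvar_abort(
                       "`scheme` must be \"panel\" or \"spike_in\".", "config"))
  ref_ids <- if (inherits(reference, "normalizer_panel")) reference$assay_ids
             else as.character(reference)
  missing_ref <- setdiff(ref_ids, unique(data$assay_id))
  if (length(missing_ref) > 0) {
    ctvar_abort(paste0("Reference assay(s) not in data: ",
                       paste(missing_ref, collapse = ", ")), "config")
  }
  if (scheme == "spike_in" && length(ref_ids) != 1) {
    ctvar_abort("Spike-in scheme needs exactly one reference assay id.", "config")
  }
  ref_per_sample <- data |>
    dplyr::filter(.data$assay_id %in% ref_ids) |>
    dplyr::group_by(.data$donor_id, .data$visit_index) |>
    dplyr::summarise(
      .ref = if (dplyr::n() == length(ref_ids) && !anyNA(.data$mean_ct)) {
        mean(.data$mean_ct)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  out <- data |>
    dplyr::left_join(ref_per_sample, by = c("donor_id", "visit_index")) |>
    dplyr::mutate(delta_ct = .data$mean_ct - .data$.ref) |>
    dplyr::select("donor_id", "visit_index", "assay_id", "is_spike_in",
                  "delta_ct")
  attr(out, "scheme") <- scheme
  attr(out, "reference_description") <- paste(ref_ids, collapse = ",")
  out
}

#' Convert delta-Ct to relative expression
#'
#' Relative expression is `2^(-dCt)`: one cycle fewer to threshold means
#' twice the template. The geometric mean of relative expression equals
#' `2^(-mean(dCt))`, so arithmetic summaries on the dCt scale correspond to
#' geometric summaries on the expression scale.
#'
#' @param x A numeric vector of dCt values, or a tibble with a `delta_ct`
#'   column (as from [delta_ct()]), in which case a `rel_expr` column is
#'   added.
#' @return Numeric vector, or the input tibble with `rel_expr` appended.
#' @examples
#' relative_expression(0)      # 1
#' relative_expression(-1.17)  # ~2.25
#' @export
relative_expression <- function(x) {
  if (is.data.frame(x)) {
    if (!"delta_ct" %in% names(x)) {
      ctvar_abort("Data frame input must have a `delta_ct` column.", "config")
    }
    dplyr::mutate(x, rel_expr = 2^(-.data$delta_ct))
  } else {
    2^(-x)
  }
}
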