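# Independent oracles used across test files. These deliberately use naive
# brute-force / closed-form routes, not the package's own code paths.

# Exhaustive best-subset panel selection: the size-p subset minimizing the
# mean pairwise sd of per-sample Ct differences.
brute_force_panel <- function(mean_ct_tbl, panel_size) {
  wide <- tidyr::pivot_wider(mean_ct_tbl,
                             id_cols = c("donor_id", "visit_index"),
                             names_from = "assay_id", values_from = "mean_ct")
  ids <- sort(setdiff(names(wide), c("donor_id", "visit_index")))
  mat <- as.matrix(wide[, ids])
  combos <- utils::combn(ids, panel_size, simplify = FALSE)
  score <- vapply(combos, function(set) {
    pairs <- utils::combn(set, 2, simplify = FALSE)
    mean(vapply(pairs, function(p) sd(mat[, p[1]] - mat[, p[2]], na.rm = TRUE),
                0))
  }, 0)
  sort(combos[[which.min(score)]])
}

# Textbook one-way ANOVA variance components, written out longhand.
hand_anova <- function(y, g) {
  g <- as.character(g)
  means <- tapply(y, g, mean)
  n_i <- tapply(y, g, length)
  k <- length(means)
  n <- length(y)
  msw <- sum((y - means[g])^2) / (n - k)
  msb <- sum(n_i * (means - mean(y))^2) / (k - 1)
  m0 <- (n - sum(n_i^2) / n) / (k - 1)
  list(between = max(0, (msb - msw) / m0), within = msw)
}

# Profile-REML by dense grid search over the variance ratio (independent of
# the package's optimizer).
grid_reml <- function(y, g, lambdas = exp(seq(log(1e-6), log(1e3),
                                              length.out = 4000))) {
  g <- as.character(g)
  means <- tapply(y, g, mean)
  n_i <- tapply(y, g, length)
  n <- length(y)
  ssw <- sum((y - means[g])^2)
  obj <- vapply(c(0, lambdas), function(l) {
    w <- n_i / (1 + n_i * l)
    mu <- sum(w * means) / sum(w)
    q <- ssw + sum(w * (means - mu)^2)
    (n - 1) * log(q) + sum(log1p(n_i * l)) + log(sum(w))
  }, 0)
  l <- c(0, lambdas)[which.min(obj)]
  w <- n_i / (1 + n_i * l)
  mu <- sum(w * means) / sum(w)
  s2w <- (ssw + sum(w * (means - mu)^2)) / (n - 1)
  list(between = l * s2w, within = s2w)
}

# Long replicate tibble from a compact spec: list(donor, visit, assay, cts)
replicate_rows <- function(donor, visit, assay, cts) {
  tibble::tibble(donor_id = donor, visit_index = visit, assay_id = assay,
                 replicate_index = seq_along(cts), ct = cts,
                 is_spike_in = FALSE)
}

# Balanced one-way Gaussian draws for property tests
draw_oneway <- function(k, m, s2b, s2w, mu = 0) {
  b <- rnorm(k, 0, sqrt(s2b))
  tibble::tibble(
    donor_id = rep(sprintf("D%02d", seq_len(k)), each = m),
    y = mu + rep(b, each = m) + rnorm(k * m, 0, sqrt(s2w))
  )
}
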