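# State-contrast statistics: one-way ANOVA of connectivity strength and
# topology features across the three driving states, Bonferroni-corrected
# within an explicitly declared test family, plus top-k connectivity
# difference maps and a simulation-based calibration check.

#' One-way ANOVA across driving states with Bonferroni correction
#'
#' @param values Numeric vector of feature values (e.g. per-epoch
#'   connection strength).
#' @param states Factor or character vector of the same length giving each
#'   value's state.
#' @param n_tests Declared Bonferroni family size `m` (default 1); the
#'   adjusted p-value is `min(1, m * p)`.
#' @param feature,band Optional names recorded in the result.
#' @return An object of class `state_contrast`: group means, `F`, raw and
#'   adjusted p-values, and the family size.
#' @export
anova_states <- function(values, states, n_tests = 1,
                         feature = NA_character_, band = NA_character_) {
  states <- factor(states)
  if (nlevels(states) < 2) stop("need at least 2 groups")
  if (any(table(states) < 2)) stop("need at least 2 values per group")
  if (length(values) != length(states)) stop("values and states differ in length")
  groups <- split(values, states)
  means <- vapply(groups, mean, numeric(1))
  if (all(vapply(groups, function(g) var(g) == 0, logical(1))) &&
      max(means) - min(means) == 0) {
    # degenerate: all values identical; no evidence against the null
    message("zero variance in all groups with equal means; p set to 1")
    f <- 0; p <- 1
  } else {
    fit <- stats::oneway.test(values ~ states, var.equal = TRUE)
    f <- unname(fit$statistic)
    p <- fit$p.value
    if (!is.finite(p)) { f <- 0; p <- 1 }
  }
  structure(
    list(feature = feature, band = band, group_means = means,
         F = f, p = p, p_adjusted = min(1, n_tests * p), n_tests = n_tests),
    class = "state_contrast")
}

#' @export
print.state_contrast <- function(x, ...) {
  cat(sprintf("<state_contrast> %s/%s F = %.3f, p = %.4g, adj. p = %.4g (m = %d)\n",
              x$feature, x$band, x$F, x$p, x$p_adjusted, x$n_tests))
  print(round(x$group_means, 4))
  invisible(x)
}

#' Band-wise state contrasts of a feature table
#'
#' Runs [anova_states()] for every feature column of a table from
#' [build_feature_table()], using the number of columns tested as the
#' Bonferroni family size (override with `n_tests`).
#'
#' @param table Feature table with `label` column.
#' @param features Feature column names (default: all).
#' @param n_tests Family size (default: number of features tested).
#' @return Data frame with one row per feature: group means, `F`, `p`,
#'   `p_adjusted`.
#' @export
contrast_table <- function(table, features = NULL, n_tests = NULL) {
  if (is.null(features)) features <- feature_cols(table)
  if (is.null(n_tests)) n_tests <- length(features)
  rows <- lapply(features, function(fc) {
    parts <- strsplit(fc, "_", fixed = TRUE)[[1]]
    res <- anova_states(table[[fc]], table$label, n_tests = n_tests,
                        feature = fc, band = if (length(parts) >= 2) parts[2] else NA)
    data.frame(feature = fc, t(res$group_means), F = res$F, p = res$p,
               p_adjusted = res$p_adjusted, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Top-k connectivity difference map
#'
#' Signed difference `A - B` between two mean connectivity matrices with a
#' mask retaining the `ceiling(k * n(n-1)/2)` largest strictly positive
#' (increased) differences; ties are broken deterministically by descending
#' difference then ascending (row, column).
#'
#' @param mat_a,mat_b Mean connectivity matrices of the same shape (state A
#'   and state B).
#' @param k Retention fraction (default 0.02, i.e. the top 2% of possible
#'   connections).
#' @return List of class `difference_map`: `difference` (signed matrix),
#'   `mask` (logical matrix, symmetric), `edges` (data frame of retained
#'   edges), `k`.
#' @export
difference_top_k <- function(mat_a, mat_b, k = 0.02) {
  if (!all(dim(mat_a) == dim(mat_b))) stop("matrices differ in shape")
  ea <- attr(mat_a, "estimator"); eb <- attr(mat_b, "estimator")
  if (!is.null(ea) && !is.null(eb) && !identical(ea, eb))
    stop("matrices come from different estimators: ", ea, " vs ", eb)
  d <- unclass(mat_a) - unclass(mat_b)
  n <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  n_keep <- ceiling(k * n * (n - 1) / 2)
  pos <- which(w > 0)
  ord <- pos[order(-w[pos], ut[pos, 1], ut[pos, 2])]
  keep <- ord[seq_len(min(n_keep, length(ord)))]
  mask <- matrix(FALSE, n, n)
  mask[cbind(ut[keep, 1], ut[keep, 2])] <- TRUE
  mask <- mask | t(mask)
  edges <- data.frame(from = ut[keep, 1], to = ut[keep, 2],
                      difference = w[keep])
  structure(list(difference = d, mask = mask, edges = edges, k = k),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("<difference_map> %d x %d, k = %g, %d retained increase(s)\n",
              nrow(x$difference), ncol(x$difference), x$k, nrow(x$edges)))
  invisible(x)
}

#' Write a difference map as matrix + edge-list TSV
#'
#' @param dmap A [difference_top_k()] result.
#' @param path Base path; writes `<path>.tsv` (square matrix) and
#'   `<path>_edges.tsv`.
#' @return `path`, invisibly.
#' @export
write_difference_map <- function(dmap, path) {
  write.table(format(dmap$difference, digits = 10, trim = TRUE),
              paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  write.table(dmap$edges, paste0(path, "_edges.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulation-based rejection rate of the state contrast
#'
#' Repeatedly generates cohorts from `cspec`, computes per-epoch band
#' connection strengths for one estimator, runs the band-wise ANOVA with
#' Bonferroni family size equal to the number of bands, and reports
#' rejection rates: family-wise (any band significant) and per band. With
#' identical state specs this calibrates the type-I error; with the default
#' effect specs it measures power (e.g. of the theta contrast).
#'
#' @param cspec A [cohort_spec()]; its master seed is re-derived per
#'   simulation from `seed`.
#' @param n_sims Number of simulated cohorts (>= 1).
#' @param seed Integer seed.
#' @param estimator Estimator used for the strength features (default
#'   `"PLV"`, the cheapest phase-based one).
#' @param bands Band definitions.
#' @param alpha Significance level (default 0.05).
#' @param method Band-decomposition method (default `"fir"` for speed).
#' @return List with `familywise_rate`, `band_rates` (named vector),
#'   `alpha`, `n_sims`.
#' @export
power_check <- function(cspec, n_sims, seed = 1, estimator = "PLV",
                        bands = eeg_bands(), alpha = 0.05, method = "fir") {
  if (n_sims < 1) stop("n_sims must be >= 1")
  estimator <- match.arg(estimator, c("SL", "PLV", "COH"))
  nb <- nrow(bands)
  rej <- matrix(FALSE, n_sims, nb, dimnames = list(NULL, bands$band))
  for (sim in seq_len(n_sims)) {
    cs <- cspec
    cs$seed <- epoch_seed(seed, sim, "normal", 1)
    cohort <- generate_cohort(cs)
    strength <- matrix(NA_real_, length(cohort), nb)
    states <- vapply(cohort, `[[`, character(1), "state")
    for (i in seq_along(cohort)) {
      ep <- decompose_bands(cohort[[i]], bands, method = method)
      conn <- connectivity_epoch(ep, estimator, bands = bands)
      strength[i, ] <- vapply(bands$band, function(b)
        mean_strength(conn[[estimator]][[b]]), numeric(1))
    }
    for (bi in seq_len(nb)) {
      res <- anova_states(strength[, bi], states, n_tests = nb)
      rej[sim, bi] <- res$p_adjusted < alpha
    }
  }
  list(familywise_rate = mean(apply(rej, 1, any)),
       band_rates = colMeans(rej), alpha = alpha, n_sims = n_sims)
}
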