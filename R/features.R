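# Assembly of the per-epoch feature table: for every requested estimator and
# band, the topology profile over the sparsity sweep contributes its five
# scalars (V, Cg, Lg, Eg, El), giving 3 x 4 x 5 = 60 named features for the
# full set. Column names follow estimator_band_feature (e.g. sl_theta_El).

topo_feature_names <- function() c("V", "Cg", "Lg", "Eg", "El")

feature_columns <- function(estimators, bands = band_names()) {
  unlist(lapply(tolower(estimators), function(e)
    unlist(lapply(bands, function(b)
      paste(e, b, topo_feature_names(), sep = "_")))))
}

#' Build the epoch-level feature table
#'
#' Decomposes each epoch (unless already decomposed), computes the requested
#' connectivity matrices per band, runs the sparsity sweep and assembles one
#' row of AUC-aggregated topology features plus connection strength per
#' epoch. With all three estimators and four bands the table has 60 feature
#' columns plus `label`, `subject`, `epoch`.
#'
#' @param cohort List of [eeg_epoch()] objects.
#' @param estimators Subset of `c("SL", "PLV", "COH")`.
#' @param bands Band definitions, as from [eeg_bands()].
#' @param sl,spectral Estimator parameters ([sl_params()],
#'   [spectral_params()]).
#' @param sweep A [sparsity_sweep()].
#' @param method Band-decomposition method passed to [decompose_bands()]
#'   for epochs lacking one.
#' @return Data frame, one row per epoch.
#' @export
build_feature_table <- function(cohort, estimators = c("SL", "PLV", "COH"),
                                bands = eeg_bands(), sl = sl_params(),
                                spectral = spectral_params(),
                                sweep = sparsity_sweep(),
                                method = "wpt") {
  if (length(cohort) == 0) stop("empty cohort")
  estimators <- match.arg(estimators, c("SL", "PLV", "COH"), several.ok = TRUE)
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    ep <- cohort[[i]]
    if (!inherits(ep, "eeg_epoch"))
      stop("cohort element ", i, " is not an eeg_epoch")
    if (is.null(ep$bands)) ep <- decompose_bands(ep, bands, method = method)
    conn <- connectivity_epoch(ep, estimators, sl = sl, spectral = spectral,
                               bands = bands)
    vals <- list()
    for (est in estimators) {
      for (b in bands$band) {
        mat <- conn[[est]][[b]]
        if (is.null(mat))
          stop("missing ", est, "/", b, " profile for epoch ", i,
               " (subject ", ep$subject, ", state ", ep$state, ")")
        prof <- topology_profile(mat, sweep, compute_sigma = FALSE)
        nm <- paste(tolower(est), b, topo_feature_names(), sep = "_")
        vals[nm] <- prof[topo_feature_names()]
      }
    }
    rows[[i]] <- data.frame(label = ep$state, subject = ep$subject,
                            epoch = ep$epoch, vals,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  bad <- !vapply(tab[feature_columns(estimators, bands$band)],
                 function(col) all(is.finite(col)), logical(1))
  if (any(bad))
    stop("non-finite feature column(s): ", paste(names(bad)[bad], collapse = ", "))
  tab
}

#' Select a feature subset by estimator
#'
#' Restricts a feature table to the columns of the named estimators (e.g.
#' `c("SL")` for the single-network comparison, or all three for the full
#' combination), keeping the metadata columns.
#'
#' @param table Feature table from [build_feature_table()].
#' @param estimators Estimator names to keep.
#' @return The reduced data frame.
#' @export
feature_subset <- function(table, estimators) {
  estimators <- match.arg(estimators, c("SL", "PLV", "COH"), several.ok = TRUE)
  keep <- unlist(lapply(tolower(estimators), function(e)
    grep(paste0("^", e, "_"), names(table), value = TRUE)))
  if (length(keep) == 0) stop("no feature columns for: ",
                              paste(estimators, collapse = ", "))
  table[, c("label", "subject", "epoch", keep), drop = FALSE]
}

#' Write a feature table as TSV
#'
#' @param table Feature table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  num <- vapply(table, is.numeric, logical(1))
  table[num] <- lapply(table[num], function(col) signif(col, 12))
  write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
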