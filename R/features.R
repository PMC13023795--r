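# Assembly of the per-segment feature vector: 7 time-domain statistics plus
# the 23 registry entropies for each of the 13 components, named
# "<component>_<measure>" -- 390 features for a full component set.

.time_domain_names <- c("min", "max", "mean", "variance", "rms",
                        "skewness", "kurtosis")

#' Feature names for a set of components
#'
#' @param components character vector of component names (default the full
#'   13).
#' @return character vector, `30 * length(components)` names in
#'   deterministic order (components outer, the 7 statistics then the 23
#'   registry measures inner).
#' @export
feature_names <- function(components = component_names()) {
  measures <- c(.time_domain_names, entropy_registry())
  as.vector(t(outer(components, measures, paste, sep = "_")))
}

#' Extract the feature vector of one component set
#'
#' For every present component computes the 7 time-domain statistics and the
#' 23 entropy measures; absent components (e.g. IMFs the sifting did not
#' produce) yield `NA` for their 30 features.  Individual measure
#' degeneracies also yield `NA` (flagged via the `n_missing` attribute).
#'
#' @param components a [build_component_set()] result, or any named list of
#'   numeric vectors.
#' @param params an [entropy_params()].
#' @return named numeric vector (length `30 * #components`; 390 for the full
#'   set) with attribute `n_missing`.
#' @export
extract_features <- function(components, params = entropy_params()) {
  comp_names <- names(components)
  if (!length(comp_names)) stop("component set is empty")
  present <- !vapply(components, is.null, logical(1))
  if (!any(present)) stop("all components are absent")
  reg <- entropy_registry()
  out <- numeric(0)
  for (nm in comp_names) {
    v <- components[[nm]]
    if (is.null(v)) {
      vals <- rep(NA_real_, 7 + length(reg))
    } else {
      td <- time_domain_features(v)
      ent <- vapply(reg, function(mn) {
        tryCatch(compute_measure(mn, v, params),
                 error = function(e) NA_real_)
      }, numeric(1))
      vals <- c(td, ent)
    }
    names(vals) <- paste(nm, c(.time_domain_names, reg), sep = "_")
    out <- c(out, vals)
  }
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Build the feature matrix for a list of segments
#'
#' Runs [build_component_set()] and [extract_features()] on every segment
#' and assembles the Table-style feature matrix: columns `record_id`,
#' `segment_index`, `label`, then the named feature columns in deterministic
#' order.
#'
#' @param segments list of `ecg_segment` objects.
#' @param params an [entropy_params()].
#' @param emd an [emd_params()].
#' @param wavelet_name,levels DWT settings.
#' @param verbose print progress every 100 segments.
#' @return data.frame, one row per segment.
#' @export
feature_matrix <- function(segments, params = entropy_params(),
                           emd = emd_params(), wavelet_name = "db6",
                           levels = 6, verbose = FALSE) {
  rows <- vector("list", length(segments))
  for (i in seq_along(segments)) {
    cs <- build_component_set(segments[[i]], wavelet_name, levels, emd)
    rows[[i]] <- extract_features(cs, params)
    if (verbose && i %% 100 == 0)
      message("features: ", i, "/", length(segments), " segments")
  }
  feats <- do.call(rbind, rows)
  meta <- data.frame(
    record_id = vapply(segments, function(s) s$record_id, character(1)),
    segment_index = vapply(segments, function(s) as.integer(s$segment_index),
                           integer(1)),
    label = vapply(segments, function(s) s$label, character(1)),
    stringsAsFactors = FALSE)
  cbind(meta, as.data.frame(feats))
}

#' Column names of a feature subset
#'
#' Convenience selector for the experiment grids: all features belonging to
#' the given components.
#'
#' @param components character vector of component names, e.g. `"orj"`,
#'   `c("d1", ..., "a6")`.
#' @return character vector of feature column names.
#' @export
subset_features <- function(components) feature_names(components)

#' Named feature subsets used by the report tables
#'
#' @return named list: each DWT band alone, each IMF alone, the original
#'   signal, all detail+approximation bands, all IMFs, and the combined
#'   390-feature set.
#' @export
standard_subsets <- function() {
  dwt <- c(paste0("d", 1:6), "a6")
  imf <- paste0("imf", 1:5)
  subs <- c(list(orj = "orj"),
            stats::setNames(as.list(dwt), dwt),
            list(all_dwt = dwt),
            stats::setNames(as.list(imf), imf),
            list(all_imf = imf, combined = c("orj", dwt, imf)))
  lapply(subs, subset_features)
}
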