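# Pipeline driver and file I/O: validated configuration, full-precision CSV
# round-tripping of the feature matrix, manifests with a config hash, and
# the end-to-end synthetic experiment.

#' Validated pipeline configuration
#'
#' Collects every tunable of the pipeline in one document.  Unknown keys are
#' rejected; a serialized copy is embedded in every output manifest.
#'
#' @param n_mi,n_healthy synthetic record counts.
#' @param record_duration seconds per record.
#' @param seed master seed driving record generation, fold assignment and
#'   every stochastic stage.
#' @param segment_length samples per segment (default 10000).
#' @param norm_scope `"record"` (default) or `"segment"`.
#' @param denoise a [denoise_params()].
#' @param emd an [emd_params()].
#' @param entropy an [entropy_params()].
#' @param swarm a [swarm_params()] (used when `select = TRUE`).
#' @param classifier a [classifier_config()].
#' @param classifiers classifier ids to evaluate.
#' @param folds outer CV folds (default 10).
#' @param select run PSO feature selection and a before/after comparison.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_mi = 50, n_healthy = 50, record_duration = 100,
                            seed = 1L, segment_length = 10000,
                            norm_scope = "record",
                            denoise = denoise_params(),
                            emd = emd_params(),
                            entropy = entropy_params(),
                            swarm = swarm_params(),
                            classifier = classifier_config(),
                            classifiers = "bt", folds = 10,
                            select = FALSE) {
  if (segment_length < 1) stop("invalid config: segment_length must be >= 1")
  if (n_mi < 0 || n_healthy < 0) stop("invalid config: negative record count")
  if (!norm_scope %in% c("record", "segment"))
    stop("invalid config: norm_scope must be 'record' or 'segment'")
  if (!all(classifiers %in% c("bt", "svm", "ann", "knn")))
    stop("invalid config: unknown classifier id")
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  cfg
}

#' Write / read a feature matrix as full-precision CSV
#'
#' Numeric columns are written with `%.17g` so a write/read round trip
#' reproduces the doubles exactly and reruns are byte-identical.
#'
#' @param features data.frame from [feature_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  out <- features
  num <- vapply(out, is.numeric, logical(1))
  for (j in which(num)) {
    col <- sprintf("%.17g", out[[j]])
    col[is.na(out[[j]])] <- "NA"
    out[[j]] <- col
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- intersect(c("record_id", "label"), names(df))
  for (j in setdiff(names(df), meta))
    if (!is.numeric(df[[j]])) df[[j]] <- as.numeric(df[[j]])
  if ("segment_index" %in% names(df))
    df$segment_index <- as.integer(df$segment_index)
  df
}

.config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> denoise/normalize/segment -> decompose -> extract features ->
#' (optional) PSO selection -> cross-validated classification -> reports.
#' Every stage's counts, the config hash and the seed are written to
#' `manifest.json`; the feature matrix and report tables are CSV; metrics
#' are also emitted as JSON.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param verbose print stage progress.
#' @return list with `features`, `results`, `selection` (or `NULL`),
#'   `manifest`, and the output paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ecgmi_"),
                         verbose = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("config must be a pipeline_config object")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)

  say("stage 1/5: simulate")
  records <- generate_dataset(config$n_mi, config$n_healthy,
                              config$record_duration, config$seed)
  say("stage 2/5: preprocess")
  segments <- preprocess(records, config$segment_length, config$norm_scope,
                         config$denoise)
  say("stage 3/5: decompose + extract features (", length(segments),
      " segments)")
  features <- feature_matrix(segments, config$entropy, config$emd,
                             config$denoise$wavelet_name, config$denoise$levels,
                             verbose = verbose)
  fpath <- file.path(out_dir, "features.csv")
  write_feature_csv(features, fpath)

  meta <- c("record_id", "segment_index", "label")
  X <- as.matrix(features[, setdiff(names(features), meta)])
  labels <- features$label

  selection <- NULL
  subsets <- NULL
  if (config$select) {
    say("stage 4/5: PSO feature selection")
    complete <- stats::complete.cases(X)
    selection <- run_pso(X[complete, , drop = FALSE], labels[complete],
                         config$swarm)
    jsonlite::write_json(
      list(selected = selection$selected, fitness = selection$fitness,
           history = selection$history, n_selected = selection$n_selected),
      file.path(out_dir, "mask.json"), auto_unbox = TRUE, digits = NA)
    subsets <- list(combined = colnames(X), pso_selected = selection$selected)
  }

  say("stage 5/5: classification")
  results <- run_experiment(features, subsets = subsets,
                            classifiers = config$classifiers,
                            k = config$folds, seed = config$seed,
                            config = config$classifier)
  rpath <- file.path(out_dir, "report.csv")
  write_feature_csv(results, rpath)
  gpath <- file.path(out_dir, "accuracy_grid.csv")
  write_feature_csv(accuracy_grid(results), gpath)
  jsonlite::write_json(results, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  manifest <- list(
    config_hash = .config_hash(unclass(config)[setdiff(names(config),
      c("denoise", "emd", "entropy", "swarm", "classifier"))]),
    seed = config$seed,
    n_records = length(records),
    n_segments = length(segments),
    n_features = ncol(X),
    n_selected = if (is.null(selection)) NA else selection$n_selected,
    outputs = c("features.csv", "report.csv", "accuracy_grid.csv",
                "metrics.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(features = features, results = results, selection = selection,
       manifest = manifest, out_dir = out_dir,
       paths = c(features = fpath, report = rpath, grid = gpath))
}
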