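# Cross-validated evaluation of the four classifiers with MI as the
# positive class.  Confusion counts are pooled across folds before metric
# computation (the single-confusion-matrix framing), which is well defined
# with imbalanced folds; the pooled accuracy equals the sample-weighted mean
# of per-fold accuracies exactly.

.positive_class <- "MI"

#' Stratified k-fold assignment
#'
#' @param labels label vector; every class must have at least `k` members.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1..k`; per-fold class counts are
#'   within one of proportional.
#' @export
make_folds <- function(labels, k = 10, seed = 1L) {
  with_seed(seed, .stratified_folds(labels, k))
}

#' Default classifier hyperparameters
#'
#' Common default settings: 30 bagged trees; RBF SVM with `C = 1` and
#' kernel scale `1/p`; one hidden layer of 10 units; `k = 5` neighbours.
#'
#' @param bt_trees,svm_cost,ann_hidden,ann_maxit,ann_decay,knn_k see above.
#' @return list of hyperparameters.
#' @export
classifier_config <- function(bt_trees = 30, svm_cost = 1, ann_hidden = 10,
                              ann_maxit = 150, ann_decay = 1e-4, knn_k = 5) {
  list(bt_trees = bt_trees, svm_cost = svm_cost, ann_hidden = ann_hidden,
       ann_maxit = ann_maxit, ann_decay = ann_decay, knn_k = knn_k)
}

.standardize_pair <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, sd)
  sdv[sdv == 0] <- 1
  list(tr = sweep(sweep(Xtr, 2, mu), 2, sdv, "/"),
       te = sweep(sweep(Xte, 2, mu), 2, sdv, "/"),
       mu = mu, sd = sdv)
}

#' Train one classifier and predict test labels
#'
#' `"bt"` = bootstrap-aggregated decision trees (majority vote, all features
#' per split); `"svm"` = RBF support vector machine; `"ann"` = single
#' hidden-layer feed-forward network trained by backpropagation; `"knn"` =
#' k-nearest neighbours with Euclidean distance.  Distance/scale-sensitive
#' learners (svm, ann, knn) receive features standardized by training-fold
#' statistics only.  Deterministic given `seed`.
#'
#' @param classifier one of `"bt"`, `"svm"`, `"ann"`, `"knn"`.
#' @param Xtr,ytr training matrix and labels (both classes present).
#' @param Xte test matrix.
#' @param config a [classifier_config()].
#' @param seed integer seed for the stochastic learners.
#' @return factor of predicted labels with the training label levels.
#' @export
train_predict <- function(classifier = c("bt", "svm", "ann", "knn"),
                          Xtr, ytr, Xte, config = classifier_config(),
                          seed = 1L) {
  classifier <- match.arg(classifier)
  if (length(unique(ytr)) < 2) stop("training data contains a single class")
  Xtr <- as.matrix(Xtr); Xte <- as.matrix(Xte)
  ytr <- factor(ytr)
  if (classifier == "bt") {
    fit <- with_seed(seed, randomForest::randomForest(
      x = Xtr, y = ytr, ntree = config$bt_trees, mtry = ncol(Xtr)))
    return(predict(fit, Xte))
  }
  st <- .standardize_pair(Xtr, Xte)
  if (classifier == "svm") {
    fit <- e1071::svm(st$tr, ytr, kernel = "radial", cost = config$svm_cost,
                      gamma = 1 / ncol(Xtr), scale = FALSE)
    return(predict(fit, st$te))
  }
  if (classifier == "ann") {
    nw <- config$ann_hidden * (ncol(Xtr) + 1) + config$ann_hidden + 1
    fit <- with_seed(seed, nnet::nnet(
      x = st$tr, y = as.numeric(ytr == .positive_class), size = config$ann_hidden,
      decay = config$ann_decay, maxit = config$ann_maxit,
      MaxNWts = nw + 1000, trace = FALSE))
    pr <- predict(fit, st$te)
    return(factor(ifelse(pr[, 1] > 0.5, .positive_class,
                         setdiff(levels(ytr), .positive_class)),
                  levels = levels(ytr)))
  }
  # knn resolves exact distance ties by random draw; seed it so reruns are
  # byte-identical regardless of ambient RNG state
  with_seed(seed, class::knn(st$tr, st$te, ytr, k = config$knn_k))
}

#' Confusion counts with MI as the positive class
#'
#' @param truth,pred label vectors.
#' @return named vector `TP, FP, TN, FN`.
#' @export
confusion_counts <- function(truth, pred) {
  pos <- .positive_class
  c(TP = sum(truth == pos & pred == pos),
    FP = sum(truth != pos & pred == pos),
    TN = sum(truth != pos & pred != pos),
    FN = sum(truth == pos & pred != pos))
}

#' Performance metrics from confusion counts
#'
#' Accuracy, recall (sensitivity), specificity, PPV and NPV as percentages:
#' Acc = (TP+TN)/total, Rec = TP/(TP+FN), Spe = TN/(TN+FP),
#' PPV = TP/(TP+FP), NPV = TN/(TN+FN).  A zero denominator yields `NA` for
#' that metric; all-zero counts are an error.
#'
#' @param counts named vector with `TP`, `FP`, `TN`, `FN`.
#' @return named numeric vector `acc, rec, spe, ppv, npv` in percent (full
#'   precision; report tables round to one decimal).
#' @export
compute_metrics <- function(counts) {
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  total <- tp + fp + tn + fn
  if (total == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  c(acc = 100 * (tp + tn) / total,
    rec = ratio(tp, tp + fn),
    spe = ratio(tn, tn + fp),
    ppv = ratio(tp, tp + fp),
    npv = ratio(tn, tn + fn))
}

#' k-fold cross-validated evaluation of one classifier
#'
#' @param X feature matrix, `y` labels, `classifier` id, `k` folds.
#' @param y labels.
#' @param classifier classifier id (see [train_predict()]).
#' @param k folds (default 10).
#' @param seed integer seed (controls fold assignment and per-fold model
#'   seeds).
#' @param config a [classifier_config()].
#' @param folds optional precomputed fold assignment (shared across
#'   experiment cells).
#' @return list with `pooled` counts, `per_fold` count matrix, `metrics`
#'   (from pooled counts) and `folds`.
#' @export
cv_evaluate <- function(X, y, classifier = "bt", k = 10, seed = 1L,
                        config = classifier_config(), folds = NULL) {
  X <- as.matrix(X)
  if (is.null(folds)) folds <- make_folds(y, k, seed)
  per_fold <- matrix(0L, max(folds), 4,
                     dimnames = list(NULL, c("TP", "FP", "TN", "FN")))
  for (f in seq_len(max(folds))) {
    tr <- folds != f
    pred <- train_predict(classifier, X[tr, , drop = FALSE], y[tr],
                          X[!tr, , drop = FALSE], config, seed = seed + f)
    per_fold[f, ] <- confusion_counts(y[!tr], as.character(pred))
  }
  pooled <- colSums(per_fold)
  list(pooled = pooled, per_fold = per_fold,
       metrics = compute_metrics(pooled), folds = folds)
}

#' Run a grid of (classifier x feature subset) CV experiments
#'
#' Every cell shares the same stratified fold assignment (fixed by `seed`),
#' so before/after-selection comparisons are paired.  Rows with missing
#' feature values in the requested subset are dropped (with a message).
#'
#' @param features feature data.frame from [feature_matrix()] (metadata
#'   columns plus feature columns), or a plain matrix with `labels`.
#' @param subsets named list of feature-column vectors (default
#'   [standard_subsets()]).
#' @param classifiers character vector among `"bt", "svm", "ann", "knn"`.
#' @param k folds.
#' @param seed integer seed.
#' @param config a [classifier_config()].
#' @param labels labels (taken from `features$label` if present).
#' @return data.frame with one row per cell: `classifier`, `feature_set`,
#'   `n_features`, `acc`, `rec`, `spe`, `ppv`, `npv` (percent, one-decimal
#'   rounding applied) plus pooled counts; per-fold counts are attached as
#'   the `per_fold` attribute.
#' @export
run_experiment <- function(features, subsets = NULL,
                           classifiers = c("bt", "svm", "ann", "knn"),
                           k = 10, seed = 1L, config = classifier_config(),
                           labels = NULL) {
  if (is.data.frame(features) && "label" %in% names(features)) {
    labels <- features$label
    meta <- intersect(c("record_id", "segment_index", "label"),
                      names(features))
    X <- as.matrix(features[, setdiff(names(features), meta), drop = FALSE])
  } else {
    X <- as.matrix(features)
  }
  if (is.null(labels)) stop("labels are required")
  if (is.null(subsets)) {
    subsets <- standard_subsets()
    subsets <- lapply(subsets, intersect, y = colnames(X))
    subsets <- subsets[vapply(subsets, length, integer(1)) > 0]
  }
  complete <- stats::complete.cases(X)
  if (!all(complete)) {
    message("dropping ", sum(!complete),
            " segment(s) with missing feature values")
    X <- X[complete, , drop = FALSE]
    labels <- labels[complete]
  }
  folds <- make_folds(labels, k, seed)
  rows <- list(); per_fold <- list()
  for (cl in classifiers) {
    for (sn in names(subsets)) {
      cols <- subsets[[sn]]
      cv <- cv_evaluate(X[, cols, drop = FALSE], labels, cl, k, seed,
                        config, folds = folds)
      m <- round(cv$metrics, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = cl, feature_set = sn, n_features = length(cols),
        acc = m[["acc"]], rec = m[["rec"]], spe = m[["spe"]],
        ppv = m[["ppv"]], npv = m[["npv"]],
        TP = cv$pooled[["TP"]], FP = cv$pooled[["FP"]],
        TN = cv$pooled[["TN"]], FN = cv$pooled[["FN"]],
        stringsAsFactors = FALSE)
      per_fold[[paste(cl, sn, sep = ".")]] <- cv$per_fold
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_fold") <- per_fold
  out
}

#' Accuracy grid in the per-component report layout
#'
#' Reshapes [run_experiment()] output into a feature-set x classifier
#' accuracy table (the per-DWT-band / per-IMF report style).
#'
#' @param results data.frame from [run_experiment()].
#' @return data.frame, rows = feature sets, columns = classifiers.
#' @export
accuracy_grid <- function(results) {
  sets <- unique(results$feature_set)
  cls <- unique(results$classifier)
  grid <- matrix(NA_real_, length(sets), length(cls),
                 dimnames = list(sets, cls))
  for (i in seq_len(nrow(results)))
    grid[results$feature_set[i], results$classifier[i]] <- results$acc[i]
  data.frame(feature_set = sets, grid, row.names = NULL,
             check.names = FALSE)
}
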