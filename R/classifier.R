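## Multi-feature response classification: balanced subsampling into subsets,
## RBF-SVM grid search, sequential forward selection, leave-one-out
## validation and consensus feature selection.

#' Classifier configuration
#'
#' Defaults follow the study protocol: an RBF-SVM with a grid search over
#' `C = 2^8..2^15` and `gamma = 2^-18..2^-5`, 10 balanced subsets, six
#' features selected per subset by sequential forward selection, leave-one-out
#' validation.
#'
#' @param CGrid candidate SVM cost values.
#' @param gammaGrid candidate RBF kernel widths.
#' @param nSubsets number of balanced subsets.
#' @param nSelected number of features chosen per subset.
#' @param seed integer seed driving the balanced subsampling.
#' @param task "three_class" (CR/PR/NR) or "responder_vs_nonresponder"
#'   (CR+PR merged into "R" before balancing).
#' @return a list of class `ClassifierConfig`.
#' @export
classifierConfig <- function(CGrid = 2^(8:15), gammaGrid = 2^(-18:-5),
                             nSubsets = 10L, nSelected = 6L, seed = 1L,
                             task = c("three_class", "responder_vs_nonresponder")) {
  task <- match.arg(task)
  if (!length(CGrid) || !length(gammaGrid)) stopf("parameter grids must be nonempty")
  if (nSelected < 1L) stopf("nSelected must be >= 1")
  structure(list(CGrid = sort(CGrid), gammaGrid = sort(gammaGrid),
                 nSubsets = as.integer(nSubsets),
                 nSelected = as.integer(nSelected),
                 seed = as.integer(seed), task = task),
            class = "ClassifierConfig")
}

#' Balanced class-subsampled subsets
#'
#' Draws `nSubsets` subsets in which every class appears exactly
#' `min(class sizes)` times: classes at the minimum size contribute all their
#' members, larger classes are subsampled without replacement. Deterministic
#' under the seed.
#'
#' @param labels vector of class labels, one per sample.
#' @param nSubsets number of subsets.
#' @param seed integer seed.
#' @return a list of class `SubsetPlan`: `subsets` (list of integer index
#'   vectors), `perClass` (samples per class in each subset), `classes`.
#' @examples
#' plan <- balancedSubsets(rep(c("CR", "PR", "NR"), c(21, 52, 23)), 10, seed = 3)
#' lengths(plan$subsets)  # all 63
#' @export
balancedSubsets <- function(labels, nSubsets = 10L, seed = 1L) {
  tab <- table(labels)
  if (any(tab == 0) || length(tab) < 2L)
    stopf("every class must be nonempty")
  m <- min(tab)
  classes <- names(tab)
  set.seed(deriveSeed(seed, 303L))
  subsets <- lapply(seq_len(nSubsets), function(s) {
    idx <- unlist(lapply(classes, function(cl) {
      members <- which(labels == cl)
      if (length(members) == m) members else sample(members, m)
    }))
    sort(idx)
  })
  structure(list(subsets = subsets, perClass = m, classes = classes),
            class = "SubsetPlan")
}

## Per-fold standardization: statistics from the training rows only.
#' @noRd
standardize <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu), 2, sdv, "/"))
}

## Leave-one-out predictions of an RBF-SVM with per-fold standardization.
## Training folds are class-weighted (inverse class frequency): leaving one
## sample out always under-represents its own class in the training fold,
## which would otherwise bias LOO accuracy below chance on label-free data.
#' @noRd
looPredictions <- function(X, y, C, gamma) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- factor(y)
  pred <- character(n)
  for (i in seq_len(n)) {
    st <- standardize(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    yi <- droplevels(y[-i])
    tb <- table(yi)
    cw <- as.numeric(sum(tb) / (length(tb) * tb))
    names(cw) <- names(tb)
    fit <- e1071::svm(st$train, yi, kernel = "radial",
                      cost = C, gamma = gamma, scale = FALSE,
                      class.weights = cw)
    pred[i] <- as.character(stats::predict(fit, st$test))
  }
  factor(pred, levels = levels(y))
}

#' @noRd
looAccuracy <- function(X, y, C, gamma) {
  mean(looPredictions(X, y, C, gamma) == factor(y))
}

#' RBF-SVM hyperparameter grid search
#'
#' Evaluates every (C, gamma) pair of the configured grids by leave-one-out
#' accuracy and returns the maximizer; ties are broken toward the smallest C,
#' then the smallest gamma.
#'
#' @param X feature matrix or data frame (samples x features).
#' @param y class labels.
#' @param config a [classifierConfig()].
#' @return list with `C`, `gamma`, `accuracy` and the full `grid` of results.
#' @export
gridSearchSVM <- function(X, y, config = classifierConfig()) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stopf("grid search needs at least two classes present")
  grid <- expand.grid(C = config$CGrid, gamma = config$gammaGrid)
  grid <- grid[order(grid$C, grid$gamma), ]
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(k)
    looAccuracy(X, y, grid$C[k], grid$gamma[k]), numeric(1))
  best <- which.max(grid$accuracy)   # first maximum in (C, gamma) order
  list(C = grid$C[best], gamma = grid$gamma[best],
       accuracy = grid$accuracy[best], grid = grid)
}

#' Sequential forward feature selection
#'
#' Greedily adds the feature that maximizes the leave-one-out accuracy of the
#' RBF-SVM on the already-selected set plus the candidate, stopping at
#' `nSelected` features. Ties go to the earliest feature in column order.
#'
#' @param X feature matrix or data frame.
#' @param y class labels.
#' @param config a [classifierConfig()] (supplies `nSelected`).
#' @param C,gamma SVM hyperparameters (typically from [gridSearchSVM()]).
#' @return list with `selected` (ordered feature names) and `accuracyPath`
#'   (training-criterion LOO accuracy after each addition).
#' @export
sfsSelect <- function(X, y, config = classifierConfig(), C = 1, gamma = 0.1) {
  X <- as.matrix(X)
  y <- factor(y)
  feats <- colnames(X)
  if (is.null(feats)) feats <- colnames(X) <- paste0("V", seq_len(ncol(X)))
  k <- config$nSelected
  if (ncol(X) < k) {
    warning("fewer candidate features than nSelected; selecting all",
            call. = FALSE)
    k <- ncol(X)
  }
  selected <- character(0)
  accPath <- numeric(0)
  remaining <- feats
  for (step in seq_len(k)) {
    accs <- vapply(remaining, function(f)
      looAccuracy(X[, c(selected, f), drop = FALSE], y, C, gamma), numeric(1))
    best <- remaining[which.max(accs)]   # which.max: first (lowest index) tie
    selected <- c(selected, best)
    accPath <- c(accPath, max(accs))
    remaining <- setdiff(remaining, best)
  }
  list(selected = selected, accuracyPath = accPath)
}

#' Consensus features from per-subset selections
#'
#' Builds the occurrence histogram of all features selected across subsets and
#' returns the top-k; ties are broken by the fixed feature order.
#'
#' @param selection a `SelectionResult` (list with `perSubset` selections and
#'   `featureOrder`), as produced by [runResponseClassification()], or a list
#'   of per-subset character vectors.
#' @param k number of consensus features.
#' @return character vector of the k most frequently selected features (with a
#'   `counts` attribute).
#' @export
consensusFeatures <- function(selection, k = 6L) {
  perSubset <- if (!is.null(selection$perSubset)) selection$perSubset else selection
  all <- unlist(perSubset)
  if (!length(all)) stopf("empty selection histogram")
  order0 <- if (!is.null(selection$featureOrder)) selection$featureOrder
            else unique(all)
  counts <- table(factor(all, levels = order0))
  counts <- counts[counts > 0]
  if (k > length(counts)) {
    warning("fewer distinct features than k; returning all", call. = FALSE)
    k <- length(counts)
  }
  if (length(unique(as.integer(counts))) == 1L && length(counts) > k)
    warning("all occurrence counts equal; ties broken by fixed feature order",
            call. = FALSE)
  ## stable sort: decreasing count, ties keep featureOrder position
  ord <- order(-as.integer(counts), seq_along(counts))
  top <- names(counts)[ord][seq_len(k)]
  attr(top, "counts") <- as.integer(counts[ord][seq_len(k)])
  top
}

#' Leave-one-out evaluation of a selected feature set
#'
#' One fold per sample; standardization statistics are fitted on the training
#' portion of each fold. Reports pooled accuracy, per-class sensitivity and
#' specificity (percent) and the confusion matrix.
#'
#' @param X feature matrix or data frame.
#' @param y class labels.
#' @param selected feature names to use (default: all columns).
#' @param C,gamma SVM hyperparameters.
#' @return a list of class `EvalMetrics`: `accuracy` (%), `sensitivity`,
#'   `specificity` (named, %), `confusion` (true x predicted counts).
#' @export
looEvaluate <- function(X, y, selected = colnames(X), C = 1, gamma = 0.1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (any(table(y) < 2L))
    warning("a class has fewer than 2 samples; folds still executed",
            call. = FALSE)
  pred <- looPredictions(X[, selected, drop = FALSE], y, C, gamma)
  confusion <- table(true = y, predicted = pred)
  total <- sum(confusion)
  acc <- 100 * sum(diag(confusion)) / total
  sens <- spec <- stats::setNames(numeric(nlevels(y)), levels(y))
  for (cl in levels(y)) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- total - tp - fn - fp
    sens[cl] <- 100 * tp / (tp + fn)
    spec[cl] <- 100 * tn / (tn + fp)
  }
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 confusion = confusion),
            class = "EvalMetrics")
}

#' @export
print.EvalMetrics <- function(x, ...) {
  cat(sprintf("EvalMetrics: accuracy %.1f%%\n", x$accuracy))
  print(x$confusion)
  invisible(x)
}

#' Run the full response-classification protocol
#'
#' For the requested feature mode and task: draw balanced subsets, then per
#' subset run the hyperparameter grid search, sequential forward selection to
#' `nSelected` features and leave-one-out evaluation of the selected set;
#' finally pool the per-subset selections into a consensus feature histogram.
#' The reported accuracy is the mean LOO accuracy over subsets.
#'
#' @param featureTable data frame with columns `id`, `label` and the 65
#'   features (see [cohortFeatureTable()]).
#' @param mode feature set: "combined", "qus_texture" or "molecular".
#' @param config a [classifierConfig()].
#' @return a list of class `ResponseClassification`: `meanAccuracy` (%),
#'   `perSubset` (list of `EvalMetrics`), `selection` (a `SelectionResult`
#'   with `perSubset`, `histogram`, `consensus`, `featureOrder`), `plan`,
#'   `mode`, `config`.
#' @export
runResponseClassification <- function(featureTable,
                                      mode = c("combined", "qus_texture", "molecular"),
                                      config = classifierConfig()) {
  mode <- match.arg(mode)
  cols <- intersect(featureModeColumns(mode), colnames(featureTable))
  if (!length(cols)) stopf("feature table lacks the %s columns", mode)
  labels <- featureTable$label
  if (config$task == "responder_vs_nonresponder")
    labels <- ifelse(labels == "NR", "NR", "R")
  plan <- balancedSubsets(labels, config$nSubsets, config$seed)
  X <- as.matrix(featureTable[, cols, drop = FALSE])
  perSel <- vector("list", config$nSubsets)
  perMetrics <- vector("list", config$nSubsets)
  for (s in seq_len(config$nSubsets)) {
    idx <- plan$subsets[[s]]
    Xs <- X[idx, , drop = FALSE]
    ys <- labels[idx]
    gs <- gridSearchSVM(Xs, ys, config)
    sel <- sfsSelect(Xs, ys, config, C = gs$C, gamma = gs$gamma)
    perSel[[s]] <- sel$selected
    perMetrics[[s]] <- looEvaluate(Xs, ys, sel$selected, gs$C, gs$gamma)
  }
  selection <- list(perSubset = perSel, featureOrder = cols)
  selection$histogram <- table(factor(unlist(perSel), levels = cols))
  selection$consensus <- consensusFeatures(selection, config$nSelected)
  structure(list(
    meanAccuracy = mean(vapply(perMetrics, function(m) m$accuracy, numeric(1))),
    perSubset = perMetrics, selection = selection, plan = plan,
    mode = mode, config = config),
    class = "ResponseClassification")
}

#' @export
print.ResponseClassification <- function(x, ...) {
  cat(sprintf("ResponseClassification (%s, %s): mean LOO accuracy %.1f%% over %d subsets\n",
              x$mode, x$config$task, x$meanAccuracy, length(x$perSubset)))
  cat("consensus features:", paste(x$selection$consensus, collapse = ", "), "\n")
  invisible(x)
}
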