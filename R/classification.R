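## Multiclass segment classifier on IMS features, the per-segment binary
## deep/superficial classifiers, and their cross-validated metrics.
##
## Cross-validation is grouped by glomerulus (ROI): all pixels of one
## glomerulus land in the same fold, so spatial autocorrelation within a
## glomerulus can never leak between train and test.

#' Classifier settings
#'
#' @param folds CV folds (default 5).
#' @param groupBy grouping key for CV, `"roi"` (default; no ROI spans
#'   folds) or `"none"` (plain stratified pixels).
#' @param nrounds,maxDepth,eta,subsample,colsample gradient-boosted tree
#'   hyperparameters.
#' @param seed integer seed (fold assignment and boosting).
#' @return a list of settings for [trainSegmentClassifier()].
#' @export
classifierSpec <- function(folds = 5, groupBy = c("roi", "none"),
                           nrounds = 150, maxDepth = 5, eta = 0.2,
                           subsample = 0.9, colsample = 0.9, seed = 1) {
  stopifnot(folds >= 2)
  list(folds = as.integer(folds), groupBy = match.arg(groupBy),
       nrounds = nrounds, maxDepth = maxDepth, eta = eta,
       subsample = subsample, colsample = colsample, seed = as.integer(seed))
}

#' Gradient-boosted tree model with per-class probability output
#' @slot booster the fitted xgboost handle.
#' @slot classes class labels in output column order.
#' @export
setClass("GradientBoostedModel",
         representation(booster = "ANY", classes = "character"))

#' @rdname predictProba
#' @export
setMethod("predictProba", "GradientBoostedModel", function(object, X) {
  p <- predict(object@booster, as.matrix(X))
  colnames(p) <- object@classes
  p
})

#' Per-class margins (log-odds scale) of a gradient-boosted model
#'
#' Unlike the softmax probabilities, a class's margin depends only on that
#' class's trees, so margin-scale attributions decompose per segment
#' without cross-class renormalization effects.
#'
#' @param object a [GradientBoostedModel-class].
#' @param X numeric feature matrix.
#' @return matrix of per-class raw margins.
#' @export
predictMargin <- function(object, X) {
  p <- predict(object@booster, as.matrix(X), outputmargin = TRUE)
  colnames(p) <- object@classes
  p
}

#' @rdname predictProba
#' @export
setMethod("predictProba", "function", function(object, X) {
  p <- object(as.matrix(X))
  if (is.null(dim(p))) p <- cbind(p)
  p
})

.fitGBM <- function(X, y, classes, spec) {
  lab <- match(y, classes) - 1L
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = lab, nthread = 1)
  params <- list(objective = "multi:softprob", num_class = length(classes),
                 max_depth = spec$maxDepth, eta = spec$eta,
                 subsample = spec$subsample,
                 colsample_bytree = spec$colsample,
                 nthread = 1, seed = spec$seed)
  booster <- xgboost::xgb.train(params = params, data = dm,
                                nrounds = spec$nrounds, verbose = 0)
  new("GradientBoostedModel", booster = booster, classes = classes)
}

## Assign groups (ROIs) to folds so per-class pixel counts stay balanced:
## greedy over groups in decreasing size (seeded tie order), each group to
## the fold minimizing the across-fold class-count variance.
.groupedStratifiedFolds <- function(groups, labels, nFolds, seed) {
  classes <- sort(unique(labels))
  gids <- unique(groups)
  gclass <- t(vapply(gids, function(g)
    tabulate(match(labels[groups == g], classes), length(classes)),
    integer(length(classes))))
  ord <- withr::with_seed(seed, order(-rowSums(gclass),
                                      sample.int(length(gids))))
  foldCounts <- matrix(0, nFolds, length(classes))
  foldOf <- integer(length(gids))
  for (i in ord) {
    cost <- vapply(seq_len(nFolds), function(f) {
      fc <- foldCounts
      fc[f, ] <- fc[f, ] + gclass[i, ]
      sum(apply(fc, 2L, var))
    }, numeric(1))
    f <- which.min(cost)
    foldOf[i] <- f
    foldCounts[f, ] <- foldCounts[f, ] + gclass[i, ]
  }
  foldOf[match(groups, gids)]
}

.stratifiedFolds <- function(labels, nFolds, seed) {
  fold <- integer(length(labels))
  withr::with_seed(seed, for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(nFolds), length(idx)))
  })
  fold
}

#' One-vs-rest metrics from a confusion matrix
#'
#' Balanced accuracy `(recall + specificity) / 2`, F1, precision and
#' recall for every class of a (truth x predicted) confusion matrix.
#'
#' @param cm square confusion matrix with identical row/col names.
#' @return data.frame: `segment`, `balanced_accuracy`, `f1`, `precision`,
#'   `recall`.
#' @export
metricsFromConfusion <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  out <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]; fn <- sum(cm[i, ]) - tp; fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else NA_real_
    data.frame(segment = rownames(cm)[i] %||% as.character(i),
               balanced_accuracy = (rec + spec) / 2, f1 = f1,
               precision = prec, recall = rec)
  })
  do.call(rbind, out)
}

.cvClassifier <- function(X, y, groups, spec) {
  classes <- sort(unique(y))
  fold <- if (spec$groupBy == "roi")
    .groupedStratifiedFolds(groups, y, spec$folds, spec$seed)
  else .stratifiedFolds(y, spec$folds, spec$seed)
  cmAll <- matrix(0, length(classes), length(classes),
                  dimnames = list(classes, classes))
  perFold <- vector("list", spec$folds)
  for (f in seq_len(spec$folds)) {
    te <- fold == f
    if (!any(te) || length(unique(y[!te])) < 2L) next
    m <- .fitGBM(X[!te, , drop = FALSE], y[!te], classes, spec)
    p <- predictProba(m, X[te, , drop = FALSE])
    pred <- classes[max.col(p, ties.method = "first")]
    cm <- table(factor(y[te], classes), factor(pred, classes))
    cmAll <- cmAll + cm
    perFold[[f]] <- metricsFromConfusion(cm)
  }
  perFold <- perFold[!vapply(perFold, is.null, logical(1))]
  long <- do.call(rbind, lapply(seq_along(perFold), function(i)
    cbind(fold = i, perFold[[i]])))
  metricNames <- c("balanced_accuracy", "f1", "precision", "recall")
  metrics <- do.call(rbind, lapply(classes, function(cl) {
    rows <- long[long$segment == cl, , drop = FALSE]
    do.call(rbind, lapply(metricNames, function(mn)
      data.frame(segment = cl, metric = mn,
                 mean = mean(rows[[mn]], na.rm = TRUE),
                 sd = sd(rows[[mn]], na.rm = TRUE))))
  }))
  list(metrics = metrics,
       confusion = matrix(cmAll, nrow(cmAll), dimnames = dimnames(cmAll)),
       fold = fold, classes = classes)
}

#' Train and cross-validate the multiclass segment classifier
#'
#' ROI-grouped stratified k-fold CV of a gradient-boosted tree classifier
#' that predicts each IMS pixel's segment from its ion intensities;
#' one-vs-rest balanced accuracy, F1, precision and recall are computed on
#' the held-out pixels of each fold, and a final model is refit on all
#' pixels for attribution.
#'
#' @param labeled a [LabeledIMSTable-class].
#' @param spec settings from [classifierSpec()].
#' @param ticNormalize divide each pixel's intensities by its total ion
#'   count (scaled by the mean total) before training; default FALSE (raw
#'   picked intensities).
#' @return a [ClassifierResult-class].
#' @export
trainSegmentClassifier <- function(labeled, spec = classifierSpec(),
                                   ticNormalize = FALSE) {
  X <- labeled@intensities
  if (ticNormalize) X <- ticNormalizeIntensities(X)
  y <- as.character(labeled@table$segment)
  groups <- labeled@table$roi_id
  sz <- table(y)
  small <- names(sz)[sz < spec$folds]
  if (length(small)) {
    warning("dropping segment(s) with fewer pixels than folds: ",
            paste(small, collapse = ", "), call. = FALSE)
    keep <- !(y %in% small)
    X <- X[keep, , drop = FALSE]; y <- y[keep]; groups <- groups[keep]
  }
  if (length(unique(y)) < 2L)
    stop("need at least 2 segments with >= folds pixels each", call. = FALSE)
  cv <- .cvClassifier(X, y, groups, spec)
  final <- .fitGBM(X, y, cv$classes, spec)
  new("ClassifierResult", metrics = cv$metrics, confusion = cv$confusion,
      folds = as.integer(cv$fold), model = final, classes = cv$classes,
      featureNames = mzLabel(labeled@mz), spec = spec)
}

#' TIC-normalize an intensity matrix
#'
#' Divides each row by its total ion count and rescales by the mean total
#' so intensities stay on their original magnitude.
#' @param X numeric matrix, pixels x features.
#' @return normalized matrix.
#' @export
ticNormalizeIntensities <- function(X) {
  tot <- rowSums(X)
  tot[tot == 0] <- 1
  X / tot * mean(tot)
}

#' Train the binary deep/superficial classifier for one segment
#'
#' Restricts the labeled table to one segment and classifies its pixels by
#' glomerulus depth class. CV is always grouped by glomerulus: depth is a
#' per-ROI property, so pixel-level splits would leak it.
#'
#' @param labeled a [LabeledIMSTable-class] with known depth classes.
#' @param segmentId the segment to analyze.
#' @param spec settings from [classifierSpec()] (`groupBy` is forced to
#'   `"roi"`).
#' @param ticNormalize as in [trainSegmentClassifier()].
#' @return a [ClassifierResult-class] with classes `deep`/`superficial`.
#' @export
trainDepthClassifier <- function(labeled, segmentId, spec = classifierSpec(),
                                 ticNormalize = FALSE) {
  sel <- labeled@table$segment == segmentId &
    labeled@table$depth_class %in% c("deep", "superficial")
  if (!any(sel))
    stop("segment ", segmentId, " has no pixels with known depth class",
         call. = FALSE)
  X <- labeled@intensities[sel, , drop = FALSE]
  if (ticNormalize) X <- ticNormalizeIntensities(X)
  y <- labeled@table$depth_class[sel]
  if (length(unique(y)) < 2L)
    stop("segment ", segmentId, " lacks one depth class entirely",
         call. = FALSE)
  groups <- labeled@table$roi_id[sel]
  spec$groupBy <- "roi"
  cv <- .cvClassifier(X, y, groups, spec)
  final <- .fitGBM(X, y, cv$classes, spec)
  new("ClassifierResult", metrics = cv$metrics, confusion = cv$confusion,
      folds = as.integer(cv$fold), model = final, classes = cv$classes,
      featureNames = mzLabel(labeled@mz), spec = spec)
}
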