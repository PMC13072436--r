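## Shapley-value interpretation of fitted segment classifiers: per-pixel
## signed attributions on the class-probability scale, global per-segment
## importance scores, correlation-sign directions, rankings and the
## bubble-plot export.

#' Shapley attributions of a model's per-class outputs
#'
#' Computes, for every evaluated pixel and every model output class, one
#' signed attribution per feature such that attributions sum to the model
#' output minus the per-class baseline (local accuracy). Two estimators:
#'
#' * `"exact"` — full subset enumeration against the background set
#'   (`2^d` coalitions; refused for d > 12).
#' * `"permutation"` — seeded permutation sampling: `nSamples`
#'   (permutation, background row) pairs are drawn once and shared by all
#'   evaluated pixels, so local accuracy holds exactly for the reported
#'   baseline (the mean model output over the drawn background rows).
#'
#' @param model anything with a [predictProba()] method (a fitted
#'   [GradientBoostedModel-class] or a plain `function(X) -> matrix`).
#' @param pixels numeric matrix of evaluated feature rows.
#' @param background numeric matrix of background feature rows (nonempty).
#' @param method `"permutation"` (default) or `"exact"`.
#' @param nSamples permutation/background draws for the sampling estimator.
#' @param seed integer seed for the sampling estimator.
#' @param chunkRows predict-batch cap (memory knob).
#' @return list: `shap` (per class, matrix pixels x features), `baseline`
#'   (per class), `prediction` (pixels x classes model output).
#' @export
shapleyAttributions <- function(model, pixels, background,
                                method = c("permutation", "exact"),
                                nSamples = 30, seed = 1,
                                chunkRows = 200000L) {
  method <- match.arg(method)
  pixels <- as.matrix(pixels); background <- as.matrix(background)
  if (nrow(background) == 0L) stop("background must be nonempty", call. = FALSE)
  d <- ncol(pixels)
  pred <- predictProba(model, pixels)
  K <- ncol(pred)
  if (method == "exact") {
    if (d > 12L)
      stop("exact enumeration is limited to d <= 12 features; ",
           "use method = \"permutation\"", call. = FALSE)
    res <- .shapExact(model, pixels, background, pred)
  } else {
    res <- .shapPermutation(model, pixels, background, pred, nSamples, seed,
                            chunkRows)
  }
  names(res$shap) <- colnames(pred)
  names(res$baseline) <- colnames(pred)
  res$prediction <- pred
  res
}

.shapExact <- function(model, pixels, background, pred) {
  d <- ncol(pixels); n <- nrow(pixels); nb <- nrow(background)
  K <- ncol(pred)
  nS <- 2L^d
  masks <- matrix(FALSE, nS, d)
  for (f in seq_len(d))
    masks[, f] <- bitwAnd(0:(nS - 1L), bitwShiftL(1L, f - 1L)) > 0L
  sizes <- rowSums(masks)
  wgt <- ifelse(sizes < d,
                factorial(sizes) * factorial(pmax(d - sizes - 1L, 0L)) /
                  factorial(d),
                0)                                  # w(|S|); full set unused
  shap <- lapply(seq_len(K), function(k) matrix(0, n, d))
  baseline <- numeric(K)
  for (i in seq_len(n)) {
    ## composite rows: for each subset S, background rows with x on S
    comp <- background[rep(seq_len(nb), nS), , drop = FALSE]
    sub <- rep(seq_len(nS), each = nb)
    xrep <- matrix(pixels[i, ], nS * nb, d, byrow = TRUE)
    m <- masks[sub, , drop = FALSE]
    comp[m] <- xrep[m]
    p <- predictProba(model, comp)
    for (k in seq_len(K)) {
      v <- rowsum(p[, k], sub) / nb               # v(S), one per subset
      for (f in seq_len(d)) {
        without <- which(!masks[, f])
        with_ <- without + bitwShiftL(1L, f - 1L)
        shap[[k]][i, f] <- sum(wgt[without] * (v[with_] - v[without]))
      }
    }
  }
  for (k in seq_len(K))
    baseline[k] <- mean(predictProba(model, background)[, k])
  list(shap = shap, baseline = baseline)
}

.shapPermutation <- function(model, pixels, background, pred, nSamples, seed,
                             chunkRows) {
  d <- ncol(pixels); n <- nrow(pixels); K <- ncol(pred)
  ## background rows are cycled in seeded order rather than resampled, so
  ## coverage is balanced (and, for linear models, the estimate matches the
  ## closed form whenever nSamples is a multiple of the background size)
  draws <- withr::with_seed(seed, list(
    perms = replicate(nSamples, sample.int(d), simplify = FALSE),
    bg = rep_len(sample.int(nrow(background)), nSamples)))
  shap <- lapply(seq_len(K), function(k) matrix(0, n, d))
  bgRows <- background[draws$bg, , drop = FALSE]
  baseline <- colMeans(predictProba(model, bgRows))
  ## chain of d+1 composites per (pixel, draw); batch over pixels
  perChain <- d + 1L
  pixPerChunk <- max(1L, chunkRows %/% (nSamples * perChain))
  for (start in seq(1L, n, by = pixPerChunk)) {
    idx <- start:min(n, start + pixPerChunk - 1L)
    rows <- vector("list", length(idx) * nSamples)
    ri <- 0L
    for (i in idx) {
      x <- pixels[i, ]
      for (j in seq_len(nSamples)) {
        chain <- matrix(bgRows[j, ], perChain, d, byrow = TRUE)
        pj <- draws$perms[[j]]
        for (t in seq_len(d))
          chain[(t + 1L):perChain, pj[t]] <- x[pj[t]]
        ri <- ri + 1L
        rows[[ri]] <- chain
      }
    }
    p <- predictProba(model, do.call(rbind, rows))
    off <- 0L
    for (i in idx) {
      for (j in seq_len(nSamples)) {
        pj <- draws$perms[[j]]
        blk <- p[off + seq_len(perChain), , drop = FALSE]
        dif <- blk[-1L, , drop = FALSE] - blk[-perChain, , drop = FALSE]
        for (k in seq_len(K))
          shap[[k]][i, pj] <- shap[[k]][i, pj] + dif[, k]
        off <- off + perChain
      }
    }
  }
  for (k in seq_len(K)) shap[[k]] <- shap[[k]] / nSamples
  list(shap = shap, baseline = baseline)
}

#' Global SHAP score: mean absolute attribution per class and feature
#'
#' The evaluated-pixel set is shared by all classes (not class-restricted).
#'
#' @param shap list of per-class attribution matrices
#'   (from [shapleyAttributions()]).
#' @return matrix classes x features of non-negative scores.
#' @export
globalShapScore <- function(shap) {
  out <- t(vapply(shap, function(m) colMeans(abs(m)),
                  numeric(ncol(shap[[1L]]))))
  rownames(out) <- names(shap)
  out
}

#' Correlation direction of each feature for each class
#'
#' Sign of the correlation between a feature's intensity and its
#' attribution across evaluated pixels; 0 inside the dead zone
#' `|r| < rMin` or when either column has zero variance.
#'
#' @param shap list of per-class attribution matrices.
#' @param featureValues matrix of the evaluated pixels' feature values.
#' @param rMin dead-zone radius (default 0.1).
#' @param corMethod `"pearson"` (default) or `"spearman"`.
#' @return matrix classes x features with entries in -1/0/+1.
#' @export
correlationDirection <- function(shap, featureValues, rMin = 0.1,
                                 corMethod = c("pearson", "spearman")) {
  corMethod <- match.arg(corMethod)
  featureValues <- as.matrix(featureValues)
  if (nrow(featureValues) < 3L)
    stop("need at least 3 evaluated pixels", call. = FALSE)
  d <- ncol(featureValues)
  out <- matrix(0, length(shap), d, dimnames = list(names(shap), NULL))
  for (k in seq_along(shap)) {
    for (f in seq_len(d)) {
      x <- featureValues[, f]; phi <- shap[[k]][, f]
      if (var(x) == 0 || var(phi) == 0) next
      r <- cor(x, phi, method = corMethod)
      if (is.finite(r) && abs(r) >= rMin) out[k, f] <- sign(r)
    }
  }
  out
}

#' Interpret a fitted segment classifier with Shapley attributions
#'
#' Samples a background set (uniformly) and an evaluation set (stratified
#' by segment, so the global score is not dominated by the largest
#' segment's pixels) from the labeled IMS table, computes per-pixel
#' Shapley attributions of the classifier's per-class outputs, and
#' summarizes them into global scores, correlation directions and a
#' ranked marker-candidate list per segment (ties in the score broken by
#' ascending m/z). Every class's score is averaged over the same full
#' evaluation set.
#'
#' @param classifier a [ClassifierResult-class].
#' @param labeled the [LabeledIMSTable-class] it was trained on.
#' @param method,nSamples passed to [shapleyAttributions()].
#' @param backgroundN background pixels sampled uniformly (default 200).
#' @param nEval evaluated pixels sampled uniformly (default 300).
#' @param rMin,corMethod passed to [correlationDirection()].
#' @param seed integer seed for both samples.
#' @param ticNormalize apply the same TIC normalization used at training.
#' @param scale model output attributed: `"margin"` (default; per-class
#'   log-odds, which decompose independently per segment) or
#'   `"probability"` (softmax outputs, which couple classes through
#'   renormalization). Recorded in the result's metadata.
#' @return an [AttributionResult-class].
#' @export
attributeSegments <- function(classifier, labeled,
                              method = c("permutation", "exact"),
                              backgroundN = 200, nEval = 300, nSamples = 30,
                              rMin = 0.1, corMethod = "pearson", seed = 1,
                              ticNormalize = FALSE,
                              scale = c("margin", "probability")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  X <- labeled@intensities
  if (ticNormalize) X <- ticNormalizeIntensities(X)
  n <- nrow(X)
  idx <- withr::with_seed(seed, {
    bySeg <- split(seq_len(n), labeled@table$segment)
    per <- ceiling(min(nEval, n) / length(bySeg))
    ev <- unlist(lapply(bySeg, function(i) sample(i, min(per, length(i)))),
                 use.names = FALSE)
    list(bg = sample.int(n, min(backgroundN, n)), ev = sort(ev))
  })
  model <- classifier@model
  modelFun <- if (scale == "margin" && is(model, "GradientBoostedModel"))
    function(Z) predictMargin(model, Z)
  else {
    scale <- "probability"
    model
  }
  res <- shapleyAttributions(modelFun, X[idx$ev, , drop = FALSE],
                             X[idx$bg, , drop = FALSE], method = method,
                             nSamples = nSamples, seed = seed)
  score <- globalShapScore(res$shap)
  dir <- correlationDirection(res$shap, X[idx$ev, , drop = FALSE],
                              rMin = rMin, corMethod = corMethod)
  mz <- labeled@mz
  ranking <- lapply(seq_len(nrow(score)), function(k)
    order(-score[k, ], mz))
  names(ranking) <- rownames(score)
  new("AttributionResult", shapValues = res$shap, baseline = res$baseline,
      globalScore = score, direction = dir, ranking = ranking, mz = mz,
      classes = rownames(score), evaluated = as.integer(idx$ev),
      meta = list(method = method, scale = scale,
                  global_score = "mean absolute attribution",
                  background_n = length(idx$bg), n_samples = nSamples,
                  r_min = rMin, cor_method = corMethod, seed = seed))
}

#' Long-format bubble table of top marker candidates
#'
#' One row per (segment, feature) over the union of every segment's
#' `topN` features by global score (score ties broken by ascending m/z);
#' rows ordered by segment then ascending m/z.
#'
#' @param attribution an [AttributionResult-class].
#' @param topN features kept per segment (default 10).
#' @return data.frame: `segment`, `mz`, `score`, `sign`.
#' @export
exportBubbleTable <- function(attribution, topN = 10) {
  sc <- attribution@globalScore
  keep <- sort(unique(unlist(lapply(attribution@ranking, head, topN))))
  out <- do.call(rbind, lapply(seq_len(nrow(sc)), function(k)
    data.frame(segment = attribution@classes[k],
               mz = attribution@mz[keep],
               score = sc[k, keep], sign = attribution@direction[k, keep])))
  out <- out[order(match(out$segment, attribution@classes), out$mz), ]
  rownames(out) <- NULL
  out
}

#' Bubble plot of the global SHAP summary
#'
#' Size encodes the global importance of an ion (column) for recognizing a
#' segment (row); color encodes a positive (red) or negative (blue)
#' correlation of its abundance with the segment's recognition.
#'
#' @param bubbleTable output of [exportBubbleTable()].
#' @return a ggplot object.
#' @export
plotBubble <- function(bubbleTable) {
  bubbleTable$mz_label <- factor(mzLabel(bubbleTable$mz),
                                 levels = mzLabel(sort(unique(bubbleTable$mz))))
  bubbleTable$correlation <- factor(
    c("negative", "none", "positive")[bubbleTable$sign + 2],
    levels = c("positive", "negative", "none"))
  ggplot2::ggplot(bubbleTable,
                  ggplot2::aes(x = mz_label, y = segment,
                               size = score, color = correlation)) +
    ggplot2::geom_point(alpha = 0.85) +
    ggplot2::scale_color_manual(values = c(positive = "#c23b22",
                                           negative = "#2c5aa0",
                                           none = "grey60")) +
    ggplot2::labs(x = "m/z", y = NULL, size = "global SHAP") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
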