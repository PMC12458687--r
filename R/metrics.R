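# Evaluation suite: formula metrics, AUROC, Cohen's kappa, PCA,
# permutation and impurity feature importance.

#' Confusion counts from truth/prediction vectors
#'
#' @param truth logical (or 0/1) true positive-class membership.
#' @param pred logical (or 0/1) predicted membership.
#' @return Named list TP, TN, FP, FN.
#' @export
confusionCounts <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth & pred), TN = sum(!truth & !pred),
       FP = sum(!truth & pred), FN = sum(truth & !pred))
}

#' The five formula metrics from confusion counts
#'
#' sensitivity = TP/(TP+FN); specificity = TN/(TN+FP);
#' precision = TP/(TP+FP); accuracy = (TP+TN)/total;
#' F1 = 2/(1/sensitivity + 1/precision), computed through the equivalent
#' 2TP/(2TP+FP+FN). A metric whose denominator is zero is returned as NA
#' and listed in the \code{undefined} attribute (no NaN propagation).
#'
#' @param counts list/vector with TP, TN, FP, FN (all >= 0, total > 0).
#' @return Named list sensitivity, specificity, precision, accuracy, f1;
#'   attribute \code{undefined} names the metrics with zero denominators.
#' @export
classificationMetrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  tot <- tp + tn + fp + fn
  stopifnot(tot > 0, tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(sensitivity = safe(tp, tp + fn),
              specificity = safe(tn, tn + fp),
              precision = safe(tp, tp + fp),
              accuracy = (tp + tn) / tot,
              f1 = safe(2 * tp, 2 * tp + fp + fn))
  attr(out, "undefined") <- names(out)[vapply(out, is.na, TRUE)]
  out
}

#' F1 from sensitivity and precision
#'
#' The harmonic mean 2/(1/sensitivity + 1/precision); this is the form
#' used when recomputing F1 from reported sensitivity and precision.
#'
#' @param sensitivity,precision values in (0, 1].
#' @return F1 score.
#' @export
f1Score <- function(sensitivity, precision) {
  stopifnot(sensitivity > 0, precision > 0)
  2 / (1 / sensitivity + 1 / precision)
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) form, equivalent to the trapezoidal area under
#' the ROC over all distinct score thresholds; tied scores contribute 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels logical (or 0/1) true class; both classes must be
#'   present.
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, labels) {
  labels <- as.logical(labels)
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0 || nNeg == 0)
    stop("undefined AUROC: one class absent")
  r <- rank(scores)
  (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC curve points
#'
#' Sensitivity and 1-specificity swept over the distinct scores plus
#' sentinels at +/- infinity.
#'
#' @param scores,labels as in \code{\link{aurocScore}}.
#' @return data.frame: threshold, sensitivity, fpr.
#' @export
rocCurve <- function(scores, labels) {
  labels <- as.logical(labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  do.call(rbind, lapply(th, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               sensitivity = sum(pred & labels) / sum(labels),
               fpr = sum(pred & !labels) / sum(!labels))
  }))
}

#' Cohen's kappa from confusion counts
#'
#' (p_o - p_e) / (1 - p_e) with p_o the observed accuracy and p_e the
#' chance agreement from the marginals; undefined (NA with flag) when
#' p_e = 1.
#'
#' @param counts list/vector with TP, TN, FP, FN.
#' @return Kappa in [-1, 1], or NA flagged \code{undefined}.
#' @export
cohensKappa <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  n <- tp + tn + fp + fn
  stopifnot(n > 0)
  po <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  if (abs(1 - pe) < 1e-12) {
    out <- NA_real_
    attr(out, "undefined") <- "kappa"
    return(out)
  }
  (po - pe) / (1 - pe)
}

#' PCA of descriptor space
#'
#' Columns are standardized to zero mean and unit variance before the
#' decomposition (the descriptors span cubic-Angstrom volumes to unitless
#' fractions, so an unstandardized PCA would be dominated by volume);
#' constant columns are dropped with a warning.
#'
#' @param table a \code{\linkS4class{DescriptorTable}} (>= 2 rows).
#' @param nComponents number of components to report.
#' @return List: scores (rows x components), explained (variance
#'   fractions, non-increasing), loadings (descriptor x component),
#'   dropped (names of constant columns).
#' @export
pcaProject <- function(table, nComponents = 2) {
  dm <- designMatrix(table)
  x <- dm$x
  stopifnot(nrow(x) >= 2)
  sds <- apply(x, 2, sd)
  dropped <- colnames(x)[sds == 0 | is.na(sds)]
  if (length(dropped)) {
    warning("dropping constant descriptor column(s): ",
            paste(dropped, collapse = ", "))
    x <- x[, !(colnames(x) %in% dropped), drop = FALSE]
  }
  if (ncol(x) < nComponents)
    stop("fewer non-constant descriptors than components requested")
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(nComponents)
  list(scores = p$x[, k, drop = FALSE], explained = expl[k],
       loadings = p$rotation[, k, drop = FALSE], dropped = dropped)
}

#' Permutation feature importance (delta F1)
#'
#' For each descriptor, the column is shuffled \code{nRepeats} times
#' (seeded) and the drop in F1 relative to the unpermuted baseline is
#' recorded.
#'
#' @param model a \code{\linkS4class{PocketClassifier}}.
#' @param table labeled evaluation \code{\linkS4class{DescriptorTable}}
#'   with the model's schema.
#' @param nRepeats shuffles per feature, default 10.
#' @param seed RNG seed.
#' @return data.frame: feature, mean_delta_f1, sd_delta_f1, ordered as the
#'   model's feature order.
#' @export
permutationImportance <- function(model, table, nRepeats = 10, seed = 1L) {
  r <- descriptorRows(table)
  truth <- r$label == "LBP"
  feats <- featureOrder(model)
  f1Of <- function(rows) {
    pred <- predictPocket(model, rows) >= scoreThreshold(model)
    cm <- confusionCounts(truth, pred)
    m <- classificationMetrics(cm)
    if (is.na(m$f1)) 0 else m$f1
  }
  baseline <- f1Of(r)
  res <- lapply(seq_along(feats), function(i) {
    deltas <- vapply(seq_len(nRepeats), function(k) {
      perm <- withSeed(childSeed(childSeed(seed, i), k),
                       sample(nrow(r)))
      r2 <- r
      r2[[feats[i]]] <- r2[[feats[i]]][perm]
      baseline - f1Of(r2)
    }, numeric(1))
    data.frame(feature = feats[i], mean_delta_f1 = mean(deltas),
               sd_delta_f1 = sd(deltas), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "baseline_f1") <- baseline
  out
}

#' Impurity-based feature importance of a tree ensemble
#'
#' Mean decrease in impurity accumulated over all splits, normalized to
#' fractions summing to 1.
#'
#' @param model a \code{\linkS4class{PocketClassifier}} with a tree
#'   ensemble fit.
#' @return Named numeric vector of fractions (>= 0, sum 1).
#' @export
impurityImportance <- function(model) {
  if (model@algorithm != "random_forest")
    stop("unsupported: impurity importance needs a tree-ensemble model")
  imp <- ranger::importance(model@fit)
  imp / sum(imp)
}

#' Box-plot summary of a metric distribution
#'
#' Quartiles plus whiskers; outliers are the points beyond 1.5 times the
#' interquartile range from the first and third quartiles, and whiskers
#' extend to the most extreme non-outlier points.
#'
#' @param values numeric vector.
#' @return List: min, q1, median, q3, max, whisker_lo, whisker_hi,
#'   outliers.
#' @export
boxplotSummary <- function(values) {
  q <- as.numeric(quantile(values, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inl <- values[values >= lo & values <= hi]
  list(min = min(values), q1 = q[1], median = q[2], q3 = q[3],
       max = max(values),
       whisker_lo = if (length(inl)) min(inl) else NA_real_,
       whisker_hi = if (length(inl)) max(inl) else NA_real_,
       outliers = out)
}
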