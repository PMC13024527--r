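#' Confusion matrix
#'
#' K x K count table with rows = ground truth, columns = prediction.
#'
#' @param y_true,y_pred integer labels in `1..K`.
#' @param K number of classes.
#' @param class_names optional row/column names.
#' @return integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(y_true, y_pred, K, class_names = NULL) {
  if (length(y_true) != length(y_pred))
    stop("confusion: label vectors differ in length")
  if (any(y_true < 1L | y_true > K) || any(y_pred < 1L | y_pred > K))
    stop("confusion: label out of range 1..K")
  cm <- matrix(0L, K, K)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  if (!is.null(class_names)) dimnames(cm) <- list(truth = class_names,
                                                  prediction = class_names)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Collapse a multi-class confusion matrix to lesion vs normal
#'
#' Sums counts over a positive class set: TP are positives predicted as any
#' positive class, FN positives predicted as any negative class, and so on.
#' The lesion-vs-normal framing of a screening test.
#'
#' @param cm K x K confusion matrix (rows = truth).
#' @param positive indices (or names) of the positive classes; must be a
#'   non-empty proper subset.
#' @return 2 x 2 matrix with rows/cols (positive, negative), entries
#'   TP, FN, FP, TN.
#' @export
binary_collapse <- function(cm, positive) {
  K <- nrow(cm)
  if (is.character(positive)) positive <- match(positive, rownames(cm))
  if (length(positive) == 0L || length(positive) >= K || anyNA(positive))
    stop("binary_collapse: positive classes must be a non-empty proper subset")
  neg <- setdiff(seq_len(K), positive)
  m <- matrix(c(sum(cm[positive, positive]), sum(cm[positive, neg]),
                sum(cm[neg, positive]), sum(cm[neg, neg])),
              2L, 2L, byrow = TRUE,
              dimnames = list(truth = c("positive", "negative"),
                              prediction = c("positive", "negative")))
  m
}

#' Diagnostic metrics from a 2 x 2 table
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy, F1 (harmonic mean of precision and sensitivity)
#' and the Youden index `J = sensitivity + specificity - 1` (exact by
#' construction). A zero denominator yields `NA` for that metric rather
#' than 0.
#'
#' @param m 2 x 2 matrix from [binary_collapse()] (rows = truth, row 1 =
#'   positive).
#' @return list of metrics, proportions in `[0, 1]`.
#' @export
binary_metrics <- function(m) {
  tp <- m[1, 1]; fn <- m[1, 2]; fp <- m[2, 1]; tn <- m[2, 2]
  div <- function(a, b) if (b > 0) a / b else NA_real_
  sens <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  prec <- div(tp, tp + fp)
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(sensitivity = sens, specificity = spec, precision = prec,
       accuracy = div(tp + tn, tp + fn + fp + tn), f1 = f1,
       youden = sens + spec - 1, n = tp + fn + fp + tn)
}

#' Area under the ROC curve
#'
#' `"rank"` computes the Mann-Whitney statistic (the probability a random
#' positive scores above a random negative, ties counted 1/2) via average
#' ranks; `"trapezoid"` integrates the empirical ROC curve. The two agree to
#' numerical precision.
#'
#' @param scores numeric scores, larger = more lesion-like.
#' @param labels binary labels (logical, or 0/1) with both classes present.
#' @param method `"rank"` or `"trapezoid"`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  npos <- sum(labels); nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L)
    stop("roc_auc: both classes must be present")
  if (method == "rank") {
    r <- rank(scores, ties.method = "average")
    return((sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg))
  }
  rc <- roc_points(scores, labels)
  sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
}

# Empirical ROC polyline over the distinct-score thresholds,
# from (0,0) to (1,1) with fpr increasing.
roc_points <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  lab <- as.logical(labels)[o]
  sc <- scores[o]
  tp <- cumsum(lab); fp <- cumsum(!lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- c(0, tp[keep] / sum(lab))
  fpr <- c(0, fp[keep] / sum(!lab))
  list(fpr = fpr, tpr = tpr)
}

#' Youden-optimal operating threshold
#'
#' Scans the candidate set of observed scores, classifying positive when
#' `score >= threshold`, and returns the threshold maximizing the Youden
#' index `J = sensitivity + specificity - 1`. Ties are broken towards the
#' lowest threshold, favoring sensitivity.
#'
#' @param scores numeric scores.
#' @param labels binary labels with both classes present.
#' @return list with `threshold`, `metrics` (from [binary_metrics()] at the
#'   chosen threshold) and `youden`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("youden_threshold: both classes must be present")
  cand <- sort(unique(scores))
  best <- NULL
  for (th in cand) {
    pred <- scores >= th
    m <- matrix(c(sum(labels & pred), sum(labels & !pred),
                  sum(!labels & pred), sum(!labels & !pred)), 2L, 2L,
                byrow = TRUE)
    j <- binary_metrics(m)$youden
    if (is.null(best) || j > best$youden + 1e-12) {
      best <- list(threshold = th, metrics = binary_metrics(m), youden = j)
    }
  }
  best
}

#' Worked-example screening confusion matrix
#'
#' The published 3-class confusion matrix of the screening model after
#' disease-specific fine-tuning (truth in rows): 16,273 normal frames and
#' 11,725 lesion frames across two lesion categories. Used as the reference
#' input for the diagnostic-metric worked example.
#'
#' @return 3 x 3 integer matrix of class `confusion_matrix`.
#' @export
example_screening_confusion <- function() {
  cm <- matrix(c(16060L, 187L, 26L,
                 151L, 8666L, 88L,
                 144L, 194L, 2482L),
               3L, 3L, byrow = TRUE,
               dimnames = list(
                 truth = c("normal", "inflammation_ulcer_bleeding_erosion",
                           "polyp_protrusion"),
                 prediction = c("normal", "inflammation_ulcer_bleeding_erosion",
                                "polyp_protrusion")))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Perturbation-robustness report
#'
#' Evaluates a trained model on the clean dataset and under each requested
#' perturbation, reporting lesion-vs-normal sensitivity and specificity and
#' their deltas in percentage points (negative = degradation).
#'
#' @param model trained model.
#' @param data dataset list from [generate_dataset()].
#' @param kinds perturbation kinds, a subset of `"brightness"`,
#'   `"contrast"`, `"random_transform"`.
#' @param magnitudes named magnitudes per kind (defaults: brightness 1.2,
#'   contrast 1.2, random_transform 15 degrees).
#' @param seed RNG seed for the random transforms.
#' @return data frame with one row per scenario (first row: clean),
#'   columns `sensitivity`, `specificity`, `accuracy` (percent) and
#'   `delta_sensitivity`, `delta_specificity` (percentage points).
#' @export
perturbation_report <- function(model, data, kinds = c("brightness",
                                                       "contrast",
                                                       "random_transform"),
                                magnitudes = NULL, seed = 1L) {
  mags <- list(brightness = 1.2, contrast = 1.2, random_transform = 15)
  if (!is.null(magnitudes)) mags <- utils::modifyList(mags, as.list(magnitudes))
  normal_id <- match("normal", data$class_names)
  eval_one <- function(d) {
    ev <- evaluate_model(model, d$x, d$labels)
    bm <- binary_metrics(binary_collapse(ev$confusion,
                                         setdiff(seq_along(data$class_names),
                                                 normal_id)))
    c(sensitivity = 100 * bm$sensitivity, specificity = 100 * bm$specificity,
      accuracy = 100 * ev$accuracy)
  }
  out <- data.frame(scenario = "clean", t(eval_one(data)))
  for (k in kinds) {
    pd <- perturb_dataset(data, k, mags[[k]], seed = seed)
    out <- rbind(out, data.frame(scenario = k, t(eval_one(pd))))
  }
  out$delta_sensitivity <- out$sensitivity - out$sensitivity[1]
  out$delta_specificity <- out$specificity - out$specificity[1]
  out
}
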