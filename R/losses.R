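#' Smooth L1 (Huber) loss
#'
#' Quadratic for small residuals and linear for large ones:
#' `0.5 x^2` when `|x| < 1`, `|x| - 0.5` otherwise. Continuous with
#' continuous first derivative at `|x| = 1`, which keeps box-regression
#' gradients bounded for outlying residuals. The linear branch uses `|x|`,
#' as symmetry is required of a residual loss.
#'
#' @param x numeric vector of residuals.
#' @return elementwise loss values.
#' @export
smooth_l1 <- function(x) {
  if (!all(is.finite(x))) stop("smooth_l1: non-finite input")
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}

smooth_l1_grad <- function(x) ifelse(abs(x) < 1, x, sign(x))

#' Cross-entropy classification loss
#'
#' Mean negative log-likelihood of the true class, with optional per-class
#' weights (e.g. inverse-frequency weights for minority lesion classes).
#' Probabilities are clamped at `eps` before the log, with a warning, so a
#' zero probability at the true class yields a large finite loss.
#'
#' @param y_true integer class labels (1-based, length N) or a `K x N`
#'   one-hot matrix.
#' @param y_prob `K x N` matrix of predicted probabilities (columns sum
#'   to 1).
#' @param class_weights optional positive weights, length K.
#' @param eps clamping floor for probabilities.
#' @return mean weighted loss (scalar).
#' @export
cross_entropy_loss <- function(y_true, y_prob, class_weights = NULL,
                               eps = 1e-12) {
  if (is.matrix(y_true)) y_true <- apply(y_true, 2L, which.max)
  K <- nrow(y_prob); n <- ncol(y_prob)
  if (length(y_true) != n) stop("cross_entropy_loss: label/probability mismatch")
  if (any(y_true < 1L | y_true > K)) stop("cross_entropy_loss: label out of range")
  if (is.null(class_weights)) class_weights <- rep(1, K)
  if (any(class_weights <= 0)) stop("cross_entropy_loss: weights must be positive")
  p <- y_prob[cbind(y_true, seq_len(n))]
  if (any(p < eps)) {
    warning("cross_entropy_loss: probabilities clamped at eps")
    p <- pmax(p, eps)
  }
  mean(-class_weights[y_true] * log(p))
}

#' Masked bounding-box regression loss
#'
#' Mean Smooth-L1 deviation over the four box parameters, restricted to
#' images whose mask marks a lesion box; lesion-free images contribute no
#' regression signal. An all-normal batch yields 0.
#'
#' @param pred,target `4 x N` matrices of predicted / ground-truth
#'   normalized boxes.
#' @param lesion_mask logical length-N vector, `TRUE` where a box exists.
#' @return scalar loss.
#' @export
bbox_regression_loss <- function(pred, target, lesion_mask) {
  if (!any(lesion_mask)) return(0)
  d <- pred[, lesion_mask, drop = FALSE] - target[, lesion_mask, drop = FALSE]
  mean(smooth_l1(d))
}

#' Composite training objective
#'
#' `total = classification + lambda * regression`, the joint detection
#' objective balancing lesion recognition and localization. The identity
#' holds exactly in the returned breakdown.
#'
#' @param cls classification loss (scalar, >= 0).
#' @param reg regression loss (scalar, >= 0).
#' @param lambda non-negative balance hyperparameter.
#' @return list with `total`, `classification`, `regression`, `lambda`.
#' @export
total_loss <- function(cls, reg, lambda = 1) {
  if (lambda < 0) stop("total_loss: lambda must be >= 0")
  list(total = cls + lambda * reg, classification = cls,
       regression = reg, lambda = lambda)
}

#' Inverse-frequency class weights
#'
#' Weights proportional to `n / (K * n_k)`, emphasizing minority lesion
#' classes; classes absent from the labels get weight 1.
#'
#' @param labels integer class labels (1-based).
#' @param K number of classes.
#' @return positive weight vector of length K.
#' @export
inverse_frequency_weights <- function(labels, K) {
  counts <- tabulate(labels, nbins = K)
  w <- rep(1, K)
  nz <- counts > 0
  w[nz] <- length(labels) / (K * counts[nz])
  w
}
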