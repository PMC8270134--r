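#' Classification and model evaluation metrics
#'
#' `overall_accuracy()` is the fraction of matching labels.
#' `cohens_kappa()` is the chance-corrected agreement
#' \eqn{(p_o - p_e) / (1 - p_e)}, with \eqn{p_e} from the products of the
#' confusion-matrix marginals; when both marginals are degenerate on the
#' same class (\eqn{p_e = 1}, necessarily \eqn{p_o = 1}) it returns 1.
#' `r_squared()` is \eqn{1 - SS_{res} / SS_{tot}}.
#'
#' @param predicted,true_labels Equal-length label vectors.
#' @return A scalar metric.
#' @export
overall_accuracy <- function(predicted, true_labels) {
  if (length(predicted) != length(true_labels))
    stop("predicted and true labels differ in length")
  if (!length(predicted)) stop("empty label vectors")
  mean(predicted == true_labels)
}

#' @rdname overall_accuracy
#' @export
cohens_kappa <- function(predicted, true_labels) {
  if (length(predicted) != length(true_labels))
    stop("predicted and true labels differ in length")
  if (!length(predicted)) stop("empty label vectors")
  lev <- union(unique(predicted), unique(true_labels))
  cm <- table(factor(predicted, levels = lev), factor(true_labels, levels = lev))
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  p_e <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps^0.5) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' @rdname overall_accuracy
#' @param observed Numeric vector of observed values (variance > 0).
#' @return `r_squared()` returns NA with a warning when the observed values
#'   have zero variance (the statistic is undefined).
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed differ in length")
  if (length(observed) < 2) stop("need at least 2 observations")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    warning("r_squared undefined: observed values have zero variance")
    return(NA_real_)
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' presence scores above a randomly chosen absence, counting ties as one
#' half. Computed from midranks, so it equals the brute-force all-pairs
#' count exactly.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 (or logical) labels; 1 = presence.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both presence and absence labels are required")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
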