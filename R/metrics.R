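## Prediction-evaluation statistics for regression and classification.

#' Regression evaluation: RMSE, R-squared, Bias
#'
#' \deqn{RMSE = \sqrt{\tfrac{1}{n}\sum_i (P_i - O_i)^2}}
#' \deqn{R^2 = 1 - \sum_i (O_i - P_i)^2 / \sum_i (O_i - \bar O)^2}
#' \deqn{Bias = \tfrac{1}{n}\sum_i (P_i - O_i)}
#' This R-squared is one minus the error-to-total sum-of-squares ratio, not
#' a squared correlation: on validation data it can be negative (the model
#' predicts worse than the observation mean). With constant observations
#' the total sum of squares is zero and R-squared is returned as NA.
#'
#' @param observations numeric vector O.
#' @param predictions numeric vector P of the same length.
#' @return named numeric vector `c(RMSE, R2, Bias)`.
#' @export
regression_metrics <- function(observations, predictions) {
  o <- as.numeric(observations); p <- as.numeric(predictions)
  if (length(o) != length(p) || length(o) < 1L)
    stop("observations and predictions must be equal-length, non-empty",
         call. = FALSE)
  e <- p - o
  rmse <- sqrt(mean(e^2))
  sst <- sum((o - mean(o))^2)
  r2 <- if (sst == 0) NA_real_ else 1 - sum(e^2) / sst
  c(RMSE = rmse, R2 = r2, Bias = mean(e))
}

#' Classification evaluation: Accuracy and Cohen's kappa
#'
#' Accuracy is the fraction of correct classifications c/n. Kappa corrects
#' it for chance agreement \eqn{E = \tfrac{1}{n^2}\sum_k np_k \, no_k},
#' where \eqn{np_k} and \eqn{no_k} are the predicted and observed counts of
#' class k: \eqn{Kappa = (Accuracy - E)/(1 - E)}. The class universe is the
#' union of observed and predicted labels, so a class present on only one
#' side still contributes its marginal. When both marginals concentrate on
#' a single class, E = 1 and Kappa is undefined (NA).
#'
#' @param observations vector of class labels O.
#' @param predictions vector of class labels P of the same length.
#' @return named numeric vector `c(Accuracy, E, Kappa)`.
#' @export
classification_metrics <- function(observations, predictions) {
  o <- as.character(observations); p <- as.character(predictions)
  if (length(o) != length(p) || length(o) < 1L)
    stop("observations and predictions must be equal-length, non-empty",
         call. = FALSE)
  n <- length(o)
  acc <- sum(o == p) / n
  classes <- union(o, p)
  np <- vapply(classes, function(k) sum(p == k), numeric(1))
  no <- vapply(classes, function(k) sum(o == k), numeric(1))
  E <- sum(np * no) / n^2
  kappa <- if (E == 1) NA_real_ else (acc - E) / (1 - E)
  c(Accuracy = acc, E = E, Kappa = kappa)
}
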