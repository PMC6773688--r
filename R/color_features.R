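## Color features: four population moment statistics per transformed image.
## All sums run over the N non-NA (plant) pixels only, and all four use
## population denominators (divide by N), not sample corrections: the
## camera sees essentially the whole canopy of a plot, so its pixels are
## treated as the population, not a sample from it.

.color_stat_names <- c("mu", "sigma", "skew", "kurt")

#' Moment statistics of one transformed image
#'
#' Computes mean, standard deviation, skewness and kurtosis of the plant
#' pixels of a transform:
#' \deqn{\mu = \sum T / N, \quad \sigma = \sqrt{\sum (T-\mu)^2 / N}}
#' \deqn{\theta = \sum (T-\mu)^3 / (N\sigma^3), \quad
#'       \delta = \sum (T-\mu)^4 / (N\sigma^4)}
#' Kurtosis is the raw fourth standardized moment (not excess), so
#' \eqn{\delta \ge 1} whenever defined. On a constant raster \eqn{\sigma = 0}
#' and the skewness and kurtosis are 0/0: both are returned as NA rather
#' than an arbitrary number.
#'
#' @param t a `transformed_image`, or a numeric vector/matrix with NAs at
#'   masked pixels.
#' @return named numeric vector `c(mu, sigma, skew, kurt)`.
#' @export
color_stats <- function(t) {
  v <- if (inherits(t, "transformed_image")) t$values else t
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0L) stop("color_stats: no plant pixels (N = 0)", call. = FALSE)
  mu <- sum(v) / n
  d <- v - mu
  sigma <- sqrt(sum(d^2) / n)
  if (sigma == 0) {
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    skew <- sum(d^3) / (n * sigma^3)
    kurt <- sum(d^4) / (n * sigma^4)
  }
  c(mu = mu, sigma = sigma, skew = skew, kurt = kurt)
}

#' All 140 color features of a transform bank
#'
#' Applies [color_stats()] to each of the 35 transforms, yielding
#' 35 x 4 = 140 features named `<transform>_<stat>` in canonical transform
#' order with stats ordered mu, sigma, skew, kurt.
#'
#' @param bank named list of 35 `transformed_image` objects from
#'   [transform_bank()].
#' @return named numeric vector of length 140.
#' @export
all_color_features <- function(bank) {
  out <- unlist(lapply(bank, function(t) color_stats(t)))
  names(out) <- as.vector(t(outer(names(bank), .color_stat_names,
                                  paste, sep = "_")))
  out
}

#' Names of the 140 color-feature columns
#' @return character vector of length 140.
#' @export
color_feature_names <- function() {
  as.vector(t(outer(.transform_names, .color_stat_names, paste, sep = "_")))
}
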