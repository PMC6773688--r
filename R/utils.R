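#' Round half away from zero
#'
#' Deterministic rounding used everywhere an image is quantized back to
#' integers (contrast stretching, gray-level quantization). Unlike base
#' [round()], which rounds half to even, halves are rounded away from zero
#' so that repeated runs are bit-identical across platforms and the rule is
#' easy to state: 127.5 becomes 128.
#'
#' @param x numeric vector/matrix/array.
#' @return object of the same shape with integral values (still double).
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Min-max rescale to \[0, 1\]
#'
#' Linear rescale of all finite values to the unit interval. A constant
#' raster (no spread) maps to all zeros; NA/NaN pass through unchanged.
#'
#' @param x numeric vector/matrix.
#' @return rescaled object of the same shape.
#' @export
rescale01 <- function(x) {
  r <- range(x, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) {
    out <- x
    out[!is.na(out)] <- 0
    return(out)
  }
  (x - r[1]) / (r[2] - r[1])
}

## Validate an H x W x 3 8-bit RGB array; stops with a clear message.
assert_rgb_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("image must be an H x W x 3 array", call. = FALSE)
  d <- dim(image)
  if (d[1] < 2L || d[2] < 2L)
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop("image channels must lie in [0, 255] with no missing values",
         call. = FALSE)
  invisible(image)
}
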