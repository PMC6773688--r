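## The 35-image transform bank: the three stretched RGB channels, four
## alternative color spaces (XYZ, L*a*b*, HSI, Y'CbCr) and 20 vegetation
## indices built from the R, G, B bands: (1 + 4) x 3 + 20 = 35 rasters per
## image. ExG itself is not a member: rescaled to [0, 1] it coincides with
## the normalized-green index NG, which is.

.transform_names <- c("R", "G", "B",
                      "X", "Y", "Z", "Lstar", "astar", "bstar",
                      "H", "S", "I", "Yprime", "Cb", "Cr",
                      "NR", "NG", "NB", "ExR", "ExB", "ExGR",
                      "GBD", "RBD", "RGD", "GRR", "GBR",
                      "NGRD", "NGBD", "MNGRD", "VD", "RGBVI",
                      "CI", "CIVE", "TGI", "MExG")

.vegetation_index_names <- .transform_names[16:35]

#' Names of the 35 transforms, in canonical order
#'
#' `Lstar`, `astar`, `bstar` and `Yprime` are the column-name-safe spellings
#' of L*, a*, b* and Y'.
#'
#' @return character vector of length 35.
#' @export
transform_names <- function() .transform_names

#' Evaluate one vegetation index
#'
#' Per-pixel evaluation of one of the 20 empirical RGB-band indices on
#' stretched 8-bit channel values, at full double precision. Zero
#' denominators yield NaN or +/-Inf, which [sanitize_raster()] later
#' replaces; no special-casing is done here.
#'
#' @param image H x W x 3 stretched RGB array.
#' @param name one of the 20 empirical index abbreviations: NR, NG, NB,
#'   ExR, ExB, ExGR, GBD, RBD, RGD, GRR, GBR, NGRD, NGBD, MNGRD, VD,
#'   RGBVI, CI, CIVE, TGI, MExG.
#' @return H x W numeric matrix.
#' @export
vegetation_index <- function(image, name) {
  assert_rgb_image(image)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  s <- R + G + B
  switch(name,
    NR    = R / s,
    NG    = G / s,
    NB    = B / s,
    ExR   = (1.4 * R - G) / s,
    ExB   = (1.4 * B - G) / s,
    ExGR  = (3 * G - 2.4 * R - B) / s,
    GBD   = G - B,
    RBD   = R - B,
    RGD   = R - G,
    GRR   = G / R,
    GBR   = G / B,
    NGRD  = (G - R) / (G + R),
    NGBD  = (G - B) / (G + B),
    MNGRD = (G^2 - R^2) / (G^2 + R^2),
    VD    = (2 * G - B - R) / (2 * G + B + R),
    RGBVI = (G^2 - B * R) / (G^2 + B * R),
    CI    = 2 * B / (R + B),
    CIVE  = 0.441 * R - 0.811 * G + 0.385 * B + 18.78745,
    TGI   = 95 * G - 35 * R - 60 * B,
    MExG  = 1.262 * G - 0.884 * R - 0.311 * B,
    stop("unknown vegetation index: ", name, call. = FALSE)
  )
}

#' Color-space channel rasters
#'
#' The 12 theoretical transforms: X, Y, Z (CIE 1931, D65, 2-degree
#' observer), L*, a*, b* (CIE 1976, D65), H, S, I and Y', Cb, Cr. See the
#' convention notes in [rgb_to_xyz()], [rgb_to_hsi()] and [rgb_to_ycbcr()].
#'
#' @param image H x W x 3 stretched RGB array.
#' @param assume_linear_rgb passed to [rgb_to_xyz()].
#' @return named list of 12 H x W matrices in canonical order.
#' @export
color_space_channels <- function(image, assume_linear_rgb = FALSE) {
  assert_rgb_image(image)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  xyz <- rgb_to_xyz(R, G, B, assume_linear_rgb = assume_linear_rgb)
  lab <- xyz_to_lab(xyz)
  hsi <- rgb_to_hsi(R, G, B)
  ycc <- rgb_to_ycbcr(R, G, B)
  c(xyz, lab, hsi, ycc)
}

#' Sanitize a transform raster and apply the plant mask
#'
#' NaN values and negative infinities produced by a transform (e.g. ratio
#' indices at zero denominators) are replaced by the minimum finite value
#' of the raster, positive infinities by the maximum finite value; the
#' plant mask's NAs are then applied on top. Values are kept at full double
#' precision.
#'
#' @param x H x W numeric matrix (a raw transform raster).
#' @param mask H x W plant mask in \{1, NA\}, or NULL to skip masking.
#' @param name transform name carried along for error messages and output.
#' @return object of class `transformed_image`: list with `name`, `values`
#'   (masked raster), `unmasked` (sanitized raster before masking) and `n`
#'   (number of non-NA plant pixels).
#' @export
sanitize_and_mask <- function(x, mask = NULL, name = "") {
  u <- sanitize_raster(x)
  v <- u
  if (!is.null(mask)) {
    if (!all(dim(mask) == dim(u)))
      stop("mask shape does not match raster", call. = FALSE)
    v[is.na(mask)] <- NA_real_
  }
  structure(list(name = name, values = v, unmasked = u,
                 n = sum(!is.na(v))),
            class = "transformed_image")
}

#' @rdname sanitize_and_mask
#' @export
sanitize_raster <- function(x) {
  fin <- is.finite(x)
  if (!any(fin))
    stop("raster has no finite values", call. = FALSE)
  if (all(fin)) return(x)
  r <- range(x[fin])
  x[is.nan(x) | x == -Inf] <- r[1]
  x[x == Inf] <- r[2]
  x
}

#' Compute the full 35-transform bank
#'
#' Applies all 35 transforms to a contrast-stretched RGB image, sanitizes
#' each raster and applies the plant mask. The stretched R, G, B channels
#' pass through as transforms themselves.
#'
#' @param image H x W x 3 stretched RGB array.
#' @param mask H x W plant mask in \{1, NA\}.
#' @param assume_linear_rgb passed to [color_space_channels()].
#' @return named list of 35 `transformed_image` objects in canonical order.
#' @export
transform_bank <- function(image, mask, assume_linear_rgb = FALSE) {
  assert_rgb_image(image)
  raw <- c(list(R = image[, , 1], G = image[, , 2], B = image[, , 3]),
           color_space_channels(image, assume_linear_rgb = assume_linear_rgb),
           lapply(stats::setNames(nm = .vegetation_index_names),
                  function(nm) vegetation_index(image, nm)))
  stopifnot(identical(names(raw), .transform_names))
  mapply(function(x, nm) sanitize_and_mask(x, mask, name = nm),
         raw, names(raw), SIMPLIFY = FALSE)
}

#' @export
print.transformed_image <- function(x, ...) {
  cat(sprintf("<transformed_image '%s': %d x %d, %d plant pixels>\n",
              x$name, nrow(x$values), ncol(x$values), x$n))
  invisible(x)
}

#' Write a transform bank to disk for inspection
#'
#' Each transform is written as a 16-bit grayscale PNG normalized to its
#' own value range (computed before masking; masked pixels render as 0),
#' with a JSON sidecar recording each transform's min/max so values can be
#' recovered.
#'
#' @param bank result of [transform_bank()].
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
write_transform_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ranges <- lapply(bank, function(t) {
    r <- range(t$unmasked, finite = TRUE)
    v <- t$values
    if (r[1] == r[2]) v[] <- 0 else v <- (v - r[1]) / (r[2] - r[1])
    v[is.na(v)] <- 0
    png::writePNG(v, file.path(dir, paste0(t$name, ".png")), dpi = NULL)
    list(min = r[1], max = r[2], n_plant = t$n)
  })
  side <- file.path(dir, "transform_ranges.json")
  jsonlite::write_json(ranges, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(side)
}
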