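#' Contrast-stretch an 8-bit RGB image
#'
#' Each channel is independently remapped so that its 1st percentile goes to
#' 0 and its 99th percentile to 255, saturating the bottom and top 1% of
#' pixel values and stretching linearly in between. Percentiles are computed
#' by linear interpolation between order statistics (R's default quantile
#' type 7). The remapped values are rounded half away from zero back to
#' 8-bit integers. A flat channel (lower limit equal to upper limit) has no
#' contrast to stretch and is returned unchanged.
#'
#' @param image H x W x 3 numeric array with values in \[0, 255\].
#' @param lower_pct,upper_pct saturation percentiles (defaults 0.01, 0.99).
#' @return H x W x 3 array of stretched 8-bit values (doubles holding
#'   integers in \[0, 255\]).
#' @export
stretch_contrast <- function(image, lower_pct = 0.01, upper_pct = 0.99) {
  assert_rgb_image(image)
  out <- image
  for (ch in 1:3) {
    v <- image[, , ch]
    lim <- stats::quantile(v, c(lower_pct, upper_pct), names = FALSE, type = 7)
    out[, , ch] <- stretch_channel(v, lim[1], lim[2])
  }
  out
}

## Linear stretch of one channel between old limits [lo, uo] and new limits
## [0, 255]; values below lo saturate to 0, above uo to 255.
stretch_channel <- function(v, lo, uo, ln = 0, un = 255) {
  if (uo <= lo) return(v)  # flat channel: undefined slope, leave unchanged
  e <- (v - lo) * (un - ln) / (uo - lo) + ln
  e[v < lo] <- ln
  e[v > uo] <- un
  round_half_away(e)
}

#' Vegetation index images used for segmentation
#'
#' Computes the three vegetation index images that drive plant/soil
#' segmentation — excess green (ExG), modified excess green (MExG) and
#' color index of vegetation extraction (CIVE) — from a contrast-stretched
#' RGB image, together with copies of each rescaled to \[0, 1\]:
#' \deqn{ExG = (2G - R - B)/(R + G + B)} with the convention ExG = -1 where
#' R = G = B = 0;
#' \deqn{MExG = 1.262 G - 0.884 R - 0.311 B}
#' \deqn{CIVE = 0.441 R - 0.811 G + 0.385 B + 18.78745}
#'
#' @param image H x W x 3 stretched RGB array.
#' @return object of class `seg_indices`: a list with raw rasters `exg`,
#'   `mexg`, `cive` and rescaled rasters `exg01`, `mexg01`, `cive01`.
#' @export
compute_seg_indices <- function(image) {
  assert_rgb_image(image)
  R <- image[, , 1]; G <- image[, , 2]; B <- image[, , 3]
  s <- R + G + B
  exg <- (2 * G - R - B) / s
  exg[s == 0] <- -1
  mexg <- 1.262 * G - 0.884 * R - 0.311 * B
  cive <- 0.441 * R - 0.811 * G + 0.385 * B + 18.78745
  structure(list(exg = exg, mexg = mexg, cive = cive,
                 exg01 = rescale01(exg), mexg01 = rescale01(mexg),
                 cive01 = rescale01(cive)),
            class = "seg_indices")
}

#' Otsu threshold over 256 gray levels
#'
#' Quantizes a real-valued raster into 256 levels (linear min-max map,
#' rounded half away from zero) and returns the level threshold t in
#' 0..254 that maximizes the between-class variance of the split
#' level <= t vs level > t. Ties take the smallest t.
#'
#' @param x numeric matrix (NAs ignored).
#' @param levels number of gray levels for the histogram (default 256).
#' @return list with `threshold` (integer level) and `value` (the threshold
#'   mapped back to the scale of `x`, the upper edge of class 0).
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- x[is.finite(x)]
  if (length(v) == 0L) stop("Otsu: no finite values", call. = FALSE)
  r <- range(v)
  if (r[1] == r[2])
    stop("Otsu: constant image, no threshold exists", call. = FALSE)
  lev <- round_half_away((v - r[1]) / (r[2] - r[1]) * (levels - 1))
  h <- tabulate(lev + 1L, nbins = levels)
  p <- h / sum(h)
  g <- 0:(levels - 1L)
  w0 <- cumsum(p)                       # weight of class {0..t}
  m0 <- cumsum(p * g)                   # unnormalized mean of class {0..t}
  mt <- m0[levels]                      # global mean
  t_cand <- 1:(levels - 1L)             # t = 0..levels-2 (both classes nonempty)
  w <- w0[t_cand]
  sb <- (mt * w - m0[t_cand])^2 / (w * (1 - w))
  sb[!is.finite(sb)] <- -Inf            # empty class: invalid split
  t_best <- which.max(sb) - 1L
  list(threshold = t_best,
       value = r[1] + (t_best + 0.5) / (levels - 1) * (r[2] - r[1]))
}

#' Build the plant/soil segmentation mask
#'
#' Combines two binary masks: `M1`, obtained by Otsu-thresholding the
#' difference image (rescaled MExG - rescaled CIVE) with plant pixels
#' strictly above the threshold, and `M2`, the pixels whose rescaled ExG
#' strictly exceeds `exg_threshold`. The combined mask is NA only where both
#' are 0 and 1 elsewhere (a union), after which connected objects of
#' `min_object_pixels` or fewer pixels are removed as noise.
#'
#' @param indices a `seg_indices` object from [compute_seg_indices()].
#' @param exg_threshold cutoff on rescaled ExG for `M2` (default 0.5).
#' @param min_object_pixels objects with this many pixels or fewer are
#'   removed (default 300).
#' @param connectivity pixel connectivity for object cleaning, 4 or 8
#'   (default 8).
#' @return H x W plant mask matrix with 1 at plant pixels and NA elsewhere.
#'   Attributes `m1` and `m2` carry the two intermediate binary masks.
#' @export
build_plant_mask <- function(indices, exg_threshold = 0.5,
                             min_object_pixels = 300L, connectivity = 8L) {
  stopifnot(inherits(indices, "seg_indices"))
  d <- indices$mexg01 - indices$cive01
  ot <- otsu_threshold(d)
  m1 <- (d > ot$value) * 1
  m2 <- (indices$exg01 > exg_threshold) * 1
  m <- matrix(1, nrow(m1), ncol(m1))
  m[m1 == 0 & m2 == 0] <- NA
  m <- remove_small_objects(m, min_pixels = min_object_pixels,
                            connectivity = connectivity)
  attr(m, "m1") <- m1
  attr(m, "m2") <- m2
  m
}

#' Label connected components of a binary mask
#'
#' Labels the TRUE/1 pixels of a mask into connected components under 4- or
#' 8-connectivity. Component discovery is delegated to an adjacency graph
#' over foreground pixels and \code{igraph::components()}.
#'
#' @param fg logical or 0/1 matrix (NA treated as background).
#' @param connectivity 4 or 8.
#' @return integer matrix of the same shape: 0 for background, 1..k
#'   component labels for foreground.
#' @export
label_components <- function(fg, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop("connectivity must be 4 or 8", call. = FALSE)
  fg <- !is.na(fg) & fg != 0
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  idx <- which(fg)
  if (length(idx) == 0L) return(lab)
  row_i <- ((idx - 1L) %% h) + 1L
  col_i <- ((idx - 1L) %/% h) + 1L
  offs <- list(c(1L, 0L), c(0L, 1L))            # down, right
  if (connectivity == 8L)
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))  # two diagonals
  from <- integer(0); to <- integer(0)
  for (o in offs) {
    r2 <- row_i + o[1]; c2 <- col_i + o[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    keep <- fg[nb]
    from <- c(from, idx[ok][keep])
    to <- c(to, nb[keep])
  }
  ## vertices are foreground pixels; isolated pixels still get a label
  vid <- integer(h * w)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(vid[from], vid[to]))
  memb <- igraph::components(g)$membership
  lab[idx] <- as.integer(memb)
  lab
}

#' Remove small objects from a plant mask
#'
#' Sets every connected component of plant pixels whose size is
#' `min_pixels` or fewer (the bound is inclusive) to NA; larger components
#' are untouched. The plant-pixel count is therefore non-increasing.
#'
#' @param mask H x W matrix in \{1, NA\} (0 also accepted as background).
#' @param min_pixels inclusive size cutoff (default 300).
#' @param connectivity 4 or 8 (default 8).
#' @return cleaned mask in \{1, NA\}.
#' @export
remove_small_objects <- function(mask, min_pixels = 300L, connectivity = 8L) {
  lab <- label_components(mask, connectivity = connectivity)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes > min_pixels)
    out[lab %in% keep] <- 1
  }
  out
}

#' Segment a stretched RGB image in one call
#'
#' Convenience wrapper: vegetation indices + mask construction + cleaning.
#'
#' @inheritParams build_plant_mask
#' @param image H x W x 3 contrast-stretched RGB array.
#' @return plant mask as in [build_plant_mask()].
#' @export
segment_plants <- function(image, exg_threshold = 0.5,
                           min_object_pixels = 300L, connectivity = 8L) {
  build_plant_mask(compute_seg_indices(image),
                   exg_threshold = exg_threshold,
                   min_object_pixels = min_object_pixels,
                   connectivity = connectivity)
}
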