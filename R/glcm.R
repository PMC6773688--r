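## GLCM texture features.
##
## Each transform is quantized to 256 gray levels from its UNMASKED value
## range (the mask is applied afterwards), then two symmetric gray-level
## co-occurrence matrices are accumulated at displacement d = 1 along the
## 0 and 90 degree scanning directions. Pixel pairs containing an NA are
## skipped. A symmetric GLCM counts each pair in both orders, so the matrix
## equals its transpose and its two marginals coincide, which licenses the
## single-margin forms of the GLCM mean and variance. Nine statistics per
## direction are averaged over the two directions: 35 x 9 = 315 texture
## features per image.

.texture_stat_names <- c("MP", "MEA", "VAR", "COR", "ASM",
                         "ENT", "DIS", "CON", "IDM")

#' Quantize a transform to 256 gray levels
#'
#' Linear min-max map of the unmasked sanitized raster to integers 0..255
#' (rounded half away from zero), after which the plant mask's NAs are
#' applied. Quantizing before masking keeps the gray scale anchored to the
#' whole image rather than to whatever the mask retained. A constant raster
#' quantizes to all zeros (its GLCM collapses to a single cell).
#'
#' @param t a `transformed_image` (its `unmasked` raster is used), or a
#'   plain numeric matrix.
#' @param mask H x W plant mask in \{1, NA\}, or NULL.
#' @param levels number of gray levels (default 256).
#' @return H x W integer-valued matrix in \{0..levels-1, NA\}.
#' @export
quantize_gray <- function(t, mask = NULL, levels = 256L) {
  x <- if (inherits(t, "transformed_image")) t$unmasked else t
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r))) stop("quantize: no finite values", call. = FALSE)
  q <- if (r[1] == r[2]) {
    x * 0
  } else {
    round_half_away((x - r[1]) / (r[2] - r[1]) * (levels - 1))
  }
  if (!is.null(mask)) q[is.na(mask)] <- NA_real_
  q
}

#' Symmetric gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at displacement `d` along one
#' scanning direction. For 0 degrees the pairs are horizontal neighbours
#' (same row, columns y and y+d); for 90 degrees vertical neighbours (same
#' column, rows x and x+d); 45/135 degrees take the two diagonals. Both
#' orders of every pair are counted (symmetric GLCM), so the total count is
#' twice the number of valid pairs. Pairs with an NA member are ignored.
#'
#' @param q quantized matrix from [quantize_gray()].
#' @param d pixel displacement (default 1).
#' @param direction scanning direction in degrees: 0, 45, 90 or 135.
#' @param levels number of gray levels (default 256).
#' @return `levels` x `levels` integer count matrix of class `glcm` with
#'   attributes `d` and `direction`.
#' @export
compute_glcm <- function(q, d = 1L, direction = 0, levels = 256L) {
  h <- nrow(q); w <- ncol(q)
  off <- switch(as.character(direction),
    "0"   = c(0L, d),
    "90"  = c(d, 0L),
    "45"  = c(d, d),   # (x, y) paired with (x+d, y+d)
    "135" = c(d, -1L * d),
    stop("direction must be one of 0, 45, 90, 135", call. = FALSE))
  a_rows <- if (off[1] >= 0) seq_len(h - off[1]) else seq(1L - off[1], h)
  b_rows <- a_rows + off[1]
  a_cols <- if (off[2] >= 0) seq_len(w - off[2]) else seq(1L - off[2], w)
  b_cols <- a_cols + off[2]
  if (length(a_rows) == 0L || length(a_cols) == 0L)
    stop("empty GLCM: image too small for displacement", call. = FALSE)
  a <- q[a_rows, a_cols, drop = FALSE]
  b <- q[b_rows, b_cols, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok))
    stop("empty GLCM: no valid pixel pairs", call. = FALSE)
  i <- a[ok]; j <- b[ok]
  idx <- c(i * levels + j, j * levels + i) + 1        # both scan orders
  counts <- matrix(tabulate(idx, nbins = levels^2), levels, levels,
                   byrow = TRUE)                      # row = i, col = j
  structure(counts, class = c("glcm", class(counts)),
            d = d, direction = direction)
}

#' Normalize a GLCM to joint probabilities
#'
#' Divides the counts by their total so the entries sum to 1.
#'
#' @param P count matrix from [compute_glcm()].
#' @return probability matrix of the same shape (symmetric, entries >= 0,
#'   summing to 1).
#' @export
normalize_glcm <- function(P) {
  tot <- sum(P)
  if (tot <= 0) stop("cannot normalize an empty GLCM", call. = FALSE)
  p <- unclass(P) / tot
  attr(p, "d") <- NULL; attr(p, "direction") <- NULL
  p
}

#' Nine texture statistics of a normalized GLCM
#'
#' For a symmetric normalized GLCM p(i, j) with gray levels g = 0..L-1:
#' maximum probability MP = max p; mean MEA = sum_i g_i p_i. (single
#' margin; both margins coincide by symmetry); variance
#' VAR = sum_i (g_i - MEA)^2 p_i.; correlation
#' COR = (sum_{ij} g_i g_j p_ij - MEA^2) / VAR; angular second moment
#' ASM = sum p^2; entropy ENT = -sum p log2 p (0 log 0 = 0); dissimilarity
#' DIS = sum |i-j| p; contrast CON = sum (i-j)^2 p; inverse difference
#' moment IDM = sum p / (1 + (i-j)^2). COR is NA when VAR = 0 (a constant
#' quantized region makes it 0/0).
#'
#' @param p normalized symmetric GLCM from [normalize_glcm()].
#' @return named numeric vector of the nine statistics.
#' @export
texture_stats <- function(p) {
  L <- nrow(p)
  g <- 0:(L - 1)
  pi_ <- rowSums(p)                    # single margin (= colSums by symmetry)
  MEA <- sum(g * pi_)
  VAR <- sum((g - MEA)^2 * pi_)
  nz <- p > 0
  ENT <- -sum(p[nz] * log2(p[nz]))
  ASM <- sum(p^2)
  dif <- abs(outer(g, g, "-"))
  DIS <- sum(dif * p)
  CON <- sum(dif^2 * p)
  IDM <- sum(p / (1 + dif^2))
  COR <- if (VAR == 0) NA_real_ else (sum(outer(g, g) * p) - MEA^2) / VAR
  c(MP = max(p), MEA = MEA, VAR = VAR, COR = COR, ASM = ASM,
    ENT = ENT, DIS = DIS, CON = CON, IDM = IDM)
}

#' Direction-averaged texture features of one quantized transform
#'
#' Accumulates one symmetric GLCM per scanning direction (default 0 and 90
#' degrees at displacement 1), computes the nine statistics for each and
#' averages them element-wise. A statistic that is NA in either direction
#' (COR over a constant region) stays NA.
#'
#' @param q quantized matrix from [quantize_gray()].
#' @param d pixel displacement (default 1).
#' @param directions scanning directions in degrees (default `c(0, 90)`).
#' @param levels number of gray levels (default 256).
#' @return named numeric vector of the nine averaged statistics.
#' @export
texture_features_for_transform <- function(q, d = 1L, directions = c(0, 90),
                                           levels = 256L) {
  per_dir <- vapply(directions, function(th) {
    texture_stats(normalize_glcm(compute_glcm(q, d = d, direction = th,
                                              levels = levels)))
  }, numeric(9L))
  rowMeans(per_dir)                    # NA in any direction propagates
}

#' All 315 texture features of a transform bank
#'
#' Quantizes each of the 35 transforms and computes its direction-averaged
#' nine texture statistics: features named `<transform>_<stat>`.
#'
#' @param bank named list from [transform_bank()].
#' @param mask H x W plant mask in \{1, NA\}.
#' @inheritParams texture_features_for_transform
#' @return named numeric vector of length 315.
#' @export
all_texture_features <- function(bank, mask, d = 1L, directions = c(0, 90),
                                 levels = 256L) {
  out <- unlist(lapply(bank, function(t) {
    q <- quantize_gray(t, mask, levels = levels)
    tryCatch(
      texture_features_for_transform(q, d = d, directions = directions,
                                     levels = levels),
      error = function(e) stop("transform '", t$name, "': ",
                               conditionMessage(e), call. = FALSE))
  }))
  names(out) <- as.vector(t(outer(names(bank), .texture_stat_names,
                                  paste, sep = "_")))
  out
}

#' Names of the 315 texture-feature columns
#' @return character vector of length 315.
#' @export
texture_feature_names <- function() {
  as.vector(t(outer(.transform_names, .texture_stat_names, paste, sep = "_")))
}

#' Write per-transform GLCMs as text matrices for debugging
#'
#' @param bank named list from [transform_bank()].
#' @param mask plant mask.
#' @param dir output directory.
#' @param d,directions,levels as in [texture_features_for_transform()].
#' @return invisibly, the directory.
#' @export
write_glcm_matrices <- function(bank, mask, dir, d = 1L,
                                directions = c(0, 90), levels = 256L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in bank) {
    q <- quantize_gray(t, mask, levels = levels)
    for (th in directions) {
      P <- tryCatch(compute_glcm(q, d = d, direction = th, levels = levels),
                    error = function(e) NULL)
      if (is.null(P)) next
      utils::write.table(unclass(P),
                         file.path(dir, sprintf("%s_d%d_%ddeg.txt",
                                                t$name, d, th)),
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}
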