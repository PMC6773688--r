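## Color-space conversions for the transform bank.
##
## Inputs are stretched 8-bit R, G, B matrices (0..255). Conventions:
##  - XYZ / L*a*b*: CIE 1931 2-degree observer, standard illuminant D65.
##    By default the 8-bit values are treated as nonlinear sRGB and the
##    standard sRGB inverse companding is applied before the linear-RGB ->
##    XYZ matrix; set assume_linear_rgb = TRUE to skip companding. XYZ are
##    scaled so the white point is (95.047, 100, 108.883); L* in [0, 100].
##  - HSI: Gonzalez & Woods variant. I = (R+G+B)/3 scaled to [0, 1],
##    S = 1 - 3 min(R,G,B)/(R+G+B), H from the arccos form in degrees
##    [0, 360); H = 0 where undefined (S = 0 or R = G = B); S = 0 where
##    R + G + B = 0.
##  - Y'CbCr: ITU-R BT.601 full-range coefficients on 8-bit values
##    (Y' in [0, 255], Cb/Cr centered on 128).

srgb_to_linear <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}

#' RGB to CIE 1931 XYZ channels
#'
#' @param R,G,B numeric matrices of 8-bit values (0..255).
#' @param assume_linear_rgb if TRUE, skip the sRGB inverse companding and
#'   treat the values as linear RGB.
#' @return list of matrices `X`, `Y`, `Z` on the 0..100 scale.
#' @export
rgb_to_xyz <- function(R, G, B, assume_linear_rgb = FALSE) {
  r <- R / 255; g <- G / 255; b <- B / 255
  if (!assume_linear_rgb) {
    r <- srgb_to_linear(r); g <- srgb_to_linear(g); b <- srgb_to_linear(b)
  }
  ## sRGB D65 matrix (IEC 61966-2-1)
  X <- (0.4124564 * r + 0.3575761 * g + 0.1804375 * b) * 100
  Y <- (0.2126729 * r + 0.7151522 * g + 0.0721750 * b) * 100
  Z <- (0.0193339 * r + 0.1191920 * g + 0.9503041 * b) * 100
  list(X = X, Y = Y, Z = Z)
}

#' XYZ to CIE 1976 L*a*b* channels (D65 white)
#'
#' @param xyz list with `X`, `Y`, `Z` on the 0..100 scale.
#' @return list of matrices `Lstar`, `astar`, `bstar`.
#' @export
xyz_to_lab <- function(xyz) {
  wp <- c(95.047, 100, 108.883)
  f <- function(t) {
    d <- 6 / 29
    ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
  }
  fx <- f(xyz$X / wp[1]); fy <- f(xyz$Y / wp[2]); fz <- f(xyz$Z / wp[3])
  list(Lstar = 116 * fy - 16, astar = 500 * (fx - fy), bstar = 200 * (fy - fz))
}

#' RGB to HSI channels
#'
#' @param R,G,B numeric matrices of 8-bit values (0..255).
#' @return list of matrices `H` (degrees, \[0, 360)), `S` (\[0, 1\]),
#'   `I` (\[0, 1\]).
#' @export
rgb_to_hsi <- function(R, G, B) {
  s <- R + G + B
  I <- s / (3 * 255)
  mn <- pmin(R, G, B)
  S <- ifelse(s == 0, 0, 1 - 3 * mn / s)
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  ct <- ifelse(den == 0, 1, pmin(pmax(num / den, -1), 1))
  H <- acos(ct) * 180 / pi
  H <- ifelse(B > G, 360 - H, H)
  H[den == 0 | S == 0] <- 0
  list(H = H, S = S, I = I)
}

#' RGB to Y'CbCr channels (BT.601 full range)
#'
#' @param R,G,B numeric matrices of 8-bit values (0..255).
#' @return list of matrices `Yprime`, `Cb`, `Cr` on the 8-bit scale.
#' @export
rgb_to_ycbcr <- function(R, G, B) {
  list(Yprime = 0.299 * R + 0.587 * G + 0.114 * B,
       Cb = 128 - 0.168736 * R - 0.331264 * G + 0.5 * B,
       Cr = 128 + 0.5 * R - 0.418688 * G - 0.081312 * B)
}
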