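# Independent brute-force oracles used to validate the vectorized
# implementations. These deliberately use the slowest, most literal
# formulations.

# Population moments by literal two-pass summation over non-NA values.
oracle_moments <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  mu <- sum(v) / n
  sigma <- sqrt(sum((v - mu)^2) / n)
  if (sigma == 0) return(c(mu = mu, sigma = 0, skew = NA, kurt = NA))
  c(mu = mu, sigma = sigma,
    skew = sum((v - mu)^3) / (n * sigma^3),
    kurt = sum((v - mu)^4) / (n * sigma^4))
}

# Symmetric GLCM by exhaustive per-pixel pair enumeration.
oracle_glcm <- function(q, d = 1L, direction = 0, levels = 256L) {
  h <- nrow(q); w <- ncol(q)
  off <- switch(as.character(direction),
                "0" = c(0L, d), "90" = c(d, 0L),
                "45" = c(d, d), "135" = c(d, -d))
  counts <- matrix(0L, levels, levels)
  for (x in seq_len(h)) for (y in seq_len(w)) {
    x2 <- x + off[1]; y2 <- y + off[2]
    if (x2 < 1 || x2 > h || y2 < 1 || y2 > w) next
    a <- q[x, y]; b <- q[x2, y2]
    if (is.na(a) || is.na(b)) next
    counts[a + 1, b + 1] <- counts[a + 1, b + 1] + 1L
    counts[b + 1, a + 1] <- counts[b + 1, a + 1] + 1L
  }
  counts
}

# Otsu by brute force: try every candidate threshold level and maximize
# between-class variance computed directly from the binned values.
oracle_otsu <- function(x, levels = 256L) {
  v <- x[is.finite(x)]
  r <- range(v)
  lev <- sign((v - r[1])) * floor(abs((v - r[1]) / (r[2] - r[1]) *
                                        (levels - 1)) + 0.5)
  best_t <- NA; best_sb <- -Inf
  for (t in 0:(levels - 2)) {
    lo <- lev[lev <= t]; hi <- lev[lev > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(lev); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best_sb + 1e-12) { best_sb <- sb; best_t <- t }
  }
  best_t
}

# Connected components by recursive-free flood fill (stack-based).
oracle_components <- function(fg, connectivity = 8L) {
  fg <- !is.na(fg) & fg != 0
  h <- nrow(fg); w <- ncol(fg)
  lab <- matrix(0L, h, w)
  cur <- 0L
  neigh <- if (connectivity == 8L)
    expand.grid(dr = -1:1, dc = -1:1)[-5, ]
  else data.frame(dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  for (start in which(fg & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    while (length(stack)) {
      s <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[s] != 0L) next
      lab[s] <- cur
      r0 <- ((s - 1L) %% h) + 1L; c0 <- ((s - 1L) %/% h) + 1L
      for (k in seq_len(nrow(neigh))) {
        r2 <- r0 + neigh$dr[k]; c2 <- c0 + neigh$dc[k]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            fg[r2, c2] && lab[r2, c2] == 0L)
          stack <- c(stack, (c2 - 1L) * h + r2)
      }
    }
  }
  lab
}

# Texture statistics by literal double loop over all GLCM cells.
oracle_texture <- function(p) {
  L <- nrow(p)
  MEA <- 0; for (i in 1:L) for (j in 1:L) MEA <- MEA + (i - 1) * p[i, j]
  VAR <- 0; for (i in 1:L) for (j in 1:L) VAR <- VAR + (i - 1 - MEA)^2 * p[i, j]
  COR <- 0; ASM <- 0; ENT <- 0; DIS <- 0; CON <- 0; IDM <- 0
  for (i in 1:L) for (j in 1:L) {
    pij <- p[i, j]
    ASM <- ASM + pij^2
    if (pij > 0) ENT <- ENT - pij * log2(pij)
    DIS <- DIS + abs(i - j) * pij
    CON <- CON + (i - j)^2 * pij
    IDM <- IDM + pij / (1 + (i - j)^2)
    COR <- COR + ((i - 1) - MEA) * ((j - 1) - MEA) * pij
  }
  COR <- if (VAR == 0) NA_real_ else COR / VAR
  c(MP = max(p), MEA = MEA, VAR = VAR, COR = COR, ASM = ASM,
    ENT = ENT, DIS = DIS, CON = CON, IDM = IDM)
}

# A tiny flat-color test scene: soil background with rectangular and
# elliptical pure-green patches; returns image + truth mask.
flat_scene <- function(h = 80, w = 100, fg = c(40, 200, 40),
                       bg = c(120, 90, 60)) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- bg[ch]
  truth <- matrix(FALSE, h, w)
  truth[10:40, 10:50] <- TRUE                       # 31 x 41 block
  truth[50:75, 60:95] <- TRUE                       # 26 x 36 block
  for (ch in 1:3) { p <- img[, , ch]; p[truth] <- fg[ch]; img[, , ch] <- p }
  list(image = img, truth = ifelse(truth, 1, NA))
}

rand_rgb <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
}
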