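## Synthetic canopy scenes with known ground-truth masks.
##
## A scene is a soil-textured background (multiplicative illumination noise
## on a brown soil color) overlaid with randomly placed, rotated ellipse
## "leaflets" (green, with per-leaf color jitter and per-pixel noise),
## optionally darkened by circular shadow patches. The ground-truth mask is
## exactly the union of the rendered ellipses. The generator never consults
## the segmentation code or its thresholds, so segmentation accuracy scored
## against the truth mask is a genuine end-to-end test.

#' Parameters of a synthetic canopy scene
#'
#' Defaults emulate early-vegetative (V4/V5) row-crop canopies seen from
#' above: brown soil around (120, 95, 70), green foliage around
#' (60, 150, 55), leaflet semi-major axes 16--24 px so single leaflets
#' exceed the 300-pixel cleaning floor of the segmenter. `difficulty`
#' presets: `"easy"` uses saturated green and no shadows, `"hard"`
#' desaturates the foliage, adds shadows and more noise.
#'
#' @param width,height scene size in pixels.
#' @param n_leaves number of leaflet ellipses.
#' @param leaf_color mean foliage RGB.
#' @param leaf_jitter_sd per-leaf RGB jitter standard deviation.
#' @param pixel_noise_sd per-pixel additive noise on foliage.
#' @param leaf_axis_range semi-major axis range in pixels.
#' @param leaf_aspect_range semi-minor/semi-major aspect range.
#' @param trifoliolate if TRUE, each "leaf" is a 3-lobed cluster of
#'   ellipses around a common center, mimicking trifoliolate leaves.
#' @param soil_color mean soil RGB.
#' @param soil_noise_sd multiplicative illumination noise sd on soil.
#' @param shadow_frac approximate fraction of the scene darkened by shadow
#'   patches (0 disables shadows).
#' @param difficulty optional preset `"easy"` or `"hard"` overriding the
#'   color/noise/shadow arguments.
#' @return named list of generator parameters.
#' @export
scene_params <- function(width = 320L, height = 240L, n_leaves = 60L,
                         leaf_color = c(60, 150, 55), leaf_jitter_sd = 12,
                         pixel_noise_sd = 5,
                         leaf_axis_range = c(16, 24),
                         leaf_aspect_range = c(0.5, 0.8),
                         trifoliolate = FALSE,
                         soil_color = c(120, 95, 70), soil_noise_sd = 0.08,
                         shadow_frac = 0, difficulty = NULL) {
  p <- list(width = as.integer(width), height = as.integer(height),
            n_leaves = as.integer(n_leaves), leaf_color = leaf_color,
            leaf_jitter_sd = leaf_jitter_sd, pixel_noise_sd = pixel_noise_sd,
            leaf_axis_range = leaf_axis_range,
            leaf_aspect_range = leaf_aspect_range,
            trifoliolate = isTRUE(trifoliolate),
            soil_color = soil_color, soil_noise_sd = soil_noise_sd,
            shadow_frac = shadow_frac)
  if (!is.null(difficulty)) {
    if (difficulty == "easy") {
      p$leaf_color <- c(50, 170, 45); p$leaf_jitter_sd <- 6
      p$pixel_noise_sd <- 3; p$shadow_frac <- 0
    } else if (difficulty == "hard") {
      p$leaf_color <- c(85, 125, 75); p$leaf_jitter_sd <- 18
      p$pixel_noise_sd <- 9; p$shadow_frac <- 0.15
      p$soil_noise_sd <- 0.12
    } else stop("difficulty must be 'easy' or 'hard'", call. = FALSE)
    p$difficulty <- difficulty
  }
  p
}

clamp8 <- function(x) pmin(pmax(x, 0), 255)

## Pixel set of one rotated ellipse; returns linear indices into an h x w
## matrix. cx/cy are column/row centers, a/b semi-axes, ang radians.
ellipse_pixels <- function(h, w, cy, cx, a, b, ang) {
  rr <- max(a, b)
  rows <- max(1L, floor(cy - rr)):min(h, ceiling(cy + rr))
  cols <- max(1L, floor(cx - rr)):min(w, ceiling(cx + rr))
  if (!length(rows) || !length(cols)) return(integer(0))
  ry <- rep(rows, times = length(cols)) - cy
  rx <- rep(cols, each = length(rows)) - cx
  u <- rx * cos(ang) + ry * sin(ang)
  v <- -rx * sin(ang) + ry * cos(ang)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  ((rep(cols, each = length(rows)) - 1L) * h + rep(rows, times = length(cols)))[inside]
}

#' Generate one synthetic canopy scene
#'
#' Deterministic in `(params, seed)`: the same inputs always render the
#' same scene, down to the PNG bytes.
#'
#' @param params generator parameters from [scene_params()].
#' @param seed integer RNG seed.
#' @return object of class `canopy_scene`: list with `image` (H x W x 3
#'   array in \[0, 255\]), `truth_mask` (H x W in \{1, NA\}; exactly the
#'   rendered foliage pixels), and `params` (including the seed).
#' @export
generate_scene <- function(params = scene_params(), seed = 1L) {
  stopifnot(params$n_leaves >= 0, params$width >= 2L, params$height >= 2L,
            all(params$leaf_color >= 0 & params$leaf_color <= 255),
            all(params$soil_color >= 0 & params$soil_color <= 255))
  set.seed(seed)
  h <- params$height; w <- params$width
  illum <- matrix(stats::rnorm(h * w, 1, params$soil_noise_sd), h, w)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- params$soil_color[ch] * illum
  truth <- matrix(FALSE, h, w)
  if (params$n_leaves > 0) {
    n_lobes <- if (params$trifoliolate) 3L else 1L
    for (k in seq_len(params$n_leaves)) {
      cy0 <- stats::runif(1, 1, h); cx0 <- stats::runif(1, 1, w)
      col_k <- params$leaf_color +
        stats::rnorm(3, 0, params$leaf_jitter_sd)
      for (lb in seq_len(n_lobes)) {
        a <- stats::runif(1, params$leaf_axis_range[1],
                          params$leaf_axis_range[2])
        b <- a * stats::runif(1, params$leaf_aspect_range[1],
                              params$leaf_aspect_range[2])
        ang <- stats::runif(1, 0, pi)
        if (n_lobes > 1L) {
          cy <- cy0 + stats::rnorm(1, 0, a / 2)
          cx <- cx0 + stats::rnorm(1, 0, a / 2)
        } else { cy <- cy0; cx <- cx0 }
        px <- ellipse_pixels(h, w, cy, cx, a, b, ang)
        if (!length(px)) next
        truth[px] <- TRUE
        for (ch in 1:3) {
          plane <- img[, , ch]
          plane[px] <- col_k[ch] +
            stats::rnorm(length(px), 0, params$pixel_noise_sd)
          img[, , ch] <- plane
        }
      }
    }
  }
  if (params$shadow_frac > 0) {
    area <- 0; target <- params$shadow_frac * h * w
    while (area < target) {
      r <- stats::runif(1, 0.08, 0.18) * min(h, w)
      px <- ellipse_pixels(h, w, stats::runif(1, 1, h), stats::runif(1, 1, w),
                           r, r, 0)
      if (!length(px)) next
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[px] <- plane[px] * 0.55
        img[, , ch] <- plane
      }
      area <- area + length(px)
    }
  }
  img <- round_half_away(clamp8(img))
  mask <- matrix(NA_real_, h, w)
  mask[truth] <- 1
  params$seed <- seed
  structure(list(image = img, truth_mask = mask, params = params),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene %d x %d, %d leaves, %.1f%% foliage, seed %d>\n",
              x$params$height, x$params$width, x$params$n_leaves,
              100 * mean(!is.na(x$truth_mask)), x$params$seed))
  invisible(x)
}

#' Intersection-over-union of two plant masks
#'
#' @param mask,truth H x W masks in \{1, NA\} (or logical).
#' @return IoU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(mask, truth) {
  a <- !is.na(mask) & mask != 0
  b <- !is.na(truth) & truth != 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Generate a suite of scenes with a pipeline-ready manifest
#'
#' Writes `n_scenes` scene PNGs and their ground-truth mask PNGs to
#' `out_dir`, cycling through the given difficulty presets, with synthetic
#' location codes 1--4 and planting/measuring dates in plausible
#' early-season windows. The returned manifest (also written as
#' `manifest.csv`) is directly consumable by [run_batch()].
#'
#' @param n_scenes number of scenes (>= 1).
#' @param difficulties character vector of presets cycled over scenes.
#' @param out_dir output directory.
#' @param seed integer seed; scene k uses `seed + k`.
#' @param base_params base [scene_params()] the presets are applied to.
#' @return data.frame manifest with columns `image_path`, `image_id`,
#'   `location`, `planting_date`, `measuring_date`, `mask_path`,
#'   `difficulty`.
#' @export
generate_suite <- function(n_scenes, difficulties = c("easy", "hard"),
                           out_dir, seed = 1L,
                           base_params = scene_params()) {
  stopifnot(n_scenes >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  plantings <- as.Date(c("2016-05-20", "2016-05-21", "2016-06-03",
                         "2016-06-04"))
  rows <- lapply(seq_len(n_scenes), function(k) {
    diff_k <- difficulties[(k - 1L) %% length(difficulties) + 1L]
    p <- base_params
    p$difficulty <- NULL
    p <- do.call(scene_params, c(p, list(difficulty = diff_k)))
    sc <- generate_scene(p, seed = seed + k)
    id <- sprintf("scene_%03d_%s", k, diff_k)
    img_path <- file.path(out_dir, paste0(id, ".png"))
    msk_path <- file.path(out_dir, paste0(id, "_mask.png"))
    write_image_png(sc$image, img_path)
    write_image_png(sc$truth_mask, msk_path)
    loc <- (k - 1L) %% 4L + 1L
    planting <- plantings[loc]
    measuring <- planting + 30L + (k %% 8L)  # ~V4/V5 window
    data.frame(image_path = img_path, image_id = id, location = loc,
               planting_date = as.character(planting),
               measuring_date = as.character(measuring),
               mask_path = msk_path, difficulty = diff_k,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
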