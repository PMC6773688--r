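## Batch driver: per-image feature extraction, Location/Time covariates,
## rectangular feature table with a config sidecar, and the
## feature-correlation summary.

#' Read an 8-bit RGB PNG as a 0..255 array
#'
#' @param path PNG file path.
#' @return H x W x 3 numeric array of integers in \[0, 255\].
#' @export
read_rgb_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L)
    stop("expected an RGB image, got grayscale: ", path, call. = FALSE)
  if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  round_half_away(a * 255)
}

#' Write an RGB array or a plant mask as PNG
#'
#' Masks are written single-channel with plant = 255 and background = 0.
#'
#' @param x H x W x 3 array in \[0, 255\], or an H x W mask in \{1, NA\}.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_image_png <- function(x, path) {
  if (is.matrix(x)) {
    v <- ifelse(is.na(x), 0, 1)
    png::writePNG(v, path)
  } else {
    png::writePNG(x / 255, path)
  }
  invisible(path)
}

#' Days from planting to measurement
#'
#' The Time covariate: the calendar-day difference measuring - planting.
#'
#' @param planting_date,measuring_date `Date`s or ISO "YYYY-MM-DD" strings.
#' @return integer number of days (>= 0).
#' @export
compute_time <- function(planting_date, measuring_date) {
  p <- as.Date(planting_date)
  m <- as.Date(measuring_date)
  if (anyNA(p) || anyNA(m)) stop("unparseable date", call. = FALSE)
  d <- as.integer(m - p)
  if (any(d < 0))
    stop("measuring_date precedes planting_date", call. = FALSE)
  d
}

#' Default extraction configuration
#'
#' @param exg_threshold ExG cutoff for the second segmentation mask.
#' @param min_object_pixels inclusive small-object cleaning floor.
#' @param connectivity 4 or 8.
#' @param assume_linear_rgb skip sRGB companding before XYZ/L*a*b*.
#' @param glcm_levels gray levels for texture quantization.
#' @param glcm_d GLCM pixel displacement.
#' @param glcm_directions scanning directions in degrees.
#' @return named list of class `canopyfeat_config`.
#' @export
canopyfeat_config <- function(exg_threshold = 0.5, min_object_pixels = 300L,
                              connectivity = 8L, assume_linear_rgb = FALSE,
                              glcm_levels = 256L, glcm_d = 1L,
                              glcm_directions = c(0, 90)) {
  structure(list(exg_threshold = exg_threshold,
                 min_object_pixels = as.integer(min_object_pixels),
                 connectivity = as.integer(connectivity),
                 assume_linear_rgb = assume_linear_rgb,
                 glcm_levels = as.integer(glcm_levels),
                 glcm_d = as.integer(glcm_d),
                 glcm_directions = glcm_directions),
            class = "canopyfeat_config")
}

#' Names of the feature-table columns
#'
#' The full schema is `image_id`, `valid`, `reason`, the 140 color
#' features, the 315 texture features, and the two covariates `location`
#' and `time` (455 image features, 457 predictors with the covariates).
#'
#' @return character vector of the 457 predictor column names.
#' @export
feature_column_names <- function() {
  c(color_feature_names(), texture_feature_names(), "location", "time")
}

#' Extract the full feature record of one image
#'
#' Runs the whole per-image pipeline: contrast stretch, vegetation-index
#' segmentation, the 35-transform bank, 140 color moments, 315 GLCM texture
#' statistics, plus the Location and Time covariates — one row of 457
#' predictors. If the plant mask cleans to empty or any transform yields an
#' empty GLCM, the record is returned with `valid = FALSE` and all features
#' NA rather than a partially filled row.
#'
#' @param image H x W x 3 RGB array in \[0, 255\], or a PNG file path.
#' @param image_id identifier string for the row.
#' @param location integer location code.
#' @param planting_date,measuring_date dates for the Time covariate.
#' @param config a [canopyfeat_config()].
#' @return one-row `data.frame`: `image_id`, `valid`, `reason`, 455 feature
#'   columns, `location`, `time`.
#' @export
extract_features <- function(image, image_id = "image", location = NA_integer_,
                             planting_date = NA, measuring_date = NA,
                             config = canopyfeat_config()) {
  time_days <- if (is.na(planting_date) || is.na(measuring_date)) NA_integer_
               else compute_time(planting_date, measuring_date)
  empty_row <- function(reason) {
    feats <- stats::setNames(
      as.list(rep(NA_real_, 455L)),
      c(color_feature_names(), texture_feature_names()))
    cbind(data.frame(image_id = image_id, valid = FALSE, reason = reason,
                     stringsAsFactors = FALSE),
          as.data.frame(feats, check.names = FALSE),
          data.frame(location = as.integer(location), time = time_days))
  }
  res <- tryCatch({
    if (is.character(image)) image <- read_rgb_png(image)
    stretched <- stretch_contrast(image)
    mask <- segment_plants(stretched,
                           exg_threshold = config$exg_threshold,
                           min_object_pixels = config$min_object_pixels,
                           connectivity = config$connectivity)
    if (!any(!is.na(mask))) stop("plant mask is empty after cleaning",
                                 call. = FALSE)
    bank <- transform_bank(stretched, mask,
                           assume_linear_rgb = config$assume_linear_rgb)
    col_f <- all_color_features(bank)
    tex_f <- all_texture_features(bank, mask, d = config$glcm_d,
                                  directions = config$glcm_directions,
                                  levels = config$glcm_levels)
    cbind(data.frame(image_id = image_id, valid = TRUE, reason = "",
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(c(col_f, tex_f)), check.names = FALSE),
          data.frame(location = as.integer(location), time = time_days))
  }, error = function(e) empty_row(conditionMessage(e)))
  rownames(res) <- NULL
  res
}

#' Batch feature extraction over a manifest
#'
#' The manifest (a data.frame or CSV path) must have columns `image_path`,
#' `image_id`, `location`, `planting_date`, `measuring_date` (ISO dates).
#' Each row is extracted with [extract_features()]; failures (unreadable
#' files, empty masks) become flagged `valid = FALSE` rows instead of
#' aborting the batch. When `out_csv` is given, the table is written as CSV
#' (UTF-8, NA spelled `NA`, full precision) with a JSON sidecar
#' `<out_csv>.config.json` recording the configuration and package version.
#'
#' @param manifest data.frame or CSV path.
#' @param config a [canopyfeat_config()].
#' @param out_csv optional output CSV path.
#' @param quiet suppress per-image progress messages.
#' @return the feature table, invisibly if `out_csv` is given.
#' @export
run_batch <- function(manifest, config = canopyfeat_config(),
                      out_csv = NULL, quiet = FALSE) {
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("image_path", "image_id", "location",
            "planting_date", "measuring_date")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    if (!quiet) message("extracting ", r$image_id, " (", i, "/",
                        nrow(manifest), ")")
    rec <- extract_features(r$image_path, image_id = r$image_id,
                            location = r$location,
                            planting_date = r$planting_date,
                            measuring_date = r$measuring_date,
                            config = config)
    if (!rec$valid && !quiet)
      message("  -> invalid: ", rec$reason)
    rec
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out_csv)) {
    utils::write.csv(tab, out_csv, row.names = FALSE, fileEncoding = "UTF-8")
    side <- paste0(out_csv, ".config.json")
    jsonlite::write_json(
      c(unclass(config),
        list(package = "canopyfeat",
             version = as.character(utils::packageVersion("canopyfeat")),
             n_images = nrow(tab), n_valid = sum(tab$valid))),
      side, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(tab))
  }
  tab
}

#' Reduced predictor views of a feature table
#'
#' `"all"` returns the 455 image features plus `location`/`time` (457
#' columns); `"color"` the 140 color moments; `"texture"` the 315 texture
#' statistics; `"color_texture"` the 455 image features; `"rgb_lnt"` the
#' color and texture features of the raw R, G, B channels plus the
#' covariates (12 + 27 + 2 = 41 columns).
#'
#' @param table feature table from [run_batch()] / [extract_features()].
#' @param which one of `"all"`, `"color"`, `"texture"`, `"color_texture"`,
#'   `"rgb_lnt"`.
#' @return the column-projected data.frame.
#' @export
feature_subset <- function(table, which = c("all", "color", "texture",
                                            "color_texture", "rgb_lnt")) {
  which <- match.arg(which)
  rgb <- c("R", "G", "B")
  cols <- switch(which,
    all = feature_column_names(),
    color = color_feature_names(),
    texture = texture_feature_names(),
    color_texture = c(color_feature_names(), texture_feature_names()),
    rgb_lnt = c(as.vector(t(outer(rgb, .color_stat_names, paste, sep = "_"))),
                as.vector(t(outer(rgb, .texture_stat_names, paste, sep = "_"))),
                "location", "time"))
  table[, cols, drop = FALSE]
}

#' Pearson correlation matrix of the 455 image features
#'
#' Correlates every pair of the 455 image-derived feature columns over the
#' valid rows. Pairs involving a constant (or all-NA) column are NA;
#' incomplete pairs use pairwise-complete observations. The matrix is
#' symmetric with a unit diagonal for non-constant features.
#'
#' @param table feature table with at least 3 valid rows.
#' @return 455 x 455 correlation matrix.
#' @export
feature_correlation <- function(table) {
  tab <- table[table$valid, , drop = FALSE]
  if (nrow(tab) < 3L)
    stop("need at least 3 valid rows for a correlation matrix",
         call. = FALSE)
  x <- as.matrix(feature_subset(tab, "color_texture"))
  suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
}
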