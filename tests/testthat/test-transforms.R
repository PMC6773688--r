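test_that("the bank has exactly 35 uniquely named transforms sharing the mask", {
  set.seed(51)
  img <- rand_rgb(12, 14)
  mask <- matrix(ifelse(runif(12 * 14) < 0.7, 1, NA), 12, 14)
  bank <- transform_bank(img, mask)
  expect_length(bank, 35L)
  expect_identical(names(bank), transform_names())
  expect_false(anyDuplicated(names(bank)) > 0)
  n_ref <- sum(!is.na(mask))
  for (t in bank) {
    expect_identical(is.na(t$values), is.na(mask))
    expect_equal(t$n, n_ref)
    expect_true(all(is.finite(t$unmasked)))
  }
  # R, G, B pass through as-is
  expect_equal(bank$R$unmasked, img[, , 1])
  expect_equal(bank$G$unmasked, img[, , 2])
  expect_equal(bank$B$unmasked, img[, , 3])
})

test_that("vegetation indices evaluate their printed formulas", {
  px <- function(r, g, b) {
    a <- array(0, c(2, 2, 3)); a[, , 1] <- r; a[, , 2] <- g; a[, , 3] <- b; a
  }
  v <- function(nm, r, g, b) vegetation_index(px(r, g, b), nm)[1, 1]
  # symmetric numerators vanish / ratio of equals on gray
  expect_equal(v("NGRD", 100, 100, 100), 0)
  expect_equal(v("VD", 100, 100, 100), 0)
  expect_equal(v("RGBVI", 100, 100, 100), 0)
  expect_equal(v("GRR", 100, 100, 100), 1)
  # direct evaluations
  expect_equal(v("TGI", 60, 180, 60), 95 * 180 - 35 * 60 - 60 * 60) # 11400
  expect_equal(v("MExG", 0, 255, 0), 321.81)
  expect_equal(v("CIVE", 100, 100, 100), 20.28745)
  expect_equal(v("NG", 50, 100, 100), 0.4)
  expect_equal(v("ExR", 50, 100, 100), (1.4 * 50 - 100) / 250)
  expect_equal(v("ExGR", 10, 20, 30), (3 * 20 - 2.4 * 10 - 30) / 60)
  expect_equal(v("CI", 30, 10, 90), 2 * 90 / 120)
  expect_equal(v("MNGRD", 30, 40, 0), (1600 - 900) / (1600 + 900))
  # division by zero surfaces as Inf/NaN before sanitization
  expect_identical(v("GRR", 0, 50, 10), Inf)
  expect_true(is.nan(v("NR", 0, 0, 0)))
  expect_error(vegetation_index(px(1, 1, 1), "NDVI"), "unknown")
})

test_that("channel-swap symmetries hold across the index bank", {
  set.seed(52)
  img <- rand_rgb(8, 9)
  img_sw <- img[, , c(3, 2, 1)]               # swap R and B
  expect_equal(vegetation_index(img_sw, "RBD"),
               -vegetation_index(img, "RBD"))
  expect_equal(vegetation_index(img_sw, "ExR"),
               vegetation_index(img, "ExB"))
  expect_equal(vegetation_index(img_sw, "NGBD"),
               vegetation_index(img, "NGRD"))
  expect_equal(vegetation_index(img_sw, "GBR"),
               vegetation_index(img, "GRR"))
})

test_that("bounded indices stay within their closed-form ranges", {
  set.seed(53)
  img <- rand_rgb(16, 16) + 1   # avoid zero denominators; still in range
  img[img > 255] <- 255
  for (nm in c("NR", "NG", "NB")) {
    x <- vegetation_index(img, nm)
    expect_true(all(x >= 0 & x <= 1))
  }
  for (nm in c("NGRD", "NGBD", "MNGRD", "VD", "RGBVI")) {
    x <- vegetation_index(img, nm)
    expect_true(all(x >= -1 & x <= 1))
  }
})

test_that("color-space channels hit their reference points", {
  white <- array(255, c(2, 2, 3))
  cs <- color_space_channels(white)
  expect_equal(cs$Lstar[1, 1], 100, tolerance = 1e-4)
  expect_equal(cs$Yprime[1, 1], 255)
  expect_equal(cs$Cb[1, 1], 128, tolerance = 1e-3)
  expect_equal(cs$Cr[1, 1], 128, tolerance = 1e-3)
  gray <- array(100, c(2, 2, 3))
  cg <- color_space_channels(gray)
  # the standard matrix rows sum to 1 only to ~1e-7, so the neutral axis
  # is zero to ~1e-5, not machine precision
  expect_equal(cg$astar[1, 1], 0, tolerance = 1e-4)
  expect_equal(cg$bstar[1, 1], 0, tolerance = 1e-4)
  expect_equal(cg$S[1, 1], 0)
  expect_equal(cg$H[1, 1], 0)
  expect_equal(cg$I[1, 1], 100 / 255)
  # primary-color hues under the arccos HSI form
  red <- rgb_to_hsi(matrix(255), matrix(0), matrix(0))
  expect_equal(red$H[1, 1], 0)
  grn <- rgb_to_hsi(matrix(0), matrix(255), matrix(0))
  expect_equal(grn$H[1, 1], 120)
  blu <- rgb_to_hsi(matrix(0), matrix(0), matrix(255))
  expect_equal(blu$H[1, 1], 240)
})

test_that("XYZ and L*a*b* agree with grDevices::convertColor", {
  set.seed(54)
  rgb8 <- matrix(sample(0:255, 30, replace = TRUE), ncol = 3)
  R <- matrix(rgb8[, 1]); G <- matrix(rgb8[, 2]); B <- matrix(rgb8[, 3])
  xyz <- rgb_to_xyz(R, G, B)
  lab <- xyz_to_lab(xyz)
  ref_xyz <- grDevices::convertColor(rgb8 / 255, from = "sRGB", to = "XYZ")
  ref_lab <- grDevices::convertColor(rgb8 / 255, from = "sRGB", to = "Lab")
  # convertColor derives its matrix from chromaticities, so coefficients
  # differ from the standard sRGB matrix in the third decimal (~1%)
  expect_equal(cbind(xyz$X, xyz$Y, xyz$Z) / 100, unname(ref_xyz),
               tolerance = 1e-2)
  expect_equal(cbind(lab$Lstar, lab$astar, lab$bstar), unname(ref_lab),
               tolerance = 2e-2)
})

test_that("sanitization replaces NaN and infinities by the finite extremes", {
  expect_equal(sanitize_raster(matrix(c(1, NaN, 3), 1)),
               matrix(c(1, 1, 3), 1))
  expect_equal(sanitize_raster(matrix(c(1, Inf, 3), 1)),
               matrix(c(1, 3, 3), 1))
  expect_equal(sanitize_raster(matrix(c(1, -Inf, 3), 1)),
               matrix(c(1, 1, 3), 1))
  x <- matrix(c(0.5, 2, 7, -3), 2)
  expect_equal(sanitize_raster(x), x)        # all-finite: identity
  expect_error(sanitize_raster(matrix(NaN, 2, 2)), "no finite")
  # masking applies on top of sanitization
  t <- sanitize_and_mask(matrix(c(1, Inf, 3, 4), 2),
                         matrix(c(1, 1, NA, 1), 2), name = "t")
  expect_equal(t$unmasked, matrix(c(1, 4, 3, 4), 2))
  expect_true(is.na(t$values[1, 2]))
  expect_equal(t$n, 3L)
})

test_that("rescaled ExG coincides with the normalized-green transform", {
  set.seed(55)
  img <- rand_rgb(10, 12) + 1; img[img > 255] <- 255
  si <- compute_seg_indices(img)
  ng <- vegetation_index(img, "NG")
  # ExG = 3*NG - 1 is affine in NG, so min-max rescaling collapses them
  expect_equal(si$exg01, rescale01(ng), tolerance = 1e-12)
})
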