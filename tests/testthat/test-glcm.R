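test_that("gray-level quantization maps extremes and rounds half away", {
  expect_equal(quantize_gray(matrix(c(0, 0.5, 1), 1)),
               matrix(c(0, 128, 255), 1))       # 127.5 rounds up
  expect_equal(quantize_gray(matrix(7, 2, 2)), matrix(0, 2, 2))
  q <- quantize_gray(matrix(c(0, 1, 2, 3), 2), mask = matrix(c(1, NA, 1, 1), 2))
  expect_true(is.na(q[2, 1]))
  expect_equal(q[1, 1], 0)
  expect_equal(q[2, 2], 255)
  # quantization uses the unmasked range: masked extremes still anchor it
  t <- sanitize_and_mask(matrix(c(0, 10, 5, 5), 2),
                         matrix(c(NA, NA, 1, 1), 2))
  expect_equal(unique(as.vector(quantize_gray(t, matrix(c(NA, NA, 1, 1), 2)))),
               c(NA, 128))
})

test_that("GLCM counting matches exhaustive pair enumeration", {
  # worked micro-examples
  g <- compute_glcm(matrix(0, 2, 2), direction = 0)
  expect_equal(g[1, 1], 4)                    # 2 pairs, both orders
  expect_equal(sum(g), 4)
  g2 <- compute_glcm(matrix(c(0, 1), 1, 2), direction = 0)
  expect_equal(g2[1, 2], 1)
  expect_equal(g2[2, 1], 1)
  expect_error(compute_glcm(matrix(c(0, NA, 1), 1, 3), direction = 0),
               "empty GLCM")
  # randomized oracle equivalence at 8 levels, all four directions
  set.seed(71)
  for (rep in 1:30) {
    h <- sample(2:16, 1); w <- sample(2:16, 1)
    q <- matrix(sample(0:7, h * w, replace = TRUE), h, w)
    q[runif(h * w) < 0.2] <- NA
    for (th in c(0, 45, 90, 135)) {
      ref <- oracle_glcm(q, direction = th, levels = 8L)
      if (sum(ref) == 0) {
        expect_error(compute_glcm(q, direction = th, levels = 8L),
                     "empty GLCM")
      } else {
        got <- compute_glcm(q, direction = th, levels = 8L)
        expect_equal(unclass(got)[1:8, 1:8], ref, ignore_attr = TRUE)
        # symmetric with even total = 2 x number of valid pairs
        expect_identical(unclass(got), t(unclass(got)), ignore_attr = TRUE)
        expect_equal(sum(got) %% 2, 0)
      }
    }
  }
})

test_that("normalization yields a symmetric probability matrix", {
  q <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
  P <- compute_glcm(q, direction = 90, levels = 4L)
  p <- normalize_glcm(P)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p >= 0))
  expect_equal(p, t(p))
  expect_equal(rowSums(p), colSums(p))        # equal margins
  # a second normalization is the identity
  expect_equal(normalize_glcm(p), p)
  # worked example: counts {0,1}=1, {1,0}=1 -> probs 0.5 each
  p2 <- normalize_glcm(compute_glcm(matrix(c(0, 1), 1, 2), direction = 0,
                                    levels = 2L))
  expect_equal(as.vector(p2), c(0, 0.5, 0.5, 0))
})

test_that("texture statistics reproduce hand-worked GLCMs", {
  # degenerate single cell
  p1 <- matrix(0, 4, 4); p1[1, 1] <- 1
  s1 <- texture_stats(p1)
  expect_equal(unname(s1[c("MP", "MEA", "VAR", "ASM", "ENT",
                           "DIS", "CON", "IDM")]),
               c(1, 0, 0, 1, 0, 0, 0, 1))
  expect_true(is.na(s1[["COR"]]))
  # two-cell antidiagonal: perfect negative association
  p2 <- matrix(0, 2, 2); p2[1, 2] <- 0.5; p2[2, 1] <- 0.5
  s2 <- texture_stats(p2)
  expect_equal(unname(s2[c("MEA", "VAR", "COR", "ENT", "DIS",
                           "CON", "IDM", "ASM", "MP")]),
               c(0.5, 0.25, -1, 1, 1, 1, 0.5, 0.5, 0.5))
  # uniform 2x2
  p3 <- matrix(0.25, 2, 2)
  s3 <- texture_stats(p3)
  expect_equal(unname(s3[c("MEA", "VAR", "COR", "ENT", "ASM")]),
               c(0.5, 0.25, 0, 2, 0.25))
})

test_that("texture statistics match the double-loop oracle", {
  set.seed(72)
  for (rep in 1:10) {
    q <- matrix(sample(0:7, 12 * 12, replace = TRUE), 12)
    p <- normalize_glcm(compute_glcm(q, direction = 0, levels = 8L))
    expect_equal(texture_stats(p), oracle_texture(p), tolerance = 1e-12)
  }
})

test_that("texture identities and inequalities hold on random GLCMs", {
  set.seed(73)
  for (rep in 1:10) {
    q <- matrix(sample(0:15, 20 * 20, replace = TRUE), 20)
    p <- normalize_glcm(compute_glcm(q, direction = 90, levels = 16L))
    s <- texture_stats(p)
    expect_gte(s[["CON"]], s[["DIS"]]^2)            # Jensen
    expect_lte(s[["ENT"]], log2(sum(p > 0)) + 1e-12)
    expect_true(s[["MP"]] > 0 && s[["MP"]] <= 1)
    expect_true(s[["ASM"]] > 0 && s[["ASM"]] <= 1)
    expect_true(s[["IDM"]] > 0 && s[["IDM"]] <= 1)
    expect_true(abs(s[["COR"]]) <= 1 + 1e-12)
  }
})

test_that("direction averaging is transpose-invariant", {
  set.seed(74)
  for (rep in 1:50) {
    h <- sample(3:10, 1); w <- sample(3:10, 1)
    q <- matrix(sample(0:7, h * w, replace = TRUE), h, w)
    f <- texture_features_for_transform(q, levels = 8L)
    ft <- texture_features_for_transform(t(q), levels = 8L)
    expect_equal(f, ft, tolerance = 1e-12)
  }
  # identical 0/90 GLCMs average to either one
  q4 <- matrix(c(0, 1, 1, 0), 2, 2)
  s0 <- texture_stats(normalize_glcm(compute_glcm(q4, direction = 0,
                                                  levels = 2L)))
  expect_equal(texture_features_for_transform(q4, levels = 2L), s0)
})

test_that("a bank yields 315 deterministically named texture features", {
  set.seed(75)
  img <- rand_rgb(12, 12)
  mask <- matrix(ifelse(runif(144) < 0.85, 1, NA), 12, 12)
  bank <- transform_bank(img, mask)
  feats <- all_texture_features(bank, mask)
  expect_length(feats, 315L)
  expect_identical(names(feats), texture_feature_names())
  # spot-check one transform against the direct route
  q <- quantize_gray(bank$TGI, mask)
  expect_equal(unname(feats[paste0("TGI_", c("MP", "MEA", "VAR", "COR",
                                             "ASM", "ENT", "DIS", "CON",
                                             "IDM"))]),
               unname(texture_features_for_transform(q)))
})
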