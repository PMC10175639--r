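test_that("quantization bins [0,255] uniformly", {
  expect_true(all(quantize_image(matrix(7, 3, 3), 16) == 0))
  expect_equal(as.vector(quantize_image(matrix(c(0, 255, 0, 255), 2, 2), 2)),
               c(0L, 1L, 0L, 1L))
  expect_equal(as.vector(quantize_image(matrix(c(0, 100, 200, 255), 2, 2),
                                        4)),
               c(0L, 1L, 3L, 3L))  # bin width 64, clipped to Q-1
  expect_error(quantize_image(matrix(0, 2, 2), 1), "at least 2")
})

test_that("first-order statistics match hand arithmetic and the brute-force oracle", {
  f <- fos_features(matrix(7, 2, 2))
  expect_equal(unname(f), c(28, 7, 0, 0, 0, 0, 1),
               ignore_attr = TRUE)  # degenerate histogram conventions
  f2 <- fos_features(matrix(c(0, 0, 255, 255), 2, 2))
  expect_equal(f2[["Mean"]], 127.5)
  expect_equal(f2[["Variance"]], 16256.25)
  expect_equal(f2[["Energy"]], 0.5)
  expect_equal(f2[["Skewness"]], 0)
  set.seed(42)
  for (i in 1:5) {
    img <- matrix(sample(0:255, 64, replace = TRUE), 8, 8)
    expect_equal(fos_features(img), oracle_fos(img), tolerance = 1e-12)
  }
})

test_that("GLCM pair counts match enumeration and normalize to 1", {
  g <- glcm(matrix(c(0L, 1L, 0L, 1L), 2, 2), "0", 2)
  expect_equal(g$matrix, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  gc <- glcm(matrix(5L, 4, 4), "45", 8)
  expect_equal(gc$matrix[6, 6], 1)
  expect_equal(sum(gc$matrix), 1)
  set.seed(7)
  for (i in 1:5) {
    imgQ <- matrix(sample(0:3, 48, replace = TRUE), 6, 8)
    for (d in all_directions) {
      g <- glcm(imgQ, d, 4)
      expect_equal(sum(g$matrix), 1)
      expect_equal(g$matrix, oracle_glcm(imgQ, offset_of(d), 4))
    }
  }
  expect_error(glcm(matrix(0L, 1, 1), "0", 2), "too small")
})

test_that("Haralick features match hand arithmetic and the double-loop oracle", {
  g <- structure(list(levels = 2L, direction = "0",
                      matrix = matrix(c(0.5, 0, 0, 0.5), 2, 2)),
                 class = "glcm")
  h <- haralick_features(g)
  expect_equal(h[["Contrast"]], 0)
  expect_equal(h[["Energy"]], 0.5)
  expect_equal(h[["Entropy"]], log(2))
  expect_equal(h[["Homogeneity"]], 1)
  expect_equal(h[["Symmetry"]], 1)
  expect_equal(h[["Correlation"]], 1)
  # uniform GLCM: symmetric, energy 1/Q^2, zero correlation
  q <- 4
  gu <- structure(list(levels = q, direction = "0",
                       matrix = matrix(1 / q^2, q, q)), class = "glcm")
  hu <- haralick_features(gu)
  expect_equal(hu[["Symmetry"]], 1)
  expect_equal(hu[["Energy"]], 1 / q^2)
  expect_equal(hu[["Correlation"]], 0)
  set.seed(11)
  for (i in 1:5) {
    p <- matrix(rgamma(25, 1), 5, 5); p <- p / sum(p)
    hf <- haralick_features(structure(list(levels = 5L, direction = "0",
                                           matrix = p), class = "glcm"))
    expect_equal(hf, oracle_haralick(p), tolerance = 1e-9)
  }
  # degenerate marginals: correlation falls back to 0
  pd <- matrix(0, 3, 3); pd[2, 2] <- 1
  hd <- haralick_features(structure(list(levels = 3L, direction = "0",
                                         matrix = pd), class = "glcm"))
  expect_equal(hd[["Correlation"]], 0)
})

test_that("GLRLM counts maximal runs and conserves pixels", {
  r <- glrlm(matrix(c(0L, 0L, 1L), 1, 3), "0", 2)
  expect_equal(r$n_runs, 2)
  expect_equal(r$n_pixels, 3)
  expect_equal(r$matrix[1, 2], 1)  # gray 0, length 2
  expect_equal(r$matrix[2, 1], 1)  # gray 1, length 1
  rc <- glrlm(matrix(3L, 1, 6), "0", 4)
  expect_equal(rc$n_runs, 1)
  expect_equal(rc$matrix[4, 6], 1)
  set.seed(13)
  for (i in 1:5) {
    imgQ <- matrix(sample(0:2, 35, replace = TRUE), 5, 7)
    for (d in all_directions) {
      r <- glrlm(imgQ, d, 3)
      runlen <- sweep(r$matrix, 2, seq_len(ncol(r$matrix)), "*")
      expect_equal(sum(runlen), length(imgQ))  # pixel conservation
      expect_equal(r$matrix, oracle_glrlm(imgQ, offset_of(d), 3))
    }
  }
})

test_that("Galloway features match hand arithmetic and closed forms", {
  r <- glrlm(matrix(c(0L, 0L, 1L), 1, 3), "0", 2)
  g <- galloway_features(r)
  expect_equal(g[["SRE"]], 0.625)
  expect_equal(g[["LRE"]], 2.5)
  expect_equal(g[["GLNU"]], 1)
  expect_equal(g[["RLNU"]], 1)
  expect_equal(g[["RP"]], 2 / 3)
  # single run of length L: SRE = 1/L^2, LRE = L^2, RP = 1/L
  L <- 9
  gs <- galloway_features(glrlm(matrix(2L, 1, L), "0", 4))
  expect_equal(gs[["SRE"]], 1 / L^2)
  expect_equal(gs[["LRE"]], L^2)
  expect_equal(gs[["RP"]], 1 / L)
  set.seed(17)
  for (i in 1:5) {
    imgQ <- matrix(sample(0:3, 64, replace = TRUE), 8, 8)
    r <- glrlm(imgQ, "135", 4)
    expect_equal(galloway_features(r),
                 oracle_galloway(r$matrix, r$n_pixels), tolerance = 1e-9)
  }
})

test_that("LBP codes and histogram statistics behave classically", {
  cst <- matrix(100, 5, 5)
  expect_true(all(lbp_codes(cst) == 255))  # >= comparison: all bits set
  f <- lbp_features(cst)
  expect_equal(f[["Energy"]], 1)
  expect_equal(f[["Entropy"]], 0)
  # hand-computed codes on a 4x4 ramp: east/counter-clockwise bit order
  ramp <- matrix(1:16, 4, 4)  # columns increase by 4, rows by 1
  codes <- lbp_codes(ramp)
  hand <- matrix(NA_integer_, 2, 2)
  dr <- c(0, -1, -1, -1, 0, 1, 1, 1)
  dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
  for (r in 2:3) for (c in 2:3) {
    bits <- sapply(1:8, function(k) ramp[r + dr[k], c + dc[k]] >= ramp[r, c])
    hand[r - 1, c - 1] <- sum(bits * 2^(0:7))
  }
  expect_equal(codes, hand)
  set.seed(19)
  img <- matrix(sample(0:255, 100, replace = TRUE), 10, 10)
  fr <- lbp_features(img)
  expect_gt(fr[["Energy"]], 0)
  expect_lte(fr[["Energy"]], 1)
  expect_gte(fr[["Entropy"]], 0)
  expect_lte(fr[["Entropy"]], log(256))
  expect_error(lbp_features(matrix(0, 2, 3)), "3x3")
})

test_that("rotating a square image by 90 degrees permutes direction-qualified features", {
  set.seed(23)
  img <- matrix(sample(0:255, 32 * 32, replace = TRUE), 32, 32)
  imgQ <- quantize_image(img, 8)
  rot <- t(imgQ[nrow(imgQ):1, ])  # 90-degree rotation
  pairs <- list(c("0", "90"), c("90", "0"), c("45", "135"), c("135", "45"))
  for (pr in pairs) {
    expect_equal(haralick_features(glcm(imgQ, pr[1], 8)),
                 haralick_features(glcm(rot, pr[2], 8)), tolerance = 1e-9)
    expect_equal(galloway_features(glrlm(imgQ, pr[1], 8)),
                 galloway_features(glrlm(rot, pr[2], 8)), tolerance = 1e-9)
  }
})

test_that("all features are finite on degenerate 8-bit inputs", {
  for (img in list(matrix(0, 33, 33), matrix(255, 33, 33),
                   cbind(matrix(0, 33, 16), matrix(255, 33, 17)))) {
    s <- list(image = img, swe_mean_kpa = 10, swe_std_kpa = 1)
    f <- extract_roi_features(s)
    expect_true(all(is.finite(f)))
  }
})
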