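## Per-ROI texture feature bank: first-order statistics, Haralick features
## from gray-level co-occurrence matrices (GLCM), Galloway features from
## gray-level run-length matrices (GLRLM), and local-binary-pattern (LBP)
## histogram statistics. Directions follow the usual image convention with
## rows increasing downwards: 0 deg = (0,1), 45 deg = (-1,1), 90 deg = (-1,0),
## 135 deg = (-1,-1), all at distance 1.

direction_offset <- function(direction) {
  switch(as.character(direction),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("direction must be one of 0, 45, 90, 135"))
}

#' Quantize an 8-bit image to Q gray levels
#'
#' Uniform binning of `[0, 255]` into `Q` equal-width bins:
#' `floor(v * Q / 256)` clipped to `Q - 1`.
#'
#' @param image Numeric/integer matrix with values in `[0, 255]`.
#' @param levels Number of gray levels `Q >= 2`.
#' @return Integer matrix with values in `[0, Q - 1]`.
#' @export
quantize_image <- function(image, levels) {
  if (levels < 2) stop("levels must be at least 2")
  q <- floor(image * levels / 256)
  q[q > levels - 1] <- levels - 1
  matrix(as.integer(q), nrow(image), ncol(image))
}

#' First-order (histogram) statistics of an 8-bit image
#'
#' @param image Numeric/integer matrix, values in `[0, 255]`.
#' @return Named vector: `IOD` (sum of pixel values), `Mean`, `Std`
#'   (population), `Variance`, `Skewness` (`m3 / sd^3`), `Kurtosis`
#'   (`m4 / sd^4`, non-excess), `Energy` (sum of squared 256-bin histogram
#'   probabilities). Skewness and kurtosis are 0 by convention for a
#'   constant image.
#' @export
fos_features <- function(image) {
  v <- as.numeric(image)
  n <- length(v)
  if (n == 0) stop("empty image")
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  s <- sqrt(m2)
  if (s > 0) {
    skew <- mean((v - mu)^3) / s^3
    kurt <- mean((v - mu)^4) / s^4
  } else {
    skew <- 0
    kurt <- 0
  }
  p <- tabulate(as.integer(v) + 1L, nbins = 256L) / n
  c(IOD = sum(v), Mean = mu, Std = s, Variance = m2, Skewness = skew,
    Kurtosis = kurt, Energy = sum(p^2))
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Single-direction (non-symmetrized) pair counts at distance 1, normalized
#' to sum 1.
#'
#' @param imageQ Quantized integer matrix (values in `[0, Q - 1]`).
#' @param direction One of `"0"`, `"45"`, `"90"`, `"135"` (degrees).
#' @param levels Number of gray levels `Q`.
#' @return A list of class `glcm` with `levels`, `direction` and `matrix`
#'   (`Q x Q`, sums to 1).
#' @export
glcm <- function(imageQ, direction, levels) {
  off <- direction_offset(direction)
  if (nrow(imageQ) <= abs(off[1]) || ncol(imageQ) <= abs(off[2])) {
    stop("image too small for the requested offset")
  }
  counts <- .glcm_counts(imageQ, off[1], off[2], as.integer(levels))
  total <- sum(counts)
  if (total == 0) stop("no pixel pairs for this direction")
  structure(list(levels = as.integer(levels),
                 direction = as.character(direction),
                 matrix = counts / total),
            class = "glcm")
}

#' Haralick features of a co-occurrence matrix
#'
#' @param g A [glcm()].
#' @return Named vector: `Contrast` = sum (i-j)^2 P; `Correlation` =
#'   sum (i-mu_i)(j-mu_j) P / (sd_i sd_j) (0 by convention when either
#'   marginal is degenerate); `Energy` = sum P^2; `Entropy` = -sum P ln P;
#'   `Homogeneity` = sum P / (1 + |i-j|); `Symmetry` =
#'   1 - 0.5 * sum |P - t(P)|.
#' @export
haralick_features <- function(g) {
  p <- g$matrix
  q <- g$levels
  i <- matrix(0:(q - 1), q, q)
  j <- t(i)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  gl <- 0:(q - 1)
  mi <- sum(gl * pi_)
  mj <- sum(gl * pj_)
  si <- sqrt(sum((gl - mi)^2 * pi_))
  sj <- sqrt(sum((gl - mj)^2 * pj_))
  corr <- if (si > 0 && sj > 0) {
    sum((i - mi) * (j - mj) * p) / (si * sj)
  } else 0
  nz <- p[p > 0]
  c(Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    Energy = sum(p^2),
    Entropy = -sum(nz * log(nz)),
    Homogeneity = sum(p / (1 + abs(i - j))),
    Symmetry = 1 - 0.5 * sum(abs(p - t(p))))
}

#' Gray-level run-length matrix for one direction
#'
#' Counts maximal constant-gray runs along each line of the direction; every
#' pixel of the image lies on exactly one line, so the pixel conservation
#' `sum(count * run_length) == n_pixels` holds for all four directions.
#'
#' @inheritParams glcm
#' @return A list of class `glrlm` with `levels`, `direction`, `matrix`
#'   (`Q x max_run` raw counts), `n_runs` and `n_pixels`.
#' @export
glrlm <- function(imageQ, direction, levels) {
  off <- direction_offset(direction)
  counts <- .glrlm_counts(imageQ, off[1], off[2], as.integer(levels))
  structure(list(levels = as.integer(levels),
                 direction = as.character(direction),
                 matrix = counts,
                 n_runs = sum(counts),
                 n_pixels = length(imageQ)),
            class = "glrlm")
}

#' Galloway run-length features
#'
#' With raw counts `p(i, j)` (gray level i, run length j) and `N_r` total
#' runs: SRE = (1/N_r) sum p / j^2; LRE = (1/N_r) sum p j^2;
#' GLNU = (1/N_r) sum_i (sum_j p)^2; RLNU = (1/N_r) sum_j (sum_i p)^2;
#' RP = N_r / n_pixels.
#'
#' @param r A [glrlm()].
#' @return Named vector `SRE`, `LRE`, `GLNU`, `RLNU`, `RP`.
#' @export
galloway_features <- function(r) {
  p <- r$matrix
  nr <- r$n_runs
  if (nr < 1) stop("empty run-length matrix")
  j2 <- (seq_len(ncol(p)))^2
  c(SRE = sum(sweep(p, 2, j2, "/")) / nr,
    LRE = sum(sweep(p, 2, j2, "*")) / nr,
    GLNU = sum(rowSums(p)^2) / nr,
    RLNU = sum(colSums(p)^2) / nr,
    RP = nr / r$n_pixels)
}

#' Local binary pattern histogram statistics
#'
#' Classic radius-1 8-neighbour LBP (bit set when neighbour >= centre,
#' neighbour order starting east and proceeding counter-clockwise) over
#' interior pixels; features are the energy and entropy of the normalized
#' 256-bin code histogram.
#'
#' @param image Numeric/integer matrix, at least 3x3.
#' @return Named vector `Energy` (sum h^2) and `Entropy` (-sum h ln h).
#' @export
lbp_features <- function(image) {
  if (nrow(image) < 3 || ncol(image) < 3) stop("image must be at least 3x3")
  img <- matrix(as.integer(image), nrow(image), ncol(image))
  h <- .lbp_hist(img)
  h <- h / sum(h)
  nz <- h[h > 0]
  c(Energy = sum(h^2), Entropy = -sum(nz * log(nz)))
}

#' LBP codes of the interior pixels (for inspection and testing)
#'
#' @param image Numeric/integer matrix, at least 3x3.
#' @return Integer matrix of codes, `(nrow-2) x (ncol-2)`.
#' @export
lbp_codes <- function(image) {
  if (nrow(image) < 3 || ncol(image) < 3) stop("image must be at least 3x3")
  img <- matrix(as.integer(image), nrow(image), ncol(image))
  dr <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  nr <- nrow(img)
  nc <- ncol(img)
  ctr <- img[2:(nr - 1), 2:(nc - 1), drop = FALSE]
  code <- matrix(0L, nrow(ctr), ncol(ctr))
  for (k in seq_len(8)) {
    nb <- img[(2 + dr[k]):(nr - 1 + dr[k]), (2 + dc[k]):(nc - 1 + dc[k]),
              drop = FALSE]
    code <- code + as.integer(nb >= ctr) * 2L^(k - 1L)
  }
  code
}
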