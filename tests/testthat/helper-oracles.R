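# Independent brute-force oracles used to check the fast implementations.

# first-order statistics recomputed directly from the raw pixel list
oracle_fos <- function(img) {
  v <- as.numeric(img)
  mu <- sum(v) / length(v)
  m2 <- sum((v - mu)^2) / length(v)
  s <- sqrt(m2)
  hist256 <- sapply(0:255, function(g) sum(v == g)) / length(v)
  c(IOD = sum(v), Mean = mu, Std = s, Variance = m2,
    Skewness = if (s > 0) sum((v - mu)^3) / length(v) / s^3 else 0,
    Kurtosis = if (s > 0) sum((v - mu)^4) / length(v) / s^4 else 0,
    Energy = sum(hist256^2))
}

# co-occurrence probabilities by explicit pixel-pair enumeration
oracle_glcm <- function(imgQ, off, Q) {
  counts <- matrix(0, Q, Q)
  for (r in seq_len(nrow(imgQ))) {
    for (c in seq_len(ncol(imgQ))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(imgQ) && c2 >= 1 && c2 <= ncol(imgQ)) {
        counts[imgQ[r, c] + 1, imgQ[r2, c2] + 1] <-
          counts[imgQ[r, c] + 1, imgQ[r2, c2] + 1] + 1
      }
    }
  }
  counts / sum(counts)
}

# Haralick statistics by naive double loop over all (i, j) cells
oracle_haralick <- function(p) {
  q <- nrow(p)
  mi <- 0; mj <- 0
  for (i in 1:q) for (j in 1:q) {
    mi <- mi + (i - 1) * p[i, j]; mj <- mj + (j - 1) * p[i, j]
  }
  vi <- 0; vj <- 0
  for (i in 1:q) for (j in 1:q) {
    vi <- vi + (i - 1 - mi)^2 * p[i, j]; vj <- vj + (j - 1 - mj)^2 * p[i, j]
  }
  con <- 0; cor <- 0; ene <- 0; ent <- 0; hom <- 0; sym <- 0
  for (i in 1:q) for (j in 1:q) {
    con <- con + (i - j)^2 * p[i, j]
    cor <- cor + (i - 1 - mi) * (j - 1 - mj) * p[i, j]
    ene <- ene + p[i, j]^2
    if (p[i, j] > 0) ent <- ent - p[i, j] * log(p[i, j])
    hom <- hom + p[i, j] / (1 + abs(i - j))
    sym <- sym + abs(p[i, j] - p[j, i])
  }
  cor <- if (vi > 0 && vj > 0) cor / sqrt(vi * vj) else 0
  c(Contrast = con, Correlation = cor, Energy = ene, Entropy = ent,
    Homogeneity = hom, Symmetry = 1 - 0.5 * sym)
}

# run-length counts by collecting each line of the direction and rle-ing it
oracle_glrlm <- function(imgQ, off, Q) {
  nr <- nrow(imgQ); nc <- ncol(imgQ)
  counts <- matrix(0, Q, max(nr, nc))
  for (r0 in seq_len(nr)) {
    for (c0 in seq_len(nc)) {
      rp <- r0 - off[1]; cp <- c0 - off[2]
      if (rp >= 1 && rp <= nr && cp >= 1 && cp <= nc) next  # not a line start
      line <- c(); r <- r0; c <- c0
      while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
        line <- c(line, imgQ[r, c]); r <- r + off[1]; c <- c + off[2]
      }
      runs <- rle(line)
      for (k in seq_along(runs$lengths)) {
        counts[runs$values[k] + 1, runs$lengths[k]] <-
          counts[runs$values[k] + 1, runs$lengths[k]] + 1
      }
    }
  }
  counts
}

oracle_galloway <- function(counts, n_pixels) {
  nr <- sum(counts)
  sre <- 0; lre <- 0
  for (j in seq_len(ncol(counts))) {
    sre <- sre + sum(counts[, j]) / j^2
    lre <- lre + sum(counts[, j]) * j^2
  }
  c(SRE = sre / nr, LRE = lre / nr, GLNU = sum(rowSums(counts)^2) / nr,
    RLNU = sum(colSums(counts)^2) / nr, RP = nr / n_pixels)
}

# AUC by O(n^2) enumeration of all (positive, negative) score pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == "moderate_severe"]
  neg <- scores[labels == "mild"]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

offset_of <- function(direction) {
  switch(direction, "0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
         "135" = c(-1, -1))
}

all_directions <- c("0", "45", "90", "135")

# small cohort config for fast unit tests (32x32 ROIs, 5+5 subjects)
tiny_config <- function(seed = 1, ...) {
  cohort_config(n_mild = 5, n_moderate_severe = 5, seed = seed,
                roi_size = c(32, 32), ...)
}

# feature matrix with the real 800 serialized column names but synthetic
# values: pure noise plus an optional mean shift on given columns
synthetic_feature_matrix <- function(n_mild, n_mod, shift_cols = character(),
                                     shift = 0, seed = 1) {
  uni <- feature_universe()
  set.seed(seed)
  x <- matrix(rnorm((n_mild + n_mod) * nrow(uni)), n_mild + n_mod)
  colnames(x) <- uni$name
  labels <- c(rep("mild", n_mild), rep("moderate_severe", n_mod))
  x[labels == "moderate_severe", shift_cols] <-
    x[labels == "moderate_severe", shift_cols] + shift
  list(x = x, labels = labels)
}
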