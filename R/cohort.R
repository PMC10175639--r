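## Synthetic cohort generator.
##
## Stands in for the clinical acquisition: each subject gets 14 speckle-
## textured B-mode ROIs laid out per the acquisition protocol, one SWE
## elasticity (mean, std) pair per ROI, two side-averaged thicknesses and a
## VAS pain score. Class effects (texture correlation length / speckle shape,
## SWE mean shift, thickness shift) are explicit knobs so that with all
## effects zero the two classes are exchangeable in distribution.

# Table-style demographic moments per class (mild, moderate-severe)
DEMOGRAPHICS <- list(
  mild = list(p_male = 12 / 24, weight = c(65.52, 11.52),
              height = c(1.69, 0.10), age = c(35.96, 7.62)),
  moderate_severe = list(p_male = 15 / 28, weight = c(64.38, 10.82),
                         height = c(1.69, 0.07), age = c(41.11, 10.24)))

#' Configuration for the synthetic cohort generator
#'
#' @param n_mild,n_moderate_severe Class sizes; defaults 24 and 28.
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   config.
#' @param roi_size `c(height, width)` of each ROI in pixels, at least 32x32.
#' @param texture_effect Non-negative class shift of the speckle model:
#'   the moderate-severe class gets correlation lengths scaled by
#'   `1 + texture_effect` and gamma speckle shape scaled by
#'   `1 / (1 + texture_effect)`. 0 makes the classes' images exchangeable.
#' @param swe_effect Additive shift (kPa) of the moderate-severe class's
#'   median SWE elasticity above the mild baseline.
#' @param thickness_effect Reduction (mm) of the moderate-severe class's mean
#'   TLF/TrA thickness.
#' @param noise_scale Positive multiplier on the SWE log-sd, thickness sd and
#'   demographic sds.
#' @param swe_mild_kpa Mild-class median SWE elasticity (kPa).
#' @param swe_sdlog Log-sd of the log-normal SWE elasticity draw.
#' @param axial_corr,lateral_corr Speckle background correlation lengths in
#'   pixels along the axial (column) and lateral (row) directions.
#' @param gamma_shape Shape of the unit-mean multiplicative gamma speckle.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_mild = 24, n_moderate_severe = 28, seed = 1L,
                          roi_size = c(64, 64), texture_effect = 0.15,
                          swe_effect = 6, thickness_effect = 0.3,
                          noise_scale = 1, swe_mild_kpa = 20,
                          swe_sdlog = 0.2, axial_corr = 2, lateral_corr = 4,
                          gamma_shape = 4) {
  cfg <- list(n_mild = as.integer(n_mild),
              n_moderate_severe = as.integer(n_moderate_severe),
              seed = as.integer(seed), roi_size = as.integer(roi_size),
              texture_effect = texture_effect, swe_effect = swe_effect,
              thickness_effect = thickness_effect, noise_scale = noise_scale,
              swe_mild_kpa = swe_mild_kpa, swe_sdlog = swe_sdlog,
              axial_corr = axial_corr, lateral_corr = lateral_corr,
              gamma_shape = gamma_shape)
  class(cfg) <- "cohort_config"
  check_cohort_config(cfg)
  cfg
}

check_cohort_config <- function(cfg) {
  if (length(cfg$roi_size) != 2 || any(cfg$roi_size < 32)) {
    stop("roi_size must be at least 32x32 pixels (got ",
         paste(cfg$roi_size, collapse = "x"), ")")
  }
  if (cfg$n_mild < 1 || cfg$n_moderate_severe < 1) {
    stop("class sizes must be positive")
  }
  if (cfg$texture_effect < 0 || cfg$swe_effect < 0) {
    stop("texture_effect and swe_effect must be non-negative")
  }
  if (cfg$noise_scale <= 0) stop("noise_scale must be positive")
  invisible(cfg)
}

# Gaussian smoothing matrix (n x n, rows L2-normalized) with correlation
# length `len` pixels; identity when len is (near) zero.
smoothing_matrix <- function(n, len) {
  if (len < 1e-8) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-(d^2) / (2 * len^2))
  k / sqrt(rowSums(k^2))
}

#' Generate one speckle-textured B-mode ROI image
#'
#' A smooth anisotropic background (Gaussian-smoothed white noise with
#' configurable axial/lateral correlation lengths) is multiplied by unit-mean
#' gamma-distributed speckle, log-compressed and affinely quantized to
#' 0--255. The moderate-severe class scales both correlation lengths by
#' `1 + texture_effect` and the gamma shape by `1 / (1 + texture_effect)`,
#' so `texture_effect = 0` makes the classes exchangeable. Draws come from
#' R's current RNG stream, so the image is deterministic given the RNG state.
#'
#' @param key A row of [roi_protocol()] (level/side/muscle/position); carried
#'   for provenance, it does not alter the texture model.
#' @param class_label `"mild"` or `"moderate_severe"`.
#' @param config A [cohort_config()].
#' @return Integer matrix in `[0, 255]` of size `config$roi_size`.
#' @export
generate_roi_image <- function(key, class_label, config) {
  check_cohort_config(config)
  h <- config$roi_size[1]
  w <- config$roi_size[2]
  bump <- if (identical(class_label, "moderate_severe")) {
    1 + config$texture_effect
  } else 1
  la <- config$axial_corr * bump
  ll <- config$lateral_corr * bump
  shape <- config$gamma_shape / bump
  kr <- smoothing_matrix(h, la)
  kc <- smoothing_matrix(w, ll)
  z <- kr %*% matrix(rnorm(h * w), h, w) %*% t(kc)
  z <- (z - mean(z)) / max(sd(z), 1e-12)
  field <- exp(0.3 * z)
  speckle <- matrix(rgamma(h * w, shape = shape, rate = shape), h, w)
  compressed <- log1p(3 * field * speckle)
  rng <- range(compressed)
  if (diff(rng) < 1e-12) {
    img <- matrix(0L, h, w)
  } else {
    img <- matrix(as.integer(round(
      (compressed - rng[1]) / diff(rng) * 255)), h, w)
  }
  img
}

#' Generate one subject's full acquisition record
#'
#' Samples demographics near the per-class reference moments (truncated at
#' physiologic bounds), a VAS score uniform on `[1, 3]` for the mild class
#' and on `(3, 8]` for moderate-severe, the 14 protocol ROIs, per-ROI SWE
#' elasticity from a class-shifted log-normal, and two side-averaged
#' thicknesses with a class shift. Uses R's current RNG stream.
#'
#' @param class_label `"mild"` or `"moderate_severe"`.
#' @param config A [cohort_config()].
#' @param subject_id Identifier string.
#' @return A list of class `acq_record` with fields `meta`, `rois` (named
#'   list of 14 ROI samples keyed by `site_id`), `tlf_thickness_mm`,
#'   `tra_thickness_mm`.
#' @export
generate_subject <- function(class_label, config, subject_id = "S000") {
  check_cohort_config(config)
  stopifnot(class_label %in% c("mild", "moderate_severe"))
  dem <- DEMOGRAPHICS[[class_label]]
  ns <- config$noise_scale
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  weight <- clamp(rnorm(1, dem$weight[1], dem$weight[2] * ns), 40, 120)
  height <- clamp(rnorm(1, dem$height[1], dem$height[2] * ns), 1.40, 2.00)
  age <- clamp(rnorm(1, dem$age[1], dem$age[2] * ns), 18, 80)
  sex <- if (rbinom(1, 1, dem$p_male) == 1) "M" else "F"
  vas <- if (class_label == "mild") runif(1, 1, 3) else {
    3 + runif(1) * 5  # open at 3: P(vas == 3) = 0
  }
  meta <- list(subject_id = subject_id, sex = sex, weight_kg = weight,
               height_m = height, bmi = weight / height^2, age_years = age,
               vas = vas, group = if (vas <= 3) "mild" else "moderate_severe")
  swe_shift <- if (class_label == "moderate_severe") config$swe_effect else 0
  swe_median <- config$swe_mild_kpa + swe_shift
  proto <- roi_protocol()
  rois <- lapply(seq_len(nrow(proto)), function(i) {
    key <- proto[i, ]
    img <- generate_roi_image(key, class_label, config)
    swe_mean <- rlnorm(1, meanlog = log(swe_median),
                       sdlog = config$swe_sdlog * ns)
    swe_std <- swe_mean * exp(rnorm(1, log(0.2), 0.25 * ns))
    list(key = key, image = img, swe_mean_kpa = swe_mean,
         swe_std_kpa = swe_std)
  })
  names(rois) <- proto$site_id
  th_shift <- if (class_label == "moderate_severe") {
    config$thickness_effect
  } else 0
  thick <- function(mu, s) max(rnorm(1, mu - th_shift, s * ns), 0.2)
  rec <- list(meta = meta, rois = rois,
              tlf_thickness_mm = thick(2.2, 0.25),
              tra_thickness_mm = thick(4.0, 0.50))
  class(rec) <- "acq_record"
  rec
}

#' Generate a synthetic cohort
#'
#' Produces `n_mild + n_moderate_severe` acquisition records, reproducible
#' from `config$seed` (the caller's RNG state is left untouched).
#'
#' @param config A [cohort_config()].
#' @return A list of `acq_record` of class `sonolbp_cohort`, with the config
#'   attached as attribute `config`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_mild = 5, n_moderate_severe = 5,
#'                                      roi_size = c(32, 32)))
#' length(coh)  # 10
generate_cohort <- function(config) {
  check_cohort_config(config)
  if (config$n_mild < 5 || config$n_moderate_severe < 5) {
    stop("cohort too small for stratified 5-fold cross-validation: ",
         "each class needs at least 5 subjects (got ", config$n_mild,
         " mild, ", config$n_moderate_severe, " moderate-severe)")
  }
  labels <- c(rep("mild", config$n_mild),
              rep("moderate_severe", config$n_moderate_severe))
  ids <- sprintf("S%03d", seq_along(labels))
  cohort <- local_seed(config$seed, {
    lapply(seq_along(labels), function(i) {
      generate_subject(labels[i], config, subject_id = ids[i])
    })
  })
  names(cohort) <- ids
  attr(cohort, "config") <- config
  class(cohort) <- "sonolbp_cohort"
  cohort
}

#' Validate an acquisition record against the protocol
#'
#' Checks the 14-ROI layout, 8-bit image range, VAS/group consistency and
#' BMI identity.
#'
#' @param rec An `acq_record`.
#' @return `TRUE` invisibly; stops with a message on the first violation.
#' @export
validate_record <- function(rec) {
  proto <- roi_protocol()
  if (!setequal(names(rec$rois), proto$site_id) ||
      length(rec$rois) != 14L) {
    stop("record must hold exactly the 14 protocol ROIs; missing: ",
         paste(setdiff(proto$site_id, names(rec$rois)), collapse = ", "))
  }
  for (s in rec$rois) {
    img <- s$image
    if (!all(img == floor(img)) || min(img) < 0 || max(img) > 255) {
      stop("ROI image values must be integers in [0, 255]")
    }
    if (any(dim(img) < 32)) stop("ROI image smaller than 32x32")
    if (s$swe_mean_kpa <= 0 || s$swe_std_kpa < 0) {
      stop("invalid SWE values for ", s$key$site_id)
    }
  }
  m <- rec$meta
  grp <- if (m$vas <= 3) "mild" else "moderate_severe"
  if (!identical(m$group, grp)) stop("group label inconsistent with VAS")
  if (abs(m$bmi - m$weight_kg / m$height_m^2) > 1e-9) {
    stop("BMI inconsistent with weight/height")
  }
  if (rec$tlf_thickness_mm <= 0 || rec$tra_thickness_mm <= 0) {
    stop("thicknesses must be positive")
  }
  invisible(TRUE)
}

#' Write a cohort to disk as PNG images plus a CSV manifest
#'
#' Each ROI goes to `{subject_id}_{level}_{side}_{muscle}_{position}.png`
#' (8-bit grayscale); the manifest has one row per subject with demographics,
#' thicknesses and per-ROI SWE columns.
#'
#' @param cohort A `sonolbp_cohort`.
#' @param dir Output directory (created if absent).
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  proto <- roi_protocol()
  rows <- lapply(cohort, function(rec) {
    m <- rec$meta
    row <- data.frame(subject_id = m$subject_id, sex = m$sex,
                      weight_kg = m$weight_kg, height_m = m$height_m,
                      bmi = m$bmi, age_years = m$age_years, vas = m$vas,
                      group = m$group,
                      tlf_thickness_mm = rec$tlf_thickness_mm,
                      tra_thickness_mm = rec$tra_thickness_mm,
                      stringsAsFactors = FALSE)
    for (sid in proto$site_id) {
      s <- rec$rois[[sid]]
      png::writePNG(s$image / 255,
                    file.path(dir, paste0(m$subject_id, "_", sid, ".png")))
      row[[paste0(sid, "_swe_mean")]] <- s$swe_mean_kpa
      row[[paste0(sid, "_swe_std")]] <- s$swe_std_kpa
    }
    row
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.csv` and the ROI PNGs.
#' @return A `sonolbp_cohort` (without a generator config attribute).
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE, check.names = FALSE)
  proto <- roi_protocol()
  cohort <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    rois <- lapply(proto$site_id, function(sid) {
      img <- png::readPNG(file.path(dir, paste0(row$subject_id, "_", sid,
                                                ".png")))
      if (length(dim(img)) == 3) img <- img[, , 1]
      list(key = proto[proto$site_id == sid, ],
           image = matrix(as.integer(round(img * 255)), nrow(img), ncol(img)),
           swe_mean_kpa = row[[paste0(sid, "_swe_mean")]],
           swe_std_kpa = row[[paste0(sid, "_swe_std")]])
    })
    names(rois) <- proto$site_id
    rec <- list(meta = list(subject_id = row$subject_id, sex = row$sex,
                            weight_kg = row$weight_kg,
                            height_m = row$height_m, bmi = row$bmi,
                            age_years = row$age_years, vas = row$vas,
                            group = row$group),
                rois = rois, tlf_thickness_mm = row$tlf_thickness_mm,
                tra_thickness_mm = row$tra_thickness_mm)
    class(rec) <- "acq_record"
    rec
  })
  names(cohort) <- manifest$subject_id
  class(cohort) <- "sonolbp_cohort"
  cohort
}
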