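## Feature assembly: 57 features per ROI (2 MFAF + 7 FOS + 24 Haralick +
## 20 Galloway + 2 LBP + 2 SWE), 14 ROIs per subject, plus the 2 side-averaged
## thickness features = the 800-feature subject vector.

#' Side-averaged muscle thickness
#'
#' @param left_mm,right_mm Positive thicknesses (mm) of the left and right
#'   side.
#' @return Their arithmetic mean.
#' @export
thickness_feature <- function(left_mm, right_mm) {
  if (left_mm <= 0 || right_mm <= 0) stop("thicknesses must be positive")
  (left_mm + right_mm) / 2
}

#' Extract the 57 features of one ROI
#'
#' @param sample An ROI sample: list with `image` (8-bit matrix),
#'   `swe_mean_kpa`, `swe_std_kpa`.
#' @param levels Gray levels Q for GLCM/GLRLM quantization.
#' @param burg_order,n_tapers Spectral estimator settings, see [mfaf()].
#' @return Named numeric vector of length 57; names are
#'   `family.statistic[.qualifier]` slot keys matching
#'   the per-ROI feature table.
#' @export
extract_roi_features <- function(sample, levels = 32, burg_order = 8,
                                 n_tapers = 4) {
  img <- sample$image
  imgQ <- quantize_image(img, levels)
  out <- c(
    mfaf.MFAF.maxent = mfaf(img, "maxent", burg_order = burg_order),
    mfaf.MFAF.multiwindow = mfaf(img, "multiwindow", n_tapers = n_tapers))
  fos <- fos_features(img)
  names(fos) <- paste0("fos.", names(fos))
  out <- c(out, fos)
  for (stat in HARALICK_STATS) {
    for (d in DIRECTIONS) {
      out[paste0("haralick.", stat, ".", d)] <- NA_real_
    }
  }
  for (stat in GALLOWAY_STATS) {
    for (d in DIRECTIONS) {
      out[paste0("galloway.", stat, ".", d)] <- NA_real_
    }
  }
  for (d in DIRECTIONS) {
    h <- haralick_features(glcm(imgQ, d, levels))
    out[paste0("haralick.", names(h), ".", d)] <- h
    g <- galloway_features(glrlm(imgQ, d, levels))
    out[paste0("galloway.", names(g), ".", d)] <- g
  }
  lbp <- lbp_features(img)
  names(lbp) <- paste0("lbp.", names(lbp))
  swe <- c(swe.Mean = sample$swe_mean_kpa, swe.Std = sample$swe_std_kpa)
  c(out, lbp, swe)
}

# slot key ("family.statistic[.qualifier]") for universe rows
slot_key <- function(universe) {
  ifelse(is.na(universe$qualifier),
         paste(universe$family, universe$statistic, sep = "."),
         paste(universe$family, universe$statistic, universe$qualifier,
               sep = "."))
}

#' Assemble a subject's 800-feature vector
#'
#' Computes the 57 features for each of the 14 protocol ROIs and appends the
#' two thickness features, in the canonical order of [feature_universe()].
#'
#' @param rec An `acq_record`.
#' @inheritParams extract_roi_features
#' @return Named numeric vector of length 800 (serialized feature names).
#' @export
assemble_subject_vector <- function(rec, levels = 32, burg_order = 8,
                                    n_tapers = 4) {
  proto <- roi_protocol()
  missing <- setdiff(proto$site_id, names(rec$rois))
  if (length(missing) > 0) {
    stop("record is missing protocol ROI(s): ",
         paste(missing, collapse = ", "))
  }
  uni <- feature_universe()
  ix <- get0("universe_index", envir = .sonolbp_cache)
  if (is.null(ix)) {
    site <- paste(uni$level, uni$side, uni$muscle, uni$position, sep = "_")
    ix <- list(keys = slot_key(uni),
               site_idx = lapply(proto$site_id, function(s) which(site == s)))
    names(ix$site_idx) <- proto$site_id
    assign("universe_index", ix, envir = .sonolbp_cache)
  }
  out <- numeric(nrow(uni))
  names(out) <- uni$name
  for (sid in proto$site_id) {
    f <- extract_roi_features(rec$rois[[sid]], levels = levels,
                              burg_order = burg_order, n_tapers = n_tapers)
    idx <- ix$site_idx[[sid]]
    out[idx] <- f[ix$keys[idx]]
  }
  # record thicknesses are already side-averaged (see thickness_feature)
  thick <- uni$family == "morphological"
  out[thick & uni$muscle == "TLF"] <- rec$tlf_thickness_mm
  out[thick & uni$muscle == "TrA"] <- rec$tra_thickness_mm
  out
}

#' Extract the feature table of a whole cohort
#'
#' @param cohort A `sonolbp_cohort` (or list of `acq_record`).
#' @inheritParams extract_roi_features
#' @return A data.frame with `subject_id`, `group`, `vas` and the 800
#'   serialized feature columns (one row per subject).
#' @export
extract_cohort_features <- function(cohort, levels = 32, burg_order = 8,
                                    n_tapers = 4) {
  mats <- t(vapply(cohort, assemble_subject_vector,
                   numeric(nrow(feature_universe())),
                   levels = levels, burg_order = burg_order,
                   n_tapers = n_tapers))
  meta <- data.frame(
    subject_id = vapply(cohort, function(r) r$meta$subject_id, ""),
    group = vapply(cohort, function(r) r$meta$group, ""),
    vas = vapply(cohort, function(r) r$meta$vas, 0),
    stringsAsFactors = FALSE)
  out <- cbind(meta, as.data.frame(mats, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Feature column names of a cohort feature table
#'
#' @param features A data.frame from [extract_cohort_features()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(features) {
  setdiff(names(features), c("subject_id", "group", "vas"))
}

#' Numeric feature matrix of a cohort feature table
#'
#' @inheritParams feature_columns
#' @return Numeric matrix (subjects x features) with serialized column names.
#' @export
feature_matrix <- function(features) {
  as.matrix(features[, feature_columns(features), drop = FALSE])
}
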