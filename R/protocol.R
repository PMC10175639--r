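## Acquisition protocol and feature identity.
##
## The protocol images four structures -- multifidus (MF), erector spinae
## (ES), thoracolumbar fascia (TLF) and transversus abdominis (TrA) -- on both
## sides of the spine. MF is imaged at the L2-L3 and L4-L5 levels in both the
## prone and tabletop positions (8 images); ES, TLF and TrA are imaged at
## L2-L3 in the prone position only (6 images), giving 14 regions of interest
## per subject. Each ROI also carries a shear-wave-elastography (SWE)
## mean/std pair, and TLF/TrA contribute one side-averaged thickness each.

LEVELS    <- c("L2-L3", "L4-L5")
SIDES     <- c("L", "R")
MUSCLES   <- c("MF", "ES", "TLF", "TrA")
POSITIONS <- c("prone", "tabletop")
FAMILIES  <- c("morphological", "mfaf", "fos", "haralick", "galloway",
               "lbp", "swe")
DIRECTIONS <- c("0", "45", "90", "135")
MFAF_METHODS <- c("maxent", "multiwindow")

FOS_STATS      <- c("IOD", "Mean", "Std", "Variance", "Skewness",
                    "Kurtosis", "Energy")
HARALICK_STATS <- c("Contrast", "Correlation", "Energy", "Entropy",
                    "Homogeneity", "Symmetry")
GALLOWAY_STATS <- c("SRE", "LRE", "GLNU", "RLNU", "RP")
LBP_STATS      <- c("Energy", "Entropy")
SWE_STATS      <- c("Mean", "Std")

# display token per family, used by the Table-style serialized name
FAMILY_TOKEN <- c(morphological = "Morphological",
                  mfaf          = "MFAF",
                  fos           = "FirstOrderFeature",
                  haralick      = "HaralickFeature",
                  galloway      = "GallowayFeature",
                  lbp           = "LBPFeature",
                  swe           = "SWE")

MFAF_METHOD_LABEL <- c(maxent = "maximum entropy",
                       multiwindow = "multi-window")

#' The 14-ROI acquisition protocol
#'
#' Returns one row per imaged region of interest: MF at both lumbar levels,
#' both sides and both positions; ES, TLF and TrA at L2-L3, both sides,
#' prone position only.
#'
#' @return A data.frame with columns `level`, `side`, `muscle`, `position`
#'   and `site_id` (e.g. `"L2-L3_L_MF_prone"`), 14 rows in canonical order.
#' @export
#' @examples
#' nrow(roi_protocol())  # 14
roi_protocol <- function() {
  rows <- list()
  for (level in LEVELS) {
    for (side in SIDES) {
      for (muscle in MUSCLES) {
        for (position in POSITIONS) {
          ok <- (muscle == "MF") ||
            (level == "L2-L3" && position == "prone")
          if (muscle != "MF" && level == "L4-L5") ok <- FALSE
          if (ok) {
            rows[[length(rows) + 1L]] <-
              data.frame(level = level, side = side, muscle = muscle,
                         position = position, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$level, LEVELS), match(out$side, SIDES),
                   match(out$muscle, MUSCLES),
                   match(out$position, POSITIONS)), , drop = FALSE]
  out$site_id <- paste(out$level, out$side, out$muscle, out$position,
                       sep = "_")
  rownames(out) <- NULL
  out
}

# 57 per-ROI feature slots (family, statistic, qualifier), canonical order.
roi_feature_slots <- function() {
  slot <- function(family, statistic, qualifier = NA_character_) {
    data.frame(family = family, statistic = statistic,
               qualifier = qualifier, stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in MFAF_METHODS) out[[length(out) + 1L]] <- slot("mfaf", "MFAF", m)
  for (s in FOS_STATS) out[[length(out) + 1L]] <- slot("fos", s)
  for (s in HARALICK_STATS) {
    for (d in DIRECTIONS) out[[length(out) + 1L]] <- slot("haralick", s, d)
  }
  for (s in GALLOWAY_STATS) {
    for (d in DIRECTIONS) out[[length(out) + 1L]] <- slot("galloway", s, d)
  }
  for (s in LBP_STATS) out[[length(out) + 1L]] <- slot("lbp", s)
  for (s in SWE_STATS) out[[length(out) + 1L]] <- slot("swe", s)
  do.call(rbind, out)
}

#' Serialize a feature identity to its display name
#'
#' Produces names in the reporting style used throughout the package, e.g.
#' `"L4-L5_L_MF_FirstOrderFeature.IOD (prone position)"`,
#' `"L2-L3_R_TLF_HaralickFeature.Homogeneity (prone position, direction = 90°)"`
#' or `"L2-L3_R_TLF_MFAF (prone position, calculated by multi-window method)"`.
#'
#' @param level,side,muscle,position,family,statistic,qualifier character
#'   vectors (recycled) describing the feature; `qualifier` is a direction
#'   (`"0"`, `"45"`, `"90"`, `"135"`) for haralick/galloway features, a
#'   method (`"maxent"`, `"multiwindow"`) for mfaf, and `NA` otherwise.
#' @return Character vector of serialized names.
#' @export
format_feature_name <- function(level, side, muscle, position, family,
                                statistic, qualifier = NA_character_) {
  n <- max(length(level), length(side), length(muscle), length(position),
           length(family), length(statistic), length(qualifier))
  args <- data.frame(level = rep_len(level, n), side = rep_len(side, n),
                     muscle = rep_len(muscle, n),
                     position = rep_len(position, n),
                     family = rep_len(family, n),
                     statistic = rep_len(statistic, n),
                     qualifier = rep_len(as.character(qualifier), n),
                     stringsAsFactors = FALSE)
  token <- FAMILY_TOKEN[args$family]
  stem <- ifelse(args$family == "mfaf", paste0(token),
                 paste0(token, ".", args$statistic))
  qual <- rep("", n)
  dirfam <- args$family %in% c("haralick", "galloway")
  qual[dirfam] <- sprintf(", direction = %s°", args$qualifier[dirfam])
  mfaf <- args$family == "mfaf"
  qual[mfaf] <- sprintf(", calculated by %s method",
                        MFAF_METHOD_LABEL[args$qualifier[mfaf]])
  sprintf("%s_%s_%s_%s (%s position%s)", args$level, args$side, args$muscle,
          stem, args$position, qual)
}

#' Parse serialized feature names back to their components
#'
#' Inverse of [format_feature_name()].
#'
#' @param names Character vector of serialized feature names.
#' @return A data.frame with columns `level`, `side`, `muscle`, `position`,
#'   `family`, `statistic`, `qualifier` and `name`.
#' @export
parse_feature_name <- function(names) {
  pat <- paste0("^(L2-L3|L4-L5)_(L|R|global)_(MF|ES|TLF|TrA)_",
                "([A-Za-z]+)(?:\\.([A-Za-z]+))? ",
                "\\((prone|tabletop) position",
                "(?:, direction = ([0-9]+)°)?",
                "(?:, calculated by (maximum entropy|multi-window) method)?\\)$")
  m <- regmatches(names, regexec(pat, names))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unparseable feature name(s): ",
         paste(utils::head(names[bad], 3), collapse = "; "))
  }
  parts <- do.call(rbind, lapply(m, function(x) x[-1]))
  token <- parts[, 4]
  fam <- names(FAMILY_TOKEN)[match(token, FAMILY_TOKEN)]
  if (anyNA(fam)) {
    stop("unknown feature family token: ",
         paste(unique(token[is.na(fam)]), collapse = ", "))
  }
  statistic <- ifelse(fam == "mfaf", "MFAF", parts[, 5])
  qualifier <- rep(NA_character_, length(names))
  qualifier[fam %in% c("haralick", "galloway")] <-
    parts[fam %in% c("haralick", "galloway"), 7]
  mfaf <- fam == "mfaf"
  qualifier[mfaf] <- names(MFAF_METHOD_LABEL)[
    match(parts[mfaf, 8], MFAF_METHOD_LABEL)]
  data.frame(level = parts[, 1], side = parts[, 2], muscle = parts[, 3],
             position = parts[, 6], family = fam, statistic = statistic,
             qualifier = qualifier, name = names, stringsAsFactors = FALSE)
}

#' The 800-name feature universe
#'
#' Enumerates every feature a protocol-complete subject yields: 57 features
#' for each of the 14 ROIs (2 spectral mean-frequency, 7 first-order, 24
#' Haralick, 20 Galloway, 2 local-binary-pattern, 2 SWE) plus the 2
#' side-averaged thickness features of TLF and TrA. Thickness features are
#' measured at L2-L3 in the prone position and are side-global, which is how
#' they are tallied in the attribution tables.
#'
#' @return A data.frame of 800 rows in canonical order (level, side, muscle,
#'   position, family, statistic, qualifier) with a serialized `name` column.
#' @export
#' @examples
#' nrow(feature_universe())  # 800
feature_universe <- function() {
  cached <- get0("universe", envir = .sonolbp_cache)
  if (!is.null(cached)) return(cached)
  proto <- roi_protocol()
  slots <- roi_feature_slots()
  per_roi <- do.call(rbind, lapply(seq_len(nrow(proto)), function(i) {
    cbind(proto[rep(i, nrow(slots)), c("level", "side", "muscle", "position")],
          slots, row.names = NULL)
  }))
  thick <- data.frame(level = "L2-L3", side = "global",
                      muscle = c("TLF", "TrA"), position = "prone",
                      family = "morphological", statistic = "Thickness",
                      qualifier = NA_character_, stringsAsFactors = FALSE)
  uni <- rbind(per_roi, thick)
  stat_rank <- function(fam, stat) {
    ord <- c("morphological Thickness", "mfaf MFAF",
             paste("fos", FOS_STATS), paste("haralick", HARALICK_STATS),
             paste("galloway", GALLOWAY_STATS), paste("lbp", LBP_STATS),
             paste("swe", SWE_STATS))
    match(paste(fam, stat), ord)
  }
  qual_rank <- ifelse(is.na(uni$qualifier), 0L,
                      ifelse(uni$qualifier %in% DIRECTIONS,
                             match(uni$qualifier, DIRECTIONS),
                             match(uni$qualifier, MFAF_METHODS)))
  uni <- uni[order(match(uni$level, LEVELS),
                   match(uni$side, c(SIDES, "global")),
                   match(uni$muscle, MUSCLES),
                   match(uni$position, POSITIONS),
                   match(uni$family, FAMILIES),
                   stat_rank(uni$family, uni$statistic),
                   qual_rank), , drop = FALSE]
  uni$name <- format_feature_name(uni$level, uni$side, uni$muscle,
                                  uni$position, uni$family, uni$statistic,
                                  uni$qualifier)
  rownames(uni) <- NULL
  assign("universe", uni, envir = .sonolbp_cache)
  uni
}
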