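#' Integer class codes used in segmentation label masks
#'
#' Single-channel masks code pixels as 0 = background (no tissue),
#' 1 = BrdU-negative granulosa, 2 = BrdU-positive granulosa, 3 = antrum,
#' 4 = oocyte.
#'
#' @format Named integer vector of length 5.
#' @export
MASK_CLASSES <- c(background = 0L, brdu_neg = 1L, brdu_pos = 2L,
                  antrum = 3L, oocyte = 4L)

#' Class-area quantification of a mask region
#'
#' Container for the BrdU-positive and BrdU-negative granulosa areas (and the
#' area of all other classes) measured inside a region of interest.
#'
#' @param area_brdu_positive,area_brdu_negative Granulosa areas, um^2 (>= 0).
#' @param area_other_classes Area of antrum + oocyte + background inside the
#'   ROI, um^2 (excluded from the LI).
#' @param pixel_size Pixel edge length, um/pixel.
#' @return Object of class `mask_quantification`.
#' @export
mask_quantification <- function(area_brdu_positive, area_brdu_negative,
                                area_other_classes = 0, pixel_size = 1) {
  stopifnot(area_brdu_positive >= 0, area_brdu_negative >= 0,
            area_other_classes >= 0, pixel_size > 0)
  structure(list(area_brdu_positive = area_brdu_positive,
                 area_brdu_negative = area_brdu_negative,
                 area_other_classes = area_other_classes,
                 pixel_size = pixel_size),
            class = "mask_quantification")
}

#' BrdU labeling index from quantified areas
#'
#' \eqn{LI = A_{BrdU+} / (A_{BrdU+} + A_{BrdU-})}: the area fraction of
#' BrdU-labeled granulosa inside the ROI. Invariant to rescaling both areas
#' (hence to pixel size).
#'
#' @param q A [mask_quantification()] object.
#' @return LI fraction in \[0, 1\].
#' @export
labeling_index <- function(q) {
  stopifnot(inherits(q, "mask_quantification"))
  total <- q$area_brdu_positive + q$area_brdu_negative
  if (total <= 0)
    stop("labeling index undefined: no granulosa area in the region of interest")
  q$area_brdu_positive / total
}

#' Region of interest around a follicle
#'
#' A closed polygon following the basal lamina, plus zero or more exclusion
#' polygons that excise the cumulus granulosa from the measurement. Polygons
#' are n x 2 matrices of (x, y) vertices in um; they are treated as closed
#' (last vertex joins the first). Vertices must be finite; polygons are
#' assumed simple (non-self-intersecting).
#'
#' @param basal_lamina n x 2 numeric matrix (n >= 3).
#' @param cumulus_exclusions List of n x 2 numeric matrices.
#' @return Object of class `region_of_interest`.
#' @export
region_of_interest <- function(basal_lamina, cumulus_exclusions = list()) {
  check_poly <- function(p, what) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3 || any(!is.finite(p)))
      stop(what, " must be a finite n x 2 matrix with n >= 3")
    p
  }
  basal_lamina <- check_poly(basal_lamina, "basal_lamina polygon")
  cumulus_exclusions <- lapply(cumulus_exclusions, check_poly,
                               what = "cumulus exclusion polygon")
  structure(list(basal_lamina = basal_lamina,
                 cumulus_exclusions = cumulus_exclusions),
            class = "region_of_interest")
}

#' Quantify class areas of a label mask inside a region of interest
#'
#' Sums per-class pixel areas inside the basal-lamina polygon, minus any
#' cumulus exclusion polygons. Pixel (i, j) (row i, column j) is counted
#' through its centre at x = (j - 0.5), y = (i - 0.5) pixels, scaled by
#' `pixel_size`. Only classes 1 (BrdU-) and 2 (BrdU+) contribute to the LI
#' areas; antrum, oocyte and background are pooled into `area_other_classes`.
#'
#' @param mask Integer matrix with values in [MASK_CLASSES], or path to a
#'   grayscale PNG written by [write_mask_png()].
#' @param roi A [region_of_interest()] (coordinates in um).
#' @param pixel_size Pixel edge length, um/pixel.
#' @return A [mask_quantification()] object (areas in um^2).
#' @export
quantify_mask <- function(mask, roi, pixel_size = 1) {
  if (is.character(mask)) mask <- read_mask_png(mask)
  stopifnot(is.matrix(mask), inherits(roi, "region_of_interest"),
            pixel_size > 0)
  codes <- sort(unique(as.integer(mask)))
  unknown <- setdiff(codes, unname(MASK_CLASSES))
  if (length(unknown) > 0)
    stop("unknown mask class code(s): ", paste(unknown, collapse = ", "))
  w_um <- ncol(mask) * pixel_size
  h_um <- nrow(mask) * pixel_size
  polys <- c(list(roi$basal_lamina), roi$cumulus_exclusions)
  for (p in polys) {
    if (any(p[, 1] < 0) || any(p[, 1] > w_um) ||
        any(p[, 2] < 0) || any(p[, 2] > h_um))
      stop("ROI polygon extends outside the image bounds")
  }
  x <- (rep(seq_len(ncol(mask)), each = nrow(mask)) - 0.5) * pixel_size
  y <- (rep(seq_len(nrow(mask)), times = ncol(mask)) - 0.5) * pixel_size
  inside <- pracma::inpolygon(x, y, roi$basal_lamina[, 1], roi$basal_lamina[, 2])
  for (p in roi$cumulus_exclusions)
    inside <- inside & !pracma::inpolygon(x, y, p[, 1], p[, 2])
  cls <- as.integer(mask)[inside]
  px_area <- pixel_size^2
  mask_quantification(
    area_brdu_positive = sum(cls == MASK_CLASSES[["brdu_pos"]]) * px_area,
    area_brdu_negative = sum(cls == MASK_CLASSES[["brdu_neg"]]) * px_area,
    area_other_classes = sum(cls %in% MASK_CLASSES[c("background", "antrum",
                                                     "oocyte")]) * px_area,
    pixel_size = pixel_size
  )
}

#' Pseudodiameter of a follicle cross-section
#'
#' Diameter of the circle whose area equals the measured maximal
#' cross-sectional area: \eqn{D = 2\sqrt{A/\pi}}.
#'
#' @param cross_sectional_area Area(s), um^2 (>= 0).
#' @return Pseudodiameter(s), um.
#' @examples
#' pseudodiameter(pi * 50^2)  # 100
#' @export
pseudodiameter <- function(cross_sectional_area) {
  if (any(!is.finite(cross_sectional_area)) || any(cross_sectional_area < 0))
    stop("cross_sectional_area must be finite and >= 0")
  2 * sqrt(cross_sectional_area / pi)
}

#' Serial-section profile of one follicle
#'
#' The ordered (section index, cross-sectional area) profile of a follicle in
#' a serial-section series. The 2-h pulse-chase design uses 75 consecutive
#' 5-um sections (interval 1); the 48-h design samples every 25th section
#' (125-um intervals).
#'
#' @param section_index Strictly increasing integer section indices.
#' @param area Cross-sectional areas, um^2 (>= 0), same length.
#' @param section_thickness Section thickness, um (> 0; default 5).
#' @param sampling_interval Sections between consecutive samples (default 1).
#' @return Object of class `section_series` (a data frame with attributes).
#' @export
section_series <- function(section_index, area, section_thickness = 5,
                           sampling_interval = 1) {
  stopifnot(length(section_index) == length(area),
            length(section_index) >= 1,
            all(area >= 0), section_thickness > 0, sampling_interval >= 1)
  if (any(diff(section_index) <= 0))
    stop("section indices must be strictly increasing")
  out <- data.frame(section_index = as.integer(section_index), area = area)
  attr(out, "section_thickness") <- section_thickness
  attr(out, "sampling_interval") <- sampling_interval
  class(out) <- c("section_series", "data.frame")
  out
}

#' Widest section of a follicle profile
#'
#' Entry with the maximal cross-sectional area; ties are broken in favour of
#' the lowest section index.
#'
#' @param series A [section_series()].
#' @return List with `section_index` and `area`.
#' @export
widest_section <- function(series) {
  stopifnot(inherits(series, "section_series"), nrow(series) >= 1)
  i <- which.max(series$area)  # first maximum = lowest index (rows are ordered)
  list(section_index = series$section_index[i], area = series$area[i])
}

#' Serial-section inclusion rule
#'
#' A follicle is excluded when its widest observed section is the first or the
#' last section of the sampled series, because the true widest point could
#' then lie outside the sampling volume.
#'
#' @param series A [section_series()].
#' @return `TRUE` if the follicle is measurable (widest point interior to the
#'   series), `FALSE` if it must be excluded.
#' @export
include_follicle <- function(series) {
  w <- widest_section(series)
  !(w$section_index == series$section_index[1] ||
      w$section_index == series$section_index[nrow(series)])
}

#' Classify follicle atresia from the five morphological criteria
#'
#' A follicle is atretic if it exhibits any of: pyknotic nuclei accumulated in
#' the antrum, a non-contiguous cumulus layer, a pleated/wrinkled oocyte
#' membrane, a pyknotic oocyte nucleus, or separation of the oocyte from the
#' zona pellucida; non-atretic only if none are present.
#'
#' @param x Either a data frame containing the five logical columns
#'   `atresia_pyknotic_antrum`, `atresia_noncontiguous_cumulus`,
#'   `atresia_pleated_oocyte_membrane`, `atresia_pyknotic_oocyte_nucleus`,
#'   `atresia_zona_separation`, or a logical vector/matrix giving the first
#'   flag (with the remaining four supplied via `...`).
#' @param ... Remaining four logical flag vectors when `x` is a vector.
#' @return Factor with levels `non_atretic`, `atretic`.
#' @export
classify_atresia <- function(x, ...) {
  if (is.data.frame(x)) {
    missing_cols <- setdiff(ATRESIA_FLAGS, names(x))
    if (length(missing_cols) > 0)
      stop("missing atresia flag column(s): ", paste(missing_cols, collapse = ", "))
    flags <- as.matrix(x[ATRESIA_FLAGS])
  } else {
    rest <- list(...)
    if (length(rest) != 4)
      stop("all five atresia criterion flags are required")
    flags <- cbind(x, rest[[1]], rest[[2]], rest[[3]], rest[[4]])
  }
  if (!is.logical(flags) || anyNA(flags))
    stop("atresia flags must be non-missing logicals")
  factor(ifelse(rowSums(flags) > 0, "atretic", "non_atretic"),
         levels = c("non_atretic", "atretic"))
}

#' @rdname classify_atresia
#' @format NULL
#' @export
ATRESIA_FLAGS <- c("atresia_pyknotic_antrum", "atresia_noncontiguous_cumulus",
                   "atresia_pleated_oocyte_membrane",
                   "atresia_pyknotic_oocyte_nucleus",
                   "atresia_zona_separation")

#' Assign the developmental stage of a follicle from its diameter
#'
#' Stages partition diameters above 80 um: preantral/secondary \[80, 130),
#' FSH-sensitive \[130, 170), FSH-dependent \[170, 350\], preovulatory
#' (> 350, strictly). Diameters below 80 um are labelled `sub_threshold`.
#' Boundaries follow the lower-inclusive convention except the preovulatory
#' cut-off, which is strict.
#'
#' @param diameter Diameter(s), um (> 0).
#' @param thresholds A [stage_thresholds()] object.
#' @return Factor with levels `sub_threshold`, `preantral`, `fsh_sensitive`,
#'   `fsh_dependent`, `preovulatory`.
#' @export
assign_stage <- function(diameter, thresholds = stage_thresholds()) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("diameter must be finite and > 0")
  out <- character(length(diameter))
  out[diameter < thresholds$preantral[1]] <- "sub_threshold"
  out[diameter >= thresholds$preantral[1] &
        diameter < thresholds$preantral[2]] <- "preantral"
  out[diameter >= thresholds$fsh_sensitive[1] &
        diameter < thresholds$fsh_sensitive[2]] <- "fsh_sensitive"
  out[diameter >= thresholds$fsh_dependent[1] &
        diameter <= thresholds$fsh_dependent[2]] <- "fsh_dependent"
  out[diameter > thresholds$preovulatory_min] <- "preovulatory"
  factor(out, levels = c("sub_threshold", "preantral", "fsh_sensitive",
                         "fsh_dependent", "preovulatory"))
}
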