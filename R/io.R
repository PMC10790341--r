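#' Write / read an integer-coded label mask as a grayscale PNG
#'
#' Class codes (see [MASK_CLASSES]) are stored in the 8-bit gray channel as
#' `code / 255`, so the round trip is exact.
#'
#' @param mask Integer matrix of class codes.
#' @param path Output PNG path.
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns the integer class matrix.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask %in% 0:255))
  png::writePNG(mask / 255, target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow = nrow(img))
}

#' Write / read a region of interest as a JSON sidecar
#'
#' Polygons are stored as arrays of \[x, y\] coordinate pairs (um) under keys
#' `basal_lamina` and `cumulus_exclusions`.
#'
#' @param roi A [region_of_interest()].
#' @param path JSON path.
#' @return `write_roi_json()` returns `path` invisibly; `read_roi_json()`
#'   returns a [region_of_interest()].
#' @export
write_roi_json <- function(roi, path) {
  stopifnot(inherits(roi, "region_of_interest"))
  jsonlite::write_json(
    list(basal_lamina = unname(roi$basal_lamina),
         cumulus_exclusions = lapply(roi$cumulus_exclusions, unname)),
    path, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path)
  to_mat <- function(poly) do.call(rbind, lapply(poly, function(pt)
    as.numeric(unlist(pt))))
  excl <- obj$cumulus_exclusions
  if (is.null(excl)) excl <- list()
  region_of_interest(to_mat(obj$basal_lamina), lapply(excl, to_mat))
}

#' Normalise a table of follicle observations
#'
#' Accepts the CSV schema of the pipeline (one row per follicle) and fills in
#' derivable columns: `pseudodiameter` from `area_um2` when absent, the
#' `atresia` classification from the five criterion flags, and `included =
#' TRUE` when unstated. Rows failing validation are reported by row number.
#'
#' @param records Data frame with at least `pseudodiameter` (um) or `area_um2`
#'   (um^2) and `labeling_index`; optionally `follicle_id`, `animal_id`,
#'   `cycle_stage`, the five `atresia_*` flags, `atresia`, `included`.
#' @return The normalised data frame.
#' @export
as_follicle_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (!"pseudodiameter" %in% names(records)) {
    if (!"area_um2" %in% names(records))
      stop("records need a 'pseudodiameter' or 'area_um2' column")
    records$pseudodiameter <- pseudodiameter(records$area_um2)
  }
  if (!"labeling_index" %in% names(records))
    stop("records need a 'labeling_index' column")
  if (!"follicle_id" %in% names(records))
    records$follicle_id <- sprintf("f%04d", seq_len(nrow(records)))
  if (!"atresia" %in% names(records)) {
    records$atresia <- if (all(ATRESIA_FLAGS %in% names(records))) {
      classify_atresia(records)
    } else {
      factor(rep("non_atretic", nrow(records)),
             levels = c("non_atretic", "atretic"))
    }
  }
  if (!"included" %in% names(records)) records$included <- TRUE
  bad <- which(!is.finite(records$pseudodiameter) | records$pseudodiameter <= 0 |
                 !is.finite(records$labeling_index) |
                 records$labeling_index < 0 | records$labeling_index > 1)
  if (length(bad) > 0)
    stop("invalid follicle record(s) at row(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         " (pseudodiameter must be > 0 and labeling_index in [0, 1])")
  records
}

#' Read / write follicle observation tables as CSV
#'
#' UTF-8, comma-separated, header required; diameters in um, LIs as fractions.
#'
#' @param path CSV path.
#' @param records Data frame of follicle records.
#' @return `read_follicle_csv()` returns a normalised data frame.
#' @export
read_follicle_csv <- function(path) {
  as_follicle_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_follicle_csv
#' @export
write_follicle_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort scenario from YAML
#'
#' The YAML either lists starting follicles inline (`starting_follicles:` a
#' list of `{diameter, li}` maps) or references a population CSV
#' (`population_csv:`, whose non-atretic records supply diameter and LI).
#' Remaining keys (`cohort_target`, `preovulatory_min`, `max_days`) are passed
#' to [cohort_scenario()].
#'
#' @param path YAML path.
#' @param base_dir Directory against which a relative `population_csv` is
#'   resolved (defaults to the YAML's directory).
#' @return A [cohort_scenario()].
#' @export
read_scenario <- function(path, base_dir = dirname(path)) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$starting_follicles)) {
    sf <- do.call(rbind, lapply(cfg$starting_follicles, function(f)
      data.frame(diameter = f$diameter, li = f$li)))
  } else if (!is.null(cfg$population_csv)) {
    p <- cfg$population_csv
    if (!file.exists(p)) p <- file.path(base_dir, cfg$population_csv)
    rec <- read_follicle_csv(p)
    rec <- rec[rec$atresia == "non_atretic" & rec$included, ]
    sf <- data.frame(diameter = rec$pseudodiameter, li = rec$labeling_index)
  } else {
    stop("scenario must provide 'starting_follicles' or 'population_csv'")
  }
  args <- cfg[intersect(names(cfg),
                        c("cohort_target", "preovulatory_min", "max_days"))]
  do.call(cohort_scenario, c(list(starting_follicles = sf), args))
}

#' Write a JSON run manifest
#'
#' Records the inputs, parameters, seed and package version of a pipeline run
#' so it can be reproduced exactly.
#'
#' @param path Output JSON path.
#' @param inputs Named list or character vector of input identifiers/paths.
#' @param params Named list of parameters (e.g. a [growth_params()]).
#' @param seed Integer seed used for the run.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, inputs = list(), params = list(),
                               seed = NA_integer_) {
  if (inherits(params, "growth_params")) params <- unclass(params)
  jsonlite::write_json(
    list(inputs = inputs, params = params, seed = seed,
         package = "follicledyn",
         version = as.character(utils::packageVersion("follicledyn"))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}
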