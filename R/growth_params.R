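#' Growth-model parameters
#'
#' Bundles every constant of the iterative granulosa-cell growth model: the
#' mural-volume allometry \eqn{V_M = c \cdot D^k} (defaults \eqn{c = 0.18},
#' \eqn{k = 3.05}, volume in \eqn{\mu m^3} for diameter in \eqn{\mu m}), the
#' volume of a single granulosa cell (132.6 \eqn{\mu m^3}), the proliferation
#' adjustment factor applied to every iteration (0.795), and the linear decline
#' of the labeling index (LI) with diameter (slope 0.0008 LI-fraction per
#' \eqn{\mu m}, intercept 0.57 at \eqn{D = 0}; the exact line through the mean
#' proliferation-rate column of the published summary table, 49\% at 100
#' \eqn{\mu m} down to 21\% at 450 \eqn{\mu m}). Iterations are synchronous
#' 24-h steps because ovulation can occur only once per day.
#'
#' @param volume_coefficient Coefficient of the mural-volume power law
#'   (dimensionless; default 0.18).
#' @param volume_exponent Exponent of the power law (> 1; default 3.05).
#' @param granulosa_cell_volume Volume of one granulosa cell in \eqn{\mu m^3}
#'   (default 132.6).
#' @param adjustment_factor Multiplicative adjustment applied to the effective
#'   LI at every iteration, in (0, 1.5] (default 0.795; values above 1 are only
#'   reached by calibration).
#' @param li_decline_slope Decline in LI fraction per \eqn{\mu m} of diameter
#'   increase (>= 0; default 8e-4).
#' @param li_intercept LI fraction at zero diameter of the median decline line
#'   (default 0.57). Used by [median_li()] and by the table regeneration
#'   defaults; the iterative model itself only uses the slope.
#' @param iteration_interval_h Length of one iteration in hours (default 24).
#' @return An object of class `growth_params`.
#' @seealso [mural_volume()], [simulate_growth()], [growth_params_from_config()]
#' @examples
#' p <- growth_params()
#' mural_volume(350, p)  # ~1.0e7 um^3
#' @export
growth_params <- function(volume_coefficient = 0.18,
                          volume_exponent = 3.05,
                          granulosa_cell_volume = 132.6,
                          adjustment_factor = 0.795,
                          li_decline_slope = 8e-4,
                          li_intercept = 0.57,
                          iteration_interval_h = 24) {
  stopifnot(
    is.numeric(volume_coefficient), volume_coefficient > 0,
    is.numeric(volume_exponent), volume_exponent > 1,
    is.numeric(granulosa_cell_volume), granulosa_cell_volume > 0,
    is.numeric(adjustment_factor), adjustment_factor > 0,
    adjustment_factor <= 1.5,
    is.numeric(li_decline_slope), li_decline_slope >= 0,
    is.numeric(li_intercept), li_intercept >= 0, li_intercept <= 1,
    is.numeric(iteration_interval_h), iteration_interval_h > 0
  )
  structure(
    list(
      volume_coefficient = volume_coefficient,
      volume_exponent = volume_exponent,
      granulosa_cell_volume = granulosa_cell_volume,
      adjustment_factor = adjustment_factor,
      li_decline_slope = li_decline_slope,
      li_intercept = li_intercept,
      iteration_interval_h = iteration_interval_h
    ),
    class = "growth_params"
  )
}

#' @export
print.growth_params <- function(x, ...) {
  cat("Granulosa-cell growth model parameters\n")
  cat(sprintf("  mural volume:        V = %g * D^%g  [um^3]\n",
              x$volume_coefficient, x$volume_exponent))
  cat(sprintf("  cell volume:         %g um^3\n", x$granulosa_cell_volume))
  cat(sprintf("  adjustment factor:   %g\n", x$adjustment_factor))
  cat(sprintf("  LI decline:          %g /um (intercept %g)\n",
              x$li_decline_slope, x$li_intercept))
  cat(sprintf("  iteration interval:  %g h\n", x$iteration_interval_h))
  invisible(x)
}

#' Read growth-model parameters from a YAML or JSON config file
#'
#' Keys mirror the [growth_params()] argument names; missing keys fall back to
#' the defaults, unknown keys are an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `growth_params` object.
#' @export
growth_params_from_config <- function(path) {
  stopifnot(file.exists(path))
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)")
  )
  allowed <- names(formals(growth_params))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad) > 0)
    stop("unknown growth parameter key(s): ", paste(bad, collapse = ", "))
  do.call(growth_params, cfg)
}

#' Median labeling index predicted at a given diameter
#'
#' Evaluates the median LI-decline line `li_intercept - li_decline_slope * D`,
#' clamped to \[0, 1\]. This is the "median growth rate" parameterisation of
#' antral follicles (0.434 at 170 um, 0.37 at 250 um, 0.29 at 350 um).
#'
#' @param diameter Follicle diameter(s), um.
#' @param params A [growth_params()] object.
#' @return LI fraction(s) in \[0, 1\].
#' @export
median_li <- function(diameter, params = growth_params()) {
  stopifnot(all(diameter >= 0))
  clamp01(params$li_intercept - params$li_decline_slope * diameter)
}

#' Antral follicle stage thresholds
#'
#' Diameter intervals (um) bounding the successive stages: preantral/secondary
#' (80-130), FSH-sensitive (130-170), FSH-dependent (170-350) and preovulatory
#' (strictly > 350). Intervals must be contiguous and increasing.
#'
#' @param preantral,fsh_sensitive,fsh_dependent Length-2 numeric intervals, um.
#' @param preovulatory_min Minimum preovulatory diameter, um (exclusive bound).
#' @return An object of class `stage_thresholds`.
#' @seealso [assign_stage()]
#' @export
stage_thresholds <- function(preantral = c(80, 130),
                             fsh_sensitive = c(130, 170),
                             fsh_dependent = c(170, 350),
                             preovulatory_min = 350) {
  ints <- list(preantral = preantral, fsh_sensitive = fsh_sensitive,
               fsh_dependent = fsh_dependent)
  for (nm in names(ints)) {
    v <- ints[[nm]]
    if (length(v) != 2 || v[1] >= v[2])
      stop("interval '", nm, "' must be increasing and of length 2")
  }
  if (preantral[2] != fsh_sensitive[1] || fsh_sensitive[2] != fsh_dependent[1])
    stop("stage intervals must be contiguous")
  if (fsh_dependent[2] != preovulatory_min)
    stop("fsh_dependent upper bound must equal preovulatory_min")
  structure(c(ints, list(preovulatory_min = preovulatory_min)),
            class = "stage_thresholds")
}
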