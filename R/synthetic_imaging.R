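#' Configuration for synthetic histology rendering
#'
#' Geometry of the rendered serial-section stacks and label masks: section
#' thickness and sampling design, the linear mural-shell-thickness-versus-
#' diameter relation, and the pixel size. The shell-thickness coefficients
#' default to the least-squares line that makes the volume of a spherical
#' shell of that thickness match the mural-volume power law over 170-450 um
#' (within 10%); they can be overridden.
#'
#' @param section_thickness Section thickness, um (default 5).
#' @param design `"2h"` (75 consecutive sections) or `"48h"` (every 25th
#'   section over a wider window).
#' @param series_length Number of sections in the window (default 75 for
#'   `"2h"`, 176 for `"48h"`).
#' @param sampling_interval Sections between samples (default 1 for `"2h"`,
#'   25 for `"48h"`).
#' @param mural_thickness_coefs Length-2 `c(intercept, slope)` of shell
#'   thickness (um) versus diameter (um); default derived from `params`.
#' @param pixel_size Pixel edge length for masks, um/pixel (default 1).
#' @param params A [growth_params()] object used to derive the default shell
#'   coefficients.
#' @return Object of class `synthetic_histology_config`.
#' @export
synthetic_histology_config <- function(section_thickness = 5,
                                       design = c("2h", "48h"),
                                       series_length = NULL,
                                       sampling_interval = NULL,
                                       mural_thickness_coefs = NULL,
                                       pixel_size = 1,
                                       params = growth_params()) {
  design <- match.arg(design)
  if (is.null(series_length))
    series_length <- if (design == "2h") 75L else 176L
  if (is.null(sampling_interval))
    sampling_interval <- if (design == "2h") 1L else 25L
  if (is.null(mural_thickness_coefs))
    mural_thickness_coefs <- derive_mural_thickness_coefs(params)
  stopifnot(section_thickness > 0, series_length >= 2,
            sampling_interval >= 1, pixel_size > 0,
            length(mural_thickness_coefs) == 2)
  structure(list(section_thickness = section_thickness,
                 design = design,
                 series_length = as.integer(series_length),
                 sampling_interval = as.integer(sampling_interval),
                 mural_thickness_coefs = mural_thickness_coefs,
                 pixel_size = pixel_size),
            class = "synthetic_histology_config")
}

#' Derive the mural shell thickness line from the volume power law
#'
#' For each diameter on a grid over `range`, solves the spherical-shell
#' equation \eqn{(4/3)\pi(R^3 - (R - t)^3) = V_M(D)} exactly for the shell
#' thickness t, then fits `t ~ D` by least squares. The returned line keeps
#' the rendered shell volume within 10% of the power law over the range.
#'
#' @param params A [growth_params()] object.
#' @param range Diameter range, um (default c(170, 450)).
#' @return Named numeric `c(intercept, slope)`.
#' @export
derive_mural_thickness_coefs <- function(params = growth_params(),
                                         range = c(170, 450)) {
  d <- seq(range[1], range[2], length.out = 29)
  r <- d / 2
  inner3 <- r^3 - 3 * mural_volume(d, params) / (4 * pi)
  t_exact <- r - pmax(0, inner3)^(1 / 3)
  fit <- lm(t_exact ~ d)
  c(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]))
}

# shell thickness at a diameter under a config (floored at 2 pixels)
mural_thickness <- function(diameter, config) {
  t <- config$mural_thickness_coefs[1] + config$mural_thickness_coefs[2] * diameter
  max(t, 2 * config$pixel_size)
}

#' Render the serial-section profile of a spherical follicle
#'
#' Slices a sphere of the given diameter at the midplanes of the sampled
#' sections of the series window (the window spans
#' `series_length * section_thickness` um starting at 0): the cross-sectional
#' area at signed distance z from the equator is \eqn{\pi(R^2 - z^2)}, zero
#' outside the sphere. Sections where the follicle is absent carry zero area,
#' so the inclusion rule sees the full sampled series.
#'
#' @param diameter Sphere diameter, um (> 0).
#' @param config A [synthetic_histology_config()].
#' @param equator_offset Position of the sphere centre (its equator), um from
#'   the start of the window; may place the equator anywhere, including
#'   outside the window.
#' @return A [section_series()] over the sampled section indices.
#' @export
render_section_stack <- function(diameter, config = synthetic_histology_config(),
                                 equator_offset) {
  stopifnot(diameter > 0, is.numeric(equator_offset))
  th <- config$section_thickness
  idx <- seq(1L, config$series_length, by = config$sampling_interval)
  z_mid <- (idx - 0.5) * th
  r2 <- (diameter / 2)^2 - (z_mid - equator_offset)^2
  section_series(idx, pi * pmax(0, r2), section_thickness = th,
                 sampling_interval = config$sampling_interval)
}

#' Render a class-labeled follicle cross-section mask
#'
#' Draws the equatorial cross-section of a follicle as an integer mask (see
#' [MASK_CLASSES]): a mural granulosa annulus whose thickness follows the
#' shell-thickness line, an antrum filling the interior, an oocyte with an
#' adjacent cumulus granulosa patch, and background outside. A fraction `li`
#' of the mural granulosa pixels is labeled BrdU-positive in one contiguous
#' angular patch starting at a random angle (spatial clustering); cumulus
#' granulosa is rendered BrdU-negative (cumulus proliferation is confined
#' near the oocyte and is excised from LI measurements), so omitting the
#' cumulus exclusion biases the measured LI low. The returned ROI contains a
#' basal-lamina polygon just outside the annulus and one cumulus exclusion
#' polygon.
#'
#' @param diameter Follicle diameter, um (default 300).
#' @param li Target mural labeling index in \[0, 1\].
#' @param config A [synthetic_histology_config()].
#' @param seed Integer seed (patch placement and oocyte position).
#' @return List with `mask` (integer matrix), `roi`
#'   ([region_of_interest()], um coordinates), `pixel_size`, and `truth`
#'   (list: requested `li`, planted pixel fraction `li_planted`, mural pixel
#'   count `n_mural`, cumulus pixel count `n_cumulus`).
#' @export
render_mask <- function(diameter = 300, li, config = synthetic_histology_config(),
                        seed = 1) {
  stopifnot(li >= 0, li <= 1, diameter > 0)
  set.seed(seed)
  ps <- config$pixel_size
  margin <- 3 * ps + 2
  side_um <- diameter + 2 * margin
  npx <- ceiling(side_um / ps)
  cx <- npx * ps / 2
  cy <- cx
  R <- diameter / 2
  t <- mural_thickness(diameter, config)
  r_antrum <- R - t

  # pixel-centre coordinates, um
  xs <- (rep(seq_len(npx), each = npx) - 0.5) * ps
  ys <- (rep(seq_len(npx), times = npx) - 0.5) * ps
  dx <- xs - cx
  dy <- ys - cy
  rr <- sqrt(dx^2 + dy^2)

  cls <- rep(MASK_CLASSES[["background"]], npx * npx)
  cls[rr <= r_antrum] <- MASK_CLASSES[["antrum"]]
  mural <- rr > r_antrum & rr <= R
  cls[mural] <- MASK_CLASSES[["brdu_neg"]]

  # oocyte + cumulus patch, kept clear of the mural annulus
  r_oo <- 0.30 * r_antrum
  t_cum <- max(0.15 * r_antrum, 2 * ps)
  offset <- 0.35 * r_antrum
  ang <- runif(1, 0, 2 * pi)
  ox <- cx + offset * cos(ang)
  oy <- cy + offset * sin(ang)
  rr_oo <- sqrt((xs - ox)^2 + (ys - oy)^2)
  cls[rr_oo <= r_oo + t_cum & rr <= r_antrum] <- MASK_CLASSES[["brdu_neg"]]
  cls[rr_oo <= r_oo] <- MASK_CLASSES[["oocyte"]]
  n_cumulus <- sum(cls == MASK_CLASSES[["brdu_neg"]] & !mural)

  # clustered BrdU+ patch: contiguous angular arc of the mural annulus
  n_mural <- sum(mural)
  k <- round(n_mural * li)
  if (k > 0) {
    theta0 <- runif(1, 0, 2 * pi)
    arc <- (atan2(dy[mural], dx[mural]) - theta0) %% (2 * pi)
    lab <- which(mural)[order(arc)][seq_len(k)]
    cls[lab] <- MASK_CLASSES[["brdu_pos"]]
  }

  mask <- matrix(cls, nrow = npx)  # column-major: index = (col-1)*npx + row

  circle_poly <- function(x0, y0, r, n = 72) {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    cbind(x0 + r * cos(th), y0 + r * sin(th))
  }
  roi <- region_of_interest(
    basal_lamina = circle_poly(cx, cy, R + 1.5 * ps),
    cumulus_exclusions = list(circle_poly(ox, oy, r_oo + t_cum + ps, n = 36))
  )
  list(mask = mask, roi = roi, pixel_size = ps,
       truth = list(li = li, li_planted = if (n_mural > 0) k / n_mural else NA,
                    n_mural = n_mural, n_cumulus = n_cumulus))
}
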