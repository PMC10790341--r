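#' Mural granulosa layer volume from follicle diameter
#'
#' Power-law allometry between follicle diameter and the volume of the mural
#' granulosa layer, \eqn{V_M = c \cdot D^k} (defaults \eqn{0.18 \cdot D^{3.05}}).
#'
#' @param diameter Follicle diameter(s), um (>= 0).
#' @param params A [growth_params()] object.
#' @return Mural volume(s), um^3. Strictly increasing in diameter.
#' @examples
#' mural_volume(c(100, 350, 450))  # ~2.3e5, 1.0e7, 2.2e7 um^3
#' @export
mural_volume <- function(diameter, params = growth_params()) {
  if (any(!is.finite(diameter)) || any(diameter < 0))
    stop("diameter must be finite and >= 0")
  params$volume_coefficient * diameter^params$volume_exponent
}

#' Mural granulosa cell count from follicle diameter
#'
#' Number of granulosa cells required to fill the mural volume:
#' [mural_volume()] divided by the single-cell volume.
#'
#' @inheritParams mural_volume
#' @return Cell count(s), real-valued.
#' @examples
#' cell_count_from_diameter(200)  # ~1.4e4 cells
#' @export
cell_count_from_diameter <- function(diameter, params = growth_params()) {
  mural_volume(diameter, params) / params$granulosa_cell_volume
}

#' Follicle diameter from mural granulosa cell count
#'
#' Closed-form inverse of [cell_count_from_diameter()]:
#' \eqn{D = (N V_G / c)^{1/k}}.
#'
#' @param cell_count Mural granulosa cell count(s) (>= 0).
#' @inheritParams mural_volume
#' @return Diameter(s), um.
#' @export
diameter_from_cell_count <- function(cell_count, params = growth_params()) {
  if (any(!is.finite(cell_count)) || any(cell_count < 0))
    stop("cell_count must be finite and >= 0")
  (cell_count * params$granulosa_cell_volume / params$volume_coefficient)^
    (1 / params$volume_exponent)
}

#' Effective labeling index applied at one growth iteration
#'
#' The raw day-0 LI is corrected for the decline of proliferation with
#' follicle development: the decline slope times the diameter gained since the
#' start is subtracted from the initial LI, the result is floored at zero and
#' multiplied by the adjustment factor. At the first iteration (no diameter
#' gain yet) this reduces to `adjustment_factor * li_initial`. The result is
#' clamped to \[0, 1\].
#'
#' @param li_initial LI fraction at day 0, in \[0, 1\].
#' @param diameter_now Current diameter, um (>= `diameter_start`).
#' @param diameter_start Diameter at day 0, um (> 0).
#' @param params A [growth_params()] object.
#' @return Effective LI fraction in \[0, 1\].
#' @examples
#' effective_li(0.30, 334, 334)        # first iteration: 0.795 * 0.30
#' effective_li(0.30, 434, 334)        # after 100 um of growth
#' @export
effective_li <- function(li_initial, diameter_now, diameter_start,
                         params = growth_params()) {
  stopifnot(all(li_initial >= 0), all(li_initial <= 1),
            all(diameter_start > 0))
  if (any(diameter_now < diameter_start - 1e-9))
    stop("diameter_now must be >= diameter_start")
  raw <- li_initial - params$li_decline_slope * (diameter_now - diameter_start)
  clamp01(params$adjustment_factor * pmax(0, raw))
}

#' Follicle state for the iterative growth model
#'
#' @param diameter Diameter, um (> 0).
#' @param li_initial LI fraction at day 0.
#' @param cell_count Mural cell count; computed from `diameter` when omitted,
#'   otherwise checked for consistency with the volume model (relative
#'   tolerance 1e-9).
#' @param day Non-negative integer day index.
#' @param params A [growth_params()] object.
#' @return An object of class `follicle_state`.
#' @export
follicle_state <- function(diameter, li_initial, cell_count = NULL, day = 0L,
                           params = growth_params()) {
  stopifnot(length(diameter) == 1, diameter > 0,
            li_initial >= 0, li_initial <= 1, day >= 0)
  implied <- cell_count_from_diameter(diameter, params)
  if (is.null(cell_count)) {
    cell_count <- implied
  } else if (abs(cell_count - implied) > 1e-9 * implied) {
    stop("cell_count inconsistent with diameter under the volume model")
  }
  structure(list(diameter = diameter, cell_count = cell_count,
                 li_initial = li_initial, day = as.integer(day)),
            class = "follicle_state")
}

# one implicit-equation step for the literal reading of the printed growth
# equation, where the correction multiplies the cell-number increase itself:
# dN = N * (LI0 - f * dN)  =>  dN = N * LI0 / (1 + N * f)
literal_step <- function(cell_count, li_initial, f) {
  cell_count * li_initial / (1 + cell_count * f)
}

#' Advance a follicle by one 24-h growth iteration
#'
#' Applies one step of the iterative model: the cell count is multiplied by
#' `1 + effective LI` and the new diameter follows from the volume allometry.
#' Cell counts stay real-valued (the model is a deterministic rate equation).
#'
#' @param state Current [follicle_state()].
#' @param start The day-0 [follicle_state()] (carries `li_initial` and the
#'   reference diameter for the LI decline).
#' @param params A [growth_params()] object.
#' @param strategy `"diameter_decline"` (default): effective LI declines with
#'   the diameter gained since day 0. `"literal"`: the correction factor
#'   multiplies the daily cell-number increase itself, solved implicitly; this
#'   alternative reading is dimensionally degenerate (the first iteration
#'   stalls because the dimensionless correction is applied per cell of
#'   increase, and later steps alternate erratically) and is provided for
#'   comparison only.
#' @return The next [follicle_state()] (day incremented by 1).
#' @export
grow_one_day <- function(state, start, params = growth_params(),
                         strategy = c("diameter_decline", "literal")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(state, "follicle_state"), inherits(start, "follicle_state"),
            start$day == 0L)
  if (strategy == "diameter_decline") {
    li <- effective_li(start$li_initial, state$diameter, start$diameter, params)
    n_new <- state$cell_count * (1 + li)
  } else {
    f <- if (state$diameter <= start$diameter) {
      params$adjustment_factor
    } else {
      params$adjustment_factor * params$li_decline_slope *
        (state$diameter - start$diameter)
    }
    dn <- literal_step(state$cell_count, start$li_initial, f)
    li <- dn / state$cell_count
    n_new <- state$cell_count + dn
  }
  d_new <- diameter_from_cell_count(n_new, params)
  out <- follicle_state(d_new, start$li_initial, cell_count = n_new,
                        day = state$day + 1L, params = params)
  attr(out, "li_applied") <- li
  out
}

#' Simulate follicle growth over consecutive days
#'
#' Iterates [grow_one_day()] from a starting diameter and day-0 LI.
#'
#' @param diameter_start Starting diameter, um (> 0).
#' @param li_initial LI fraction at day 0.
#' @param days Number of 24-h iterations (>= 0).
#' @param params A [growth_params()] object.
#' @inheritParams grow_one_day
#' @return A `growth_trajectory`: a data frame with columns `day`, `diameter`
#'   (um), `cell_count`, and `li_applied` (the effective LI used in the step
#'   ending at that day; `NA` at day 0).
#' @examples
#' tr <- simulate_growth(250, 0.37, 5)
#' tr$diameter
#' @export
simulate_growth <- function(diameter_start, li_initial, days,
                            params = growth_params(),
                            strategy = c("diameter_decline", "literal")) {
  strategy <- match.arg(strategy)
  stopifnot(days >= 0, days == round(days))
  start <- follicle_state(diameter_start, li_initial, params = params)
  n <- as.integer(days)
  out <- data.frame(day = 0:n, diameter = NA_real_, cell_count = NA_real_,
                    li_applied = NA_real_)
  out$diameter[1] <- start$diameter
  out$cell_count[1] <- start$cell_count
  state <- start
  for (i in seq_len(n)) {
    state <- grow_one_day(state, start, params, strategy)
    out$diameter[i + 1] <- state$diameter
    out$cell_count[i + 1] <- state$cell_count
    out$li_applied[i + 1] <- attr(state, "li_applied")
  }
  class(out) <- c("growth_trajectory", "data.frame")
  out
}

#' @export
print.growth_trajectory <- function(x, ...) {
  cat(sprintf("Growth trajectory: %d day(s), %.1f -> %.1f um\n",
              max(x$day), x$diameter[1], x$diameter[nrow(x)]))
  print.data.frame(x, row.names = FALSE, digits = 6)
  invisible(x)
}

#' First day a growing follicle reaches a target diameter
#'
#' @inheritParams simulate_growth
#' @param diameter_target Target diameter, um (> `diameter_start`).
#' @param max_days Maximum number of iterations to attempt (>= 1).
#' @return Smallest day index at which the trajectory diameter is >= the
#'   target, or `NA_integer_` if unreached within `max_days`.
#' @examples
#' days_to_diameter(250, 0.37, 350)  # median-rate follicle
#' @export
days_to_diameter <- function(diameter_start, li_initial, diameter_target,
                             params = growth_params(), max_days = 365L) {
  stopifnot(diameter_target > diameter_start, max_days >= 1)
  start <- follicle_state(diameter_start, li_initial, params = params)
  state <- start
  for (i in seq_len(max_days)) {
    state <- grow_one_day(state, start, params)
    if (state$diameter >= diameter_target) return(i)
    # no further growth possible once the effective LI has hit zero
    if (attr(state, "li_applied") <= 0) return(NA_integer_)
  }
  NA_integer_
}

#' Regenerate the granulosa-cell increase summary table
#'
#' For each diameter: mural volume (power law), mural cell count (volume over
#' single-cell volume), the proliferation rate, and the daily cell-number
#' increase (count times rate). Defaults reproduce the published 100-450 um
#' table with rates from the median LI decline line.
#'
#' @param diameters Diameters, um.
#' @param proliferation_rates LI fractions in \[0, 1\], same length as
#'   `diameters`; default [median_li()] at each diameter.
#' @param params A [growth_params()] object.
#' @return Data frame with columns `diameter_um`, `mural_volume_um3`,
#'   `cell_count`, `proliferation_rate`, `cell_increase`.
#' @export
generate_table1 <- function(diameters = seq(100, 450, by = 50),
                            proliferation_rates = median_li(diameters, params),
                            params = growth_params()) {
  if (length(diameters) != length(proliferation_rates))
    stop("diameters and proliferation_rates must have the same length")
  stopifnot(all(proliferation_rates >= 0), all(proliferation_rates <= 1))
  vol <- mural_volume(diameters, params)
  n <- vol / params$granulosa_cell_volume
  data.frame(
    diameter_um = diameters,
    mural_volume_um3 = vol,
    cell_count = n,
    proliferation_rate = proliferation_rates,
    cell_increase = n * proliferation_rates
  )
}

#' Calibrate the proliferation adjustment factor against observed growth
#'
#' Finds the scalar adjustment factor in (0, 1.5] minimising the sum of squared
#' diameter residuals between [simulate_growth()] (started from the first
#' observation) and a sequence of observed (day, mean diameter) points, by 1-D
#' bounded minimisation. Deterministic given its inputs.
#'
#' @param observed Data frame with numeric columns `day` (strictly increasing)
#'   and `diameter` (um, strictly increasing); at least 2 rows.
#' @param li_initial LI fraction at the first observation.
#' @param params A [growth_params()] object; its `adjustment_factor` is ignored
#'   and replaced by the candidate value during the search.
#' @return The fitted adjustment factor (numeric scalar).
#' @examples
#' obs <- simulate_growth(300, 0.33, 4)
#' calibrate_adjustment(obs[c("day", "diameter")], 0.33)  # ~0.795
#' @export
calibrate_adjustment <- function(observed, li_initial,
                                 params = growth_params()) {
  if (!is.data.frame(observed) || !all(c("day", "diameter") %in% names(observed)))
    stop("observed must be a data frame with columns 'day' and 'diameter'")
  if (nrow(observed) < 2)
    stop("at least 2 observations are required to calibrate")
  if (any(diff(observed$day) <= 0) || any(diff(observed$diameter) <= 0))
    stop("observations must have strictly increasing days and diameters")
  d0 <- observed$diameter[1]
  day0 <- observed$day[1]
  horizon <- max(observed$day) - day0
  objective <- function(a) {
    p <- params
    p$adjustment_factor <- a
    tr <- simulate_growth(d0, li_initial, horizon, p)
    pred <- tr$diameter[match(observed$day - day0, tr$day)]
    sum((pred - observed$diameter)^2)
  }
  optimize(objective, interval = c(1e-6, 1.5), tol = 1e-7)$minimum
}
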