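#' Configuration for synthetic follicle populations
#'
#' Describes the population of antral and preantral follicles observed in one
#' ovary section series at a given estrous-cycle stage: how many follicles,
#' their diameter distribution, the mean LI trajectory with its four phases
#' (slow preantral below 130 um, rising growth spurt to 170 um, linear decline
#' beyond), between-follicle LI heterogeneity at fixed diameter, measurement
#' noise, and the stage- and LI-dependent atresia hazard above the onset
#' diameter.
#'
#' @param n_follicles Named counts of sub-preovulatory follicles per cycle
#'   stage (defaults near the per-stage totals of the 2-h study: 170, 250,
#'   220).
#' @param n_preovulatory Named counts of planted preovulatory (> 350 um)
#'   follicles per stage (progressive accumulation: 1, 5, 10). The planted
#'   cohort represents the surviving dominant cohort and is generated
#'   non-atretic.
#' @param diameter_meanlog,diameter_sdlog Log-normal parameters of the
#'   small-follicle (below the antral band) diameter component.
#' @param antral_fraction Fraction of sub-preovulatory follicles drawn
#'   uniformly from `antral_range` (default 0.4) — the FSH-dependent antral
#'   band is roughly evenly populated in sectioned ovaries, while smaller
#'   follicles dominate numerically.
#' @param antral_range Diameter range of the uniform antral component, um
#'   (default c(170, 350)).
#' @param diameter_min,diameter_max Truncation bounds for sub-preovulatory
#'   diameters, um (defaults 80 and 350).
#' @param preovulatory_range Diameter range of planted preovulatory follicles,
#'   um (default 355-460, within the observed 331-462 um span).
#' @param li_preantral_mean Mean LI of preantral follicles (default 0.20;
#'   preantral LIs rarely exceed 0.30).
#' @param li_spurt_knots Diameters bounding the growth spurt, um (default
#'   c(130, 170)).
#' @param li_intercept,li_slope Linear LI decline beyond the second knot
#'   (defaults 0.57 and 8e-4 per um).
#' @param li_sd Between-follicle SD of the true LI at fixed diameter
#'   (default 0.07).
#' @param li_noise_sd SD of additive measurement noise on the measured LI,
#'   truncated to \[0, 1\] (default 0.03).
#' @param atresia An [atresia_hazard()] (its `base_rate` may be set to 0 to
#'   disable atresia).
#' @param n_animals Animals per stage (default 6).
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_follicles = c(estrus = 170, metestrus = 250,
                                              diestrus = 220),
                              n_preovulatory = c(estrus = 1, metestrus = 5,
                                                 diestrus = 10),
                              diameter_meanlog = log(115),
                              diameter_sdlog = 0.30,
                              antral_fraction = 0.4,
                              antral_range = c(170, 350),
                              diameter_min = 80,
                              diameter_max = 350,
                              preovulatory_range = c(355, 460),
                              li_preantral_mean = 0.20,
                              li_spurt_knots = c(130, 170),
                              li_intercept = 0.57,
                              li_slope = 8e-4,
                              li_sd = 0.07,
                              li_noise_sd = 0.03,
                              atresia = atresia_hazard(base_rate = 0.25),
                              n_animals = 6) {
  stopifnot(all(n_follicles >= 1), all(n_preovulatory >= 0),
            antral_fraction >= 0, antral_fraction <= 1,
            length(antral_range) == 2, diff(antral_range) > 0,
            diameter_min > 0, diameter_max > diameter_min,
            preovulatory_range[1] > diameter_max,
            li_preantral_mean >= 0, li_preantral_mean <= 1,
            length(li_spurt_knots) == 2, diff(li_spurt_knots) > 0,
            li_intercept >= 0, li_intercept <= 1, li_slope >= 0,
            li_sd >= 0, li_noise_sd >= 0, n_animals >= 1,
            inherits(atresia, "atresia_hazard"))
  structure(as.list(environment()), class = "population_config")
}

#' Mean LI trajectory across follicle development
#'
#' Piecewise-linear mean of the true LI as a function of diameter: constant at
#' `li_preantral_mean` below the first spurt knot, linear rise through the
#' spurt, then the linear decline `li_intercept - li_slope * D` beyond the
#' second knot (continuous at that knot).
#'
#' @param diameter Diameter(s), um.
#' @param config A [population_config()].
#' @return Mean LI fraction(s) in \[0, 1\].
#' @export
li_mean_trajectory <- function(diameter, config = population_config()) {
  k1 <- config$li_spurt_knots[1]
  k2 <- config$li_spurt_knots[2]
  li_k2 <- config$li_intercept - config$li_slope * k2
  out <- numeric(length(diameter))
  pre <- diameter < k1
  spurt <- diameter >= k1 & diameter < k2
  post <- diameter >= k2
  out[pre] <- config$li_preantral_mean
  out[spurt] <- config$li_preantral_mean +
    (li_k2 - config$li_preantral_mean) * (diameter[spurt] - k1) / (k2 - k1)
  out[post] <- config$li_intercept - config$li_slope * diameter[post]
  clamp01(out)
}

# truncated log-normal sampler (rejection)
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic follicle population at one cycle stage
#'
#' Draws a reproducible population of follicle records: truncated log-normal
#' sub-preovulatory diameters plus the planted preovulatory cohort, true LIs
#' from the piecewise mean trajectory with between-follicle heterogeneity,
#' noisy measured LIs, and atresia flags assigned from the LI-percentile
#' hazard above the onset diameter. Ground-truth columns (`truth_*`) are
#' retained for testing.
#'
#' @param config A [population_config()].
#' @param stage One of `"estrus"`, `"metestrus"`, `"diestrus"`.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return Normalised follicle records data frame with ground-truth columns.
#' @examples
#' pop <- sample_population(population_config(), "diestrus", seed = 1)
#' table(pop$atresia)
#' @export
sample_population <- function(config = population_config(), stage, seed = 1) {
  stopifnot(inherits(config, "population_config"))
  if (!stage %in% names(config$n_follicles))
    stop("invalid cycle stage: ", stage)
  set.seed(seed)
  n_body <- config$n_follicles[[stage]]
  n_pre <- config$n_preovulatory[[stage]]
  n_antral <- rbinom(1, n_body, config$antral_fraction)
  d_small <- rlnorm_trunc(n_body - n_antral, config$diameter_meanlog,
                          config$diameter_sdlog,
                          config$diameter_min, config$diameter_max)
  d_band <- runif(n_antral, config$antral_range[1],
                  min(config$antral_range[2], config$diameter_max))
  d_body <- sample(c(d_small, d_band))
  d_pre <- if (n_pre > 0)
    runif(n_pre, config$preovulatory_range[1], config$preovulatory_range[2])
  else numeric(0)
  d <- c(d_body, d_pre)
  n <- length(d)
  planted <- c(rep(FALSE, n_body), rep(TRUE, n_pre))
  truth_mean <- li_mean_trajectory(d, config)
  truth_li <- clamp01(rnorm(n, truth_mean, config$li_sd))
  measured <- clamp01(truth_li + rnorm(n, 0, config$li_noise_sd))

  # atresia: LI-percentile hazard among susceptible (>= onset) body follicles
  atretic <- rep(FALSE, n)
  rule <- config$atresia
  suscept <- !planted & d >= rule$onset_diameter
  if (any(suscept) && rule$base_rate > 0) {
    pct <- rank(truth_li[suscept]) / (sum(suscept) + 1)
    p <- hazard_probability(rule, pct, stage)
    atretic[suscept] <- rbinom(sum(suscept), 1, p) == 1
  }
  flags <- matrix(FALSE, n, length(ATRESIA_FLAGS),
                  dimnames = list(NULL, ATRESIA_FLAGS))
  for (i in which(atretic)) {
    f <- rbinom(length(ATRESIA_FLAGS), 1, 0.5) == 1
    if (!any(f)) f[sample.int(length(f), 1)] <- TRUE
    flags[i, ] <- f
  }

  rec <- data.frame(
    follicle_id = sprintf("%s_%04d", stage, seq_len(n)),
    animal_id = sprintf("m%02d", sample.int(config$n_animals, n, replace = TRUE)),
    cycle_stage = stage,
    pseudodiameter = d,
    labeling_index = measured,
    included = TRUE,
    truth_li = truth_li,
    truth_mean_li = truth_mean,
    truth_atretic = atretic,
    truth_preovulatory = planted
  )
  rec <- cbind(rec, as.data.frame(flags))
  as_follicle_records(rec)
}

#' Simulate a BrdU pulse-chase design on a follicle population
#'
#' For the 2-h design the measured LI is simply the true instantaneous LI plus
#' measurement noise (the chase is too short for growth). For the 48-h design
#' each non-atretic follicle is grown by the iterative model for the elapsed
#' 1-2 days, the injection-time LI is carried as the pulse-label signal
#' (`label_li`), and (optionally) the LI-percentile hazard preferentially
#' removes slow-growing FSH-dependent follicles during the chase.
#'
#' @param records Follicle records at injection time, with `truth_li`.
#' @param design `"2h"` or `"48h"`.
#' @param params A [growth_params()] object.
#' @param days_elapsed Days between injection and euthanasia (48-h design
#'   only; 1 or 2).
#' @param hazard An [atresia_hazard()] or `NULL` to disable chase atresia.
#' @param stage Cycle stage at the end of the chase (hazard multiplier).
#' @param noise_sd Measurement noise on the label LI (default 0.03).
#' @param seed Integer seed.
#' @return Records at chase end: `pseudodiameter` updated by growth,
#'   `diameter_at_injection` retained, `label_li` the measured pulse label,
#'   `atresia` updated for chase atresia.
#' @export
simulate_pulse_chase <- function(records, design = c("2h", "48h"),
                                 params = growth_params(),
                                 days_elapsed = NULL,
                                 hazard = atresia_hazard(),
                                 stage = "diestrus",
                                 noise_sd = 0.03, seed = 1) {
  design <- match.arg(design)
  records <- as_follicle_records(records)
  if (!"truth_li" %in% names(records))
    stop("records need a 'truth_li' ground-truth column")
  set.seed(seed)
  n <- nrow(records)
  records$diameter_at_injection <- records$pseudodiameter
  if (design == "2h") {
    records$label_li <- clamp01(records$truth_li + rnorm(n, 0, noise_sd))
    return(records)
  }
  if (is.null(days_elapsed) || !days_elapsed %in% 1:2)
    stop("the 48h design requires days_elapsed of 1 or 2")
  grows <- records$atresia == "non_atretic"
  d_new <- records$pseudodiameter
  d_new[grows] <- vapply(which(grows), function(i)
    simulate_growth(records$pseudodiameter[i], records$truth_li[i],
                    days_elapsed, params)$diameter[days_elapsed + 1],
    numeric(1))
  records$pseudodiameter <- d_new
  records$label_li <- clamp01(records$truth_li + rnorm(n, 0, noise_sd))
  if (!is.null(hazard)) {
    at_risk <- grows & records$diameter_at_injection >= hazard$onset_diameter &
      d_new <= 350
    if (any(at_risk)) {
      pct <- rank(records$truth_li[at_risk]) / (sum(at_risk) + 1)
      p <- 1 - (1 - hazard_probability(hazard, pct, stage))^days_elapsed
      dies <- rbinom(sum(at_risk), 1, p) == 1
      idx <- which(at_risk)[dies]
      records$atresia[idx] <- "atretic"
      if (all(ATRESIA_FLAGS %in% names(records))) {
        for (i in idx) {
          f <- rbinom(length(ATRESIA_FLAGS), 1, 0.5) == 1
          if (!any(f)) f[sample.int(length(f), 1)] <- TRUE
          records[i, ATRESIA_FLAGS] <- as.list(f)
        }
      }
    }
  }
  records
}
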