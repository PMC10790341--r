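#' Fit a labeling-index-versus-diameter regression
#'
#' Ordinary least-squares line of LI on pseudodiameter over antral follicles,
#' characterising either the "median" rate of LI decline (all non-atretic,
#' included follicles in the diameter range) or the "fast" rate (per-bin top
#' 20% of follicles by LI in 50-um bins \[170, 220), \[220, 270), \[270, 320),
#' \[320, 350\], plus all follicles above 350 um).
#'
#' @param records Follicle records (see [as_follicle_records()]).
#' @param subset_rule `"median_all"` or `"fast_top20"`.
#' @param diameter_range Length-2 numeric, um; follicles with pseudodiameter
#'   in \[lo, hi\] are eligible (default `c(170, Inf)`).
#' @param min_per_bin Minimum follicles per 50-um bin required for the fast
#'   subset (default 5).
#' @return Object of class `li_regression`: list with `intercept` (LI at
#'   D = 0), `slope` (LI per um, signed; negative = decline), `subset_rule`,
#'   `diameter_range`, `n`, and the underlying `lm` fit in `model`.
#' @examples
#' pop <- sample_population(population_config(), "diestrus", seed = 1)
#' fit_li_regression(pop, "median_all")
#' @export
fit_li_regression <- function(records,
                              subset_rule = c("median_all", "fast_top20"),
                              diameter_range = c(170, Inf),
                              min_per_bin = 5) {
  subset_rule <- match.arg(subset_rule)
  records <- as_follicle_records(records)
  d <- records$pseudodiameter
  keep <- records$atresia == "non_atretic" & records$included &
    d >= diameter_range[1] & d <= diameter_range[2]
  records <- records[keep, ]
  if (subset_rule == "fast_top20") {
    records <- fast_top20_subset(records, min_per_bin = min_per_bin)
  }
  if (nrow(records) < 3)
    stop("at least 3 follicles are required to fit an LI regression")
  fit <- lm(labeling_index ~ pseudodiameter, data = records)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 subset_rule = subset_rule,
                 diameter_range = diameter_range,
                 n = nrow(records),
                 model = fit),
            class = "li_regression")
}

#' @export
print.li_regression <- function(x, ...) {
  cat(sprintf("LI regression (%s, n = %d): LI = %.4f %+.3g * D\n",
              x$subset_rule, x$n, x$intercept, x$slope))
  invisible(x)
}

#' Predicted LI from a fitted regression, clamped to \[0, 1\]
#'
#' @param object A `li_regression`.
#' @param diameter Diameter(s), um.
#' @param ... Unused.
#' @return LI fraction(s).
#' @export
predict_li <- function(object, diameter, ...) {
  stopifnot(inherits(object, "li_regression"))
  clamp01(object$intercept + object$slope * diameter)
}

#' Fast-growing subset: per-bin top 20% of follicles by LI
#'
#' Bins \[170, 220), \[220, 270), \[270, 320), \[320, 350\]; within each bin
#' the top `ceiling(0.2 * n)` follicles by LI are retained (ties broken in
#' favour of the smaller diameter); all follicles above 350 um are retained
#' unconditionally.
#'
#' @param records Normalised follicle records already filtered to the eligible
#'   set.
#' @param min_per_bin Minimum follicles per bin (default 5).
#' @return The subset of `records`.
#' @export
fast_top20_subset <- function(records, min_per_bin = 5) {
  d <- records$pseudodiameter
  lows <- c(170, 220, 270, 320)
  highs <- c(220, 270, 320, 350)
  picked <- list()
  for (b in seq_along(lows)) {
    in_bin <- if (b < length(lows)) d >= lows[b] & d < highs[b]
              else d >= lows[b] & d <= highs[b]
    n <- sum(in_bin)
    if (n < min_per_bin)
      stop(sprintf("bin [%d, %d) has %d follicle(s); %d required",
                   lows[b], highs[b], n, min_per_bin))
    bin <- records[in_bin, ]
    ord <- order(-bin$labeling_index, bin$pseudodiameter)
    picked[[b]] <- bin[ord[seq_len(ceiling(0.2 * n))], ]
  }
  rbind(do.call(rbind, picked), records[d > 350, ])
}

#' Count preovulatory follicles per animal and cycle stage
#'
#' Counts non-atretic, included follicles with pseudodiameter strictly above
#' the threshold, grouped by animal then cycle stage. Animals and stages
#' present in the input appear with zero counts when they contribute no
#' preovulatory follicles.
#'
#' @param records Follicle records with `animal_id` and `cycle_stage`.
#' @param preovulatory_min Diameter threshold, um (default 350).
#' @return Data frame with columns `animal_id`, `cycle_stage`,
#'   `n_preovulatory`.
#' @export
count_preovulatory <- function(records, preovulatory_min = 350) {
  if (nrow(records) == 0) {
    return(data.frame(animal_id = character(), cycle_stage = character(),
                      n_preovulatory = integer()))
  }
  records <- as_follicle_records(records)
  if (!all(c("animal_id", "cycle_stage") %in% names(records)))
    stop("records need 'animal_id' and 'cycle_stage' columns")
  animals <- sort(unique(records$animal_id))
  stages <- unique(as.character(records$cycle_stage))
  sel <- records$atresia == "non_atretic" & records$included &
    records$pseudodiameter > preovulatory_min
  tab <- table(factor(records$animal_id[sel], levels = animals),
               factor(records$cycle_stage[sel], levels = stages))
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("animal_id", "cycle_stage", "n_preovulatory")
  out$n_preovulatory <- as.integer(out$n_preovulatory)
  out[order(out$animal_id, out$cycle_stage), , drop = FALSE]
}

#' Cohort-recruitment scenario
#'
#' Starting population and rules for simulating recruitment of the
#' preovulatory cohort: each follicle grows by the iterative model from its
#' starting diameter and day-0 LI; the cycle can end (ovulation at the next
#' proestrus) once `cohort_target` follicles have reached the preovulatory
#' size.
#'
#' @param starting_follicles Data frame with columns `diameter` (um, > 0) and
#'   `li` (fraction).
#' @param cohort_target Number of preovulatory follicles required (>= 1;
#'   default 10, the full mouse cohort; observed range 6-12).
#' @param preovulatory_min Preovulatory threshold, um (default 350).
#' @param max_days Maximum days to simulate (default 10).
#' @param atresia_rule Optional [atresia_hazard()] applied during growth.
#' @return Object of class `cohort_scenario`.
#' @export
cohort_scenario <- function(starting_follicles, cohort_target = 10,
                            preovulatory_min = 350, max_days = 10,
                            atresia_rule = NULL) {
  stopifnot(is.data.frame(starting_follicles),
            all(c("diameter", "li") %in% names(starting_follicles)),
            all(starting_follicles$diameter > 0),
            all(starting_follicles$li >= 0), all(starting_follicles$li <= 1),
            cohort_target >= 1, max_days >= 1)
  if (!is.null(atresia_rule)) stopifnot(inherits(atresia_rule, "atresia_hazard"))
  structure(list(starting_follicles = starting_follicles,
                 cohort_target = cohort_target,
                 preovulatory_min = preovulatory_min,
                 max_days = max_days,
                 atresia_rule = atresia_rule),
            class = "cohort_scenario")
}

#' LI-percentile atresia hazard
#'
#' Daily probability of atresia for an FSH-dependent follicle, logistic-
#' decreasing in its LI percentile within the cohort (slow-growing follicles
#' are preferentially removed) and scaled by a stage multiplier:
#' `min(1, 2 * base_rate * stage_multiplier * plogis(steepness * (0.5 - pct)))`.
#' Follicles below `onset_diameter` (or already preovulatory) are not at risk.
#'
#' @param base_rate Daily hazard at the median LI percentile before the stage
#'   multiplier (default 0.35).
#' @param steepness Logistic steepness in percentile units (default 6).
#' @param stage_multiplier Named multipliers per cycle stage (estrus low,
#'   metestrus/diestrus higher, matching the rarity of atresia at estrus).
#' @param onset_diameter Diameter of atresia-susceptibility onset, um
#'   (default 170).
#' @return Object of class `atresia_hazard`.
#' @export
atresia_hazard <- function(base_rate = 0.35, steepness = 6,
                           stage_multiplier = c(estrus = 0.2, metestrus = 1,
                                                diestrus = 1.5, proestrus = 1),
                           onset_diameter = 170) {
  stopifnot(base_rate >= 0, base_rate <= 1, steepness >= 0,
            all(stage_multiplier >= 0), onset_diameter > 0)
  structure(list(base_rate = base_rate, steepness = steepness,
                 stage_multiplier = stage_multiplier,
                 onset_diameter = onset_diameter),
            class = "atresia_hazard")
}

#' Daily atresia probability under an LI-percentile hazard
#'
#' @param rule An [atresia_hazard()].
#' @param li_percentile LI percentile(s) within the cohort, in \[0, 1\].
#' @param stage Cycle stage name (must match a `stage_multiplier` entry), or
#'   `NULL` for multiplier 1.
#' @return Probability vector in \[0, 1\].
#' @export
hazard_probability <- function(rule, li_percentile, stage = NULL) {
  stopifnot(inherits(rule, "atresia_hazard"),
            all(li_percentile >= 0), all(li_percentile <= 1))
  mult <- if (is.null(stage)) 1 else {
    if (!stage %in% names(rule$stage_multiplier))
      stop("unknown cycle stage: ", stage)
    rule$stage_multiplier[[stage]]
  }
  pmin(1, 2 * rule$base_rate * mult *
         plogis(rule$steepness * (0.5 - li_percentile)))
}

#' Simulate recruitment of the preovulatory cohort
#'
#' Grows every starting follicle by the iterative model, optionally applies
#' the LI-percentile atresia hazard each day to at-risk follicles (FSH
#' dependent, not yet preovulatory), and reports the first day on which the
#' cohort target of preovulatory follicles is met. The minimum estrous-cycle
#' length is that day plus one (the proestrus/ovulation day).
#'
#' @param scenario A [cohort_scenario()].
#' @param params A [growth_params()] object.
#' @param seed Integer seed (only consumed when an atresia rule is present;
#'   the growth itself is deterministic).
#' @param stage Cycle stage passed to the hazard (default `"diestrus"`).
#' @return Object of class `cohort_simulation`: list with `report` (per-day
#'   data frame: `day`, `follicle_id`, `diameter`, `status`,
#'   `cumulative_preovulatory`), `target_met_day` (integer or `NA` when the
#'   target is unmet within `max_days`), `min_cycle_length_days`, and
#'   `target_met`.
#' @examples
#' sc <- cohort_scenario(data.frame(diameter = rep(250, 12), li = 0.45))
#' simulate_cohort(sc, seed = 1)$target_met_day  # 4
#' @export
simulate_cohort <- function(scenario, params = growth_params(), seed = 1,
                            stage = "diestrus") {
  stopifnot(inherits(scenario, "cohort_scenario"))
  set.seed(seed)
  sf <- scenario$starting_follicles
  n <- nrow(sf)
  nd <- scenario$max_days
  # deterministic growth paths, one column per follicle
  diam <- vapply(seq_len(n), function(i)
    simulate_growth(sf$diameter[i], sf$li[i], nd, params)$diameter,
    numeric(nd + 1))
  diam <- matrix(diam, nrow = nd + 1)
  alive <- rep(TRUE, n)
  reached <- rep(FALSE, n)
  rows <- vector("list", nd + 1)
  target_met_day <- NA_integer_
  for (day in 0:nd) {
    d_now <- diam[day + 1, ]
    reached <- reached | (d_now > scenario$preovulatory_min)
    if (!is.null(scenario$atresia_rule)) {
      rule <- scenario$atresia_rule
      at_risk <- alive & !reached & d_now >= rule$onset_diameter
      if (day > 0 && any(at_risk)) {
        pct <- rank(sf$li[at_risk]) / (sum(at_risk) + 1)
        dies <- rbinom(sum(at_risk), 1, hazard_probability(rule, pct, stage)) == 1
        alive[which(at_risk)[dies]] <- FALSE
      }
    }
    cum <- sum(alive & reached)
    if (is.na(target_met_day) && cum >= scenario$cohort_target)
      target_met_day <- day
    rows[[day + 1]] <- data.frame(
      day = day,
      follicle_id = seq_len(n),
      diameter = d_now,
      status = ifelse(!alive, "atretic",
                      ifelse(reached, "preovulatory", "growing")),
      cumulative_preovulatory = cum
    )
  }
  structure(list(report = do.call(rbind, rows),
                 target_met_day = target_met_day,
                 min_cycle_length_days = if (is.na(target_met_day)) NA_integer_
                                         else target_met_day + 1L,
                 target_met = !is.na(target_met_day)),
            class = "cohort_simulation")
}

#' @export
print.cohort_simulation <- function(x, ...) {
  if (x$target_met) {
    cat(sprintf("Cohort target met at day %d (minimum cycle length %d days)\n",
                x$target_met_day, x$min_cycle_length_days))
  } else {
    cat("Cohort target unmet within the simulated horizon\n")
  }
  invisible(x)
}

#' Survivor-effect summary of pulse-label LIs
#'
#' Compares the injection-time pulse-label LI of the follicles that reached
#' the preovulatory stage (the survivors) with the full population at
#' injection. A positive difference indicates preferential removal of
#' slow-growing follicles. Statistical testing (survivors versus
#' non-survivors) is delegated to the rank-based Wilcoxon test.
#'
#' @param population Data frame of the full population at injection, with
#'   `follicle_id` and `labeling_index`.
#' @param survivors Subset of `population` (matched by `follicle_id`), or a
#'   vector of surviving `follicle_id`s.
#' @return List with group sizes, means, medians, `difference_mean`,
#'   `difference_median`, and `p_value` (NA when the survivors are the whole
#'   population).
#' @export
survivor_effect <- function(population, survivors) {
  stopifnot(is.data.frame(population),
            all(c("follicle_id", "labeling_index") %in% names(population)))
  ids <- if (is.data.frame(survivors)) survivors$follicle_id else survivors
  if (length(ids) == 0) stop("survivor set is empty")
  if (!all(ids %in% population$follicle_id))
    stop("survivors must be a subset of the population")
  is_surv <- population$follicle_id %in% ids
  li_pop <- population$labeling_index
  li_surv <- li_pop[is_surv]
  li_rest <- li_pop[!is_surv]
  p <- if (length(li_rest) == 0) NA_real_ else
    suppressWarnings(wilcox.test(li_surv, li_rest, exact = FALSE)$p.value)
  list(n_population = length(li_pop),
       n_survivors = length(li_surv),
       mean_population = mean(li_pop),
       mean_survivors = mean(li_surv),
       median_population = median(li_pop),
       median_survivors = median(li_surv),
       difference_mean = mean(li_surv) - mean(li_pop),
       difference_median = median(li_surv) - median(li_pop),
       p_value = p)
}

#' Survivor-effect experiment on a synthetic same-size cohort
#'
#' Emulates the long-term pulse-chase design: a cohort of FSH-dependent
#' follicles of identical starting diameter but heterogeneous LI is labeled,
#' grown for `days` 24-h iterations under the LI-percentile atresia hazard,
#' and the pulse-label LI of the follicles that survive to exceed the
#' preovulatory threshold is compared with the injection-time population
#' mean. Fixing the starting size isolates growth-rate selection from the
#' size-LI confound.
#'
#' @param n Cohort size (default 150).
#' @param start_diameter Starting diameter, um (default 300).
#' @param li_mean Mean injection-time LI; default the median LI at
#'   `start_diameter`.
#' @param li_sd Between-follicle LI standard deviation (default 0.07).
#' @param days Chase duration in days (default 2).
#' @param hazard An [atresia_hazard()] or `NULL` to disable atresia.
#' @param preovulatory_min Preovulatory threshold, um (default 350).
#' @param params A [growth_params()] object.
#' @param stage Cycle stage for the hazard multiplier (default "diestrus").
#' @param seed Integer seed.
#' @return List with the [survivor_effect()] summary under `effect` and the
#'   per-follicle cohort table under `cohort`.
#' @export
survivor_experiment <- function(n = 150, start_diameter = 300, li_mean = NULL,
                                li_sd = 0.07, days = 2,
                                hazard = atresia_hazard(),
                                preovulatory_min = 350,
                                params = growth_params(),
                                stage = "diestrus", seed = 1) {
  set.seed(seed)
  if (is.null(li_mean)) li_mean <- median_li(start_diameter, params)
  li <- clamp01(rnorm(n, li_mean, li_sd))
  final_d <- vapply(li, function(l)
    simulate_growth(start_diameter, l, days, params)$diameter[days + 1],
    numeric(1))
  alive <- rep(TRUE, n)
  if (!is.null(hazard)) {
    pct <- rank(li) / (n + 1)
    p_day <- hazard_probability(hazard, pct, stage)
    for (d in seq_len(days)) {
      at_risk <- alive & final_d <= preovulatory_min  # never-preovulatory only
      dies <- rbinom(sum(at_risk), 1, p_day[at_risk]) == 1
      alive[which(at_risk)[dies]] <- FALSE
    }
  }
  cohort <- data.frame(follicle_id = sprintf("c%03d", seq_len(n)),
                       diameter_injection = start_diameter,
                       labeling_index = li,
                       diameter_final = final_d,
                       atretic = !alive,
                       survivor = alive & final_d > preovulatory_min)
  surv <- cohort[cohort$survivor, ]
  list(effect = if (nrow(surv) > 0) survivor_effect(cohort, surv) else NULL,
       cohort = cohort)
}
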