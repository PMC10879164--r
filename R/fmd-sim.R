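# Annual fasting-mimicking-diet (FMD) lifecourse simulation.
#
# Each simulated year has three anchor points: A (start of year), C (after
# the three FMD cycles, ~3 months in), and D (after the rebound on a normal
# diet, ~6 months in; carried forward as next year's A). Two published
# linear response surfaces drive the cycle change (A to C) and the rebound
# (C to D) as functions of biological and chronological age. Composing them
# gives an affine one-year map of biological age, whose fixed-point slope
# determines the stabilized rate of biological aging under annual use.
# Mortality during the simulated period is deliberately ignored: trajectories
# describe biological age conditional on remaining alive.

#' FMD response-surface coefficients
#'
#' Defaults are the published ordinary-least-squares coefficients for the
#' two response surfaces: the change in biological age over three FMD cycles,
#' `0.1017 - 0.1906 * BioAge + 0.1227 * Age`, and the rebound after
#' returning to a normal diet,
#' `0.6687 - 0.5567 * BioAge_A + 0.4008 * BioAge_C + 0.1157 * Age`.
#' Standard errors default to zero (deterministic simulation); supplying
#' them enables per-draw coefficient uncertainty.
#'
#' @param cycle Named numeric: `intercept`, `bioage`, `age`.
#' @param rebound Named numeric: `intercept`, `bioage_a`, `bioage_c`, `age`.
#' @param cycle_se,rebound_se Standard errors aligned with `cycle` and
#'   `rebound` (default all zero).
#' @return An object of class `fmd_coefficients`.
#' @export
fmd_coefficients <- function(
    cycle = c(intercept = 0.1017, bioage = -0.1906, age = 0.1227),
    rebound = c(intercept = 0.6687, bioage_a = -0.5567,
                bioage_c = 0.4008, age = 0.1157),
    cycle_se = c(intercept = 0, bioage = 0, age = 0),
    rebound_se = c(intercept = 0, bioage_a = 0, bioage_c = 0, age = 0)) {
  stopifnot(
    all(c("intercept", "bioage", "age") %in% names(cycle)),
    all(c("intercept", "bioage_a", "bioage_c", "age") %in% names(rebound)),
    all(cycle_se >= 0), all(rebound_se >= 0)
  )
  structure(
    list(cycle = cycle, rebound = rebound,
         cycle_se = cycle_se[names(cycle)],
         rebound_se = rebound_se[names(rebound)]),
    class = "fmd_coefficients"
  )
}

#' @export
print.fmd_coefficients <- function(x, ...) {
  cat("FMD response-surface coefficients\n cycle (A->C): ")
  cat(sprintf("%s=%g", names(x$cycle), x$cycle), sep = ", ")
  cat("\n rebound (C->D): ")
  cat(sprintf("%s=%g", names(x$rebound), x$rebound), sep = ", ")
  cat("\n")
  invisible(x)
}

has_uncertainty <- function(coeffs) {
  any(coeffs$cycle_se > 0) || any(coeffs$rebound_se > 0)
}

draw_fmd_coefficients <- function(coeffs) {
  cyc <- stats::rnorm(length(coeffs$cycle), coeffs$cycle, coeffs$cycle_se)
  reb <- stats::rnorm(length(coeffs$rebound), coeffs$rebound,
                      coeffs$rebound_se)
  names(cyc) <- names(coeffs$cycle)
  names(reb) <- names(coeffs$rebound)
  fmd_coefficients(cycle = cyc, rebound = reb)
}

#' Change in biological age over three FMD cycles
#'
#' @param bioage Biological age at the start of the year (years).
#' @param age Chronological age at the start of the year (years).
#' @param coeffs An [fmd_coefficients()] object.
#' @return Signed change in biological age (years).
#' @export
fmd_cycle_change <- function(bioage, age, coeffs = fmd_coefficients()) {
  coeffs$cycle[["intercept"]] + coeffs$cycle[["bioage"]] * bioage +
    coeffs$cycle[["age"]] * age
}

#' Rebound change in biological age after returning to a normal diet
#'
#' @param bioage_a Biological age at the start of the year (point A, years).
#' @param bioage_c Biological age after the FMD cycles (point C, years).
#' @param age Chronological age at the start of the year (years).
#' @param coeffs An [fmd_coefficients()] object.
#' @return Signed change in biological age (years).
#' @export
rebound_change <- function(bioage_a, bioage_c, age,
                           coeffs = fmd_coefficients()) {
  coeffs$rebound[["intercept"]] + coeffs$rebound[["bioage_a"]] * bioage_a +
    coeffs$rebound[["bioage_c"]] * bioage_c + coeffs$rebound[["age"]] * age
}

#' Effect-decay multiplier by years since baseline
#'
#' The sensitivity schedule shrinking the FMD effect in later years. Mode
#' `"none"` returns 1. The published wording ("dividing by 2 multiplied by
#' years since baseline") and its worked examples (half as effective in year
#' 2, a quarter in year 3) agree at years 1-2 but diverge afterwards, so
#' both readings are provided: `"linear"` gives `1/(2y)` and `"doubling"`
#' gives `1/2^y`, each equal to 1 at `y = 0`.
#'
#' @param years_since_baseline Non-negative integer(s).
#' @param mode `"none"`, `"linear"` (default decay reading) or `"doubling"`.
#' @return Multiplier(s) in (0, 1].
#' @export
decay_multiplier <- function(years_since_baseline,
                             mode = c("none", "linear", "doubling")) {
  mode <- match.arg(mode)
  y <- years_since_baseline
  if (any(y < 0)) stop("years_since_baseline must be >= 0", call. = FALSE)
  switch(mode,
    none = rep(1, length(y)),
    linear = ifelse(y == 0, 1, 1 / (2 * y)),
    doubling = ifelse(y == 0, 1, 1 / 2^y)
  )
}

#' Advance one simulated year of annual FMD use
#'
#' Applies the cycle change and then the rebound, each multiplied by the
#' decay multiplier, completing the current year's C and D points; the
#' returned state is positioned at the start of the next year (chronological
#' age incremented by one, biological age A equal to this year's D).
#'
#' @param state List with `year` (index since baseline), `age` (chronological
#'   years at the start of the year) and `bioage_a` (biological age at point
#'   A).
#' @param coeffs An [fmd_coefficients()] object.
#' @param decay Decay multiplier in (0, 1] applied to both changes (set
#'   `decay_rebound = FALSE` to decay the cycle change only).
#' @param decay_rebound Whether the decay also scales the rebound change.
#' @return State list for the next year, with `bioage_c` and `bioage_d`
#'   recording the completed year's points.
#' @export
one_year_update <- function(state, coeffs = fmd_coefficients(), decay = 1,
                            decay_rebound = TRUE) {
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]", call. = FALSE)
  b_a <- state$bioage_a
  age <- state$age
  b_c <- b_a + decay * fmd_cycle_change(b_a, age, coeffs)
  d_mult <- if (decay_rebound) decay else 1
  b_d <- b_c + d_mult * rebound_change(b_a, b_c, age, coeffs)
  list(year = state$year + 1L, age = age + 1, bioage_a = b_d,
       bioage_c = b_c, bioage_d = b_d)
}

#' Affine coefficients of the composed one-year map
#'
#' With no decay the composition of the cycle and rebound surfaces is affine
#' in the start-of-year state: `B_next = a * B + b * A + c`. Returned by
#' symbolic composition of the coefficient set; used as the closed-form
#' oracle for the iterative engine, whose stabilized annual increment is
#' `b / (1 - a)`.
#'
#' @param coeffs An [fmd_coefficients()] object.
#' @return Named numeric `c(a, b, c)`.
#' @export
fmd_affine_map <- function(coeffs = fmd_coefficients()) {
  c5 <- coeffs$cycle; c6 <- coeffs$rebound
  # C = c5_int + (1 + c5_b) B + c5_a A ; D = (1 + c6_c) C + c6_ba B + c6_a A + c6_int
  g <- 1 + c6[["bioage_c"]]
  a <- g * (1 + c5[["bioage"]]) + c6[["bioage_a"]]
  b <- g * c5[["age"]] + c6[["age"]]
  cc <- g * c5[["intercept"]] + c6[["intercept"]]
  c(a = a, b = b, c = cc)
}

#' Simulation configuration
#'
#' @param horizon Chronological age at which the simulation stops (default
#'   70 years).
#' @param draws Monte Carlo draws per person (default 1000); with all
#'   coefficient standard errors zero every draw is identical.
#' @param weight_divisor Divisor converting a survey sampling weight into a
#'   number of draws to average (default 548.5).
#' @param decay Decay mode, see [decay_multiplier()].
#' @param seed Integer RNG seed (required whenever uncertainty or draw
#'   selection is stochastic).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(horizon = 70, draws = 1000, weight_divisor = 548.5,
                       decay = c("none", "linear", "doubling"), seed = 1L) {
  decay <- match.arg(decay)
  if (draws < 1) stop("draws must be >= 1", call. = FALSE)
  if (weight_divisor <= 0) stop("weight_divisor must be > 0", call. = FALSE)
  structure(
    list(horizon = horizon, draws = as.integer(draws),
         weight_divisor = weight_divisor, decay = decay,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic single trajectory for one coefficient draw
simulate_trajectory <- function(start_age, start_bioage, horizon, coeffs,
                                decay_mode) {
  n_years <- ceiling(horizon - start_age)
  b_a <- b_c <- b_d <- numeric(n_years)
  b <- start_bioage
  age0 <- start_age
  for (i in seq_len(n_years)) {
    y <- i - 1L
    mult <- decay_multiplier(y, decay_mode)
    b_a[i] <- b
    c_i <- b + mult * fmd_cycle_change(b, age0 + y, coeffs)
    d_i <- c_i + mult * rebound_change(b, c_i, age0 + y, coeffs)
    b_c[i] <- c_i
    b_d[i] <- d_i
    b <- d_i
  }
  data.frame(
    year = seq_len(n_years) - 1L, age = age0 + seq_len(n_years) - 1L,
    bioage_a = b_a, bioage_c = b_c, bioage_d = b_d
  )
}

#' Simulate one person's annual-FMD lifecourse
#'
#' Runs the yearly cycle/rebound update from the starting state until the
#' configured horizon age. With any nonzero coefficient standard error,
#' coefficients are redrawn per Monte Carlo draw from
#' `Normal(coefficient, SE)`; with all standard errors zero the trajectory
#' is deterministic and simply replicated across draws.
#'
#' @param start_age Chronological age at baseline (years; below the horizon).
#' @param start_bioage Biological age at baseline (years).
#' @param config A [sim_config()].
#' @param coeffs An [fmd_coefficients()] object.
#' @return Long data frame with columns `draw`, `year`, `age`, `bioage_a`,
#'   `bioage_c`, `bioage_d`.
#' @export
simulate_person <- function(start_age, start_bioage,
                            config = sim_config(),
                            coeffs = fmd_coefficients()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$horizon <= start_age) {
    stop("horizon must exceed start_age", call. = FALSE)
  }
  if (!has_uncertainty(coeffs)) {
    traj <- simulate_trajectory(start_age, start_bioage, config$horizon,
                                coeffs, config$decay)
    out <- traj[rep(seq_len(nrow(traj)), times = config$draws), ]
    out$draw <- rep(seq_len(config$draws), each = nrow(traj))
    rownames(out) <- NULL
    return(out[, c("draw", "year", "age", "bioage_a", "bioage_c", "bioage_d")])
  }
  with_seed(config$seed, {
    per_draw <- lapply(seq_len(config$draws), function(d) {
      traj <- simulate_trajectory(start_age, start_bioage, config$horizon,
                                  draw_fmd_coefficients(coeffs), config$decay)
      traj$draw <- d
      traj
    })
    out <- do.call(rbind, per_draw)
    rownames(out) <- NULL
    out[, c("draw", "year", "age", "bioage_a", "bioage_c", "bioage_d")]
  })
}

#' Survey-weighted aggregation of per-draw trajectories
#'
#' Converts a survey sampling weight into a number of draws
#' `k = round(weight / divisor)` (half away from zero, clamped to at least
#' 1), selects `k` of the available draws uniformly at random (seeded), and
#' returns their per-year mean trajectory.
#'
#' @param trajectories Long data frame from [simulate_person()].
#' @param sampling_weight Survey sampling weight (raw scale, before
#'   division).
#' @param config A [sim_config()] (supplies the divisor and seed).
#' @return Data frame with one row per year: `year`, `age`, mean `bioage_a`,
#'   `bioage_c`, `bioage_d`, and the number of draws `k` averaged.
#' @export
weighted_aggregate <- function(trajectories, sampling_weight,
                               config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  draw_ids <- unique(trajectories$draw)
  k <- max(1, round_half_away(sampling_weight / config$weight_divisor))
  if (k > length(draw_ids)) {
    stop(sprintf("weight implies %d draws but only %d are available",
                 k, length(draw_ids)), call. = FALSE)
  }
  chosen <- if (k == length(draw_ids)) draw_ids else {
    with_seed(config$seed, sample(draw_ids, k))
  }
  sub <- trajectories[trajectories$draw %in% chosen, ]
  agg <- stats::aggregate(
    sub[, c("age", "bioage_a", "bioage_c", "bioage_d")],
    by = list(year = sub$year), FUN = mean
  )
  agg$k <- k
  agg
}

#' Population-level annual-FMD simulation
#'
#' Runs [simulate_person()] plus [weighted_aggregate()] for every row of a
#' scored cohort and summarizes the population: mean biological age (point
#' D) by attained chronological age, the stabilized annual biological-age
#' increment (mean across persons of the final-year increment), and the
#' biological-minus-chronological age gap at the horizon.
#'
#' @param cohort Data frame with columns `age`, `bioage` and
#'   `sample_weight`; persons at or above the horizon age are skipped.
#' @param config A [sim_config()].
#' @param coeffs An [fmd_coefficients()] object.
#' @return List with `per_person` (long data frame of weighted mean
#'   trajectories), `mean_by_age` (population mean of point D by attained
#'   age), `stabilized_increment` (years of biological age per chronological
#'   year) and `horizon_gap` (mean biological minus chronological age in the
#'   final simulated year).
#' @export
population_simulation <- function(cohort, config = sim_config(),
                                  coeffs = fmd_coefficients()) {
  stop_if_missing_cols(cohort, c("age", "bioage", "sample_weight"), "cohort")
  if (anyNA(cohort$bioage)) {
    stop("cohort lacks biological age scores for some persons", call. = FALSE)
  }
  active <- cohort[cohort$age < config$horizon, ]
  if (nrow(active) == 0) stop("no persons below the horizon age", call. = FALSE)
  deterministic <- !has_uncertainty(coeffs)
  per_person <- lapply(seq_len(nrow(active)), function(i) {
    if (deterministic) {
      # with zero coefficient SEs every draw is identical, so the weighted
      # mean equals the single deterministic trajectory for any k
      agg <- simulate_trajectory(active$age[i], active$bioage[i],
                                 config$horizon, coeffs, config$decay)
      agg$k <- max(1, round_half_away(
        active$sample_weight[i] / config$weight_divisor
      ))
    } else {
      traj <- simulate_person(active$age[i], active$bioage[i], config, coeffs)
      agg <- weighted_aggregate(traj, active$sample_weight[i], config)
    }
    agg$id <- if ("id" %in% names(active)) active$id[i] else i
    agg
  })
  long <- do.call(rbind, per_person)
  long$attained_age <- long$age + 1  # age at the year's D point carry-over
  mean_by_age <- stats::aggregate(
    list(mean_bioage_d = long$bioage_d),
    by = list(attained_age = round(long$attained_age)), FUN = mean
  )
  final_increment <- vapply(per_person, function(tr) {
    n <- nrow(tr)
    if (n < 2) return(NA_real_)
    tr$bioage_d[n] - tr$bioage_d[n - 1]
  }, numeric(1))
  horizon_gap <- vapply(per_person, function(tr) {
    n <- nrow(tr)
    tr$bioage_d[n] - (tr$age[n] + 1)
  }, numeric(1))
  list(
    per_person = long,
    mean_by_age = mean_by_age,
    stabilized_increment = mean(final_increment, na.rm = TRUE),
    horizon_gap = mean(horizon_gap)
  )
}
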