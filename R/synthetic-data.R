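# Synthetic reference populations and trial cohorts.
#
# The generators reproduce the statistical structure the downstream analysis
# assumes -- biomarkers linear in age plus independent Gaussian noise, and
# Gompertz-distributed mortality with right censoring at a fixed horizon --
# so that every stage of the pipeline can be exercised and validated against
# known ground truth without any external survey or trial data.

#' Default seven-marker clinical chemistry panel
#'
#' The marker set used throughout: albumin, alkaline phosphatase, serum
#' creatinine, C-reactive protein, glycated hemoglobin, systolic blood
#' pressure and total cholesterol.
#'
#' @return Character vector of the seven marker column names.
#' @export
kdm_markers <- function() {
  c("albumin", "alp", "creatinine", "crp", "hba1c", "sbp", "totchol")
}

#' Generative model for age-linear biomarkers
#'
#' Describes a reference population in which each biomarker follows
#' `intercept + slope * age` plus independent Gaussian noise. Defaults are
#' plausible adult cross-sectional age trends for the seven-marker panel
#' (albumin in g/dL declining with age, alkaline phosphatase in U/L,
#' creatinine in mg/dL, CRP in mg/L on the raw scale, HbA1c in %, systolic
#' blood pressure in mmHg, total cholesterol in mg/dL).
#'
#' @param markers Character vector of marker names.
#' @param intercepts,slopes,noise_sd Numeric vectors aligned with `markers`:
#'   the marker value at age zero (marker units), the change per year of age,
#'   and the residual standard deviation (marker units; strictly positive).
#' @param age_range Length-2 numeric, the age span of the reference
#'   population in years (lower < upper).
#' @return An object of class `marker_model`.
#' @export
marker_model <- function(markers = kdm_markers(),
                         intercepts = c(4.90, 55, 0.70, 0.20, 4.70, 95, 150),
                         slopes = c(-0.010, 0.50, 0.004, 0.040, 0.015, 0.60, 1.00),
                         noise_sd = c(0.20, 10, 0.08, 0.80, 0.30, 12, 20),
                         age_range = c(30, 90)) {
  m <- length(markers)
  stopifnot(
    length(intercepts) == m, length(slopes) == m, length(noise_sd) == m,
    length(age_range) == 2
  )
  if (any(noise_sd < 0)) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (age_range[1] >= age_range[2]) {
    stop("age_range lower bound must be below upper bound", call. = FALSE)
  }
  structure(
    list(
      markers = as.character(markers),
      intercepts = stats::setNames(as.numeric(intercepts), markers),
      slopes = stats::setNames(as.numeric(slopes), markers),
      noise_sd = stats::setNames(as.numeric(noise_sd), markers),
      age_range = as.numeric(age_range)
    ),
    class = "marker_model"
  )
}

#' @export
print.marker_model <- function(x, ...) {
  cat(sprintf(
    "marker_model: %d markers, ages %g-%g\n",
    length(x$markers), x$age_range[1], x$age_range[2]
  ))
  print(data.frame(
    intercept = x$intercepts, slope = x$slopes, noise_sd = x$noise_sd
  ))
  invisible(x)
}

#' Invert the Gompertz survival function to sample an event time
#'
#' For hazard `h(t) = lambda * exp(gamma * t)` the survival function is
#' `s(t) = exp((lambda/gamma) * (1 - exp(gamma * t)))`; given a uniform draw
#' `u` the event time solving `s(t) = u` is
#' `t = (1/gamma) * log(1 - (gamma/lambda) * log(u))`.
#'
#' @param hazard_scale Baseline hazard scale `lambda` (> 0), per year.
#' @param gamma Gompertz shape (per year), nonzero.
#' @param u Uniform(0,1) draw(s), strictly inside the unit interval.
#' @return Event time(s) in years.
#' @export
sample_gompertz_event_time <- function(hazard_scale, gamma, u) {
  if (any(hazard_scale <= 0)) stop("hazard_scale must be > 0", call. = FALSE)
  if (any(gamma == 0)) stop("gamma must be nonzero", call. = FALSE)
  if (any(u <= 0 | u >= 1)) stop("u must lie strictly in (0, 1)", call. = FALSE)
  (1 / gamma) * log1p(-(gamma / hazard_scale) * log(u))
}

#' Default cause-of-death mixture
#'
#' Multinomial shares used to label simulated deaths with a cause; roughly
#' the adult US cause-of-death mix across the causes the mortality models
#' distinguish.
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_cause_probs <- function() {
  c(heart = 0.32, cancer = 0.30, cerebrovascular = 0.07,
    diabetes = 0.04, other = 0.27)
}

#' Generate a synthetic reference population
#'
#' Draws `n` people with ages uniform over the model's age range, biomarkers
#' on their generative age lines plus Gaussian noise, body weight, survey
#' sampling weights, and Gompertz-distributed mortality follow-up with right
#' censoring at `censor_horizon` years.
#'
#' The per-person hazard scale is `exp(beta_age * age + beta_bioage *
#' bioage + const)` from `gompertz`, where the person's biological age is
#' their KDM score under `kdm_truth` when supplied, and their chronological
#' age otherwise. Deaths are assigned a cause by a multinomial draw.
#'
#' Survey sampling weights are drawn log-normal and shifted to be at least 1,
#' scaled so that division by 548.5 and rounding spans roughly 6-1000.
#'
#' @param model A [marker_model()].
#' @param gompertz A [gompertz_model()] with covariates `age` and `bioage`.
#' @param kdm_truth Optional [kdm_parameters()] used to score the true
#'   biological age entering the hazard; `NULL` uses chronological age.
#' @param n Number of people (>= 10).
#' @param censor_horizon Administrative censoring time in years (> 0).
#' @param seed Integer RNG seed; required, the draw is deterministic given it.
#' @param cause_probs Named probabilities for cause-of-death labels.
#' @return A data frame with columns `id`, `age`, the seven markers, `weight`
#'   (kg), `sample_weight`, `bioage` (the generative truth entering the
#'   hazard), `time` (years), `event` (0/1) and `cause` (`NA` when censored).
#' @export
generate_reference_population <- function(model,
                                          gompertz,
                                          kdm_truth = NULL,
                                          n = 5000,
                                          censor_horizon = 23,
                                          seed,
                                          cause_probs = default_cause_probs()) {
  stopifnot(inherits(model, "marker_model"))
  if (n < 10) stop("n must be at least 10", call. = FALSE)
  if (censor_horizon <= 0) stop("censor_horizon must be > 0", call. = FALSE)
  if (abs(sum(cause_probs) - 1) > 1e-8) {
    stop("cause_probs must sum to 1", call. = FALSE)
  }
  with_seed(seed, {
    age <- stats::runif(n, model$age_range[1], model$age_range[2])
    panel <- sapply(model$markers, function(mk) {
      model$intercepts[mk] + model$slopes[mk] * age +
        stats::rnorm(n, 0, model$noise_sd[mk])
    })
    panel <- as.data.frame(panel)
    weight <- pmax(stats::rnorm(n, 75, 15), 35)
    # survey weight: lognormal on the divisor scale, floor at 1
    sample_weight <- pmax(548.5 * exp(stats::rnorm(n, log(144), 1.0)), 1)

    bioage <- if (is.null(kdm_truth)) {
      age
    } else {
      kdm_bioage(panel, age, kdm_truth)$ba_ec
    }
    lambda <- exp(gompertz$coef["age"] * age +
                    gompertz$coef["bioage"] * bioage +
                    gompertz$coef["const"])
    u <- stats::runif(n)
    t_event <- sample_gompertz_event_time(lambda, gompertz$gamma, u)
    event <- as.integer(t_event <= censor_horizon)
    time <- pmin(t_event, censor_horizon)
    cause <- rep(NA_character_, n)
    n_ev <- sum(event)
    if (n_ev > 0) {
      cause[event == 1] <- sample(names(cause_probs), n_ev,
                                  replace = TRUE, prob = cause_probs)
    }
    out <- data.frame(id = seq_len(n), age = age)
    out <- cbind(out, panel)
    out$weight <- weight
    out$sample_weight <- sample_weight
    out$bioage <- bioage
    out$time <- time
    out$event <- event
    out$cause <- cause
    out
  })
}

#' Specification of a synthetic intervention trial cohort
#'
#' Describes a paired baseline/follow-up cohort: each person is drawn from
#' the reference model at baseline, and at follow-up each marker is shifted
#' by a signed intervention effect plus measurement noise; a configurable
#' fraction of "non-responders" get the effects with flipped sign. Body
#' weight change is drawn from a normal distribution (default a modest loss,
#' mean -2.5 kg, SD 2.0 kg, typical of three diet cycles).
#'
#' @param n Sample size (>= 2).
#' @param effects Named numeric vector of signed per-marker intervention
#'   effects (marker units); names must match the reference model's markers.
#' @param weight_change_mean,weight_change_sd Normal distribution of the
#'   baseline-to-follow-up body-weight change, in kg.
#' @param nonresponder_fraction Fraction of people whose marker effects are
#'   sign-flipped (in \[0, 1\]).
#' @param followup_noise_frac Follow-up measurement noise SD as a fraction of
#'   each marker's cross-sectional noise SD.
#' @param age_range Optional length-2 numeric restricting the trial's age
#'   span; defaults to the reference model's range.
#' @param seed Integer RNG seed.
#' @return An object of class `trial_cohort_spec`.
#' @export
trial_cohort_spec <- function(n = 52,
                              effects,
                              weight_change_mean = -2.5,
                              weight_change_sd = 2.0,
                              nonresponder_fraction = 0,
                              followup_noise_frac = 0.5,
                              age_range = NULL,
                              seed) {
  if (n < 2) stop("trial sample size must be at least 2", call. = FALSE)
  if (nonresponder_fraction < 0 || nonresponder_fraction > 1) {
    stop("nonresponder_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n = as.integer(n), effects = effects,
      weight_change_mean = weight_change_mean,
      weight_change_sd = weight_change_sd,
      nonresponder_fraction = nonresponder_fraction,
      followup_noise_frac = followup_noise_frac,
      age_range = age_range,
      seed = seed
    ),
    class = "trial_cohort_spec"
  )
}

#' KDM parameters implied by a generative marker model
#'
#' Under the generative model the population regression of each marker on
#' age has slope `k_j = slope_j`, intercept `q_j = intercept_j` and residual
#' scale `s_j = noise_sd_j` exactly. With independent marker noise the
#' marker-only estimator deviates from chronological age with variance
#' `1 / sum_j (k_j/s_j)^2`, which is therefore the theoretical `s_BA^2`.
#'
#' @param model A [marker_model()].
#' @param s_ba2 Optional fixed override for `s_BA^2`.
#' @return A [kdm_parameters()] object (the generative truth).
#' @export
kdm_truth_from_model <- function(model, s_ba2 = NULL) {
  stopifnot(inherits(model, "marker_model"))
  if (any(model$noise_sd == 0)) {
    stop("all noise standard deviations must be positive to imply KDM truth",
         call. = FALSE)
  }
  w <- sum((model$slopes / model$noise_sd)^2)
  kdm_parameters(
    k = model$slopes, q = model$intercepts, s = model$noise_sd,
    s_ba2 = s_ba2 %||% (1 / w)
  )
}

#' Per-marker effects equivalent to a target biological-age shift
#'
#' Translates a desired shift in KDM biological age (years) into per-marker
#' intervention effects by moving every marker along its generative age
#' line. Because the KDM estimator is a precision-weighted mean of the
#' marker-implied age and chronological age, a marker shift worth `years`
#' along the lines changes the score by only
#' `years * w / (w + 1/s_BA^2)` with `w = sum_j (k_j/s_j)^2`; by default the
#' effects are inflated by the inverse of that attenuation factor so that
#' the realized change in scored biological age equals the target.
#'
#' @param model A [marker_model()].
#' @param years Signed target shift in scored biological age, in years
#'   (negative = rejuvenation).
#' @param params KDM parameters defining the attenuation (default the
#'   generative truth from [kdm_truth_from_model()]).
#' @param correct_attenuation If `FALSE`, return the uncorrected
#'   `slope_j * years`.
#' @return Named numeric vector of marker effects.
#' @export
marker_effects_for_bioage_shift <- function(model, years,
                                            params = kdm_truth_from_model(model),
                                            correct_attenuation = TRUE) {
  stopifnot(inherits(model, "marker_model"))
  eff <- model$slopes * years
  if (correct_attenuation) {
    w <- sum((params$k / params$s)^2)
    eff <- eff * (w + 1 / params$s_ba2) / w
  }
  eff
}

#' Generate a paired baseline/follow-up trial cohort
#'
#' @param model A [marker_model()] describing the population the trial
#'   samples from.
#' @param spec A [trial_cohort_spec()].
#' @return A wide data frame with one row per person: `id`, `age`,
#'   `weight_bl`, `weight_fu`, `weight_change`, `bmi`, `glucose`,
#'   `<marker>_bl` and `<marker>_fu` for each marker, and `nonresponder`
#'   (the generative truth flag). `bmi` and fasting `glucose` (mg/dL) are
#'   baseline covariates used by the at-risk filter and responder models.
#' @export
generate_trial_cohort <- function(model, spec) {
  stopifnot(inherits(model, "marker_model"), inherits(spec, "trial_cohort_spec"))
  effects <- spec$effects
  missing <- setdiff(model$markers, names(effects))
  if (length(missing)) {
    stop("effects missing for marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rng <- spec$age_range %||% model$age_range
  with_seed(spec$seed, {
    n <- spec$n
    age <- stats::runif(n, rng[1], rng[2])
    baseline <- sapply(model$markers, function(mk) {
      model$intercepts[mk] + model$slopes[mk] * age +
        stats::rnorm(n, 0, model$noise_sd[mk])
    })
    baseline <- as.data.frame(baseline)
    n_nr <- round_half_away(spec$nonresponder_fraction * n)
    nonresponder <- rep(0L, n)
    if (n_nr > 0) nonresponder[sample.int(n, n_nr)] <- 1L
    sign_flip <- ifelse(nonresponder == 1L, -1, 1)
    followup <- sapply(model$markers, function(mk) {
      baseline[[mk]] + sign_flip * effects[mk] +
        stats::rnorm(n, 0, spec$followup_noise_frac * model$noise_sd[mk])
    })
    followup <- as.data.frame(followup)
    weight_bl <- pmax(stats::rnorm(n, 75, 15), 40)
    weight_change <- stats::rnorm(n, spec$weight_change_mean, spec$weight_change_sd)
    height_m <- pmax(stats::rnorm(n, 1.67, 0.09), 1.4)
    out <- data.frame(
      id = seq_len(n),
      age = age,
      weight_bl = weight_bl,
      weight_fu = weight_bl + weight_change,
      weight_change = weight_change,
      bmi = weight_bl / height_m^2,
      glucose = pmax(stats::rnorm(n, 95, 10), 60)
    )
    names(baseline) <- paste0(model$markers, "_bl")
    names(followup) <- paste0(model$markers, "_fu")
    out <- cbind(out, baseline, followup)
    out$nonresponder <- nonresponder
    out
  })
}

#' Write a cohort to CSV with a reproducibility sidecar
#'
#' Writes the data frame as plain CSV and a `<path>.meta.json` sidecar
#' recording the seed, a content hash of the configuration, and the column
#' order, so every output file is traceable to its generating configuration.
#'
#' @param cohort Data frame to write.
#' @param path Output CSV path.
#' @param seed Seed used to generate the cohort (recorded in the sidecar).
#' @param config Optional list recorded (hashed) in the sidecar.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, seed = NULL, config = NULL) {
  utils::write.csv(cohort, path, row.names = FALSE)
  meta <- list(
    seed = seed,
    config_hash = config_hash(config),
    columns = names(cohort),
    n = nrow(cohort)
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# stable content hash of a configuration list (no extra deps: sum over
# serialized bytes is enough for provenance labelling, not cryptography)
config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  raw <- serialize(config, NULL, version = 2)
  sprintf("%08x", sum(as.integer(raw)) %% 4294967291)
}
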