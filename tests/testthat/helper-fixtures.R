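# shared fixtures built in code

# the two-marker worked example: marker1 on x = 10 + 1.0*age (s = 5),
# marker2 on x = 100 - 2.0*age (s = 10), s_BA^2 = 25
toy_kdm <- function() {
  kdm_parameters(
    k = c(m1 = 1.0, m2 = -2.0),
    q = c(m1 = 10, m2 = 100),
    s = c(m1 = 5, m2 = 10),
    s_ba2 = 25
  )
}

# a panel lying exactly on every regression line of `params` at age `ca`
panel_on_lines <- function(params, ca) {
  as.data.frame(as.list(params$q + params$k * ca))
}

# random KDM parameter set (for property-style loops)
random_kdm <- function(m = 5) {
  mk <- paste0("m", seq_len(m))
  kdm_parameters(
    k = stats::setNames(stats::runif(m, 0.2, 3) * sample(c(-1, 1), m, TRUE), mk),
    q = stats::setNames(stats::runif(m, -50, 150), mk),
    s = stats::setNames(stats::runif(m, 0.5, 20), mk),
    s_ba2 = stats::runif(1, 4, 100)
  )
}

# small survival dataset simulated from a known Gompertz PH truth
simulate_survival_records <- function(n, model, censor_horizon = 23,
                                      seed = 1) {
  set.seed(seed)
  age <- stats::runif(n, 30, 90)
  bioage <- age + stats::rnorm(n, 0, 7)
  lambda <- exp(model$coef["age"] * age + model$coef["bioage"] * bioage +
                  model$coef["const"])
  t_ev <- sample_gompertz_event_time(lambda, model$gamma, stats::runif(n))
  data.frame(
    time = pmin(t_ev, censor_horizon),
    event = as.integer(t_ev <= censor_horizon),
    age = age, bioage = bioage
  )
}
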