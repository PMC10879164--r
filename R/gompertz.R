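# Gompertz proportional-hazard mortality model.
#
# Hazard: h(t) = lambda * exp(gamma * t), with the person-level scale
# lambda = exp(X beta + const) driven by chronological age, biological age
# and optionally body weight. Survival:
#   s(t) = exp((lambda / gamma) * (1 - exp(gamma * t)))
# Fitted by maximum likelihood under right censoring; per-record
# log-likelihood  delta * (log lambda + gamma t) + (lambda/gamma)(1 - e^{gamma t}).
# Competing risks are handled as cause-specific hazards: fitting one cause
# treats deaths from other causes as censored.

#' Construct a Gompertz proportional-hazard model
#'
#' @param coef Named numeric vector of log-hazard coefficients, one per
#'   covariate (e.g. `age`, `bioage`, optionally `weight`) plus the
#'   intercept named `const`.
#' @param gamma Gompertz shape (per year); finite and nonzero.
#' @param cause Optional cause label the model was fit for (`"all"` for
#'   all-cause).
#' @return An object of class `gompertz_model`.
#' @export
gompertz_model <- function(coef, gamma, cause = "all") {
  if (is.null(names(coef)) || !"const" %in% names(coef)) {
    stop("coef must be named and include 'const'", call. = FALSE)
  }
  if (!is.finite(gamma) || gamma == 0) {
    stop("gamma must be finite and nonzero", call. = FALSE)
  }
  covariates <- setdiff(names(coef), "const")
  structure(
    list(coef = coef, gamma = as.numeric(gamma),
         covariates = covariates, cause = cause),
    class = "gompertz_model"
  )
}

#' @export
print.gompertz_model <- function(x, ...) {
  cat(sprintf("gompertz_model (cause: %s), gamma = %.5g /year\n",
              x$cause, x$gamma))
  print(x$coef)
  if (!is.null(x$loglik)) cat(sprintf("log-likelihood: %.2f\n", x$loglik))
  invisible(x)
}

# lambda for each row of newdata
gompertz_lambda <- function(model, newdata) {
  stop_if_missing_cols(newdata, model$covariates, "newdata")
  lp <- model$coef["const"]
  for (cv in model$covariates) lp <- lp + model$coef[cv] * newdata[[cv]]
  exp(as.numeric(lp))
}

# cumulative-hazard factor (lambda/gamma)(1 - e^{gamma t}) with a series
# expansion for |gamma t| below 1e-6 (the exponential limit -lambda t)
gompertz_log_surv <- function(lambda, gamma, t) {
  gt <- gamma * t
  out <- numeric(length(t))
  small <- abs(gt) < 1e-6
  if (any(small)) {
    ts <- t[small]; gts <- gt[small]
    out[small] <- -lambda[small] * ts * (1 + gts / 2 + gts^2 / 6)
  }
  if (any(!small)) {
    out[!small] <- (lambda[!small] / gamma) * (1 - exp(gt[!small]))
  }
  out
}

#' Fit a Gompertz proportional-hazard model by maximum likelihood
#'
#' @param records Data frame with columns `time` (years, > 0), `event`
#'   (0/1), optionally `cause`, and one column per requested covariate.
#' @param covariates Covariate column names entering the log-hazard scale
#'   (default chronological and biological age).
#' @param cause `"all"` for all-cause mortality, or a cause label: events of
#'   other causes are then treated as censored (cause-specific hazard).
#' @param init_gamma Starting value for the shape (per year).
#' @param max_restarts Number of jittered restarts attempted on
#'   non-convergence.
#' @return A [gompertz_model()] with `loglik`, `n`, `n_events` and
#'   `convergence` fields added.
#' @export
fit_gompertz_ph <- function(records, covariates = c("age", "bioage"),
                            cause = "all", init_gamma = 0.1,
                            max_restarts = 3) {
  stop_if_missing_cols(records, c("time", "event", covariates), "records")
  if (nrow(records) < 50) {
    stop("need at least 50 records", call. = FALSE)
  }
  if (any(records$time <= 0)) stop("all times must be > 0", call. = FALSE)
  delta <- as.integer(records$event)
  if (!identical(cause, "all")) {
    stop_if_missing_cols(records, "cause", "records")
    delta <- as.integer(delta == 1L & !is.na(records$cause) &
                          records$cause == cause)
  }
  if (sum(delta) == 0) {
    stop("no events for the requested cause: cannot fit", call. = FALSE)
  }
  if (sum(delta) < 10) {
    stop(sprintf("only %d events for cause '%s'; need at least 10",
                 sum(delta), cause), call. = FALSE)
  }
  X <- as.matrix(records[, covariates, drop = FALSE])
  t <- records$time
  p <- ncol(X)

  negll <- function(par) {
    beta <- par[seq_len(p)]
    const <- par[p + 1]
    gamma <- par[p + 2]
    if (gamma == 0) gamma <- 1e-12
    loglam <- as.numeric(X %*% beta) + const
    lambda <- exp(loglam)
    ll <- delta * (loglam + gamma * t) + gompertz_log_surv(lambda, gamma, t)
    if (!all(is.finite(ll))) return(1e10)
    -sum(ll)
  }

  negll_grad <- function(par) {
    beta <- par[seq_len(p)]
    const <- par[p + 1]
    gamma <- par[p + 2]
    if (gamma == 0) gamma <- 1e-12
    loglam <- as.numeric(X %*% beta) + const
    lambda <- exp(loglam)
    G <- gompertz_log_surv(lambda, gamma, t)  # (lambda/gamma)(1 - e^{gamma t})
    common <- delta + G
    g_beta <- as.numeric(crossprod(X, common))
    g_const <- sum(common)
    g_gamma <- sum(delta * t - (lambda / gamma) * t * exp(gamma * t) -
                     G / gamma)
    out <- -c(g_beta, g_const, g_gamma)
    if (!all(is.finite(out))) out[!is.finite(out)] <- 0
    out
  }

  # start beta at 0 and const at the exponential-fit rate
  start <- c(rep(0, p), log(sum(delta) / sum(t)), init_gamma)
  fit <- NULL
  for (attempt in 0:max_restarts) {
    par0 <- if (attempt == 0) start else {
      start + stats::rnorm(length(start), 0, 0.05 * (1 + abs(start)))
    }
    cand <- stats::optim(par0, negll, gr = negll_grad, method = "BFGS",
                         control = list(maxit = 1000, reltol = 1e-14))
    if (cand$convergence == 0 &&
        (is.null(fit) || cand$value < fit$value)) {
      fit <- cand
      break
    }
    if (is.null(fit) || cand$value < fit$value) fit <- cand
  }
  if (is.null(fit) || fit$convergence != 0) {
    stop(sprintf(
      "Gompertz fit did not converge (optim code %s, nll %.4f)",
      fit$convergence %||% NA, fit$value
    ), call. = FALSE)
  }
  coef <- stats::setNames(fit$par[seq_len(p + 1)], c(covariates, "const"))
  model <- gompertz_model(coef, gamma = fit$par[p + 2], cause = cause)
  model$loglik <- -fit$value
  model$n <- nrow(records)
  model$n_events <- sum(delta)
  model$convergence <- fit$convergence
  model
}

#' Gompertz survival probability
#'
#' Evaluates `s(t) = exp((lambda/gamma)(1 - e^{gamma t}))` with the
#' person-level `lambda` from the model's covariates.
#'
#' @param model A [gompertz_model()].
#' @param newdata Data frame (or named list for one person) with the model's
#'   covariate columns.
#' @param t Time(s) in years, >= 0.
#' @return Survival probabilities in \[0, 1\], vectorized over rows of
#'   `newdata` (or over `t` for a single person).
#' @export
survival_prob <- function(model, newdata, t) {
  stopifnot(inherits(model, "gompertz_model"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  lambda <- gompertz_lambda(model, newdata)
  if (length(lambda) == 1) lambda <- rep(lambda, length(t))
  exp(gompertz_log_surv(lambda, model$gamma, rep(t, length.out = length(lambda))))
}

#' Closed-form Gompertz quantile time
#'
#' Time at which survival reaches `p`:
#' `t = (1/gamma) * log(1 - (gamma/lambda) * log(p))`.
#'
#' @param lambda Hazard scale(s) (> 0).
#' @param gamma Gompertz shape, nonzero.
#' @param p Target survival probability in (0, 1); default 0.5 (median).
#' @return Time(s) in years.
#' @export
gompertz_quantile_time <- function(lambda, gamma, p = 0.5) {
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)", call. = FALSE)
  (1 / gamma) * log1p(-(gamma / lambda) * log(p))
}

#' Median remaining life expectancy
#'
#' Solves `s(t) = 0.5` for each person by numeric root finding on the
#' survival function (the closed form [gompertz_quantile_time()] exists and
#' serves as an independent check in the test suite).
#'
#' @param model A [gompertz_model()].
#' @param newdata Data frame (or named list for one person) with the model's
#'   covariates; if it contains an `age` column the predicted median age at
#'   death (`age + t`) is reported alongside.
#' @return Data frame with `median_le` (years remaining until s(t) = 0.5)
#'   and, when age is available, `median_age_at_death`.
#' @export
median_remaining_le <- function(model, newdata) {
  stopifnot(inherits(model, "gompertz_model"))
  if (!is.data.frame(newdata)) newdata <- as.data.frame(as.list(newdata))
  lambda <- gompertz_lambda(model, newdata)
  if (any(lambda <= 0)) stop("hazard scale must be > 0", call. = FALSE)
  t_med <- vapply(lambda, function(lam) {
    f <- function(t) exp(gompertz_log_surv(lam, model$gamma, t)) - 0.5
    upper <- 1
    while (f(upper) > 0 && upper < 1e6) upper <- upper * 2
    stats::uniroot(f, c(0, upper), tol = 1e-12)$root
  }, numeric(1))
  out <- data.frame(median_le = t_med)
  if ("age" %in% names(newdata)) {
    out$median_age_at_death <- newdata$age + t_med
  }
  out
}

#' Mortality risk over a horizon
#'
#' `1 - s(horizon)`; the paper-style quantity uses a 20-year horizon.
#'
#' @inheritParams survival_prob
#' @param horizon Horizon in years (default 20).
#' @return Probabilities of death within the horizon.
#' @export
mortality_risk <- function(model, newdata, horizon = 20) {
  1 - survival_prob(model, newdata, horizon)
}

#' Cause-specific mortality risks side by side
#'
#' @param models Named list of [gompertz_model()]s, one per cause.
#' @param newdata Covariate data frame (rows = persons).
#' @param horizon Horizon in years (default 20).
#' @return Data frame with one risk column per cause.
#' @export
cause_specific_risk_suite <- function(models, newdata, horizon = 20) {
  if (is.null(names(models)) || any(!nzchar(names(models)))) {
    stop("models must be a named list (one name per cause)", call. = FALSE)
  }
  bad <- !vapply(models, inherits, logical(1), "gompertz_model")
  if (any(bad)) {
    stop("missing or invalid cause model(s): ",
         paste(names(models)[bad], collapse = ", "), call. = FALSE)
  }
  as.data.frame(lapply(models, mortality_risk, newdata = newdata,
                       horizon = horizon))
}

#' Relative reduction between baseline and follow-up risks
#'
#' `100 * (p_baseline - p_followup) / p_baseline`, in percent. Inputs may be
#' probabilities or percentages as long as both are on the same scale.
#'
#' @param p_baseline Baseline risk (> 0).
#' @param p_followup Follow-up risk, same units as baseline.
#' @param digits Decimal places to round the reported percent to (default
#'   1); `NULL` for no rounding.
#' @return Percent reduction (negative if risk increased).
#' @export
relative_reduction <- function(p_baseline, p_followup, digits = 1) {
  if (any(p_baseline <= 0)) stop("baseline risk must be > 0", call. = FALSE)
  out <- 100 * (p_baseline - p_followup) / p_baseline
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Serialize a Gompertz model to JSON
#' @param model A [gompertz_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gompertz_model <- function(model, path) {
  stopifnot(inherits(model, "gompertz_model"))
  obj <- list(coef = as.list(model$coef), gamma = model$gamma,
              cause = model$cause)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a Gompertz model written by [write_gompertz_model()]
#' @param path JSON path.
#' @return A [gompertz_model()].
#' @export
read_gompertz_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gompertz_model(unlist(obj$coef), gamma = obj$gamma, cause = obj$cause)
}
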