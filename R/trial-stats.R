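# Trial-level statistics: paired change tests, robust correlation,
# responder modelling, and clinical index utilities.

#' Wilcoxon signed-rank test for paired change
#'
#' Tests whether paired baseline/follow-up differences are symmetric about
#' zero. The trial design is paired, so the signed-rank form is the primary
#' test (a two-sample rank-sum variant is available for unpaired use). Zero
#' differences are dropped; ties among the remaining absolute differences
#' get average ranks. For `n <= 12` nonzero differences the null
#' distribution of the positive-rank sum is enumerated exactly over all
#' `2^n` sign patterns; above that a normal approximation with tie
#' correction and continuity correction is used. Two-sided p-values.
#'
#' @param baseline,followup Numeric vectors aligned per person; or, with
#'   `paired = FALSE`, the two independent samples for the rank-sum variant.
#' @param paired If `TRUE` (default) the signed-rank test on differences.
#' @param exact_max Largest number of nonzero differences for the exact
#'   enumeration path (default 12).
#' @return List with `statistic` (positive-rank sum `V` for the paired
#'   test, rank-sum `W` otherwise), `p_value`, `n_used`, and `method`.
#' @export
wilcoxon_change_test <- function(baseline, followup, paired = TRUE,
                                 exact_max = 12) {
  if (paired) {
    if (length(baseline) != length(followup)) {
      stop("paired samples must be aligned", call. = FALSE)
    }
    d <- followup - baseline
    d <- d[d != 0]
    n <- length(d)
    if (n == 0) {
      stop("all paired differences are zero: test degenerate", call. = FALSE)
    }
    r <- rank(abs(d))
    v <- sum(r[d > 0])
    if (n <= exact_max) {
      # enumerate the positive-rank sum over all sign patterns
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
      w_all <- as.numeric(signs %*% r)
      p_le <- mean(w_all <= v)
      p_ge <- mean(w_all >= v)
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "exact signed-rank (enumeration)"
    } else {
      # Edgeworth-corrected normal approximation: the null is symmetric, so
      # the leading correction is the (negative) fourth cumulant of the
      # rank sum; with continuity correction this is accurate to ~1e-3 in p
      # even at the exact/asymptotic crossover
      mu <- n * (n + 1) / 4
      tie_tab <- table(r)
      sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
        sum(tie_tab^3 - tie_tab) / 48
      k4 <- -sum(r^4) / 8
      cdf <- function(w) {
        z <- (w - mu + 0.5) / sqrt(sigma2)
        stats::pnorm(z) -
          stats::dnorm(z) * (k4 / (24 * sigma2^2)) * (z^3 - 3 * z)
      }
      p_le <- cdf(v)
      p_ge <- 1 - cdf(v - 1)
      p <- min(1, 2 * min(p_le, p_ge))
      method <- "asymptotic signed-rank (tie, continuity and Edgeworth corrected)"
    }
    list(statistic = c(V = v), p_value = p, n_used = n, method = method)
  } else {
    ht <- stats::wilcox.test(baseline, followup, exact = FALSE, correct = TRUE)
    list(statistic = ht$statistic, p_value = ht$p.value,
         n_used = length(baseline) + length(followup),
         method = "rank-sum (two-sample)")
  }
}

#' Biweight midcorrelation
#'
#' Robust correlation: each vector is median-centered and scaled by nine
#' times its median absolute deviation; observations with `|u| >= 1` receive
#' zero weight, the rest the biweight `(1 - u^2)^2`. The correlation of the
#' weighted deviations behaves like a Pearson correlation while
#' down-weighting outliers. A two-sided p-value is computed from the
#' t-approximation with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), with nonzero median
#'   absolute deviation.
#' @param fallback_pearson If `TRUE`, fall back to Pearson correlation when
#'   a vector has zero MAD instead of erroring.
#' @return List with `bicor` in \[-1, 1\], `p_value`, and `n`.
#' @export
bicor <- function(x, y, fallback_pearson = FALSE) {
  if (length(x) != length(y)) stop("x and y must be aligned", call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  mad_x <- stats::median(abs(x - stats::median(x)))
  mad_y <- stats::median(abs(y - stats::median(y)))
  if (mad_x == 0 || mad_y == 0) {
    if (!fallback_pearson) {
      stop("zero median absolute deviation; biweight undefined", call. = FALSE)
    }
    r <- stats::cor(x, y)
  } else {
    wdev <- function(v, madv) {
      u <- (v - stats::median(v)) / (9 * madv)
      w <- (1 - u^2)^2 * (abs(u) < 1)
      (v - stats::median(v)) * w
    }
    xt <- wdev(x, mad_x)
    yt <- wdev(y, mad_y)
    r <- sum(xt * yt) / sqrt(sum(xt^2) * sum(yt^2))
  }
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(bicor = r, p_value = p, n = n)
}

#' Logistic regression of responder status on baseline covariates
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares,
#' reporting per-covariate coefficients, odds ratios, and Wald p-values.
#' Intended use: modelling the odds of being a non-responder (biological age
#' increased after the intervention, flag 1) from baseline characteristics.
#'
#' @param covariates Data frame of numeric baseline covariates (an intercept
#'   is added automatically).
#' @param flags 0/1 response vector aligned with the rows.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return Data frame with one row per term: `term`, `estimate`,
#'   `odds_ratio`, `std_error`, `z`, `p_value`.
#' @export
responder_logistic <- function(covariates, flags, max_iter = 50, tol = 1e-10) {
  flags <- as.numeric(flags)
  if (!all(flags %in% c(0, 1))) stop("flags must be 0/1", call. = FALSE)
  if (length(unique(flags)) < 2) {
    stop("both responder classes must be present", call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (nrow(X) != length(flags)) {
    stop("covariates and flags must be aligned", call. = FALSE)
  }
  beta <- rep(0, ncol(X))
  for (iter in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) {
      # fitted probabilities pinned at 0/1: likely separation
      sep <- which.max(abs(beta[-1]))
      stop(sprintf(
        "perfect or quasi-separation detected (covariate '%s')",
        colnames(X)[-1][sep]
      ), call. = FALSE)
    }
    z <- eta + (flags - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol) {
      beta <- new_beta
      break
    }
    beta <- new_beta
  }
  eta <- as.numeric(X %*% beta)
  mu <- 1 / (1 + exp(-eta))
  w <- mu * (1 - mu)
  info <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(info)))
  zval <- beta / se
  data.frame(
    term = colnames(X),
    estimate = unname(beta),
    odds_ratio = exp(unname(beta)),
    std_error = unname(se),
    z = unname(zval),
    p_value = 2 * stats::pnorm(-abs(unname(zval))),
    row.names = NULL
  )
}

#' Homeostatic model assessment of insulin resistance (HOMA-IR)
#'
#' `glucose * insulin / 405` with fasting glucose in mg/dL and fasting
#' insulin in micro-units per mL.
#'
#' @param fasting_glucose Fasting glucose (mg/dL, > 0).
#' @param fasting_insulin Fasting insulin (uU/mL, > 0).
#' @return HOMA-IR index (dimensionless).
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  if (any(fasting_glucose <= 0) || any(fasting_insulin <= 0)) {
    stop("glucose and insulin must be > 0", call. = FALSE)
  }
  fasting_glucose * fasting_insulin / 405
}

#' Lymphoid-to-myeloid ratio from a white-cell differential
#'
#' `lymphocytes / (neutrophils + monocytes)` by default; eosinophils and
#' basophils can optionally be included in the myeloid denominator. Counts
#' may be absolute or percentages as long as all are on a common scale (the
#' ratio is scale invariant).
#'
#' @param lymphocytes,neutrophils,monocytes Non-negative counts.
#' @param eosinophils,basophils Optional non-negative counts added to the
#'   denominator when `include_granulocyte_subtypes = TRUE`.
#' @param include_granulocyte_subtypes Include eosinophils and basophils in
#'   the myeloid denominator.
#' @return Lymphoid-to-myeloid ratio(s).
#' @export
lymphoid_myeloid_ratio <- function(lymphocytes, neutrophils, monocytes,
                                   eosinophils = 0, basophils = 0,
                                   include_granulocyte_subtypes = FALSE) {
  vals <- c(lymphocytes, neutrophils, monocytes, eosinophils, basophils)
  if (any(vals < 0)) stop("counts must be non-negative", call. = FALSE)
  denom <- neutrophils + monocytes
  if (include_granulocyte_subtypes) denom <- denom + eosinophils + basophils
  if (any(denom <= 0)) {
    stop("myeloid denominator must be > 0", call. = FALSE)
  }
  lymphocytes / denom
}
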