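# Klemera-Doubal (KDM) biological age.
#
# The estimator combines m biomarker regression lines with chronological age
# into a single biological age:
#
#   BA_EC = [ sum_j (x_j - q_j) k_j / s_j^2  +  CA / s_BA^2 ]
#           / [ sum_j (k_j / s_j)^2  +  1 / s_BA^2 ]
#
# where each marker follows x_j = q_j + k_j * age in the reference
# population, s_j is the residual scale of that line, and s_BA^2 is the
# variance of the deviation of biological from chronological age. The lines
# are fitted marker-on-age: that is the direction under which the estimator
# has the defining identity BA_EC = CA for a person lying exactly on every
# line, and matches the original Klemera-Doubal construction.

#' KDM parameter set
#'
#' @param k Named numeric vector of per-marker slopes (marker units per year
#'   of age); no slope may be zero.
#' @param q Named numeric vector of per-marker intercepts (marker units).
#' @param s Named numeric vector of per-marker residual scales (marker
#'   units; strictly positive).
#' @param s_ba2 Variance (years^2) of the deviation of biological from
#'   chronological age; strictly positive.
#' @return An object of class `kdm_parameters`.
#' @export
kdm_parameters <- function(k, q, s, s_ba2) {
  markers <- names(k)
  if (is.null(markers) || is.null(names(q)) || is.null(names(s))) {
    stop("k, q and s must be named by marker", call. = FALSE)
  }
  stopifnot(
    length(k) >= 1,
    identical(sort(markers), sort(names(q))),
    identical(sort(markers), sort(names(s)))
  )
  q <- q[markers]; s <- s[markers]
  if (any(s <= 0)) stop("all residual scales s must be > 0", call. = FALSE)
  if (any(k == 0)) stop("no slope k may be zero", call. = FALSE)
  if (!is.numeric(s_ba2) || length(s_ba2) != 1 || s_ba2 <= 0) {
    stop("s_ba2 must be a single positive number", call. = FALSE)
  }
  structure(
    list(markers = markers, k = k, q = q, s = s,
         s_ba2 = as.numeric(s_ba2), m = length(markers)),
    class = "kdm_parameters"
  )
}

#' @export
print.kdm_parameters <- function(x, ...) {
  cat(sprintf("kdm_parameters: %d markers, s_BA^2 = %.4g years^2\n",
              x$m, x$s_ba2))
  print(data.frame(k = x$k, q = x$q, s = x$s, row.names = x$markers))
  invisible(x)
}

#' Fit KDM parameters from a reference cohort
#'
#' Fits each marker on chronological age by ordinary least squares, giving
#' slope `k_j`, intercept `q_j`, and residual scale `s_j` (root mean squared
#' residual). `s_BA^2` is then estimated as the empirical variance over the
#' cohort of `BA_E - CA`, where `BA_E` is the marker-only estimator (the
#' scoring formula with the chronological-age term removed); a fixed value
#' may be supplied instead.
#'
#' @param cohort Data frame with an age column and one column per marker.
#' @param markers Marker column names; default the seven-marker panel.
#' @param age_col Name of the chronological-age column.
#' @param s_ba2 Optional fixed override for `s_BA^2`; `NULL` (default)
#'   estimates it empirically.
#' @param log_crp If `TRUE`, natural-log-transform the `crp` column before
#'   fitting (the transformation must then also be applied at scoring time;
#'   [kdm_bioage()] does this when the parameter object carries the flag).
#' @return A [kdm_parameters()] object.
#' @export
fit_kdm_parameters <- function(cohort, markers = kdm_markers(),
                               age_col = "age", s_ba2 = NULL,
                               log_crp = FALSE) {
  stop_if_missing_cols(cohort, c(age_col, markers), "cohort")
  cohort <- cohort[stats::complete.cases(cohort[, c(age_col, markers)]), ]
  if (nrow(cohort) < 30) {
    stop("need at least 30 complete records to fit KDM parameters",
         call. = FALSE)
  }
  if (log_crp && "crp" %in% markers) {
    if (any(cohort$crp <= 0)) {
      stop("log_crp requires strictly positive crp values", call. = FALSE)
    }
    cohort$crp <- log(cohort$crp)
  }
  age <- cohort[[age_col]]
  k <- q <- s <- stats::setNames(numeric(length(markers)), markers)
  for (mk in markers) {
    x <- cohort[[mk]]
    if (stats::sd(x) == 0) {
      stop(sprintf("marker '%s' is degenerate (zero variance)", mk),
           call. = FALSE)
    }
    fit <- stats::lm.fit(cbind(1, age), x)
    q[mk] <- fit$coefficients[1]
    k[mk] <- fit$coefficients[2]
    if (k[mk] == 0) {
      stop(sprintf("marker '%s' has zero slope on age", mk), call. = FALSE)
    }
    s[mk] <- sqrt(mean(fit$residuals^2))
  }
  if (is.null(s_ba2)) {
    # marker-only estimator BA_E (no chronological-age anchor)
    w <- (k / s)^2
    num <- rowSums(sapply(markers, function(mk) {
      (cohort[[mk]] - q[mk]) * k[mk] / s[mk]^2
    }))
    ba_e <- num / sum(w)
    s_ba2 <- stats::var(ba_e - age)
  }
  params <- kdm_parameters(k, q, s, s_ba2)
  params$log_crp <- isTRUE(log_crp)
  params
}

#' KDM biological age of one or more biomarker panels
#'
#' Evaluates the KDM estimator exactly as written: a precision-weighted
#' combination of each marker's implied age and chronological age.
#'
#' @param panel Data frame (or named list/vector for a single person) with
#'   one column per marker in `params`; all markers must be present and
#'   non-missing (no imputation is attempted).
#' @param ca Chronological age(s) in years, > 0, recycled against the panel
#'   rows.
#' @param params A [kdm_parameters()] object.
#' @return Data frame with columns `ba_ec` (biological age, years), `ca`,
#'   and `delta = ba_ec - ca`.
#' @export
kdm_bioage <- function(panel, ca, params) {
  stopifnot(inherits(params, "kdm_parameters"))
  if (!is.data.frame(panel)) panel <- as.data.frame(as.list(panel))
  missing <- setdiff(params$markers, names(panel))
  if (length(missing)) {
    stop("panel is missing marker(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(panel[, params$markers, drop = FALSE])
  if (anyNA(X) || anyNA(ca)) {
    stop("missing values in panel or ca; the estimator requires a full panel",
         call. = FALSE)
  }
  if (any(ca <= 0)) stop("chronological age must be > 0", call. = FALSE)
  if (isTRUE(params$log_crp) && "crp" %in% params$markers) {
    X[, "crp"] <- log(X[, "crp"])
  }
  k <- params$k; q <- params$q; s <- params$s
  num <- X %*% (k / s^2) - sum(q * k / s^2) + ca / params$s_ba2
  den <- sum((k / s)^2) + 1 / params$s_ba2
  ba <- as.numeric(num) / den
  data.frame(ba_ec = ba, ca = ca, delta = ba - ca)
}

#' Weight-adjusted follow-up biological age
#'
#' Regresses follow-up biological age (or, in the `"change"` variant, the
#' baseline-to-follow-up change in biological age) on the change in body
#' weight by ordinary least squares, and returns the residuals re-centered
#' at the cohort mean of the response: per person, the follow-up biological
#' age (or change) expected had their weight not changed.
#'
#' @param followup_bioage Numeric vector, follow-up biological age in years
#'   (for `variant = "change"`, supply the change in biological age).
#' @param weight_change Numeric vector, follow-up minus baseline weight (kg),
#'   aligned with `followup_bioage`; must not be constant.
#' @param variant `"followup"` (regress follow-up biological age) or
#'   `"change"` (regress change in biological age); affects only how the
#'   inputs are interpreted and reported.
#' @return List with `adjusted` (residual + cohort mean response, per
#'   person), `residuals`, `coefficients` (intercept, slope on weight
#'   change), and `variant`.
#' @export
weight_adjusted_change <- function(followup_bioage, weight_change,
                                   variant = c("followup", "change")) {
  variant <- match.arg(variant)
  if (length(followup_bioage) != length(weight_change)) {
    stop("inputs must be aligned per person", call. = FALSE)
  }
  if (length(followup_bioage) < 3) {
    stop("need at least 3 persons", call. = FALSE)
  }
  if (stats::sd(weight_change) == 0) {
    stop("all weight changes identical: regression undefined", call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, weight_change), followup_bioage)
  res <- fit$residuals
  list(
    adjusted = res + mean(followup_bioage),
    residuals = res,
    coefficients = stats::setNames(fit$coefficients,
                                   c("intercept", "weight_change")),
    variant = variant
  )
}

#' Classify trial participants as responders or non-responders
#'
#' A non-responder (flag 1) is a participant whose biological age increased
#' strictly from baseline to follow-up; decreases and exact ties are flagged
#' 0 ("increased" is read strictly).
#'
#' @param baseline,followup Numeric vectors of biological ages (years),
#'   aligned per person, or data frames from [kdm_bioage()] (column `ba_ec`
#'   is used).
#' @return Integer vector of 0/1 flags.
#' @export
classify_responders <- function(baseline, followup) {
  if (is.data.frame(baseline)) baseline <- baseline$ba_ec
  if (is.data.frame(followup)) followup <- followup$ba_ec
  if (length(baseline) != length(followup)) {
    stop("baseline and followup must be aligned per person", call. = FALSE)
  }
  if (anyNA(baseline) || anyNA(followup)) {
    stop("missing biological ages", call. = FALSE)
  }
  as.integer(followup > baseline)
}

#' Serialize KDM parameters to JSON
#' @param params A [kdm_parameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kdm_parameters <- function(params, path) {
  stopifnot(inherits(params, "kdm_parameters"))
  obj <- list(
    markers = lapply(stats::setNames(params$markers, params$markers),
                     function(mk) {
      list(k = params$k[[mk]], q = params$q[[mk]], s = params$s[[mk]])
    }),
    s_ba2 = params$s_ba2,
    log_crp = isTRUE(params$log_crp)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read KDM parameters written by [write_kdm_parameters()]
#' @param path JSON path.
#' @return A [kdm_parameters()] object.
#' @export
read_kdm_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk <- names(obj$markers)
  params <- kdm_parameters(
    k = vapply(obj$markers, `[[`, numeric(1), "k"),
    q = vapply(obj$markers, `[[`, numeric(1), "q"),
    s = vapply(obj$markers, `[[`, numeric(1), "s"),
    s_ba2 = obj$s_ba2
  )
  params$log_crp <- isTRUE(obj$log_crp)
  params
}
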