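# Time-to-onset (TTO): interval in days from therapy start to event
# occurrence, modeled with a two-parameter Weibull distribution
#   f(t) = (alpha/beta) (t/beta)^(alpha-1) exp(-(t/beta)^alpha)
# whose shape alpha classifies the hazard trend: decreasing (early failure),
# constant (random failure) or increasing (wear-out / degradation).

#' Compute time-to-onset for every report in a cohort
#'
#' TTO is the difference in days between the earliest full-precision
#' primary-suspect therapy start date and the full-precision event date.
#' Reports with a partial or missing date on either side, or a difference
#' below one day, are excluded (TTO is `NA`); exclusion reasons are counted
#' in the `exclusions` attribute.
#'
#' @param cohort An `icsr_set` or `pv_cohort`.
#' @return data.table `(primaryid, tto)` with one row per report; attribute
#'   `exclusions` tallies `missing_event`, `missing_start`, `nonpositive`.
#' @export
compute_tto <- function(cohort) {
  stopifnot(inherits(cohort, "icsr_set"))
  demo <- cohort$demo
  ps <- cohort$drug[role_cod == "PS" & is_full_date(start_dt)]
  starts <- ps[, .(start = min(faers_date_to_idate(start_dt))), by = primaryid]
  out <- merge(demo[, .(primaryid, event_dt)], starts, by = "primaryid",
               all.x = TRUE)
  ev_ok <- is_full_date(out$event_dt)
  ev <- faers_date_to_idate(out$event_dt)
  tto <- as.numeric(ev - out$start)
  tto[!ev_ok | is.na(out$start)] <- NA_real_
  n_missing_event <- sum(!ev_ok)
  n_missing_start <- sum(ev_ok & is.na(out$start))
  nonpos <- !is.na(tto) & tto < 1
  tto[nonpos] <- NA_real_
  res <- data.table(primaryid = out$primaryid, tto = tto)
  setattr(res, "exclusions", c(missing_event = n_missing_event,
                               missing_start = n_missing_start,
                               nonpositive = sum(nonpos)))
  res
}

#' Gather the TTO sample of one drug's cases
#'
#' @param cohort A `pv_cohort`.
#' @param drug Drug name, or `NULL` for all cases pooled.
#' @return Numeric vector of TTOs (days, all `>= 1`) among miscarriage cases
#'   exposed to the drug as primary suspect.
#' @export
tto_sample <- function(cohort, drug = NULL) {
  stopifnot(inherits(cohort, "pv_cohort"))
  tt <- compute_tto(cohort)
  ids <- cohort$demo[is_case == TRUE, primaryid]
  if (!is.null(drug)) {
    dn <- normalize_drug(drug)
    ids <- intersect(ids, cohort$drug[role_cod == "PS" & drugname_norm == dn,
                                      primaryid])
  }
  v <- tt[primaryid %in% ids & !is.na(tto), tto]
  as.numeric(v)
}

#' Weibull maximum-likelihood fit with hazard-shape classification
#'
#' Maximizes the Weibull log-likelihood over `(log alpha, log beta)` by
#' quasi-Newton iteration from moment-based starting values; 95% confidence
#' intervals come from the observed-information covariance on the log scale,
#' mapped back by exponentiation. Deterministic given the sample.
#'
#' @param ttos Positive TTOs in days.
#' @param min_n Fit-size floor; below it only the empirical summary is
#'   returned (`fitted = FALSE`).
#' @param fix_shape Optional fixed shape; then the scale MLE is the closed
#'   form `mean(t^alpha)^(1/alpha)` and no shape interval is produced.
#' @param conf_level Interval coverage.
#' @return Object of class `weibull_fit`: `shape`, `shape_lo`, `shape_hi`,
#'   `scale`, `scale_lo`, `scale_hi`, `n`, empirical `median`, `q1`, `q3`,
#'   `min`, `max`, and `failure_type`.
#' @export
fit_weibull <- function(ttos, min_n = 30, fix_shape = NULL, conf_level = 0.95) {
  t <- as.numeric(ttos)
  if (any(!is.finite(t)) || any(t <= 0))
    stop("TTOs must be positive and finite", call. = FALSE)
  n <- length(t)
  emp <- summarize_tto(t)
  base <- list(n = n, median = emp$median, q1 = emp$q1, q3 = emp$q3,
               min = emp$min, max = emp$max)
  if (n < min_n) {
    out <- c(base, list(shape = NA_real_, shape_lo = NA_real_,
                        shape_hi = NA_real_, scale = NA_real_,
                        scale_lo = NA_real_, scale_hi = NA_real_,
                        failure_type = NA_character_, fitted = FALSE))
    return(structure(out, class = "weibull_fit"))
  }
  if (stats::var(t) == 0) stop("no dispersion in TTO sample", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (!is.null(fix_shape)) {
    a <- fix_shape
    b <- mean(t^a)^(1 / a)
    # observed information for log(beta) at fixed shape: alpha^2 * n
    se_lb <- 1 / (a * sqrt(n))
    out <- c(base, list(shape = a, shape_lo = NA_real_, shape_hi = NA_real_,
                        scale = b, scale_lo = b * exp(-z * se_lb),
                        scale_hi = b * exp(z * se_lb),
                        failure_type = NA_character_, fitted = TRUE))
    return(structure(out, class = "weibull_fit"))
  }

  # Profile-likelihood MLE: for fixed shape a the scale MLE is
  # b = mean(t^a)^(1/a); the profile score for a reduces to
  #   1/a + mean(log t) - sum(t^a log t) / sum(t^a) = 0,
  # monotone decreasing in a, solved by bisection/Brent to near machine
  # precision. (Numerically stabilized by factoring out max(t).)
  lt <- log(t)
  mlt <- mean(lt)
  tmax <- max(t)
  score <- function(a) {
    za <- (t / tmax)^a              # in (0, 1], no overflow
    1 / a + mlt - sum(za * lt) / sum(za)
  }
  lo_a <- 1e-3; hi_a <- pi / (sqrt(6) * stats::sd(lt)) * 2 + 1
  while (score(hi_a) > 0) hi_a <- hi_a * 2
  a <- stats::uniroot(score, c(lo_a, hi_a), tol = 1e-12)$root
  b <- tmax * mean((t / tmax)^a)^(1 / a)

  # analytic observed information in (log shape, log scale)
  w <- lt - log(b)
  zz <- exp(a * w)                  # (t/b)^a
  n_ <- length(t)
  h_uu <- a * (sum(w) - sum(zz * w) - a * sum(zz * w^2))
  h_vv <- -a^2 * sum(zz)
  h_uv <- -a * n_ + a * sum(zz) + a^2 * sum(zz * w)
  H <- matrix(c(h_uu, h_uv, h_uv, h_vv), 2, 2)
  vc <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(vc), 0))
  lpar <- c(log(a), log(b))
  lo <- exp(lpar - z * se); hi <- exp(lpar + z * se)
  out <- c(base, list(shape = a, shape_lo = lo[1], shape_hi = hi[1],
                      scale = b, scale_lo = lo[2], scale_hi = hi[2],
                      fitted = TRUE))
  out$failure_type <- classify_failure(a, lo[1], hi[1])
  structure(out, class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (isTRUE(x$fitted) && !is.na(x$shape_lo)) {
    cat(sprintf("Weibull fit (n=%d): shape %.3f [%.3f, %.3f], scale %.1f [%.1f, %.1f] days -> %s\n",
                x$n, x$shape, x$shape_lo, x$shape_hi, x$scale, x$scale_lo,
                x$scale_hi, x$failure_type))
  } else {
    cat(sprintf("TTO summary (n=%d): median %.1f [%.1f, %.1f] days (no fit)\n",
                x$n, x$median, x$min, x$max))
  }
  invisible(x)
}

#' Classify the hazard shape of a Weibull fit
#'
#' Early failure (decreasing hazard) when the shape interval lies entirely
#' below 1; degradation / wear-out (increasing hazard) when it lies entirely
#' above 1; random failure (roughly constant hazard) when the interval
#' straddles or touches 1. Operates on unrounded bounds. When classifying
#' from values printed at limited precision, `printed_precision` widens the
#' boundary by half an ulp of the printed scale, so a lower bound printed as
#' exactly 1 with a shape above 1 is recognized as degradation.
#'
#' @param shape Shape estimate, or a `weibull_fit`.
#' @param ci_lo,ci_hi Interval bounds (ignored when `shape` is a fit).
#' @param printed_precision Optional number of printed decimals.
#' @return `"early"`, `"random"` or `"degradation"`.
#' @export
classify_failure <- function(shape, ci_lo = NULL, ci_hi = NULL,
                             printed_precision = NULL) {
  if (inherits(shape, "weibull_fit")) {
    ci_lo <- shape$shape_lo; ci_hi <- shape$shape_hi; shape <- shape$shape
  }
  eps <- if (is.null(printed_precision)) 0 else 0.5 * 10^(-printed_precision)
  if (ci_hi < 1) "early"
  else if (ci_lo > 1 || (eps > 0 && shape > 1 && ci_lo >= 1 - eps)) "degradation"
  else "random"
}

#' Empirical TTO summary
#'
#' @param ttos Positive TTOs in days.
#' @param threshold Cumulative-mass threshold in days (default 730, i.e. two
#'   years).
#' @return List: `n`, `median`, `q1`, `q3` (linear-interpolation quantiles),
#'   `min`, `max`, `frac_within` (fraction with TTO `<= threshold`).
#' @export
summarize_tto <- function(ttos, threshold = 730) {
  t <- as.numeric(ttos)
  stopifnot(length(t) >= 1, all(is.finite(t)))
  q <- stats::quantile(t, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = length(t), median = q[2], q1 = q[1], q3 = q[3],
       min = min(t), max = max(t), frac_within = mean(t <= threshold))
}

#' Per-drug TTO table
#'
#' One row per drug (plus a pooled `"TOTAL"` row): sample size, empirical
#' median (IQR) and range, Weibull shape and scale with intervals, and the
#' hazard classification. Drugs below the fit floor report the summary only.
#'
#' @param cohort A `pv_cohort`.
#' @param drugs Character vector of drugs.
#' @param min_n Fit-size floor, as in [fit_weibull()].
#' @param total Include the all-drugs pooled row.
#' @return data.table mirroring the standard TTO results layout.
#' @export
tto_table <- function(cohort, drugs, min_n = 30, total = TRUE) {
  one <- function(name, sample) {
    if (!length(sample))
      return(data.table(drug = name, n = 0L, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, min = NA_real_, max = NA_real_,
                        shape = NA_real_, shape_lo = NA_real_,
                        shape_hi = NA_real_, scale = NA_real_,
                        scale_lo = NA_real_, scale_hi = NA_real_,
                        failure_type = NA_character_))
    f <- fit_weibull(sample, min_n = min_n)
    data.table(drug = name, n = f$n, median = f$median, q1 = f$q1, q3 = f$q3,
               min = f$min, max = f$max, shape = f$shape,
               shape_lo = f$shape_lo, shape_hi = f$shape_hi, scale = f$scale,
               scale_lo = f$scale_lo, scale_hi = f$scale_hi,
               failure_type = f$failure_type)
  }
  rows <- list()
  if (total) rows[["TOTAL"]] <- one("TOTAL", tto_sample(cohort, NULL))
  for (d in drugs) rows[[d]] <- one(normalize_drug(d), tto_sample(cohort, d))
  rbindlist(rows)
}
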