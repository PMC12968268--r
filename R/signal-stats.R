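# Disproportionality statistics on 2x2 contingency tables: ROR, PRR, the
# BCPNN information component, and the MGPS empirical-Bayes gamma-Poisson
# shrinker, with signal thresholds, a multi-method consensus rule, and
# Benjamini-Hochberg FDR control.
#
# The 2x2 table for one drug x one event over a background cohort:
#     a  drug & event     b  drug & other events
#     c  other drugs & event   d  other drugs & other events
# E = (a+b)(a+c)/N is the expected count of cell a under independence.

#' Construct a 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer cell counts: (drug, event), (drug,
#'   other events), (other drugs, event), (other drugs, other events).
#' @return An object of class `contingency_table` with `N` and the expected
#'   count `E` of cell `a` under independence.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  N <- a + b + c + d
  if (N <= 0) stop("table must contain at least one report", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d, N = N,
                 E = (a + b) * (a + c) / N),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<2x2> a=%d b=%d c=%d d=%d  N=%d  E=%.3f\n",
              x$a, x$b, x$c, x$d, x$N, x$E))
  invisible(x)
}

#' Build the 2x2 table for one drug against a cohort
#'
#' Exposure is primary-suspect reporting of the (normalized) drug; the event
#' axis is the cohort's case flag. Cell counts satisfy `a+b+c+d = |background|`.
#'
#' @param cohort A `pv_cohort` from [filter_cohort()].
#' @param drug Drug name (normalized internally).
#' @return A `contingency_table`. When the drug is absent (`a + b = 0`) the
#'   table is flagged via attribute `drug_absent` and downstream statistics
#'   return undefined markers (`NA`).
#' @export
build_contingency <- function(cohort, drug) {
  stopifnot(inherits(cohort, "pv_cohort"))
  dn <- normalize_drug(drug)
  exposed <- unique(cohort$drug[role_cod == "PS" & drugname_norm == dn, primaryid])
  is_exp <- cohort$demo$primaryid %in% exposed
  is_case <- cohort$demo$is_case
  tab <- contingency_table(a = sum(is_exp & is_case),
                           b = sum(is_exp & !is_case),
                           c = sum(!is_exp & is_case),
                           d = sum(!is_exp & !is_case))
  if (tab$a + tab$b == 0) attr(tab, "drug_absent") <- TRUE
  tab
}

# Vectorized Pearson chi-square (df = 1, no continuity correction) on raw
# cells; NA when a margin is empty.
chi2_pearson <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  out <- N * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  out[r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0] <- NA_real_
  out
}

# Zero-cell policy: Haldane-Anscombe +0.5 on all four cells for point
# estimates and intervals only when any cell is zero; chi-square always on
# the raw cells.
haldane <- function(a, b, c, d) {
  k <- as.numeric(a == 0 | b == 0 | c == 0 | d == 0) * 0.5
  list(a = a + k, b = b + k, c = c + k, d = d + k)
}

ror_vec <- function(a, b, c, d, conf_z = 1.959963984540054) {
  h <- haldane(a, b, c, d)
  est <- (h$a * h$d) / (h$b * h$c)
  se <- sqrt(1 / h$a + 1 / h$b + 1 / h$c + 1 / h$d)
  chi2 <- chi2_pearson(a, b, c, d)
  undef <- (a + b) == 0 | (a + c) == 0
  est[undef] <- NA_real_
  list(ror = est,
       ror_lo = exp(log(est) - conf_z * se),
       ror_hi = exp(log(est) + conf_z * se),
       chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

prr_vec <- function(a, b, c, d) {
  h <- haldane(a, b, c, d)
  est <- (h$a / (h$a + h$b)) / (h$c / (h$c + h$d))
  chi2 <- chi2_pearson(a, b, c, d)
  undef <- (a + b) == 0 | (c + d) == 0
  est[undef] <- NA_real_
  list(prr = est, chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

ic_vec <- function(a, E) {
  ic <- log2((a + 0.5) / (E + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  undef <- !is.finite(E) | E < 0
  ic[undef] <- NA_real_; ic025[undef] <- NA_real_
  list(ic = ic, ic025 = ic025)
}

#' Reporting odds ratio with Woolf 95% interval
#'
#' `ROR = (a d)/(b c)`; the interval is
#' `exp(ln ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero
#' all four cells receive the Haldane-Anscombe +0.5 correction for the
#' estimate and interval; the chi-square p-value (Pearson, df 1) always uses
#' the raw cells. Empty margins yield `NA` markers.
#'
#' @param table A `contingency_table`.
#' @return List with `ror`, `ror_lo`, `ror_hi`, `chi2`, `p_value`.
#' @export
ror <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  lapply(ror_vec(table$a, table$b, table$c, table$d), unname)
}

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`, with the same zero-cell policy as [ror()];
#' the chi-square is the Pearson statistic without continuity correction on
#' the raw cells.
#'
#' @param table A `contingency_table`.
#' @return List with `prr`, `chi2`, `p_value`.
#' @export
prr <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  lapply(prr_vec(table$a, table$b, table$c, table$d), unname)
}

#' BCPNN information component (closed form)
#'
#' `IC = log2[(a + 0.5)/(E + 0.5)]` with the asymptotic lower credibility
#' bound `IC025 = IC - 3.3 (a+0.5)^-1/2 - 2 (a+0.5)^-3/2`.
#'
#' @param table A `contingency_table`.
#' @return List with `ic`, `ic025`.
#' @export
bcpnn_ic <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  ic_vec(table$a, table$E)
}

#' Default MGPS two-gamma mixture prior
#' @return A `gps_prior` with the customary starting values
#'   (`alpha1=0.2, beta1=0.1, alpha2=2, beta2=4, P=1/3`).
#' @export
default_gps_prior <- function() gps_prior(0.2, 0.1, 2, 4, 1 / 3)

#' Construct an MGPS prior
#' @param alpha1,beta1,alpha2,beta2 Positive shape/rate parameters of the two
#'   gamma components.
#' @param P Mixture weight of the first component, in `[0, 1]`.
#' @return Object of class `gps_prior`.
#' @export
gps_prior <- function(alpha1, beta1, alpha2, beta2, P) {
  v <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("gamma parameters must be positive", call. = FALSE)
  if (!is_prob(P)) stop("P must be in [0, 1]", call. = FALSE)
  structure(as.list(c(v, P = P)), class = "gps_prior")
}

# Mixture negative-binomial marginal log-likelihood of observed counts a
# given expected counts E under the two-gamma prior (stabilized log-sum-exp).
gps_marginal_ll <- function(par, a, E) {
  a1 <- exp(par[1]); b1 <- exp(par[2]); a2 <- exp(par[3]); b2 <- exp(par[4])
  P <- stats::plogis(par[5])
  l1 <- stats::dnbinom(a, size = a1, prob = b1 / (b1 + E), log = TRUE)
  l2 <- stats::dnbinom(a, size = a2, prob = b2 / (b2 + E), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(P * exp(l1 - m) + (1 - P) * exp(l2 - m)))
}

#' Fit the MGPS prior by marginal maximum likelihood
#'
#' Maximizes the summed log marginal likelihood of the observed `a` counts
#' given their expected counts `E` under the two-gamma negative-binomial
#' mixture, using BFGS on log-transformed gamma parameters (logit for the
#' weight) with deterministic jittered restarts from the documented
#' initialization.
#'
#' @param tables A list of `contingency_table`s, or a data.frame with columns
#'   `a` and `E` (the screening universe).
#' @param init Starting prior.
#' @param restarts Number of additional jittered starts.
#' @param min_tables Below this many usable tables (E > 0) the default prior
#'   is returned with a warning.
#' @return A `gps_prior` with attributes `logLik` and `convergence`.
#' @export
fit_gps_prior <- function(tables, init = default_gps_prior(), restarts = 5,
                          min_tables = 50) {
  if (is.data.frame(tables)) {
    a <- tables$a; E <- tables$E
  } else {
    a <- vapply(tables, `[[`, 0, "a"); E <- vapply(tables, `[[`, 0, "E")
  }
  ok <- is.finite(E) & E > 0
  a <- a[ok]; E <- E[ok]
  if (length(a) < min_tables) {
    warning(sprintf("only %d usable tables (< %d); returning default prior",
                    length(a), min_tables))
    return(default_gps_prior())
  }
  p0 <- c(log(init$alpha1), log(init$beta1), log(init$alpha2), log(init$beta2),
          stats::qlogis(min(max(init$P, 1e-6), 1 - 1e-6)))
  jitters <- with_seed(1L, lapply(seq_len(restarts), function(i)
    stats::rnorm(5, sd = 0.5)))
  starts <- c(list(p0), lapply(jitters, function(j) p0 + j))
  best <- NULL
  for (s in starts) {
    # exploratory restarts can propose extreme parameters where the NB
    # density underflows to NaN; optim treats those points as worse
    fit <- tryCatch(
      suppressWarnings(
        stats::optim(s, function(p) -gps_marginal_ll(p, a, E),
                     method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-10))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value - 1e-8))
      best <- fit
  }
  if (is.null(best))
    stop("MGPS prior optimization failed to converge from all starts",
         call. = FALSE)
  p <- best$par
  out <- gps_prior(exp(p[1]), exp(p[2]), exp(p[3]), exp(p[4]),
                   stats::plogis(p[5]))
  attr(out, "logLik") <- -best$value
  attr(out, "convergence") <- best$convergence
  out
}

#' Empirical-Bayes geometric mean and 5th posterior percentile
#'
#' Under the two-gamma prior the posterior of the relative reporting rate is
#' the mixture `Q Ga(alpha1+a, beta1+E) + (1-Q) Ga(alpha2+a, beta2+E)` with
#' `Q` the posterior component weight. `EBGM = 2^(E[log2 lambda])` (the
#' posterior geometric mean) and `EB05` is the 5th percentile of the
#' posterior mixture found by monotone root finding on its CDF.
#'
#' @param table A `contingency_table` (requires `E > 0`).
#' @param prior A `gps_prior`.
#' @return List with `ebgm`, `eb05`.
#' @export
ebgm <- function(table, prior = default_gps_prior()) {
  stopifnot(inherits(table, "contingency_table"), inherits(prior, "gps_prior"))
  res <- ebgm_vec(table$a, table$E, prior)
  list(ebgm = res$ebgm[1], eb05 = res$eb05[1])
}

ebgm_vec <- function(a, E, prior) {
  a1 <- prior$alpha1; b1 <- prior$beta1
  a2 <- prior$alpha2; b2 <- prior$beta2; P <- prior$P
  n <- length(a)
  out_g <- rep(NA_real_, n); out_q <- rep(NA_real_, n)
  ok <- is.finite(E) & E > 0
  if (!any(ok)) return(list(ebgm = out_g, eb05 = out_q))
  ai <- a[ok]; Ei <- E[ok]
  l1 <- stats::dnbinom(ai, size = a1, prob = b1 / (b1 + Ei), log = TRUE) + log(P)
  l2 <- stats::dnbinom(ai, size = a2, prob = b2 / (b2 + Ei), log = TRUE) + log1p(-P)
  # degenerate weights at P = 0 or 1
  if (P == 0) { Q <- rep(0, length(ai)) } else if (P == 1) { Q <- rep(1, length(ai)) } else {
    m <- pmax(l1, l2)
    Q <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  }
  elog <- Q * (digamma(a1 + ai) - log(b1 + Ei)) +
    (1 - Q) * (digamma(a2 + ai) - log(b2 + Ei))
  out_g[ok] <- exp(elog)
  out_q[ok] <- vapply(seq_along(ai), function(i) {
    cdf <- function(q) Q[i] * stats::pgamma(q, a1 + ai[i], rate = b1 + Ei[i]) +
      (1 - Q[i]) * stats::pgamma(q, a2 + ai[i], rate = b2 + Ei[i]) - 0.05
    qs <- c(stats::qgamma(0.05, a1 + ai[i], rate = b1 + Ei[i]),
            stats::qgamma(0.05, a2 + ai[i], rate = b2 + Ei[i]))
    lo <- min(qs) * 0.5; hi <- max(qs) * 2 + 1e-12
    stats::uniroot(cdf, c(lo, hi), tol = 1e-10, extendInt = "upX")$root
  }, 0)
  list(ebgm = out_g, eb05 = out_q)
}

#' Default per-method signal thresholds
#'
#' The canonical literature thresholds: ROR requires `a >= 3` reports and a
#' 95% interval lower bound above 1; PRR requires `PRR >= 2`, `chi2 >= 4` and
#' `a >= 3`; BCPNN requires `IC025 > 0`; MGPS requires `EB05 >= 2`.
#'
#' @return Named list of threshold values.
#' @export
default_thresholds <- function() {
  list(ror_min_a = 3, ror_lo_gt = 1,
       prr_min = 2, prr_chi2_min = 4, prr_min_a = 3,
       ic025_gt = 0, eb05_min = 2)
}

#' Apply signal thresholds and the consensus rule
#'
#' A drug is a consensus signal when the ROR flag holds together with at
#' least one of the other three method flags. Undefined statistics count as
#' not flagged.
#'
#' @param stats A list or one-row data.frame with `a`, `ror_lo`, `prr`,
#'   `chi2`, `ic025`, `eb05`.
#' @param thresholds See [default_thresholds()].
#' @return List of logical flags `ror`, `prr`, `bcpnn`, `mgps`, `consensus`.
#' @export
apply_thresholds <- function(stats, thresholds = default_thresholds()) {
  g <- function(x) !is.na(x) & x
  f_ror <- g(stats$a >= thresholds$ror_min_a & stats$ror_lo > thresholds$ror_lo_gt)
  f_prr <- g(stats$prr >= thresholds$prr_min & stats$chi2 >= thresholds$prr_chi2_min &
               stats$a >= thresholds$prr_min_a)
  f_ic <- g(stats$ic025 > thresholds$ic025_gt)
  f_eb <- g(stats$eb05 >= thresholds$eb05_min)
  list(ror = f_ror, prr = f_prr, bcpnn = f_ic, mgps = f_eb,
       consensus = f_ror & (f_prr | f_ic | f_eb))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, order-preserving, capped at 1.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Full disproportionality scan of a cohort
#'
#' Builds the 2x2 table for every primary-suspect drug (or a supplied list),
#' fits the MGPS prior over the screening universe, computes all four
#' statistics, applies the thresholds and consensus rule, and attaches BH-FDR
#' q-values from the association chi-square p-values.
#'
#' @param cohort A `pv_cohort`.
#' @param drugs Optional character vector restricting the scan.
#' @param min_count Minimum `a` for a drug to be retained in the output.
#' @param thresholds See [default_thresholds()].
#' @param prior Optional fixed `gps_prior`; fitted when `NULL`.
#' @return data.table: one row per drug with cells, all statistics, interval
#'   bounds, per-method flags, consensus and `q_value`.
#' @export
signal_scan <- function(cohort, drugs = NULL, min_count = 1,
                        thresholds = default_thresholds(), prior = NULL) {
  stopifnot(inherits(cohort, "pv_cohort"))
  ps <- unique(cohort$drug[role_cod == "PS", .(primaryid, drugname_norm)])
  if (!is.null(drugs)) ps <- ps[drugname_norm %in% normalize_drug(drugs)]
  flt <- attr(cohort, "filter")
  if (!is.null(flt)) ps <- ps[!drugname_norm %in% flt$drug_exclusions]
  demo <- cohort$demo[, .(primaryid, is_case)]
  m <- merge(ps, demo, by = "primaryid")
  counts <- m[, .(a = sum(is_case), n_exposed = .N), by = drugname_norm]
  n_total <- nrow(demo); n_cases <- sum(demo$is_case)
  counts[, `:=`(b = n_exposed - a, c = n_cases - a,
                d = n_total - n_exposed - (n_cases - a))]
  counts[, `:=`(N = n_total, E = n_exposed * n_cases / n_total)]
  counts <- counts[a >= min_count]
  setorder(counts, drugname_norm)

  if (is.null(prior))
    prior <- fit_gps_prior(data.frame(a = counts$a, E = counts$E))

  rr <- ror_vec(counts$a, counts$b, counts$c, counts$d)
  pp <- prr_vec(counts$a, counts$b, counts$c, counts$d)
  ic <- ic_vec(counts$a, counts$E)
  eb <- ebgm_vec(counts$a, counts$E, prior)
  res <- data.table(
    drug = counts$drugname_norm,
    a = counts$a, b = counts$b, c = counts$c, d = counts$d, E = counts$E,
    ror = rr$ror, ror_lo = rr$ror_lo, ror_hi = rr$ror_hi,
    prr = pp$prr, chi2 = rr$chi2, p_value = rr$p_value,
    ic = ic$ic, ic025 = ic$ic025,
    ebgm = eb$ebgm, eb05 = eb$eb05)
  fl <- apply_thresholds(res, thresholds)
  res[, `:=`(flag_ror = fl$ror, flag_prr = fl$prr, flag_bcpnn = fl$bcpnn,
             flag_mgps = fl$mgps, consensus = fl$consensus,
             q_value = bh_fdr(p_value))]
  setattr(res, "prior", prior)
  res[]
}
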