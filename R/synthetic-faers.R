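# Synthetic FAERS-style report generator with known ground truth.
#
# The generator emulates the structural features of spontaneous reporting
# data that the downstream pipeline must cope with: per-case versioned
# duplicates, drug role codes, target vs background MedDRA preferred terms,
# heavy non-random demographic missingness, partial dates, and per-drug
# Weibull time-to-onset distributions with configurable injected relative
# risks. Because events follow an explicit Bernoulli model with
# multiplicative RR on the base rate, the implied 2x2 cell probabilities are
# available in closed form for oracle checks.

.BG_DRUGS <- sprintf("BACKGROUND DRUG %02d", 1:12)
.BG_PTS <- c("HEADACHE", "NAUSEA", "PYREXIA", "FATIGUE", "RASH",
             "DRUG INEFFECTIVE", "DIZZINESS", "VOMITING")
.TARGET_PTS <- c("ABORTION SPONTANEOUS", "ABORTION")
.COUNTRIES <- c("US", "CA", "GB", "DE", "FR", "JP", "BR", "IT", "DK",
                "NL", "ES", "SE", "OTHER")
.COUNTRY_PROBS <- c(0.36, 0.11, 0.08, 0.06, 0.05, 0.02, 0.02, 0.02, 0.013,
                    0.012, 0.011, 0.010, 0.214)

#' Default reporter-occupation mix
#'
#' Occupation proportions typical of miscarriage safety reports: roughly a
#' third physicians, a third consumers, a quarter other health professionals,
#' with a small lawyer share and ~5% missing.
#'
#' @return Named numeric vector over `MD, CN, PH, HP, OT, LW, missing`
#'   summing to 1.
#' @export
default_occupation_mix <- function() {
  c(MD = 0.3080, CN = 0.3125, PH = 0.0213, HP = 0.0846, OT = 0.2213,
    LW = 0.0063, missing = 0.0460)
}

#' Configuration for the synthetic report generator
#'
#' @param n_reports Number of unique cases to generate (before duplicate
#'   versions are appended).
#' @param drugs A `data.frame` (or list coercible to one) with columns
#'   `name`, `use_prob` (probability the drug appears as primary suspect on a
#'   report), `injected_rr` (multiplicative relative risk on the base event
#'   rate), `tto_shape`, `tto_scale` (Weibull time-to-onset parameters in
#'   days).
#' @param event_base_rate Baseline probability that a report is a miscarriage
#'   case in the absence of any configured drug.
#' @param duplicate_rate Fraction of cases re-emitted as an extra version in
#'   `[0, 1)`.
#' @param missing_age_rate,missing_weight_rate,missing_date_rate Missingness
#'   probabilities. Masked dates become partial (month precision) half the
#'   time and fully missing otherwise.
#' @param age_dist,weight_dist Distribution descriptors: a list with
#'   `family` (`"normal"`, `"lognormal"` or `"uniform"`) plus its parameters
#'   (`mean`/`sd`, `meanlog`/`sdlog`, or `min`/`max`).
#' @param occupation_mix Named probability vector over occupation codes
#'   (`missing` allowed); must sum to 1.
#' @param seed Integer seed; identical configs produce bitwise-identical
#'   cohorts.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports,
                             drugs,
                             event_base_rate = 0.01,
                             duplicate_rate = 0.1,
                             missing_age_rate = 0.454,
                             missing_weight_rate = 0.782,
                             missing_date_rate = 0.30,
                             age_dist = list(family = "normal", mean = 32, sd = 9),
                             weight_dist = list(family = "normal", mean = 68, sd = 16),
                             occupation_mix = default_occupation_mix(),
                             seed = 1L) {
  drugs <- as.data.frame(drugs, stringsAsFactors = FALSE)
  cfg <- structure(list(
    n_reports = n_reports, drugs = drugs,
    event_base_rate = event_base_rate, duplicate_rate = duplicate_rate,
    missing_age_rate = missing_age_rate,
    missing_weight_rate = missing_weight_rate,
    missing_date_rate = missing_date_rate,
    age_dist = age_dist, weight_dist = weight_dist,
    occupation_mix = occupation_mix, seed = as.integer(seed)),
    class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' Validate a synthetic generator configuration
#'
#' @param config A `synthetic_config`.
#' @return The config, invisibly, or an error naming the offending field.
#' @export
validate_synthetic_config <- function(config) {
  c0 <- config
  if (!is.numeric(c0$n_reports) || length(c0$n_reports) != 1 ||
      !is.finite(c0$n_reports) || c0$n_reports < 1)
    stop_field("n_reports", "must be a positive integer")
  d <- c0$drugs
  need <- c("name", "use_prob", "injected_rr", "tto_shape", "tto_scale")
  if (!is.data.frame(d) || !all(need %in% names(d)))
    stop_field("drugs", paste("must have columns", paste(need, collapse = ", ")))
  if (nrow(d) > 0) {
    if (anyDuplicated(d$name)) stop_field("drugs$name", "must be unique")
    if (!all(is.finite(d$use_prob)) || any(d$use_prob < 0 | d$use_prob > 1))
      stop_field("drugs$use_prob", "must be probabilities in [0,1]")
    if (!all(is.finite(d$injected_rr)) || any(d$injected_rr <= 0))
      stop_field("drugs$injected_rr", "must be positive")
    if (!all(is.finite(d$tto_shape)) || any(d$tto_shape <= 0))
      stop_field("drugs$tto_shape", "must be positive")
    if (!all(is.finite(d$tto_scale)) || any(d$tto_scale <= 0))
      stop_field("drugs$tto_scale", "must be positive")
  }
  for (f in c("event_base_rate", "missing_age_rate", "missing_weight_rate",
              "missing_date_rate"))
    if (!is_prob(c0[[f]])) stop_field(f, "must be a probability in [0,1]")
  if (!is_prob(c0$duplicate_rate) || c0$duplicate_rate >= 1)
    stop_field("duplicate_rate", "must be a probability in [0,1)")
  mix <- c0$occupation_mix
  if (is.null(names(mix)) || any(!is.finite(mix)) || any(mix < 0) ||
      abs(sum(mix) - 1) > 1e-9)
    stop_field("occupation_mix", "must be a named non-negative vector summing to 1")
  ok_codes <- c("MD", "CN", "PH", "HP", "OT", "LW", "missing")
  if (!all(names(mix) %in% ok_codes))
    stop_field("occupation_mix", paste("codes must be among",
                                       paste(ok_codes, collapse = ", ")))
  for (dn in c("age_dist", "weight_dist")) {
    dd <- c0[[dn]]
    if (!is.list(dd) || is.null(dd$family) ||
        !dd$family %in% c("normal", "lognormal", "uniform"))
      stop_field(dn, "family must be 'normal', 'lognormal' or 'uniform'")
  }
  invisible(config)
}

draw_dist <- function(dist, n) {
  switch(dist$family,
    normal    = stats::rnorm(n, dist$mean, dist$sd),
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    uniform   = stats::runif(n, dist$min, dist$max))
}

#' Generate a synthetic FAERS-like cohort with ground truth
#'
#' Each report is exposed to each configured drug independently with its
#' `use_prob` (as primary suspect). The report is a miscarriage case with
#' probability `event_base_rate` multiplied by the product of the injected
#' relative risks of its exposed drugs, capped at 1. Event-positive exposed
#' reports carry a therapy start date preceding the event date by a Weibull
#' draw rounded up to whole days (>= 1). Reports with no configured exposure
#' receive a background primary-suspect drug so that every report passes the
#' role filter. A `duplicate_rate` fraction of cases is re-emitted as an
#' extra version (half with a bumped case version, half with the same version
#' and a later FDA receipt date, occasionally with one previously missing
#' demographic filled in) so every deduplication rule is exercised.
#'
#' @param config A validated [synthetic_config()].
#' @return A list with `cohort` (an `icsr_set`: linked `demo`, `drug`, `reac`
#'   data.tables) and `truth` (per-drug injected RR and Weibull parameters,
#'   `n_unique_cases`, `n_duplicate_versions`).
#' @export
generate_cohort <- function(config) {
  validate_synthetic_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n  <- as.integer(config$n_reports)
  dr <- config$drugs
  nd <- nrow(dr)

  expo <- if (nd > 0) {
    matrix(stats::runif(n * nd) < rep(dr$use_prob, each = n), n, nd)
  } else matrix(FALSE, n, 0)

  log_rr <- if (nd > 0) as.numeric(expo %*% log(dr$injected_rr)) else numeric(n)
  p_event <- pmin(1, config$event_base_rate * exp(log_rr))
  event <- stats::runif(n) < p_event

  age <- round_half_up(pmin(84, pmax(0, draw_dist(config$age_dist, n))), 1)
  wt  <- round_half_up(pmin(250, pmax(35, draw_dist(config$weight_dist, n))), 1)
  age[stats::runif(n) < config$missing_age_rate] <- NA_real_
  wt[stats::runif(n) < config$missing_weight_rate] <- NA_real_
  sex <- ifelse(stats::runif(n) < 0.85, "F", "M")
  occ <- sample(names(config$occupation_mix), n, replace = TRUE,
                prob = config$occupation_mix)
  occ[occ == "missing"] <- NA_character_
  country <- sample(.COUNTRIES, n, replace = TRUE, prob = .COUNTRY_PROBS)

  fda_dt <- as.IDate("2005-01-01") + floor(stats::runif(n) * 7305)
  event_date <- fda_dt - floor(stats::runif(n) * 181)

  caseid <- as.character(100000000L + seq_len(n))
  demo <- data.table(
    primaryid = paste0(caseid, "-1"), caseid = caseid, caseversion = 1L,
    fda_dt = fda_dt, event_dt = idate_to_faers(event_date),
    age = age, age_cod = ifelse(is.na(age), "", "YR"),
    wt = wt, wt_cod = ifelse(is.na(wt), "", "KG"),
    sex = sex, occp_cod = occ, reporter_country = country)

  # Drug rows: configured exposures (role PS), background PS for unexposed
  # reports, plus occasional concomitant rows to exercise the role filter.
  drug_rows <- vector("list", nd + 2L)
  if (nd > 0) for (j in seq_len(nd)) {
    idx <- which(expo[, j])
    if (!length(idx)) next
    ev <- event[idx]
    tto <- integer(length(idx))
    if (any(ev))
      tto[ev] <- pmax(1, ceiling(stats::rweibull(sum(ev), dr$tto_shape[j],
                                                 dr$tto_scale[j])))
    if (any(!ev))
      tto[!ev] <- sample.int(720L, sum(!ev), replace = TRUE)
    drug_rows[[j]] <- data.table(
      row = idx, drugname = dr$name[j], role_cod = "PS",
      start_dt = idate_to_faers(event_date[idx] - tto))
  }
  unexposed <- if (nd > 0) which(rowSums(expo) == 0) else seq_len(n)
  if (length(unexposed)) {
    drug_rows[[nd + 1L]] <- data.table(
      row = unexposed,
      drugname = sample(.BG_DRUGS, length(unexposed), replace = TRUE),
      role_cod = "PS",
      start_dt = idate_to_faers(
        event_date[unexposed] - sample.int(720L, length(unexposed), TRUE)))
  }
  conc <- which(stats::runif(n) < 0.2)
  if (length(conc)) {
    drug_rows[[nd + 2L]] <- data.table(
      row = conc, drugname = sample(.BG_DRUGS, length(conc), replace = TRUE),
      role_cod = "C", start_dt = "")
  }
  drug <- rbindlist(drug_rows)
  setorder(drug, row)
  drug[, drug_seq := seq_len(.N), by = row]

  # Date missingness: masked starts/events become month-precision partials
  # half the time, fully missing otherwise.
  mask_date <- function(x, rate) {
    m <- stats::runif(length(x)) < rate
    part <- m & stats::runif(length(x)) < 0.5
    x[part] <- substr(x[part], 1, 6)
    x[m & !part] <- ""
    x
  }
  drug[, start_dt := mask_date(start_dt, config$missing_date_rate)]
  demo[, event_dt := mask_date(event_dt, config$missing_date_rate)]

  # Reactions: target PT for cases, background PTs otherwise / extra.
  pt_main <- ifelse(event,
                    ifelse(stats::runif(n) < 0.8, .TARGET_PTS[1], .TARGET_PTS[2]),
                    sample(.BG_PTS, n, replace = TRUE))
  extra <- which(stats::runif(n) < 0.3)
  reac <- rbindlist(list(
    data.table(row = seq_len(n), pt = pt_main),
    data.table(row = extra, pt = sample(.BG_PTS, length(extra), replace = TRUE))))
  setorder(reac, row)

  drug <- cbind(demo[drug$row, .(primaryid, caseid)], drug[, !"row"])
  reac <- cbind(demo[reac$row, .(primaryid, caseid)], reac[, !"row"])

  # Duplicate versions.
  n_dup <- as.integer(round(config$duplicate_rate * n))
  if (n_dup > 0) {
    dup_idx <- sample.int(n, n_dup)
    dd <- copy(demo[dup_idx])
    bump <- stats::runif(n_dup) < 0.5
    dd[bump, caseversion := caseversion + 1L]
    dd[, fda_dt := fda_dt + ifelse(bump, sample.int(90L, n_dup, TRUE),
                                   sample(0:90, n_dup, TRUE))]
    fill <- stats::runif(n_dup) < 0.5
    fa <- fill & is.na(dd$age)
    dd[fa, `:=`(age = round_half_up(pmin(84, pmax(
      0, draw_dist(config$age_dist, sum(fa)))), 1), age_cod = "YR")]
    fw <- fill & !fa & is.na(dd$wt)
    dd[fw, `:=`(wt = round_half_up(pmin(250, pmax(
      35, draw_dist(config$weight_dist, sum(fw)))), 1), wt_cod = "KG")]
    dd[, primaryid := paste0(caseid, "-2")]
    dup_drug <- copy(drug[primaryid %in% demo$primaryid[dup_idx]])
    dup_reac <- copy(reac[primaryid %in% demo$primaryid[dup_idx]])
    dup_drug[, primaryid := paste0(caseid, "-2")]
    dup_reac[, primaryid := paste0(caseid, "-2")]
    demo <- rbindlist(list(demo, dd))
    drug <- rbindlist(list(drug, dup_drug))
    reac <- rbindlist(list(reac, dup_reac))
  }

  # canonical layout shared with parse_quarter, so that a written quarter
  # parses back field- and order-identical
  drug <- drug[, .(primaryid, caseid, drug_seq, role_cod, drugname, start_dt)]
  setorder(drug, primaryid, drug_seq)
  setorder(reac, primaryid)

  truth <- structure(list(
    injected_rr = stats::setNames(dr$injected_rr, dr$name),
    tto = stats::setNames(
      lapply(seq_len(nd), function(j) c(shape = dr$tto_shape[j],
                                        scale = dr$tto_scale[j])),
      dr$name),
    n_unique_cases = n,
    n_duplicate_versions = n_dup), class = "ground_truth")

  list(cohort = new_icsr_set(demo, drug, reac), truth = truth)
}

#' Write an `icsr_set` as FAERS-dialect quarterly ASCII files
#'
#' Emits `DEMO<q>.txt`, `DRUG<q>.txt`, `REAC<q>.txt` and `THER<q>.txt` in the
#' `$`-delimited dialect consumed by [parse_quarter()]. Therapy start dates
#' travel in THER keyed by `(primaryid, dsg_drug_seq)` as in the real
#' extracts; missing values are empty fields.
#'
#' @param records An `icsr_set` (e.g. from [generate_cohort()]).
#' @param directory Output directory (created if absent).
#' @param quarter Label appended to file names, e.g. `"24Q4"`.
#' @return Invisibly, the vector of file paths written.
#' @export
write_faers_quarter <- function(records, directory, quarter = "24Q4") {
  stopifnot(inherits(records, "icsr_set"))
  if (nrow(records$demo) == 0) stop("records must be non-empty", call. = FALSE)
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory: ", directory, call. = FALSE)
  demo <- copy(records$demo)
  demo[, fda_dt := idate_to_faers(fda_dt)]
  ther <- records$drug[start_dt != "",
                       .(primaryid, caseid, dsg_drug_seq = drug_seq, start_dt)]
  files <- file.path(directory, paste0(c("DEMO", "DRUG", "REAC", "THER"),
                                       quarter, ".txt"))
  fwrite(demo, files[1], sep = "$", quote = FALSE, na = "")
  fwrite(records$drug[, .(primaryid, caseid, drug_seq, role_cod, drugname)],
         files[2], sep = "$", quote = FALSE, na = "")
  fwrite(records$reac[, .(primaryid, caseid, pt)],
         files[3], sep = "$", quote = FALSE, na = "")
  fwrite(ther, files[4], sep = "$", quote = FALSE, na = "")
  invisible(files)
}
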