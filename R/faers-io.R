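# Reading FAERS-dialect quarterly extracts, case-version deduplication,
# cohort selection, and descriptive summaries.
#
# A report set is represented relationally, as in the source extracts: a
# DEMO table (one row per case version, keyed by `primaryid`), a DRUG table
# (one row per reported drug, with role code and therapy start date) and a
# REAC table (one row per MedDRA preferred term). This keeps joins and
# filters vectorized over hundreds of thousands of reports.

new_icsr_set <- function(demo, drug, reac) {
  # drop any auto-created index cache so equal sets compare identical()
  for (tb in list(demo, drug, reac))
    if (data.table::is.data.table(tb)) data.table::setindex(tb, NULL)
  structure(list(demo = demo, drug = drug, reac = reac), class = "icsr_set")
}

#' @export
print.icsr_set <- function(x, ...) {
  cat(sprintf("<icsr_set> %d report versions (%d unique cases), %d drug rows, %d reactions\n",
              nrow(x$demo), data.table::uniqueN(x$demo$caseid),
              nrow(x$drug), nrow(x$reac)))
  invisible(x)
}

.DEMO_REQUIRED <- c("primaryid", "caseid", "caseversion", "fda_dt")
.DEMO_OPTIONAL <- c("event_dt", "age", "age_cod", "wt", "wt_cod", "sex",
                    "occp_cod", "reporter_country")

#' Parse a FAERS-dialect quarterly file set
#'
#' Reads the `$`-delimited DEMO/DRUG/REAC/THER ASCII files of one quarter and
#' joins them into an `icsr_set`: one record per DEMO row, drugs and
#' reactions attached by `primaryid`, therapy start dates joined from THER by
#' `(primaryid, dsg_drug_seq)`. Unparseable dates are kept as partial strings
#' or made missing, never fabricated. DRUG/REAC rows whose key is absent from
#' DEMO are skipped; their counts are recorded in the `skipped` attribute.
#'
#' @param path A directory containing `DEMO*`, `DRUG*`, `REAC*` (and
#'   optionally `THER*`) files, or a named list/vector with elements `demo`,
#'   `drug`, `reac`, `ther` giving file paths.
#' @return An `icsr_set`. Attribute `skipped` counts orphan DRUG/REAC rows;
#'   attribute `n_drugless` counts DEMO rows with no drug rows.
#' @export
parse_quarter <- function(path) {
  if (is.character(path) && length(path) == 1 && dir.exists(path)) {
    find1 <- function(prefix) {
      f <- list.files(path, pattern = paste0("^", prefix), ignore.case = TRUE,
                      full.names = TRUE)
      if (length(f)) f[1] else NA_character_
    }
    files <- list(demo = find1("DEMO"), drug = find1("DRUG"),
                  reac = find1("REAC"), ther = find1("THER"))
  } else {
    files <- as.list(path)
  }
  if (is.na(files$demo %||% NA) || is.na(files$drug %||% NA))
    stop("DEMO and DRUG files are required", call. = FALSE)
  for (opt in c("reac", "ther"))
    if (is.na(files[[opt]] %||% NA))
      warning(sprintf("%s file missing; %s", toupper(opt),
                      if (opt == "reac") "records will have no reactions"
                      else "therapy start dates unavailable"))

  read1 <- function(f) {
    fread(f, sep = "$", colClasses = "character", na.strings = NULL,
          quote = "", header = TRUE)
  }
  demo <- read1(files$demo)
  miss <- setdiff(.DEMO_REQUIRED, names(demo))
  if (length(miss))
    stop(sprintf("format error in %s: missing column(s) %s",
                 basename(files$demo), paste(miss, collapse = ", ")),
         call. = FALSE)
  for (col in setdiff(.DEMO_OPTIONAL, names(demo))) demo[, (col) := ""]
  demo[, `:=`(
    caseversion = suppressWarnings(as.integer(caseversion)),
    fda_dt = faers_date_to_idate(fda_dt),
    age = suppressWarnings(as.numeric(age)),
    wt = suppressWarnings(as.numeric(wt)))]
  demo[is.na(caseversion), caseversion := 1L]
  for (col in c("sex", "occp_cod", "reporter_country"))
    demo[get(col) == "", (col) := NA_character_]
  if (any(demo$caseid == "" | is.na(demo$caseid)))
    stop("format error: empty CASEID in DEMO", call. = FALSE)

  drug <- read1(files$drug)
  for (col in c("primaryid", "caseid", "role_cod", "drugname"))
    if (!col %in% names(drug))
      stop(sprintf("format error in %s: missing column(s) %s",
                   basename(files$drug), col), call. = FALSE)
  if (!"drug_seq" %in% names(drug)) drug[, drug_seq := seq_len(.N), by = primaryid]
  drug[, drug_seq := suppressWarnings(as.integer(drug_seq))]

  reac <- if (!is.na(files$reac %||% NA)) read1(files$reac) else
    data.table(primaryid = character(), caseid = character(), pt = character())

  skipped <- c(drug = sum(!drug$primaryid %in% demo$primaryid),
               reac = sum(!reac$primaryid %in% demo$primaryid))
  drug <- drug[primaryid %in% demo$primaryid]
  reac <- reac[primaryid %in% demo$primaryid]

  if (!is.na(files$ther %||% NA)) {
    ther <- read1(files$ther)
    ther[, drug_seq := suppressWarnings(as.integer(dsg_drug_seq))]
    drug <- merge(drug, ther[, .(primaryid, drug_seq, start_dt)],
                  by = c("primaryid", "drug_seq"), all.x = TRUE)
    drug[is.na(start_dt), start_dt := ""]
  } else drug[, start_dt := ""]
  setorder(drug, primaryid, drug_seq)
  drug <- drug[, .(primaryid, caseid, drug_seq, role_cod, drugname, start_dt)]

  out <- new_icsr_set(demo[, c(.DEMO_REQUIRED, .DEMO_OPTIONAL), with = FALSE],
                      drug, reac[, .(primaryid, caseid, pt)])
  setattr(out, "skipped", skipped)
  setattr(out, "n_drugless", sum(!out$demo$primaryid %in% out$drug$primaryid))
  out
}

.DEDUP_FIELDS <- c("age", "wt", "sex", "occp_cod", "reporter_country", "event_dt")

#' Deduplicate case versions
#'
#' Retains exactly one report per `CASEID` following the FDA quarterly-extract
#' guidance: keep the highest case version; among equal versions the most
#' recent FDA receipt date; among those the version with the fewest missing
#' values over age, weight, sex, occupation, country and event date; final
#' ties broken deterministically by keeping the last record in input order.
#' Idempotent.
#'
#' @param records An `icsr_set`.
#' @param drop_caseids Optional character vector of obsolete/deleted CASEIDs
#'   to remove before version selection (no-op when empty).
#' @return A deduplicated `icsr_set` with attribute `n_removed`.
#' @export
deduplicate <- function(records, drop_caseids = character()) {
  stopifnot(inherits(records, "icsr_set"))
  d <- copy(records$demo)
  if (length(drop_caseids)) d <- d[!caseid %in% drop_caseids]
  if (nrow(d) == 0)
    return(new_icsr_set(d, records$drug[0], records$reac[0]))
  miss_n <- rowSums(vapply(.DEDUP_FIELDS, function(f) {
    v <- d[[f]]
    if (is.character(v)) is.na(v) | v == "" else is.na(v)
  }, logical(nrow(d))))
  d[, `:=`(..miss = miss_n, ..ord = .I)]
  setorder(d, caseid, caseversion, fda_dt, -..miss, ..ord)
  keep <- d[, .(primaryid = primaryid[.N]), by = caseid]$primaryid
  demo <- records$demo[primaryid %in% keep]
  out <- new_icsr_set(demo,
                      records$drug[primaryid %in% keep],
                      records$reac[primaryid %in% keep])
  # clear index caches the queries above may have planted on the input, so
  # dedup(dedup(x)) compares identical to dedup(x)
  for (tb in records[c("demo", "drug", "reac")])
    if (data.table::is.data.table(tb)) data.table::setindex(tb, NULL)
  setattr(out, "n_removed", nrow(records$demo) - nrow(demo))
  out
}

#' Normalize drug names
#'
#' Uppercases, trims, collapses internal whitespace and strips trailing salt
#' qualifiers (configurable suffix list). No ingredient-dictionary mapping is
#' attempted.
#'
#' @param x Character vector of drug names.
#' @param salt_suffixes Trailing tokens to strip.
#' @return Normalized character vector.
#' @export
normalize_drug <- function(x, salt_suffixes = c(
  "HYDROCHLORIDE", "HCL", "SODIUM", "SULFATE", "SULPHATE", "ACETATE",
  "MESYLATE", "TARTRATE", "MALEATE", "CITRATE", "PHOSPHATE", "BESYLATE")) {
  out <- toupper(trimws(x))
  out <- gsub("[[:space:]]+", " ", out)
  pat <- paste0(" (", paste(salt_suffixes, collapse = "|"), ")$")
  gsub(pat, "", out)
}

#' Drugs excluded to avoid protopathic / indication bias
#'
#' Progestogens and related formulations used for miscarriage prevention or
#' contraception, whose reporting pattern confounds association with the
#' outcome.
#'
#' @return Character vector of normalized drug names.
#' @export
progestogen_exclusions <- function() {
  c("MEDROXYPROGESTERONE", "PROGESTERONE",
    "INTRAUTERINE CONTRACEPTIVE DEVICE", "ETHINYLESTRADIOL/ETONOGESTREL",
    "ETONOGESTREL", "LEVONORGESTREL", "ETHINYLESTRADIOL/NORELGESTROMIN",
    "ULIPRISTAL")
}

#' Cohort-selection rules
#'
#' @param window Character vector of two `"yyyyQq"` labels (inclusive study
#'   window on the FDA receipt date).
#' @param roles_kept Drug role codes that qualify a report (default primary
#'   suspect only).
#' @param occupations_kept Reporter occupation codes retained. The default
#'   keeps health professionals and consumers; the lawyer code and missing
#'   occupations are dropped but the filter is configurable.
#' @param pt_targets MedDRA preferred terms defining a case (exact match
#'   after trimming and case folding).
#' @param drug_exclusions Normalized drug names whose primary-suspect
#'   exposure disqualifies nothing but is ignored when qualifying a report.
#' @return An object of class `cohort_filter`.
#' @export
cohort_filter <- function(window = c("2005Q1", "2024Q4"),
                          roles_kept = "PS",
                          occupations_kept = c("MD", "CN", "PH", "HP", "OT"),
                          pt_targets = c("ABORTION SPONTANEOUS", "ABORTION"),
                          drug_exclusions = progestogen_exclusions()) {
  stopifnot(length(window) == 2, length(pt_targets) >= 1)
  if (!all(roles_kept %in% c("PS", "SS", "C", "I")))
    stop_field("roles_kept", "must be a subset of PS, SS, C, I")
  structure(list(window = window, roles_kept = roles_kept,
                 occupations_kept = occupations_kept,
                 pt_targets = pt_targets,
                 drug_exclusions = normalize_drug(drug_exclusions)),
            class = "cohort_filter")
}

#' Exact preferred-term matching for miscarriage
#'
#' @param pts Character vector of reaction PTs (one record's reactions, or
#'   any vector).
#' @param pt_targets Target PTs.
#' @return `TRUE` iff any PT equals a target after trimming and case folding
#'   (no substring matching).
#' @export
match_miscarriage <- function(pts, pt_targets = c("ABORTION SPONTANEOUS", "ABORTION")) {
  if (!length(pts)) return(FALSE)
  any(toupper(trimws(pts)) %in% toupper(trimws(pt_targets)))
}

#' Build the analysis cohort
#'
#' Applies the study-window, occupation and drug-role rules to a
#' deduplicated report set. The background consists of reports inside the
#' window, passing the occupation filter, carrying at least one qualifying
#' (by role) drug not on the exclusion list; cases are the background subset
#' whose reactions include a target PT.
#'
#' @param records A deduplicated `icsr_set`.
#' @param filter A [cohort_filter()].
#' @return A `pv_cohort`: an `icsr_set` restricted to the background whose
#'   `demo` carries an `is_case` flag and whose `drug` table carries
#'   `drugname_norm`; attribute `funnel` records row counts at each step.
#' @export
filter_cohort <- function(records, filter = cohort_filter()) {
  stopifnot(inherits(records, "icsr_set"), inherits(filter, "cohort_filter"))
  demo <- records$demo
  w <- quarter_label_to_num(filter$window)
  q <- date_quarter(demo$fda_dt)
  in_window <- !is.na(q) & q >= w[1] & q <= w[2]
  occ_ok <- demo$occp_cod %in% filter$occupations_kept |
    ("missing" %in% filter$occupations_kept & is.na(demo$occp_cod))

  drug <- copy(records$drug)
  drug[, drugname_norm := normalize_drug(drugname)]
  qualifying <- unique(drug[role_cod %in% filter$roles_kept &
                              !drugname_norm %in% filter$drug_exclusions,
                            primaryid])
  keep <- demo$primaryid[in_window & occ_ok]
  keep <- keep[keep %in% qualifying]
  if (!length(keep))
    stop("empty background cohort; consider widening the study window or filters",
         call. = FALSE)

  demo <- demo[primaryid %in% keep]
  drug <- drug[primaryid %in% keep]
  reac <- records$reac[primaryid %in% keep]
  targets <- toupper(trimws(filter$pt_targets))
  case_ids <- unique(reac[toupper(trimws(pt)) %in% targets, primaryid])
  demo[, is_case := primaryid %in% case_ids]

  out <- new_icsr_set(demo, drug, reac)
  class(out) <- c("pv_cohort", "icsr_set")
  setattr(out, "filter", filter)
  setattr(out, "funnel", c(
    n_input = nrow(records$demo),
    n_window = sum(in_window),
    n_occupation = sum(in_window & occ_ok),
    n_background = nrow(demo),
    n_cases = length(case_ids)))
  out
}

#' Subset a cohort by primaryid
#' @param cohort An `icsr_set` or `pv_cohort`.
#' @param primaryids Keys to keep.
#' @return Object of the same class restricted to the given reports.
#' @export
subset_cohort <- function(cohort, primaryids) {
  out <- new_icsr_set(cohort$demo[primaryid %in% primaryids],
                      cohort$drug[primaryid %in% primaryids],
                      cohort$reac[primaryid %in% primaryids])
  class(out) <- class(cohort)
  out
}

#' Convert reported age to years
#'
#' FAERS age-unit codes: `DEC` decades (x10), `YR` years, `MON` months
#' (/12), `DY` days (/365.25). Unknown codes and implausible values
#' (negative, > 120 y) become missing.
#'
#' @param age Numeric vector.
#' @param age_cod Character unit codes.
#' @return Age in years.
#' @export
age_years <- function(age, age_cod) {
  f <- c(DEC = 10, YR = 1, MON = 1 / 12, DY = 1 / 365.25)
  out <- age * unname(f[toupper(age_cod)])
  out[!is.finite(out) | out < 0 | out > 120] <- NA_real_
  out
}

#' Convert reported weight to kilograms
#'
#' `LBS`/`LB` converts at 0.453592; values above 650 kg or non-positive are
#' treated as missing (implausible-entry guard).
#'
#' @param wt Numeric vector.
#' @param wt_cod Character unit codes (`KG`, `LBS`).
#' @return Weight in kg.
#' @export
weight_kg <- function(wt, wt_cod) {
  f <- c(KG = 1, KGS = 1, LBS = 0.453592, LB = 0.453592)
  out <- wt * unname(f[toupper(wt_cod)])
  out[!is.finite(out) | out <= 0 | out > 650] <- NA_real_
  out
}

#' Descriptive summary of a cohort
#'
#' Produces the standard demographic table: median \[min, max\] for
#' continuous variables, stratum counts with percentages over the
#' known-value denominator (missing tabulated separately, excluded from
#' percentages), age dichotomized at 35 years and weight at 70 kg, plus
#' reporter occupation and country tabulations. Percentages are rounded
#' half-up to 2 decimals.
#'
#' @param cohort An `icsr_set`/`pv_cohort`, or a `data.frame` with columns
#'   `age`, `age_cod`, `wt`, `wt_cod`, `occp_cod`, `reporter_country`.
#' @param age_cut,weight_cut Dichotomization points (years, kg).
#' @return A list with `continuous` (variable, median, min, max, n_known,
#'   n_missing) and `categorical` (variable, level, n, pct) data.tables.
#' @export
summarize_demographics <- function(cohort, age_cut = 35, weight_cut = 70) {
  d <- if (inherits(cohort, "icsr_set")) cohort$demo else as.data.table(cohort)
  if (nrow(d) == 0) stop("cohort must be non-empty", call. = FALSE)
  ay <- age_years(d$age, d$age_cod)
  wk <- weight_kg(d$wt, d$wt_cod)

  cont <- rbindlist(list(
    data.table(variable = "age", median = stats::median(ay, na.rm = TRUE),
               min = suppressWarnings(min(ay, na.rm = TRUE)),
               max = suppressWarnings(max(ay, na.rm = TRUE)),
               n_known = sum(!is.na(ay)), n_missing = sum(is.na(ay))),
    data.table(variable = "weight", median = stats::median(wk, na.rm = TRUE),
               min = suppressWarnings(min(wk, na.rm = TRUE)),
               max = suppressWarnings(max(wk, na.rm = TRUE)),
               n_known = sum(!is.na(wk)), n_missing = sum(is.na(wk)))))
  cont[n_known == 0, c("median", "min", "max") := NA_real_]

  strat <- function(variable, values, labels) {
    n <- vapply(labels$pred, function(p) sum(p(values), na.rm = TRUE), 0L)
    known <- sum(n)
    pct <- if (known > 0) round_half_up(100 * n / known, 2) else rep(NA_real_, length(n))
    rbindlist(list(
      data.table(variable = variable, level = labels$label, n = as.integer(n), pct = pct),
      data.table(variable = variable, level = "missing",
                 n = sum(is.na(values)), pct = NA_real_)))
  }
  age_lab <- list(pred = list(function(x) x < age_cut, function(x) x >= age_cut),
                  label = paste0(c("<", ">="), age_cut, " years"))
  wt_lab <- list(pred = list(function(x) x < weight_cut, function(x) x >= weight_cut),
                 label = paste0(c("<", ">="), weight_cut, " kg"))

  tab_cat <- function(variable, v) {
    known <- v[!is.na(v)]
    tb <- sort(table(known), decreasing = TRUE)
    lev <- data.table(variable = character(), level = character(),
                      n = integer(), pct = numeric())
    if (length(tb))
      lev <- data.table(variable = variable, level = names(tb),
                        n = as.integer(tb),
                        pct = round_half_up(100 * as.integer(tb) / length(known), 2))
    rbindlist(list(
      lev,
      data.table(variable = variable, level = "missing",
                 n = sum(is.na(v)), pct = NA_real_)))
  }

  categorical <- rbindlist(list(
    strat("age", ay, age_lab),
    strat("weight", wk, wt_lab),
    tab_cat("occupation", d$occp_cod),
    tab_cat("country", d$reporter_country)))
  list(continuous = cont, categorical = categorical)
}

#' Aggregate country report counts into regions
#'
#' @param country_counts Named integer vector or two-column data.frame
#'   (`country`, `n`) of report counts per reporter country.
#' @param groups Named list mapping region name to country codes.
#' @return data.table with `region`, `n` and `pct` over the known-country
#'   total (countries supplied, including any "Others" bucket).
#' @export
aggregate_countries <- function(country_counts,
                                groups = list(
                                  us_canada = c("US", "CA"),
                                  western_europe = c("GB", "UK", "DE", "FR",
                                                     "IT", "NL", "SE", "ES", "DK"))) {
  if (is.data.frame(country_counts)) {
    cc <- stats::setNames(country_counts[[2]], country_counts[[1]])
  } else cc <- country_counts
  total <- sum(cc)
  rbindlist(lapply(names(groups), function(g) {
    n <- sum(cc[names(cc) %in% groups[[g]]])
    data.table(region = g, n = n, pct = round_half_up(100 * n / total, 2))
  }))
}
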