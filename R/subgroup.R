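# Stratified disproportionality by age and body weight.
#
# Each stratum is analyzed as a self-contained cohort: the comparator is the
# within-stratum non-case background, so the stratum 2x2 tables of one
# variable sum cell-wise to the pooled complete-data table.

#' Split a cohort at a cutpoint of age or weight
#'
#' Strict partition: values below the cutpoint vs greater-or-equal; records
#' with the variable missing are excluded and counted.
#'
#' @param cohort A `pv_cohort`.
#' @param variable `"age"` (years) or `"weight"` (kg); units normalized via
#'   [age_years()] / [weight_kg()].
#' @param cutpoint Dichotomization point (default 35 years / 70 kg).
#' @return List with `below`, `above` (both `pv_cohort`s), `n_missing`, and
#'   the stratum `labels`.
#' @export
stratify <- function(cohort, variable = c("age", "weight"), cutpoint = NULL) {
  stopifnot(inherits(cohort, "pv_cohort"))
  variable <- match.arg(variable)
  cutpoint <- cutpoint %||% switch(variable, age = 35, weight = 70)
  v <- switch(variable,
              age = age_years(cohort$demo$age, cohort$demo$age_cod),
              weight = weight_kg(cohort$demo$wt, cohort$demo$wt_cod))
  unit <- switch(variable, age = "y", weight = "kg")
  below <- subset_cohort(cohort, cohort$demo$primaryid[!is.na(v) & v < cutpoint])
  above <- subset_cohort(cohort, cohort$demo$primaryid[!is.na(v) & v >= cutpoint])
  list(below = below, above = above, n_missing = sum(is.na(v)),
       labels = c(sprintf("<%g %s", cutpoint, unit),
                  sprintf(">=%g %s", cutpoint, unit)))
}

#' Disproportionality of one drug within one stratum
#'
#' Identical arithmetic to [ror()] applied to the within-stratum 2x2 table
#' (cases vs non-cases restricted to the stratum).
#'
#' @param stratum A `pv_cohort` produced by [stratify()].
#' @param drug Drug name.
#' @param label Stratum label carried into the output.
#' @param min_a Minimum exposed-case count for reporting an estimate; below
#'   it the row carries `NA` statistics.
#' @return One-row data.table: drug, stratum, cells, ROR with interval,
#'   p-value, `n_reports`.
#' @export
stratum_signal <- function(stratum, drug, label = "", min_a = 3) {
  tab <- build_contingency(stratum, drug)
  r <- ror(tab)
  if (tab$a + tab$b == 0 || tab$a < min_a)
    r <- list(ror = NA_real_, ror_lo = NA_real_, ror_hi = NA_real_,
              chi2 = NA_real_, p_value = NA_real_)
  data.table(drug = normalize_drug(drug), stratum = label,
             a = tab$a, b = tab$b, c = tab$c, d = tab$d,
             ror = r$ror, ror_lo = r$ror_lo, ror_hi = r$ror_hi,
             p_value = r$p_value, n_reports = tab$a + tab$b)
}

#' Stratified analysis over a drug list
#'
#' @param cohort A `pv_cohort`.
#' @param variable,cutpoint See [stratify()].
#' @param drugs Drugs to analyze; default: every primary-suspect drug with at
#'   least `min_reports_subgroup` case reports overall (rarer drugs keep their
#'   overall signal only and are not sub-stratified).
#' @param min_reports_subgroup Report-count floor for subgroup inclusion.
#' @param min_a Per-stratum minimum exposed-case count.
#' @return List: `below`, `above` (stacked [stratum_signal()] rows),
#'   `comparison` (see [compare_strata()]), `n_missing`.
#' @export
subgroup_analysis <- function(cohort, variable = "age", cutpoint = NULL,
                              drugs = NULL, min_reports_subgroup = 100,
                              min_a = 3) {
  st <- stratify(cohort, variable, cutpoint)
  if (is.null(drugs)) {
    ps <- unique(cohort$drug[role_cod == "PS", .(primaryid, drugname_norm)])
    cases <- cohort$demo[is_case == TRUE, primaryid]
    cnt <- ps[primaryid %in% cases, .N, by = drugname_norm]
    drugs <- sort(cnt[N >= min_reports_subgroup, drugname_norm])
  }
  empty <- stratum_signal(st$below, "..none..")[0]
  below <- rbindlist(c(list(empty), lapply(drugs, function(d)
    stratum_signal(st$below, d, st$labels[1], min_a))))
  above <- rbindlist(c(list(empty), lapply(drugs, function(d)
    stratum_signal(st$above, d, st$labels[2], min_a))))
  list(below = below, above = above,
       comparison = compare_strata(below, above),
       n_missing = st$n_missing)
}

#' Compare stratum-level signals
#'
#' Per drug: the log2 ratio of the two stratum RORs, each stratum's
#' `-log10 p`, and a flag for drugs significant (interval above 1) in exactly
#' one stratum. Drugs undefined in either stratum are excluded from the ratio
#' table but remain in the per-stratum listings.
#'
#' @param below,above Tables from [stratum_signal()].
#' @return Tidy comparison data.table.
#' @export
compare_strata <- function(below, above) {
  m <- merge(below[, .(drug, ror_b = ror, lo_b = ror_lo, p_b = p_value)],
             above[, .(drug, ror_a = ror, lo_a = ror_lo, p_a = p_value)],
             by = "drug")
  m <- m[!is.na(ror_b) & !is.na(ror_a)]
  m[, `:=`(log2_ror_ratio = log2(ror_b / ror_a),
           neglog10_p_below = -log10(p_b),
           neglog10_p_above = -log10(p_a),
           sig_below = lo_b > 1, sig_above = lo_a > 1)]
  m[, sig_one_stratum := xor(sig_below, sig_above)]
  m[, .(drug, ror_below = ror_b, ror_above = ror_a, log2_ror_ratio,
        neglog10_p_below, neglog10_p_above, sig_below, sig_above,
        sig_one_stratum)]
}
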