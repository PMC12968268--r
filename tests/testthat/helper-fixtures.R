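# Shared fixtures and independent oracles used across test files.

library(data.table)

# A small two-drug synthetic study: one planted signal, one null drug.
small_config <- function(n = 20000, rr = 5, seed = 1,
                         duplicate_rate = 0.1) {
  synthetic_config(
    n_reports = n,
    drugs = data.frame(
      name = c("DRUG X", "DRUG Y"),
      use_prob = c(0.05, 0.05),
      injected_rr = c(rr, 1),
      tto_shape = c(0.8, 1.2),
      tto_scale = c(400, 300)),
    event_base_rate = 0.02,
    duplicate_rate = duplicate_rate,
    seed = seed)
}

make_cohort <- function(...) {
  g <- generate_cohort(small_config(...))
  filter_cohort(deduplicate(g$cohort))
}

# Hand-built icsr_set: the minimal constructor tests need full control of
# every field.
hand_icsr <- function(demo_rows, drug_rows = NULL, reac_rows = NULL) {
  demo_defaults <- data.table(
    primaryid = NA_character_, caseid = NA_character_, caseversion = 1L,
    fda_dt = as.IDate("2020-01-01"), event_dt = "20200101",
    age = 30, age_cod = "YR", wt = 60, wt_cod = "KG", sex = "F",
    occp_cod = "MD", reporter_country = "US")
  demo <- rbindlist(lapply(demo_rows, function(r) {
    row <- copy(demo_defaults)
    for (nm in names(r)) data.table::set(row, j = nm, value = r[[nm]])
    row
  }))
  drug <- if (is.null(drug_rows)) {
    data.table(primaryid = demo$primaryid, caseid = demo$caseid,
               drug_seq = 1L, role_cod = "PS", drugname = "DRUG X",
               start_dt = "20190101")
  } else rbindlist(drug_rows, fill = TRUE)
  reac <- if (is.null(reac_rows)) {
    data.table(primaryid = demo$primaryid, caseid = demo$caseid,
               pt = "ABORTION SPONTANEOUS")
  } else rbindlist(reac_rows, fill = TRUE)
  pvsignal:::new_icsr_set(demo, drug, reac)
}

# Independent step-up BH implementation: direct double-loop evaluation of
# q_(i) = min_{j >= i} m p_(j) / j (capped at 1), used as the oracle for
# bh_fdr().
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) m * ps[j] / j, 0)
    q[o[i]] <- min(1, min(cands))
  }
  q
}
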