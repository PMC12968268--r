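test_that("contingency construction counts cells exactly", {
  # 4-record toy cohort: 2 exposed cases, 1 exposed non-case, 1 unexposed non-case
  s <- hand_icsr(
    list(list(primaryid = "1-1", caseid = "1"),
         list(primaryid = "2-1", caseid = "2"),
         list(primaryid = "3-1", caseid = "3"),
         list(primaryid = "4-1", caseid = "4")),
    list(data.table(primaryid = c("1-1", "2-1", "3-1", "4-1"),
                    caseid = c("1", "2", "3", "4"), drug_seq = 1L,
                    role_cod = "PS",
                    drugname = c("DRUG X", "DRUG X", "DRUG X", "OTHER"),
                    start_dt = "")),
    list(data.table(primaryid = c("1-1", "2-1", "3-1", "4-1"),
                    caseid = c("1", "2", "3", "4"),
                    pt = c("ABORTION", "ABORTION SPONTANEOUS", "HEADACHE",
                           "NAUSEA"))))
  co <- filter_cohort(s)
  tab <- build_contingency(co, "drug x")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2, 1, 0, 1))
  expect_equal(tab$N, 4)
})

test_that("contingency cells match a brute-force scan on a synthetic cohort", {
  co <- make_cohort(n = 5000, seed = 6)
  tab <- build_contingency(co, "DRUG X")
  # independent scan over raw tables
  exp_ids <- unique(co$drug[role_cod == "PS" &
                              normalize_drug(drugname) == "DRUG X", primaryid])
  a <- 0L; b <- 0L; cc <- 0L; d <- 0L
  for (i in seq_len(nrow(co$demo))) {
    e <- co$demo$primaryid[i] %in% exp_ids
    k <- co$demo$is_case[i]
    if (e && k) a <- a + 1L else if (e) b <- b + 1L
    else if (k) cc <- cc + 1L else d <- d + 1L
  }
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(a, b, cc, d))
})

test_that("ROR, PRR and chi-square match hand values on printed tables", {
  t1 <- contingency_table(10, 90, 100, 9900)
  expect_equal(ror(t1)$ror, 11.0)
  expect_equal(prr(t1)$prr, 10.0)
  t2 <- contingency_table(10, 10, 10, 10)
  r2 <- ror(t2)
  expect_equal(r2$ror, 1)
  expect_equal(r2$ror_lo, exp(-qnorm(0.975) * sqrt(0.4)), tolerance = 1e-10)
  expect_equal(r2$ror_hi, exp(+qnorm(0.975) * sqrt(0.4)), tolerance = 1e-10)
  # independence: PRR 1, chi2 0
  t3 <- contingency_table(5, 45, 50, 450)
  expect_equal(prr(t3)$prr, 1)
  expect_equal(prr(t3)$chi2, 0)
})

test_that("zero cells trigger the Haldane-Anscombe policy, chi2 stays raw", {
  t0 <- contingency_table(0, 5, 3, 1000)
  r <- ror(t0)
  expect_true(is.finite(r$ror))
  expect_equal(r$ror, (0.5 * 1000.5) / (5.5 * 3.5))
  # a zero a-cell with a sparse event margin keeps the estimate below 1
  t1 <- contingency_table(0, 1000, 5, 3000)
  expect_lt(ror(t1)$ror, 1)
  # chi-square computed on the raw cells, matching the base-R oracle
  expect_equal(r$chi2,
               unname(suppressWarnings(
                 chisq.test(matrix(c(0, 5, 3, 1000), 2, byrow = TRUE),
                            correct = FALSE))$statistic))
})

test_that("formulas match independent oracles on an exhaustive small-table grid", {
  grid <- as.data.table(expand.grid(a = c(1, 3, 7, 12), b = c(1, 4, 12),
                                    c = c(1, 5, 12), d = c(1, 6, 12)))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i]
    tab <- contingency_table(g$a, g$b, g$c, g$d)
    m <- matrix(c(g$a, g$b, g$c, g$d), 2, byrow = TRUE)
    expect_equal(ror(tab)$chi2,
                 unname(suppressWarnings(
                   chisq.test(m, correct = FALSE))$statistic),
                 tolerance = 1e-12)
    expect_equal(ror(tab)$ror, (g$a * g$d) / (g$b * g$c), tolerance = 1e-12)
    expect_equal(prr(tab)$prr,
                 (g$a / (g$a + g$b)) / (g$c / (g$c + g$d)), tolerance = 1e-12)
    expect_equal(bcpnn_ic(tab)$ic,
                 log2((g$a + 0.5) / (tab$E + 0.5)), tolerance = 1e-12)
  }
})

test_that("ROR equals the odds ratio of the expanded unit-record data", {
  # expansion oracle: rebuild the table from unit records and fit the
  # saturated logistic model; exp(coef) is the MLE odds ratio
  for (cells in list(c(2, 3, 4, 5), c(7, 2, 9, 12), c(1, 1, 12, 8))) {
    exposure <- rep(c(1, 1, 0, 0), cells)
    outcome <- rep(c(1, 0, 1, 0), cells)
    fit <- glm(outcome ~ exposure, family = binomial())
    tab <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    expect_equal(ror(tab)$ror, unname(exp(coef(fit)["exposure"])),
                 tolerance = 1e-6)
  }
})

test_that("information component matches hand evaluation", {
  tab <- contingency_table(10, 0, 0, 90)   # E = 10*10/100 = 1
  expect_equal(tab$E, 1)
  ic <- bcpnn_ic(tab)
  expect_equal(ic$ic, log2(10.5 / 1.5), tolerance = 1e-10)
  expect_equal(ic$ic025, log2(10.5 / 1.5) - 3.3 / sqrt(10.5) - 2 / 10.5^1.5,
               tolerance = 1e-10)
  expect_equal(ic$ic, 2.8074, tolerance = 1e-4)
  expect_equal(ic$ic025, 1.7302, tolerance = 1e-4)
  # a = E gives IC = 0; a = 0 gives negative IC
  t2 <- contingency_table(8, 8, 8, 8)
  expect_equal(bcpnn_ic(t2)$ic, 0)
  t3 <- contingency_table(0, 10, 20, 70)   # E = 10*20/100 = 2
  expect_lt(bcpnn_ic(t3)$ic, 0)
})

test_that("EBGM posterior summaries match gamma closed forms", {
  pr <- gps_prior(1, 1, 2, 4, 1)
  res <- pvsignal:::ebgm_vec(5, 1, pr)   # posterior Ga(6, 2)
  expect_equal(res$ebgm, exp(digamma(6) - log(2)), tolerance = 1e-8)
  expect_equal(res$eb05, qgamma(0.05, 6) / 2, tolerance = 1e-6)
  # NB marginal at a=0 with alpha=beta=1, E=1 is (beta/(beta+E))^alpha = 0.5
  expect_equal(dnbinom(0, size = 1, prob = 0.5), 0.5)
  expect_equal(exp(pvsignal:::gps_marginal_ll(
    c(log(1), log(1), log(1), log(1), qlogis(0.999999)), 0, 1)),
    0.5, tolerance = 1e-5)
  # shrinkage vanishes for large counts: ebgm -> a/E
  big <- pvsignal:::ebgm_vec(1000, 100, default_gps_prior())
  expect_equal(big$ebgm, 10, tolerance = 0.05 * 10)
})

test_that("eb05 < ebgm, ic025 < ic, and ebgm is monotone in a", {
  pr <- default_gps_prior()
  prev <- 0
  for (a in c(0, 1, 2, 5, 10, 50, 200)) {
    res <- pvsignal:::ebgm_vec(a, 7.5, pr)
    expect_lt(res$eb05, res$ebgm)
    expect_gte(res$ebgm, prev)
    prev <- res$ebgm
    tab <- contingency_table(a, 10, 15, 100)
    ic <- bcpnn_ic(tab)
    expect_lt(ic$ic025, ic$ic)
  }
})

test_that("MGPS prior fit recovers a single-component truth", {
  # simulate from Ga(2, 2): lambda_i ~ Ga(2, rate 2), a_i ~ Pois(lambda E)
  set.seed(99)
  n <- 5000
  E <- runif(n, 1, 100)
  lam <- rgamma(n, 2, rate = 2)
  a <- rpois(n, lam * E)
  fit <- fit_gps_prior(data.frame(a = a, E = E))
  # identify the dominant component
  if (fit$P >= 0.5) {
    alpha <- fit$alpha1; beta <- fit$beta1; w <- fit$P
  } else {
    alpha <- fit$alpha2; beta <- fit$beta2; w <- 1 - fit$P
  }
  expect_gt(w, 0.9)
  expect_lt(abs(alpha - 2) / 2, 0.2)
  expect_lt(abs(beta - 2) / 2, 0.2)
  # coarse grid-search oracle on a single gamma component agrees
  grid <- expand.grid(alpha = seq(1, 3, 0.25), beta = seq(1, 3, 0.25))
  ll <- mapply(function(al, be)
    sum(dnbinom(a, size = al, prob = be / (be + E), log = TRUE)),
    grid$alpha, grid$beta)
  best <- grid[which.max(ll), ]
  expect_lt(abs(alpha - best$alpha), 0.5)
  expect_lt(abs(beta - best$beta), 0.5)
})

test_that("too few tables fall back to the default prior with a warning", {
  expect_warning(pr <- fit_gps_prior(data.frame(a = 1:5, E = rep(1, 5))),
                 "default prior")
  expect_equal(pr$alpha1, 0.2)
  expect_warning(fit_gps_prior(data.frame(a = integer(), E = numeric())),
                 "default prior")
})

test_that("threshold flags and the ROR-anchored consensus follow the rule", {
  th <- default_thresholds()
  # ROR + BCPNN flags -> consensus
  s1 <- list(a = 10, ror_lo = 1.5, prr = 1.5, chi2 = 2, ic025 = 0.5, eb05 = 1)
  f1 <- apply_thresholds(s1, th)
  expect_true(f1$ror); expect_true(f1$bcpnn); expect_true(f1$consensus)
  # PRR + MGPS without ROR -> no consensus
  s2 <- list(a = 10, ror_lo = 0.9, prr = 3, chi2 = 10, ic025 = -0.1, eb05 = 3)
  f2 <- apply_thresholds(s2, th)
  expect_true(f2$prr); expect_true(f2$mgps)
  expect_false(f2$ror); expect_false(f2$consensus)
  # minimum-count gate: a = 2 with huge ROR is not flagged
  s3 <- list(a = 2, ror_lo = 50, prr = 100, chi2 = 100, ic025 = 2, eb05 = 10)
  expect_false(apply_thresholds(s3, th)$ror)
  # undefined statistics count as not flagged
  s4 <- list(a = 10, ror_lo = NA_real_, prr = NA_real_, chi2 = NA_real_,
             ic025 = NA_real_, eb05 = NA_real_)
  f4 <- apply_thresholds(s4, th)
  expect_false(any(unlist(f4)))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(42)
  for (k in 1:20) {
    p <- round(runif(sample(2:8, 1)), 3)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("large balanced tables put all four statistics near the true RR", {
  # cells >= 1000 drawn with true reporting rate ratio r
  # exposure must be a small fraction of the background so the expected
  # count E tracks the unexposed rate and 2^IC / EBGM estimate the same RR
  set.seed(7)
  for (r in c(1.5, 2.5)) {
    n_exp <- 40000; n_un <- 800000; p0 <- 0.02
    a <- rbinom(1, n_exp, min(1, p0 * r)); b <- n_exp - a
    cc <- rbinom(1, n_un, p0); d <- n_un - cc
    tab <- contingency_table(a, b, cc, d)
    expect_true(all(c(a, b, cc, d) >= 1000))
    expect_equal(prr(tab)$prr, r, tolerance = 0.1)
    expect_equal(2^bcpnn_ic(tab)$ic, r, tolerance = 0.1)
    eb <- ebgm(tab, default_gps_prior())
    expect_equal(eb$ebgm, r, tolerance = 0.1)
    # odds ratio slightly exceeds the risk ratio at p0 = 5%
    expect_equal(ror(tab)$ror, r, tolerance = 0.15)
  }
})

test_that("signal_scan flags the planted drug and only it", {
  co <- make_cohort(n = 50000, rr = 5, seed = 12)
  sc <- suppressWarnings(signal_scan(co, min_count = 1))
  expect_true(sc[drug == "DRUG X", consensus])
  expect_false(any(sc[drug != "DRUG X", consensus]))
  expect_lt(sc[drug == "DRUG X", q_value], 0.05)
  # excluded drugs never yield a table
  expect_false(any(sc$drug %in% progestogen_exclusions()))
})
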