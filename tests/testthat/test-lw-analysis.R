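test_that("maximum lookback is the gap to the first data year", {
  expect_identical(max_lookback(2001, 1996), 5L)
  expect_identical(max_lookback(2010, 1996), 14L)
  expect_identical(max_lookback(2012, 1996), 16L)
  expect_identical(max_lookback(1996, 1996), 0L)
  expect_error(max_lookback(1995, 1996), "precedes")
})

test_that("lookback intervals are half-open and empty at k = 0", {
  iv0 <- lookback_interval(window_spec(2012, 0))
  expect_true(iv0$empty)
  expect_equal(iv0$start, iv0$end)

  iv16 <- lookback_interval(window_spec(2012, 16))
  expect_equal(iv16$start, as.Date("1996-01-01"))
  expect_equal(iv16$end, as.Date("2012-01-01"))

  iv1 <- lookback_interval(window_spec(2012, 1))
  expect_equal(iv1$start, as.Date("2011-01-01"))
  expect_false(iv1$empty)

  expect_error(window_spec(2012, 17), "lookback_years")
})

test_that("window membership drives prevalent/at-risk/incident status", {
  def <- fx_single_claim_def()

  # old claim: invisible to a 2-year LW, prevalent (not incident) at 4
  old <- fx_claims("a", "2009-05-01")
  k2 <- classify(old, def, window_spec(2012, 2), "a")
  expect_false(k2$is_prevalent)
  expect_false(k2$is_incident)
  k4 <- classify(old, def, window_spec(2012, 4), "a")
  expect_true(k4$is_prevalent)
  expect_false(k4$is_at_risk)
  expect_false(k4$is_incident)

  # a new diagnosis inside the estimation year is prevalent AND incident
  # regardless of the lookback length
  new <- fx_claims("a", "2012-06-15")
  for (k in c(0, 1, 8, 16)) {
    ck <- classify(new, def, window_spec(2012, k), "a")
    expect_true(ck$is_prevalent)
    expect_true(ck$is_incident)
    expect_equal(ck$identification_date, as.Date("2012-06-15"))
  }
})

test_that("multi-claim rules may complete across the LW boundary", {
  def <- case_definition("toy", clause("physician", "401", min_count = 2,
                                       within_days = 730))
  pair <- fx_claims(c("a", "a"), c("2011-09-01", "2012-03-01"))

  ck <- classify(pair, def, window_spec(2012, 2), "a")
  expect_true(ck$is_at_risk)    # single LW claim: no prior prevalent case
  expect_true(ck$is_incident)   # rule completes 2012-03-01, in-year
  expect_equal(ck$identification_date, as.Date("2012-03-01"))
  expect_equal(as.data.frame(ck),
               as.data.frame(oracle_classify(pair, def, 2012, 2, "a")))

  k0 <- classify(pair, def, window_spec(2012, 0), "a")
  expect_false(k0$is_prevalent)  # only one in-window claim at k = 0
  expect_false(k0$is_incident)
})

test_that("estimates match a hand-enumerated ten-person cohort", {
  # persons a-j; single-claim rule
  #   a,b: claims well before 2012 (prior prevalent at k >= 4)
  #   c:   claim in 2012 only (incident)
  #   d:   claims in LW and 2012 (prevalent, not incident)
  #   e-j: no qualifying claims
  ids <- letters[1:10]
  cohort <- fx_persons(ids, population = rep(c("index", "control"), 5))
  claims <- dplyr::bind_rows(
    fx_claims(c("a", "b"), c("2008-03-01", "2009-07-01")),
    fx_claims("c", "2012-05-20"),
    fx_claims(c("d", "d"), c("2010-01-10", "2012-02-02")))
  def <- fx_single_claim_def()

  cls <- classify(claims, def, window_spec(2012, 4), cohort)
  est <- compute_estimates(cls, cohort)

  # brute-force per-person tally by population
  orc <- oracle_classify(claims, def, 2012, 4, ids)
  for (pop in c("index", "control")) {
    sub <- orc[orc$person_id %in% cohort$person_id[cohort$population == pop], ]
    row <- est[est$population == pop, ]
    expect_equal(row$n_denominator, nrow(sub))
    expect_equal(row$n_prevalent, sum(sub$is_prevalent))
    expect_equal(row$n_at_risk, sum(sub$is_at_risk))
    expect_equal(row$n_incident, sum(sub$is_incident))
  }
  # spot values: index = {a,c,e,g,i}: a prior-prevalent; c incident
  idx <- est[est$population == "index", ]
  expect_equal(idx$n_prevalent, 2)            # a and c
  expect_equal(idx$n_at_risk, 4)              # all but a
  expect_equal(idx$n_incident, 1)             # c
  expect_equal(idx$prevalence_pct, 40)
  expect_equal(idx$incidence_pct, 25)
})

test_that("zero at-risk denominators flag incidence as undefined", {
  ids <- c("a", "b")
  cohort <- fx_persons(ids, population = "index")
  claims <- fx_claims(ids, c("2005-01-01", "2006-01-01"))
  cls <- classify(claims, fx_single_claim_def(), window_spec(2012, 16),
                  cohort)
  est <- compute_estimates(cls, cohort)
  expect_equal(est$n_at_risk, 0)
  expect_true(is.na(est$incidence_pct))
  expect_equal(est$flag, "incidence_undefined_zero_at_risk")

  # no cases anywhere: defined zeros, no flag
  empty_cls <- classify(fx_claims("z", "2000-01-01"),
                        fx_single_claim_def(), window_spec(2012, 16),
                        cohort)
  est0 <- compute_estimates(empty_cls, cohort)
  expect_equal(est0$prevalence_pct, 0)
  expect_equal(est0$incidence_pct, 0)
  expect_true(is.na(est0$flag))
})

test_that("misclassification proportions are set-based", {
  mk <- function(ids, prev, at_risk, inc, k) {
    tibble::tibble(person_id = ids, disease = "toy",
                   estimation_year = 2012L, k = as.integer(k),
                   is_prevalent = prev, is_at_risk = at_risk,
                   is_incident = inc,
                   identification_date = as.Date(NA))
  }
  ids <- letters[1:6]
  ref <- mk(ids, prev = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
            at_risk = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
            inc = rep(FALSE, 6), k = 16)
  short <- mk(ids, prev = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
              at_risk = rep(TRUE, 6),
              inc = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE), k = 2)

  # Prev_ref = {a,b,c,d}, Prev_k = {a,b} -> 0.5
  expect_equal(misclassified_prevalent(short, ref)$proportion, 0.5)
  # Inc_k = {a,c}; only a is prior-prevalent under ref -> 1/2
  expect_equal(misclassified_incident(short, ref)$proportion, 0.5)
  # k = ref: both zero
  expect_equal(misclassified_prevalent(ref, ref)$proportion, 0)

  # undefined cases carry flags, not zeros
  none <- mk(ids, prev = rep(FALSE, 6), at_risk = rep(TRUE, 6),
             inc = rep(FALSE, 6), k = 16)
  mp <- misclassified_prevalent(none, none)
  expect_true(is.na(mp$proportion))
  expect_equal(mp$flag, "undefined_zero_reference_prevalent")
  mi <- misclassified_incident(none, none)
  expect_true(is.na(mi$proportion))
  expect_equal(mi$flag, "undefined_zero_incident")
})

test_that("misclassification equals an independent re-scan on random data", {
  withr::local_seed(31)
  for (i in 1:10) {
    inst <- fx_random_instance(n_persons = 50, max_claims = 8)
    def <- fx_random_definition()
    k <- sample(0:8, 1)
    cls_k <- classify(inst$claims, def, window_spec(2012, k), inst$ids)
    cls_ref <- classify(inst$claims, def, window_spec(2012, 16), inst$ids)
    orc_k <- oracle_classify(inst$claims, def, 2012, k, inst$ids)
    orc_ref <- oracle_classify(inst$claims, def, 2012, 16, inst$ids)
    mp <- misclassified_prevalent(cls_k, cls_ref)$proportion
    mi <- misclassified_incident(cls_k, cls_ref)$proportion
    expect_equal(mp, oracle_misclassified_prevalent(orc_k, orc_ref))
    expect_equal(mi, oracle_misclassified_incident(orc_k, orc_ref))
  }
})

test_that("sweeps validate inputs and are reference-free in the estimates", {
  ids <- letters[1:8]
  cohort <- fx_persons(ids, population = rep(c("index", "control"), 4))
  claims <- fx_claims(ids[1:4],
                      c("2000-05-01", "2007-02-01", "2011-11-30",
                        "2012-06-01"))
  def <- fx_single_claim_def()

  expect_error(sweep_lookbacks(claims, cohort, def, 2012, ref_k = 16,
                               k_list = c(0, 17)), "maximum")
  expect_error(sweep_lookbacks(claims, cohort, def, 2012, ref_k = 12,
                               k_list = c(0, 16)), "ref_k")

  # singleton sweep: one row per population, zero misclassification
  single <- sweep_lookbacks(claims, cohort, def, 2012, ref_k = 16,
                            k_list = 16)
  expect_equal(nrow(single$misclassification), 2)
  expect_equal(single$misclassification$prop_misclassified_prevalent,
               c(0, 0))

  res16 <- sweep_lookbacks(claims, cohort, def, 2012, ref_k = 16,
                           k_list = c(0, 5, 10, 16))
  res10 <- sweep_lookbacks(claims, cohort, def, 2012, ref_k = 10,
                           k_list = c(0, 5, 10, 16))
  expect_equal(res16$estimates, res10$estimates)
  # reference rows always show zero misclassification
  refrows <- res10$misclassification[res10$misclassification$k == 10, ]
  expect_true(all(refrows$prop_misclassified_prevalent == 0))
})

test_that("age restrictions shape per-disease analysis populations", {
  cohort <- fx_persons(c("young", "old"), birth_year = c(1990, 1950))
  claims <- fx_claims(c("young", "old"), c("2012-03-01", "2012-03-01"),
                      code = "4019")
  def <- case_definition("htn", clause("physician", "401"),
                         min_age_years = 20)
  res <- sweep_lookbacks(claims, cohort, def, 2012, ref_k = 2,
                         k_list = 0:2)
  # strict bound: the 22-year-old passes, an exactly-20-year-old would not
  expect_equal(unique(res$estimates$n_denominator), 2L)
  strict <- sweep_lookbacks(
    claims, fx_persons(c("young", "old"), birth_year = c(1992, 1950)),
    def, 2012, ref_k = 2, k_list = 0:2)
  expect_equal(unique(strict$estimates$n_denominator), 1L)
})

test_that("annual trends cap lookbacks at the feasible maximum per year", {
  ids <- sprintf("T%02d", 1:20)
  cohort <- fx_persons(ids, population = rep(c("index", "control"), 10))
  withr::local_seed(17)
  claims <- fx_claims(sample(ids, 40, replace = TRUE),
                      as.Date("1996-01-01") + sample.int(6209, 40))
  def <- fx_single_claim_def()

  expect_warning(
    tr01 <- annual_trends(claims, cohort, def, years = 2001,
                          k_list = 0:16),
    "skipping")
  expect_equal(sort(unique(tr01$k)), 0:5)

  tr12 <- annual_trends(claims, cohort, def, years = 2012, k_list = 0:16)
  expect_equal(nrow(tr12), 17 * 2)  # 17 windows x 2 populations

  expect_error(annual_trends(claims, cohort, def, years = integer(0)),
               "non-empty")
})

test_that("presence is re-evaluated per trend year", {
  cohort <- dplyr::bind_rows(
    fx_persons("stay"),
    fx_persons("leaver", end = as.Date("2005-06-30")))
  claims <- fx_claims(c("stay", "leaver"), c("2000-01-01", "2000-01-01"))
  tr <- annual_trends(claims, cohort, fx_single_claim_def(),
                      years = c(2004, 2006), k_list = 0)
  expect_equal(tr$n_denominator[tr$estimation_year == 2004], 2)
  expect_equal(tr$n_denominator[tr$estimation_year == 2006], 1)
})
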