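# builds a neonatal cohort + assignments with prescribed cause/onset/
# maternal structure so the association machinery can be checked against
# exact counts
onsetFixture <- function(design) {
  # design: data.frame(cause, onset_day, maternal, count)
  rows <- design[rep(seq_len(nrow(design)), design$count), ]
  n <- nrow(rows)
  df <- data.frame(death_id = sprintf("d%04d", 1:n), age_group = "neonate",
                   age_at_death = 5, sex = "f", region = "r",
                   cluster_id = "c", survey_weight = 1,
                   illness_onset_day = rows$onset_day,
                   stringsAsFactors = FALSE)
  cohort <- asVACohort(df)
  assign <- data.frame(death_id = df$death_id, reporting = rows$cause,
                       stringsAsFactors = FALSE)
  maternal <- stats::setNames(rows$maternal, df$death_id)
  list(cohort = cohort, assignments = assign, maternal = maternal)
}

test_that("the severe-infection contrast reproduces a direct 2x2 computation", {
  # severe infection: 95 early (28 maternal), 146 late (17 maternal);
  # the rest of the cohort: 212 other deaths, 48 with maternal infection
  design <- rbind(
    data.frame(cause = "sepsis", onset_day = 0, maternal = TRUE, count = 28),
    data.frame(cause = "sepsis", onset_day = 0, maternal = FALSE, count = 67),
    data.frame(cause = "sepsis", onset_day = 5, maternal = TRUE, count = 17),
    data.frame(cause = "sepsis", onset_day = 5, maternal = FALSE, count = 129),
    data.frame(cause = "other", onset_day = 3, maternal = TRUE, count = 48),
    data.frame(cause = "other", onset_day = 3, maternal = FALSE, count = 164))
  fx <- onsetFixture(design)
  oa <- onsetAssociation(fx$cohort, fx$assignments, fx$maternal)
  row <- oa[oa$group == "severe_infection_combined", ]
  expect_equal(row$n_early, 95)
  expect_equal(row$maternal_early, 28)
  expect_equal(row$n_late, 146)
  expect_equal(row$maternal_late, 17)
  oracle <- twoPropChi2(28, 95, 17, 146)$statistic
  expect_equal(row$chi2, oracle)
  expect_equal(round(row$chi2, 1), 12.0)
  expect_lt(row$p, 0.001)
  # early + late + not-applicable reconcile to the cohort size per group
  all_row <- oa[oa$group == "severe_early_vs_all_other", ]
  expect_equal(all_row$n_early + all_row$n_late, nrow(fx$cohort))
})

test_that("perfect separation drives the association p-value toward zero", {
  design <- rbind(
    data.frame(cause = "sepsis", onset_day = 0, maternal = TRUE, count = 40),
    data.frame(cause = "sepsis", onset_day = 5, maternal = FALSE, count = 60))
  fx <- onsetFixture(design)
  oa <- onsetAssociation(fx$cohort, fx$assignments, fx$maternal)
  row <- oa[oa$group == "sepsis", ]
  expect_lt(row$p, 1e-10)
  expect_equal(row$pct_maternal_early, 100)
  expect_equal(row$pct_maternal_late, 0)
})

test_that("empty strata are flagged, not fatal", {
  design <- data.frame(cause = "meningitis", onset_day = 0, maternal = FALSE,
                     count = 10)
  fx <- onsetFixture(design)
  oa <- onsetAssociation(fx$cohort, fx$assignments, fx$maternal)
  expect_true(oa$empty_stratum[oa$group == "meningitis"])
  expect_true(is.na(oa$chi2[oa$group == "meningitis"]))
})

regionalFixture <- function(deaths_per_region, meningitis_per_region) {
  regions <- names(deaths_per_region)
  rows <- rep(regions, deaths_per_region)
  n <- length(rows)
  men <- unlist(mapply(function(rg, k)
    rep(c(TRUE, FALSE), c(k, deaths_per_region[[rg]] - k)),
    regions, meningitis_per_region, SIMPLIFY = FALSE))
  df <- data.frame(death_id = sprintf("d%04d", 1:n), age_group = "child",
                   age_at_death = 12, sex = "m", region = rows,
                   cluster_id = "c", survey_weight = 1,
                   stringsAsFactors = FALSE)
  assign <- data.frame(death_id = df$death_id,
                       reporting = ifelse(men, "meningitis", "malaria"),
                       stringsAsFactors = FALSE)
  list(cohort = asVACohort(df), assignments = assign)
}

surveillanceFixture <- function(cases) {
  asSurveillance(data.frame(region = names(cases), year = 2008,
                            cases_notified = unname(cases),
                            deaths = round(unname(cases) * 0.1),
                            stringsAsFactors = FALSE))
}

test_that("regional proportional mortality and surveillance shares are exact", {
  fx <- regionalFixture(c(agadez = 8, zinder = 100),
                        c(agadez = 2, zinder = 10))
  sv <- surveillanceFixture(c(agadez = 300, zinder = 700))
  rm <- regionalMeningitis(fx$cohort, fx$assignments, sv)
  expect_equal(rm$proportional_mortality[rm$region == "agadez"], 25)
  expect_equal(rm$proportional_mortality[rm$region == "zinder"], 10)
  expect_equal(rm$surveillance_case_share[rm$region == "agadez"], 30)
  expect_equal(sum(rm$surveillance_case_share), 100, tolerance = 1e-9)
  expect_true(rm$small_denominator[rm$region == "agadez"])
  expect_false(rm$small_denominator[rm$region == "zinder"])
})

test_that("a region with zero meningitis deaths reports 0%", {
  fx <- regionalFixture(c(dosso = 50, maradi = 50), c(dosso = 0, maradi = 5))
  sv <- surveillanceFixture(c(dosso = 400, maradi = 600))
  rm <- regionalMeningitis(fx$cohort, fx$assignments, sv)
  expect_equal(rm$proportional_mortality[rm$region == "dosso"], 0)
})

test_that("a flat meningitis profile is recovered as flat", {
  fx <- regionalFixture(c(a = 100, b = 200, c = 50),
                        c(a = 10, b = 20, c = 5))
  sv <- surveillanceFixture(c(a = 100, b = 500, c = 400))
  rm <- regionalMeningitis(fx$cohort, fx$assignments, sv)
  expect_true(all(abs(rm$proportional_mortality - 10) < 1e-9))
})

test_that("a VA region absent from surveillance is flagged, not dropped", {
  fx <- regionalFixture(c(a = 50, b = 50), c(a = 5, b = 5))
  sv <- surveillanceFixture(c(a = 1000))
  rm <- regionalMeningitis(fx$cohort, fx$assignments, sv)
  expect_true(rm$missing_surveillance[rm$region == "b"])
  expect_false(rm$missing_surveillance[rm$region == "a"])
})

test_that("surveillance invariants are enforced", {
  expect_error(asSurveillance(data.frame(region = "a", year = 2008,
                                         cases_notified = 10,
                                         csf_samples_received = 12)),
               "exceeds cases_notified")
  expect_error(asSurveillance(data.frame(region = "a", year = 2008,
                                         cases_notified = -1)),
               "non-negative")
})
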