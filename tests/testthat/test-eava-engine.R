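test_that("neonatal meningitis needs a focal sign plus lethargy/unconsciousness", {
  rs <- defaultRuleset("neonate")
  rec <- neonatalRecord(yes = c("bulging_fontanelle", "lethargy"))
  expect_true(evaluateRule(rs$causes$meningitis, rec, rs))
  # fontanelle alone is not enough for the algorithm
  rec2 <- neonatalRecord(yes = "bulging_fontanelle")
  expect_false(evaluateRule(rs$causes$meningitis, rec2, rs))
})

test_that("no rule fires on an all-missing record", {
  rec <- neonatalRecord()
  rs <- defaultRuleset("neonate")
  for (cz in rs$causes)
    expect_false(evaluateRule(cz, rec, rs), label = cz$id)
  reck <- childRecord()
  rsk <- defaultRuleset("child")
  for (cz in rsk$causes)
    expect_false(evaluateRule(cz, reck, rsk), label = cz$id)
})

test_that("vectorised evaluation matches the brute-force evaluator on random records", {
  set.seed(7)
  rsk <- defaultRuleset("child")
  vocab <- defaultVocabulary()
  n <- 200
  df <- data.frame(death_id = sprintf("r%03d", 1:n), age_group = "child",
                   age_at_death = sample(1:59, n, TRUE), sex = "f",
                   region = "r", cluster_id = "c", survey_weight = 1,
                   stringsAsFactors = FALSE)
  for (s in vocab$child) {
    df[[paste0("sign.", s)]] <- sample(c("yes", "no", NA), n, TRUE,
                                       prob = c(.4, .4, .2))
    d <- sample(c(NA, 1, 2, 5, 15, 30), n, TRUE)
    d[is.na(df[[paste0("sign.", s)]]) | df[[paste0("sign.", s)]] != "yes"] <- NA
    df[[paste0("dur.", s)]] <- d
  }
  cohort <- asVACohort(df, vocab)
  for (cz in rsk$causes) {
    fast <- evalResult <- sapply(seq_len(n), function(i)
      evaluateRule(cz, cohort[i, , drop = FALSE], rsk))
    slow <- sapply(seq_len(n), function(i)
      oracleEval(cz$rule, as.data.frame(cohort)[i, , drop = FALSE], rsk))
    expect_identical(unname(fast), unname(slow), label = cz$id)
  }
})

test_that("co-morbidity example: meningitis over sepsis, sepsis reported co-morbid", {
  rec <- neonatalRecord(yes = c("bulging_fontanelle", "lethargy", "fever",
                                "stopped_suckling"))
  a <- classify(rec)
  expect_equal(a$primary, "meningitis")
  expect_true("sepsis" %in% a$comorbid[[1]])
})

test_that("empty eligible set leaves the death unspecified", {
  a <- classify(neonatalRecord())
  expect_equal(a$primary, "unspecified")
  expect_length(a$comorbid[[1]], 0)
  expect_length(a$combined[[1]], 0)
})

test_that("preterm delivery is selected only when it is the sole condition", {
  rec <- neonatalRecord(pregnancy_duration = 7)
  expect_equal(classify(rec)$primary, "preterm_delivery")
  # with sepsis signs as well, preterm drops to co-morbid
  rec2 <- neonatalRecord(yes = c("fever", "lethargy"), pregnancy_duration = 7)
  a2 <- classify(rec2)
  expect_equal(a2$primary, "sepsis")
  expect_true("preterm_delivery" %in% a2$comorbid[[1]])
})

test_that("primary selection equals brute-force minimum-rank over random eligible sets", {
  h <- defaultHierarchy("child")
  set.seed(11)
  for (i in 1:1000) {
    el <- sample(h$causes, sample(0:6, 1))
    brute <- if (!length(el)) "unspecified" else {
      ranks <- match(el, h$causes)
      el[which.min(ranks)]
    }
    expect_identical(selectPrimary(el, h), brute)
  }
  expect_error(selectPrimary("no_such_cause", h), "missing from the hierarchy")
})

test_that("classification is deterministic and order-invariant", {
  out <- generateCohort(generatorConfig("child", n = 120, seed = 5),
                        certificates = FALSE)
  a1 <- classify(out$records)
  a2 <- classify(out$records)
  expect_identical(a1, a2)
  perm <- sample(nrow(out$records))
  a3 <- classify(out$records[perm, ])
  expect_identical(a3$primary, a1$primary[perm])
})

test_that("adding an eligible cause never demotes the primary", {
  h <- defaultHierarchy("neonate")
  set.seed(21)
  for (i in 1:200) {
    el <- sample(h$causes, sample(0:4, 1))
    extra <- sample(setdiff(h$causes, el), 1)
    r0 <- match(selectPrimary(el, h), c(h$causes, unspecified = NA))
    r1 <- match(selectPrimary(c(el, extra), h), c(h$causes, unspecified = NA))
    r0 <- ifelse(is.na(r0), length(h$causes) + 1, r0)
    r1 <- ifelse(is.na(r1), length(h$causes) + 1, r1)
    expect_lte(r1, r0)
  }
})

test_that("a possible cause and its probable counterpart never co-occur in the combined set", {
  out <- generateCohort(generatorConfig("child", n = 400, seed = 13),
                        certificates = FALSE)
  a <- classify(out$records)
  rs <- defaultRuleset("child")
  pairs <- lapply(Filter(function(cz) cz$tier == "possible", rs$causes),
                  function(cz) c(cz$id, cz$counterpart))
  for (i in seq_len(nrow(a)))
    for (p in pairs)
      expect_false(all(p %in% a$combined[[i]]))
})

test_that("reporting merge conserves counts: probable + possible = merged", {
  out <- generateCohort(generatorConfig("child", n = 500, seed = 17),
                        certificates = FALSE)
  a <- classify(out$records)
  rs <- defaultRuleset("child")
  for (cz in Filter(function(cz) cz$tier == "possible", rs$causes)) {
    n_poss <- sum(a$primary == cz$id)
    n_prob <- sum(a$primary == cz$counterpart)
    expect_equal(sum(a$reporting == cz$counterpart), n_poss + n_prob)
  }
})

test_that("exhaustive small-sign-space agreement with the brute-force classifier", {
  # covered at 2^12 scale in the acceptance suite; spot-check 2^8 here
  rs <- readRuleset(toyRulesetPath(), toyVocabulary())
  h <- readHierarchy(toyHierarchyPath(), rs)
  grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 8)))
  mat <- cbind(grid, matrix(FALSE, nrow(grid), 4))
  cohort <- toyCohort(mat)
  a <- classify(cohort, rs, h)
  brute <- sapply(seq_len(nrow(cohort)), function(i)
    oracleClassify(as.data.frame(cohort)[i, , drop = FALSE], rs, h))
  expect_identical(a$primary, unname(brute))
})

test_that("maternal infection algorithm reads maternal signs only", {
  rec <- neonatalRecord(maternal_yes = "m_fever_labor")
  expect_true(unname(maternalInfection(rec)))
  expect_false(unname(maternalInfection(neonatalRecord())))
  expect_error(maternalInfection(childRecord(yes = "fever")),
               "neonatal records only")
  # random records against the scalar oracle
  set.seed(31)
  rule <- defaultRuleset("neonate")$maternal
  vocab <- defaultVocabulary()
  n <- 100
  df <- data.frame(death_id = sprintf("m%03d", 1:n), age_group = "neonate",
                   age_at_death = 1, sex = "f", region = "r",
                   cluster_id = "c", survey_weight = 1,
                   stringsAsFactors = FALSE)
  for (s in vocab$maternal)
    df[[paste0("msign.", s)]] <- sample(c("yes", "no", NA), n, TRUE)
  cohort <- asVACohort(df, vocab)
  fast <- unname(maternalInfection(cohort, rule))
  slow <- sapply(seq_len(n), function(i)
    oracleEval(rule$rule, as.data.frame(cohort)[i, , drop = FALSE]))
  expect_identical(fast, unname(slow))
})

test_that("early onset splits strictly at day 2 and tolerates missing onset", {
  rec <- function(d) neonatalRecord(illness_onset_day = d)
  expect_equal(as.character(earlyOnset(rec(0L))), "early")
  expect_equal(as.character(earlyOnset(rec(1L))), "early")
  expect_equal(as.character(earlyOnset(rec(2L))), "late")
  expect_equal(as.character(earlyOnset(rec(NA_integer_))), "not_applicable")
  expect_error(earlyOnset(childRecord()), "neonatal records only")
})

test_that("configuration errors surface at load time, not evaluation time", {
  bad <- tempfile(fileext = ".yaml")
  writeLines('
age_group: neonate
causes:
  - id: x
    rule: {sign: no_such_sign, present: "yes"}
', bad)
  expect_error(readRuleset(bad), "not in the neonate vocabulary")
  bad2 <- tempfile(fileext = ".yaml")
  writeLines('
age_group: neonate
causes:
  - id: x
    tier: possible
    rule: {sign: fever, present: "yes"}
', bad2)
  expect_error(readRuleset(bad2), "counterpart")
  # age-group mismatch between cohort and rule set
  expect_error(classify(childRecord(yes = "fever"),
                        defaultRuleset("neonate"),
                        defaultHierarchy("neonate")),
               "other age group")
})
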