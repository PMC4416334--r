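test_that("with equal weights the CSMF equals the unweighted count ratio", {
  n <- 453
  df <- data.frame(death_id = sprintf("d%03d", 1:n), age_group = "neonate",
                   age_at_death = 1, sex = "f", region = "r",
                   cluster_id = "c", survey_weight = 1,
                   stringsAsFactors = FALSE)
  cohort <- asVACohort(df)
  assign <- data.frame(death_id = cohort$death_id,
                       reporting = rep(c("diarrhea", "other"), c(26, n - 26)),
                       stringsAsFactors = FALSE)
  d <- weightedCSMF(cohort, assign)
  expect_equal(d$percent[d$cause == "diarrhea"], 100 * 26 / 453)
  expect_equal(round(d$percent[d$cause == "diarrhea"], 1), 5.7)
  expect_equal(sum(d$percent), 100, tolerance = 1e-9)
})

test_that("a single-cause cohort reaches 100% with CI upper bound 100", {
  df <- data.frame(death_id = c("a", "b"), age_group = "child",
                   age_at_death = 2, sex = "m", region = "r",
                   cluster_id = "c", survey_weight = c(2, 3),
                   stringsAsFactors = FALSE)
  assign <- data.frame(death_id = c("a", "b"), reporting = "malaria",
                       stringsAsFactors = FALSE)
  d <- weightedCSMF(asVACohort(df), assign)
  expect_equal(d$percent[d$cause == "malaria"], 100)
  expect_equal(d$ci_high[d$cause == "malaria"], 100)
})

test_that("weighted proportions equal a direct weighted-sum oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 150
    causes <- c("a", "b", "c", "unspecified")
    df <- data.frame(death_id = sprintf("d%03d", 1:n), age_group = "child",
                     age_at_death = 2, sex = "m", region = "r",
                     cluster_id = "c",
                     survey_weight = stats::rlnorm(n, 0, 0.6),
                     stringsAsFactors = FALSE)
    cohort <- asVACohort(df)
    val <- sample(causes, n, TRUE)
    assign <- data.frame(death_id = df$death_id, reporting = val,
                         stringsAsFactors = FALSE)
    d <- weightedCSMF(cohort, assign, causes = causes)
    for (cz in causes) {
      oracle <- 100 * sum(df$survey_weight[val == cz]) / sum(df$survey_weight)
      expect_equal(d$percent[d$cause == cz], oracle, tolerance = 1e-12)
    }
    expect_true(all(d$ci_low <= d$percent + 1e-12 &
                      d$percent <= d$ci_high + 1e-12))
    expect_equal(sum(d$percent), 100, tolerance = 1e-9)
  }
})

test_that("missing assignments are reported by death id", {
  df <- data.frame(death_id = c("a", "b"), age_group = "child",
                   age_at_death = 2, sex = "m", region = "r",
                   cluster_id = "c", survey_weight = 1,
                   stringsAsFactors = FALSE)
  assign <- data.frame(death_id = "a", reporting = "malaria",
                       stringsAsFactors = FALSE)
  expect_error(weightedCSMF(asVACohort(df), assign), "b")
})

test_that("two-proportion chi-square reproduces hand-checked values", {
  expect_equal(round(twoPropChi2(18, 453, 2, 453)$statistic, 1), 13.1)
  expect_equal(round(twoPropChi2(121, 620, 14, 620)$statistic, 1), 95.2)
  expect_equal(twoPropChi2(7, 50, 7, 50)$statistic, 0)
  deg <- twoPropChi2(0, 10, 0, 20)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)
})

test_that("chi-square agrees with the textbook Pearson 2x2 statistic", {
  set.seed(3)
  for (i in 1:50) {
    n1 <- sample(20:400, 1); n2 <- sample(20:400, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    got <- twoPropChi2(x1, n1, x2, n2)$statistic
    # independent oracle: Pearson chi-square over the 2x2 expected counts
    tab <- rbind(c(x1, n1 - x1), c(x2, n2 - x2))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    oracle <- sum((tab - expected)^2 / expected)
    expect_equal(got, oracle, tolerance = 1e-10)
    # symmetry and scaling
    expect_equal(twoPropChi2(x2, n2, x1, n1)$statistic, got)
    expect_equal(twoPropChi2(2 * x1, 2 * n1, 2 * x2, 2 * n2)$statistic,
                 2 * got, tolerance = 1e-9)
  }
})

test_that("the mid-p exact p-value is flagged and below the Fisher exact p", {
  tst <- twoPropChi2(18, 453, 2, 453, midp = TRUE)
  expect_match(tst$method, "mid-p")
  expect_true(tst$p_value_midp > 0 && tst$p_value_midp < 1)
  fisher <- stats::fisher.test(rbind(c(18, 435), c(2, 451)))$p.value
  expect_lt(tst$p_value_midp, fisher)
})

test_that("kappa reproduces hand-checked values and grades", {
  k1 <- cohenKappa(58, 18, 0, 544)
  expect_equal(round(k1$kappa, 2), 0.85)
  expect_equal(k1$grade, "excellent")
  k2 <- cohenKappa(84, 19, 29, 321)
  expect_equal(round(k2$kappa, 2), 0.71)
  expect_equal(k2$grade, "good")
  k3 <- cohenKappa(50, 0, 0, 50)
  expect_equal(k3$kappa, 1)
  expect_equal(k3$grade, "excellent")
})

test_that("kappa matches the direct formula on random tables", {
  set.seed(8)
  for (i in 1:100) {
    cells <- sample(0:200, 4, replace = TRUE)
    a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
    N <- sum(cells)
    if (N == 0) next
    po <- (a + d) / N
    pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
    if (1 - pe < 1e-12) next
    oracle <- (po - pe) / (1 - pe)
    got <- cohenKappa(a, b, c, d)
    expect_equal(got$kappa, oracle, tolerance = 1e-12)
    # relabeling both raters (swap a<->d, b<->c) leaves kappa unchanged
    expect_equal(cohenKappa(d, c, b, a)$kappa, got$kappa, tolerance = 1e-12)
    # kappa = 1 exactly when there is no discordance
    if (b == 0 && c == 0 && a > 0 && d > 0) expect_equal(got$kappa, 1)
    if (oracle == 1) expect_true(b == 0 && c == 0)
    expect_true(got$ci[1] <= got$kappa && got$kappa <= got$ci[2])
  }
})

test_that("agreement cells count per-death set membership", {
  ids <- sprintf("d%02d", 1:30)
  s1 <- stats::setNames(rep(list(c("x", "y")), 30), ids)
  expect_equal(agreementTable(s1, s1, "x"),
               c(a = 30, b = 0, c = 0, d = 0))
  s2 <- stats::setNames(rep(list("z"), 30), ids)
  cells <- agreementTable(s1, s2, "x")
  expect_equal(unname(cells["a"]), 0)
  set.seed(12)
  r1 <- stats::setNames(lapply(ids, function(i)
    sample(c("x", "y", "z"), sample(0:3, 1))), ids)
  r2 <- stats::setNames(lapply(ids, function(i)
    sample(c("x", "y", "z"), sample(0:3, 1))), ids)
  got <- agreementTable(r1, r2, "x")
  in1 <- sapply(ids, function(i) "x" %in% r1[[i]])
  in2 <- sapply(ids, function(i) "x" %in% r2[[i]])
  expect_equal(unname(got),
               c(sum(in1 & in2), sum(in1 & !in2), sum(!in1 & in2),
                 sum(!in1 & !in2)))
  expect_error(agreementTable(r1[1:10], r2, "x"), "different death universes")
})

test_that("rank comparison uses dense ranks and excludes unspecified deaths", {
  mk <- function(causes, pct) {
    structure(data.frame(cause = causes, n = 1, percent = pct,
                         ci_low = pct, ci_high = pct,
                         stringsAsFactors = FALSE),
              N = 100, class = c("va_csmf", "data.frame"))
  }
  d1 <- mk(c("a", "b", "unspecified"), c(60, 30, 10))
  expect_true(all(rankComparison(d1, d1)$rank_diff == 0))
  expect_false("unspecified" %in% rankComparison(d1, d1)$cause)
  d2 <- mk(c("a", "b", "unspecified"), c(30, 60, 10))
  rc <- rankComparison(d1, d2)
  expect_equal(rc$rank_diff[rc$cause == "a"], -1)
  expect_equal(rc$rank_diff[rc$cause == "b"], 1)
  # random distributions against a sort-based oracle
  set.seed(9)
  for (i in 1:20) {
    causes <- letters[1:6]
    p1 <- sample(1:50, 6); p2 <- sample(1:50, 6)
    rc <- rankComparison(mk(causes, p1), mk(causes, p2))
    expect_equal(rc$rank1, rank(-p1, ties.method = "min"))
    expect_equal(rc$rank2, rank(-p2, ties.method = "min"))
  }
})
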