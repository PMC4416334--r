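# Shared fixtures and independent oracle implementations. The oracles are
# deliberately written as plain scalar recursion over one record at a time,
# independent of the package's vectorised evaluation path.

# ---- independent rule evaluator -------------------------------------------

# record: a one-row data frame in the cohort layout
oracleEval <- function(expr, record, ruleset = NULL) {
  nm <- names(expr)[1]
  if (nm == "all") {
    for (sub in expr$all) if (!oracleEval(sub, record, ruleset)) return(FALSE)
    return(TRUE)
  }
  if (nm == "any") {
    for (sub in expr$any) if (oracleEval(sub, record, ruleset)) return(TRUE)
    return(FALSE)
  }
  if (nm == "not") return(!oracleEval(expr$not, record, ruleset))
  if (nm == "not_cause") {
    for (id in expr$not_cause)
      if (oracleEval(ruleset$causes[[id]]$rule, record, ruleset))
        return(FALSE)
    return(TRUE)
  }
  if ("sign" %in% names(expr) || "maternal_sign" %in% names(expr)) {
    mat <- "maternal_sign" %in% names(expr)
    key <- if (mat) expr$maternal_sign else expr$sign
    v <- record[[paste0(if (mat) "msign." else "sign.", key)]]
    if (is.null(v) || is.na(v) || v != expr$present) return(FALSE)
    if (!is.null(expr$min_duration)) {
      d <- record[[paste0(if (mat) "mdur." else "dur.", key)]]
      if (is.null(d) || is.na(d) || d < expr$min_duration) return(FALSE)
    }
    if (!is.null(expr$max_duration)) {
      d <- record[[paste0(if (mat) "mdur." else "dur.", key)]]
      if (is.null(d) || is.na(d) || d > expr$max_duration) return(FALSE)
    }
    if (!mat && !is.null(expr$max_onset_order)) {
      r <- record[[paste0("ord.", key)]]
      if (is.null(r) || is.na(r) || r > expr$max_onset_order) return(FALSE)
    }
    return(TRUE)
  }
  if ("field" %in% names(expr)) {
    x <- record[[expr$field]]
    if (is.na(x)) return(FALSE)
    if (!is.null(expr$lt) && !(x < expr$lt)) return(FALSE)
    if (!is.null(expr$le) && !(x <= expr$le)) return(FALSE)
    if (!is.null(expr$gt) && !(x > expr$gt)) return(FALSE)
    if (!is.null(expr$ge) && !(x >= expr$ge)) return(FALSE)
    return(TRUE)
  }
  stop("oracle: unknown node")
}

# full classification oracle: eligibility per cause, possible suppression,
# then minimum hierarchy rank
oracleClassify <- function(record, ruleset, hierarchy) {
  fire <- vapply(ruleset$causes, function(cz)
    oracleEval(cz$rule, record, ruleset), logical(1))
  for (cz in ruleset$causes)
    if (cz$tier == "possible" && fire[[cz$id]] && fire[[cz$counterpart]])
      fire[[cz$id]] <- FALSE
  eligible <- names(fire)[fire]
  if (!length(eligible)) return("unspecified")
  hierarchy$causes[min(match(eligible, hierarchy$causes))]
}

# ---- toy configuration (12 binary signs, 6 causes) ------------------------

toyVocabulary <- function() {
  keys <- paste0("s", 1:12)
  structure(list(version = "toy", neonate = keys, child = keys,
                 maternal = "m1"), class = "va_vocab")
}

toyRulesetPath <- function() {
  path <- tempfile(fileext = ".yaml")
  writeLines('
version: "toy-1"
age_group: neonate
causes:
  - id: c1
    tier: probable
    rule:
      all:
        - {sign: s1, present: "yes"}
        - any:
            - {sign: s2, present: "yes"}
            - {sign: s3, present: "yes"}
  - id: c2
    tier: probable
    rule:
      any:
        - all:
            - {sign: s4, present: "yes"}
            - {sign: s5, present: "yes"}
        - {sign: s6, present: "yes"}
  - id: c3
    tier: probable
    rule:
      all:
        - any:
            - {sign: s7, present: "yes"}
            - {sign: s8, present: "yes"}
        - not: {sign: s9, present: "yes"}
  - id: c4
    tier: probable
    rule:
      all:
        - {sign: s10, present: "yes"}
        - {sign: s11, present: "yes"}
  - id: c5
    tier: probable
    rule:
      {sign: s12, present: "yes"}
  - id: c6
    tier: possible
    counterpart: c2
    rule:
      {sign: s4, present: "yes"}
', path)
  path
}

toyHierarchyPath <- function() {
  path <- tempfile(fileext = ".yaml")
  writeLines('
age_group: neonate
order:
  - {cause: c1, comorbid: true}
  - {cause: c2, comorbid: true}
  - {cause: c3, comorbid: true}
  - {cause: c4, comorbid: false}
  - {cause: c5, comorbid: true}
  - {cause: c6, comorbid: true}
', path)
  path
}

# cohort over the toy vocabulary from a yes/no matrix (cols s1..s12)
toyCohort <- function(mat) {
  n <- nrow(mat)
  df <- data.frame(death_id = sprintf("t%04d", seq_len(n)),
                   age_group = "neonate", age_at_death = 1, sex = "female",
                   region = "r1", cluster_id = "c1", survey_weight = 1,
                   stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat)))
    df[[paste0("sign.s", j)]] <- ifelse(mat[, j], "yes", "no")
  asVACohort(df, toyVocabulary())
}

# a blank single-record neonatal cohort over the default vocabulary with
# chosen signs set; durations given as sign = c(dur = x)
neonatalRecord <- function(yes = character(), dur = list(),
                           pregnancy_duration = NA_real_,
                           illness_onset_day = NA_integer_,
                           maternal_yes = character()) {
  df <- data.frame(death_id = "n1", age_group = "neonate", age_at_death = 3,
                   sex = "male", region = "r1", cluster_id = "c1",
                   survey_weight = 1,
                   pregnancy_duration = pregnancy_duration,
                   illness_onset_day = illness_onset_day,
                   stringsAsFactors = FALSE)
  for (s in yes) df[[paste0("sign.", s)]] <- "yes"
  for (s in names(dur)) df[[paste0("dur.", s)]] <- dur[[s]]
  for (s in maternal_yes) df[[paste0("msign.", s)]] <- "yes"
  asVACohort(df)
}

childRecord <- function(yes = character(), dur = list()) {
  df <- data.frame(death_id = "k1", age_group = "child", age_at_death = 14,
                   sex = "male", region = "r1", cluster_id = "c1",
                   survey_weight = 1, stringsAsFactors = FALSE)
  for (s in yes) df[[paste0("sign.", s)]] <- "yes"
  for (s in names(dur)) df[[paste0("dur.", s)]] <- dur[[s]]
  asVACohort(df)
}
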