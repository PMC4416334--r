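#' Evaluate one cause rule on one record
#'
#' Pure function of the record: the result depends only on the record's
#' fields and the rule expression. Missing responses are conservative — a
#' predicate on a sign coded missing is false, never imputed — which
#' mirrors the specificity-first design of the algorithms.
#'
#' @param rule A single cause entry from a [readRuleset()] rule set (or any
#'   list with a `rule` expression), or a bare expression list.
#' @param record A one-row [asVACohort()] cohort (or a cohort plus `i`).
#' @param ruleset The enclosing rule set; required only when the expression
#'   uses `not_cause`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' rs <- defaultRuleset("neonate")
#' cfg <- generatorConfig("neonate", n = 1, seed = 1)
#' rec <- generateCohort(cfg)$records
#' evaluateRule(rs$causes$sepsis, rec, rs)
#' @export
evaluateRule <- function(rule, record, ruleset = NULL) {
  stopifnot(inherits(record, "va_cohort"), nrow(record) == 1L)
  expr <- if (!is.null(rule$rule)) rule$rule else rule
  as.logical(evalExpr(expr, record, ruleset))
}

# Vectorised expression evaluation over a whole cohort: returns a logical
# vector of length nrow(cohort). NA never propagates: every predicate is
# FALSE on a missing response.
evalExpr <- function(expr, cohort, ruleset = NULL) {
  n <- nrow(cohort)
  nm <- names(expr)
  if (nm[1] == "all")
    return(Reduce(`&`, lapply(expr$all, evalExpr, cohort, ruleset),
                  accumulate = FALSE))
  if (nm[1] == "any")
    return(Reduce(`|`, lapply(expr$any, evalExpr, cohort, ruleset),
                  accumulate = FALSE))
  if (nm[1] == "not")
    return(!evalExpr(expr$not, cohort, ruleset))
  if (nm[1] == "not_cause") {
    if (is.null(ruleset))
      stop("a not_cause predicate needs the enclosing rule set to evaluate")
    hit <- Reduce(`|`, lapply(expr$not_cause, function(id)
      evalExpr(ruleset$causes[[id]]$rule, cohort, ruleset)))
    return(!hit)
  }
  if ("sign" %in% nm || "maternal_sign" %in% nm) {
    maternal <- "maternal_sign" %in% nm
    key <- if (maternal) expr$maternal_sign else expr$sign
    pcol <- paste0(if (maternal) "msign." else "sign.", key)
    v <- cohort[[pcol]]
    if (is.null(v)) return(rep(FALSE, n))
    ok <- !is.na(v) & v == expr$present
    if (!is.null(expr$min_duration) || !is.null(expr$max_duration)) {
      d <- cohort[[paste0(if (maternal) "mdur." else "dur.", key)]]
      if (is.null(d)) d <- rep(NA_real_, n)
      if (!is.null(expr$min_duration))
        ok <- ok & !is.na(d) & d >= expr$min_duration
      if (!is.null(expr$max_duration))
        ok <- ok & !is.na(d) & d <= expr$max_duration
    }
    if (!maternal && !is.null(expr$max_onset_order)) {
      r <- cohort[[paste0("ord.", key)]]
      if (is.null(r)) r <- rep(NA_real_, n)
      ok <- ok & !is.na(r) & r <= expr$max_onset_order
    }
    return(ok)
  }
  if ("field" %in% nm) {
    x <- cohort[[expr$field]]
    ok <- rep(TRUE, n)
    if (!is.null(expr$lt)) ok <- ok & x < expr$lt
    if (!is.null(expr$le)) ok <- ok & x <= expr$le
    if (!is.null(expr$gt)) ok <- ok & x > expr$gt
    if (!is.null(expr$ge)) ok <- ok & x >= expr$ge
    ok[is.na(ok)] <- FALSE
    return(ok)
  }
  stop("unrecognised expression node: ", paste(nm, collapse = ","))
}

#' Eligibility of every cause on every record
#'
#' Evaluates each cause rule on each record, then applies the
#' possible/probable suppression: a possible-tier cause is eligible only
#' when its probable counterpart is not, so the possible tiers claim deaths
#' from the unspecified group without double-diagnosing.
#'
#' @param cohort A [asVACohort()] cohort of a single age group.
#' @param ruleset A [readRuleset()] rule set for that age group.
#' @return Logical matrix, rows = deaths, columns = cause ids.
#' @export
eligibilityMatrix <- function(cohort, ruleset) {
  stopifnot(inherits(cohort, "va_cohort"), inherits(ruleset, "va_ruleset"))
  if (nrow(cohort) && any(cohort$age_group != ruleset$age_group))
    stop("rule set is for ", ruleset$age_group,
         " deaths but the cohort holds other age group(s)")
  ids <- names(ruleset$causes)
  elig <- matrix(FALSE, nrow(cohort), length(ids), dimnames = list(NULL, ids))
  for (id in ids)
    elig[, id] <- evalExpr(ruleset$causes[[id]]$rule, cohort, ruleset)
  for (cz in ruleset$causes)
    if (cz$tier == "possible")
      elig[, cz$id] <- elig[, cz$id] & !elig[, cz$counterpart]
  elig
}

#' Primary cause from an eligible set
#'
#' The hierarchy is a total order; the primary cause is simply the
#' top-ranked (minimum-rank) eligible cause, and an empty eligible set
#' yields `"unspecified"`. Exposed separately from [classify()] so the
#' selection step can be tested in isolation.
#'
#' @param eligible Character vector of eligible cause ids.
#' @param hierarchy A [readHierarchy()] hierarchy.
#' @return A single cause id, or `"unspecified"`.
#' @examples
#' h <- defaultHierarchy("neonate")
#' selectPrimary(c("sepsis", "meningitis"), h)  # meningitis outranks sepsis
#' @export
selectPrimary <- function(eligible, hierarchy) {
  stopifnot(inherits(hierarchy, "va_hierarchy"))
  unknown <- setdiff(eligible, hierarchy$causes)
  if (length(unknown))
    stop("eligible cause(s) missing from the hierarchy: ",
         paste(unknown, collapse = ", "))
  if (!length(eligible)) return("unspecified")
  hierarchy$causes[min(match(eligible, hierarchy$causes))]
}

#' Hierarchical cause-of-death classification
#'
#' Assigns each death its EAVA primary cause (the top-ranked cause whose
#' rule fires), the co-morbid causes (every other firing cause flagged
#' co-morbid-capable in the hierarchy), the reporting cause (possible tiers
#' merged into their probable counterparts, as used for final cause
#' distributions) and the combined algorithmic-cause set (primary plus
#' co-morbid), which is the unit of comparison against the combined
#' physician cause.
#'
#' @inheritParams eligibilityMatrix
#' @param hierarchy A [readHierarchy()] hierarchy covering the rule set.
#' @return A data frame of class `va_assignments`: columns `death_id`,
#'   `primary`, `reporting`, and list columns `comorbid`, `combined`,
#'   `eligible`. The rule-set version is attached as attribute
#'   `ruleset_version`.
#' @examples
#' cfg <- generatorConfig("neonate", n = 25, seed = 7)
#' rec <- generateCohort(cfg)$records
#' a <- classify(rec, defaultRuleset("neonate"), defaultHierarchy("neonate"))
#' table(a$primary)
#' @export
classify <- function(cohort, ruleset = defaultRuleset(age),
                     hierarchy = defaultHierarchy(age)) {
  age <- if (nrow(cohort)) cohort$age_group[1] else "neonate"
  checkHierarchy(hierarchy, ruleset)
  elig <- eligibilityMatrix(cohort, ruleset)
  elig <- elig[, hierarchy$causes, drop = FALSE]  # hierarchy order
  n <- nrow(cohort)
  k <- ncol(elig)
  first <- rep(NA_integer_, n)
  any_fire <- rowSums(elig) > 0
  if (any(any_fire))
    first[any_fire] <- max.col(elig[any_fire, , drop = FALSE],
                               ties.method = "first")
  primary <- ifelse(is.na(first), "unspecified", hierarchy$causes[first])
  com_ok <- hierarchy$comorbid[hierarchy$causes]
  comorbid <- vector("list", n)
  eligible <- vector("list", n)
  for (i in seq_len(n)) {
    el <- hierarchy$causes[elig[i, ]]
    eligible[[i]] <- el
    if (is.na(first[i])) { comorbid[[i]] <- character() ; next }
    below <- elig[i, ] & seq_len(k) > first[i]
    comorbid[[i]] <- hierarchy$causes[below & com_ok]
  }
  reporting <- mergePossible(primary, ruleset)
  combined <- mapply(function(p, cm) if (p == "unspecified") cm else c(p, cm),
                     primary, comorbid, SIMPLIFY = FALSE)
  out <- data.frame(death_id = cohort$death_id, primary = primary,
                    reporting = reporting, stringsAsFactors = FALSE)
  out$comorbid <- unname(comorbid)
  out$combined <- unname(combined)
  out$eligible <- unname(eligible)
  structure(out, ruleset_version = ruleset$version,
            age_group = ruleset$age_group,
            class = c("va_assignments", "data.frame"))
}

#' Merge possible tiers into their probable counterparts
#'
#' Final cause-of-death distributions combine each probable diagnosis with
#' its related possible diagnosis; this maps possible-tier cause ids to the
#' probable counterpart and leaves every other id unchanged.
#'
#' @param causes Character vector of cause ids.
#' @param ruleset The rule set defining the tier structure.
#' @return Character vector of the same length.
#' @export
mergePossible <- function(causes, ruleset) {
  map <- vapply(ruleset$causes, function(cz)
    if (cz$tier == "possible") cz$counterpart else cz$id, "")
  out <- causes
  hit <- causes %in% names(map)
  out[hit] <- unname(map[causes[hit]])
  out
}

#' @export
print.va_assignments <- function(x, ...) {
  cat("EAVA assignments for ", nrow(x), " deaths (rule set version ",
      attr(x, "ruleset_version"), ")\n", sep = "")
  if (nrow(x)) {
    tab <- sort(table(x$primary), decreasing = TRUE)
    cat("primary causes:\n")
    print(tab)
  }
  invisible(x)
}

#' Maternal infection algorithm
#'
#' Applies the maternal-infection rule (infection before or during labor
#' and delivery) to the maternal signs of neonatal records. Pure and
#' deterministic; all-missing maternal signs yield `FALSE`.
#'
#' @param cohort A neonatal [asVACohort()] cohort.
#' @param rule The maternal rule; defaults to the one shipped with the
#'   neonatal rule set.
#' @param ruleset Rule set context (only needed for exotic rules).
#' @return Named logical vector, one element per death.
#' @export
maternalInfection <- function(cohort, rule = defaultRuleset("neonate")$maternal,
                              ruleset = NULL) {
  stopifnot(inherits(cohort, "va_cohort"))
  if (nrow(cohort) && any(cohort$age_group != "neonate"))
    stop("the maternal infection algorithm applies to neonatal records only")
  expr <- if (!is.null(rule$rule)) rule$rule else rule
  stats::setNames(evalExpr(expr, cohort, ruleset), cohort$death_id)
}

#' Early-onset classification of neonatal illness
#'
#' Early-onset neonatal infection is illness onset before day 2 of life;
#' onset on day 2 or later is late; a missing onset day is not applicable.
#'
#' @param cohort A neonatal [asVACohort()] cohort.
#' @return Factor with levels `early`, `late`, `not_applicable`.
#' @export
earlyOnset <- function(cohort) {
  stopifnot(inherits(cohort, "va_cohort"))
  if (nrow(cohort) && any(cohort$age_group != "neonate"))
    stop("early-onset classification applies to neonatal records only")
  d <- cohort$illness_onset_day
  out <- ifelse(is.na(d), "not_applicable", ifelse(d < 2, "early", "late"))
  factor(out, levels = c("early", "late", "not_applicable"))
}
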