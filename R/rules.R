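#' Load an expert-algorithm rule set
#'
#' A rule set is declarative YAML (a JSON equivalent parses identically):
#' one entry per cause with an `id`, a `tier` (`"probable"` or
#' `"possible"`, the latter naming its probable `counterpart`), and a
#' boolean `rule` expression. Expressions nest `all:`/`any:`/`not:`
#' combinators over predicate leaves:
#'
#' * `{sign: key, present: "yes", min_duration: d, max_duration: d,
#'   max_onset_order: r}` — a sign predicate; a missing response never
#'   satisfies a predicate, so missingness cannot create a diagnosis;
#' * `{maternal_sign: key, present: "yes"}` — a maternal sign predicate;
#' * `{field: pregnancy_duration | illness_onset_day | age_at_death,
#'   lt|le|gt|ge: x}` — a record-field comparison;
#' * `{not_cause: [ids]}` — satisfied when none of the named causes' rules
#'   fires on the record (used by "possible malaria": fever with no other
#'   infectious diagnosis). The named rules may not themselves use
#'   `not_cause`.
#'
#' Every sign key is checked against the vocabulary at load time; a
#' predicate referencing an unknown key is a configuration error, reported
#' here rather than silently evaluating false later.
#'
#' @param path Path to a rule-set YAML/JSON file.
#' @param vocab Vocabulary to validate sign keys against.
#' @return An object of class `va_ruleset`: a list with `age_group`,
#'   `version`, a named list `causes` (each with `id`, `label`, `tier`,
#'   `counterpart`, `rule`) and optionally `maternal` (the maternal
#'   infection rule).
#' @examples
#' rs <- defaultRuleset("neonate")
#' names(rs$causes)
#' @export
readRuleset <- function(path, vocab = defaultVocabulary()) {
  raw <- if (tolower(tools::file_ext(path)) == "json")
    jsonlite::fromJSON(path, simplifyVector = FALSE) else yaml::read_yaml(path)
  age_group <- raw$age_group
  if (is.null(age_group) || !age_group %in% c("neonate", "child"))
    stop("rule set must declare age_group neonate or child: ", path)
  if (!length(raw$causes)) stop("rule set declares no causes: ", path)
  causes <- list()
  for (entry in raw$causes) {
    id <- entry$id
    if (is.null(id) || is.null(entry$rule))
      stop("each cause needs an id and a non-empty rule: ", path)
    tier <- entry$tier %||% "probable"
    if (!tier %in% c("probable", "possible"))
      stop("cause ", id, ": tier must be probable or possible")
    if (tier == "possible" && is.null(entry$counterpart))
      stop("possible-tier cause ", id, " must name its probable counterpart")
    causes[[id]] <- list(
      id = id, label = entry$label %||% id, tier = tier,
      counterpart = entry$counterpart %||% NA_character_,
      rule = normalizeExpr(entry$rule)
    )
  }
  for (cz in causes) {
    if (cz$tier == "possible" && !cz$counterpart %in% names(causes))
      stop("possible-tier cause ", cz$id, " names unknown counterpart ",
           cz$counterpart)
  }
  rs <- structure(
    list(age_group = age_group,
         version = as.character(raw$version %||% "unversioned"),
         causes = causes),
    class = "va_ruleset"
  )
  if (!is.null(raw$maternal)) {
    rs$maternal <- list(id = raw$maternal$id %||% "maternal_infection",
                        label = raw$maternal$label %||% "Maternal infection",
                        rule = normalizeExpr(raw$maternal$rule))
    checkExpr(rs$maternal$rule, rs, vocab, age_group, rs$maternal$id,
              allow_not_cause = FALSE)
  }
  for (cz in rs$causes)
    checkExpr(cz$rule, rs, vocab, age_group, cz$id, allow_not_cause = TRUE)
  rs
}

#' @param age_group `"neonate"` or `"child"`.
#' @rdname readRuleset
#' @export
defaultRuleset <- function(age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  readRuleset(system.file("extdata", paste0("rules_", age_group, ".yaml"),
                          package = "vacause", mustWork = TRUE))
}

#' @export
print.va_ruleset <- function(x, ...) {
  tiers <- vapply(x$causes, `[[`, "", "tier")
  cat("EAVA rule set (", x$age_group, ", version ", x$version, "): ",
      sum(tiers == "probable"), " probable + ",
      sum(tiers == "possible"), " possible cause rules",
      if (!is.null(x$maternal)) " + maternal rule", "\n", sep = "")
  invisible(x)
}

# Coerce parsed YAML booleans back to "yes"/"no" and check leaf shape.
normalizeExpr <- function(expr) {
  if (!is.list(expr)) stop("rule expression must be a mapping, got: ",
                           deparse(expr))
  nm <- names(expr)
  if ("all" %in% nm || "any" %in% nm) {
    key <- intersect(c("all", "any"), nm)[1]
    return(stats::setNames(list(lapply(expr[[key]], normalizeExpr)), key))
  }
  if ("not" %in% nm) return(list(not = normalizeExpr(expr$not)))
  if ("not_cause" %in% nm)
    return(list(not_cause = as.character(unlist(expr$not_cause))))
  if ("sign" %in% nm || "maternal_sign" %in% nm) {
    p <- expr$present %||% "yes"
    if (isTRUE(p)) p <- "yes"
    if (isFALSE(p)) p <- "no"
    if (!p %in% c("yes", "no"))
      stop("predicate 'present' must be yes or no, got: ", p)
    expr$present <- p
    return(expr)
  }
  if ("field" %in% nm) {
    if (!any(c("lt", "le", "gt", "ge") %in% nm))
      stop("field predicate needs a comparator lt/le/gt/ge")
    return(expr)
  }
  stop("unrecognised rule expression node: ", paste(nm, collapse = ","))
}

# Configuration-time validation of an expression against the vocabulary.
checkExpr <- function(expr, ruleset, vocab, age_group, cause_id,
                      allow_not_cause = TRUE, depth = 0L) {
  nm <- names(expr)
  if (nm[1] %in% c("all", "any")) {
    for (sub in expr[[1]])
      checkExpr(sub, ruleset, vocab, age_group, cause_id, allow_not_cause)
    return(invisible(TRUE))
  }
  if (nm[1] == "not")
    return(checkExpr(expr$not, ruleset, vocab, age_group, cause_id,
                     allow_not_cause))
  if (nm[1] == "not_cause") {
    if (!allow_not_cause)
      stop("cause ", cause_id, ": not_cause is not allowed here")
    for (id in expr$not_cause) {
      tgt <- ruleset$causes[[id]]
      if (is.null(tgt))
        stop("cause ", cause_id, ": not_cause names unknown cause ", id)
      if (exprUsesNotCause(tgt$rule))
        stop("cause ", cause_id, ": not_cause target ", id,
             " itself uses not_cause (cycles are not allowed)")
    }
    return(invisible(TRUE))
  }
  if ("sign" %in% nm) {
    if (!expr$sign %in% vocabSigns(vocab, age_group))
      stop("cause ", cause_id, ": sign '", expr$sign,
           "' is not in the ", age_group, " vocabulary")
    for (th in c("min_duration", "max_duration", "max_onset_order"))
      if (!is.null(expr[[th]]) && expr[[th]] <= 0)
        stop("cause ", cause_id, ": ", th, " must be positive")
    return(invisible(TRUE))
  }
  if ("maternal_sign" %in% nm) {
    if (!expr$maternal_sign %in% vocab$maternal)
      stop("cause ", cause_id, ": maternal sign '", expr$maternal_sign,
           "' is not in the maternal vocabulary")
    return(invisible(TRUE))
  }
  if ("field" %in% nm) {
    ok <- c("pregnancy_duration", "illness_onset_day", "age_at_death")
    if (!expr$field %in% ok)
      stop("cause ", cause_id, ": field predicate on unknown field ",
           expr$field)
    return(invisible(TRUE))
  }
  stop("cause ", cause_id, ": unrecognised expression node")
}

exprUsesNotCause <- function(expr) {
  nm <- names(expr)
  if (nm[1] %in% c("all", "any"))
    return(any(vapply(expr[[1]], exprUsesNotCause, logical(1))))
  if (nm[1] == "not") return(exprUsesNotCause(expr$not))
  identical(nm[1], "not_cause")
}

#' Load a cause hierarchy
#'
#' A hierarchy is the total order over cause ids (rank 1 = top) used to
#' select the primary cause when several rules fire, plus a per-cause flag
#' saying whether the cause may be reported as co-morbid. Invariants
#' enforced at load time: no duplicate causes; every possible-tier cause
#' ranks strictly below its probable counterpart (when a rule set is given).
#'
#' @param path Path to a hierarchy YAML file.
#' @param ruleset Optional `va_ruleset` to cross-check cause ids and tier
#'   ordering against.
#' @return An object of class `va_hierarchy`: list with `age_group`,
#'   `causes` (ordered character vector) and `comorbid` (named logical).
#' @examples
#' defaultHierarchy("neonate")$causes
#' @export
readHierarchy <- function(path, ruleset = NULL) {
  raw <- yaml::read_yaml(path)
  entries <- raw$order
  if (!length(entries)) stop("hierarchy declares no causes: ", path)
  ids <- vapply(entries, function(e) as.character(e$cause), "")
  if (anyDuplicated(ids)) stop("hierarchy lists a cause twice: ", path)
  com <- vapply(entries, function(e) isTRUE(e$comorbid), logical(1))
  names(com) <- ids
  h <- structure(list(age_group = raw$age_group %||% NA_character_,
                      causes = ids, comorbid = com),
                 class = "va_hierarchy")
  if (!is.null(ruleset)) checkHierarchy(h, ruleset)
  h
}

#' @rdname readHierarchy
#' @export
defaultHierarchy <- function(age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  readHierarchy(system.file("extdata", paste0("hierarchy_", age_group, ".yaml"),
                            package = "vacause", mustWork = TRUE),
                ruleset = defaultRuleset(age_group))
}

checkHierarchy <- function(hierarchy, ruleset) {
  miss <- setdiff(names(ruleset$causes), hierarchy$causes)
  if (length(miss))
    stop("hierarchy omits rule-set cause(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(hierarchy$causes, names(ruleset$causes))
  if (length(extra))
    stop("hierarchy lists cause(s) with no rule: ", paste(extra, collapse = ", "))
  rank <- stats::setNames(seq_along(hierarchy$causes), hierarchy$causes)
  for (cz in ruleset$causes) {
    if (cz$tier == "possible" && rank[[cz$id]] <= rank[[cz$counterpart]])
      stop("possible-tier cause ", cz$id,
           " must rank strictly below its probable counterpart ",
           cz$counterpart)
  }
  invisible(TRUE)
}

#' @export
print.va_hierarchy <- function(x, ...) {
  cat("Cause hierarchy (", x$age_group, "), rank 1 first:\n", sep = "")
  cat(paste0("  ", seq_along(x$causes), ". ", x$causes,
             ifelse(x$comorbid, "", " [never co-morbid]")), sep = "\n")
  invisible(x)
}

#' Minimal diagnostic criteria for physician certification
#'
#' Loads the per-cause minimal-criteria floors used by
#' [auditMinimumCriteria()]. The file format is a rule set without tiers.
#'
#' @inheritParams readRuleset
#' @return A `va_ruleset` whose rules are the minimal-criteria floors.
#' @export
readMinimumCriteria <- function(path, vocab = defaultVocabulary()) {
  readRuleset(path, vocab)
}

#' @rdname readMinimumCriteria
#' @export
defaultMinimumCriteria <- function(age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  readRuleset(system.file("extdata",
                          paste0("pcva_minimum_criteria_", age_group, ".yaml"),
                          package = "vacause", mustWork = TRUE))
}
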