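#' Verbal autopsy cohort objects
#'
#' A `va_cohort` is a data frame with one row per death. Core columns:
#'
#' * `death_id` — unique identifier;
#' * `age_group` — `"neonate"` (age at death in days, 0–27) or `"child"`
#'   (age at death in months, 1–59); the unit differs by group and no
#'   silent conversion is ever performed;
#' * `age_at_death`, `sex`, `region`, `cluster_id`;
#' * `survey_weight` — positive sampling weight from the survey design;
#' * `pregnancy_duration` — completed months of pregnancy, or `NA`;
#' * `illness_onset_day` — day of life at illness onset (neonates), or `NA`.
#'
#' Each sign key `k` in the vocabulary contributes up to three columns:
#' `sign.k` (tri-state `"yes"`/`"no"`/`NA`; a missing response is distinct
#' from "no"), `dur.k` (duration in days, meaningful only when the sign is
#' present) and `ord.k` (onset-order rank from the single illness-ordering
#' item). Maternal signs use `msign.k`.
#'
#' @param data A data frame holding the columns above.
#' @param vocab A `va_vocab` vocabulary; defaults to the shipped one.
#' @return `asVACohort()` returns a `va_cohort` data frame with every
#'   vocabulary sign column present (filled with `NA` where absent).
#' @export
asVACohort <- function(data, vocab = defaultVocabulary()) {
  core <- c("death_id", "age_group", "age_at_death", "sex", "region",
            "cluster_id", "survey_weight")
  miss <- setdiff(core, names(data))
  if (length(miss))
    stop("record data lacks required column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$death_id <- as.character(data$death_id)
  if (anyDuplicated(data$death_id))
    stop("death_id values are not unique")
  if (is.null(data$pregnancy_duration))
    data$pregnancy_duration <- rep(NA_real_, nrow(data))
  if (is.null(data$illness_onset_day))
    data$illness_onset_day <- rep(NA_real_, nrow(data))

  signs <- union(vocab$neonate, vocab$child)
  known <- c(paste0("sign.", signs), paste0("dur.", signs), paste0("ord.", signs),
             paste0("msign.", vocab$maternal), paste0("mdur.", vocab$maternal))
  extra <- grep("^(sign|dur|ord|msign|mdur)\\.", names(data), value = TRUE)
  unknown <- setdiff(extra, known)
  if (length(unknown))
    warning("sign column(s) not in the active vocabulary, kept as-is: ",
            paste(unknown, collapse = ", "))
  for (col in setdiff(known, names(data))) {
    data[[col]] <- rep(if (grepl("^(sign|msign)\\.", col)) NA_character_
                       else NA_real_, nrow(data))
  }
  for (col in grep("^(dur|ord|mdur)\\.", names(data), value = TRUE))
    data[[col]] <- as.numeric(data[[col]])
  for (col in c("age_at_death", "survey_weight", "pregnancy_duration",
                "illness_onset_day"))
    data[[col]] <- as.numeric(data[[col]])
  for (col in grep("^(sign|msign)\\.", names(data), value = TRUE)) {
    v <- as.character(data[[col]])
    bad <- !is.na(v) & !v %in% c("yes", "no")
    if (any(bad))
      stop("column ", col, " holds value(s) outside yes/no/missing: ",
           paste(unique(v[bad]), collapse = ", "))
    data[[col]] <- v
  }
  structure(data, vocab = vocab, class = c("va_cohort", "data.frame"))
}

#' @export
print.va_cohort <- function(x, ...) {
  tab <- table(factor(x$age_group, levels = c("neonate", "child")))
  cat("VA cohort: ", nrow(x), " deaths (",
      tab[["neonate"]], " neonatal, ", tab[["child"]], " child), ",
      length(unique(x$cluster_id)), " cluster(s)\n", sep = "")
  invisible(x)
}

#' Read and write verbal autopsy records
#'
#' Records are stored as flat CSV (UTF-8, comma-separated, header required)
#' or as a JSON array of row objects mirroring the same schema. Tri-state
#' sign coding is preserved: an empty CSV cell (or JSON `null`) is a
#' missing response and is never collapsed to `"no"`.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param vocab Vocabulary used to validate sign columns.
#' @return `readVARecords()` returns a [asVACohort()] cohort;
#'   `writeVARecords()` returns `path` invisibly.
#' @examples
#' cfg <- generatorConfig(age_group = "neonate", n = 5, seed = 1)
#' cohort <- generateCohort(cfg)$records
#' f <- tempfile(fileext = ".csv")
#' writeVARecords(cohort, f)
#' again <- readVARecords(f)
#' nrow(again)
#' @export
readVARecords <- function(path, vocab = defaultVocabulary()) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  data <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), check.names = FALSE),
    json = {
      x <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
      if (length(x) == 0) x <- data.frame()
      as.data.frame(x, stringsAsFactors = FALSE)
    },
    stop("unsupported record file extension: ", ext)
  )
  if (nrow(data) == 0) {
    message("read 0 VA records from ", path)
    tmpl <- data.frame(death_id = character(), age_group = character(),
                       age_at_death = numeric(), sex = character(),
                       region = character(), cluster_id = character(),
                       survey_weight = numeric(), stringsAsFactors = FALSE)
    return(asVACohort(tmpl, vocab))
  }
  out <- tryCatch(asVACohort(data, vocab), error = function(e) {
    stop("malformed record file ", path, ": ", conditionMessage(e))
  })
  message("read ", nrow(out), " VA records from ", path)
  out
}

#' @param cohort A `va_cohort`.
#' @rdname readVARecords
#' @export
writeVARecords <- function(cohort, path) {
  stopifnot(inherits(cohort, "va_cohort"))
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(cohort)
  if (ext == "csv") {
    # full-precision numeric formatting so read-write round trips exactly
    for (col in names(df)) {
      if (is.double(df[[col]])) {
        v <- sprintf("%.17g", df[[col]])
        v[is.na(df[[col]])] <- NA_character_
        df[[col]] <- v
      }
    }
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else stop("unsupported record file extension: ", ext)
  invisible(path)
}

#' Validate a cohort against the record invariants
#'
#' Reports (rather than fails on) violations of the record invariants: age
#' at death outside the window for the age group (0–27 days for neonates,
#' 1–59 months for children), non-positive survey weight, and a sign
#' duration recorded for a sign that was not reported present.
#'
#' @param cohort A [asVACohort()] cohort.
#' @return A data frame of class `va_validation` with columns `death_id`,
#'   `field` and `problem`; zero rows means a clean cohort.
#' @export
validateCohort <- function(cohort) {
  stopifnot(inherits(cohort, "va_cohort"))
  out <- list()
  flag <- function(id, field, problem)
    out[[length(out) + 1L]] <<- data.frame(death_id = id, field = field,
                                           problem = problem,
                                           stringsAsFactors = FALSE)
  bad_grp <- !cohort$age_group %in% c("neonate", "child")
  for (i in which(bad_grp))
    flag(cohort$death_id[i], "age_group", "unknown age group")
  neo <- !bad_grp & cohort$age_group == "neonate"
  chd <- !bad_grp & cohort$age_group == "child"
  bad_age <- (neo & (is.na(cohort$age_at_death) | cohort$age_at_death < 0 |
                       cohort$age_at_death > 27)) |
             (chd & (is.na(cohort$age_at_death) | cohort$age_at_death < 1 |
                       cohort$age_at_death > 59))
  for (i in which(bad_age))
    flag(cohort$death_id[i], "age_at_death",
         "age at death outside the window for the age group")
  bad_w <- is.na(cohort$survey_weight) | cohort$survey_weight <= 0
  for (i in which(bad_w))
    flag(cohort$death_id[i], "survey_weight", "survey weight not positive")
  for (col in grep("^sign\\.", names(cohort), value = TRUE)) {
    dcol <- sub("^sign\\.", "dur.", col)
    if (!dcol %in% names(cohort)) next
    orphan <- !is.na(cohort[[dcol]]) &
      (is.na(cohort[[col]]) | cohort[[col]] != "yes")
    for (i in which(orphan))
      flag(cohort$death_id[i], dcol, "duration recorded without sign presence")
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(death_id = character(), field = character(),
               problem = character(), stringsAsFactors = FALSE)
  class(res) <- c("va_validation", "data.frame")
  res
}

#' @export
print.va_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("cohort valid: 0 violations\n")
  else {
    cat(nrow(x), "violation(s):\n")
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}
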