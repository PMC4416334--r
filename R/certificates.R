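#' Death certificate objects
#'
#' Physician-certified VA is captured as an international death
#' certificate per death: part 1 holds the causal chain on lines 1a–1d
#' (1a = direct cause, the lowest completed line = underlying cause) and
#' part 2 holds contributing causes. For neonatal deaths the physician may
#' also certify maternal causes; any maternal part-1 entry is always
#' placed beneath all child entries.
#'
#' The data layout is long: one row per certificate entry with columns
#' `death_id`, `line` (`"1a"`, `"1b"`, `"1c"`, `"1d"` or `"2"` for
#' part 2), `cause` and logical `maternal`.
#'
#' @param data Data frame with the columns above.
#' @return A `va_certificates` data frame.
#' @export
asCertificates <- function(data) {
  need <- c("death_id", "line", "cause")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("certificate data lacks column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$death_id <- as.character(data$death_id)
  data$line <- as.character(data$line)
  data$cause <- as.character(data$cause)
  if (is.null(data$maternal)) data$maternal <- FALSE
  data$maternal <- as.logical(data$maternal)
  bad <- !data$line %in% c("1a", "1b", "1c", "1d", "2")
  if (any(bad))
    stop("invalid certificate line label(s): ",
         paste(unique(data$line[bad]), collapse = ", "))
  for (id in unique(data$death_id)) {
    p1 <- data[data$death_id == id & data$line != "2", , drop = FALSE]
    if (!nrow(p1) || !"1a" %in% p1$line)
      stop("certificate ", id, ": part 1 must start at line 1a")
    if (anyDuplicated(p1$line))
      stop("certificate ", id, ": duplicated part-1 line")
    idx <- match(p1$line, c("1a", "1b", "1c", "1d"))
    if (any(p1$maternal) && any(!p1$maternal) &&
        min(idx[p1$maternal]) < max(idx[!p1$maternal]))
      stop("certificate ", id,
           ": maternal part-1 entries must lie beneath all child entries")
    if (!any(!p1$maternal))
      stop("certificate ", id, ": part 1 holds no child cause")
  }
  structure(data, class = c("va_certificates", "data.frame"))
}

#' @export
print.va_certificates <- function(x, ...) {
  cat("PCVA death certificates: ", length(unique(x$death_id)),
      " deaths, ", nrow(x), " entries (",
      sum(x$line != "2"), " part-1, ", sum(x$line == "2"), " part-2)\n",
      sep = "")
  invisible(x)
}

#' Read and write death certificates
#'
#' CSV and JSON mirrors of the long certificate layout documented in
#' [asCertificates()].
#'
#' @param path File path ending in `.csv` or `.json`.
#' @return `readCertificates()` returns a `va_certificates` object.
#' @export
readCertificates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  data <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE,
                          na.strings = c("", "NA")),
    json = as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE),
    stop("unsupported certificate file extension: ", ext))
  asCertificates(data)
}

#' @param certs A `va_certificates` object.
#' @rdname readCertificates
#' @export
writeCertificates <- function(certs, path) {
  stopifnot(inherits(certs, "va_certificates"))
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(certs)
  if (ext == "csv") utils::write.csv(df, path, row.names = FALSE, na = "")
  else if (ext == "json")
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  else stop("unsupported certificate file extension: ", ext)
  invisible(path)
}

#' Underlying cause of death from a certificate
#'
#' The underlying cause is the antecedent cause on the lowest completed
#' part-1 line: the child cause lowest in lines 1a–1c is the underlying
#' cause of death, and (for neonates) the maternal cause lowest in lines
#' 1b–1d is the underlying maternal cause.
#'
#' @param certs A [asCertificates()] object.
#' @return Data frame with one row per death: `death_id`, `underlying`,
#'   `maternal_underlying` (`NA` when no maternal cause was certified).
#' @examples
#' cert <- asCertificates(data.frame(
#'   death_id = "d1", line = c("1a", "1b"),
#'   cause = c("birth_injury_asphyxia", "obstructed_labor"),
#'   maternal = c(FALSE, TRUE)))
#' underlyingCause(cert)
#' @export
underlyingCause <- function(certs) {
  stopifnot(inherits(certs, "va_certificates"))
  ids <- unique(certs$death_id)
  line_rank <- c("1a" = 1L, "1b" = 2L, "1c" = 3L, "1d" = 4L)
  res <- lapply(ids, function(id) {
    p1 <- certs[certs$death_id == id & certs$line != "2", , drop = FALSE]
    idx <- line_rank[p1$line]
    child <- p1[!p1$maternal, , drop = FALSE]
    u <- child$cause[which.max(line_rank[child$line])]
    mat <- p1[p1$maternal, , drop = FALSE]
    mu <- if (nrow(mat)) mat$cause[which.max(line_rank[mat$line])]
          else NA_character_
    data.frame(death_id = id, underlying = u, maternal_underlying = mu,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Combined physician cause set
#'
#' All direct, antecedent and contributing child causes on a certificate,
#' deduplicated into one overall physician-cause set per death. Maternal
#' entries are excluded (they describe the mother, not the child's cause).
#'
#' @param certs A [asCertificates()] object.
#' @return Named list (by `death_id`) of character vectors.
#' @export
combinedPhysicianCause <- function(certs) {
  stopifnot(inherits(certs, "va_certificates"))
  ids <- unique(certs$death_id)
  out <- lapply(ids, function(id) {
    rows <- certs[certs$death_id == id & !certs$maternal, , drop = FALSE]
    unique(rows$cause)
  })
  stats::setNames(out, ids)
}

#' Audit certified causes against minimal diagnostic criteria
#'
#' For each certified child cause, checks whether the matching VA record
#' satisfies the configured minimal diagnostic criteria for that cause.
#' Causes with no configured criteria are reported as uncheckable.
#'
#' @param certs A [asCertificates()] object.
#' @param cohort The [asVACohort()] cohort sharing `death_id`s with the
#'   certificates.
#' @param criteria A [readMinimumCriteria()] rule set of per-cause floors.
#' @return A data frame of class `va_audit` with one row per certified
#'   cause: `death_id`, `cause`, `status` in
#'   `satisfied`/`not_satisfied`/`uncheckable`. Per-cause summary counts
#'   are attached as attribute `summary`.
#' @export
auditMinimumCriteria <- function(certs, cohort,
                                 criteria = defaultMinimumCriteria(
                                   cohort$age_group[1])) {
  stopifnot(inherits(certs, "va_certificates"),
            inherits(cohort, "va_cohort"))
  ids <- unique(certs$death_id)
  miss <- setdiff(ids, cohort$death_id)
  if (length(miss))
    stop("certificate death_id(s) absent from the cohort: ",
         paste(utils::head(miss, 5), collapse = ", "))
  entries <- certs[!certs$maternal, c("death_id", "cause")]
  entries <- unique(entries)
  status <- character(nrow(entries))
  for (i in seq_len(nrow(entries))) {
    cz <- criteria$causes[[entries$cause[i]]]
    if (is.null(cz)) { status[i] <- "uncheckable"; next }
    rec <- cohort[cohort$death_id == entries$death_id[i], , drop = FALSE]
    status[i] <- if (evaluateRule(cz, rec, criteria)) "satisfied"
                 else "not_satisfied"
  }
  out <- data.frame(entries, status = status, stringsAsFactors = FALSE)
  summ <- as.data.frame.matrix(table(out$cause, factor(
    out$status, levels = c("satisfied", "not_satisfied", "uncheckable"))))
  structure(out, summary = summ, class = c("va_audit", "data.frame"))
}

#' @export
print.va_audit <- function(x, ...) {
  cat("Minimal-criteria audit of", nrow(x), "certified causes:\n")
  print(attr(x, "summary"))
  invisible(x)
}
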