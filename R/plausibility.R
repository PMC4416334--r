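#' Surveillance tables
#'
#' Regional disease-surveillance counts: one row per region and year with
#' `cases_notified` and optionally `csf_samples_received`,
#' `positive_cultures` and `deaths`. Invariants: counts are non-negative
#' integers, CSF samples do not exceed notified cases, and positive
#' cultures do not exceed samples received.
#'
#' @param data Data frame with the columns above.
#' @return A `va_surveillance` data frame.
#' @export
asSurveillance <- function(data) {
  need <- c("region", "year", "cases_notified")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("surveillance data lacks column(s): ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  for (col in c("cases_notified", "csf_samples_received",
                "positive_cultures", "deaths")) {
    if (is.null(data[[col]])) { data[[col]] <- NA_integer_; next }
    v <- data[[col]]
    if (any(!is.na(v) & (v < 0 | v != round(v))))
      stop("surveillance column ", col, " must hold non-negative integers")
    data[[col]] <- as.integer(v)
  }
  bad <- !is.na(data$csf_samples_received) &
    data$csf_samples_received > data$cases_notified
  if (any(bad)) stop("csf_samples_received exceeds cases_notified")
  bad <- !is.na(data$positive_cultures) & !is.na(data$csf_samples_received) &
    data$positive_cultures > data$csf_samples_received
  if (any(bad)) stop("positive_cultures exceeds csf_samples_received")
  structure(data, class = c("va_surveillance", "data.frame"))
}

#' @param path CSV file path.
#' @rdname asSurveillance
#' @export
readSurveillance <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  asSurveillance(utils::read.csv(path, stringsAsFactors = FALSE,
                                 na.strings = c("", "NA")))
}

#' Maternal infection and early-onset severe neonatal infection
#'
#' The first internal-validity analysis: does maternal infection (as
#' flagged by the maternal algorithm) associate with early-onset (illness
#' onset before day 2 of life) severe neonatal infection? For each cause
#' group — meningitis, pneumonia, sepsis, and the three combined — the
#' early and late onset strata among deaths with that primary cause are
#' cross-tabulated against maternal infection and tested with
#' [twoPropChi2()]; a final contrast compares early-onset severe-infection
#' deaths against all other neonatal deaths.
#'
#' @param cohort Neonatal [asVACohort()] cohort.
#' @param assignments [classify()] result for the cohort.
#' @param maternal Named logical vector from [maternalInfection()].
#' @param severe_causes Cause ids constituting severe infection.
#' @param weighted Report weighted maternal-infection percentages
#'   (unweighted stratum counts are always reported).
#' @return Data frame of class `va_onset`: one row per contrast with
#'   stratum sizes, maternal-infected counts, weighted percentages,
#'   chi-square and p. Empty strata yield `NA` statistics with a flag, not
#'   an error.
#' @export
onsetAssociation <- function(cohort, assignments, maternal,
                             severe_causes = c("meningitis", "pneumonia",
                                               "sepsis"),
                             weighted = TRUE) {
  stopifnot(inherits(cohort, "va_cohort"))
  if (nrow(cohort) && any(cohort$age_group != "neonate"))
    stop("the onset association analysis applies to neonatal cohorts only")
  idx <- match(cohort$death_id, assignments$death_id)
  if (anyNA(idx)) stop("assignments do not cover the cohort")
  primary <- assignments$reporting[idx]
  ms <- maternal[cohort$death_id]
  onset <- earlyOnset(cohort)
  w <- cohort$survey_weight

  groups <- c(as.list(stats::setNames(severe_causes, severe_causes)),
              list(severe_infection_combined = severe_causes))
  rowFor <- function(label, early_sel, late_sel) {
    n_e <- sum(early_sel); n_l <- sum(late_sel)
    ms_e <- sum(ms & early_sel); ms_l <- sum(ms & late_sel)
    pct <- function(sel, num_sel) {
      if (!sum(sel)) return(NA_real_)
      if (weighted) 100 * sum(w[sel & num_sel]) / sum(w[sel])
      else 100 * sum(num_sel & sel) / sum(sel)
    }
    flagged <- n_e == 0 || n_l == 0
    tst <- if (flagged) list(statistic = NA_real_, p_value = NA_real_)
           else twoPropChi2(ms_e, n_e, ms_l, n_l)
    data.frame(group = label, n_early = n_e, maternal_early = ms_e,
               pct_maternal_early = pct(early_sel, ms),
               n_late = n_l, maternal_late = ms_l,
               pct_maternal_late = pct(late_sel, ms),
               chi2 = tst$statistic, p = tst$p_value, empty_stratum = flagged,
               stringsAsFactors = FALSE)
  }
  out <- lapply(names(groups), function(g) {
    in_g <- primary %in% groups[[g]]
    rowFor(g, in_g & onset == "early", in_g & onset == "late")
  })
  severe_early <- primary %in% severe_causes & onset == "early"
  out <- c(out, list(rowFor("severe_early_vs_all_other",
                            severe_early, !severe_early)))
  res <- do.call(rbind, out)
  structure(res, class = c("va_onset", "data.frame"))
}

#' @export
print.va_onset <- function(x, ...) {
  cat("Maternal infection vs early-onset neonatal infection\n")
  df <- x
  for (col in intersect(c("pct_maternal_early", "pct_maternal_late", "chi2"),
                        names(df)))
    df[[col]] <- round(df[[col]], 2)
  if ("p" %in% names(df)) df$p <- signif(df$p, 3)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Regional meningitis ecological comparison
#'
#' The second internal-validity analysis: within each region, the
#' VA-diagnosed meningitis-specific proportional mortality among child
#' deaths (weighted meningitis deaths over weighted all-cause child deaths
#' in the region) is set against the region's share of the whole country's
#' surveillance-detected meningitis cases (and deaths, when reported).
#' Proportional mortality — rather than each region's share of VA
#' meningitis deaths — is used because the latter would be driven by the
#' regional population distribution. A Spearman rank correlation between
#' proportional mortality and the case share is attached as a quantitative
#' summary, with small-denominator regions (fewer than `min_denominator`
#' deaths) flagged since their proportions are unstable.
#'
#' @param cohort Child [asVACohort()] cohort.
#' @param assignments [classify()] result; the primary cause is used, as
#'   the assessment targets the cause reportable for vital statistics.
#' @param surveillance A [asSurveillance()] table.
#' @param cause Cause id counted as meningitis.
#' @param min_denominator Flag regions with fewer (unweighted) deaths.
#' @return Data frame of class `va_regional`: per region the child death
#'   counts, VA meningitis deaths, proportional mortality (%), the
#'   surveillance shares (%), and a small-denominator flag. Attributes:
#'   `spearman` (correlation of proportional mortality with case share)
#'   and `spearman_excl_flagged`.
#' @export
regionalMeningitis <- function(cohort, assignments, surveillance,
                               cause = "meningitis", min_denominator = 20) {
  stopifnot(inherits(cohort, "va_cohort"),
            inherits(surveillance, "va_surveillance"))
  idx <- match(cohort$death_id, assignments$death_id)
  if (anyNA(idx)) stop("assignments do not cover the cohort")
  primary <- assignments$reporting[idx]
  w <- cohort$survey_weight
  sv <- stats::aggregate(
    cbind(cases_notified, deaths) ~ region, data = surveillance,
    FUN = function(v) sum(v, na.rm = TRUE), na.action = stats::na.pass)
  total_cases <- sum(sv$cases_notified)
  total_deaths <- sum(sv$deaths)
  if (total_cases <= 0) stop("surveillance case total must be positive")
  regions <- sort(unique(c(cohort$region, sv$region)))
  rows <- lapply(regions, function(rg) {
    sel <- cohort$region == rg
    n <- sum(sel)
    men <- primary == cause & sel
    pm <- if (sum(w[sel]) > 0) 100 * sum(w[men]) / sum(w[sel]) else NA_real_
    j <- match(rg, sv$region)
    data.frame(region = rg, child_deaths = n,
               meningitis_deaths = sum(men),
               proportional_mortality = pm,
               surveillance_case_share =
                 if (is.na(j)) NA_real_
                 else 100 * sv$cases_notified[j] / total_cases,
               surveillance_death_share =
                 if (is.na(j) || total_deaths <= 0) NA_real_
                 else 100 * sv$deaths[j] / total_deaths,
               small_denominator = n < min_denominator,
               missing_surveillance = is.na(j),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$proportional_mortality) &
    !is.na(out$surveillance_case_share)
  # a constant profile has no rank correlation: report NA, not a warning
  spear <- function(sel) {
    x <- out$proportional_mortality[sel]
    y <- out$surveillance_case_share[sel]
    if (sum(sel) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
      return(NA_real_)
    stats::cor(x, y, method = "spearman")
  }
  rho <- spear(ok)
  rho2 <- spear(ok & !out$small_denominator)
  structure(out, spearman = rho, spearman_excl_flagged = rho2,
            class = c("va_regional", "data.frame"))
}

#' @export
print.va_regional <- function(x, ...) {
  cat("Regional meningitis: VA proportional mortality vs surveillance\n")
  df <- x
  for (col in intersect(c("proportional_mortality",
                          "surveillance_case_share",
                          "surveillance_death_share"), names(df)))
    df[[col]] <- round(df[[col]], 1)
  print.data.frame(df, row.names = FALSE)
  cat("Spearman (all regions): ", round(attr(x, "spearman"), 2),
      "; excluding small denominators: ",
      round(attr(x, "spearman_excl_flagged"), 2), "\n", sep = "")
  invisible(x)
}

#' Paired-bar chart of the regional comparison
#'
#' Base-graphics grouped bar chart of surveillance shares and VA
#' proportional mortality per region.
#'
#' @param x A [regionalMeningitis()] result.
#' @param file Optional PNG path; when given the plot is written there.
#' @return `x`, invisibly.
#' @export
plotRegionalComparison <- function(x, file = NULL) {
  stopifnot(inherits(x, "va_regional"))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  m <- t(as.matrix(x[, c("surveillance_case_share",
                         "surveillance_death_share",
                         "proportional_mortality")]))
  colnames(m) <- x$region
  graphics::barplot(m, beside = TRUE, las = 2,
                    legend.text = c("surveillance cases (% of national)",
                                    "surveillance deaths (% of national)",
                                    "VA meningitis proportional mortality (%)"),
                    args.legend = list(x = "topright", cex = 0.8),
                    ylab = "percent")
  invisible(x)
}
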