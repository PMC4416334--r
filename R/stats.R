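#' Survey-weighted cause-specific mortality fractions
#'
#' The cause-specific mortality fraction (CSMF) for cause X is the
#' weighted share of deaths assigned X: sum of survey weights of deaths
#' with cause X over the sum of all weights, expressed in percent. Counts
#' are reported unweighted. Confidence intervals are Wilson intervals
#' computed on the Kish effective sample size
#' \eqn{n_{eff} = (\sum w)^2 / \sum w^2}, a design-effect adjustment that
#' respects cluster weighting without requiring replicate weights; the CI
#' method is deliberately swappable via `ci_method`.
#'
#' @param cohort A [asVACohort()] cohort.
#' @param assignments A [classify()] result (or any data frame with
#'   `death_id` and the column named by `cause_field`) covering every
#'   record.
#' @param cause_field Which assignment column to tabulate: `"reporting"`
#'   (default; possible tiers merged into their probable counterparts, as
#'   used for final distributions) or `"primary"`.
#' @param causes Optional cause universe (character); defaults to every
#'   cause observed plus `"unspecified"`.
#' @param conf_level Confidence level for the interval.
#' @param ci_method `"wilson_kish"` (default) or `"wilson"` (no
#'   design-effect adjustment).
#' @return A data frame of class `va_csmf`: `cause`, `n` (unweighted
#'   count), `percent`, `ci_low`, `ci_high`; attributes `N` (deaths),
#'   `n_eff` and `age_group`. Percentages sum to 100 across the cause
#'   universe.
#' @examples
#' cfg <- generatorConfig("neonate", n = 200, seed = 3)
#' rec <- generateCohort(cfg)$records
#' a <- classify(rec)
#' weightedCSMF(rec, a)
#' @export
weightedCSMF <- function(cohort, assignments, cause_field = "reporting",
                         causes = NULL, conf_level = 0.95,
                         ci_method = c("wilson_kish", "wilson")) {
  stopifnot(inherits(cohort, "va_cohort"))
  ci_method <- match.arg(ci_method)
  idx <- match(cohort$death_id, assignments$death_id)
  if (anyNA(idx))
    stop("no assignment for death_id(s): ",
         paste(utils::head(cohort$death_id[is.na(idx)], 5), collapse = ", "))
  val <- assignments[[cause_field]][idx]
  w <- cohort$survey_weight
  if (any(is.na(w) | w <= 0)) stop("survey weights must be positive")
  if (is.null(causes)) causes <- union(unique(val), "unspecified")
  val <- factor(val, levels = causes)
  if (anyNA(val)) stop("assignment value outside the cause universe")
  W <- sum(w)
  n_eff <- W^2 / sum(w^2)
  n_eff_used <- if (ci_method == "wilson_kish") n_eff else nrow(cohort)
  wshare <- tapply(w, val, sum, default = 0) / W
  cnt <- as.integer(table(val))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- wilsonInterval(wshare, n_eff_used, z)
  out <- data.frame(cause = causes, n = cnt,
                    percent = 100 * as.numeric(wshare),
                    ci_low = 100 * ci$low, ci_high = 100 * ci$high,
                    stringsAsFactors = FALSE)
  structure(out, N = nrow(cohort), n_eff = n_eff,
            age_group = if (nrow(cohort)) cohort$age_group[1] else NA,
            class = c("va_csmf", "data.frame"))
}

# Wilson score interval for a proportion p at effective size n.
wilsonInterval <- function(p, n, z) {
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' @export
print.va_csmf <- function(x, digits = 1, ...) {
  cat("Cause-specific mortality fractions (N = ", attr(x, "N"),
      ", effective n = ", round(attr(x, "n_eff"), 1), ")\n", sep = "")
  df <- x
  for (col in intersect(c("percent", "ci_low", "ci_high"), names(df)))
    df[[col]] <- round(df[[col]], digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Two-proportion chi-square test
#'
#' Pearson chi-square for the difference of two independent proportions,
#' with no continuity correction:
#' \deqn{\chi^2 = (p_1 - p_2)^2 / [\bar p (1 - \bar p)(1/n_1 + 1/n_2)]}
#' with \eqn{\bar p = (x_1 + x_2)/(n_1 + n_2)}. The default p-value is the
#' asymptotic one (1 d.f.); `midp = TRUE` additionally computes the exact
#' conditional mid-p value, which halves the probability of the observed
#' table in the two-sided tail sum. Degenerate pooled proportions (0 or 1)
#' give a statistic of 0 and p = 1.
#'
#' @param x1,n1 Successes and size of group 1.
#' @param x2,n2 Successes and size of group 2.
#' @param midp Also compute the exact mid-p value?
#' @return A list of class `va_test`: `statistic`, `p_value`,
#'   `p_value_midp` (`NA` unless requested), `method` and the inputs.
#' @examples
#' twoPropChi2(18, 453, 2, 453)   # chi-square 13.1
#' @export
twoPropChi2 <- function(x1, n1, x2, n2, midp = FALSE) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pbar <- (x1 + x2) / (n1 + n2)
  if (pbar <= 0 || pbar >= 1) {
    stat <- 0
    p <- 1
  } else {
    p1 <- x1 / n1
    p2 <- x2 / n2
    stat <- (p1 - p2)^2 / (pbar * (1 - pbar) * (1 / n1 + 1 / n2))
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  pm <- NA_real_
  if (midp) pm <- midpExact(x1, n1, x2, n2)
  structure(list(statistic = stat, p_value = p, p_value_midp = pm,
                 method = if (midp) "Pearson chi-square (mid-p exact p)"
                          else "Pearson chi-square (asymptotic p)",
                 x1 = x1, n1 = n1, x2 = x2, n2 = n2),
            class = "va_test")
}

# Two-sided exact conditional mid-p for a 2x2 table: probability-ordering
# tail sum over the hypergeometric distribution of x1 given the margins,
# counting the observed table at half weight.
midpExact <- function(x1, n1, x2, n2) {
  k <- x1 + x2
  support <- max(0, k - n2):min(k, n1)
  pr <- stats::dhyper(support, n1, n2, k)
  pobs <- stats::dhyper(x1, n1, n2, k)
  eps <- 1e-12
  sum(pr[pr < pobs - eps]) + 0.5 * sum(pr[abs(pr - pobs) <= eps])
}

#' @export
print.va_test <- function(x, ...) {
  cat(x$method, "\n  x1/n1 = ", x$x1, "/", x$n1,
      ", x2/n2 = ", x$x2, "/", x$n2, "\n", sep = "")
  cat("  chi-square = ", format(round(x$statistic, 2)),
      ", p = ", format.pval(x$p_value, digits = 3), sep = "")
  if (!is.na(x$p_value_midp))
    cat(", mid-p = ", format.pval(x$p_value_midp, digits = 3), sep = "")
  cat("\n")
  invisible(x)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement between two binary classifications from the
#' cells a (both positive), b (method 1 only), c (method 2 only), d (both
#' negative): observed agreement \eqn{p_o = (a+d)/N}, chance agreement
#' \eqn{p_e = [(a+b)(a+c) + (c+d)(b+d)]/N^2}, and
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}. The CI uses the large-sample
#' standard error \eqn{\sqrt{p_o(1-p_o)}/[\sqrt N (1-p_e)]}. Agreement
#' grades follow the conventional bands with strictly-greater boundaries:
#' kappa > 0.80 excellent, > 0.60 good, > 0.40 moderate, > 0.20 fair,
#' otherwise poor (less-than-chance when kappa is at or below 0). Cells
#' may be survey-weighted totals; the formula is unchanged.
#'
#' @param a,b,c,d Non-negative cell counts (or weighted totals).
#' @param conf_level Confidence level.
#' @return A list of class `va_kappa`: `kappa`, `se`, `ci` (length 2),
#'   `grade`, `po`, `pe` and the cells.
#' @examples
#' cohenKappa(58, 18, 0, 544)    # kappa 0.85, excellent
#' @export
cohenKappa <- function(a, b, c, d, conf_level = 0.95) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  N <- a + b + c + d
  if (N <= 0) stop("empty agreement table")
  po <- (a + d) / N
  pe <- ((a + b) * (a + c) + (c + d) * (b + d)) / N^2
  if (1 - pe < .Machine$double.eps) {
    if (po >= 1 - .Machine$double.eps) {
      kappa <- 1; se <- 0
    } else stop("degenerate margins: chance agreement is 1 but observed is not")
  } else {
    kappa <- (po - pe) / (1 - pe)
    se <- sqrt(po * (1 - po) / N) / (1 - pe)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(-1, kappa - z * se), min(1, kappa + z * se))
  grade <- if (kappa > 0.8) "excellent" else if (kappa > 0.6) "good"
    else if (kappa > 0.4) "moderate" else if (kappa > 0.2) "fair"
    else if (kappa > 0) "poor" else "less-than-chance"
  structure(list(kappa = kappa, se = se, ci = ci, grade = grade,
                 po = po, pe = pe, cells = c(a = a, b = b, c = c, d = d)),
            class = "va_kappa")
}

#' @export
print.va_kappa <- function(x, ...) {
  cat("Cohen's kappa: ", round(x$kappa, 2), " (95% CL ",
      round(x$ci[1], 2), ", ", round(x$ci[2], 2), ") — ", x$grade,
      " agreement\n", sep = "")
  cat("  cells (a,b,c,d): ", paste(round(x$cells, 2), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' 2x2 agreement cells for one cause across two cause-set assignments
#'
#' Builds the agreement table for a single cause between two per-death
#' cause sets (e.g. the combined algorithmic cause versus the combined
#' physician cause): a = deaths where both sets contain the cause,
#' b = first only, c = second only, d = neither.
#'
#' @param sets1,sets2 Named lists (by `death_id`) of character cause sets
#'   over the same death universe.
#' @param cause The cause id to tabulate.
#' @return Named integer vector `c(a, b, c, d)`.
#' @export
agreementTable <- function(sets1, sets2, cause) {
  ids1 <- sort(names(sets1))
  ids2 <- sort(names(sets2))
  if (!identical(ids1, ids2))
    stop("the two assignments cover different death universes")
  in1 <- vapply(sets1[ids1], function(s) cause %in% s, logical(1))
  in2 <- vapply(sets2[ids1], function(s) cause %in% s, logical(1))
  c(a = sum(in1 & in2), b = sum(in1 & !in2),
    c = sum(!in1 & in2), d = sum(!in1 & !in2))
}

#' Per-death cause sets from assignments or certificates
#'
#' Convenience extractors feeding [agreementTable()]: the combined
#' algorithmic cause (primary plus co-morbid) per death, and the combined
#' physician cause per death.
#'
#' @param assignments A [classify()] result.
#' @return Named list of character vectors keyed by `death_id`.
#' @export
combinedAlgorithmicCause <- function(assignments) {
  stats::setNames(assignments$combined, assignments$death_id)
}

#' Rank-order comparison of two cause distributions
#'
#' Dense ranks by descending mortality fraction within each distribution,
#' leaving aside unspecified deaths, with the per-cause rank difference.
#' Ties are broken by cause-list order and flagged.
#'
#' @param dist1,dist2 Two [weightedCSMF()] tables over a shared cause list.
#' @param exclude Causes excluded from ranking (default `"unspecified"`).
#' @return Data frame: `cause`, `percent1`, `percent2`, `rank1`, `rank2`,
#'   `rank_diff`; attribute `ties` flags any tied proportions.
#' @export
rankComparison <- function(dist1, dist2, exclude = "unspecified") {
  shared <- intersect(dist1$cause, dist2$cause)
  shared <- setdiff(shared, exclude)
  if (!length(shared)) stop("no shared causes to rank")
  p1 <- dist1$percent[match(shared, dist1$cause)]
  p2 <- dist2$percent[match(shared, dist2$cause)]
  denseRank <- function(p) {
    o <- order(-p, seq_along(p))   # ties broken by cause-list order
    r <- integer(length(p))
    r[o] <- seq_along(p)
    match(r, sort(unique(r)))
  }
  out <- data.frame(cause = shared, percent1 = p1, percent2 = p2,
                    rank1 = denseRank(p1), rank2 = denseRank(p2),
                    stringsAsFactors = FALSE)
  out$rank_diff <- out$rank1 - out$rank2
  ties <- anyDuplicated(p1) > 0 || anyDuplicated(p2) > 0
  structure(out, ties = ties)
}

#' Cause-by-cause comparison of two distributions
#'
#' Table of mortality fractions from two methods with the two-proportion
#' chi-square per cause, computed from the unweighted counts.
#'
#' @param dist1,dist2 Two [weightedCSMF()] tables (their `N` attributes
#'   give the group sizes).
#' @param labels Length-2 method labels.
#' @param midp Compute mid-p exact p-values as well?
#' @return Data frame with percent and CI columns for each method,
#'   `chi2` and `p` per cause.
#' @export
compareCSMF <- function(dist1, dist2, labels = c("method1", "method2"),
                        midp = FALSE) {
  shared <- intersect(dist1$cause, dist2$cause)
  n1 <- attr(dist1, "N")
  n2 <- attr(dist2, "N")
  rows <- lapply(shared, function(cz) {
    i <- match(cz, dist1$cause)
    j <- match(cz, dist2$cause)
    tst <- twoPropChi2(dist1$n[i], n1, dist2$n[j], n2, midp = midp)
    data.frame(cause = cz,
               pct1 = dist1$percent[i], lo1 = dist1$ci_low[i],
               hi1 = dist1$ci_high[i],
               pct2 = dist2$percent[j], lo2 = dist2$ci_low[j],
               hi2 = dist2$ci_high[j],
               chi2 = tst$statistic, p = tst$p_value,
               p_midp = tst$p_value_midp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("cause",
                  paste0(labels[1], c("_percent", "_ci_low", "_ci_high")),
                  paste0(labels[2], c("_percent", "_ci_low", "_ci_high")),
                  "chi2", "p", "p_midp")
  out
}
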