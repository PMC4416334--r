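#' Pipeline run configuration
#'
#' Bundles the inputs of a full analysis run: record/certificate/
#' surveillance paths (or in-memory objects), rule-set and hierarchy
#' paths, output directory and options. Referenced paths must exist at
#' construction time.
#'
#' @param records Path to a record file, or a [asVACohort()] cohort.
#' @param certificates Optional path to a certificate file, or a
#'   [asCertificates()] object; when absent the EAVA-vs-PCVA comparison
#'   stages are skipped with a warning.
#' @param surveillance Optional path to a surveillance CSV, or a
#'   [asSurveillance()] table; needed for the regional meningitis stage.
#' @param ruleset,hierarchy Optional paths to rule-set/hierarchy files;
#'   defaults to the shipped configuration for the cohort's age group.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest and used for any resampling.
#' @param format `"csv"` or `"json"` for the output tables.
#' @return A list of class `va_runconfig`.
#' @export
pipelineConfig <- function(records, certificates = NULL, surveillance = NULL,
                           ruleset = NULL, hierarchy = NULL,
                           out_dir = "va_output", seed = 1L,
                           format = c("csv", "json")) {
  format <- match.arg(format)
  for (p in c(if (is.character(records)) records,
              if (is.character(certificates)) certificates,
              if (is.character(surveillance)) surveillance,
              ruleset, hierarchy))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(records = records, certificates = certificates,
                 surveillance = surveillance, ruleset = ruleset,
                 hierarchy = hierarchy, out_dir = out_dir,
                 seed = as.integer(seed), format = format),
            class = "va_runconfig")
}

#' Run the full verbal autopsy analysis pipeline
#'
#' Stages: read and validate the records; classify every death with the
#' expert algorithms and hierarchy; tabulate the weighted EAVA cause
#' distribution; when certificates are present, extract PCVA underlying
#' and combined causes, tabulate the PCVA distribution, compare the
#' distributions (chi-square per cause) and compute per-cause kappa
#' agreement; for neonatal cohorts run the maternal-infection onset
#' association, and for child cohorts with surveillance data the regional
#' meningitis comparison. All tables are written to the output directory
#' together with a run manifest (rule-set version, seed, cohort counts,
#' file list with content hashes). Reruns with identical inputs produce
#' byte-identical outputs.
#'
#' @param config A [pipelineConfig()] object.
#' @return Invisibly, a list with every computed table plus the manifest.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "va_runconfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  vocab <- defaultVocabulary()
  records <- if (is.character(config$records))
    readVARecords(config$records, vocab) else config$records
  if (!nrow(records)) stop("the record file holds no deaths")
  age <- records$age_group[1]
  ruleset <- if (is.null(config$ruleset)) defaultRuleset(age)
             else readRuleset(config$ruleset, vocab)
  hierarchy <- if (is.null(config$hierarchy)) defaultHierarchy(age)
               else readHierarchy(config$hierarchy, ruleset)

  validation <- validateCohort(records)
  assignments <- classify(records, ruleset, hierarchy)
  eava_dist <- weightedCSMF(records, assignments,
                            causes = c(unique(mergePossible(
                              hierarchy$causes, ruleset)), "unspecified"))
  out <- list(validation = validation, assignments = assignments,
              eava_csmf = eava_dist)

  certificates <- if (is.character(config$certificates))
    readCertificates(config$certificates) else config$certificates
  if (!is.null(certificates)) {
    und <- underlyingCause(certificates)
    pcva_assign <- data.frame(death_id = und$death_id,
                              reporting = und$underlying,
                              stringsAsFactors = FALSE)
    pcva_dist <- weightedCSMF(records, pcva_assign,
                              causes = union(eava_dist$cause,
                                             unique(und$underlying)))
    comparison <- compareCSMF(eava_dist, pcva_dist,
                              labels = c("eava", "pcva"))
    ranks <- rankComparison(eava_dist, pcva_dist)
    sets_e <- combinedAlgorithmicCause(assignments)
    sets_e <- lapply(sets_e, function(s) unique(mergePossible(s, ruleset)))
    sets_p <- combinedPhysicianCause(certificates)
    sets_p <- sets_p[names(sets_e)]
    names(sets_p) <- names(sets_e)
    agree <- do.call(rbind, lapply(
      setdiff(eava_dist$cause, "unspecified"), function(cz) {
        cells <- agreementTable(sets_e, sets_p, cz)
        k <- cohenKappa(cells["a"], cells["b"], cells["c"], cells["d"])
        data.frame(cause = cz, a = cells["a"], b = cells["b"],
                   c = cells["c"], d = cells["d"], kappa = k$kappa,
                   ci_low = k$ci[1], ci_high = k$ci[2], grade = k$grade,
                   stringsAsFactors = FALSE, row.names = NULL)
      }))
    out$pcva_csmf <- pcva_dist
    out$comparison <- comparison
    out$ranks <- ranks
    out$agreement <- agree
  } else {
    warning("no certificates supplied: EAVA-vs-PCVA comparison stages skipped")
  }

  if (age == "neonate") {
    ms <- maternalInfection(records, ruleset$maternal %||%
                              defaultRuleset("neonate")$maternal)
    out$onset_association <- onsetAssociation(records, assignments, ms)
  }
  surveillance <- if (is.character(config$surveillance))
    readSurveillance(config$surveillance) else config$surveillance
  if (age == "child" && !is.null(surveillance)) {
    out$regional <- regionalMeningitis(records, assignments, surveillance)
  }

  # write tables + manifest
  files <- character()
  writeTable <- function(obj, name) {
    path <- file.path(config$out_dir, paste0(name, ".", config$format))
    df <- as.data.frame(obj)
    df <- df[, !vapply(df, is.list, logical(1)), drop = FALSE]
    if (config$format == "csv")
      utils::write.csv(df, path, row.names = FALSE, na = "")
    else jsonlite::write_json(df, path, dataframe = "rows",
                              auto_unbox = TRUE, digits = NA)
    files <<- c(files, path)
  }
  writeTable(out$eava_csmf, "eava_csmf")
  writeTable(data.frame(out$assignments[c("death_id", "primary",
                                          "reporting")],
                        comorbid = vapply(out$assignments$comorbid,
                                          paste, "", collapse = ";")),
             "assignments")
  if (nrow(validation)) writeTable(validation, "validation")
  for (nm in c("pcva_csmf", "comparison", "ranks", "agreement",
               "onset_association", "regional"))
    if (!is.null(out[[nm]])) writeTable(out[[nm]], nm)

  manifest <- list(
    package_version = as.character(utils::packageVersion("vacause")),
    ruleset_version = ruleset$version,
    age_group = age, seed = config$seed,
    n_deaths = nrow(records), n_violations = nrow(validation),
    n_certificates = if (is.null(certificates)) 0L
                     else length(unique(certificates$death_id)),
    stages_skipped = if (is.null(certificates)) "comparison" else character(),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f))))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
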