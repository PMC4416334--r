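#' Synthetic VA cohort generator configuration
#'
#' Builds a fully specified generator configuration with known truth, so
#' every pipeline stage can be exercised without field data. The defaults
#' emulate the structure of a national two-stage cluster mortality survey:
#' cohort sizes of 453 neonatal or 620 child deaths, eight regions with a
#' realistic population spread, cluster-level weight dispersion, per-cause
#' sign profiles that make the default rule set recover the cause, explicit
#' co-morbidity couplings (e.g. sepsis signs overlaid on meningitis
#' deaths), a maternal-infection model with a tunable odds multiplier for
#' early-onset severe-infection deaths, and a physician-behaviour model
#' that certifies from truth with noise (including diagnosing at the
#' minimal-criteria floor) so agreement statistics are nontrivial.
#'
#' @param age_group `"neonate"` or `"child"`.
#' @param n Cohort size; defaults to 453 neonates / 620 children.
#' @param seed Integer seed recorded in the config; [generateCohort()] is
#'   reproducible given the seed.
#' @param csmf Named numeric vector of true cause fractions (must sum
#'   to 1); defaults to a plausible distribution over the default cause
#'   list including `"unspecified"`.
#' @param profiles Per-cause sign profiles; see [defaultSignProfiles()].
#' @param couplings List of co-morbidity couplings, each
#'   `list(cause=, overlay=, p=)`: with probability `p` a death from
#'   `cause` also carries the sign profile of `overlay` and `overlay` is
#'   recorded as a true co-morbid cause.
#' @param background_p Probability that any sign not in the active profile
#'   is reported present anyway (reporting noise).
#' @param missingness Probability that a sign response is missing.
#' @param duration_noise If `TRUE` durations are Poisson around the
#'   profile mean; if `FALSE` they equal the profile value exactly.
#' @param n_clusters,weight_dispersion Survey design: number of clusters
#'   and the log-scale standard deviation of cluster weights
#'   (0 = equal weights).
#' @param regions Named probability vector over region names.
#' @param onset Named list per cause: `p_early` (probability of illness
#'   onset before day 2, neonates) — remaining onsets are late.
#' @param maternal List: `baseline` infection probability, the
#'   `odds_multiplier` applied to early-onset severe-infection deaths,
#'   sign sensitivity `sens` and false-positive rate `fp`.
#' @param physician List: `accuracy` (probability the certified underlying
#'   cause equals truth), `floor_prob` (when wrong, probability of picking
#'   a cause whose minimal criteria the record satisfies), `chain_p`
#'   (probability of certifying a direct cause above the underlying one),
#'   `contrib_p` (probability each remaining true co-morbid cause is
#'   listed in part 2), `maternal_record_p` (probability a true maternal
#'   infection is certified beneath the child causes).
#' @return A validated list of class `va_genconfig`.
#' @examples
#' cfg <- generatorConfig("neonate", n = 100, seed = 1)
#' out <- generateCohort(cfg)
#' table(out$truth$true_cause)
#' @export
generatorConfig <- function(age_group = c("neonate", "child"),
                            n = NULL, seed = 1L,
                            csmf = NULL,
                            profiles = NULL,
                            couplings = NULL,
                            background_p = 0.02,
                            missingness = 0.05,
                            duration_noise = TRUE,
                            n_clusters = 50L,
                            weight_dispersion = 0.25,
                            regions = NULL,
                            onset = NULL,
                            maternal = list(),
                            physician = list()) {
  age_group <- match.arg(age_group)
  n <- n %||% if (age_group == "neonate") 453L else 620L
  csmf <- csmf %||% defaultCSMF(age_group)
  profiles <- profiles %||% defaultSignProfiles(age_group)
  couplings <- couplings %||% defaultCouplings(age_group)
  regions <- regions %||% defaultRegions()
  onset <- onset %||% defaultOnset(age_group)
  maternal <- utils::modifyList(
    list(baseline = 0.15, odds_multiplier = 1, sens = 0.9, fp = 0.02),
    maternal)
  physician <- utils::modifyList(
    list(accuracy = 0.75, floor_prob = 0.6, chain_p = 0.4,
         contrib_p = 0.6, maternal_record_p = 0.8),
    physician)

  if (n < 0) stop("cohort size must be non-negative")
  if (abs(sum(csmf) - 1) > 1e-8) stop("true CSMF must sum to 1")
  if (any(csmf < 0)) stop("CSMF fractions must be non-negative")
  unknown <- setdiff(names(csmf), c(defaultHierarchyCauses(age_group),
                                    "unspecified"))
  if (length(unknown))
    stop("CSMF names outside the default cause list: ",
         paste(unknown, collapse = ", "),
         " (supply matching profiles and rules for custom causes)")
  probs <- c(background_p, missingness, maternal$baseline, maternal$sens,
             maternal$fp, physician$accuracy, physician$floor_prob,
             physician$chain_p, physician$contrib_p,
             physician$maternal_record_p, unlist(regions))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (maternal$odds_multiplier < 1)
    stop("the maternal odds multiplier must be >= 1")
  for (cp in couplings)
    if (cp$p < 0 || cp$p > 1) stop("coupling probabilities must lie in [0,1]")
  if (abs(sum(regions) - 1) > 1e-8) stop("region probabilities must sum to 1")
  structure(list(age_group = age_group, n = as.integer(n),
                 seed = as.integer(seed), csmf = csmf, profiles = profiles,
                 couplings = couplings, background_p = background_p,
                 missingness = missingness, duration_noise = duration_noise,
                 n_clusters = as.integer(n_clusters),
                 weight_dispersion = weight_dispersion,
                 regions = regions, onset = onset, maternal = maternal,
                 physician = physician),
            class = "va_genconfig")
}

#' @export
print.va_genconfig <- function(x, ...) {
  cat("Synthetic cohort config: ", x$n, " ", x$age_group, " deaths, seed ",
      x$seed, "\n  causes: ", paste(names(x$csmf), collapse = ", "),
      "\n  maternal odds multiplier: ", x$maternal$odds_multiplier,
      ", missingness: ", x$missingness, "\n", sep = "")
  invisible(x)
}

defaultHierarchyCauses <- function(age_group) {
  # kept in sync with the shipped hierarchies; avoids a file read in the
  # config validator
  if (age_group == "neonate")
    c("neonatal_tetanus", "congenital_malformation", "birth_injury_asphyxia",
      "meningitis", "diarrhea", "pneumonia", "sepsis", "neonatal_jaundice",
      "hemorrhagic_disease", "sudden_unexplained_death", "preterm_delivery")
  else
    c("injury", "aids", "malnutrition", "measles", "meningitis", "dysentery",
      "diarrhea", "pertussis", "pneumonia", "malaria", "hemorrhagic_fever",
      "possible_dysentery", "possible_diarrhea", "possible_pneumonia",
      "possible_malaria", "other_infections")
}

#' Default true cause fractions for the generator
#'
#' A plausible high-mortality-setting cause mix over the default cause
#' lists; deliberately generic — the generator emulates the *structure* of
#' a VA study, not any particular country's observed distribution.
#'
#' @inheritParams generatorConfig
#' @return Named numeric vector summing to 1.
#' @export
defaultCSMF <- function(age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  if (age_group == "neonate")
    c(neonatal_tetanus = 0.03, congenital_malformation = 0.02,
      birth_injury_asphyxia = 0.20, meningitis = 0.05, diarrhea = 0.05,
      pneumonia = 0.12, sepsis = 0.30, neonatal_jaundice = 0.01,
      hemorrhagic_disease = 0.01, sudden_unexplained_death = 0.02,
      preterm_delivery = 0.09, unspecified = 0.10)
  else
    c(injury = 0.02, aids = 0.02, malnutrition = 0.04, measles = 0.03,
      meningitis = 0.12, dysentery = 0.05, diarrhea = 0.16,
      pertussis = 0.02, pneumonia = 0.14, malaria = 0.25,
      hemorrhagic_fever = 0.01, other_infections = 0.06,
      unspecified = 0.08)
}

#' Default per-cause sign profiles
#'
#' For each cause, the probability that each relevant sign is reported
#' present given the cause (conditional-independence Bernoulli), the mean
#' reported duration in days where the rule uses one, and any fixed record
#' fields (e.g. pregnancy duration for preterm delivery). Signs not listed
#' are reported at the background rate.
#'
#' @inheritParams generatorConfig
#' @return Named list: cause id -> list(signs = list(key -> list(p, dur)),
#'   fields = list()).
#' @export
defaultSignProfiles <- function(age_group = c("neonate", "child")) {
  age_group <- match.arg(age_group)
  S <- function(...) list(...)
  sg <- function(p, dur = NULL) list(p = p, dur = dur)
  if (age_group == "neonate") list(
    neonatal_tetanus = list(signs = S(
      suckled_normally_first_2d = sg(0.95), stopped_suckling = sg(0.95),
      convulsions = sg(0.9), spasms = sg(0.6))),
    congenital_malformation = list(signs = S(malformation = sg(0.95))),
    birth_injury_asphyxia = list(signs = S(
      not_breathe_at_birth = sg(0.85), not_cry_at_birth = sg(0.80))),
    meningitis = list(signs = S(
      bulging_fontanelle = sg(0.85), stiff_neck = sg(0.45),
      lethargy = sg(0.85), fever = sg(0.80))),
    diarrhea = list(signs = S(loose_stools = sg(0.95, dur = 3),
                              vomiting = sg(0.4))),
    pneumonia = list(signs = S(
      fast_breathing = sg(0.90, dur = 4),
      difficult_breathing = sg(0.60, dur = 4), chest_indrawing = sg(0.50),
      fever = sg(0.5))),
    sepsis = list(signs = S(fever = sg(0.85), stopped_suckling = sg(0.70),
                            lethargy = sg(0.70))),
    neonatal_jaundice = list(signs = S(yellow_skin = sg(0.95),
                                       yellow_eyes = sg(0.90))),
    hemorrhagic_disease = list(signs = S(bleeding = sg(0.95))),
    sudden_unexplained_death = list(signs = S(died_suddenly = sg(0.95))),
    preterm_delivery = list(signs = S(grunting = sg(0.5),
                                      chest_indrawing = sg(0.4)),
                            fields = list(pregnancy_duration = 7)),
    unspecified = list(signs = S())
  ) else list(
    injury = list(signs = S(injury_event = sg(0.95))),
    aids = list(signs = S(wasting = sg(0.9), oral_thrush = sg(0.8),
                          swollen_glands = sg(0.5),
                          loose_stools = sg(0.5, dur = 20))),
    malnutrition = list(signs = S(wasting = sg(0.85), edema_feet = sg(0.4))),
    measles = list(signs = S(fever = sg(0.95), rash = sg(0.95),
                             cough = sg(0.6), red_eyes = sg(0.6))),
    meningitis = list(signs = S(fever = sg(0.9), stiff_neck = sg(0.7),
                                bulging_fontanelle = sg(0.4),
                                convulsions = sg(0.5), unconscious = sg(0.3))),
    dysentery = list(signs = S(loose_stools = sg(0.95, dur = 4),
                               blood_in_stool = sg(0.9))),
    diarrhea = list(signs = S(loose_stools = sg(0.95, dur = 4),
                              vomiting = sg(0.4))),
    pertussis = list(signs = S(cough = sg(0.95, dur = 21),
                               whooping_cough = sg(0.8),
                               post_tussive_vomiting = sg(0.5))),
    pneumonia = list(signs = S(cough = sg(0.9),
                               fast_breathing = sg(0.85, dur = 4),
                               difficult_breathing = sg(0.6, dur = 4),
                               chest_indrawing = sg(0.5), fever = sg(0.7))),
    malaria = list(signs = S(fever = sg(0.95), convulsions = sg(0.6),
                             unconscious = sg(0.4))),
    hemorrhagic_fever = list(signs = S(fever = sg(0.9), bleeding = sg(0.85))),
    other_infections = list(signs = S(fever = sg(0.9))),
    unspecified = list(signs = S())
  )
}

defaultCouplings <- function(age_group) {
  if (age_group == "neonate") list(
    list(cause = "meningitis", overlay = "sepsis", p = 0.9),
    list(cause = "pneumonia", overlay = "sepsis", p = 0.8),
    list(cause = "diarrhea", overlay = "sepsis", p = 0.8),
    list(cause = "birth_injury_asphyxia", overlay = "sepsis", p = 0.6),
    list(cause = "birth_injury_asphyxia", overlay = "pneumonia", p = 0.3),
    list(cause = "sepsis", overlay = "preterm_delivery", p = 0.1)
  ) else list(
    list(cause = "meningitis", overlay = "diarrhea", p = 0.4),
    list(cause = "meningitis", overlay = "pneumonia", p = 0.4),
    list(cause = "malaria", overlay = "pneumonia", p = 0.2),
    list(cause = "malaria", overlay = "diarrhea", p = 0.1),
    list(cause = "diarrhea", overlay = "pneumonia", p = 0.25),
    list(cause = "aids", overlay = "pneumonia", p = 0.5)
  )
}

defaultRegions <- function() {
  # eight regions with an uneven population spread typical of a Sahelian
  # national survey frame
  p <- c(agadez = 0.03, diffa = 0.03, dosso = 0.135, maradi = 0.205,
         tahoua = 0.175, tillaberi = 0.17, zinder = 0.19, niamey = 0.065)
  p / sum(p)
}

defaultOnset <- function(age_group) {
  if (age_group != "neonate") return(list())
  list(neonatal_tetanus = list(p_early = 0.05),
       congenital_malformation = list(p_early = 0.8),
       birth_injury_asphyxia = list(p_early = 1.0),
       meningitis = list(p_early = 0.4),
       diarrhea = list(p_early = 0.2),
       pneumonia = list(p_early = 0.4),
       sepsis = list(p_early = 0.4),
       neonatal_jaundice = list(p_early = 0.6),
       hemorrhagic_disease = list(p_early = 0.5),
       sudden_unexplained_death = list(p_early = 0.3),
       preterm_delivery = list(p_early = 0.9),
       unspecified = list(p_early = 0.3))
}

#' Raise the maternal-infection odds for early-onset infectious deaths
#'
#' Returns the configuration with the maternal-infection odds multiplier
#' set: deaths whose true cause is a severe infection with early onset
#' carry maternal infection at `plogis(qlogis(baseline) + log(m))` instead
#' of the baseline rate. `m = 1` is the null (maternal infection
#' independent of onset and cause).
#'
#' @param config A [generatorConfig()] object.
#' @param odds_multiplier Multiplier `m >= 1`.
#' @return The modified config.
#' @export
injectMaternalAssociation <- function(config, odds_multiplier) {
  stopifnot(inherits(config, "va_genconfig"))
  if (odds_multiplier < 1) stop("the odds multiplier must be >= 1")
  config$maternal$odds_multiplier <- odds_multiplier
  config
}

#' Generate a synthetic cohort with known truth
#'
#' Draws true causes from the configured CSMF, overlays per-cause and
#' co-morbid sign profiles plus background reporting noise and
#' missingness, builds the survey design (clusters, weights, regions),
#' simulates maternal infection and illness onset, and produces physician
#' death certificates from truth plus behaviour noise. Reproducible given
#' `config$seed`; the generated records always pass [validateCohort()].
#'
#' @param config A [generatorConfig()] object.
#' @param vocab Vocabulary defining the record schema.
#' @param certificates Also simulate physician certificates? (Switch off
#'   for record-only simulation studies.)
#' @return List with elements `records` (a [asVACohort()] cohort),
#'   `certificates` (a [asCertificates()] object, `NULL` for an empty
#'   cohort), `truth` (data frame: `death_id`, `true_cause`,
#'   `true_comorbid` list column, `maternal_infected`, `onset_day`) and
#'   `surveillance` (a regional [asSurveillance()] table consistent with
#'   the configured region spread).
#' @export
generateCohort <- function(config, vocab = defaultVocabulary(),
                           certificates = TRUE) {
  stopifnot(inherits(config, "va_genconfig"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n <- config$n
  ag <- config$age_group
  signs <- vocabSigns(vocab, ag)
  severe <- c("meningitis", "pneumonia", "sepsis")

  truth_cause <- if (n) sample(names(config$csmf), n, replace = TRUE,
                               prob = config$csmf) else character()
  comorbid <- replicate(n, character(), simplify = FALSE)
  for (cp in config$couplings) {
    hit <- truth_cause == cp$cause & stats::runif(n) < cp$p
    for (i in which(hit)) comorbid[[i]] <- union(comorbid[[i]], cp$overlay)
  }

  # presence probabilities per record x sign: max over active profiles
  p_mat <- matrix(config$background_p, n, length(signs),
                  dimnames = list(NULL, signs))
  d_mat <- matrix(NA_real_, n, length(signs), dimnames = list(NULL, signs))
  preg <- numeric(n)
  preg[] <- sample(c(8, 9, 10), n, replace = TRUE, prob = c(0.1, 0.75, 0.15))
  applyProfile <- function(i, cause) {
    prof <- config$profiles[[cause]]
    if (is.null(prof)) return()
    for (key in names(prof$signs)) {
      if (!key %in% signs) next
      sp <- prof$signs[[key]]
      if (sp$p > p_mat[i, key]) p_mat[i, key] <<- sp$p
      if (!is.null(sp$dur)) d_mat[i, key] <<- sp$dur
    }
    if (!is.null(prof$fields$pregnancy_duration))
      preg[i] <<- prof$fields$pregnancy_duration
  }
  for (i in seq_len(n)) {
    applyProfile(i, truth_cause[i])
    for (cm in comorbid[[i]]) applyProfile(i, cm)
  }
  present <- matrix(stats::runif(n * length(signs)), n,
                    length(signs)) < p_mat

  # durations: profile mean where defined, else a short background draw
  dur <- matrix(NA_real_, n, length(signs), dimnames = list(NULL, signs))
  need <- present
  base_dur <- ifelse(is.na(d_mat), 2, d_mat)
  if (any(need)) {
    dur[need] <- if (config$duration_noise)
      pmax(1, stats::rpois(sum(need), base_dur[need])) else base_dur[need]
  }

  # missingness masks the response and, with it, the duration
  if (config$missingness > 0 && n) {
    miss <- matrix(stats::runif(n * length(signs)), n,
                   length(signs)) < config$missingness
    present[miss] <- NA
    dur[miss] <- NA_real_
  }
  dur[!is.na(present) & !present] <- NA_real_

  # onset and ages
  onset_day <- rep(NA_integer_, n)
  if (ag == "neonate" && n) {
    p_early <- vapply(truth_cause, function(cz)
      config$onset[[cz]]$p_early %||% 0.3, numeric(1))
    early <- stats::runif(n) < p_early
    onset_day[early] <- sample(0:1, sum(early), replace = TRUE)
    onset_day[!early] <- sample(2:20, sum(!early), replace = TRUE)
    age <- pmin(27L, onset_day + stats::rpois(n, 2))
  } else {
    age <- if (n) sample(1:59, n, replace = TRUE,
                         prob = 1 / (1:59 + 3)) else integer()
  }

  # maternal infection: baseline odds, multiplied for early-onset severe
  maternal_inf <- rep(FALSE, n)
  msign <- matrix(NA_character_, n, length(vocab$maternal),
                  dimnames = list(NULL, vocab$maternal))
  if (ag == "neonate" && n) {
    elevated <- truth_cause %in% severe & !is.na(onset_day) & onset_day < 2
    pm <- stats::plogis(stats::qlogis(config$maternal$baseline) +
                          log(config$maternal$odds_multiplier) * elevated)
    maternal_inf <- stats::runif(n) < pm
    sens <- config$maternal$sens
    fp <- config$maternal$fp
    for (key in vocab$maternal) {
      p_yes <- ifelse(maternal_inf, sens, fp)
      # only the signs the maternal rule reads are driven at sensitivity;
      # the others stay at the false-positive rate
      if (!key %in% c("m_fever_pregnancy", "m_fever_labor",
                      "m_foul_discharge"))
        p_yes <- rep(fp, n)
      msign[, key] <- ifelse(stats::runif(n) < p_yes, "yes", "no")
    }
  }

  # survey design
  cluster_w <- exp(stats::rnorm(config$n_clusters, 0,
                                config$weight_dispersion))
  cluster_w <- cluster_w / mean(cluster_w)
  cluster <- if (n) sample(config$n_clusters, n, replace = TRUE) else integer()
  region <- if (n) sample(names(config$regions), n, replace = TRUE,
                          prob = config$regions) else character()

  df <- data.frame(
    death_id = if (n) sprintf("d%04d", seq_len(n)) else character(),
    age_group = rep(ag, n),
    age_at_death = age,
    sex = if (n) sample(c("male", "female"), n, replace = TRUE)
          else character(),
    region = region,
    cluster_id = if (n) sprintf("c%03d", cluster) else character(),
    survey_weight = if (n) cluster_w[cluster] else numeric(),
    pregnancy_duration = if (ag == "neonate") preg else rep(NA_real_, n),
    illness_onset_day = onset_day,
    stringsAsFactors = FALSE
  )
  tri <- function(x) ifelse(is.na(x), NA_character_,
                            ifelse(x, "yes", "no"))
  for (j in seq_along(signs)) {
    df[[paste0("sign.", signs[j])]] <- tri(present[, j])
    df[[paste0("dur.", signs[j])]] <- dur[, j]
  }
  if (ag == "neonate")
    for (j in seq_along(vocab$maternal))
      df[[paste0("msign.", vocab$maternal[j])]] <- msign[, j]
  records <- asVACohort(df, vocab)

  truth <- data.frame(death_id = df$death_id, true_cause = truth_cause,
                      maternal_infected = maternal_inf,
                      onset_day = onset_day, stringsAsFactors = FALSE)
  truth$true_comorbid <- comorbid

  certificates <- if (n && certificates)
    generateCertificates(records, truth, config) else NULL
  surveillance <- generateSurveillance(config)
  list(records = records, certificates = certificates, truth = truth,
       surveillance = surveillance)
}

# Physician certificates from truth plus behaviour noise. Certifying is
# deliberately NOT a re-run of the algorithmic rules, so EAVA-vs-PCVA
# agreement is nontrivial and tunable.
generateCertificates <- function(records, truth, config) {
  beh <- config$physician
  causes <- setdiff(names(config$csmf), "unspecified")
  crit <- tryCatch(defaultMinimumCriteria(config$age_group),
                   error = function(e) NULL)
  crit_fire <- NULL
  if (!is.null(crit)) {
    ids <- intersect(names(crit$causes), causes)
    crit_fire <- matrix(FALSE, nrow(records), length(ids),
                        dimnames = list(NULL, ids))
    for (id in ids)
      crit_fire[, id] <- evalExpr(crit$causes[[id]]$rule, records, crit)
  }
  n <- nrow(records)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tc <- truth$true_cause[i]
    cm <- truth$true_comorbid[[i]]
    if (tc == "unspecified") {
      underlying <- "unspecified"
      cm <- character()
    } else if (stats::runif(1) < beh$accuracy) {
      underlying <- tc
    } else if (!is.null(crit_fire) && stats::runif(1) < beh$floor_prob &&
               any(crit_fire[i, ])) {
      # diagnose at the minimal-criteria floor: any cause whose floor the
      # record satisfies
      underlying <- sample(colnames(crit_fire)[crit_fire[i, ]], 1)
    } else {
      underlying <- sample(setdiff(causes, tc), 1)
    }
    # preterm is never certified as underlying when another condition is
    # known: promote a co-morbid cause instead
    extra <- setdiff(cm, underlying)
    if (underlying == "preterm_delivery" && length(extra)) {
      underlying <- extra[1]
      extra <- unique(c(setdiff(extra, underlying), "preterm_delivery"))
    }
    direct <- character()
    if (length(extra) && stats::runif(1) < beh$chain_p) {
      direct <- extra[1]
      extra <- extra[-1]
    }
    part2 <- extra[stats::runif(length(extra)) < beh$contrib_p]
    chain <- c(direct, underlying)
    lines <- c("1a", "1b", "1c", "1d")[seq_along(chain)]
    ent <- data.frame(death_id = truth$death_id[i], line = lines,
                      cause = chain, maternal = FALSE,
                      stringsAsFactors = FALSE)
    if (config$age_group == "neonate" && truth$maternal_infected[i] &&
        length(chain) < 4 && stats::runif(1) < beh$maternal_record_p) {
      ent <- rbind(ent, data.frame(
        death_id = truth$death_id[i],
        line = c("1a", "1b", "1c", "1d")[length(chain) + 1L],
        cause = "maternal_infection", maternal = TRUE,
        stringsAsFactors = FALSE))
    }
    if (length(part2))
      ent <- rbind(ent, data.frame(death_id = truth$death_id[i], line = "2",
                                   cause = part2, maternal = FALSE,
                                   stringsAsFactors = FALSE))
    rows[[i]] <- ent
  }
  asCertificates(do.call(rbind, rows))
}

#' Generate a regional surveillance table
#'
#' Multinomial regional case counts over the configured region spread for
#' four surveillance years, with CSF samples received for roughly 41% of
#' notified cases, positive cultures for 45% of samples, and a case
#' fatality applied to notified cases. Labelled synthetic: the counts
#' carry no information beyond the configured region distribution.
#'
#' @param config A [generatorConfig()] object.
#' @param total_cases National notified-case total across years.
#' @param years Surveillance years.
#' @param cfr Case fatality ratio.
#' @return A [asSurveillance()] table.
#' @export
generateSurveillance <- function(config, total_cases = 20000L,
                                 years = 2007:2010, cfr = 0.08) {
  shares <- config$regions
  per_year <- stats::rmultinom(length(years), ceiling(total_cases /
                                                        length(years)),
                               prob = shares)
  rows <- lapply(seq_along(years), function(t) {
    cases <- per_year[, t]
    csf <- stats::rbinom(length(cases), cases, 0.41)
    pos <- stats::rbinom(length(cases), csf, 0.45)
    if (years[t] == max(years)) { csf[] <- NA_integer_; pos[] <- NA_integer_ }
    data.frame(region = names(shares), year = years[t],
               cases_notified = as.integer(cases),
               csf_samples_received = as.integer(csf),
               positive_cultures = as.integer(pos),
               deaths = as.integer(stats::rbinom(length(cases), cases, cfr)),
               stringsAsFactors = FALSE)
  })
  asSurveillance(do.call(rbind, rows))
}

#' Noise-free deterministic generator configuration
#'
#' A configuration in which every profile sign appears with probability 1
#' at a fixed duration, with no background noise, no missingness, no
#' co-morbidity couplings and equal weights — so the default classifier
#' recovers the true cause of every death exactly and any residual
#' deviation of the recovered CSMF from the configured one is pure
#' multinomial sampling error.
#'
#' @param csmf Named true CSMF over a subset of the default cause list.
#' @inheritParams generatorConfig
#' @return A [generatorConfig()] object.
#' @export
noiseFreeConfig <- function(csmf, age_group = "neonate", n = 5000L,
                            seed = 1L) {
  profiles <- defaultSignProfiles(age_group)
  profiles <- lapply(profiles, function(prof) {
    prof$signs <- lapply(prof$signs, function(sp) {
      sp$p <- 1
      sp
    })
    prof
  })
  generatorConfig(age_group = age_group, n = n, seed = seed, csmf = csmf,
                  profiles = profiles, couplings = list(),
                  background_p = 0, missingness = 0, duration_noise = FALSE,
                  weight_dispersion = 0)
}
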