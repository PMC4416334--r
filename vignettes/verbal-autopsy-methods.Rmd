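---
title: "Methods: hierarchical expert-algorithm verbal autopsy and its comparison statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical expert-algorithm verbal autopsy and its comparison statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacause)
```

## The problem and the data model

A verbal autopsy (VA) record is one death's interview: the child's age
group and age at death (days for neonates aged 0–27 days, months for
children aged 1–59 months; the units differ by group and are never
silently converted), the survey design fields (region, cluster id,
positive sampling weight), and the reported illness signs. Every sign is
**tri-state** — `"yes"`, `"no"`, or missing — and the distinction is load
bearing: a missing response is *not* "no". Neonatal records additionally
carry the pregnancy duration in completed months, the day of life at
illness onset, and the mother's own illness signs.

Two analytic routes assign causes to such records:

* **EAVA** — computerised expert algorithms: one boolean criterion per
  cause over the signs, arranged in a hierarchy;
* **PCVA** — a physician reads the interview and completes a death
  certificate (part 1 causal chain on lines 1a–1d, part 2 contributing
  causes; maternal causes, when certified for a neonate, always beneath
  the child causes).

The package treats certificates as data: it extracts causes from them but
never simulates physician judgment outside the synthetic generator.

## Rule evaluation semantics

A cause rule is a boolean expression (`all`/`any`/`not`) over predicates:
sign presence (optionally with a minimum/maximum duration in days or an
onset-order bound), maternal-sign presence, record-field comparisons
(pregnancy duration, onset day, age), and `not_cause` (no listed cause's
rule fires — used by "possible malaria": fever with no other infectious
diagnosis; its targets may not themselves use `not_cause`, which rules
out cycles by construction).

Two semantic choices matter:

* **Missing is conservative.** A predicate on a missing sign is false,
  never imputed. The algorithms in this tradition are chosen for
  specificity over sensitivity — false positives distort cause fractions
  more than false negatives in high-mortality settings — and imputing
  missing responses would let missingness create diagnoses. A duration
  predicate on a sign with a missing duration is likewise false.
* **Purity.** Rule evaluation is a pure function of the record (plus the
  rule set for `not_cause`); configuration errors (a predicate naming a
  sign outside the vocabulary, a possible tier without a probable
  counterpart) surface at load time, not at evaluation time.

## Hierarchy, co-morbidity and the probable/possible tiers

The hierarchy is a total order over cause ids. Classification is:

1. evaluate every rule → the *eligible* set;
2. suppress any possible-tier cause whose probable counterpart is also
   eligible;
3. the **primary cause** is the minimum-rank eligible cause (or
   `unspecified` if none); every other eligible cause flagged
   co-morbid-capable is reported as **co-morbid**;
4. the **reporting cause** merges possible tiers into their probable
   counterparts (final distributions combine the two);
5. the **combined algorithmic cause** is primary ∪ co-morbid — the unit
   compared against the physician's combined cause set.

Because the order is total there are no ties to break; the selection is
deterministic and order-invariant, and adding a cause to the eligible set
can only move the primary up. The default orders encode the standard
principles: site-specific/severe infections above less specific ones
(meningitis above sepsis), measles above pneumonia and diarrhea above
pneumonia (consequence ordering), malnutrition high so it can surface as
an underlying cause, every possible tier strictly below its probable
counterpart, and preterm delivery last among neonatal causes so it is
primary only when it is the sole condition known.

The shipped rule content is a **reconstruction**: the complete published
criteria compendium for this family of studies is not openly deposited,
so each rule keeps the criteria that are documented in the main study
literature (neonatal meningitis requiring a focal sign *plus* lethargy or
unconsciousness; minimum durations on respiratory signs — the shipped
default is 2 days; preterm delivery as pregnancy duration < 8 months or
< 9 months with respiratory-distress signs; pertussis adapted from a
14-day cough plus whoop or post-tussive vomiting) and fills the remainder
with standard VA case definitions. Everything is plain YAML, validated at
load time, with the version string recorded in classification output and
the pipeline manifest, so a deployment can substitute its instrument's
exact criteria without touching code.

## PCVA extraction and the minimal-criteria audit

The underlying cause is the child cause on the lowest completed part-1
line (1a–1c), and for neonates the underlying maternal cause is the
lowest maternal entry in 1b–1d. The combined physician cause is the
deduplicated union of all part-1 child causes and part-2 contributors —
order-invariant and idempotent, and invariant to appending part-2 rows.
`auditMinimumCriteria()` re-checks each certified cause against
configured per-cause floors (e.g. meningitis requires at minimum bulging
fontanelle or convulsions; pneumonia at least fast or difficult
breathing, with no duration floor, unlike the algorithm); causes without
configured floors are reported as uncheckable rather than silently
passed.

## Statistics

**Weighted CSMF.** The cause-specific mortality fraction is the weighted
share of deaths assigned the cause; counts are reported unweighted. The
survey's cluster weights enter all analyses. The paper trail for this
class of study does not state a CI method for weighted proportions, so
the package makes an explicit, swappable choice: a Wilson score interval
evaluated at the Kish effective sample size $n_{\mathrm{eff}} =
(\sum w_i)^2 / \sum w_i^2$. This respects the precision loss from unequal
weights without requiring replicate weights or cluster-level resampling;
with equal weights it reduces to the ordinary Wilson interval, and the
interval always contains the point estimate.

**Two-proportion chi-square.** The statistic is the uncorrected Pearson
form $\chi^2 = (p_1-p_2)^2 / [\bar p(1-\bar p)(1/n_1+1/n_2)]$, which is
what the recomputable published values correspond to. The default
p-value is asymptotic (1 d.f.); an exact conditional **mid-p** value —
probability-ordered hypergeometric tail sum with the observed table
counted at half weight — is available behind a flag and labelled in the
output, since the exact mid-p construction used by any given study is
rarely recoverable. A degenerate pooled proportion (0 or 1) yields
statistic 0 and p = 1 by definition rather than 0/0.

**Kappa.** $\kappa = (p_o - p_e)/(1 - p_e)$ from the 2×2 cells, with the
large-sample standard error $\sqrt{p_o(1-p_o)}/[\sqrt N\,(1-p_e)]$ and
grades at strictly-greater thresholds 0.8/0.6/0.4/0.2 (excellent, good,
moderate, fair; at or below zero, less-than-chance). Weighted cell totals
feed the same formula; unweighted cells are the default because printed
agreement tables in this literature are unweighted counts. Degenerate
margins with $p_e = 1$ are defined as $\kappa = 1$ when agreement is
perfect and are an explicit error otherwise.

**Rank comparison.** Dense ranks by descending fraction, unspecified
deaths excluded (a death without a diagnosis carries no rank
information); ties are broken by cause-list order and flagged.

## Plausibility analyses

Two internal-validity checks exploit structure the classifier does not
use directly:

* **Maternal infection × early onset.** Early-onset severe neonatal
  infection (meningitis, pneumonia, sepsis; illness onset before day 2 of
  life) should associate with maternal infection if the diagnoses are
  real. For each cause group the early/late strata are cross-tabulated
  against the maternal-infection flag and tested with the two-proportion
  chi-square; a final contrast compares early-onset severe-infection
  deaths with all other deaths. Empty strata are flagged, not fatal, and
  the strata always reconcile to the cohort size.
* **Regional meningitis ecology.** Within each region, the weighted
  meningitis-specific proportional mortality among child VA deaths is set
  against the region's share of national surveillance-detected meningitis
  cases (and deaths). Proportional mortality is used rather than the
  region's share of VA meningitis deaths because the latter is driven by
  the regional population distribution. The qualitative comparison is
  summarised quantitatively — an addition of this package, clearly
  labelled — by a Spearman rank correlation, reported with and without
  small-denominator regions (< 20 deaths), whose proportions are
  unstable; a constant profile reports `NA` rather than a spurious
  correlation. Only primary/underlying causes enter, since the check
  targets the cause reportable for vital statistics.

## The synthetic generator

The generator emulates the *structure* of a two-stage cluster national
mortality survey so that every stage has a testable ground truth:

* default cohort sizes 453 neonates / 620 children across eight regions
  with an uneven population spread; 50 clusters with log-normal weight
  dispersion (sd 0.25 on the log scale; 0 gives exact equal weights);
* true causes drawn from a configured CSMF (defaults are a plausible
  generic high-mortality mix — deliberately *not* fitted to any observed
  national distribution, which would be circular);
* per-cause conditional-independence Bernoulli sign profiles with
  durations, plus explicit co-morbidity couplings (sepsis signs overlaid
  on neonatal meningitis/pneumonia/diarrhea deaths; malaria–pneumonia and
  meningitis–diarrhea overlap for children) — the simplest structure that
  exercises the hierarchy's co-morbidity logic;
* a maternal-infection model: baseline rate 0.15, with an odds multiplier
  (default 1 = null) applied to early-onset severe-infection deaths, and
  maternal signs observed at sensitivity 0.9 / false-positive rate 0.02;
* a physician-behaviour model generating certificates from truth with
  noise — accuracy 0.75 for the underlying cause, otherwise often
  certifying a cause whose minimal-criteria floor the record happens to
  satisfy (floor-diagnosis behaviour), a causal-chain depth model,
  part-2 contributors from true co-morbidities, and preterm never left as
  underlying when another condition is known. Certificates are generated
  from truth, *not* by re-running the rules, so EAVA-vs-PCVA agreement is
  nontrivial and tunable;
* background sign noise 0.02 and response missingness 0.05.

What it does **not** emulate: recall decay with time since death,
correlated sign reporting beyond the configured couplings, interviewer
effects, age-dependent sign profiles within an age group, or any real
country's cause mix. Passing recovery tests therefore demonstrates the
*internal* consistency of the pipeline — rules, hierarchy, weighting and
tests recover a known truth under the generator's assumptions — not field
validity of the rule content.

`noiseFreeConfig()` is the degenerate corner used for parameter-recovery
checks: profile signs at probability 1 with fixed durations, no
background noise, no missingness, no couplings, equal weights. Under it
the classifier recovers every true cause exactly, so the recovered CSMF
differs from the configured one only by multinomial sampling error.

## Problem sizes and numerical choices

The validation suite enumerates all $2^{12}$ records of a 12-sign toy
vocabulary against an independently written brute-force classifier;
parameter recovery uses one noise-free cohort of n = 5000 (±0.02
tolerance per cause, comfortably above the ~0.007 binomial standard
error); the null calibration of the onset-association test uses 1000
replicates of n = 453 with acceptance band 0.05 ± 0.02; power is
estimated at odds multiplier 4 over 200 replicates. These sizes were
chosen to keep Monte-Carlo error well inside each tolerance. Equality
oracles for the weighted-sum and kappa formulas are asserted at 1e-12 and
the chi-square oracle at 1e-10; file round-trips write doubles at 17
significant digits so read∘write is the identity.

## Limitations

The shipped rules are reconstructions and should be reviewed against the
deployment instrument before substantive use; the CI method for weighted
proportions is a design-effect approximation, not a full survey-variance
estimator (no replicate weights, no stratification term); the mid-p
variant is one defensible construction among several; and the weighted
kappa option reweights cells without adjusting the standard error for the
design. All are documented, isolated behind the module surfaces, and
swappable.
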