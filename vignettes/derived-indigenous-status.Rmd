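---
title: "Deriving and validating Indigenous status from linked administrative records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating Indigenous status from linked administrative records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkenhance)
options(linkenhance.verbose = FALSE)
```

## The problem

Aboriginal and Torres Strait Islander people are under-reported on Australian
administrative health collections: the Indigenous-status question is not
always asked, and people may choose not to identify in a clinical setting.
When the same person appears on many linked records — hospital admissions
(APDC), emergency presentations (EDDC), perinatal records (PDC), birth
registrations (RBDM) and death registrations (CODURF) — the set of linked
records can be used to *derive* a more complete person-level status. Many
derivation rules have been proposed; this package implements them and
quantifies their accuracy against an independent self-reported reference
standard, at the level of the individual record.

`linkenhance` provides three things:

1. the derivation rules themselves (`derive_all()` and the `derive_*()`
   family);
2. a record-level validity evaluation against a reference standard
   (`build_confusion()`, `evaluate_table()`, `compare_methods()`);
3. a synthetic linked-cohort generator (`simulate_cohort()`) calibrated to
   the published structure of the NSW Patient Survey Program (PSP) linkage
   population, because the real linked data are confidential and cannot be
   redistributed.

## The derivation rules

A **unit of information** is one linked record with a non-missing
Indigenous-status flag. Missing flags carry no evidence under any rule and
reduce the unit count; this mirrors the upstream exclusion of persons with
missing reference information and treats record flags symmetrically.

The central rule is the weight-of-evidence decision (`era_rule()`), the
Enhanced Reporting of Aboriginality (ERA) algorithm: with $n \ge 3$ units of
information a person is derived Aboriginal when at least two units indicate
so; with $n \in \{1, 2\}$ a single indicating unit suffices. The Multi-stage
median (MSM) applies the same decision twice: first within each data
collection, then across the per-collection results, so that a collection
holding many records about a person cannot dominate the derived status by
volume alone. When all of a person's records lie in a single collection the
two stages collapse and MSM equals ERA exactly (a property the test suite
checks).

The remaining rules are the simpler proposals from the linkage literature:
*ever reported* (any Aboriginal-flagged record), *always reported* (all
usable records Aboriginal-flagged), *index record* and *most recent record*
(the flag of the chronologically first/last usable record), *majority of
records* (at least 50% of public hospital admissions, i.e. APDC records;
`majority_scope = "all"` widens the base), and *at least two hospitals*
(Aboriginal flags at two or more distinct APDC/EDDC facilities). The
baseline against which they are compared is *As-recorded*: the flag on the
one hospital record originally sampled for the survey.

### Decisions where the rules' definitions are open

* **Granularity of an ERA unit.** We count each linked record with a usable
  flag as one unit. The alternative — one unit per independent *source* — is
  exactly what MSM's first stage provides, so record-level ERA units are
  what make the two rules genuinely different.
* **Zero-evidence persons** derive non-Aboriginal rather than "unknown":
  the evaluation is binary, and an enhancement rule that cannot find any
  Aboriginal-flagged evidence has not enhanced anything. Such persons are
  counted and logged.
* **Date ties** for index/most-recent are broken deterministically: by
  collection priority APDC > EDDC > PDC > RBDM > CODURF, then by the
  Aboriginal flag first, then by input order. Any fixed order would do; this
  one prefers the collections with the most complete identification
  practice and makes reruns byte-identical.
* **Most recent / index scope** defaults to all five collections
  (`recency_scope = "hospital"` restricts to APDC/EDDC, since "most recent
  admission or presentation" can be read either way).
* **The sampled record** counts as an ordinary evidence unit for the
  enhancement rules; only the As-recorded baseline treats it specially. The
  survey response itself is never evidence — it is the reference standard.

## Record-level evaluation

Accuracy is measured per *record*, not per person: every usable record of
the chosen source (APDC or EDDC) contributes one cell to the confusion
matrix, its truth being the person's self-reported reference status. For
the enhancement rules the record inherits the person's derived status; for
As-recorded in the default `all_records` mode the record is judged by its
own flag. A `sampled_only` mode restricts the evaluation to the originally
sampled records, because the baseline's definition refers to exactly those;
both modes are available and neither is asserted as canonical. Age
stratification always uses the reference table's age group.

The five measures are the standard ones — sensitivity, specificity, PPV,
NPV on the percent scale — plus the F score, defined here as the harmonic
mean of PPV and sensitivity on the unit scale:
$$\mathcal{F} = \frac{2 \cdot \mathrm{PPV} \cdot \mathrm{sens}}{\mathrm{PPV} + \mathrm{sens}}.$$
This is the F1 score with PPV playing precision and sensitivity playing
recall; it is the balance the validation literature uses between the
sensitivity gained by enhancement and the PPV lost to it. Zero denominators
yield `NA` — an undefined measure is reported as missing, never as 0 or
100. Display rounding (rates to one decimal, F to two, ties away from zero)
is applied only by `format_validity_table()`; all computation is at full
precision.

## The synthetic cohort

No generative model is published for the real linked data, so
`simulate_cohort()` invents the *minimal* structure that exercises every
rule:

* a person-level **never-identified stratum**: a fraction $f$ of
  reference-Aboriginal persons whose records are all non-Aboriginal-flagged.
  These persons are unreachable by any linkage rule, which caps every
  method's record-level sensitivity at $100(1 - \text{their record share})$
  — the "absolute ceiling" property the acceptance suite verifies;
* **independent per-record flagging** for the remaining reference-Aboriginal
  persons, with a per-collection sensitivity $s_c$;
* a small **misreporter stratum** of reference-non-Aboriginal persons with
  one forced Aboriginal-flagged record plus further flags at rate 0.5 per
  record, producing both once-only and consistently misreported persons;
* a uniform **missing-flag overlay**, and an optional record-reassignment
  noise standing in for false links (default 0).

### Calibration defaults and where they come from

The defaults are the published cohort structure: 130,514 persons, 3.9%
prevalence, $f = 0.164$, record-count distributions (5/9/86)% and
(10/12/78)% over 1/2/3+ records, and collection shares
(56.5/40.8/1.1/1.3/0.3)%. Three defaults are this package's own choices:

* **3+ tail.** The count of records beyond three is truncated-geometric
  (truncated at 200). Status-specific means of 13.8 (Aboriginal) and 8.7
  (non-Aboriginal) reproduce the published records-per-person of ~14.7 and
  ~9.5 by status and ~9.7 overall.
* **Per-collection flag sensitivities.** Under this model the expected
  record-level As-recorded sensitivity is $(1-f)\,s_c$. Solving against the
  published overall sensitivities gives $s_{\mathrm{APDC}} = 1.00$ (84% is
  at the $(1-f)$ ceiling) and $s_{\mathrm{EDDC}} = 0.926$; the three
  non-hospital collections are not measured by the validation design and
  are set to 0.80, a deliberate under-identification typical of registry
  data. A consequence of $s_{\mathrm{APDC}} = 1$ is that APDC enhancement
  has almost no sensitivity headroom in the synthetic cohort — which is
  the published finding for the APDC (no enhanced method beat the
  As-recorded F score there) — while the EDDC shows clear enhancement
  gains.
* **Missing-flag rate** 0.01: record-level status missingness in these
  collections is a low single-digit phenomenon; 1% keeps missing-flag
  handling exercised without materially moving the measures.

Demographic marginals (age by status, sex, remoteness) follow the published
study-population percentages, which is what makes the age-stratified
evaluation meaningful. Facilities (220) and event dates (uniform over
2011–2016) are plumbing for the two-hospitals and recency rules.

### What the generator does and does not emulate

It reproduces the person-level strata, record-volume distributions and
per-collection flagging gradients of the real cohort. It does **not** model
correlation between record count and never-identification, within-person
temporal trends in identification (so index vs most-recent differences are
muted relative to real data), collection-specific misreporting, family
structure, or linkage error beyond uniform reassignment. Tests passing on
this cohort therefore demonstrate the correctness and calibration of the
*rules and measures*, not the real-world magnitude of enhancement gains.

## Reproducibility and numerical choices

One integer seed drives the whole cohort; all downstream stages are
deterministic, so `run_pipeline()` bundles are byte-identical across reruns
and the manifest's MD5 hashes verify it. Monte-Carlo checks use 3-standard-
error bands; for record-level quantities the standard errors are
cluster-robust by person, because flags are correlated within a person
through the never-identified stratum and shared record counts. Probability
vectors must sum to 1 within 1e-9 (published marginals are normalised once
in the defaults). Problem sizes in the test suite are the package's own
choices: the full 130,514-person cohort is simulated once and shared where
the calibration itself is under test, and cohorts of 500–4,000 persons are
used for structural properties that do not depend on scale.

## Limitations

* The reference standard is treated as perfect; the validation literature
  discusses why self-report collected in a safe context is the best
  available standard, not why it is error-free.
* Person identity is taken as ground truth (linkage is upstream); the
  reassignment-noise parameter is a crude stand-in for false links.
* The published stratum-level F cells can disagree with recomputation from
  the printed one-decimal inputs by one unit in the second decimal; the
  arithmetic checks therefore demand exactness only where the printed
  precision supports it.
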