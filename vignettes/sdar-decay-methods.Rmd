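---
title: "Measuring SDAR production and URL decay: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring SDAR production and URL decay: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdarlink)
library(dplyr)
```

## The problem

Scientific Data Analysis Resources (SDARs) — published software packages,
databases and web servers — are referenced in biomedical abstracts almost
exclusively by URL, and URLs decay: hosts are retired, labs move, funding
lapses. `sdarlink` implements a complete desk-scale pipeline for studying
this phenomenon on MEDLINE-format citation data:

1. parse citation XML into record tables (`read_medline_xml()`,
   `filter_records()`);
2. find, normalize and deduplicate URLs in titles and abstracts, and
   diagnose entry errors (`extract_urls()`, `deduplicate_urls()`,
   `diagnose_urls()`, `validate_doi()`);
3. split archival from author-hosted URLs and label SDARs by abstract
   key terms (`classify_urls()`);
4. survey availability with repeated probes and the at-least-3-of-30
   accessibility rule (`plan_survey()`, `run_survey()`, `decay_curve()`);
5. extract institutions and ZIP codes from affiliation strings and
   quantify concentration with Lorenz/Gini statistics
   (`extract_institution()`, `extract_zip()`, `concentration()`,
   `annual_gini_trend()`);
6. model decay with logistic regression in resource age, author-team
   size and publication-year effects (`build_design()`,
   `fit_decay_model()`, `sequential_anova()`), plus Welch comparisons of
   authorship (`compare_author_counts()`, `senior_author_analysis()`).

Every stage is testable offline against the synthetic corpus generator
(`generate_corpus()`), which produces MEDLINE-dialect XML together with
ground-truth tables.

## The availability survey

Each URL is probed `per_day` times (default 3) at uniform-random times
within each of `days` (default 10) consecutive days — 30 probes. A URL is
**accessible** when at least `min_successes` (default 3) probes succeed.
The low threshold is deliberate: a URL answering even a tenth of probes
is reachable in principle (flaky hosting), whereas one answering almost
never has effectively decayed. Prior surveys of this design report only
2–3% of URLs in the intermittent band (available between 0% and 90% of
the time), which `intermittency_summary()` measures.

The prober is an injected contract `function(url, time) -> logical`, so
analyses are testable with `mock_fetcher()` over synthetic ground truth.
A live deployment would wrap an HTTP client; we take "success" to mean a
response with status below 400 after following redirects within a
timeout (30 s is a sensible default), since the survey rule itself is
protocol-agnostic. A fetcher error on one probe is logged and recorded
as a failure; it never aborts the survey.

## Concentration statistics

For entity counts $x_1 \le x_2 \le \dots \le x_n$ with mean $\mu$, the
Gini coefficient is computed by the mean-difference formula

$$G = \frac{\sum_{i=1}^{n} (2i - n - 1)\,x_i}{n^2 \mu},$$

with 1-based ranks over the ascending sort — the convention the formula
requires; a descending sort would flip the sign. $G = 0$ is perfect
equality and $G = (n-1)/n$ total concentration. The implementation is
checked in the test suite against an independent oracle: twice the area
between the Lorenz curve and the diagonal by trapezoid integration,
which must agree to $10^{-12}$.

`top_share(counts, f)` sorts entities descending and sums the top
$\lceil f\,n \rceil$ entities over the grand total. We use the ceiling
(rather than floor) so that "top 1%" of, say, 150 entities means 2
entities, never 0; ties at the boundary are broken deterministically by
entity label. `annual_gini_trend()` computes a per-year Gini over the
entities active (count > 0) in that year and fits ordinary least squares
over years, reporting the slope absolutely and as a percentage of the
mean annual Gini.

## The decay model

For each SDAR URL, `build_design()` produces `decay` (1 = inaccessible
at survey time), `NumAuthors`, `SDAR_Age` = survey year − publication
year (whole years), and the publication year as a factor.
`fit_decay_model()` fits the maximum-likelihood logit via iteratively
reweighted least squares (convergence at a relative deviance change of
1e-8, at most 100 iterations), reporting Wald $z$ and $p$ per term,
null/residual deviances, and the likelihood-ratio $\chi^2$ against the
intercept-only model.

Two modelling subtleties deserve note:

* **Age/year collinearity.** `SDAR_Age` is an exact linear function of
  the year factor, so in the full model one year level is aliased; the
  factor captures only departures from the linear age trend. The aliased
  level is reported in `$aliased`, never dropped silently. The baseline
  year level is configurable (default: earliest year present), since
  which years form the reference of a published dummy table is often
  ambiguous.
* **Sequential ANOVA, twice.** Published ANOVA tables for binary
  outcomes sometimes show sums of squares (a linear-probability
  decomposition) under a "logistic" heading. `sequential_anova()`
  therefore emits both decompositions, clearly labeled: OLS-on-binary
  (Df, Sum Sq, Mean Sq, F) and sequential deviance drops with
  chi-square tests. Term order changes the sequential rows but never
  the full-model residual row.

Perfect separation is detected both from the IRLS warning stream and
from a saturated perfect fit (all $|\hat\mu_i - y_i| < 10^{-6}$), and
surfaced as a diagnostic rather than silent divergence.

Authorship contrasts (accessible vs decayed SDARs; multi- vs single-SDAR
senior authors) use Welch's unequal-variance two-sample $t$ with
Welch–Satterthwaite degrees of freedom, two-tailed. When both samples
are constant with equal means the comparison is vacuous and returns
$p = 1$ with an explicit flag. "Senior author" is operationalized as the
last-listed author; records with no authors are excluded and logged.

## Affiliation heuristics

Institution extraction follows comma tokenization plus a prioritized
multilingual keyword scan ("Universi" covers six languages; "hôpital",
"Istituto" and similar cover common non-English forms after
transliteration). Priorities run university-type > department-type >
hospital-type, so the most generic entity wins. Normalization:
transliterate to ASCII (`stringi` Latin-ASCII, since publisher
transliteration of diacritics is inconsistent), case-insensitive
comparison, strip a leading "The", and truncate text after "University"
only when text precedes it — "Foo University School of Medicine" becomes
"Foo University" while "University of Foo" is untouched. Email addresses
and digit runs are masked before scanning to avoid false keyword hits.
The keyword table and the country list ship as editable plain-text
configs under `inst/extdata/`.

ZIP extraction first applies the US-ness test (contains "USA"/"United
States", or at least names no other country), then takes the *last*
5-digit token not embedded in a longer digit run, truncating ZIP+4
forms — operationalizing "preferably toward the end of the string",
since ZIPs close US addresses.

Because affiliation parsing is noisy, `drop_singletons()` removes
entities observed exactly once before concentration analysis.

## URL grammar and repair rules

No published URL regex exists for this extraction task, so the grammar
is: `http`/`https`/`ftp` scheme-prefixed forms plus bare
`www.`-prefixed hosts (scheme imputed as `http`), with trailing sentence
punctuation stripped and a trailing `)` or `]` removed only when
unbalanced within the match. Scheme and host are lowercased; paths keep
their case.

Repair rules are data (a CSV of pattern/replacement/label), seeded with
the documented entry-error classes: `webcitation` missing its `.org`
suffix, `clinical-trials.gov` hyphenation (which does not redirect),
"trials" misspelled "trails", and a registry host with no top-level
domain. A URL is `repairable` when exactly one rule fires; a suggested
repair always satisfies the grammar itself. Classification treats a
repairable URL by its repaired host — a mistyped registry link is still
a registry link. DOI strings are checked for the standard
`10.<registrant>/<suffix>` body; a missing registrant or suffix is
diagnosed as `missing_field` (unrecoverable), while stray whitespace or
a comma typed for the registrant dot is `repairable`.

## The synthetic corpus generator

`sim_config()` fixes the study conditions; `generate_corpus()` realizes
them deterministically from a seed. The defaults describe a URL-rich
testing corpus over 1996–2013:

| parameter | default | rationale |
|---|---|---|
| `authors_mean_base`, `authors_mean_slope` | 3.5, +0.1/yr | mean team size growing from ~3.5 to ~5.2 over the corpus years, the observed scale for biomedical papers of that era |
| `url_rate` | 0.6 | URL-rich by design: the generator exists to exercise the URL pipeline, not to mimic MEDLINE's base rate |
| `sdar_keyword_rate` | 0.5 | roughly half of non-archival URLs are SDARs, the observed proportion |
| `archival_rate` | 0.1 | archival URLs are ~10% of the unique URL population |
| `error_injection_rate` | 0.034 | the observed 3.4% entry-error rate among archival URLs |
| `institution_gini`, `zip_gini` | 0.62, 0.65 | the SDAR-production concentration scale |
| `decay_betas` | (−2.88, +0.268, −0.0236) | the published coefficient scale for SDAR decay |
| `intermittent_rate` | 0.02 | the observed share of intermittently available URLs |

Accessibility is realized per non-archival URL from
$\operatorname{logit} p_{\text{decay}} = \beta_0 + \beta_{\text{age}}
\cdot \text{age} + \beta_{\text{authors}} \cdot \text{authors}$.
Archival URLs are accessible unless their written form was corrupted,
which reproduces the observation that archival inaccessibility is
essentially an entry-error phenomenon. Intermittent URLs draw a
per-probe success probability uniformly in (0.25, 0.7): the floor keeps
the probability of failing the 3-of-30 rule near $2\times10^{-3}$, so
the stored ground truth and the realized survey decision almost surely
agree, and the ceiling keeps the availability fraction below the 0.9
intermittency band edge.

`concentration_calibrator(n, g)` supplies entity weights from the Zipf
family $w_i = i^{-s}$ with the exponent solved by root-finding so the
weight vector's Gini is within 0.02 of the target; the degenerate
maximum $(n-1)/n$ maps to the one-entity-holds-all vector, and targets
beyond it error.

Affiliation strings are rendered from comma templates that deliberately
include the hard cases every heuristic must survive: leading "The",
diacritic renders ("Université de …", "Hôpital …"), "School of
Medicine" suffixes, ZIP+4 forms, US strings with no country marker, and
non-US strings with 5-digit postal codes (which must *not* yield a
ZIP).

**What the generator does not emulate** — and hence what passing tests
do not show about real data: linguistically realistic abstracts (keyword
matching is exercised, not disambiguated), real institution gazetteers
and their misspellings, multiple URLs per abstract, URL content change
without loss of accessibility, and HTTP-level behaviours (timeouts,
redirect chains, robots policies). Pipeline-fidelity results on
synthetic corpora are upper bounds; the affiliation heuristics in
particular will do worse on real MEDLINE strings.

## Numerical choices and test scale

* Gini/Lorenz agreement is asserted to $10^{-12}$ (pure arithmetic).
* IRLS agreement between `fit_decay_model()` and a from-scratch solver
  is asserted to $10^{-8}$ on toy designs.
* The statistical test suite runs at deliberate desk scale: shared
  corpora of 600–2,000 records for pipeline fidelity, 5,000-record
  corpora for coefficient recovery (about 2,700 modelled URLs each),
  and 50 replicates for the Wald-interval coverage study. Monte-Carlo
  assertions use 4-sigma bands on binomial error throughout, except
  where a contract is exact (recall, label fidelity, determinism).
* Publication year is taken from the first available of `PubDate`,
  `ArticleDate`, `DateCompleted` — print date wins over electronic when
  both exist, since indexing practice keys on the print issue.
* A URL appearing in both the title and abstract of one record is
  counted once for that record.

## Known limitations

* The archival host list is a seed configuration (DOI resolvers,
  webcitation.org, clinicaltrials.gov, a few journal-archive hosts); a
  production deployment needs a curated list.
* SDAR classification is keyword co-occurrence, with a configurable
  proximity window (default: whole abstract). Both readings of
  "keyword proximity" are supported, but neither is a semantic
  classifier.
* Multi-campus university systems ("University of California") are one
  entity by construction of the truncation rule.
* The Gini implementation is the plain formula; no small-sample bias
  correction or bootstrap intervals are provided.
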