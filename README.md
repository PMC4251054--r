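# sdarlink

Tools for studying the production and persistence of **Scientific Data
Analysis Resources (SDARs)** — published software, databases and web
servers that papers reference by URL — in MEDLINE-style citation
corpora.

Published URLs decay: hosts get retired, labs move, projects lose
funding. `sdarlink` implements the full measurement pipeline around that
phenomenon, for bibliometricians and research-infrastructure groups who
want to quantify it:

* **Citation I/O** — parse MEDLINE-dialect citation XML into tidy record
  tables (id, year, title, abstract, authors, affiliation) and filter by
  publication year.
* **URL extraction** — find URLs in titles/abstracts, normalize and
  deduplicate them, and diagnose entry errors (a registry link typed
  `clinical-trials.gov`, `webcitation` missing its `.org`, malformed
  DOIs) with data-driven repair rules.
* **Classification** — split *archival* URLs (DOI resolvers,
  webcitation.org, clinicaltrials.gov, journal archives) from
  author-hosted ones, and label SDARs by abstract key terms
  ("informatics", "algorithm", "software", "web server", "computer
  program").
* **Availability survey** — schedule 3 random probes/day over 10 days
  per URL and apply the accessibility rule: a URL is *accessible* iff it
  answers at least 3 of its 30 probes. Probing is an injected contract,
  so everything runs offline against a mock fetcher.
* **Concentration** — Lorenz curves, top-share statistics and the Gini
  coefficient over ascending-sorted entity counts
  `G = Σᵢ (2i − n − 1) xᵢ / (n² µ)`, plus annual Gini trend fits.
* **Decay modelling** — logistic regression of decay on `SDAR_Age`
  (years since publication), `NumAuthors` and publication-year effects,
  with Wald tables, likelihood-ratio deviance comparisons, dual
  sequential ANOVA decompositions, odds ratios, and Welch
  unequal-variance comparisons of authorship.
* **Synthetic corpora** — a seed-deterministic generator emitting
  MEDLINE-dialect XML plus ground-truth tables, so every stage and every
  statistical claim is testable without downloads.

## Worked example

```r
library(sdarlink)
library(dplyr)

corpus <- generate_corpus(sim_config(n_records = 1000, seed = 42))
corpus
#> Synthetic MEDLINE corpus: 1000 records (1996-2013), 601 URLs (79 archival, 287 SDAR)

obs <- corpus$records |>
  extract_urls() |>
  deduplicate_urls() |>
  diagnose_urls() |>
  classify_urls(corpus$records)
count(obs, class)
#> # A tibble: 3 × 2
#>   class        n
#>   <chr>    <int>
#> 1 archival    79
#> 2 other      235
#> 3 sdar       287

logs <- run_survey(plan_survey(obs$normalized_url, seed = 43),
                   mock_fetcher(corpus$urls, seed = 43))
mean(logs$accessible)          # 65.7% of URLs answered >= 3 of 30 probes

design <- build_design(obs, logs, corpus$records, survey_year = 2014)
fit <- fit_decay_model(design, decay ~ SDAR_Age + NumAuthors)
tidy(fit)
#> # A tibble: 3 × 5
#>   term        estimate std_error      z  p_value
#>   <chr>          <dbl>     <dbl>  <dbl>    <dbl>
#> 1 (Intercept)  -3.07      0.562  -5.47  4.62e- 8
#> 2 SDAR_Age      0.247     0.0327  7.56  3.88e-14
#> 3 NumAuthors    0.0628    0.0785  0.800 4.24e- 1
odds_ratio(tidy(fit)$estimate[2])   # 1.28: each year of age multiplies decay odds
```

Each added year of resource age multiplies the odds of decay by ~1.3 in
this corpus (the generator's truth is 0.268 on the log-odds scale);
author count is a weak effect at this sample size. Concentration of
production across institutions:

```r
inst <- extract_institution(corpus$records$affiliation)
counts <- count(inst, institution, name = "n") |>
  tidyr::drop_na() |>
  drop_singletons()
concentration(tibble::tibble(entity = counts$institution, n = counts$n))
#> Concentration over 49 entities (mean count 20.39)
#>   Gini: 0.634
#>   top_0.01 share: 25.9%
#>   top_0.1 share: 54.4%
```

The Gini of 0.63 reproduces the generator's configured institution
concentration (0.62) after the full parse–extract–normalize round trip.
`plot_lorenz()`, `plot_decay_curve()`, `plot_author_trends()` and the
`autoplot()` methods draw the standard figures; `tidy()`/`glance()`
methods cover the fitted objects.

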