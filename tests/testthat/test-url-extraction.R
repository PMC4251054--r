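test_that("URL matching strips sentence punctuation and keeps balanced parens", {
  hit <- find_urls("available at http://clinicaltrials.gov/ct2/show/NCT1.")[[1]]
  expect_equal(hit$raw_text, "http://clinicaltrials.gov/ct2/show/NCT1")
  expect_equal(nrow(find_urls("no links here")[[1]]), 0)

  cases <- c(
    "see (http://a.org/x) for details" = "http://a.org/x",
    "tool (http://a.org/x(1)) works"   = "http://a.org/x(1)",
    "at www.example.org/Path;"         = "www.example.org/Path",
    "ftp://files.example.org/data,"    = "ftp://files.example.org/data"
  )
  for (txt in names(cases)) {
    expect_equal(find_urls(txt)[[1]]$raw_text, unname(cases[txt]), label = txt)
  }
})

test_that("extraction is position-stable under concatenation", {
  a <- "First http://one.example.org/a here."
  b <- "Then www.two.example.org and http://three.example.org/c."
  joined <- find_urls(paste(a, b))[[1]]
  separate <- c(find_urls(a)[[1]]$raw_text, find_urls(b)[[1]]$raw_text)
  expect_equal(joined$raw_text, separate)
})

test_that("normalization lowercases scheme and host only, imputing http for www", {
  expect_equal(normalize_url("HTTP://ClinicalTrials.GOV/ct2/show/NCT1"),
               "http://clinicaltrials.gov/ct2/show/NCT1")
  expect_equal(normalize_url("www.Example.org/CaseSensitive"),
               "http://www.example.org/CaseSensitive")
})

test_that("extraction recovers generator ground truth with recall and precision 1", {
  corpus <- shared_corpus
  obs <- extract_urls(corpus$records)
  expect_setequal(obs$normalized_url, corpus$urls$normalized_url)
  expect_equal(nrow(obs), nrow(corpus$urls))
})

test_that("deduplication keeps the earliest year and is idempotent", {
  obs <- tibble::tibble(
    citation_id = c("a", "b"), pub_year = c(2005L, 1999L),
    raw_text = "http://x.org/t", normalized_url = "http://x.org/t"
  )
  out <- deduplicate_urls(obs)
  expect_equal(nrow(out), 1)
  expect_equal(out$pub_year, 1999L)

  distinct_obs <- extract_urls(shared_corpus$records)
  expect_identical(
    deduplicate_urls(distinct_obs)$normalized_url,
    distinct_obs$normalized_url  # all-distinct input: identity
  )
  once <- deduplicate_urls(distinct_obs)
  expect_equal(deduplicate_urls(once)$normalized_url, once$normalized_url)
  # set-cardinality oracle on a corpus with forced duplicates
  dup <- dplyr::bind_rows(distinct_obs, distinct_obs[1:20, ])
  expect_equal(nrow(deduplicate_urls(dup)),
               length(unique(dup$normalized_url)))
})

test_that("diagnosis reproduces the documented entry-error classes", {
  obs <- tibble::tibble(normalized_url = c(
    "http://www.webcitation/query?id=5",
    "http://clinical-trials.gov/ct2/show/NCT2",
    "http://clinicaltrails.gov/ct2/show/NCT3",
    "http://clinicaltrials.gov/ct2/show/NCT4"
  ))
  d <- diagnose_urls(obs)
  expect_equal(d$diagnosis,
               c("repairable", "repairable", "repairable", "well_formed"))
  expect_equal(d$suggested_repair[1:3], c(
    "http://www.webcitation.org/query?id=5",
    "http://clinicaltrials.gov/ct2/show/NCT2",
    "http://clinicaltrials.gov/ct2/show/NCT3"
  ))
})

test_that("suggested repairs always satisfy the URL grammar and match truth", {
  obs <- classified_obs(error_corpus)
  tab <- dplyr::left_join(obs, error_corpus$urls, by = "normalized_url")
  err <- dplyr::filter(tab, injected_error, archival_kind != "doi")
  expect_gt(nrow(err), 30)
  expect_true(all(err$diagnosis == "repairable"))
  expect_true(all(sdarlink:::is_wellformed_url(err$suggested_repair)))
  expect_equal(err$suggested_repair, err$correct_url)
})

test_that("DOI validation classifies a hand-labeled mutation set", {
  expect_equal(validate_doi("http://dx.doi.org/10.1186/1471-2105-99-S1-S9"),
               "valid_format")
  expect_equal(validate_doi("http://dx.doi.org/1471-2105-99"),
               "missing_field")
  fixture <- tibble::tribble(
    ~input,                                         ~expected,
    "10.1186/1471-2105-99-S1-S9",                   "valid_format",
    "doi:10.1000/xyz123",                           "valid_format",
    "http://doi.org/10.99999/a.b/c",                "valid_format",
    "10.1186/",                                     "missing_field",
    "10.1186",                                      "missing_field",
    "1186/1471-2105",                               "missing_field",
    "http://dx.doi.org/",                           "missing_field",
    "10./suffix",                                   "missing_field",
    "10.1186 /1471-2105-99",                        "repairable",
    "10. 1186/1471-2105-99",                        "repairable",
    "10,1186/1471-2105-99",                         "repairable",
    "http://dx.doi.org/10.1186/1471 2105",          "repairable",
    "10.1/ok",                                      "missing_field",
    "10.12/ok",                                     "valid_format",
    "doi:10.5555/12345678",                         "valid_format",
    "DOI:10.5555/12345678",                         "valid_format",
    "http://dx.doi.org/10.1093/nar/gkt1001",        "valid_format",
    "nar/gkt1001",                                  "missing_field",
    "10.2105-15-S11",                               "missing_field",
    "http://dx.doi.org/10,1093/nar/gkt1001",        "repairable"
  )
  expect_equal(validate_doi(fixture$input), fixture$expected)
})
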