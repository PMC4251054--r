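# Synthetic MEDLINE corpus generator with full ground truth.
#
# Emulates the structures the pipeline consumes: citation records over a
# year range with author counts whose mean grows linearly by year,
# comma-templated affiliation strings drawn from institution and ZIP
# catalogs with calibrated concentration, abstracts embedding URLs and
# SDAR key terms at configurable rates, archival URLs corrupted with the
# documented entry-error classes, and per-URL accessibility realized
# from a logistic decay model in resource age and author count.
# Deliberately hard affiliation cases (leading "The", diacritics, ZIP+4,
# country-less US strings) appear at configurable rates. Ground truth is
# returned as separate tables, never embedded in the XML.

#' Synthetic corpus configuration
#'
#' @param n_records Number of citation records.
#' @param year_range Inclusive publication-year range.
#' @param authors_mean_base Mean author count in the first year.
#' @param authors_mean_slope Yearly growth of the mean author count
#'   (authors/year); counts are `1 + Poisson(mean - 1)`.
#' @param url_rate Fraction of records whose abstract embeds a URL.
#' @param sdar_keyword_rate Fraction of non-archival-URL abstracts that
#'   receive an SDAR key term near the URL.
#' @param archival_rate Fraction of URLs pointing at archival hosts (DOI
#'   resolver, clinical-trials registry, webcitation archive).
#' @param error_injection_rate Fraction of archival URLs corrupted with a
#'   documented entry-error class (default the observed 3.4% rate).
#' @param n_institutions,institution_gini Institution catalog size and
#'   target concentration of records across it (calibrated Zipf weights).
#' @param n_zips,zip_gini ZIP catalog size and target concentration.
#' @param nonus_rate Fraction of affiliations based outside the US.
#' @param leading_the_rate,diacritic_rate,zip_plus4_rate,countryless_us_rate
#'   Rates of the hard affiliation cases.
#' @param decay_betas Named vector `c(intercept, age, authors)` of the
#'   true decay logit; defaults are the coefficient scale observed for
#'   published SDARs (intercept -2.88, +0.268/year of age, -0.0236/author).
#' @param intermittent_rate Fraction of non-archival URLs that are
#'   intermittently available (per-probe success drawn in 0.15–0.7)
#'   rather than cleanly up or down.
#' @param survey_year Year of the availability survey.
#' @param seed Integer seed; same seed and config give a byte-identical
#'   corpus.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_records = 1000,
                       year_range = c(1996, 2013),
                       authors_mean_base = 3.5,
                       authors_mean_slope = 0.1,
                       url_rate = 0.6,
                       sdar_keyword_rate = 0.5,
                       archival_rate = 0.1,
                       error_injection_rate = 0.034,
                       n_institutions = 50,
                       institution_gini = 0.62,
                       n_zips = 40,
                       zip_gini = 0.65,
                       nonus_rate = 0.3,
                       leading_the_rate = 0.15,
                       diacritic_rate = 0.1,
                       zip_plus4_rate = 0.2,
                       countryless_us_rate = 0.15,
                       decay_betas = c(intercept = -2.88, age = 0.268,
                                       authors = -0.0236),
                       intermittent_rate = 0.02,
                       survey_year = 2014,
                       seed) {
  rates <- c(url_rate = url_rate, sdar_keyword_rate = sdar_keyword_rate,
             archival_rate = archival_rate,
             error_injection_rate = error_injection_rate,
             nonus_rate = nonus_rate, leading_the_rate = leading_the_rate,
             diacritic_rate = diacritic_rate,
             zip_plus4_rate = zip_plus4_rate,
             countryless_us_rate = countryless_us_rate,
             intermittent_rate = intermittent_rate)
  if (any(rates < 0 | rates > 1)) {
    abort(paste("rates must lie in [0, 1]; offending:",
                paste(names(rates)[rates < 0 | rates > 1], collapse = ", ")))
  }
  if (n_records < 1) abort("`n_records` must be >= 1")
  if (year_range[1] > year_range[2]) abort("invalid `year_range`")
  if (url_rate > 0 && (n_institutions < 1 || n_zips < 1)) {
    abort("non-empty institution and ZIP catalogs required when url_rate > 0")
  }
  if (missing(seed)) abort("`seed` is required for reproducibility")
  structure(
    list(n_records = as.integer(n_records),
         year_range = as.integer(year_range),
         authors_mean_base = authors_mean_base,
         authors_mean_slope = authors_mean_slope,
         url_rate = url_rate, sdar_keyword_rate = sdar_keyword_rate,
         archival_rate = archival_rate,
         error_injection_rate = error_injection_rate,
         n_institutions = as.integer(n_institutions),
         institution_gini = institution_gini,
         n_zips = as.integer(n_zips), zip_gini = zip_gini,
         nonus_rate = nonus_rate, leading_the_rate = leading_the_rate,
         diacritic_rate = diacritic_rate, zip_plus4_rate = zip_plus4_rate,
         countryless_us_rate = countryless_us_rate,
         decay_betas = decay_betas,
         intermittent_rate = intermittent_rate,
         survey_year = as.integer(survey_year),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Calibrate a count vector to a target Gini coefficient
#'
#' Returns entity production weights from the Zipf family
#' `w_i = i^(-s)`, with the exponent solved so that `gini(w)` is within
#' 0.02 of `target_gini`. The exact maximum `(n-1)/n` is handled by the
#' degenerate one-entity-holds-all vector; targets beyond it error.
#'
#' @param n_entities Number of entities.
#' @param target_gini Target concentration in `[0, (n-1)/n]`.
#' @return Numeric weight vector of length `n_entities`, descending.
#' @examples
#' gini(concentration_calibrator(50, 0.62))
#' @export
concentration_calibrator <- function(n_entities, target_gini) {
  if (target_gini < 0 || target_gini >= 1) {
    abort("`target_gini` must be in [0, 1)")
  }
  gmax <- (n_entities - 1) / n_entities
  if (abs(target_gini - gmax) < 1e-9) {
    return(c(1, rep(0, n_entities - 1)))
  }
  if (target_gini > gmax) {
    abort(sprintf(
      "target Gini %.3f unreachable with %d entities (max %.3f)",
      target_gini, n_entities, gmax))
  }
  if (target_gini == 0) return(rep(1, n_entities))
  g_of <- function(s) gini(seq_len(n_entities)^(-s))
  upper <- 1
  while (g_of(upper) < target_gini && upper < 64) upper <- upper * 2
  if (g_of(upper) < target_gini) {
    abort(sprintf("target Gini %.3f unreachable with %d entities",
                  target_gini, n_entities))
  }
  s <- stats::uniroot(function(s) g_of(s) - target_gini,
                      c(0, upper), tol = 1e-10)$root
  w <- seq_len(n_entities)^(-s)
  if (abs(gini(w) - target_gini) > 0.02) {
    abort("calibration failed to reach target within 0.02")
  }
  w
}

# --- name pools -------------------------------------------------------

place_names <- function(n) {
  a <- c("Ar", "Bel", "Cor", "Dun", "El", "Fen", "Gal", "Hol", "Is",
         "Jor", "Kel", "Lor", "Mar", "Nor", "Or", "Pel", "Quin", "Ros",
         "Sel", "Tor")
  b <- c("dale", "berg", "ford", "ham", "mont", "wick", "more", "ton",
         "brook", "haven")
  grid <- as.vector(outer(a, b, paste0))
  if (n > length(grid)) abort("place-name pool exhausted")
  grid[seq_len(n)]
}

surname_pool <- function() {
  a <- c("Ald", "Bren", "Cald", "Dor", "Ever", "Fal", "Gren", "Hart",
         "Ing", "Jun", "Kell", "Lind", "Mor", "Nash", "Ost", "Parn",
         "Quill", "Rend", "Silt", "Thorn")
  b <- c("er", "on", "well", "by", "sen", "man", "ley", "wood", "stone",
         "rick")
  as.vector(outer(a, b, paste0))
}

institution_catalog <- function(n) {
  places <- place_names(n)
  form <- seq_len(n) %% 10
  name <- character(n)
  render <- character(n)
  type <- character(n)
  for (i in seq_len(n)) {
    p <- places[i]
    if (form[i] %in% c(0, 5)) {
      name[i] <- paste("University of", p); render[i] <- name[i]
      type[i] <- "university"
    } else if (form[i] %in% c(1, 6)) {
      name[i] <- paste(p, "University"); render[i] <- name[i]
      type[i] <- "university_suffixable"
    } else if (form[i] %in% c(2, 7)) {
      name[i] <- paste(p, "Institute of Technology"); render[i] <- name[i]
      type[i] <- "university"
    } else if (form[i] %in% c(3, 8)) {
      name[i] <- paste("Universite de", p)
      render[i] <- paste("Université de", p)  # diacritic render
      type[i] <- "university"
    } else if (form[i] == 4) {
      name[i] <- paste(p, "Medical College"); render[i] <- name[i]
      type[i] <- "university"
    } else {
      name[i] <- paste("Hopital", p)
      render[i] <- paste("Hôpital", p)
      type[i] <- "hospital"
    }
  }
  tibble(institution = name, render = render, type = type)
}

sdar_phrases <- c(
  "We present a software package for this task.",
  "An algorithm for rapid screening is introduced.",
  "A web server implementing the approach is provided.",
  "The computer program supports batch processing.",
  "An informatics framework underlies the resource."
)

filler_sentences <- c(
  "We examined longitudinal marker dynamics in a synthetic cohort.",
  "Measurements were collected across repeated sampling waves.",
  "The findings were consistent across demonstration subgroups.",
  "Replication used an independent synthetic panel."
)

# --- generator --------------------------------------------------------

#' Generate a synthetic MEDLINE corpus with ground truth
#'
#' Realizes a corpus under a [sim_config()]: citation records (with
#' authors and affiliation strings), embedded URLs with known classes and
#' injected entry errors, and realized per-URL accessibility. Two runs
#' with the same config produce identical output.
#'
#' @param config A [sim_config()].
#' @return A `sdar_corpus` list:
#' \describe{
#'   \item{records}{citation tibble, the shape [read_medline_xml()]
#'     returns.}
#'   \item{urls}{per-URL ground truth: as-written and correct forms,
#'     true class (`archival`/`sdar`/`other`), injected-error class,
#'     decay probability, realized accessibility, intermittency.}
#'   \item{affiliations}{per-record true institution, ZIP and country.}
#'   \item{institution_weights, zip_weights}{the calibrated catalogs.}
#'   \item{config}{the input configuration.}
#' }
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(cfg) {
  n <- cfg$n_records
  id <- sprintf("SYN%06d", seq_len(n))
  years <- sample(seq(cfg$year_range[1], cfg$year_range[2]), n,
                  replace = TRUE)

  mean_authors <- cfg$authors_mean_base +
    cfg$authors_mean_slope * (years - cfg$year_range[1])
  author_count <- 1L + rpois(n, pmax(mean_authors - 1, 0))
  surnames <- surname_pool()
  initials_pool <- apply(expand.grid(LETTERS, c("", LETTERS[1:10])), 1,
                         paste0, collapse = "")
  total_authors <- sum(author_count)
  all_names <- paste(sample(surnames, total_authors, replace = TRUE),
                     sample(initials_pool, total_authors, replace = TRUE))
  authors <- split(all_names, rep(seq_len(n), author_count))
  authors <- unname(authors[as.character(seq_len(n))])

  # --- affiliations ---
  inst_w <- concentration_calibrator(cfg$n_institutions,
                                     cfg$institution_gini)
  zip_w <- concentration_calibrator(cfg$n_zips, cfg$zip_gini)
  catalog <- institution_catalog(cfg$n_institutions)
  zips <- sprintf("%05d", sample(10000:99899, cfg$n_zips))
  cities <- place_names(cfg$n_institutions)
  states <- c("OK", "MA", "CA", "NY", "TX", "WA", "MN", "PA", "MI", "IA")
  nonus_countries <- c("France", "Germany", "Italy", "Japan", "Canada",
                       "Spain", "Sweden", "China", "Australia", "India")

  inst_idx <- sample(cfg$n_institutions, n, replace = TRUE, prob = inst_w)
  zip_idx <- sample(cfg$n_zips, n, replace = TRUE, prob = zip_w)
  nonus <- runif(n) < cfg$nonus_rate
  lead_the <- runif(n) < cfg$leading_the_rate
  suffix_med <- runif(n) < 0.3
  plus4 <- runif(n) < cfg$zip_plus4_rate
  countryless <- runif(n) < cfg$countryless_us_rate
  dept <- runif(n) < 0.4
  use_diacritic <- runif(n) < cfg$diacritic_rate

  inst_name <- catalog$institution[inst_idx]
  inst_type <- catalog$type[inst_idx]
  inst_txt <- ifelse(use_diacritic, catalog$render[inst_idx], inst_name)
  inst_txt <- ifelse(inst_type == "university_suffixable" & suffix_med,
                     paste(inst_txt, "School of Medicine"), inst_txt)
  inst_txt <- ifelse(lead_the & inst_type != "hospital",
                     paste("The", inst_txt), inst_txt)
  dept_txt <- ifelse(dept & inst_type != "hospital",
                     "Department of Synthetic Studies, ", "")

  zip_txt <- zips[zip_idx]
  zip_full <- ifelse(plus4, paste0(zip_txt, sprintf("-%04d",
                                                    sample(1000:9999, n, replace = TRUE))),
                     zip_txt)
  city <- cities[sample(cfg$n_institutions, n, replace = TRUE)]
  state <- sample(states, n, replace = TRUE)
  country <- sample(nonus_countries, n, replace = TRUE)

  affiliation <- ifelse(
    nonus,
    paste0(dept_txt, inst_txt, ", ", city, ", ", country),
    paste0(dept_txt, inst_txt, ", ", city, ", ", state, " ", zip_full,
           ifelse(countryless, "", ", USA"))
  )
  truth_institution <- inst_name  # catalog name survives all renderings
  truth_zip <- ifelse(nonus, NA_character_, zip_txt)

  # --- URLs ---
  has_url <- runif(n) < cfg$url_rate
  is_archival <- has_url & (runif(n) < cfg$archival_rate)
  kind_draw <- sample(c("doi", "clinicaltrials", "webcitation"), n,
                      replace = TRUE)
  archival_kind <- ifelse(is_archival, kind_draw, NA_character_)
  correct_url <- rep(NA_character_, n)
  correct_url[has_url & !is_archival] <-
    paste0("http://lab", tolower(id[has_url & !is_archival]),
           ".example.org/tool")
  ai <- which(is_archival)
  correct_url[ai] <- vapply(ai, function(i) {
    switch(archival_kind[i],
           doi = paste0("http://dx.doi.org/10.1186/synth-", id[i]),
           clinicaltrials = paste0("http://clinicaltrials.gov/ct2/show/NCT",
                                   sub("SYN", "", id[i])),
           webcitation = paste0("http://www.webcitation.org/query?id=",
                                sub("SYN0*", "", id[i])))
  }, character(1))

  err <- is_archival & (runif(n) < cfg$error_injection_rate)
  error_class <- rep(NA_character_, n)
  written_url <- correct_url
  ct_errors <- c("hyphenated clinical-trials", "trials misspelled as trails",
                 "clinicaltrials missing top-level domain")
  ct_pick <- sample(ct_errors, n, replace = TRUE)
  for (i in which(err)) {
    if (archival_kind[i] == "doi") {
      error_class[i] <- "missing DOI registrant field"
      written_url[i] <- sub("10\\.1186/", "", correct_url[i])
    } else if (archival_kind[i] == "webcitation") {
      error_class[i] <- "webcitation missing .org suffix"
      written_url[i] <- sub("webcitation\\.org", "webcitation",
                            correct_url[i])
    } else {
      error_class[i] <- ct_pick[i]
      written_url[i] <- switch(
        ct_pick[i],
        "hyphenated clinical-trials" =
          sub("clinicaltrials\\.gov", "clinical-trials.gov", correct_url[i]),
        "trials misspelled as trails" =
          sub("clinicaltrials\\.gov", "clinicaltrails.gov", correct_url[i]),
        "clinicaltrials missing top-level domain" =
          sub("clinicaltrials\\.gov", "clinicaltrials", correct_url[i])
      )
    }
  }

  # --- SDAR keywords ---
  sdar <- has_url & !is_archival & (runif(n) < cfg$sdar_keyword_rate)
  phrase <- sample(sdar_phrases, n, replace = TRUE)
  filler1 <- sample(filler_sentences, n, replace = TRUE)
  filler2 <- sample(filler_sentences, n, replace = TRUE)
  abstract <- ifelse(
    has_url,
    paste0(filler1, " ", ifelse(sdar, paste0(phrase, " "), ""),
           "The resource is available at ", written_url, ". ", filler2),
    ifelse(runif(n) < 0.1, "", paste0(filler1, " ", filler2))
  )
  title <- paste0("A synthetic cohort study of marker dynamics (",
                  id, ")")

  # --- accessibility ---
  age <- cfg$survey_year - years
  b <- cfg$decay_betas
  p_decay <- stats::plogis(b[["intercept"]] + b[["age"]] * age +
                             b[["authors"]] * author_count)
  decayed <- rep(NA, n)
  nonarch <- has_url & !is_archival
  decayed[nonarch] <- runif(sum(nonarch)) < p_decay[nonarch]
  # archival URLs are accessible unless their written form is corrupted
  decayed[is_archival] <- err[is_archival]
  intermittent <- nonarch & !decayed & (runif(n) < cfg$intermittent_rate /
                                          mean(!decayed[nonarch]))
  # floor 0.25 keeps P(<3 of 30 successes) ~ 2e-3, so the realized
  # threshold decision almost surely agrees with the stored truth;
  # ceiling 0.7 keeps P(>=27 of 30) negligible, below the 0.9 band edge
  p_success <- ifelse(intermittent, runif(n, 0.25, 0.7), NA_real_)

  records <- tibble(
    citation_id = id, pub_year = as.integer(years), title = title,
    abstract = abstract, author_count = as.integer(author_count),
    authors = authors, affiliation = affiliation
  )
  urls <- tibble(
    citation_id = id[has_url],
    pub_year = as.integer(years[has_url]),
    url = written_url[has_url],
    normalized_url = normalize_url(written_url[has_url]),
    correct_url = normalize_url(correct_url[has_url]),
    class = ifelse(is_archival[has_url], "archival",
                   ifelse(sdar[has_url], "sdar", "other")),
    archival_kind = archival_kind[has_url],
    injected_error = err[has_url],
    error_class = error_class[has_url],
    author_count = as.integer(author_count[has_url]),
    sdar_age = as.integer(age[has_url]),
    p_decay = unname(p_decay[has_url]),
    accessible = !decayed[has_url],
    intermittent = intermittent[has_url],
    p_success = p_success[has_url]
  )
  affiliations <- tibble(
    citation_id = id,
    institution = truth_institution,
    zip5 = truth_zip,
    country = ifelse(nonus, country, "USA"),
    template_conforming = TRUE
  )
  structure(
    list(records = records, urls = urls, affiliations = affiliations,
         institution_weights = inst_w, zip_weights = zip_w,
         config = cfg),
    class = "sdar_corpus"
  )
}

#' @export
print.sdar_corpus <- function(x, ...) {
  cat(sprintf(
    "Synthetic MEDLINE corpus: %d records (%d-%d), %d URLs (%d archival, %d SDAR)\n",
    nrow(x$records), x$config$year_range[1], x$config$year_range[2],
    nrow(x$urls), sum(x$urls$class == "archival"),
    sum(x$urls$class == "sdar")))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' MEDLINE-dialect XML plus ground-truth CSVs (kept out of the XML so
#' parsers cannot leak truth).
#'
#' @param corpus A `sdar_corpus` from [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly; writes `corpus.xml`, `truth_urls.csv`,
#'   `truth_affiliations.csv`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "sdar_corpus"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_medline_xml(corpus$records, file.path(dir, "corpus.xml"))
  utils::write.csv(corpus$urls, file.path(dir, "truth_urls.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$affiliations,
                   file.path(dir, "truth_affiliations.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Mock probe fetcher answering from ground truth
#'
#' Builds a `function(url, time)` probe contract for [run_survey()] from
#' a corpus's URL ground truth: accessible non-intermittent URLs always
#' succeed, inaccessible ones always fail, and intermittent URLs succeed
#' with their stored per-probe probability, deterministically in
#' `(url, time, seed)`. Probing an unknown URL warns and fails.
#'
#' @param truth URL ground-truth tibble with `normalized_url`,
#'   `accessible`, `intermittent`, `p_success`.
#' @param seed Integer controlling the intermittent outcome stream.
#' @return A fetcher closure.
#' @export
mock_fetcher <- function(truth, seed = 1) {
  assert_df_cols(truth, c("normalized_url", "accessible", "intermittent",
                          "p_success"))
  lookup <- truth[!duplicated(truth$normalized_url), ]
  rownames_idx <- setNames(seq_len(nrow(lookup)), lookup$normalized_url)
  function(url, time) {
    i <- rownames_idx[url]
    if (is.na(i)) {
      warn(sprintf("probe for unknown URL: %s", url))
      return(FALSE)
    }
    if (!lookup$accessible[i]) return(FALSE)
    if (!lookup$intermittent[i]) return(TRUE)
    u <- hash_seed(paste0(url, "@", as.numeric(time)), salt = seed) /
      2147483646
    u < lookup$p_success[i]
  }
}
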