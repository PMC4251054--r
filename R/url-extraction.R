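# URL discovery, normalization, deduplication and format-error diagnosis.
#
# The URL grammar: a scheme-prefixed form (http, https, ftp) or a bare
# "www."-prefixed host (scheme imputed as http). Trailing sentence
# punctuation is stripped; a trailing ")" or "]" only when unbalanced
# within the match, so parenthesized path segments survive.

url_pattern <- "(?i)\\b(?:(?:https?|ftp)://|www\\.)[^\\s<>\"']+"

strip_trailing_punct <- function(u) {
  repeat {
    last <- stringr::str_sub(u, -1)
    if (last %in% c(".", ",", ";", ":", "!", "?")) {
      u <- stringr::str_sub(u, 1, -2)
    } else if (last == ")" &&
               stringr::str_count(u, "\\(") < stringr::str_count(u, "\\)")) {
      u <- stringr::str_sub(u, 1, -2)
    } else if (last == "]" &&
               stringr::str_count(u, "\\[") < stringr::str_count(u, "\\]")) {
      u <- stringr::str_sub(u, 1, -2)
    } else {
      return(u)
    }
  }
}

#' Find URLs in free text
#'
#' Returns every maximal substring of `text` matching the URL grammar, in
#' order of occurrence, with trailing sentence punctuation stripped.
#' Deterministic and position-stable: the result on two texts joined by
#' whitespace is the concatenation of the per-text results.
#'
#' @param text Character vector of plain text (entities already decoded).
#' @return A list (one element per input string) of tibbles with `raw_text`
#'   (as matched, after punctuation stripping) and `position` (1-based
#'   character offset of the match start).
#' @examples
#' find_urls("available at http://clinicaltrials.gov/ct2/show/NCT1.")
#' @export
find_urls <- function(text) {
  locs <- stringr::str_locate_all(text, url_pattern)
  matches <- stringr::str_extract_all(text, url_pattern)
  purrr::map2(matches, locs, function(m, l) {
    if (length(m) == 0) {
      return(tibble(raw_text = character(), position = integer()))
    }
    tibble(
      raw_text = vapply(m, strip_trailing_punct, character(1),
                        USE.NAMES = FALSE),
      position = as.integer(l[, "start"])
    )
  })
}

#' Normalize a URL to canonical form
#'
#' Lowercases the scheme and host (DNS is case-insensitive) while leaving
#' the path untouched (paths are case-sensitive), and imputes `http://`
#' for bare `www.`-prefixed matches.
#'
#' @param url Character vector of raw URL strings.
#' @return Character vector of normalized URLs.
#' @examples
#' normalize_url(c("HTTP://ClinicalTrials.GOV/ct2/show/NCT1", "www.example.org/P"))
#' @export
normalize_url <- function(url) {
  url <- ifelse(grepl("^(?i)(https?|ftp)://", url, perl = TRUE),
                url, paste0("http://", url))
  m <- regexec("^([A-Za-z]+)://([^/?#]+)(.*)$", url)
  parts <- regmatches(url, m)
  vapply(seq_along(url), function(i) {
    p <- parts[[i]]
    if (length(p) == 0) return(url[i])
    paste0(tolower(p[2]), "://", tolower(p[3]), p[4])
  }, character(1))
}

url_host <- function(url) {
  sub("^[a-z]+://([^/?#]+).*$", "\\1", url)
}

# Grammar check on a normalized URL: known scheme, dotted host of
# DNS-legal characters.
is_wellformed_url <- function(url) {
  grepl("^(https?|ftp)://[a-z0-9-]+(\\.[a-z0-9-]+)+(:[0-9]+)?([/?#]|$)",
        url)
}

#' Extract URL observations from citation records
#'
#' Scans the title and abstract of each record for URLs and returns one
#' observation per distinct normalized URL per record (a URL appearing in
#' both title and abstract of the same record is counted once). `position`
#' is the character offset of the first occurrence within its source field,
#' used by proximity-window SDAR classification.
#'
#' @param records Record tibble with `citation_id`, `pub_year`, `title`,
#'   `abstract` columns.
#' @return Tibble with `citation_id`, `pub_year`, `raw_text`,
#'   `normalized_url`, `source` (`"title"` or `"abstract"`), `position`.
#' @export
extract_urls <- function(records) {
  assert_df_cols(records, c("citation_id", "pub_year", "title", "abstract"))
  in_title <- find_urls(records$title)
  in_abstract <- find_urls(records$abstract)
  per_record <- purrr::pmap(
    list(records$citation_id, records$pub_year, in_title, in_abstract),
    function(id, yr, ti, ab) {
      hits <- bind_rows(
        mutate(ti, source = "title"),
        mutate(ab, source = "abstract")
      )
      if (nrow(hits) == 0) return(NULL)
      hits$citation_id <- id
      hits$pub_year <- yr
      hits$normalized_url <- normalize_url(hits$raw_text)
      hits[!duplicated(hits$normalized_url), ]
    }
  )
  out <- bind_rows(per_record)
  if (nrow(out) == 0) {
    return(tibble(citation_id = character(), pub_year = integer(),
                  raw_text = character(), normalized_url = character(),
                  source = character(), position = integer()))
  }
  select(out, "citation_id", "pub_year", "raw_text", "normalized_url",
         "source", "position")
}

#' Deduplicate URL observations corpus-wide
#'
#' Keeps one observation per distinct `normalized_url`; when a URL occurs
#' in several records the earliest `pub_year` occurrence is kept (ties
#' broken by input order). Idempotent.
#'
#' @param observations Tibble from [extract_urls()].
#' @return Deduplicated tibble; the number of distinct URLs is `nrow()` and
#'   is also attached as attribute `"n_unique"`.
#' @export
deduplicate_urls <- function(observations) {
  assert_df_cols(observations, c("normalized_url", "pub_year"))
  ord <- order(observations$pub_year, seq_len(nrow(observations)))
  obs <- observations[ord, , drop = FALSE]
  obs <- obs[!duplicated(obs$normalized_url), , drop = FALSE]
  obs <- obs[order(match(obs$normalized_url, observations$normalized_url)), ,
             drop = FALSE]
  attr(obs, "n_unique") <- nrow(obs)
  obs
}

#' Default URL repair rules
#'
#' The documented entry-error classes seen in published abstracts: the
#' webcitation.org archive cited without its ".org" suffix, the clinical
#' trials registry cited as "clinical-trials.gov" (which does not
#' redirect), "trials" misspelled "trails", and the registry host cited
#' with no top-level domain at all. Rules are data: a tibble of Perl
#' regular expressions, replacements and labels, editable or replaceable
#' via [read_repair_rules()].
#'
#' @return Tibble with `pattern`, `replacement`, `label`.
#' @export
default_repair_rules <- function() {
  read_repair_rules(system.file("extdata", "repair_rules.csv",
                                package = "sdarlink", mustWork = TRUE))
}

#' Read URL repair rules from a CSV config file
#'
#' @param path CSV with columns `pattern`, `replacement`, `label`.
#' @return Tibble of rules.
#' @export
read_repair_rules <- function(path) {
  rules <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  assert_df_cols(rules, c("pattern", "replacement", "label"))
  as_tibble(rules)
}

#' Diagnose URL format errors
#'
#' Labels each observation `well_formed`, `repairable` or `malformed`.
#' A URL is `repairable` when exactly one repair rule fires; the repaired
#' form is returned in `suggested_repair` (and always satisfies the URL
#' grammar itself). A URL violating the grammar with no applicable rule is
#' `malformed`; otherwise it is `well_formed`.
#'
#' @param observations Tibble with a `normalized_url` column.
#' @param rules Repair rule tibble, see [default_repair_rules()].
#' @return `observations` with `diagnosis` and `suggested_repair`
#'   (`NA` unless repairable) columns added.
#' @examples
#' obs <- tibble::tibble(normalized_url = "http://www.webcitation/query?id=5")
#' diagnose_urls(obs)
#' @export
diagnose_urls <- function(observations, rules = default_repair_rules()) {
  assert_df_cols(observations, "normalized_url")
  urls <- observations$normalized_url
  fired <- vapply(seq_len(nrow(rules)), function(i) {
    grepl(rules$pattern[i], urls, perl = TRUE)
  }, logical(length(urls)))
  fired <- matrix(fired, nrow = length(urls))
  n_fired <- rowSums(fired)

  repair <- rep(NA_character_, length(urls))
  idx <- which(n_fired == 1)
  for (i in idx) {
    r <- which(fired[i, ])
    repair[i] <- normalize_url(
      gsub(rules$pattern[r], rules$replacement[r], urls[i], perl = TRUE)
    )
  }
  diagnosis <- ifelse(
    n_fired == 1, "repairable",
    ifelse(is_wellformed_url(urls), "well_formed", "malformed")
  )
  observations$diagnosis <- diagnosis
  observations$suggested_repair <- repair
  observations
}

#' Validate DOI format
#'
#' Checks whether a string (a bare DOI, a `doi:` form, or a DOI-resolver
#' URL) carries the standard `10.<registrant>/<suffix>` body.
#'
#' @param url_or_doi Character vector.
#' @return Character vector with values `"valid_format"` (the body is
#'   present and well-formed), `"repairable"` (a trivial fix -- removing
#'   stray internal whitespace or a comma typed for the registrant dot --
#'   yields a valid body), or `"missing_field"` (registrant prefix or
#'   suffix absent).
#' @examples
#' validate_doi("http://dx.doi.org/10.1186/1471-2105-99-S1-S9")
#' validate_doi("http://dx.doi.org/1471-2105-99")
#' @export
validate_doi <- function(url_or_doi) {
  body <- sub("(?i)^https?://(dx\\.)?doi\\.org/", "", url_or_doi, perl = TRUE)
  body <- sub("(?i)^doi:\\s*", "", body, perl = TRUE)
  valid <- function(b) grepl("^10\\.\\d{2,9}/\\S+$", b)
  vapply(body, function(b) {
    if (valid(b)) return("valid_format")
    fixed <- gsub("\\s+", "", b)
    fixed <- sub("^10,", "10.", fixed)
    if (valid(fixed)) return("repairable")
    "missing_field"
  }, character(1), USE.NAMES = FALSE)
}
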