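# Archival vs SDAR classification.
#
# Archival URLs (DOI resolvers, webcitation.org, clinicaltrials.gov,
# journal archives) are maintained by organizations and expected stable;
# they are separated from author-hosted URLs by host. Non-archival URLs
# are labelled SDAR when an SDAR key term co-occurs with the URL in the
# abstract. Code-hosting sites (code.google.com, sourceforge.net) host
# author resources despite their organizational domains, so they are
# explicitly exempt from the archival list.

#' Classification configuration
#'
#' @param archival_domains Host suffixes treated as archival. The default
#'   seeds the documented examples (DOI resolvers, webcitation.org,
#'   clinicaltrials.gov) plus a small journal-archive placeholder list;
#'   a full deployment supplies its own curated list.
#' @param sdar_exempt_hosts Hosts never archival even if matched (SDAR
#'   code-hosting organizations).
#' @param sdar_keywords Key terms whose presence near the URL marks an
#'   SDAR. Matched case-insensitively as raw substrings, so "algorithms"
#'   matches via "algorithm".
#' @param proximity_window Characters either side of the URL within which
#'   a keyword must fall, or `Inf` for whole-abstract co-occurrence (the
#'   default reading).
#' @return A `classification_config` list.
#' @export
classification_config <- function(
    archival_domains = c("doi.org", "dx.doi.org", "webcitation.org",
                         "clinicaltrials.gov",
                         "jmir.org", "biomedcentral.com", "nature.com"),
    sdar_exempt_hosts = c("code.google.com", "sourceforge.net"),
    sdar_keywords = c("informatics", "algorithm", "software", "web server",
                      "computer program"),
    proximity_window = Inf) {
  overlap <- intersect(tolower(archival_domains), tolower(sdar_exempt_hosts))
  if (length(overlap) > 0) {
    abort(paste0("archival_domains and sdar_exempt_hosts overlap: ",
                 paste(overlap, collapse = ", ")))
  }
  if (length(sdar_keywords) == 0) abort("sdar_keywords must be non-empty")
  structure(
    list(archival_domains = tolower(archival_domains),
         sdar_exempt_hosts = tolower(sdar_exempt_hosts),
         sdar_keywords = tolower(sdar_keywords),
         proximity_window = proximity_window),
    class = "classification_config"
  )
}

host_matches <- function(host, domains) {
  vapply(host, function(h) {
    any(h == domains | endsWith(h, paste0(".", domains)))
  }, logical(1), USE.NAMES = FALSE)
}

#' Classify URLs as archival or non-archival
#'
#' A URL is archival when its host matches the configured archival domain
#' list (by exact host or parent-domain suffix) and is not an exempt
#' code-hosting host. DOI-resolver URLs are always archival. When the
#' observations carry a `suggested_repair` column (from
#' [diagnose_urls()]), classification uses the repaired form where one
#' exists: a mistyped registry link is still a registry link.
#'
#' @param observations Tibble with `normalized_url` (and optionally
#'   `suggested_repair`).
#' @param config A [classification_config()].
#' @return `observations` with a logical `archival` column added.
#' @examples
#' obs <- tibble::tibble(normalized_url = c(
#'   "http://dx.doi.org/10.1186/x", "http://sourceforge.net/projects/x"))
#' classify_archival(obs)$archival
#' @export
classify_archival <- function(observations, config = classification_config()) {
  assert_df_cols(observations, "normalized_url")
  url <- observations$normalized_url
  if ("suggested_repair" %in% names(observations)) {
    url <- dplyr::coalesce(observations$suggested_repair, url)
  }
  host <- url_host(url)
  is_doi <- host_matches(host, c("doi.org", "dx.doi.org"))
  archival <- is_doi |
    (host_matches(host, config$archival_domains) &
       !host_matches(host, config$sdar_exempt_hosts))
  observations$archival <- archival
  observations
}

#' Classify non-archival URLs as SDARs by abstract key terms
#'
#' A non-archival URL is an SDAR when at least one configured keyword
#' occurs (case-insensitively) within the proximity window of the URL.
#' With the default whole-abstract window this is keyword/URL
#' co-occurrence in the abstract; a finite window restricts to the
#' `proximity_window` characters either side of the URL match.
#'
#' @param observations Tibble from [extract_urls()] (needs `citation_id`,
#'   `position`, `source`) with an `archival` column from
#'   [classify_archival()].
#' @param records Record tibble supplying abstracts by `citation_id`.
#' @param config A [classification_config()].
#' @return `observations` with logical `sdar` (always `FALSE` for archival
#'   rows) and `class` (`"archival"`, `"sdar"`, `"other"`) columns added:
#'   every URL lands in exactly one class.
#' @export
classify_sdar <- function(observations, records,
                          config = classification_config()) {
  assert_df_cols(observations, c("citation_id", "normalized_url", "archival",
                                 "position", "source"))
  assert_df_cols(records, c("citation_id", "abstract"))
  abstracts <- setNames(tolower(records$abstract), records$citation_id)
  window <- config$proximity_window
  kw <- config$sdar_keywords

  sdar <- vapply(seq_len(nrow(observations)), function(i) {
    if (observations$archival[i]) return(FALSE)
    ab <- abstracts[[observations$citation_id[i]]]
    if (is.null(ab) || !nzchar(ab)) return(FALSE)
    if (is.infinite(window)) {
      hay <- ab
    } else {
      # window anchored on the URL's abstract occurrence; title URLs fall
      # back to whole-abstract
      if (observations$source[i] == "abstract") {
        start <- max(1L, observations$position[i] - window)
        end <- min(nchar(ab),
                   observations$position[i] +
                     nchar(observations$raw_text[i]) + window)
        hay <- substr(ab, start, end)
      } else {
        hay <- ab
      }
    }
    any(vapply(kw, function(k) grepl(k, hay, fixed = TRUE), logical(1)))
  }, logical(1))

  observations$sdar <- sdar
  observations$class <- ifelse(observations$archival, "archival",
                               ifelse(sdar, "sdar", "other"))
  observations
}

#' Classify URLs end-to-end
#'
#' Convenience wrapper: [classify_archival()] then [classify_sdar()].
#'
#' @inheritParams classify_sdar
#' @return Observations with `archival`, `sdar` and `class` columns.
#' @export
classify_urls <- function(observations, records,
                          config = classification_config()) {
  observations %>%
    classify_archival(config) %>%
    classify_sdar(records, config)
}
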