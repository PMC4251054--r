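# Institution and ZIP extraction from raw MEDLINE Affiliation strings.
#
# The goal is the most generic identifier that uniquely names an entity:
# the string is tokenized on commas, then scanned with a prioritized
# keyword list so that university-level tokens beat department- and
# hospital-level ones. Names are transliterated to ASCII (publisher
# transliteration of non-English names is inconsistent), compared
# case-insensitively, stripped of a leading "The", and text after
# "University" is dropped when text precedes it ("Foo University School
# of Medicine" -> "Foo University", while "University of Foo" is kept).

#' Default institution keyword table
#'
#' Prioritized, multilingual keyword stems (lower number = higher
#' priority): university-type stems first ("Universi" covers English,
#' French, German, Italian, Portuguese and Spanish spellings), then
#' school/department-type, then hospital-type ("hopital", "Istituto" and
#' friends cover common non-English forms after transliteration). Shipped
#' as an editable CSV config.
#'
#' @return Tibble with `keyword` (ASCII, lowercase), `priority`, `type`.
#' @export
default_institution_keywords <- function() {
  kw <- utils::read.csv(
    system.file("extdata", "institution_keywords.csv",
                package = "sdarlink", mustWork = TRUE),
    stringsAsFactors = FALSE
  )
  as_tibble(kw[order(kw$priority), ])
}

#' Default non-US country name list
#'
#' Used by the US-ness test in [extract_zip()]: an affiliation with no
#' "USA"/"United States" marker is still treated as US-based as long as
#' it names no other country. Shipped as an editable plain-text config.
#'
#' @return Character vector of country names.
#' @export
default_country_names <- function() {
  readLines(system.file("extdata", "countries.txt",
                        package = "sdarlink", mustWork = TRUE))
}

normalize_institution_token <- function(token) {
  token <- trimws(gsub("\\s+", " ", token))
  token <- sub("(?i)^the\\s+", "", token, perl = TRUE)
  # keep up to and including "University" when text precedes it
  m <- regexpr("(?i)universit(y|a|e|at|aet)?", token, perl = TRUE)
  if (m > 1) {
    token <- substr(token, 1, m + attr(m, "match.length") - 1)
  }
  trimws(token, whitespace = "[\\s[:punct:]]")
}

#' Extract a normalized institution name from an affiliation string
#'
#' Tokenizes on commas, masks email addresses, then scans tokens with the
#' prioritized keyword table; the highest-priority keyword that fires
#' anywhere wins, and its token is normalized. Idempotent on its own
#' output and invariant (up to letter case) to input case.
#'
#' @param affiliation Character vector of raw affiliation strings.
#' @param keywords Keyword table, see [default_institution_keywords()].
#' @return Tibble with `raw`, `institution` (`NA` when no keyword fires)
#'   and `matched_keyword`.
#' @examples
#' extract_institution("Foo University School of Medicine, Anytown")$institution
#' extract_institution("The University of California, San Diego")$institution
#' @export
extract_institution <- function(affiliation,
                                keywords = default_institution_keywords()) {
  kw <- keywords$keyword[order(keywords$priority)]
  one <- function(raw) {
    x <- to_ascii(raw)
    x <- gsub("\\S+@\\S+", " ", x)        # mask emails
    tokens <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0) {
      return(list(institution = NA_character_,
                  matched_keyword = NA_character_))
    }
    scan <- tolower(gsub("[0-9]+", " ", tokens))  # mask postal codes
    for (k in kw) {
      hit <- which(stringr::str_detect(scan, stringr::fixed(k)))
      if (length(hit) > 0) {
        return(list(institution = normalize_institution_token(tokens[hit[1]]),
                    matched_keyword = k))
      }
    }
    list(institution = NA_character_, matched_keyword = NA_character_)
  }
  res <- lapply(affiliation, one)
  tibble(
    raw = affiliation,
    institution = vapply(res, `[[`, character(1), "institution"),
    matched_keyword = vapply(res, `[[`, character(1), "matched_keyword")
  )
}

#' Drop entities seen only once
#'
#' Affiliation parsing is noisy; an institution string appearing a single
#' time corpus-wide is more likely a parse artifact than a real entity,
#' so singleton entities are excluded before concentration analysis.
#'
#' @param counts Either a tibble with an `n` count column, or a named
#'   numeric vector of counts.
#' @return Same shape as the input, with count-1 entries removed.
#' @examples
#' drop_singletons(c(A = 5, B = 1))
#' @export
drop_singletons <- function(counts) {
  if (is.data.frame(counts)) {
    assert_df_cols(counts, "n")
    counts[counts$n != 1, , drop = FALSE]
  } else {
    counts[counts != 1]
  }
}

#' Extract a 5-digit US ZIP code from an affiliation string
#'
#' The string must first look US-based: containing "USA" or "United
#' States", or at least naming no other country. The ZIP is then the last
#' 5-digit token not embedded in a longer digit run (ZIP+4 forms are
#' truncated to the leading five digits), matching the convention that
#' ZIPs close US addresses.
#'
#' @param affiliation Character vector.
#' @param country_names Non-US country list for the US-ness test.
#' @return Tibble with `raw` and `zip5` (`NA` when absent); `zip5` always
#'   matches `\\d{5}` exactly when present.
#' @examples
#' extract_zip("Oklahoma City, OK 73104-5005, USA")$zip5
#' extract_zip("75005 Paris, France")$zip5
#' @export
extract_zip <- function(affiliation, country_names = default_country_names()) {
  country_re <- paste0("(?i)\\b(", paste(country_names, collapse = "|"),
                       ")\\b")
  one <- function(raw) {
    x <- to_ascii(raw)
    x <- gsub("\\S+@\\S+", " ", x)
    us <- grepl("\\bUSA\\b", x) || grepl("(?i)\\bUnited States\\b", x, perl = TRUE) ||
      !grepl(country_re, x, perl = TRUE)
    if (!us) return(NA_character_)
    hits <- stringr::str_extract_all(
      x, "(?<![0-9-])[0-9]{5}(-[0-9]{4})?(?![0-9])")[[1]]
    if (length(hits) == 0) return(NA_character_)
    substr(hits[length(hits)], 1, 5)
  }
  tibble(
    raw = affiliation,
    zip5 = vapply(affiliation, one, character(1), USE.NAMES = FALSE)
  )
}
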