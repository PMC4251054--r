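#' Read MEDLINE-format citation XML
#'
#' Parses a MEDLINE/PubMed-dialect citation XML file into a tibble with one
#' row per citation. Only the fields the downstream analysis uses are kept:
#' identifier, publication year, title, abstract, author list and the raw
#' affiliation string. All other MEDLINE elements are ignored.
#'
#' Publication year is taken from the first available of `PubDate/Year`,
#' `ArticleDate/Year`, `DateCompleted/Year` (in that precedence order).
#' Records with no parseable year are skipped and logged, not errored:
#' the skip log is attached as the `"skip_log"` attribute (a tibble with
#' `citation_id` and `reason`).
#'
#' @param path Path to a MEDLINE-format XML file. Malformed XML raises a
#'   parse error naming the offending position.
#' @return A tibble with columns `citation_id`, `pub_year`, `title`,
#'   `abstract`, `author_count`, `authors` (list column of
#'   `"LastName Initials"` strings, last element = senior author) and
#'   `affiliation`. Missing abstracts and affiliations are empty strings.
#' @examples
#' corpus <- generate_corpus(sim_config(n_records = 5, seed = 1))
#' path <- tempfile(fileext = ".xml")
#' write_medline_xml(corpus$records, path)
#' read_medline_xml(path)
#' @export
read_medline_xml <- function(path) {
  doc <- xml2::read_xml(path)
  cites <- xml2::xml_find_all(doc, "//MedlineCitation")

  one <- function(node) {
    id <- xml2::xml_text(xml2::xml_find_first(node, "./PMID"))
    year <- NA_integer_
    for (xp in c(".//Article//PubDate/Year", ".//ArticleDate/Year",
                 ".//DateCompleted/Year")) {
      y <- xml2::xml_text(xml2::xml_find_first(node, xp))
      if (!is.na(y) && grepl("^\\d{4}$", y)) {
        year <- as.integer(y)
        break
      }
    }
    authors <- xml2::xml_find_all(node, ".//AuthorList/Author")
    author_names <- vapply(authors, function(a) {
      last <- xml2::xml_text(xml2::xml_find_first(a, "./LastName"))
      init <- xml2::xml_text(xml2::xml_find_first(a, "./Initials"))
      trimws(paste(last, if (is.na(init)) "" else init))
    }, character(1))
    abstract <- paste(
      xml2::xml_text(xml2::xml_find_all(node, ".//Abstract/AbstractText")),
      collapse = " "
    )
    affil <- xml2::xml_text(xml2::xml_find_first(node, ".//Affiliation"))
    list(
      citation_id = if (is.na(id)) "" else id,
      pub_year = year,
      title = xml2::xml_text(xml2::xml_find_first(node, ".//ArticleTitle")),
      abstract = abstract,
      author_names = author_names,
      affiliation = if (is.na(affil)) "" else affil
    )
  }

  parsed <- lapply(cites, one)
  years <- vapply(parsed, function(p) p$pub_year, integer(1))
  keep <- !is.na(years)

  skip_log <- tibble(
    citation_id = vapply(parsed[!keep], function(p) p$citation_id, character(1)),
    reason = rep("missing publication year", sum(!keep))
  )
  parsed <- parsed[keep]

  records <- tibble(
    citation_id = vapply(parsed, function(p) p$citation_id, character(1)),
    pub_year = vapply(parsed, function(p) p$pub_year, integer(1)),
    title = vapply(parsed, function(p) {
      if (is.na(p$title)) "" else p$title
    }, character(1)),
    abstract = vapply(parsed, function(p) p$abstract, character(1)),
    author_count = vapply(parsed, function(p) length(p$author_names), integer(1)),
    authors = lapply(parsed, function(p) p$author_names),
    affiliation = vapply(parsed, function(p) p$affiliation, character(1))
  )
  attr(records, "skip_log") <- skip_log
  records
}

#' Write citation records as MEDLINE-format XML
#'
#' Serializes a record tibble (as returned by [read_medline_xml()] or
#' [generate_corpus()]) back to the MEDLINE citation dialect, so corpora
#' round-trip through the reader.
#'
#' @param records Tibble with `citation_id`, `pub_year`, `title`,
#'   `abstract`, `authors` (list column) and `affiliation` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_medline_xml <- function(records, path) {
  assert_df_cols(records, c("citation_id", "pub_year", "title", "abstract",
                            "authors", "affiliation"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  author_xml <- vapply(records$authors, function(a) {
    if (length(a) == 0) return("")
    last <- sub("\\s+\\S*$", "", a)
    init <- ifelse(grepl("\\s", a), sub("^.*\\s+", "", a), "")
    paste0(
      "<AuthorList>",
      paste0("<Author><LastName>", esc(last), "</LastName><Initials>",
             esc(init), "</Initials></Author>", collapse = ""),
      "</AuthorList>"
    )
  }, character(1))
  abstract_xml <- ifelse(
    nzchar(records$abstract),
    paste0("<Abstract><AbstractText>", esc(records$abstract),
           "</AbstractText></Abstract>"),
    ""
  )
  affil_xml <- ifelse(
    nzchar(records$affiliation),
    paste0("<Affiliation>", esc(records$affiliation), "</Affiliation>"),
    ""
  )
  body <- paste0(
    "<MedlineCitation><PMID>", esc(records$citation_id), "</PMID><Article>",
    "<Journal><JournalIssue><PubDate><Year>", records$pub_year,
    "</Year></PubDate></JournalIssue></Journal>",
    "<ArticleTitle>", esc(records$title), "</ArticleTitle>",
    abstract_xml, author_xml, affil_xml,
    "</Article></MedlineCitation>"
  )
  writeLines(
    c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
      "<MedlineCitationSet>", body, "</MedlineCitationSet>"),
    path, useBytes = TRUE
  )
  invisible(path)
}

#' Filter citation records by publication year
#'
#' Keeps records with `min_year <= pub_year <= max_year` whose year is not
#' in `exclude_years`, preserving order. Excluding the survey year itself
#' avoids the indexing-lag bias of partially indexed recent journals.
#' Idempotent: filtering twice with the same bounds changes nothing.
#'
#' @param records Record tibble with a `pub_year` column.
#' @param min_year,max_year Inclusive year bounds.
#' @param exclude_years Integer vector of years to drop outright.
#' @return The filtered tibble.
#' @examples
#' recs <- tibble::tibble(citation_id = as.character(1:4),
#'                        pub_year = c(1995L, 1996L, 2013L, 2014L))
#' filter_records(recs, 1996, 2013)$pub_year
#' @export
filter_records <- function(records, min_year, max_year,
                           exclude_years = integer()) {
  assert_df_cols(records, "pub_year")
  if (min_year > max_year) abort("`min_year` must be <= `max_year`")
  records[records$pub_year >= min_year & records$pub_year <= max_year &
            !(records$pub_year %in% exclude_years), , drop = FALSE]
}
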