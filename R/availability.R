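# The repeated-probe availability survey: each URL is probed at random
# times (default 3 per day over 10 days, 30 probes) and called accessible
# when it answers at least `min_successes` (default 3) of them. The low
# threshold deliberately counts intermittently-available URLs as
# accessible: a resource answering even a few probes is reachable in
# principle, while one answering almost never has decayed.

#' Plan a probe survey
#'
#' Draws, for every URL, `per_day` probe times uniformly at random within
#' each of `days` consecutive days. Identical seeds give identical
#' schedules.
#'
#' @param urls Character vector of normalized URLs (may be empty).
#' @param days,per_day Survey extent; defaults give the 30-probe design.
#' @param seed Integer seed controlling the schedule draw.
#' @param start Date of the first survey day.
#' @return Tibble with `url`, `probe` (1..days*per_day, in time order
#'   within URL), `day`, and `time` (POSIXct, UTC).
#' @examples
#' plan_survey("http://example.org", seed = 1)
#' @export
plan_survey <- function(urls, days = 10, per_day = 3, seed,
                        start = as.Date("2014-03-05")) {
  if (days < 1 || per_day < 1) abort("`days` and `per_day` must be >= 1")
  if (length(urls) == 0) {
    return(tibble(url = character(), probe = integer(), day = integer(),
                  time = as.POSIXct(character(), tz = "UTC")))
  }
  n_per_url <- days * per_day
  offsets <- with_seed(seed, {
    # seconds since survey start, per_day draws within each day
    day_idx <- rep(rep(seq_len(days) - 1L, each = per_day), length(urls))
    day_idx * 86400 + runif(length(urls) * n_per_url, 0, 86400)
  })
  plan <- tibble(
    url = rep(urls, each = n_per_url),
    day = rep(rep(seq_len(days), each = per_day), length(urls)),
    time = as.POSIXct(as.numeric(as.POSIXct(start, tz = "UTC")) + offsets,
                      tz = "UTC", origin = "1970-01-01")
  )
  plan <- plan %>% group_by(.data$url) %>% arrange(.data$time, .by_group = TRUE) %>%
    mutate(probe = row_number()) %>% ungroup()
  plan[order(match(plan$url, urls), plan$probe),
       c("url", "probe", "day", "time")]
}

#' Execute a probe survey
#'
#' Runs every scheduled probe through the fetcher and derives the
#' per-URL accessibility decision. The fetcher is an injected contract —
#' any `function(url, time)` returning `TRUE` (success) or `FALSE`; tests
#' and offline analyses use [mock_fetcher()] over synthetic ground truth,
#' a live deployment would wrap an HTTP client (success = status < 400
#' after redirects, within a timeout). A fetcher error on one probe is
#' recorded as a failure and logged; it never aborts the survey.
#'
#' @param plan Schedule tibble from [plan_survey()].
#' @param fetcher `function(url, time) -> logical(1)`.
#' @param min_successes Accessibility threshold: a URL is accessible iff
#'   it succeeds on at least this many probes (default 3).
#' @return Per-URL tibble with `url`, `outcomes` (list of logicals in
#'   probe-time order), `successes`, `n_probes`, `availability_fraction`
#'   and `accessible`. Probe-level detail is attached as attribute
#'   `"probes"` (tibble url/probe/time/success) and fetcher errors as
#'   attribute `"error_log"`.
#' @export
run_survey <- function(plan, fetcher, min_successes = 3) {
  assert_df_cols(plan, c("url", "probe", "time"))
  errors <- character()
  success <- vapply(seq_len(nrow(plan)), function(i) {
    tryCatch(
      isTRUE(fetcher(plan$url[i], plan$time[i])),
      error = function(e) {
        errors[[length(errors) + 1L]] <<-
          sprintf("%s @ %s: %s", plan$url[i],
                  format(plan$time[i]), conditionMessage(e))
        FALSE
      }
    )
  }, logical(1))
  probes <- mutate(plan, success = success)
  logs <- probes %>%
    group_by(.data$url) %>%
    arrange(.data$probe, .by_group = TRUE) %>%
    summarise(
      outcomes = list(.data$success),
      successes = sum(.data$success),
      n_probes = n(),
      .groups = "drop"
    ) %>%
    mutate(
      availability_fraction = .data$successes / .data$n_probes,
      accessible = .data$successes >= min_successes
    )
  logs <- logs[match(unique(plan$url), logs$url), ]
  attr(logs, "probes") <- probes
  attr(logs, "error_log") <- errors
  logs
}

#' Summarise intermittent availability
#'
#' Fraction of surveyed URLs that were available some but less than 90%
#' of the time — the signature of flaky hosting rather than clean decay —
#' plus the full availability-fraction histogram (bins of width 0.1).
#'
#' @param logs Survey log tibble from [run_survey()].
#' @return List with `fraction` (scalar; `NA` with a warning on empty
#'   input) and `histogram` (tibble `bin`, `n`).
#' @export
intermittency_summary <- function(logs) {
  assert_df_cols(logs, "availability_fraction")
  f <- logs$availability_fraction
  if (length(f) == 0) {
    warn("no probe logs: intermittency fraction undefined")
    return(list(fraction = NA_real_,
                histogram = tibble(bin = character(), n = integer())))
  }
  breaks <- seq(0, 1, by = 0.1)
  bins <- cut(f, breaks = breaks, include.lowest = TRUE, right = FALSE)
  # top bin must include exactly-1 fractions
  bins[f == 1] <- levels(bins)[length(levels(bins))]
  hist <- tibble(bin = levels(bins),
                 n = as.integer(table(bins)[levels(bins)]))
  list(fraction = mean(f > 0 & f < 0.9), histogram = hist)
}

#' Per-year accessible fraction (the decay curve)
#'
#' Joins survey logs to each URL's publication year and tabulates, per
#' year, how many URLs were surveyed and what fraction proved accessible.
#' Older publication years show lower fractions under time-dependent
#' decay.
#'
#' @param logs Survey log tibble (`url`, `accessible`).
#' @param observations URL observation tibble (`normalized_url`,
#'   `pub_year`); each surveyed URL must join to exactly one year.
#' @return Tibble `pub_year`, `n_urls`, `n_accessible`, `fraction`.
#' @export
decay_curve <- function(logs, observations) {
  assert_df_cols(logs, c("url", "accessible"))
  assert_df_cols(observations, c("normalized_url", "pub_year"))
  joined <- left_join(
    select(logs, "url", "accessible"),
    distinct(observations, .data$normalized_url, .data$pub_year),
    by = c(url = "normalized_url")
  )
  if (anyNA(joined$pub_year)) {
    abort("some surveyed URLs have no publication year in `observations`")
  }
  joined %>%
    group_by(.data$pub_year) %>%
    summarise(
      n_urls = n(),
      n_accessible = sum(.data$accessible),
      fraction = .data$n_accessible / .data$n_urls,
      .groups = "drop"
    ) %>%
    arrange(.data$pub_year)
}
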