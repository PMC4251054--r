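# Concentration of publication output across entities (institutions or
# ZIP codes): Gini coefficient, Lorenz curve, top-share statistics and
# annual trend fits.

check_counts <- function(counts) {
  if (length(counts) == 0) abort("`counts` must be non-empty")
  if (any(counts < 0)) abort("`counts` must be non-negative")
  if (all(counts == 0)) {
    abort("Gini is undefined for all-zero counts (no mass to distribute)")
  }
  invisible(counts)
}

#' Gini coefficient of a count distribution
#'
#' Computes `G = sum_i (2i - n - 1) x_i / (n^2 mu)` over the
#' ascending-sorted counts `x_1 <= ... <= x_n` with mean `mu` — the
#' classical mean-difference form. 0 means every entity produced the
#' same number of publications; (n-1)/n (tending to 1) means one entity
#' produced everything. Scale-invariant and permutation-invariant.
#'
#' @param counts Non-negative numeric vector, not all zero (all-zero
#'   input is an explicit error).
#' @return `G` in `[0, 1]`.
#' @examples
#' gini(c(5, 5, 5, 5))   # 0
#' gini(c(0, 0, 0, 10))  # 0.75 = (n-1)/n
#' @export
gini <- function(counts) {
  check_counts(counts)
  x <- sort(counts)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Lorenz curve of a count distribution
#'
#' Cumulative share of total output held by the bottom fraction of
#' entities (sorted ascending), anchored at (0,0) and (1,1). The curve is
#' non-decreasing and convex; twice the area between it and the diagonal
#' equals the Gini coefficient.
#'
#' @inheritParams gini
#' @return Tibble with `p` (population fraction) and `share` (cumulative
#'   count share), `length(counts) + 1` rows.
#' @export
lorenz_curve <- function(counts) {
  check_counts(counts)
  x <- sort(counts)
  n <- length(x)
  tibble(p = c(0, seq_len(n) / n),
         share = c(0, cumsum(x) / sum(x)))
}

#' Share of output held by the top fraction of entities
#'
#' Entities are sorted by descending count (ties broken deterministically
#' by entity label) and the top `ceiling(fraction * n)` entities' counts
#' are summed over the grand total.
#'
#' @param counts Named numeric vector, or tibble with `entity` and `n`
#'   columns.
#' @param fraction Top fraction of entities, in (0, 1].
#' @return Share in `[0, 1]`; `top_share(x, 1)` is exactly 1.
#' @examples
#' top_share(c(a = 97, b = 1, c = 1, d = 1), 0.25)
#' @export
top_share <- function(counts, fraction = 0.01) {
  if (is.data.frame(counts)) {
    assert_df_cols(counts, c("entity", "n"))
    values <- counts$n
    labels <- counts$entity
  } else {
    values <- as.numeric(counts)
    labels <- if (!is.null(names(counts))) names(counts) else
      as.character(seq_along(counts))
  }
  check_counts(values)
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  ord <- order(-values, labels)
  k <- ceiling(fraction * length(values))
  sum(values[ord][seq_len(k)]) / sum(values)
}

#' Full concentration analysis of one count distribution
#'
#' Bundles [gini()], [lorenz_curve()] and [top_share()] for a set of
#' entity counts into a `concentration` object with [tidy()], [glance()]
#' and [autoplot()] methods.
#'
#' @inheritParams top_share
#' @param top_fractions Fractions to report top-shares for.
#' @return A `concentration` object: list with `x` (sorted counts), `n`,
#'   `mu`, `gini`, `lorenz` (tibble), `top_shares` (named vector).
#' @export
concentration <- function(counts, top_fractions = c(0.01, 0.1)) {
  values <- if (is.data.frame(counts)) counts$n else as.numeric(counts)
  check_counts(values)
  shares <- vapply(top_fractions, function(f) top_share(counts, f),
                   numeric(1))
  structure(
    list(
      x = sort(values),
      n = length(values),
      mu = mean(values),
      gini = gini(values),
      lorenz = lorenz_curve(values),
      top_shares = setNames(shares, paste0("top_", top_fractions))
    ),
    class = "concentration"
  )
}

#' @export
print.concentration <- function(x, ...) {
  cat(sprintf("Concentration over %d entities (mean count %.2f)\n",
              x$n, x$mu))
  cat(sprintf("  Gini: %.3f\n", x$gini))
  for (nm in names(x$top_shares)) {
    cat(sprintf("  %s share: %.1f%%\n", nm, 100 * x$top_shares[[nm]]))
  }
  invisible(x)
}

#' @rdname concentration
#' @param x A `concentration` object.
#' @param ... Unused.
#' @method tidy concentration
#' @export
tidy.concentration <- function(x, ...) {
  x$lorenz
}

#' @rdname concentration
#' @method glance concentration
#' @export
glance.concentration <- function(x, ...) {
  out <- tibble(n = x$n, mu = x$mu, gini = x$gini)
  for (nm in names(x$top_shares)) out[[nm]] <- x$top_shares[[nm]]
  out
}

#' Annual Gini trend
#'
#' Computes an annual Gini coefficient from per-year entity counts (only
#' entities active — count > 0 — in a year enter that year's
#' coefficient), then fits an ordinary least-squares line over the years.
#' The slope is reported both absolutely and as a percentage of the mean
#' annual Gini per year; a rising slope means production is becoming more
#' concentrated.
#'
#' @param counts_by_year Tibble with `year`, `entity`, `n` columns.
#' @param min_years Minimum number of usable years (default 3).
#' @return A `gini_trend` object: `per_year` tibble (`year`, `gini`,
#'   `n_entities`), `slope`, `slope_pct_per_year`, `p_value`, and the
#'   underlying `lm` fit. Years whose counts are all zero are dropped
#'   with a warning.
#' @export
annual_gini_trend <- function(counts_by_year, min_years = 3) {
  assert_df_cols(counts_by_year, c("year", "entity", "n"))
  years <- sort(unique(counts_by_year$year))
  rows <- lapply(years, function(y) {
    x <- counts_by_year$n[counts_by_year$year == y]
    x <- x[x > 0]
    if (length(x) == 0) {
      warn(sprintf("year %s has no active entities; dropped", y))
      return(NULL)
    }
    tibble(year = y, gini = gini(x), n_entities = length(x))
  })
  per_year <- bind_rows(rows)
  if (nrow(per_year) < min_years) {
    abort(sprintf("need at least %d years with computable Gini, have %d",
                  min_years, nrow(per_year)))
  }
  fit <- lm(gini ~ year, data = per_year)
  sm <- summary(fit)$coefficients
  structure(
    list(
      per_year = per_year,
      slope = unname(coef(fit)["year"]),
      slope_pct_per_year = 100 * unname(coef(fit)["year"]) /
        mean(per_year$gini),
      p_value = unname(sm["year", "Pr(>|t|)"]),
      fit = fit
    ),
    class = "gini_trend"
  )
}

#' @export
print.gini_trend <- function(x, ...) {
  cat(sprintf(
    "Annual Gini trend over %d years: slope %+.4f/yr (%+.2f%%/yr), p = %.3g\n",
    nrow(x$per_year), x$slope, x$slope_pct_per_year, x$p_value))
  invisible(x)
}

#' @rdname annual_gini_trend
#' @param x A `gini_trend` object.
#' @param ... Unused.
#' @method tidy gini_trend
#' @export
tidy.gini_trend <- function(x, ...) {
  x$per_year
}

#' @rdname annual_gini_trend
#' @method glance gini_trend
#' @export
glance.gini_trend <- function(x, ...) {
  tibble(n_years = nrow(x$per_year), slope = x$slope,
         slope_pct_per_year = x$slope_pct_per_year, p_value = x$p_value)
}
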