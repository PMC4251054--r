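# Logistic decay modelling: probability an SDAR URL has decayed
# (is inaccessible at survey time) as a function of resource age,
# author-team size and publication-year effects, plus the authorship
# comparisons between accessible and decayed resources.

#' Build the decay model design table
#'
#' Joins SDAR URL observations to their survey outcome and source record,
#' producing one row per SDAR URL with the modelling variables: `decay`
#' (1 = inaccessible), `NumAuthors`, `SDAR_Age` (whole years between
#' publication and survey) and `year` (publication year as a factor,
#' baseline = earliest year unless overridden). Rows with a missing or
#' zero author count are dropped and logged in the `"drop_log"`
#' attribute.
#'
#' Note `SDAR_Age` is an exact linear function of `year`; fitting both
#' leaves the year factor to capture only departures from the linear age
#' trend, with collinear levels aliased by the fitter.
#'
#' @param observations Classified URL tibble (rows with `class == "sdar"`
#'   are used; needs `normalized_url`, `citation_id`, `pub_year`).
#' @param logs Survey log tibble (`url`, `accessible`).
#' @param records Record tibble (`citation_id`, `author_count`).
#' @param survey_year Integer year of the availability survey.
#' @param baseline_year Baseline level for the year factor; default
#'   earliest year present.
#' @return Tibble with `normalized_url`, `decay`, `NumAuthors`,
#'   `SDAR_Age`, `year`.
#' @export
build_design <- function(observations, logs, records, survey_year,
                         baseline_year = NULL) {
  assert_df_cols(observations, c("normalized_url", "citation_id", "pub_year"))
  assert_df_cols(logs, c("url", "accessible"))
  assert_df_cols(records, c("citation_id", "author_count"))
  obs <- observations
  if ("class" %in% names(obs)) obs <- obs[obs$class == "sdar", ]
  design <- obs %>%
    left_join(select(logs, "url", "accessible"),
              by = c(normalized_url = "url")) %>%
    left_join(select(records, "citation_id", "author_count"),
              by = "citation_id")
  if (anyNA(design$accessible)) {
    abort("some SDAR URLs have no survey log entry")
  }
  bad <- is.na(design$author_count) | design$author_count < 1
  drop_log <- tibble(
    normalized_url = design$normalized_url[bad],
    reason = rep("missing author count", sum(bad))
  )
  design <- design[!bad, ]
  if (any(design$pub_year > survey_year)) {
    abort("records published after the survey year: SDAR_Age would be negative")
  }
  levels_years <- sort(unique(design$pub_year))
  baseline <- if (is.null(baseline_year)) levels_years[1] else baseline_year
  out <- tibble(
    normalized_url = design$normalized_url,
    decay = as.integer(!design$accessible),
    NumAuthors = as.integer(design$author_count),
    SDAR_Age = as.integer(survey_year - design$pub_year),
    year = stats::relevel(factor(design$pub_year, levels = levels_years),
                          ref = as.character(baseline))
  )
  attr(out, "drop_log") <- drop_log
  attr(out, "survey_year") <- survey_year
  out
}

#' Fit the logistic decay model
#'
#' Maximum-likelihood logistic regression of `decay` on the supplied
#' terms, via iteratively reweighted least squares. Reports per-term
#' estimates with standard errors, Wald `z = estimate/std_error` and
#' two-sided p-values, plus null/residual deviances and degrees of
#' freedom. Perfect separation and rank deficiency are surfaced as
#' explicit diagnostics (`separation`, `aliased` fields), never silent.
#'
#' @param design Tibble from [build_design()] (or any tibble with the
#'   formula's variables).
#' @param formula Model formula; default
#'   `decay ~ SDAR_Age + NumAuthors + year`.
#' @param epsilon,maxit Convergence tolerance on relative deviance change
#'   and iteration cap.
#' @return A `decay_fit` object with a `coefficients` tibble (`term`,
#'   `estimate`, `std_error`, `z`, `p_value`), deviance fields, and the
#'   underlying `glm` in `$fit`.
#' @export
fit_decay_model <- function(design,
                            formula = decay ~ SDAR_Age + NumAuthors + year,
                            epsilon = 1e-8, maxit = 100) {
  if (length(unique(design$decay)) < 2) {
    abort("`decay` must contain both outcome classes")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(formula, family = binomial(), data = design,
        control = list(epsilon = epsilon, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # warning-based detection misses small separated designs that converge
  # cleanly to a saturated fit; a perfect 0/1 fit is separation too
  if (all(abs(fit$fitted.values - fit$y) < 1e-6)) separation <- TRUE
  aliased <- names(which(is.na(coef(fit))))
  sm <- summary(fit)$coefficients
  coefs <- tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std_error = sm[, "Std. Error"],
    z = sm[, "z value"],
    p_value = sm[, "Pr(>|z|)"]
  )
  structure(
    list(
      coefficients = coefs,
      null_deviance = fit$null.deviance,
      null_df = fit$df.null,
      residual_deviance = fit$deviance,
      residual_df = fit$df.residual,
      n = nrow(fit$model),
      iterations = fit$iter,
      converged = fit$converged,
      separation = separation,
      aliased = aliased,
      formula = formula,
      fit = fit
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Logistic decay model: %s\n", deparse(x$formula)))
  cat(sprintf("  n = %d, residual deviance %.0f on %d df (null %.0f on %d df)\n",
              x$n, x$residual_deviance, x$residual_df,
              x$null_deviance, x$null_df))
  if (x$separation) cat("  WARNING: possible perfect separation\n")
  if (length(x$aliased) > 0) {
    cat("  aliased (collinear) terms:", paste(x$aliased, collapse = ", "), "\n")
  }
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' @rdname fit_decay_model
#' @param x A `decay_fit` object.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  x$coefficients
}

#' @rdname fit_decay_model
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(
    n = x$n,
    null_deviance = x$null_deviance, null_df = x$null_df,
    residual_deviance = x$residual_deviance, residual_df = x$residual_df,
    lr_chi2 = x$null_deviance - x$residual_deviance,
    lr_df = x$null_df - x$residual_df,
    iterations = x$iterations, converged = x$converged
  )
}

#' Odds ratio from a log-odds coefficient
#'
#' Exponentiates a logistic coefficient into a multiplicative change in
#' the decay odds per unit of the covariate, with a Wald confidence
#' interval when a standard error is supplied.
#'
#' @param estimate Log-odds coefficient(s).
#' @param std_error Optional standard error(s).
#' @param level Confidence level for the interval.
#' @return Without `std_error`, a numeric vector `exp(estimate)`;
#'   with it, a tibble `odds_ratio`, `conf_low`, `conf_high`.
#' @examples
#' odds_ratio(0.268)  # 1.307: each year of age multiplies decay odds
#' @export
odds_ratio <- function(estimate, std_error = NULL, level = 0.95) {
  if (is.null(std_error)) return(exp(estimate))
  zq <- qnorm(1 - (1 - level) / 2)
  tibble(
    odds_ratio = exp(estimate),
    conf_low = exp(estimate - zq * std_error),
    conf_high = exp(estimate + zq * std_error)
  )
}

#' Likelihood-ratio comparison against the null model
#'
#' The improvement of a fitted logistic model over the intercept-only
#' model: `lr_chi2 = null deviance - residual deviance` on
#' `lr_df = null df - residual df`, with its chi-square tail p-value.
#' Can also be applied directly to printed deviance/df pairs.
#'
#' @param fit A `decay_fit`, or the null deviance as a number.
#' @param null_df,residual_deviance,residual_df Supplied when `fit` is a
#'   bare null deviance.
#' @return Tibble `lr_chi2`, `lr_df`, `p_value`.
#' @examples
#' deviance_comparison(12890, 12047, 11502, 12035)
#' @export
deviance_comparison <- function(fit, null_df = NULL,
                                residual_deviance = NULL,
                                residual_df = NULL) {
  if (inherits(fit, "decay_fit")) {
    nd <- fit$null_deviance; ndf <- fit$null_df
    rd <- fit$residual_deviance; rdf <- fit$residual_df
  } else {
    nd <- fit; ndf <- null_df; rd <- residual_deviance; rdf <- residual_df
  }
  lr <- nd - rd
  df <- ndf - rdf
  tibble(
    lr_chi2 = lr,
    lr_df = df,
    p_value = if (df > 0) pchisq(lr, df, lower.tail = FALSE) else NA_real_
  )
}

tidy_anova_table <- function(a) {
  tab <- as.data.frame(a)
  out <- tibble(term = rownames(tab))
  for (nm in names(tab)) out[[nm]] <- tab[[nm]]
  names(out) <- c("term", gsub("[^A-Za-z0-9]+", "_", names(tab)))
  out
}

#' Sequential (Type I) ANOVA for the decay model
#'
#' Adds terms in the stated order and reports both decompositions the
#' binary-outcome literature prints: a linear-probability variant (OLS on
#' the 0/1 outcome; Df, Sum Sq, Mean Sq, F, p) and a logistic variant
#' (sequential deviance drops with chi-square tests). Term order changes
#' the sequential rows but never the full-model residual row.
#'
#' @param design Design tibble.
#' @param terms Character vector of term names in entry order.
#' @return List with `linear` and `logistic` tidy ANOVA tibbles.
#' @export
sequential_anova <- function(design,
                             terms = c("SDAR_Age", "NumAuthors", "year")) {
  f <- stats::reformulate(terms, response = "decay")
  lin <- lm(f, data = design)
  logit <- suppressWarnings(glm(f, family = binomial(), data = design))
  list(
    linear = tidy_anova_table(anova(lin)),
    logistic = tidy_anova_table(anova(logit, test = "Chisq"))
  )
}

#' Welch comparison of author counts between groups
#'
#' Two-sample t-test with unequal variances (Welch–Satterthwaite degrees
#' of freedom), two-tailed — used to compare the author-team sizes behind
#' accessible versus decayed resources, and accessibility fractions
#' between multi- and single-SDAR authors. Swapping the groups negates
#' `t` and preserves `p`. When both samples are constant with equal
#' means the comparison is vacuous: `t = 0`, `p = 1`, flagged.
#'
#' @param group_a,group_b Numeric samples (non-empty).
#' @return One-row tibble: per-group n/mean/sd, `t`, `df`, `p_value`,
#'   `flag` (`NA` or `"zero variance in both groups"`).
#' @export
compare_author_counts <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both samples must be non-empty")
  }
  base <- tibble(
    n_a = length(group_a), mean_a = mean(group_a),
    sd_a = stats::sd(group_a),
    n_b = length(group_b), mean_b = mean(group_b),
    sd_b = stats::sd(group_b)
  )
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if ((is.na(va) || va == 0) && (is.na(vb) || vb == 0)) {
    if (isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      return(mutate(base, t = 0, df = NA_real_, p_value = 1,
                    flag = "zero variance in both groups"))
    }
    return(mutate(base, t = sign(mean(group_a) - mean(group_b)) * Inf,
                  df = NA_real_, p_value = 0,
                  flag = "zero variance in both groups"))
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  mutate(base, t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, flag = NA_character_)
}

#' Senior-author SDAR production and decay analysis
#'
#' Attributes each SDAR to the senior (last-listed) author of its source
#' record, tabulates per-author SDAR counts and the fraction still
#' accessible, and compares that fraction between multi-SDAR and
#' single-SDAR authors (thresholds >= 2 and >= 5) with Welch t-tests.
#' Records without authors are excluded and logged.
#'
#' @param observations Classified URL tibble (`class == "sdar"` rows
#'   used).
#' @param logs Survey log tibble (`url`, `accessible`).
#' @param records Record tibble with an `authors` list column.
#' @param top_k Rows of the leaderboard to return.
#' @return List: `per_author` (author, n_sdars, n_accessible,
#'   frac_accessible), `top` (first `top_k` by SDAR count),
#'   `comparisons` (one row per threshold with Welch statistics), and a
#'   `drop_log` attribute on `per_author`.
#' @export
senior_author_analysis <- function(observations, logs, records, top_k = 25) {
  assert_df_cols(observations, c("normalized_url", "citation_id"))
  assert_df_cols(records, c("citation_id", "authors"))
  obs <- observations
  if ("class" %in% names(obs)) obs <- obs[obs$class == "sdar", ]
  senior <- tibble(
    citation_id = records$citation_id,
    senior_author = vapply(records$authors, function(a) {
      if (length(a) == 0) NA_character_ else a[length(a)]
    }, character(1))
  )
  joined <- obs %>%
    left_join(select(logs, "url", "accessible"),
              by = c(normalized_url = "url")) %>%
    left_join(senior, by = "citation_id")
  dropped <- is.na(joined$senior_author)
  drop_log <- tibble(
    citation_id = joined$citation_id[dropped],
    reason = rep("record has no authors", sum(dropped))
  )
  joined <- joined[!dropped, ]
  per_author <- joined %>%
    group_by(author = .data$senior_author) %>%
    summarise(
      n_sdars = n(),
      n_accessible = sum(.data$accessible),
      frac_accessible = .data$n_accessible / .data$n_sdars,
      .groups = "drop"
    ) %>%
    arrange(dplyr::desc(.data$n_sdars), .data$author)
  attr(per_author, "drop_log") <- drop_log

  single <- per_author$frac_accessible[per_author$n_sdars == 1]
  comparisons <- bind_rows(lapply(c(2, 5), function(thr) {
    multi <- per_author$frac_accessible[per_author$n_sdars >= thr]
    if (length(multi) == 0 || length(single) == 0) {
      return(tibble(threshold = thr, n_multi = length(multi),
                    n_single = length(single), t = NA_real_,
                    df = NA_real_, p_value = NA_real_))
    }
    cmp <- compare_author_counts(multi, single)
    tibble(threshold = thr, n_multi = length(multi),
           n_single = length(single),
           mean_multi = cmp$mean_a, mean_single = cmp$mean_b,
           t = cmp$t, df = cmp$df, p_value = cmp$p_value)
  }))
  list(per_author = per_author, top = head(per_author, top_k),
       comparisons = comparisons)
}

#' Authorship trends over time
#'
#' Per-year mean author counts for all papers, URL-containing papers and
#' SDAR papers, plus per-decade author-count histograms. The SDAR series
#' is flagged in the output where it sits below the overall series.
#'
#' @param records Record tibble (`citation_id`, `pub_year`,
#'   `author_count`).
#' @param observations Optional classified URL tibble; when supplied, the
#'   `url` and `sdar` series are computed over records with any URL and
#'   with an SDAR URL respectively.
#' @param bin_cap Author counts at or above this are pooled into one
#'   open-ended histogram bin.
#' @return List: `per_year` (year, group, n_papers, mean_authors),
#'   `sdar_below_overall` (year, flag) when SDAR series available,
#'   `histograms` (decade, authors, n).
#' @export
authorship_trends <- function(records, observations = NULL, bin_cap = 10) {
  assert_df_cols(records, c("citation_id", "pub_year", "author_count"))
  series <- list(all = records)
  if (!is.null(observations)) {
    url_ids <- unique(observations$citation_id)
    series$url <- records[records$citation_id %in% url_ids, ]
    if ("class" %in% names(observations)) {
      sdar_ids <- unique(observations$citation_id[observations$class == "sdar"])
      series$sdar <- records[records$citation_id %in% sdar_ids, ]
    }
  }
  per_year <- bind_rows(lapply(names(series), function(g) {
    series[[g]] %>%
      group_by(year = .data$pub_year) %>%
      summarise(n_papers = n(), mean_authors = mean(.data$author_count),
                .groups = "drop") %>%
      mutate(group = g)
  }))
  per_year <- per_year[, c("year", "group", "n_papers", "mean_authors")]

  flag <- NULL
  if (all(c("all", "sdar") %in% per_year$group)) {
    wide <- tidyr::pivot_wider(per_year[, c("year", "group", "mean_authors")],
                               names_from = "group",
                               values_from = "mean_authors")
    flag <- tibble(year = wide$year,
                   sdar_below_overall = wide$sdar < wide$all)
  }
  histograms <- records %>%
    mutate(
      decade = 10L * (.data$pub_year %/% 10L),
      authors = pmin(.data$author_count, bin_cap)
    ) %>%
    count(.data$decade, .data$authors, name = "n")
  list(per_year = per_year, sdar_below_overall = flag,
       histograms = histograms)
}
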