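test_that("design rows encode decay, age and author count by definition", {
  obs <- tibble::tibble(
    normalized_url = c("http://a.org", "http://b.org"),
    citation_id = c("r1", "r2"), pub_year = c(2010L, 2014L),
    class = "sdar"
  )
  logs <- tibble::tibble(url = obs$normalized_url,
                         accessible = c(TRUE, FALSE))
  records <- tibble::tibble(citation_id = c("r1", "r2"),
                            author_count = c(4L, 2L))
  d <- build_design(obs, logs, records, survey_year = 2014)
  expect_equal(d$decay, c(0L, 1L))
  expect_equal(d$NumAuthors, c(4L, 2L))
  expect_equal(d$SDAR_Age, c(4L, 0L))
  expect_equal(levels(d$year)[1], "2010")  # earliest year is baseline

  # missing author count drops the row with a log entry
  records$author_count[2] <- NA
  d2 <- build_design(obs, logs, records, survey_year = 2014)
  expect_equal(nrow(d2), 1)
  expect_equal(attr(d2, "drop_log")$normalized_url, "http://b.org")
})

test_that("design row count equals a brute-force join on the synthetic corpus", {
  corpus <- shared_corpus
  obs <- classified_obs(corpus)
  logs <- run_survey(plan_survey(obs$normalized_url, seed = 4),
                     mock_fetcher(corpus$urls, seed = 4))
  d <- build_design(obs, logs, corpus$records, survey_year = 2014)
  brute <- sum(obs$class == "sdar")  # every record has >= 1 author
  expect_equal(nrow(d), brute)
  # decisions agree with ground truth accessibility
  truth <- corpus$urls$accessible[match(d$normalized_url,
                                        corpus$urls$normalized_url)]
  expect_equal(d$decay, as.integer(!truth))
})

test_that("logistic fits match a from-scratch IRLS oracle on a toy design", {
  set.seed(17)
  n <- 40
  d <- tibble::tibble(
    SDAR_Age = sample(1:15, n, replace = TRUE),
    NumAuthors = sample(1:9, n, replace = TRUE)
  )
  eta <- -2 + 0.25 * d$SDAR_Age - 0.05 * d$NumAuthors
  d$decay <- as.integer(runif(n) < plogis(eta))
  fit <- fit_decay_model(d, decay ~ SDAR_Age + NumAuthors)
  X <- cbind(1, d$SDAR_Age, d$NumAuthors)
  oracle <- irls_logit(X, d$decay)
  expect_equal(unname(fit$coefficients$estimate), unname(oracle),
               tolerance = 1e-8)

  # z column identity and the likelihood-ratio/deviance identity
  expect_equal(fit$coefficients$z,
               fit$coefficients$estimate / fit$coefficients$std_error,
               tolerance = 1e-10)
  ll_full <- bernoulli_loglik(X, d$decay, oracle)
  p0 <- mean(d$decay)
  ll_null <- sum(d$decay * log(p0) + (1 - d$decay) * log(1 - p0))
  expect_equal(fit$null_deviance - fit$residual_deviance,
               2 * (ll_full - ll_null), tolerance = 1e-6)

  # intercept-only fit: residual deviance equals null deviance
  null_fit <- fit_decay_model(d, decay ~ 1)
  expect_equal(null_fit$residual_deviance, null_fit$null_deviance)
  expect_equal(nrow(deviance_comparison(null_fit)), 1)
  expect_equal(deviance_comparison(null_fit)$lr_chi2, 0)
})

test_that("degenerate designs are diagnosed, not silently fit", {
  d <- tibble::tibble(SDAR_Age = c(1, 2, 10, 11), decay = c(0L, 0L, 1L, 1L))
  fit <- fit_decay_model(d, decay ~ SDAR_Age)
  expect_true(fit$separation)
  d2 <- tibble::tibble(SDAR_Age = 1:20, Twice = 2 * (1:20),
                       decay = rep(c(0L, 1L), 10))
  fit2 <- fit_decay_model(d2, decay ~ SDAR_Age + Twice)
  expect_equal(fit2$aliased, "Twice")
  expect_error(fit_decay_model(tibble::tibble(decay = c(0L, 0L), SDAR_Age = 1:2)),
               "both outcome classes")
})

test_that("parameter recovery is unbiased across corpora at n = 5000", {
  # pooled z over 5 replicates: a biased fitter drifts away from 0, a
  # calibrated one stays within 3 sigma of it
  z_age <- z_auth <- numeric(5)
  for (r in 1:5) {
    corpus <- generate_corpus(sim_config(
      n_records = 5000, seed = 100 + r,
      decay_betas = c(intercept = -2.88, age = 0.27, authors = -0.024)))
    d <- dplyr::filter(corpus$urls, class != "archival")
    design <- tibble::tibble(decay = as.integer(!d$accessible),
                             SDAR_Age = d$sdar_age,
                             NumAuthors = d$author_count)
    co <- fit_decay_model(design, decay ~ SDAR_Age + NumAuthors)$coefficients
    z_age[r] <- (co$estimate[co$term == "SDAR_Age"] - 0.27) /
      co$std_error[co$term == "SDAR_Age"]
    z_auth[r] <- (co$estimate[co$term == "NumAuthors"] - (-0.024)) /
      co$std_error[co$term == "NumAuthors"]
  }
  expect_lt(abs(mean(z_age)) * sqrt(5), 3)
  expect_lt(abs(mean(z_auth)) * sqrt(5), 3)
})

test_that("odds ratios exponentiate log-odds with optional Wald intervals", {
  expect_equal(round(odds_ratio(0.268), 3), 1.307)
  expect_equal(odds_ratio(0), 1)
  expect_equal(round(odds_ratio(-0.0236), 4), 0.9767)
  ci <- odds_ratio(0.268, std_error = 0.022)
  expect_equal(ci$odds_ratio, exp(0.268))
  expect_equal(ci$conf_low, exp(0.268 - qnorm(0.975) * 0.022))
})

test_that("deviance comparisons recompute the likelihood-ratio test", {
  out <- deviance_comparison(12890, 12047, 11502, 12035)
  expect_equal(out$lr_chi2, 1388)
  expect_equal(out$lr_df, 12)
  expect_lt(out$p_value, 2.2e-16)
  same <- deviance_comparison(100, 50, 100, 50)
  expect_equal(same$lr_chi2, 0)
  expect_equal(same$lr_df, 0)
})

test_that("sequential ANOVA matches nested-model decompositions", {
  set.seed(23)
  n <- 120
  d <- tibble::tibble(
    SDAR_Age = sample(1:15, n, replace = TRUE),
    NumAuthors = sample(1:9, n, replace = TRUE)
  )
  d$decay <- as.integer(runif(n) < plogis(-1.5 + 0.2 * d$SDAR_Age))

  # single-term model: F equals the squared t of the OLS slope
  a1 <- sequential_anova(d, "SDAR_Age")$linear
  tt <- summary(lm(decay ~ SDAR_Age, data = d))$coefficients["SDAR_Age", "t value"]
  expect_equal(a1$F_value[1], tt^2, tolerance = 1e-10)

  # sequential Sum Sq equals nested-fit RSS differences
  a2 <- sequential_anova(d, c("SDAR_Age", "NumAuthors"))$linear
  rss <- function(f) sum(residuals(lm(f, data = d))^2)
  expect_equal(a2$Sum_Sq[1], rss(decay ~ 1) - rss(decay ~ SDAR_Age),
               tolerance = 1e-10)
  expect_equal(a2$Sum_Sq[2],
               rss(decay ~ SDAR_Age) - rss(decay ~ SDAR_Age + NumAuthors),
               tolerance = 1e-10)

  # term order permutes sequential rows but not the residual row
  a3 <- sequential_anova(d, c("NumAuthors", "SDAR_Age"))$linear
  expect_equal(a2$Sum_Sq[a2$term == "Residuals"],
               a3$Sum_Sq[a3$term == "Residuals"])
  expect_false(isTRUE(all.equal(a2$Sum_Sq[1], a3$Sum_Sq[1])))

  # logistic variant: sequential deviance drops sum to the model chi-square
  al <- sequential_anova(d, c("SDAR_Age", "NumAuthors"))$logistic
  fit <- fit_decay_model(d, decay ~ SDAR_Age + NumAuthors)
  expect_equal(sum(al$Deviance, na.rm = TRUE),
               fit$null_deviance - fit$residual_deviance, tolerance = 1e-8)
})

test_that("Welch comparisons match hand-computed statistics and are symmetric", {
  same <- compare_author_counts(c(2, 4, 6), c(2, 4, 6))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  a <- 1:6; b <- 2:7
  got <- compare_author_counts(a, b)
  # hand computation of Welch's statistic and df
  se2 <- var(a) / 6 + var(b) / 6
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 6)^2 / 5 + (var(b) / 6)^2 / 5)
  expect_equal(got$t, t_hand, tolerance = 1e-12)
  expect_equal(got$df, df_hand, tolerance = 1e-12)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  flipped <- compare_author_counts(b, a)
  expect_equal(flipped$t, -got$t)
  expect_equal(flipped$p_value, got$p_value)

  const <- compare_author_counts(c(3, 3, 3), c(3, 3))
  expect_equal(const$p_value, 1)
  expect_equal(const$flag, "zero variance in both groups")
})

test_that("senior-author tables aggregate SDARs by last-listed author", {
  obs <- tibble::tibble(
    normalized_url = paste0("http://u", 1:4, ".org"),
    citation_id = paste0("r", 1:4), class = "sdar"
  )
  logs <- tibble::tibble(url = obs$normalized_url,
                         accessible = c(TRUE, FALSE, TRUE, TRUE))
  records <- tibble::tibble(
    citation_id = paste0("r", 1:4),
    authors = list(c("First A", "Thornwell K"), c("Solo B", "Thornwell K"),
                   c("Lindsen A"), character())
  )
  res <- senior_author_analysis(obs, logs, records)
  rag <- res$per_author[res$per_author$author == "Thornwell K", ]
  expect_equal(rag$n_sdars, 2)
  expect_equal(rag$frac_accessible, 0.5)
  expect_equal(attr(res$per_author, "drop_log")$citation_id, "r4")

  # group-by oracle on the synthetic corpus
  corpus <- shared_corpus
  cobs <- classified_obs(corpus)
  clogs <- run_survey(plan_survey(cobs$normalized_url, seed = 8),
                      mock_fetcher(corpus$urls, seed = 8))
  full <- senior_author_analysis(cobs, clogs, corpus$records)
  sdar_obs <- cobs[cobs$class == "sdar", ]
  senior <- vapply(corpus$records$authors[match(sdar_obs$citation_id,
                                                corpus$records$citation_id)],
                   function(a) a[length(a)], character(1))
  expect_equal(sum(full$per_author$n_sdars), nrow(sdar_obs))
  expect_equal(sort(unique(full$per_author$author)), sort(unique(senior)))
  brute <- table(senior)
  expect_equal(full$per_author$n_sdars[match(names(brute), full$per_author$author)],
               as.integer(brute))
  expect_equal(nrow(full$top), min(25, nrow(full$per_author)))
})

test_that("authorship trends recover the generator's mean growth", {
  one <- tibble::tibble(citation_id = c("a", "b"), pub_year = 2005L,
                        author_count = 3L)
  tr <- authorship_trends(one)
  expect_equal(tr$per_year$mean_authors, 3)

  corpus <- shared_corpus
  obs <- classified_obs(corpus)
  tr2 <- authorship_trends(corpus$records, obs)
  expect_setequal(unique(tr2$per_year$group), c("all", "url", "sdar"))
  # histogram conservation
  expect_equal(sum(tr2$histograms$n), nrow(corpus$records))
  # linear growth of the mean: slope within 2 SE of the configured 0.1/yr
  allyr <- tr2$per_year[tr2$per_year$group == "all", ]
  fit <- lm(mean_authors ~ year, data = allyr, weights = allyr$n_papers)
  se <- summary(fit)$coefficients["year", "Std. Error"]
  expect_lt(abs(coef(fit)["year"] - 0.1), 2 * se)
})
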