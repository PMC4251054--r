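# Shared synthetic fixtures, built once per test run.

# mid-size corpus exercising every pipeline stage
shared_corpus <- generate_corpus(sim_config(n_records = 600, seed = 101))

# corpus rich in archival URLs and injected entry errors
error_corpus <- generate_corpus(sim_config(
  n_records = 1500, seed = 202, archival_rate = 0.5,
  error_injection_rate = 0.3
))

# full classified observation table for the shared corpus
classified_obs <- function(corpus = shared_corpus) {
  corpus$records |>
    extract_urls() |>
    deduplicate_urls() |>
    diagnose_urls() |>
    classify_urls(corpus$records)
}

# Independent Bernoulli log-likelihood for a fitted logit, computed
# directly from the design matrix (no glm internals).
bernoulli_loglik <- function(X, y, beta) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}

# From-scratch IRLS solver for logistic regression, the oracle for
# fit_decay_model on small designs.
irls_logit <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  drop(beta)
}
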