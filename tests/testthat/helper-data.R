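# Shared small fixtures, built in code (cached per test file).

shared_data <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dat <- simulate_cohort(sim_config(n_cases = 1200, n_controls = 1200,
                                        n_loci = 40, seed = 42))
      cache <<- list(
        dat = dat,
        cohort = add_prs(dat$cohort, dat$dosages, dat$panel))
    }
    cache
  }
})

# Direct logistic-model draw (no cohort machinery): design matrix X, coefs b.
draw_logistic <- function(X, b, intercept = 0) {
  rbinom(nrow(X), 1L, plogis(intercept + drop(X %*% b)))
}
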