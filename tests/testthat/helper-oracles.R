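# Independent oracles used across the suite. These deliberately take the
# slow/obvious route so they stay independent of the implementation paths
# they check.

# AUROC by exhaustive comparison of every positive-negative pair.
oracle_auc <- function(scores, outcome) {
  pos <- scores[outcome]
  neg <- scores[!outcome]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Random small score/outcome instance with heavy ties (ordinal scores).
random_instance <- function(n_max = 200, k_levels = 7) {
  n <- sample(4:n_max, 1)
  scores <- sample(0:(k_levels - 1), n, replace = TRUE)
  repeat {
    outcome <- stats::runif(n) < stats::plogis(-1 + 0.4 * scores)
    if (any(outcome) && !all(outcome)) break
  }
  list(scores = scores, outcome = outcome)
}

# A scored copy of the built-in 400-patient fixture, shared across tests.
scored_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- score_cohort(expand_fixture(table1_fixture()))
    cache
  }
})
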