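# Independent oracles and small fixtures, built in code.

# Brute-force 1-D partial-likelihood maximiser working straight from the
# risk-set definitions (no counting shortcuts): the reference both fitters
# are checked against.
brute_force_coef <- function(t, delta, z, event, model) {
  ev_idx <- which(delta == event)
  loglik <- function(b) {
    sum(vapply(ev_idx, function(j) {
      at_risk <- if (model == "cause_specific") {
        t >= t[j]
      } else {
        t >= t[j] | (t < t[j] & delta != event)
      }
      b * z[j] - log(sum(exp(b * z[at_risk])))
    }, numeric(1)))
  }
  optimize(loglik, c(-10, 10), maximum = TRUE, tol = 1e-10)$maximum
}

# The six-subject worked dataset used across estimator tests.
worked_sample <- function() {
  tibble::tibble(
    t = 1:6,
    delta = c(1L, 1L, 2L, 1L, 2L, 1L),
    z = c(1L, 0L, 1L, 1L, 0L, 0L)
  )
}

# Random small competing-risks dataset with both arms and both event types.
random_small_sample <- function(n = 10L) {
  repeat {
    d <- tibble::tibble(
      t = round(rexp(n), 3),  # rounding occasionally induces ties on purpose
      delta = sample(c(1L, 2L), n, replace = TRUE),
      z = sample(c(0L, 1L), n, replace = TRUE)
    )
    # identifiability: each event type observed in each arm, and the
    # brute-force optimum interior for every (model, event) combination —
    # rules out monotone-likelihood (separated) datasets where the MLE
    # diverges and no finite coefficient exists to compare
    ok <- all(d$t > 0) &&
      all(vapply(1:2, function(ev) {
        all(c(0L, 1L) %in% d$z[d$delta == ev])
      }, logical(1)))
    if (ok) {
      combos <- expand.grid(ev = 1:2,
                            m = c("cause_specific", "subdistribution"),
                            stringsAsFactors = FALSE)
      interior <- all(vapply(seq_len(nrow(combos)), function(i) {
        abs(brute_force_coef(d$t, d$delta, d$z, combos$ev[i], combos$m[i])) < 5
      }, logical(1)))
      if (interior) return(d)
    }
  }
}

# Convenience: simulate a full population in one call.
sim_population <- function(n, rho, pi, hp, seed) {
  pop <- generate_confounded_covariates(n, rho = rho, pi = pi, seed = seed)
  simulate_events(pop, hp, seed = seed + 1L)
}
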