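# Small cohort specs used across tests. Effects planted on exactly observed
# binary/continuous covariates so that refits are free of errors-in-variables
# attenuation.
tiny_spec <- function(n = 120, seed = 1, effects = c(hemiplegia = 2.5,
                                                     dementia = 1.4,
                                                     male = 0.9)) {
  cohort_spec(n_patients = n, seed = seed, effect_log_odds = effects)
}

# brute-force weighted stump search, independent of the training code:
# enumerates every (feature, midpoint, polarity) plus the two constant
# votes, and scans errors directly
brute_force_stump <- function(x, y, w) {
  best <- list(err = Inf)
  for (j in seq_len(ncol(x))) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2) next
    for (t in (u[-1] + u[-length(u)]) / 2) {
      for (pol in c(1, -1)) {
        pred <- ifelse(x[, j] <= t, pol, -pol)
        err <- sum(w[pred != y])
        if (err < best$err - 1e-15) {
          best <- list(index = j, threshold = t, polarity = pol, err = err)
        }
      }
    }
  }
  for (pol in c(1, -1)) {
    err <- sum(w[y != pol])
    if (err < best$err - 1e-15) {
      best <- list(index = NA, threshold = Inf, polarity = pol, err = err)
    }
  }
  best
}

# exponential survival times with planted log-hazard effects, censored
# administratively; an oracle data source for Cox recovery
simulate_survival <- function(n, beta, seed, horizon = 30, base_rate = 0.02) {
  set.seed(seed)
  x <- matrix(rbinom(n * length(beta), 1, 0.3), ncol = length(beta),
              dimnames = list(NULL, names(beta)))
  rate <- base_rate * exp(drop(x %*% beta))
  t_event <- rexp(n, rate)
  list(time = pmin(t_event, horizon), event = t_event <= horizon,
       design = as.data.frame(x))
}
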