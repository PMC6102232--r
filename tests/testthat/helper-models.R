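# Shared fixtures: the fitted rate sets of the three experimental
# geometries, experiment-like emission rates, and brute-force oracles for
# the likelihood and the decoder.

ncbd_rates <- function() {
  rate_spec(kon1_prime = 6.0, kon2_prime = 3.0, koff1 = 7.3, koff2 = 30,
            k12 = 0.04, k21 = 0.07, kb_plus = 1.7, kb_minus = 38,
            c_ligand = 65e-9)
}

actr_rates <- function() {
  rate_spec(kon1_prime = 3.3, kon2_prime = 1.6, koff1 = 5.6, koff2 = 30,
            kb_plus = 5, kb_minus = 200, c_ligand = 17e-9)
}

p20a_rates <- function() {
  rate_spec(kon1_prime = 5.1, koff1 = 23, kb_plus = 1.7, kb_minus = 38,
            c_ligand = 65e-9)
}

test_emissions <- function() default_emission_rates()

# Exhaustive path-sum evaluation of the binned-photon likelihood:
# sum over all state sequences (s_0, ..., s_T) of
#   p0(s_0) * prod_t P(s_t | s_{t-1}) * Pois(N_D,t; mu_D(s_t)) *
#   Pois(N_A,t; mu_A(s_t)).
oracle_loglik <- function(trace, model, emissions) {
  delta <- attr(trace, "delta")
  P <- propagator(model, delta)
  p0 <- unname(equilibrium_distribution(model)$p_eq)
  mus <- photonhmm:::state_bin_means(model, emissions, delta)
  S <- length(model$states); Tm <- nrow(trace)
  em <- vapply(seq_len(S), function(i)
    stats::dpois(trace$donor, mus$mu_d[i]) *
      stats::dpois(trace$acceptor, mus$mu_a[i]),
    numeric(Tm))
  em <- matrix(em, nrow = Tm)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tm + 1)))
  tot <- 0
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    w <- p0[s[1]]
    for (t in seq_len(Tm)) w <- w * P[s[t + 1], s[t]] * em[t, s[t + 1]]
    tot <- tot + w
  }
  log(tot)
}

# Exhaustive best-path search; returns the maximal path probability over
# all state sequences (the quantity the Viterbi decode must attain).
oracle_best_path_prob <- function(trace, model, emissions) {
  delta <- attr(trace, "delta")
  P <- propagator(model, delta)
  p0 <- unname(equilibrium_distribution(model)$p_eq)
  mus <- photonhmm:::state_bin_means(model, emissions, delta)
  S <- length(model$states); Tm <- nrow(trace)
  em <- matrix(vapply(seq_len(S), function(i)
    stats::dpois(trace$donor, mus$mu_d[i]) *
      stats::dpois(trace$acceptor, mus$mu_a[i]),
    numeric(Tm)), nrow = Tm)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), Tm + 1)))
  best <- -Inf
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    w <- p0[s[1]]
    for (t in seq_len(Tm)) w <- w * P[s[t + 1], s[t]] * em[t, s[t + 1]]
    if (w > best) best <- w
  }
  best
}

# probability of a specific decoded path (1-based state indices per bin)
path_prob <- function(trace, model, emissions, states_idx) {
  delta <- attr(trace, "delta")
  P <- propagator(model, delta)
  p0 <- unname(equilibrium_distribution(model)$p_eq)
  mus <- photonhmm:::state_bin_means(model, emissions, delta)
  Tm <- nrow(trace)
  # maximize over the unobserved start state s_0
  best <- -Inf
  for (s0 in seq_along(model$states)) {
    w <- p0[s0]
    prev <- s0
    for (t in seq_len(Tm)) {
      i <- states_idx[t]
      w <- w * P[i, prev] *
        stats::dpois(trace$donor[t], mus$mu_d[i]) *
        stats::dpois(trace$acceptor[t], mus$mu_a[i])
      prev <- i
    }
    if (w > best) best <- w
  }
  best
}

# random valid rate specification covering all eight rate fields
random_rate_spec <- function() {
  rate_spec(kon1_prime = stats::runif(1, 0.1, 50),
            kon2_prime = stats::runif(1, 0.1, 50),
            koff1 = stats::runif(1, 0.1, 50),
            koff2 = stats::runif(1, 0.1, 50),
            k12 = stats::runif(1, 0.01, 5),
            k21 = stats::runif(1, 0.01, 5),
            kb_plus = stats::runif(1, 0.1, 20),
            kb_minus = stats::runif(1, 1, 200))
}

random_model <- function() {
  builders <- list(build_two_state, build_two_state_blink,
                   build_three_state_blink, build_four_state_blink)
  builders[[sample.int(4, 1)]](random_rate_spec())
}

# short random two-channel trace for oracle comparisons
random_short_trace <- function(Tm, delta = 0.05, lambda_d = 3,
                               lambda_a = 1.5) {
  photon_trace(stats::rpois(Tm, lambda_d), stats::rpois(Tm, lambda_a),
               delta = delta)
}
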