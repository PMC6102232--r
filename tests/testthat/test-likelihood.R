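test_that("single-bin likelihood equals the product of Poisson pmfs", {
  tr <- photon_trace(3, 1, delta = 1)
  # degenerate kinetics: both states identical, so one-state behaviour
  m <- build_two_state(rate_spec(kon1_prime = 1e-12, koff1 = 1e-12))
  em <- emission_rates(c("unbound", "bound"), c(5, 5), c(2, 2))
  expect_equal(trace_log_likelihood(tr, m, em),
               log(stats::dpois(3, 5) * stats::dpois(1, 2)),
               tolerance = 1e-12)
  expect_equal(trace_log_likelihood(tr, m, em), -3.270, tolerance = 1e-3)
})

test_that("forward likelihood equals the exhaustive path-sum oracle", {
  set.seed(201)
  for (rep in seq_len(8)) {
    two_state <- rep %% 2 == 0
    m <- if (two_state)
      build_two_state(rate_spec(kon1_prime = stats::runif(1, 0.5, 20),
                                koff1 = stats::runif(1, 0.5, 20)))
    else
      build_two_state_blink(rate_spec(kon1_prime = stats::runif(1, 0.5, 20),
                                      koff1 = stats::runif(1, 0.5, 20),
                                      kb_plus = stats::runif(1, 0.5, 10),
                                      kb_minus = stats::runif(1, 5, 50)))
    em <- if (two_state)
      emission_rates(c("unbound", "bound"), c(60, 10), c(5, 40))
    else
      emission_rates(c("unbound", "bound", "dark"), c(60, 10, 2),
                     c(5, 40, 2))
    Tm <- sample(4:8, 1)
    tr <- random_short_trace(Tm)
    ll <- trace_log_likelihood(tr, m, em)
    expect_equal(ll, oracle_loglik(tr, m, em), tolerance = 1e-10)
  }
})

test_that("log-likelihood is invariant to the rescaling schedule", {
  set.seed(202)
  m <- build_two_state_blink(rate_spec(kon1_prime = 6, koff1 = 7.3,
                                       kb_plus = 1.7, kb_minus = 38))
  em <- test_emissions()
  path <- simulate_state_path(m, 5)
  tr <- emit_photons(path, m, em, 0.001)
  P <- propagator(m, 0.001)
  p0 <- unname(equilibrium_distribution(m)$p_eq)
  mus <- photonhmm:::state_bin_means(m, em, 0.001)
  ll1 <- photonhmm:::forward_loglik_stride_cpp(tr$donor, tr$acceptor, P,
                                               mus$mu_d, mus$mu_a, p0, 1L)
  ll7 <- photonhmm:::forward_loglik_stride_cpp(tr$donor, tr$acceptor, P,
                                               mus$mu_d, mus$mu_a, p0, 7L)
  ll <- trace_log_likelihood(tr, m, em)
  expect_equal(ll1, ll7, tolerance = 1e-9)
  expect_equal(ll, ll1, tolerance = 1e-9)
})

test_that("two lumped identical states reproduce the one-state likelihood", {
  set.seed(203)
  tr <- random_short_trace(200, delta = 0.02, lambda_d = 4, lambda_a = 1)
  m2 <- build_two_state(rate_spec(kon1_prime = 3, koff1 = 3))
  em_same <- emission_rates(c("unbound", "bound"), c(200, 200), c(50, 50))
  # one-state reference: product of Poisson pmfs at the shared rates
  ll_ref <- sum(stats::dpois(tr$donor, 200 * 0.02, log = TRUE) +
                  stats::dpois(tr$acceptor, 50 * 0.02, log = TRUE))
  expect_equal(trace_log_likelihood(tr, m2, em_same), ll_ref,
               tolerance = 1e-9)
})

test_that("impossible traces give -Inf and are flagged, not errors", {
  tr <- photon_trace(c(0, 2, 0), c(0, 0, 0), delta = 0.02)
  m <- build_two_state(rate_spec(kon1_prime = 1, koff1 = 1))
  em0 <- emission_rates(c("unbound", "bound"), c(0, 0), c(0, 0))
  expect_identical(trace_log_likelihood(tr, m, em0), -Inf)
})

test_that("a single trace fits to the generating kinetics", {
  set.seed(204)
  m <- build_two_state(rate_spec(kon1_prime = 6.0, koff1 = 7.3))
  em <- test_emissions()
  path <- simulate_state_path(m, 60)
  tr <- emit_photons(path, m, em, 0.001)
  fit <- fit_trace(tr, "two_state",
                   rate_spec(kon1_prime = 3, koff1 = 4),
                   emission_rates(c("unbound", "bound"), c(1500, 700),
                                  c(200, 900)),
                   rebin_to = 0.02)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$kon1_prime - 6.0) / 6.0, 0.3)
  expect_lt(abs(fit$estimates$koff1 - 7.3) / 7.3, 0.3)
  # photon rates are tightly determined
  expect_lt(abs(fit$estimates$`unbound.D` - 2000) / 2000, 0.1)
  expect_lt(abs(fit$estimates$`bound.A` - 1200) / 1200, 0.1)
})

test_that("global fits recover shared rates across traces", {
  set.seed(205)
  m <- build_two_state_blink(rate_spec(kon1_prime = 6.0, koff1 = 7.3,
                                       kb_plus = 1.7, kb_minus = 38))
  em <- test_emissions()
  ds <- simulate_dataset(m, em, n_traces = 25, mean_duration = 20,
                         delta = 0.001, seed = 205)
  fit <- fit_global(ds$traces, "two_state_blink",
                    rate_spec(kon1_prime = 3, koff1 = 4, kb_plus = 3,
                              kb_minus = 60),
                    em)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates$kon1_prime - 6.0) / 6.0, 0.15)
  expect_lt(abs(fit$estimates$koff1 - 7.3) / 7.3, 0.15)
  expect_lt(abs(fit$estimates$kb_plus - 1.7) / 1.7, 0.35)
  expect_lt(abs(fit$estimates$kb_minus - 38) / 38, 0.35)
})

test_that("nested models: the blink fit never has lower likelihood", {
  set.seed(206)
  m <- build_two_state_blink(rate_spec(kon1_prime = 6.0, koff1 = 7.3,
                                       kb_plus = 1.7, kb_minus = 38))
  em <- test_emissions()
  path <- simulate_state_path(m, 40)
  tr <- emit_photons(path, m, em, 0.001)
  em2 <- em[em$class != "dark", ]
  class(em2) <- class(em)
  fit2 <- fit_trace(tr, "two_state", rate_spec(kon1_prime = 5, koff1 = 6),
                    em2, free_emissions = character(0), rebin_to = NULL)
  fit3 <- fit_trace(tr, "two_state_blink",
                    rate_spec(kon1_prime = 5, koff1 = 6, kb_plus = 2,
                              kb_minus = 40),
                    em, free_emissions = character(0), rebin_to = NULL)
  expect_gte(fit3$log_likelihood, fit2$log_likelihood - 1e-6)
})

test_that("rate estimates are stable under joint photon-rate scaling", {
  m <- build_two_state(rate_spec(kon1_prime = 6.0, koff1 = 7.3))
  em1 <- emission_rates(c("unbound", "bound"), c(2000, 500), c(100, 1200))
  em2 <- emission_rates(c("unbound", "bound"), c(4000, 1000), c(200, 2400))
  fits <- lapply(list(em1, em2), function(em) {
    set.seed(207)  # identical state path, brighter photons for em2
    path <- simulate_state_path(m, 60)
    tr <- emit_photons(path, m, em, 0.001)
    fit_trace(tr, "two_state", rate_spec(kon1_prime = 4, koff1 = 5), em,
              free_emissions = character(0), rebin_to = 0.02)
  })
  expect_lt(abs(fits[[1]]$estimates$kon1_prime -
                  fits[[2]]$estimates$kon1_prime) /
              fits[[1]]$estimates$kon1_prime, 0.15)
  expect_lt(abs(fits[[1]]$estimates$koff1 - fits[[2]]$estimates$koff1) /
              fits[[1]]$estimates$koff1, 0.15)
})

test_that("a trace without transitions flags the degenerate fit", {
  set.seed(208)
  # all-unbound trace: no binding events to constrain koff
  tr <- photon_trace(stats::rpois(2000, 2000 * 0.02),
                     stats::rpois(2000, 100 * 0.02), delta = 0.02)
  em <- emission_rates(c("unbound", "bound"), c(2000, 500), c(100, 1200))
  fit <- fit_trace(tr, "two_state", rate_spec(kon1_prime = 1, koff1 = 5),
                   em, free_emissions = character(0), rebin_to = NULL)
  expect_false(fit$converged)
  expect_lt(fit$estimates$kon1_prime, 2e-4)
})

test_that("bootstrap errors are reproducible and collapse for copies", {
  set.seed(209)
  m <- build_two_state(rate_spec(kon1_prime = 6.0, koff1 = 7.3))
  em <- test_emissions()
  ds <- simulate_dataset(m, em, n_traces = 6, mean_duration = 15,
                         delta = 0.001, seed = 209)
  fit <- fit_global(ds$traces, "two_state",
                    rate_spec(kon1_prime = 5, koff1 = 6), em,
                    free_rates = c("kon1_prime", "koff1"))
  b1 <- bootstrap_errors(ds$traces, fit, n_boot = 4, seed = 11)
  b2 <- bootstrap_errors(ds$traces, fit, n_boot = 4, seed = 11)
  expect_equal(b1$bootstrap_sd, b2$bootstrap_sd)
  expect_true(all(b1$bootstrap_sd > 0))
  expect_equal(names(b1$bootstrap_sd), c("kon1_prime", "koff1"))

  # identical traces: every resample is the same dataset, SD collapses
  same <- rep(ds$traces[1], 5)
  fit_s <- fit_global(same, "two_state",
                      rate_spec(kon1_prime = 5, koff1 = 6), em,
                      free_rates = c("kon1_prime", "koff1"))
  b_s <- bootstrap_errors(same, fit_s, n_boot = 3, seed = 2)
  expect_true(all(b_s$bootstrap_sd < 1e-8))
})

test_that("fit results serialize to JSON", {
  set.seed(210)
  m <- build_two_state(rate_spec(kon1_prime = 6, koff1 = 7.3))
  em <- test_emissions()
  ds <- simulate_dataset(m, em, n_traces = 2, mean_duration = 8,
                         delta = 0.001, seed = 210)
  fit <- fit_global(ds$traces, "two_state",
                    rate_spec(kon1_prime = 5, koff1 = 6), em,
                    free_rates = c("kon1_prime", "koff1"))
  js <- jsonlite::fromJSON(fit_to_json(fit))
  expect_equal(js$model_type, "two_state")
  expect_equal(js$n_traces, 2)
  expect_true(is.finite(js$log_likelihood))
  td <- tidy(fit)
  expect_equal(td$term, c("kon1_prime", "koff1"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_true(gl$converged)
})
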