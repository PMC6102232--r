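test_that("two-state generator matches the printed binding scheme", {
  m <- build_two_state(rate_spec(kon1_prime = 6.0, koff1 = 7.3))
  expect_equal(unname(m$K),
               matrix(c(-6.0, 6.0, 7.3, -7.3), 2, 2))
  expect_equal(m$states, c("unbound", "bound"))

  z <- build_two_state(rate_spec(kon1_prime = 0, koff1 = 0))
  expect_equal(unname(z$K), matrix(0, 2, 2))

  s <- build_two_state(rate_spec(kon1_prime = 1, koff1 = 1))
  expect_equal(colSums(s$K), c(unbound = 0, bound = 0))
  expect_equal(s$K[2, 1], 1)
  expect_equal(s$K[1, 2], 1)
})

test_that("blink generator has a dark state reachable only from unbound", {
  m <- build_two_state_blink(rate_spec(kon1_prime = 6.0, koff1 = 7.3,
                                       kb_plus = 1.7, kb_minus = 38))
  expect_equal(unname(m$K),
               matrix(c(-(6 + 1.7), 6, 1.7,
                        7.3, -7.3, 0,
                        38, 0, -38), 3, 3))
  # no bound -> dark or dark -> bound link
  expect_equal(m$K["dark", "bound"], 0)
  expect_equal(m$K["bound", "dark"], 0)

  # blink-off only: dark state carries no stationary mass
  m0 <- build_two_state_blink(rate_spec(kon1_prime = 6.0, koff1 = 7.3,
                                        kb_plus = 0, kb_minus = 38))
  expect_equal(unname(equilibrium_distribution(m0)$p_eq["dark"]), 0)

  ma <- build_two_state_blink(rate_spec(kon1_prime = 5, koff1 = 30,
                                        kb_plus = 5, kb_minus = 200))
  expect_equal(ma$K["unbound", "unbound"], -(5 + 5))
  expect_equal(ma$K["unbound", "dark"], 200)
})

test_that("three-state generator matches the two-bound-state scheme", {
  m <- build_three_state_blink(actr_rates())
  expect_equal(unname(m$K),
               matrix(c(-(3.3 + 1.6 + 5), 3.3, 1.6, 5,
                        5.6, -5.6, 0, 0,
                        30, 0, -30, 0,
                        200, 0, 0, -200), 4, 4))
  # no direct exchange between the two bound states
  expect_equal(m$K["bound2", "bound1"], 0)
  expect_equal(m$K["bound1", "bound2"], 0)
  # both bound states share the emission class
  expect_equal(unname(m$emission_class[c("bound1", "bound2")]),
               c("bound", "bound"))

  # degenerate second pathway reduces to the blink scheme
  m0 <- build_three_state_blink(
    rate_spec(kon1_prime = 3.3, kon2_prime = 0, koff1 = 5.6, koff2 = 0,
              kb_plus = 5, kb_minus = 200))
  keep <- c("unbound", "bound1", "dark")
  m3 <- build_two_state_blink(rate_spec(kon1_prime = 3.3, koff1 = 5.6,
                                        kb_plus = 5, kb_minus = 200))
  expect_equal(unname(m0$K[keep, keep]), unname(m3$K))
})

test_that("four-state generator matches the full isomerization scheme", {
  m <- build_four_state_blink(ncbd_rates())
  K <- m$K
  expect_equal(unname(diag(K)),
               -c(0.04 + 6.0 + 1.7, 7.3, 38 + 0.04,
                  0.07 + 3.0 + 1.7, 30, 38 + 0.07))
  expect_equal(K["unbound1", "unbound2"], 0.07)
  expect_equal(K["unbound2", "unbound1"], 0.04)
  expect_equal(K["dark2", "dark1"], 0.04)
  expect_equal(K["dark1", "dark2"], 0.07)
  expect_equal(K["bound1", "unbound1"], 6.0)
  expect_equal(K["bound2", "unbound2"], 3.0)
  # the bound states never interconvert directly
  expect_equal(K["bound1", "bound2"], 0)
  expect_equal(K["bound2", "bound1"], 0)
  expect_equal(unname(colSums(K)), rep(0, 6), tolerance = 1e-12)
})

test_that("four-state scheme with frozen isomerization is block diagonal", {
  rs <- rate_spec(kon1_prime = 6.0, kon2_prime = 3.0, koff1 = 7.3,
                  koff2 = 30, k12 = 0, k21 = 0, kb_plus = 1.7,
                  kb_minus = 38)
  m <- build_four_state_blink(rs)
  b1 <- c("unbound1", "bound1", "dark1")
  b2 <- c("unbound2", "bound2", "dark2")
  expect_equal(unname(m$K[b2, b1]), matrix(0, 3, 3))
  expect_equal(unname(m$K[b1, b2]), matrix(0, 3, 3))
  e1 <- build_two_state_blink(rate_spec(kon1_prime = 6.0, koff1 = 7.3,
                                        kb_plus = 1.7, kb_minus = 38))
  e2 <- build_two_state_blink(rate_spec(kon1_prime = 3.0, koff1 = 30,
                                        kb_plus = 1.7, kb_minus = 38))
  expect_equal(unname(m$K[b1, b1]), unname(e1$K))
  expect_equal(unname(m$K[b2, b2]), unname(e2$K))
})

test_that("rate specifications are validated", {
  expect_error(rate_spec(kon1_prime = -1), ">= 0")
  expect_error(build_two_state(rate_spec(koff1 = 1)), "missing rate")
  expect_error(rate_spec(kon1 = 1e8), "c_ligand")
  # kon' = kon * c consistency enforced and auto-filled
  expect_error(rate_spec(kon1_prime = 5, kon1 = 1e8, c_ligand = 65e-9),
               "inconsistent")
  rs <- rate_spec(kon1 = 0.93e8, c_ligand = 65e-9)
  expect_equal(rs$kon1_prime, 6.045)
  rs2 <- rate_spec(kon1_prime = 6.0, c_ligand = 65e-9)
  expect_equal(rs2$kon1, 6.0 / 65e-9)
})

test_that("random generators are valid and propagators stochastic", {
  set.seed(11)
  for (i in seq_len(1000)) {
    m <- random_model()
    expect_true(all(abs(colSums(m$K)) < 1e-10))
    off <- m$K; diag(off) <- 0
    expect_true(all(off >= 0))
    expect_true(all(diag(m$K) <= 0))
  }
  # propagator columns sum to one on a smaller random sample
  for (i in seq_len(50)) {
    m <- random_model()
    delta <- stats::runif(1, 0, 100 / max(abs(m$K)))
    P <- propagator(m, delta)
    expect_true(all(abs(colSums(P) - 1) < 1e-9))
    expect_true(all(P >= 0 & P <= 1 + 1e-12))
  }
})

test_that("equilibrium solves K p = 0 and matches the long-time limit", {
  m <- build_two_state(rate_spec(kon1_prime = 6.0, koff1 = 7.3))
  eq <- equilibrium_distribution(m)
  expect_equal(unname(eq$p_eq), c(7.3, 6.0) / 13.3, tolerance = 1e-12)

  sym <- build_two_state(rate_spec(kon1_prime = 1, koff1 = 1))
  expect_equal(unname(equilibrium_distribution(sym)$p_eq), c(0.5, 0.5))

  set.seed(12)
  for (i in seq_len(25)) {
    m <- random_model()
    p <- equilibrium_distribution(m)$p_eq
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(max(abs(m$K %*% p)) < 1e-9 * max(abs(m$K)))
    # horizon set by the slowest relaxation mode (smallest nonzero |Re λ|)
    ev <- Re(eigen(m$K, only.values = TRUE)$values)
    gap <- min(abs(ev[abs(ev) > 1e-12 * max(abs(ev))]))
    Pinf <- propagator(m, 40 / gap)
    expect_equal(unname(Pinf[, 1]), unname(p), tolerance = 1e-6)
  }
})

test_that("reducible chains need a start state to disambiguate", {
  # two disconnected binding systems: two recurrent classes
  rs <- rate_spec(kon1_prime = 6.0, kon2_prime = 3.0, koff1 = 7.3,
                  koff2 = 30, k12 = 0, k21 = 0, kb_plus = 1.7,
                  kb_minus = 38)
  m <- build_four_state_blink(rs)
  expect_error(equilibrium_distribution(m), "multiple recurrent classes")
  eq <- equilibrium_distribution(m, start = "unbound1")
  expect_equal(sum(eq$p_eq[c("unbound2", "bound2", "dark2")]), 0)
  expect_equal(sum(eq$p_eq), 1, tolerance = 1e-10)
})

test_that("propagator limits: identity at zero, closed-form relaxation", {
  m <- build_two_state(rate_spec(kon1_prime = 6.0, koff1 = 7.3))
  expect_equal(unname(propagator(m, 0)), diag(2))
  P <- propagator(m, 0.02)
  expect_equal(P["bound", "unbound"],
               (6.0 / 13.3) * (1 - exp(-13.3 * 0.02)), tolerance = 1e-12)
})

test_that("derived quantities reproduce the closed-form definitions", {
  dq <- derive_quantities(ncbd_rates())
  expect_equal(dq$Kd1, 7.3 / (6.0 / 65e-9), tolerance = 1e-12)
  expect_equal(dq$Kd1 * 1e9, 79.08, tolerance = 1e-3)
  expect_equal(dq$p1, 0.07 / 0.11)
  expect_equal(dq$p1 + dq$p2, 1)

  # printed second-order rates give the published dissociation constants
  dq2 <- derive_quantities(rate_spec(koff1 = 7.3, kon1 = 0.93e8,
                                     koff2 = 30, kon2 = 0.46e8,
                                     c_ligand = 65e-9))
  expect_equal(round(dq2$Kd1 * 1e9), 78)
  expect_equal(signif(dq2$Kd2 * 1e9, 2), 650)

  dq3 <- derive_quantities(rate_spec(k12 = 0.04, k21 = 0.07,
                                     kon1 = 3.2e8, kon2 = 2.5e8,
                                     c_ligand = 17e-9))
  expect_equal(dq3$frac_fast, 0.3086, tolerance = 1e-3)

  eqk <- derive_quantities(rate_spec(k12 = 0.3, k21 = 0.3))
  expect_equal(eqk$p1, 0.5)
  expect_equal(eqk$p2, 0.5)

  expect_error(derive_quantities(rate_spec(koff1 = 1, kon1 = 0,
                                           c_ligand = 1e-9)),
               "zero kon")
})

test_that("finite-concentration equilibrium is mass balanced", {
  rs <- list(Kd1 = 78e-9, Kd2 = 650e-9, k12 = 0.04, k21 = 0.07)
  res <- four_state_binding_equilibrium(rs, 3e-3, 6e-3)
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
  # total ligand is conserved (relative tolerance)
  expect_equal(res$free_ligand + res$bound_total, 6e-3, tolerance = 1e-9)
  expect_equal(unname(res$fractions["bound_cis"]), 0.064, tolerance = 0.01)

  set.seed(3)
  for (i in seq_len(20)) {
    rs <- list(Kd1 = stats::runif(1, 1e-9, 1e-6),
               Kd2 = stats::runif(1, 1e-9, 1e-6),
               k12 = stats::runif(1, 0.01, 1),
               k21 = stats::runif(1, 0.01, 1))
    Rt <- stats::runif(1, 1e-9, 1e-2); Lt <- stats::runif(1, 1e-9, 1e-2)
    res <- four_state_binding_equilibrium(rs, Rt, Lt)
    expect_true(abs(res$free_ligand + res$bound_total - Lt) <=
                  1e-9 * max(Lt, Rt))
    expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
  }
})

test_that("equilibrium limits: no ligand, equal affinities", {
  rs <- list(Kd1 = 78e-9, Kd2 = 650e-9, k12 = 0.04, k21 = 0.07)
  res0 <- four_state_binding_equilibrium(rs, 1e-6, 0)
  expect_equal(unname(res0$fractions["bound_trans"] +
                        res0$fractions["bound_cis"]), 0)
  expect_equal(unname(res0$fractions["unbound_trans"]), 0.07 / 0.11,
               tolerance = 1e-12)

  rs_eq <- list(Kd1 = 1e-7, Kd2 = 1e-7, k12 = 0.04, k21 = 0.07)
  res <- four_state_binding_equilibrium(rs_eq, 1e-6, 2e-6)
  expect_equal(res$fractions[["bound_cis"]] / res$fractions[["bound_trans"]],
               res$fractions[["unbound_cis"]] /
                 res$fractions[["unbound_trans"]],
               tolerance = 1e-9)
})

test_that("kinetic models serialize to JSON and back", {
  m <- build_four_state_blink(ncbd_rates())
  js <- model_to_json(m)
  m2 <- model_from_json(js)
  expect_equal(m2$K, m$K)
  expect_equal(m2$states, m$states)
  expect_equal(m2$emission_class, m$emission_class)
  expect_equal(m2$rates$k12, 0.04)
})
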