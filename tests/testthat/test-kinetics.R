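test_that("closed-form unbound count satisfies the ODE by substitution", {
  # independent check: central finite difference of N_u(t) against the
  # right-hand side -a N_u - b N_u^2
  cases <- list(c(a = 1.091, b = 2.794e-6, N0 = 9.46e8),
                c(a = 1e-3, b = 1e-9, N0 = 1e6),
                c(a = 50, b = 1e-4, N0 = 1e5))
  for (p in cases) {
    ts <- exp(seq(log(1e-3 / (p["a"] + p["b"] * p["N0"])),
                  log(time_to_count(p["a"], p["b"], p["N0"], 10)),
                  length.out = 25))
    for (t in ts) {
      nu <- closed_form_unbound(p["a"], p["b"], p["N0"], t)
      # step ~1e-3 of the local decay time: O(h^2) truncation stays ~1e-7
      # while the difference is large enough to avoid cancellation
      h <- min(t, 1e-3 / (p[["a"]] + 2 * p[["b"]] * nu))
      lhs <- (closed_form_unbound(p["a"], p["b"], p["N0"], t + h) -
                closed_form_unbound(p["a"], p["b"], p["N0"], t - h)) / (2 * h)
      rhs <- -p[["a"]] * nu - p[["b"]] * nu^2
      expect_equal(lhs, rhs, tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("closed-form limits: initial condition, pure decay, hyperbola", {
  expect_equal(closed_form_unbound(2, 3e-6, 1e7, 0), 1e7)
  # b = 0: exponential diffusion loss
  expect_equal(closed_form_unbound(2, 0, 1e7, 1.3), 1e7 * exp(-2.6))
  # a = 0, b N0 t = 1: Smoluchowski half-decay
  expect_equal(closed_form_unbound(0, 1e-7, 1e7, 1), 5e6)
  # a = b = 0: no dynamics
  expect_equal(closed_form_unbound(0, 0, 1e7, 100), 1e7)
})

test_that("final gel count matches brute-force quadrature of b N_u^2", {
  for (p in list(c(a = 1.091, b = 2.794e-6, N0 = 9.46e8),
                 c(a = 0.5, b = 1e-8, N0 = 1e7),
                 c(a = 10, b = 1e-5, N0 = 1e6))) {
    quad <- stats::integrate(
      function(t) p[["b"]] * closed_form_unbound(p["a"], p["b"],
                                                 p["N0"], t)^2,
      0, Inf, rel.tol = 1e-10)$value
    expect_equal(final_gel_count(p[["a"]], p[["b"]], p[["N0"]]), quad,
                 tolerance = 1e-7)
  }
  # limits: no loss -> everything gels; weak coalescence -> almost nothing
  expect_equal(final_gel_count(0, 1e-6, 1e8), 1e8)
  expect_lt(final_gel_count(100, 1e-12, 1e6) / 1e6, 1e-3)
})

test_that("numerical trajectories match the closed-form oracle while at
           least one motif remains", {
  set.seed(42)
  for (i in 1:20) {
    a <- 10^runif(1, -3, 3)
    N0 <- 10^runif(1, 4, 9)
    b <- 10^runif(1, -3, 3) * a / N0  # b N0 / a spans 1e-3..1e3
    t_end <- time_to_count(a, b, N0, 1)
    ts <- exp(seq(log(1e-3 / (a + b * N0)), log(t_end), length.out = 40))
    traj <- solve_kinetics(rate_constants_ab(a, b), N0, t_end, times = ts,
                           rel_tol = 1e-11, abs_tol = 1e-8)
    cf <- closed_form_unbound(a, b, N0, traj$t_s)
    expect_lt(max(abs(traj$N_u - cf) / pmax(cf, 1)), 1e-6)
  }
})

test_that("mass is conserved and gelled/lost pools are monotone", {
  set.seed(7)
  rel_tol <- 1e-9
  for (i in 1:10) {
    a <- 10^runif(1, -2, 2)
    N0 <- 10^runif(1, 5, 9)
    b <- 10^runif(1, -2, 2) * a / N0
    traj <- solve_kinetics(rate_constants_ab(a, b), N0,
                           t_end = 5 * time_to_count(a, b, N0, 1),
                           rel_tol = rel_tol)
    balance <- traj$N_u + traj$N_g + traj$N_lost
    expect_lt(max(abs(balance - N0)) / N0, 1e-7)
    expect_true(all(diff(traj$N_g) > -1e-6 * N0))
    expect_true(all(diff(traj$N_lost) > -1e-6 * N0))
    expect_true(all(traj$N_u >= 0))
  }
})

test_that("degenerate inputs: empty droplet and failed preconditions", {
  traj <- solve_kinetics(rate_constants_ab(1, 1e-6), 0, t_end = 10)
  expect_true(all(traj$N_u == 0 & traj$N_g == 0 & traj$N_lost == 0))
  expect_error(solve_kinetics(rate_constants_ab(1, 1e-6), -1, 10), "N0")
  expect_error(solve_kinetics(rate_constants_ab(1, 1e-6), 1e6, 0), "t_end")
})

test_that("b = 0 reduces to exponential decay, a = 0 to the Smoluchowski
           hyperbola", {
  a <- 0.8; N0 <- 1e7
  traj <- solve_kinetics(rate_constants_ab(a, 0), N0, t_end = 15)
  expect_lt(max(abs(traj$N_u - N0 * exp(-a * traj$t_s)) /
                  pmax(N0 * exp(-a * traj$t_s), 1)), 1e-6)
  expect_true(all(traj$N_g == 0))

  b <- 1e-7
  traj <- solve_kinetics(rate_constants_ab(0, b), N0, t_end = 100)
  hyper <- N0 / (1 + b * N0 * traj$t_s)
  expect_lt(max(abs(traj$N_u - hyper) / pmax(hyper, 1)), 1e-6)
  expect_true(all(traj$N_lost == 0))
})

test_that("steady-state integration agrees with the closed-form final gel
           count", {
  for (p in list(c(a = 1.091, b = 2.794e-6, N0 = 9.46e8),
                 c(a = 0.1, b = 1e-9, N0 = 1e8),
                 c(a = 5, b = 1e-5, N0 = 1e6))) {
    traj <- gelwell:::solve_to_steady(rate_constants_ab(p[["a"]], p[["b"]]),
                                      p[["N0"]])
    expect_equal(traj$N_g[nrow(traj)],
                 final_gel_count(p[["a"]], p[["b"]], p[["N0"]]),
                 tolerance = 1e-4)
  }
})

test_that("annealing rounds dissociate aggregates and monotonically bleed
           motifs into the PEG phase", {
  rc <- ref_rates()
  N0 <- ref_N0()

  # one round is plain kinetics run to steady state
  one <- run_annealing(rc, N0, annealing_schedule(n_rounds = 1))
  expect_equal(one$N_g[nrow(one)],
               final_gel_count(rc$loss_rate_a, rc$coalescence_rate_b, N0),
               tolerance = 1e-4)

  # without diffusive loss every round re-gels everything
  lossless <- run_annealing(rate_constants_ab(0, 1e-6), 1e7,
                            annealing_schedule(n_rounds = 3))
  expect_equal(lossless$N_g[nrow(lossless)], 1e7, tolerance = 1e-6)

  # each extra round loses a little more
  two <- run_annealing(rc, N0, annealing_schedule(n_rounds = 2))
  expect_lt(two$N_g[nrow(two)], one$N_g[nrow(one)])
  # and the loss per round matches iterating the closed form
  ng1 <- final_gel_count(rc$loss_rate_a, rc$coalescence_rate_b, N0)
  ng2 <- final_gel_count(rc$loss_rate_a, rc$coalescence_rate_b, ng1)
  expect_equal(two$N_g[nrow(two)], ng2, tolerance = 1e-4)
  expect_gt(two$N_lost[nrow(two)], one$N_lost[nrow(one)])

  # conservation across round boundaries
  balance <- two$N_u + two$N_g + two$N_lost
  expect_lt(max(abs(balance - N0)) / N0, 1e-7)
})

test_that("cooling profile is exponential between the hot and ambient
           temperatures", {
  s <- annealing_schedule(hot_temperature = 348.15,
                          ambient_temperature = 298,
                          cooling_time_constant = 30)
  expect_equal(cooling_profile(s, 0), 348.15)
  expect_equal(cooling_profile(s, 1e6), 298)
  expect_equal(cooling_profile(s, 30), 298 + (348.15 - 298) / exp(1))
  expect_error(annealing_schedule(cooling_time_constant = -1),
               "cooling_time_constant")
})
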