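test_that("zero dynamics leave the state constant", {
  tc <- simulate_kinetics(rate_constants(), c(p = 50, S = 10, Sp = 5),
                          times = c(0, 60, 300, 1200))
  w <- timecourse_wide(tc)
  expect_equal(w$p, rep(50, 4))
  expect_equal(w$S, rep(10, 4))
  expect_equal(w$Sp, rep(5, 4))
})

test_that("a target at its transcription-degradation balance stays put", {
  alpha_p <- steady_state_transcription(beta_p = 0.002, p0 = 100)
  expect_equal(alpha_p, 0.2)
  expect_equal(steady_state_transcription(0, 100), 0)
  p <- rate_constants(alpha_p = alpha_p, beta_p = 0.002)
  tc <- simulate_kinetics(p, c(p = 100, S = 0, Sp = 0), c(0, 300, 1200))
  expect_equal(timecourse_wide(tc)$p, rep(100, 3), tolerance = 1e-7)
})

test_that("copy-number / molar conversion matches Avogadro arithmetic", {
  expect_equal(copies_to_molar(0, 0.7), 0)
  expect_equal(copies_to_molar(200, 0.7), 200 / (6.02214076e23 * 0.7e-15),
               tolerance = 1e-12)
  expect_equal(copies_to_molar(200, 0.7), 4.744e-7, tolerance = 1e-3)
  expect_equal(molar_to_copies(copies_to_molar(137, 0.7), 0.7), 137,
               tolerance = 1e-12)
  expect_error(copies_to_molar(10, 0), "positive")
})

test_that("dissociation constant is k_off/k_on", {
  expect_equal(dissociation_constant(rate_constants(k_on = 1.9e5, k_off = 0.22)),
               1.16e-6, tolerance = 2e-3)
  expect_equal(dissociation_constant(rate_constants(k_on = 2e5, k_off = 0.2)),
               1.0e-6)
  expect_equal(dissociation_constant(rate_constants(k_on = 5e4, k_off = 0)), 0)
  expect_error(dissociation_constant(rate_constants(k_on = 0, k_off = 0.1)),
               "undefined")
})

test_that("search metrics reproduce the binding-event and timing algebra", {
  p <- rate_constants(k_on = 1.9e5, k_off = 0.22, k_cat = 0.3)
  sm <- search_metrics(p, s_conc = 0.48e-6)
  expect_equal(sm$mean_binding_events, (0.22 + 0.3) / 0.3)
  expect_equal(sm$mean_binding_events, 1.73, tolerance = 2e-3)
  expect_equal(sm$search_time_s, 1 / (1.9e5 * 0.48e-6))
  expect_equal(sm$search_time_s, 11, tolerance = 5e-3)
  expect_equal(sm$destruction_time_s, sm$mean_binding_events * sm$search_time_s)
  # no dissociation: exactly one binding event, no rejection
  p0 <- rate_constants(k_on = 1.9e5, k_off = 0, k_cat = 0.3)
  expect_equal(search_metrics(p0, 1e-6)$mean_binding_events, 1)
  pk <- rate_constants(k_on = 1.9e5, k_off = 0.2, k_cat = 0)
  expect_error(search_metrics(pk, 1e-6), "diverge")
})

test_that("adaptive solution matches a fixed-step RK4 oracle", {
  set.seed(42)
  times <- c(0, 15, 40, 80, 120)
  for (i in 1:10) {
    params <- random_rate_constants()
    y0 <- c(p = runif(1, 20, 150), S = runif(1, 0, 30), Sp = runif(1, 0, 5))
    tc <- simulate_kinetics(params, y0, times)
    w <- as.matrix(timecourse_wide(tc)[, c("p", "S", "Sp")])
    kon_cell <- params$k_on / (6.02214076e23 * 0.7e-15)
    orc <- rk4_oracle(list(alpha_p = params$alpha_p, beta_p = params$beta_p,
                           alpha_S = params$alpha_S, beta_Sp = params$beta_Sp,
                           kon_cell = kon_cell, k_off = params$k_off,
                           k_cat = params$k_cat),
                      unname(y0), times, dt = 0.01)
    expect_lt(max(abs(w - orc) / pmax(abs(orc), 1e-8)), 1e-6)
  }
})

test_that("the two integrator backends agree", {
  params <- default_true_params()
  times <- c(0, 2, 4, 6, 8, 10, 15, 20) * 60
  a <- simulate_kinetics(params, c(p = 100, S = 2, Sp = 0.5), times)
  b <- simulate_kinetics(params, c(p = 100, S = 2, Sp = 0.5), times,
                         method = "lsoda")
  expect_equal(a$copies, b$copies, tolerance = 1e-6)
})

test_that("mass is conserved without sources, sinks or co-degradation", {
  p <- rate_constants(k_on = 2e5, k_off = 0.1)
  tc <- simulate_kinetics(p, c(p = 80, S = 40, Sp = 10), c(0, 60, 300, 900))
  w <- timecourse_wide(tc)
  expect_equal(w$p + w$Sp, rep(90, 4), tolerance = 1e-7)
  expect_equal(w$S + w$Sp, rep(50, 4), tolerance = 1e-7)
})

test_that("trajectories stay non-negative for non-negative inputs", {
  set.seed(7)
  for (i in 1:10) {
    params <- random_rate_constants()
    y0 <- c(p = runif(1, 0, 100), S = runif(1, 0, 100), Sp = runif(1, 0, 10))
    tc <- simulate_kinetics(params, y0, seq(0, 1200, by = 120))
    expect_true(all(tc$copies >= 0))
  }
})

test_that("weaker association leaves more target at the end", {
  finals <- vapply(c(1e6, 3e5, 1e5, 3e4, 1e4, 0), function(kon) {
    p <- rate_constants(k_on = kon, k_off = 0.2, k_cat = 0.3, alpha_p = 0.5,
                        alpha_S = 0.6, beta_p = 0.005, beta_Sp = 0.001)
    tc <- simulate_kinetics(p, c(p = 100, S = 2, Sp = 0.5), c(0, 1200))
    tc$copies[tc$species == "p" & tc$time_s == 1200]
  }, numeric(1))
  expect_true(all(diff(finals) > 0))
})

test_that("invalid simulation inputs are rejected", {
  expect_error(rate_constants(k_on = -1), "non-negative")
  expect_error(simulate_kinetics(rate_constants(), c(p = -1, S = 0, Sp = 0),
                                 c(0, 10)), "non-negative")
  expect_error(simulate_kinetics(rate_constants(), c(p = 1, S = 0, Sp = 0),
                                 c(10, 5)), "increasing")
})
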