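test_that("error sign sets the direction of cortical plasticity", {
  p <- okr_params()
  b <- baseline_state(p)
  for (d in c(0.1, 0.5, 0.9, 1.5, 2, 3, 4)) {
    if (d > p$d0) {
      expect_lt(dw_pf_pc(b, p, d = d), 0)   # LTD
      expect_gt(dw_pf_mli(b, p, d = d), 0)  # LTP
    } else if (d < p$d0) {
      expect_gt(dw_pf_pc(b, p, d = d), 0)
      expect_lt(dw_pf_mli(b, p, d = d), 0)
    }
  }
})

test_that("gating: gamma and beta coefficients isolate their pathways", {
  # gamma = 0: the nuclear rate depends only on (W_MF_DN, W0_MF_DN, tau6)
  p0 <- okr_params(gamma = 0)
  set.seed(3)
  for (i in 1:10) {
    dn <- runif(1, 0, 2)
    r <- vapply(1:3, function(j)
      dw_mf_dn(okr_state(runif(1, 0, 2), runif(1, 0, 2), dn), p0), numeric(1))
    expect_equal(r, rep((1 / p0$tau6) * (p0$w0_mf_dn - dn), 3))
  }
  # beta1 = beta3 = 0: cortical rates independent of the error signal
  pb <- okr_params(beta1 = 0, beta3 = 0)
  s <- okr_state(0.9, 1.2, 1.1)
  expect_identical(dw_pf_pc(s, pb, d = 0.3), dw_pf_pc(s, pb, d = 3))
  expect_identical(dw_pf_mli(s, pb, d = 0.3), dw_pf_mli(s, pb, d = 3))
})

test_that("off-task gains diminish but do not return to the previous level", {
  sm <- cached_sim("normal")$sessions
  expect_true(all(sm$gain_end_rest < sm$gain_post))
  expect_true(all(sm$gain_end_rest > sm$gain_pre))
})

test_that("pre-training gains rise session by session toward a plateau", {
  sim <- simulate_okr("normal", std_protocol(n_sessions = 8))
  sm <- sim$sessions
  expect_true(all(diff(sm$gain_pre) > 0))
  # shrinking daily increments: slow approach to equilibrium
  inc <- diff(sm$gain_post)
  expect_true(all(inc > -1e-7))
  expect_lt(inc[7], inc[1])
  expect_true(all(diff(sm$gain_post[4:8]) < 0.005))
})

test_that("consolidation accumulates in the nuclear weight across sessions", {
  sm <- cached_sim("normal")$sessions
  expect_true(all(diff(sm$w_mf_dn_end) > 0))
  # cortical weight: depressed by training, then monotone recovery toward
  # baseline during each rest phase
  tr <- cached_sim("normal")$trajectory
  for (s in c(1, 3, 5)) {
    rest <- tr[tr$session == s & tr$phase == "rest", "w_pf_pc"]
    expect_true(all(diff(rest) > -1e-10))
    expect_true(all(rest <= 1 + 1e-9))
  }
  # full recovery in extended darkness after training ends
  p <- okr_params()
  end <- coef(cached_sim("normal"))
  dark <- integrate_phase(okr_state(end[1], end[2], end[3]), p,
                          d = p$d0, training = FALSE, duration = 24 * 14,
                          dt_record = 1)
  expect_equal(unname(dark[nrow(dark), "w_pf_pc"]), 1, tolerance = 0.01)
})

test_that("corticonuclear cut after session 4 erases that day's learning", {
  sm <- cached_sim("pc_dn_block")$sessions
  # gain falls back close to the session-4 pre-training level and the
  # nuclear weight stops growing (memory transfer disrupted)
  expect_lt(sm$gain_end_rest[4], sm$gain_post[4])
  expect_lt(abs(sm$gain_end_rest[4] - sm$gain_pre[4]), 0.03)
  expect_lte(sm$w_mf_dn_end[4], sm$w_mf_dn_post[4])
  expect_lte(sm$w_mf_dn_end[5], sm$w_mf_dn_end[4] + 1e-9)
  # while the same run before the event matches the normal run exactly
  nrm <- cached_sim("normal")$sessions
  expect_equal(sm$gain_post[1:4], nrm$gain_post[1:4], tolerance = 1e-8)
})

test_that("learning and recovery rates shape short- vs long-term memory", {
  d <- calibrated_d()
  n <- session_metrics(cached_sim("normal"), 5)
  # faster cortical recovery (shorter tau3): less consolidation, short-term
  # adaptation not degraded
  fast <- run_protocol(okr_params(tau3 = 36), std_protocol())
  mf <- session_metrics(fast, 5)
  expect_lt(mf$ltm_increment, n$ltm_increment)
  expect_gte(mf$stm_increment, n$stm_increment - 1e-6)
  # slower induction (longer tau1): smaller short-term increment
  slow <- run_protocol(okr_params(tau1 = 2), std_protocol())
  ms <- session_metrics(slow, 5)
  expect_lt(ms$stm_increment, n$stm_increment)
  # the registered combined alteration reduces long-term adaptation
  ra <- session_metrics(cached_sim("pf_pc_rate_alteration"), 5)
  expect_lt(ra$ltm_increment, n$ltm_increment)
})

test_that("granular-layer attenuation scales down every downstream change", {
  n5 <- session_metrics(cached_sim("normal"), 5)
  a5 <- session_metrics(cached_sim("mf_gc_attenuation"), 5)
  expect_gt(a5$ltm_increment, 0)
  expect_lt(a5$ltm_increment, n5$ltm_increment)
  expect_lt(a5$stm_increment, n5$stm_increment)
})
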