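test_that("transmission coefficient matches the granular-layer balance", {
  expect_equal(transmission_coefficient(0, 0), 1)     # no Golgi inhibition
  expect_equal(transmission_coefficient(1, 0), 0)     # total feedback inhibition
  expect_equal(transmission_coefficient(0.4, 1.0), 0.3)
  # parameterised: alpha always in [0, 1] on the admissible domain
  for (wp in c(0, 0.25, 0.6, 1)) for (wm in c(0, 0.5, 2)) {
    a <- transmission_coefficient(wp, wm)
    expect_gte(a, 0); expect_lte(a, 1)
  }
  expect_error(transmission_coefficient(1.2, 0), "exceed")
  expect_error(transmission_coefficient(0.5, -0.5), "non-negative")
  expect_error(transmission_coefficient(-1, 0), "outside")
})

test_that("layer rates and error signal follow the circuit definitions", {
  p <- okr_params()
  lr <- layer_rates(okr_state(1, 1, 1), p, d = 1)
  expect_equal(lr$f_pf, 1)
  expect_equal(lr$f_pc, 0)
  expect_equal(lr$f_dn, 1)
  expect_equal(lr$e, 0)
  expect_equal(layer_rates(okr_state(1, 1, 1), p, d = 2)$e, 1)
  expect_equal(layer_rates(okr_state(1, 0.5, 1), p, d = 1)$f_pc, 0.5)
  # structural identities across random states
  set.seed(42)
  for (i in 1:20) {
    w <- runif(3, 0, 2)
    pa <- okr_params(alpha = runif(1), f_mf = runif(1, 0.5, 1.5))
    lr <- layer_rates(okr_state(w[1], w[2], w[3]), pa, d = runif(1, 0, 3))
    expect_equal(lr$f_pf, pa$alpha * pa$f_mf)
    expect_equal(lr$f_dn, w[3] * pa$f_mf - lr$f_pc)
  }
})

test_that("plasticity rates reproduce hand-computed values", {
  p <- okr_params()
  b <- baseline_state(p)
  # fixed point at baseline with d = d0
  expect_equal(dw_pf_pc(b, p, d = 1), 0)
  expect_equal(dw_pf_mli(b, p, d = 1), 0)
  expect_equal(dw_mf_dn(b, p), 0)
  # error-driven terms: -(1/0.33)*1*1*1*1 and +(1/0.33)*0.5*1*1
  expect_equal(dw_pf_pc(b, p, d = 2, ramp = 1), -1 / 0.33, tolerance = 1e-12)
  expect_equal(dw_pf_mli(b, p, d = 2), 0.5 / 0.33, tolerance = 1e-12)
  # LTD blockade: beta1 = 0 kills the drive at baseline
  expect_equal(dw_pf_pc(b, okr_params(beta1 = 0), d = 3), 0)
  # nuclear transfer: (1/5.5)*0.4 at the displaced cortical state
  p55 <- okr_params(tau4 = 5.5)
  expect_equal(dw_mf_dn(okr_state(0.8, 1.2, 1), p55), 0.4 / 5.5,
               tolerance = 1e-12)
  # gamma = 0 at baseline MF-DN leaves pure (zero) decay
  expect_equal(dw_mf_dn(b, okr_params(gamma = 0)), 0)
  # ramp scales the PF-PC drive linearly
  expect_equal(dw_pf_pc(b, p, d = 2, ramp = 0.5), -0.5 / 0.33,
               tolerance = 1e-12)
})

test_that("OKR gain read-out is the linear cerebellar-space projection", {
  p <- okr_params()
  expect_equal(okr_gain(okr_state(1, 1, 1), p), 0.3)
  expect_equal(okr_gain(okr_state(1, 1, 1), okr_params(g_okr0 = 0)), 0)
  expect_equal(okr_gain(okr_state(1, 1, 2), p), 0.6)
  # linearity in g_okr0 and in each weight
  set.seed(7)
  for (i in 1:10) {
    w <- runif(3, 0, 2); k <- runif(1, 0, 3)
    pa <- okr_params(alpha = runif(1))
    pk <- okr_params(alpha = pa$alpha, g_okr0 = pa$g_okr0 * k)
    s <- okr_state(w[1], w[2], w[3])
    expect_equal(okr_gain(s, pk), k * okr_gain(s, pa))
    sk <- okr_state(k * w[1], k * w[2], k * w[3])
    expect_equal(okr_gain(sk, pa), k * okr_gain(s, pa))
  }
  # baseline identity
  pa <- okr_params(alpha = 0.3, w0_pf_pc = 1.1, w0_pf_mli = 0.9, w0_mf_dn = 0.5)
  expect_equal(okr_gain(baseline_state(pa), pa),
               pa$g_okr0 * pa$w0_mf_dn +
                 pa$g_okr0 * pa$alpha * (pa$w0_pf_mli - pa$w0_pf_pc))
})

test_that("baseline balance holds for every registered scenario", {
  for (nm in list_scenarios()) {
    res <- check_baseline_balance(scenario_params(nm))
    expect_equal(unname(res), c(0, 0), info = nm)
  }
})

test_that("a corrupted baseline produces the expected residual", {
  p <- okr_params()
  res <- check_baseline_balance(p, state = okr_state(1.2, 1, 1))
  expect_equal(unname(res["pf_pc"]), -(1 / p$tau3) * 0.2, tolerance = 1e-12)
  expect_error(check_baseline_balance(p, state = okr_state(1.2, 1, 1),
                                      tol = 1e-6),
               "inconsistency")
})

test_that("eliminated symbols never influence the reduced equations", {
  # lambda2, lambda5, LTD_spon, f_PC_max are documentation-only: setting
  # them to arbitrary values changes no evaluated rate
  p1 <- okr_params()
  p2 <- okr_params(lambda2 = 99, lambda5 = -3, ltd_spon = 7, f_pc_max = 1e6,
                   dn_bar = 2, cf_bar = 5)
  s <- okr_state(0.7, 1.3, 1.4)
  for (d in c(0.5, 1, 2)) {
    expect_identical(dw_pf_pc(s, p1, d), dw_pf_pc(s, p2, d))
    expect_identical(dw_pf_mli(s, p1, d), dw_pf_mli(s, p2, d))
  }
  expect_identical(dw_mf_dn(s, p1), dw_mf_dn(s, p2))
})

test_that("parameter validation rejects inadmissible values", {
  expect_error(okr_params(alpha = 1.2), "alpha")
  expect_error(okr_params(alpha = -0.1), "alpha")
  expect_error(okr_params(beta1 = -1), "beta1")
  expect_error(okr_params(tau1 = 0), "tau1")
  expect_error(okr_params(tau3 = -2), "tau3")
  expect_no_error(okr_params(tau3 = Inf))  # lambda3 = 0 is representable
  expect_error(okr_state(-0.1, 1, 1), "non-negative")
})
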