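test_that("the registry exposes the twelve lesion configurations", {
  nms <- list_scenarios()
  expect_length(nms, 12)
  expect_true("normal" %in% nms)
  for (nm in nms) expect_s3_class(get_scenario(nm), "okr_scenario")
  expect_error(get_scenario("nope"), "registered scenarios")
  expect_error(get_scenario("nope"), "normal")  # error lists the names
})

test_that("scenario columns carry the registered parameter values", {
  n <- scenario_params("normal")
  expect_equal(get_scenario("normal")$overrides, list())
  expect_equal(c(n$alpha, n$beta1, n$beta3, n$gamma), c(1, 1, 0.5, 1))
  expect_equal(c(n$w0_pf_pc, n$w0_pf_mli, n$w0_mf_dn), c(1, 1, 1))
  expect_equal(n$tau1, 0.33)

  expect_equal(scenario_params("mf_gc_attenuation")$alpha, 0.3)
  expect_equal(scenario_params("pf_pc_train_ltd_partial")$beta1, 0.3)
  expect_equal(scenario_params("pf_pc_train_ltd_complete")$beta1, 0)

  sl <- scenario_params("pf_pc_spont_ltd_block")
  expect_equal(c(sl$w0_pf_pc, sl$w0_pf_mli, sl$w0_mf_dn), c(1.1, 1.1, 0))

  lp <- scenario_params("pf_pc_spont_ltp_block")
  expect_equal(c(lp$w0_pf_pc, lp$beta1, lp$beta3), c(0, 0, 0.48))
  expect_true(is.infinite(lp$tau3))  # lambda3 = 0
  expect_equal(c(lp$w0_pf_mli, lp$w0_mf_dn), c(0.5, 0.5))

  ra <- scenario_params("pf_pc_rate_alteration")
  expect_equal(c(ra$tau1, ra$tau3), c(2, 36))
  # parameterised family
  ra2 <- scenario_params(get_scenario("pf_pc_rate_alteration",
                                      tau1 = 1, tau3 = 48))
  expect_equal(c(ra2$tau1, ra2$tau3), c(1, 48))

  for (nm in c("cf_block_partial", "cf_block_complete")) {
    cf <- scenario_params(nm)
    b2 <- if (nm == "cf_block_partial") 0.3 else 0
    expect_equal(c(cf$beta1, cf$beta3, cf$beta2), c(b2, b2, b2), info = nm)
  }

  np <- scenario_params("pf_mli_no_plasticity")
  expect_equal(np$beta3, 0)
  expect_true(np$freeze_pf_mli)

  nb <- scenario_params("pf_mli_no_baseline")
  expect_equal(c(nb$w0_pf_pc, nb$w0_pf_mli, nb$w0_mf_dn), c(0.4, 0, 0))
  expect_equal(c(nb$beta1, nb$beta3), c(0.1, 0.2))

  pd <- get_scenario("pc_dn_block")
  expect_length(pd$events, 1)
  expect_equal(pd$events[[1]]$after_training_of_session, 4)
  expect_equal(pd$events[[1]]$set$gamma, 0)
})

test_that("applying a scenario is idempotent", {
  for (nm in c("normal", "mf_gc_attenuation", "pf_pc_spont_ltp_block")) {
    p1 <- scenario_params(nm)
    p2 <- scenario_params(get_scenario(nm), base = p1)
    expect_equal(unclass(p1), unclass(p2), info = nm)
  }
})

test_that("frozen PF-MLI weight never leaves its baseline", {
  sim <- cached_sim("pf_mli_no_plasticity")
  expect_true(all(abs(sim$trajectory$w_pf_mli - 1) < 1e-12))
  expect_equal(weight_change_pct(sim, 3, "PF-MLI"), 0)
})

test_that("complete CF blockade makes cortical rates error-independent", {
  p <- scenario_params("cf_block_complete")
  set.seed(11)
  for (i in 1:10) {
    s <- okr_state(runif(1, 0, 2), runif(1, 0, 2), runif(1, 0, 2))
    # rates identical across desired gains: no error-driven component
    r1 <- c(dw_pf_pc(s, p, d = 0.2), dw_pf_mli(s, p, d = 0.2))
    r2 <- c(dw_pf_pc(s, p, d = 3), dw_pf_mli(s, p, d = 3))
    expect_identical(r1, r2)
  }
  # and the full run stays flat at the baseline gain
  sim <- cached_sim("cf_block_complete")
  expect_true(all(abs(sim$trajectory$gain - 0.3) < 1e-10))
})

test_that("spontaneous-LTP blockade keeps PF-PC clamped at zero", {
  sim <- cached_sim("pf_pc_spont_ltp_block")
  expect_true(all(sim$trajectory$w_pf_pc == 0))
})

test_that("off-balance-by-design scenarios drift under the training drive", {
  # both exceptional configurations are relaxation-balanced at rest but are
  # displaced by the first training phase in a documented direction
  d <- calibrated_d()
  nb <- scenario_params("pf_mli_no_baseline")
  expect_lt(dw_pf_pc(baseline_state(nb), nb, d = d), 0)   # immediate LTD
  expect_gt(dw_pf_mli(baseline_state(nb), nb, d = d), 0)  # immediate LTP
  lp <- scenario_params("pf_pc_spont_ltp_block")
  expect_gt(dw_pf_mli(baseline_state(lp), lp, d = d), 0)
  expect_equal(dw_pf_pc(baseline_state(lp), lp, d = d), 0)  # beta1 = 0, clamped
})
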