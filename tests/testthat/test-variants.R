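test_that("penalty ramp is zero through the onset then linear and unbounded", {
  vc <- variant_config("penalty")
  expect_equal(penalty_magnitude(0, vc), 0)
  expect_equal(penalty_magnitude(150, vc), 0)
  expect_equal(penalty_magnitude(300, vc), 1)
  expect_equal(penalty_magnitude(300, vc) * vc$c_p, 0.1)
  expect_equal(penalty_magnitude(1500, vc), 9)  # pure linear ramp, no cap
  t_v <- 0:400
  p <- penalty_magnitude(t_v, vc)
  expect_true(all(p[t_v <= 150] == 0))
  expect_true(all(diff(p[t_v >= 150]) > 0))
})

test_that("variant adjustments hit exactly the quantities they should", {
  none <- stay_adjustments(variant_config("none"), t_v = 500)
  expect_equal(none, list(selection = 0, rpe = 0, true_report = 0))

  pen <- stay_adjustments(variant_config("penalty"), t_v = 300)
  expect_equal(pen$selection, 0.1)
  expect_equal(pen$rpe, 0.1)
  expect_equal(pen$true_report, 0.1)
  early <- stay_adjustments(variant_config("penalty"), t_v = 100)
  expect_equal(early, list(selection = 0, rpe = 0, true_report = 0))

  # regret is invisible at selection time but felt in the RPEs afterwards
  reg <- stay_adjustments(variant_config("regret"), t_v = 300)
  expect_equal(reg$selection, 0)
  expect_equal(reg$rpe, 0.02)
  expect_equal(reg$true_report, 0.02)
  # zero regret reduces to the base model
  reg0 <- stay_adjustments(variant_config("regret", c_r = 0))
  expect_equal(reg0, list(selection = 0, rpe = 0, true_report = 0))
})

test_that("penalty shifts the selection-time STAY value; regret does not", {
  q_stay <- 0.5268013921875
  pen <- stay_adjustments(variant_config("penalty"), t_v = 300)
  expect_equal(q_stay - pen$selection, 0.4268013921875)
  reg <- stay_adjustments(variant_config("regret"), t_v = 300)
  # identical choice probabilities at fixed weight under regret
  expect_equal(softmax_go_prob(0.4, q_stay - reg$selection, 20),
               softmax_go_prob(0.4, q_stay, 20))
})

test_that("regret shifts the STAY-step TD error by exactly c_r", {
  x <- goal_based_features(5, 0.85)
  w <- 0.6
  adj <- stay_adjustments(variant_config("regret"))
  for (k in 1:4) {
    v_k <- approx_state_value(w, x[k])
    expect_equal(td_error(0, 0.85, v_k, v_k) - adj$rpe,
                 (0.85 - 1) * w * x[k] - 0.02)
  }
})

test_that("SR feature updates encode slowed goal approach", {
  x <- goal_based_features(5, 0.85)
  # GO with self-consistent features is a no-op
  expect_equal(sr_feature_update(x, 2, 3, 0.05, 0.85), x, tolerance = 1e-12)
  # STAY shrinks the visited feature by the factor 1 - alpha (1 - gamma)
  x2 <- sr_feature_update(x, 2, 2, 0.05, 0.85)
  expect_equal(x2[2], x[2] * 0.9925)
  expect_equal(x2[-2], x[-2])
  # the goal feature is protected
  expect_error(sr_feature_update(x, 5, 5, 0.05, 0.85), "goal")
  # repeated STAYs strictly decrease the feature but keep it in (0, 1]
  xx <- x
  prev <- xx[3]
  for (i in 1:200) {
    xx <- sr_feature_update(xx, 3, 3, 0.05, 0.85)
    expect_lt(xx[3], prev)
    prev <- xx[3]
  }
  expect_true(all(xx > 0 & xx <= 1))
  expect_equal(xx[5], 1)
})

test_that("a variant-free run is identical to the base model", {
  base <- run_simulation(quick_cfg(n_runs = 1, seed = 11))
  none <- run_simulation(quick_cfg(n_runs = 1, seed = 11,
                                   variant = variant_config("none")))
  expect_identical(base, none)
  # regret with c_r = 0 also reduces to the base model
  reg0 <- run_simulation(quick_cfg(n_runs = 1, seed = 11,
                                   variant = variant_config("regret", c_r = 0)))
  expect_equal(reg0[names(reg0) != "config"], base[names(base) != "config"])
})

test_that("penalty and regret never alter GO-step updates", {
  # school term is all GO: the weight path must match the base model even if
  # a variant is configured (variants act only on STAY quantities)
  for (type in c("penalty", "regret")) {
    cfg <- quick_cfg(n_runs = 1, seed = 3, variant = variant_config(type))
    expect_equal(run_school_term(cfg)$w_trace,
                 run_school_term(quick_cfg(n_runs = 1, seed = 3))$w_trace)
  }
})
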