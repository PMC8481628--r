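test_that("learning-rate schedule decays within a phase and supports constants", {
  expect_equal(learning_rate(1), 0.5 / 1.2)
  expect_equal(learning_rate(20), 0.1)
  expect_true(all(diff(learning_rate(1:20)) < 0))
  expect_equal(learning_rate(1:20, "constant", 0.2), rep(0.2, 20))
  expect_equal(learning_rate(7, "constant", 0.4), 0.4)
})

test_that("school term is deterministic and follows the per-step structure", {
  cfg <- quick_cfg()
  s1 <- run_school_term(cfg)
  s2 <- run_school_term(cfg)
  expect_identical(s1, s2)
  expect_equal(dim(s1$w_trace), c(20L, 5L))
  # independent oracle: with exact features every non-terminal GO update is
  # w <- w - a * cost * x_k and the terminal update is w <- w + a * (R - w),
  # a recursion solvable by hand
  x <- goal_based_features(5, 0.85)
  w <- 0
  for (m in 1:20) {
    a <- 0.5 / (1 + 0.2 * m)
    for (k in 1:4) {
      w <- w - a * cfg$chain$cost * x[k]
      expect_equal(s1$w_trace[m, k], w, tolerance = 1e-12)
    }
    w <- w + a * (1 - w)
    expect_equal(s1$w_trace[m, 5], w, tolerance = 1e-12)
  }
  # w rises at the goal-state update whenever w < R
  expect_true(all(s1$w_trace[, 5] > s1$w_trace[, 4]))
})

test_that("forced GO with a small constant rate reaches the TD fixed point", {
  cfg <- sim_config(school_episodes = 500, lr_mode = "constant",
                    lr_constant = 0.05, vacation_episodes = 0, n_runs = 1)
  st <- run_school_term(cfg)
  # the stationarity condition pins the weight just after leaving S4 at
  # w* = R - cost * sum(gamma^j); the post-terminal value sits a * cost * S
  # above it
  expect_lt(abs(st$w_trace[500, 4] - W_STAR), 1e-3)
  expect_equal(st$w, W_STAR + 0.05 * 0.1 * sum(0.85^(1:4)), tolerance = 1e-6)
})

test_that("vacation episodes record stays, gaps and weights coherently", {
  cfg <- quick_cfg(n_runs = 1, seed = 4)
  rec <- run_simulation(cfg)
  expect_equal(dim(rec$stay_counts), c(20L, 4L))
  expect_true(all(rec$stay_counts >= 0))
  expect_false(any(rec$truncated))
  # every state was entered in every episode, so no gap is missing
  expect_false(anyNA(rec$gap_approx))
  # the episode-1 entry gap at S1 is deterministic: it only depends on the
  # school-term weight
  w20 <- run_school_term(cfg)$w
  x <- goal_based_features(5, 0.85)
  q <- approx_action_values(w20, x, 1, 0.85, 0.1)
  expect_equal(rec$gap_approx[1, 1], unname(q["GO"] - q["STAY"]))
  # and the true gap at vacation start is the closed-form one
  expect_equal(rec$gap_true[1, 1], 0.0305015625)
})

test_that("compiled and reference engines are identical on a shared stream", {
  for (variant in c("none", "penalty", "regret", "sr_update")) {
    cfg <- quick_cfg(n_runs = 3, seed = 17,
                     variant = variant_config(variant))
    cpp <- run_ensemble(cfg, engine = "cpp")
    ref <- run_ensemble(cfg, engine = "r")
    expect_equal(cpp$stay_counts, ref$stay_counts)
    expect_equal(cpp$gap_approx, ref$gap_approx, tolerance = 1e-14)
    expect_equal(cpp$gap_true, ref$gap_true, tolerance = 1e-14)
    expect_equal(cpp$w_vacation, ref$w_vacation, tolerance = 1e-14)
    expect_equal(cpp$w_school, ref$w_school, tolerance = 1e-14)
  }
})

test_that("ensembles are deterministic and substreams are counter-based", {
  cfg <- quick_cfg(n_runs = 30, seed = 9)
  e1 <- run_ensemble(cfg)
  e2 <- run_ensemble(cfg)
  expect_identical(e1$stay_counts, e2$stay_counts)
  expect_identical(e1$gap_approx, e2$gap_approx)
  # growing the ensemble leaves earlier runs untouched
  big <- run_ensemble(quick_cfg(n_runs = 60, seed = 9))
  expect_identical(big$stay_counts[1:30, , ], e1$stay_counts)
  # distinct runs get distinct seeds; same run always the same seed
  s <- run_seeds(9, 10000)
  expect_equal(anyDuplicated(s), 0L)
  expect_identical(run_seeds(9, 100), s[1:100])
  # single-run ensemble equals the corresponding simulation record
  one <- run_ensemble(quick_cfg(n_runs = 1, seed = 9))
  rec <- run_simulation(quick_cfg(n_runs = 1, seed = 9), run = 1)
  expect_equal(one$stay_counts[1, , ], unname(rec$stay_counts))
})

test_that("school phase has no stochasticity; stays happen only in vacation", {
  ens <- run_ensemble(quick_cfg(n_runs = 10, seed = 2))
  # the shared school-term weight path is the deterministic one
  expect_equal(ens$w_school,
               run_school_term(quick_cfg(seed = 2))$w_trace)
  # all runs start the vacation from the same weight, so the S1 episode-1
  # gap is constant across runs
  expect_equal(length(unique(ens$gap_approx[, 1, 1])), 1L)
})

test_that("disjoint sub-ensembles agree within sampling error", {
  a <- run_ensemble(sim_config(n_runs = 400, seed = 21))
  b <- run_ensemble(sim_config(n_runs = 400, seed = 22))
  ma <- apply(a$stay_counts[, 1, ], 2, mean)
  mb <- apply(b$stay_counts[, 1, ], 2, mean)
  se <- sqrt(apply(a$stay_counts[, 1, ], 2, var) / 400 +
             apply(b$stay_counts[, 1, ], 2, var) / 400)
  expect_true(all(abs(ma - mb) < 3 * se + 1e-9))
})

test_that("parameter sweeps cover the grid and a single cell matches run_ensemble", {
  sw <- parameter_sweep(quick_cfg(n_runs = 10, seed = 3),
                        cost = c(0.05, 0.1))
  expect_equal(nrow(sw), 2L)
  expect_equal(sw$cost, c(0.05, 0.1))
  single <- summarize_ensemble(run_ensemble(
    quick_cfg(n_runs = 10, seed = 3,
              chain = task_chain(cost = 0.05))))
  expect_equal(sw$summary[[1]]$stays, single$stays)
})
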