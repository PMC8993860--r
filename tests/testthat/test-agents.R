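test_that("delta-rule update has the right arithmetic and fixed point", {
  expect_equal(rw_update(0.5, 1, 0), 0.5)
  expect_equal(rw_update(0, 1, 0.2), 0.2)
  expect_equal(rw_update(0.7, 0.7, 0.9), 0.7) # fixed point at v = r
  expect_error(rw_update(0, 1, 1.5), "alpha")
  # long-run mean under Bernoulli(0.8) unit rewards approaches E[r] = 0.8
  set.seed(1)
  v <- 0
  vs <- numeric(500)
  for (i in 1:500) {
    v <- rw_update(v, rbinom(1, 1, 0.8), 0.2)
    vs[i] <- v
  }
  expect_lt(abs(mean(vs[101:500]) - 0.8), 0.05)
})

test_that("value traces are bounded and degenerate correctly", {
  sched <- make_conditioning_schedule(design_config(), default_pairing(), 1)
  frozen <- simulate_conditioning_session(agent_params(alpha = 0), sched, 2)
  expect_true(all(frozen$trace == 0))
  learner <- simulate_conditioning_session(agent_params(alpha = 0.9), sched, 2)
  expect_true(all(abs(learner$trace) <= 1))
  # appetitive cues end positive, aversive negative, neutral at 0
  expect_gt(learner$v_final[[names(which(sched$pairing == "points"))]], 0)
  expect_lt(learner$v_final[[names(which(sched$pairing == "aversive_noise"))]], 0)
  expect_equal(learner$v_final[[names(which(sched$pairing == "neutral"))]], 0)
})

test_that("RTs speed with salience and respect truncation", {
  sched <- make_conditioning_schedule(design_config(), default_pairing(), 1)
  # near-noiseless agent: RT tracks base - gain * salience
  a <- agent_params(rt_base_ms = 650, rt_gain_ms = 300, rt_sd_ms = 1e-6)
  out <- simulate_conditioning_session(a, sched, 3)
  expect_equal(out$trials$rt_ms, 650 - 300 * out$trials$salience,
               tolerance = 1e-3)
  expect_true(all(out$trials$rt_ms >= 150 & out$trials$rt_ms <= 1500))
  # rt_gain = 0: condition means indistinguishable beyond noise
  flat <- simulate_conditioning_session(
    agent_params(rt_gain_ms = 0, rt_sd_ms = 30), sched, 4)
  mns <- tapply(flat$trials$rt_ms, flat$trials$condition, mean)
  expect_lt(max(mns) - min(mns), 5 * 30 / sqrt(14))
})

test_that("salient cues end with larger |V| than neutral in most sessions", {
  sched <- make_conditioning_schedule(design_config(), default_pairing(), 1)
  a <- agent_params(alpha = 0.2)
  points_cue <- names(which(sched$pairing == "points"))
  neutral_cue <- names(which(sched$pairing == "neutral"))
  wins <- 0
  n_rep <- 200
  for (s in 1:n_rep) {
    sch <- make_conditioning_schedule(design_config(), default_pairing(), s)
    out <- simulate_conditioning_session(a, sch, s + 10000)
    wins <- wins + (abs(out$v_final[[points_cue]]) >
                      abs(out$v_final[[neutral_cue]]))
  }
  expect_gte(wins / n_rep, 0.95)
})

test_that("VAS ratings follow value and stay in bounds", {
  v <- c(circle = 1, square = -1, triangle = 0, star = 0.5, diamond = 0)
  a0 <- agent_params(vas_gain = 0, vas_sd = 1e-12)
  r0 <- generate_vas_ratings(a0, v, default_pairing(), 1)
  expect_equal(r0$pre, rep(50, 5), tolerance = 1e-6)
  expect_equal(r0$post, r0$pre, tolerance = 1e-6)
  a30 <- agent_params(vas_gain = 30, vas_sd = 1e-12)
  r30 <- generate_vas_ratings(a30, v, default_pairing(), 1)
  expect_equal(r30$post - r30$pre, 30 * unname(v), tolerance = 1e-6)
  # clipping property under extreme parameters
  wild <- agent_params(vas_gain = 500, vas_sd = 200)
  for (s in 1:50) {
    r <- generate_vas_ratings(wild, v, default_pairing(), s)
    expect_true(all(r$pre >= 0 & r$pre <= 100 & r$post >= 0 & r$post <= 100))
  }
})

test_that("choice policy is a calibrated, monotone softmax", {
  expect_equal(choice_policy(0, 7), 0.5)
  expect_equal(choice_policy(c(-2, 0.3, 2), 0), rep(0.5, 3))
  expect_equal(choice_policy(1, 10), 1 / (1 + exp(-10)))
  v <- seq(-1, 1, by = 0.05)
  expect_true(all(diff(choice_policy(v, 3)) > 0))
})

test_that("choice sessions express value and can keep learning", {
  cfg <- design_config()
  sched <- make_choice_schedule(cfg, default_pairing(), 0, seed = 2)
  v <- c(circle = 0, square = 0, triangle = 0, star = 0, diamond = 0)
  v[names(which(sched$pairing == "points"))] <- 0.8
  v[names(which(sched$pairing == "aversive_noise"))] <- -0.8

  indiff <- simulate_choice_session(agent_params(beta_choice = 0), sched, v, 3)
  expect_lt(abs(mean(indiff$trials$approach) - 0.5), 0.15)

  sharp <- simulate_choice_session(agent_params(beta_choice = 20), sched, v, 3)
  rates <- tapply(sharp$trials$approach, sharp$trials$condition, mean)
  expect_gt(rates[["points"]], 0.95)
  expect_lt(rates[["aversive_noise"]], 0.05)

  # within-task learning: starting from V = 0, late approach of the points
  # cue exceeds early approach in most sessions
  a_learn <- agent_params(beta_choice = 6, alpha = 0.3,
                          continue_learning = TRUE)
  v0 <- v * 0
  late_gt_early <- 0
  n_rep <- 200
  for (s in 1:n_rep) {
    sch <- make_choice_schedule(cfg, default_pairing(), 0, seed = s)
    out <- simulate_choice_session(a_learn, sch, v0, s + 5000)
    pts <- out$trials[out$trials$condition == "points", ]
    late_gt_early <- late_gt_early +
      (mean(pts$approach[10:14]) > mean(pts$approach[1:5]))
  }
  expect_gt(late_gt_early / n_rep, 0.5)
  # without continue_learning values are untouched
  fixed <- simulate_choice_session(agent_params(continue_learning = FALSE),
                                   sched, v, 4)
  expect_identical(fixed$v_final, v)
})

test_that("recall accuracy follows the retrieval/guessing model", {
  p <- default_pairing()
  perfect <- simulate_recall(agent_params(p_recall = 1), p, 1)
  expect_equal(mean(perfect$correct), 1)
  expect_setequal(unique(perfect$block),
                  c("shape_to_outcome", "outcome_to_shape"))
  # distractor-only guessing: retrieval failure can never be correct
  amnesic <- do.call(rbind, lapply(1:40, function(s) {
    simulate_recall(agent_params(p_recall = 0), p, s)
  }))
  expect_equal(mean(amnesic$correct), 0)
  # guess-among-all-4 variant: accuracy p + (1 - p) / 4
  p_r <- 0.25
  all4 <- do.call(rbind, lapply(1:1000, function(s) {
    simulate_recall(agent_params(p_recall = p_r, recall_guess_all4 = TRUE),
                    p, s)
  }))
  expected <- p_r + (1 - p_r) / 4
  se <- sqrt(expected * (1 - expected) / nrow(all4))
  expect_lt(abs(mean(all4$correct) - expected), 4 * se)
})

test_that("beat series are constant without noise or reactivity", {
  sched <- make_conditioning_schedule(design_config(), default_pairing(), 1)
  a <- agent_params(ibi_base_ms = 800, ibi_react_ms = 0, ibi_sd_ms = 0)
  beats <- simulate_ibi_series(a, sched, 2)
  expect_true(all(abs(diff(beats) - 800) < 1e-9))
})

test_that("agent parameter invariants are enforced", {
  expect_error(agent_params(alpha = 1.5), "alpha")
  expect_error(agent_params(rt_sd_ms = 0), "rt_sd_ms")
  expect_error(agent_params(rt_base_ms = 200, rt_gain_ms = 100), "floor")
  expect_error(agent_params(p_recall = 2), "p_recall")
})
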