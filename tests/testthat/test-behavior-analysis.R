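test_that("residualized change satisfies the OLS normal equations", {
  set.seed(4)
  for (rep in 1:20) {
    pre <- runif(30, 20, 80)
    post <- condval:::clip(pre + rnorm(30, 5, 10), 0, 100)
    r <- residualized_change(pre, post)
    expect_lt(abs(sum(r)), 1e-10)
    expect_lt(abs(cor(r, pre)), 1e-10)
  }
  # zero change -> zero residuals
  pre <- c(40, 50, 60, 70)
  expect_equal(as.numeric(residualized_change(pre, pre)), rep(0, 4))
  # degenerate regressor -> centered change, with a warning
  expect_warning(r <- residualized_change(rep(50, 5), c(52, 55, 60, 48, 50)),
                 "constant")
  expect_equal(as.numeric(r), c(52, 55, 60, 48, 50) - 53)
  expect_true(attr(r, "degenerate"))
  expect_error(residualized_change(1:3, c(5, 5)), "equal length")
  expect_error(residualized_change(c(50, 120, 30), c(50, 50, 50)), "0, 100")
})

test_that("residualized change agrees with an independent lm fit", {
  set.seed(9)
  pre <- runif(40, 10, 90)
  post <- condval:::clip(pre + rnorm(40, 0, 12), 0, 100)
  expect_equal(as.numeric(residualized_change(pre, post)),
               unname(stats::resid(stats::lm(I(post - pre) ~ pre))),
               tolerance = 1e-10)
})

make_choice_table <- function(approaches_by_subject, condition = "points") {
  do.call(rbind, lapply(names(approaches_by_subject), function(id) {
    app <- approaches_by_subject[[id]]
    data.frame(participant_id = id, trial_index = seq_along(app) - 1L,
               condition = condition, approach = app,
               stringsAsFactors = FALSE)
  }))
}

test_that("expected-use scores count expected responses among early trials", {
  tab <- make_choice_table(list(A = rep(TRUE, 5),
                                B = c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  u <- expected_use_score(tab, "points")
  expect_equal(u$use_score[u$participant_id == "A"], 1.0)
  expect_equal(u$use_score[u$participant_id == "B"], 0.6)
  # approaching an aversive cue is anti-expected
  av <- make_choice_table(list(A = rep(TRUE, 5)), condition = "aversive_noise")
  expect_equal(expected_use_score(av, "aversive_noise")$use_score, 0)
  expect_error(expected_use_score(tab, "neutral"), "neutral")
  short <- make_choice_table(list(A = rep(TRUE, 3)))
  expect_error(expected_use_score(short, "points"), "fewer than")
})

test_that("whole-task scope restricts to the session's first trials", {
  # points trials at session positions 0 and 3; positions 1, 2, 4 other cues
  tab <- data.frame(participant_id = "A", trial_index = 0:4,
                    condition = c("points", "neutral", "neutral", "points",
                                  "aversive_noise"),
                    approach = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  u <- expected_use_score(tab, "points", first_k = 5, scope = "whole_task")
  expect_equal(u$use_score, 0.5) # one approach of two early points trials
})

test_that("feature building sign-aligns learning and standardizes", {
  cohort <- tiny_cohort(n = 16, seed = 12)
  for (cond in c("points", "aversive_noise")) {
    f <- build_features(cohort$ratings, cohort$choices, cond)
    expect_equal(mean(f$learn_z), 0, tolerance = 1e-10)
    expect_equal(sd(f$learn_z), 1, tolerance = 1e-10)
    expect_equal(mean(f$use_z), 0, tolerance = 1e-10)
    expect_equal(sd(f$use_z), 1, tolerance = 1e-10)
  }
  # sign alignment: aversive learn score = -residual, appetitive = +residual
  raw_av <- build_features(cohort$ratings, cohort$choices, "aversive_noise",
                           sign_align = FALSE)
  ali_av <- build_features(cohort$ratings, cohort$choices, "aversive_noise",
                           sign_align = TRUE)
  expect_equal(ali_av$learn_score, -raw_av$learn_score)
  raw_pt <- build_features(cohort$ratings, cohort$choices, "points",
                           sign_align = FALSE)
  ali_pt <- build_features(cohort$ratings, cohort$choices, "points")
  expect_equal(ali_pt$learn_score, raw_pt$learn_score)
  # missing subjects are named
  expect_error(
    build_features(cohort$ratings[cohort$ratings$participant_id != "P003", ],
                   cohort$choices, "points"), "P003")
})

test_that("k-means recovers well-separated planted quadrants", {
  hits <- replicate(20, {
    f <- planted_blobs(seed = sample.int(1e6, 1))
    cl <- cluster_learn_use(f, k = 4, restarts = 20, seed = 2,
                            truth = setNames(f$truth, f$participant_id))
    cl$agreement
  })
  expect_gte(mean(hits >= 0.95), 0.95)
  # quadrant labels are a bijection at k = 4 on separated data
  f <- planted_blobs(seed = 3)
  cl <- cluster_learn_use(f, k = 4, seed = 2)
  expect_setequal(cl$cluster_quadrant, c("HH", "HL", "LH", "LL"))
})

test_that("degenerate geometries error or resolve exactly", {
  f <- planted_blobs(n_per = 2, sd = 0)
  # 4 distinct points, k = 4: each point is its own centroid
  cl <- cluster_learn_use(f, k = 4, restarts = 10, seed = 1)
  expect_equal(cl$inertia, 0, tolerance = 1e-12)
  expect_error(cluster_learn_use(planted_blobs(n_per = 1), k = 5, seed = 1),
               "at least k")
  same <- planted_blobs(n_per = 3, sd = 0)
  same[, c("learn_z", "use_z")] <- 0
  expect_error(cluster_learn_use(same, k = 4, seed = 1), "distinct")
})

test_that("best-of-restarts inertia never exceeds a single run's", {
  f <- planted_blobs(n_per = 10, sep = 1.5, sd = 0.8, seed = 5)
  multi <- cluster_learn_use(f, k = 4, restarts = 30, seed = 7)
  for (s in 1:10) {
    single <- cluster_learn_use(f, k = 4, restarts = 1, seed = s)
    expect_lte(multi$inertia, single$inertia + 1e-9)
  }
})

test_that("silhouette-based k selection finds the planted cluster count", {
  four <- select_k(planted_blobs(seed = 11), k_range = 2:6, seed = 1)
  expect_equal(four$k, 4)
  expect_false(four$no_structure)
  # two planted blobs
  f2 <- planted_blobs(seed = 12)
  f2$use_z <- f2$learn_z # collapse to two groups along one diagonal axis
  f2$learn_z <- as.numeric(scale(f2$learn_score))
  two <- select_k(f2, k_range = 2:6, seed = 1)
  expect_equal(two$k, 2)
  # a single Gaussian blob scores well below planted structure at every k
  set.seed(13)
  blob <- planted_blobs(seed = 13)
  blob$learn_z <- rnorm(nrow(blob))
  blob$use_z <- rnorm(nrow(blob))
  null_res <- select_k(blob, k_range = 2:6, seed = 1)
  expect_lt(max(null_res$scores$mean_silhouette),
            max(four$scores$mean_silhouette) - 0.2)
})

test_that("recall scoring reports per-block and overall accuracy", {
  rec <- rbind(
    data.frame(participant_id = "A", block = "shape_to_outcome",
               correct = c(TRUE, TRUE, TRUE, TRUE, TRUE), n_options = 4L),
    data.frame(participant_id = "A", block = "outcome_to_shape",
               correct = c(FALSE, FALSE, FALSE, TRUE, TRUE), n_options = 4L))
  sc <- score_recall(rec)
  expect_equal(sc$accuracy_shape_to_outcome, 1.0)
  expect_equal(sc$accuracy_outcome_to_shape, 0.4)
  expect_equal(sc$accuracy_overall, 0.7)
  expect_equal(attr(sc, "chance"), 0.25)
  bad <- rec
  bad$n_options <- 5L
  expect_error(score_recall(bad), "4-option")
})

test_that("kappa matches closed-form values on hand-computed tables", {
  expect_equal(cohen_kappa(matrix(c(10, 0, 0, 10), 2)), 1)
  # p_o = 0.75, p_e = 0.5 -> kappa = 0.5
  expect_equal(cohen_kappa(matrix(c(30, 10, 10, 30), 2)), 0.5)
  expect_equal(cohen_kappa(matrix(c(0, 10, 10, 0), 2)), -1)
  expect_error(cohen_kappa(matrix(1:6, 2)), "square")
})

test_that("concordance dichotomizes, cross-tabulates and flags degeneracy", {
  f <- planted_blobs(seed = 21)
  keep <- f$truth %in% c("HH", "LL")
  conc <- concordance(f[keep, ])
  expect_equal(conc$kappa, 1)
  anti <- f[f$truth %in% c("HL", "LH"), ]
  expect_equal(concordance(anti)$kappa, -1)
  # independent labels: kappa near zero over shuffles
  set.seed(22)
  ks <- replicate(200, {
    g <- f
    g$use_z <- sample(g$use_z)
    concordance(g)$kappa
  })
  expect_lt(abs(mean(ks)), 0.05)
  # a constant axis puts everyone in "low": degenerate margin, kappa NA
  one_sided <- f
  one_sided$learn_z <- rep(-1, nrow(f))
  res <- concordance(one_sided)
  expect_true(res$degenerate)
  expect_true(is.na(res$kappa))
})

test_that("sign-flip permutation test behaves at the extremes", {
  pre <- c(40, 45, 50, 55, 60, 42, 58)
  expect_equal(permutation_conditioning_test(pre, pre, 500, 1)$p_value, 1)
  expect_warning(permutation_conditioning_test(pre, pre + 5, n_perm = 50),
                 "coarse")
  # strong planted shift: decisive rejection in nearly all replicates
  set.seed(30)
  rejections <- replicate(60, {
    pre <- runif(72, 30, 60)
    post <- condval:::clip(pre + rnorm(72, 15, 5), 0, 100)
    permutation_conditioning_test(pre, post, 999,
                                  sample.int(1e6, 1))$p_value < 0.01
  })
  expect_gte(mean(rejections), 0.99)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(31)
  pvals <- replicate(500, {
    d <- rnorm(24, 0, 8)
    permutation_conditioning_test(rep(50, 24), 50 + d, n_perm = 199,
                                  seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals) - 0.5), 0.05)
})
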