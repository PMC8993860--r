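#' End-to-end run configuration
#'
#' Bundles every knob of the simulate -> fit -> analyze pipeline: the task
#' design, cohort size and phenotype mixture, the learning-rate grid, and
#' the clustering settings.
#'
#' @param n cohort size.
#' @param design a [design_config()].
#' @param phenotypes list of [phenotype_spec()] (weights summing to 1).
#' @param grid learning-rate grid for [fit_subject()].
#' @param k number of clusters for the headline analysis.
#' @param first_k early choice trials used for the use score.
#' @param scope use-score scope, `"per_condition"` or `"whole_task"`.
#' @param restarts k-means restarts.
#' @param seed master seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(n = 72, design = design_config(),
                       phenotypes = default_phenotypes(),
                       grid = alpha_grid(), k = 4, first_k = 5,
                       scope = "per_condition", restarts = 25, seed = 1) {
  validate_design_config(design)
  structure(list(n = n, design = design, phenotypes = phenotypes,
                 grid = grid, k = k, first_k = first_k, scope = scope,
                 restarts = restarts, seed = seed),
            class = "run_config")
}

#' Simulate a study dataset (and optionally write it to disk)
#'
#' @param config a [run_config()].
#' @param dir optional output directory; when given, the dataset and a
#'   manifest are written there via [write_dataset()].
#' @param simulate_physio passed to [sample_cohort()].
#' @return the `cohort_dataset`, invisibly when written to disk.
#' @export
simulate_study <- function(config = run_config(), dir = NULL,
                           simulate_physio = TRUE) {
  cohort <- sample_cohort(n = config$n, phenotypes = config$phenotypes,
                          config = config$design, seed = config$seed,
                          simulate_physio = simulate_physio)
  if (!is.null(dir)) {
    write_dataset(cohort, dir)
    return(invisible(cohort))
  }
  cohort
}

#' Run the behavioral analysis chain on a cohort
#'
#' For each non-neutral reinforcer condition: builds the standardized
#' learn-by-use features, clusters them at `k`, and computes the
#' learn-use concordance; also scores recall and runs the sign-flip
#' permutation test of the conditioning effect on ratings (appetitive and
#' aversive conditions separately, on signed rating change).
#'
#' @param dataset a `cohort_dataset`.
#' @param k,first_k,scope,restarts,seed analysis settings (see
#'   [run_config()]).
#' @return list with `features` (stacked data frame), `clusters` (named
#'   list of `cluster_result`), `concordance` (named list), `recall_scores`,
#'   and `conditioning_tests` (per-valence permutation tests).
#' @export
analyze_cohort <- function(dataset, k = 4, first_k = 5,
                           scope = "per_condition", restarts = 25, seed = 1) {
  validate_dataset(dataset)
  conditions <- setdiff(reinforcer_kinds(), "neutral")
  truth <- NULL
  if ("phenotype" %in% names(dataset$participants)) {
    truth <- stats::setNames(dataset$participants$phenotype,
                             dataset$participants$participant_id)
  }
  seeds <- spawn_seeds(seed, length(conditions) + 2L)
  features <- list()
  clusters <- list()
  conc <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    f <- build_features(dataset$ratings, dataset$choices, cond,
                        first_k = first_k, scope = scope)
    features[[cond]] <- f
    clusters[[cond]] <- cluster_learn_use(f, k = k, restarts = restarts,
                                          seed = seeds[i], truth = truth)
    conc[[cond]] <- concordance(f)
  }
  tests <- list()
  for (vlab in c("appetitive", "aversive")) {
    v <- if (vlab == "appetitive") 1L else -1L
    r <- dataset$ratings[reinforcer_valence(dataset$ratings$condition) == v, ]
    agg <- stats::aggregate(cbind(pre, post) ~ participant_id, data = r,
                            FUN = mean)
    tests[[vlab]] <- permutation_conditioning_test(
      agg$pre, agg$post, seed = seeds[length(conditions) + match(
        vlab, c("appetitive", "aversive")) - 1L])
  }
  list(features = do.call(rbind, c(features, list(make.row.names = FALSE))),
       clusters = clusters, concordance = conc,
       recall_scores = score_recall(dataset$recall),
       conditioning_tests = tests)
}

#' End-to-end recovery experiment
#'
#' The package's integration check, run on a fresh synthetic cohort:
#' simulate -> fit learning rates -> analyze. Reports the pooled
#' learning-rate estimate against the generating value, quadrant coverage
#' of the k = 4 clusters per reinforcer condition, cluster-truth agreement,
#' recall accuracy, and the planted anticipatory IBI contrast
#' (aversive-noise minus neutral epoch means across subjects).
#'
#' @param config a [run_config()].
#' @param simulate_physio include the cardiac pipeline (default `TRUE`).
#' @return object of class `recovery_report`; its `pass` element flags
#'   whether the pooled alpha is within one grid step of the generating
#'   value and all four quadrants are populated in every condition.
#' @export
recover_study <- function(config = run_config(), simulate_physio = TRUE) {
  cohort <- simulate_study(config, simulate_physio = simulate_physio)
  fit <- fit_cohort_alpha(cohort, grid = config$grid)
  analysis <- analyze_cohort(cohort, k = config$k, first_k = config$first_k,
                             scope = config$scope,
                             restarts = config$restarts, seed = config$seed)

  true_alpha <- mean(cohort$participants$alpha)
  grid_step <- min(diff(sort(config$grid)))
  quadrant_cov <- vapply(analysis$clusters, function(cl) {
    length(unique(cl$quadrant))
  }, numeric(1))
  agreement <- vapply(analysis$clusters, `[[`, numeric(1), "agreement")

  ibi_contrast <- NA_real_
  if (simulate_physio && nrow(cohort$beats) > 0) {
    ibi_contrast <- mean(vapply(
      split(cohort$beats, cohort$beats$participant_id),
      function(b) {
        pid <- b$participant_id[1]
        sched <- reconstruct_conditioning_schedule(cohort, pid)
        ep <- epoch_means(resample_ibi(b$beat_time_ms), sched)
        s <- summarize_epochs(ep)
        a <- s$mean_ibi_ms[s$condition == "aversive_noise" &
                             s$window == "anticipation"]
        n0 <- s$mean_ibi_ms[s$condition == "neutral" &
                              s$window == "anticipation"]
        if (length(a) == 1 && length(n0) == 1) a - n0 else NA_real_
      }, numeric(1)), na.rm = TRUE)
  }

  pass <- abs(fit$pooled_alpha - true_alpha) <= grid_step + 1e-9 &&
    all(quadrant_cov == 4)
  structure(list(
    pooled_alpha = fit$pooled_alpha, median_alpha = fit$median_alpha,
    true_alpha = true_alpha, grid_step = grid_step,
    quadrant_coverage = quadrant_cov, cluster_agreement = agreement,
    recall_mean = mean(analysis$recall_scores$accuracy_overall),
    ibi_anticipation_contrast_ms = ibi_contrast,
    conditioning_tests = analysis$conditioning_tests,
    n = config$n, seed = config$seed, pass = pass
  ), class = "recovery_report")
}

# Rebuild one participant's conditioning schedule object from the stored
# trial table (onsets and ITIs are in the table; config in the dataset).
reconstruct_conditioning_schedule <- function(dataset, participant_id) {
  tr <- dataset$conditioning[dataset$conditioning$participant_id ==
                               participant_id, ]
  tr <- tr[order(tr$trial_index), ]
  pairing <- stats::setNames(
    unique(tr[, c("cue_id", "condition")])$condition,
    unique(tr[, c("cue_id", "condition")])$cue_id)
  new_session_schedule(tr, dataset$config, pairing, NA_integer_,
                       task = "conditioning")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("End-to-end recovery report (n =", x$n, ", seed", x$seed, ")\n")
  cat(sprintf("  pooled learning rate: %.2f (truth %.2f, grid step %.2f) -- %s\n",
              x$pooled_alpha, x$true_alpha, x$grid_step,
              if (abs(x$pooled_alpha - x$true_alpha) <= x$grid_step + 1e-9)
                "recovered" else "NOT recovered"))
  cat(sprintf("  median per-subject alpha: %.2f\n", x$median_alpha))
  cat("  quadrant coverage (of 4) per condition:\n")
  for (cond in names(x$quadrant_coverage)) {
    cat(sprintf("    %-15s %d  (truth agreement %.2f)\n", cond,
                x$quadrant_coverage[[cond]], x$cluster_agreement[[cond]]))
  }
  cat(sprintf("  mean recall accuracy: %.2f (chance 0.25)\n", x$recall_mean))
  if (!is.na(x$ibi_anticipation_contrast_ms)) {
    cat(sprintf("  anticipatory IBI, aversive-noise minus neutral: %+.1f ms\n",
                x$ibi_anticipation_contrast_ms))
  }
  for (v in names(x$conditioning_tests)) {
    t <- x$conditioning_tests[[v]]
    cat(sprintf("  conditioning effect (%s): mean change %+.1f, p = %.4f\n",
                v, t$observed, t$p_value))
  }
  cat("  overall:", if (x$pass) "PASS" else "FAIL", "\n")
  invisible(x)
}
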