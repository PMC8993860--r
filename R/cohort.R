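#' Phenotype specification for the planted learn-by-use mixture
#'
#' The cohort generator plants a 2 x 2 mixture of latent phenotypes defined
#' by how strongly learned value is expressed on each task: `vas_gain`
#' governs the conditioning-task evidence (rating change), `beta_choice`
#' governs use on the approach-avoid task. Learning itself (`alpha`) is
#' shared across phenotypes. Labels: first letter = conditioning-task
#' expression (learn), second = choice-task use; e.g. `HL` = high learn
#' expression, low use.
#'
#' @param label one of `"HH"`, `"HL"`, `"LH"`, `"LL"`.
#' @param weight mixing weight (the four weights must sum to 1 in a spec
#'   set).
#' @param alpha_range length-2 range for the learning rate.
#' @param vas_gain_range length-2 range for the rating gain.
#' @param beta_choice_range length-2 range for the choice inverse
#'   temperature.
#' @return an object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(label, weight = 0.25,
                           alpha_range = c(0.2, 0.2),
                           vas_gain_range, beta_choice_range) {
  stopifnot(label %in% c("HH", "HL", "LH", "LL"),
            weight >= 0, length(alpha_range) == 2L,
            length(vas_gain_range) == 2L, length(beta_choice_range) == 2L)
  structure(list(label = label, weight = weight, alpha_range = alpha_range,
                 vas_gain_range = vas_gain_range,
                 beta_choice_range = beta_choice_range),
            class = "phenotype_spec")
}

#' Default 2 x 2 phenotype mixture
#'
#' Equal-weight mixture with alpha fixed at the group learning rate 0.2,
#' `vas_gain` in the low band 2 or high band 30 rating points per unit
#' value, and `beta_choice` in the low band 0.3 or high band 6. The bands
#' are far enough apart that the four phenotypes separate cleanly in
#' standardized learn-by-use feature space at n = 72.
#'
#' @return named list of four [phenotype_spec()] objects.
#' @export
default_phenotypes <- function() {
  list(
    HH = phenotype_spec("HH", 0.25, vas_gain_range = c(30, 30),
                        beta_choice_range = c(6, 6)),
    HL = phenotype_spec("HL", 0.25, vas_gain_range = c(30, 30),
                        beta_choice_range = c(0.3, 0.3)),
    LH = phenotype_spec("LH", 0.25, vas_gain_range = c(2, 2),
                        beta_choice_range = c(6, 6)),
    LL = phenotype_spec("LL", 0.25, vas_gain_range = c(2, 2),
                        beta_choice_range = c(0.3, 0.3))
  )
}

runif_range <- function(r) stats::runif(1, r[1], r[2])

# Draw one agent's full parameter set given its phenotype. Nuisance
# parameters (RT linkage, rating noise, recall, IBI) vary across subjects
# within fixed bands.
sample_agent <- function(phen) {
  agent_params(
    alpha = runif_range(phen$alpha_range),
    rt_base_ms = stats::runif(1, 600, 700),
    rt_gain_ms = stats::runif(1, 170, 230),
    rt_sd_ms = stats::runif(1, 50, 70),
    vas_gain = runif_range(phen$vas_gain_range),
    vas_sd = stats::runif(1, 5, 10),
    beta_choice = runif_range(phen$beta_choice_range),
    p_recall = stats::runif(1, 0.6, 0.95),
    ibi_base_ms = stats::runif(1, 700, 900),
    ibi_react_ms = stats::runif(1, 40, 60),
    ibi_sd_ms = stats::runif(1, 15, 25)
  )
}

#' Simulate a full study cohort
#'
#' Samples `n` agents from the phenotype mixture and runs each through the
#' whole paradigm: conditioning session, pre/post ratings, behavioral-choice
#' session, two-block recall, and a cardiac beat series for the conditioning
#' session. Cue-condition pairings are Latin-square counterbalanced across
#' participants; each participant gets an independent child seed spawned
#' from the master seed, so the full dataset is reproducible from
#' `(n, phenotypes, config, seed)` alone.
#'
#' @param n cohort size (default 72, the study's child sample).
#' @param phenotypes list of four [phenotype_spec()] (weights summing to 1).
#' @param config a [design_config()].
#' @param seed master integer seed.
#' @param simulate_physio set `FALSE` to skip beat-series generation.
#' @return an object of class `cohort_dataset`: tidy tables `participants`,
#'   `conditioning`, `ratings`, `choices`, `recall`, `beats`, plus `config`,
#'   `phenotypes`, and `seed`.
#' @export
#' @examples
#' cohort <- sample_cohort(n = 6, seed = 42)
#' table(cohort$participants$phenotype)
sample_cohort <- function(n = 72, phenotypes = default_phenotypes(),
                          config = design_config(), seed = 1,
                          simulate_physio = TRUE) {
  if (n < 4) stop("n must be >= 4")
  w <- vapply(phenotypes, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("phenotype weights must sum to 1")
  labels <- vapply(phenotypes, `[[`, character(1), "label")

  seeds <- spawn_seeds(seed, n + 1L)
  truth <- local_rng(seeds[n + 1L],
                     sample(labels, n, replace = TRUE, prob = w))
  square <- build_latin_square(config$n_conditions)

  participants <- vector("list", n)
  conditioning <- ratings <- choices <- recall <- beats <- vector("list", n)

  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    pidx <- i - 1L # 0-based participant index
    sub_seeds <- spawn_seeds(seeds[i], 7L)
    phen <- phenotypes[[match(truth[i], labels)]]
    agent <- local_rng(sub_seeds[1], sample_agent(phen))
    pairing <- assign_pairings(pidx, square)

    cond_sched <- make_conditioning_schedule(config, pairing, sub_seeds[2])
    cond <- simulate_conditioning_session(agent, cond_sched, sub_seeds[3])
    rate <- generate_vas_ratings(agent, cond$v_final, pairing, sub_seeds[4])
    choice_sched <- make_choice_schedule(config, pairing, pidx, sub_seeds[5])
    choice <- simulate_choice_session(agent, choice_sched, cond$v_final,
                                      sub_seeds[6])
    rec_seeds <- spawn_seeds(sub_seeds[7], 2L)
    rec <- simulate_recall(agent, pairing, rec_seeds[1],
                           block_order_flag = pidx %% 2L)

    participants[[i]] <- data.frame(
      participant_id = pid, phenotype = truth[i],
      alpha = agent$alpha, rt_base_ms = agent$rt_base_ms,
      rt_gain_ms = agent$rt_gain_ms, rt_sd_ms = agent$rt_sd_ms,
      vas_gain = agent$vas_gain, vas_sd = agent$vas_sd,
      beta_choice = agent$beta_choice, p_recall = agent$p_recall,
      ibi_base_ms = agent$ibi_base_ms, ibi_react_ms = agent$ibi_react_ms,
      ibi_sd_ms = agent$ibi_sd_ms, stringsAsFactors = FALSE)
    conditioning[[i]] <- cbind(participant_id = pid, task = "conditioning",
                               cond$trials, stringsAsFactors = FALSE)
    ratings[[i]] <- cbind(participant_id = pid, rate,
                          stringsAsFactors = FALSE)
    ch <- choice$trials
    choices[[i]] <- cbind(participant_id = pid, task = "choice", ch,
                          stringsAsFactors = FALSE)
    recall[[i]] <- cbind(participant_id = pid, rec, stringsAsFactors = FALSE)
    if (simulate_physio) {
      bt <- simulate_ibi_series(agent, cond_sched, rec_seeds[2])
      beats[[i]] <- data.frame(participant_id = pid, beat_time_ms = bt,
                               stringsAsFactors = FALSE)
    }
  }

  structure(list(
    participants = do.call(rbind, participants),
    conditioning = do.call(rbind, conditioning),
    ratings = do.call(rbind, ratings),
    choices = do.call(rbind, choices),
    recall = do.call(rbind, recall),
    beats = if (simulate_physio) do.call(rbind, beats) else
      data.frame(participant_id = character(), beat_time_ms = numeric()),
    config = config, phenotypes = phenotypes, seed = seed
  ), class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset: %d participants, %d conditioning + %d choice trials, seed %s>\n",
              nrow(x$participants), nrow(x$conditioning), nrow(x$choices),
              format(x$seed)))
  print(table(phenotype = x$participants$phenotype))
  invisible(x)
}

cohort_tables <- c("participants", "conditioning", "ratings", "choices",
                   "recall", "beats")

#' Write / read a cohort dataset as a directory of CSV tables
#'
#' `write_dataset()` writes one CSV per table plus a YAML manifest recording
#' the design configuration, phenotype bands and master seed.
#' `read_dataset()` reads the directory back and validates it: all required
#' tables present, every participant present in every behavioral table,
#' ratings within \[0, 100\], and per-participant cue-condition pairings
#' bijective. Violations raise errors naming the offending table.
#'
#' @param dataset a `cohort_dataset`.
#' @param dir directory path (created if needed).
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   returns a `cohort_dataset`.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in cohort_tables) {
    utils::write.csv(dataset[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(
    config = unclass(dataset$config),
    seed = dataset$seed,
    n = nrow(dataset$participants),
    phenotypes = lapply(dataset$phenotypes, unclass)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("no such dataset directory: ", dir)
  out <- list()
  for (tab in cohort_tables) {
    path <- file.path(dir, paste0(tab, ".csv"))
    if (!file.exists(path)) stop("missing required table: ", tab)
    out[[tab]] <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  cfg <- manifest$config
  out$config <- design_config(cfg$n_conditions, cfg$trials_per_condition,
                              cfg$p_reinforce, cfg$cue_duration_s,
                              cfg$delay_s, cfg$outcome_duration_s,
                              unlist(cfg$iti_range_s), cfg$exact_ratio)
  out$phenotypes <- lapply(manifest$phenotypes, function(p) {
    phenotype_spec(p$label, p$weight, unlist(p$alpha_range),
                   unlist(p$vas_gain_range), unlist(p$beta_choice_range))
  })
  out$seed <- manifest$seed
  class(out) <- "cohort_dataset"
  validate_dataset(out)
  out
}

#' Validate a cohort dataset's invariants
#'
#' @param dataset a `cohort_dataset`.
#' @return the dataset, invisibly; errors name the offending table.
#' @export
validate_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  for (tab in cohort_tables) {
    if (is.null(dataset[[tab]])) stop("missing required table: ", tab)
  }
  if (nrow(dataset$choices) == 0) stop("missing required table: choices")
  if (nrow(dataset$conditioning) == 0) {
    stop("missing required table: conditioning")
  }
  ids <- dataset$participants$participant_id
  for (tab in c("conditioning", "ratings", "choices", "recall")) {
    missing <- setdiff(ids, dataset[[tab]]$participant_id)
    if (length(missing) > 0) {
      stop("table '", tab, "' is missing participants: ",
           paste(missing, collapse = ", "))
    }
  }
  r <- dataset$ratings
  bad <- which(r$pre < 0 | r$pre > 100 | r$post < 0 | r$post > 100)
  if (length(bad) > 0) {
    stop("ratings table: rating outside [0, 100] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  pair <- unique(dataset$conditioning[, c("participant_id", "cue_id",
                                          "condition")])
  per <- split(pair, pair$participant_id)
  for (p in per) {
    if (anyDuplicated(p$cue_id) || anyDuplicated(p$condition)) {
      stop("conditioning table: non-bijective cue-condition pairing for ",
           p$participant_id[1])
    }
  }
  n_per <- table(dataset$conditioning$participant_id)
  expect_n <- dataset$config$n_conditions * dataset$config$trials_per_condition
  if (any(n_per != expect_n)) {
    stop("conditioning table: trial counts differ from the design (",
         expect_n, " expected)")
  }
  invisible(dataset)
}
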