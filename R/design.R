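#' Reinforcer conditions and their valences
#'
#' The paradigm pairs five geometric cues with five outcome conditions: a
#' points reward and a positive image (appetitive, valence +1), an aversive
#' noise and a negative image (aversive, valence -1), and a neutral condition
#' whose cue is only ever followed by a scrambled image (valence 0).
#'
#' @return `reinforcer_kinds()` returns a character vector of the five
#'   condition labels, in canonical order.
#' @export
#' @examples
#' reinforcer_kinds()
#' reinforcer_valence("aversive_noise")
reinforcer_kinds <- function() {
  c("points", "positive_image", "aversive_noise", "negative_image", "neutral")
}

#' @rdname reinforcer_kinds
#' @param condition character vector of condition labels.
#' @return `reinforcer_valence()` returns an integer vector in \{-1, 0, +1\}.
#' @export
reinforcer_valence <- function(condition) {
  v <- c(points = 1L, positive_image = 1L,
         aversive_noise = -1L, negative_image = -1L, neutral = 0L)
  bad <- setdiff(unique(condition), names(v))
  if (length(bad) > 0) {
    stop("unknown reinforcer condition(s): ", paste(bad, collapse = ", "))
  }
  unname(v[condition])
}

#' Default cue identifiers (geometric shapes)
#' @return character vector of five cue ids.
#' @export
default_cue_ids <- function() {
  c("circle", "square", "triangle", "star", "diamond")
}

#' Task design configuration
#'
#' Trial-structure constants for the conditioning and behavioral-choice tasks:
#' five cue conditions, 14 trials each (70 trials per task), a 1.5 s cue
#' window, a 6 s delay (fixation) between cue and outcome, a 1.5 s outcome,
#' probabilistic reinforcement at p = 0.8 on non-neutral trials (scrambled
#' neutral image otherwise), and a jittered 2.5-5.5 s inter-trial interval.
#'
#' @param n_conditions number of cue conditions.
#' @param trials_per_condition trials per condition in one session.
#' @param p_reinforce probability that a non-neutral trial delivers the
#'   paired reinforcer rather than the scrambled image.
#' @param cue_duration_s maximum cue display time, seconds.
#' @param delay_s cue-to-outcome delay, seconds.
#' @param outcome_duration_s outcome display time, seconds.
#' @param iti_range_s length-2 numeric, uniform inter-trial-interval range in
#'   seconds.
#' @param exact_ratio logical; if `TRUE`, reinforcement is delivered on a
#'   fixed round(p * trials) subset of each non-neutral condition's trials
#'   instead of independent Bernoulli draws. Default `FALSE` (Bernoulli).
#' @return an object of class `design_config` (a validated list).
#' @export
#' @examples
#' cfg <- design_config()
#' cfg$n_conditions * cfg$trials_per_condition  # 70 trials
design_config <- function(n_conditions = 5L,
                          trials_per_condition = 14L,
                          p_reinforce = 0.8,
                          cue_duration_s = 1.5,
                          delay_s = 6,
                          outcome_duration_s = 1.5,
                          iti_range_s = c(2.5, 5.5),
                          exact_ratio = FALSE) {
  cfg <- list(
    n_conditions = as.integer(n_conditions),
    trials_per_condition = as.integer(trials_per_condition),
    p_reinforce = p_reinforce,
    cue_duration_s = cue_duration_s,
    delay_s = delay_s,
    outcome_duration_s = outcome_duration_s,
    iti_range_s = as.numeric(iti_range_s),
    exact_ratio = isTRUE(exact_ratio)
  )
  class(cfg) <- "design_config"
  validate_design_config(cfg)
  cfg
}

validate_design_config <- function(cfg) {
  stopifnot(inherits(cfg, "design_config"))
  if (cfg$n_conditions < 1L || cfg$trials_per_condition < 1L) {
    stop("n_conditions and trials_per_condition must be >= 1")
  }
  if (cfg$p_reinforce < 0 || cfg$p_reinforce > 1) {
    stop("p_reinforce must lie in [0, 1]")
  }
  if (any(c(cfg$cue_duration_s, cfg$delay_s, cfg$outcome_duration_s) <= 0)) {
    stop("all durations must be positive")
  }
  if (length(cfg$iti_range_s) != 2L || cfg$iti_range_s[1] > cfg$iti_range_s[2] ||
      cfg$iti_range_s[1] <= 0) {
    stop("iti_range_s must be an increasing positive interval")
  }
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("Task design:", x$n_conditions, "conditions x", x$trials_per_condition,
      "trials =", x$n_conditions * x$trials_per_condition, "trials/session\n")
  cat(sprintf("  p(reinforcer | non-neutral) = %.2f%s\n", x$p_reinforce,
              if (x$exact_ratio) " (fixed ratio)" else " (Bernoulli)"))
  cat(sprintf("  cue %.1fs | delay %.1fs | outcome %.1fs | ITI %.1f-%.1fs\n",
              x$cue_duration_s, x$delay_s, x$outcome_duration_s,
              x$iti_range_s[1], x$iti_range_s[2]))
  invisible(x)
}

#' Cyclic Latin square for cue-condition counterbalancing
#'
#' Constructs the deterministic cyclic n x n Latin square whose row `i` is
#' the canonical order 1..n rotated left by `i - 1`. Row `p` gives the
#' cue-to-condition assignment for participant `p`, so across any block of
#' `n` consecutive participants every cue is paired with every condition
#' exactly once.
#'
#' @param n square size (number of cues = number of conditions).
#' @return an `n` x `n` integer matrix; every row and column is a permutation
#'   of `1:n`.
#' @export
#' @examples
#' build_latin_square(5)
build_latin_square <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a single integer >= 1")
  }
  n <- as.integer(n)
  outer(seq_len(n) - 1L, seq_len(n) - 1L, function(i, j) (i + j) %% n) + 1L
}

#' Assign cue-condition pairings for one participant
#'
#' Uses row `(participant_index mod n) + 1` of a Latin square to map cue ids
#' to reinforcer conditions, implementing the across-participant
#' counterbalance of shape-reinforcer pairings.
#'
#' @param participant_index 0-based participant index.
#' @param square an n x n Latin square as from [build_latin_square()].
#' @param cue_ids character vector of n cue identifiers.
#' @param conditions character vector of n condition labels.
#' @return named character vector: `pairing[cue_id] == condition`.
#' @export
#' @examples
#' sq <- build_latin_square(5)
#' assign_pairings(0, sq, default_cue_ids(), reinforcer_kinds())
assign_pairings <- function(participant_index, square,
                            cue_ids = default_cue_ids(),
                            conditions = reinforcer_kinds()) {
  n <- nrow(square)
  if (is.null(n) || ncol(square) != n) stop("square must be a square matrix")
  if (length(cue_ids) != n || length(conditions) != n) {
    stop("cue_ids and conditions must both have length ", n)
  }
  if (participant_index < 0) stop("participant_index must be >= 0")
  row <- square[(as.integer(participant_index) %% n) + 1L, ]
  stats::setNames(conditions[row], cue_ids)
}

# Sample trial order, outcomes and timing shared by both tasks.
schedule_core <- function(config, pairing) {
  validate_design_config(config)
  if (anyDuplicated(names(pairing)) || anyDuplicated(pairing)) {
    stop("pairing must be a bijection between cue ids and conditions")
  }
  if (length(pairing) != config$n_conditions) {
    stop("pairing must cover exactly n_conditions cues")
  }
  n_trials <- config$n_conditions * config$trials_per_condition
  cue_id <- sample(rep(names(pairing), config$trials_per_condition))
  condition <- unname(pairing[cue_id])
  valence <- reinforcer_valence(condition)

  if (config$exact_ratio) {
    n_hit <- round(config$p_reinforce * config$trials_per_condition)
    outcome <- rep("scrambled", n_trials)
    for (cue in names(pairing)) {
      idx <- which(cue_id == cue)
      if (reinforcer_valence(pairing[[cue]]) != 0L) {
        outcome[sample(idx, n_hit)] <- "reinforcer"
      }
    }
  } else {
    hit <- stats::runif(n_trials) < config$p_reinforce
    outcome <- ifelse(valence != 0L & hit, "reinforcer", "scrambled")
  }

  iti_s <- stats::runif(n_trials, config$iti_range_s[1], config$iti_range_s[2])
  # bookkeeping uses the full cue window; outcome onset = cue + window + delay
  trial_len <- config$cue_duration_s + config$delay_s +
    config$outcome_duration_s + iti_s
  cue_onset_s <- c(0, cumsum(trial_len))[seq_len(n_trials)]
  outcome_onset_s <- cue_onset_s + config$cue_duration_s + config$delay_s

  data.frame(
    trial_index = seq_len(n_trials) - 1L,
    condition = condition,
    cue_id = cue_id,
    outcome = outcome,
    cue_onset_s = cue_onset_s,
    outcome_onset_s = outcome_onset_s,
    iti_s = iti_s,
    stringsAsFactors = FALSE
  )
}

new_session_schedule <- function(trials, config, pairing, seed, task) {
  structure(
    list(trials = trials, config = config, pairing = pairing,
         seed = seed, task = task),
    class = "session_schedule"
  )
}

#' Build a randomized conditioning-session schedule
#'
#' Generates one participant's conditioning session: the 70-trial multiset
#' (14 trials per condition) in uniform-random order, reinforcer/scrambled
#' outcome flags drawn independently at `p_reinforce` on non-neutral trials
#' (neutral trials are always followed by the scrambled image), jittered
#' ITIs, and cumulative onset times from a session origin of t = 0 s.
#'
#' @param config a [design_config()].
#' @param pairing named character vector mapping cue ids to conditions, as
#'   from [assign_pairings()].
#' @param seed integer RNG seed; the schedule is reproducible given
#'   (config, pairing, seed).
#' @return a `session_schedule`: list with `trials` (data frame), `config`,
#'   `pairing`, `seed`, `task`.
#' @export
#' @examples
#' sched <- make_conditioning_schedule(design_config(),
#'   assign_pairings(0, build_latin_square(5)), seed = 1)
#' table(sched$trials$condition)
make_conditioning_schedule <- function(config = design_config(), pairing,
                                       seed) {
  out <- local_rng(seed, schedule_core(config, pairing))
  new_session_schedule(out, config, pairing, seed, task = "conditioning")
}

#' Build a behavioral-choice (approach-avoid) schedule
#'
#' Same trial structure as the conditioning task, plus a per-participant
#' counterbalance of which side of the screen holds the green (approach)
#' button: even participant indices see green on the left, odd on the right.
#'
#' @inheritParams make_conditioning_schedule
#' @param participant_index 0-based index, used for the button-side
#'   counterbalance.
#' @return a `session_schedule` whose `trials` include `button_green_side`.
#' @export
make_choice_schedule <- function(config = design_config(), pairing,
                                 participant_index, seed) {
  trials <- local_rng(seed, schedule_core(config, pairing))
  trials$button_green_side <-
    if (as.integer(participant_index) %% 2L == 0L) "left" else "right"
  new_session_schedule(trials, config, pairing, seed, task = "choice")
}

#' @export
print.session_schedule <- function(x, ...) {
  cat(sprintf("<session_schedule: %s task, %d trials, seed %s>\n",
              x$task, nrow(x$trials), format(x$seed)))
  invisible(x)
}
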