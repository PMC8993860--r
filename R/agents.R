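#' Generative parameters for one simulated participant
#'
#' Bundles the cognitive and physiological parameters of the generative
#' model: a Rescorla-Wagner learning rate, a linear salience-to-RT linkage,
#' a value-to-rating gain for the 0-100 visual analogue scale, a softmax
#' inverse temperature for approach/avoid choice, recall fidelity for the
#' four-alternative memory test, and inter-beat-interval (IBI) reactivity.
#'
#' @param alpha learning rate in \[0, 1\]; speed of integration of recent
#'   outcomes into cue value.
#' @param rt_base_ms baseline simple reaction time, ms.
#' @param rt_gain_ms RT speeding per unit cue salience |V|, ms; conditioned
#'   cues are detected faster regardless of valence.
#' @param rt_sd_ms Gaussian RT noise SD, ms (> 0).
#' @param vas_gain rating points moved per unit of learned value on the
#'   post-conditioning visual analogue scale.
#' @param vas_sd rating noise SD, points.
#' @param beta_choice softmax inverse temperature (>= 0) linking signed value
#'   to the probability of an approach response.
#' @param p_recall probability a cue-reinforcer pairing is retrieved from
#'   memory on a recall item.
#' @param recall_guess_all4 if `TRUE`, a retrieval failure leads to a uniform
#'   guess among all 4 options (chance 1/4 accuracy contribution); default
#'   `FALSE` guesses among the 3 distractors only.
#' @param ibi_base_ms baseline inter-beat interval, ms.
#' @param ibi_react_ms IBI lengthening (cardiac deceleration) during the
#'   anticipation window of motivationally salient cues, ms.
#' @param ibi_sd_ms beat-to-beat Gaussian IBI noise SD, ms.
#' @param continue_learning if `TRUE`, values keep updating from observed
#'   outcomes during the choice task (avoided outcomes are unobserved and do
#'   not update).
#' @param rt_floor_ms smallest producible RT, ms.
#' @return an object of class `agent_params`.
#' @export
#' @examples
#' agent_params(alpha = 0.2)
agent_params <- function(alpha = 0.2,
                         rt_base_ms = 650,
                         rt_gain_ms = 200,
                         rt_sd_ms = 60,
                         vas_gain = 30,
                         vas_sd = 8,
                         beta_choice = 6,
                         p_recall = 0.8,
                         recall_guess_all4 = FALSE,
                         ibi_base_ms = 800,
                         ibi_react_ms = 50,
                         ibi_sd_ms = 20,
                         continue_learning = FALSE,
                         rt_floor_ms = 150) {
  p <- list(alpha = alpha, rt_base_ms = rt_base_ms, rt_gain_ms = rt_gain_ms,
            rt_sd_ms = rt_sd_ms, vas_gain = vas_gain, vas_sd = vas_sd,
            beta_choice = beta_choice, p_recall = p_recall,
            recall_guess_all4 = isTRUE(recall_guess_all4),
            ibi_base_ms = ibi_base_ms, ibi_react_ms = ibi_react_ms,
            ibi_sd_ms = ibi_sd_ms,
            continue_learning = isTRUE(continue_learning),
            rt_floor_ms = rt_floor_ms)
  class(p) <- "agent_params"
  validate_agent_params(p)
  p
}

validate_agent_params <- function(p) {
  stopifnot(inherits(p, "agent_params"))
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must lie in [0, 1]")
  if (p$rt_sd_ms <= 0) stop("rt_sd_ms must be > 0")
  if (p$vas_sd < 0) stop("vas_sd must be >= 0")
  if (p$beta_choice < 0) stop("beta_choice must be >= 0")
  if (p$p_recall < 0 || p$p_recall > 1) stop("p_recall must lie in [0, 1]")
  if (p$rt_base_ms - p$rt_gain_ms < p$rt_floor_ms) {
    stop("rt_base_ms - rt_gain_ms must stay above the RT floor (",
         p$rt_floor_ms, " ms)")
  }
  if (p$ibi_base_ms <= 0 || p$ibi_sd_ms < 0) stop("invalid IBI parameters")
  invisible(p)
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "<agent: alpha=%.2f, RT %.0f-%.0f*|V| (sd %.0f) ms, vas_gain=%.1f, beta=%.2f, p_recall=%.2f>\n",
    x$alpha, x$rt_base_ms, x$rt_gain_ms, x$rt_sd_ms, x$vas_gain,
    x$beta_choice, x$p_recall))
  invisible(x)
}

#' Rescorla-Wagner delta-rule update
#'
#' `V <- V + alpha * (r - V)`: the prediction error `r - V` moves the cue's
#' value toward the delivered reward code `r` at speed `alpha`. Appetitive
#' reinforcers are coded r = +1, aversive r = -1, and the scrambled neutral
#' image r = 0. Vectorized over `v` and `r`.
#'
#' @param v current value(s), in \[-1, 1\].
#' @param r reward code(s), in \[-1, 1\].
#' @param alpha learning rate in \[0, 1\].
#' @return updated value(s); fixed point at `v == r`.
#' @export
#' @examples
#' rw_update(0, 1, 0.2)    # 0.2
#' rw_update(0.5, 1, 0)    # unchanged
rw_update <- function(v, r, alpha) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]")
  }
  v + alpha * (r - v)
}

# Reward code for a realized outcome: valence on reinforcer, 0 on scrambled.
reward_code <- function(condition, outcome) {
  reinforcer_valence(condition) * as.numeric(outcome == "reinforcer")
}

#' Simulate one conditioning session
#'
#' Plays an agent through a conditioning schedule. On each trial the cue's
#' salience is `S_t = |V_t(cue)|` (the unsigned value learned so far); the
#' emitted RT is `rt_base_ms - rt_gain_ms * S_t` plus Gaussian noise,
#' truncated to \[rt_floor_ms, 1000 * cue_duration_s\]. After the outcome is
#' shown, the cue's value is updated by the delta rule with reward code
#' valence * 1 on reinforcer trials and 0 on scrambled trials.
#'
#' @param agent an [agent_params()].
#' @param schedule a conditioning `session_schedule`.
#' @param seed integer RNG seed.
#' @return list with `trials` (the schedule's trials plus `salience`,
#'   `rt_ms`, `v_pre`, `v_post`), `trace` (a (n_trials + 1) x n_cues matrix
#'   of values, row t = values before trial t), and `v_final` (named vector
#'   of end-of-session values per cue).
#' @export
simulate_conditioning_session <- function(agent, schedule, seed) {
  validate_agent_params(agent)
  stopifnot(inherits(schedule, "session_schedule"))
  if (schedule$task != "conditioning") stop("expected a conditioning schedule")
  trials <- schedule$trials
  cues <- names(schedule$pairing)
  n <- nrow(trials)
  rt_cap <- 1000 * schedule$config$cue_duration_s

  local_rng(seed, {
    v <- stats::setNames(numeric(length(cues)), cues)
    trace <- matrix(0, n + 1L, length(cues), dimnames = list(NULL, cues))
    salience <- v_pre <- v_post <- numeric(n)
    r <- reward_code(trials$condition, trials$outcome)
    for (t in seq_len(n)) {
      cue <- trials$cue_id[t]
      v_pre[t] <- v[[cue]]
      salience[t] <- abs(v[[cue]])
      v[[cue]] <- rw_update(v[[cue]], r[t], agent$alpha)
      v_post[t] <- v[[cue]]
      trace[t + 1L, ] <- v
    }
    rt <- agent$rt_base_ms - agent$rt_gain_ms * salience +
      stats::rnorm(n, 0, agent$rt_sd_ms)
    trials$salience <- salience
    trials$rt_ms <- clip(rt, agent$rt_floor_ms, rt_cap)
    trials$v_pre <- v_pre
    trials$v_post <- v_post
    list(trials = trials, trace = trace, v_final = v)
  })
}

#' Generate pre/post visual-analogue-scale ratings
#'
#' Pre-conditioning ratings are drawn around the scale midpoint (50); the
#' post-conditioning rating adds `vas_gain` points per unit of final learned
#' value plus noise. Both are clipped to the 0 (Bad) to 100 (Good) scale.
#'
#' @param agent an [agent_params()].
#' @param v_final named vector of final cue values, as from
#'   [simulate_conditioning_session()].
#' @param pairing cue-to-condition map (for labeling the output).
#' @param seed integer RNG seed.
#' @return data frame: `cue_id`, `condition`, `pre`, `post`, all ratings in
#'   \[0, 100\].
#' @export
generate_vas_ratings <- function(agent, v_final, pairing, seed) {
  validate_agent_params(agent)
  cues <- names(v_final)
  local_rng(seed, {
    pre <- clip(stats::rnorm(length(cues), 50, agent$vas_sd), 0, 100)
    post <- clip(pre + agent$vas_gain * unname(v_final) +
                   stats::rnorm(length(cues), 0, agent$vas_sd), 0, 100)
    data.frame(cue_id = cues, condition = unname(pairing[cues]),
               pre = pre, post = post, stringsAsFactors = FALSE)
  })
}

#' Softmax approach probability
#'
#' Two-action softmax on signed cue value: the probability of an approach
#' (green-button) response is `1 / (1 + exp(-beta * v))`, strictly
#' increasing in `v` for `beta > 0` and 0.5 at `v = 0` or `beta = 0`.
#'
#' @param v signed learned value(s).
#' @param beta_choice inverse temperature (>= 0).
#' @return approach probability in (0, 1); vectorized over `v`.
#' @export
#' @examples
#' choice_policy(0, 5)        # 0.5
#' choice_policy(1, 10)       # ~0.99995
choice_policy <- function(v, beta_choice) {
  if (beta_choice < 0) stop("beta_choice must be >= 0")
  stats::plogis(beta_choice * v)
}

#' Simulate one behavioral-choice (approach-avoid) session
#'
#' Each trial presents a learned cue; the agent approaches with probability
#' `choice_policy(V(cue), beta_choice)`. An approach reveals the scheduled
#' outcome (reinforcer or scrambled image); an avoid shows a blank screen
#' and reveals nothing. With `continue_learning = TRUE`, observed outcomes
#' keep updating cue values by the delta rule; avoided trials never update.
#'
#' @param agent an [agent_params()].
#' @param schedule a choice `session_schedule`.
#' @param v_start named vector of cue values carried over from conditioning.
#' @param seed integer RNG seed.
#' @return list with `trials` (schedule trials plus `v_used`, `p_approach`,
#'   `approach`, `outcome_shown`) and `v_final`.
#' @export
simulate_choice_session <- function(agent, schedule, v_start, seed) {
  validate_agent_params(agent)
  stopifnot(inherits(schedule, "session_schedule"))
  if (schedule$task != "choice") stop("expected a choice schedule")
  trials <- schedule$trials
  n <- nrow(trials)
  local_rng(seed, {
    v <- v_start
    v_used <- p_app <- numeric(n)
    approach <- logical(n)
    outcome_shown <- character(n)
    for (t in seq_len(n)) {
      cue <- trials$cue_id[t]
      v_used[t] <- v[[cue]]
      p_app[t] <- choice_policy(v[[cue]], agent$beta_choice)
      approach[t] <- stats::runif(1) < p_app[t]
      if (approach[t]) {
        outcome_shown[t] <- trials$outcome[t]
        if (agent$continue_learning) {
          r <- reward_code(trials$condition[t], trials$outcome[t])
          v[[cue]] <- rw_update(v[[cue]], r, agent$alpha)
        }
      } else {
        outcome_shown[t] <- "none"
      }
    }
    trials$v_used <- v_used
    trials$p_approach <- p_app
    trials$approach <- approach
    trials$outcome_shown <- outcome_shown
    list(trials = trials, v_final = v)
  })
}

#' Simulate the two-block four-alternative recall test
#'
#' Memory for the cue-reinforcer pairings is probed twice: once cueing with
#' the shape and asking which outcome followed it, and once cueing with the
#' outcome and asking which shape preceded it. Each item is answered from
#' memory with probability `p_recall`; on a retrieval failure the agent
#' guesses uniformly among the 3 distractors (or among all 4 options when
#' `recall_guess_all4`).
#'
#' @param agent an [agent_params()].
#' @param pairing bijective cue-to-condition map.
#' @param seed integer RNG seed.
#' @param block_order_flag 0 or 1; which block came first (counterbalance
#'   bookkeeping only).
#' @return data frame: `block` (`shape_to_outcome` / `outcome_to_shape`),
#'   `block_order`, `probe`, `target`, `chosen`, `correct`, `n_options`.
#' @export
simulate_recall <- function(agent, pairing, seed, block_order_flag = 0L) {
  validate_agent_params(agent)
  if (anyDuplicated(names(pairing)) || anyDuplicated(pairing)) {
    stop("pairing must be bijective")
  }
  one_block <- function(block, probes, targets) {
    n_item <- length(probes)
    chosen <- character(n_item)
    for (i in seq_len(n_item)) {
      if (stats::runif(1) < agent$p_recall) {
        chosen[i] <- targets[i]
      } else {
        distractors <- sample(setdiff(targets, targets[i]), 3)
        pool <- if (agent$recall_guess_all4) c(targets[i], distractors) else
          distractors
        chosen[i] <- sample(pool, 1)
      }
    }
    data.frame(block = block, block_order = as.integer(block_order_flag),
               probe = probes, target = targets, chosen = chosen,
               correct = chosen == targets, n_options = 4L,
               stringsAsFactors = FALSE)
  }
  local_rng(seed, {
    b1 <- one_block("shape_to_outcome", names(pairing), unname(pairing))
    b2 <- one_block("outcome_to_shape", unname(pairing), names(pairing))
    rbind(b1, b2)
  })
}

#' Simulate a cardiac beat-time series for one session
#'
#' Generates successive heart-beat times whose local inter-beat interval is
#' `ibi_base_ms + ibi_react_ms * |valence(trial)|` while inside a trial's
#' 6 s anticipation window (cue onset to reinforcer onset) and `ibi_base_ms`
#' elsewhere, plus beat-to-beat Gaussian noise. Motivationally salient cues
#' thus produce cardiac deceleration (longer IBIs) during anticipation;
#' neutral trials do not. The series spans the whole session plus a short
#' tail so the last trial's epochs are covered.
#'
#' @param agent an [agent_params()].
#' @param schedule a `session_schedule` with onset times.
#' @param seed integer RNG seed.
#' @return numeric vector of beat times in ms from session start, strictly
#'   increasing.
#' @export
simulate_ibi_series <- function(agent, schedule, seed) {
  validate_agent_params(agent)
  trials <- schedule$trials
  antic_start <- trials$cue_onset_s * 1000
  antic_end <- antic_start + 6000 # 6 s anticipation window
  amp <- abs(reinforcer_valence(trials$condition))
  last <- nrow(trials)
  session_end <- (trials$outcome_onset_s[last] +
                    schedule$config$outcome_duration_s +
                    trials$iti_s[last]) * 1000

  local_rng(seed, {
    t <- 0
    beats <- numeric(ceiling(session_end / max(agent$ibi_base_ms / 2, 1)) + 16L)
    k <- 0L
    while (t <= session_end) {
      k <- k + 1L
      beats[k] <- t
      in_win <- which(antic_start <= t & t < antic_end)
      deflect <- if (length(in_win) > 0) agent$ibi_react_ms * amp[in_win[1]] else 0
      ibi <- agent$ibi_base_ms + deflect + stats::rnorm(1, 0, agent$ibi_sd_ms)
      t <- t + max(ibi, 250) # physiological floor keeps times increasing
    }
    beats[seq_len(k)]
  })
}
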