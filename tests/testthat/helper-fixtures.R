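# Shared fixtures, built in code at test time.

default_pairing <- function() assign_pairings(0, build_latin_square(5))

# One subject's conditioning trial table with noiseless RTs generated from a
# known learning rate -- the oracle input for exact alpha recovery.
noiseless_rt_trials <- function(alpha_true, seed = 1, base = 650, gain = 200) {
  sched <- make_conditioning_schedule(design_config(), default_pairing(), seed)
  tr <- sched$trials
  s <- predict_salience_series(alpha_true, tr)
  tr$rt_ms <- base - gain * s
  tr
}

# Small cohort without the cardiac series (fast path for analysis tests).
tiny_cohort <- function(n = 8, seed = 7) {
  sample_cohort(n = n, seed = seed, simulate_physio = FALSE)
}

# Four synthetic quadrant blobs in feature space with known membership --
# the planted-partition fixture for clustering tests.
planted_blobs <- function(n_per = 15, sep = 4, sd = 0.4, seed = 1) {
  set.seed(seed)
  centers <- rbind(HH = c(1, 1), HL = c(1, -1), LH = c(-1, 1), LL = c(-1, -1))
  pts <- do.call(rbind, lapply(rownames(centers), function(lab) {
    cbind(centers[lab, 1] * sep / 2 + rnorm(n_per, 0, sd),
          centers[lab, 2] * sep / 2 + rnorm(n_per, 0, sd))
  }))
  truth <- rep(rownames(centers), each = n_per)
  data.frame(participant_id = sprintf("S%02d", seq_len(nrow(pts))),
             condition = "points",
             learn_score = pts[, 1], use_score = pts[, 2],
             learn_z = as.numeric(scale(pts[, 1])),
             use_z = as.numeric(scale(pts[, 2])),
             truth = truth, stringsAsFactors = FALSE)
}

# Phenotype mixtures restricted to a subset of the 2x2 (weights renormalized).
subset_phenotypes <- function(labels) {
  ph <- default_phenotypes()[labels]
  for (i in seq_along(ph)) ph[[i]]$weight <- 1 / length(ph)
  ph
}
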