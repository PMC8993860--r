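#' Unstandardized residualized change scores
#'
#' The learning score on the conditioning task is the change in a cue's
#' 0-100 rating from before to after conditioning, with baseline dependence
#' removed: the change `post - pre` is regressed on the pre-conditioning
#' rating (simple OLS with intercept) and the unstandardized residuals are
#' returned. Residuals sum to zero and are uncorrelated with `pre`. When
#' `pre` has zero variance the regression is degenerate and the centered
#' change is returned with a `degenerate` attribute and a warning.
#'
#' @param pre,post equal-length rating vectors in \[0, 100\], n >= 3.
#' @return numeric vector of residuals, with attribute `degenerate`.
#' @export
#' @examples
#' residualized_change(c(40, 50, 60), c(45, 55, 60))
residualized_change <- function(pre, post) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  if (length(pre) < 3L) stop("need n >= 3 subjects")
  if (any(pre < 0 | pre > 100 | post < 0 | post > 100, na.rm = TRUE)) {
    stop("ratings must lie in [0, 100]")
  }
  change <- post - pre
  if (stats::var(pre) == 0) {
    warning("pre-conditioning ratings are constant; returning centered change")
    res <- change - mean(change)
    attr(res, "degenerate") <- TRUE
    return(res)
  }
  slope <- stats::cov(change, pre) / stats::var(pre)
  res <- change - (mean(change) + slope * (pre - mean(pre)))
  attr(res, "degenerate") <- FALSE
  res
}

#' Expected-use score on the behavioral-choice task
#'
#' The expected response is approach for appetitive cues (valence +1) and
#' avoid for aversive cues (valence -1); the score is the fraction of
#' expected responses over the first `first_k` qualifying trials. Because
#' the choice task itself affords further learning, the early trials are the
#' cleanest read-out of what was brought into the task. With
#' `scope = "per_condition"` (default) the first `first_k` trials *of that
#' condition* count; with `scope = "whole_task"` only that condition's
#' trials falling among the first `first_k` trials of the whole session
#' count (may be fewer, or none -> NA).
#'
#' @param choices choice-trial table: `participant_id`, `trial_index`,
#'   `condition`, `approach` (logical).
#' @param condition a non-neutral condition label.
#' @param first_k number of early trials scored.
#' @param scope `"per_condition"` or `"whole_task"`.
#' @return data frame: `participant_id`, `use_score` in \[0, 1\].
#' @export
expected_use_score <- function(choices, condition, first_k = 5,
                               scope = c("per_condition", "whole_task")) {
  scope <- match.arg(scope)
  val <- reinforcer_valence(condition)
  if (val == 0L) stop("expected-use score is undefined for the neutral condition")
  per <- split(choices, choices$participant_id)
  score_one <- function(d) {
    d <- d[order(d$trial_index), ]
    sel <- if (scope == "per_condition") {
      utils::head(which(d$condition == condition), first_k)
    } else {
      which(d$condition == condition &
              d$trial_index < sort(d$trial_index)[first_k] + 1e-9)
    }
    if (scope == "per_condition" && length(sel) < first_k) {
      stop("fewer than ", first_k, " '", condition, "' trials available")
    }
    if (length(sel) == 0) return(NA_real_)
    expected <- if (val > 0) d$approach[sel] else !d$approach[sel]
    mean(expected)
  }
  data.frame(participant_id = names(per),
             use_score = vapply(per, score_one, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build learn-by-use features for one reinforcer condition
#'
#' Combines the conditioning-task learning score (residualized rating
#' change) with the choice-task use score for every subject. With
#' `sign_align = TRUE` (default) the learning score is multiplied by the
#' condition's valence so that larger always means more learning: for
#' appetitive reinforcers more positive rating change indicates learning,
#' for aversive reinforcers more negative change does. Both features are
#' also z-standardized within the condition, matching the standardized axes
#' on which the phenotype clusters are defined.
#'
#' @param ratings ratings table: `participant_id`, `condition`, `pre`,
#'   `post`.
#' @param choices choice-trial table (see [expected_use_score()]).
#' @param condition non-neutral condition label.
#' @param sign_align multiply the residualized change by the valence.
#' @param first_k,scope passed to [expected_use_score()].
#' @return data frame: `participant_id`, `condition`, `learn_score`,
#'   `use_score`, `learn_z`, `use_z`.
#' @export
build_features <- function(ratings, choices, condition, sign_align = TRUE,
                           first_k = 5, scope = "per_condition") {
  r <- ratings[ratings$condition == condition, ]
  r <- r[order(r$participant_id), ]
  u <- expected_use_score(choices, condition, first_k, scope)
  u <- u[order(u$participant_id), ]
  miss <- c(setdiff(u$participant_id, r$participant_id),
            setdiff(r$participant_id, u$participant_id))
  if (length(miss) > 0) {
    stop("subjects missing from ratings or choices: ",
         paste(unique(miss), collapse = ", "))
  }
  learn <- residualized_change(r$pre, r$post)
  if (sign_align) learn <- learn * reinforcer_valence(condition)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (is.na(s) || s == 0) x - mean(x) else (x - mean(x)) / s
  }
  data.frame(participant_id = r$participant_id, condition = condition,
             learn_score = as.numeric(learn), use_score = u$use_score,
             learn_z = zscore(as.numeric(learn)), use_z = zscore(u$use_score),
             stringsAsFactors = FALSE)
}

# Bijective quadrant labels for k = 4: assign centroids to the four quadrant
# prototypes (+-1, +-1) by the minimum-cost permutation. For other k, label
# each centroid by its own signs (labels may repeat).
quadrant_labels <- function(centroids) {
  sign_label <- function(l, u) {
    paste0(if (l >= 0) "H" else "L", if (u >= 0) "H" else "L")
  }
  k <- nrow(centroids)
  if (k != 4L) {
    return(vapply(seq_len(k),
                  function(i) sign_label(centroids[i, 1], centroids[i, 2]),
                  character(1)))
  }
  protos <- rbind(HH = c(1, 1), HL = c(1, -1), LH = c(-1, 1), LL = c(-1, -1))
  # scale prototypes to the centroid spread so the assignment is geometric
  protos <- protos * mean(abs(centroids))
  perms <- rbind_permutations(4L)
  cost <- apply(perms, 1, function(p) {
    sum((centroids - protos[p, , drop = FALSE])^2)
  })
  rownames(protos)[perms[which.min(cost), ]]
}

# All permutations of 1..n as rows (n small).
rbind_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- rbind_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ifelse(sub >= i, sub + 1L, sub))
  }))
}

#' Cluster subjects in standardized learn-by-use space
#'
#' k-means (Lloyd) on the z-standardized learning and use scores of one
#' reinforcer condition, with multiple random restarts keeping the
#' lowest-inertia solution. Clusters are labeled by the quadrant of their
#' centroid: high/low learning x high/low use (HH, HL, LH, LL); at k = 4
#' the labeling is a bijection obtained by optimally matching centroids to
#' the four quadrant prototypes. When ground-truth phenotype labels are
#' supplied, an agreement index (best-matching relabeling accuracy) is
#' reported.
#'
#' @param features output of [build_features()] for one condition.
#' @param k number of clusters (default 4).
#' @param restarts random initializations (default 25).
#' @param seed integer RNG seed.
#' @param truth optional named vector `participant_id -> phenotype` for
#'   recovery diagnostics.
#' @return object of class `cluster_result`: `condition`, `k`,
#'   `assignments` (named vector), `centroids`, `quadrant`,
#'   `cluster_quadrant` (per-cluster labels), `inertia`, `seed`, `restarts`,
#'   `agreement` (or NA).
#' @export
cluster_learn_use <- function(features, k = 4, restarts = 25, seed = 1,
                              truth = NULL) {
  X <- cbind(learn = features$learn_z, use = features$use_z)
  if (nrow(X) < k) stop("need at least k = ", k, " subjects")
  if (nrow(unique(X)) < k) stop("fewer than k distinct points; cannot form ",
                                k, " clusters")
  centers <- if (nrow(unique(X)) == k) unique(X) else k
  km <- local_rng(seed,
                  suppressWarnings(stats::kmeans(X, centers = centers,
                                                 nstart = if (is.matrix(centers))
                                                   1 else restarts,
                                                 iter.max = 100,
                                                 algorithm = "Lloyd")))
  labs <- quadrant_labels(km$centers)
  assignments <- stats::setNames(km$cluster, features$participant_id)
  agreement <- NA_real_
  if (!is.null(truth)) {
    tr <- truth[features$participant_id]
    agreement <- max(apply(rbind_permutations(k), 1, function(p) {
      mean(c("HH", "HL", "LH", "LL")[p][km$cluster] == tr)
    }))
  }
  structure(list(
    condition = features$condition[1], k = k, assignments = assignments,
    centroids = km$centers, quadrant = stats::setNames(labs[km$cluster],
                                                       features$participant_id),
    cluster_quadrant = labs, inertia = km$tot.withinss, seed = seed,
    restarts = restarts, agreement = agreement
  ), class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: %s, k=%d, inertia=%.2f%s>\n", x$condition,
              x$k, x$inertia,
              if (is.na(x$agreement)) "" else
                sprintf(", truth agreement %.2f", x$agreement)))
  print(table(quadrant = x$quadrant))
  invisible(x)
}

#' Choose the number of clusters by mean silhouette
#'
#' Runs [cluster_learn_use()] for each k in `k_range` and picks the k with
#' the highest mean silhouette width. A `no_structure` flag is raised when
#' the best mean silhouette is below 0.25 (no convincing clustering).
#'
#' @param features output of [build_features()].
#' @param k_range candidate cluster counts (subset of 2..n-1).
#' @param restarts,seed as in [cluster_learn_use()].
#' @return list with `k` (chosen), `scores` (data frame k, mean_silhouette,
#'   inertia), `no_structure`.
#' @export
select_k <- function(features, k_range = 2:6, restarts = 25, seed = 1) {
  X <- cbind(features$learn_z, features$use_z)
  n <- nrow(X)
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]")
  }
  d <- stats::dist(X)
  rows <- lapply(k_range, function(k) {
    cl <- cluster_learn_use(features, k = k, restarts = restarts, seed = seed)
    sil <- cluster::silhouette(unname(cl$assignments), d)
    data.frame(k = k, mean_silhouette = mean(sil[, "sil_width"]),
               inertia = cl$inertia)
  })
  scores <- do.call(rbind, rows)
  best <- scores$k[which.max(scores$mean_silhouette)]
  list(k = best, scores = scores,
       no_structure = max(scores$mean_silhouette) < 0.25)
}

#' Score the four-alternative recall test
#'
#' @param recall recall table: `participant_id`, `block`, `correct`.
#' @return data frame with one row per participant: accuracy per block and
#'   overall; the chance level for 4-option items (0.25) is attached as
#'   attribute `chance`.
#' @export
score_recall <- function(recall) {
  if (!all(c("participant_id", "block", "correct") %in% names(recall))) {
    stop("recall table must have participant_id, block, correct columns")
  }
  if ("n_options" %in% names(recall) && any(recall$n_options != 4L)) {
    stop("recall items must be 4-option")
  }
  per <- split(recall, recall$participant_id)
  out <- do.call(rbind, lapply(per, function(d) {
    blocks <- tapply(d$correct, d$block, mean)
    data.frame(participant_id = d$participant_id[1],
               accuracy_shape_to_outcome =
                 unname(blocks["shape_to_outcome"]),
               accuracy_outcome_to_shape =
                 unname(blocks["outcome_to_shape"]),
               accuracy_overall = mean(d$correct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "chance") <- 0.25
  out
}

#' Learn-use concordance: 2 x 2 agreement table, Cohen's kappa, chi-square
#'
#' Dichotomizes the learning and use scores (median split by default, with
#' subjects at the median assigned to "low"; or a 2-cluster split on each
#' axis) and cross-tabulates high/low learning against high/low use. If the
#' two tasks index the same underlying acquisition, subjects concentrate in
#' the agreement cells; the off-diagonal cells are the dissociated
#' learn-without-use and use-without-learn groups.
#'
#' @param features output of [build_features()] for one condition.
#' @param split `"median"` or `"cluster"`.
#' @param seed RNG seed for the cluster split.
#' @return list with `table` (2 x 2), `kappa`, `chisq` (statistic), `p_o`,
#'   `p_e`, `degenerate` flag.
#' @export
concordance <- function(features, split = c("median", "cluster"), seed = 1) {
  split <- match.arg(split)
  dichotomize <- function(x) {
    if (split == "median") {
      factor(x > stats::median(x), levels = c(FALSE, TRUE),
             labels = c("low", "high"))
    } else {
      km <- local_rng(seed, stats::kmeans(x, 2, nstart = 10))
      hi <- which.max(km$centers)
      factor(km$cluster == hi, levels = c(FALSE, TRUE),
             labels = c("low", "high"))
    }
  }
  learn <- dichotomize(features$learn_z)
  use <- dichotomize(features$use_z)
  tab <- table(learn = learn, use = use)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (degenerate || p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  chisq <- if (degenerate) NA_real_ else
    suppressWarnings(unname(stats::chisq.test(tab, correct = FALSE)$statistic))
  list(table = tab, kappa = kappa, chisq = chisq, p_o = p_o, p_e = p_e,
       degenerate = degenerate)
}

#' Cohen's kappa from a square agreement table
#'
#' @param tab a square contingency table or matrix.
#' @return kappa = (p_o - p_e) / (1 - p_e).
#' @export
#' @examples
#' cohen_kappa(matrix(c(30, 10, 10, 30), 2)) # 0.5
cohen_kappa <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("table must be square")
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Sign-flip permutation test for a conditioning effect on ratings
#'
#' Tests whether post-conditioning ratings shifted relative to
#' pre-conditioning ratings. The observed statistic is the mean paired
#' change; the null distribution is built by randomly flipping the sign of
#' each subject's change (exchangeability of +d and -d under no effect),
#' and the two-sided p-value is `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`.
#'
#' @param pre,post paired rating vectors, n >= 5.
#' @param n_perm number of sign-flip permutations (warning below 100).
#' @param seed integer RNG seed.
#' @return list with `observed` (mean change), `p_value`, `n_perm`.
#' @export
permutation_conditioning_test <- function(pre, post, n_perm = 2000, seed = 1) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  n <- length(pre)
  if (n < 5) stop("need n >= 5 pairs")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")
  d <- post - pre
  obs <- mean(d)
  perm <- local_rng(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    as.numeric(signs %*% d) / n
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(observed = obs, p_value = p, n_perm = n_perm)
}
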