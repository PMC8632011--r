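#' Accuracy by test type
#'
#' Per-participant proportion correct for each test type (within condition if
#' a `condition` column is present), then group mean, SD and SE per
#' condition x test type cell.
#'
#' @param responses Response records with columns `participant_id`,
#'   `test_type`, `correct` (logical), optionally `condition`.
#' @return An `accuracy_summary`: list with `summary` (one row per cell:
#'   `n`, `mean`, `sd`, `se`) and `by_participant` (per-participant
#'   proportions, plus `k`, `n_items` and the empirical-logit transform
#'   `elogit`).
#' @export
accuracy_by_type <- function(responses) {
  req <- c("participant_id", "test_type", "correct")
  if (!is.data.frame(responses) || nrow(responses) == 0L ||
      !all(req %in% names(responses)))
    stop("responses must be a nonempty data frame with columns ",
         paste(req, collapse = ", "))
  if (!"condition" %in% names(responses)) responses$condition <- "all"

  key <- list(participant_id = responses$participant_id,
              condition = responses$condition,
              test_type = responses$test_type)
  by_p <- stats::aggregate(list(k = responses$correct), key, FUN = sum)
  by_p$n_items <- stats::aggregate(list(n = responses$correct), key,
                                   FUN = length)$n
  by_p$proportion <- by_p$k / by_p$n_items
  by_p$elogit <- empirical_logit(by_p$k, by_p$n_items)

  grp <- list(condition = by_p$condition, test_type = by_p$test_type)
  summ <- stats::aggregate(list(mean = by_p$proportion), grp, FUN = mean)
  summ$sd <- stats::aggregate(list(sd = by_p$proportion), grp,
                              FUN = stats::sd)$sd
  summ$n <- stats::aggregate(list(n = by_p$proportion), grp, FUN = length)$n
  summ$se <- summ$sd / sqrt(summ$n)
  summ <- summ[order(summ$condition, summ$test_type), ]
  rownames(summ) <- NULL
  out <- list(summary = summ, by_participant = by_p)
  class(out) <- "accuracy_summary"
  out
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat("<accuracy_summary>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Empirical logit transform of a proportion
#'
#' `log((k + 0.5) / (n - k + 0.5))`: a boundary-safe logit, finite at
#' `k = 0` and `k = n`, and antisymmetric (`f(k, n) = -f(n - k, n)`).
#'
#' @param k Successes, `0 <= k <= n` (vectorized).
#' @param n Trials, `n > 0`.
#' @return Empirical logit value(s).
#' @examples
#' empirical_logit(0, 20)   # -3.714
#' empirical_logit(10, 20)  # 0
#' @export
empirical_logit <- function(k, n) {
  if (any(n <= 0) || any(k < 0) || any(k > n))
    stop("need 0 <= k <= n and n > 0")
  log((k + 0.5) / (n - k + 0.5))
}

#' Cohen's d and the effect-size correlation
#'
#' `d = (m1 - m2) / sqrt((s1^2 + s2^2) / 2)` (pooled-SD denominator for
#' equal-weight groups) and `r = d / sqrt(d^2 + 4)`.
#'
#' @param m1,s1 Mean and SD of group 1.
#' @param m2,s2 Mean and SD of group 2.
#' @return An `effect_size_report`: list with `d`, `r`, `m1`, `s1`, `m2`,
#'   `s2`.
#' @examples
#' cohens_d(0.96, 0.10, 0.75, 0.27)$d  # 1.03
#' cohens_d(0.99, 0.04, 0.90, 0.18)$d  # 0.69
#' @export
cohens_d <- function(m1, s1, m2, s2) {
  if (s1 < 0 || s2 < 0) stop("SDs must be nonnegative")
  if (s1 == 0 && s2 == 0 && m1 != m2)
    stop("infinite effect: both SDs are zero with unequal means")
  d <- if (m1 == m2) 0 else (m1 - m2) / sqrt((s1^2 + s2^2) / 2)
  out <- list(d = d, r = d / sqrt(d^2 + 4), m1 = m1, s1 = s1, m2 = m2,
              s2 = s2)
  class(out) <- "effect_size_report"
  out
}

#' @export
print.effect_size_report <- function(x, ...) {
  cat(sprintf("<effect_size_report> d = %.2f, r = %.2f  (m1 = %.3g, s1 = %.3g; m2 = %.3g, s2 = %.3g)\n",
              x$d, x$r, x$m1, x$s1, x$m2, x$s2))
  invisible(x)
}

#' One-sample Wilcoxon signed-rank test against chance
#'
#' Two-tailed signed-rank test of per-participant scores against a chance
#' level `mu`. Exact ties with `mu` are dropped. For `n <= exact_max` the
#' null distribution of the positive-rank sum V is computed exactly by
#' convolution over the (mid)ranks of the absolute deviations, which remains
#' exact under ties; above that, a normal approximation with continuity and
#' tie correction is used. Effect size is reported both as `r = |Z| /
#' sqrt(n)` and as the matched rank-biserial correlation.
#'
#' @param scores Numeric vector of per-participant scores (e.g. proportions).
#' @param mu Chance level (default 0.5).
#' @param exact_max Largest n for the exact path (default 25).
#' @return A list of class `c("wilcoxon_chance", "htest")` with `statistic`
#'   (V, the positive-rank sum), `p.value`, `z`, `r`, `rank_biserial`, `n`
#'   (after dropping ties with `mu`), `method`.
#' @examples
#' wilcoxon_vs_chance(c(.7, .8, .9, .75, .85, .6, .95, .7, .8, .9))$p.value
#' @export
wilcoxon_vs_chance <- function(scores, mu = 0.5, exact_max = 25) {
  d <- as.numeric(scores) - mu
  if (all(d == 0)) stop("degenerate sample: all scores equal mu")
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop("need at least 5 scores not tied with mu")
  r_abs <- rank(abs(d))
  V <- sum(r_abs[d > 0])

  # normal approximation pieces (used for z / r in both paths)
  mu_v <- n * (n + 1) / 4
  tie_tab <- table(r_abs)
  sigma_v <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(tie_tab^3 - tie_tab) / 48)
  cc <- sign(V - mu_v) * 0.5
  z <- (V - mu_v - cc) / sigma_v

  if (n <= exact_max) {
    # exact null: distribution of sum of a random subset of the (doubled,
    # hence integer) midranks; convolution DP over achievable sums
    w <- as.integer(round(2 * r_abs))
    dp <- numeric(sum(w) + 1L)
    dp[1L] <- 1
    for (wi in w) {
      shifted <- c(numeric(wi), dp[seq_len(length(dp) - wi)])
      dp <- dp + shifted
    }
    dp <- dp / 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(dp[seq_len(v2 + 1L)])
    p_ge <- sum(dp[(v2 + 1L):length(dp)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact (convolution over signed midranks)"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity and tie correction"
  }
  out <- list(statistic = c(V = V), parameter = c(n = n), p.value = p,
              z = z, r = abs(z) / sqrt(n),
              rank_biserial = (2 * V - n * (n + 1) / 2) / (n * (n + 1) / 2),
              mu = mu, method = paste("One-sample Wilcoxon signed-rank,",
                                      method),
              data.name = deparse(substitute(scores)))
  class(out) <- c("wilcoxon_chance", "htest")
  out
}

#' Signal-detection sensitivity (d-prime)
#'
#' `d' = qnorm(hit_rate) - qnorm(fa_rate)` from hit and false-alarm counts.
#' The default log-linear correction adds 0.5 to each count and 1 to each
#' denominator, keeping both rates strictly inside (0, 1) even at ceiling or
#' floor; `correction = "none"` uses the raw rates (which can be infinite at
#' the boundaries).
#'
#' @param hits,fas Hit and false-alarm counts.
#' @param n_targets,n_foils Numbers of targets and foils (default 13 each,
#'   the incidental-memory test layout).
#' @param correction `"loglinear"` (default) or `"none"`.
#' @return A `dprime_report`: list with `hits`, `fas`, `n_targets`,
#'   `n_foils`, `hit_rate`, `fa_rate`, `dprime`.
#' @examples
#' dprime(13, 0)$dprime  # 3.61
#' @export
dprime <- function(hits, fas, n_targets = 13, n_foils = 13,
                   correction = c("loglinear", "none")) {
  correction <- match.arg(correction)
  if (hits < 0 || hits > n_targets || fas < 0 || fas > n_foils)
    stop("counts must lie within [0, n_targets] and [0, n_foils]")
  if (correction == "loglinear") {
    hr <- (hits + 0.5) / (n_targets + 1)
    fr <- (fas + 0.5) / (n_foils + 1)
  } else {
    hr <- hits / n_targets
    fr <- fas / n_foils
  }
  out <- list(hits = hits, fas = fas, n_targets = n_targets,
              n_foils = n_foils, hit_rate = hr, fa_rate = fr,
              dprime = stats::qnorm(hr) - stats::qnorm(fr))
  class(out) <- "dprime_report"
  out
}

#' @export
print.dprime_report <- function(x, ...) {
  cat(sprintf("<dprime_report> d' = %.3f  (hit rate %.3f, FA rate %.3f)\n",
              x$dprime, x$hit_rate, x$fa_rate))
  invisible(x)
}

#' Score a forward digit span task
#'
#' The standard scoring: the highest list length recalled correctly.
#'
#' @param lengths Integer vector of list lengths, nondecreasing over trials.
#' @param correct Logical vector: was each list recalled correctly?
#' @return Integer span (0, with a warning, if no list was recalled).
#' @examples
#' score_digit_span(4:7, c(TRUE, TRUE, TRUE, FALSE))  # 6
#' @export
score_digit_span <- function(lengths, correct) {
  stopifnot(length(lengths) == length(correct))
  if (is.unsorted(lengths)) stop("lengths must be nondecreasing")
  if (!any(correct)) {
    warning("no correct recalls; span scored 0")
    return(0L)
  }
  as.integer(max(lengths[correct]))
}

#' Early-versus-late acceptance trend over test trials
#'
#' Per participant, mean acceptance over the first `n_edge` and last `n_edge`
#' test trials (by trial order), then a one-sided paired t test of early >
#' late. Overgeneralizers whose acceptance decays over the test produce a
#' positive early-late difference; constant responders produce zero.
#'
#' @param responses Response records with `participant_id`, `trial_index`,
#'   and `answer` (`"accept"`/`"reject"`).
#' @param n_edge Number of trials in each window (default 3).
#' @return List with `early_mean`, `late_mean`, `mean_diff`, `statistic`,
#'   `p.value`, `n`.
#' @export
positional_acceptance_trend <- function(responses, n_edge = 3) {
  req <- c("participant_id", "trial_index", "answer")
  stopifnot(is.data.frame(responses), all(req %in% names(responses)))
  parts <- split(responses, responses$participant_id)
  if (any(vapply(parts, nrow, integer(1)) < 2 * n_edge))
    stop("every participant needs at least ", 2 * n_edge, " test trials")
  edge <- vapply(parts, function(df) {
    df <- df[order(df$trial_index), ]
    acc <- df$answer == "accept"
    c(mean(acc[seq_len(n_edge)]), mean(acc[seq(nrow(df) - n_edge + 1,
                                               nrow(df))]))
  }, numeric(2))
  early <- edge[1, ]
  late <- edge[2, ]
  diffs <- early - late
  if (stats::sd(diffs) == 0) {
    stat <- NA_real_
    p <- if (mean(diffs) > 0) 0 else 1
  } else {
    tt <- stats::t.test(early, late, paired = TRUE, alternative = "greater")
    stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(early_mean = mean(early), late_mean = mean(late),
       mean_diff = mean(diffs), statistic = stat, p.value = p,
       n = length(parts))
}

#' Export a tidy response table for external model fitting
#'
#' One row per judgment with condition, test type, correctness and the
#' participant's covariates merged in, as expected by mixed-effects fitting
#' tools.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param path Optional path; when given, the table is written as CSV.
#' @return The tidy data frame (invisibly if `path` is given).
#' @export
export_tidy_responses <- function(cohort, path = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  out <- merge(cohort$responses,
               cohort$covariates[, setdiff(names(cohort$covariates),
                                           "condition")],
               by = "participant_id", sort = FALSE)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
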