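#' Learner parameters for the channel-capacity encoding model
#'
#' Parameters of the simulated learner. A participant exposed at source bit
#' rate H' (bits/s) adopts category-based encoding with probability
#' `plogis(slope * (H' - capacity))`: below capacity, item-bound encoding
#' dominates; above it, the encoding mode shifts toward category-based
#' generalization.
#'
#' @param capacity Channel capacity C, bits/s (> 0).
#' @param slope Logistic slope k per (bit/s) of the mode-transition link
#'   (>= 0; 0 gives a flat link, mode probability 0.5 everywhere).
#' @param lapse Lapse rate in `[0, 0.5)`: with probability `2 * lapse` a
#'   judgment is replaced by a fair coin flip, so `lapse` is the error rate
#'   of an otherwise deterministic responder and 0.5 drives every response
#'   to chance.
#' @param overgen_rate Probability that an aXb learner pushed past capacity
#'   overgeneralizes the a/b elements into open categories (accepting any
#'   aXb-shaped string) rather than guessing.
#' @param drift Per-trial decrement of an overgeneralizer's acceptance
#'   tendency over the test (their early acceptances exceed late ones).
#' @param guess_rate Probability that a below-capacity aXb learner fails to
#'   learn the frames and guesses (yields the bimodal slow-rate accuracy
#'   distribution).
#' @param capacity_sd Between-participant SD of capacity; 0 (default) makes C
#'   a population constant.
#' @return A `learner_params` object.
#' @examples
#' learner_params(capacity = 6, slope = 2)
#' @export
learner_params <- function(capacity = 6, slope = 2, lapse = 0.05,
                           overgen_rate = 0.7, drift = 0.08,
                           guess_rate = 0.3, capacity_sd = 0) {
  if (!is.finite(capacity) || capacity <= 0) stop("capacity must be > 0")
  if (!is.finite(slope) || slope < 0) stop("slope must be >= 0")
  if (lapse < 0 || lapse >= 0.5) stop("lapse must be in [0, 0.5)")
  for (p in c(overgen_rate, drift, guess_rate))
    if (p < 0 || p > 1) stop("rates must be probabilities in [0, 1]")
  if (capacity_sd < 0) stop("capacity_sd must be >= 0")
  out <- list(capacity = capacity, slope = slope, lapse = lapse,
              overgen_rate = overgen_rate, drift = drift,
              guess_rate = guess_rate, capacity_sd = capacity_sd)
  class(out) <- "learner_params"
  out
}

#' @export
print.learner_params <- function(x, ...) {
  cat(sprintf(paste0("<learner_params> C = %.3g bits/s (sd %.3g), k = %.3g,",
                     " lapse = %.3g,\n  overgen_rate = %.3g, drift = %.3g,",
                     " guess_rate = %.3g\n"),
              x$capacity, x$capacity_sd, x$slope, x$lapse,
              x$overgen_rate, x$drift, x$guess_rate))
  invisible(x)
}

#' Acceptance profiles of the XXY encoding modes
#'
#' Per-test-type acceptance probabilities for each encoding mode. A
#' category-based learner applies the same-same-different rule: accept every
#' XXY string (familiar or new), reject every X1X2Y string. An item-bound
#' learner accepts familiar XXY strings, accepts new-syllable XXY strings at
#' a modest base level (0.55), and occasionally accepts familiar-syllable
#' X1X2Y strings (0.10) because memory traces of the familiar syllables
#' prompt incorrect acceptance; fully novel X1X2Y strings are almost always
#' rejected (0.02). A guessing profile sits at 0.5 everywhere. These are
#' package defaults, replaceable by the caller.
#'
#' @return Named list of numeric vectors (`CATEGORY_BASED`, `ITEM_BOUND`,
#'   `GUESS`), each named by test type.
#' @export
default_mode_profiles <- function() {
  types <- c("FAM_XXY", "NEW_XXY", "FAM_X1X2Y", "NEW_X1X2Y")
  list(
    CATEGORY_BASED = stats::setNames(c(1, 1, 0, 0), types),
    ITEM_BOUND = stats::setNames(c(1, 0.55, 0.10, 0.02), types),
    GUESS = stats::setNames(rep(0.5, 4), types)
  )
}

#' Probability of category-based encoding at a given bit rate
#'
#' The mode-transition link: `plogis(slope * (h_prime - capacity))`. At
#' `h_prime == capacity` it is 0.5; it is monotone nondecreasing in
#' `h_prime`, approaching 1 when the source rate far exceeds capacity.
#'
#' @param h_prime Source bit rate H', bits/s (>= 0).
#' @param params A [learner_params()] object.
#' @return Probability in `[0, 1]`.
#' @examples
#' p_category_mode(8.4, learner_params(capacity = 8.4))  # 0.5
#' @export
p_category_mode <- function(h_prime, params) {
  if (any(h_prime < 0)) stop("h_prime must be >= 0")
  stats::plogis(params$slope * (h_prime - params$capacity))
}

# internal: mix acceptance probabilities toward 0.5. With probability
# 2*lapse a judgment is a fair coin flip, so a deterministic profile (p = 0
# or 1) errs at rate `lapse`, and lapse -> 0.5 drives every response to
# chance.
lapse_mix <- function(p, lapse) lapse + (1 - 2 * lapse) * p

# internal: draw a participant capacity (per-individual variation optional)
draw_capacity <- function(params) {
  if (params$capacity_sd == 0) return(params$capacity)
  max(1e-6, stats::rnorm(1, params$capacity, params$capacity_sd))
}

#' Simulate one participant's XXY test judgments
#'
#' The participant's encoding mode is drawn once from
#' [p_category_mode()] (category-based vs item-bound), then each battery item
#' receives a Bernoulli accept/reject with the mode's acceptance probability
#' for that test type, mixed toward 0.5 by the lapse rate.
#'
#' @param battery An XXY `test_battery` from [generate_test_battery()].
#' @param h_prime Source bit rate of the participant's condition, bits/s.
#' @param params A [learner_params()] object.
#' @param seed Integer seed for this participant.
#' @param profiles Mode acceptance profiles; see [default_mode_profiles()].
#' @param mode Optional fixed mode (`"CATEGORY_BASED"`, `"ITEM_BOUND"`,
#'   `"GUESS"`), bypassing the mode draw.
#' @return Data frame of response records: the battery columns plus
#'   `response` (`"accept"`/`"reject"`), `correct` (logical), `mode`,
#'   `h_prime`.
#' @export
simulate_responses_xxy <- function(battery, h_prime, params, seed,
                                   profiles = default_mode_profiles(),
                                   mode = NULL) {
  stopifnot(inherits(battery, "data.frame"),
            all(battery$test_type %in% names(profiles[[1]])))
  set.seed(seed)
  if (is.null(mode)) {
    cap <- draw_capacity(params)
    p_cat <- stats::plogis(params$slope * (h_prime - cap))
    mode <- if (stats::runif(1) < p_cat) "CATEGORY_BASED" else "ITEM_BOUND"
  }
  base <- profiles[[mode]][battery$test_type]
  p <- lapse_mix(base, params$lapse)
  resp <- ifelse(stats::runif(nrow(battery)) < p, "accept", "reject")
  out <- as.data.frame(battery)
  out$response <- resp
  out$correct <- resp == battery$correct_answer
  out$mode <- mode
  out$h_prime <- h_prime
  out
}

#' Simulate one participant's aXb test judgments
#'
#' One of three behaviours is drawn once per participant. With probability
#' `p_category_mode(h_prime) * overgen_rate` the participant is an
#' OVERGENERALIZER who treats the a/b elements as open categories: every
#' aXb-shaped string is acceptable, with acceptance decaying by `drift` per
#' test trial (early acceptances exceed late ones). With probability
#' `p_category_mode(h_prime) * (1 - overgen_rate)` the capacity-driven
#' restructuring yields no usable frame knowledge and the participant
#' GUESSes. Otherwise the participant learned the item-bound frames
#' (VERIDICAL: accept grammatical, reject ungrammatical), except that a
#' fraction `guess_rate` of below-capacity learners fail to learn and GUESS.
#' All judgments are lapse-mixed toward 0.5.
#'
#' @inheritParams simulate_responses_xxy
#' @param battery A 12-item aXb `test_battery`.
#' @param mode Optional fixed mode (`"VERIDICAL"`, `"OVERGENERALIZER"`,
#'   `"GUESS"`).
#' @return Data frame of response records as in [simulate_responses_xxy()].
#' @export
simulate_responses_axb <- function(battery, h_prime, params, seed,
                                   mode = NULL) {
  stopifnot(inherits(battery, "data.frame"),
            all(battery$test_type %in% c("AXB_GRAMMATICAL",
                                         "AXB_UNGRAMMATICAL")))
  set.seed(seed)
  if (is.null(mode)) {
    cap <- draw_capacity(params)
    p_cat <- stats::plogis(params$slope * (h_prime - cap))
    u <- stats::runif(2)
    mode <- if (u[1] < p_cat) {
      if (u[2] < params$overgen_rate) "OVERGENERALIZER" else "GUESS"
    } else {
      if (u[2] < params$guess_rate) "GUESS" else "VERIDICAL"
    }
  }
  j <- seq_len(nrow(battery))
  base <- switch(mode,
    VERIDICAL = as.numeric(battery$correct_answer == "accept"),
    OVERGENERALIZER = pmax(0, 1 - params$drift * (j - 1)),
    GUESS = rep(0.5, nrow(battery))
  )
  p <- lapse_mix(base, params$lapse)
  resp <- ifelse(stats::runif(nrow(battery)) < p, "accept", "reject")
  out <- as.data.frame(battery)
  out$response <- resp
  out$correct <- resp == battery$correct_answer
  out$mode <- mode
  out$h_prime <- h_prime
  out
}

#' Describe one cohort condition
#'
#' Bundles everything [simulate_cohort()] needs for one between-subjects
#' condition: the grammar, the (possibly sped-up) timing, the familiarization
#' design, the novel test inventory, and the number of participants.
#'
#' @param experiment `"xxy"` or `"axb"`.
#' @param grammar A `grammar_spec`.
#' @param timing A `timing_params` for the slow-rate schedule.
#' @param n Number of participants.
#' @param novel_inventory Novel syllables/words for [generate_test_battery()].
#' @param repetitions,phases Familiarization design (defaults: 4 x 3 for XXY,
#'   12 x 1 for aXb).
#' @param speed_factor Proportional speed-up applied to `timing` (1 = slow
#'   rate).
#' @return A `cohort_condition` list.
#' @export
cohort_condition <- function(experiment = c("xxy", "axb"), grammar, timing, n,
                             novel_inventory,
                             repetitions = if (experiment == "xxy") 4L else 12L,
                             phases = if (experiment == "xxy") 3L else 1L,
                             speed_factor = 1) {
  experiment <- match.arg(experiment)
  stopifnot(inherits(grammar, "grammar_spec"), inherits(timing, "timing_params"),
            n >= 1)
  out <- list(experiment = experiment, grammar = grammar,
              timing = apply_speedup(timing, speed_factor), n = as.integer(n),
              novel_inventory = novel_inventory,
              repetitions = as.integer(repetitions),
              phases = as.integer(phases), speed_factor = speed_factor)
  class(out) <- "cohort_condition"
  out
}

#' Simulate a full cohort across conditions
#'
#' For each condition the source bit rate H' is computed from the grammar's
#' entropy and its familiarization schedule; each participant then gets an
#' independently randomized test battery and responses from the encoding-mode
#' model, plus covariate task scores (forward digit span, incidental-memory
#' hits/false alarms, pattern-recognition percentile) sampled independently
#' of responses. One master seed derives all per-participant streams, so the
#' whole cohort is reproducible.
#'
#' @param conditions Named list of [cohort_condition()] objects.
#' @param params A [learner_params()] object.
#' @param master_seed Integer master seed.
#' @param covariate_params List of covariate distribution settings:
#'   `span_mean`, `span_sd` (truncated-normal digit span), `memo_hit_p`,
#'   `memo_fa_p` (binomial over 13 targets / 13 foils), `ravens_mean`,
#'   `ravens_sd` (percentile, clamped to 1..99).
#' @return A list of class `cohort`: `responses` (one row per judgment:
#'   `participant_id`, `experiment`, `condition`, `phase`, `trial_index`,
#'   `test_type`, `stimulus`, `answer`, `correct`, `mode`, `h_prime`),
#'   `covariates` (one row per participant), and `conditions` (per-condition
#'   H, m, H' metadata).
#' @export
simulate_cohort <- function(conditions, params, master_seed,
                            covariate_params = list(
                              span_mean = 6.7, span_sd = 1.2,
                              memo_hit_p = 0.85, memo_fa_p = 0.2,
                              ravens_mean = 71.5, ravens_sd = 20)) {
  stopifnot(length(conditions) >= 1, !is.null(names(conditions)),
            all(nzchar(names(conditions))))
  n_total <- sum(vapply(conditions, function(cc) cc$n, integer(1)))
  seeds <- derive_seeds(master_seed, 3L * n_total + length(conditions))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }

  resp <- list()
  covs <- list()
  meta <- list()
  pid <- 0L
  for (cname in names(conditions)) {
    cc <- conditions[[cname]]
    h <- grammar_entropy(cc$grammar)$h_total
    fam <- generate_familiarization(cc$grammar, cc$repetitions, cc$phases,
                                    seed = next_seed())
    rate <- source_rate(fam, cc$timing, h)
    meta[[cname]] <- data.frame(
      condition = cname, experiment = cc$experiment, n = cc$n,
      h_total = h, symbols_per_second = rate$symbols_per_second,
      h_prime = rate$bits_per_second, speed_factor = cc$speed_factor,
      stringsAsFactors = FALSE)
    for (i in seq_len(cc$n)) {
      pid <- pid + 1L
      battery <- generate_test_battery(cc$grammar, cc$novel_inventory,
                                       seed = next_seed())
      rec <- if (cc$experiment == "xxy") {
        simulate_responses_xxy(battery, rate$bits_per_second, params,
                               seed = next_seed())
      } else {
        simulate_responses_axb(battery, rate$bits_per_second, params,
                               seed = next_seed())
      }
      resp[[pid]] <- data.frame(
        participant_id = pid, experiment = cc$experiment, condition = cname,
        phase = rec$phase, trial_index = rec$item_index,
        test_type = rec$test_type,
        stimulus = paste(rec$s1, rec$s2, rec$s3),
        answer = rec$response, correct = rec$correct, mode = rec$mode,
        h_prime = rec$h_prime, stringsAsFactors = FALSE)
      covs[[pid]] <- data.frame(
        participant_id = pid, condition = cname,
        digit_span = min(12L, max(2L, round(stats::rnorm(
          1, covariate_params$span_mean, covariate_params$span_sd)))),
        memo_hits = stats::rbinom(1, 13L, covariate_params$memo_hit_p),
        memo_fas = stats::rbinom(1, 13L, covariate_params$memo_fa_p),
        ravens_percentile = min(99, max(1, round(stats::rnorm(
          1, covariate_params$ravens_mean, covariate_params$ravens_sd)))),
        stringsAsFactors = FALSE)
    }
  }
  out <- list(responses = do.call(rbind, resp),
              covariates = do.call(rbind, covs),
              conditions = do.call(rbind, meta))
  rownames(out$responses) <- rownames(out$covariates) <-
    rownames(out$conditions) <- NULL
  attr(out, "master_seed") <- master_seed
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d responses\n",
              nrow(x$covariates), nrow(x$responses)))
  print(x$conditions)
  invisible(x)
}
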