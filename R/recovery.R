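#' Recover learner parameters from XXY cohort responses
#'
#' Maximum-likelihood estimation of the encoding-mode model from yes/no
#' judgments observed at two or more source bit rates. Each participant's
#' acceptance counts per test type are modelled as a two-component mixture:
#' with probability `plogis(slope * (h_prime - capacity))` the participant is
#' category-based, otherwise item-bound; within a mode, acceptances are
#' binomial with the mode profile's probabilities lapse-mixed toward 0.5.
#' The negative log-likelihood is minimized over (capacity, slope, lapse) by
#' bounded multi-start optimization (`optim`, L-BFGS-B), deterministic given
#' `seed`.
#'
#' A design with a single H' level cannot separate capacity from slope and is
#' flagged as non-converged rather than silently fitted. A flat link (e.g.
#' data generated with `slope = 0`) is flagged the same way: the full model
#' must beat a rate-independent mixture (the `slope -> 0` limit) by a 1-df
#' likelihood-ratio margin, otherwise capacity is unidentified.
#'
#' @param responses Response records with `participant_id`, `test_type`,
#'   `answer` (`"accept"`/`"reject"`) and `h_prime` (or a `condition` column
#'   resolved through `design`).
#' @param design Optional data frame with columns `condition`, `h_prime`,
#'   used when `responses` lacks an `h_prime` column.
#' @param profiles Mode acceptance profiles (known constants of the model);
#'   see [default_mode_profiles()].
#' @param bounds List of length-2 numeric ranges for `capacity`, `slope`,
#'   `lapse`.
#' @param seed Integer seed for the multi-start jitter.
#' @param n_starts Number of optimizer starts.
#' @return A `recovery_result`: list with `estimates` (named vector:
#'   `capacity`, `slope`, `lapse`), `loglik`, `converged`, `message`, `se`,
#'   `ci` (Wald 95%), `n_participants`, `h_levels`.
#' @export
recover_learner_parameters <- function(responses, design = NULL,
                                       profiles = default_mode_profiles(),
                                       bounds = list(capacity = c(1, 20),
                                                     slope = c(0.02, 10),
                                                     lapse = c(1e-4, 0.49)),
                                       seed = 1, n_starts = 6) {
  stopifnot(is.data.frame(responses),
            all(c("participant_id", "test_type", "answer") %in%
                  names(responses)))
  if (!"h_prime" %in% names(responses)) {
    if (is.null(design) ||
        !all(c("condition", "h_prime") %in% names(design)))
      stop("responses lack h_prime; supply a design with condition + h_prime")
    responses$h_prime <-
      design$h_prime[match(responses$condition, design$condition)]
  }
  types <- names(profiles[[1]])
  stopifnot(all(responses$test_type %in% types))

  # per-participant acceptance counts per test type
  acc <- responses$answer == "accept"
  tab_k <- tapply(acc, list(responses$participant_id, responses$test_type),
                  sum)
  tab_n <- tapply(acc, list(responses$participant_id, responses$test_type),
                  length)
  tab_k[is.na(tab_k)] <- 0
  tab_n[is.na(tab_n)] <- 0
  K <- tab_k[, types, drop = FALSE]
  N <- tab_n[, types, drop = FALSE]
  h <- tapply(responses$h_prime, responses$participant_id, function(x) x[1])
  h <- h[rownames(K)]
  h_levels <- sort(unique(h))

  flagged <- function(msg) {
    out <- list(estimates = c(capacity = NA_real_, slope = NA_real_,
                              lapse = NA_real_),
                loglik = NA_real_, converged = FALSE, message = msg,
                se = NULL, ci = NULL, n_participants = nrow(K),
                h_levels = h_levels)
    class(out) <- "recovery_result"
    warning(msg)
    out
  }
  if (length(h_levels) < 2)
    return(flagged("non-identifiable design: a single H' level cannot separate capacity from slope"))

  pi_cat <- profiles$CATEGORY_BASED[types]
  pi_ib <- profiles$ITEM_BOUND[types]
  negll <- function(theta) {
    cap <- theta[1]; k <- theta[2]; eps <- theta[3]
    p_cat <- stats::plogis(k * (h - cap))
    ll_mode <- function(pi) {
      p <- pmin(1 - 1e-12, pmax(1e-12, lapse_mix(pi, eps)))
      drop(K %*% log(p) + (N - K) %*% log(1 - p))
    }
    a <- log(pmax(p_cat, 1e-300)) + ll_mode(pi_cat)
    b <- log(pmax(1 - p_cat, 1e-300)) + ll_mode(pi_ib)
    m <- pmax(a, b)
    -sum(m + log(exp(a - m) + exp(b - m)))
  }

  # reduced model: one mixture weight shared across H' levels (the k -> 0
  # limit). If the rate-dependent link does not beat it by a likelihood-ratio
  # margin, capacity is not identified from these data.
  negll_flat <- function(theta) {
    w <- theta[1]; eps <- theta[2]
    ll_mode <- function(pi) {
      p <- pmin(1 - 1e-12, pmax(1e-12, lapse_mix(pi, eps)))
      drop(K %*% log(p) + (N - K) %*% log(1 - p))
    }
    a <- log(max(w, 1e-300)) + ll_mode(pi_cat)
    b <- log(max(1 - w, 1e-300)) + ll_mode(pi_ib)
    m <- pmax(a, b)
    -sum(m + log(exp(a - m) + exp(b - m)))
  }
  flat_fit <- stats::optim(c(0.5, 0.1), negll_flat, method = "L-BFGS-B",
                           lower = c(1e-6, bounds$lapse[1]),
                           upper = c(1 - 1e-6, bounds$lapse[2]))

  lo <- c(bounds$capacity[1], bounds$slope[1], bounds$lapse[1])
  hi <- c(bounds$capacity[2], bounds$slope[2], bounds$lapse[2])
  set.seed(seed)
  starts <- cbind(
    capacity = stats::runif(n_starts, min(h_levels), max(h_levels)),
    slope = exp(stats::runif(n_starts, log(0.2), log(5))),
    lapse = stats::runif(n_starts, 0.02, 0.2))
  starts <- pmin(pmax(starts, rep(lo, each = n_starts)),
                 rep(hi, each = n_starts))
  fits <- apply(starts, 1L, function(s)
    tryCatch(stats::optim(s, negll, method = "L-BFGS-B", lower = lo,
                          upper = hi),
             error = function(e) NULL))
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits)) return(flagged("optimization failed from all starts"))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  est <- stats::setNames(best$par, c("capacity", "slope", "lapse"))

  if (2 * (flat_fit$value - best$value) < stats::qchisq(0.95, df = 1))
    return(flagged("flat mode-transition link (no improvement over a rate-independent mixture): capacity not identified"))

  # Wald standard errors from a numerical Hessian at the optimum
  hess <- tryCatch(stats::optimHess(best$par, negll), error = function(e) NULL)
  se <- ci <- NULL
  if (!is.null(hess)) {
    cov <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov) && all(diag(cov) > 0)) {
      se <- stats::setNames(sqrt(diag(cov)), names(est))
      ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
    }
  }
  out <- list(estimates = est, loglik = -best$value,
              converged = best$convergence == 0,
              message = if (best$convergence == 0) "converged"
                        else paste("optim convergence code", best$convergence),
              se = se, ci = ci, n_participants = nrow(K),
              h_levels = h_levels)
  class(out) <- "recovery_result"
  out
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("<recovery_result>",
      if (x$converged) "converged" else paste("NOT converged:", x$message),
      "\n")
  if (!all(is.na(x$estimates))) {
    est <- data.frame(estimate = x$estimates)
    if (!is.null(x$se)) {
      est$se <- x$se
      est <- cbind(est, x$ci)
    }
    print(round(est, 4))
    cat(sprintf("log-likelihood %.2f over %d participants at H' levels %s\n",
                x$loglik, x$n_participants,
                paste(round(x$h_levels, 2), collapse = ", ")))
  }
  invisible(x)
}

#' Parameter-recovery study for the encoding-mode model
#'
#' Simulates replicate cohorts from known learner parameters and refits them
#' with [recover_learner_parameters()], measuring how well the generating
#' capacity is recovered. By default participants are spread over four source
#' bit rates: the slow-rate XXY schedule's H' multiplied by 1, 1.34, 1.71 and
#' 1.34 x 1.71 (the two designs' speed-up coefficients and their
#' composition), a ladder that brackets plausible capacities the way
#' psychometric-function designs bracket a threshold.
#'
#' @param n_replicates Number of replicate cohorts (default 20).
#' @param n_per_condition Participants per H' level (default 200).
#' @param true_params Generating [learner_params()] (default capacity 8.4
#'   bits/s, slope 2, lapse 0.05).
#' @param h_levels Source bit rates; `NULL` for the default ladder.
#' @param seed Master seed.
#' @return A `recovery_study` data frame (one row per replicate: estimates,
#'   convergence, `rel_error_capacity`) with attributes `true_params` and
#'   `summary` (median relative error and bias of the capacity estimate).
#' @export
recovery_study <- function(n_replicates = 20, n_per_condition = 200,
                           true_params = learner_params(capacity = 8.4,
                                                        slope = 2,
                                                        lapse = 0.05),
                           h_levels = NULL, seed = 1) {
  xs <- make_syllables(7, "cv", seed = 101)
  ys <- make_syllables(7, "cv", seed = 202,
                       blocklist = xs)
  g <- build_xxy_grammar(xs, ys)
  if (is.null(h_levels)) {
    fam <- generate_familiarization(g, 4, 3, seed = 1)
    base <- source_rate(fam, xxy_timing(),
                        grammar_entropy(g)$h_total)$bits_per_second
    h_levels <- base * c(1, 1.34, 1.71, 1.34 * 1.71)
  }
  nov_pool <- make_syllables(8, "cv", seed = 303,
                             blocklist = c(xs, ys))
  nov <- rbind(syllable_inventory(nov_pool[1:4], "X"),
               syllable_inventory(nov_pool[5:8], "Y"))
  battery <- generate_test_battery(g, nov, seed = 404)

  master <- derive_seeds(seed, n_replicates)
  rows <- lapply(seq_len(n_replicates), function(rep_i) {
    seeds <- derive_seeds(master[rep_i], n_per_condition * length(h_levels))
    s <- 0L
    resp <- lapply(seq_along(h_levels), function(li) {
      lapply(seq_len(n_per_condition), function(i) {
        s <<- s + 1L
        r <- simulate_responses_xxy(battery, h_levels[li], true_params,
                                    seed = seeds[s])
        data.frame(participant_id = paste0("L", li, "P", i),
                   test_type = r$test_type, answer = r$response,
                   h_prime = r$h_prime, stringsAsFactors = FALSE)
      })
    })
    resp <- do.call(rbind, unlist(resp, recursive = FALSE))
    fit <- recover_learner_parameters(resp, seed = master[rep_i])
    data.frame(replicate = rep_i,
               capacity_hat = fit$estimates["capacity"],
               slope_hat = fit$estimates["slope"],
               lapse_hat = fit$estimates["lapse"],
               converged = fit$converged,
               rel_error_capacity =
                 abs(fit$estimates["capacity"] - true_params$capacity) /
                   true_params$capacity,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "true_params") <- true_params
  attr(out, "h_levels") <- h_levels
  attr(out, "summary") <- list(
    median_rel_error_capacity = stats::median(out$rel_error_capacity),
    bias_capacity = mean(out$capacity_hat) - true_params$capacity)
  class(out) <- c("recovery_study", "data.frame")
  out
}
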