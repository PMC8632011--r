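#' Timing parameters for stimulus presentation
#'
#' Durations of the auditory elements and pauses making up a presentation
#' schedule, all in milliseconds. Element durations are named by role
#' (`X`, `Y`, `a`, `b`, `AXB_X`). The default constructors below give the
#' slow-rate schedules of the two designs; the element durations are package
#' defaults (only the pause durations and speed-up ratios are fixed by the
#' designs).
#'
#' @param element_durations Named numeric vector, ms per role.
#' @param within_string_pause Pause between syllables within a string, ms.
#' @param between_string_pause Pause between successive strings, ms.
#' @return A `timing_params` object.
#' @examples
#' timing_params(c(X = 350, Y = 350), 50, 750)
#' @export
timing_params <- function(element_durations, within_string_pause,
                          between_string_pause) {
  d <- c(element_durations, within = within_string_pause,
         between = between_string_pause)
  if (any(!is.finite(d)) || any(d <= 0))
    stop("all durations must be positive")
  if (is.null(names(element_durations)) || any(!nzchar(names(element_durations))))
    stop("element_durations must be named by role")
  out <- list(element_durations = element_durations,
              within_string_pause = within_string_pause,
              between_string_pause = between_string_pause)
  class(out) <- "timing_params"
  out
}

#' @rdname timing_params
#' @export
xxy_timing <- function() timing_params(c(X = 350, Y = 350), 50, 750)

#' @rdname timing_params
#' @export
axb_timing <- function() timing_params(c(a = 350, b = 350, AXB_X = 500),
                                       100, 750)

#' @export
print.timing_params <- function(x, ...) {
  cat("<timing_params> (ms)\n  elements:",
      paste(sprintf("%s=%.4g", names(x$element_durations),
                    x$element_durations), collapse = ", "),
      sprintf("\n  within-string pause: %.4g\n  between-string pause: %.4g\n",
              x$within_string_pause, x$between_string_pause))
  invisible(x)
}

# internal: total presentation time of a 3-symbol trial sequence, in ms.
# Each trial contributes its three element durations plus two within-string
# pauses; one between-string pause per string boundary (n - 1 for n strings).
sequence_duration_ms <- function(sequence, timing) {
  roles <- attr(sequence, "roles")
  if (is.null(roles)) stop("sequence carries no role template")
  el <- timing$element_durations[roles]
  if (any(is.na(el)))
    stop("timing lacks durations for roles: ",
         paste(setdiff(roles, names(timing$element_durations)), collapse = ", "))
  n <- nrow(sequence)
  n * (sum(el) + 2 * timing$within_string_pause) +
    (n - 1) * timing$between_string_pause
}

#' Source rate of information transmission
#'
#' Computes the average symbol rate `m` (symbols/s) of a presentation
#' schedule, averaged over the whole sequence including between-string
#' pauses, and the source bit rate `H' = m * H` (bits/s) for a grammar with
#' entropy `H` bits/symbol. If an equivocation rate `E` (bits/s lost to
#' noise) is supplied, the actual rate `R = H' - E` is reported as well; `E`
#' is never estimated here.
#'
#' @param sequence A nonempty `trial_sequence` (or `test_battery`).
#' @param timing A `timing_params` covering the sequence's roles.
#' @param bits_per_symbol Grammar entropy H, bits/symbol.
#' @param equivocation Optional equivocation rate E, bits/s.
#' @return A `rate_report`: list with `symbols_per_second`,
#'   `bits_per_symbol`, `bits_per_second`, and optionally `equivocation`,
#'   `actual_rate`.
#' @examples
#' g <- build_xxy_grammar(make_syllables(7, seed = 1), make_syllables(7, seed = 2))
#' fam <- generate_familiarization(g, 4, 3, seed = 11)
#' source_rate(fam, xxy_timing(), grammar_entropy(g)$h_total)
#' @export
source_rate <- function(sequence, timing, bits_per_symbol,
                        equivocation = NULL) {
  if (!is.data.frame(sequence) || nrow(sequence) == 0L)
    stop("sequence must be a nonempty trial sequence")
  dur_s <- sequence_duration_ms(sequence, timing) / 1000
  if (dur_s <= 0) stop("schedule has nonpositive duration")
  m <- 3 * nrow(sequence) / dur_s
  out <- list(symbols_per_second = m,
              bits_per_symbol = bits_per_symbol,
              bits_per_second = m * bits_per_symbol)
  if (!is.null(equivocation)) {
    if (equivocation < 0) stop("equivocation must be nonnegative")
    out$equivocation <- equivocation
    out$actual_rate <- out$bits_per_second - equivocation
  }
  class(out) <- "rate_report"
  out
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("<rate_report> m = %.3f symbols/s, H = %.3f bits/symbol, H' = %.3f bits/s\n",
              x$symbols_per_second, x$bits_per_symbol, x$bits_per_second))
  if (!is.null(x$equivocation))
    cat(sprintf("  E = %.3f bits/s, R = H' - E = %.3f bits/s\n",
                x$equivocation, x$actual_rate))
  invisible(x)
}

#' Speed-up factor equating source bit rates across entropy conditions
#'
#' To present a low-entropy grammar at the bit rate of a high-entropy one
#' while holding entropy per symbol constant, the symbol rate must grow by
#' `h_high / h_low` (from `m2 * H_L = m1 * H_H`). The published endpoints
#' give `4.8 / 2.8 = 1.71` for the XXY design and `4.71 / 3.52 = 1.34` for
#' the aXb design.
#'
#' @param h_high,h_low Entropies in bits/symbol, `h_low > 0`.
#' @return A `speedup_plan`: list with `h_low`, `h_high`, `factor`.
#' @examples
#' speedup_factor(4.8, 2.8)$factor    # 1.714...
#' speedup_factor(4.71, 3.52)$factor  # 1.338...
#' @export
speedup_factor <- function(h_high, h_low) {
  if (!is.finite(h_low) || h_low <= 0)
    stop("h_low must be positive")
  out <- list(h_low = h_low, h_high = h_high, factor = h_high / h_low)
  class(out) <- "speedup_plan"
  out
}

#' @export
print.speedup_plan <- function(x, ...) {
  cat(sprintf("<speedup_plan> factor = H_H / H_L = %.4g / %.4g = %.2f\n",
              x$h_high, x$h_low, x$factor))
  invisible(x)
}

#' Apply a proportional speed-up to a timing schedule
#'
#' Divides every element duration and both pauses by `factor`, so the
#' symbol rate and bit rate of any schedule built from the result are
#' multiplied by exactly `factor`.
#'
#' @param timing A `timing_params`.
#' @param factor Positive speed-up factor (a `speedup_plan` is also accepted).
#' @return A new `timing_params`.
#' @examples
#' apply_speedup(xxy_timing(), 1.71)$within_string_pause  # 50 / 1.71 = 29.24
#' @export
apply_speedup <- function(timing, factor) {
  if (inherits(factor, "speedup_plan")) factor <- factor$factor
  if (!is.finite(factor) || factor <= 0)
    stop("speed-up factor must be positive")
  timing_params(timing$element_durations / factor,
                timing$within_string_pause / factor,
                timing$between_string_pause / factor)
}

#' Export a presentation schedule with onsets and offsets
#'
#' Expands a trial sequence into one row per acoustic event (element or
#' pause) with onset/offset times in ms, suitable for presentation software.
#'
#' @param sequence A `trial_sequence`.
#' @param timing A `timing_params`.
#' @return Data frame with columns `trial_index`, `label`, `onset_ms`,
#'   `offset_ms`.
#' @export
timing_schedule <- function(sequence, timing) {
  roles <- attr(sequence, "roles")
  n <- nrow(sequence)
  rows <- vector("list", n)
  t0 <- 0
  for (i in seq_len(n)) {
    labs <- c(sequence$s1[i], sequence$s2[i], sequence$s3[i])
    durs <- c(timing$element_durations[roles[1]], timing$within_string_pause,
              timing$element_durations[roles[2]], timing$within_string_pause,
              timing$element_durations[roles[3]])
    ev <- c(labs[1], "<pause>", labs[2], "<pause>", labs[3])
    if (i < n) {
      durs <- c(durs, timing$between_string_pause)
      ev <- c(ev, "<pause>")
    }
    off <- t0 + cumsum(durs)
    rows[[i]] <- data.frame(trial_index = sequence$trial_index[i], label = ev,
                            onset_ms = c(t0, off[-length(off)]),
                            offset_ms = off, stringsAsFactors = FALSE)
    t0 <- off[length(off)]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
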