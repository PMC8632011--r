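# shared fixtures, built in code at test time

xxy_fixture <- function() {
  xs <- make_syllables(7, "cv", seed = 1)
  ys <- make_syllables(7, "cv", seed = 2, blocklist = xs)
  list(xs = xs, ys = ys, grammar = build_xxy_grammar(xs, ys))
}

xxy_novel_fixture <- function(fx = xxy_fixture()) {
  pool <- make_syllables(8, "cv", seed = 7, blocklist = c(fx$xs, fx$ys))
  rbind(syllable_inventory(pool[1:4], "X"),
        syllable_inventory(pool[5:8], "Y"))
}

axb_frames <- function() {
  data.frame(a = c("tep", "sot", "rak"), b = c("lut", "jik", "tuf"),
             stringsAsFactors = FALSE)
}

axb_fixture <- function(mode = "low", variant = "L1") {
  xw <- make_syllables(18, "cvcv", seed = 3)
  list(x_words = xw,
       grammar = build_axb_grammar(axb_frames(), xw, mode, variant),
       novel_x = make_syllables(4, "cvcv", seed = 9, blocklist = xw))
}

# independent oracle: positional n-gram entropy by explicit enumeration of
# padded token strings and direct probability tallying
oracle_positional_entropy <- function(strings, probs, n, pos) {
  padded <- cbind("<s>", strings[, 1], strings[, 2], strings[, 3], "</s>")
  tok <- apply(padded[, pos:(pos + n - 1), drop = FALSE], 1, paste,
               collapse = "\r")
  tot <- 0
  for (t in unique(tok)) {
    p <- sum(probs[tok == t])
    if (p > 0) tot <- tot - p * log2(p)
  }
  tot
}

# independent oracle: exact one-sample signed-rank tail probabilities by full
# enumeration of all 2^n sign assignments (n <= 12)
oracle_signed_rank_p <- function(scores, mu) {
  d <- scores - mu
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_le <- mean(v_all <= v_obs + 1e-9)
  p_ge <- mean(v_all >= v_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
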