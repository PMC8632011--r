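---
title: "Entropy, bit rate and encoding mode in artificial grammar learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy, bit rate and encoding mode in artificial grammar learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entrate)
```

## The model

`entrate` operationalizes a channel-capacity account of rule induction.
A learner exposed to a stream of three-symbol strings receives information
at the **source rate**

$$H' = m \cdot H \quad \text{(bits/s)},$$

where $m$ is the average number of symbols per second (averaged over a whole
familiarization phase, pauses included) and $H$ is the input entropy in
bits/symbol. The learner is modelled as a noisy channel with finite capacity
$C = \max(H' - E)$ bits/s, $E$ being the equivocation (information lost to
noise). When $H' \le C$, the input can be encoded with item-level fidelity
(*item-bound generalization*); when $H' > C$, that encoding cannot keep up,
and the learner shifts to a compressed *category-based* encoding that
abstracts over items. The package renders this qualitative claim as a
logistic link: a participant exposed at rate $H'$ adopts category-based
encoding with probability

$$p_{\text{cat}}(H') = \operatorname{logit}^{-1}\!\big(k\,(H' - C)\big),$$

with slope $k$ per (bit/s). The logistic form is the package's choice — the
account itself only requires a monotone transition centred at $C$ — and is
the standard psychometric-function shape for a threshold-like process.

## Input entropy of a finite grammar

Entropy is computed positionally. Each string $s_1 s_2 s_3$ is padded with
begin/end markers; at each of the four bigram positions and three trigram
positions the Shannon entropy (base 2) of the distribution over the distinct
n-gram tokens occupying that position is taken, weighting by string
probability. These are *joint token* entropies, not conditional ones: the aX
position of the low-entropy aXb grammar carries 18 equiprobable aX pairs,
hence $\log_2 18 = 4.17$ bits — the only reading consistent with treating
that position as a unit. Position entropies are averaged within each order,
and

$$H_{\text{total}} = \tfrac{1}{2}(H_{\text{bigram}} + H_{\text{trigram}}).$$

```{r entropy}
xs <- make_syllables(7, "cv", seed = 1)
ys <- make_syllables(7, "cv", seed = 2, blocklist = xs)
grammar_entropy(build_xxy_grammar(xs, ys))

frames <- data.frame(a = c("tep", "sot", "rak"), b = c("lut", "jik", "tuf"))
x_words <- make_syllables(18, "cvcv", seed = 3)
round(grammar_entropy(build_axb_grammar(frames, x_words, "low"))$h_total, 2)
round(grammar_entropy(build_axb_grammar(frames, x_words, "high"))$h_total, 2)
```

One bookkeeping note: for the low-entropy aXb grammar the four bigram
positions are $1.585, 4.170, 4.170, 1.585$ bits, whose mean is $2.877$
($2.88$ at two decimals), while the corresponding mean is sometimes quoted
as $2.86$; the total $H_{\text{total}} = 3.52$ is unaffected, and this
package reports the full-precision mean.

## The two experimental designs

* **XXY**: 7 X-syllables, 7 Y-syllables, a fixed bijection X→Y (so each X
  always takes the same Y), 7 equiprobable strings. Familiarization presents
  each string 4 times per phase over 3 phases (28 trials/phase, 84 total).
  The test battery interleaves three 4-item intermediate tests (one per test
  type) after each familiarization phase and closes with an 8-item final
  test: 20 items, 5 per type. XXY items (familiar or new syllables) are to
  be accepted, X1X2Y items (first two syllables differ) rejected; new-item
  types use syllables fully disjoint from familiarization.
* **aXb**: 3 monosyllabic $a\_b$ frames, 18 bisyllabic X words. Low-entropy:
  each frame takes its own disjoint 6 Xs (18 strings, presented 12 times =
  216 trials); high-entropy: exhaustive crossing (54 strings). Two language
  variants (L1/L2) re-pair the same a/b elements cyclically so each
  variant's grammatical frames are exactly the other's ungrammatical ones.
  The 12-item test crosses the 3 own-language and 3 other-language frames
  with two novel X words (6 accept / 6 reject), testing frame knowledge
  generalized over novel middles.

Timing defaults (`xxy_timing()`, `axb_timing()`): 50 ms within-string and
750 ms between-string pauses for XXY, 100/750 ms for aXb — these pause
values are fixed by the designs — and 350 ms monosyllables / 500 ms
bisyllabic words, which are *package defaults*: only the pause structure and
the speed-up ratios are design-determined, so absolute element durations are
configuration inputs. Between-string pauses are counted once per string
boundary ($n-1$ for $n$ strings). A speed-up divides every duration by the
same factor, which multiplies $m$ and $H'$ by exactly that factor; hence the
rate-matching identity

```{r rate}
g <- build_xxy_grammar(xs, ys)
fam <- generate_familiarization(g, 4, 3, seed = 11)
f <- speedup_factor(4.8, 2.8)$factor
source_rate(fam, apply_speedup(xxy_timing(), f), 2.8)$bits_per_second -
  source_rate(fam, xxy_timing(), 4.8)$bits_per_second
```

holds to machine precision (tested at 1e-9). Whether sped pauses also apply
between *test* trials is left to the caller (speed-ups are applied to
whatever `timing_params` a condition uses); familiarization-only speeding is
the default composition.

## What the synthetic cohorts emulate

`simulate_cohort()` stands in for human participants so that every analysis
stage is testable end to end. Per participant:

* **XXY**: one encoding mode is drawn from $p_{\text{cat}}(H')$.
  Category-based responders apply same-same-different exactly (accept all
  XXY, reject all X1X2Y). Item-bound responders accept familiar XXY at 1.0,
  new-syllable XXY at 0.55 (novel items carry no stored trace, so acceptance
  is near-neutral), familiar-syllable X1X2Y at 0.10 (memory traces of
  familiar syllables occasionally prompt incorrect acceptance), novel X1X2Y
  at 0.02. These profile values are package defaults chosen once so that
  default cohorts reproduce the ordinal pattern of the two rate conditions;
  they are arguments, not constants.
* **aXb**: above capacity, a learner either *overgeneralizes* the a/b
  elements into open categories (probability `overgen_rate = 0.7` given the
  category outcome) — accepting any aXb-shaped string, with acceptance
  decaying by `drift = 0.08` per test trial as the uniform acceptability of
  the test list arouses suspicion — or is left with no usable frame
  knowledge and guesses. Below capacity, a fraction `guess_rate = 0.3`
  fails to learn and guesses; the rest respond veridically. The
  veridical/guess split is what produces the bimodal accuracy distribution
  characteristic of slow-rate nonadjacent-dependency learning.
* All judgments pass through a lapse: with probability $2\varepsilon$
  (default $\varepsilon = 0.05$) a response is a fair coin flip, so
  $\varepsilon$ is the error rate of an otherwise deterministic responder
  and $\varepsilon \to 0.5$ pins every accuracy at chance.
* **Capacity default** $C_0 = 6$ bits/s, slope $k = 2$: the default XXY
  timing yields $H' = 4.45$ bits/s slow and $7.64$ fast, so the default
  capacity sits between the two conditions — the regime the designs were
  built to probe. Whether capacity is a population constant or varies by
  individual is genuinely open; `capacity_sd` (default 0) exposes the
  choice, with 0 recovering the population-constant reading.
* **Covariates** (forward digit span ~ N(6.7, 1.2) truncated to 2–12,
  incidental-memory hits/false alarms ~ Binomial(13, 0.85)/(13, 0.2),
  pattern-recognition percentile ~ N(71.5, 20) clamped to 1–99) are sampled
  independently of responses, mirroring the finding of no reliable
  covariate effects; couplings can be added by post-processing the tidy
  table from `export_tidy_responses()`.

What the generator does **not** emulate: acoustic variability (it emits
timing schedules, not sound), within-session mode switching (one mode per
participant per experiment; the transition is across participants and
conditions), reaction times, fatigue or attention drift, and any
response–covariate dependence. Passing tests therefore certify the
pipeline's statistical machinery and the model's internal logic, not claims
about human data.

## Scoring and statistics

* `empirical_logit(k, n)` = $\log\frac{k + 0.5}{n - k + 0.5}$, the standard
  boundary-safe transform (the 0.5 constants are the usual choice; no other
  constants are implied by the analysis it supports).
* `cohens_d(m1, s1, m2, s2)` uses the equal-weight pooled SD
  $\sqrt{(s_1^2 + s_2^2)/2}$ and $r = d/\sqrt{d^2 + 4}$; this denominator is
  validated by reproducing published effect sizes from their group
  statistics in the test suite.
* `wilcoxon_vs_chance()` drops exact ties with the chance level (the
  standard signed-rank convention), computes the exact two-sided tail for
  $n \le 25$ by convolution over doubled midranks — which stays exact under
  tied ranks, where the textbook no-ties enumeration does not apply — and
  otherwise a normal approximation with continuity and tie corrections.
  Effect size is reported both as $|Z|/\sqrt{n}$ and as the matched
  rank-biserial correlation, since either convention is in circulation.
* `dprime()` applies the log-linear correction (add 0.5 to each count, 1 to
  each denominator) by default, keeping rates off the boundaries; the raw
  (`"none"`) variant is available and documented as boundary-unsafe.
* `positional_acceptance_trend()` compares acceptance over the first and
  last 3 test trials per participant with a one-sided paired t test
  (early > late), the overgeneralization signature; a zero-variance
  difference vector short-circuits to p = 1 (or 0 for a strictly positive
  constant difference) rather than erroring inside `t.test`.

## Parameter recovery

`recover_learner_parameters()` estimates $(C, k, \varepsilon)$ by
maximizing the mode-mixture likelihood of per-participant acceptance counts
(two binomial-product components weighted by $p_{\text{cat}}$), with
log-sum-exp pooling, L-BFGS-B under bounds, and multi-start initialization
(deterministic given a seed). Identifiability is guarded twice: a design
with a single $H'$ level is refused outright, and the fitted model must beat
a rate-independent mixture (the $k \to 0$ limit, in which $C$ drops out) by
a 1-df likelihood-ratio margin, else the fit is flagged non-converged. Wald
standard errors come from the numerical Hessian at the optimum.

`recovery_study()` wraps the full loop — simulate replicate cohorts from
known parameters, refit, summarize. Its default design places participants
at four source rates: the slow XXY schedule's $H'$ times
$\{1, 1.34, 1.71, 1.34 \times 1.71\}$, i.e. the two designs' speed-up
coefficients and their composition. A ladder that brackets the generating
capacity was chosen a priori for the same reason psychometric-function
designs bracket the threshold: levels on one side of $C$ constrain only the
product $k(H' - C)$ and leave the two parameters trading off along a ridge.
Study sizes in the test suite (20 replicate cohorts, 200 participants per
level) complete in well under a minute each and recover the generating
capacity with a median relative error below 10% (typically under 1%).

## Numerical choices and degenerate inputs

* Log base 2 throughout; probability validation at 1e-12 (grammar
  construction) and 1e-9 (entropy input); $0 \log 0 = 0$.
* Display rounding is 2 decimals (1 for the XXY total, matching its printed
  precision); all objects retain full precision and tests compare at 0.01
  or tighter.
* Single-string grammars are legal and have zero entropy everywhere; empty
  grammars, non-bijective XXY pairings, overlapping low-mode X partitions,
  inventory label collisions and undersized novel inventories raise typed
  errors.
* Likelihood probabilities are clamped to $[10^{-12}, 1 - 10^{-12}]$ before
  logs; mixture weights to $10^{-300}$.
* One master seed derives all per-participant streams
  (`derive_seeds()`), so cohorts are byte-identical under regeneration;
  stimulus sampling within a battery is independent across test phases (the
  alternative — reusing item identities across phases — is unspecified in
  the designs this package follows).

## Limitations

* The encoding-mode model is intentionally minimal: logistic link, one mode
  per participant, known mode profiles during recovery. Estimating the
  profiles jointly with $(C, k, \varepsilon)$, or modelling equivocation
  $E$ (accepted as an input, never estimated), is out of scope.
* Mixed-effects inference on the tidy response table is delegated to
  dedicated tools (`lme4`/`lmerTest`); the package exports the table rather
  than re-implementing GLMMs.
* Entropy is defined for finite sets of fixed-length-3 strings; entropy
  rates of recursive grammars and estimation from sampled corpora are
  non-goals.
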