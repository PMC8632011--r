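#' Build a syllable inventory
#'
#' An inventory is a small data frame of stimulus elements sharing one
#' structural role. Roles follow the two grammar designs: `"X"`/`"Y"` are the
#' monosyllables of the XXY repetition grammar, `"a"`/`"b"` the monosyllabic
#' frame elements of the aXb grammar, and `"AXB_X"` its bisyllabic middle
#' words.
#'
#' @param labels Character vector of distinct, nonempty element labels.
#' @param role One of `"X"`, `"Y"`, `"a"`, `"b"`, `"AXB_X"`.
#' @return A data frame with columns `label`, `role`, `n_syllables`.
#' @examples
#' syllable_inventory(c("ke:", "da:", "mo:"), "X")
#' @export
syllable_inventory <- function(labels, role = c("X", "Y", "a", "b", "AXB_X")) {
  role <- match.arg(role)
  labels <- as.character(labels)
  if (length(labels) == 0L || any(is.na(labels)) || any(!nzchar(labels)))
    stop("inventory labels must be nonempty strings")
  if (anyDuplicated(labels))
    stop("duplicate labels within an inventory")
  data.frame(
    label = labels,
    role = role,
    n_syllables = if (role == "AXB_X") 2L else 1L,
    stringsAsFactors = FALSE
  )
}

#' Generate nonsense syllables or bisyllabic words
#'
#' A syllable factory for stimulus sets when no fixed list is supplied.
#' Monosyllables are consonant + long vowel (e.g. "ke:"), the shape used for
#' X/Y/a/b elements; bisyllabic words are CVCV (e.g. "naspu"), the shape of
#' aXb middle words. Candidates are enumerated from the consonant and vowel
#' sets, any blocklisted items (e.g. real words) are removed, and `n` items
#' are drawn without replacement.
#'
#' @param n Number of items to generate.
#' @param shape `"cv"` for monosyllables, `"cvcv"` for bisyllabic words.
#' @param consonants,vowels Character vectors to build syllables from;
#'   defaults are Dutch-like sets.
#' @param blocklist Labels that must not be produced (default none).
#' @param seed Integer seed controlling the draw.
#' @return Character vector of `n` distinct labels.
#' @examples
#' make_syllables(7, "cv", seed = 1)
#' @export
make_syllables <- function(n,
                           shape = c("cv", "cvcv"),
                           consonants = c("b", "d", "f", "g", "h", "j", "k",
                                          "l", "m", "n", "p", "r", "s", "t",
                                          "v", "w", "z"),
                           vowels = NULL,
                           blocklist = character(),
                           seed = 1) {
  shape <- match.arg(shape)
  if (is.null(vowels))
    vowels <- if (shape == "cv") c("a:", "e:", "i:", "o:", "u:", "y:")
              else c("a", "e", "i", "o", "u", "y")
  pool <- if (shape == "cv") {
    as.vector(outer(consonants, vowels, paste0))
  } else {
    syl <- as.vector(outer(consonants, vowels, paste0))
    as.vector(outer(syl, syl, paste0))
  }
  pool <- setdiff(pool, blocklist)
  if (length(pool) < n)
    stop("candidate pool too small: ", length(pool), " items for n = ", n)
  set.seed(seed)
  sample(pool, n)
}

# internal: coerce a character vector or inventory data frame to an inventory
as_inventory <- function(x, role) {
  if (is.character(x)) return(syllable_inventory(x, role))
  stopifnot(is.data.frame(x), all(c("label", "role") %in% names(x)))
  if (!all(x$role == role))
    stop("inventory role mismatch: expected ", role)
  syllable_inventory(x$label, role)
}

new_grammar_spec <- function(kind, inventories, strings, roles,
                             variant = "NA", name = "", extra = list()) {
  if (nrow(strings) == 0L) stop("empty grammar: no strings")
  if (abs(sum(strings$prob) - 1) > 1e-12)
    stop("string probabilities must sum to 1")
  if (anyDuplicated(inventories$label))
    stop("inventory collision: duplicate labels across inventories")
  spec <- c(list(kind = kind, inventories = inventories, strings = strings,
                 roles = roles, variant = variant, name = name), extra)
  class(spec) <- "grammar_spec"
  spec
}

#' @export
print.grammar_spec <- function(x, ...) {
  cat(sprintf("<grammar_spec> %s grammar%s: %d strings, %d elements%s\n",
              x$kind,
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              nrow(x$strings), nrow(x$inventories),
              if (x$variant != "NA") paste0(" (", x$variant, ")") else ""))
  utils::head(x$strings, 6L)
}

#' Build an XXY repetition grammar
#'
#' Constructs the low-entropy repetition design: each string is a twice
#' repeated X syllable followed by the Y syllable uniquely paired with that X
#' (a fixed bijection, so the grammar has as many strings as X syllables, all
#' equiprobable).
#'
#' @param x_inventory,y_inventory Character vectors (or inventories from
#'   [syllable_inventory()]) of equal length with disjoint labels.
#' @param pairing Integer permutation mapping the i-th X to
#'   `y_inventory[pairing[i]]`; default is identity order.
#' @param name Optional grammar name.
#' @return A `grammar_spec` with `kind = "XXY"`.
#' @examples
#' g <- build_xxy_grammar(make_syllables(7, seed = 1), make_syllables(7, seed = 2))
#' nrow(g$strings)  # 7
#' @export
build_xxy_grammar <- function(x_inventory, y_inventory, pairing = NULL,
                              name = "xxy") {
  xs <- as_inventory(x_inventory, "X")
  ys <- as_inventory(y_inventory, "Y")
  if (nrow(xs) != nrow(ys))
    stop("X and Y inventories must have equal size")
  if (length(intersect(xs$label, ys$label)))
    stop("inventory collision: X and Y inventories share labels")
  n <- nrow(xs)
  if (is.null(pairing)) pairing <- seq_len(n)
  if (length(pairing) != n || !setequal(pairing, seq_len(n)))
    stop("pairing error: pairing must be a bijection X -> Y")
  strings <- data.frame(
    s1 = xs$label, s2 = xs$label, s3 = ys$label[pairing],
    prob = rep(1 / n, n), stringsAsFactors = FALSE
  )
  new_grammar_spec("XXY", rbind(xs, ys), strings,
                   roles = c("X", "X", "Y"), name = name)
}

#' Build an aXb nonadjacent-dependency grammar
#'
#' Three `a_b` frames are combined with 18 bisyllabic X words. In `"low"`
#' (low-entropy) mode each frame takes its own disjoint subset of 6 X words
#' (18 equiprobable strings); in `"high"` mode every frame combines with all
#' 18 X words (54 equiprobable strings). Two language variants share the same
#' a/b elements but pair them differently: the L2 pairing is a cyclic
#' re-pairing of the L1 frames, so every L1 `a_i__b_i` pair is ungrammatical
#' in L2 and vice versa. The foil frames (the other variant's pairs) are kept
#' on the spec for test construction.
#'
#' @param frames Data frame with columns `a`, `b` (3 rows), giving the L1
#'   frame pairing.
#' @param x_words Character vector of 18 distinct bisyllabic X words.
#' @param mode `"low"` (3 frames x 6 Xs) or `"high"` (3 frames x 18 Xs).
#' @param variant `"L1"` or `"L2"`.
#' @param x_assignment For `"low"` mode, a list of three disjoint index sets
#'   partitioning `seq_along(x_words)` into the per-frame subsets; default is
#'   consecutive blocks of 6.
#' @param name Optional grammar name.
#' @return A `grammar_spec` with `kind = "AXB"`, carrying `frames` (the
#'   variant's own pairs) and `foil_frames` (the other variant's pairs).
#' @examples
#' fr <- data.frame(a = c("tep", "sot", "rak"), b = c("lut", "jik", "tuf"))
#' g <- build_axb_grammar(fr, make_syllables(18, "cvcv", seed = 3))
#' nrow(g$strings)  # 18
#' @export
build_axb_grammar <- function(frames, x_words,
                              mode = c("low", "high"),
                              variant = c("L1", "L2"),
                              x_assignment = NULL,
                              name = "axb") {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  frames <- as.data.frame(frames, stringsAsFactors = FALSE)
  if (!all(c("a", "b") %in% names(frames)) || nrow(frames) != 3L)
    stop("arity error: exactly 3 (a, b) frames are required")
  x_words <- as.character(x_words)
  if (length(x_words) != 18L || anyDuplicated(x_words))
    stop("18 distinct X words are required")

  # L2 re-pairs the same a/b elements by a cyclic shift of the b column,
  # guaranteeing the L1/L2 pair sets are disjoint
  l1 <- data.frame(a = frames$a, b = frames$b, stringsAsFactors = FALSE)
  l2 <- data.frame(a = frames$a, b = frames$b[c(2L, 3L, 1L)],
                   stringsAsFactors = FALSE)
  own <- if (variant == "L1") l1 else l2
  foil <- if (variant == "L1") l2 else l1

  if (mode == "low") {
    if (is.null(x_assignment))
      x_assignment <- split(seq_len(18L), rep(1:3, each = 6L))
    if (length(x_assignment) != 3L ||
        any(lengths(x_assignment) != 6L) ||
        anyDuplicated(unlist(x_assignment)) ||
        !setequal(unlist(x_assignment), seq_len(18L)))
      stop("partition error: x_assignment must split the 18 X words into three disjoint sets of 6")
    rows <- do.call(rbind, lapply(1:3, function(i) {
      data.frame(s1 = own$a[i], s2 = x_words[x_assignment[[i]]],
                 s3 = own$b[i], stringsAsFactors = FALSE)
    }))
  } else {
    rows <- do.call(rbind, lapply(1:3, function(i) {
      data.frame(s1 = own$a[i], s2 = x_words, s3 = own$b[i],
                 stringsAsFactors = FALSE)
    }))
  }
  rows$prob <- 1 / nrow(rows)

  inv <- rbind(syllable_inventory(own$a, "a"),
               syllable_inventory(own$b, "b"),
               syllable_inventory(x_words, "AXB_X"))
  new_grammar_spec("AXB", inv, rows, roles = c("a", "AXB_X", "b"),
                   variant = variant, name = name,
                   extra = list(mode = mode, frames = own, foil_frames = foil))
}

new_trial_sequence <- function(df, roles, seed) {
  rownames(df) <- NULL
  attr(df, "roles") <- roles
  attr(df, "seed") <- seed
  class(df) <- c("trial_sequence", "data.frame")
  df
}

#' Generate a familiarization sequence
#'
#' Each familiarization phase presents every grammar string exactly
#' `repetitions` times, in a seeded random order, with the same string
#' multiset in every phase (so input entropy is constant across phases).
#'
#' @param spec A `grammar_spec`.
#' @param repetitions Times each string occurs per phase.
#' @param phases Number of familiarization phases.
#' @param seed Integer seed; the same seed reproduces the identical order.
#' @return A `trial_sequence` data frame with columns `phase`, `trial_index`,
#'   `s1`, `s2`, `s3`, `is_test`, `test_type`, `correct_answer`.
#' @examples
#' g <- build_xxy_grammar(make_syllables(7, seed = 1), make_syllables(7, seed = 2))
#' fam <- generate_familiarization(g, repetitions = 4, phases = 3, seed = 11)
#' table(fam$phase)  # 28 trials per phase
#' @export
generate_familiarization <- function(spec, repetitions, phases, seed) {
  stopifnot(inherits(spec, "grammar_spec"))
  if (repetitions < 1L || phases < 1L)
    stop("repetitions and phases must be >= 1")
  base <- spec$strings[rep(seq_len(nrow(spec$strings)), repetitions),
                       c("s1", "s2", "s3")]
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_len(phases), function(ph) {
    ord <- sample.int(nrow(base))
    cbind(data.frame(phase = ph), base[ord, , drop = FALSE])
  }))
  out$trial_index <- seq_len(nrow(out))
  out$is_test <- FALSE
  out$test_type <- NA_character_
  out$correct_answer <- NA_character_
  new_trial_sequence(out[, c("phase", "trial_index", "s1", "s2", "s3",
                             "is_test", "test_type", "correct_answer")],
                     roles = spec$roles, seed = seed)
}

#' Generate a yes/no test battery
#'
#' For an XXY grammar: three intermediate test phases of 4 items (one per
#' test type) plus a final phase of 8 (two per type), 20 items total. The
#' four types are familiar-syllable XXY and new-syllable XXY (correct answer
#' accept) and familiar-syllable X1X2Y and new-syllable X1X2Y, whose first
#' two syllables differ (correct answer reject). New-syllable items use only
#' syllables disjoint from the familiarization inventory.
#'
#' For an aXb grammar: each of the variant's 3 frames and each of the other
#' variant's 3 (foil) frames is combined with two novel X words, giving 6
#' grammatical (accept) and 6 ungrammatical (reject) items in one randomized
#' phase; every test item carries an X absent from familiarization.
#'
#' @param spec A `grammar_spec`.
#' @param novel_inventory For XXY, a data frame of novel `"X"` and `"Y"`
#'   syllables (rbind two [syllable_inventory()] calls); for AXB, a character
#'   vector (or `"AXB_X"` inventory) of novel X words, of which two are used.
#' @param seed Integer seed for item sampling and within-phase order.
#' @return A `test_battery` data frame with columns `phase`, `item_index`,
#'   `s1`, `s2`, `s3`, `test_type`, `correct_answer`.
#' @examples
#' g <- build_xxy_grammar(make_syllables(7, seed = 1), make_syllables(7, seed = 2))
#' nov <- rbind(syllable_inventory(make_syllables(4, seed = 5), "X"),
#'              syllable_inventory(make_syllables(4, seed = 6), "Y"))
#' nov <- nov[!nov$label %in% g$inventories$label, ]
#' bat <- generate_test_battery(g, nov, seed = 42)
#' table(bat$test_type)
#' @export
generate_test_battery <- function(spec, novel_inventory, seed) {
  stopifnot(inherits(spec, "grammar_spec"))
  set.seed(seed)
  if (spec$kind == "XXY") {
    battery <- xxy_test_battery(spec, novel_inventory)
  } else {
    battery <- axb_test_battery(spec, novel_inventory)
  }
  attr(battery, "roles") <- spec$roles
  attr(battery, "kind") <- spec$kind
  attr(battery, "variant") <- spec$variant
  attr(battery, "seed") <- seed
  class(battery) <- c("test_battery", "data.frame")
  battery
}

xxy_test_battery <- function(spec, novel_inventory) {
  stopifnot(is.data.frame(novel_inventory))
  nov_x <- novel_inventory$label[novel_inventory$role == "X"]
  nov_y <- novel_inventory$label[novel_inventory$role == "Y"]
  if (length(intersect(novel_inventory$label, spec$inventories$label)))
    stop("novel inventory must be disjoint from the familiarization inventory")
  if (length(nov_x) < 2L || length(nov_y) < 1L)
    stop("inventory-size error: need at least 2 novel X and 1 novel Y syllables")
  fam_x <- spec$inventories$label[spec$inventories$role == "X"]
  fam_y <- spec$inventories$label[spec$inventories$role == "Y"]

  one_item <- function(type) {
    s <- switch(type,
      FAM_XXY = {
        row <- spec$strings[sample.int(nrow(spec$strings), 1L), ]
        c(row$s1, row$s2, row$s3)
      },
      NEW_XXY = {
        x <- sample(nov_x, 1L)
        c(x, x, sample(nov_y, 1L))
      },
      FAM_X1X2Y = c(sample(fam_x, 2L), sample(fam_y, 1L)),
      NEW_X1X2Y = c(sample(nov_x, 2L), sample(nov_y, 1L))
    )
    data.frame(s1 = s[1], s2 = s[2], s3 = s[3], test_type = type,
               correct_answer = if (type %in% c("FAM_XXY", "NEW_XXY"))
                 "accept" else "reject",
               stringsAsFactors = FALSE)
  }
  types <- c("FAM_XXY", "NEW_XXY", "FAM_X1X2Y", "NEW_X1X2Y")
  out <- do.call(rbind, lapply(1:4, function(ph) {
    reps <- if (ph == 4L) 2L else 1L
    items <- do.call(rbind, lapply(rep(types, reps), one_item))
    items <- items[sample.int(nrow(items)), , drop = FALSE]
    cbind(data.frame(phase = ph), items)
  }))
  out$item_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("phase", "item_index", "s1", "s2", "s3", "test_type",
          "correct_answer")]
}

axb_test_battery <- function(spec, novel_inventory) {
  nov <- if (is.data.frame(novel_inventory)) novel_inventory$label
         else as.character(novel_inventory)
  if (length(intersect(nov, spec$inventories$label)))
    stop("novel X words must be disjoint from the familiarization inventory")
  if (length(nov) < 2L)
    stop("inventory-size error: need at least 2 novel X words")
  nov <- sample(nov, 2L)
  mk <- function(frames, type, answer) {
    do.call(rbind, lapply(seq_len(nrow(frames)), function(i) {
      data.frame(s1 = frames$a[i], s2 = nov, s3 = frames$b[i],
                 test_type = type, correct_answer = answer,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- rbind(mk(spec$frames, "AXB_GRAMMATICAL", "accept"),
               mk(spec$foil_frames, "AXB_UNGRAMMATICAL", "reject"))
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  out <- cbind(data.frame(phase = 1L), out)
  out$item_index <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("phase", "item_index", "s1", "s2", "s3", "test_type",
          "correct_answer")]
}

#' Read a grammar from a YAML/JSON config
#'
#' Config keys: `kind` (`"XXY"` or `"AXB"`) plus, for XXY, `x_inventory` and
#' `y_inventory` (and optional `pairing`); for AXB, `frames` (lists with `a`,
#' `b`), `x_words`, `mode`, `variant`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `grammar_spec`.
#' @export
grammar_from_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required to read JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml is required to read YAML configs")
    yaml::read_yaml(path)
  }
  kind <- toupper(cfg$kind)
  if (kind == "XXY") {
    build_xxy_grammar(unlist(cfg$x_inventory), unlist(cfg$y_inventory),
                      pairing = cfg$pairing,
                      name = cfg$name %||% "xxy")
  } else if (kind == "AXB") {
    frames <- as.data.frame(do.call(rbind, lapply(cfg$frames, function(f)
      c(a = f$a, b = f$b))), stringsAsFactors = FALSE)
    build_axb_grammar(frames, unlist(cfg$x_words),
                      mode = tolower(cfg$mode %||% "low"),
                      variant = cfg$variant %||% "L1",
                      name = cfg$name %||% "axb")
  } else stop("unknown grammar kind: ", cfg$kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive reproducible per-participant seeds from a master seed
#'
#' One master seed spawns an arbitrary number of independent participant
#' streams, so whole cohorts are reproducible while participants remain
#' independently randomized.
#'
#' @param master_seed Integer master seed.
#' @param n Number of seeds to derive.
#' @return Integer vector of `n` seeds.
#' @export
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max, n)
}
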