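test_that("XXY grammar has one equiprobable string per X, with its paired Y", {
  fx <- xxy_fixture()
  g <- fx$grammar
  expect_s3_class(g, "grammar_spec")
  expect_equal(nrow(g$strings), 7)
  expect_equal(g$strings$prob, rep(1 / 7, 7))
  expect_true(all(g$strings$s1 == g$strings$s2))
  expect_true(all(g$strings$s3 %in% fx$ys))
  # fixed bijection: 7 distinct XY bigrams
  expect_equal(anyDuplicated(paste(g$strings$s1, g$strings$s3)), 0L)

  # degenerate single-string grammar
  g1 <- build_xxy_grammar("ba:", "mi:")
  expect_equal(nrow(g1$strings), 1)
  expect_equal(g1$strings$prob, 1)
})

test_that("XXY construction rejects bad inventories and pairings", {
  fx <- xxy_fixture()
  expect_error(build_xxy_grammar(fx$xs, c(fx$ys[-1], fx$xs[1])),
               "collision")
  expect_error(build_xxy_grammar(fx$xs, fx$ys[1:5]), "equal size")
  expect_error(build_xxy_grammar(fx$xs, fx$ys, pairing = rep(1L, 7)),
               "pairing")
})

test_that("aXb grammar sizes and L1/L2 pairings are as designed", {
  low <- axb_fixture("low")$grammar
  high <- axb_fixture("high")$grammar
  expect_equal(nrow(low$strings), 18)
  expect_equal(low$strings$prob, rep(1 / 18, 18))
  expect_equal(nrow(high$strings), 54)
  expect_equal(high$strings$prob, rep(1 / 54, 54))

  # low mode: each X word occurs in exactly one frame's string set
  x_per_frame <- table(low$strings$s2, low$strings$s1)
  expect_true(all(rowSums(x_per_frame > 0) == 1))

  # L1 and L2 share no (a, b) pair, in either grammar's own/foil split
  l1 <- axb_fixture("low", "L1")$grammar
  l2 <- axb_fixture("low", "L2")$grammar
  pair <- function(fr) paste(fr$a, fr$b)
  expect_length(intersect(pair(l1$frames), pair(l2$frames)), 0)
  expect_setequal(pair(l1$foil_frames), pair(l2$frames))
  expect_setequal(pair(l2$foil_frames), pair(l1$frames))
})

test_that("aXb construction rejects bad partitions and frame counts", {
  fr <- axb_frames()
  xw <- make_syllables(18, "cvcv", seed = 3)
  expect_error(build_axb_grammar(fr[1:2, ], xw), "arity")
  bad <- split(c(1:6, 4:9, 10:15), rep(1:3, each = 6))
  expect_error(build_axb_grammar(fr, xw, x_assignment = bad), "partition")
  expect_error(build_axb_grammar(fr, xw[c(1:17, 1)]), "18 distinct")
})

test_that("familiarization phases contain the full string multiset, reproducibly", {
  fx <- xxy_fixture()
  fam <- generate_familiarization(fx$grammar, repetitions = 4, phases = 3,
                                  seed = 11)
  expect_equal(nrow(fam), 84)
  expect_equal(unname(table(fam$phase)), rep(28L, 3), ignore_attr = TRUE)
  expect_equal(fam$trial_index, 1:84)
  for (ph in 1:3) {
    counts <- table(paste(fam$s1, fam$s2, fam$s3)[fam$phase == ph])
    expect_equal(unname(counts), rep(4L, 7), ignore_attr = TRUE)
  }

  # byte-identical regeneration under the same seed
  fam2 <- generate_familiarization(fx$grammar, 4, 3, seed = 11)
  expect_identical(serialize(fam, NULL), serialize(fam2, NULL))
  fam3 <- generate_familiarization(fx$grammar, 4, 3, seed = 12)
  expect_false(identical(fam$s1, fam3$s1))

  # aXb familiarization: 18 strings x 12 repetitions
  ax <- axb_fixture()
  fam_a <- generate_familiarization(ax$grammar, 12, 1, seed = 4)
  expect_equal(nrow(fam_a), 216)

  # degenerate single permutation
  fam1 <- generate_familiarization(fx$grammar, 1, 1, seed = 2)
  expect_equal(nrow(fam1), 7)
  expect_error(generate_familiarization(fx$grammar, 0, 1, seed = 2), ">= 1")
})

test_that("XXY test battery has 20 items, 5 per type, with disjoint novel items", {
  fx <- xxy_fixture()
  nov <- xxy_novel_fixture(fx)
  bat <- generate_test_battery(fx$grammar, nov, seed = 42)
  expect_equal(nrow(bat), 20)
  expect_equal(unname(table(bat$test_type)), rep(5L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(bat$phase)), c(4L, 4L, 4L, 8L),
               ignore_attr = TRUE)
  expect_equal(sort(unique(bat$correct_answer[grepl("XXY$",
                                                    bat$test_type)])),
               "accept")
  expect_equal(sort(unique(bat$correct_answer[grepl("X1X2Y$",
                                                    bat$test_type)])),
               "reject")

  # X1X2Y items really have differing first syllables; XXY items repeat
  x1x2 <- bat[grepl("X1X2Y", bat$test_type), ]
  expect_true(all(x1x2$s1 != x1x2$s2))
  xxy <- bat[grepl("^(FAM|NEW)_XXY$", bat$test_type), ]
  expect_true(all(xxy$s1 == xxy$s2))

  # NEW_* items share no syllable with the familiarization inventory
  new_items <- bat[grepl("^NEW", bat$test_type), ]
  used <- unique(c(new_items$s1, new_items$s2, new_items$s3))
  expect_length(intersect(used, fx$grammar$inventories$label), 0)

  expect_identical(generate_test_battery(fx$grammar, nov, seed = 42), bat)
  expect_error(generate_test_battery(fx$grammar, nov[1:2, ], seed = 1),
               "inventory-size")
})

test_that("aXb battery is 12 items, 6 accept / 6 reject, all with novel X", {
  ax <- axb_fixture("low", "L1")
  bat <- generate_test_battery(ax$grammar, ax$novel_x, seed = 5)
  expect_equal(nrow(bat), 12)
  expect_equal(sum(bat$correct_answer == "accept"), 6)
  expect_equal(sum(bat$correct_answer == "reject"), 6)
  expect_length(intersect(bat$s2, ax$x_words), 0)
  expect_equal(length(unique(bat$s2)), 2)

  # L1/L2 symmetry: same item strings, inverted accept/reject partition
  ax2 <- axb_fixture("low", "L2")
  bat2 <- generate_test_battery(ax2$grammar, ax2$novel_x, seed = 5)
  key <- function(b) paste(b$s1, b$s2, b$s3)
  expect_setequal(key(bat), key(bat2))
  m <- match(key(bat), key(bat2))
  expect_true(all(bat$correct_answer != bat2$correct_answer[m]))
})

test_that("grammar configs round-trip through YAML", {
  skip_if_not_installed("yaml")
  fx <- xxy_fixture()
  cfg <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(kind = "XXY", x_inventory = fx$xs,
                        y_inventory = fx$ys), cfg)
  g <- grammar_from_config(cfg)
  expect_equal(g$strings, fx$grammar$strings)
  unlink(cfg)
})
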