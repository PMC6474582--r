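# Logic task enumeration, canonicalization and detection.

test_that("catalog sizes match the brute-force enumerator", {
  expect_equal(nrow(logic_tasks(1)), 1L)
  expect_equal(nrow(logic_tasks(2)), 9L)
  expect_equal(nrow(logic_tasks(3)), 77L)
  # independent oracle over all 2^(2^k) functions
  expect_equal(oracle_task_count(1), 1L)
  expect_equal(oracle_task_count(2), 9L)
  expect_equal(nrow(CT3), oracle_task_count(3))
})

test_that("the logic-9 names and basic set are present", {
  expect_setequal(CT2$name,
                  c("NOT", "NAND", "AND", "ORN", "OR", "ANDN", "NOR",
                    "XOR", "EQU"))
  expect_setequal(CT3$name[CT3$basic], c("XOR", "EQU"))
  expect_true(all(CT2$bits %in% CT3$bits))
})

test_that("enumeration is deterministic, deduplicated and canonical", {
  expect_identical(logic_tasks(3), CT3)
  expect_false(any(duplicated(CT3$bits)))
  # every stored table is its own canonical (lexicographically minimal)
  # representative under input permutation, and is not constant
  for (i in sample(nrow(CT3), 20)) {
    tt <- CT3$truth_table[[i]]
    expect_false(all(tt) || !any(tt))
    expect_identical(mutscape:::tt_canonical_key(tt, CT3$arity[i]),
                     CT3$bits[i])
  }
  expect_true(all(diff(order(CT3$arity, CT3$bits)) == 1))
})

test_that("max_inputs outside 1..3 is rejected", {
  expect_error(logic_tasks(0), "max_inputs")
  expect_error(logic_tasks(4), "max_inputs")
  expect_error(logic_tasks(NA), "max_inputs")
})

test_that("detection credits tasks from their target words", {
  nand <- word_not(word_and(INS[1], INS[2]))
  expect_identical(detect_tasks(nand, INS, CT3),
                   CT3$id[CT3$name == "NAND"])
  xor <- word_xor(INS[1], INS[2])
  equ <- word_not(xor)
  ids <- detect_tasks(c(equ, xor), INS, CT3)
  expect_setequal(CT3$name[match(ids, CT3$id)], c("XOR", "EQU"))
  # echoing an input is no task (echo excluded from the catalog)
  expect_length(detect_tasks(INS[1], INS, CT3), 0)
  expect_error(detect_tasks(nand, integer(), CT3), "non-empty")
})

test_that("detection is invariant under permutation of the input tuple", {
  for (nm in c("AND", "ANDN", "ORN", "EQU")) {
    i <- match(nm, CT3$name)
    tt <- CT3$truth_table[[i]]
    w12 <- mutscape:::apply_truth_table(tt, INS[c(1, 2)])
    w21 <- mutscape:::apply_truth_table(tt, INS[c(2, 1)])
    expect_identical(detect_tasks(w12, INS, CT3), CT3$id[i])
    expect_identical(detect_tasks(w21, INS, CT3), CT3$id[i])
  }
})

test_that("a collision-free input triple separates all tasks", {
  tg <- task_targets(CT3, INS)
  # no word belongs to two tasks, and no target equals a plain input
  per_word <- split(tg$id, tg$word)
  expect_true(all(vapply(per_word, function(x) length(unique(x)),
                         integer(1)) == 1))
  expect_false(any(tg$word %in% INS))
})

test_that("catalog JSON export round-trips ids and truth tables", {
  js <- write_task_catalog_json(CT2)
  rec <- jsonlite::fromJSON(js)
  expect_equal(nrow(rec), 9)
  expect_equal(rec$id, CT2$id)
  expect_equal(rec$truth_table, CT2$bits)
  path <- withr::local_tempfile(fileext = ".json")
  write_task_catalog_json(CT3, path)
  expect_equal(nrow(jsonlite::fromJSON(path)), 77)
})
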