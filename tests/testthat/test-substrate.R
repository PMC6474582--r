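# Virtual CPU execution, phenotype evaluation and site knockouts.

test_that("execution is deterministic and bounded", {
  set.seed(1)
  for (i in 1:20) {
    g <- paste0(sample(letters, 50, TRUE), collapse = "")
    r1 <- execute_genome(g, INS)
    r2 <- execute_genome(g, INS)
    expect_identical(r1, r2)
    expect_lte(length(r1$outputs), 50) # halts within one pass
  }
})

test_that("an all-inert genome emits nothing and does not replicate", {
  r <- execute_genome(strrep("a", 30), INS)
  expect_length(r$outputs, 0)
  expect_false(r$replicated)
  ph <- evaluate_phenotype(strrep("a", 30), INS, CT3)
  expect_false(ph$viable)
  expect_false(any(ph$tasks))
})

test_that("constructed task genomes execute to their phenotype", {
  ph <- evaluate_phenotype(NAND_FIXTURE$genome, INS, CT3)
  expect_true(ph$viable)
  expect_identical(names(ph$tasks)[ph$tasks], "NAND")
  r <- execute_genome(NAND_FIXTURE$genome, INS)
  expect_true(r$replicated)
  expect_true(word_not(word_and(INS[1], INS[2])) %in% r$outputs)
  ph2 <- evaluate_phenotype(XE_FIXTURE$genome, INS, CT3)
  expect_setequal(names(ph2$tasks)[ph2$tasks], c("XOR", "EQU"))
})

test_that("the alphabet has 26 symbols with the designated roles", {
  is <- instruction_set()
  expect_equal(nrow(is), 26)
  expect_identical(is$symbol, letters)
  expect_true(all(c("nand", "io-load", "io-emit", "repro") %in% is$name))
  expect_equal(is$name[is$symbol == "a"], "nop-a")
})

test_that("knockout replaces one site with the inert symbol", {
  g <- XE_FIXTURE$genome
  l <- genome_length(g)
  ko <- knockout_site(g, 5)
  expect_equal(genome_length(ko), l)
  expect_identical(substr(unclass(ko), 5, 5), "a")
  expect_identical(substr(unclass(ko), 1, 4), substr(unclass(g), 1, 4))
  # knockout of an already-inert site is the identity
  inert_at <- which(strsplit(unclass(g), "")[[1]] == "a")[1]
  expect_identical(unclass(knockout_site(g, inert_at)), unclass(g))
  expect_error(knockout_site(g, 0), "site")
  expect_error(knockout_site(g, l + 1), "site")
})

test_that("knocking out the replication instruction kills the organism", {
  g <- NAND_FIXTURE$genome
  y_at <- which(strsplit(unclass(g), "")[[1]] == "y")
  ph <- evaluate_phenotype(knockout_site(g, y_at), INS, CT3)
  expect_false(ph$viable)
  expect_false(any(ph$tasks)) # non-viable implies no tasks
})

test_that("classify_sites performs l knockouts and partitions sites", {
  cl <- classify_sites(NAND_FIXTURE$genome, INS, CT3)
  expect_equal(nrow(cl), genome_length(NAND_FIXTURE$genome))
  expect_true(all(cl$label %in% c("none", "NAND", "replication")))
  # labels agree with the fixture's constructed ground truth
  m <- NAND_FIXTURE$site_map
  expect_identical(cl$label[m$role == "functional"],
                   m$task[m$role == "functional"])
  expect_true(all(cl$label[m$role == "none"] == "none"))
  expect_error(classify_sites(strrep("a", 20), INS, CT3), "non-viable")
})

test_that("input triples are rejected until bit-columns cover all patterns", {
  w <- survey_inputs(seed = 5)
  expect_length(w, 3)
  expect_true(mutscape:::input_patterns_covered(w))
  # a degenerate triple fails the cover test
  expect_false(mutscape:::input_patterns_covered(c(0L, 0L, 0L)))
})
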