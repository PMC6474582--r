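# Per-site entropy and task discovery / performance counters.

test_that("entropy of degenerate and hand-computed populations", {
  # clonal population: zero everywhere
  p <- per_site_entropy(rep("abcabc", 7))
  expect_true(all(p$entropy == 0))
  expect_equal(mean_entropy(p), 0)
  # two equal-frequency genotypes differing at one site: 1 bit there
  p2 <- per_site_entropy(c("aaaa", "aaaa", "abaa", "abaa"))
  expect_equal(p2$entropy, c(0, 1, 0, 0))
  # three-genotype mixture, hand-computed at site 1: f = (.5, .25, .25)
  p3 <- per_site_entropy(c("ax", "ax", "bx", "cx"))
  expect_equal(p3$entropy[1], -(0.5 * log2(0.5) + 2 * 0.25 * log2(0.25)))
  expect_equal(p3$entropy[2], 0)
  expect_error(per_site_entropy(character()), "non-empty")
})

test_that("entropy approaches log2(26) for uniform random populations", {
  set.seed(42)
  pop <- vapply(1:3000, function(i) {
    paste0(sample(letters, 5, TRUE), collapse = "")
  }, character(1))
  p <- per_site_entropy(pop)
  expect_true(all(abs(p$entropy - log2(26)) < 0.05))
  expect_true(all(p$entropy <= log2(26)))
})

test_that("mean entropy is invariant under a uniform site permutation", {
  set.seed(8)
  pop <- vapply(1:50, function(i) {
    paste0(sample(letters[1:5], 8, TRUE), collapse = "")
  }, character(1))
  perm <- sample(8)
  pop2 <- vapply(pop, function(g) {
    paste0(strsplit(g, "")[[1]][perm], collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_equal(mean_entropy(per_site_entropy(pop)),
               mean_entropy(per_site_entropy(pop2)))
})

test_that("the non-ephemeral threshold reproduces the printed instance", {
  expect_equal(non_ephemeral_threshold(3600, 0.001), 4L)
  expect_equal(non_ephemeral_threshold(400, 0.001), 1L)
  # strictly exceeding: an exact integer product still needs one more
  expect_equal(non_ephemeral_threshold(4000, 0.001), 5L)
  expect_error(non_ephemeral_threshold(3600, 0), "threshold")
})

test_that("discovery requires 4 of 3600 and is monotone", {
  st <- character()
  st <- update_task_discovery(st, c(NAND = 3L), 3600)
  expect_length(st, 0)
  st <- update_task_discovery(st, c(NAND = 4L), 3600)
  expect_identical(st, "NAND")
  # dropping back to zero performers does not un-discover
  st <- update_task_discovery(st, c(NAND = 0L, XOR = 5L), 3600)
  expect_setequal(st, c("NAND", "XOR"))
})

test_that("discovery is monotone under arbitrary count sequences", {
  set.seed(13)
  tasks <- paste0("T", 1:12)
  st <- character()
  sizes <- integer()
  for (i in 1:60) {
    counts <- stats::setNames(rpois(12, 2), tasks)
    st <- update_task_discovery(st, counts, 1000)
    sizes <- c(sizes, length(st))
  }
  expect_true(all(diff(sizes) >= 0))
  expect_lte(length(st), length(tasks))
})

test_that("performance counts non-ephemeral tasks and never exceeds discovery", {
  counts <- c(XOR = 3500L, EQU = 3400L, NAND = 2L)
  expect_equal(task_performance_count(counts, 3600), 2L)
  expect_equal(task_performance_count(c(A = 0L, B = 0L), 3600), 0L)
  set.seed(5)
  st <- character()
  for (i in 1:40) {
    counts <- stats::setNames(rpois(6, 1.5), paste0("T", 1:6))
    st <- update_task_discovery(st, counts, 500)
    perf <- task_performance_count(counts, 500)
    expect_lte(perf, length(st))
  }
})
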