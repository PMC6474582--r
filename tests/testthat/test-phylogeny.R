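# Ancestry: depth, MRCA, sweeps and vestigial profiling.

chain_tree <- function(changed) {
  n <- length(changed) + 1L
  tibble::tibble(id = seq_len(n),
                 parent = c(NA_integer_, seq_len(n - 1L)),
                 update = seq_len(n) - 1L,
                 changed = c(FALSE, changed))
}

test_that("depth counts genotype-changing births only", {
  tr <- chain_tree(c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(lineage_depth(tr, 1), 0)
  expect_equal(lineage_depth(tr, 6), 3)
  # monotone non-decreasing along the path
  depths <- vapply(tr$id, function(i) lineage_depth(tr, i), numeric(1))
  expect_true(all(diff(depths) >= 0))
  expect_error(lineage_depth(tr, 99), "unknown id")
})

test_that("MRCA equals brute-force ancestor-set intersection", {
  set.seed(21)
  for (rep in 1:8) {
    n <- 50
    parent <- c(NA_integer_, vapply(2:n, function(i) {
      sample.int(i - 1L, 1)
    }, integer(1)))
    tr <- tibble::tibble(id = 1:n, parent = parent)
    living <- sample(2:n, sample(2:8, 1))
    got <- find_mrca(tr, living)
    # oracle: intersect full ancestor sets, take the one with the longest
    # root path
    anc <- lapply(living, function(v) {
      out <- v
      while (!is.na(tr$parent[out[1]])) out <- c(tr$parent[out[1]], out)
      out
    })
    common <- Reduce(intersect, anc)
    oracle <- common[which.max(vapply(common, function(v) {
      length(anc[[1]][seq_len(match(v, anc[[1]]))])
    }, integer(1)))]
    expect_equal(got, oracle)
  }
})

test_that("MRCA degenerate cases", {
  tr <- chain_tree(c(TRUE, TRUE))
  expect_equal(find_mrca(tr, 3), 3)        # single survivor: itself
  expect_equal(find_mrca(tr, c(2, 3)), 2)  # ancestor-descendant pair
  two_roots <- tibble::tibble(id = 1:2, parent = c(NA, NA))
  expect_true(is.na(find_mrca(two_roots, c(1, 2))))
  expect_error(find_mrca(tr, integer()), "non-empty")
  # siblings coalesce in their parent
  sib <- tibble::tibble(id = 1:3, parent = c(NA, 1L, 1L))
  expect_equal(find_mrca(sib, c(2, 3)), 1)
})

test_that("sweeps count MRCA identity changes between samples", {
  expect_equal(count_sweeps(rep(7, 10)), 0L)
  expect_equal(count_sweeps(c(1, 1, 2, 2, 2, 5, 5, 9)), 3L)
  expect_equal(count_sweeps(c(3, NA, 3, 4)), 1L)
  expect_equal(count_sweeps(integer()), 0L)
})

test_that("lineage fixtures round-trip their parameters", {
  set.seed(77)
  for (i in 1:10) {
    depth <- sample(0:20, 1)
    n_sweeps <- sample(0:depth, 1)
    fx <- make_lineage_fixture(n_sweeps, depth)
    expect_equal(count_sweeps(fx$mrca_series), n_sweeps)
    expect_equal(lineage_depth(fx$tree, fx$tip), depth)
  }
  expect_error(make_lineage_fixture(5, 3), "sweeps")
})

test_that("vestigial sites are detected along a constructed lineage", {
  # ancestor performs XOR with an intact-but-disabled EQU motif; its
  # parent had EQU enabled: the motif sites are vestigial-EQU
  fx <- make_task_genome("XOR", l = 60, inputs = INS, catalog = CT3,
                         vestigial_tasks = "EQU")
  dis <- fx$disabled_sites[["EQU"]]
  enabled <- mutscape:::sub_site(fx$genome, dis, "e")
  vp <- vestigial_profile(
    genomes = list(unclass(enabled), unclass(fx$genome)),
    mutated_sites = list(integer(), dis),
    inputs = INS, catalog = CT3)
  motif <- fx$site_map$site[fx$site_map$role == "vestigial"]
  expect_true(length(motif) > 0)
  expect_true(all(vp$label[motif] == "vestigial-EQU"))
  # the disabling site itself mutated, so it is not vestigial
  expect_true(is.na(vp$label[dis]))
  # functional and vestigial labels are mutually exclusive per task
  cur_equ <- grepl("EQU", vp$current)
  vest_equ <- vapply(vp$vestigial_tasks, function(x) "EQU" %in% x,
                     logical(1))
  expect_false(any(cur_equ & vest_equ))
})

test_that("a site mutated after losing function is not vestigial", {
  fx <- make_task_genome("XOR", l = 60, inputs = INS, catalog = CT3,
                         vestigial_tasks = "EQU")
  dis <- fx$disabled_sites[["EQU"]]
  enabled <- mutscape:::sub_site(fx$genome, dis, "e")
  motif <- fx$site_map$site[fx$site_map$role == "vestigial"]
  # mutate one motif site after the disabling event
  hit <- motif[1]
  after <- mutscape:::sub_site(fx$genome, hit, "b")
  vp <- vestigial_profile(
    genomes = list(unclass(enabled), unclass(fx$genome), unclass(after)),
    mutated_sites = list(integer(), dis, hit),
    inputs = INS, catalog = CT3)
  expect_true(is.na(vp$label[hit]))
  expect_true(all(vp$label[setdiff(motif, hit)] == "vestigial-EQU"))
})

test_that("currently functional sites are never vestigial for that task", {
  fx <- XE_FIXTURE
  vp <- vestigial_profile(genomes = list(unclass(fx$genome)),
                          mutated_sites = list(integer()),
                          inputs = INS, catalog = CT3)
  expect_true(all(is.na(vp$label)))
})
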