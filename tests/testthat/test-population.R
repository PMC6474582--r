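# Mutation, the grid update rule, and experiment reproducibility.

small_world <- function(organisms, width = 5, height = 5, mu = 0,
                        treatment = "static", cost = NULL) {
  sch <- environment_schedule(treatment, cycle_length = 1000,
                              stage2_start = 1e6, tasks = CT3$name)
  make_world(organisms, width, height, sch, CT3, INS,
             model = mutation_model(mu), cost = cost)
}

test_that("mutation respects mu = 0 and mu = 1", {
  g <- unclass(XE_FIXTURE$genome)
  m0 <- mutate_genome(g, mutation_model(0))
  expect_identical(m0$genome, g)
  expect_length(m0$mutated_sites, 0)
  set.seed(1)
  m1 <- mutate_genome(g, mutation_model(1))
  s0 <- strsplit(g, "")[[1]]
  s1 <- strsplit(m1$genome, "")[[1]]
  expect_true(all(s0 != s1))
  expect_length(m1$mutated_sites, nchar(g))
})

test_that("mean Hamming distance matches the binomial expectation", {
  set.seed(6)
  mu <- 0.00075
  l <- 121
  g <- paste0(sample(letters, l, TRUE), collapse = "")
  n <- 1e5
  hits <- vapply(seq_len(n), function(i) {
    length(mutate_genome(g, mutation_model(mu))$mutated_sites)
  }, integer(1))
  se <- sqrt(mu * l / n) # Poisson-binomial standard error of the mean
  expect_lt(abs(mean(hits) - mu * l), 3 * se)
})

test_that("zero-fitness organisms never reproduce", {
  w <- small_world(tibble::tibble(cell = 13, genome = strrep("a", 30)))
  w <- step_update(w, 50)
  expect_equal(nrow(w$organisms), 1)
  expect_equal(w$last_births, 0)
})

test_that("first birth lands at update ceil(cost / fitness)", {
  g <- unclass(XE_FIXTURE$genome) # fitness 256 under static reward
  f <- 256
  cost <- 1000
  expected <- ceiling(cost / f)
  w <- small_world(tibble::tibble(cell = 13, genome = g), cost = cost)
  set.seed(2)
  w1 <- step_update(w, expected - 1)
  expect_equal(w1$last_births, 0)
  set.seed(2)
  w2 <- step_update(w, expected)
  expect_equal(w2$last_births, 1)
  expect_equal(nrow(w2$organisms), 2)
  # child lands in the Moore neighborhood of cell 13 on the 5x5 torus
  child <- setdiff(w2$organisms$cell, 13)
  nb <- c(7, 8, 9, 12, 14, 17, 18, 19)
  expect_true(child %in% nb)
})

test_that("the higher-merit genotype usually fixes from a 4:1 ratio", {
  # EQU-only (merit 32) vs XOR-only (merit 8): a 4:1 fitness ratio;
  # mu = 0 so only replacement dynamics act
  hi <- unclass(make_task_genome("EQU", l = 60, inputs = INS,
                                 catalog = CT3, verify = FALSE)$genome)
  lo <- unclass(make_task_genome("XOR", l = 60, inputs = INS,
                                 catalog = CT3, verify = FALSE)$genome)
  wins <- 0
  set.seed(77)
  for (rep in 1:20) {
    w <- small_world(tibble::tibble(cell = c(7, 19),
                                    genome = c(hi, lo)),
                     width = 5, height = 5)
    w <- step_update(w, 60)
    freq <- mean(w$organisms$genome == hi)
    if (freq > 0.5) wins <- wins + 1
  }
  expect_gt(wins, 10) # majority of seeded runs
})

test_that("population never exceeds capacity and mu = 0 keeps one genotype", {
  g <- unclass(XE_FIXTURE$genome)
  w <- small_world(tibble::tibble(cell = 1, genome = g))
  set.seed(3)
  w <- step_update(w, 200)
  expect_lte(nrow(w$organisms), 25)
  expect_true(all(w$organisms$genome == g))
})

test_that("runs replay bit-identically from their seed", {
  cfg <- experiment_config(treatment = "harsh", width = 10, height = 10,
                           genome_length = 60, stage1_cycles = 4,
                           cycle_length = 100, seed = 12345)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$logs, r2$logs)
  expect_identical(r1$genotypes, r2$genotypes)
  expect_identical(as.data.frame(r1$phylogeny), as.data.frame(r2$phylogeny))
  expect_identical(r1$population, r2$population)
})

test_that("static control keeps EQU at carrying capacity after fixation", {
  cfg <- experiment_config(treatment = "static", seed = 5,
                           stage1_cycles = 10)
  run <- run_experiment(cfg)
  lg <- run$logs
  full <- lg[lg$occupied == max(lg$occupied), ]
  late <- full[full$update > 500, ]
  # no sustained loss: EQU performers stay near occupancy throughout
  expect_true(all(late$equ_performers > 0.8 * late$occupied))
})

test_that("harsh treatment loses EQU within punishment phases", {
  cfg <- experiment_config(treatment = "harsh", seed = 5,
                           stage1_cycles = 10)
  run <- run_experiment(cfg)
  lg <- run$logs
  punish_end <- lg[lg$update %% 400 == 0, ]
  reward_end <- lg[lg$update %% 400 == 200, ]
  expect_lt(median(punish_end$equ_performers),
            0.25 * median(pmax(reward_end$equ_performers, 1)))
})
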