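# Reward schedules, merit and expected fitness.

test_that("EQU multipliers follow the treatment tables", {
  harsh <- environment_schedule("harsh")
  benign <- environment_schedule("benign")
  static <- environment_schedule("static")
  expect_equal(task_multiplier(harsh, "EQU", 0), 32)
  expect_equal(task_multiplier(harsh, "EQU", 1500), 0.03125)
  expect_equal(task_multiplier(benign, "EQU", 1500), 1)
  expect_equal(task_multiplier(static, "EQU", 123456), 32)
  expect_equal(task_multiplier(harsh, "XOR", 1500), 8)
  expect_error(task_multiplier(harsh, "FROB", 0), "unknown task")
  expect_error(task_multiplier(harsh, "EQU", -1), "update")
})

test_that("expanded tasks earn 1.2 only in stage 2", {
  sch <- environment_schedule("harsh")
  expect_equal(task_multiplier(sch, "NAND", 0), 1)
  expect_equal(task_multiplier(sch, "NAND", 200000), 1.2)
  # quiescent treatments stop the fluctuation in stage 2
  hq <- environment_schedule("harsh_quiescent")
  expect_equal(task_multiplier(hq, "EQU", 1500), 0.03125)
  expect_equal(task_multiplier(hq, "EQU", 201000), 32)
  expect_equal(task_multiplier(hq, "EQU", 201000 + 1000), 32)
})

test_that("schedules are periodic with period 2 * cycle_length", {
  sch <- environment_schedule("harsh", cycle_length = 50)
  u <- 0:400
  within_stage <- u + 100 < sch$stage2_start
  expect_equal(task_multiplier(sch, "EQU", u[within_stage]),
               task_multiplier(sch, "EQU", u[within_stage] + 100))
  # phase multiplier ratio and swing magnitudes
  expect_equal(task_multiplier(sch, "EQU", 0) /
                 task_multiplier(sch, "EQU", 50), 1024)
  expect_equal(task_multiplier(sch, "EQU", 0), 2^5)
  expect_equal(1 / task_multiplier(sch, "EQU", 50), 2^5)
})

test_that("merit is multiplicative over tasks with base 1", {
  sch <- environment_schedule("harsh")
  expect_equal(organism_fitness(character(), sch, 0), 1)
  expect_equal(organism_fitness("XOR", sch, 0), 8)
  expect_equal(organism_fitness(c("XOR", "EQU"), sch, 0), 256)
  expect_equal(organism_fitness(c("XOR", "EQU"), sch, 1000), 0.25)
  # removing a task divides fitness by exactly its multiplier
  expect_equal(organism_fitness(c("XOR", "EQU"), sch, 0) /
                 organism_fitness("XOR", sch, 0),
               task_multiplier(sch, "EQU", 0))
  # a non-viable phenotype has zero fitness
  ph <- evaluate_phenotype(strrep("a", 20), INS, CT3)
  expect_equal(organism_fitness(ph, sch, 0), 0)
})

test_that("expected fitness is the probability-weighted sum", {
  expect_equal(expected_fitness(5, 1)$value, 5)
  expect_equal(expected_fitness(c(32, 0.03125), c(0.5, 0.5))$value,
               16.015625)
  expect_error(expected_fitness(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(expected_fitness(c(1, 2), 1), "length")
  expect_error(expected_fitness(c(1, 2), c(1.5, -0.5)), "non-negative")
})

test_that("describe_schedule tabulates per-phase multipliers", {
  d <- describe_schedule(environment_schedule("benign"))
  expect_true(all(c("update", "stage", "phase", "task", "multiplier")
                  %in% names(d)))
  equ <- d[d$task == "EQU", ]
  expect_equal(equ$multiplier[equ$stage == 1 & equ$phase == 0], 32)
  expect_equal(equ$multiplier[equ$stage == 1 & equ$phase == 1], 1)
})
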