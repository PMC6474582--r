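# Synthetic fixtures: each returns its own ground truth.

test_that("task genomes perform exactly the requested set", {
  fx <- make_task_genome(c("NOT", "AND"), l = 60, inputs = INS,
                         catalog = CT3)
  ph <- evaluate_phenotype(fx$genome, INS, CT3)
  expect_setequal(names(ph$tasks)[ph$tasks], c("NOT", "AND"))
  expect_error(make_task_genome("NAND", l = 12, inputs = INS,
                                catalog = CT3), "too small")
  expect_error(make_task_genome("FROB", l = 60, inputs = INS,
                                catalog = CT3), "unknown task")
})

test_that("classify_sites matches the fixture map exactly", {
  for (tasks in list("NAND", c("XOR", "EQU"), c("NOT", "ORN"))) {
    fx <- make_task_genome(tasks, l = 70, inputs = INS, catalog = CT3,
                           verify = FALSE)
    cl <- classify_sites(fx$genome, INS, CT3)
    expect_identical(cl$label, mutscape:::fixture_expected_labels(fx))
  }
})

test_that("layouts change the site map, not the phenotype", {
  a <- make_task_genome(c("XOR", "EQU"), l = 80, inputs = INS,
                        catalog = CT3, layout = "compact")
  b <- make_task_genome(c("XOR", "EQU"), l = 80, inputs = INS,
                        catalog = CT3, layout = "scattered")
  expect_false(identical(unclass(a$genome), unclass(b$genome)))
  pa <- evaluate_phenotype(a$genome, INS, CT3)
  pb <- evaluate_phenotype(b$genome, INS, CT3)
  expect_identical(pa$tasks, pb$tasks)
  # same functional footprint size at different positions
  expect_equal(sum(a$site_map$role == "functional"),
               sum(b$site_map$role == "functional"))
  expect_false(identical(a$site_map$role, b$site_map$role))
})

test_that("vestigial motifs restore their task via the disabling site", {
  fx <- make_task_genome("XOR", l = 70, inputs = INS, catalog = CT3,
                         vestigial_tasks = "EQU")
  expect_false(evaluate_phenotype(fx$genome, INS, CT3)$tasks[["EQU"]])
  restored <- mutscape:::sub_site(fx$genome, fx$disabled_sites[["EQU"]],
                                  "e")
  ph <- evaluate_phenotype(restored, INS, CT3)
  expect_true(ph$tasks[["EQU"]])
  expect_true(ph$tasks[["XOR"]])
})

test_that("population fixtures realize exact frequencies and entropy", {
  fx <- make_population_fixture(c(g1 = 2L, g2 = 2L))
  expect_length(fx$genomes, 4)
  p <- per_site_entropy(fx$genomes)
  expect_equal(p$entropy, fx$entropy$entropy)
  expect_equal(p$entropy[1], 1) # 50/50 split at the differing site
  # single genotype: zero entropy
  f1 <- make_population_fixture(c(only = 5L))
  expect_equal(mean_entropy(per_site_entropy(f1$genomes)), 0)
  # three-genotype fixture against the hand calculation
  f3 <- make_population_fixture(c(a = 2L, b = 1L, c = 1L))
  expect_equal(per_site_entropy(f3$genomes)$entropy[1],
               -(0.5 * log2(0.5) + 0.25 * log2(0.25) +
                   0.25 * log2(0.25)))
})

test_that("survey stubs realize requested fractions within 1/n", {
  for (pd in c(0, 0.25, 0.4, 1)) {
    for (pp in c(0, 0.3, 0.5)) {
      if (pd + pp > 1) next
      stub <- make_survey_stub(pd, pp, l = 10, alphabet = letters[1:4])
      sv <- one_step_survey(stub$parent, stub$evaluator,
                            alphabet = stub$alphabet)
      expect_equal(attr(sv, "n_total"), stub$n)
      expect_lte(abs(attr(sv, "p_d") - pd), 1 / stub$n)
      expect_lte(abs(attr(sv, "p_pnu") - pp), 1 / stub$n)
      expect_equal(attr(sv, "p_d"), stub$p_d)
      expect_equal(attr(sv, "p_pnu"), stub$p_pnu)
    }
  }
})

test_that("stub surveys reproduce the worked diffusion values", {
  # a stub with the worked fractions feeds the same oracle values
  stub <- make_survey_stub(0.4, 0.5, l = 20, alphabet = letters[1:6])
  sv <- one_step_survey(stub$parent, stub$evaluator,
                        alphabet = stub$alphabet)
  dm <- diffusion_metrics(mu = 0.00075, l = 121,
                          p_d = attr(sv, "p_d"),
                          p_pnu = attr(sv, "p_pnu"))
  expect_equal(dm$D_g, 0.051130792932947084, tolerance = 1e-6)
  expect_equal(dm$D_p, 0.0087147752813822517, tolerance = 1e-6)
})
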