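# One-step and two-step neighborhood surveys and diffusion metrics.

vm_ev <- function(treatment = "static", mode = "expected") {
  sch <- environment_schedule(treatment, cycle_length = 200,
                              stage2_start = 8000, tasks = CT3$name)
  phenotype_evaluator(survey_context(sch, CT3, mode = mode), INS, CT3)
}

test_that("the one-step neighborhood has l * 25 mutants on the VM", {
  sv <- one_step_survey(XE_FIXTURE$genome, vm_ev())
  expect_equal(attr(sv, "n_total"), 60 * 25)
  expect_equal(nrow(sv), 1500)
  # every (site, symbol) pair distinct and non-parental
  expect_false(any(duplicated(sv[, c("site", "symbol")])))
  s <- strsplit(unclass(XE_FIXTURE$genome), "")[[1]]
  expect_true(all(sv$symbol != s[sv$site]))
  expect_error(one_step_survey(strrep("a", 30), vm_ev()), "not viable")
})

test_that("survey fractions satisfy their identities", {
  sv <- one_step_survey(XE_FIXTURE$genome, vm_ev("harsh"))
  fr <- survey_fractions(sv)
  expect_equal(fr$p_nu + fr$p_d, 1)
  expect_lte(fr$p_pnu, fr$p_nu)
  expect_gte(fr$p_pnu, 0)
  # subset convention vs literal reading
  expect_lte(attr(sv, "p_pnu_subset"), attr(sv, "p_pnu_literal") + 1e-12)
})

test_that("a flat stub landscape gives p_d = 0", {
  flat <- function(g) list(fitness = 1, phenotype = "P")
  sv <- one_step_survey("aaaa", flat, alphabet = letters[1:3])
  expect_equal(attr(sv, "p_d"), 0)
  expect_equal(attr(sv, "p_nu"), 1)
  expect_equal(attr(sv, "n_total"), 4 * 2)
})

test_that("diffusion metrics reproduce the arbitrary-precision oracle", {
  dm <- diffusion_metrics(mu = 0.00075, l = 121, p_d = 0.4, p_pnu = 0.5)
  # frozen mpmath (40-digit) reference values
  expect_equal(dm$F, 0.91321489993959595, tolerance = 1e-9)
  expect_equal(dm$F_nu, 0.96434569287254303, tolerance = 1e-9)
  expect_equal(dm$mu_pheno, 0.000375, tolerance = 1e-12)
  expect_equal(dm$F_pnu, 0.95563091759116078, tolerance = 1e-9)
  expect_equal(dm$D_g, 0.051130792932947084, tolerance = 1e-9)
  expect_equal(dm$D_p, 0.0087147752813822517, tolerance = 1e-9)
})

test_that("diffusion limits and monotonicity hold", {
  z <- diffusion_metrics(mu = 0, l = 121, p_d = 0.4, p_pnu = 0.5)
  expect_equal(z$F, 1)
  expect_equal(z$D_g, 0)
  expect_equal(z$D_p, 0)
  # p_d = 1 forces F_nu = F and D_g = 0
  d1 <- diffusion_metrics(mu = 0.001, l = 50, p_d = 1, p_pnu = 0)
  expect_equal(d1$D_g, 0)
  # D_g non-increasing in p_d at fixed mu, l
  dg <- vapply(seq(0, 1, by = 0.05), function(p) {
    diffusion_metrics(mu = 0.002, l = 80, p_d = p, p_pnu = 0)$D_g
  }, numeric(1))
  expect_true(all(diff(dg) <= 1e-12))
  expect_true(all(dg >= 0))
  expect_error(diffusion_metrics(mu = 2, l = 10, p_d = 0, p_pnu = 0),
               "mu")
})

test_that("one-step surveys match brute force on toy maps", {
  alphabet <- letters[1:4]
  set.seed(7)
  for (salt in c(0L, 3L, 11L)) {
    fn <- toy_map(salt)
    for (l in 1:4) {
      g <- paste0(sample(alphabet, l, TRUE), collapse = "")
      sv <- one_step_survey(g, fn, alphabet = alphabet)
      or <- oracle_one_step(g, fn, alphabet)
      expect_equal(nrow(sv), nrow(or))
      expect_equal(sv$fitness, or$fitness)
      expect_equal(sv$neutral, or$neutral)
      expect_equal(sv$preserving, or$preserving)
      expect_equal(attr(sv, "p_d"), mean(!or$neutral))
    }
  }
})

test_that("two-step regain matches brute force and handles edge cases", {
  alphabet <- letters[1:4]
  fn <- toy_map(5L)
  # find a parent performing T_even
  g <- "abca"
  stopifnot("T_even" %in% fn(g)$tasks)
  sv <- one_step_survey(g, fn, alphabet = alphabet)
  rg <- two_step_regain_survey(sv, "T_even")
  or <- oracle_two_step(g, fn, alphabet, "T_even")
  expect_equal(rg$n_lost, or$n_lost)
  expect_equal(rg$fraction, or$fraction)
  # sampled mode with budget >= full enumeration equals exhaustive
  rg2 <- two_step_regain_survey(sv, "T_even", mode = "sampled",
                                budget = 1e7)
  expect_equal(rg2$fraction, rg$fraction)
  expect_error(two_step_regain_survey(sv, "T_even", mode = "sampled",
                                      budget = 0), "budget")
})

test_that("a never-lost task yields a missing regain fraction", {
  fn <- function(g) list(fitness = 1, phenotype = "P", tasks = "T")
  sv <- one_step_survey("aaa", fn, alphabet = letters[1:3])
  rg <- two_step_regain_survey(sv, "T")
  expect_equal(rg$n_lost, 0L)
  expect_true(is.na(rg$fraction))
})

test_that("two-step VM survey excludes reversion and matches R brute force", {
  ev <- vm_ev()
  g <- NAND_FIXTURE$genome
  sv <- one_step_survey(g, ev)
  rg <- two_step_regain_survey(sv, "NAND")
  l <- genome_length(g)
  expect_true(all(rg$per_mutant$n_tested == (l - 1) * 25))
  # spot-check one first-step mutant against direct enumeration
  pm <- rg$per_mutant[1, ]
  g1 <- strsplit(unclass(g), "")[[1]]
  g1[pm$site] <- pm$symbol
  regain <- 0L
  for (site in setdiff(seq_len(l), pm$site)) {
    for (a in letters[letters != g1[site]]) {
      g2 <- g1
      g2[site] <- a
      ph <- evaluate_phenotype(paste0(g2, collapse = ""), INS, CT3)
      if (ph$viable && ph$tasks[["NAND"]]) regain <- regain + 1L
    }
  }
  expect_equal(pm$n_regain, regain)
})

test_that("multi-mutation sampling converges to the exhaustive survey", {
  alphabet <- letters[1:4]
  fn <- toy_map(2L)
  g <- "abcd"
  sv <- one_step_survey(g, fn, alphabet = alphabet)
  set.seed(31)
  # mu = 0 gives no mutants at all
  s0 <- sampled_multimutation_survey(g, 50, mutation_model(0), fn,
                                     alphabet = alphabet)
  expect_equal(s0$p_d, 0)
  expect_true(all(s0$draws$n_mutations == 0))
  # tiny mu: conditional on a single hit, p_d matches the exhaustive value
  sm <- sampled_multimutation_survey(g, 4000, mutation_model(0.02), fn,
                                     alphabet = alphabet)
  one <- sm$draws[sm$draws$n_mutations == 1, ]
  p_hat <- mean(!one$neutral)
  p_ref <- attr(sv, "p_d")
  se <- sqrt(p_ref * (1 - p_ref) / nrow(one))
  expect_lt(abs(p_hat - p_ref), 3 * se + 1e-9)
  # seeded draws are reproducible
  set.seed(99)
  a <- sampled_multimutation_survey(g, 20, mutation_model(0.1), fn,
                                    alphabet = alphabet)
  set.seed(99)
  b <- sampled_multimutation_survey(g, 20, mutation_model(0.1), fn,
                                    alphabet = alphabet)
  expect_equal(a$draws, b$draws)
})

test_that("aggregation across environments follows expected fitness", {
  # single environment with P = 1 is the identity
  ev <- vm_ev("harsh", mode = "expected")
  sv <- one_step_survey(XE_FIXTURE$genome, ev)
  ag1 <- aggregate_across_environments(list(sv), 1)
  expect_equal(ag1$fitness, sv$fitness)
  expect_equal(attr(ag1, "p_d"), attr(sv, "p_d"))
  # symmetric two-environment aggregation is the arithmetic mean
  f1 <- function(g) list(fitness = 1 + (utf8ToInt(substr(g, 1, 1)) %% 3),
                         phenotype = substr(g, 1, 1))
  f2 <- function(g) list(fitness = 3 - (utf8ToInt(substr(g, 1, 1)) %% 3),
                         phenotype = substr(g, 1, 1))
  s1 <- one_step_survey("ab", f1, alphabet = letters[1:3])
  s2 <- one_step_survey("ab", f2, alphabet = letters[1:3])
  ag <- aggregate_across_environments(list(s1, s2), c(0.5, 0.5))
  expect_equal(ag$fitness, (s1$fitness + s2$fitness) / 2)
  expect_error(aggregate_across_environments(list(s1, s2), c(0.9, 0.2)),
               "sum to 1")
  s3 <- one_step_survey("bb", f1, alphabet = letters[1:3])
  expect_error(aggregate_across_environments(list(s1, s3), c(0.5, 0.5)),
               "different parent")
})

test_that("EQU loss flips sign across harsh phases and is classified by E(w)", {
  sch <- environment_schedule("harsh", cycle_length = 200,
                              stage2_start = 8000, tasks = CT3$name)
  ev0 <- phenotype_evaluator(survey_context(sch, CT3, mode = "phase",
                                            phase = 0), INS, CT3)
  ev1 <- phenotype_evaluator(survey_context(sch, CT3, mode = "phase",
                                            phase = 1), INS, CT3)
  g <- XE_FIXTURE$genome
  s0 <- one_step_survey(g, ev0)
  s1 <- one_step_survey(g, ev1)
  masks <- attr(s0, "masks")
  equ <- match("EQU", CT3$name)
  loser <- which(!masks[, equ] & masks[, match("XOR", CT3$name)] &
                   s0$viable)[1]
  expect_false(s0$neutral[loser]) # reward phase: losing EQU is detrimental
  expect_true(s1$neutral[loser])  # punish phase: losing EQU is a relief
  # expected-fitness aggregation: classification by sign of E(w) - E(w_p)
  ag <- aggregate_across_environments(list(s0, s1), c(0.5, 0.5))
  ew <- (s0$fitness[loser] + s1$fitness[loser]) / 2
  ewp <- (attr(s0, "parent_fitness") + attr(s1, "parent_fitness")) / 2
  expect_equal(ag$neutral[loser], ew >= ewp * (1 - 1e-9))
  expect_false(ag$neutral[loser]) # E keeps EQU favoured: (32 + 1/32)/2 > 1
})
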