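# One-step and non-reversion two-step mutational-neighborhood surveys,
# mutant classification, and the genomic/phenotypic diffusion-rate metrics
# with expected-fitness aggregation across environments.

#' Build a survey evaluation context from a schedule
#'
#' Surveys of fluctuating treatments evaluate each mutant's fitness in
#' every phase of the cycle and aggregate by expected value (default:
#' both phases of stage 1 at P = (0.5, 0.5)); `mode = "phase"` instead
#' evaluates in a single named phase.
#'
#' @param schedule An `env_schedule`.
#' @param catalog A `task_catalog`.
#' @param mode `"expected"` or `"phase"`.
#' @param phase Phase used when `mode = "phase"` (0 = reward).
#' @param stage Experiment stage (1 or 2).
#' @param P Environment probabilities for `mode = "expected"`.
#' @return An object of class `survey_context`: multiplier matrix
#'   (environments x tasks) and `P`.
#' @export
survey_context <- function(schedule, catalog, mode = c("expected", "phase"),
                           phase = 0, stage = 1, P = c(0.5, 0.5)) {
  mode <- match.arg(mode)
  m <- multiplier_matrix(schedule, catalog)
  rows <- if (stage == 1) 1:2 else 3:4
  if (mode == "phase") {
    stopifnot(phase %in% 0:1)
    mult <- m[rows[phase + 1], , drop = FALSE]
    P <- 1
  } else {
    mult <- m[rows, , drop = FALSE]
    if (length(P) != nrow(mult) || any(P < 0) || abs(sum(P) - 1) > 1e-9) {
      stop("`P` must be ", nrow(mult), " non-negative values summing to 1",
           call. = FALSE)
    }
  }
  structure(list(mult = mult, P = P, treatment = schedule$treatment,
                 mode = mode),
            class = "survey_context")
}

#' Virtual-CPU phenotype evaluator for surveys
#'
#' Packages the fixed evaluation inputs, task catalog and survey context
#' into an evaluator usable by [one_step_survey()] and friends.
#'
#' @param context A `survey_context`.
#' @param inputs Evaluation input triple (see [survey_inputs()]).
#' @param catalog A `task_catalog`.
#' @param max_steps Step budget per execution (default: genome length).
#' @return An object of class `vm_evaluator`.
#' @export
phenotype_evaluator <- function(context, inputs, catalog, max_steps = NULL) {
  stopifnot(inherits(context, "survey_context"),
            inherits(catalog, "task_catalog"))
  structure(list(context = context, inputs = as_word(inputs),
                 catalog = catalog, ta = target_arrays(catalog, inputs),
                 max_steps = max_steps),
            class = "vm_evaluator")
}

# expected fitness of task-mask rows under a context; mask: n x n_tasks
mask_fitness <- function(mask, viable, context) {
  mult <- context$mult
  logm <- log(mult)
  w <- matrix(0, nrow(mask), nrow(mult))
  for (i in seq_len(nrow(mult))) {
    w[, i] <- exp(as.numeric(mask %*% logm[i, ]))
  }
  as.numeric(w %*% context$P) * as.numeric(viable)
}

#' Exhaustive one-step mutational-neighborhood survey
#'
#' Enumerates all `l * (alphabet - 1)` single-site substitutions of a
#' genome, classifies each mutant's fitness against the parent
#' (neutral-or-better vs detrimental-or-lethal, with relative tolerance
#' `epsilon`) and phenotype identity, and records per-task loss.
#'
#' The phenotype-preserving fraction `p_pnu` is, by default, the fraction
#' of mutants that are both phenotype-identical and fitness
#' neutral-or-better (`ppnu = "subset"`, which guarantees
#' `p_pnu <= p_nu` and a non-negative phenotypic diffusion rate); set
#' `ppnu = "literal"` for the fraction of phenotype-identical mutants
#' regardless of fitness.
#'
#' @param g Parent genome (string for the VM path; any string over
#'   `alphabet` for a function evaluator).
#' @param evaluator A `vm_evaluator`, or a function mapping a genome
#'   string to `list(fitness, phenotype, tasks)` (`tasks` optional).
#' @param alphabet Symbols available per site (function evaluators only;
#'   the VM always uses the 26-letter alphabet).
#' @param epsilon Relative fitness tolerance for neutrality (default 1e-9).
#' @param ppnu `"subset"` (default) or `"literal"`, see above.
#' @return A tibble of class `neighborhood_survey` (one row per mutant:
#'   `site`, `symbol`, `viable`, `fitness`, `neutral`, `preserving`) with
#'   attributes `parent_fitness`, `parent_tasks`, `p_nu`, `p_d`, `p_pnu`,
#'   `n_total`, `task_loss` (tibble) and the survey ingredients needed by
#'   [two_step_regain_survey()].
#' @export
one_step_survey <- function(g, evaluator, alphabet = letters,
                            epsilon = 1e-9,
                            ppnu = c("subset", "literal")) {
  ppnu <- match.arg(ppnu)
  if (inherits(evaluator, "vm_evaluator")) {
    one_step_survey_vm(g, evaluator, epsilon, ppnu)
  } else if (is.function(evaluator)) {
    one_step_survey_fn(g, evaluator, alphabet, epsilon, ppnu)
  } else {
    stop("`evaluator` must be a vm_evaluator or a function", call. = FALSE)
  }
}

one_step_survey_vm <- function(g, ev, epsilon, ppnu) {
  g <- genome(g)
  l <- genome_length(g)
  max_steps <- if (is.null(ev$max_steps)) l else ev$max_steps
  pg <- cpp_phenotype(genome_codes(g), ev$inputs, max_steps,
                      ev$ta$words, ev$ta$task0, ev$ta$n)
  if (!pg$viable) {
    stop("parent genome is not viable in this context", call. = FALSE)
  }
  parent_mask <- pg$tasks
  parent_fitness <- mask_fitness(matrix(parent_mask, 1), TRUE, ev$context)
  sv <- cpp_survey_masks(genome_codes(g), N_SYMBOLS, ev$inputs, max_steps,
                         ev$ta$words, ev$ta$task0, ev$ta$n)
  masks <- sv$tasks
  fitness <- mask_fitness(masks, sv$viable, ev$context)
  neutral <- fitness >= parent_fitness * (1 - epsilon)
  same_mask <- rowSums(masks != matrix(parent_mask, nrow(masks),
                                       ncol(masks), byrow = TRUE)) == 0
  preserving <- same_mask & sv$viable
  out <- tibble::tibble(
    site = sv$site,
    symbol = letters[sv$symbol + 1L],
    viable = sv$viable,
    fitness = fitness,
    neutral = neutral,
    preserving = preserving
  )
  parent_names <- ev$catalog$name[parent_mask]
  task_loss <- tibble::tibble(
    task = parent_names,
    n_lost = vapply(which(parent_mask), function(t) sum(!masks[, t]),
                    integer(1)),
    fraction = vapply(which(parent_mask), function(t) mean(!masks[, t]),
                      numeric(1))
  )
  finish_survey(out, ppnu, epsilon,
                parent_genome = unclass(g),
                parent_fitness = parent_fitness,
                parent_tasks = parent_names,
                task_loss = task_loss,
                masks = masks, evaluator = ev, alphabet = letters)
}

one_step_survey_fn <- function(g, fn, alphabet, epsilon, ppnu) {
  g <- unclass(genome_chr(g))
  s <- strsplit(g, "")[[1]]
  l <- length(s)
  parent <- fn(g)
  rows <- list()
  for (site in seq_len(l)) {
    for (a in alphabet[alphabet != s[site]]) {
      mutant <- s
      mutant[site] <- a
      r <- fn(paste0(mutant, collapse = ""))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site = site, symbol = a,
        viable = if (is.null(r$viable)) NA else r$viable,
        fitness = r$fitness,
        phenotype = r$phenotype,
        tasks = list(if (is.null(r$tasks)) character() else r$tasks)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$neutral <- out$fitness >= parent$fitness * (1 - epsilon)
  out$preserving <- out$phenotype == parent$phenotype
  parent_tasks <- if (is.null(parent$tasks)) character() else parent$tasks
  task_loss <- tibble::tibble(
    task = parent_tasks,
    n_lost = vapply(parent_tasks, function(tk) {
      sum(!vapply(out$tasks, function(x) tk %in% x, logical(1)))
    }, integer(1)),
    fraction = vapply(parent_tasks, function(tk) {
      mean(!vapply(out$tasks, function(x) tk %in% x, logical(1)))
    }, numeric(1))
  )
  finish_survey(out, ppnu, epsilon,
                parent_genome = g, parent_fitness = parent$fitness,
                parent_tasks = parent_tasks, task_loss = task_loss,
                masks = NULL, evaluator = fn, alphabet = alphabet)
}

# accept plain strings for function-evaluator surveys (any alphabet)
genome_chr <- function(g) {
  if (inherits(g, "genome")) return(g)
  stopifnot(is.character(g), length(g) == 1)
  structure(g, class = "genome")
}

finish_survey <- function(out, ppnu, epsilon, parent_genome, parent_fitness,
                          parent_tasks, task_loss, masks, evaluator,
                          alphabet) {
  p_nu <- mean(out$neutral)
  p_pnu_subset <- mean(out$preserving & out$neutral)
  p_pnu_literal <- mean(out$preserving)
  structure(out,
            class = c("neighborhood_survey", class(out)),
            parent_genome = parent_genome,
            parent_fitness = parent_fitness,
            parent_tasks = parent_tasks,
            n_total = nrow(out),
            p_nu = p_nu, p_d = 1 - p_nu,
            p_pnu = if (ppnu == "subset") p_pnu_subset else p_pnu_literal,
            p_pnu_subset = p_pnu_subset, p_pnu_literal = p_pnu_literal,
            ppnu = ppnu, epsilon = epsilon,
            task_loss = task_loss, masks = masks,
            evaluator = evaluator, alphabet = alphabet)
}

#' @export
print.neighborhood_survey <- function(x, ...) {
  cat("<neighborhood_survey>", attr(x, "n_total"), "mutants | parent",
      "fitness", signif(attr(x, "parent_fitness"), 6), "| tasks:",
      paste(attr(x, "parent_tasks"), collapse = ", "), "\n")
  cat("  p_nu =", signif(attr(x, "p_nu"), 6),
      " p_d =", signif(attr(x, "p_d"), 6),
      " p_pnu =", signif(attr(x, "p_pnu"), 6), "\n")
  NextMethod()
}

#' Survey summary fractions
#'
#' @param survey A `neighborhood_survey`.
#' @return A one-row tibble: `n_total`, `p_nu`, `p_d`, `p_pnu`.
#' @export
survey_fractions <- function(survey) {
  tibble::tibble(n_total = attr(survey, "n_total"),
                 p_nu = attr(survey, "p_nu"),
                 p_d = attr(survey, "p_d"),
                 p_pnu = attr(survey, "p_pnu"))
}

#' Genomic and phenotypic diffusion rates
#'
#' From the mutation rate, genome length and the one-step neighborhood
#' fractions, computes fidelity `F = (1 - mu)^l`, neutral fidelity
#' `F_nu = (1 - mu * p_d)^l`, the genomic diffusion rate
#' `D_g = F_nu - F`, the phenotype-changing mutation probability
#' `mu_pheno = mu * (1 - p_pnu)`, the phenotype-preserving fidelity
#' `F_pnu = (1 - mu_pheno)^l`, and the phenotypic diffusion rate
#' `D_p = F_nu - F_pnu`.
#'
#' @param survey A `neighborhood_survey`, or `NULL` if `p_d`, `p_pnu` and
#'   `l` are given directly.
#' @param mu Per-site substitution probability.
#' @param p_d,p_pnu,l Survey fractions and genome length (read from
#'   `survey` when supplied).
#' @return A one-row tibble of class `diffusion_metrics` with columns
#'   `mu`, `l`, `p_d`, `p_pnu`, `F`, `F_nu`, `mu_pheno`, `F_pnu`, `D_g`,
#'   `D_p`.
#' @examples
#' diffusion_metrics(mu = 0.00075, l = 121, p_d = 0.4, p_pnu = 0.5)
#' @export
diffusion_metrics <- function(survey = NULL, mu, p_d = NULL, p_pnu = NULL,
                              l = NULL) {
  if (!is.null(survey)) {
    stopifnot(inherits(survey, "neighborhood_survey"))
    p_d <- attr(survey, "p_d")
    p_pnu <- attr(survey, "p_pnu")
    l <- nchar(attr(survey, "parent_genome"))
  }
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]", call. = FALSE)
  stopifnot(!is.null(p_d), !is.null(p_pnu), !is.null(l))
  F_ <- (1 - mu)^l
  F_nu <- (1 - mu * p_d)^l
  mu_pheno <- mu * (1 - p_pnu)
  F_pnu <- (1 - mu_pheno)^l
  out <- tibble::tibble(mu = mu, l = as.integer(l), p_d = p_d,
                        p_pnu = p_pnu, F = F_, F_nu = F_nu,
                        mu_pheno = mu_pheno, F_pnu = F_pnu,
                        D_g = F_nu - F_, D_p = F_nu - F_pnu)
  class(out) <- c("diffusion_metrics", class(out))
  out
}

#' Two-step regain survey (non-reversion second mutations)
#'
#' For every one-step mutant that lost `task`, enumerates (or samples)
#' its single-site substitutions excluding any change at the originally
#' mutated site, and reports the fraction of these second-step mutants
#' that perform the task again. If the task was never lost in step one,
#' the fraction is reported as missing.
#'
#' @param survey A `neighborhood_survey`.
#' @param task Task name (VM surveys) or task label (function evaluators
#'   returning a `tasks` field).
#' @param mode `"exhaustive"`, or `"sampled"` with `budget` total
#'   second-step evaluations.
#' @param budget Maximum total evaluations in sampled mode (default 1e6);
#'   exhaustive enumeration is used whenever it fits the budget.
#' @return A list of class `regain_survey`: `fraction` (pooled),
#'   `mean_fraction` (mean of per-first-mutant fractions), `n_lost`
#'   (first-step mutants that lost the task), `per_mutant` tibble.
#' @export
two_step_regain_survey <- function(survey, task,
                                   mode = c("exhaustive", "sampled"),
                                   budget = 1e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(survey, "neighborhood_survey"))
  if (mode == "sampled" && budget <= 0) {
    stop("`budget` must be positive in sampled mode", call. = FALSE)
  }
  ev <- attr(survey, "evaluator")
  if (inherits(ev, "vm_evaluator")) {
    two_step_vm(survey, task, mode, budget, ev)
  } else {
    two_step_fn(survey, task, mode, budget, ev)
  }
}

two_step_vm <- function(survey, task, mode, budget, ev) {
  catalog <- ev$catalog
  if (!task %in% catalog$name) stop("unknown task: ", task, call. = FALSE)
  t0 <- match(task, catalog$name) - 1L
  masks <- attr(survey, "masks")
  if (!task %in% attr(survey, "parent_tasks")) {
    stop("parent does not perform ", task, call. = FALSE)
  }
  lost <- which(!masks[, t0 + 1L])
  g <- attr(survey, "parent_genome")
  l <- nchar(g)
  per_first <- (l - 1L) * (N_SYMBOLS - 1L)
  if (length(lost) == 0) {
    return(empty_regain(task))
  }
  total <- length(lost) * per_first
  per_budget <- if (mode == "exhaustive" || total <= budget) 0L
                else max(1L, as.integer(budget %/% length(lost)))
  max_steps <- if (is.null(ev$max_steps)) l else ev$max_steps
  res <- cpp_two_step(genome_codes(genome(g)), N_SYMBOLS,
                      survey$site[lost], match(survey$symbol[lost],
                                               letters) - 1L,
                      ev$inputs, max_steps,
                      ev$ta$words, ev$ta$task0, ev$ta$n, t0, per_budget)
  build_regain(task, survey$site[lost], survey$symbol[lost],
               res$n_tested, res$n_regain,
               sampled = per_budget > 0L)
}

two_step_fn <- function(survey, task, mode, budget, fn) {
  if (!"tasks" %in% names(survey)) {
    stop("this survey's evaluator reports no tasks", call. = FALSE)
  }
  alphabet <- attr(survey, "alphabet")
  g <- attr(survey, "parent_genome")
  s0 <- strsplit(g, "")[[1]]
  l <- length(s0)
  if (!task %in% attr(survey, "parent_tasks")) {
    stop("parent does not perform ", task, call. = FALSE)
  }
  lost <- which(!vapply(survey$tasks, function(x) task %in% x, logical(1)))
  if (length(lost) == 0) return(empty_regain(task))
  per_first <- (l - 1L) * (length(alphabet) - 1L)
  total <- length(lost) * per_first
  sampled <- !(mode == "exhaustive" || total <= budget)
  per_budget <- if (sampled) max(1L, as.integer(budget %/% length(lost)))
                else per_first
  n_tested <- integer(length(lost))
  n_regain <- integer(length(lost))
  for (i in seq_along(lost)) {
    s <- s0
    s1 <- survey$site[lost[i]]
    s[s1] <- survey$symbol[lost[i]]
    tested <- 0L
    regain <- 0L
    if (!sampled) {
      for (site in setdiff(seq_len(l), s1)) {
        for (a in alphabet[alphabet != s[site]]) {
          mutant <- s
          mutant[site] <- a
          r <- fn(paste0(mutant, collapse = ""))
          tested <- tested + 1L
          if (!is.null(r$tasks) && task %in% r$tasks) regain <- regain + 1L
        }
      }
    } else {
      for (b in seq_len(per_budget)) {
        site <- sample(setdiff(seq_len(l), s1), 1)
        a <- sample(alphabet[alphabet != s[site]], 1)
        mutant <- s
        mutant[site] <- a
        r <- fn(paste0(mutant, collapse = ""))
        tested <- tested + 1L
        if (!is.null(r$tasks) && task %in% r$tasks) regain <- regain + 1L
      }
    }
    n_tested[i] <- tested
    n_regain[i] <- regain
  }
  build_regain(task, survey$site[lost], survey$symbol[lost], n_tested,
               n_regain, sampled)
}

empty_regain <- function(task) {
  structure(list(task = task, fraction = NA_real_,
                 mean_fraction = NA_real_, n_lost = 0L,
                 per_mutant = tibble::tibble(site = integer(),
                                             symbol = character(),
                                             n_tested = integer(),
                                             n_regain = integer(),
                                             fraction = numeric()),
                 sampled = FALSE),
            class = "regain_survey")
}

build_regain <- function(task, site, symbol, n_tested, n_regain, sampled) {
  per <- tibble::tibble(site = site, symbol = symbol,
                        n_tested = n_tested, n_regain = n_regain,
                        fraction = ifelse(n_tested > 0,
                                          n_regain / n_tested, NA_real_))
  structure(list(task = task,
                 fraction = sum(n_regain) / sum(n_tested),
                 mean_fraction = mean(per$fraction, na.rm = TRUE),
                 n_lost = nrow(per),
                 per_mutant = per,
                 sampled = sampled),
            class = "regain_survey")
}

#' @export
print.regain_survey <- function(x, ...) {
  cat("<regain_survey>", x$task, "|", x$n_lost, "task-losing mutants |",
      if (x$sampled) "sampled" else "exhaustive", "\n")
  cat("  pooled regain fraction:", signif(x$fraction, 6),
      "| mean per-mutant:", signif(x$mean_fraction, 6), "\n")
  invisible(x)
}

#' Sampled multi-mutation offspring survey
#'
#' Draws `n_offspring` offspring genomes through the mutation model
#' (multiple simultaneous substitutions allowed) and classifies them as in
#' [one_step_survey()]. As `mu` shrinks, the detrimental-fraction
#' estimate converges to the exhaustive single-step value.
#'
#' @param g Parent genome.
#' @param n_offspring Number of offspring to draw.
#' @param model A [mutation_model()].
#' @param evaluator A `vm_evaluator` or evaluator function.
#' @param alphabet Symbols per site for function evaluators.
#' @param epsilon Neutrality tolerance.
#' @return A list of class `sampled_survey`: `draws` tibble
#'   (`n_mutations`, `fitness`, `neutral`, `preserving`), `p_d`, `p_nu`,
#'   `p_pnu`, `se_p_d`.
#' @export
sampled_multimutation_survey <- function(g, n_offspring, model, evaluator,
                                         alphabet = letters,
                                         epsilon = 1e-9) {
  stopifnot(n_offspring > 0)
  vm <- inherits(evaluator, "vm_evaluator")
  if (vm) {
    g <- genome(g)
    max_steps <- if (is.null(evaluator$max_steps)) genome_length(g)
                 else evaluator$max_steps
    pg <- cpp_phenotype(genome_codes(g), evaluator$inputs, max_steps,
                        evaluator$ta$words, evaluator$ta$task0,
                        evaluator$ta$n)
    parent_fitness <- mask_fitness(matrix(pg$tasks, 1), pg$viable,
                                   evaluator$context)
    parent_key <- paste0(as.integer(pg$tasks), collapse = "")
  } else {
    parent <- evaluator(unclass(genome_chr(g)))
    parent_fitness <- parent$fitness
    parent_key <- parent$phenotype
  }
  rows <- lapply(seq_len(n_offspring), function(i) {
    off <- mutate_genome(g, model, alphabet = alphabet)
    if (vm) {
      ph <- cpp_phenotype(genome_codes(genome(off$genome)),
                          evaluator$inputs, max_steps,
                          evaluator$ta$words, evaluator$ta$task0,
                          evaluator$ta$n)
      fit <- mask_fitness(matrix(ph$tasks, 1), ph$viable,
                          evaluator$context)
      key <- paste0(as.integer(ph$tasks), collapse = "")
      viable <- ph$viable
    } else {
      r <- evaluator(off$genome)
      fit <- r$fitness
      key <- r$phenotype
      viable <- if (is.null(r$viable)) NA else r$viable
    }
    tibble::tibble(n_mutations = length(off$mutated_sites), fitness = fit,
                   preserving = key == parent_key &
                     (is.na(viable) | viable))
  })
  draws <- dplyr::bind_rows(rows)
  draws$neutral <- draws$fitness >= parent_fitness * (1 - epsilon)
  p_d <- mean(!draws$neutral)
  structure(list(draws = draws, p_d = p_d, p_nu = 1 - p_d,
                 p_pnu = mean(draws$preserving & draws$neutral),
                 se_p_d = sqrt(p_d * (1 - p_d) / nrow(draws)),
                 parent_fitness = parent_fitness),
            class = "sampled_survey")
}

#' Aggregate one-step surveys across environments
#'
#' Replaces every mutant's fitness (and the parent's) by its expected
#' value over the supplied per-environment surveys and recomputes the
#' neutrality classification from the expected fitnesses.
#'
#' @param surveys List of `neighborhood_survey` objects over the same
#'   parent genome, one per environment, in matching mutant order.
#' @param P Environment probabilities (non-negative, sum 1).
#' @return A `neighborhood_survey` with expected fitnesses.
#' @export
aggregate_across_environments <- function(surveys, P) {
  stopifnot(length(surveys) >= 1, length(P) == length(surveys))
  if (any(P < 0) || abs(sum(P) - 1) > 1e-9) {
    stop("`P` must be non-negative and sum to 1", call. = FALSE)
  }
  parents <- vapply(surveys, function(s) attr(s, "parent_genome"),
                    character(1))
  if (length(unique(parents)) != 1) {
    stop("surveys have different parent genomes", call. = FALSE)
  }
  base <- surveys[[1]]
  fit <- Reduce(`+`, Map(function(s, p) s$fitness * p, surveys, P))
  pf <- sum(vapply(surveys, function(s) attr(s, "parent_fitness"),
                   numeric(1)) * P)
  eps <- attr(base, "epsilon")
  out <- base
  out$fitness <- fit
  out$neutral <- fit >= pf * (1 - eps)
  finish_survey(out, attr(base, "ppnu"), eps,
                parent_genome = parents[1], parent_fitness = pf,
                parent_tasks = attr(base, "parent_tasks"),
                task_loss = attr(base, "task_loss"),
                masks = attr(base, "masks"),
                evaluator = attr(base, "evaluator"),
                alphabet = attr(base, "alphabet"))
}
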