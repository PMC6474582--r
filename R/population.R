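# Evolution on a toroidal grid: substitution mutation, energy-accrual
# reproduction with Moore-neighborhood replacement, and the two-stage
# experiment driver.

#' Substitution mutation model
#'
#' Each site is independently substituted with probability `mu`, uniformly
#' among the 25 non-parental symbols.
#'
#' @param mu Per-site substitution probability (default 0.00075).
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu = 0.00075) {
  if (mu < 0 || mu > 1) stop("`mu` must be in [0, 1]", call. = FALSE)
  structure(list(mu = mu), class = "mutation_model")
}

#' Mutate a genome
#'
#' @param g Parent genome (or any string over `alphabet`).
#' @param model A [mutation_model()].
#' @param alphabet Symbols available per site (default the 26 letters).
#' @return A list with `genome` (the child string) and `mutated_sites`
#'   (integer positions, 1-based).
#' @export
mutate_genome <- function(g, model, alphabet = letters) {
  stopifnot(inherits(model, "mutation_model"))
  g <- unclass(genome_chr(g))
  s <- strsplit(g, "")[[1]]
  hits <- which(stats::runif(length(s)) < model$mu)
  for (site in hits) {
    alts <- alphabet[alphabet != s[site]]
    s[site] <- alts[sample.int(length(alts), 1)]
  }
  list(genome = paste0(s, collapse = ""), mutated_sites = hits)
}

#' Configure an evolution experiment
#'
#' Defaults are the desk-scale study conditions: 20 x 20 torus, genome
#' length 60, 200-update phases and 200 stage-1 phases (the full design's
#' phase count, each phase 5x shorter). The full-scale configuration is a
#' 60 x 60 torus, length 121, 1000-update phases, 200 phases per stage
#' and mu = 0.00075.
#'
#' @param treatment Treatment name, see [environment_schedule()].
#' @param width,height Grid dimensions.
#' @param genome_length Fixed genome length `l`.
#' @param mu Per-site substitution probability.
#' @param cycle_length Updates per environmental phase.
#' @param stage1_cycles,stage2_cycles Number of phases per stage
#'   (stage2_cycles = 0 runs stage 1 only).
#' @param sampling_interval Updates between time-series samples.
#' @param threshold Non-ephemeral population fraction (default 0.001).
#' @param scheduler `"relative"` (default): energy gain per update is
#'   merit divided by the population's mean merit, so generation time is
#'   set by `cost` updates for an average-merit organism regardless of the
#'   absolute reward scale (merit-proportional CPU allocation);
#'   `"absolute"`: energy gain equals merit itself.
#' @param cost Gestation cost in energy units; defaults to 10 (about 20
#'   generations per desk-scale phase) under the relative scheduler and
#'   to `genome_length` under the absolute one.
#' @param seed Integer seed; every source of randomness derives from it.
#' @param ancestor Optional ancestor genome string; default: a
#'   [make_task_genome()] organism performing XOR and EQU.
#' @param max_steps Execution step budget (default `genome_length`).
#' @return An object of class `experiment_config`.
#' @details The desk-scale default `mu = 0.003` is four times the
#'   full-scale 0.00075: with 400 instead of 3600 cells and 200- instead
#'   of 1000-update phases it keeps the population's mutational supply
#'   per phase within a small factor of the full-scale study's.
#' @export
experiment_config <- function(treatment = "static", width = 20L,
                              height = 20L, genome_length = 60L,
                              mu = 0.003, cycle_length = 200L,
                              stage1_cycles = 200L, stage2_cycles = 0L,
                              sampling_interval = 10L, threshold = 0.001,
                              scheduler = c("relative", "absolute"),
                              cost = NULL, seed = 1L, ancestor = NULL,
                              max_steps = NULL) {
  scheduler <- match.arg(scheduler)
  stopifnot(width >= 3, height >= 3, genome_length >= 10,
            cycle_length >= 1, stage1_cycles >= 1, stage2_cycles >= 0,
            sampling_interval >= 1, threshold > 0, threshold < 1,
            mu >= 0, mu <= 1)
  if (is.null(cost)) {
    cost <- if (scheduler == "relative") 10 else genome_length
  }
  structure(list(treatment = treatment, scheduler = scheduler,
                 width = as.integer(width),
                 height = as.integer(height),
                 genome_length = as.integer(genome_length), mu = mu,
                 cycle_length = as.integer(cycle_length),
                 stage1_cycles = as.integer(stage1_cycles),
                 stage2_cycles = as.integer(stage2_cycles),
                 sampling_interval = as.integer(sampling_interval),
                 threshold = threshold, cost = cost,
                 seed = as.integer(seed), ancestor = ancestor,
                 max_steps = max_steps),
            class = "experiment_config")
}

#' Run a two-stage evolution experiment
#'
#' Seeds a single ancestor at the grid center and evolves it under the
#' configured schedule: stage 1 rewards the basic task set (XOR constant,
#' EQU per treatment); stage 2, if configured, adds the expanded task set.
#' Emits sampled time series (task performer counts, mean per-site
#' entropy, MRCA identity and depth, task discovery and performance),
#' the genotype-changing birth records of the phylogeny, and the final
#' population. Fully reproducible from `config$seed`.
#'
#' @param config An [experiment_config()].
#' @return An object of class `evo_run`; see Details.
#' @details The returned list contains `logs` (tibble of samples),
#'   `task_counts` (samples x tasks performer-count matrix), `phylogeny`
#'   (tibble: id, parent, update, depth, genotype; per-node mutations in
#'   attributes), `genotypes` (tibble: id, genome, viable), `population`
#'   (final grid tibble), `discovered` (final overall discovery flags),
#'   plus the catalog, schedule, inputs, ancestor and config used.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  set.seed(config$seed)
  catalog <- logic_tasks(3)
  inputs <- survey_inputs()
  l <- config$genome_length
  stage2_start <- config$stage1_cycles * config$cycle_length
  n_updates <- stage2_start + config$stage2_cycles * config$cycle_length
  schedule <- environment_schedule(config$treatment,
                                   cycle_length = config$cycle_length,
                                   stage2_start = stage2_start,
                                   tasks = catalog$name)
  ancestor <- config$ancestor
  if (is.null(ancestor)) {
    ancestor <- unclass(make_task_genome(c("XOR", "EQU"), l = l,
                                         inputs = inputs,
                                         catalog = catalog,
                                         verify = FALSE)$genome)
  }
  stopifnot(nchar(ancestor) == l)
  max_steps <- if (is.null(config$max_steps)) l else config$max_steps
  ta <- target_arrays(catalog, inputs)
  mm <- multiplier_matrix(schedule, catalog)
  center <- (config$height %/% 2) * config$width + config$width %/% 2 + 1L

  raw <- cpp_run_evolution(
    init_cells = center,
    init_genomes = list(genome_codes(genome(ancestor))),
    W = config$width, H = config$height, mu = config$mu,
    cost = config$cost, n_updates = n_updates, start_update = 0L,
    multipliers = mm, cycle_length = config$cycle_length,
    stage2_start = stage2_start, inputs = inputs, max_steps = max_steps,
    sorted_words = ta$words, word_task0 = ta$task0, n_tasks = ta$n,
    n_symbols = N_SYMBOLS, sampling_interval = config$sampling_interval,
    init_energy = 0,
    relative_scheduler = config$scheduler == "relative")

  finish_run(raw, config, catalog, schedule, inputs, ancestor,
             stage2_start)
}

# assemble an evo_run object from the C++ result
finish_run <- function(raw, config, catalog, schedule, inputs, ancestor,
                       stage2_start) {
  s <- raw$samples
  counts <- s$task_counts
  colnames(counts) <- catalog$name
  capacity <- config$width * config$height
  thr <- non_ephemeral_threshold(capacity, config$threshold)
  non_eph <- counts >= thr
  logs <- tibble::tibble(
    update = s$update,
    occupied = s$occupied,
    births = s$births,
    mean_entropy = s$entropy,
    mrca = s$mrca,
    mrca_depth = s$mrca_depth,
    dominant = s$dominant,
    equ_performers = counts[, "EQU"],
    xor_performers = counts[, "XOR"],
    performed = rowSums(non_eph),
    discovered_overall = cumulative_discovery(non_eph),
    phase = as.integer(((s$update - 1L) %/% config$cycle_length) %% 2),
    stage = ifelse(s$update - 1L >= stage2_start, 2L, 1L)
  )
  post <- s$update - 1L >= stage2_start
  logs$discovered_post <- NA_integer_
  if (any(post)) {
    logs$discovered_post[post] <-
      cumulative_discovery(non_eph[post, , drop = FALSE])
  }
  ph <- raw$phylogeny
  phylo <- tibble::tibble(
    id = seq_along(ph$parent),
    parent = ifelse(ph$parent < 0, NA_integer_, ph$parent + 1L),
    update = ph$update,
    depth = ph$depth,
    genotype = ph$genotype + 1L,
    changed = !is.na(ifelse(ph$parent < 0, NA_integer_, 1L))
  )
  attr(phylo, "mut_offset") <- ph$mut_offset
  attr(phylo, "mut_site") <- ph$mut_site
  attr(phylo, "mut_symbol") <- ph$mut_symbol
  genotypes <- tibble::tibble(id = seq_along(raw$genotypes$genome),
                              genome = as.character(raw$genotypes$genome),
                              viable = raw$genotypes$viable)
  W <- config$width
  cells <- seq_len(capacity)
  population <- tibble::tibble(
    cell = cells,
    x = (cells - 1L) %% W + 1L,
    y = (cells - 1L) %/% W + 1L,
    genotype = ifelse(raw$grid == 0, NA_integer_, raw$grid),
    node = ifelse(raw$node == 0, NA_integer_, raw$node),
    energy = raw$energy
  )
  structure(list(logs = logs, task_counts = counts, phylogeny = phylo,
                 genotypes = genotypes, population = population,
                 discovered = apply(non_eph, 2, any),
                 catalog = catalog, schedule = schedule, inputs = inputs,
                 ancestor = ancestor, config = config,
                 n_births = raw$n_births),
            class = "evo_run")
}

#' @export
print.evo_run <- function(x, ...) {
  cfg <- x$config
  cat("<evo_run>", cfg$treatment, "|", cfg$width, "x", cfg$height,
      "torus | l =", cfg$genome_length, "| mu =", cfg$mu, "\n")
  cat("  ", max(x$logs$update), "updates,", format(x$n_births, big.mark = ","),
      "births,", nrow(x$phylogeny), "genotype-changing;",
      nrow(x$genotypes), "distinct genotypes\n")
  cat("  final: EQU performers", dplyr::last(x$logs$equ_performers),
      "| mean entropy", signif(dplyr::last(x$logs$mean_entropy), 4),
      "| MRCA depth", dplyr::last(x$logs$mrca_depth), "\n")
  invisible(x)
}

#' Create a small world for stepwise inspection
#'
#' A `world` holds explicit organisms on a toroidal grid and can be
#' advanced update by update with [step_update()]. Useful for examining
#' the update rule at small scale; [run_experiment()] is the driver for
#' full experiments.
#'
#' @param organisms Tibble (or data frame) with columns `cell` (1-based
#'   grid index) and `genome` (strings of equal length), optionally
#'   `energy`.
#' @param width,height Grid dimensions.
#' @param schedule An `env_schedule`.
#' @param catalog A `task_catalog`.
#' @param inputs Evaluation input triple.
#' @param model A [mutation_model()].
#' @param cost Gestation cost (default genome length).
#' @param max_steps Execution budget (default genome length).
#' @return An object of class `world`.
#' @export
make_world <- function(organisms, width, height, schedule, catalog,
                       inputs, model = mutation_model(), cost = NULL,
                       max_steps = NULL) {
  stopifnot(all(c("cell", "genome") %in% names(organisms)),
            nrow(organisms) >= 1,
            all(organisms$cell >= 1),
            all(organisms$cell <= width * height),
            !any(duplicated(organisms$cell)))
  l <- nchar(organisms$genome[1])
  stopifnot(all(nchar(organisms$genome) == l))
  if (is.null(cost)) cost <- l
  if (is.null(max_steps)) max_steps <- l
  if (!"energy" %in% names(organisms)) organisms$energy <- 0
  structure(list(organisms = tibble::as_tibble(organisms),
                 width = as.integer(width), height = as.integer(height),
                 schedule = schedule, catalog = catalog,
                 inputs = as_word(inputs), model = model, cost = cost,
                 max_steps = max_steps, update = 0L,
                 last = NULL),
            class = "world")
}

#' Advance a world by whole updates
#'
#' One update: every organism gains energy equal to its fitness at the
#' current update; any organism whose energy reaches the gestation cost
#' reproduces -- the child (mutated per the model) is placed in a
#' uniformly random cell of the parent's Moore neighborhood, replacing
#' the occupant; parent and child energies reset to 0. Cells act in fixed
#' scan order; newborns act from the next update.
#'
#' @param world A `world`.
#' @param n_updates Number of updates to advance (default 1).
#' @return The advanced `world`; `$last` holds the C++ sample of the final
#'   update (occupancy, births, entropy, task counts).
#' @export
step_update <- function(world, n_updates = 1L) {
  stopifnot(inherits(world, "world"), n_updates >= 1)
  org <- world$organisms
  ta <- target_arrays(world$catalog, world$inputs)
  mm <- multiplier_matrix(world$schedule, world$catalog)
  raw <- cpp_run_evolution(
    init_cells = as.integer(org$cell),
    init_genomes = lapply(org$genome, function(g) genome_codes(genome(g))),
    W = world$width, H = world$height, mu = world$model$mu,
    cost = world$cost, n_updates = as.integer(n_updates),
    start_update = world$update,
    multipliers = mm, cycle_length = world$schedule$cycle_length,
    stage2_start = world$schedule$stage2_start,
    inputs = world$inputs, max_steps = world$max_steps,
    sorted_words = ta$words, word_task0 = ta$task0, n_tasks = ta$n,
    n_symbols = N_SYMBOLS, sampling_interval = as.integer(n_updates),
    init_energy = as.numeric(org$energy),
    relative_scheduler = FALSE)
  occupied <- which(raw$grid > 0)
  world$organisms <- tibble::tibble(
    cell = occupied,
    genome = as.character(raw$genotypes$genome)[raw$grid[occupied]],
    energy = raw$energy[occupied]
  )
  world$update <- world$update + as.integer(n_updates)
  world$last <- raw$samples
  world$last_births <- raw$n_births
  world
}

#' @export
print.world <- function(x, ...) {
  cat("<world>", x$width, "x", x$height, "| update", x$update, "|",
      nrow(x$organisms), "organisms\n")
  invisible(x)
}
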