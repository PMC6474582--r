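# Reward schedules: static control, benign and harsh cyclic fluctuation,
# and the stage-2 quiescent variants; merit (fitness) computation and
# expected fitness across environments.

#' Construct an environment reward schedule
#'
#' Defines the per-task fitness multipliers over the two-stage experiment.
#' XOR (the backbone task) is constantly rewarded with a 2^3 = 8-fold CPU
#' speed multiplier. EQU (the fluctuating task) is rewarded 2^5 = 32-fold:
#' constantly in the static control; in the benign treatment the reward
#' alternates with no reward (2^0); in the harsh treatment with a 32-fold
#' penalty (2^-5). A phase lasts `cycle_length` updates, reward first.
#' From `stage2_start` the expanded task set (all other catalog tasks)
#' earns a constant 1.2-fold bonus; quiescent treatments additionally stop
#' the fluctuation in stage 2 and reward the basic set constantly.
#'
#' @param treatment One of `"static"`, `"benign"`, `"harsh"`,
#'   `"benign_quiescent"`, `"harsh_quiescent"`.
#' @param cycle_length Updates per environmental phase (default 1000).
#' @param stage2_start Update at which stage 2 begins (default 200000).
#' @param xor_reward,equ_reward Reward-phase multipliers (defaults 8, 32).
#' @param equ_off Off-phase EQU multiplier; defaults to 1 (benign) or
#'   2^-5 (harsh); ignored for the static control.
#' @param expanded_bonus Stage-2 multiplier for expanded tasks (default 1.2).
#' @param tasks Character vector of recognized task names (typically
#'   `logic_tasks(3)$name`); defaults to the Logic-77 names.
#' @return An object of class `env_schedule`.
#' @export
environment_schedule <- function(treatment = c("static", "benign", "harsh",
                                               "benign_quiescent",
                                               "harsh_quiescent"),
                                 cycle_length = 1000L,
                                 stage2_start = 200000L,
                                 xor_reward = 2^3, equ_reward = 2^5,
                                 equ_off = NULL, expanded_bonus = 1.2,
                                 tasks = NULL) {
  treatment <- match.arg(treatment)
  if (cycle_length <= 0) stop("`cycle_length` must be positive", call. = FALSE)
  if (is.null(equ_off)) {
    equ_off <- switch(treatment,
                      static = equ_reward,
                      benign = , benign_quiescent = 1,
                      harsh = , harsh_quiescent = 2^-5)
  }
  if (is.null(tasks)) tasks <- logic_tasks(3)$name
  stopifnot(all(c("XOR", "EQU") %in% tasks),
            xor_reward > 0, equ_reward > 0, equ_off > 0, expanded_bonus > 0)
  structure(list(treatment = treatment,
                 cycle_length = as.integer(cycle_length),
                 stage2_start = as.integer(stage2_start),
                 xor_reward = xor_reward, equ_reward = equ_reward,
                 equ_off = equ_off, expanded_bonus = expanded_bonus,
                 tasks = tasks),
            class = "env_schedule")
}

#' @export
print.env_schedule <- function(x, ...) {
  cat("<env_schedule>", x$treatment,
      "| cycle", x$cycle_length, "updates | stage 2 from", x$stage2_start,
      "\n  XOR x", x$xor_reward, "| EQU x", x$equ_reward, "/",
      x$equ_off, "| expanded x", x$expanded_bonus, "(stage 2)\n")
  invisible(x)
}

#' Fitness multiplier of a task at a given update
#'
#' The phase is `floor(update / cycle_length) mod 2`; phase 0 rewards.
#' Quiescent treatments follow their parent treatment before
#' `stage2_start` and the static schedule for the basic set after it.
#'
#' @param schedule An `env_schedule`.
#' @param task A task name known to the schedule.
#' @param update Non-negative update (vectorized).
#' @return Numeric vector of positive multipliers.
#' @examples
#' sch <- environment_schedule("harsh")
#' task_multiplier(sch, "EQU", 0)     # 32
#' task_multiplier(sch, "EQU", 1000)  # 1/32
#' @export
task_multiplier <- function(schedule, task, update) {
  stopifnot(inherits(schedule, "env_schedule"))
  if (length(task) != 1 || !task %in% schedule$tasks) {
    stop("unknown task: ", paste(task, collapse = ","), call. = FALSE)
  }
  if (any(update < 0)) stop("`update` must be >= 0", call. = FALSE)
  phase <- (update %/% schedule$cycle_length) %% 2
  stage2 <- update >= schedule$stage2_start
  quiescent <- grepl("quiescent", schedule$treatment)
  if (task == "XOR") {
    rep(schedule$xor_reward, length(update))
  } else if (task == "EQU") {
    off <- ifelse(stage2 & quiescent, schedule$equ_reward, schedule$equ_off)
    ifelse(phase == 0, schedule$equ_reward, off)
  } else {
    ifelse(stage2, schedule$expanded_bonus, 1)
  }
}

#' Multiplier matrix over stage/phase rows
#'
#' Internal-facing helper: the four (stage, phase) combinations as rows
#' (stage 1 phase 0/1, stage 2 phase 0/1) by catalog task columns.
#'
#' @param schedule An `env_schedule`.
#' @param catalog A `task_catalog`.
#' @return A 4 x `nrow(catalog)` numeric matrix.
#' @export
multiplier_matrix <- function(schedule, catalog) {
  u <- c(0, schedule$cycle_length,
         schedule$stage2_start, schedule$stage2_start + schedule$cycle_length)
  # stage-2 representative updates must land in the right phase
  u[4] <- schedule$stage2_start +
    schedule$cycle_length * (1 + (schedule$stage2_start %/% schedule$cycle_length) %% 2)
  u[3] <- schedule$stage2_start +
    schedule$cycle_length * ((schedule$stage2_start %/% schedule$cycle_length) %% 2)
  m <- vapply(catalog$name, function(nm) task_multiplier(schedule, nm, u),
              numeric(4))
  dimnames(m) <- list(c("s1p0", "s1p1", "s2p0", "s2p1"), catalog$name)
  m
}

#' Merit (fitness) of a phenotype under a schedule
#'
#' Merit is multiplicative over performed tasks with base 1: the product
#' of the active task multipliers, or 0 for a non-viable organism. Merit
#' drives reproduction rate (CPU speed).
#'
#' @param phenotype A `phenotype` object, or a character vector of task
#'   names performed by a viable organism.
#' @param schedule An `env_schedule`.
#' @param update The update at which to evaluate.
#' @return A non-negative scalar.
#' @examples
#' sch <- environment_schedule("static")
#' organism_fitness(c("XOR"), sch, 0)        # 8
#' organism_fitness(c("XOR", "EQU"), sch, 0) # 256
#' @export
organism_fitness <- function(phenotype, schedule, update = 0) {
  if (inherits(phenotype, "phenotype")) {
    if (!phenotype$viable) return(0)
    performed <- names(phenotype$tasks)[phenotype$tasks]
  } else {
    performed <- as.character(phenotype)
  }
  if (length(performed) == 0) return(1)
  prod(vapply(performed, function(nm) task_multiplier(schedule, nm, update),
              numeric(1)))
}

#' Expected fitness across environments
#'
#' Aggregates per-environment fitness values by the probability of each
#' environment occurring: `E(w) = sum_i w_i P_i`.
#'
#' @param w Numeric vector of per-environment fitness values.
#' @param P Environment probabilities; non-negative, summing to 1 (within
#'   1e-9).
#' @return An object of class `expected_fitness` with fields `w`, `P`,
#'   `value`.
#' @examples
#' expected_fitness(c(32, 2^-5), c(0.5, 0.5))$value
#' @export
expected_fitness <- function(w, P) {
  if (length(w) != length(P)) {
    stop("`w` and `P` must have equal length", call. = FALSE)
  }
  if (any(P < 0) || abs(sum(P) - 1) > 1e-9) {
    stop("`P` must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(w = w, P = P, value = sum(w * P)),
            class = "expected_fitness")
}

#' @export
print.expected_fitness <- function(x, ...) {
  cat("<expected_fitness> E(w) =", x$value, "over", length(x$w),
      "environment(s)\n")
  invisible(x)
}

#' Tabulate a schedule's multipliers for audit
#'
#' @param schedule An `env_schedule`.
#' @param updates Updates at which to report (default: one per phase of
#'   each stage).
#' @param tasks Task names to include (default XOR, EQU and one expanded
#'   representative).
#' @return A tibble with columns `update`, `stage`, `phase`, `task`,
#'   `multiplier`.
#' @export
describe_schedule <- function(schedule, updates = NULL, tasks = NULL) {
  stopifnot(inherits(schedule, "env_schedule"))
  if (is.null(updates)) {
    updates <- c(0L, schedule$cycle_length,
                 schedule$stage2_start,
                 schedule$stage2_start + schedule$cycle_length)
  }
  if (is.null(tasks)) {
    tasks <- intersect(c("XOR", "EQU", "NAND"), schedule$tasks)
  }
  out <- tidyr::expand_grid(update = as.integer(updates), task = tasks)
  out$stage <- ifelse(out$update >= schedule$stage2_start, 2L, 1L)
  out$phase <- as.integer((out$update %/% schedule$cycle_length) %% 2)
  out$multiplier <- vapply(seq_len(nrow(out)), function(i) {
    task_multiplier(schedule, out$task[i], out$update[i])
  }, numeric(1))
  out[, c("update", "stage", "phase", "task", "multiplier")]
}
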