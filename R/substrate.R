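#' @useDynLib mutscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# letters with special roles in the instruction set
INERT_SYMBOL <- "a"
INERT_SYMBOLS <- c("a", "b", "c", "z")
REPRO_SYMBOL <- "y"
N_SYMBOLS <- 26L

#' The 26-instruction set of the virtual CPU
#'
#' The substrate executes fixed-length genomes over a 26-symbol alphabet
#' (letters a-z) on a deterministic 3-register (AX, BX, CX) machine with a
#' small stack and cycling input cursor. Each site therefore has exactly 25
#' alternative symbols under substitution. `a` is the designated inert
#' instruction used for knockouts (`b`, `c`, `z` are also inert), `y` is the
#' replication instruction, `d`/`e` are the input/output instructions and
#' `l` is NAND, which together with io suffices to express every logic task.
#'
#' @return A tibble with columns `symbol`, `name`, `description`.
#' @export
instruction_set <- function() {
  tibble::tibble(
    symbol = letters,
    name = c("nop-a", "nop-b", "nop-c", "io-load", "io-emit", "swap",
             "mov-cb", "mov-ab", "mov-ba", "push", "pop", "nand", "and",
             "or", "xor", "not", "shl", "shr", "rewind", "inc", "zero",
             "ones", "add", "sub", "repro", "nop-z"),
    description = c(
      "inert (knockout filler)", "inert", "inert",
      "BX <- next input word (cursor cycles)",
      "emit BX as an output", "swap BX and CX", "CX <- BX", "AX <- BX",
      "BX <- AX", "push BX", "pop into BX (0 if empty)",
      "BX <- NOT(BX AND CX)", "BX <- BX AND CX", "BX <- BX OR CX",
      "BX <- BX XOR CX", "BX <- NOT BX", "BX <- BX << 1", "BX <- BX >> 1",
      "reset the input cursor", "BX <- BX + 1", "BX <- 0",
      "BX <- all ones", "BX <- BX + CX", "BX <- BX - CX",
      "mark replication", "inert")
  )
}

#' Construct and validate a genome
#'
#' A genome is a fixed-length sequence over the 26-letter instruction
#' alphabet, held as a single lowercase string. Genomes are logically
#' circular during execution and serialized linearly from a fixed origin.
#'
#' @param sequence A single string of letters a-z.
#' @return The validated sequence with class `genome`.
#' @examples
#' g <- genome(strrep("a", 10))
#' genome_length(g)
#' @export
genome <- function(sequence) {
  if (inherits(sequence, "genome")) return(sequence)
  if (!is.character(sequence) || length(sequence) != 1 || is.na(sequence)) {
    stop("`sequence` must be a single string", call. = FALSE)
  }
  if (!grepl("^[a-z]+$", sequence)) {
    stop("genome may contain only letters a-z", call. = FALSE)
  }
  structure(sequence, class = "genome")
}

#' @rdname genome
#' @param g A genome.
#' @export
genome_length <- function(g) nchar(unclass(genome(g)))

#' @export
print.genome <- function(x, ...) {
  cat("<genome> length", genome_length(x), "\n")
  cat(unclass(x), "\n")
  invisible(x)
}

genome_codes <- function(g) {
  utf8ToInt(unclass(genome(g))) - utf8ToInt("a")
}

codes_genome <- function(codes) {
  genome(intToUtf8(codes + utf8ToInt("a")))
}

#' Draw a collision-free evaluation input triple
#'
#' Experiments evaluate every organism against one fixed triple of 32-bit
#' machine words. A triple is accepted only if its 32 bit-columns cover all
#' 8 three-bit patterns; under that condition any two distinct boolean
#' functions of the inputs produce distinct output words, so no two catalog
#' tasks (nor a task and a plain input echo) can collide in detection.
#'
#' @param seed Optional integer seed; when supplied, the current RNG state
#'   is left untouched.
#' @return Three machine words (doubles in `[0, 2^32)`) with attribute
#'   `n_rejected`.
#' @export
survey_inputs <- function(seed = NULL) {
  draw <- function() {
    rejected <- 0L
    repeat {
      w <- floor(stats::runif(3, 0, 2^32))
      if (input_patterns_covered(w)) {
        attr(w, "n_rejected") <- rejected
        return(w)
      }
      rejected <- rejected + 1L
    }
  }
  if (is.null(seed)) return(draw())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  draw()
}

input_patterns_covered <- function(words) {
  words <- as_word(words)
  seen <- rep(FALSE, 8)
  for (b in 0:31) {
    r <- 0L
    for (j in 1:3) {
      if ((words[j] %/% 2^b) %% 2 >= 1) r <- r + 2L^(j - 1L)
    }
    seen[r + 1L] <- TRUE
    if (all(seen)) return(TRUE)
  }
  all(seen)
}

#' Execute a genome on the virtual CPU
#'
#' Runs the deterministic virtual CPU for at most `max_steps` instructions
#' (default: one full pass over the genome; the instruction pointer wraps
#' circularly if more are requested). Execution always halts within the
#' step budget; malformed programs simply emit nothing.
#'
#' @param g A genome (or string).
#' @param inputs Machine words available to `io-load` (doubles in `[0, 2^32)`).
#' @param max_steps Positive step budget; default `genome_length(g)`.
#' @return A list with `outputs` (machine words emitted, in order) and
#'   `replicated` (TRUE iff the replication instruction executed).
#' @export
execute_genome <- function(g, inputs, max_steps = NULL) {
  g <- genome(g)
  if (is.null(max_steps)) max_steps <- genome_length(g)
  if (max_steps <= 0) stop("`max_steps` must be positive", call. = FALSE)
  cpp_execute(genome_codes(g), as_word(inputs), as.integer(max_steps))
}

# internal: (sorted word, 0-based task) lookup arrays for the C++ core;
# words are doubles in [0, 2^32), sorted ascending (= unsigned order).
# Memoized per (inputs, catalog size): target enumeration dominates
# otherwise.
.target_cache <- new.env(parent = emptyenv())
target_arrays <- function(catalog, inputs) {
  inputs <- as_word(inputs)
  key <- paste(c(nrow(catalog), format(inputs, digits = 12)),
               collapse = "_")
  hit <- .target_cache[[key]]
  if (!is.null(hit)) return(hit)
  tg <- task_targets(catalog, inputs)
  ord <- order(tg$word)
  out <- list(words = as.numeric(tg$word[ord]),
              task0 = as.integer(match(tg$id[ord], catalog$id) - 1L),
              n = nrow(catalog))
  if (length(.target_cache) > 32) {
    rm(list = ls(.target_cache), envir = .target_cache)
  }
  .target_cache[[key]] <- out
  out
}

#' Evaluate the phenotype of a genome
#'
#' Executes the genome and detects the logic tasks its outputs perform.
#' Viability requires the replication instruction to execute; a non-viable
#' organism performs no tasks by definition.
#'
#' @inheritParams execute_genome
#' @param catalog A `task_catalog`.
#' @return An object of class `phenotype`: list with `viable` (logical) and
#'   `tasks` (named logical vector over the catalog).
#' @export
evaluate_phenotype <- function(g, inputs, catalog, max_steps = NULL) {
  g <- genome(g)
  if (is.null(max_steps)) max_steps <- genome_length(g)
  ta <- target_arrays(catalog, inputs)
  res <- cpp_phenotype(genome_codes(g), as_word(inputs),
                       as.integer(max_steps), ta$words, ta$task0, ta$n)
  new_phenotype(res$viable, res$tasks, catalog)
}

new_phenotype <- function(viable, mask, catalog) {
  tasks <- as.logical(mask)
  names(tasks) <- catalog$name
  structure(list(viable = viable, tasks = tasks), class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  on <- names(x$tasks)[x$tasks]
  cat("<phenotype>", if (x$viable) "viable" else "non-viable",
      "| tasks:", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Knock out a genome site
#'
#' Replaces the instruction at `site` by the designated inert instruction
#' (`a`), leaving length unchanged. Used to identify functional sites.
#'
#' @param g A genome.
#' @param site Site index, 1-based.
#' @return The knocked-out genome.
#' @export
knockout_site <- function(g, site) {
  g <- genome(g)
  l <- genome_length(g)
  if (!is.numeric(site) || length(site) != 1 || is.na(site) ||
      site < 1 || site > l) {
    stop("`site` must be in 1..", l, call. = FALSE)
  }
  s <- strsplit(unclass(g), "")[[1]]
  s[site] <- INERT_SYMBOL
  genome(paste0(s, collapse = ""))
}

#' Classify every site of a viable genome by knockout
#'
#' Performs all `l` single-site knockouts and labels each site by its
#' functional role: `"replication"` if the knockout is non-viable (the site
#' is critical for replication), otherwise the sorted `+`-joined names of
#' the tasks lost (e.g. `"EQU"`, `"XOR+EQU"`), or `"none"` if the knockout
#' changes nothing.
#'
#' @inheritParams evaluate_phenotype
#' @return A tibble with columns `site`, `symbol`, `viable` (of the
#'   knockout), `tasks_lost` (list of task names) and `label`. The parent
#'   phenotype is attached as attribute `parent_phenotype`.
#' @export
classify_sites <- function(g, inputs, catalog, max_steps = NULL) {
  g <- genome(g)
  l <- genome_length(g)
  if (is.null(max_steps)) max_steps <- l
  parent <- evaluate_phenotype(g, inputs, catalog, max_steps)
  if (!parent$viable) {
    stop("cannot classify sites of a non-viable genome", call. = FALSE)
  }
  ta <- target_arrays(catalog, inputs)
  ko <- cpp_knockout_masks(genome_codes(g),
                           utf8ToInt(INERT_SYMBOL) - utf8ToInt("a"),
                           as_word(inputs), as.integer(max_steps),
                           ta$words, ta$task0, ta$n)
  masks <- ko$tasks
  lost <- lapply(seq_len(l), function(s) {
    catalog$name[parent$tasks & !masks[s, ]]
  })
  label <- vapply(seq_len(l), function(s) {
    if (!ko$viable[s]) "replication"
    else if (length(lost[[s]]) > 0) {
      paste(catalog$name[catalog$name %in% lost[[s]]], collapse = "+")
    } else "none"
  }, character(1))
  out <- tibble::tibble(
    site = seq_len(l),
    symbol = strsplit(unclass(g), "")[[1]],
    viable = as.logical(ko$viable),
    tasks_lost = lost,
    label = label
  )
  attr(out, "parent_phenotype") <- parent
  out
}

#' Count functional sites per label from a site classification
#'
#' Convenience summary of [classify_sites()]: the number of sites whose
#' knockout loses each task combination, plus replication-critical sites.
#'
#' @param classification Output of [classify_sites()].
#' @return A tibble with columns `label` and `n_sites`.
#' @export
count_functional_sites <- function(classification) {
  dplyr::count(classification, label = .data$label, name = "n_sites")
}

#' @importFrom rlang .data
NULL
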