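#' Enumerate the catalog of bitwise logic tasks
#'
#' Builds the catalog of boolean logic functions of 1 to `max_inputs` inputs
#' that define organism phenotypes. Functions are deduplicated under
#' permutation of their inputs, and the two constant functions and the
#' single-input identity (echo) are excluded. With `max_inputs = 3` this
#' yields the 77-task "Logic-77" set; with 2 it yields the classic logic-9
#' set (NOT, NAND, AND, ORN, OR, ANDN, NOR, XOR, EQU); with 1 only NOT.
#'
#' XOR and EQU form the *basic* task set (the constantly rewarded backbone
#' task and the fluctuating task); all remaining tasks are the *expanded*
#' task set, rewarded only in stage 2 of the two-stage experimental design.
#'
#' @param max_inputs Maximum task arity, an integer in 1..3.
#' @return A tibble of class `task_catalog` with columns `id`, `name`,
#'   `arity`, `basic` (logical; TRUE for XOR and EQU), `bits` (canonical
#'   truth table as a bit string, input row 0 first) and `truth_table`
#'   (list column of logical vectors of length `2^arity`). Rows are ordered
#'   by arity, then canonical truth table (lexicographic).
#' @examples
#' logic_tasks(2)
#' nrow(logic_tasks(3)) # 77
#' @export
logic_tasks <- function(max_inputs = 3) {
  if (!is.numeric(max_inputs) || length(max_inputs) != 1 ||
      is.na(max_inputs) || max_inputs != as.integer(max_inputs) ||
      max_inputs < 1 || max_inputs > 3) {
    stop("`max_inputs` must be an integer in 1, 2, 3", call. = FALSE)
  }
  max_inputs <- as.integer(max_inputs)

  rows <- list()
  for (k in seq_len(max_inputs)) {
    n_rows <- 2L^k
    seen <- character()
    # enumerate all 2^(2^k) functions in increasing truth-table order
    for (code in 0:(2L^n_rows - 1L)) {
      tt <- as.logical(bitwAnd(bitwShiftR(code, 0:(n_rows - 1L)), 1L))
      if (!tt_essential(tt, k)) next          # drops constants and
      if (k == 1L && tt[1] == FALSE) next     # arity-padded functions; echo
      key <- tt_canonical_key(tt, k)
      if (key %in% seen) next
      seen <- c(seen, key)
      rows[[length(rows) + 1L]] <- list(arity = k, bits = key)
    }
  }

  out <- tibble::tibble(
    arity = vapply(rows, function(r) r$arity, integer(1)),
    bits = vapply(rows, function(r) r$bits, character(1))
  )
  out <- out[order(out$arity, out$bits), ]
  out$id <- seq_len(nrow(out))
  out$truth_table <- lapply(out$bits, function(b) {
    as.logical(as.integer(strsplit(b, "")[[1]]))
  })
  out$name <- task_names(out$bits, out$arity)
  out$basic <- out$name %in% c("XOR", "EQU")
  out <- out[, c("id", "name", "arity", "basic", "bits", "truth_table")]
  structure(out, class = c("task_catalog", class(tibble::tibble())),
            max_inputs = max_inputs)
}

# TRUE iff the truth table depends on every one of its k inputs: for each
# input j there must be a row whose output changes when bit j is flipped.
tt_essential <- function(tt, k) {
  r <- 0:(length(tt) - 1L)
  for (j in seq_len(k)) {
    flip <- bitwXor(r, 2L^(j - 1L))
    if (all(tt == tt[flip + 1L])) return(FALSE)
  }
  TRUE
}

# Canonical key: lexicographically smallest truth-table bit string over all
# permutations of the inputs. Row index convention: bit (j-1) of the row is
# the value of input j.
tt_canonical_key <- function(tt, k) {
  perms <- input_permutations(k)
  r <- 0:(length(tt) - 1L)
  keys <- vapply(perms, function(p) {
    # row r of the permuted function: input j takes the value that input
    # p[j] had, i.e. new row bits are a shuffle of the old row bits
    newr <- integer(length(r))
    for (j in seq_len(k)) {
      bit <- bitwAnd(bitwShiftR(r, p[j] - 1L), 1L)
      newr <- bitwOr(newr, bitwShiftL(bit, j - 1L))
    }
    paste0(as.integer(tt[newr + 1L]), collapse = "")
  }, character(1))
  min(keys)
}

input_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  if (k == 2L) return(list(c(1L, 2L), c(2L, 1L)))
  list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
       c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
}

# Field names for the 1- and 2-input tasks; 3-input tasks are named by the
# hex value of their canonical truth table (row 0 = least significant bit).
task_names <- function(bits, arity) {
  known <- c(
    "10"   = "NOT",
    "0001" = "AND",  "0111" = "OR",   "1110" = "NAND", "1000" = "NOR",
    "0110" = "XOR",  "1001" = "EQU",  "0010" = "ANDN", "1011" = "ORN"
  )
  nm <- unname(known[bits])
  miss <- is.na(nm)
  if (any(miss)) {
    val <- vapply(bits[miss], function(b) {
      d <- as.integer(strsplit(b, "")[[1]])
      as.integer(sum(d * 2^(seq_along(d) - 1)))
    }, integer(1))
    nm[miss] <- sprintf("L%d_%02X", arity[miss], val)
  }
  nm
}

# --- 32-bit machine words ---------------------------------------------------
# Words are represented as doubles in [0, 2^32): R's integer type cannot
# hold the bit pattern 0x80000000 (it is NA_integer_). Bitwise operations
# split each word into two 16-bit halves, which base bitwAnd/bitwOr handle
# exactly.

#' Bitwise operations on 32-bit machine words
#'
#' Machine words are doubles in `[0, 2^32)`. These helpers implement the
#' bitwise operations the logic tasks are built from.
#'
#' @param a,b Words (vectorized).
#' @return A word (double).
#' @examples
#' word_not(0) # 4294967295
#' word_and(12, 10)
#' @export
word_and <- function(a, b) {
  bitwAnd(a %/% 65536, b %/% 65536) * 65536 +
    bitwAnd(a %% 65536, b %% 65536)
}

#' @rdname word_and
#' @export
word_or <- function(a, b) {
  bitwOr(a %/% 65536, b %/% 65536) * 65536 +
    bitwOr(a %% 65536, b %% 65536)
}

#' @rdname word_and
#' @export
word_xor <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 +
    bitwXor(a %% 65536, b %% 65536)
}

#' @rdname word_and
#' @export
word_not <- function(a) {
  (65535 - a %/% 65536) * 65536 + (65535 - a %% 65536)
}

# normalize any numeric to the double-word representation
as_word <- function(x) {
  x <- as.numeric(x)
  ifelse(x < 0, x + 2^32, x)
}

#' Target output words for every task under a fixed input tuple
#'
#' For each task and each ordered selection of `arity` distinct inputs from
#' `inputs`, computes the machine word the task would produce bitwise. An
#' organism is credited with a task iff it emits one of that task's target
#' words. Words are 32-bit, represented as doubles in `[0, 2^32)`.
#'
#' @param catalog A `task_catalog`.
#' @param inputs Machine words (length >= max arity).
#' @return A tibble with columns `id` (task id) and `word`, one row per
#'   distinct (task, target word) pair.
#' @export
task_targets <- function(catalog, inputs) {
  stopifnot(inherits(catalog, "task_catalog"))
  inputs <- as_word(inputs)
  if (length(inputs) < max(catalog$arity)) {
    stop("need at least ", max(catalog$arity), " inputs", call. = FALSE)
  }
  res <- lapply(seq_len(nrow(catalog)), function(i) {
    tt <- catalog$truth_table[[i]]
    k <- catalog$arity[i]
    words <- unique(vapply(
      ordered_tuples(length(inputs), k),
      function(sel) apply_truth_table(tt, inputs[sel]),
      numeric(1)
    ))
    tibble::tibble(id = catalog$id[i], word = words)
  })
  dplyr::bind_rows(res)
}

# All ordered tuples of k distinct indices out of n.
ordered_tuples <- function(n, k) {
  combs <- utils::combn(n, k, simplify = FALSE)
  out <- list()
  for (cm in combs) {
    for (p in input_permutations(k)) {
      out[[length(out) + 1L]] <- cm[p]
    }
  }
  unique(out)
}

# Apply a truth table bitwise to k machine words.
apply_truth_table <- function(tt, words) {
  words <- as_word(words)
  k <- length(words)
  out <- 0
  for (r in 0:(2L^k - 1L)) {
    if (!tt[r + 1L]) next
    term <- word_not(0)
    for (j in seq_len(k)) {
      x <- if (bitwAnd(r, 2L^(j - 1L)) != 0L) words[j] else
        word_not(words[j])
      term <- word_and(term, x)
    }
    out <- word_or(out, term)
  }
  out
}

#' Detect which tasks a set of outputs performs
#'
#' Task T is detected iff some emitted output equals T applied bitwise to
#' some ordered selection of distinct inputs. Each task is credited at most
#' once per organism, however many outputs match it.
#'
#' @param outputs Integer vector of emitted machine words.
#' @param inputs Integer vector of the machine words supplied as inputs.
#' @param catalog A `task_catalog`.
#' @return Sorted integer vector of detected task ids.
#' @export
detect_tasks <- function(outputs, inputs, catalog) {
  if (length(inputs) == 0) stop("`inputs` must be non-empty", call. = FALSE)
  stopifnot(inherits(catalog, "task_catalog"))
  if (length(outputs) == 0) return(integer())
  tg <- task_targets(catalog, inputs)
  sort(unique(tg$id[tg$word %in% as_word(outputs)]))
}

#' Export a task catalog as JSON
#'
#' Writes one record per task with its id, name, arity and truth table as a
#' bit string (input row 0 first).
#'
#' @param catalog A `task_catalog`.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string when `path` is `NULL`.
#' @export
write_task_catalog_json <- function(catalog, path = NULL) {
  stopifnot(inherits(catalog, "task_catalog"))
  rec <- catalog[, c("id", "name", "arity", "bits")]
  names(rec)[names(rec) == "bits"] <- "truth_table"
  js <- jsonlite::toJSON(rec, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
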