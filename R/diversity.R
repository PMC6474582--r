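# Population diversity (per-site Shannon entropy) and task discovery /
# performance counters with the non-ephemeral threshold.

#' Per-site Shannon entropy of a population
#'
#' For each genome site, `H = -sum_s f_s log2 f_s` over the population's
#' symbol frequencies at that site (bits; 0 for a monomorphic site, up to
#' log2(26) ~ 4.70 for a uniformly random site).
#'
#' @param genomes Character vector of equal-length genome strings, one
#'   per individual (repeats allowed), or a character matrix
#'   (individuals x sites).
#' @return A tibble of class `entropy_profile` with columns `site`,
#'   `entropy`, and attribute `mean` (the mean over sites).
#' @examples
#' per_site_entropy(c("aaab", "aaab", "caab", "caab"))
#' @export
per_site_entropy <- function(genomes) {
  if (is.matrix(genomes)) {
    m <- genomes
  } else {
    if (length(genomes) == 0) {
      stop("population must be non-empty", call. = FALSE)
    }
    stopifnot(is.character(genomes))
    m <- do.call(rbind, strsplit(genomes, ""))
  }
  ent <- vapply(seq_len(ncol(m)), function(s) {
    f <- table(m[, s]) / nrow(m)
    -sum(f * log2(f))
  }, numeric(1))
  out <- tibble::tibble(site = seq_len(ncol(m)), entropy = ent)
  structure(out, class = c("entropy_profile", class(out)),
            mean = mean(ent), n = nrow(m))
}

#' @rdname per_site_entropy
#' @param profile An `entropy_profile`.
#' @export
mean_entropy <- function(profile) attr(profile, "mean")

#' Non-ephemeral performer threshold
#'
#' A task is non-ephemeral when performed by strictly more than
#' `threshold` of the population capacity: the smallest such integer
#' count (at least 1). At the full-scale capacity of 3600 cells and the
#' 0.1% threshold this is 4 performers.
#'
#' @param capacity Population capacity (cells).
#' @param threshold Population fraction (default 0.001).
#' @return Integer count.
#' @examples
#' non_ephemeral_threshold(3600) # 4
#' @export
non_ephemeral_threshold <- function(capacity, threshold = 0.001) {
  stopifnot(threshold > 0, threshold < 1, capacity >= 1)
  max(1L, as.integer(floor(threshold * capacity)) + 1L)
}

#' Update a monotone task-discovery state
#'
#' A task joins the discovered set when its performer count meets the
#' non-ephemeral threshold at a sampling point; once discovered, a task
#' is never un-discovered.
#'
#' @param state Character vector of previously discovered task names
#'   (possibly empty).
#' @param performer_counts Named integer vector: task name -> number of
#'   organisms performing it at this sample.
#' @param capacity Population capacity.
#' @param threshold Non-ephemeral fraction (default 0.001).
#' @return The updated character vector of discovered task names.
#' @export
update_task_discovery <- function(state, performer_counts, capacity,
                                  threshold = 0.001) {
  thr <- non_ephemeral_threshold(capacity, threshold)
  union(state, names(performer_counts)[performer_counts >= thr])
}

#' Count currently performed non-ephemeral tasks
#'
#' The number of unique tasks whose performer count meets the
#' non-ephemeral threshold at this sample -- never more than the number
#' of tasks discovered so far when tracked alongside
#' [update_task_discovery()].
#'
#' @inheritParams update_task_discovery
#' @return Integer count.
#' @export
task_performance_count <- function(performer_counts, capacity,
                                   threshold = 0.001) {
  thr <- non_ephemeral_threshold(capacity, threshold)
  sum(performer_counts >= thr)
}

# cumulative number of tasks ever seen non-ephemeral, per sample row
cumulative_discovery <- function(non_ephemeral) {
  seen <- rep(FALSE, ncol(non_ephemeral))
  vapply(seq_len(nrow(non_ephemeral)), function(i) {
    seen <<- seen | non_ephemeral[i, ]
    sum(seen)
  }, integer(1))
}
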