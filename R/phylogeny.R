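# Ancestry: phylogenetic depth, most recent common ancestor, sweep
# counting, and vestigial-site profiling along a line of descent.

# validate/coerce a phylogeny tibble: columns id, parent (NA for roots),
# optionally update, changed (TRUE = genotype-changing birth)
as_phylo_tibble <- function(tree) {
  if (inherits(tree, "evo_run")) return(tree$phylogeny)
  stopifnot(is.data.frame(tree), all(c("id", "parent") %in% names(tree)))
  tree
}

#' Phylogenetic depth of an organism
#'
#' The number of genotype-changing births on the path from the root to
#' the organism (mutational steps from the ancestor). Births whose
#' `changed` flag is FALSE (identical-genome offspring) do not add depth;
#' if the tree has no `changed` column every non-root birth counts.
#'
#' @param tree A phylogeny tibble (columns `id`, `parent`, optionally
#'   `changed`) or an `evo_run`.
#' @param id Node id.
#' @return Integer depth.
#' @export
lineage_depth <- function(tree, id) {
  tree <- as_phylo_tibble(tree)
  if ("depth" %in% names(tree)) {
    i <- match(id, tree$id)
    if (is.na(i)) stop("unknown id: ", id, call. = FALSE)
    return(tree$depth[i])
  }
  path <- line_of_descent(tree, id)
  changed <- if ("changed" %in% names(tree)) tree$changed else
    rep(TRUE, nrow(tree))
  idx <- match(path, tree$id)
  root <- is.na(tree$parent[idx])
  sum(changed[idx] & !root)
}

#' Line of descent from root to a node
#'
#' @inheritParams lineage_depth
#' @return Integer vector of node ids, root first.
#' @export
line_of_descent <- function(tree, id) {
  tree <- as_phylo_tibble(tree)
  i <- match(id, tree$id)
  if (is.na(i)) stop("unknown id: ", id, call. = FALSE)
  pidx <- match(tree$parent, tree$id) # parent row per row, computed once
  guard <- nrow(tree) + 1L
  path <- integer(guard)
  k <- 0L
  while (!is.na(i)) {
    k <- k + 1L
    path[k] <- tree$id[i]
    i <- pidx[i]
    guard <- guard - 1L
    if (guard < 0) stop("cycle detected in tree", call. = FALSE)
  }
  rev(path[seq_len(k)])
}

#' Most recent common ancestor of a set of organisms
#'
#' The deepest node ancestral to (or equal to) every member of `living`.
#' For a single organism, the organism itself.
#'
#' @inheritParams lineage_depth
#' @param living Non-empty vector of node ids.
#' @return The MRCA node id, or `NA` if the members descend from
#'   different roots.
#' @export
find_mrca <- function(tree, living) {
  tree <- as_phylo_tibble(tree)
  living <- unique(living)
  if (length(living) == 0) {
    stop("`living` must be non-empty", call. = FALSE)
  }
  if (!all(living %in% tree$id)) {
    stop("unknown id(s) in `living`", call. = FALSE)
  }
  paths <- lapply(living, function(v) line_of_descent(tree, v))
  common <- Reduce(intersect, paths)
  if (length(common) == 0) return(NA_integer_)
  common[length(common)] # paths are root-first, so the last is deepest
}

#' Count selective sweeps in an MRCA sample series
#'
#' A sweep is a change in the identity of the population's most recent
#' common ancestor between consecutive samples.
#'
#' @param mrca_series Vector of MRCA node ids sampled at a fixed
#'   interval; missing values are skipped.
#' @return Integer number of identity changes.
#' @examples
#' count_sweeps(c(1, 1, 4, 4, 9)) # 2
#' @export
count_sweeps <- function(mrca_series) {
  s <- mrca_series[!is.na(mrca_series)]
  if (length(s) < 2) return(0L)
  sum(s[-1] != s[-length(s)])
}

#' Reconstruct the genome at a phylogeny node of a run
#'
#' Applies the recorded mutations along the line of descent to the
#' ancestor genome.
#'
#' @param run An `evo_run`.
#' @param node Phylogeny node id.
#' @return A `genome`.
#' @export
node_genome <- function(run, node) {
  stopifnot(inherits(run, "evo_run"))
  gt <- run$phylogeny$genotype[match(node, run$phylogeny$id)]
  if (is.na(gt)) stop("unknown node: ", node, call. = FALSE)
  genome(run$genotypes$genome[gt])
}

# per-node mutation records (sites and new symbols) for a run
node_mutations <- function(run, node) {
  ph <- run$phylogeny
  off <- attr(ph, "mut_offset")
  i <- match(node, ph$id)
  if (is.na(i)) stop("unknown node: ", node, call. = FALSE)
  lo <- off[i] + 1L
  hi <- off[i + 1L]
  if (hi < lo) return(tibble::tibble(site = integer(), symbol = character()))
  tibble::tibble(site = attr(ph, "mut_site")[lo:hi],
                 symbol = letters[attr(ph, "mut_symbol")[lo:hi] + 1L])
}

#' Vestigial-site profile along a line of descent
#'
#' A site is vestigial for task T iff, at some sampled ancestor after
#' (or at) the site's last mutation, the site was functional for T, and
#' the site is not currently functional for T: it has remained unchanged
#' since it previously coded for a task that a mutation elsewhere
#' disabled. Functional and vestigial labels for the same task are
#' mutually exclusive per site.
#'
#' @param genomes List (or character vector) of genome strings along the
#'   line of descent, root first, ending at the focal organism.
#' @param mutated_sites List of integer vectors: the sites mutated at
#'   each birth (first element, the root, is empty).
#' @param inputs Evaluation input triple.
#' @param catalog A `task_catalog`.
#' @param thin Classify every `thin`-th ancestor (the root and the focal
#'   organism are always classified).
#' @return A tibble with columns `site`, `current` (the focal organism's
#'   functional label), `vestigial_tasks` (list), `label`
#'   (`"vestigial-XOR"` etc. or `NA`).
#' @export
vestigial_profile <- function(genomes, mutated_sites, inputs, catalog,
                              thin = 1L) {
  genomes <- as.character(unlist(genomes))
  n <- length(genomes)
  stopifnot(length(mutated_sites) == n, n >= 1)
  l <- nchar(genomes[1])
  keep <- unique(c(seq(1L, n, by = thin), n))
  # classification of sampled ancestors
  cls <- vector("list", n)
  for (i in keep) {
    cls[[i]] <- classify_sites(genomes[i], inputs, catalog)
  }
  # last birth index at which each site mutated (1 = root state)
  last_mut <- rep(1L, l)
  for (i in seq_len(n)) {
    for (s in mutated_sites[[i]]) last_mut[s] <- i
  }
  current <- cls[[n]]
  vest <- lapply(seq_len(l), function(s) {
    cur_tasks <- current$tasks_lost[[s]]
    anc <- keep[keep >= last_mut[s]]
    seen <- unique(unlist(lapply(anc, function(i) cls[[i]]$tasks_lost[[s]])))
    setdiff(seen, cur_tasks)
  })
  label <- vapply(seq_len(l), function(s) {
    if (length(vest[[s]]) == 0) NA_character_
    else paste0("vestigial-", paste(vest[[s]], collapse = "+"))
  }, character(1))
  tibble::tibble(site = seq_len(l), current = current$label,
                 vestigial_tasks = vest, label = label)
}

#' Vestigial profile of a run's organism
#'
#' Convenience wrapper: reconstructs the line of descent of a phylogeny
#' node of an `evo_run` and calls [vestigial_profile()].
#'
#' @param run An `evo_run`.
#' @param node Phylogeny node id (default: the node of the final
#'   dominant genotype's first occurrence in the population).
#' @param thin Ancestor thinning passed through.
#' @return See [vestigial_profile()].
#' @export
run_vestigial_profile <- function(run, node = NULL, thin = 1L) {
  stopifnot(inherits(run, "evo_run"))
  if (is.null(node)) {
    dom <- dplyr::last(run$logs$dominant)
    cand <- run$population$node[!is.na(run$population$genotype) &
                                  run$population$genotype == dom]
    node <- cand[1]
  }
  ph <- run$phylogeny
  path <- line_of_descent(ph, node)
  rows <- match(path, ph$id)
  genomes <- run$genotypes$genome[ph$genotype[rows]]
  off <- attr(ph, "mut_offset")
  sites <- attr(ph, "mut_site")
  muts <- lapply(rows, function(i) {
    if (off[i + 1L] < off[i] + 1L) integer(0)
    else sites[(off[i] + 1L):off[i + 1L]]
  })
  muts[[1]] <- integer(0)
  vestigial_profile(genomes, muts, run$inputs, run$catalog, thin = thin)
}
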