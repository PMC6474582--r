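# Synthetic fixtures: constructive genomes, lineages, populations and
# survey stubs that carry their own ground truth, so every downstream
# metric can be tested without running evolution.

#' Construct a genome that performs exactly a given task set
#'
#' Emits, for each requested task, a self-contained code segment computing
#' the task as a sum of products (minterm AND-chains combined through the
#' stack and OR), followed by the replication instruction and inert padding.
#' Segments are independent: each begins by rewinding the input cursor, so
#' a knockout in one segment never disturbs another. Tasks listed in
#' `vestigial_tasks` get a full segment whose emit instruction is replaced
#' by the inert symbol -- an intact motif disconnected by a single
#' disabling site; restoring that site restores the task.
#'
#' @param tasks Character vector of task names to perform (e.g.
#'   `c("XOR", "EQU")`).
#' @param l Genome length.
#' @param inputs Evaluation input triple (see [survey_inputs()]).
#' @param catalog A `task_catalog`.
#' @param layout `"compact"` (segments back to back) or `"scattered"`
#'   (segments spread across the genome with inert gaps). Phenotypes are
#'   identical; only the site map differs.
#' @param vestigial_tasks Character vector of task names to build as
#'   disabled (vestigial) motifs.
#' @param verify Check the returned site map against [classify_sites()]
#'   and the vestigial restore contract (default TRUE).
#' @return A list of class `task_genome_fixture`: `genome`, `site_map`
#'   (tibble: site, symbol, role, task), `disabled_sites` (named integer,
#'   one per vestigial task), `tasks`, `vestigial_tasks`.
#' @export
make_task_genome <- function(tasks, l, inputs, catalog,
                             layout = c("compact", "scattered"),
                             vestigial_tasks = character(),
                             verify = TRUE) {
  layout <- match.arg(layout)
  tasks <- unique(as.character(tasks))
  vestigial_tasks <- unique(as.character(vestigial_tasks))
  all_names <- c(tasks, vestigial_tasks)
  if (!all(all_names %in% catalog$name)) {
    stop("unknown task(s): ",
         paste(setdiff(all_names, catalog$name), collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(tasks, vestigial_tasks)) > 0) {
    stop("a task cannot be both performed and vestigial", call. = FALSE)
  }

  segs <- list()
  pos <- 0L # input cursor position entering the next segment
  for (nm in all_names) {
    i <- match(nm, catalog$name)
    cs <- compile_task_segment(catalog$truth_table[[i]], catalog$arity[i],
                               pos)
    code <- cs$code
    emit_at <- length(code) # the final instruction is the emit
    if (nm %in% vestigial_tasks) code[emit_at] <- INERT_SYMBOL
    segs[[nm]] <- list(code = code, emit_at = emit_at,
                       vestigial = nm %in% vestigial_tasks)
    pos <- cs$pos
  }

  seg_len <- vapply(segs, function(s) length(s$code), integer(1))
  need <- sum(seg_len) + 1L # + repro
  if (l < need) {
    stop("genome length ", l, " too small; need at least ", need,
         call. = FALSE)
  }

  # gap sizes before each segment (and implicitly trailing padding)
  slack <- l - need
  n_seg <- length(segs)
  gaps <- if (layout == "compact") rep(0L, n_seg) else {
    g <- rep(slack %/% (n_seg + 1L), n_seg)
    g
  }

  sym <- rep(INERT_SYMBOL, l)
  segment <- rep(NA_character_, l)
  disabled <- integer(0)
  at <- 1L
  for (i in seq_along(segs)) {
    at <- at + gaps[i]
    s <- segs[[i]]
    nm <- names(segs)[i]
    idx <- at:(at + length(s$code) - 1L)
    sym[idx] <- s$code
    segment[idx] <- nm
    if (s$vestigial) disabled[nm] <- at + s$emit_at - 1L
    at <- at + length(s$code)
  }
  sym[at] <- REPRO_SYMBOL

  g <- genome(paste0(sym, collapse = ""))
  # exact per-site roles from the truth-table-domain (symbolic) knockouts
  role <- symbolic_site_roles(sym, catalog)
  task_col <- ifelse(role %in% c("replication", "none"), NA_character_,
                     role)
  role <- ifelse(role %in% c("replication", "none"), role, "functional")
  # vestigial motif sites: functional in the re-enabled variant of each
  # disabled segment, inert-classifying in the actual genome
  for (nm in names(disabled)) {
    sym2 <- sym
    sym2[disabled[nm]] <- "e"
    role2 <- symbolic_site_roles(sym2, catalog)
    vest <- which(role2 == nm & role == "none")
    role[vest] <- "vestigial"
    task_col[vest] <- nm
    role[disabled[nm]] <- "disabled"
    task_col[disabled[nm]] <- nm
  }

  out <- structure(
    list(genome = g,
         site_map = tibble::tibble(site = seq_len(l), symbol = sym,
                                   role = role, task = task_col,
                                   segment = segment),
         disabled_sites = disabled,
         tasks = tasks, vestigial_tasks = vestigial_tasks),
    class = "task_genome_fixture")

  if (verify) verify_task_genome(out, inputs, catalog)
  out
}

# --- symbolic (truth-table domain) execution ------------------------------
# Registers hold 8-row truth tables over the three inputs, encoded as
# integers 0..255 (bit r = output on input row r). With evaluation inputs
# whose bit-columns cover all 8 input patterns, equality of emitted words
# is exactly equality of these tables, so this abstract executor decides
# task detection without reference to the concrete words. Only the
# pointwise instruction subset used by the code generator is supported.
symbolic_exec <- function(sym, max_steps = length(sym)) {
  PROJ <- c(0xAAL, 0xCCL, 0xF0L) # x1, x2, x3
  M <- 0xFFL
  ax <- 0L; bx <- 0L; cx <- 0L
  stack <- integer(0)
  pos <- 0L
  emitted <- integer(0)
  replicated <- FALSE
  l <- length(sym)
  ip <- 1L
  for (step in seq_len(max_steps)) {
    op <- sym[ip]
    if (op == "d") { bx <- PROJ[pos + 1L]; pos <- (pos + 1L) %% 3L }
    else if (op == "e") emitted <- c(emitted, bx)
    else if (op == "f") { t <- bx; bx <- cx; cx <- t }
    else if (op == "g") cx <- bx
    else if (op == "h") ax <- bx
    else if (op == "i") bx <- ax
    else if (op == "j") { if (length(stack) < 16L) stack <- c(stack, bx) }
    else if (op == "k") {
      if (length(stack) > 0L) { bx <- stack[length(stack)]; stack <- stack[-length(stack)] }
      else bx <- 0L
    }
    else if (op == "l") bx <- bitwAnd(bitwNot(bitwAnd(bx, cx)), M)
    else if (op == "m") bx <- bitwAnd(bx, cx)
    else if (op == "n") bx <- bitwOr(bx, cx)
    else if (op == "o") bx <- bitwXor(bx, cx)
    else if (op == "p") bx <- bitwAnd(bitwNot(bx), M)
    else if (op == "s") pos <- 0L
    else if (op == "u") bx <- 0L
    else if (op == "v") bx <- M
    else if (op == "y") replicated <- TRUE
    else if (!op %in% c("a", "b", "c", "z")) {
      stop("symbolic executor does not support instruction '", op, "'",
           call. = FALSE)
    }
    ip <- ip %% l + 1L
  }
  list(emitted = unique(emitted), replicated = replicated)
}

# symbolic task detection: emitted table == task target table; names are
# returned in catalog order (matching classify_sites label order)
symbolic_tasks <- function(sym, catalog) {
  res <- symbolic_exec(sym)
  if (!res$replicated) return(character(0))
  tg <- sym_target_table(catalog)
  hit <- unique(tg$name[tg$table %in% res$emitted])
  catalog$name[catalog$name %in% hit]
}

sym_target_table <- local({
  cache <- NULL
  function(catalog) {
    if (!is.null(cache) && identical(attr(cache, "n"), nrow(catalog))) {
      return(cache)
    }
    tg <- task_targets(catalog, c(0xAAL, 0xCCL, 0xF0L))
    out <- tibble::tibble(name = catalog$name[match(tg$id, catalog$id)],
                          table = as.integer(tg$word %% 256))
    attr(out, "n") <- nrow(catalog)
    cache <<- out
    out
  }
})

# role of every site: "replication", a task name (knockout loses it), or
# "none"; computed by symbolic knockouts
symbolic_site_roles <- function(sym, catalog) {
  parent <- symbolic_tasks(sym, catalog)
  vapply(seq_along(sym), function(s) {
    sym2 <- sym
    sym2[s] <- INERT_SYMBOL
    res <- symbolic_exec(sym2)
    if (!res$replicated) return("replication")
    now <- symbolic_tasks(sym2, catalog)
    lost <- setdiff(parent, now)
    if (length(lost) == 0) "none" else paste(lost, collapse = "+")
  }, character(1))
}

# Irredundant prime-implicant cover of a truth table (Quine-McCluskey at
# toy scale, k <= 3). Each term is a list(vars, vals): the inputs fixed by
# the product and their required values. Using prime implicants guarantees
# that dropping any literal expands the term outside the function, and an
# irredundant cover guarantees that dropping any whole term uncovers a row
# -- the properties the knockout site map relies on.
prime_cover <- function(tt, k) {
  rows <- which(tt) - 1L
  subsets <- list()
  for (m in 1:(2L^k - 1L)) {
    subsets[[length(subsets) + 1L]] <- which(bitwAnd(m, 2L^(0:(k - 1L))) > 0L)
  }
  covers_rows <- function(vars, vals) {
    r <- 0:(2L^k - 1L)
    keep <- rep(TRUE, length(r))
    for (i in seq_along(vars)) {
      bit <- bitwAnd(bitwShiftR(r, vars[i] - 1L), 1L)
      keep <- keep & (bit == vals[i])
    }
    r[keep]
  }
  valid <- list()
  for (vars in subsets) {
    vals_grid <- expand.grid(rep(list(0:1), length(vars)))
    for (vi in seq_len(nrow(vals_grid))) {
      vals <- as.integer(vals_grid[vi, ])
      cov <- covers_rows(vars, vals)
      if (all(cov %in% rows)) {
        valid[[length(valid) + 1L]] <- list(vars = vars, vals = vals,
                                            rows = cov)
      }
    }
  }
  n_lit <- vapply(valid, function(x) length(x$vars), integer(1))
  prime <- vapply(seq_along(valid), function(i) {
    !any(vapply(seq_along(valid), function(j) {
      i != j && n_lit[j] < n_lit[i] &&
        all(valid[[j]]$vars %in% valid[[i]]$vars) &&
        all(valid[[i]]$rows %in% valid[[j]]$rows)
    }, logical(1)))
  }, logical(1))
  primes <- valid[prime]
  # greedy cover, then prune to irredundancy (fixed deterministic order)
  uncovered <- rows
  chosen <- integer(0)
  while (length(uncovered) > 0) {
    gain <- vapply(primes, function(p) sum(p$rows %in% uncovered), integer(1))
    pick <- which.max(gain)
    chosen <- c(chosen, pick)
    uncovered <- setdiff(uncovered, primes[[pick]]$rows)
  }
  repeat {
    dropped <- FALSE
    for (i in seq_along(chosen)) {
      rest <- unlist(lapply(primes[chosen[-i]], `[[`, "rows"))
      if (all(primes[[chosen[i]]]$rows %in% rest)) {
        chosen <- chosen[-i]
        dropped <- TRUE
        break
      }
    }
    if (!dropped) break
  }
  primes[chosen]
}

# Compile one task segment from its irredundant prime cover. `pos` is the
# input-cursor position on entry (for the intact genome). Each term opens
# with rewind/zero/clear (s, u, g) so that register or cursor state never
# couples one term's knockout to another term or segment: a knocked-out
# load meets a zeroed register (term drops or a literal drops, both of
# which change the function because the cover is prime and irredundant).
# Returns instruction letters, a parallel role vector ("task" for sites
# whose knockout loses the task, "none" for prologue sites that are
# no-ops in isolation), and the exit cursor position.
#
# Rewind roles: with several terms a missing rewind garbles its own term
# (a mixture function), so it is essential unless the cursor is already at
# 0; with a single term a missing rewind shifts the product onto a
# different ordered tuple of distinct inputs -- still a valid assignment
# of the same task -- so it is never essential.
compile_task_segment <- function(tt, arity, pos) {
  code <- character()
  roles <- character()
  put <- function(x, r = "task") {
    code <<- c(code, x)
    roles <<- c(roles, rep(r, length(x)))
  }
  terms <- prime_cover(tt, arity)
  single <- length(terms) == 1L
  cur <- pos
  for (tm in terms) {
    put("s", if (single || cur == 0L) "none" else "task")
    cur <- 0L
    put(c("u", "g"), "none") # BX <- 0, CX <- 0: decouple register state
    nl <- length(tm$vars)
    for (i in seq_len(nl)) {
      j <- tm$vars[i]
      n_d <- ((j - 1L - cur) %% 3L) + 1L
      put(rep("d", n_d))
      cur <- j %% 3L
      if (tm$vals[i] == 0L) put("p")
      if (i == 1L && nl > 1L) put("g")
      if (i > 1L) {
        put("m")
        if (i < nl) put("g")
      }
    }
    if (!single) put("j")
  }
  if (!single) {
    put("k")
    for (q in seq_len(length(terms) - 1L)) put(c("g", "k", "n"))
  }
  put("e")
  list(code = code, roles = roles, pos = cur)
}

verify_task_genome <- function(fx, inputs, catalog) {
  ph <- evaluate_phenotype(fx$genome, inputs, catalog)
  performed <- names(ph$tasks)[ph$tasks]
  if (!ph$viable || !setequal(performed, fx$tasks)) {
    stop("fixture construction failed: phenotype {",
         paste(performed, collapse = ","), "} != requested {",
         paste(fx$tasks, collapse = ","), "}", call. = FALSE)
  }
  cl <- classify_sites(fx$genome, inputs, catalog)
  want <- fixture_expected_labels(fx)
  bad <- which(cl$label != want)
  if (length(bad) > 0) {
    stop("fixture construction failed: site(s) ",
         paste(utils::head(bad, 5), collapse = ","),
         " classify as ", paste(utils::head(cl$label[bad], 5), collapse = ","),
         " but map says ", paste(utils::head(want[bad], 5), collapse = ","),
         call. = FALSE)
  }
  for (nm in fx$vestigial_tasks) {
    s <- fx$disabled_sites[[nm]]
    restored <- sub_site(fx$genome, s, "e")
    ph2 <- evaluate_phenotype(restored, inputs, catalog)
    if (!ph2$tasks[[nm]]) {
      stop("fixture construction failed: restoring site ", s,
           " does not regain ", nm, call. = FALSE)
    }
  }
  invisible(fx)
}

# expected classify_sites labels implied by a fixture site map
fixture_expected_labels <- function(fx) {
  m <- fx$site_map
  ifelse(m$role == "functional", m$task,
         ifelse(m$role == "replication", "replication", "none"))
}

# substitute one site (internal)
sub_site <- function(g, site, symbol) {
  s <- strsplit(unclass(genome(g)), "")[[1]]
  s[site] <- symbol
  genome(paste0(s, collapse = ""))
}

#' Build a lineage fixture with a prescribed sweep count and depth
#'
#' Constructs a root-to-tip chain of births, `depth` of which change the
#' genotype, plus `n_extra` silent (mutation-free) births, and an MRCA
#' sample series containing exactly `n_sweeps` identity changes drawn from
#' the chain. The returned series and tip recover (`n_sweeps`, `depth`)
#' by construction.
#'
#' @param n_sweeps Number of MRCA identity changes in the series.
#' @param depth Number of genotype-changing births root to tip.
#' @param n_extra Number of interleaved silent births (default 2).
#' @param series_length Length of the MRCA sample series.
#' @return List of class `lineage_fixture`: `tree` (tibble: id, parent,
#'   update, changed), `tip`, `mrca_series`, `n_sweeps`, `depth`.
#' @export
make_lineage_fixture <- function(n_sweeps, depth, n_extra = 2L,
                                 series_length = max(n_sweeps + 1L, 10L)) {
  if (n_sweeps < 0 || depth < 0) {
    stop("`n_sweeps` and `depth` must be non-negative", call. = FALSE)
  }
  if (n_sweeps > depth) {
    stop("cannot place ", n_sweeps, " sweeps on a lineage of depth ", depth,
         call. = FALSE)
  }
  if (series_length < n_sweeps + 1L) {
    stop("`series_length` must exceed `n_sweeps`", call. = FALSE)
  }
  changed <- c(rep(TRUE, depth), rep(FALSE, n_extra))
  if (length(changed) > 1) changed <- sample(changed)
  n <- length(changed) + 1L
  tree <- tibble::tibble(
    id = seq_len(n),
    parent = c(NA_integer_, seq_len(n - 1L)),
    update = seq_len(n) - 1L,
    changed = c(TRUE, changed) # root flag unused by depth counting
  )
  tree$changed[1] <- FALSE
  # MRCA series: n_sweeps + 1 blocks over increasing chain nodes
  chain <- tree$id
  nodes <- sort(sample(chain, n_sweeps + 1L)) # increasing => advancing MRCA
  if (n_sweeps == 0L) nodes <- chain[1]
  sizes <- rep(series_length %/% (n_sweeps + 1L), n_sweeps + 1L)
  sizes[1] <- sizes[1] + series_length - sum(sizes)
  series <- rep(nodes, times = sizes)
  list(tree = tree, tip = n, mrca_series = series,
       n_sweeps = n_sweeps, depth = depth) |>
    structure(class = "lineage_fixture")
}

#' Build a population with exact genotype counts
#'
#' Expands a set of genotypes to an individual-level population whose
#' realized per-site symbol frequencies match the requested counts exactly,
#' and returns the implied per-site entropy as ground truth.
#'
#' @param counts Named integer vector: genotype label -> number of copies.
#' @param genomes Character vector of genome strings, parallel to `counts`;
#'   if `NULL`, genomes of length `l` differing at site 1 are generated.
#' @param l Genome length used when `genomes` is `NULL`.
#' @return List of class `population_fixture`: `genomes` (one string per
#'   individual), `counts`, `entropy` (tibble: site, entropy).
#' @export
make_population_fixture <- function(counts, genomes = NULL, l = 10L) {
  if (is.null(names(counts)) && !is.null(genomes)) {
    names(counts) <- genomes
  }
  k <- length(counts)
  if (is.null(genomes)) {
    if (k > 26) stop("at most 26 auto-generated genotypes", call. = FALSE)
    base <- strrep("a", l - 1L)
    genomes <- paste0(letters[seq_len(k)], base)
  }
  stopifnot(length(genomes) == k, all(counts >= 0))
  pop <- rep(genomes, times = counts)
  n <- length(pop)
  lg <- nchar(genomes[1])
  mat <- do.call(rbind, strsplit(genomes, ""))
  ent <- vapply(seq_len(lg), function(s) {
    f <- tapply(counts, mat[, s], sum) / n
    f <- f[f > 0]
    -sum(f * log2(f))
  }, numeric(1))
  structure(list(genomes = pop, counts = counts,
                 entropy = tibble::tibble(site = seq_len(lg), entropy = ent)),
            class = "population_fixture")
}

#' Build a deterministic one-step survey stub
#'
#' Produces an evaluator over the one-step neighborhood of an all-`a`
#' parent genome that realizes prescribed detrimental and
#' phenotype-preserving fractions exactly up to floor rounding: of the
#' `l * (alphabet - 1)` mutants, the first `floor(p_d * n)` (site-major
#' order) are detrimental, the next `floor(p_pnu * n)` are neutral and
#' phenotype-preserving, and the remainder are neutral with a changed
#' phenotype. Genomes outside the one-step neighborhood get a
#' deterministic hash-based value (used only by two-step scans).
#'
#' @param p_d Requested detrimental-or-lethal fraction.
#' @param p_pnu Requested phenotype-preserving neutral fraction.
#' @param l Genome length.
#' @param alphabet Character vector of symbols; default `letters[1:4]`.
#' @return List of class `survey_stub`: `parent` (genome string),
#'   `evaluator` (function(genome string) -> list(fitness, phenotype)),
#'   `alphabet`, `p_d`, `p_pnu` (the realized fractions), `n`.
#' @export
make_survey_stub <- function(p_d, p_pnu, l = 10L, alphabet = letters[1:4]) {
  stopifnot(p_d >= 0, p_d <= 1, p_pnu >= 0, p_pnu <= 1, p_d + p_pnu <= 1)
  a <- length(alphabet)
  n <- l * (a - 1L)
  n_d <- floor(p_d * n)
  n_p <- min(floor(p_pnu * n), n - n_d)
  parent <- strrep(alphabet[1], l)
  # mutant index in site-major, symbol-ascending (parent symbol skipped)
  mutant_index <- function(g) {
    s <- strsplit(g, "")[[1]]
    p <- strsplit(parent, "")[[1]]
    d <- which(s != p)
    if (length(d) != 1) return(NA_integer_)
    alts <- alphabet[alphabet != p[d]]
    (d - 1L) * (a - 1L) + match(s[d], alts)
  }
  evaluator <- function(g) {
    g <- unclass(genome(g))
    if (g == parent) return(list(fitness = 1, phenotype = "P0"))
    i <- mutant_index(g)
    if (!is.na(i)) {
      if (i <= n_d) return(list(fitness = 0.5, phenotype = paste0("D", i)))
      if (i <= n_d + n_p) return(list(fitness = 1, phenotype = "P0"))
      return(list(fitness = 1, phenotype = paste0("N", i)))
    }
    h <- sum(utf8ToInt(g) * seq_len(nchar(g))) %% 97L
    list(fitness = if (h %% 3L == 0L) 0.5 else 1,
         phenotype = paste0("H", h %% 7L))
  }
  structure(list(parent = parent, evaluator = evaluator,
                 alphabet = alphabet, p_d = n_d / n, p_pnu = n_p / n,
                 n = n),
            class = "survey_stub")
}
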