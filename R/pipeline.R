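# Orchestration: run replicated treatments, survey end-of-run dominants,
# extract per-replicate landscape/diversity/ancestry metrics, and emit
# cross-treatment reports.

#' Run replicated treatments
#'
#' Runs `replicates` seeded evolution experiments per treatment from a
#' shared base configuration, then surveys each replicate: sweep count
#' and final diversity from the logs; the one-step mutational
#' neighborhood and diffusion rates of the end-of-run dominant genotype;
#' functional site counts and the vestigial profile along its line of
#' descent; task discovery and performance.
#'
#' Landscape measures (p_d, p_pnu, diffusion rates) are taken on the most
#' abundant genotype at the end of the experiment. The per-task loss
#' fraction for the fluctuating task requires a parent that performs it,
#' so it is taken on the most abundant EQU-performing genotype of the
#' final population, falling back to the dominant at the end of the last
#' rewarded stage-1 phase when the final population holds none (under the
#' harsh schedule the task is, by construction, absent at
#' punishment-phase ends).
#'
#' @param treatments Character vector of treatment names.
#' @param replicates Runs per treatment.
#' @param seed Master seed; per-run seeds derive from it.
#' @param base An [experiment_config()] used as template.
#' @param two_step Also run the two-step EQU regain survey (slower).
#' @param keep_runs Keep the full `evo_run` objects (memory-heavy).
#' @param vestigial_ancestors Max ancestors classified per vestigial
#'   profile (lineage thinned to this count).
#' @return An object of class `treatment_runs` with `$metrics` (one row
#'   per replicate) and optionally `$runs`.
#' @export
run_treatments <- function(treatments = c("static", "benign", "harsh"),
                           replicates = 10L, seed = 1L,
                           base = experiment_config(),
                           two_step = FALSE, keep_runs = FALSE,
                           vestigial_ancestors = 100L) {
  known <- c("static", "benign", "harsh", "benign_quiescent",
             "harsh_quiescent")
  if (!all(treatments %in% known)) {
    stop("unknown treatment(s): ",
         paste(setdiff(treatments, known), collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  grid <- tidyr::expand_grid(treatment = treatments,
                             replicate = seq_len(replicates))
  grid$seed <- sample.int(.Machine$integer.max, nrow(grid))
  runs <- vector("list", nrow(grid))
  logs <- vector("list", nrow(grid))
  metrics <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    cfg <- base
    cfg$treatment <- grid$treatment[i]
    cfg$seed <- grid$seed[i]
    run <- run_experiment(cfg)
    metrics[[i]] <- dplyr::bind_cols(grid[i, ],
                                     run_metrics(run, two_step,
                                                 vestigial_ancestors))
    logs[[i]] <- run$logs
    if (keep_runs) runs[[i]] <- run
  }
  structure(list(metrics = dplyr::bind_rows(metrics),
                 logs = logs,
                 runs = if (keep_runs) runs,
                 base = base, treatments = treatments, seed = seed),
            class = "treatment_runs")
}

# dominant genotype id at the last stage-1 reward-phase sample
reward_phase_dominant <- function(run) {
  logs <- run$logs
  i <- which(logs$stage == 1L & logs$phase == 0L)
  if (length(i) == 0) i <- seq_len(nrow(logs))
  logs$dominant[max(i)]
}

# most abundant EQU-performing genotype of the final population (id), or
# NA when there is none
final_equ_dominant <- function(run) {
  pop <- run$population$genotype[!is.na(run$population$genotype)]
  ab <- sort(table(pop), decreasing = TRUE)
  ids <- as.integer(names(ab))
  equ_col <- match("EQU", run$catalog$name)
  ta <- target_arrays(run$catalog, run$inputs)
  for (id in ids) {
    ph <- cpp_phenotype(genome_codes(genome(run$genotypes$genome[id])),
                        run$inputs, nchar(run$genotypes$genome[id]),
                        ta$words, ta$task0, ta$n)
    if (ph$viable && ph$tasks[equ_col]) return(id)
  }
  NA_integer_
}

# per-replicate metric extraction
run_metrics <- function(run, two_step = FALSE, vestigial_ancestors = 100L) {
  cfg <- run$config
  logs <- run$logs
  ctx <- survey_context(run$schedule, run$catalog, mode = "expected",
                        stage = 1)
  ev <- phenotype_evaluator(ctx, run$inputs, run$catalog)

  survey_of <- function(gt_id) {
    if (is.na(gt_id)) return(NULL)
    g <- run$genotypes$genome[gt_id]
    s <- try(one_step_survey(g, ev), silent = TRUE)
    if (inherits(s, "try-error")) NULL else s
  }
  # end-of-experiment dominant: landscape metrics (diffusion rates)
  dom_final <- dplyr::last(logs$dominant)
  sv_final <- survey_of(dom_final)
  dm <- if (!is.null(sv_final)) diffusion_metrics(sv_final, mu = cfg$mu)

  # most abundant EQU performer (fallback: reward-phase-end dominant):
  # fluctuating-task loss and functional architecture
  dom_equ <- final_equ_dominant(run)
  if (is.na(dom_equ)) dom_equ <- reward_phase_dominant(run)
  sv_equ <- if (!is.na(dom_equ) && identical(dom_equ, dom_final)) sv_final
            else survey_of(dom_equ)
  equ_loss <- NA_real_
  if (!is.null(sv_equ) && "EQU" %in% attr(sv_equ, "parent_tasks")) {
    tl <- attr(sv_equ, "task_loss")
    equ_loss <- tl$fraction[tl$task == "EQU"]
  } else {
    sv_equ <- NULL
  }

  # functional architecture of the EQU-performing genotype
  n_equ <- n_xor <- n_both <- NA_integer_
  if (!is.null(sv_equ)) {
    g <- run$genotypes$genome[dom_equ]
    cl <- try(classify_sites(g, run$inputs, run$catalog), silent = TRUE)
    if (!inherits(cl, "try-error")) {
      lost <- vapply(cl$tasks_lost, function(x) {
        paste(sort(intersect(x, c("XOR", "EQU"))), collapse = "+")
      }, character(1))
      n_equ <- sum(lost == "EQU")
      n_xor <- sum(lost == "XOR")
      n_both <- sum(lost == "EQU+XOR")
    }
  }

  # vestigial reservoir along the final dominant's line of descent
  n_vest <- NA_integer_
  node <- run$population$node[!is.na(run$population$genotype) &
                                run$population$genotype == dom_final][1]
  if (!is.na(node)) {
    depth_n <- length(line_of_descent(run$phylogeny, node))
    thin <- max(1L, ceiling(depth_n / vestigial_ancestors))
    vp <- try(run_vestigial_profile(run, node, thin = thin),
              silent = TRUE)
    if (!inherits(vp, "try-error")) n_vest <- sum(!is.na(vp$label))
  }

  regain <- NA_real_
  if (two_step && !is.null(sv_equ)) {
    rg <- two_step_regain_survey(sv_equ, "EQU", mode = "sampled",
                                 budget = 2e5)
    regain <- rg$fraction
  }

  tibble::tibble(
    sweeps = count_sweeps(logs$mrca),
    final_entropy = dplyr::last(logs$mean_entropy),
    final_depth = dplyr::last(logs$mrca_depth),
    final_equ_performers = dplyr::last(logs$equ_performers),
    discovered_overall = dplyr::last(logs$discovered_overall),
    discovered_post = dplyr::last(logs$discovered_post),
    performed = dplyr::last(logs$performed),
    dominant_performs_equ = !is.null(sv_final) &&
      "EQU" %in% attr(sv_final, "parent_tasks"),
    equ_loss = equ_loss,
    p_d = if (!is.null(sv_final)) attr(sv_final, "p_d") else NA_real_,
    p_pnu = if (!is.null(sv_final)) attr(sv_final, "p_pnu") else NA_real_,
    D_g = if (!is.null(dm)) dm$D_g else NA_real_,
    D_p = if (!is.null(dm)) dm$D_p else NA_real_,
    n_equ_sites = n_equ, n_xor_sites = n_xor, n_both_sites = n_both,
    n_vestigial_sites = n_vest,
    equ_regain = regain,
    n_births = run$n_births
  )
}

#' @export
print.treatment_runs <- function(x, ...) {
  cat("<treatment_runs>", length(x$treatments), "treatments x",
      max(x$metrics$replicate), "replicates\n")
  s <- dplyr::summarise(
    dplyr::group_by(x$metrics, .data$treatment),
    sweeps = stats::median(.data$sweeps),
    entropy = stats::median(.data$final_entropy),
    equ_loss = stats::median(.data$equ_loss, na.rm = TRUE),
    D_p = stats::median(.data$D_p, na.rm = TRUE))
  print(s)
  invisible(x)
}

#' Aggregate treatment runs into comparison reports
#'
#' Applies the package's statistical comparisons across treatments: sweep
#' counts, final entropy, EQU loss fraction, genomic and phenotypic
#' diffusion rates (and discovery/performance counts when stage 2 was
#' run), plus the task-length regression of EQU loss on EQU-only
#' functional site counts.
#'
#' @param tr A `treatment_runs`.
#' @param out_dir Optional directory; when given, writes `metrics.csv`,
#'   `comparisons.csv` and `summary.json`.
#' @return A list of class `treatment_report`: `comparisons` (named list
#'   of `group_comparison`), `loss_fit` (or NULL), `summary` tibble.
#' @export
emit_reports <- function(tr, out_dir = NULL) {
  stopifnot(inherits(tr, "treatment_runs"))
  m <- tr$metrics
  if (nrow(m) == 0) stop("no run metrics to report", call. = FALSE)
  cmp <- list()
  add_cmp <- function(name, col) {
    d <- m[!is.na(m[[col]]), ]
    if (length(unique(d$treatment)) >= 2 &&
        all(table(d$treatment) >= 2)) {
      cmp[[name]] <<- compare_groups(d, !!rlang::sym(col),
                                     .data$treatment)
    }
  }
  add_cmp("sweeps", "sweeps")
  add_cmp("final_entropy", "final_entropy")
  add_cmp("equ_loss", "equ_loss")
  add_cmp("D_g", "D_g")
  add_cmp("D_p", "D_p")
  add_cmp("discovered_overall", "discovered_overall")
  if (any(!is.na(m$discovered_post))) add_cmp("discovered_post",
                                              "discovered_post")
  add_cmp("performed", "performed")

  loss_fit <- NULL
  d <- m[!is.na(m$equ_loss) & !is.na(m$n_equ_sites), ]
  if (nrow(d) > 3 && length(unique(d$n_equ_sites)) > 1) {
    loss_fit <- fit_task_loss_regression(d, equ_loss ~ n_equ_sites)
  }

  summary <- dplyr::summarise(
    dplyr::group_by(m, .data$treatment),
    dplyr::across(c("sweeps", "final_entropy", "equ_loss", "D_g", "D_p",
                    "discovered_overall", "performed"),
                  ~ stats::median(.x, na.rm = TRUE)),
    n = dplyr::n())

  out <- structure(list(comparisons = cmp, loss_fit = loss_fit,
                        summary = summary),
                   class = "treatment_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(m, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    pw <- dplyr::bind_rows(lapply(names(cmp), function(nm) {
      dplyr::mutate(cmp[[nm]]$pairwise, measure = nm, .before = 1)
    }))
    utils::write.csv(pw, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(summary = summary,
           kruskal = lapply(cmp, function(x) x$kruskal),
           regression = if (!is.null(loss_fit)) glance(loss_fit)),
      file.path(out_dir, "summary.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.treatment_report <- function(x, ...) {
  cat("<treatment_report>\n")
  print(x$summary)
  for (nm in names(x$comparisons)) {
    k <- x$comparisons[[nm]]$kruskal
    cat(sprintf("  %-20s H(%d) = %.3g, p = %.3g\n", nm, k$df,
                k$statistic, k$p_value))
  }
  if (!is.null(x$loss_fit)) {
    cat("  EQU loss ~ EQU-only sites: R^2 =",
        signif(glance(x$loss_fit)$r_squared, 3), "\n")
  }
  invisible(x)
}

#' Write run logs and genomes to a directory
#'
#' Persists an `evo_run` as plain text: `logs.csv`, `genotypes.fasta`
#' (final population genotypes with abundances in the headers) and
#' `config.json`.
#'
#' @param run An `evo_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "evo_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$logs, file.path(dir, "logs.csv"),
                   row.names = FALSE)
  pop <- run$population[!is.na(run$population$genotype), ]
  ab <- table(pop$genotype)
  ids <- as.integer(names(ab))
  fa <- character(0)
  for (i in seq_along(ids)) {
    fa <- c(fa, sprintf(">genotype_%d abundance=%d", ids[i], ab[[i]]),
            run$genotypes$genome[ids[i]])
  }
  writeLines(fa, file.path(dir, "genotypes.fasta"))
  cfg <- run$config
  cfg$ancestor <- run$ancestor
  jsonlite::write_json(c(unclass(cfg), list(inputs = run$inputs)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read genomes from a FASTA-style genome file
#'
#' One record per genotype, sequence over letters a-z; an
#' `abundance=<n>` field in the header is honored.
#'
#' @param path File path.
#' @return A tibble with columns `name`, `genome`, `abundance`.
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path, call. = FALSE)
  idx <- cumsum(hdr)
  names <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, character(1),
                 collapse = "")
  ab <- suppressWarnings(
    as.integer(sub(".*abundance=(\\d+).*", "\\1", names)))
  tibble::tibble(name = sub("\\s.*", "", names),
                 genome = unname(seqs),
                 abundance = ifelse(is.na(ab), 1L, ab))
}
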