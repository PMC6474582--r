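# ggplot2 autoplot methods for the package's result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evolution run's time series
#'
#' EQU performer counts (with reward/punishment phases shaded) and mean
#' per-site entropy over updates.
#'
#' @param object An `evo_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.evo_run <- function(object, ...) {
  logs <- object$logs
  d <- tidyr::pivot_longer(
    logs[, c("update", "equ_performers", "mean_entropy")],
    cols = c("equ_performers", "mean_entropy"),
    names_to = "series", values_to = "value")
  d$series <- factor(d$series, c("equ_performers", "mean_entropy"),
                     c("EQU performers", "mean entropy (bits)"))
  cl <- object$config$cycle_length
  off <- logs[logs$phase == 1L, "update", drop = FALSE]
  shade <- NULL
  if (nrow(off) > 0) {
    starts <- unique((off$update - 1L) %/% cl) * cl
    shade <- tibble::tibble(xmin = starts, xmax = starts + cl)
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$update,
                                       y = .data$value))
  if (!is.null(shade)) {
    p <- p + ggplot2::geom_rect(
      data = shade,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85", alpha = 0.5)
  }
  p + ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "update", y = NULL,
                  title = paste0(object$config$treatment, " run (",
                                 object$config$width, "x",
                                 object$config$height, ", l = ",
                                 object$config$genome_length, ")"),
                  subtitle = "shaded: off/punishment phases") +
    ggplot2::theme_minimal()
}

#' Plot a per-site entropy profile
#'
#' @param object An `entropy_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.entropy_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$site,
                                       y = .data$entropy)) +
    ggplot2::geom_col(fill = "firebrick", width = 1) +
    ggplot2::geom_hline(yintercept = attr(object, "mean"),
                        linetype = "dashed") +
    ggplot2::labs(x = "genome site", y = "entropy (bits)",
                  subtitle = sprintf("mean %.3f bits over %d individuals",
                                     attr(object, "mean"),
                                     attr(object, "n"))) +
    ggplot2::theme_minimal()
}

#' Plot a one-step neighborhood survey
#'
#' Mutant fitness relative to the parent by genome site, colored by
#' classification.
#'
#' @param object A `neighborhood_survey`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.neighborhood_survey <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$class <- ifelse(!d$neutral, "detrimental",
                    ifelse(d$preserving, "neutral (same phenotype)",
                           "neutral (new phenotype)"))
  pf <- attr(object, "parent_fitness")
  d$rel <- ifelse(d$fitness > 0, d$fitness / pf, NA)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site, y = .data$rel,
                                  color = .data$class)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "mutated site", y = "fitness relative to parent",
                  color = NULL,
                  subtitle = sprintf("p_d = %.3f, p_pnu = %.3f",
                                     attr(object, "p_d"),
                                     attr(object, "p_pnu"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Boxplots of a per-replicate metric across treatments
#'
#' @param tr A `treatment_runs`.
#' @param metric Metric column name (e.g. `"sweeps"`, `"D_p"`).
#' @return A ggplot.
#' @export
plot_treatment_metric <- function(tr, metric = "sweeps") {
  stopifnot(inherits(tr, "treatment_runs"),
            metric %in% names(tr$metrics))
  ggplot2::ggplot(tr$metrics,
                  ggplot2::aes(x = .data$treatment,
                               y = .data[[metric]],
                               fill = .data$treatment)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7, size = 1) +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @export
glance.evo_run <- function(x, ...) {
  tibble::tibble(
    treatment = x$config$treatment,
    updates = max(x$logs$update),
    births = x$n_births,
    genotypes = nrow(x$genotypes),
    sweeps = count_sweeps(x$logs$mrca),
    final_entropy = dplyr::last(x$logs$mean_entropy),
    final_mrca_depth = dplyr::last(x$logs$mrca_depth),
    final_equ_performers = dplyr::last(x$logs$equ_performers)
  )
}

#' @export
tidy.evo_run <- function(x, ...) x$logs

#' @export
tidy.neighborhood_survey <- function(x, ...) {
  d <- tibble::as_tibble(x)
  d$class <- ifelse(d$neutral, "neutral", "detrimental")
  d
}

#' @export
glance.neighborhood_survey <- function(x, ...) {
  dplyr::bind_cols(survey_fractions(x),
                   tibble::tibble(
                     parent_fitness = attr(x, "parent_fitness"),
                     parent_tasks = paste(attr(x, "parent_tasks"),
                                          collapse = "+")))
}
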