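# Non-parametric group comparisons (Wilcoxon rank-sum with normal
# approximation Z, Kruskal-Wallis), Bonferroni correction, Spearman rank
# correlation, and OLS regressions of task loss/regain on site counts.

#' Compare treatment groups (Kruskal-Wallis + pairwise rank-sum)
#'
#' Runs a Kruskal-Wallis test across all groups and, optionally, pairwise
#' Wilcoxon rank-sum tests with a normal-approximation Z statistic
#' (tie-corrected, no continuity correction) and Bonferroni-adjusted
#' p-values over the number of pairwise comparisons.
#'
#' @param data A data frame.
#' @param value Column with the response values (tidy-eval).
#' @param group Column with the group labels (tidy-eval).
#' @param pairwise Run all pairwise rank-sum tests (default TRUE).
#' @param alternative Alternative hypothesis for the pairwise tests
#'   (`"two.sided"`, `"less"`, `"greater"`; applied as group1 vs group2).
#' @return An object of class `group_comparison`: list with `kruskal`
#'   (one-row tibble: statistic, df, p_value) and `pairwise` (tibble:
#'   group1, group2, n1, n2, z, p_value, p_bonferroni).
#' @export
compare_groups <- function(data, value, group, pairwise = TRUE,
                           alternative = "two.sided") {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  x <- rlang::eval_tidy(value, data)
  g <- as.character(rlang::eval_tidy(group, data))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- g[keep]
  lv <- unique(g)
  if (length(lv) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  kw <- stats::kruskal.test(x, factor(g))
  kruskal <- tibble::tibble(statistic = unname(kw$statistic),
                            df = unname(kw$parameter),
                            p_value = kw$p.value)
  pw <- NULL
  if (pairwise) {
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    m <- length(pairs)
    pw <- dplyr::bind_rows(lapply(pairs, function(p) {
      x1 <- x[g == p[1]]
      x2 <- x[g == p[2]]
      rs <- rank_sum_z(x1, x2, alternative)
      tibble::tibble(group1 = p[1], group2 = p[2],
                     n1 = length(x1), n2 = length(x2),
                     z = rs$z, p_value = rs$p)
    }))
    pw$p_bonferroni <- pmin(1, pw$p_value * m)
  }
  structure(list(kruskal = kruskal, pairwise = pw,
                 alternative = alternative),
            class = "group_comparison")
}

# Wilcoxon rank-sum Z via the normal approximation with tie correction.
rank_sum_z <- function(x1, x2, alternative = "two.sided") {
  n1 <- length(x1)
  n2 <- length(x2)
  r <- rank(c(x1, x2))
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n2 + n1 + 1) / 2
  n <- n1 + n2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sig2 > 0) (w - mu) / sqrt(sig2) else 0
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              less = stats::pnorm(z),
              greater = stats::pnorm(z, lower.tail = FALSE),
              stop("bad alternative", call. = FALSE))
  list(z = z, p = min(1, p))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> Kruskal-Wallis H(", x$kruskal$df, ") = ",
      signif(x$kruskal$statistic, 4), ", p = ",
      signif(x$kruskal$p_value, 3), "\n", sep = "")
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$pairwise)) return(x$kruskal)
  x$pairwise
}

#' @export
glance.group_comparison <- function(x, ...) x$kruskal

#' OLS regression of task loss / regain fractions on site counts
#'
#' Fits `y ~ x` (one predictor) or `y ~ x1 + x2` (two predictors, e.g.
#' regain fraction on functional and vestigial site counts) by ordinary
#' least squares.
#'
#' @param data A data frame.
#' @param formula A model formula with 1 or 2 predictors.
#' @return An object of class `task_loss_fit` wrapping the `lm` fit.
#' @export
fit_task_loss_regression <- function(data, formula) {
  mf <- stats::model.frame(formula, data)
  p <- ncol(mf) - 1
  if (p < 1 || p > 2) {
    stop("regression supports 1 or 2 predictors", call. = FALSE)
  }
  if (nrow(mf) <= p + 1) {
    stop("need more than ", p + 1, " observations", call. = FALSE)
  }
  fit <- stats::lm(formula, data = data)
  if (fit$rank < p + 1) {
    stop("rank-deficient design (collinear predictors)", call. = FALSE)
  }
  structure(list(fit = fit, formula = formula, n = nrow(mf),
                 predictors = p),
            class = "task_loss_fit")
}

#' @export
print.task_loss_fit <- function(x, ...) {
  s <- summary(x$fit)
  cat("<task_loss_fit> n =", x$n, " R-squared:",
      signif(s$r.squared, 4), " adj:", signif(s$adj.r.squared, 4), "\n")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.task_loss_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1]),
                 std_error = unname(s[, 2]), statistic = unname(s[, 3]),
                 p_value = unname(s[, 4]))
}

#' @export
glance.task_loss_fit <- function(x, ...) {
  s <- summary(x$fit)
  f <- s$fstatistic
  tibble::tibble(r_squared = s$r.squared,
                 adj_r_squared = s$adj.r.squared,
                 statistic = unname(f[1]),
                 p_value = unname(stats::pf(f[1], f[2], f[3],
                                            lower.tail = FALSE)),
                 df = unname(f[2]), n = x$n,
                 aic = stats::AIC(x$fit), bic = stats::BIC(x$fit))
}

#' Confidence intervals for regression coefficients
#'
#' @param x A `task_loss_fit`.
#' @param level Confidence level (default 0.95).
#' @return A tibble with `term`, `lower`, `upper`.
#' @export
fit_confint <- function(x, level = 0.95) {
  ci <- stats::confint(x$fit, level = level)
  tibble::tibble(term = rownames(ci), lower = ci[, 1], upper = ci[, 2])
}

#' Spearman rank correlation
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return A one-row tibble: `rho`, `p_value`, `n`; `rho` is `NA` (with a
#'   warning) for constant input.
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input: rho undefined")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
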