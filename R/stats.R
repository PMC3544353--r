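#' Per-group mean and standard deviation
#'
#' Summarizes a grouped column as mean and sample standard deviation
#' (denominator n - 1, the convention of common statistics packages); the
#' SD of a single-value group is reported as `NA`.
#'
#' @param data Data frame with one row per observation.
#' @param value Column of values (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return Tibble: `group`, `n`, `mean`, `sd`.
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 3), y = c(1, 2, 3, 2, 3, 4))
#' summarize_groups(df, y, g)
#' @export
summarize_groups <- function(data, value, group) {
  if (nrow(data) == 0L) stop_dfa("input", "no observations")
  v <- dplyr::pull(data, {{ value }})
  if (!all(is.finite(v))) stop_dfa("input", "values must be finite")
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sd = sd({{ value }}),
      .groups = "drop")
}

#' One-way ANOVA with Tukey all-pairwise comparisons
#'
#' Compares a value (typically the short-range exponent alpha1) across
#' groups with a one-way analysis of variance followed by the Tukey HSD
#' studentized-range test on all `G(G-1)/2` pairs; unbalanced designs use
#' the Tukey-Kramer adjustment (what [stats::TukeyHSD()] computes).  Pairs
#' are flagged significant when the adjusted p-value falls below
#' `alpha_level`.
#'
#' When every group has zero internal variance but means differ, the F
#' statistic is infinite: the report carries `statistic = Inf`,
#' `p.value = 0` and a warning, with pairwise flags from mean equality.
#'
#' @param data Data frame, one row per observation.
#' @param value Value column (tidy-eval).
#' @param group Group column (tidy-eval); at least 2 groups, total
#'   observations exceeding the group count.
#' @param alpha_level Significance threshold (default 0.05).
#' @return A `dfa_group_comparison` with `summary` (per-group mean/SD),
#'   `anova` (F, degrees of freedom, p), `pairwise` (Tukey table with
#'   `significant` flags) and `alpha_level`.  Has `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 4),
#'                  y = c(rnorm(4), rnorm(4, 1), rnorm(4, 2)))
#' compare_groups(df, y, g)
#' @export
compare_groups <- function(data, value, group, alpha_level = 0.05) {
  df <- tibble(value = dplyr::pull(data, {{ value }}),
               group = as.character(dplyr::pull(data, {{ group }})))
  if (any(!nzchar(df$group)) || anyNA(df$group)) stop_dfa("input", "group labels must be non-empty")
  if (!all(is.finite(df$value))) stop_dfa("input", "values must be finite")
  groups <- sort(unique(df$group))
  G <- length(groups)
  if (G < 2L) stop_dfa("input", "need at least 2 groups")
  if (nrow(df) <= G) stop_dfa("input", "need more observations than groups")
  df$group <- factor(df$group, levels = groups)

  summary <- summarize_groups(df, value, group)
  pair_names <- utils::combn(groups, 2L, paste, collapse = "-")

  ss_within <- sum(tapply(df$value, df$group, function(v) sum((v - mean(v))^2)))
  means <- tapply(df$value, df$group, mean)
  if (ss_within <= .Machine$double.eps * sum(df$value^2) && diff(range(means)) > 0) {
    warn("zero within-group variance with unequal means: F is infinite")
    combos <- utils::combn(groups, 2L)
    gap <- abs(means[combos[1L, ]] - means[combos[2L, ]])
    pairwise <- tibble(
      contrast = pair_names,
      estimate = unname(means[combos[2L, ]] - means[combos[1L, ]]),
      conf.low = NA_real_, conf.high = NA_real_,
      adj.p.value = ifelse(gap > 0, 0, 1),
      significant = gap > 0)
    anova_row <- tibble(statistic = Inf, df_between = G - 1L,
                        df_within = nrow(df) - G, p.value = 0)
  } else {
    fit <- aov(value ~ group, data = df)
    an <- summary(fit)[[1L]]
    anova_row <- tibble(
      statistic = an[["F value"]][1L],
      df_between = an[["Df"]][1L], df_within = an[["Df"]][2L],
      p.value = an[["Pr(>F)"]][1L])
    tk <- TukeyHSD(fit, conf.level = 1 - alpha_level)$group
    pairwise <- tibble(
      contrast = rownames(tk),
      estimate = unname(tk[, "diff"]),
      conf.low = unname(tk[, "lwr"]), conf.high = unname(tk[, "upr"]),
      adj.p.value = unname(tk[, "p adj"]),
      significant = unname(tk[, "p adj"] < alpha_level))
  }
  structure(
    list(summary = summary, anova = anova_row, pairwise = pairwise,
         alpha_level = alpha_level),
    class = "dfa_group_comparison")
}

#' @export
print.dfa_group_comparison <- function(x, ...) {
  cat("Group comparison (one-way ANOVA + Tukey pairwise)\n\n")
  for (i in seq_len(nrow(x$summary))) {
    r <- x$summary[i, ]
    cat(sprintf("  %-12s n = %2d   %.3f +/- %s\n", r$group, r$n, r$mean,
                if (is.na(r$sd)) "NA" else sprintf("%.3f", r$sd)))
  }
  cat(sprintf("\n  F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$statistic, x$anova$p.value))
  for (i in seq_len(nrow(x$pairwise))) {
    r <- x$pairwise[i, ]
    cat(sprintf("  %-16s adj. p = %.4g%s\n", r$contrast, r$adj.p.value,
                if (isTRUE(r$significant)) " *" else ""))
  }
  cat(sprintf("  (* adjusted p < %g)\n", x$alpha_level))
  invisible(x)
}

#' Tidy the pairwise table of a group comparison
#'
#' @param x A `dfa_group_comparison`.
#' @param ... Unused.
#' @return The Tukey pairwise tibble: `contrast`, `estimate`, confidence
#'   bounds, `adj.p.value`, `significant`.
#' @method tidy dfa_group_comparison
#' @export
tidy.dfa_group_comparison <- function(x, ...) x$pairwise

#' One-row ANOVA summary of a group comparison
#'
#' @param x A `dfa_group_comparison`.
#' @param ... Unused.
#' @return One-row tibble: F `statistic`, degrees of freedom, `p.value`,
#'   group count, total n.
#' @method glance dfa_group_comparison
#' @export
glance.dfa_group_comparison <- function(x, ...) {
  dplyr::mutate(x$anova, n_groups = nrow(x$summary), n = sum(x$summary$n))
}

#' @method autoplot dfa_group_comparison
#' @export
autoplot.dfa_group_comparison <- function(object, ...) {
  stats <- object$summary
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - dplyr::coalesce(.data$sd, 0),
      ymax = .data$mean + dplyr::coalesce(.data$sd, 0))) +
    ggplot2::labs(x = NULL, y = "mean +/- SD",
                  title = sprintf("Group means (ANOVA p = %.3g)", object$anova$p.value)) +
    ggplot2::theme_minimal()
}
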