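#' One-way repeated-measures ANOVA engine
#'
#' Two-way layout without replication: one observation per (level, unit)
#' cell; the factor of interest is tested against its interaction with the
#' repeated unit, F = MS_factor / MS_residual with dfs
#' (L - 1, (L - 1)(U - 1)). Sphericity is not corrected by default; a
#' Greenhouse-Geisser option scales both dfs.
#'
#' @param data Data frame with the three columns named below.
#' @param value,factor,unit Column names (strings).
#' @param gg Apply the Greenhouse-Geisser epsilon to the dfs (default FALSE).
#' @param bonferroni_pairwise Also run paired t-tests on every level pair
#'   with Bonferroni adjustment (family size = number of pairs).
#' @return An object of class `rm_anova` with elements `df1`, `df2`,
#'   `statistic` (F), `p_value`, `epsilon` (if `gg`), `pairwise` (tibble or
#'   NULL), `term`, `n_units`.
#' @export
rm_anova <- function(data, value, factor, unit, gg = FALSE,
                     bonferroni_pairwise = TRUE) {
  d <- tibble::tibble(value = data[[value]],
                      level = base::factor(data[[factor]]),
                      unit = base::factor(data[[unit]]))
  if (anyNA(d$value)) {
    abort("repeated-measures ANOVA requires complete cells",
          class = "playpref_validation_error")
  }
  if (nlevels(d$level) < 2L || nlevels(d$unit) < 2L) {
    abort("repeated-measures ANOVA needs >= 2 factor levels and >= 2 units",
          class = "playpref_validation_error")
  }
  cells <- table(d$level, d$unit)
  if (any(cells != 1L)) {
    bad <- which(cells != 1L, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "unbalanced table: level '%s' x unit '%s' has %d observation(s)",
      rownames(cells)[bad[1]], colnames(cells)[bad[2]],
      cells[bad[1], bad[2]]), class = "playpref_validation_error")
  }
  fit <- aov(value ~ level + unit, data = d)
  tab <- summary(fit)[[1]]
  rownames(tab) <- trimws(rownames(tab))
  ms_level <- tab["level", "Mean Sq"]
  ms_resid <- tab["Residuals", "Mean Sq"]
  df1 <- tab["level", "Df"]
  df2 <- tab["Residuals", "Df"]
  # mean squares at rounding-noise level are structural zeros
  eps <- 1e-10 * (mean(d$value^2) + .Machine$double.xmin)
  ms_level <- if (ms_level < eps) 0 else ms_level
  ms_resid <- if (ms_resid < eps) 0 else ms_resid
  f_stat <- if (ms_resid == 0) {
    if (ms_level == 0) 0 else Inf
  } else ms_level / ms_resid
  eps <- NULL
  if (gg) {
    eps <- gg_epsilon(d)
    df1 <- df1 * eps
    df2 <- df2 * eps
  }
  p <- if (is.infinite(f_stat)) 0 else stats::pf(f_stat, df1, df2,
                                                 lower.tail = FALSE)
  pw <- if (bonferroni_pairwise) pairwise_bonferroni(d) else NULL
  structure(list(term = factor, df1 = df1, df2 = df2, statistic = f_stat,
                 p_value = p, epsilon = eps, pairwise = pw,
                 n_units = nlevels(d$unit), n_levels = nlevels(d$level)),
            class = "rm_anova")
}

# Greenhouse-Geisser epsilon from the levels-by-units data.
gg_epsilon <- function(d) {
  wide <- tapply(d$value, list(d$unit, d$level), identity)
  S <- stats::cov(wide)
  k <- ncol(S)
  dbar <- mean(diag(S))
  gbar <- mean(S)
  rowbar <- rowMeans(S)
  num <- (k * (dbar - gbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowbar^2) + k^2 * gbar^2)
  if (den == 0) 1 else min(1, num / den)
}

# Paired t-tests on all level pairs, Bonferroni family = number of pairs.
pairwise_bonferroni <- function(d) {
  lev <- levels(d$level)
  pairs <- utils::combn(lev, 2L)
  m <- ncol(pairs)
  wide <- tapply(d$value, list(d$unit, d$level), identity)
  purrr::map_dfr(seq_len(m), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    diffs <- wide[, a] - wide[, b]
    if (sd(diffs) == 0) {
      p_raw <- if (mean(diffs) == 0) 1 else 0
    } else {
      p_raw <- stats::t.test(diffs)$p.value
    }
    tibble::tibble(level_a = a, level_b = b, mean_diff = mean(diffs),
                   p_raw = p_raw, p_adjusted = min(1, m * p_raw))
  }) |> dplyr::mutate(m_comparisons = m)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on '%s': F(%s, %s) = %.3f, p = %.4g\n",
              x$term, format(x$df1), format(x$df2), x$statistic, x$p_value))
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) {
  tibble::tibble(term = x$term, df1 = x$df1, df2 = x$df2,
                 statistic = x$statistic, p_value = x$p_value)
}

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(df1 = x$df1, df2 = x$df2, statistic = x$statistic,
                 p_value = x$p_value, n_units = x$n_units,
                 n_levels = x$n_levels)
}

#' Popularity ANOVA: are some animals consistently favoured?
#'
#' Within-subject ANOVA over target identity on the percentage of play each
#' rater directs at each target, with rater-day combinations as the repeated
#' units. At the standard design (6 targets, 5 raters x 4 days) the dfs are
#' (5, 95).
#'
#' Each target is rated by the other k-1 animals, so units are positional:
#' unit u of a target is its u-th rater (label order, skipping the target
#' itself) on a given day.
#'
#' @param pop_table Popularity tibble ([popularity()] rows bound over days)
#'   for one group: columns `day`, `rater`, `target`, `pct`.
#' @param ... Passed to [rm_anova()].
#' @return An `rm_anova` object.
#' @export
popularity_anova <- function(pop_table, ...) {
  units <- pop_table |>
    dplyr::group_by(.data$target, .data$day) |>
    dplyr::arrange(.data$rater, .by_group = TRUE) |>
    dplyr::mutate(rater_slot = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(unit = paste0("d", .data$day, "_r", .data$rater_slot))
  rm_anova(units, value = "pct", factor = "target", unit = "unit", ...)
}

#' Day-to-day popularity ANOVA for one target
#'
#' Tests whether the percentage of play directed at a given animal changes
#' across days, with its raters as repeated units; dfs are
#' (D - 1, (D - 1)(k - 2)) = (3, 12) at the standard design.
#'
#' @param pop_table Popularity tibble for one group.
#' @param target Animal id to test.
#' @param ... Passed to [rm_anova()].
#' @return An `rm_anova` object.
#' @export
daily_popularity_anova <- function(pop_table, target, ...) {
  d <- dplyr::filter(pop_table, .data$target == !!target)
  rm_anova(d, value = "pct", factor = "day", unit = "rater", ...)
}

#' Group-totals ANOVA: do some groups play more than others?
#'
#' Compares total attacks per group across the scored days (days as the
#' repeated units); at the standard design of 8 groups x 4 days the dfs are
#' (7, 21).
#'
#' @param events Event tibble for the whole study.
#' @param ... Passed to [rm_anova()].
#' @return An `rm_anova` object.
#' @export
group_totals_anova <- function(events, ...) {
  totals <- events |>
    dplyr::count(.data$group_id, .data$day, name = "total_attacks")
  full <- tidyr::expand_grid(group_id = unique(events$group_id),
                             day = unique(events$day)) |>
    dplyr::left_join(totals, by = c("group_id", "day")) |>
    dplyr::mutate(total_attacks = tidyr::replace_na(.data$total_attacks, 0L))
  rm_anova(full, value = "total_attacks", factor = "group_id", unit = "day",
           ...)
}
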