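#' Build the dyad-day feature table for the preference models
#'
#' One row per classified directed dyad-day (strongly preferred or avoided
#' partner), combining the play-style predictors (how the partner responded
#' to the focal animal's attacks), play quality (role reversals, symmetry),
#' dyadic proximity, and the weight and dominance asymmetries.
#'
#' @param events Event tibble.
#' @param index_table [thompson_index()] rows over the analysed group-days.
#' @param symmetry [play_symmetry()] rows over the same group-days.
#' @param proximity Proximity tibble (`group_id`, `day`, `animal_a`,
#'   `animal_b`, `proximity_s`).
#' @param animals Animal metadata with `weight_g` and `dominance_rank`.
#' @param screen Optional [mantel_screen_all()] result; group-days with
#'   `excluded = TRUE` are dropped before building rows.
#' @return Tibble with one row per classified dyad-day: `group_id`, `day`,
#'   `initiator_id`, `partner_id`, `outcome` (1 = preferred, 0 = not
#'   preferred), `partner_play_frequency`, `pct_no_response`, `pct_evasion`,
#'   `pct_pin`, `pct_role_reversal`, `symmetry`, `proximity_s`,
#'   `weight_diff_g`, `dominance_diff`. Dyads whose focal animal launched no
#'   attacks at the partner have undefined percentages; such rows are
#'   dropped with a warning.
#' @export
build_feature_table <- function(events, index_table, symmetry, proximity,
                                animals, screen = NULL) {
  focal <- dplyr::filter(index_table,
                         .data$classification %in%
                           c("strong_preferred", "avoided"))
  if (!is.null(screen)) {
    keep <- dplyr::filter(screen, !.data$excluded)
    focal <- dplyr::semi_join(focal, keep, by = c("group_id", "day"))
  }
  if (nrow(focal) == 0) return(empty_feature_table())

  # partner's responses to the focal animal's attacks (focal -> partner)
  tactic <- events |>
    dplyr::group_by(.data$group_id, .data$day,
                    initiator = .data$initiator, recipient = .data$recipient) |>
    dplyr::summarise(
      n_attacks = dplyr::n(),
      pct_no_response = 100 * mean(.data$response == "no_response"),
      pct_evasion = 100 * mean(.data$response == "evasion"),
      pct_pin = 100 * mean(.data$response == "pin"),
      pct_role_reversal = 100 * mean(.data$role_reversal),
      .groups = "drop")
  # attacks launched by the partner toward the focal animal
  partner_freq <- events |>
    dplyr::count(.data$group_id, .data$day, .data$initiator,
                 .data$recipient, name = "partner_play_frequency") |>
    dplyr::rename(initiator = "recipient", recipient = "initiator")

  rows <- focal |>
    dplyr::left_join(tactic, by = c("group_id", "day", "initiator",
                                    "recipient")) |>
    dplyr::left_join(partner_freq, by = c("group_id", "day", "initiator",
                                          "recipient")) |>
    dplyr::mutate(partner_play_frequency =
                    tidyr::replace_na(.data$partner_play_frequency, 0L),
                  animal_a = pmin(.data$initiator, .data$recipient),
                  animal_b = pmax(.data$initiator, .data$recipient)) |>
    dplyr::left_join(dplyr::select(symmetry, "group_id", "day", "animal_a",
                                   "animal_b", "symmetry"),
                     by = c("group_id", "day", "animal_a", "animal_b")) |>
    dplyr::left_join(dplyr::select(proximity, "group_id", "day", "animal_a",
                                   "animal_b", "proximity_s"),
                     by = c("group_id", "day", "animal_a", "animal_b")) |>
    dplyr::left_join(dplyr::select(animals, "group_id",
                                   initiator = "animal_id",
                                   w_i = "weight_g", r_i = "dominance_rank"),
                     by = c("group_id", "initiator")) |>
    dplyr::left_join(dplyr::select(animals, "group_id",
                                   recipient = "animal_id",
                                   w_j = "weight_g", r_j = "dominance_rank"),
                     by = c("group_id", "recipient"))

  undefined <- is.na(rows$n_attacks) | rows$n_attacks == 0
  if (any(undefined)) {
    warn(sprintf(
      "dropping %d classified dyad-day(s) with zero attacks at the partner (tactic percentages undefined)",
      sum(undefined)))
    rows <- rows[!undefined, , drop = FALSE]
  }
  dplyr::transmute(
    rows, .data$group_id, .data$day,
    initiator_id = paste0("g", .data$group_id, "_", .data$initiator),
    partner_id = paste0("g", .data$group_id, "_", .data$recipient),
    outcome = as.integer(.data$classification == "strong_preferred"),
    .data$partner_play_frequency,
    .data$pct_no_response, .data$pct_evasion, .data$pct_pin,
    .data$pct_role_reversal, .data$symmetry, .data$proximity_s,
    weight_diff_g = .data$w_i - .data$w_j,
    dominance_diff = .data$r_i - .data$r_j)
}

empty_feature_table <- function() {
  tibble::tibble(group_id = integer(), day = integer(),
                 initiator_id = character(), partner_id = character(),
                 outcome = integer(), partner_play_frequency = integer(),
                 pct_no_response = double(), pct_evasion = double(),
                 pct_pin = double(), pct_role_reversal = double(),
                 symmetry = double(), proximity_s = double(),
                 weight_diff_g = double(), dominance_diff = double())
}

#' Binary mixed-effects logistic model of partner preference
#'
#' Fits a logistic regression of preferred (1) vs not-preferred (0) partner
#' status on the given predictors (entered untransformed, so odds ratios are
#' per unit of each predictor) with random intercepts for the identities in
#' `random` — the focal initiator by default; crossed initiator and partner
#' intercepts for the dyadic-asymmetry model. Estimation is by Laplace
#' approximation (`lme4::glmer`). When a random-intercept variance estimates
#' at the boundary (0), the model is refit as an ordinary logistic
#' regression and the fallback is recorded.
#'
#' @param rows Feature tibble from [build_feature_table()].
#' @param predictors Character vector of predictor column names.
#' @param random Character vector of random-intercept grouping columns
#'   (default `"initiator_id"`).
#' @param ci_level Wald confidence level (default 0.95, multiplier 1.96).
#' @return Object of class `playpref_glmm` with a coefficient table
#'   (estimate, SE, z, p, OR, Wald CI on the link scale and on the OR
#'   scale), random-intercept variances, `n_rows`, `convergence` and
#'   `fallback`.
#' @export
fit_binary_glmm <- function(rows, predictors, random = "initiator_id",
                            ci_level = 0.95) {
  if (length(unique(rows$outcome)) < 2L) {
    abort("need both outcome classes present", class = "playpref_error")
  }
  missing_p <- setdiff(c(predictors, random), names(rows))
  if (length(missing_p) > 0) {
    abort(paste0("unknown column(s): ", paste(missing_p, collapse = ", ")),
          class = "playpref_error")
  }
  d <- rows[stats::complete.cases(rows[, c("outcome", predictors, random)]), ]
  check_separation(d, predictors)

  fixed <- paste("outcome ~", paste(predictors, collapse = " + "))
  re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
  form <- stats::as.formula(paste(fixed, "+", re))

  fit <- withCallingHandlers(
    lme4::glmer(form, data = d, family = stats::binomial()),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
  re_var <- re_variances(fit)
  # fall back to ordinary logistic only when every random-intercept variance
  # estimates at the boundary; a partially singular crossed fit keeps the
  # informative intercepts and is flagged via the variance table
  singular <- all(re_var < 1e-8)
  fallback <- NULL
  if (singular) {
    fallback <- "glm_boundary_variance"
    glm_fit <- stats::glm(stats::as.formula(fixed), data = d,
                          family = stats::binomial())
    tab <- summary(glm_fit)$coefficients
    conv <- glm_fit$converged
  } else {
    tab <- summary(fit)$coefficients
    conv <- isTRUE(fit@optinfo$conv$opt == 0)
  }
  mult <- stats::qnorm(1 - (1 - ci_level) / 2)
  coefs <- tibble::tibble(
    term = rownames(tab),
    estimate = unname(tab[, "Estimate"]),
    std_error = unname(tab[, "Std. Error"]),
    z = estimate / std_error,
    p_value = 2 * pnorm(-abs(z)),
    odds_ratio = exp(estimate),
    ci_lower = estimate - mult * std_error,
    ci_upper = estimate + mult * std_error,
    or_ci_lower = exp(ci_lower),
    or_ci_upper = exp(ci_upper))
  structure(list(coefficients = coefs, random_variances = re_var,
                 n_rows = nrow(d), convergence = conv,
                 fallback = fallback, predictors = predictors,
                 random = random, ci_level = ci_level,
                 fit = if (singular) glm_fit else fit),
            class = "playpref_glmm")
}

re_variances <- function(fit) {
  vc <- lme4::VarCorr(fit)
  setNames(vapply(vc, function(m) as.numeric(m[1, 1]), numeric(1)),
           names(vc))
}

# Complete separation: a plain logistic fit with fitted probabilities
# numerically at 0/1 and exploding coefficients.
check_separation <- function(d, predictors) {
  form <- stats::as.formula(
    paste("outcome ~", paste(predictors, collapse = " + ")))
  glm_fit <- suppressWarnings(
    stats::glm(form, data = d, family = stats::binomial()))
  fitted_extreme <- all(glm_fit$fitted.values < 1e-6 |
                          glm_fit$fitted.values > 1 - 1e-6)
  if (fitted_extreme) {
    abort(paste0("complete separation detected: a predictor perfectly ",
                 "classifies the outcome; consider a penalized fit"),
          class = "playpref_separation_error")
  }
  invisible(NULL)
}

#' @export
print.playpref_glmm <- function(x, ...) {
  cat(sprintf(
    "Binary GLMM (%d rows; random: %s%s)\n", x$n_rows,
    paste(x$random, collapse = " + "),
    if (is.null(x$fallback)) "" else
      sprintf("; fallback: %s", x$fallback)))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Coefficient table of a fitted preference model
#'
#' @param x A `playpref_glmm`.
#' @param ... Unused.
#' @return Tibble with one row per fixed effect: estimate, standard error,
#'   z, p, odds ratio and Wald confidence limits (link and OR scale).
#' @export
tidy.playpref_glmm <- function(x, ...) x$coefficients

#' One-row model summary of a fitted preference model
#'
#' @param x A `playpref_glmm`.
#' @param ... Unused.
#' @return One-row tibble with `n_rows`, the random-intercept variance(s),
#'   convergence status and fallback flag.
#' @export
glance.playpref_glmm <- function(x, ...) {
  out <- tibble::tibble(n_rows = x$n_rows,
                        convergence = x$convergence,
                        fallback = x$fallback %||% NA_character_)
  for (nm in names(x$random_variances)) {
    out[[paste0("var_", nm)]] <- x$random_variances[[nm]]
  }
  out
}
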