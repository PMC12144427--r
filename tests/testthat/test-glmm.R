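test_that("feature table percentages equal brute-force tallies", {
  ev <- dplyr::bind_rows(
    make_events(rep("A", 10), rep("B", 10),
                response = c(rep("pin", 5), rep("evasion", 3),
                             rep("no_response", 2)),
                role_reversal = c(rep(TRUE, 4), rep(FALSE, 6)),
                time_s = 1:10),
    make_events(rep("B", 4), rep("A", 4), response = "pin",
                time_s = 11:14),
    make_events(c("A", "C"), c("F", "A"), response = "box",
                time_s = 15:16))
  idx <- tibble::tibble(group_id = 1L, day = 1L, initiator = "A",
                        recipient = c("B", "F"),
                        classification = c("strong_preferred", "avoided"))
  sym <- play_symmetry(build_count_matrix(ev, 1L, 1L, LETTERS[1:6]))
  prox <- tibble::tibble(group_id = 1L, day = 1L,
                         animal_a = c("A", "A"), animal_b = c("B", "F"),
                         proximity_s = c(300, 120))
  animals <- tibble::tibble(group_id = 1L, animal_id = LETTERS[1:6],
                            weight_g = c(110, 100, 95, 90, 85, 130),
                            dominance_rank = 1:6)
  rows <- build_feature_table(ev, idx, sym, prox, animals)
  a_b <- rows[rows$partner_id == "g1_B", ]
  expect_equal(a_b$outcome, 1L)
  expect_equal(a_b$pct_pin, 50)
  expect_equal(a_b$pct_evasion, 30)
  expect_equal(a_b$pct_no_response, 20)
  expect_equal(a_b$pct_role_reversal, 40)
  expect_equal(a_b$partner_play_frequency, 4L)
  expect_equal(a_b$symmetry, 1 - abs(10 - 4) / 14)
  expect_equal(a_b$proximity_s, 300)
  expect_equal(a_b$weight_diff_g, 10)
  expect_equal(a_b$dominance_diff, -1L)
  a_f <- rows[rows$partner_id == "g1_F", ]
  expect_equal(a_f$outcome, 0L)
  expect_equal(a_f$pct_no_response, 0)
  expect_equal(a_f$pct_pin, 0)
})

test_that("dyads with no attacks at the partner are dropped with a warning", {
  ev <- make_events("A", "B", response = "pin")
  idx <- tibble::tibble(group_id = 1L, day = 1L, initiator = "A",
                        recipient = c("B", "C"),
                        classification = c("strong_preferred", "avoided"))
  sym <- play_symmetry(build_count_matrix(ev, 1L, 1L, LETTERS[1:6]))
  prox <- tibble::tibble(group_id = integer(), day = integer(),
                         animal_a = character(), animal_b = character(),
                         proximity_s = double())
  animals <- tibble::tibble(group_id = 1L, animal_id = LETTERS[1:6],
                            weight_g = 100, dominance_rank = 1:6)
  expect_warning(rows <- build_feature_table(ev, idx, sym, prox, animals),
                 "zero attacks")
  expect_equal(nrow(rows), 1)
})

test_that("screened-out group-days contribute no model rows", {
  ev <- dplyr::bind_rows(make_events("A", "B", day = 1L),
                         make_events("A", "B", day = 3L, time_s = 2))
  idx <- tibble::tibble(group_id = 1L, day = c(1L, 3L),
                        initiator = "A", recipient = "B",
                        classification = "strong_preferred")
  screen <- tibble::tibble(group_id = 1L, day = c(1L, 3L),
                           excluded = c(TRUE, FALSE))
  sym <- dplyr::bind_rows(
    play_symmetry(build_count_matrix(ev, 1L, 1L, LETTERS[1:6])),
    play_symmetry(build_count_matrix(ev, 1L, 3L, LETTERS[1:6])))
  prox <- tibble::tibble(group_id = 1L, day = c(1L, 3L), animal_a = "A",
                         animal_b = "B", proximity_s = 100)
  animals <- tibble::tibble(group_id = 1L, animal_id = LETTERS[1:6],
                            weight_g = 100, dominance_rank = 1:6)
  rows <- build_feature_table(ev, idx, sym, prox, animals, screen = screen)
  expect_equal(nrow(rows), 1)
  expect_equal(rows$day, 3L)
})

test_that("the study design's 27 + 31 classified dyads give 58 model rows", {
  # classified dyad-days spread over groups and days as in the design
  slots <- tidyr::expand_grid(group_id = 1:8, day = c(1L, 3L, 5L, 8L),
                              initiator = "A",
                              recipient = c("B", "C")) |>
    dplyr::mutate(classification = rep(c("strong_preferred", "avoided"),
                                       length.out = dplyr::n()))
  focal <- dplyr::bind_rows(
    utils::head(dplyr::filter(slots, classification == "strong_preferred"),
                31),
    utils::head(dplyr::filter(slots, classification == "avoided"), 27))
  ev <- focal |>
    dplyr::group_by(group_id, day) |>
    dplyr::group_map(function(d, key) {
      make_events(rep("A", nrow(d)), d$recipient, group_id = key$group_id,
                  day = key$day, time_s = seq_len(nrow(d)))
    }) |>
    dplyr::bind_rows()
  sym <- tidyr::expand_grid(group_id = 1:8, day = c(1L, 3L, 5L, 8L),
                            animal_a = "A", animal_b = c("B", "C")) |>
    dplyr::mutate(symmetry = 0.5)
  prox <- dplyr::mutate(sym, proximity_s = 200, symmetry = NULL)
  animals <- tidyr::expand_grid(group_id = 1:8,
                                animal_id = LETTERS[1:6]) |>
    dplyr::mutate(weight_g = 100, dominance_rank = rep(1:6, 8))
  rows <- build_feature_table(ev, focal, sym, prox, animals)
  expect_equal(nrow(rows), 58)
  expect_equal(sum(rows$outcome == 1), 31)
  expect_equal(sum(rows$outcome == 0), 27)
})

test_that("OR and Wald CI are exact transforms of estimate and SE", {
  rows <- make_glmm_rows(n = 150, beta = 0.1, seed = 2)
  fit <- fit_binary_glmm(rows, "pct_role_reversal")
  co <- tidy(fit)
  expect_equal(co$odds_ratio, exp(co$estimate), tolerance = 1e-12)
  mult <- stats::qnorm(0.975)
  expect_equal(co$or_ci_lower, exp(co$estimate - mult * co$std_error),
               tolerance = 1e-12)
  expect_equal(co$or_ci_upper, exp(co$estimate + mult * co$std_error),
               tolerance = 1e-12)
  expect_equal(co$z, co$estimate / co$std_error, tolerance = 1e-12)
  expect_true(all(co$or_ci_lower < co$or_ci_upper))
  expect_true(all(co$odds_ratio > 0))
})

test_that("row order does not change the fit", {
  rows <- make_glmm_rows(n = 120, beta = 0.08, seed = 3)
  f1 <- fit_binary_glmm(rows, "pct_role_reversal")
  withr::local_seed(4)
  f2 <- fit_binary_glmm(rows[sample.int(nrow(rows)), ],
                        "pct_role_reversal")
  # the Laplace objective is permutation-invariant; allow optimiser jitter
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-4)
  expect_equal(tidy(f1)$std_error, tidy(f2)$std_error, tolerance = 1e-4)
})

test_that("boundary random-effect variance falls back to plain logistic", {
  rows <- make_glmm_rows(n = 200, beta = 0.05, re_sd = 0, seed = 5)
  fit <- fit_binary_glmm(rows, "pct_role_reversal")
  if (!is.null(fit$fallback)) {
    glm_fit <- stats::glm(outcome ~ pct_role_reversal, data = rows,
                          family = binomial())
    expect_equal(tidy(fit)$estimate,
                 unname(coef(glm_fit)), tolerance = 1e-8)
    expect_equal(glance(fit)$fallback, "glm_boundary_variance")
  }
  # the limit equivalence must hold whenever the variance estimates at zero
  expect_true(is.null(fit$fallback) ||
                glance(fit)$var_initiator_id < 1e-8)
})

test_that("a null predictor has an estimate near zero with CI covering 0", {
  # predictor values identical across outcome classes by construction
  rows <- tibble::tibble(
    initiator_id = rep(paste0("rat", 1:10), 4),
    partner_id = rep(paste0("rat", 10:1), 4),
    outcome = rep(c(0L, 1L), each = 20),
    pct_role_reversal = rep(seq(5, 52.5, by = 2.5), 2))
  fit <- fit_binary_glmm(rows, "pct_role_reversal")
  co <- tidy(fit)[2, ]
  expect_lt(abs(co$estimate), 1e-6)
  expect_lt(co$ci_lower, 0)
  expect_gt(co$ci_upper, 0)
})

test_that("degenerate inputs raise typed errors", {
  rows <- make_glmm_rows(n = 50, seed = 6)
  same <- dplyr::mutate(rows, outcome = 1L)
  expect_error(fit_binary_glmm(same, "pct_role_reversal"),
               class = "playpref_error")
  # complete separation: predictor = outcome
  sep <- dplyr::mutate(make_glmm_rows(n = 80, seed = 7),
                       sep_pred = outcome * 10 + runif(80))
  expect_error(fit_binary_glmm(sep, "sep_pred"),
               class = "playpref_separation_error")
  expect_error(fit_binary_glmm(rows, "not_a_column"),
               class = "playpref_error")
})

test_that("crossed random intercepts for initiator and partner are fitted", {
  rows <- make_glmm_rows(n = 250, beta = 0.08, seed = 8)
  fit <- fit_binary_glmm(rows, "pct_role_reversal",
                         random = c("initiator_id", "partner_id"))
  gl <- glance(fit)
  expect_true(all(c("var_initiator_id", "var_partner_id") %in% names(gl)))
})
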