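test_that("identical seeds give identical studies", {
  a <- simulate_study(sim_config(n_groups = 2), seed = 99)
  b <- simulate_study(sim_config(n_groups = 2), seed = 99)
  expect_identical(a$events, b$events)
  expect_identical(a$animals, b$animals)
  expect_identical(a$proximity, b$proximity)
  expect_identical(a$tube_trials, b$tube_trials)
  c <- simulate_study(sim_config(n_groups = 2), seed = 100)
  expect_false(identical(a$events, c$events))
})

test_that("infinite concentration gives uniform partner choice", {
  cfg <- sim_config(n_groups = 1, days = 1L, concentration = Inf,
                    rate_range = c(2000, 2000))
  study <- simulate_study(cfg, seed = 3)
  shares <- study$events |>
    dplyr::filter(initiator == "A") |>
    dplyr::count(recipient) |>
    dplyr::mutate(share = n / sum(n))
  expect_equal(nrow(shares), 5)
  expect_true(all(abs(shares$share - 0.2) < 0.02))
})

test_that("a planted 0.6-weight dyad yields about 60% of the attacks", {
  planted <- tibble::tibble(group_id = 1L, initiator = "A",
                            recipient = "B", weight = 0.6)
  cfg <- sim_config(n_groups = 1, days = 1L, planted_dyads = planted,
                    rate_range = c(5000, 5000))
  study <- simulate_study(cfg, seed = 8)
  a_events <- dplyr::filter(study$events, initiator == "A")
  expect_gt(nrow(a_events), 4000)
  expect_lt(abs(mean(a_events$recipient == "B") - 0.6), 0.03)
})

test_that("tactic profiles are recovered for preferred-class recipients", {
  planted <- tibble::tibble(group_id = 1L, initiator = "A",
                            recipient = "B", weight = 0.6)
  cfg <- sim_config(n_groups = 1, days = 1L, planted_dyads = planted,
                    rate_range = c(8000, 8000))
  study <- simulate_study(cfg, seed = 21)
  ab <- dplyr::filter(study$events, initiator == "A", recipient == "B")
  prof <- cfg$tactic_preferred
  obs <- prop.table(table(factor(ab$response, levels = names(prof)[1:4])))
  expect_true(all(abs(obs - prof[1:4]) < 0.02))
  # configured role-reversal is the per-attack marginal
  expect_lt(abs(mean(ab$role_reversal) - prof[["role_reversal"]]), 0.02)
  # and reversals never follow an unanswered attack
  expect_false(any(study$events$role_reversal &
                     study$events$response == "no_response"))
})

test_that("availability marginals match the configured fractions", {
  study <- simulate_study(sim_config(n_groups = 8), seed = 13)
  ev <- study$events
  expect_lt(abs(mean(ev$all_available) - 0.6), 0.02)
  expect_lt(abs(mean(ev$n_partners_available >= 2) - 0.988), 0.01)
})

test_that("tube test produces 5 trials per pair and rank concordance", {
  animals <- tibble::tibble(group_id = 1L, animal_id = LETTERS[1:6])
  trials <- simulate_tube_test(animals, strengths <- c(32, 16, 8, 4, 2, 1),
                               seed = 4, tie_prob = 0)
  expect_equal(nrow(trials), 15 * 5)
  ranks <- tube_rank(trials)
  # strictly ordered strengths: tally ranking recovers the strength ranking
  expect_equal(ranks$animal_id[order(ranks$rank)], LETTERS[1:6])
})

test_that("equal strengths win about half their trials", {
  animals <- tibble::tibble(group_id = 1L, animal_id = c("A", "B"))
  trials <- simulate_tube_test(animals, c(1, 1), seed = 6, tie_prob = 0,
                               n_trials = 10000L)
  expect_lt(abs(mean(trials$outcome == "win_a") - 0.5), 0.02)
})

test_that("impossible configs are rejected", {
  expect_error(sim_config(rate_range = c(0, 0)),
               class = "playpref_config_error")
  expect_error(sim_config(n_groups = 0), class = "playpref_config_error")
  expect_error(sim_config(tactic_preferred = c(no_response = 0.5,
                                               evasion = 0.5, pin = 0.5,
                                               box = 0.5,
                                               role_reversal = 0.1)),
               class = "playpref_config_error")
})

test_that("planted strong dyads are recovered as strong preferences", {
  # frozen calibration: at the default strong-preference settings a planted
  # 0.6-weight dyad classifies as a strong preference in >= 80% of groups
  planted <- tibble::tibble(group_id = 1L, initiator = "A",
                            recipient = "B", weight = 0.6)
  hits <- vapply(1:25, function(i) {
    st <- simulate_study(sim_config(n_groups = 1, days = 1L,
                                    planted_dyads = planted),
                         seed = 7000 + i)
    m <- build_count_matrix(st$events, 1L, 1L, LETTERS[1:6])
    idx <- thompson_index(m)
    idx$classification[idx$initiator == "A" & idx$recipient == "B"] ==
      "strong_preferred"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("day-to-day drift reshuffles favourites by a rank or two", {
  study <- simulate_study(sim_config(n_groups = 8), seed = 31)
  rc <- rank_changes(study$events, study$animals)
  med <- median(rc$favorite_change, na.rm = TRUE)
  expect_gte(med, 1)
  expect_lte(med, 2)
})
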