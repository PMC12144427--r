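test_that("preference index reproduces the worked threshold cases", {
  # initiator A launches 50 attacks: 20 at B (strong), 10 at C/D, 8 at E,
  # 2 at F (avoided)
  m <- make_counts(rbind(c(0, 20, 10, 10, 8, 2),
                         matrix(0, 5, 6)))
  idx <- thompson_index(m)
  a <- dplyr::filter(idx, initiator == "A")
  expect_equal(a$index[a$recipient == "B"], 2.0)
  expect_equal(a$classification[a$recipient == "B"], "strong_preferred")
  expect_equal(a$index[a$recipient == "F"], 0.2)
  expect_equal(a$classification[a$recipient == "F"], "avoided")
  # silent initiators are flagged undefined
  expect_true(all(idx$undefined[idx$initiator != "A"]))
  expect_true(all(is.na(idx$index[idx$initiator != "A"])))
})

test_that("uniform play gives index exactly 1 for every dyad", {
  m <- make_counts(matrix(10, 6, 6))
  idx <- thompson_index(m)
  expect_true(all(idx$index == 1))
  expect_true(all(idx$classification == "chance"))
})

test_that("per-initiator indices average exactly 1 on random matrices", {
  set.seed(71)
  for (i in 1:50) {
    m <- make_counts(matrix(rpois(36, sample(1:20, 1)), 6, 6))
    idx <- dplyr::filter(thompson_index(m), !undefined)
    means <- tapply(idx$index, idx$initiator, mean)
    expect_true(all(abs(means - 1) < 1e-12))
  }
})

test_that("classification boundaries are honoured exactly", {
  thr <- preference_thresholds()
  expect_equal(classify_index(2, thr), "strong_preferred")   # >= 2
  expect_equal(classify_index(1.999, thr), "preferred")
  expect_equal(classify_index(1, thr), "chance")
  expect_equal(classify_index(0.25, thr), "avoided")         # <= 0.25
  expect_equal(classify_index(0.2501, thr), "chance")
  expect_error(preference_thresholds(strong = 0.2),
               class = "playpref_config_error")
})

test_that("symmetry matches its closed forms and is order-symmetric", {
  m <- matrix(0, 6, 6)
  m[1, 2] <- 10; m[2, 1] <- 10   # A-B perfectly reciprocal
  m[1, 3] <- 10; m[3, 1] <- 0    # A-C one-sided
  m[1, 4] <- 15; m[4, 1] <- 5    # A-D 1 - 10/20
  s <- play_symmetry(make_counts(m))
  val <- function(a, b) s$symmetry[s$animal_a == a & s$animal_b == b]
  expect_equal(val("A", "B"), 1.0)
  expect_equal(val("A", "C"), 0.0)
  expect_equal(val("A", "D"), 0.5)
  expect_true(all(s$undefined[s$animal_a != "A"]))

  set.seed(72)
  for (i in 1:1000) {
    b_ab <- rpois(1, 5); b_ba <- rpois(1, 5)
    m2 <- matrix(0, 2, 2); m2[1, 2] <- b_ab; m2[2, 1] <- b_ba
    m2r <- m2[2:1, 2:1]
    s1 <- play_symmetry(make_counts(m2))$symmetry
    s2 <- play_symmetry(make_counts(m2r))$symmetry
    expect_identical(s1, s2)
  }
})

test_that("popularity percentages per rater sum to 100", {
  m <- make_counts(matrix(10, 6, 6))
  pop <- popularity(to_proportions(m))
  expect_true(all(pop$pct == 20))

  m2 <- matrix(0, 6, 6); m2[1, 2] <- 7
  pop2 <- popularity(to_proportions(make_counts(m2)))
  expect_equal(pop2$pct[pop2$rater == "A" & pop2$target == "B"], 100)

  study <- simulate_study(sim_config(n_groups = 1), seed = 14)
  pop3 <- popularity(to_proportions(build_count_matrix(study$events, 1L, 1L)))
  sums <- tapply(pop3$pct, pop3$rater, sum)
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("daily z-scores match a hand computation and centre at zero", {
  ev <- dplyr::bind_rows(purrr::imap(
    c(A = 10L, B = 10L, C = 10L, D = 10L, E = 10L, F = 22L),
    function(n, a) make_events(rep(a, n),
                               rep(setdiff(LETTERS[1:6], a)[1], n),
                               time_s = seq_len(n))))
  z <- daily_zscores(ev)
  # mean 12, sample sd sqrt((5*4 + 100)/5)
  sd_hand <- sqrt(120 / 5)
  expect_equal(z$z[z$animal_id == "F"], 10 / sd_hand)
  expect_equal(z$z[z$animal_id == "A"], -2 / sd_hand)
  expect_equal(which.max(z$z), which(z$animal_id == "F"))
  expect_lt(abs(sum(z$z)), 1e-9)
  expect_equal(z$direction[z$animal_id == "F"], "above")

  # zero-SD day: all equal
  ev2 <- make_events(LETTERS[1:6], c("B", "A", "D", "C", "F", "E"))
  z2 <- daily_zscores(ev2)
  expect_true(all(z2$undefined))
  expect_true(all(is.na(z2$z)))
})

test_that("rank change reproduces the worked stability scenarios", {
  base <- function(day, a_counts) {
    # A's attacks per partner B..F plus a fixed pattern for the others
    rows <- tibble::tibble(initiator = "A", recipient = LETTERS[2:6],
                           n = a_counts)
    others <- purrr::map_dfr(LETTERS[2:6], function(x) {
      tibble::tibble(initiator = x,
                     recipient = setdiff(LETTERS[1:6], x),
                     n = c(5, 4, 3, 2, 1))
    })
    ev <- tidyr::uncount(dplyr::bind_rows(rows, others), weights = n)
    make_events(ev$initiator, ev$recipient, day = day,
                time_s = seq_len(nrow(ev)))
  }
  day1 <- base(1L, c(50, 40, 30, 20, 10))  # A: fav B ... least F
  scenarios <- list(
    same = list(counts = c(50, 40, 30, 20, 10), change = 0L),
    second = list(counts = c(40, 50, 30, 20, 10), change = 1L),
    reversal = list(counts = c(10, 20, 30, 40, 50), change = 4L)
  )
  for (sc in scenarios) {
    ev <- dplyr::bind_rows(day1, base(3L, sc$counts))
    rc <- rank_changes(ev, day_pairs = list(c(1L, 3L)))
    expect_equal(rc$favorite_change[rc$animal_id == "A"], sc$change)
  }
  # full reversal also moves the least favourite maximally
  ev <- dplyr::bind_rows(day1, base(3L, c(10, 20, 30, 40, 50)))
  rc <- rank_changes(ev, day_pairs = list(c(1L, 3L)))
  expect_equal(rc$least_favorite_change[rc$animal_id == "A"], 4L)
  expect_error(rank_changes(day1, day_pairs = list(c(1L, 3L))),
               "missing day", class = "playpref_validation_error")
})

test_that("rank changes stay within 0..k-2 on simulated studies", {
  study <- simulate_study(sim_config(n_groups = 3), seed = 44)
  rc <- rank_changes(study$events, study$animals)
  expect_true(all(rc$favorite_change %in% 0:4))
  expect_true(all(rc$least_favorite_change %in% 0:4))
  expect_equal(nrow(rc), 3 * 6 * 3)  # groups x animals x day pairs
})

test_that("tube tallies and ranks match a brute-force count", {
  animals <- tibble::tibble(group_id = 1L, animal_id = LETTERS[1:6])
  trials <- simulate_tube_test(animals, c(30, 10, 8, 6, 4, 2), seed = 9,
                               tie_prob = 0.1)
  ranks <- tube_rank(trials)
  wins_hand <- table(factor(c(
    trials$animal_a[trials$outcome == "win_a"],
    trials$animal_b[trials$outcome == "win_b"]), levels = LETTERS[1:6]))
  expect_equal(ranks$wins[order(ranks$animal_id)], as.integer(wins_hand),
               ignore_attr = TRUE)
  expect_equal(ranks$animal_id[ranks$rank == 1],
               names(which.max(wins_hand)))

  # all ties: tallies zero, every rank flagged as tied
  all_tie <- dplyr::mutate(trials, outcome = "tie")
  r2 <- tube_rank(all_tie)
  expect_true(all(r2$wins == 0))
  expect_true(all(r2$tied))

  missing_pair <- trials[!(trials$animal_a == "A" & trials$animal_b == "B"), ]
  expect_error(tube_rank(missing_pair),
               class = "playpref_validation_error")
})

test_that("availability correction filters and classifies as a hand tally", {
  ev <- make_events(
    rep("A", 10),
    c(rep("B", 4), rep("C", 3), rep("D", 2), "E"),
    n_partners_available = c(5L, 5L, 5L, 2L, 5L, 5L, 3L, 5L, 4L, 0L))
  focal <- tibble::tibble(group_id = 1L, day = 1L, initiator = "A",
                          recipient = c("B", "E"),
                          classification = c("strong_preferred", "avoided"))
  animals <- tibble::tibble(group_id = 1L, animal_id = LETTERS[1:6])
  out <- availability_adjusted_counts(ev, focal, animals)
  expect_equal(out$retained_fraction, 0.6)
  adj <- out$adjusted
  pick <- function(r) adj$count[adj$initiator == "A" & adj$recipient == r]
  expect_equal(pick("B"), 3L)  # hand tally of all-available events
  expect_equal(pick("C"), 2L)
  expect_equal(pick("D"), 1L)
  expect_equal(pick("E"), 0L)
  # A's adjusted counts (3,2,1,0,0): median 1
  expect_true(all(out$focal$median_count == 1))
  expect_true(all(out$focal$as_predicted))

  all_avail <- dplyr::mutate(ev, n_partners_available = 5L,
                             all_available = TRUE)
  out2 <- availability_adjusted_counts(all_avail, focal, animals)
  expect_equal(out2$retained_fraction, 1.0)
  expect_equal(sum(out2$adjusted$count), 10L)

  none <- dplyr::mutate(ev, n_partners_available = 2L,
                        all_available = FALSE)
  out3 <- availability_adjusted_counts(none, focal, animals)
  expect_equal(out3$retained_fraction, 0.0)
  expect_true(all(out3$adjusted$count == 0))
})

test_that("availability sign tests summarise predicted directions", {
  focal <- tibble::tibble(
    classification = rep(c("strong_preferred", "avoided"), c(31, 27)),
    as_predicted = c(rep(TRUE, 24), rep(FALSE, 7),
                     rep(TRUE, 26), FALSE))
  st <- availability_sign_tests(focal)
  expect_equal(st$p_two_sided[st$classification == "strong_preferred"],
               0.0033, tolerance = 1e-2)
  expect_lt(st$p_two_sided[st$classification == "avoided"], 1e-4)
})
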