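#' Classification thresholds for the partner-preference index
#'
#' @param strong Strong-preference threshold (index >= strong; default 2).
#' @param avoided Avoidance threshold (index <= avoided; default 0.25).
#' @param chance Chance expectation (default 1); indices above it but below
#'   `strong` are "preferred".
#' @return Named list, validated so avoided < chance < strong.
#' @export
preference_thresholds <- function(strong = 2, avoided = 0.25, chance = 1) {
  if (!(avoided < chance && chance < strong)) {
    abort("thresholds must satisfy avoided < chance < strong",
          class = "playpref_config_error")
  }
  list(strong = strong, avoided = avoided, chance = chance)
}

#' Partner-preference index for every directed dyad
#'
#' For initiator i and recipient j, the index is the observed attack count
#' divided by the equal-partner expectation:
#' \deqn{I_{ij} = \frac{B_{ij}}{B_i / (k - 1)}}
#' where \eqn{B_i} is i's total attacks and k the group size. An index of 1
#' is the chance expectation; values >= 2 indicate a strong preference and
#' values <= 0.25 indicate avoidance. For every initiator with positive
#' \eqn{B_i}, the mean index over its k-1 partners is exactly 1.
#'
#' @param counts A `play_matrix` of type `"count"` (k >= 2).
#' @param thresholds A [preference_thresholds()] list.
#' @return Tibble with one row per directed dyad: `group_id`, `day`,
#'   `initiator`, `recipient`, `b_ij`, `b_i`, `index`, `classification` in
#'   `strong_preferred` / `preferred` / `chance` / `avoided`, and `undefined`
#'   (TRUE when the initiator launched no attacks).
#' @export
thompson_index <- function(counts, thresholds = preference_thresholds()) {
  stopifnot(inherits(counts, "play_matrix"),
            attr(counts, "type") == "count")
  m <- unclass_matrix(counts)
  k <- nrow(m)
  if (k < 2L) abort("need at least 2 animals", class = "playpref_error")
  long <- tidy(counts)
  b_i <- rowSums(m)
  long |>
    dplyr::mutate(
      b_ij = .data$count,
      b_i = unname(b_i[.data$initiator]),
      undefined = .data$b_i == 0,
      index = ifelse(.data$undefined, NA_real_,
                     .data$b_ij / (.data$b_i / (k - 1))),
      classification = classify_index(.data$index, thresholds)
    ) |>
    dplyr::select(-"count")
}

#' Classify preference-index values against the standard thresholds
#'
#' @param index Numeric vector of preference indices (NA for undefined).
#' @param thresholds A [preference_thresholds()] list.
#' @return Character vector in `strong_preferred` / `preferred` / `chance` /
#'   `avoided`, with NA propagated.
#' @export
classify_index <- function(index, thresholds = preference_thresholds()) {
  dplyr::case_when(
    is.na(index) ~ NA_character_,
    index <= thresholds$avoided ~ "avoided",
    index >= thresholds$strong ~ "strong_preferred",
    index > thresholds$chance ~ "preferred",
    TRUE ~ "chance"
  )
}

#' Play symmetry of every unordered dyad
#'
#' Symmetry of a pair is one minus the absolute difference of the two
#' directed attack counts over their sum:
#' \deqn{S = 1 - \frac{|B_{ij} - B_{ji}|}{B_{ij} + B_{ji}}}
#' 1 means perfectly reciprocal play, 0 entirely one-sided. A dyad that
#' never played has undefined symmetry and is flagged.
#'
#' @param counts A `play_matrix` of type `"count"`.
#' @return Tibble with `group_id`, `day`, `animal_a`, `animal_b` (a < b),
#'   `symmetry`, `undefined`.
#' @export
play_symmetry <- function(counts) {
  stopifnot(inherits(counts, "play_matrix"))
  m <- unclass_matrix(counts)
  labels <- rownames(m)
  pairs <- utils::combn(labels, 2L)
  b_ab <- m[cbind(pairs[1, ], pairs[2, ])]
  b_ba <- m[cbind(pairs[2, ], pairs[1, ])]
  tot <- b_ab + b_ba
  tibble::tibble(
    group_id = attr(counts, "group_id"), day = attr(counts, "day"),
    animal_a = pairs[1, ], animal_b = pairs[2, ],
    symmetry = ifelse(tot == 0, NA_real_, 1 - abs(b_ab - b_ba) / tot),
    undefined = tot == 0
  )
}

#' Popularity: percentage of each rater's play directed at each target
#'
#' @param proportions A `play_matrix` of type `"proportion"`.
#' @return Tibble with `group_id`, `day`, `rater`, `target`, `pct`; for each
#'   rater with any play, percentages over its k-1 targets sum to 100.
#' @export
popularity <- function(proportions) {
  stopifnot(inherits(proportions, "play_matrix"),
            attr(proportions, "type") == "proportion")
  tidy(proportions) |>
    dplyr::transmute(.data$group_id, .data$day,
                     rater = .data$initiator, target = .data$recipient,
                     pct = .data$proportion * 100)
}

#' Per-animal z-scores of daily play initiation
#'
#' Standardises each animal's total attacks initiated against its group's
#' mean and SD on the same day, to show who plays above or below the group
#' norm.
#'
#' @param events Event tibble (one or more group-days).
#' @param animals Optional metadata so non-playing animals count as zeros.
#' @param z_cutoff Threshold flagged as significantly above/below the mean
#'   (default 1.96).
#' @return Tibble with `group_id`, `day`, `animal_id`, `attacks`, `z`,
#'   `direction` in `above` / `below` / `ns`, `undefined` (TRUE for zero-SD
#'   days, where z is not defined).
#' @export
daily_zscores <- function(events, animals = NULL, z_cutoff = 1.96) {
  ids <- if (is.null(animals)) {
    dplyr::distinct(events, .data$group_id, animal_id = .data$initiator)
  } else {
    dplyr::distinct(animals, .data$group_id, .data$animal_id)
  }
  totals <- events |>
    dplyr::count(.data$group_id, .data$day, animal_id = .data$initiator,
                 name = "attacks")
  full <- dplyr::distinct(events, .data$group_id, .data$day) |>
    dplyr::inner_join(ids, by = "group_id",
                      relationship = "many-to-many") |>
    dplyr::left_join(totals, by = c("group_id", "day", "animal_id")) |>
    dplyr::mutate(attacks = tidyr::replace_na(.data$attacks, 0L))
  full |>
    dplyr::group_by(.data$group_id, .data$day) |>
    dplyr::mutate(
      day_sd = sd(.data$attacks),
      undefined = is.na(.data$day_sd) | .data$day_sd == 0,
      z = ifelse(.data$undefined, NA_real_,
                 (.data$attacks - mean(.data$attacks)) / .data$day_sd),
      direction = dplyr::case_when(
        .data$undefined ~ NA_character_,
        .data$z >= z_cutoff ~ "above",
        .data$z <= -z_cutoff ~ "below",
        TRUE ~ "ns"
      )
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"day_sd") |>
    dplyr::arrange(.data$group_id, .data$day, .data$animal_id)
}

#' Rank each initiator's partners by the share of play directed at them
#'
#' Rank 1 is the favourite (largest proportion), rank k-1 the least
#' favourite; ties are broken by recipient label order and flagged.
#'
#' @param proportions A `play_matrix` of type `"proportion"`.
#' @return Tibble with `group_id`, `day`, `initiator`, `recipient`,
#'   `proportion`, `pref_rank`, `tied`.
#' @export
partner_ranks <- function(proportions) {
  stopifnot(inherits(proportions, "play_matrix"))
  tidy(proportions) |>
    dplyr::group_by(.data$initiator) |>
    dplyr::arrange(dplyr::desc(.data$proportion), .data$recipient,
                   .by_group = TRUE) |>
    dplyr::mutate(pref_rank = dplyr::row_number(),
                  tied = duplicated(.data$proportion) |
                    duplicated(.data$proportion, fromLast = TRUE)) |>
    dplyr::ungroup()
}

#' Day-to-day stability of favourite and least-favourite partners
#'
#' For each initiator and each adjacent pair of scored days, computes how far
#' today's favourite partner sat in yesterday's ranking (0 = same favourite,
#' k-2 = yesterday's least favourite) and symmetrically for the least
#' favourite.
#'
#' @param events Event tibble covering the days in `day_pairs`.
#' @param animals Optional metadata fixing the matrix axes.
#' @param day_pairs List of length-2 day vectors (default adjacent scored
#'   days `(1,3)`, `(3,5)`, `(5,8)`).
#' @return Tibble with `group_id`, `animal_id`, `day_from`, `day_to`,
#'   `favorite_change`, `least_favorite_change` (each in `0..(k-2)`),
#'   `tied` (rank ties on either day).
#' @export
rank_changes <- function(events, animals = NULL,
                         day_pairs = list(c(1L, 3L), c(3L, 5L), c(5L, 8L))) {
  mats <- count_matrices(events, animals)
  ranks <- mats |>
    dplyr::mutate(ranks = purrr::map(.data$counts,
                                     ~ partner_ranks(to_proportions(.x)))) |>
    dplyr::pull(.data$ranks) |>
    dplyr::bind_rows()
  purrr::map_dfr(day_pairs, function(dp) {
    prev <- dplyr::filter(ranks, .data$day == dp[1])
    cur <- dplyr::filter(ranks, .data$day == dp[2])
    if (nrow(prev) == 0 || nrow(cur) == 0) {
      abort(sprintf("missing day %s or %s in events", dp[1], dp[2]),
            class = "playpref_validation_error")
    }
    k1 <- max(cur$pref_rank)  # k - 1 partners
    fav <- dplyr::filter(cur, .data$pref_rank == 1L)
    least <- dplyr::filter(cur, .data$pref_rank == k1)
    prev_rank <- function(tbl) {
      dplyr::left_join(
        tbl,
        dplyr::select(prev, "group_id", "initiator", "recipient",
                      prev_rank = "pref_rank", prev_tied = "tied"),
        by = c("group_id", "initiator", "recipient"))
    }
    fav <- prev_rank(fav)
    least <- prev_rank(least)
    dplyr::full_join(
      dplyr::transmute(fav, .data$group_id, animal_id = .data$initiator,
                       favorite_change = .data$prev_rank - 1L,
                       tied_f = .data$tied | .data$prev_tied),
      dplyr::transmute(least, .data$group_id, animal_id = .data$initiator,
                       least_favorite_change = k1 - .data$prev_rank,
                       tied_l = .data$tied | .data$prev_tied),
      by = c("group_id", "animal_id")) |>
      dplyr::transmute(.data$group_id, .data$animal_id,
                       day_from = dp[1], day_to = dp[2],
                       .data$favorite_change, .data$least_favorite_change,
                       tied = .data$tied_f | .data$tied_l)
  })
}

#' Dominance tallies and ranks from tube-test trials
#'
#' Each win scores one point (ties score nothing); animals are ranked within
#' group by descending tally, ties broken by label order and flagged.
#'
#' @param trials Tibble from [simulate_tube_test()] or
#'   a CSV with the same columns (`group_id`, `animal_a`, `animal_b`,
#'   `trial`, `outcome`).
#' @return Tibble with `group_id`, `animal_id`, `wins`, `rank`
#'   (1 = most dominant), `tied`.
#' @export
tube_rank <- function(trials) {
  pairs <- dplyr::distinct(trials, .data$group_id, .data$animal_a,
                           .data$animal_b)
  ids <- dplyr::bind_rows(
    dplyr::transmute(pairs, .data$group_id, animal_id = .data$animal_a),
    dplyr::transmute(pairs, .data$group_id, animal_id = .data$animal_b)
  ) |> dplyr::distinct()
  n_ids <- dplyr::count(ids, .data$group_id, name = "k")
  n_pairs <- dplyr::count(pairs, .data$group_id, name = "n_pairs") |>
    dplyr::left_join(n_ids, by = "group_id")
  if (any(n_pairs$n_pairs != choose(n_pairs$k, 2))) {
    abort("tube-test trials missing for some pair(s)",
          class = "playpref_validation_error")
  }
  wins <- dplyr::bind_rows(
    trials |> dplyr::filter(.data$outcome == "win_a") |>
      dplyr::transmute(.data$group_id, animal_id = .data$animal_a),
    trials |> dplyr::filter(.data$outcome == "win_b") |>
      dplyr::transmute(.data$group_id, animal_id = .data$animal_b)
  ) |> dplyr::count(.data$group_id, .data$animal_id, name = "wins")
  ids |>
    dplyr::left_join(wins, by = c("group_id", "animal_id")) |>
    dplyr::mutate(wins = tidyr::replace_na(.data$wins, 0L)) |>
    dplyr::group_by(.data$group_id) |>
    dplyr::arrange(dplyr::desc(.data$wins), .data$animal_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  tied = duplicated(.data$wins) |
                    duplicated(.data$wins, fromLast = TRUE)) |>
    dplyr::ungroup()
}

#' Partner-availability correction
#'
#' Restricts the event log to attacks launched while all k-1 potential
#' partners were free, retallies the directed counts, and checks for each
#' focal (classified) dyad whether the adjusted count still falls on the
#' predicted side of the initiator's median adjusted count across its
#' partners: above for preferred dyads, below for avoided ones. Ties at the
#' median count as failures and are flagged.
#'
#' @param events Event tibble carrying `all_available`.
#' @param focal_dyads Tibble of classified dyads with `group_id`, `day`,
#'   `initiator`, `recipient` and `classification` (`strong_preferred` or
#'   `avoided`), e.g. filtered from [thompson_index()] output.
#' @param animals Optional metadata fixing matrix axes.
#' @return List with `adjusted` (long tibble of adjusted counts per directed
#'   dyad), `retained_fraction` (share of original attacks kept), and
#'   `focal` (per focal dyad: adjusted count, initiator median,
#'   `as_predicted`, `tie_at_median`).
#' @export
availability_adjusted_counts <- function(events, focal_dyads,
                                         animals = NULL) {
  if (!"all_available" %in% names(events)) {
    abort("events must carry the all_available flag",
          class = "playpref_validation_error")
  }
  kept <- dplyr::filter(events, .data$all_available)
  retained <- if (nrow(events) == 0) NA_real_ else nrow(kept) / nrow(events)
  combos <- dplyr::distinct(events, .data$group_id, .data$day)
  adjusted <- purrr::pmap_dfr(combos, function(group_id, day) {
    labels <- if (is.null(animals)) {
      ev <- dplyr::filter(events, .data$group_id == !!group_id,
                          .data$day == !!day)
      sort(unique(c(ev$initiator, ev$recipient)))
    } else sort(animals$animal_id[animals$group_id == group_id])
    tidy(build_count_matrix(kept, group_id, day, labels))
  })
  medians <- adjusted |>
    dplyr::group_by(.data$group_id, .data$day, .data$initiator) |>
    dplyr::summarise(median_count = median(.data$count), .groups = "drop")
  focal <- focal_dyads |>
    dplyr::left_join(adjusted,
                     by = c("group_id", "day", "initiator", "recipient")) |>
    dplyr::left_join(medians, by = c("group_id", "day", "initiator")) |>
    dplyr::mutate(
      count = tidyr::replace_na(.data$count, 0L),
      tie_at_median = .data$count == .data$median_count,
      as_predicted = dplyr::case_when(
        .data$classification == "strong_preferred" ~
          .data$count > .data$median_count,
        .data$classification == "avoided" ~
          .data$count < .data$median_count,
        TRUE ~ NA
      )
    ) |>
    dplyr::rename(adjusted_count = "count")
  list(adjusted = adjusted, retained_fraction = retained, focal = focal)
}

#' Sign tests on the availability-corrected focal dyads
#'
#' @param focal The `focal` tibble from [availability_adjusted_counts()].
#' @return Tibble with one row per classification: successes (dyads on the
#'   predicted side of the median), trials, and the exact two-sided binomial
#'   p at success probability 1/2.
#' @export
availability_sign_tests <- function(focal) {
  focal |>
    dplyr::filter(!is.na(.data$as_predicted)) |>
    dplyr::group_by(.data$classification) |>
    dplyr::summarise(n_success = sum(.data$as_predicted),
                     n_trials = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(p_two_sided = purrr::map2_dbl(
      .data$n_success, .data$n_trials,
      ~ sign_test_exact(.x, .y)$p_two_sided))
}
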