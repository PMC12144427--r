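#' Simulation configuration for a synthetic play study
#'
#' Assembles the parameters of the emulated study design: groups of six
#' familiar juvenile males observed in 20-min sessions on days 1, 3, 5 and 8
#' of the peak play period. Each animal carries a latent per-session attack
#' rate and a vector of partner-choice weights; recipients of each attack are
#' multinomial draws from those weights, and the recipient's defensive
#' response is drawn from a tactic profile that differs between strongly
#' preferred and other partners.
#'
#' @param n_groups Number of groups (default 8).
#' @param k Animals per group (default 6).
#' @param days Scored day labels (default `c(1, 3, 5, 8)`).
#' @param session_s Session length in seconds (default 1200).
#' @param rate_range Per-animal attacks-per-session range; each animal's
#'   latent rate is uniform on this interval and its per-day count is Poisson
#'   around it (default `c(20, 60)`).
#' @param concentration Dirichlet concentration for partner weights: each
#'   animal's weight vector over its k-1 partners is Dirichlet(concentration)
#'   symmetric. Small values plant strong idiosyncratic preferences; large
#'   values approach uniform partner choice. Default 0.8 (strong-preference
#'   regime). Use `Inf` for exactly uniform weights.
#' @param planted_dyads Optional tibble with columns `group_id`, `initiator`,
#'   `recipient`, `weight` forcing the initiator's weight toward that partner
#'   (remaining weights rescaled). Planted weights are held fixed across days.
#' @param tactic_preferred,tactic_other Named probability vectors over
#'   `no_response`, `evasion`, `pin`, `box` for attacks on strongly preferred
#'   vs other partners, plus `role_reversal`, the marginal role-reversal
#'   probability per attack (converted internally to a probability
#'   conditional on the recipient responding). Defaults follow the observed
#'   tactic percentages for preferred vs non-preferred partners.
#' @param preferred_weight_threshold Weight above which a recipient is
#'   treated as a "preferred-class" partner for tactic sampling; 0.4 equals
#'   twice the uniform share for k = 6, i.e. the strong-preference index
#'   threshold in expectation.
#' @param drift_sd Day-to-day instability of partner weights: each new day's
#'   weight vector is the previous day's perturbed by multiplicative
#'   log-normal noise, `w' proportional to w * exp(drift_sd * N(0, 1))`,
#'   renormalised. 0 freezes preferences across days; the default 2 yields a
#'   median favourite-partner rank change of 1-2 between adjacent scored
#'   days, so favourites typically move by a rank or two day to day.
#' @param all_available_frac Fraction of attacks launched with all k-1
#'   partners free (default 0.6); of the remainder, `two_plus_frac` have at
#'   least two partners free (default 0.97, making the overall at-least-two
#'   marginal about 0.988).
#' @param two_plus_frac See `all_available_frac`.
#' @param proximity_mean,proximity_sd Dyadic non-play proximity seconds,
#'   truncated normal on `[0, session_s]` (defaults 287 and 60).
#' @param weight_mean,weight_sd Body weight in grams (defaults 110 and 10,
#'   juvenile males at P30-P40).
#' @param tie_prob Tube-test tie probability per trial (default 0.05).
#' @param seed Default RNG seed used by [simulate_study()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_groups = 8L, k = 6L, days = c(1L, 3L, 5L, 8L),
                       session_s = 1200,
                       rate_range = c(20, 60),
                       concentration = 0.8,
                       planted_dyads = NULL,
                       tactic_preferred = c(no_response = 0.2958,
                                            evasion = 0.3161,
                                            pin = 0.3053,
                                            box = 0.0828,
                                            role_reversal = 0.4728),
                       tactic_other = c(no_response = 0.1481,
                                        evasion = 0.2963,
                                        pin = 0.1111,
                                        box = 0.4445,
                                        role_reversal = 0.0238),
                       preferred_weight_threshold = 0.4,
                       drift_sd = 2,
                       all_available_frac = 0.6,
                       two_plus_frac = 0.97,
                       proximity_mean = 287, proximity_sd = 60,
                       weight_mean = 110, weight_sd = 10,
                       tie_prob = 0.05,
                       seed = 1L) {
  cfg <- list(n_groups = as.integer(n_groups), k = as.integer(k),
              days = as.integer(days), session_s = session_s,
              rate_range = rate_range, concentration = concentration,
              planted_dyads = planted_dyads,
              tactic_preferred = tactic_preferred,
              tactic_other = tactic_other,
              preferred_weight_threshold = preferred_weight_threshold,
              drift_sd = drift_sd,
              all_available_frac = all_available_frac,
              two_plus_frac = two_plus_frac,
              proximity_mean = proximity_mean, proximity_sd = proximity_sd,
              weight_mean = weight_mean, weight_sd = weight_sd,
              tie_prob = tie_prob, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_groups < 1L || cfg$k < 2L || length(cfg$days) < 1L) {
    abort("impossible config: need >= 1 group, >= 2 animals, >= 1 day",
          class = "playpref_config_error")
  }
  if (any(cfg$rate_range <= 0)) {
    abort("impossible config: attack rates must be positive",
          class = "playpref_config_error")
  }
  for (nm in c("tactic_preferred", "tactic_other")) {
    p <- cfg[[nm]][RESPONSE_LEVELS]
    if (anyNA(p) || abs(sum(p) - 1) > 1e-6) {
      abort(sprintf("%s response probabilities must sum to 1", nm),
            class = "playpref_config_error")
    }
  }
  invisible(cfg)
}

# Symmetric Dirichlet draw via gammas; conc = Inf gives exact uniform.
rdirichlet1 <- function(n_cat, conc) {
  if (!is.finite(conc)) return(rep(1 / n_cat, n_cat))
  g <- rgamma(n_cat, shape = conc, rate = 1)
  if (sum(g) == 0) g <- rep(1, n_cat)
  g / sum(g)
}

# Partner-weight vectors for one group on day 1, with planting applied.
initial_weights <- function(labels, conc, planted) {
  k <- length(labels)
  w <- lapply(labels, function(a) {
    partners <- setdiff(labels, a)
    v <- setNames(rdirichlet1(k - 1L, conc), partners)
    plant_weights(v, a, planted)
  })
  setNames(w, labels)
}

plant_weights <- function(v, animal, planted) {
  if (is.null(planted)) return(v)
  mine <- planted[planted$initiator == animal, , drop = FALSE]
  if (nrow(mine) == 0) return(v)
  free <- setdiff(names(v), mine$recipient)
  rest <- 1 - sum(mine$weight)
  if (rest < 0) abort("planted weights for one initiator exceed 1",
                      class = "playpref_config_error")
  tot_free <- sum(v[free])
  v[free] <- if (tot_free > 0) v[free] / tot_free * rest else rest / length(free)
  v[mine$recipient] <- mine$weight
  v
}

# Day weights: multiplicative log-normal jitter around the animal's fixed
# base preference vector, renormalised; planted weights are re-imposed.
# Jittering the base (not the previous day) keeps the perturbations from
# compounding into one-hot vectors, so each animal keeps a stable underlying
# preference profile while its day-to-day favourite moves around it.
drift_weights <- function(w_base, drift_sd, animal, planted) {
  v <- w_base * exp(drift_sd * rnorm(length(w_base)))
  if (sum(v) == 0) v <- rep(1, length(v))
  v <- setNames(v / sum(v), names(w_base))
  plant_weights(v, animal, planted)
}

# n_partners_available for one attack: all free with prob p_all, otherwise
# mostly 2..4 free so that the overall at-least-two marginal is realistic.
draw_availability <- function(n, k, p_all, p_two_plus) {
  all_free <- runif(n) < p_all
  out <- integer(n)
  out[all_free] <- k - 1L
  n_rest <- sum(!all_free)
  if (n_rest > 0) {
    two_plus <- runif(n_rest) < p_two_plus
    lo <- sample(0:1, n_rest, replace = TRUE)
    hi <- sample(2:(k - 2L), n_rest, replace = TRUE)
    out[!all_free] <- ifelse(two_plus, hi, lo)
  }
  out
}

#' Simulate a full synthetic play study
#'
#' Generates event logs, animal metadata, dyadic proximity records and
#' tube-test trials for `n_groups` groups of `k` animals over the scored
#' days, with planted partner-choice, tactic and role-reversal structure.
#' Identical seeds give identical outputs.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; defaults to `config$seed`.
#' @return A list with tibbles `events`, `animals`, `proximity` and
#'   `tube_trials`, plus the `config` and `seed` used.
#' @examples
#' study <- simulate_study(sim_config(n_groups = 2), seed = 7)
#' nrow(study$events)
#' @export
simulate_study <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  labels <- LETTERS[seq_len(config$k)]
  groups <- seq_len(config$n_groups)

  animals <- purrr::map_dfr(groups, function(g) {
    tibble::tibble(
      group_id = g, animal_id = labels,
      weight_g = round(rnorm(config$k, config$weight_mean, config$weight_sd), 1),
      latent_strength = rgamma(config$k, shape = 4, rate = 1)
    )
  })

  tube_trials <- simulate_tube_test(animals, animals$latent_strength,
                                    tie_prob = config$tie_prob)
  tallies <- tube_rank(tube_trials)
  animals <- dplyr::left_join(animals,
                              dplyr::rename(tallies, tube_wins = "wins"),
                              by = c("group_id", "animal_id")) |>
    dplyr::select(-"latent_strength")

  rates <- runif(config$n_groups * config$k,
                 config$rate_range[1], config$rate_range[2])
  rate_of <- setNames(rates, paste(rep(groups, each = config$k), labels))

  events_list <- list()
  for (g in groups) {
    planted <- if (is.null(config$planted_dyads)) NULL else
      config$planted_dyads[config$planted_dyads$group_id == g, , drop = FALSE]
    w_base <- initial_weights(labels, config$concentration, planted)
    for (d in config$days) {
      w <- if (d == config$days[1]) w_base else {
        setNames(lapply(labels, function(a) {
          drift_weights(w_base[[a]], config$drift_sd, a, planted)
        }), labels)
      }
      for (a in labels) {
        n_att <- rpois(1L, rate_of[[paste(g, a)]])
        if (n_att == 0L) next
        partners <- names(w[[a]])
        recip <- sample(partners, n_att, replace = TRUE, prob = w[[a]])
        pref_class <- w[[a]][recip] >= config$preferred_weight_threshold
        resp <- character(n_att)
        rr <- logical(n_att)
        for (cls in c(TRUE, FALSE)) {
          idx <- which(pref_class == cls)
          if (length(idx) == 0) next
          prof <- if (cls) config$tactic_preferred else config$tactic_other
          resp[idx] <- sample(RESPONSE_LEVELS, length(idx), replace = TRUE,
                              prob = prof[RESPONSE_LEVELS])
          # configured role_reversal is the per-attack marginal; convert to
          # the probability conditional on the recipient responding
          p_resp <- 1 - prof[["no_response"]]
          p_rr <- if (p_resp > 0) min(1, prof[["role_reversal"]] / p_resp) else 0
          can_rr <- idx[resp[idx] != "no_response"]
          rr[can_rr] <- runif(length(can_rr)) < p_rr
        }
        events_list[[length(events_list) + 1L]] <- tibble::tibble(
          group_id = g, day = d,
          time_s = round(sort(runif(n_att, 0, config$session_s)), 1),
          initiator = a, recipient = recip,
          response = resp, role_reversal = rr,
          n_partners_available = draw_availability(
            n_att, config$k, config$all_available_frac, config$two_plus_frac)
        )
      }
    }
  }
  events <- dplyr::bind_rows(events_list) |>
    dplyr::arrange(.data$group_id, .data$day, .data$time_s, .data$initiator) |>
    dplyr::mutate(all_available = .data$n_partners_available == config$k - 1L)

  dyads <- utils::combn(labels, 2L)
  proximity <- purrr::map_dfr(groups, function(g) {
    purrr::map_dfr(config$days, function(d) {
      tibble::tibble(
        group_id = g, day = d,
        animal_a = dyads[1, ], animal_b = dyads[2, ],
        proximity_s = round(pmin(pmax(
          rnorm(ncol(dyads), config$proximity_mean, config$proximity_sd),
          0), config$session_s), 1)
      )
    })
  })

  list(events = events, animals = animals, proximity = proximity,
       tube_trials = tube_trials, config = config, seed = seed)
}

#' Simulate round-robin tube-test trials
#'
#' Every unordered pair in each group meets five times in the tube; the
#' probability that a wins is `s_a / (s_a + s_b)` on its latent strength,
#' with a configurable tie probability (both rats stay in for 60 s).
#'
#' @param animals Tibble with `group_id` and `animal_id`.
#' @param latent_strengths Positive strengths aligned with `animals` rows.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @param tie_prob Per-trial tie probability (default 0.05).
#' @param n_trials Trials per pair (default 5).
#' @return Tibble with `group_id`, `animal_a`, `animal_b`, `trial`,
#'   `outcome` in `win_a` / `win_b` / `tie`.
#' @export
simulate_tube_test <- function(animals, latent_strengths, seed = NULL,
                               tie_prob = 0.05, n_trials = 5L) {
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    set.seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  strength <- setNames(latent_strengths,
                       paste(animals$group_id, animals$animal_id))
  purrr::map_dfr(unique(animals$group_id), function(g) {
    ids <- sort(animals$animal_id[animals$group_id == g])
    pairs <- utils::combn(ids, 2L)
    purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
      a <- pairs[1, i]; b <- pairs[2, i]
      sa <- strength[[paste(g, a)]]; sb <- strength[[paste(g, b)]]
      u <- runif(n_trials)
      tie <- u < tie_prob
      win_a <- runif(n_trials) < sa / (sa + sb)
      tibble::tibble(group_id = g, animal_a = a, animal_b = b,
                     trial = seq_len(n_trials),
                     outcome = ifelse(tie, "tie",
                                      ifelse(win_a, "win_a", "win_b")))
    })
  })
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
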