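#' Configuration for a full pipeline run
#'
#' @param simulate A [sim_config()] to generate the study in silico, or
#'   `NULL` to read CSV inputs.
#' @param events,animals,proximity,tube_trials Input CSV paths (used when
#'   `simulate` is `NULL`).
#' @param alpha Exclusion level of the randomness screen (default 0.05).
#' @param n_perm Permutations for the screen and modularity test
#'   (default 9999).
#' @param thresholds [preference_thresholds()].
#' @param z_cutoff Daily z-score significance cutoff (default 1.96).
#' @param seed Master seed for all randomised stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = sim_config(), events = NULL,
                       animals = NULL, proximity = NULL, tube_trials = NULL,
                       alpha = 0.05, n_perm = 9999L,
                       thresholds = preference_thresholds(),
                       z_cutoff = 1.96, seed = 1L) {
  if (is.null(simulate) &&
      (is.null(events) || is.null(animals) || is.null(proximity))) {
    abort("need either a simulate block or events/animals/proximity paths",
          class = "playpref_config_error")
  }
  structure(list(simulate = simulate, events = events, animals = animals,
                 proximity = proximity, tube_trials = tube_trials,
                 alpha = alpha, n_perm = as.integer(n_perm),
                 thresholds = thresholds, z_cutoff = z_cutoff,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [run_config()]: top-level keys `alpha`, `n_perm`,
#' `z_cutoff`, `seed`, a `thresholds` block (`strong`, `avoided`, `chance`),
#' and either a `simulate` block of [sim_config()] fields or an `inputs`
#' block with `events`/`animals`/`proximity`/`tube_trials` paths.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$simulate)) do.call(sim_config, y$simulate) else NULL
  thr <- if (!is.null(y$thresholds)) do.call(preference_thresholds,
                                             y$thresholds)
         else preference_thresholds()
  run_config(simulate = sim,
             events = y$inputs$events, animals = y$inputs$animals,
             proximity = y$inputs$proximity,
             tube_trials = y$inputs$tube_trials,
             alpha = y$alpha %||% 0.05, n_perm = y$n_perm %||% 9999L,
             thresholds = thr, z_cutoff = y$z_cutoff %||% 1.96,
             seed = y$seed %||% 1L)
}

#' Run the full partner-preference analysis
#'
#' Executes every stage in sequence: (1) simulate or load the study;
#' (2) attack-count matrices per group-day; (3) the permutation screen
#' against equal play, excluding screened group-days from all preference
#' analyses; (4) preference indices and classifications; (5) play symmetry;
#' (6) preference networks, modularity and centrality; (7) day-to-day
#' stability; (8) popularity, daily z-scores and the repeated-measures
#' ANOVAs; (9) the two preference GLMMs (play style/quality; dyadic
#' asymmetries); (10) the partner-availability correction with exact sign
#' tests. Reruns with the same config and seed are identical.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, every stage writes a
#'   long-format CSV (plus GraphML networks and a provenance JSON).
#' @param quiet Suppress per-stage log messages.
#' @return A named list of stage results (tibbles and fitted objects).
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  res <- list(config = config)

  if (!is.null(config$simulate)) {
    study <- simulate_study(config$simulate, seed = config$seed)
    say("simulate: %d events, %d groups", nrow(study$events),
        config$simulate$n_groups)
  } else {
    animals <- read_animals(config$animals)
    study <- list(
      events = read_events(config$events),
      animals = animals,
      proximity = read_proximity(config$proximity),
      tube_trials = if (!is.null(config$tube_trials))
        readr::read_csv(config$tube_trials, show_col_types = FALSE)
      else NULL)
    study$events <- validate_events(study$events, animals = study$animals)
    say("load: %d events", nrow(study$events))
  }
  res$events <- study$events
  res$animals <- study$animals
  res$proximity <- study$proximity
  res$tube_trials <- study$tube_trials

  if (!is.null(study$tube_trials) &&
      !"dominance_rank" %in% names(res$animals)) {
    res$animals <- dplyr::left_join(
      res$animals,
      dplyr::select(tube_rank(study$tube_trials), "group_id", "animal_id",
                    tube_wins = "wins", dominance_rank = "rank"),
      by = c("group_id", "animal_id"))
  }
  if (!"dominance_rank" %in% names(res$animals) &&
      "tube_wins" %in% names(res$animals)) {
    res$animals <- add_dominance_ranks(res$animals)
  }

  mats <- count_matrices(res$events, res$animals)
  res$count_matrices <- mats
  res$matrices_long <- purrr::map_dfr(mats$counts, function(m) {
    dplyr::left_join(tidy(m), tidy(to_proportions(m)),
                     by = c("group_id", "day", "initiator", "recipient"))
  })
  say("matrices: %d group-days", nrow(mats))

  res$mantel <- mantel_screen_all(res$events, res$animals,
                                  n_perm = config$n_perm,
                                  alpha = config$alpha, seed = config$seed)
  n_excl <- sum(res$mantel$excluded)
  say("screen: %d of %d group-days excluded as random play", n_excl,
      nrow(res$mantel))

  kept <- dplyr::filter(res$mantel, !.data$excluded)
  kept_mats <- dplyr::semi_join(mats, kept, by = c("group_id", "day"))
  res$preference_indices <- purrr::map_dfr(
    kept_mats$counts, thompson_index, thresholds = config$thresholds)
  n_strong <- sum(res$preference_indices$classification == "strong_preferred",
                  na.rm = TRUE)
  n_avoid <- sum(res$preference_indices$classification == "avoided",
                 na.rm = TRUE)
  say("preferences: %d strong, %d avoided dyad-days", n_strong, n_avoid)

  res$symmetry <- purrr::map_dfr(mats$counts, play_symmetry)

  res$networks <- kept_mats |>
    dplyr::mutate(
      directed = purrr::map(.data$counts, build_directed_network),
      preference = purrr::map2(.data$group_id, .data$day, function(g, d) {
        idx <- dplyr::filter(res$preference_indices,
                             .data$group_id == g, .data$day == d)
        preference_network(
          idx, labels = sort(res$animals$animal_id[res$animals$group_id == g]))
      }),
      modularity = purrr::map(.data$counts, modularity_significance,
                              n_perm = min(config$n_perm, 999L),
                              seed = config$seed),
      centrality = purrr::map(.data$counts,
                              ~ eigenvector_centrality(
                                  build_undirected_network(.x)))) |>
    dplyr::select(-"counts", -"n_events")
  res$modularity <- res$networks |>
    dplyr::mutate(Q = purrr::map_dbl(.data$modularity, "Q"),
                  p = purrr::map_dbl(.data$modularity, "p")) |>
    dplyr::select("group_id", "day", "Q", "p")
  say("networks: modularity Q in [%.2f, %.2f]", min(res$modularity$Q),
      max(res$modularity$Q))

  res$rank_changes <- rank_changes(res$events, res$animals)
  res$zscores <- daily_zscores(res$events, res$animals,
                               z_cutoff = config$z_cutoff)

  res$popularity <- purrr::map_dfr(mats$counts,
                                   ~ popularity(to_proportions(.x)))
  res$popularity_anova <- res$popularity |>
    dplyr::group_by(.data$group_id) |>
    dplyr::group_map(~ tibble::tibble(group_id = .y$group_id,
                                      fit = list(popularity_anova(.x)))) |>
    dplyr::bind_rows() |>
    dplyr::mutate(tidy = purrr::map(.data$fit, tidy)) |>
    tidyr::unnest("tidy")
  res$group_totals_anova <- tryCatch(
    group_totals_anova(res$events),
    playpref_validation_error = function(e) {
      warn(paste0("group-totals ANOVA skipped: ", conditionMessage(e)))
      NULL
    })
  say("popularity: ANOVA dfs (%d, %d) per group",
      res$popularity_anova$df1[1], res$popularity_anova$df2[1])

  res$feature_table <- build_feature_table(
    res$events, res$preference_indices, res$symmetry, res$proximity,
    res$animals, screen = res$mantel)
  say("model rows: %d (%d preferred + %d not preferred)",
      nrow(res$feature_table), sum(res$feature_table$outcome == 1),
      sum(res$feature_table$outcome == 0))
  res$glmm_style <- try_fit(res$feature_table,
                            c("partner_play_frequency", "pct_no_response",
                              "pct_evasion", "pct_pin", "pct_role_reversal"),
                            random = "initiator_id")
  res$glmm_dyadic <- try_fit(res$feature_table,
                             c("symmetry", "proximity_s", "weight_diff_g",
                               "dominance_diff"),
                             random = c("initiator_id", "partner_id"))

  focal <- dplyr::filter(res$preference_indices,
                         .data$classification %in%
                           c("strong_preferred", "avoided"))
  res$availability <- availability_adjusted_counts(res$events, focal,
                                                   res$animals)
  res$sign_tests <- availability_sign_tests(res$availability$focal)
  say("availability: %.1f%% of attacks retained",
      100 * res$availability$retained_fraction)

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

try_fit <- function(rows, predictors, random) {
  tryCatch(fit_binary_glmm(rows, predictors, random = random),
           error = function(e) {
             warn(paste0("GLMM stage skipped: ", conditionMessage(e)))
             NULL
           })
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      readr::write_csv(x, file.path(out_dir, name))
    }
  }
  w(dplyr::select(res$events, -dplyr::any_of(".line")), "events.csv")
  w(res$animals, "animals.csv")
  w(res$proximity, "proximity.csv")
  w(res$tube_trials, "tube_trials.csv")
  w(res$matrices_long, "matrices.csv")
  w(res$mantel, "mantel_results.csv")
  w(res$preference_indices, "preference_indices.csv")
  w(res$symmetry, "symmetry.csv")
  w(res$popularity, "popularity.csv")
  w(res$zscores, "zscores.csv")
  w(res$rank_changes, "rank_changes.csv")
  w(res$modularity, "modularity_results.csv")
  w(dplyr::select(res$popularity_anova, -"fit"), "anova_results.csv")
  w(res$feature_table, "model_rows.csv")
  if (!is.null(res$glmm_style)) w(tidy(res$glmm_style), "glmm_model1.csv")
  if (!is.null(res$glmm_dyadic)) w(tidy(res$glmm_dyadic), "glmm_model2.csv")
  w(res$availability$focal, "availability.csv")
  w(res$sign_tests, "sign_tests.csv")
  for (i in seq_len(nrow(res$networks))) {
    g <- res$networks$group_id[i]; d <- res$networks$day[i]
    write_network_graphml(
      res$networks$directed[[i]],
      file.path(out_dir, sprintf("network_g%s_d%s.graphml", g, d)))
  }
  cfg <- res$config
  provenance <- list(
    seed = cfg$seed, alpha = cfg$alpha, n_perm = cfg$n_perm,
    thresholds = cfg$thresholds, z_cutoff = cfg$z_cutoff,
    simulated = !is.null(cfg$simulate),
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("playpref")))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
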