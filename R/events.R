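#' Read a play-event log
#'
#' Reads a comma-delimited log of playful nape attacks, one row per attack.
#' Required columns: `group_id`, `day`, `time_s`, `initiator`, `recipient`,
#' `response`, `role_reversal`, `n_partners_available`. The derived column
#' `all_available` (`n_partners_available == k - 1`) is added if absent.
#'
#' @param path Path to a CSV file with a header row.
#' @param k Group size used to derive `all_available` (default 6).
#' @param allow_any_day If `FALSE` (default), only the scored days
#'   1, 3, 5 and 8 are accepted; other day labels are a validation error.
#' @return A tibble of validated attack events, one row per attack, carrying
#'   the source line number in column `.line` for error reporting.
#' @seealso [write_events()], [validate_events()]
#' @export
read_events <- function(path, k = 6L, allow_any_day = FALSE) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           group_id = readr::col_integer(),
                           day = readr::col_integer(),
                           time_s = readr::col_double(),
                           initiator = readr::col_character(),
                           recipient = readr::col_character(),
                           response = readr::col_character(),
                           role_reversal = readr::col_logical(),
                           n_partners_available = readr::col_integer()
                         ))
  missing_cols <- setdiff(c("group_id", "day", "time_s", "initiator",
                            "recipient", "response", "role_reversal",
                            "n_partners_available"), names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("event log is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "playpref_validation_error")
  }
  events <- dplyr::mutate(raw, .line = dplyr::row_number() + 1L)
  validate_events(events, k = k, allow_any_day = allow_any_day)
}

#' Write a play-event log
#'
#' @param events A tibble of attack events as returned by [read_events()] or
#'   [simulate_study()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- dplyr::select(events, "group_id", "day", "time_s", "initiator",
                       "recipient", "response", "role_reversal",
                       "n_partners_available")
  readr::write_csv(out, path)
  invisible(path)
}

#' Validate a table of attack events
#'
#' Checks the structural invariants of an event log: initiator differs from
#' recipient, times lie within the session, responses are known codes, a role
#' reversal implies the recipient responded (a "no response" attack cannot be
#' counterattacked), and availability counts lie in `0..(k-1)`.
#'
#' @param events Event tibble; a `.line` column, if present, is used in error
#'   messages, otherwise row numbers are reported.
#' @param k Group size.
#' @param session_s Session length in seconds (default 1200 = 20 min).
#' @param allow_any_day Accept day labels outside the scored set 1/3/5/8.
#' @param animals Optional animal metadata tibble; if given, initiator and
#'   recipient labels are checked against it per group.
#' @return The validated events, with `all_available` added, invisibly
#'   chainable.
#' @export
validate_events <- function(events, k = 6L, session_s = 1200,
                            allow_any_day = FALSE, animals = NULL) {
  line <- if (".line" %in% names(events)) events$.line else seq_len(nrow(events))
  fail <- function(bad, what) {
    if (any(bad)) {
      abort(sprintf("invalid event log: %s (line %s)", what,
                    paste(head(line[bad], 5L), collapse = ", ")),
            class = "playpref_validation_error")
    }
  }
  fail(events$initiator == events$recipient, "initiator equals recipient")
  fail(!events$response %in% RESPONSE_LEVELS,
       paste0("unknown response code; expected one of ",
              paste(RESPONSE_LEVELS, collapse = "/")))
  fail(events$role_reversal & events$response == "no_response",
       "role_reversal set on a no_response attack")
  fail(events$time_s < 0 | events$time_s > session_s,
       "time_s outside the session")
  fail(events$n_partners_available < 0L | events$n_partners_available > k - 1L,
       "n_partners_available outside 0..(k-1)")
  if (!allow_any_day) {
    fail(!events$day %in% SCORED_DAYS,
         "day outside the scored set {1,3,5,8}; use allow_any_day = TRUE")
  }
  if (!is.null(animals)) {
    known <- dplyr::distinct(animals, .data$group_id, .data$animal_id)
    ok_i <- paste(events$group_id, events$initiator) %in%
      paste(known$group_id, known$animal_id)
    ok_r <- paste(events$group_id, events$recipient) %in%
      paste(known$group_id, known$animal_id)
    fail(!ok_i | !ok_r, "unknown animal_id for its group")
  }
  dplyr::mutate(tibble::as_tibble(events),
                all_available = .data$n_partners_available == k - 1L)
}

#' Read animal metadata
#'
#' @param path CSV with columns `group_id`, `animal_id`, `weight_g` and
#'   (optionally) `tube_wins`.
#' @return Tibble of animals; if `tube_wins` is present, `dominance_rank`
#'   (1 = most dominant) is added per group, ties broken by `animal_id`
#'   lexicographic order and flagged in `rank_tied`.
#' @export
read_animals <- function(path) {
  a <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("group_id", "animal_id", "weight_g")
  if (!all(need %in% names(a))) {
    abort(paste0("animals file needs columns: ", paste(need, collapse = ", ")),
          class = "playpref_validation_error")
  }
  dup <- dplyr::count(a, .data$group_id, .data$animal_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0) {
    abort("duplicate animal_id within a group",
          class = "playpref_validation_error")
  }
  if ("tube_wins" %in% names(a)) a <- add_dominance_ranks(a)
  tibble::as_tibble(a)
}

# Rank animals within group by descending tube-test wins; ties broken by
# animal_id so ranks are always a permutation of 1..k.
add_dominance_ranks <- function(animals) {
  animals |>
    dplyr::group_by(.data$group_id) |>
    dplyr::arrange(dplyr::desc(.data$tube_wins), .data$animal_id,
                   .by_group = TRUE) |>
    dplyr::mutate(dominance_rank = dplyr::row_number(),
                  rank_tied = duplicated(.data$tube_wins) |
                    duplicated(.data$tube_wins, fromLast = TRUE)) |>
    dplyr::ungroup()
}

#' Read dyadic proximity records
#'
#' @param path CSV with columns `group_id`, `day`, `animal_a`, `animal_b`,
#'   `proximity_s` (seconds within one body length, co-play time already
#'   subtracted). The dyad is unordered; labels are canonicalised so that
#'   `animal_a < animal_b`.
#' @param session_s Session length for range validation.
#' @return Tibble of proximity records.
#' @export
read_proximity <- function(path, session_s = 1200) {
  p <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("group_id", "day", "animal_a", "animal_b", "proximity_s")
  if (!all(need %in% names(p))) {
    abort(paste0("proximity file needs columns: ",
                 paste(need, collapse = ", ")),
          class = "playpref_validation_error")
  }
  if (any(p$proximity_s < 0 | p$proximity_s > session_s)) {
    abort("proximity_s outside [0, session length]",
          class = "playpref_validation_error")
  }
  canonicalise_dyads(tibble::as_tibble(p))
}

canonicalise_dyads <- function(tbl, a = "animal_a", b = "animal_b") {
  lo <- pmin(tbl[[a]], tbl[[b]])
  hi <- pmax(tbl[[a]], tbl[[b]])
  tbl[[a]] <- lo
  tbl[[b]] <- hi
  tbl
}

#' Build a directed attack-count matrix for one group-day
#'
#' Entry (i, j) counts the playful nape attacks initiated by animal i with j
#' as recipient. The diagonal is structurally zero.
#'
#' @param events Event tibble (any days/groups; filtered internally).
#' @param group Group id.
#' @param day Day label.
#' @param labels Ordered animal labels; defaults to the sorted labels seen in
#'   the group's events. Fixed alphabetical order keeps exports reproducible.
#' @return A `play_matrix`: an integer k x k matrix with attributes
#'   `group_id`, `day` and `type = "count"`.
#' @export
build_count_matrix <- function(events, group, day, labels = NULL) {
  ev <- dplyr::filter(events, .data$group_id == group, .data$day == !!day)
  if (is.null(labels)) {
    labels <- sort(unique(c(ev$initiator, ev$recipient)))
  }
  if (length(labels) == 0L) {
    abort("empty label list", class = "playpref_validation_error")
  }
  bad <- setdiff(unique(c(ev$initiator, ev$recipient)), labels)
  if (length(bad) > 0) {
    abort(paste0("event references unknown label(s): ",
                 paste(bad, collapse = ", ")),
          class = "playpref_validation_error")
  }
  k <- length(labels)
  m <- matrix(0L, k, k, dimnames = list(labels, labels))
  if (nrow(ev) > 0) {
    tab <- table(factor(ev$initiator, levels = labels),
                 factor(ev$recipient, levels = labels))
    m <- matrix(as.integer(tab), k, k, dimnames = list(labels, labels))
  }
  new_play_matrix(m, group_id = group, day = day, type = "count")
}

#' Coerce a plain matrix to a play matrix
#'
#' For users who already hold a directed attack-count (or proportion) matrix
#' rather than an event log. Row i / column j is initiator i to recipient j.
#'
#' @param m Square numeric matrix with non-negative entries and a zero
#'   diagonal; dimnames are used as animal labels (defaults to A, B, ...).
#' @param group_id,day Metadata attached to the matrix.
#' @param type `"count"` or `"proportion"`.
#' @return A `play_matrix`.
#' @export
as_play_matrix <- function(m, group_id = NA_integer_, day = NA_integer_,
                           type = c("count", "proportion")) {
  type <- match.arg(type)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || any(m < 0) || any(diag(m) != 0)) {
    abort("need a square non-negative matrix with a zero diagonal",
          class = "playpref_validation_error")
  }
  if (is.null(dimnames(m))) {
    dimnames(m) <- list(LETTERS[seq_len(nrow(m))],
                        LETTERS[seq_len(nrow(m))])
  }
  new_play_matrix(m, group_id = group_id, day = day, type = type)
}

new_play_matrix <- function(m, group_id, day, type, zero_rows = NULL) {
  structure(m, group_id = group_id, day = day, type = type,
            zero_rows = zero_rows,
            class = c("play_matrix", class(m)))
}

#' @export
print.play_matrix <- function(x, ...) {
  cat(sprintf("<play_matrix [%s] group %s day %s>\n", attr(x, "type"),
              attr(x, "group_id"), attr(x, "day")))
  print(unclass_matrix(x))
  invisible(x)
}

unclass_matrix <- function(x) {
  attrs <- c("group_id", "day", "type", "zero_rows")
  for (a in attrs) attr(x, a) <- NULL
  class(x) <- setdiff(class(x), "play_matrix")
  x
}

#' Row-normalise a count matrix to play proportions
#'
#' Proportions, not frequencies, are used downstream so that preference
#' strength is comparable across animals that differ in how much they play.
#'
#' @param counts A `play_matrix` of type `"count"`.
#' @return A `play_matrix` of type `"proportion"`; rows with zero attacks are
#'   left all-zero and flagged in the `zero_rows` attribute.
#' @export
to_proportions <- function(counts) {
  stopifnot(inherits(counts, "play_matrix"))
  m <- unclass_matrix(counts)
  totals <- rowSums(m)
  zero <- totals == 0
  p <- m / ifelse(totals == 0, 1, totals)
  new_play_matrix(p, group_id = attr(counts, "group_id"),
                  day = attr(counts, "day"), type = "proportion",
                  zero_rows = rownames(m)[zero])
}

#' Tidy a play matrix into a long dyad table
#'
#' @param x A `play_matrix`.
#' @param ... Unused.
#' @return Tibble with columns `group_id`, `day`, `initiator`, `recipient`
#'   and `count` or `proportion` (diagonal rows are dropped).
#' @export
tidy.play_matrix <- function(x, ...) {
  m <- unclass_matrix(x)
  value_col <- if (attr(x, "type") == "count") "count" else "proportion"
  out <- tibble::tibble(
    group_id = attr(x, "group_id"),
    day = attr(x, "day"),
    initiator = rep(rownames(m), times = ncol(m)),
    recipient = rep(colnames(m), each = nrow(m)),
    value = as.vector(m)
  )
  out <- dplyr::filter(out, .data$initiator != .data$recipient)
  names(out)[names(out) == "value"] <- value_col
  out
}

#' Count matrices for every group-day in an event log
#'
#' @param events Event tibble.
#' @param animals Optional animal metadata; if supplied, its labels define
#'   each group's matrix axes (so animals that never played still appear).
#' @return Tibble with one row per group-day and a list-column `counts` of
#'   `play_matrix` objects, plus `n_events`.
#' @export
count_matrices <- function(events, animals = NULL) {
  combos <- dplyr::distinct(events, .data$group_id, .data$day) |>
    dplyr::arrange(.data$group_id, .data$day)
  combos |>
    dplyr::mutate(counts = purrr::map2(.data$group_id, .data$day, function(g, d) {
      labels <- if (is.null(animals)) NULL else
        sort(animals$animal_id[animals$group_id == g])
      build_count_matrix(events, g, d, labels)
    }),
    n_events = purrr::map_int(.data$counts, ~ sum(unclass_matrix(.x))))
}

# Row totals (attacks initiated) of a play_matrix as a named vector.
initiated_totals <- function(counts) rowSums(unclass_matrix(counts))
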