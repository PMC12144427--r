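#' Randomness screen of a group-day against the equal-play expectation
#'
#' Tests whether a group-day's distribution of play across partners is
#' consistent with every animal dividing its attacks equally among its k-1
#' partners. The observed count matrix is compared with its row-total-
#' preserving expectation `H[i,j] = B_i/(k-1)` through the chi-square
#' deviation `X2 = sum (B[i,j] - B_i/(k-1))^2 / (B_i/(k-1))` over
#' off-diagonal cells of rows with play. The null distribution is generated
#' by Monte-Carlo permutation of each animal's attacks across its partners
#' (uniform multinomial at fixed row totals — the equal-play hypothesis made
#' generative), and `p` is the add-one fraction of null datasets at least as
#' deviant as the observed one; small `p` means the day's play is
#' significantly non-random. Days whose play cannot be distinguished from
#' the equal-play expectation (`p >= alpha`) are excluded from preference
#' analyses. The alignment correlation `r` between the observed and expected
#' matrices, reduced to dyadic dissimilarities
#' `d[i,j] = max_count - (B[i,j] + B[j,i])/2`, is reported descriptively
#' (high r = play close to the equal expectation).
#'
#' @param counts A `play_matrix` of type `"count"` with at least one
#'   positive row total.
#' @param n_perm Number of null permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param alpha Screening level (default 0.05).
#' @return One-row tibble: `group_id`, `day`, `r`, `p`, `n_perm`, `seed`,
#'   `excluded` (TRUE when the day's play is consistent with the equal-play
#'   expectation, `p >= alpha`).
#' @export
mantel_screen <- function(counts, n_perm = 9999L, seed = 1L, alpha = 0.05) {
  stopifnot(inherits(counts, "play_matrix"),
            attr(counts, "type") == "count")
  m <- unclass_matrix(counts)
  k <- nrow(m)
  b_i <- rowSums(m)
  if (all(b_i == 0)) {
    abort("degenerate matrix: no attacks on this group-day",
          class = "playpref_degenerate_error")
  }
  h <- matrix(rep(b_i / (k - 1), k), k, k)
  diag(h) <- 0
  d_obs <- dyadic_dissimilarity(m)
  d_hyp <- dyadic_dissimilarity(h)
  r_obs <- if (sd(d_obs) == 0 || sd(d_hyp) == 0) NA_real_ else
    stats::cor(d_obs, d_hyp)
  x2_obs <- equal_play_chisq(m, h)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  # null chi-squares: each row's attacks multinomial-uniform over partners,
  # drawn for all permutations at once
  x2_null <- numeric(n_perm)
  for (i in seq_len(k)) {
    if (b_i[i] > 0) {
      e_i <- b_i[i] / (k - 1)
      draws <- stats::rmultinom(n_perm, b_i[i], rep(1 / (k - 1), k - 1))
      x2_null <- x2_null + colSums((draws - e_i)^2) / e_i
    }
  }
  hits <- sum(x2_null >= x2_obs)
  p <- (hits + 1L) / (n_perm + 1L)
  tibble::tibble(group_id = attr(counts, "group_id"),
                 day = attr(counts, "day"),
                 r = r_obs, p = p, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), excluded = p >= alpha)
}

# Chi-square deviation from the equal-play expectation, off-diagonal cells
# of rows with any play.
equal_play_chisq <- function(m, h) {
  off <- row(m) != col(m) & h > 0
  sum((m[off] - h[off])^2 / h[off])
}

# Lower-triangle dyadic dissimilarity: larger when a pair plays less.
# Subtracting the symmetrised count from the matrix maximum turns shared
# play into closeness; the constant shift does not affect the correlation
# but keeps the quantity a proper dissimilarity.
dyadic_dissimilarity <- function(m) {
  s <- (m + t(m)) / 2
  d <- max(m) - s
  d[lower.tri(d)]
}

#' Exact two-sided sign test
#'
#' Two-sided binomial test of `n_success` successes in `n_trials` at success
#' probability 1/2, computed by exact summation:
#' `p = min(1, 2 * min(P(X <= s), P(X >= s)))`.
#'
#' @param n_success Number of successes.
#' @param n_trials Number of trials (> 0).
#' @return One-row tibble with `n_success`, `n_trials`, `p_two_sided`.
#' @examples
#' sign_test_exact(24, 31)$p_two_sided  # 0.0033
#' @export
sign_test_exact <- function(n_success, n_trials) {
  if (n_trials <= 0) abort("n_trials must be positive",
                           class = "playpref_error")
  if (n_success < 0 || n_success > n_trials) {
    abort("n_success must lie in 0..n_trials", class = "playpref_error")
  }
  lower <- sum(dbinom(0:n_success, n_trials, 0.5))
  upper <- sum(dbinom(n_success:n_trials, n_trials, 0.5))
  p <- min(1, 2 * min(lower, upper))
  tibble::tibble(n_success = n_success, n_trials = n_trials,
                 p_two_sided = p)
}

#' Weighted modularity of the play network with permutation significance
#'
#' Detects sub-groups in the undirected play network (edge weight = total
#' play between the pair) by greedy weighted-modularity maximisation, and
#' assesses significance by permuting the observed edge weights across the
#' fixed set of dyads: `p` is the add-one-corrected fraction of null
#' networks whose maximised modularity reaches the observed Q.
#'
#' @param counts A `play_matrix` of type `"count"`, or an igraph undirected
#'   weighted graph.
#' @param n_perm Number of weight permutations (default 999).
#' @param seed RNG seed.
#' @return List with `Q` (in `[-1, 1]`), `communities` (tibble `animal_id`,
#'   `community`), `p`, `n_perm`, `seed`.
#' @export
modularity_significance <- function(counts, n_perm = 999L, seed = 1L) {
  if (inherits(counts, "play_matrix")) {
    g <- build_undirected_network(counts)
  } else if (igraph::is_igraph(counts)) {
    g <- counts
  } else {
    abort("counts must be a play_matrix or an igraph graph",
          class = "playpref_error")
  }
  if (igraph::vcount(g) == 0) {
    abort("empty network", class = "playpref_error")
  }
  ends <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  fit <- max_modularity(ends, w, igraph::V(g)$name)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  hits <- 0L
  all_pos <- all(w > 0)
  g_fixed <- if (all_pos) {
    igraph::graph_from_data_frame(
      data.frame(from = ends[, 1], to = ends[, 2]), directed = FALSE,
      vertices = data.frame(name = igraph::V(g)$name))
  }
  for (b in seq_len(n_perm)) {
    w_b <- sample(w)
    q_b <- if (all_pos) {
      comm <- igraph::cluster_fast_greedy(g_fixed, weights = w_b)
      igraph::modularity(g_fixed, igraph::membership(comm), weights = w_b)
    } else {
      max_modularity(ends, w_b, igraph::V(g)$name)$Q
    }
    if (q_b >= fit$Q) hits <- hits + 1L
  }
  list(Q = fit$Q, communities = fit$communities,
       p = (hits + 1L) / (n_perm + 1L),
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

# Greedy modularity maximisation on an edge list with weights; zero-weight
# edges are dropped (fast_greedy requires a simple positive-weight graph).
max_modularity <- function(ends, w, vnames) {
  keep <- w > 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[keep, 1], to = ends[keep, 2], weight = w[keep]),
    directed = FALSE,
    vertices = data.frame(name = vnames))
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  list(Q = igraph::modularity(g, igraph::membership(comm),
                              weights = igraph::E(g)$weight),
       communities = tibble::tibble(
         animal_id = igraph::V(g)$name,
         community = as.integer(igraph::membership(comm))))
}

#' Run the permutation screen on every group-day of an event log
#'
#' @param events Event tibble.
#' @param animals Optional metadata fixing matrix axes.
#' @param n_perm,alpha,seed As in [mantel_screen()]; each group-day gets a
#'   distinct deterministic sub-seed derived from `seed`.
#' @return Tibble with one [mantel_screen()] row per group-day.
#' @export
mantel_screen_all <- function(events, animals = NULL, n_perm = 9999L,
                              alpha = 0.05, seed = 1L) {
  mats <- count_matrices(events, animals)
  purrr::imap_dfr(mats$counts, function(m, i) {
    mantel_screen(m, n_perm = n_perm, alpha = alpha,
                  seed = (seed + 7919L * i) %% .Machine$integer.max)
  })
}
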