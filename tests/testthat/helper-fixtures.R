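# Shared fixture builders. Everything is generated in code; no data files.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Minimal event row(s) with sensible defaults.
make_events <- function(initiator, recipient, group_id = 1L, day = 1L,
                        time_s = NULL, response = "pin",
                        role_reversal = FALSE, n_partners_available = 5L) {
  n <- max(length(initiator), length(recipient))
  tibble::tibble(
    group_id = group_id, day = day,
    time_s = time_s %||% seq(10, by = 10, length.out = n),
    initiator = initiator, recipient = recipient,
    response = response, role_reversal = role_reversal,
    n_partners_available = n_partners_available,
    all_available = n_partners_available == 5L
  )
}

# A play_matrix straight from a base matrix (labels A.., zero diagonal).
make_counts <- function(m, group_id = 1L, day = 1L) {
  diag(m) <- 0
  as_play_matrix(m, group_id = group_id, day = day)
}

# Events in which every animal attacks each partner the given number of
# times (an exactly equal-play day when `each` is scalar).
uniform_day_events <- function(each = 8L, group_id = 1L, day = 1L,
                               labels = LETTERS[1:6]) {
  grid <- expand.grid(initiator = labels, recipient = labels,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$initiator != grid$recipient, ]
  ev <- tidyr::uncount(tibble::as_tibble(grid), weights = each)
  make_events(ev$initiator, ev$recipient, group_id = group_id, day = day,
              time_s = seq_len(nrow(ev)))
}

# Events where every animal attacks one favourite heavily and the rest once.
favourite_day_events <- function(fav_n = 30L, other_n = 1L, group_id = 1L,
                                 day = 1L, labels = LETTERS[1:6]) {
  fav <- c(labels[-1], labels[1])  # A->B, B->C, ..., F->A
  names(fav) <- labels
  rows <- purrr::map_dfr(labels, function(a) {
    partners <- setdiff(labels, a)
    tibble::tibble(initiator = a, recipient = partners,
                   n = ifelse(partners == fav[[a]], fav_n, other_n))
  })
  ev <- tidyr::uncount(rows, weights = n)
  make_events(ev$initiator, ev$recipient, group_id = group_id, day = day,
              time_s = seq_len(nrow(ev)))
}

# Synthetic dyad-day rows with a known logistic generative model:
# logit P(preferred) = intercept + beta * pct_role_reversal + initiator RE.
make_glmm_rows <- function(n = 200, beta = 0, intercept = 0,
                           re_sd = 0.7, n_initiators = 30, seed = 1) {
  withr::local_seed(seed)
  initiator <- sample(paste0("rat", seq_len(n_initiators)), n, replace = TRUE)
  re <- stats::setNames(rnorm(n_initiators, 0, re_sd),
                        paste0("rat", seq_len(n_initiators)))
  x <- runif(n, 0, 60)
  eta <- intercept + beta * (x - 30) + re[initiator]
  tibble::tibble(
    initiator_id = initiator,
    partner_id = sample(paste0("rat", seq_len(n_initiators)), n,
                        replace = TRUE),
    outcome = rbinom(n, 1, stats::plogis(eta)),
    pct_role_reversal = x,
    noise_pred = rnorm(n))
}

# Independent sums-of-squares oracle for the one-way repeated-measures
# ANOVA (two-way layout without replication).
rm_anova_oracle <- function(d, value, factor, unit) {
  y <- d[[value]]
  lv <- base::factor(d[[factor]])
  un <- base::factor(d[[unit]])
  grand <- mean(y)
  L <- nlevels(lv); U <- nlevels(un)
  ss_level <- U * sum((tapply(y, lv, mean) - grand)^2)
  ss_unit <- L * sum((tapply(y, un, mean) - grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_resid <- ss_total - ss_level - ss_unit
  df1 <- L - 1; df2 <- (L - 1) * (U - 1)
  list(F = (ss_level / df1) / (ss_resid / df2), df1 = df1, df2 = df2)
}

# Brute-force two-sided sign-test p by enumeration of Binomial(n, 1/2).
sign_test_oracle <- function(s, n) {
  pmf <- choose(n, 0:n) / 2^n
  min(1, 2 * min(sum(pmf[1:(s + 1)]), sum(pmf[(s + 1):(n + 1)])))
}
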