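# Per-forager reward-use metrics at the daily and lifetime timescales.
#
# The degree of reward specialization is the larger of a forager's nectar
# and pollen bout proportions over a timescale: 0.5 for a perfectly balanced
# generalist, 1 for a complete specialist.  A forager is a reward specialist
# when it makes strictly more than 90% of its bouts (over a day, or over its
# lifetime) for one reward.

#' Classify a nectar preference into specialist classes
#'
#' @param pref Nectar bout proportion(s) in \[0, 1\].
#' @param threshold Specialist cutoff in (0.5, 1); the inequality is strict,
#'   so a preference of exactly `threshold` is a generalist.
#' @return Character vector: `"nectar"`, `"pollen"` or `"generalist"`.
#' @export
#' @examples
#' classify_specialist(c(0.95, 0.05, 0.90))
classify_specialist <- function(pref, threshold = 0.9) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0.5 || threshold >= 1) {
    stop_config("`threshold` must lie strictly between 0.5 and 1")
  }
  if (any(pref < 0 | pref > 1, na.rm = TRUE)) {
    stop_data("`pref` must lie in [0, 1]")
  }
  dplyr::case_when(
    pref > threshold ~ "nectar",
    (1 - pref) > threshold ~ "pollen",
    TRUE ~ "generalist"
  )
}

#' Summarise each forager's bouts by day
#'
#' @param bouts Bout tibble (needs `tag_id`, `reward`, `day`), e.g. from
#'   [extract_bouts()].
#' @param threshold Specialist cutoff, see [classify_specialist()].
#' @param min_daily_bouts Minimum bouts for a forager-day to be classified
#'   (rows below it are kept but classed `NA`); default 1, i.e. no minimum.
#' @return One row per (tag, day) with at least one bout: `tag_id`, `day`,
#'   `n_bouts`, `n_nectar`, `n_pollen`, `nectar_pref`, `degree` (in
#'   \[0.5, 1\]), `specialist_class`.
#' @export
summarize_forager_days <- function(bouts, threshold = 0.9,
                                   min_daily_bouts = 1) {
  bouts <- as_tibble(bouts)
  assert_reward(bouts$reward)
  assert_count(min_daily_bouts, "min_daily_bouts", min = 1L)
  out <- bouts %>%
    group_by(.data$tag_id, .data$day) %>%
    summarise(n_bouts = dplyr::n(),
              n_nectar = sum(.data$reward == "nectar"),
              n_pollen = sum(.data$reward == "pollen"),
              .groups = "drop") %>%
    mutate(nectar_pref = .data$n_nectar / .data$n_bouts,
           degree = pmax(.data$nectar_pref, 1 - .data$nectar_pref),
           specialist_class = ifelse(
             .data$n_bouts >= min_daily_bouts,
             classify_specialist(.data$nectar_pref, threshold),
             NA_character_)) %>%
    arrange(.data$tag_id, .data$day)
  out
}

#' Aggregate daily summaries into lifetime summaries
#'
#' Lifetime counts are sums over a forager's active days; the daily-degree
#' variance (variance, across active days, of the percentage degree of daily
#' specialization) measures how much a forager's daily specialization
#' fluctuated.  A single-day forager has variance 0 by convention.
#'
#' @param daily Output of [summarize_forager_days()].
#' @param threshold Specialist cutoff for the lifetime class.
#' @return One row per forager: `tag_id`, `total_days_foraged`,
#'   `lifetime_bouts`, `lifetime_nectar_bouts`, `lifetime_pollen_bouts`,
#'   `lifetime_nectar_pref`, `degree`, `specialist_class`,
#'   `mean_daily_bouts`, `daily_degree_variance`.
#' @export
summarize_forager_lifetime <- function(daily, threshold = 0.9) {
  daily <- as_tibble(daily)
  daily %>%
    group_by(.data$tag_id) %>%
    summarise(
      total_days_foraged = dplyr::n(),
      lifetime_bouts = sum(.data$n_bouts),
      lifetime_nectar_bouts = sum(.data$n_nectar),
      lifetime_pollen_bouts = sum(.data$n_pollen),
      daily_degree_variance = if (dplyr::n() < 2) 0 else
        stats::var(100 * .data$degree),
      .groups = "drop"
    ) %>%
    mutate(
      lifetime_nectar_pref = .data$lifetime_nectar_bouts / .data$lifetime_bouts,
      degree = pmax(.data$lifetime_nectar_pref, 1 - .data$lifetime_nectar_pref),
      specialist_class = classify_specialist(.data$lifetime_nectar_pref,
                                             threshold),
      mean_daily_bouts = .data$lifetime_bouts / .data$total_days_foraged
    ) %>%
    select("tag_id", "total_days_foraged", "lifetime_bouts",
           "lifetime_nectar_bouts", "lifetime_pollen_bouts",
           "lifetime_nectar_pref", "degree", "specialist_class",
           "mean_daily_bouts", "daily_degree_variance")
}

#' Jacob's constancy index of a reward sequence
#'
#' A transition-based measure of how strongly a forager forages in runs,
#' controlling for its overall reward bias.  Over the time-ordered sequence
#' of a forager's bout rewards, `c` is the observed proportion of
#' transitions between the same reward and `e = p^2 + (1 - p)^2` is the
#' proportion expected from the overall nectar frequency `p` alone; the
#' index is
#' \deqn{CI = (c - e) / (c + e - 2 c e).}
#' A forager that systematically alternates rewards has CI near -1, random
#' transitions give CI near 0, and foraging in runs gives CI near +1.  A
#' sequence containing a single distinct reward has `c = e = 1` and an
#' undefined index (flagged, not numeric).
#'
#' @param reward_sequence Character vector of `"nectar"`/`"pollen"` in bout
#'   order; length at least 2.
#' @return A one-row tibble: `n_transitions`, `c`, `e`, `ci`, `defined`.
#' @export
#' @examples
#' jacobs_ci(c("nectar", "pollen", "nectar", "pollen"))$ci      # -1
#' jacobs_ci(rep(c("nectar", "pollen"), each = 4))$ci           # 5/7
jacobs_ci <- function(reward_sequence) {
  assert_reward(reward_sequence, "reward_sequence")
  n <- length(reward_sequence)
  if (n < 2) {
    rlang::abort("need at least 2 bouts to compute a constancy index",
                 class = "rfidforage_insufficient_data_error")
  }
  same <- reward_sequence[-1] == reward_sequence[-n]
  cc <- mean(same)
  p <- mean(reward_sequence == "nectar")
  e <- p^2 + (1 - p)^2
  denom <- cc + e - 2 * cc * e
  defined <- denom != 0
  tibble(
    n_transitions = n - 1L,
    c = cc, e = e,
    ci = if (defined) (cc - e) / denom else NA_real_,
    defined = defined
  )
}

#' Constancy results for every forager in a bout table
#'
#' Computes [jacobs_ci()] on each forager's time-ordered lifetime reward
#' sequence.  Foragers with fewer than 2 bouts get an `NA` index flagged as
#' undefined rather than an error.
#'
#' @param bouts Bout tibble (`tag_id`, `reward`, `start`).
#' @return One row per forager: `tag_id`, `lifetime_bouts`,
#'   `n_transitions`, `c`, `e`, `ci`, `defined`.
#' @seealso [constancy_cohort()] for the minimum-bout inclusion rule.
#' @export
forager_constancy <- function(bouts) {
  bouts <- as_tibble(bouts) %>% arrange(.data$tag_id, .data$start)
  bouts %>%
    group_by(.data$tag_id) %>%
    summarise(res = list(
      if (dplyr::n() < 2) {
        tibble(n_transitions = dplyr::n() - 1L, c = NA_real_, e = NA_real_,
               ci = NA_real_, defined = FALSE)
      } else {
        jacobs_ci(.data$reward)
      }), lifetime_bouts = dplyr::n(), .groups = "drop") %>%
    tidyr::unnest("res") %>%
    select("tag_id", "lifetime_bouts", "n_transitions", "c", "e", "ci",
           "defined")
}

#' Apply the minimum-bout inclusion rule to constancy results
#'
#' Extreme index values (exactly -1 or +1) tend to come from foragers with
#' very few bouts, so the cohort for constancy analysis excludes foragers
#' below a minimum lifetime bout count (default 19, i.e. foragers with 18 or
#' fewer bouts are discarded) as well as foragers whose index is undefined.
#'
#' @param results Output of [forager_constancy()].
#' @param min_bouts Minimum lifetime bouts for inclusion.
#' @return A list: `included` (filtered tibble, with an `included` column
#'   set `TRUE`) and `n_excluded`.
#' @export
constancy_cohort <- function(results, min_bouts = 19) {
  assert_count(min_bouts, "min_bouts", min = 1L)
  results <- as_tibble(results)
  keep <- results$lifetime_bouts >= min_bouts & results$defined
  list(
    included = mutate(results[keep, ], included = TRUE),
    n_excluded = sum(!keep)
  )
}
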