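# Colony-level daily time series and concentration of foraging effort
# across individuals.

#' Daily colony time series
#'
#' For each day with at least one scored bout: the foraging force (number of
#' foragers with >= 1 bout that day), total bouts, the colony's nectar
#' preference (nectar bouts / total bouts, a bout-count proportion), mean
#' bouts per active forager, and the percentage of the day's foragers that
#' were daily reward specialists (total, nectar, pollen).  An optional brood
#' table joins a per-day brood percentage; days without a brood measurement
#' keep their row with `brood_pct = NA`.
#'
#' @param daily Output of [summarize_forager_days()].
#' @param brood Optional brood table (`day`, `brood_pct`), e.g. from
#'   [read_auxiliary_table()].  Duplicate days are a validation error.
#' @param threshold Specialist cutoff; classes are recomputed from
#'   `nectar_pref` at this threshold.
#' @return One row per day: `day`, `foraging_force`, `total_bouts`,
#'   `colony_nectar_pref`, `mean_bouts_per_forager`, `pct_specialists`,
#'   `pct_nectar_specialists`, `pct_pollen_specialists`, `brood_pct`.
#' @export
colony_day_series <- function(daily, brood = NULL, threshold = 0.9) {
  daily <- as_tibble(daily)
  if (nrow(daily) == 0) stop_data("`daily` has no rows")
  out <- daily %>%
    mutate(cls = classify_specialist(.data$nectar_pref, threshold)) %>%
    group_by(.data$day) %>%
    summarise(
      foraging_force = dplyr::n(),
      total_bouts = sum(.data$n_bouts),
      colony_nectar_pref = sum(.data$n_nectar) / sum(.data$n_bouts),
      mean_bouts_per_forager = sum(.data$n_bouts) / dplyr::n(),
      pct_specialists = 100 * mean(.data$cls != "generalist"),
      pct_nectar_specialists = 100 * mean(.data$cls == "nectar"),
      pct_pollen_specialists = 100 * mean(.data$cls == "pollen"),
      .groups = "drop"
    ) %>%
    arrange(.data$day)
  if (!is.null(brood)) {
    brood <- as_tibble(brood)
    if (!all(c("day", "brood_pct") %in% names(brood))) {
      stop_data("brood table needs columns day, brood_pct")
    }
    if (anyDuplicated(brood$day)) {
      stop_data("brood table has duplicate day entries")
    }
    out <- left_join(out, brood[c("day", "brood_pct")], by = "day")
  } else {
    out$brood_pct <- NA_real_
  }
  out
}

#' Concentration of foraging effort across foragers (Lorenz statistics)
#'
#' Ranks foragers by mean daily bout count (descending) and accumulates
#' their shares of the colony's effort.  `top_share_50` is the smallest
#' fraction of foragers accounting for at least half the effort — the
#' "minority doing half the work"; `bottom_half_share` is the share of
#' effort contributed by the `floor(n/2)` least-active foragers.
#'
#' @param mean_daily_bouts Numeric vector, one non-negative entry per
#'   forager (typically the `mean_daily_bouts` column of
#'   [summarize_forager_lifetime()]; pass `lifetime_bouts` instead to
#'   measure concentration of lifetime totals).
#' @return A list of class `effort_concentration`:
#'   \describe{
#'     \item{lorenz}{tibble of cumulative `(forager_frac, bout_frac)` pairs
#'       starting at (0, 0) and ending at (1, 1), foragers ranked
#'       descending.}
#'     \item{top_share_50}{minimal forager fraction holding >= 50% of
#'       effort.}
#'     \item{bottom_half_share}{effort share of the least-active half.}
#'     \item{n}{number of foragers.}
#'   }
#' @export
#' @examples
#' ec <- effort_concentration(c(10, 6, 2, 2))
#' ec$top_share_50       # 0.25
#' ec$bottom_half_share  # 0.20
effort_concentration <- function(mean_daily_bouts) {
  x <- as.numeric(mean_daily_bouts)
  if (length(x) == 0 || any(!is.finite(x) | x < 0)) {
    stop_data("`mean_daily_bouts` must be non-empty, finite and >= 0")
  }
  if (sum(x) == 0) {
    rlang::abort("all foragers have zero effort: concentration undefined",
                 class = "rfidforage_degenerate_error")
  }
  n <- length(x)
  x <- sort(x, decreasing = TRUE)
  cum_share <- cumsum(x) / sum(x)
  lorenz <- tibble(forager_frac = c(0, seq_len(n) / n),
                   bout_frac = c(0, cum_share))
  k50 <- which(cum_share >= 0.5)[1]
  n_bottom <- floor(n / 2)
  bottom_share <- if (n_bottom == 0) 0 else
    sum(x[(n - n_bottom + 1):n]) / sum(x)
  structure(
    list(lorenz = lorenz, top_share_50 = k50 / n,
         bottom_half_share = bottom_share, n = n),
    class = "effort_concentration"
  )
}

#' @export
print.effort_concentration <- function(x, ...) {
  cat(sprintf(
    "<effort_concentration> n=%d: top %.1f%% of foragers hold >=50%% of effort; bottom half holds %.1f%%\n",
    x$n, 100 * x$top_share_50, 100 * x$bottom_half_share))
  invisible(x)
}
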