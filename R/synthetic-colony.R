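# Generative model of a two-chamber colony: per-forager recruitment,
# lifespan, activity, and a persistent (Markov) reward-choice process with
# daily regime switching.  Planted bouts are emitted as paired-reader read
# quadruples so the whole extraction pipeline can be validated against
# ground truth.

REGIME_LEVELS <- c("pollen", "nectar", "mixed")
# Daily nectar preference under the pollen-day / nectar-day regimes.
REGIME_PREF <- c(pollen = 0.05, nectar = 0.95)

#' Configure a synthetic colony simulation
#'
#' Defaults describe a growth-phase colony window: 43 foraging days of 12 h
#' light, roughly one hundred foragers recruited throughout the window, a
#' heavily right-skewed distribution of individual activity (lognormal mean
#' daily bout counts spanning roughly a 40-fold range across a colony), bout
#' durations lognormal with means near 7.6 min (nectar) and 5.6 min
#' (pollen), about one sub-60 s non-foraging chamber entry per forager-day,
#' and perfect readers (no dropped or duplicated reads) unless configured
#' otherwise.
#'
#' @param n_foragers Number of foragers to simulate.
#' @param n_days Length of the colony window in days.
#' @param bout_duration_law Per-reward duration law: a list with elements
#'   `nectar` and `pollen`, each `c(mean_min =, sd_min =)` giving the
#'   arithmetic mean and SD (minutes) of a lognormal, truncated at draw time
#'   to the open interval (60 s, 30 min) so every planted bout is scoreable.
#' @param short_visit_rate Expected sub-60 s non-foraging entries per
#'   forager per active day (Poisson).
#' @param read_failure_prob Probability that any single antenna read is lost.
#' @param duplicate_read_prob Probability that a read is duplicated within
#'   1 s (tag rung twice in the field).
#' @param pairing_gap_s Seconds between the outer and inner reads of one
#'   directed transit through the paired readers.
#' @param day_length_h Hours of foraging light per day; bouts are placed
#'   inside the light window only.
#' @param seed Integer seed; the full event stream is a deterministic
#'   function of the configuration.
#' @param activity_meanlog,activity_sdlog Lognormal parameters for
#'   per-forager expected bouts/day; draws are clamped to
#'   `[activity_floor, activity_cap]`.
#' @param activity_floor Lower clamp on expected bouts/day: a bee that never
#'   reaches about one bout per active day would not register as a forager
#'   at all, and observed colonies show mean daily bout counts spanning
#'   roughly 1 to 40.
#' @param activity_cap Upper cap on expected bouts/day (a 12 h window cannot
#'   physically hold many more than ~40 mean-length bouts).
#' @param base_pref_nectar Baseline (mixed-day) probability that a fresh
#'   choice is nectar.
#' @param persistence Probability that a bout repeats the forager's previous
#'   reward instead of drawing a fresh choice; this is the run-generating
#'   parameter the constancy index estimates (see [expected_constancy()]).
#' @param regime_mix Probabilities of a pollen-day, nectar-day, mixed-day
#'   regime (must sum to 1).  Pollen/nectar days force the daily preference
#'   to `0.05`/`0.95`; mixed days use `base_pref_nectar`.
#' @param regime_persistence Probability a forager keeps yesterday's regime.
#' @param mean_lifespan_days,min_lifespan_days Mean and minimum of the
#'   per-forager foraging lifespan (a shifted geometric:
#'   `min_lifespan_days` plus a geometric excess); lifespans are truncated
#'   at the window end.  Foragers typically work for one to several weeks
#'   once they start.
#'
#' @return A `simulation_config` object (validated list).
#' @seealso [simulate_colony()], [forager_params()]
#' @export
simulation_config <- function(n_foragers = 100,
                              n_days = 43,
                              bout_duration_law = list(
                                nectar = c(mean_min = 7.6, sd_min = 5.3),
                                pollen = c(mean_min = 5.6, sd_min = 5.5)
                              ),
                              short_visit_rate = 1,
                              read_failure_prob = 0,
                              duplicate_read_prob = 0,
                              pairing_gap_s = 2,
                              day_length_h = 12,
                              seed = 1,
                              activity_meanlog = log(5),
                              activity_sdlog = 0.9,
                              activity_floor = 1,
                              activity_cap = 40,
                              base_pref_nectar = 0.5,
                              persistence = 0.3,
                              regime_mix = c(pollen = 0.3, nectar = 0.3,
                                             mixed = 0.4),
                              regime_persistence = 0.5,
                              mean_lifespan_days = 17,
                              min_lifespan_days = 3) {
  assert_count(n_foragers, "n_foragers", min = 0L)
  assert_count(n_days, "n_days", min = 1L)
  for (rw in REWARD_LEVELS) {
    law <- bout_duration_law[[rw]]
    if (is.null(law) || !all(c("mean_min", "sd_min") %in% names(law)) ||
        !all(is.finite(law)) || any(law <= 0)) {
      stop_config("bout_duration_law$%s must give positive mean_min, sd_min", rw)
    }
  }
  assert_nonneg(short_visit_rate, "short_visit_rate")
  assert_prob(read_failure_prob, "read_failure_prob")
  assert_prob(duplicate_read_prob, "duplicate_read_prob")
  if (!is.finite(pairing_gap_s) || pairing_gap_s <= 0) {
    stop_config("pairing_gap_s must be positive")
  }
  if (!is.finite(day_length_h) || day_length_h <= 0 || day_length_h > 24) {
    stop_config("day_length_h must be in (0, 24]")
  }
  assert_count(seed, "seed")
  if (!is.finite(activity_meanlog)) stop_config("activity_meanlog must be finite")
  assert_nonneg(activity_sdlog, "activity_sdlog")
  assert_nonneg(activity_floor, "activity_floor")
  assert_nonneg(activity_cap, "activity_cap")
  if (activity_floor > activity_cap) {
    stop_config("activity_floor must not exceed activity_cap")
  }
  assert_prob(base_pref_nectar, "base_pref_nectar")
  assert_prob(persistence, "persistence")
  regime_mix <- validate_regime_mix(regime_mix)
  assert_prob(regime_persistence, "regime_persistence")
  assert_count(min_lifespan_days, "min_lifespan_days", min = 1L)
  if (!is.finite(mean_lifespan_days) || mean_lifespan_days < min_lifespan_days) {
    stop_config("mean_lifespan_days must be >= min_lifespan_days")
  }
  structure(
    list(n_foragers = as.integer(n_foragers), n_days = as.integer(n_days),
         bout_duration_law = bout_duration_law,
         short_visit_rate = short_visit_rate,
         read_failure_prob = read_failure_prob,
         duplicate_read_prob = duplicate_read_prob,
         pairing_gap_s = pairing_gap_s, day_length_h = day_length_h,
         seed = as.integer(seed), activity_meanlog = activity_meanlog,
         activity_sdlog = activity_sdlog, activity_floor = activity_floor,
         activity_cap = activity_cap,
         base_pref_nectar = base_pref_nectar, persistence = persistence,
         regime_mix = regime_mix, regime_persistence = regime_persistence,
         mean_lifespan_days = mean_lifespan_days,
         min_lifespan_days = as.integer(min_lifespan_days)),
    class = "simulation_config"
  )
}

validate_regime_mix <- function(regime_mix) {
  regime_mix <- unlist(regime_mix)
  if (length(regime_mix) != 3) {
    stop_config("regime_mix must have 3 probabilities (pollen, nectar, mixed)")
  }
  if (is.null(names(regime_mix)) || any(names(regime_mix) == "")) {
    names(regime_mix) <- REGIME_LEVELS
  }
  if (!setequal(names(regime_mix), REGIME_LEVELS)) {
    stop_config("regime_mix names must be %s", paste(REGIME_LEVELS, collapse = ", "))
  }
  if (any(!is.finite(regime_mix)) || any(regime_mix < 0) ||
      abs(sum(regime_mix) - 1) > 1e-9) {
    stop_config("regime_mix must be non-negative and sum to 1")
  }
  regime_mix[REGIME_LEVELS]
}

#' Construct a table of per-forager behavioural parameters
#'
#' @param tag_id Character vector of unique tag ids.
#' @param recruit_day Integer day (0-based) each forager joins the workforce.
#' @param lifespan_days Positive integer foraging lifespan; active days past
#'   the simulation window are truncated by [simulate_colony()].
#' @param activity_rate Expected bouts per active day (Poisson mean).
#' @param base_pref_nectar,persistence,regime_persistence Per-forager
#'   probabilities (recycled if scalar); see [simulation_config()].
#' @param regime_mix A single regime mix (applied to all foragers) or a
#'   3-column matrix/data frame with one row per forager.
#' @return A tibble with one row per forager, columns `tag_id`,
#'   `recruit_day`, `lifespan_days`, `activity_rate`, `base_pref_nectar`,
#'   `persistence`, `regime_pollen`, `regime_nectar`, `regime_mixed`,
#'   `regime_persistence`.
#' @export
forager_params <- function(tag_id, recruit_day, lifespan_days, activity_rate,
                           base_pref_nectar = 0.5, persistence = 0.3,
                           regime_mix = c(pollen = 0.3, nectar = 0.3,
                                          mixed = 0.4),
                           regime_persistence = 0.5) {
  n <- length(tag_id)
  if (anyDuplicated(tag_id)) stop_config("tag_id must be unique")
  out <- tibble(
    tag_id = as.character(tag_id),
    recruit_day = as.integer(recruit_day),
    lifespan_days = as.integer(lifespan_days),
    activity_rate = as.numeric(activity_rate),
    base_pref_nectar = rep_len(as.numeric(base_pref_nectar), n),
    persistence = rep_len(as.numeric(persistence), n),
    regime_persistence = rep_len(as.numeric(regime_persistence), n)
  )
  if (is.null(dim(regime_mix))) {
    regime_mix <- validate_regime_mix(regime_mix)
    regime_mix <- matrix(rep(regime_mix, each = n), nrow = n, ncol = 3,
                         dimnames = list(NULL, REGIME_LEVELS))
  } else {
    regime_mix <- as.matrix(regime_mix)
    for (i in seq_len(nrow(regime_mix))) validate_regime_mix(regime_mix[i, ])
    regime_mix <- regime_mix[, REGIME_LEVELS, drop = FALSE]
  }
  out$regime_pollen <- regime_mix[, "pollen"]
  out$regime_nectar <- regime_mix[, "nectar"]
  out$regime_mixed <- regime_mix[, "mixed"]
  validate_forager_params(out)
}

validate_forager_params <- function(fp) {
  fp <- as_tibble(fp)
  if (any(fp$recruit_day < 0)) stop_config("recruit_day must be >= 0")
  if (any(fp$lifespan_days < 1)) stop_config("lifespan_days must be >= 1")
  if (any(!is.finite(fp$activity_rate) | fp$activity_rate < 0)) {
    stop_config("activity_rate must be finite and >= 0")
  }
  probs <- c("base_pref_nectar", "persistence", "regime_persistence",
             "regime_pollen", "regime_nectar", "regime_mixed")
  for (p in probs) {
    if (any(fp[[p]] < 0 | fp[[p]] > 1)) stop_config("%s must lie in [0, 1]", p)
  }
  mix_sum <- fp$regime_pollen + fp$regime_nectar + fp$regime_mixed
  if (any(abs(mix_sum - 1) > 1e-9)) stop_config("regime_mix rows must sum to 1")
  fp
}

# Population draw of forager parameters under a configuration; assumes the
# RNG has already been seeded by the caller.
draw_forager_params <- function(config) {
  n <- config$n_foragers
  if (n == 0L) {
    return(forager_params(character(), integer(), integer(), numeric()))
  }
  excess <- config$mean_lifespan_days - config$min_lifespan_days
  forager_params(
    tag_id = sprintf("bee%03d", seq_len(n)),
    recruit_day = sample.int(config$n_days, n, replace = TRUE) - 1L,
    lifespan_days = config$min_lifespan_days +
      rgeom(n, prob = 1 / (excess + 1)),
    activity_rate = pmax(config$activity_floor,
                         pmin(config$activity_cap,
                              rlnorm(n, config$activity_meanlog,
                                     config$activity_sdlog))),
    base_pref_nectar = config$base_pref_nectar,
    persistence = config$persistence,
    regime_mix = config$regime_mix,
    regime_persistence = config$regime_persistence
  )
}

# Lognormal meanlog/sdlog from an arithmetic mean and SD.
lognormal_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# Draw n durations (seconds) from the per-reward lognormal, rejected into
# the open interval (min_s, max_s) so every planted bout passes the scoring
# rule by construction.
draw_bout_durations <- function(n, law, min_s = 60, max_s = 1800) {
  if (n == 0L) return(numeric())
  lp <- lognormal_params(law[["mean_min"]] * 60, law[["sd_min"]] * 60)
  out <- rlnorm(n, lp[["meanlog"]], lp[["sdlog"]])
  bad <- which(out <= min_s + 1 | out >= max_s - 1)
  while (length(bad) > 0) {
    out[bad] <- rlnorm(length(bad), lp[["meanlog"]], lp[["sdlog"]])
    bad <- bad[out[bad] <= min_s + 1 | out[bad] >= max_s - 1]
  }
  out
}

# Persistent reward-choice chain: each bout repeats the forager's previous
# reward with probability s, otherwise draws fresh Bernoulli(p_day).  `prev`
# is the reward of the last bout before this block (NA if none: the first
# choice of a lifetime is always fresh).
draw_reward_chain <- function(n, p_day, s, prev = NA_character_) {
  if (n == 0L) return(character())
  fresh <- runif(n) >= s
  if (is.na(prev)) fresh[1] <- TRUE
  fresh_vals <- ifelse(rbinom(n, 1L, p_day) == 1L, "nectar", "pollen")
  last_fresh <- cummax(ifelse(fresh, seq_len(n), 0L))
  ifelse(last_fresh == 0L, prev, fresh_vals[pmax(last_fresh, 1L)])
}

# Place ordered intervals of the given durations uniformly (conditional on
# no overlap and preserved order) inside [lo, hi], with `clearance` seconds
# between consecutive intervals.  Infeasible trailing intervals are dropped.
# Returns start times (same length as the kept prefix of durations).
place_intervals <- function(durations, lo, hi, clearance) {
  n <- length(durations)
  while (n > 0 &&
         sum(durations[seq_len(n)]) + (n - 1) * clearance > (hi - lo)) {
    n <- n - 1L
  }
  if (n == 0L) return(numeric())
  durations <- durations[seq_len(n)]
  free <- (hi - lo) - sum(durations) - (n - 1) * clearance
  # Dirichlet(1,...,1) split of the free time over the n + 1 gaps.
  g <- stats::rexp(n + 1)
  g <- g / sum(g) * free
  starts <- lo + cumsum(c(g[1], durations[-n] + clearance + g[-c(1, n + 1)]))
  starts
}

# Reads emitted by chamber visits through paired readers (vectorised over
# visits): entry is outer -> inner ending at `start`, exit is inner -> outer
# starting at `end`.  `outer_of`/`inner_of` map chamber id -> reader id.
visit_reads <- function(tag_id, chamber, start, end, outer_of, inner_of, gap) {
  tibble(
    timestamp = as.vector(rbind(start - gap, start, end, end + gap)),
    tag_id = rep(rep_len(tag_id, length(start)), each = 4),
    reader_id = as.vector(rbind(outer_of[chamber], inner_of[chamber],
                                inner_of[chamber], outer_of[chamber]))
  )
}

#' Simulate a colony's RFID event stream with planted ground truth
#'
#' Generates, per forager and active day, a Poisson number of foraging bouts
#' whose rewards follow the persistent choice chain under the day's regime,
#' plus sub-60 s non-foraging chamber entries, places them without overlap
#' inside the light window, and emits the four paired-reader reads of every
#' chamber visit.  Read losses and duplicate reads are then applied via
#' [corrupt_events()].  The whole stream is a deterministic function of the
#' configuration (and `foragers`, if supplied).
#'
#' @param config A [simulation_config()].
#' @param foragers Optional [forager_params()] tibble overriding the random
#'   population draw (used for calibration experiments with fixed
#'   parameters).
#' @param setup A [setup_config()] naming readers and rewards; the default
#'   layout has chamber A = nectar, chamber B = pollen.
#'
#' @return A list of class `colony_sim`:
#' \describe{
#'   \item{events}{tibble `timestamp`, `tag_id`, `reader_id`, sorted by
#'     timestamp (ties broken by tag then reader).}
#'   \item{truth}{list with `planted_bouts` (tag_id, day, reward, start,
#'     end, duration_s), `short_visits` (same shape, sub-60 s entries) and
#'     `forager_params`.}
#'   \item{config, setup}{the inputs, for provenance.}
#' }
#' @export
#' @examples
#' sim <- simulate_colony(simulation_config(n_foragers = 3, n_days = 2, seed = 7))
#' nrow(sim$events)
#' head(sim$truth$planted_bouts)
simulate_colony <- function(config, foragers = NULL,
                            setup = default_setup_config()) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    if (is.null(foragers)) foragers <- draw_forager_params(config)
    foragers <- validate_forager_params(foragers)
    sim_colony_impl(config, foragers, setup)
  })
}

sim_colony_impl <- function(config, foragers, setup) {
  gap <- config$pairing_gap_s
  # Minimum spacing between a visit's last read and the next visit's first
  # read: keeps adjacent read quadruples outside both the pairing window and
  # the deduplication window of downstream processing.
  clearance <- 2 * gap + 6
  day_len <- config$day_length_h * 3600
  chambers <- names(setup$rewards)
  chamber_of <- setNames(names(setup$rewards), unname(setup$rewards))
  is_outer <- setup$readers$position == "outer"
  outer_of <- setNames(setup$readers$reader_id[is_outer],
                       setup$readers$chamber_id[is_outer])
  inner_of <- setNames(setup$readers$reader_id[!is_outer],
                       setup$readers$chamber_id[!is_outer])

  bout_rows <- list()
  short_rows <- list()
  event_rows <- list()
  k <- 0L

  for (i in seq_len(nrow(foragers))) {
    f <- foragers[i, ]
    if (f$recruit_day >= config$n_days) next
    last_day <- min(f$recruit_day + f$lifespan_days - 1L, config$n_days - 1L)
    days <- seq(f$recruit_day, last_day)
    mix <- c(pollen = f$regime_pollen, nectar = f$regime_nectar,
             mixed = f$regime_mixed)
    regime <- NA_character_
    prev_reward <- NA_character_

    for (d in days) {
      if (is.na(regime) || runif(1) >= f$regime_persistence) {
        regime <- sample(REGIME_LEVELS, 1, prob = mix)
      }
      p_day <- if (regime == "mixed") f$base_pref_nectar else
        REGIME_PREF[[regime]]

      n_bouts <- rpois(1, f$activity_rate)
      rewards <- draw_reward_chain(n_bouts, p_day, f$persistence, prev_reward)
      durations <- numeric(n_bouts)
      for (rw in REWARD_LEVELS) {
        sel <- rewards == rw
        durations[sel] <- draw_bout_durations(sum(sel),
                                              config$bout_duration_law[[rw]])
      }
      lo <- d * SECONDS_PER_DAY + gap
      hi <- d * SECONDS_PER_DAY + day_len - gap
      starts <- place_intervals(durations, lo, hi, clearance)
      n_kept <- length(starts)
      rewards <- rewards[seq_len(n_kept)]
      durations <- durations[seq_len(n_kept)]
      if (n_kept > 0) prev_reward <- rewards[n_kept]

      if (n_kept > 0) {
        k <- k + 1L
        bout_rows[[k]] <- tibble(
          tag_id = f$tag_id, day = d, reward = rewards,
          start = starts, end = starts + durations,
          duration_s = durations
        )
        event_rows[[length(event_rows) + 1L]] <- visit_reads(
          f$tag_id, unname(chamber_of[rewards]), starts, starts + durations,
          outer_of, inner_of, gap)
      }

      # Sub-60 s non-foraging entries, dropped into free slots of the day.
      n_short <- rpois(1, config$short_visit_rate)
      if (n_short > 0) {
        occupied <- if (n_kept > 0) cbind(starts, starts + durations) else
          matrix(numeric(), ncol = 2)
        for (q in seq_len(n_short)) {
          dur <- min(59, max(2, rlnorm(1, log(20), 0.5)))
          for (try in 1:20) {
            s0 <- runif(1, lo, hi - dur)
            ok <- nrow(occupied) == 0 ||
              all(s0 + dur + clearance < occupied[, 1] |
                    s0 > occupied[, 2] + clearance)
            if (ok) break
            s0 <- NA_real_
          }
          if (is.na(s0)) next
          occupied <- rbind(occupied, c(s0, s0 + dur))
          ch <- sample(chambers, 1)
          short_rows[[length(short_rows) + 1L]] <- tibble(
            tag_id = f$tag_id, day = d, reward = unname(setup$rewards[[ch]]),
            start = s0, end = s0 + dur, duration_s = dur
          )
          event_rows[[length(event_rows) + 1L]] <- visit_reads(
            f$tag_id, ch, s0, s0 + dur, outer_of, inner_of, gap)
        }
      }
    }
  }

  empty_truth <- tibble(tag_id = character(), day = integer(),
                        reward = character(), start = numeric(),
                        end = numeric(), duration_s = numeric())
  planted <- if (length(bout_rows)) bind_rows(bout_rows) else empty_truth
  shorts <- if (length(short_rows)) bind_rows(short_rows) else empty_truth
  planted <- planted %>% arrange(.data$tag_id, .data$start)
  events <- if (length(event_rows)) bind_rows(event_rows) else
    tibble(timestamp = numeric(), tag_id = character(), reader_id = character())
  events <- corrupt_events(events, m = config$read_failure_prob,
                           duplicate_read_prob = config$duplicate_read_prob)
  structure(
    list(events = events,
         truth = list(planted_bouts = planted, short_visits = shorts,
                      forager_params = foragers),
         config = config, setup = setup),
    class = "colony_sim"
  )
}

#' @export
print.colony_sim <- function(x, ...) {
  cat(sprintf(
    "<colony_sim> %d foragers, %d days: %d reads, %d planted bouts, %d short visits\n",
    nrow(x$truth$forager_params), x$config$n_days, nrow(x$events),
    nrow(x$truth$planted_bouts), nrow(x$truth$short_visits)))
  invisible(x)
}

#' Apply read failures and duplicate reads to an event stream
#'
#' Each read is dropped independently with probability `m`; each surviving
#' read spawns a duplicate within 1 s with probability
#' `duplicate_read_prob`.  Output order is by timestamp (ties broken by tag
#' then reader).
#'
#' @param events Event tibble (`timestamp`, `tag_id`, `reader_id`).
#' @param m Per-read loss probability.
#' @param duplicate_read_prob Per-read duplication probability.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (as when called from [simulate_colony()]).
#' @return The corrupted event tibble.
#' @export
corrupt_events <- function(events, m, duplicate_read_prob = 0, seed = NULL) {
  assert_prob(m, "m")
  assert_prob(duplicate_read_prob, "duplicate_read_prob")
  run <- function() {
    out <- as_tibble(events)
    n <- nrow(out)
    if (n == 0) return(out)
    if (m > 0) out <- out[runif(n) >= m, ]
    if (duplicate_read_prob > 0 && nrow(out) > 0) {
      dup <- out[runif(nrow(out)) < duplicate_read_prob, ]
      if (nrow(dup) > 0) {
        dup$timestamp <- dup$timestamp + runif(nrow(dup), 0, 1)
        out <- bind_rows(out, dup)
      }
    }
    arrange(out, .data$timestamp, .data$tag_id, .data$reader_id)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Closed-form constancy of the persistent choice chain
#'
#' Under the simulator's choice rule (repeat the previous reward with
#' probability `s`, otherwise draw nectar with probability `p`), the
#' long-run proportion of same-reward transitions is
#' `c = s + (1 - s) * e` with `e = p^2 + (1 - p)^2` the proportion expected
#' from the reward frequencies alone, giving a constancy index
#' `ci = (c - e) / (c + e - 2 * c * e)`.  For `p = 0.5` this reduces to
#' `ci = s` exactly, which is the calibration used by the parameter-recovery
#' tests.
#'
#' @param p Long-run nectar preference in (0, 1) exclusive; at 0 or 1 the
#'   sequence is single-reward and the index is undefined.
#' @param s Persistence (repeat) probability in \[0, 1\].
#' @return A list with `c_inf`, `e`, `ci_inf`.
#' @export
#' @examples
#' expected_constancy(0.5, 0.3)  # ci_inf = 0.3
expected_constancy <- function(p, s) {
  assert_prob(p, "p")
  assert_prob(s, "s")
  if (p == 0 || p == 1) {
    rlang::abort("degenerate preference (p of 0 or 1): constancy undefined",
                 class = "rfidforage_degenerate_error")
  }
  e <- p^2 + (1 - p)^2
  c_inf <- s + (1 - s) * e
  list(c_inf = c_inf, e = e,
       ci_inf = (c_inf - e) / (c_inf + e - 2 * c_inf * e))
}

#' Sampling SD of the empirical preference of a persistent chain
#'
#' The mean of `n` choices from the persistent chain has lag-k
#' autocorrelation `s^k`, so its sampling SD is the iid binomial SD inflated
#' by `sqrt((1 + s) / (1 - s))`.  Calibration checks of recovered
#' preferences must use this SD, not the plain binomial one.
#'
#' @param p Nectar preference.
#' @param s Persistence.
#' @param n Number of bouts.
#' @return Asymptotic SD of the empirical nectar fraction.
#' @export
preference_sampling_sd <- function(p, s, n) {
  sqrt(p * (1 - p) / n * (1 + s) / (1 - s))
}

#' Write a simulation to disk as plain CSV sidecars
#'
#' Writes `events.csv` (the event-log dialect of [write_events()]),
#' `planted_bouts.csv`, `short_visits.csv` and `forager_params.csv` into
#' `dir`.
#'
#' @param sim A `colony_sim` from [simulate_colony()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "colony_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_events(sim$events, file.path(dir, "events.csv"))
  readr::write_csv(sim$truth$planted_bouts, file.path(dir, "planted_bouts.csv"))
  readr::write_csv(sim$truth$short_visits, file.path(dir, "short_visits.csv"))
  readr::write_csv(sim$truth$forager_params,
                   file.path(dir, "forager_params.csv"))
  invisible(dir)
}

#' Build a simulation configuration from a YAML file
#'
#' The file holds top-level keys matching [simulation_config()] arguments;
#' `bout_duration_law` is a mapping `nectar:/pollen: {mean_min:, sd_min:}`
#' and `regime_mix` a mapping with keys pollen/nectar/mixed.
#'
#' @param path YAML file path.
#' @return A validated `simulation_config`.
#' @export
simulation_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_config("the 'yaml' package is required to read YAML configs")
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$bout_duration_law)) {
    vals$bout_duration_law <- lapply(vals$bout_duration_law, unlist)
  }
  if (!is.null(vals$regime_mix)) vals$regime_mix <- unlist(vals$regime_mix)
  do.call(simulation_config, vals)
}
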