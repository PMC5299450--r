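# From annotated read streams to directed transits, chamber visits, and
# scored foraging bouts.  The scoring rule is the field definition: a bout
# is a chamber visit lasting strictly more than 60 s and strictly less than
# 30 min, labelled with the chamber's reward.

#' Collapse duplicate reads
#'
#' RFID tags close to an antenna can be rung several times in quick
#' succession.  Reads of the same tag at the same reader are clustered by
#' chaining: a read within `dedup_window_s` of the previous read of that
#' tag/reader joins its cluster, and each cluster is collapsed to its first
#' read.
#'
#' @param events Sorted event tibble.
#' @param dedup_window_s Chaining window in seconds (default 2).
#' @return The deduplicated events, sorted by `(timestamp, tag_id)`, with
#'   the number of collapsed reads in the `n_collapsed` attribute.
#' @export
preprocess_events <- function(events, dedup_window_s = 2) {
  assert_nonneg(dedup_window_s, "dedup_window_s")
  events <- as_tibble(events)
  if (nrow(events) == 0) {
    attr(events, "n_collapsed") <- 0L
    return(events)
  }
  ord <- order(events$tag_id, events$reader_id, events$timestamp)
  ev <- events[ord, ]
  same_key <- c(FALSE, ev$tag_id[-1] == ev$tag_id[-nrow(ev)] &
                  ev$reader_id[-1] == ev$reader_id[-nrow(ev)])
  gap <- c(Inf, diff(ev$timestamp))
  keep <- !(same_key & gap <= dedup_window_s)
  out <- ev[keep, ] %>% arrange(.data$timestamp, .data$tag_id)
  attr(out, "n_collapsed") <- sum(!keep)
  out
}

#' Reconstruct chamber visits from paired-reader reads
#'
#' Within each (tag, chamber) stream, two reads at opposite readers within
#' `pairing_window_s` form one directed transit: outer then inner is an
#' entry (timed at the inner read, when the bee is in the chamber), inner
#' then outer is an exit (timed at the inner read, when it leaves the
#' chamber interior).  Entries are then matched to the next exit of the same
#' tag and chamber.  In `strict` mode only paired transits are used and
#' unpaired single reads are discarded (and counted); in `lenient` mode a
#' single read is resolved by the tag's last known location — an entry if
#' the bee was outside the chamber, an exit if it was inside.
#'
#' Bees that trip only one antenna are the reason extracted bout counts can
#' fall below truth under read failure; strict mode never fabricates a visit
#' from a single read.
#'
#' @param events Deduplicated, sorted events; annotated with `chamber_id`
#'   and `position` (see [annotate_events()]) or raw three-column events
#'   plus `setup`.
#' @param setup A [setup_config()]; used to annotate if needed.
#' @param pairing_window_s Maximum seconds between the two reads of a
#'   transit (must be positive).
#' @param mode `"strict"` or `"lenient"`.
#' @return A list with
#'   \describe{
#'     \item{visits}{tibble `tag_id`, `chamber_id`, `entry_time`,
#'       `exit_time`, `duration_s`, `confidence` (`"paired"` if both
#'       transits were paired, else `"single-read"`).}
#'     \item{diagnostics}{named list of counts: `n_events`, `paired_transits`,
#'       `single_reads`, `duplicate_entries`, `unmatched_entries`,
#'       `unmatched_exits`.}
#'   }
#' @export
reconstruct_visits <- function(events, setup,
                               pairing_window_s = 5,
                               mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  if (!is.numeric(pairing_window_s) || length(pairing_window_s) != 1 ||
      !is.finite(pairing_window_s) || pairing_window_s <= 0) {
    stop_config("pairing_window_s must be a positive number")
  }
  events <- as_tibble(events)
  if (!all(c("chamber_id", "position") %in% names(events))) {
    events <- annotate_events(events, setup)
  }
  diag <- list(n_events = nrow(events), paired_transits = 0L,
               single_reads = 0L, duplicate_entries = 0L,
               unmatched_entries = 0L, unmatched_exits = 0L)
  empty_visits <- tibble(tag_id = character(), chamber_id = character(),
                         entry_time = numeric(), exit_time = numeric(),
                         duration_s = numeric(), confidence = character())
  if (nrow(events) == 0) {
    return(list(visits = empty_visits, diagnostics = diag))
  }

  groups <- split(seq_len(nrow(events)),
                  paste(events$tag_id, events$chamber_id, sep = "\r"))
  visit_rows <- vector("list", length(groups))
  gi <- 0L
  for (idx in groups) {
    tt <- events$timestamp[idx]
    pos <- events$position[idx]
    o <- order(tt)
    tt <- tt[o]; pos <- pos[o]
    n <- length(tt)

    # --- pass 1: reads -> directed transits -------------------------------
    tr_time <- numeric(n); tr_dir <- character(n); tr_paired <- logical(n)
    m <- 0L
    inside <- FALSE   # only consulted in lenient mode
    i <- 1L
    while (i <= n) {
      if (i < n && (tt[i + 1] - tt[i]) <= pairing_window_s &&
          pos[i] != pos[i + 1]) {
        m <- m + 1L
        if (pos[i] == "outer") {            # outer -> inner: entry
          tr_time[m] <- tt[i + 1]; tr_dir[m] <- "entry"
        } else {                            # inner -> outer: exit
          tr_time[m] <- tt[i]; tr_dir[m] <- "exit"
        }
        tr_paired[m] <- TRUE
        inside <- tr_dir[m] == "entry"
        i <- i + 2L
      } else {
        diag$single_reads <- diag$single_reads + 1L
        if (mode == "lenient") {
          m <- m + 1L
          tr_time[m] <- tt[i]
          tr_dir[m] <- if (inside) "exit" else "entry"
          tr_paired[m] <- FALSE
          inside <- !inside
        }
        i <- i + 1L
      }
    }
    diag$paired_transits <- diag$paired_transits + sum(tr_paired[seq_len(m)])

    # --- pass 2: transits -> visits --------------------------------------
    if (m == 0L) next
    v_entry <- numeric(m); v_exit <- numeric(m); v_conf <- character(m)
    nv <- 0L
    open_entry <- NA_real_; open_paired <- NA
    for (j in seq_len(m)) {
      if (tr_dir[j] == "entry") {
        if (!is.na(open_entry)) {
          diag$duplicate_entries <- diag$duplicate_entries + 1L  # keep first
        } else {
          open_entry <- tr_time[j]; open_paired <- tr_paired[j]
        }
      } else {
        if (is.na(open_entry)) {
          diag$unmatched_exits <- diag$unmatched_exits + 1L      # discard
        } else if (tr_time[j] <= open_entry) {
          diag$unmatched_exits <- diag$unmatched_exits + 1L
        } else {
          nv <- nv + 1L
          v_entry[nv] <- open_entry; v_exit[nv] <- tr_time[j]
          v_conf[nv] <- if (open_paired && tr_paired[j]) "paired" else
            "single-read"
          open_entry <- NA_real_; open_paired <- NA
        }
      }
    }
    if (!is.na(open_entry)) {
      diag$unmatched_entries <- diag$unmatched_entries + 1L
    }
    if (nv > 0L) {
      gi <- gi + 1L
      visit_rows[[gi]] <- tibble(
        tag_id = events$tag_id[idx[1]],
        chamber_id = events$chamber_id[idx[1]],
        entry_time = v_entry[seq_len(nv)], exit_time = v_exit[seq_len(nv)],
        duration_s = v_exit[seq_len(nv)] - v_entry[seq_len(nv)],
        confidence = v_conf[seq_len(nv)]
      )
    }
  }
  visits <- if (gi > 0) {
    bind_rows(visit_rows[seq_len(gi)]) %>%
      arrange(.data$entry_time, .data$tag_id)
  } else empty_visits
  list(visits = visits, diagnostics = diag)
}

#' Score chamber visits into foraging bouts
#'
#' A visit becomes a foraging bout when its duration lies strictly between
#' `min_s` and `max_s` (defaults 60 s and 30 min).  Shorter visits are
#' non-foraging entries (bees that enter and leave the arena rapidly);
#' longer ones are excluded as `long`, and visits over 12 h are flagged as
#' sensor errors before scoring.  Bouts are labelled with the chamber's
#' configured reward and assigned to the calendar day of their start time
#' (per the setup's day boundary).
#'
#' @param visits Visit tibble from [reconstruct_visits()].
#' @param setup A [setup_config()].
#' @param min_s,max_s Open-interval duration bounds in seconds
#'   (`min_s < max_s` required).
#' @return A tibble of bouts (`tag_id`, `reward`, `start`, `end`,
#'   `duration_s`, `day`) sorted by tag and start time.  Excluded visits are
#'   never silently dropped: they are returned in the `exclusions`
#'   attribute with a `reason` code (`short`, `long`, `sensor`), so that
#'   bouts + exclusions partition the input visits.
#' @export
score_bouts <- function(visits, setup, min_s = 60, max_s = 1800) {
  if (!is.numeric(min_s) || !is.numeric(max_s) || min_s >= max_s) {
    stop_config("min_s must be smaller than max_s")
  }
  stopifnot(inherits(setup, "setup_config"))
  visits <- as_tibble(visits)
  if (nrow(visits) == 0) {
    out <- tibble(tag_id = character(), reward = character(),
                  start = numeric(), end = numeric(), duration_s = numeric(),
                  day = integer())
    attr(out, "exclusions") <- mutate(visits, reason = character(0))
    return(out)
  }
  scored <- visits %>%
    mutate(
      reward = unname(setup$rewards[.data$chamber_id]),
      day = as.integer(floor((.data$entry_time - setup$day_boundary_s) /
                               SECONDS_PER_DAY)),
      reason = dplyr::case_when(
        .data$duration_s > 12 * 3600 ~ "sensor",
        .data$duration_s <= min_s ~ "short",
        .data$duration_s >= max_s ~ "long",
        TRUE ~ "bout"
      )
    )
  bouts <- scored %>%
    filter(.data$reason == "bout") %>%
    select("tag_id", "reward", start = "entry_time", end = "exit_time",
           "duration_s", "day") %>%
    arrange(.data$tag_id, .data$start)
  attr(bouts, "exclusions") <- scored %>%
    filter(.data$reason != "bout") %>%
    select("tag_id", "chamber_id", "entry_time", "duration_s", "reason")
  bouts
}

#' One-call pipeline: raw events to scored bouts
#'
#' Convenience wrapper chaining [preprocess_events()],
#' [reconstruct_visits()] and [score_bouts()].
#'
#' @inheritParams reconstruct_visits
#' @inheritParams score_bouts
#' @param dedup_window_s Passed to [preprocess_events()].
#' @return The bout tibble from [score_bouts()], with the visit diagnostics
#'   attached as the `diagnostics` attribute.
#' @export
#' @examples
#' sim <- simulate_colony(simulation_config(n_foragers = 2, n_days = 2, seed = 1))
#' bouts <- extract_bouts(sim$events, sim$setup)
#' nrow(bouts) == nrow(sim$truth$planted_bouts)
extract_bouts <- function(events, setup, dedup_window_s = 2,
                          pairing_window_s = 5,
                          mode = c("strict", "lenient"),
                          min_s = 60, max_s = 1800) {
  ev <- preprocess_events(events, dedup_window_s)
  rec <- reconstruct_visits(ev, setup, pairing_window_s, mode)
  bouts <- score_bouts(rec$visits, setup, min_s, max_s)
  attr(bouts, "diagnostics") <- rec$diagnostics
  bouts
}
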