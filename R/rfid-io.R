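#' Describe the reader/chamber/reward geometry of a foraging setup
#'
#' A two-chamber foraging arena has one entrance per chamber, each fitted with
#' a pair of RFID readers mounted in sequence (an *outer* reader facing the
#' tunnel and an *inner* reader facing the chamber).  The order in which a
#' tagged bee trips the two readers gives the direction of movement: outer
#' then inner is an entry, inner then outer is an exit.  Each chamber offers
#' exactly one reward, nectar (sucrose solution) or pollen.
#'
#' @param readers A data frame with columns `reader_id`, `chamber_id` and
#'   `position` (`"outer"` or `"inner"`).  Each chamber must have exactly one
#'   outer and one inner reader.
#' @param rewards A named character vector mapping chamber id to reward, e.g.
#'   `c(A = "nectar", B = "pollen")`.  Every chamber must map to exactly one
#'   of `"nectar"` or `"pollen"`.
#' @param day_boundary_s Clock offset (seconds) at which a new foraging day
#'   starts; bouts belong to the day of their start time.  Defaults to 0,
#'   i.e. days are aligned with the onset of the light cycle at time 0.
#'
#' @return An object of class `setup_config`: a list with elements `readers`
#'   (tibble), `rewards` (named character) and `day_boundary_s`.
#' @seealso [default_setup_config()] for the canonical two-chamber layout.
#' @export
#' @examples
#' setup <- default_setup_config()
#' setup$rewards
setup_config <- function(readers, rewards, day_boundary_s = 0) {
  readers <- as_tibble(readers)
  needed <- c("reader_id", "chamber_id", "position")
  if (!all(needed %in% names(readers))) {
    stop_config("`readers` must have columns %s", paste(needed, collapse = ", "))
  }
  readers <- readers %>%
    mutate(across(all_of(needed), as.character))
  if (anyDuplicated(readers$reader_id)) {
    stop_config("duplicate reader_id in `readers`")
  }
  if (!all(readers$position %in% c("outer", "inner"))) {
    stop_config("reader `position` must be 'outer' or 'inner'")
  }
  per_chamber <- readers %>%
    group_by(.data$chamber_id) %>%
    summarise(n_outer = sum(.data$position == "outer"),
              n_inner = sum(.data$position == "inner"), .groups = "drop")
  if (any(per_chamber$n_outer != 1L | per_chamber$n_inner != 1L)) {
    stop_config("each chamber needs exactly one outer and one inner reader")
  }
  rewards <- unlist(rewards)
  if (is.null(names(rewards)) || any(names(rewards) == "")) {
    stop_config("`rewards` must be a named vector: chamber_id -> reward")
  }
  assert_reward(rewards, "rewards")
  if (!setequal(names(rewards), per_chamber$chamber_id)) {
    stop_config("chambers in `rewards` (%s) do not match `readers` (%s)",
                paste(sort(names(rewards)), collapse = ","),
                paste(sort(per_chamber$chamber_id), collapse = ","))
  }
  assert_nonneg(day_boundary_s, "day_boundary_s")
  structure(
    list(readers = readers, rewards = rewards,
         day_boundary_s = as.numeric(day_boundary_s)),
    class = "setup_config"
  )
}

#' @export
print.setup_config <- function(x, ...) {
  cat("<setup_config>\n")
  for (ch in sort(names(x$rewards))) {
    rd <- x$readers[x$readers$chamber_id == ch, ]
    cat(sprintf("  chamber %s (%s): outer=%s inner=%s\n", ch, x$rewards[[ch]],
                rd$reader_id[rd$position == "outer"],
                rd$reader_id[rd$position == "inner"]))
  }
  cat(sprintf("  day boundary offset: %g s\n", x$day_boundary_s))
  invisible(x)
}

#' Canonical two-chamber setup: chamber A nectar, chamber B pollen
#'
#' @inheritParams setup_config
#' @return A `setup_config` with readers `A_outer`, `A_inner`, `B_outer`,
#'   `B_inner`.
#' @export
default_setup_config <- function(day_boundary_s = 0) {
  setup_config(
    readers = tibble(
      reader_id  = c("A_outer", "A_inner", "B_outer", "B_inner"),
      chamber_id = c("A", "A", "B", "B"),
      position   = c("outer", "inner", "outer", "inner")
    ),
    rewards = c(A = "nectar", B = "pollen"),
    day_boundary_s = day_boundary_s
  )
}

#' Annotate raw reads with chamber, position and reward
#'
#' @param events Tibble with columns `timestamp`, `tag_id`, `reader_id`.
#' @param setup A [setup_config()].
#' @return `events` with `chamber_id`, `position` and `reward` columns added.
#'   Unknown reader ids are an error naming the offending rows.
#' @export
annotate_events <- function(events, setup) {
  stopifnot(inherits(setup, "setup_config"))
  events <- as_tibble(events)
  unknown <- which(!events$reader_id %in% setup$readers$reader_id)
  if (length(unknown) > 0) {
    stop_data("unknown reader_id '%s' at row %d (%d offending rows in total)",
              events$reader_id[unknown[1]], unknown[1], length(unknown))
  }
  events %>%
    left_join(setup$readers, by = "reader_id") %>%
    mutate(reward = unname(setup$rewards[.data$chamber_id]))
}

#' Read an RFID event log
#'
#' The event CSV dialect is minimal: a header row `timestamp,tag_id,reader_id`,
#' comma-separated UTF-8 values, `#` comment lines permitted.  Timestamps are
#' accepted either as numeric seconds from the colony-local epoch or as
#' ISO-8601 datetimes (converted to seconds from the first midnight).
#'
#' @param path Path to the CSV file.
#' @param setup A [setup_config()]; reads are annotated with chamber,
#'   position and reward, and an unknown `reader_id` is an error that names
#'   the offending row.
#' @return A tibble of events sorted stably by `(timestamp, tag_id)` with
#'   columns `timestamp`, `tag_id`, `reader_id`, `chamber_id`, `position`,
#'   `reward`.  Rows with missing fields are never silently dropped: they are
#'   counted, reported via a warning, and recorded in the `n_malformed`
#'   attribute.
#' @export
read_events <- function(path, setup) {
  if (!file.exists(path)) stop_data("event file not found: %s", path)
  raw <- readr::read_csv(path, comment = "#", col_types = readr::cols(
    timestamp = readr::col_character(),
    tag_id = readr::col_character(),
    reader_id = readr::col_character()
  ), progress = FALSE)
  if (!all(c("timestamp", "tag_id", "reader_id") %in% names(raw))) {
    stop_data("event file must have header timestamp,tag_id,reader_id")
  }
  malformed <- !complete.cases(raw[c("timestamp", "tag_id", "reader_id")])
  if (any(malformed)) {
    warn(sprintf("dropped %d malformed event row(s) with missing fields",
                 sum(malformed)))
    raw <- raw[!malformed, ]
  }
  ts <- suppressWarnings(as.numeric(raw$timestamp))
  iso <- is.na(ts) & !is.na(raw$timestamp)
  if (any(iso)) {
    parsed <- suppressWarnings(readr::parse_datetime(raw$timestamp[iso]))
    if (anyNA(parsed)) {
      bad <- which(iso)[which(is.na(parsed))[1]]
      stop_data("unparseable timestamp '%s' at data row %d",
                raw$timestamp[bad], bad)
    }
    # ISO datetimes are referenced to the midnight preceding the first read.
    origin <- trunc(min(parsed), units = "days")
    ts[iso] <- as.numeric(difftime(parsed, origin, units = "secs"))
  }
  if (anyNA(ts)) {
    stop_data("unparseable timestamp at data row %d", which(is.na(ts))[1])
  }
  if (any(ts < 0)) stop_data("negative timestamp at data row %d",
                             which(ts < 0)[1])
  out <- tibble(timestamp = ts, tag_id = raw$tag_id,
                reader_id = raw$reader_id) %>%
    arrange(.data$timestamp, .data$tag_id) %>%
    annotate_events(setup)
  attr(out, "n_malformed") <- sum(malformed)
  out
}

#' Write an RFID event log
#'
#' Writes the canonical three-column CSV (`timestamp,tag_id,reader_id`);
#' [read_events()] on the result reproduces the input events exactly.
#'
#' @param events Event tibble (extra annotation columns are ignored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  events <- as_tibble(events)
  needed <- c("timestamp", "tag_id", "reader_id")
  if (!all(needed %in% names(events))) {
    stop_data("`events` must have columns %s", paste(needed, collapse = ", "))
  }
  readr::write_csv(events[needed], path, progress = FALSE)
  invisible(path)
}

#' Read a validated auxiliary table (brood percentage or forager morphology)
#'
#' Brood tables give, per day, the percent of the colony's comb surface made
#' up of closed brood cells; days may be missing (photographs are not always
#' available).  Morphology tables give one row per tagged forager with linear
#' measures in millimetres and the pore-plate (sensilla placodea) count on
#' the 7th antennal flagellomere.  For morphology tables two derived columns
#' are added: `seg7_area_mm2`, the flagellomere's lateral cylindrical surface
#' area ([flagellomere_area()]), and `pore_plate_density`, plates per mm^2.
#'
#' @param path CSV path.
#' @param schema `"brood"` (columns `day`, `brood_pct`) or `"morphology"`
#'   (columns `tag_id`, `forewing_mm`, `head_mm`, `proboscis_mm`,
#'   `flagellum_mm`, `seg7_width_mm`, `seg7_length_mm`, `pore_plates`).
#' @return A typed tibble.  `brood_pct` outside \[0, 100\] or duplicate
#'   `tag_id` in a morphology table are validation errors; a zero pore-plate
#'   count is accepted with a warning.
#' @export
read_auxiliary_table <- function(path, schema = c("brood", "morphology")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_data("auxiliary table not found: %s", path)
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  if (schema == "brood") {
    if (!all(c("day", "brood_pct") %in% names(tbl))) {
      stop_data("brood table needs columns day, brood_pct")
    }
    tbl <- tbl %>%
      mutate(day = as.integer(.data$day), brood_pct = as.numeric(.data$brood_pct))
    bad <- which(!is.finite(tbl$brood_pct) | tbl$brood_pct < 0 |
                   tbl$brood_pct > 100)
    if (length(bad) > 0) {
      stop_data("brood_pct out of [0, 100] at row %d (value %s)",
                bad[1], format(tbl$brood_pct[bad[1]]))
    }
    if (anyDuplicated(tbl$day)) stop_data("duplicate day in brood table")
    return(tbl)
  }
  needed <- c("tag_id", "forewing_mm", "head_mm", "proboscis_mm",
              "flagellum_mm", "seg7_width_mm", "seg7_length_mm", "pore_plates")
  if (!all(needed %in% names(tbl))) {
    stop_data("morphology table needs columns %s",
              paste(setdiff(needed, names(tbl)), collapse = ", "))
  }
  tbl <- tbl %>%
    mutate(tag_id = as.character(.data$tag_id),
           across(all_of(setdiff(needed, "tag_id")), as.numeric))
  if (anyDuplicated(tbl$tag_id)) {
    stop_data("duplicate tag_id in morphology table: %s",
              tbl$tag_id[anyDuplicated(tbl$tag_id)])
  }
  if (any(tbl$pore_plates == 0, na.rm = TRUE)) {
    warn("morphology table contains pore_plates = 0; retained but check the cast")
  }
  tbl %>%
    mutate(seg7_area_mm2 = flagellomere_area(.data$seg7_width_mm,
                                             .data$seg7_length_mm),
           pore_plate_density = pore_plate_density(.data$pore_plates,
                                                   .data$seg7_area_mm2))
}

#' Cylindrical surface area of an antennal flagellomere
#'
#' The 7th antennal flagellomere is approximated as a cylinder with the
#' measured width as its diameter; the area used for sensilla density is the
#' lateral surface only (no end caps), `pi * width * length`.
#'
#' @param width_mm,length_mm Segment width (diameter) and length in mm.
#' @return Area in mm^2.
#' @export
#' @examples
#' flagellomere_area(0.3, 0.5)  # pi * 0.3 * 0.5
flagellomere_area <- function(width_mm, length_mm) {
  pi * width_mm * length_mm
}

#' Pore-plate density on a flagellomere
#'
#' @param count Number of pore plates (sensilla placodea).
#' @param area_mm2 Surface area from [flagellomere_area()].
#' @return Plates per mm^2.
#' @export
pore_plate_density <- function(count, area_mm2) {
  count / area_mm2
}
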