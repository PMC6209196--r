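# Snowfall categories and controls. Each wolf-day is positioned relative
# to the snowfall events that wolf experienced: a six-day window from two
# days before to three days after an event, plus randomly drawn control
# days well outside any event window.

#' Snowfall category levels
#'
#' Ordered with `day_of_snowfall` first so it is the model reference level
#' (coefficients are contrasts against the event day itself).
#' @export
snowfall_category_levels <- c("day_of_snowfall", "two_before", "one_before",
                              "one_after", "two_after", "three_after", "control")

.OFFSET_LABELS <- c("two_before", "one_before", "day_of_snowfall",
                    "one_after", "two_after", "three_after") # offsets -2..+3

#' Assign date-based snowfall categories to wolf-days
#'
#' Days at offset -2..+3 from an event get the corresponding category.
#' Where windows of two events overlap, a day resolves to the nearest
#' event (ties to the earlier event); an event date itself is always
#' `day_of_snowfall`. Days outside every window are `unassigned`
#' (control-eligible).
#'
#' @param wolf_days tibble with `wolf_id`, `camera_day` (one row per
#'   wolf-day with telemetry).
#' @param events tibble with `wolf_id`, `camera_day` of snowfall-event
#'   days (typically `is_event` rows of [join_wolf_day()] output).
#' @return `wolf_days` with a `snowfall_category` character column
#'   (`unassigned` for out-of-window days).
#' @export
assign_snowfall_categories <- function(wolf_days, events) {
  out <- mutate(wolf_days, snowfall_category = "unassigned")
  if (nrow(events) == 0) return(out)
  ev_by_wolf <- split(as.integer(events$camera_day), events$wolf_id)
  day_int <- as.integer(out$camera_day)
  for (i in seq_len(nrow(out))) {
    ev <- ev_by_wolf[[out$wolf_id[i]]]
    if (is.null(ev) || length(ev) == 0) next
    off <- day_int[i] - ev # offset of this day from each event
    if (any(off == 0)) {
      out$snowfall_category[i] <- "day_of_snowfall"
      next
    }
    in_win <- which(off >= -2 & off <= 3)
    if (length(in_win) == 0) next
    # nearest event wins; tie -> earlier event (events sorted ascending)
    ev_w <- ev[in_win]
    off_w <- off[in_win]
    ordr <- order(abs(off_w), ev_w)
    out$snowfall_category[i] <- .OFFSET_LABELS[off_w[ordr[1]] + 3L]
  }
  out
}

#' Sample control dates per wolf
#'
#' Control-eligible dates lie at least three days before or four days
#' after every snowfall event of that wolf (i.e. outside all [-2, +3]
#' windows). Up to `n_controls` eligible dates are drawn uniformly
#' without replacement per wolf, reproducibly under `seed`.
#'
#' @param wolf_days tibble `wolf_id,camera_day` of days with telemetry.
#' @param events tibble `wolf_id,camera_day` of event days.
#' @param n_controls controls per wolf (default 3), or per event when
#'   `per_event = TRUE`.
#' @param seed integer seed.
#' @param per_event draw `n_controls` per event experienced by the wolf
#'   rather than per wolf-winter (default FALSE); eligibility is always
#'   enforced against all of the wolf's events jointly.
#' @return tibble `wolf_id,camera_day` of the sampled control days.
#' @export
sample_controls <- function(wolf_days, events, n_controls = 3, seed = 1,
                            per_event = FALSE) {
  stopifnot(n_controls >= 0)
  ev_by_wolf <- split(as.integer(events$camera_day), events$wolf_id)
  wolves <- sort(unique(wolf_days$wolf_id))
  withr::with_seed(seed, {
    picks <- lapply(wolves, function(w) {
      days <- sort(unique(as.integer(wolf_days$camera_day[wolf_days$wolf_id == w])))
      ev <- ev_by_wolf[[w]]
      if (!is.null(ev) && length(ev) > 0) {
        ok <- vapply(days, function(d) all(d <= ev - 3 | d >= ev + 4), logical(1))
        days <- days[ok]
      }
      if (length(days) == 0) {
        warn(sprintf("Wolf %s has no control-eligible dates", w))
        return(NULL)
      }
      quota <- if (per_event) n_controls * max(1L, length(ev)) else n_controls
      take <- min(quota, length(days))
      tibble::tibble(wolf_id = w,
                     camera_day = as.Date(sort(sample(days, take)),
                                          origin = "1970-01-01"))
    })
  })
  bind_rows(picks)
}

#' Assemble the analysis dataset
#'
#' Joins labelled steps to snowfall categories (with sampled controls
#' overriding `unassigned`) and to wolf-day snow values. Rows left in no
#' category are omitted; rows with a category but a missing snow depth are
#' retained (models including snow depth use complete cases).
#'
#' @param steps labelled steps: output of [classify_steps()] +
#'   [label_time_of_day()].
#' @param categories output of [assign_snowfall_categories()].
#' @param controls output of [sample_controls()].
#' @param wolf_day_snow output of [join_wolf_day()].
#' @return tibble with one row per analyzed step: `wolf_id`, `camera_day`,
#'   `time_of_day`, `behavior`, `speed_mpm`, `log10_speed`,
#'   `snowfall_category` (factor, reference `day_of_snowfall`),
#'   `snow_depth_cm`.
#' @export
build_analysis_dataset <- function(steps, categories, controls, wolf_day_snow) {
  cats <- categories
  if (nrow(controls) > 0) {
    key <- paste(controls$wolf_id, controls$camera_day)
    is_ctl <- paste(cats$wolf_id, cats$camera_day) %in% key
    clobber <- is_ctl & cats$snowfall_category != "unassigned"
    if (any(clobber)) {
      abort("Control dates overlap event windows; controls must be sampled from unassigned days")
    }
    cats$snowfall_category[is_ctl] <- "control"
  }
  out <- steps %>%
    left_join(select(cats, "wolf_id", "camera_day", "snowfall_category"),
              by = c("wolf_id", "camera_day")) %>%
    left_join(select(wolf_day_snow, "wolf_id", "camera_day",
                     snow_depth_cm = "depth_cm"),
              by = c("wolf_id", "camera_day"))
  n0 <- nrow(out)
  out <- filter(out, !is.na(.data$snowfall_category),
                .data$snowfall_category != "unassigned")
  if (nrow(out) == 0) {
    abort("No steps fall in any snowfall category; review event detection and control sampling parameters")
  }
  inform(sprintf("Analysis dataset: kept %d of %d steps (%.2f%% omitted as uncategorized)",
                 nrow(out), n0, 100 * (n0 - nrow(out)) / max(n0, 1)))
  out <- out %>%
    mutate(
      snowfall_category = factor(.data$snowfall_category,
                                 levels = snowfall_category_levels),
      time_of_day = factor(.data$time_of_day, levels = c("day", "night")),
      log10_speed = log10_speed(.data$speed_mpm)
    )
  tally <- table(out$snowfall_category)
  inform(paste("Steps per category:",
               paste(names(tally), tally, sep = "=", collapse = ", ")))
  out
}
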