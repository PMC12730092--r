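#' Event intervals
#'
#' Build a table of intervals during which chamber data are invalid (door
#' openings, failures, manual exclusions).
#'
#' @param start,end POSIXct vectors of interval bounds (`start < end`).
#' @param kind Character vector: `"door"`, `"failure"` or `"manual"`.
#' @return Tibble with columns `start`, `end`, `kind`.
#' @export
event_log <- function(start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      kind = character()) {
  out <- tibble::tibble(start = start, end = end, kind = as.character(kind))
  if (any(out$start >= out$end)) {
    abort("Every event must have `start < end`.")
  }
  bad <- setdiff(unique(out$kind), c("door", "failure", "manual"))
  if (length(bad) > 0) {
    abort(paste0("Unknown event kind(s): ", paste(bad, collapse = ", "), "."))
  }
  out
}

#' Twice-daily door-opening schedule
#'
#' Chambers are opened for cleaning, feeding and milking twice a day; data in
#' those windows must be discarded even when the operator forgot to log the
#' opening. This builds the implied door events over a run.
#'
#' @param start,end POSIXct bounds of the run.
#' @param times_of_day Character `"HH:MM"` opening times (chamber local time).
#' @param duration_min Minutes each opening lasts.
#' @return An event tibble as from [event_log()].
#' @export
door_schedule <- function(start, end, times_of_day = c("07:00", "16:00"),
                          duration_min = 30) {
  days <- seq(lubridate::floor_date(start, "day"),
              lubridate::floor_date(end, "day"), by = "1 day")
  opens <- purrr::map(times_of_day, function(tod) {
    hm <- as.integer(strsplit(tod, ":", fixed = TRUE)[[1]])
    days + hm[1] * 3600 + hm[2] * 60
  })
  opens <- sort(do.call(c, opens))
  opens <- opens[opens < end & (opens + duration_min * 60) > start]
  event_log(opens, opens + duration_min * 60, rep("door", length(opens)))
}

in_any_interval <- function(times, events) {
  if (is.null(events) || nrow(events) == 0) {
    return(rep(FALSE, length(times)))
  }
  purrr::reduce(
    purrr::map2(events$start, events$end, ~ times >= .x & times < .y),
    `|`
  )
}

#' Fill gaps in a time series from an event log
#'
#' Points inside any event interval are replaced by the mean of the `k`
#' nearest valid points before the interval and the `k` nearest after (the
#' 2k values are pooled into a single mean). At a series edge where fewer
#' than `k` valid points exist on one side, the available points are used
#' and a warning is raised; an interval with no valid neighbour on either
#' side is an error.
#'
#' @param series Tibble with a `timestamp` column and the value column named
#'   by `value`; rows time-ordered.
#' @param events Event tibble (see [event_log()]); may be `NULL` or empty.
#' @param value Name of the column to fill.
#' @param k Valid points taken from each side of the gap.
#' @return `series` with the value column filled inside events and a logical
#'   `filled` column.
#' @export
fill_gaps <- function(series, events, value = "emission_lpm", k = 4) {
  series <- tibble::as_tibble(series)
  if (is.unsorted(as.numeric(series$timestamp))) {
    abort("`series` must be time-ordered.")
  }
  gap <- in_any_interval(series$timestamp, events)
  series$filled <- gap
  if (!any(gap)) {
    return(series)
  }

  vals <- series[[value]]
  # contiguous runs of in-gap points are filled together from shared neighbours
  runs <- rle(gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in which(runs$values)) {
    lo <- starts[i]
    hi <- ends[i]
    before_idx <- which(!gap[seq_len(lo - 1)])
    before <- vals[utils::tail(before_idx, k)]
    after_pool <- if (hi < length(gap)) seq(hi + 1, length(gap)) else integer()
    after_idx <- after_pool[!gap[after_pool]]
    after <- vals[utils::head(after_idx, k)]
    pooled <- c(before, after)
    if (length(pooled) == 0) {
      abort("A gap has no valid neighbouring points on either side.")
    }
    if (length(before) < k || length(after) < k) {
      warn(paste0(
        "Gap at series edge filled from ", length(pooled),
        " neighbouring point(s) instead of ", 2 * k, "."
      ))
    }
    vals[lo:hi] <- mean(pooled)
  }
  series[[value]] <- vals
  series
}
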