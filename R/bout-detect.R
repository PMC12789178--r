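#' Parse a nest-temperature logger export
#'
#' Reads a two-column comma-separated file (ISO-8601 datetime, temperature in
#' degrees C, header row) into a validated trace. The logger accuracy is
#' inferred as the minimal positive step between distinct recorded values
#' unless supplied.
#'
#' @param path path to the export file.
#' @param nest_id identifier for the nest (default: file name).
#' @param accuracy quantisation step in degrees C; inferred if `NULL`.
#' @param ambient optional ambient reference tibble (`timestamp`,
#'   `temperature` on a 30-min grid) to attach.
#' @return a `nestclock_trace`.
#' @export
parse_logger_export <- function(path, nest_id = NULL, accuracy = NULL,
                                ambient = NULL) {
  if (is.null(nest_id)) nest_id <- tools::file_path_sans_ext(basename(path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    readr::col_character(), readr::col_double()
  ), col_names = TRUE, progress = FALSE)
  names(raw)[1:2] <- c("timestamp", "temperature")
  ts <- as.POSIXct(strptime(raw$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(ts)
  if (any(alt)) {
    ts[alt] <- as.POSIXct(strptime(raw$timestamp[alt], "%Y-%m-%d %H:%M:%S",
                                   tz = "UTC"))
  }
  bad <- which(is.na(ts) | !is.finite(raw$temperature))
  if (length(bad)) {
    abort(paste0("unparseable rows in ", basename(path), " at lines: ",
                 paste(bad + 1L, collapse = ", ")))
  }
  if (any(diff(as.numeric(ts)) <= 0)) {
    dup <- which(diff(as.numeric(ts)) <= 0)
    abort(paste0("non-monotone or duplicated timestamps at lines: ",
                 paste(dup + 2L, collapse = ", ")))
  }
  if (is.null(accuracy)) {
    steps <- diff(sort(unique(raw$temperature)))
    steps <- steps[steps > 1e-9]
    accuracy <- if (length(steps)) min(steps) else 0.0625
  }
  interval <- stats::median(diff(as.numeric(ts))) / 60
  new_trace(ts, raw$temperature, nest_id = nest_id, accuracy = accuracy,
            interval_min = interval, ambient = ambient)
}

#' Attach an ambient reference series to a trace
#'
#' @param trace a `nestclock_trace`.
#' @param ambient tibble with `timestamp`, `temperature`.
#' @return the trace with ambient attached.
#' @export
attach_ambient <- function(trace, ambient) {
  attr(trace, "ambient") <- ambient
  trace
}

# ambient interpolated onto the trace's sampling grid
ambient_on_grid <- function(trace) {
  amb <- attr(trace, "ambient")
  if (is.null(amb)) abort("trace has no ambient reference attached")
  stats::approx(as.numeric(amb$timestamp), amb$temperature,
                xout = as.numeric(trace$timestamp), rule = 2)$y
}

#' Detect the start of nocturnal full incubation
#'
#' Once a female incubates through the night, the nest stays far above
#' ambient during the night window and the day-night activity pattern
#' becomes visible. The start is the first date whose night window holds
#' `nest - ambient >= margin` for at least `min_frac` of the night samples.
#' Onsets are only extracted from this date onward.
#'
#' The night window of a date is its own early morning plus its own late
#' evening (hours `< night_end` or `>= night_start`).
#'
#' @param trace a `nestclock_trace` with ambient attached.
#' @param margin degrees C above ambient that counts as incubation.
#' @param min_frac minimum fraction of qualifying night samples.
#' @param night_start,night_end night window bounds (decimal hours).
#' @return the first incubated `Date`, or `NA` if no night qualifies.
#' @export
detect_incubation_start <- function(trace, margin = 5, min_frac = 0.75,
                                    night_start = 21, night_end = 5) {
  amb <- ambient_on_grid(trace)
  hrs <- hours_since_midnight(trace$timestamp)
  dates <- as.Date(trace$timestamp, tz = "UTC")
  night <- in_night_window(hrs, night_start, night_end)
  excess <- trace$temperature - amb
  by_date <- split(excess[night], dates[night])
  frac <- vapply(by_date, function(x) mean(x >= margin), 0)
  n_samp <- vapply(by_date, length, 0L)
  ok <- frac >= min_frac & n_samp >= 10
  if (!any(ok)) return(as.Date(NA))
  as.Date(names(by_date)[which(ok)[1]])
}

#' Derive nest- and day-specific drop and rise thresholds
#'
#' Real departures must exceed the temperature variation seen in the nest at
#' night (when the female sits continuously) on that date. The drop
#' threshold is the larger of a 0.5 degree C floor and the 95th percentile
#' of absolute successive differences over the date's night window; the rise
#' threshold is derived symmetrically from the date's daytime on-bout
#' segments (daytime samples at least `margin` above ambient). Dates with
#' fewer than 10 night samples fall back to the nest-level pooled threshold
#' and are flagged.
#'
#' @param trace a `nestclock_trace` with ambient attached.
#' @param date `Date` (vectorised).
#' @param floor threshold floor in degrees C (departures are drops greater
#'   than 0.5 degrees C).
#' @param q quantile of the night/day variation used.
#' @param margin degrees C above ambient defining daytime on-bout samples.
#' @param night_start,night_end night window bounds.
#' @return tibble with `date`, `drop_threshold`, `rise_threshold`, `pooled`.
#' @export
derive_thresholds <- function(trace, date, floor = 0.5, q = 0.95,
                              margin = 5, night_start = 21, night_end = 5) {
  amb <- ambient_on_grid(trace)
  hrs <- hours_since_midnight(trace$timestamp)
  dates <- as.Date(trace$timestamp, tz = "UTC")
  night <- in_night_window(hrs, night_start, night_end)
  temp <- trace$temperature
  # daytime on-bout proxy: warm, near the date's daytime plateau, so decay
  # and recovery transients do not inflate the rise threshold
  day <- !night
  day_on <- rep(FALSE, length(temp))
  for (d in unique(dates)) {
    sel <- day & dates == d
    if (any(sel)) {
      top <- quantile(temp[sel], 0.9, na.rm = TRUE)
      day_on[sel] <- (temp[sel] - amb[sel] >= margin) & temp[sel] >= top - 1.5
    }
  }

  # q-quantile of |successive differences| restricted to time-consecutive
  # sample pairs inside the mask
  qdiff <- function(mask) {
    n <- length(temp)
    keep <- mask[-n] & mask[-1]
    d <- abs(diff(temp))[keep]
    if (length(d) < 2) return(NA_real_)
    unname(quantile(d, q, na.rm = TRUE))
  }
  pooled_drop <- qdiff(night)
  pooled_rise <- qdiff(day_on)

  out <- lapply(unique(date), function(d) {
    sel_n <- night & dates == d
    sel_d <- day_on & dates == d
    pooled <- sum(sel_n) < 10
    drop_q <- if (pooled) pooled_drop else qdiff(sel_n)
    rise_q <- if (sum(sel_d) < 10) pooled_rise else qdiff(sel_d)
    tibble::tibble(
      date = d,
      drop_threshold = max(floor, drop_q, na.rm = TRUE),
      rise_threshold = max(floor, rise_q, na.rm = TRUE),
      pooled = pooled
    )
  })
  dplyr::bind_rows(out)
}

# single-pass threshold-crossing scan over one day's samples.
# Returns integer matrix of bouts: state (1 on / 0 off), start, end indices.
# The running on-bout baseline is the maximum over the trailing `window`
# samples of the current bout (so slow drifts cannot accumulate into a
# crossing); an off-bout opens at the first sample lying more than `drop`
# below that baseline while nest-minus-ambient is decreasing AND the
# decline contains a recent fast step (>= 0.75*drop over one sample, the
# signature of a real departure as opposed to accumulated noise); the bout
# start is backtracked to the first sample of the sustained decline
# (successive steps >= drop/2). An off-bout closes on the symmetric rise
# crossing, or as soon as the temperature recovers to within drop/2 of the
# pre-departure level (absolute recovery), whichever happens first.
scan_bouts <- function(temp, excess, drop, rise, window = 5L) {
  n <- length(temp)
  states <- integer(0); starts <- integer(0); ends <- integer(0)
  push <- function(st, s, e) {
    states <<- c(states, st); starts <<- c(starts, s); ends <<- c(ends, e)
  }
  state <- 1L; bout_start <- 1L; off_ref <- temp[1]
  if (n >= 2) {
    for (i in 2:n) {
      lo <- max(bout_start, i - window)
      win <- lo:(i - 1L)
      fast_drop <- temp[i - 1L] - temp[i] >= 0.75 * drop ||
        (i > 2L && temp[i - 2L] - temp[i - 1L] >= 0.75 * drop)
      fast_rise <- temp[i] - temp[i - 1L] >= 0.75 * rise ||
        (i > 2L && temp[i - 1L] - temp[i - 2L] >= 0.75 * rise)
      if (state == 1L) {
        base <- win[which.max(temp[win])]
        if (temp[base] - temp[i] > drop && excess[i] < excess[base] &&
            fast_drop) {
          s <- i
          while (s > bout_start + 1L && temp[s - 1L] - temp[s] >= drop / 2) {
            s <- s - 1L
          }
          push(1L, bout_start, s - 1L)
          state <- 0L; bout_start <- s
          # robust plateau level for the absolute-recovery closure
          off_ref <- stats::median(temp[win])
        }
      } else {
        base <- win[which.min(temp[win])]
        if ((temp[i] - temp[base] > rise && fast_rise) ||
            temp[i] >= off_ref - drop / 2) {
          s <- i
          while (s > bout_start + 1L && temp[s] - temp[s - 1L] >= rise / 2) {
            s <- s - 1L
          }
          push(0L, bout_start, s - 1L)
          state <- 1L; bout_start <- s
        }
      }
    }
  }
  push(state, bout_start, n)
  merge_shallow_offbouts(cbind(state = states, start = starts, end = ends),
                         temp, drop)
}

# a genuine absence keeps the nest persistently below the pre-departure
# level; off-bouts whose median temperature stays within `drop` of it are
# single-sample noise excursions and are folded back into the on-bout
merge_shallow_offbouts <- function(m, temp, drop) {
  if (!nrow(m)) return(m)
  off <- which(m[, "state"] == 0L)
  shallow <- off[vapply(off, function(k) {
    ref <- temp[max(1L, m[k, "start"] - 1L)]
    stats::median(temp[m[k, "start"]:m[k, "end"]]) > ref - drop
  }, TRUE)]
  if (length(shallow)) m[shallow, "state"] <- 1L
  # merge adjacent bouts with equal state
  keep <- m[1, , drop = FALSE]
  for (r in seq_len(nrow(m))[-1]) {
    if (m[r, "state"] == keep[nrow(keep), "state"]) {
      keep[nrow(keep), "end"] <- m[r, "end"]
    } else {
      keep <- rbind(keep, m[r, , drop = FALSE])
    }
  }
  keep
}

#' Detect on- and off-bouts for given dates
#'
#' Partitions each analysed day into alternating on-bouts (female present)
#' and off-bouts (female absent) using the nest- and day-specific
#' thresholds: an off-bout opens when the cumulative temperature decline
#' since the running on-bout maximum exceeds the drop threshold while the
#' nest is cooling toward ambient, and closes when the cumulative rise since
#' the running off-bout minimum exceeds the rise threshold. Bout starts are
#' backtracked to the first sample of the sustained decline (or rise), so
#' boundaries land within one sample of the true departure for drops well
#' above the threshold. Days containing a timestamp gap of two or more
#' sampling intervals are invalidated (no bouts returned, flagged in the
#' `"qc"` attribute).
#'
#' @param trace a `nestclock_trace` with ambient attached.
#' @param thresholds tibble from [derive_thresholds()] (or a data frame with
#'   `date`, `drop_threshold`, `rise_threshold`).
#' @param date `Date` vector of days to analyse; defaults to
#'   `thresholds$date`.
#' @param window_min width (minutes) of the trailing window over which the
#'   running bout baseline (max in an on-bout, min in an off-bout) is taken.
#' @return tibble with one row per bout: `nest_id`, `date`, `state`
#'   (`"on"`/`"off"`), `start_idx`, `end_idx` (sample indices within the
#'   day), `start`, `end` (POSIXct), `start_hour`, `duration_min`. QC rows
#'   for invalidated days are attached as attribute `"qc"`.
#' @export
detect_bouts <- function(trace, thresholds, date = NULL, window_min = 15) {
  if (is.null(attr(trace, "ambient"))) {
    abort("detect_bouts() needs an ambient reference aligned to the trace")
  }
  amb <- ambient_on_grid(trace)
  if (is.null(date)) date <- thresholds$date
  dates_all <- as.Date(trace$timestamp, tz = "UTC")
  interval <- attr(trace, "interval_min") %||% 3
  excess <- trace$temperature - amb

  qc <- tibble::tibble(date = as.Date(character()), reason = character())
  res <- list()
  for (d in as.list(sort(unique(date)))) {
    idx <- which(dates_all == d)
    if (!length(idx)) {
      qc <- dplyr::bind_rows(qc, tibble::tibble(date = d, reason = "no_samples"))
      next
    }
    gaps <- diff(as.numeric(trace$timestamp[idx])) / 60
    if (any(gaps >= 2 * interval)) {
      qc <- dplyr::bind_rows(qc, tibble::tibble(date = d, reason = "gap"))
      next
    }
    th <- thresholds[thresholds$date == d, ]
    if (!nrow(th)) abort(paste0("no thresholds for date ", format(d)))
    m <- scan_bouts(trace$temperature[idx], excess[idx],
                    th$drop_threshold[1], th$rise_threshold[1],
                    window = max(1L, as.integer(round(window_min / interval))))
    st <- unname(m[, "start"]); en <- unname(m[, "end"])
    res[[length(res) + 1]] <- tibble::tibble(
      nest_id = attr(trace, "nest_id"),
      date = d,
      state = ifelse(unname(m[, "state"]) == 1L, "on", "off"),
      start_idx = st,
      end_idx = en,
      start = trace$timestamp[idx][st],
      end = trace$timestamp[idx][en],
      start_hour = hours_since_midnight(trace$timestamp[idx][st]),
      duration_min = (en - st + 1L) * interval
    )
  }
  out <- if (length(res)) dplyr::bind_rows(res) else tibble::tibble(
    nest_id = character(), date = as.Date(character()), state = character(),
    start_idx = integer(), end_idx = integer(),
    start = as.POSIXct(character()), end = as.POSIXct(character()),
    start_hour = numeric(), duration_min = numeric()
  )
  attr(out, "qc") <- qc
  out
}

#' Extract daily activity onsets from a bout series
#'
#' The activity onset of a date is the start time of the first off-bout
#' following the longest nocturnal on-bout (the night sit). Dates later than
#' `max_chick_day` days after (expected) hatch are excluded; when the hatch
#' date is unobserved it is taken as clutch completion (incubation start)
#' plus 13 days, i.e. hatching on incubation day 14.
#'
#' @param bouts tibble from [detect_bouts()].
#' @param brood one-row data frame with `female_id`, `brood_id`,
#'   `nest_box`, `year`, `incubation_start` (April day) and optionally
#'   `hatch_date` (April day, `NA` if unobserved).
#' @param max_chick_day last chick day with usable activity patterns.
#' @param night_end end of the night window (decimal hours); a nocturnal
#'   on-bout is one that starts before this hour.
#' @return tibble of onset records (`female_id`, `brood_id`, `nest_box`,
#'   `year`, `date` in April days, `onset` decimal hours, `breeding_day`,
#'   `stage`), with omitted dates logged in attribute `"qc"`.
#' @export
extract_daily_onsets <- function(bouts, brood, max_chick_day = 13,
                                 night_end = 5) {
  stopifnot(nrow(brood) == 1)
  hatch_ref <- brood$hatch_date
  if (is.null(hatch_ref) || is.na(hatch_ref)) {
    hatch_ref <- brood$incubation_start + 13L
  }
  qc <- dplyr::bind_rows(
    attr(bouts, "qc") %||% tibble::tibble(date = as.Date(character()),
                                          reason = character())
  )
  recs <- list()
  for (d in as.list(sort(unique(bouts$date)))) {
    day <- bouts[bouts$date == d, ]
    aday <- april_day(d)
    bd <- aday - hatch_ref
    if (bd > max_chick_day) {
      qc <- dplyr::bind_rows(qc, tibble::tibble(date = d, reason = "past_max_chick_day"))
      next
    }
    night_on <- day[day$state == "on" & day$start_hour < night_end, ]
    if (!nrow(night_on)) {
      qc <- dplyr::bind_rows(qc, tibble::tibble(date = d, reason = "no_nocturnal_on_bout"))
      next
    }
    anchor <- night_on$end_idx[which.max(night_on$duration_min)]
    offs <- day[day$state == "off" & day$start_idx > anchor, ]
    if (!nrow(offs)) {
      qc <- dplyr::bind_rows(qc, tibble::tibble(date = d, reason = "no_off_bout"))
      next
    }
    recs[[length(recs) + 1]] <- tibble::tibble(
      female_id = brood$female_id,
      brood_id = brood$brood_id,
      nest_box = brood$nest_box,
      year = brood$year,
      date = aday,
      onset = offs$start_hour[1],
      breeding_day = as.integer(bd),
      stage = if (bd < 0) "incubation" else "provisioning"
    )
  }
  out <- if (length(recs)) dplyr::bind_rows(recs) else tibble::tibble(
    female_id = character(), brood_id = character(), nest_box = character(),
    year = integer(), date = integer(), onset = numeric(),
    breeding_day = integer(), stage = character()
  )
  attr(out, "qc") <- qc
  out
}
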