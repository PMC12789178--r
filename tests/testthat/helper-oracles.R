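# Independent brute-force implementations used as oracles, plus small
# fixture builders. The oracle recomputes every quantity from its
# definition at each sample (no incremental state), so agreement with the
# package's single-pass scan is a real check.

# exhaustive threshold-crossing scan over one day's samples
oracle_bouts <- function(temp, excess, drop, rise, window = 5L) {
  n <- length(temp)
  states <- integer(0); starts <- integer(0); ends <- integer(0)
  state <- 1L; bs <- 1L; ref <- temp[1]
  for (i in seq_len(n)[-1]) {
    win <- seq.int(max(bs, i - window), i - 1L)
    recent <- diff(temp[seq.int(max(1L, i - 2L), i)])
    if (state == 1L) {
      bidx <- win[which.max(temp[win])]
      open <- (max(temp[win]) - temp[i] > drop) &&
        (excess[i] < excess[bidx]) &&
        any(-recent >= 0.75 * drop)
      if (open) {
        s <- i
        while (s > bs + 1L && temp[s - 1L] - temp[s] >= drop / 2) s <- s - 1L
        states <- c(states, 1L); starts <- c(starts, bs); ends <- c(ends, s - 1L)
        state <- 0L; ref <- stats::median(temp[win]); bs <- s
      }
    } else {
      close <- (temp[i] - min(temp[win]) > rise && any(recent >= 0.75 * rise)) ||
        temp[i] >= ref - drop / 2
      if (close) {
        s <- i
        while (s > bs + 1L && temp[s] - temp[s - 1L] >= rise / 2) s <- s - 1L
        states <- c(states, 0L); starts <- c(starts, bs); ends <- c(ends, s - 1L)
        state <- 1L; bs <- s
      }
    }
  }
  states <- c(states, state); starts <- c(starts, bs); ends <- c(ends, n)
  # suppress off-bouts that never stay below the pre-departure level
  for (k in which(states == 0L)) {
    lvl <- temp[max(1L, starts[k] - 1L)]
    if (stats::median(temp[starts[k]:ends[k]]) > lvl - drop) states[k] <- 1L
  }
  # merge equal-state neighbours
  keep <- 1L
  for (r in seq_along(states)[-1]) {
    if (states[r] == states[keep[length(keep)]]) {
      ends[keep[length(keep)]] <- ends[r]
    } else {
      keep <- c(keep, r)
    }
  }
  cbind(state = states[keep], start = starts[keep], end = ends[keep])
}

# build a single-day nestclock trace from a raw temperature vector through
# the public parsing interface (3-min cadence, constant ambient)
make_day_trace <- function(temp, date = as.Date("2021-04-22"), ambient_temp = 8) {
  ts <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
    seq(0, by = 180, length.out = length(temp))
  path <- tempfile(fileext = ".csv")
  readr::write_csv(
    data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"), temperature = temp),
    path
  )
  amb <- tibble::tibble(
    timestamp = seq(min(ts), max(ts) + 1800, by = 1800),
    temperature = ambient_temp
  )
  tr <- parse_logger_export(path, nest_id = "T1", ambient = amb)
  unlink(path)
  tr
}

flat_thresholds <- function(date, drop = 0.5, rise = 0.5) {
  tibble::tibble(date = date, drop_threshold = drop, rise_threshold = rise,
                 pooled = FALSE)
}

# one synthetic nest: ambient series, programmed morning departure plus two
# daytime off-bouts per day, temperature trace and the programmed truth
make_programmed_nest <- function(seed, accuracy = 0.0625, n_days = 6,
                                 onset_hour = 5.5, drop = 2) {
  cfg <- sim_config(seed = seed, logger_accuracy = accuracy)
  amb <- simulate_ambient(n_days, seed = seed + 1000,
                          start_date = as.Date("2021-04-20"))
  days <- sort(unique(as.Date(amb$timestamp, tz = "UTC")))
  sch <- do.call(rbind, lapply(days[-1], function(d) {
    data.frame(date = d, start_hour = c(onset_hour, 9.0, 14.25),
               duration_min = c(12, 18, 9), drop = drop)
  }))
  trace <- simulate_nest_temperature(sch, amb, cfg,
                                     incubation_from = days[2], seed = seed)
  list(cfg = cfg, trace = trace, days = days, schedule = sch,
       incubation_from = days[2], onset_hour = onset_hour)
}

# run detection end-to-end on a programmed nest, returning onset errors (min)
detect_programmed_onsets <- function(nest) {
  start <- detect_incubation_start(nest$trace)
  dates <- nest$days[nest$days >= start]
  th <- derive_thresholds(nest$trace, dates)
  bouts <- detect_bouts(nest$trace, th)
  brood <- data.frame(female_id = "F1", brood_id = "B1", nest_box = "NB1",
                      year = 2021,
                      incubation_start = april_day(nest$incubation_from),
                      hatch_date = NA)
  ons <- extract_daily_onsets(bouts, brood)
  (ons$onset - nest$onset_hour) * 60
}
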