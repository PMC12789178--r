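test_that("logger exports parse, validate and infer accuracy", {
  temp <- rep(c(35.0, 34.5, 35.0), length.out = 480)
  tr <- make_day_trace(temp)
  expect_s3_class(tr, "nestclock_trace")
  expect_equal(nrow(tr), 480)
  expect_equal(attr(tr, "accuracy"), 0.5)

  ts <- as.POSIXct("2021-04-22 00:00:00", tz = "UTC") + c(0, 180, 180, 360)
  path <- tempfile(fileext = ".csv")
  readr::write_csv(data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
                              temperature = 35), path)
  expect_error(parse_logger_export(path), "non-monotone|duplicated")

  readr::write_csv(data.frame(timestamp = c("2021-04-22T00:00:00", "garbage"),
                              temperature = c(35, 35)), path)
  expect_error(parse_logger_export(path), "lines: 3")
})

test_that("incubation start is found at the first incubated night", {
  amb <- simulate_ambient(5, seed = 8, noise_sd = 0)
  days <- sort(unique(as.Date(amb$timestamp, tz = "UTC")))
  ts <- seq(min(amb$timestamp), max(amb$timestamp), by = 180)
  ambg <- approx(as.numeric(amb$timestamp), amb$temperature,
                 xout = as.numeric(ts), rule = 2)$y
  # nest equal to ambient throughout -> never starts
  path <- tempfile(fileext = ".csv")
  readr::write_csv(data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
                              temperature = round(ambg, 4)), path)
  tr <- attach_ambient(parse_logger_export(path), amb)
  expect_true(is.na(detect_incubation_start(tr)))

  # heated from day 3 onward -> start = day 3
  heated <- ambg + ifelse(as.Date(ts, tz = "UTC") >= days[3], 10, 0)
  readr::write_csv(data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S"),
                              temperature = round(heated, 4)), path)
  tr2 <- attach_ambient(parse_logger_export(path), amb)
  expect_equal(detect_incubation_start(tr2), days[3])
})

test_that("programmed incubation starts are recovered across seeds", {
  hits <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s)
    amb <- simulate_ambient(5, seed = s + 500)
    days <- sort(unique(as.Date(amb$timestamp, tz = "UTC")))
    k <- 2 + (s %% 3)
    sch <- tibble::tibble(date = max(days), start_hour = 6,
                          duration_min = 12, drop = 6)
    tr <- simulate_nest_temperature(sch, amb, cfg,
                                    incubation_from = days[k], seed = s)
    identical(detect_incubation_start(tr), days[k])
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("thresholds floor at 0.5, track night noise, and are deterministic", {
  flat <- make_day_trace(rep(35, 480))
  th <- derive_thresholds(flat, as.Date("2021-04-22"))
  expect_equal(th$drop_threshold, 0.5)
  expect_false(th$pooled)

  set.seed(42)
  noisy_temp <- 35 + rnorm(480, 0, 0.4)
  noisy <- make_day_trace(noisy_temp)
  th2 <- derive_thresholds(noisy, as.Date("2021-04-22"))
  expect_gt(th2$drop_threshold, 0.5)
  # empirical-quantile oracle over the night samples
  hrs <- seq(0, by = 0.05, length.out = 480)
  night <- hrs < 5 | hrs >= 21
  d <- abs(diff(noisy_temp))
  keep <- night[-480] & night[-1]
  expect_equal(th2$drop_threshold,
               unname(quantile(d[keep], 0.95)), tolerance = 1e-10)

  expect_identical(derive_thresholds(noisy, as.Date("2021-04-22")), th2)
})

test_that("bout detection finds programmed excursions and ignores small dips", {
  d <- as.Date("2021-04-22")
  base <- rep(35, 480)

  no_exc <- detect_bouts(make_day_trace(base), flat_thresholds(d))
  expect_equal(nrow(no_exc), 1)
  expect_equal(no_exc$state, "on")
  expect_equal(no_exc$duration_min, 480 * 3)

  # a 12-min, 6-degree off-bout starting at 05:30 (sample 111)
  prog <- base
  i0 <- 111
  prog[(i0 + 1):(i0 + 4)] <- 35 - 6 * (1 - exp(-(1:4) * 3 / 8))
  prog[(i0 + 5):(i0 + 8)] <- 29 + (35 - 29) * (1 - exp(-(1:4) * 3 / 4))
  b <- detect_bouts(make_day_trace(prog), flat_thresholds(d))
  offs <- b[b$state == "off", ]
  expect_equal(nrow(offs), 1)
  expect_lte(abs(offs$start_idx - (i0 + 1)), 1)
  expect_equal(offs$start_hour, 5.5, tolerance = 0.051)

  dip <- base
  dip[200:205] <- 34.7 # 0.3 degrees: below threshold
  b2 <- detect_bouts(make_day_trace(dip), flat_thresholds(d))
  expect_equal(sum(b2$state == "off"), 0)

  # missing ambient alignment errors
  tr <- make_day_trace(base)
  attr(tr, "ambient") <- NULL
  expect_error(detect_bouts(tr, flat_thresholds(d)), "ambient")
})

test_that("within a day the bout partition conserves the day span", {
  nest <- make_programmed_nest(seed = 31)
  th <- derive_thresholds(nest$trace, nest$days)
  b <- detect_bouts(nest$trace, th)
  trace_dates <- as.Date(nest$trace$timestamp, tz = "UTC")
  for (d in unique(b$date)) {
    day <- b[b$date == d, ]
    expect_equal(sum(day$end_idx - day$start_idx + 1), sum(trace_dates == d))
    expect_true(all(day$start_idx[-1] == day$end_idx[-nrow(day)] + 1))
    expect_true(all(day$state[-1] != day$state[-nrow(day)]))
  }
})

test_that("raising the drop threshold never adds off-bouts", {
  for (s in 1:8) {
    nest <- make_programmed_nest(seed = 200 + s)
    d <- nest$days[3]
    counts <- vapply(c(0.5, 0.8, 1.2, 2, 4), function(dr) {
      b <- detect_bouts(nest$trace, flat_thresholds(d, drop = dr, rise = dr))
      sum(b$state == "off")
    }, 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("gap-broken days are invalidated, not analysed", {
  temp <- rep(35, 480)
  tr <- make_day_trace(temp)
  tr2 <- tr[-(100:110), ]
  for (a in names(attributes(tr))) {
    if (!a %in% c("row.names", "names")) attr(tr2, a) <- attr(tr, a)
  }
  b <- detect_bouts(tr2, flat_thresholds(as.Date("2021-04-22")))
  expect_equal(nrow(b), 0)
  expect_equal(attr(b, "qc")$reason, "gap")
})

test_that("daily onsets come from the first off-bout after the night sit", {
  nest <- make_programmed_nest(seed = 33)
  start <- detect_incubation_start(nest$trace)
  th <- derive_thresholds(nest$trace, nest$days[nest$days >= start])
  b <- detect_bouts(nest$trace, th)
  brood <- data.frame(female_id = "F1", brood_id = "B1", nest_box = "NB1",
                      year = 2021,
                      incubation_start = april_day(nest$incubation_from),
                      hatch_date = NA)
  ons <- extract_daily_onsets(b, brood)
  expect_true(all(abs(ons$onset - 5.5) <= 0.051))
  expect_true(all(ons$stage == "incubation"))
  # expected hatch = incubation start + 13
  expect_equal(ons$breeding_day,
               ons$date - (april_day(nest$incubation_from) + 13L))

  # an all-day on-bout yields no record for that date but a QC entry
  flat <- make_day_trace(rep(35, 480))
  bf <- detect_bouts(flat, flat_thresholds(as.Date("2021-04-22")))
  of <- extract_daily_onsets(bf, brood)
  expect_equal(nrow(of), 0)
  expect_true("no_off_bout" %in% attr(of, "qc")$reason)

  # dates beyond hatch + max_chick_day are excluded
  brood_late <- brood
  brood_late$hatch_date <- april_day(nest$days[3]) - 14L
  late <- extract_daily_onsets(b, brood_late, max_chick_day = 13)
  expect_true(all(late$date - brood_late$hatch_date <= 13))
})

test_that("detected boundaries match the brute-force oracle on random traces", {
  set.seed(77)
  for (k in 1:50) {
    n <- sample(60:200, 1)
    temp <- 35 + rnorm(n, 0, 0.15)
    # up to three random square excursions
    for (j in seq_len(sample(0:3, 1))) {
      at <- sample(5:(n - 12), 1)
      len <- sample(2:8, 1)
      amp <- runif(1, 1, 8)
      decay <- amp * (1 - exp(-(seq_len(len)) * 3 / 8))
      temp[at:(at + len - 1)] <- temp[at:(at + len - 1)] - decay
      rec <- rev(amp * (1 - exp(-(seq_len(3)) * 3 / 4)))
      idx <- (at + len):min(n, at + len + 2)
      temp[idx] <- temp[idx] - rev(rec)[seq_along(idx)]
    }
    temp <- round(temp / 0.0625) * 0.0625
    tr <- make_day_trace(temp)
    b <- detect_bouts(tr, flat_thresholds(as.Date("2021-04-22")))
    amb <- rep(8, n)
    o <- oracle_bouts(temp, temp - amb, 0.5, 0.5)
    expect_equal(b$start_idx, unname(o[, "start"]))
    expect_equal(b$end_idx, unname(o[, "end"]))
    expect_equal(b$state == "off", unname(o[, "state"] == 0L))
  }
})

test_that("re-quantising a fine trace to 0.5 degrees barely moves onsets", {
  for (s in 1:6) {
    nest <- make_programmed_nest(seed = 400 + s, accuracy = 0.0625, drop = 2)
    fine <- detect_programmed_onsets(nest)
    coarse_nest <- nest
    coarse_nest$trace$temperature <-
      round(nest$trace$temperature / 0.5) * 0.5
    attr(coarse_nest$trace, "accuracy") <- 0.5
    coarse <- detect_programmed_onsets(coarse_nest)
    common <- min(length(fine), length(coarse))
    expect_true(all(abs(fine[1:common] - coarse[1:common]) <= 3.01))
  }
})
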