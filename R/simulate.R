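#' Simulation configuration for the synthetic chronotype study
#'
#' Bundles every knob of the synthetic-data generator into a validated list.
#' The defaults describe the study conditions the package is built around: a
#' three-year island population of female great tits whose daily activity
#' onsets carry female, female-by-year, nest-box and residual variance
#' components on the standardised scale, and whose lay dates respond
#' quadratically to latent chronotype.
#'
#' Variances are on the squared standardised-onset scale (z^2); the defaults
#' `v_female = 0.15`, `v_female_year = 0.06`, `v_nestbox = 0` and
#' `v_residual = 0.79` sum to 1 and correspond to across-year repeatability
#' 0.15 and within-year repeatability 0.21. The lay-date link defaults
#' (`quad_laydate_effect = 4.095` days/z^2, `linear_laydate_effect = 0.239`
#' days/z, residual SD 5 days) make extreme chronotypes breed later.
#'
#' @param seed master seed; every stream derives a sub-seed from it.
#' @param n_females number of females (each present in all years).
#' @param n_years number of breeding seasons.
#' @param onsets_per_female onsets measured per female per year, on
#'   consecutive dates from incubation start.
#' @param v_female,v_female_year,v_nestbox,v_residual variance components of
#'   the generated onsets (z^2 units).
#' @param chronotype_sd SD of the latent chronotype C (z units).
#' @param quad_laydate_effect,linear_laydate_effect lay-date response to C^2
#'   and C (days per z^2 / per z).
#' @param laydate_resid_sd residual SD of lay date (days).
#' @param laydate_intercept population mean lay date in April days for the
#'   reference year.
#' @param year_effects per-year lay-date offsets (days); length `n_years`.
#' @param clutch_intercept,clutch_laydate_slope,clutch_sd clutch-size model:
#'   eggs at the year-mean lay date, eggs per day of within-year lay-date
#'   deviation, residual SD.
#' @param onset_intercept mean onset (decimal hours since midnight).
#' @param year_onset_effects per-year onset offsets (hours); length
#'   `n_years`.
#' @param april_day_slope onset trend per April day (default 0: no date
#'   trend beyond the year effect).
#' @param breeding_day_lin,breeding_day_quad onset response to breeding day
#'   (days relative to expected hatch) and its square.
#' @param clutch_chron_lin,fledge_chron_lin,second_chron_lin,weight_chron_lin
#'   optional chronotype effects on clutch size, fledging rate (logit),
#'   second-brood probability (logit) and female weight; all default 0 (no
#'   effect), matching the null expectations the selection suite is
#'   calibrated against.
#' @param unhatched_rate,missed_obs_rate,fledge_rate per-egg hatch-failure
#'   probability, probability a hatchling is never counted at a nest check,
#'   per-hatchling fledging probability.
#' @param desertion_rate,prehatch_failure_rate,brood_failure_rate
#'   probabilities of desertion during logger exchange, of whole-brood
#'   failure before hatching, and of whole-brood failure after hatching.
#' @param second_brood_base baseline second-brood probability for a
#'   successful first brood (probability scale).
#' @param heavy_tail_prob,heavy_tail_scale optional contamination: with this
#'   probability an onset is shifted earlier by an Exp(scale) draw (hours);
#'   default off.
#' @param logger_accuracy logger quantisation step, degrees C (0.0625 or
#'   0.5 in the field deployments).
#' @param sampling_interval logger cadence in minutes.
#' @param plateau_temp,noise_sd incubation plateau (degrees C) and sensor
#'   noise SD.
#' @param tau_off,tau_on thermal time constants (minutes) for decay toward
#'   ambient during an off-bout and recovery on return.
#' @param night_start,night_end night window bounds in decimal hours.
#' @param first_year calendar year of the first season.
#'
#' @return an object of class `nestclock_config` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_females = 164L,
                       n_years = 3L,
                       onsets_per_female = 10L,
                       v_female = 0.15,
                       v_female_year = 0.06,
                       v_nestbox = 0,
                       v_residual = 0.79,
                       chronotype_sd = 0.45,
                       quad_laydate_effect = 4.095,
                       linear_laydate_effect = 0.239,
                       laydate_resid_sd = 5,
                       laydate_intercept = 25,
                       year_effects = NULL,
                       clutch_intercept = 9,
                       clutch_laydate_slope = -0.055,
                       clutch_sd = 1.2,
                       onset_intercept = 6.2,
                       year_onset_effects = NULL,
                       april_day_slope = 0,
                       breeding_day_lin = 0,
                       breeding_day_quad = 0,
                       clutch_chron_lin = 0,
                       fledge_chron_lin = 0,
                       second_chron_lin = 0,
                       weight_chron_lin = 0,
                       unhatched_rate = 0.08,
                       missed_obs_rate = 0.1,
                       fledge_rate = 0.88,
                       desertion_rate = 0.03,
                       prehatch_failure_rate = 0.013,
                       brood_failure_rate = 0.08,
                       second_brood_base = 0.3,
                       heavy_tail_prob = 0,
                       heavy_tail_scale = 1,
                       p_multi_year = c(0.84, 0.12, 0.04),
                       box_fidelity = 0.73,
                       logger_accuracy = 0.0625,
                       sampling_interval = 3,
                       plateau_temp = 35,
                       noise_sd = 0.1,
                       tau_off = 8,
                       tau_on = 4,
                       night_start = 21,
                       night_end = 5,
                       first_year = 2020L) {
  cfg <- as.list(environment())
  if (is.null(cfg$year_effects)) {
    cfg$year_effects <- if (n_years >= 1) c(0, 4, -2, rep(0, max(0, n_years - 3)))[seq_len(n_years)] else numeric()
  }
  if (is.null(cfg$year_onset_effects)) {
    cfg$year_onset_effects <- if (n_years >= 1) c(0, -0.1, 0.3, rep(0, max(0, n_years - 3)))[seq_len(n_years)] else numeric()
  }
  validate_config(cfg)
  structure(cfg, class = "nestclock_config")
}

validate_config <- function(cfg) {
  check_scalar(cfg$seed, "seed")
  for (f in c("n_females", "n_years", "onsets_per_female")) {
    check_scalar(cfg[[f]], f, lower = 1)
  }
  for (f in c("v_female", "v_female_year", "v_nestbox", "v_residual",
              "chronotype_sd", "laydate_resid_sd", "clutch_sd", "noise_sd",
              "heavy_tail_prob")) {
    check_scalar(cfg[[f]], f, lower = 0)
  }
  for (f in c("logger_accuracy", "sampling_interval", "tau_off", "tau_on",
              "heavy_tail_scale")) {
    check_scalar(cfg[[f]], f, lower = 0, allow_zero = FALSE)
  }
  for (f in c("unhatched_rate", "missed_obs_rate", "fledge_rate",
              "desertion_rate", "prehatch_failure_rate",
              "brood_failure_rate", "second_brood_base")) {
    check_scalar(cfg[[f]], f, lower = 0)
    if (cfg[[f]] > 1) abort(sprintf("config field `%s` must be <= 1", f))
  }
  if (length(cfg$p_multi_year) != 3 || any(cfg$p_multi_year < 0) ||
      abs(sum(cfg$p_multi_year) - 1) > 1e-8) {
    abort("config field `p_multi_year` must be 3 non-negative probabilities summing to 1")
  }
  check_scalar(cfg$box_fidelity, "box_fidelity", lower = 0)
  if (cfg$box_fidelity > 1) abort("config field `box_fidelity` must be <= 1")
  if (length(cfg$year_effects) != cfg$n_years) {
    abort("config field `year_effects` must have length `n_years`")
  }
  if (length(cfg$year_onset_effects) != cfg$n_years) {
    abort("config field `year_onset_effects` must have length `n_years`")
  }
  invisible(cfg)
}

#' Read a simulation configuration from a YAML-like key/value file
#'
#' Accepts a plain `key: value` text file (one level of nesting is
#' flattened); every field of [sim_config()] is addressable. Unknown keys
#' raise an error naming them.
#'
#' @param path file path.
#' @return `nestclock_config`.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = ":"), ""))
  known <- names(formals(sim_config))
  bad <- setdiff(keys, known)
  if (length(bad)) abort(paste0("unknown config keys: ", paste(bad, collapse = ", ")))
  args <- lapply(vals, function(v) {
    if (grepl(",", v)) as.numeric(trimws(strsplit(v, ",")[[1]])) else {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) v else num
    }
  })
  names(args) <- keys
  do.call(sim_config, args)
}

#' Simulate a breeding population with latent chronotypes
#'
#' Draws one latent chronotype per female, then generates one first brood per
#' female per year: lay date responds linearly and quadratically to the
#' latent chronotype, clutch size declines with within-year lay date, and
#' hatching, fledging, desertion and second broods follow the configured
#' rates (chronotype effects on those outcomes default to zero). Nestling
#' biometrics and a female body-condition table are generated alongside.
#'
#' @param config a [sim_config()] object.
#' @return a list of tibbles: `females` (the truth ledger, one row per
#'   female with `latent_chronotype`), `broods`, `nestlings`, `condition`.
#'   Deterministic given `config$seed`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "nestclock_config"))
  cfg <- config
  set.seed(sub_seed(cfg$seed, 1L))

  nf <- as.integer(cfg$n_females)
  ny <- as.integer(cfg$n_years)
  years <- cfg$first_year + seq_len(ny) - 1L

  # staggered careers: most females are measured in a single season, a few
  # in two or three consecutive seasons
  n_present <- pmin(sample(1:3, nf, replace = TRUE, prob = cfg$p_multi_year), ny)
  entry <- vapply(n_present, function(k) sample.int(ny - k + 1L, 1L), 1L)
  females <- tibble::tibble(
    female_id = sprintf("F%04d", seq_len(nf)),
    latent_chronotype = rnorm(nf, 0, cfg$chronotype_sd),
    entry_year = years[entry],
    n_years_present = n_present
  )

  # nest-box careers: a pool larger than the population, high site fidelity
  n_boxes <- max(ceiling(1.25 * nf), 2L)
  box_of <- matrix(NA_integer_, nf, ny)
  for (i in seq_len(nf)) {
    for (j in seq(entry[i], entry[i] + n_present[i] - 1L)) {
      box_of[i, j] <- if (j > entry[i] && runif(1) < cfg$box_fidelity) {
        box_of[i, j - 1L]
      } else {
        sample.int(n_boxes, 1L)
      }
    }
  }

  grid <- females |>
    dplyr::rowwise() |>
    dplyr::mutate(year = list(seq(.data$entry_year,
                                  .data$entry_year + .data$n_years_present - 1L))) |>
    dplyr::ungroup() |>
    tidyr::unnest("year") |>
    dplyr::select("female_id", "year", "latent_chronotype")
  yi <- match(grid$year, years)
  fi <- match(grid$female_id, females$female_id)
  C <- grid$latent_chronotype

  lay <- cfg$laydate_intercept + cfg$year_effects[yi] +
    cfg$linear_laydate_effect * C + cfg$quad_laydate_effect * C^2 +
    rnorm(nrow(grid), 0, cfg$laydate_resid_sd)
  lay <- round(lay)

  broods <- grid |>
    dplyr::mutate(
      brood_id = sprintf("B%s_%s", .data$year, .data$female_id),
      nest_box = sprintf("NB%04d", box_of[cbind(fi, yi)]),
      lay_date = lay
    ) |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(lay_date_dev = .data$lay_date - mean(.data$lay_date)) |>
    dplyr::ungroup()

  clutch <- round(cfg$clutch_intercept +
                    cfg$clutch_laydate_slope * broods$lay_date_dev +
                    cfg$clutch_chron_lin * C +
                    rnorm(nrow(broods), 0, cfg$clutch_sd))
  clutch <- pmin(pmax(clutch, 1L), 14L)

  n <- nrow(broods)
  unhatched <- rbinom(n, clutch, cfg$unhatched_rate)
  prehatch_fail <- runif(n) < cfg$prehatch_failure_rate
  deserted <- !prehatch_fail & runif(n) < cfg$desertion_rate
  hatched_true <- ifelse(prehatch_fail, 0L, clutch - unhatched)
  missed <- rbinom(n, hatched_true, cfg$missed_obs_rate)
  max_obs <- hatched_true - missed

  brood_fail <- runif(n) < cfg$brood_failure_rate
  p_fledge <- plogis(qlogis(cfg$fledge_rate) + cfg$fledge_chron_lin * C)
  fledged <- ifelse(prehatch_fail | deserted | brood_fail, 0L,
                    rbinom(n, hatched_true, p_fledge))
  success <- as.integer(fledged >= 1)

  p_second <- plogis(qlogis(cfg$second_brood_base) -
                       0.12 * broods$lay_date_dev -
                       0.05 * fledged +
                       cfg$second_chron_lin * C)
  second <- ifelse(success == 1L, as.integer(runif(n) < p_second), NA_integer_)

  broods <- broods |>
    dplyr::mutate(
      clutch_size = as.integer(clutch),
      incubation_start = .data$lay_date + .data$clutch_size - 1L,
      hatch_date = ifelse(prehatch_fail, NA_integer_,
                          .data$incubation_start + 13L),
      unhatched_eggs = as.integer(unhatched),
      max_observed_nestlings = as.integer(max_obs),
      n_fledglings = as.integer(fledged),
      fledge_success = success,
      second_brood = second,
      deserted = deserted,
      failed_pre_hatch = prehatch_fail
    ) |>
    dplyr::select(-"lay_date_dev", -"latent_chronotype")

  # nestling biometrics at chick day 14-16 for surviving broods
  meas <- broods |> dplyr::filter(.data$n_fledglings >= 1)
  brood_re <- rnorm(nrow(meas), 0, 0.5)
  nestlings <- meas |>
    dplyr::mutate(
      chick_age = sample(14:16, dplyr::n(), replace = TRUE),
      .brood_re = brood_re,
      time_of_day = runif(dplyr::n(), 10, 18)
    ) |>
    dplyr::select("brood_id", "female_id", "year", "hatch_date",
                  "n_fledglings", "chick_age", "time_of_day", ".brood_re") |>
    tidyr::uncount(weights = meas$n_fledglings) |>
    dplyr::mutate(
      weight = 17 + 0.3 * (.data$chick_age - 15) -
        0.08 * (.data$n_fledglings - 7) + .data$.brood_re +
        rnorm(dplyr::n(), 0, 0.6),
      tarsus = 19.5 + 0.12 * (.data$chick_age - 15) +
        0.5 * .data$.brood_re + rnorm(dplyr::n(), 0, 0.4),
      p3 = 40 + 1.2 * (.data$chick_age - 15) + 2 * .data$.brood_re +
        rnorm(dplyr::n(), 0, 2.5)
    ) |>
    dplyr::select(-".brood_re")

  # female body condition during chick provisioning (one row per female-year)
  tarsus0 <- rnorm(nf, 19.5, 0.45)
  condition <- grid |>
    dplyr::mutate(
      tarsus = tarsus0[fi],
      time_of_day = runif(dplyr::n(), 7, 19),
      weight = 18.5 + 0.05 * .data$time_of_day +
        0.5 * (.data$tarsus - 19.5) +
        cfg$weight_chron_lin * .data$latent_chronotype +
        rnorm(dplyr::n(), 0, 0.7)
    ) |>
    dplyr::select("female_id", "year", "weight", "tarsus", "time_of_day")

  list(females = females, broods = broods,
       nestlings = nestlings, condition = condition)
}

#' Simulate an onset table with known variance components
#'
#' Generates standardised-scale activity onsets for every female-year:
#' `onset = date mean + female + female-year + nest-box + residual`, with the
#' four components drawn from the configured variances. Each female is
#' measured on `onsets_per_female` consecutive dates starting the day after
#' her incubation start (winsorised into the population's central span so
#' that measurement windows overlap and dates are shared by several
#' females).
#'
#' @param config a [sim_config()] object.
#' @param population the list returned by [simulate_population()]; generated
#'   from `config` if missing.
#' @return a tibble of onset records (`female_id`, `brood_id`, `nest_box`,
#'   `year`, `date` in April days, `onset` in decimal hours, `breeding_day`,
#'   `stage`), with the drawn random effects attached as attribute
#'   `"truth"`. Deterministic given `config$seed`.
#' @export
simulate_onsets <- function(config, population = NULL) {
  stopifnot(inherits(config, "nestclock_config"))
  cfg <- config
  if (is.null(population)) population <- simulate_population(cfg)
  if (cfg$onsets_per_female < 1) abort("config field `onsets_per_female` must be >= 1")
  broods <- population$broods
  set.seed(sub_seed(cfg$seed, 2L))

  years <- sort(unique(broods$year))
  fem_ids <- sort(unique(broods$female_id))
  box_ids <- sort(unique(broods$nest_box))
  # the female component of onsets is the latent chronotype, rescaled so its
  # variance is v_female: chronotype drives both lay date and onsets
  latent <- setNames(population$females$latent_chronotype,
                     population$females$female_id)
  scale_f <- if (cfg$chronotype_sd > 0) sqrt(cfg$v_female) / cfg$chronotype_sd else 0
  fem_eff <- latent[fem_ids] * scale_f
  fem_eff[is.na(fem_eff)] <- rnorm(sum(is.na(fem_eff)), 0, sqrt(cfg$v_female))
  box_eff <- setNames(rnorm(length(box_ids), 0, sqrt(cfg$v_nestbox)), box_ids)

  # winsorise measurement windows into the central span so dates overlap
  start0 <- broods$incubation_start + 1L
  lo <- stats::quantile(start0, 0.1, type = 1)
  hi <- stats::quantile(start0, 0.9, type = 1)
  start <- pmin(pmax(start0, lo), hi)

  k <- as.integer(cfg$onsets_per_female)
  fy_eff <- rnorm(nrow(broods), 0, sqrt(cfg$v_female_year))

  onsets <- broods |>
    dplyr::mutate(.start = start, .fy = fy_eff) |>
    dplyr::select("female_id", "brood_id", "nest_box", "year",
                  "hatch_date", "incubation_start", ".start", ".fy") |>
    tidyr::uncount(weights = rep(k, nrow(broods)), .id = ".day") |>
    dplyr::mutate(
      date = .data$.start + .data$.day - 1L,
      hatch_ref = dplyr::coalesce(.data$hatch_date,
                                  .data$incubation_start + 13L),
      breeding_day = .data$date - .data$hatch_ref,
      yi = match(.data$year, years),
      onset = cfg$onset_intercept + cfg$year_onset_effects[.data$yi] +
        cfg$april_day_slope * (.data$date - 25) +
        cfg$breeding_day_lin * .data$breeding_day +
        cfg$breeding_day_quad * .data$breeding_day^2 +
        fem_eff[.data$female_id] + .data$.fy + box_eff[.data$nest_box] +
        rnorm(dplyr::n(), 0, sqrt(cfg$v_residual))
    )

  if (cfg$heavy_tail_prob > 0) {
    contam <- runif(nrow(onsets)) < cfg$heavy_tail_prob
    onsets$onset[contam] <- onsets$onset[contam] -
      stats::rexp(sum(contam), rate = 1 / cfg$heavy_tail_scale)
  }

  out <- onsets |>
    dplyr::mutate(
      onset = unname(pmin(pmax(.data$onset, 0), 23.999)),
      stage = ifelse(.data$breeding_day < 0, "incubation", "provisioning")
    ) |>
    dplyr::select("female_id", "brood_id", "nest_box", "year", "date",
                  "onset", "breeding_day", "stage")

  attr(out, "truth") <- list(
    female_effects = fem_eff,
    female_year_effects = setNames(fy_eff, broods$brood_id),
    nestbox_effects = box_eff
  )
  out
}

#' Chronotype table from the truth ledger
#'
#' Builds the chronotype table a perfect measurement pipeline would produce:
#' each female's latent chronotype, attached to her first simulated year and
#' brood. Used to validate the selection-model machinery independently of
#' onset measurement error.
#'
#' @param population list from [simulate_population()].
#' @return tibble with the [compute_chronotype()] columns.
#' @export
truth_chronotypes <- function(population) {
  population$females |>
    dplyr::transmute(
      female_id = .data$female_id,
      chronotype = .data$latent_chronotype,
      year = .data$entry_year
    ) |>
    dplyr::left_join(
      population$broods |> dplyr::select("female_id", "year", "brood_id"),
      by = c("female_id", "year")
    ) |>
    dplyr::mutate(n_onsets = NA_integer_) |>
    dplyr::select("female_id", "chronotype", "n_onsets", "year", "brood_id")
}

#' Simulate an ambient reference temperature series
#'
#' A smooth diel sinusoid (coldest at 04:00, warmest at 16:00) plus Gaussian
#' noise on a regular 30-minute grid, mimicking the binned-and-averaged
#' ambient loggers deployed alongside the nests.
#'
#' @param days number of days (48 half-hour points per day).
#' @param seed integer seed.
#' @param start_date first day (`Date`).
#' @param mean_temp,amplitude,noise_sd sinusoid mean, half-amplitude and
#'   noise SD in degrees C.
#' @return a tibble with `timestamp` (POSIXct, UTC) and `temperature`.
#' @export
simulate_ambient <- function(days, seed = 1L,
                             start_date = as.Date("2021-04-20"),
                             mean_temp = 8, amplitude = 5, noise_sd = 0.6) {
  check_scalar(days, "days", lower = 1)
  set.seed(sub_seed(seed, 3L))
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  ts <- t0 + seq(0, by = 1800, length.out = 48 * days)
  h <- hours_since_midnight(ts)
  temp <- mean_temp - amplitude * cos(2 * pi * (h - 4) / 24) +
    rnorm(length(ts), 0, noise_sd)
  tibble::tibble(timestamp = ts, temperature = temp)
}

#' Simulate a nest-temperature logger trace from a programmed schedule
#'
#' Produces a quantised 3-minute nest-temperature series: on-bouts relax
#' toward the incubation plateau with time constant `tau_on`, programmed
#' off-bouts decay toward ambient (or toward `plateau - drop` if a finite
#' drop is given) with time constant `tau_off`, nights outside programmed
#' off-bouts are one continuous on-bout, and every value is quantised to the
#' logger accuracy. Before `incubation_from` the nest simply tracks ambient,
#' so incubation onset is detectable as the appearance of the nocturnal
#' plateau.
#'
#' @param schedule tibble of programmed off-bouts with columns `date`
#'   (`Date`), `start_hour` (decimal hours), `duration_min`, and optionally
#'   `drop` (degrees C below plateau to decay toward; default decays to
#'   ambient). Off-bouts within a date must not overlap.
#' @param ambient ambient series from [simulate_ambient()].
#' @param config a [sim_config()] (supplies accuracy, cadence, plateau,
#'   noise and time constants).
#' @param nest_id identifier stored on the trace.
#' @param incubation_from first `Date` of nocturnal incubation (default:
#'   first day of the ambient span).
#' @param seed integer seed for the sensor noise.
#' @return a `nestclock_trace`: a tibble (`timestamp`, `temperature`) with
#'   attributes `nest_id`, `accuracy`, `interval_min` and `ambient`.
#' @export
simulate_nest_temperature <- function(schedule, ambient, config = sim_config(),
                                      nest_id = "N001",
                                      incubation_from = NULL, seed = 1L) {
  stopifnot(inherits(config, "nestclock_config"))
  cfg <- config
  if (nrow(schedule)) {
    if (!all(c("date", "start_hour", "duration_min") %in% names(schedule))) {
      abort("schedule needs columns date, start_hour, duration_min")
    }
    if (!"drop" %in% names(schedule)) schedule$drop <- Inf
    sch <- schedule[order(schedule$date, schedule$start_hour), ]
    ends <- sch$start_hour + sch$duration_min / 60
    if (any(ends > 24)) abort("off-bouts must not cross midnight")
    same_day <- split(seq_len(nrow(sch)), as.character(sch$date))
    for (idx in same_day) {
      if (length(idx) > 1) {
        s <- sch$start_hour[idx]; e <- ends[idx]
        if (any(s[-1] < e[-length(e)])) abort("overlapping off-bouts in schedule")
      }
    }
    schedule <- sch
  } else {
    schedule <- tibble::tibble(date = as.Date(character()),
                               start_hour = numeric(),
                               duration_min = numeric(), drop = numeric())
  }

  set.seed(sub_seed(seed, 4L))
  dt <- cfg$sampling_interval
  t0 <- min(ambient$timestamp)
  t1 <- max(ambient$timestamp)
  ts <- seq(t0, t1, by = dt * 60)
  amb <- stats::approx(as.numeric(ambient$timestamp), ambient$temperature,
                       xout = as.numeric(ts), rule = 2)$y
  dates <- as.Date(ts, tz = "UTC")
  hrs <- hours_since_midnight(ts)
  if (is.null(incubation_from)) incubation_from <- min(dates)

  # per-sample off-bout membership and decay target
  off <- rep(FALSE, length(ts))
  target <- rep(NA_real_, length(ts))
  if (nrow(schedule)) {
    for (r in seq_len(nrow(schedule))) {
      # decay begins in the interval after the departure instant, so the
      # sample at start_hour is the last plateau sample
      sel <- dates == schedule$date[r] &
        hrs > schedule$start_hour[r] &
        hrs <= schedule$start_hour[r] + schedule$duration_min[r] / 60
      off[sel] <- TRUE
      target[sel] <- cfg$plateau_temp - schedule$drop[r]
    }
  }

  incub <- dates >= incubation_from
  temp <- numeric(length(ts))
  state <- if (incub[1]) cfg$plateau_temp else amb[1]
  a_on <- 1 - exp(-dt / cfg$tau_on)
  a_off <- 1 - exp(-dt / cfg$tau_off)
  for (i in seq_along(ts)) {
    if (!incub[i]) {
      state <- amb[i] + 1
    } else if (off[i]) {
      tgt <- max(amb[i], target[i])
      state <- state + (tgt - state) * a_off
    } else {
      state <- state + (cfg$plateau_temp - state) * a_on
    }
    temp[i] <- state
  }
  temp <- quantise_temp(temp + rnorm(length(temp), 0, cfg$noise_sd),
                        cfg$logger_accuracy)

  new_trace(ts, temp, nest_id = nest_id, accuracy = cfg$logger_accuracy,
            interval_min = dt, ambient = ambient)
}

# constructor for the trace container
new_trace <- function(timestamp, temperature, nest_id, accuracy,
                      interval_min, ambient = NULL) {
  out <- tibble::tibble(timestamp = timestamp, temperature = temperature)
  class(out) <- c("nestclock_trace", class(out))
  attr(out, "nest_id") <- nest_id
  attr(out, "accuracy") <- accuracy
  attr(out, "interval_min") <- interval_min
  attr(out, "ambient") <- ambient
  out
}

#' @export
print.nestclock_trace <- function(x, ...) {
  cat(sprintf("<nestclock_trace> nest %s, %d samples at %g min, accuracy %g degC\n",
              attr(x, "nest_id"), nrow(x), attr(x, "interval_min"),
              attr(x, "accuracy")))
  NextMethod()
}

#' Write a trace as a logger-export text file
#'
#' Two comma-separated columns, ISO-8601 timestamp and temperature, with a
#' header, mimicking an iButton export.
#'
#' @param trace a `nestclock_trace`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_logger_export <- function(trace, path) {
  df <- data.frame(
    timestamp = format(trace$timestamp, "%Y-%m-%dT%H:%M:%S"),
    temperature = trace$temperature
  )
  readr::write_csv(df, path)
  invisible(path)
}
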