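make_onsets <- function(onset, date = 20, year = 2021,
                        female = sprintf("F%02d", seq_along(onset))) {
  tibble::tibble(
    female_id = female,
    brood_id = paste0("B", female), nest_box = paste0("N", female),
    year = year, date = date, onset = onset,
    breeding_day = -5L, stage = "incubation"
  )
}

test_that("standardisation reproduces hand-computed z-scores", {
  z1 <- standardise_onsets(make_onsets(c(5, 6, 7)))
  expect_equal(z1$z, c(-1, 0, 1))
  expect_equal(z1$date_n, rep(3L, 3))

  # independently computed: mean 6.36667, sample SD 0.47258
  z2 <- standardise_onsets(make_onsets(c(6.0, 6.2, 6.9)))
  expect_equal(z2$date_mean[1], 6.366667, tolerance = 1e-6)
  expect_equal(z2$date_sd[1], 0.4725816, tolerance = 1e-6)
  expect_equal(z2$z, c(-0.776, -0.353, 1.129), tolerance = 5e-4)
})

test_that("degenerate and thin dates are dropped with a log", {
  zero_sd <- standardise_onsets(make_onsets(c(6, 6, 6)))
  expect_equal(nrow(zero_sd), 0)
  expect_equal(attr(zero_sd, "dropped")$reason, "zero_sd")

  thin <- standardise_onsets(make_onsets(c(5, 7)))
  expect_equal(nrow(thin), 0)
  expect_equal(attr(thin, "dropped")$reason, "too_few_females")

  dup <- dplyr::bind_rows(make_onsets(c(5, 6, 7)),
                          make_onsets(8, female = "F01"))
  expect_error(standardise_onsets(dup), "duplicate")
})

test_that("per-date z has mean 0, SD 1 and is affine invariant", {
  cfg <- sim_config(seed = 21, n_females = 50)
  ons <- simulate_onsets(cfg)
  std <- standardise_onsets(ons)
  agg <- std |>
    dplyr::group_by(.data$year, .data$date) |>
    dplyr::summarise(m = mean(.data$z), s = sd(.data$z), .groups = "drop")
  expect_lt(max(abs(agg$m)), 1e-9)
  expect_lt(max(abs(agg$s - 1)), 1e-9)

  scaled <- ons |> dplyr::mutate(onset = 2 * .data$onset)
  expect_identical(standardise_onsets(scaled)$z, std$z)
  shifted <- ons |> dplyr::mutate(onset = 1.5 + 2 * .data$onset)
  expect_lt(max(abs(standardise_onsets(shifted)$z - std$z)), 1e-9)
})

test_that("the brood filter counts removals and is idempotent", {
  # ten broods; three measured on a single date only
  set.seed(5)
  ons <- dplyr::bind_rows(
    make_onsets(rnorm(10, 6, 0.3), date = 21,
                female = sprintf("F%02d", 1:10)),
    make_onsets(rnorm(7, 6, 0.3), date = 22,
                female = sprintf("F%02d", 1:7))
  )
  std <- standardise_onsets(ons)
  f1 <- filter_measurement_set(std)
  expect_equal(sort(unique(f1$brood_id)), sprintf("BF%02d", 1:7))
  expect_equal(attr(f1, "removed")$n_broods_removed, 3)
  f2 <- filter_measurement_set(f1)
  expect_equal(f2$z, f1$z)
  expect_equal(attr(f2, "removed")$n_broods_removed, 0)
})

test_that("chronotype uses the first brood of the first measured year", {
  std <- tibble::tibble(
    female_id = "F1",
    brood_id = c("B2", "B2", "B1", "B1", "B3", "B3"),
    year = c(2021L, 2021L, 2021L, 2021L, 2022L, 2022L),
    date = c(25L, 26L, 10L, 11L, 20L, 21L),
    z = c(1, 1, 0.5, -0.5, 2, 2)
  )
  broods <- tibble::tibble(
    brood_id = c("B1", "B2", "B3"),
    lay_date = c(5, 20, 12),
    incubation_start = c(12, 28, 20)
  )
  ch <- compute_chronotype(std, broods = broods)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$brood_id, "B1")   # earliest lay date in first year
  expect_equal(ch$year, 2021L)
  expect_equal(ch$chronotype, 0)    # mean of +0.5 and -0.5
  expect_equal(ch$n_onsets, 2L)

  # exclusion list removes experimental females entirely
  expect_equal(nrow(compute_chronotype(std, broods, exclude = "F1")), 0)
})

test_that("chronotypes on null simulations are centred at zero", {
  cfg <- sim_config(seed = 22, n_females = 250, n_years = 1,
                    p_multi_year = c(1, 0, 0))
  std <- filter_measurement_set(standardise_onsets(simulate_onsets(cfg)))
  ch <- compute_chronotype(std)
  expect_lt(abs(mean(ch$chronotype)), 3 * sd(ch$chronotype) / sqrt(nrow(ch)) + 0.02)
  expect_true(all(abs(ch$chronotype) <= tapply(abs(std$z), std$female_id, max)[ch$female_id] + 1e-12))
})

test_that("lay date back-calculation follows the one-egg-per-day rule", {
  expect_equal(estimate_lay_date(30, 8), 23)
  expect_equal(estimate_lay_date(15, 10), 6)
  expect_equal(estimate_lay_date(12, 1), 12)
  expect_equal(estimate_lay_date(c(30, 15), c(8, 10)), c(23, 6))
  expect_error(estimate_lay_date(30, 0), "clutch_size")
})

test_that("within-year centring zeroes every year mean and keeps originals", {
  broods <- tibble::tibble(
    year = rep(c(2020L, 2021L), each = 3),
    lay_date = c(18, 20, 22, 28, 30, 32),
    hatch_date = c(40, 41, 42, 50, 51, 52)
  )
  cc <- centre_covariates(broods)
  expect_equal(cc$lay_date, broods$lay_date)
  expect_equal(cc$lay_date_c, c(-2, 0, 2, -2, 0, 2))
  # a day-25 record centres differently under each year mean (20 vs 30)
  one <- centre_covariates(tibble::tibble(year = c(2020L, 2021L),
                                          lay_date = c(25, 25)) |>
                             dplyr::bind_rows(broods[, c("year", "lay_date")]))
  expect_equal(one$lay_date_c[1:2], c(25 - mean(c(25, 18, 20, 22)),
                                      25 - mean(c(25, 28, 30, 32))))

  set.seed(1)
  rand <- tibble::tibble(year = sample(2020:2022, 200, TRUE),
                         lay_date = runif(200, 10, 40))
  rc <- centre_covariates(rand, "lay_date")
  mu <- tapply(rc$lay_date_c, rc$year, mean)
  expect_lt(max(abs(mu)), 1e-9)
})
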