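suite_from_seed <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  pop <- simulate_population(cfg)
  list(pop = pop,
       suite = build_model_suite(truth_chronotypes(pop), pop$broods,
                                 nestlings = pop$nestlings,
                                 condition = pop$condition))
}

test_that("hatchling estimates equal the half-uncertainty formula and its bounds", {
  expect_equal(estimate_hatchlings(10, 8, 0), 9)
  expect_equal(estimate_hatchlings(9, 7, 2), 7)
  expect_equal(estimate_hatchlings(8, 8, 0), 8)
  expect_error(estimate_hatchlings(5, 4, 2, brood_id = "B9"), "B9")

  lattice <- expand.grid(c = 0:15, m = 0:15, u = 0:15)
  lattice <- lattice[lattice$m + lattice$u <= lattice$c, ]
  est <- estimate_hatchlings(lattice$c, lattice$m, lattice$u)
  expect_equal(est, lattice$m + (lattice$c - lattice$m - lattice$u) / 2)
  expect_true(all(est >= lattice$m & est <= lattice$c - lattice$u))
})

test_that("the model suite carries the documented specs, terms and filters", {
  s <- suite_from_seed(51)
  suite <- s$suite
  expect_named(suite, c("lay_date", "clutch_size", "hatchlings",
                        "fledglings", "fledge_success", "second_brood",
                        "female_weight", "nestling_weight",
                        "nestling_tarsus", "nestling_p3"))

  core <- c("chronotype", "chronotype_sq", "year_f",
            "chronotype:year_f", "chronotype_sq:year_f")
  expect_setequal(suite$lay_date$terms, core)         # no lay-date covariate
  expect_setequal(suite$clutch_size$terms, c(core, "lay_date_c"))
  expect_setequal(suite$second_brood$terms,
                  c(core, "lay_date_c", "n_fledglings"))
  expect_setequal(suite$female_weight$terms,
                  c(core, "lay_date_c", "time_of_day", "I(time_of_day^2)",
                    "tarsus"))
  expect_setequal(suite$nestling_weight$terms,
                  c(core, "hatch_date_c", "chick_age", "n_fledglings",
                    "time_of_day", "I(time_of_day^2)"))
  expect_equal(suite$nestling_weight$random, "brood_id")
  expect_equal(suite$nestling_tarsus$family, "lmm")
  expect_equal(suite$fledge_success$family, "binomial")

  # exclusion bookkeeping
  broods <- s$pop$broods
  first <- dplyr::semi_join(broods, truth_chronotypes(s$pop),
                            by = c("female_id", "year"))
  expect_equal(suite$hatchlings$n, sum(!first$deserted))
  expect_equal(suite$fledge_success$n,
               sum(!first$deserted & !first$failed_pre_hatch))
  expect_true(all(suite$second_brood$data$n_fledglings >= 1))

  expect_error(build_model_suite(truth_chronotypes(s$pop),
                                 broods[, -which(names(broods) == "clutch_size")]),
               "clutch_size")
})

test_that("fitting recovers injected coefficients and ignores row order", {
  s <- suite_from_seed(52, n_females = 10000, n_years = 1,
                       quad_laydate_effect = 4, linear_laydate_effect = 0.239,
                       p_multi_year = c(1, 0, 0))
  fit <- fit_selection_model(s$suite$lay_date)
  co <- summary(fit$fit)$coefficients
  expect_lt(abs(co["chronotype_sq", 1] - 4), 3 * co["chronotype_sq", 2])
  expect_lt(abs(co["chronotype", 1] - 0.239), 3 * co["chronotype", 2])

  spec2 <- s$suite$lay_date
  set.seed(2)
  spec2$data <- spec2$data[sample(nrow(spec2$data)), ]
  fit2 <- fit_selection_model(spec2)
  expect_equal(sort(coef(fit2$fit)), sort(coef(fit$fit)), tolerance = 1e-8)
})

test_that("degenerate binomial responses are flagged, not fatal", {
  s <- suite_from_seed(53, n_females = 40)
  spec <- s$suite$fledge_success
  spec$data$fledge_success <- 0L
  fit <- fit_selection_model(spec)
  expect_s3_class(fit, "nestclock_fit")
  sep <- spec
  sep$data$fledge_success <- as.integer(sep$data$chronotype > 0)
  fit2 <- fit_selection_model(sep)
  expect_true(length(fit2$flags) > 0)
})

test_that("backward elimination matches a direct LRT oracle and marginality", {
  # a single null covariate is dropped, matching anova() run directly
  set.seed(9)
  n <- 120
  dat <- tibble::tibble(
    female_id = as.character(1:n), year = 2021L,
    brood_id = as.character(1:n), nest_box = as.character(1:n),
    lay_date = 20 + rnorm(n), clutch_size = 9L,
    incubation_start = 30, hatch_date = 43,
    unhatched_eggs = 0L, max_observed_nestlings = 8L,
    n_fledglings = 7L, fledge_success = 1L, second_brood = 0L,
    deserted = FALSE, failed_pre_hatch = FALSE
  )
  ch <- tibble::tibble(female_id = dat$female_id, chronotype = rnorm(n),
                       n_onsets = 2L, year = 2021L, brood_id = dat$brood_id)
  suite <- build_model_suite(ch, dat)
  red <- stepwise_reduce(suite$lay_date)
  expect_true(all(!red$path$retained))
  expect_equal(red$final_terms, character(0))

  d <- suite$lay_date$data
  full <- lm(lay_date ~ chronotype + chronotype_sq, data = d)
  drop_q <- lm(lay_date ~ chronotype, data = d)
  a <- anova(drop_q, full, test = "F")
  step1 <- red$path[red$path$term == "chronotype_sq", ]
  expect_equal(step1$statistic, a$F[2], tolerance = 1e-8)
  expect_equal(step1$p, a$`Pr(>F)`[2], tolerance = 1e-8)

  # a significant quadratic shields the linear term from deletion
  s <- suite_from_seed(54, quad_laydate_effect = 12, laydate_resid_sd = 2)
  red2 <- stepwise_reduce(s$suite$lay_date)
  expect_true("chronotype_sq" %in% red2$final_terms)
  expect_true("chronotype" %in% red2$final_terms)
  chron_row <- red2$path[red2$path$term == "chronotype", ]
  expect_true(is.na(chron_row$p))       # never tested while shielded

  # reduction is deterministic
  red3 <- stepwise_reduce(s$suite$lay_date)
  expect_identical(red3$path, red2$path)
  expect_identical(red3$final_terms, red2$final_terms)
})

test_that("interaction terms protect their components until dropped", {
  s <- suite_from_seed(55)
  spec <- s$suite$lay_date
  fit <- fit_selection_model(spec)
  # while chronotype_sq:year_f is in the model, neither chronotype_sq nor
  # year_f nor chronotype:year_f may be tested
  anc <- spec$ancestors
  expect_true("chronotype_sq:year_f" %in% anc[["chronotype_sq"]])
  expect_true("chronotype_sq:year_f" %in% anc[["year_f"]])
  expect_true("chronotype_sq:year_f" %in% anc[["chronotype:year_f"]])
  red <- stepwise_reduce(fit, force_retain = "chronotype_sq:year_f")
  expect_setequal(
    intersect(c("chronotype", "chronotype_sq", "year_f", "chronotype:year_f"),
              red$final_terms),
    c("chronotype", "chronotype_sq", "year_f", "chronotype:year_f")
  )
})

test_that("simulated prediction bands match their closed forms", {
  set.seed(31)
  n <- 200
  d <- data.frame(x = runif(n, -2, 2))
  d$y <- 1 + 0.5 * d$x + rnorm(n, 0, 0.4)
  fit <- lm(y ~ x, data = d)
  nd <- data.frame(x = c(-1, 0, 1.5))
  band <- simulate_prediction_band(fit, nd, n_draws = 8000, seed = 4)
  se <- sqrt(diag(model.matrix(~x, nd) %*% vcov(fit) %*%
                    t(model.matrix(~x, nd))))
  expect_equal(band$fit, unname(predict(fit, nd)), tolerance = 1e-8)
  expect_equal(band$upr - band$lwr, unname(2 * 1.96 * se), tolerance = 0.08)

  # an exact fit has zero coefficient variance: the band collapses
  d0 <- data.frame(x = 1:10, y = 2 + 3 * (1:10))
  fit0 <- suppressWarnings(lm(y ~ x, data = d0))
  band0 <- suppressWarnings(
    simulate_prediction_band(fit0, data.frame(x = c(2, 5)), seed = 1)
  )
  expect_equal(band0$upr - band0$lwr, c(0, 0), tolerance = 1e-10)

  # binomial bands live on the probability scale
  db <- data.frame(x = rnorm(300))
  db$y <- rbinom(300, 1, plogis(0.3 * db$x))
  fitb <- glm(y ~ x, data = db, family = binomial())
  bandb <- simulate_prediction_band(fitb, data.frame(x = seq(-3, 3, 0.5)),
                                    seed = 5)
  expect_true(all(bandb$lwr >= 0 & bandb$upr <= 1))
})
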