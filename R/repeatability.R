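#' Fit the standardised-onset mixed model
#'
#' Restricted-maximum-likelihood fit of the standardised onset on fixed
#' effects Year, April day, their interaction, and centred breeding day plus
#' its square, with random intercepts for Female, Female-by-year and
#' Nest-box. The variance components of the three random intercepts and the
#' residual carry the repeatability information.
#'
#' @param std_onsets standardised onsets with `z`, `year`, `date`,
#'   `breeding_day`, `female_id`, `nest_box`.
#' @return an object of class `nestclock_vc`: a list with the lme4 fit,
#'   a `components` tibble (`term`, `variance`), REML log-likelihood and
#'   group counts. Singular fits (a component estimated at the zero
#'   boundary) are flagged, not errors.
#' @export
fit_onset_lmm <- function(std_onsets) {
  need <- c("z", "year", "date", "breeding_day", "female_id", "nest_box")
  miss <- setdiff(need, names(std_onsets))
  if (length(miss)) {
    abort(paste0("standardised-onset table is missing: ",
                 paste(miss, collapse = ", ")))
  }
  dat <- std_onsets |>
    dplyr::mutate(
      year_f = factor(.data$year),
      female_year = interaction(.data$female_id, .data$year, drop = TRUE),
      breeding_day_c = .data$breeding_day - mean(.data$breeding_day),
      april_day = as.numeric(.data$date) - mean(as.numeric(.data$date))
    )
  if (dplyr::n_distinct(dat$female_id) < 2) {
    abort("need onsets from at least 2 females")
  }
  multi_year <- nlevels(dat$year_f) > 1
  fixed <- if (multi_year) {
    "z ~ year_f * april_day + breeding_day_c + I(breeding_day_c^2)"
  } else {
    "z ~ april_day + breeding_day_c + I(breeding_day_c^2)"
  }
  ran <- "(1 | female_id) + (1 | female_year) + (1 | nest_box)"
  if (!multi_year) ran <- "(1 | female_id) + (1 | nest_box)"
  form <- as.formula(paste(fixed, "+", ran))

  # calc.derivs = FALSE: components at the zero boundary (e.g. a nest-box
  # share confounded with female) otherwise trip the finite-difference
  # Hessian check; boundary fits are legitimate and flagged via isSingular
  fit <- tryCatch(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    error = function(e) abort(paste0("mixed-model fit failed: ", conditionMessage(e)))
  )
  opt <- fit@optinfo$conv$opt
  if (!is.null(opt) && opt != 0) {
    abort(paste0("mixed-model optimiser did not converge (code ", opt, ")"))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  getv <- function(g) {
    v <- vc$vcov[vc$grp == g]
    if (length(v)) v else 0
  }
  components <- tibble::tibble(
    term = c("female", "female_year", "nest_box", "residual"),
    variance = c(getv("female_id"), getv("female_year"),
                 getv("nest_box"), getv("Residual"))
  )
  structure(list(
    fit = fit,
    components = components,
    logLik = as.numeric(logLik(fit)),
    singular = lme4::isSingular(fit),
    n_obs = nrow(dat),
    n_females = dplyr::n_distinct(dat$female_id),
    n_female_years = dplyr::n_distinct(dat$female_year),
    n_nestboxes = dplyr::n_distinct(dat$nest_box),
    data = dat,
    formula = form
  ), class = "nestclock_vc")
}

#' @export
print.nestclock_vc <- function(x, ...) {
  cat("Standardised-onset variance components (REML)\n")
  print(x$components)
  r <- compute_repeatabilities(x)
  cat(sprintf("r within year  = %.3f\nr across years = %.3f\n",
              r$r_within_year, r$r_across_year))
  cat(sprintf("n = %d onsets, %d females, %d female-years, %d nest-boxes%s\n",
              x$n_obs, x$n_females, x$n_female_years, x$n_nestboxes,
              if (x$singular) " (boundary fit: some component at 0)" else ""))
  invisible(x)
}

#' Repeatabilities from variance components
#'
#' Across-year repeatability is the female variance over the total;
#' within-year repeatability adds the female-by-year variance to the
#' numerator. The total is the sum of all four components (female,
#' female-year, nest-box, residual); the total excluding nest-box is also
#' reported since the nest-box share is often estimated at zero.
#'
#' @param vc a `nestclock_vc` from [fit_onset_lmm()], or a numeric vector
#'   of length 4 `(v_female, v_female_year, v_nestbox, v_residual)`.
#' @return tibble with `r_within_year`, `r_across_year` (and the versions
#'   excluding nest-box from the denominator).
#' @export
compute_repeatabilities <- function(vc) {
  v <- if (inherits(vc, "nestclock_vc")) vc$components$variance else as.numeric(vc)
  if (length(v) != 4 || any(v < 0)) {
    abort("need 4 non-negative variance components (female, female_year, nest_box, residual)")
  }
  total <- sum(v)
  if (total <= 0) abort("total variance is zero")
  total_no_box <- v[1] + v[2] + v[4]
  tibble::tibble(
    r_across_year = v[1] / total,
    r_within_year = (v[1] + v[2]) / total,
    r_across_year_no_box = v[1] / total_no_box,
    r_within_year_no_box = (v[1] + v[2]) / total_no_box
  )
}

#' Likelihood-ratio test for one random effect
#'
#' Twice the REML log-likelihood difference between the full fit and a fit
#' with one random intercept removed, referred to a chi-square with 1 df
#' (no boundary mixture; conservative).
#'
#' @param full,reduced `nestclock_vc` objects or lme4 fits; `reduced` must
#'   remove exactly one random intercept from `full`.
#' @return tibble with `statistic`, `df`, `p`.
#' @export
lrt_random_effect <- function(full, reduced) {
  ll_full <- if (inherits(full, "nestclock_vc")) full$logLik else as.numeric(logLik(full))
  ll_red <- if (inherits(reduced, "nestclock_vc")) reduced$logLik else as.numeric(logLik(reduced))
  nre <- function(x) {
    f <- if (inherits(x, "nestclock_vc")) x$fit else x
    length(lme4::findbars(formula(f)))
  }
  if (inherits(full, c("nestclock_vc", "merMod")) &&
      inherits(reduced, c("nestclock_vc", "merMod"))) {
    d <- nre(full) - nre(reduced)
    if (!d %in% c(0L, 1L)) {
      abort("reduced model must remove exactly one random effect from the full model")
    }
  }
  stat <- max(0, 2 * (ll_full - ll_red))
  tibble::tibble(statistic = stat, df = 1L, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Repeatability analysis of standardised onsets
#'
#' Convenience wrapper: fits the onset mixed model, derives within- and
#' across-year repeatabilities, and tests each random component by removing
#' it and comparing REML log-likelihoods (chi-square, 1 df).
#'
#' @param std_onsets standardised onsets (see [fit_onset_lmm()]).
#' @return an object of class `nestclock_repeatability`: list with `vc`
#'   (the full fit), `repeatability` tibble and `tests` tibble (one LRT per
#'   random component).
#' @export
onset_repeatability <- function(std_onsets) {
  full <- fit_onset_lmm(std_onsets)
  rep_tab <- compute_repeatabilities(full)

  drop_re <- function(term) {
    form <- formula(full$fit)
    red <- update(full$fit, as.formula(paste(". ~ . - (1 |", term, ")")))
    red
  }
  terms <- c(female = "female_id", female_year = "female_year",
             nest_box = "nest_box")
  tests <- purrr::imap(terms, function(v, nm) {
    red <- drop_re(v)
    dplyr::bind_cols(tibble::tibble(term = nm),
                     lrt_random_effect(full$fit, red))
  }) |> dplyr::bind_rows()

  structure(list(vc = full, repeatability = rep_tab, tests = tests),
            class = "nestclock_repeatability")
}

#' @export
print.nestclock_repeatability <- function(x, ...) {
  print(x$vc)
  cat("\nLikelihood-ratio tests (REML, df = 1):\n")
  print(x$tests)
  invisible(x)
}

#' Likelihood-ratio tests for the fixed effects of the onset model
#'
#' Refits the model by maximum likelihood and performs single-term
#' deletions respecting marginality (the Year-by-April-day interaction is
#' tested first; main effects only once the interaction is removed; the
#' quadratic breeding-day term before the linear one).
#'
#' @param vc a `nestclock_vc` from [fit_onset_lmm()].
#' @return tibble with `term`, `statistic` (chi-square), `df`, `p`.
#' @export
fixed_effect_lrts <- function(vc) {
  stopifnot(inherits(vc, "nestclock_vc"))
  ml <- update(vc$fit, REML = FALSE)
  test_drop <- function(fit, term) {
    red <- update(fit, as.formula(paste(". ~ . -", term)))
    a <- anova(red, fit)
    tibble::tibble(term = term, statistic = a$Chisq[2],
                   df = a$Df[2], p = a$`Pr(>Chisq)`[2])
  }
  multi_year <- "year_f" %in% all.vars(formula(ml))
  out <- list()
  if (multi_year) {
    out$int <- test_drop(ml, "year_f:april_day")
    no_int <- update(ml, . ~ . - year_f:april_day)
    out$year <- test_drop(no_int, "year_f")
    out$april <- test_drop(no_int, "april_day")
  } else {
    out$april <- test_drop(ml, "april_day")
  }
  out$bd2 <- test_drop(ml, "I(breeding_day_c^2)")
  no_bd2 <- update(ml, . ~ . - I(breeding_day_c^2))
  out$bd <- test_drop(no_bd2, "breeding_day_c")
  dplyr::bind_rows(out)
}
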