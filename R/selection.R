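#' Estimate the number of hatchlings with count uncertainty
#'
#' Nest checks can miss hatchlings that die early, so the hatchling count is
#' the maximum number of nestlings observed plus half of the eggs that were
#' neither observed as nestlings nor found unhatched:
#' `hatchlings = m + (c - m - u) / 2` for clutch size `c`, maximum observed
#' nestlings `m` and unhatched eggs `u`. The estimate is possibly
#' half-integer and always lies in `[m, c - u]`.
#'
#' @param clutch_size,max_observed_nestlings,unhatched_eggs integer vectors;
#'   `clutch_size >= max_observed_nestlings + unhatched_eggs` must hold.
#' @param brood_id optional ids used in error messages.
#' @return numeric vector of hatchling estimates.
#' @examples
#' estimate_hatchlings(10, 8, 0) # 9
#' estimate_hatchlings(9, 7, 2)  # 7
#' @export
estimate_hatchlings <- function(clutch_size, max_observed_nestlings,
                                unhatched_eggs, brood_id = NULL) {
  bad <- which(clutch_size < max_observed_nestlings + unhatched_eggs)
  if (length(bad)) {
    lab <- if (!is.null(brood_id)) paste(brood_id[bad], collapse = ", ") else {
      paste("rows", paste(bad, collapse = ", "))
    }
    abort(paste0("inconsistent counts (clutch < observed + unhatched) for: ", lab))
  }
  max_observed_nestlings +
    (clutch_size - max_observed_nestlings - unhatched_eggs) / 2
}

# ---------------------------------------------------------------------------
# model specs

# terms blocked from deletion while a containing higher-order term is kept
term_ancestors <- function(terms) {
  anc <- list(
    chronotype = c("chronotype_sq", "chronotype:year_f", "chronotype_sq:year_f"),
    chronotype_sq = "chronotype_sq:year_f",
    year_f = c("chronotype:year_f", "chronotype_sq:year_f"),
    "chronotype:year_f" = "chronotype_sq:year_f",
    time_of_day = "I(time_of_day^2)"
  )
  out <- lapply(terms, function(t) intersect(anc[[t]] %||% character(), terms))
  names(out) <- terms
  out
}

core_terms <- function(multi_year) {
  if (multi_year) {
    c("chronotype", "chronotype_sq", "year_f",
      "chronotype:year_f", "chronotype_sq:year_f")
  } else {
    c("chronotype", "chronotype_sq")
  }
}

new_modelspec <- function(name, response, family, terms, data,
                          random = NULL) {
  miss <- setdiff(c(response, all.vars(as.formula(
    paste("~", paste(c(terms, random %||% character()), collapse = "+"))
  ))), names(data))
  if (length(miss)) {
    abort(paste0("model `", name, "` is missing required columns: ",
                 paste(miss, collapse = ", ")))
  }
  structure(list(
    name = name, response = response, family = family, terms = terms,
    ancestors = term_ancestors(terms), data = data, random = random,
    n = nrow(data)
  ), class = "nestclock_modelspec")
}

#' @export
print.nestclock_modelspec <- function(x, ...) {
  cat(sprintf("<modelspec %s> %s ~ %s  [%s, n = %d%s]\n",
              x$name, x$response, paste(x$terms, collapse = " + "),
              x$family, x$n,
              if (!is.null(x$random)) paste0(", (1|", x$random, ")") else ""))
  invisible(x)
}

#' Build the fitness and life-history model suite
#'
#' Constructs one model specification per response, each female entering
#' once with her chronotype year: lay date, clutch size, hatchlings and
#' fledglings (Gaussian); fledge success and second brood (binomial);
#' female body weight (Gaussian, with time-of-day, its square and tarsus);
#' and nestling weight, tarsus and P3 feather length (Gaussian mixed with a
#' brood random intercept). Every model carries linear and quadratic
#' chronotype, year and their interactions (single-year inputs drop the
#' year terms), plus within-year-centred lay date — except the lay-date
#' model itself, which has no lay-date covariate, and the nestling models,
#' where centred hatch date replaces lay date. Exclusions follow the field
#' protocol: deserting females leave the hatchling/fledgling/fledge-success
#' models, pre-hatch failures additionally leave fledge success, and only
#' successful first broods (>= 1 fledgling) enter the second-brood model,
#' which also adjusts for the first brood's fledgling count.
#'
#' @param chronotypes tibble from [compute_chronotype()].
#' @param broods brood table (see [simulate_population()]).
#' @param nestlings optional nestling biometrics table.
#' @param condition optional female condition table.
#' @return a named list of `nestclock_modelspec` objects (class
#'   `nestclock_suite`).
#' @export
build_model_suite <- function(chronotypes, broods, nestlings = NULL,
                              condition = NULL) {
  need_b <- c("female_id", "year", "lay_date", "clutch_size",
              "max_observed_nestlings", "unhatched_eggs", "n_fledglings",
              "fledge_success", "second_brood", "deserted",
              "failed_pre_hatch")
  miss <- setdiff(need_b, names(broods))
  if (length(miss)) {
    abort(paste0("brood table is missing required columns: ",
                 paste(miss, collapse = ", ")))
  }

  fem <- chronotypes |>
    dplyr::select("female_id", "chronotype", chrono_year = "year") |>
    dplyr::inner_join(broods, by = "female_id",
                      relationship = "one-to-many") |>
    dplyr::filter(.data$year == .data$chrono_year) |>
    dplyr::mutate(
      chronotype_sq = .data$chronotype^2,
      hatchlings = estimate_hatchlings(.data$clutch_size,
                                       .data$max_observed_nestlings,
                                       .data$unhatched_eggs,
                                       .data$brood_id)
    ) |>
    centre_covariates(cols = "lay_date")
  multi_year <- dplyr::n_distinct(fem$year) > 1
  fem <- fem |> dplyr::mutate(year_f = factor(.data$year))

  core <- core_terms(multi_year)
  with_lay <- c(core, "lay_date_c")

  specs <- list()
  specs$lay_date <- new_modelspec("lay_date", "lay_date", "gaussian",
                                  core, fem)
  specs$clutch_size <- new_modelspec("clutch_size", "clutch_size",
                                     "gaussian", with_lay, fem)
  no_desert <- fem |> dplyr::filter(!.data$deserted)
  specs$hatchlings <- new_modelspec("hatchlings", "hatchlings", "gaussian",
                                    with_lay, no_desert)
  specs$fledglings <- new_modelspec("fledglings", "n_fledglings",
                                    "gaussian", with_lay, no_desert)
  specs$fledge_success <- new_modelspec(
    "fledge_success", "fledge_success", "binomial", with_lay,
    no_desert |> dplyr::filter(!.data$failed_pre_hatch)
  )
  specs$second_brood <- new_modelspec(
    "second_brood", "second_brood", "binomial",
    c(with_lay, "n_fledglings"),
    fem |> dplyr::filter(.data$fledge_success == 1)
  )

  if (!is.null(condition)) {
    cond <- chronotypes |>
      dplyr::select("female_id", "chronotype", chrono_year = "year") |>
      dplyr::inner_join(condition, by = "female_id",
                        relationship = "one-to-many") |>
      dplyr::filter(.data$year == .data$chrono_year) |>
      dplyr::left_join(fem |> dplyr::select("female_id", "lay_date_c"),
                       by = "female_id") |>
      dplyr::mutate(chronotype_sq = .data$chronotype^2,
                    year_f = factor(.data$year))
    specs$female_weight <- new_modelspec(
      "female_weight", "weight", "gaussian",
      c(with_lay, "time_of_day", "I(time_of_day^2)", "tarsus"), cond
    )
  }

  if (!is.null(nestlings)) {
    nst <- chronotypes |>
      dplyr::select("female_id", "chronotype", chrono_year = "year") |>
      dplyr::inner_join(nestlings, by = "female_id",
                        relationship = "one-to-many") |>
      dplyr::filter(.data$year == .data$chrono_year) |>
      centre_covariates(cols = "hatch_date") |>
      dplyr::mutate(chronotype_sq = .data$chronotype^2,
                    year_f = factor(.data$year))
    nst_core <- c(core_terms(dplyr::n_distinct(nst$year) > 1),
                  "hatch_date_c", "chick_age", "n_fledglings")
    specs$nestling_weight <- new_modelspec(
      "nestling_weight", "weight", "lmm",
      c(nst_core, "time_of_day", "I(time_of_day^2)"), nst, random = "brood_id"
    )
    specs$nestling_tarsus <- new_modelspec(
      "nestling_tarsus", "tarsus", "lmm", nst_core, nst, random = "brood_id"
    )
    specs$nestling_p3 <- new_modelspec(
      "nestling_p3", "p3", "lmm", nst_core, nst, random = "brood_id"
    )
  }
  structure(specs, class = "nestclock_suite")
}

# ---------------------------------------------------------------------------
# fitting

spec_formula <- function(spec, terms = spec$terms) {
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  if (!is.null(spec$random)) {
    rhs <- paste(rhs, "+ (1 |", spec$random, ")")
  }
  as.formula(paste(spec$response, "~", rhs))
}

fit_engine <- function(spec, terms = spec$terms) {
  form <- spec_formula(spec, terms)
  warnings <- character()
  fit <- withCallingHandlers(
    switch(spec$family,
      gaussian = stats::lm(form, data = spec$data),
      binomial = stats::glm(form, data = spec$data, family = stats::binomial()),
      lmm = lme4::lmer(form, data = spec$data, REML = FALSE,
                       control = lme4::lmerControl(check.conv.singular = "ignore")),
      abort(paste0("unknown family: ", spec$family))
    ),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  attr(fit, "nestclock_warnings") <- warnings
  fit
}

#' Fit one selection model from its specification
#'
#' Maximum-likelihood fit of the stated family (`lm` for Gaussian GLMs,
#' `glm` for binomial, `lmer` with ML for the nestling mixed models).
#' Binomial fits with perfect separation are flagged (diverging estimates),
#' not errors.
#'
#' @param spec a `nestclock_modelspec` from [build_model_suite()].
#' @return an object of class `nestclock_fit`: list with the fitted model,
#'   the spec, and any separation/convergence flags.
#' @export
fit_selection_model <- function(spec) {
  stopifnot(inherits(spec, "nestclock_modelspec"))
  fit <- fit_engine(spec)
  flags <- attr(fit, "nestclock_warnings")
  if (spec$family == "binomial") {
    co <- coef(fit)
    if (any(abs(co[is.finite(co)]) > 15)) {
      flags <- c(flags, "possible perfect separation: diverging estimates")
    }
  }
  structure(list(spec = spec, fit = fit, terms = spec$terms, flags = flags),
            class = "nestclock_fit")
}

#' @export
print.nestclock_fit <- function(x, ...) {
  cat(sprintf("<nestclock_fit %s> %s terms, n = %d\n", x$spec$name,
              length(x$terms), x$spec$n))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  print(x$fit)
  invisible(x)
}

# single-term deletion test comparing the model with and without `term`
deletion_test <- function(spec, terms, term) {
  full <- fit_engine(spec, terms)
  red <- fit_engine(spec, setdiff(terms, term))
  if (spec$family == "gaussian") {
    a <- anova(red, full, test = "F")
    tibble::tibble(kind = "F", statistic = a$F[2],
                   df = abs(a$Df[2]), df_resid = a$Res.Df[2],
                   p = a$`Pr(>F)`[2])
  } else if (spec$family == "binomial") {
    a <- anova(red, full, test = "Chisq")
    # deviance change on dropping the term, as conventionally printed
    # (negative: the reduced model deviance is larger)
    tibble::tibble(kind = "Dev", statistic = -a$Deviance[2],
                   df = abs(a$Df[2]), df_resid = NA_real_,
                   p = a$`Pr(>Chi)`[2])
  } else {
    a <- anova(red, full)
    tibble::tibble(kind = "Chisq", statistic = a$Chisq[2],
                   df = a$Df[2], df_resid = NA_real_,
                   p = a$`Pr(>Chisq)`[2])
  }
}

# estimate and SE of a term in a fitted model, when it maps to exactly one
# coefficient; NA for factors and multi-column interactions
term_estimate <- function(fit, term) {
  co <- if (inherits(fit, "merMod")) {
    as.data.frame(summary(fit)$coefficients)
  } else {
    as.data.frame(summary(fit)$coefficients)
  }
  if (term %in% rownames(co)) {
    c(estimate = co[term, 1], se = co[term, 2])
  } else {
    c(estimate = NA_real_, se = NA_real_)
  }
}

#' Backward elimination with marginality constraints
#'
#' Starting from the full model, repeatedly tests every currently droppable
#' term by single-term deletion (F for Gaussian, deviance/chi-square for
#' binomial, chi-square LRT for mixed models) and removes the one with the
#' largest p-value at or above `alpha`. A term is droppable only while no
#' retained higher-order term contains it: interactions are removed before
#' their main effects and quadratics before the matching linear terms. The
#' estimate and standard error of each dropped term are recorded from the
#' model it was dropped from; terms surviving to the final model keep their
#' last (refused) deletion test.
#'
#' @param fit a `nestclock_fit` from [fit_selection_model()], or a
#'   `nestclock_modelspec` (fitted first).
#' @param alpha retention threshold for the deletion tests.
#' @param force_retain terms never considered for deletion.
#' @return an object of class `nestclock_reduction`: list with `spec`,
#'   `path` (one row per term in deletion order or final refusal:
#'   `term`, `kind`, `statistic`, `df`, `p`, `estimate`, `se`, `retained`),
#'   `final_terms`, and the final fitted model `fit`.
#' @export
stepwise_reduce <- function(fit, alpha = 0.05, force_retain = character()) {
  if (inherits(fit, "nestclock_modelspec")) fit <- fit_selection_model(fit)
  stopifnot(inherits(fit, "nestclock_fit"))
  spec <- fit$spec
  terms <- spec$terms
  path <- list()

  droppable <- function(terms) {
    cand <- setdiff(terms, force_retain)
    keep <- vapply(cand, function(t) {
      anc <- intersect(spec$ancestors[[t]] %||% character(), terms)
      length(anc) == 0
    }, TRUE)
    cand[keep]
  }

  repeat {
    cand <- droppable(terms)
    if (!length(cand)) break
    tests <- purrr::map(cand, function(t) {
      dplyr::bind_cols(tibble::tibble(term = t),
                       deletion_test(spec, terms, t))
    }) |> dplyr::bind_rows()
    worst <- tests[which.max(tests$p), ]
    if (worst$p < alpha) {
      # all droppable terms significant: record their refusals and stop
      cur <- fit_engine(spec, terms)
      for (i in seq_len(nrow(tests))) {
        est <- term_estimate(cur, tests$term[i])
        path[[length(path) + 1]] <- dplyr::bind_cols(
          tests[i, ],
          tibble::tibble(estimate = est[["estimate"]], se = est[["se"]],
                         retained = TRUE)
        )
      }
      break
    }
    cur <- fit_engine(spec, terms)
    est <- term_estimate(cur, worst$term)
    path[[length(path) + 1]] <- dplyr::bind_cols(
      worst,
      tibble::tibble(estimate = est[["estimate"]], se = est[["se"]],
                     retained = FALSE)
    )
    terms <- setdiff(terms, worst$term)
  }

  # retained non-droppable terms (blocked or force-retained) get their
  # current estimates without a test
  tested <- vapply(path, function(p) p$term, "")
  blocked <- setdiff(terms, tested)
  final_fit <- fit_engine(spec, terms)
  for (t in blocked) {
    est <- term_estimate(final_fit, t)
    path[[length(path) + 1]] <- tibble::tibble(
      term = t, kind = NA_character_, statistic = NA_real_, df = NA_real_,
      df_resid = NA_real_, p = NA_real_, estimate = est[["estimate"]],
      se = est[["se"]], retained = TRUE
    )
  }

  structure(list(
    spec = spec,
    path = dplyr::bind_rows(path),
    final_terms = terms,
    fit = final_fit,
    alpha = alpha,
    flags = fit$flags
  ), class = "nestclock_reduction")
}

#' @export
print.nestclock_reduction <- function(x, ...) {
  cat(sprintf("<reduction %s> final: %s ~ %s  (alpha = %g, n = %d)\n",
              x$spec$name, x$spec$response,
              if (length(x$final_terms)) paste(x$final_terms, collapse = " + ") else "1",
              x$alpha, x$spec$n))
  print(x$path)
  invisible(x)
}

#' Reduce every model of a suite
#'
#' @param suite a `nestclock_suite` from [build_model_suite()].
#' @param alpha retention threshold.
#' @param force_retain terms never dropped, applied to every model.
#' @return named list of `nestclock_reduction` objects.
#' @export
reduce_model_suite <- function(suite, alpha = 0.05,
                               force_retain = character()) {
  stopifnot(all(vapply(suite, inherits, TRUE, "nestclock_modelspec")))
  lapply(suite, function(spec) {
    stepwise_reduce(fit_selection_model(spec), alpha = alpha,
                    force_retain = force_retain)
  })
}

#' Simulation-based prediction bands
#'
#' Draws coefficient vectors from the asymptotic multivariate normal of the
#' fitted estimates, maps each draw through the linear predictor and the
#' inverse link, and summarises per-row 95% intervals from the draw
#' quantiles (2000 iterations by default, following the credible-interval
#' simulation used for the figures).
#'
#' @param fit a fitted `lm`/`glm`/`merMod`, or a `nestclock_fit` /
#'   `nestclock_reduction` (its final model is used).
#' @param newdata data frame of covariate values to predict at.
#' @param n_draws number of coefficient draws.
#' @param seed integer seed.
#' @param level interval coverage.
#' @return `newdata` with `fit`, `lwr`, `upr` columns appended.
#' @export
simulate_prediction_band <- function(fit, newdata, n_draws = 2000,
                                     seed = 1L, level = 0.95) {
  if (inherits(fit, "nestclock_reduction") || inherits(fit, "nestclock_fit")) {
    fit <- fit$fit
  }
  if (inherits(fit, "merMod")) {
    b <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    tt <- delete.response(terms(lme4::nobars(formula(fit))))
    linkinv <- identity
  } else {
    b <- coef(fit)
    V <- as.matrix(vcov(fit))
    tt <- delete.response(terms(fit))
    linkinv <- if (inherits(fit, "glm")) fit$family$linkinv else identity
  }
  if (any(!is.finite(V))) abort("singular or degenerate covariance matrix")
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev), 1))) {
    abort("covariance matrix is not positive semi-definite")
  }
  X <- model.matrix(tt, newdata)
  X <- X[, names(b), drop = FALSE]
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = b, Sigma = V)
  eta <- X %*% t(draws)
  pred <- linkinv(eta)
  alpha <- (1 - level) / 2
  out <- tibble::as_tibble(newdata)
  out$fit <- as.numeric(linkinv(X %*% b))
  out$lwr <- unname(apply(pred, 1, quantile, probs = alpha))
  out$upr <- unname(apply(pred, 1, quantile, probs = 1 - alpha))
  out
}
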