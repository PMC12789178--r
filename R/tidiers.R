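#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a repeatability analysis
#'
#' One row per variance component with its share of the total and, where
#' available, the likelihood-ratio test from removing it.
#'
#' @param x a `nestclock_repeatability` or `nestclock_vc`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy nestclock_repeatability
#' @export
tidy.nestclock_repeatability <- function(x, ...) {
  comp <- x$vc$components |>
    dplyr::mutate(proportion = .data$variance / sum(.data$variance)) |>
    dplyr::left_join(x$tests, by = "term")
  comp
}

#' @rdname tidy.nestclock_repeatability
#' @method tidy nestclock_vc
#' @export
tidy.nestclock_vc <- function(x, ...) {
  x$components |>
    dplyr::mutate(proportion = .data$variance / sum(.data$variance))
}

#' Glance at a repeatability analysis
#'
#' @param x a `nestclock_repeatability` or `nestclock_vc`.
#' @param ... unused.
#' @return a one-row tibble with the repeatabilities, log-likelihood and
#'   sample sizes.
#' @method glance nestclock_repeatability
#' @export
glance.nestclock_repeatability <- function(x, ...) {
  glance.nestclock_vc(x$vc)
}

#' @rdname glance.nestclock_repeatability
#' @method glance nestclock_vc
#' @export
glance.nestclock_vc <- function(x, ...) {
  dplyr::bind_cols(
    compute_repeatabilities(x)[, c("r_within_year", "r_across_year")],
    tibble::tibble(logLik = x$logLik, singular = x$singular,
                   n_obs = x$n_obs, n_females = x$n_females,
                   n_female_years = x$n_female_years,
                   n_nestboxes = x$n_nestboxes)
  )
}

#' Tidy a reduced selection model
#'
#' The reduction path: one row per term with its deletion-test statistic,
#' degrees of freedom and p-value, the estimate and standard error recorded
#' before dropping (or in the final model), and whether it was retained.
#'
#' @param x a `nestclock_reduction`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy nestclock_reduction
#' @export
tidy.nestclock_reduction <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(response = x$spec$name), x$path)
}

#' Glance at a reduced selection model
#'
#' @param x a `nestclock_reduction`.
#' @param ... unused.
#' @return one-row tibble with family, sample size, final terms and flags.
#' @method glance nestclock_reduction
#' @export
glance.nestclock_reduction <- function(x, ...) {
  tibble::tibble(
    response = x$spec$name,
    family = x$spec$family,
    n = x$spec$n,
    n_terms_final = length(x$final_terms),
    final_formula = paste(deparse(spec_formula(x$spec, x$final_terms)),
                          collapse = ""),
    flagged = length(x$flags) > 0
  )
}

#' Tidy a whole reduced suite
#'
#' @param x a named list of `nestclock_reduction` objects from
#'   [reduce_model_suite()].
#' @return a tibble stacking every model's reduction path.
#' @export
tidy_suite <- function(x) {
  purrr::map(x, tidy) |> dplyr::bind_rows()
}
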