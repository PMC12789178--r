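#' Standardise activity onsets against same-date conspecifics
#'
#' Converts raw onsets into z-scores relative to the other females measured
#' on the same date and year:
#' `z = (onset - date mean) / date SD`, with the sample (n-1) standard
#' deviation by default. Standardising within date removes shifts shared by
#' all females on a day (day length, weather), which is what makes the
#' resulting chronotype comparable across the season. Dates with fewer than
#' `min_females` females, or with zero SD, are dropped and logged in the
#' `"dropped"` attribute.
#'
#' @param onsets tibble of onset records with at least `female_id`, `year`,
#'   `date`, `onset`. One onset per female per date is expected; duplicates
#'   raise an error.
#' @param min_females minimum number of females on a date for it to be
#'   standardisable (default 3).
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return tibble of standardised onsets: input columns plus `z`, `date_n`,
#'   `date_mean`, `date_sd`.
#' @export
standardise_onsets <- function(onsets, min_females = 3,
                               sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  need <- c("female_id", "year", "date", "onset")
  miss <- setdiff(need, names(onsets))
  if (length(miss)) {
    abort(paste0("onset table is missing columns: ", paste(miss, collapse = ", ")))
  }
  dup <- onsets |>
    dplyr::count(.data$female_id, .data$year, .data$date) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate (female, date) onsets, e.g. ", dup$female_id[1],
                 " on date ", dup$date[1], " in ", dup$year[1]))
  }

  std <- onsets |>
    dplyr::group_by(.data$year, .data$date) |>
    dplyr::mutate(
      date_n = dplyr::n(),
      date_mean = mean(.data$onset),
      date_sd = if (sd_type == "sample") sd(.data$onset) else {
        sqrt(mean((.data$onset - mean(.data$onset))^2))
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(z = (.data$onset - .data$date_mean) / .data$date_sd)

  keep <- std$date_n >= min_females & !is.na(std$date_sd) & std$date_sd > 0
  dropped <- std[!keep, ] |>
    dplyr::distinct(.data$year, .data$date, .data$date_n, .data$date_sd) |>
    dplyr::mutate(reason = ifelse(.data$date_n < min_females,
                                  "too_few_females", "zero_sd"))
  out <- std[keep, ]
  attr(out, "dropped") <- dropped
  out
}

#' Keep only broods with enough standardised onsets
#'
#' A brood needs at least `min_onsets` retained standardised onsets to
#' contribute a chronotype; others are removed and counted.
#'
#' @param std_onsets tibble from [standardise_onsets()] with `brood_id`.
#' @param min_onsets minimum onsets per brood (default 2).
#' @return filtered tibble; removal counts in attribute `"removed"`.
#' @export
filter_measurement_set <- function(std_onsets, min_onsets = 2) {
  counts <- std_onsets |> dplyr::count(.data$brood_id, name = "n_onsets")
  bad <- counts$brood_id[counts$n_onsets < min_onsets]
  out <- std_onsets |> dplyr::filter(!.data$brood_id %in% bad)
  attr(out, "removed") <- tibble::tibble(
    n_broods_removed = length(bad),
    n_onsets_removed = nrow(std_onsets) - nrow(out)
  )
  attr(out, "dropped") <- attr(std_onsets, "dropped")
  out
}

#' Compute per-female chronotypes
#'
#' A female's chronotype is the mean standardised onset of her first
#' measured brood in her first measured year. Later broods and years stay in
#' the onset table for repeatability estimation but do not enter the
#' chronotype. The first brood is resolved by earliest lay date within the
#' first year (ties: earliest incubation start, then lowest brood id); when
#' no brood table is supplied, the brood measured earliest is used.
#'
#' @param std_onsets filtered standardised onsets (see
#'   [filter_measurement_set()]).
#' @param broods optional brood table with `brood_id`, `lay_date`,
#'   `incubation_start` used to resolve first broods.
#' @param exclude optional character vector of female ids to drop (e.g.
#'   experimental females).
#' @return tibble with `female_id`, `chronotype`, `n_onsets`, `year`,
#'   `brood_id`.
#' @export
compute_chronotype <- function(std_onsets, broods = NULL, exclude = NULL) {
  dat <- std_onsets
  if (!is.null(exclude)) dat <- dat |> dplyr::filter(!.data$female_id %in% exclude)
  if (!nrow(dat)) {
    return(tibble::tibble(female_id = character(), chronotype = numeric(),
                          n_onsets = integer(), year = integer(),
                          brood_id = character()))
  }
  first_year <- dat |>
    dplyr::group_by(.data$female_id) |>
    dplyr::summarise(year = min(.data$year), .groups = "drop")
  dat <- dplyr::semi_join(dat, first_year, by = c("female_id", "year"))

  brood_order <- dat |> dplyr::distinct(.data$female_id, .data$brood_id)
  if (!is.null(broods)) {
    brood_order <- brood_order |>
      dplyr::left_join(
        broods |> dplyr::select("brood_id", "lay_date", "incubation_start"),
        by = "brood_id"
      ) |>
      dplyr::arrange(.data$female_id, .data$lay_date,
                     .data$incubation_start, .data$brood_id)
  } else {
    first_date <- dat |>
      dplyr::group_by(.data$female_id, .data$brood_id) |>
      dplyr::summarise(first_date = min(.data$date), .groups = "drop")
    brood_order <- brood_order |>
      dplyr::left_join(first_date, by = c("female_id", "brood_id")) |>
      dplyr::arrange(.data$female_id, .data$first_date, .data$brood_id)
  }
  first_brood <- brood_order |>
    dplyr::group_by(.data$female_id) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select("female_id", "brood_id")

  dat |>
    dplyr::semi_join(first_brood, by = c("female_id", "brood_id")) |>
    dplyr::group_by(.data$female_id, .data$year, .data$brood_id) |>
    dplyr::summarise(chronotype = mean(.data$z),
                     n_onsets = dplyr::n(), .groups = "drop") |>
    dplyr::select("female_id", "chronotype", "n_onsets", "year", "brood_id")
}

#' Back-calculate lay date from incubation start and clutch size
#'
#' Females lay one egg per day and start incubating on the day the clutch is
#' completed, so `lay date = incubation start - clutch size + 1`.
#'
#' @param incubation_start April day of incubation start (vectorised).
#' @param clutch_size number of eggs (must be >= 1).
#' @return April day of the first egg.
#' @examples
#' estimate_lay_date(30, 8) # 23
#' @export
estimate_lay_date <- function(incubation_start, clutch_size) {
  if (any(clutch_size < 1, na.rm = TRUE)) {
    abort("clutch_size must be >= 1")
  }
  incubation_start - clutch_size + 1
}

#' Centre covariates within year
#'
#' Adds `<col>_c` columns holding each value minus its year mean; the
#' original columns are retained.
#'
#' @param broods data frame with a `year` column.
#' @param cols character vector of columns to centre (default `lay_date`
#'   and, when present, `hatch_date`).
#' @return the input with centred columns appended.
#' @export
centre_covariates <- function(broods, cols = NULL) {
  if (is.null(cols)) {
    cols <- intersect(c("lay_date", "hatch_date"), names(broods))
  }
  miss <- setdiff(cols, names(broods))
  if (length(miss)) {
    abort(paste0("columns not found: ", paste(miss, collapse = ", ")))
  }
  broods |>
    dplyr::group_by(.data$year) |>
    dplyr::mutate(dplyr::across(
      dplyr::all_of(cols),
      ~ .x - mean(.x, na.rm = TRUE),
      .names = "{.col}_c"
    )) |>
    dplyr::ungroup()
}
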