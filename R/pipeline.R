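#' Column schemas for the pipeline's tables
#'
#' Named list of schemas (column name -> type) used by [read_table()]:
#' `onsets`, `broods`, `chronotypes`.
#'
#' @export
nestclock_schemas <- list(
  onsets = c(female_id = "character", brood_id = "character",
             nest_box = "character", year = "integer", date = "integer",
             onset = "double", breeding_day = "integer", stage = "character"),
  broods = c(female_id = "character", year = "integer",
             brood_id = "character", nest_box = "character",
             lay_date = "double", clutch_size = "integer",
             incubation_start = "double", hatch_date = "double",
             unhatched_eggs = "integer", max_observed_nestlings = "integer",
             n_fledglings = "integer", fledge_success = "integer",
             second_brood = "integer", deserted = "logical",
             failed_pre_hatch = "logical"),
  chronotypes = c(female_id = "character", chronotype = "double",
                  n_onsets = "integer", year = "integer",
                  brood_id = "character")
)

#' Read and validate a comma-separated table against a schema
#'
#' Unknown columns warn; missing required columns error; values that cannot
#' be coerced to the declared type error with their row numbers.
#'
#' @param path file path (UTF-8, comma-separated, header row).
#' @param schema named character vector mapping column names to types
#'   (`"integer"`, `"double"`, `"character"`, `"logical"`), e.g. an entry
#'   of [nestclock_schemas].
#' @return a validated tibble.
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  miss <- setdiff(names(schema), names(raw))
  if (length(miss)) {
    abort(paste0("missing required columns in ", basename(path), ": ",
                 paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(raw), names(schema))
  if (length(extra)) {
    warn(paste0("unknown columns in ", basename(path), ": ",
                paste(extra, collapse = ", ")))
  }
  out <- raw[names(schema)]
  for (col in names(schema)) {
    x <- out[[col]]
    conv <- switch(schema[[col]],
      integer = suppressWarnings(as.integer(x)),
      double = suppressWarnings(as.numeric(x)),
      logical = as.logical(x),
      character = x,
      abort(paste0("unknown schema type: ", schema[[col]]))
    )
    bad <- which(!is.na(x) & x != "NA" & is.na(conv))
    if (length(bad)) {
      abort(paste0("column `", col, "` in ", basename(path),
                   " has invalid values at data rows: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    out[[col]] <- conv
  }
  out
}

#' Pipeline configuration
#'
#' @param seed master seed for every stochastic stage.
#' @param outdir run directory (created; write-once per run).
#' @param stages character vector of stages to run, in pipeline order, from
#'   `simulate`, `detect`, `standardise`, `repeatability`, `fit`, `report`.
#' @param sim a [sim_config()]; its seed is overridden by `seed`.
#' @param onset_path,brood_path optional precomputed input tables, used when
#'   the `simulate` stage is skipped.
#' @param traces optional list of entries `list(path, brood_id)` of logger
#'   exports for the `detect` stage; `ambient_path` may point to a shared
#'   ambient file.
#' @param ambient_path optional ambient reference CSV for `detect`.
#' @param min_females,min_onsets standardisation filters.
#' @param alpha retention threshold for the model suite.
#' @param exclude optional female ids excluded from chronotypes.
#' @return a `nestclock_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("nestclock_run_"),
                            stages = c("simulate", "standardise",
                                       "repeatability", "fit", "report"),
                            sim = sim_config(),
                            onset_path = NULL, brood_path = NULL,
                            traces = NULL, ambient_path = NULL,
                            min_females = 3, min_onsets = 2, alpha = 0.05,
                            exclude = NULL) {
  known <- c("simulate", "detect", "standardise", "repeatability", "fit",
             "report")
  bad <- setdiff(stages, known)
  if (length(bad)) abort(paste0("unknown stages: ", paste(bad, collapse = ", ")))
  sim$seed <- seed
  structure(as.list(environment())[names(formals(pipeline_config))],
            class = "nestclock_pipeline_config")
}

write_stage_table <- function(x, dir, name, files) {
  path <- file.path(dir, name)
  readr::write_csv(as.data.frame(x), path, na = "NA")
  c(files, path)
}

#' Run the chronotype pipeline end-to-end
#'
#' Executes the requested stages in order (simulate, detect, standardise,
#' repeatability, fit, report), writing every artefact into the run
#' directory together with a config snapshot, a log of the row counts of
#' every filter, and a manifest listing each output with its MD5 checksum.
#' Identical config and seed give identical manifests. A stage error aborts
#' with a stage-named message and leaves a `STALE` marker in the run
#' directory.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `outdir`, `manifest` (tibble of file and
#'   checksum) and the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "nestclock_pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  logs <- c(sprintf("seed: %d", config$seed),
            sprintf("stages: %s", paste(config$stages, collapse = ",")))
  res <- list()
  stale_on_error <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines("STALE", file.path(config$outdir, "STALE"))
      abort(paste0("stage `", stage, "` failed: ", conditionMessage(e)))
    })
  }

  if ("simulate" %in% config$stages) {
    stale_on_error("simulate", {
      pop <- simulate_population(config$sim)
      onsets <- simulate_onsets(config$sim, pop)
      res$population <- pop
      res$onsets <- onsets
      files <- write_stage_table(pop$females, config$outdir, "truth_females.csv", files)
      files <- write_stage_table(pop$broods, config$outdir, "broods.csv", files)
      files <- write_stage_table(pop$nestlings, config$outdir, "nestlings.csv", files)
      files <- write_stage_table(pop$condition, config$outdir, "condition.csv", files)
      files <- write_stage_table(onsets, config$outdir, "onsets.csv", files)
      logs <- c(logs, sprintf("simulate: %d females, %d broods, %d onsets",
                              nrow(pop$females), nrow(pop$broods), nrow(onsets)))
    })
  } else if (!is.null(config$onset_path)) {
    res$onsets <- stale_on_error("input",
                                 read_table(config$onset_path, nestclock_schemas$onsets))
    if (!is.null(config$brood_path)) {
      res$population <- list(broods = read_table(config$brood_path,
                                                 nestclock_schemas$broods))
    }
  }

  if ("detect" %in% config$stages) {
    stale_on_error("detect", {
      if (is.null(config$traces)) abort("no trace inputs configured")
      amb <- readr::read_csv(config$ambient_path,
                             col_types = "Td", progress = FALSE)
      det <- list()
      broods <- res$population$broods
      for (tr in config$traces) {
        if (!file.exists(tr$path)) abort(paste0("input path missing: ", tr$path))
        trace <- parse_logger_export(tr$path, ambient = amb)
        start <- detect_incubation_start(trace)
        if (is.na(start)) next
        dates <- sort(unique(as.Date(trace$timestamp, tz = "UTC")))
        dates <- dates[dates >= start]
        th <- derive_thresholds(trace, dates)
        bouts <- detect_bouts(trace, th)
        brood <- broods[broods$brood_id == tr$brood_id, ]
        det[[length(det) + 1]] <- extract_daily_onsets(bouts, brood)
      }
      res$onsets <- dplyr::bind_rows(det)
      files <- write_stage_table(res$onsets, config$outdir,
                                 "onsets_detected.csv", files)
      logs <- c(logs, sprintf("detect: %d onsets from %d traces",
                              nrow(res$onsets), length(config$traces)))
    })
  }

  if ("standardise" %in% config$stages) {
    stale_on_error("standardise", {
      if (is.null(res$onsets)) abort("no onset table available")
      std <- standardise_onsets(res$onsets, min_females = config$min_females)
      std <- filter_measurement_set(std, min_onsets = config$min_onsets)
      chron <- compute_chronotype(std, broods = res$population$broods,
                                  exclude = config$exclude)
      res$std_onsets <- std
      res$chronotypes <- chron
      files <- write_stage_table(std, config$outdir, "std_onsets.csv", files)
      files <- write_stage_table(chron, config$outdir, "chronotypes.csv", files)
      dropped <- attr(std, "dropped")
      removed <- attr(std, "removed")
      logs <- c(logs,
                sprintf("standardise: %d onsets kept, %d dates dropped, %d broods below min onsets",
                        nrow(std), nrow(dropped) %||% 0L,
                        removed$n_broods_removed %||% 0L),
                sprintf("chronotypes: %d females", nrow(chron)))
    })
  }

  if ("repeatability" %in% config$stages) {
    stale_on_error("repeatability", {
      if (is.null(res$std_onsets)) abort("no standardised onsets available")
      rep <- onset_repeatability(res$std_onsets)
      res$repeatability <- rep
      files <- write_stage_table(tidy(rep), config$outdir,
                                 "repeatability_components.csv", files)
      files <- write_stage_table(rep$repeatability, config$outdir,
                                 "repeatability.csv", files)
      logs <- c(logs, sprintf("repeatability: n = %d onsets, %d females",
                              rep$vc$n_obs, rep$vc$n_females))
    })
  }

  if ("fit" %in% config$stages) {
    stale_on_error("fit", {
      if (is.null(res$chronotypes)) abort("no chronotype table available")
      pop <- res$population
      suite <- build_model_suite(res$chronotypes, pop$broods,
                                 nestlings = pop$nestlings,
                                 condition = pop$condition)
      red <- reduce_model_suite(suite, alpha = config$alpha)
      res$models <- red
      files <- write_stage_table(tidy_suite(red), config$outdir,
                                 "model_paths.csv", files)
      files <- write_stage_table(
        dplyr::bind_rows(lapply(red, glance)), config$outdir,
        "model_summaries.csv", files
      )
      logs <- c(logs, vapply(red, function(r) {
        sprintf("fit %s: n = %d, final terms = %s", r$spec$name, r$spec$n,
                if (length(r$final_terms)) paste(r$final_terms, collapse = "+") else "(intercept)")
      }, ""))
    })
  }

  writeLines(logs, file.path(config$outdir, "log.txt"))
  files <- c(files, file.path(config$outdir, "log.txt"))

  cfg_snapshot <- file.path(config$outdir, "config.txt")
  writeLines(c(
    sprintf("seed: %d", config$seed),
    sprintf("stages: %s", paste(config$stages, collapse = ",")),
    sprintf("min_females: %g", config$min_females),
    sprintf("min_onsets: %g", config$min_onsets),
    sprintf("alpha: %g", config$alpha),
    vapply(setdiff(names(config$sim), "outdir"), function(k) {
      sprintf("sim.%s: %s", k, paste(format(config$sim[[k]]), collapse = ","))
    }, "")
  ), cfg_snapshot)
  files <- c(files, cfg_snapshot)

  manifest <- tibble::tibble(
    file = basename(sort(unique(files))),
    md5 = unname(tools::md5sum(sort(unique(files))))
  )
  readr::write_csv(manifest, file.path(config$outdir, "manifest.csv"))
  res$manifest <- manifest
  res$outdir <- config$outdir

  if ("report" %in% config$stages) {
    stale_on_error("report", {
      report <- render_report(config$outdir)
      writeLines(report, file.path(config$outdir, "report.txt"))
    })
  }
  invisible(res)
}

#' Render a human-readable run summary
#'
#' Summarises a completed run directory: filter counts, repeatabilities and
#' per-model reduction tables. The body carries no timestamps, so a
#' deterministic run renders byte-identically.
#'
#' @param run_dir path to a [run_pipeline()] output directory.
#' @return character vector of report lines.
#' @export
render_report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.csv")
  if (!file.exists(man_path)) abort("no manifest found; run the pipeline first")
  lines <- c("nestclock run report", "=====================", "")
  log_path <- file.path(run_dir, "log.txt")
  if (file.exists(log_path)) {
    lines <- c(lines, "Run log:", readLines(log_path), "")
  }
  rep_path <- file.path(run_dir, "repeatability.csv")
  if (file.exists(rep_path)) {
    rep <- readr::read_csv(rep_path, show_col_types = FALSE)
    lines <- c(lines, sprintf(
      "Repeatability: r within year = %.3f, r across years = %.3f",
      rep$r_within_year[1], rep$r_across_year[1]
    ), "")
  }
  mod_path <- file.path(run_dir, "model_paths.csv")
  if (file.exists(mod_path)) {
    paths <- readr::read_csv(mod_path, show_col_types = FALSE)
    lines <- c(lines, "Model reduction paths:")
    for (resp in unique(paths$response)) {
      sub <- paths[paths$response == resp, ]
      lines <- c(lines, paste0("  ", resp, ":"))
      lines <- c(lines, sprintf(
        "    %-22s %-5s stat=%8s df=%3s p=%7s est=%8s retained=%s",
        sub$term, ifelse(is.na(sub$kind), "-", sub$kind),
        ifelse(is.na(sub$statistic), "-", sprintf("%.3f", sub$statistic)),
        ifelse(is.na(sub$df), "-", sub$df),
        ifelse(is.na(sub$p), "-", sprintf("%.4f", sub$p)),
        ifelse(is.na(sub$estimate), "-", sprintf("%.3f", sub$estimate)),
        sub$retained
      ))
    }
    lines <- c(lines, "")
  }
  man <- readr::read_csv(man_path, show_col_types = FALSE)
  lines <- c(lines, "Artefacts (md5):",
             sprintf("  %-32s %s", man$file, man$md5))
  lines
}
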