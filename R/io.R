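# Plain-text serialization: frames and estimates as CSV, schedules as a
# directory of CSVs (one per schedule), configurations as YAML.

#' Write a population frame to CSV
#'
#' Long format, one row per case, with columns `period`, `age_group`
#' (band label), `sex`, `education`, `activity`, `weight` plus the `id`,
#' `age` (band lower bound) and `origin` bookkeeping columns.
#'
#' @param frame a [population_frame()].
#' @param path output file.
#' @export
write_frame_csv <- function(frame, path) {
  df <- data.frame(period = frame_period(frame),
                   age_group = age_label(frame$age),
                   age = frame$age, sex = frame$sex,
                   education = frame$education, activity = frame$activity,
                   weight = frame$weight, id = frame$id,
                   origin = frame$origin)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a population frame from CSV
#' @param path file written by [write_frame_csv()].
#' @param ladder the [education_ladder()].
#' @return a [population_frame()].
#' @export
read_frame_csv <- function(path, ladder = education_ladder()) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  period <- unique(df$period)
  if (length(period) != 1L) stop("frame CSV must hold a single period")
  population_frame(df[FRAME_COLS], period, ladder)
}

#' Read aggregate base-population estimates from CSV
#'
#' Expects columns `age` (band lower bound), `sex`, `education` (empty for
#' under-15 cells), `count`.
#'
#' @param path CSV file.
#' @return data.frame suitable for [build_base_population()].
#' @export
read_estimates_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE, na.strings = "")
}

#' Write/read rate schedules as a directory of CSVs
#'
#' One CSV per schedule (`survival_ratios.csv`, `education_entry.csv`, ...)
#' with the column headers documented at [rate_schedules()].
#'
#' @param schedules a [rate_schedules()].
#' @param dir directory (created if needed).
#' @export
write_schedules_csv <- function(schedules, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in SCHEDULE_NAMES)
    write.csv(schedules[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_schedules_csv
#' @return `read_schedules_csv` returns a [rate_schedules()].
#' @export
read_schedules_csv <- function(dir) {
  tabs <- lapply(SCHEDULE_NAMES, function(nm) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop("missing schedule file: ", f)
    read.csv(f, stringsAsFactors = FALSE, na.strings = "")
  })
  names(tabs) <- SCHEDULE_NAMES
  do.call(rate_schedules, tabs)
}

#' Read a scenario configuration from YAML
#'
#' Recognized keys mirror the arguments of [scenario_config()].
#'
#' @param path YAML file.
#' @return a [scenario_config()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  ladder <- if (!is.null(y$education_levels))
    education_ladder(y$education_levels,
                     y$reference_level %||% "upper_secondary")
  else education_ladder()
  args <- y[intersect(names(y), names(formals(scenario_config)))]
  args$ladder <- ladder
  do.call(scenario_config, args)
}
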