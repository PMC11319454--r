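# Cohort data model: animal records, long observation tables, and the
# animals x parameters severity matrix assembled for a single assessment day
# and a single sex.

animals_cols <- c("animal_id", "sex", "group", "regimen", "batch")
obs_cols <- c("animal_id", "parameter", "phase", "timepoint", "value")

#' Load and validate a cohort from CSV files
#'
#' Reads an animal table (`animal_id, sex, group, regimen, batch`) and a
#' long-format observation table (`animal_id, parameter, phase, timepoint,
#' value`), validating both against the controlled vocabularies. CSV dialect:
#' comma-separated, UTF-8, `.` decimal, explicit `NA` token for missing
#' values. Missing observation values are kept as `NA` rows, never dropped.
#'
#' @param animals_file Path to the animal CSV.
#' @param observations_file Path to the observation CSV.
#' @param timepoints Allowed timepoint vocabulary; default [cms_timepoints()].
#' @return A `cms_cohort` list with elements `animals` and `observations`
#'   (both tibbles).
#' @export
load_cohort <- function(animals_file, observations_file,
                        timepoints = cms_timepoints()) {
  stopifnot(file.exists(animals_file), file.exists(observations_file))
  animals <- readr::read_csv(
    animals_file,
    col_types = readr::cols(.default = readr::col_character()),
    na = "NA", progress = FALSE
  )
  observations <- readr::read_csv(
    observations_file,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      parameter = readr::col_character(),
      phase = readr::col_character(),
      timepoint = readr::col_character(),
      value = readr::col_character()
    ),
    na = "NA", progress = FALSE
  )
  # strtod-based conversion: correctly rounded, so full-precision values
  # round-trip bit-identically
  observations$value <- as.numeric(observations$value)
  new_cohort(animals, observations, timepoints = timepoints)
}

#' Construct a validated cohort from in-memory tables
#'
#' @param animals Data frame of animal records.
#' @param observations Long-format data frame of observations.
#' @param timepoints Allowed timepoint vocabulary.
#' @return A `cms_cohort` list.
#' @export
new_cohort <- function(animals, observations, timepoints = cms_timepoints()) {
  animals <- tibble::as_tibble(animals)
  observations <- tibble::as_tibble(observations)
  validate_animals(animals)
  validate_observations(observations, animals, timepoints)
  structure(
    list(animals = animals, observations = observations),
    class = "cms_cohort"
  )
}

validate_animals <- function(animals) {
  missing_cols <- setdiff(animals_cols, names(animals))
  if (length(missing_cols) > 0) {
    stop("animal table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  dup <- animals$animal_id[duplicated(animals$animal_id)]
  if (length(dup) > 0) {
    stop("duplicated animal_id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(animals) == 0) return(invisible(animals))
  bad_sex <- setdiff(unique(animals$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    stop("unknown sex label(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  bad_group <- setdiff(unique(animals$group), cms_groups())
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  }
  bad_reg <- setdiff(unique(animals$regimen), cms_regimens())
  if (length(bad_reg) > 0) {
    stop("unknown regimen label(s): ", paste(bad_reg, collapse = ", "),
         call. = FALSE)
  }
  # regimen is "none" exactly for naive-control animals
  inconsistent <- (animals$regimen == "none") != (animals$group == "naive-control")
  if (any(inconsistent)) {
    stop("regimen 'none' must coincide with group 'naive-control'; offending ",
         "animal(s): ", paste(animals$animal_id[inconsistent], collapse = ", "),
         call. = FALSE)
  }
  invisible(animals)
}

validate_observations <- function(observations, animals, timepoints) {
  missing_cols <- setdiff(obs_cols, names(observations))
  if (length(missing_cols) > 0) {
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(observations) == 0) return(invisible(observations))
  unknown <- setdiff(unique(observations$animal_id), animals$animal_id)
  if (length(unknown) > 0) {
    stop("observation rows reference unknown animal_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad_phase <- setdiff(unique(observations$phase), cms_phases())
  if (length(bad_phase) > 0) {
    stop("unknown phase label(s): ", paste(bad_phase, collapse = ", "),
         call. = FALSE)
  }
  bad_tp <- setdiff(unique(observations$timepoint), timepoints)
  if (length(bad_tp) > 0) {
    stop("timepoint label(s) outside declared vocabulary: ",
         paste(bad_tp, collapse = ", "), call. = FALSE)
  }
  key <- paste(observations$animal_id, observations$parameter,
               observations$phase, observations$timepoint, sep = "\r")
  dup_rows <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup_rows) > 0) {
    first_dups <- head(dup_rows, 10)
    stop("duplicated (animal, parameter, phase, timepoint) observation row(s): ",
         paste(first_dups, collapse = ", "),
         if (length(dup_rows) > 10) " ..." else "", call. = FALSE)
  }
  invisible(observations)
}

#' @export
print.cms_cohort <- function(x, ...) {
  cat("<cms_cohort> ", nrow(x$animals), " animals, ",
      nrow(x$observations), " observation rows\n", sep = "")
  invisible(x)
}

#' Write a cohort back to CSV files
#'
#' Inverse of [load_cohort()]: writes `animals.csv` and `observations.csv`
#' in the package's CSV dialect. Numeric values are written at full
#' precision so a write/load round trip reproduces them bit-identically.
#'
#' @param cohort A `cms_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cms_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    animals = file.path(dir, "animals.csv"),
    observations = file.path(dir, "observations.csv")
  )
  readr::write_csv(cohort$animals, paths[["animals"]], na = "NA")
  obs <- cohort$observations
  # %.17g guarantees binary64 round-trip through the text representation
  obs$value <- ifelse(is.na(obs$value), NA_character_,
                      sprintf("%.17g", obs$value))
  readr::write_csv(obs, paths[["observations"]], na = "NA")
  invisible(paths)
}

#' Assemble the severity matrix for one assessment day and one sex
#'
#' Restricts the observation table to one sex and one assessment day (day 1
#' by default, where postsurgical alterations concentrate) and pivots the
#' requested parameters into a complete animals x parameters matrix.
#' Severity analyses are run for each sex separately, so a matrix always
#' holds a single sex.
#'
#' Animals missing any requested parameter are handled by the missingness
#' policy: `"drop_animal"` (listwise deletion, the default; dropped IDs are
#' reported in a message) or `"impute_median"` (replace by the parameter's
#' median over the remaining animals of that sex/day).
#'
#' @param cohort A `cms_cohort`.
#' @param parameters Character vector of parameter names to include.
#' @param day Timepoint label of the assessment day.
#' @param sex `"male"` or `"female"`.
#' @param missingness Missingness policy, see Details.
#' @return A numeric matrix (class `severity_matrix`) with animal IDs as row
#'   names, parameters as columns, and attributes `day` and `sex`.
#' @export
assemble_severity_matrix <- function(cohort, parameters = cms_default_parameters(),
                                     day = "day1", sex = c("male", "female"),
                                     missingness = c("drop_animal", "impute_median")) {
  stopifnot(inherits(cohort, "cms_cohort"))
  sex <- match.arg(sex)
  missingness <- match.arg(missingness)
  obs <- cohort$observations
  absent <- setdiff(parameters, unique(obs$parameter))
  if (length(absent) > 0) {
    stop("requested parameter(s) absent from the observation table: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  ids_sex <- cohort$animals$animal_id[cohort$animals$sex == sex]
  slab <- obs[obs$animal_id %in% ids_sex &
                obs$parameter %in% parameters &
                obs$timepoint == day, , drop = FALSE]
  if (nrow(slab) == 0) {
    stop("no observations for sex '", sex, "' at day '", day, "'", call. = FALSE)
  }
  for (p in parameters) {
    if (!any(slab$parameter == p & !is.na(slab$value))) {
      stop("parameter '", p, "' has no value for any ", sex,
           " animal at '", day, "'", call. = FALSE)
    }
  }
  wide <- tidyr::pivot_wider(
    slab[, c("animal_id", "parameter", "value")],
    names_from = "parameter", values_from = "value"
  )
  # ensure all requested parameters are present as columns, stable order
  for (p in setdiff(parameters, names(wide))) wide[[p]] <- NA_real_
  wide <- wide[order(wide$animal_id), c("animal_id", parameters)]
  m <- as.matrix(wide[, parameters, drop = FALSE])
  rownames(m) <- wide$animal_id

  incomplete <- rownames(m)[rowSums(is.na(m)) > 0]
  if (length(incomplete) > 0) {
    if (missingness == "drop_animal") {
      message("dropping ", length(incomplete),
              " animal(s) with missing parameter values: ",
              paste(incomplete, collapse = ", "))
      m <- m[setdiff(rownames(m), incomplete), , drop = FALSE]
    } else {
      for (j in seq_len(ncol(m))) {
        nas <- is.na(m[, j])
        if (any(nas)) m[nas, j] <- median(m[!nas, j])
      }
    }
  }
  if (nrow(m) == 0) stop("no complete animals remain after missingness policy",
                         call. = FALSE)
  structure(m, day = day, sex = sex, class = c("severity_matrix", "matrix", "array"))
}

#' @export
print.severity_matrix <- function(x, ...) {
  cat("<severity_matrix> ", nrow(x), " ", attr(x, "sex"), " animals x ",
      ncol(x), " parameters (", attr(x, "day"), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
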