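# ETL from simulated cohorts to OMOP Common Data Model v5.4 tables, with
# Colombian DIVIPOLA location handling (municipality -> city, department ->
# state) and fixture-based concept mapping. Source codes are always retained
# in *_source_value columns.

CDM_COLUMNS <- list(
  person = c("person_id", "gender_concept_id", "year_of_birth",
             "month_of_birth", "day_of_birth", "birth_datetime",
             "race_concept_id", "ethnicity_concept_id", "location_id",
             "provider_id", "care_site_id", "person_source_value",
             "gender_source_value", "gender_source_concept_id",
             "race_source_value", "race_source_concept_id",
             "ethnicity_source_value", "ethnicity_source_concept_id"),
  location = c("location_id", "address_1", "address_2", "city", "state",
               "zip", "county", "location_source_value",
               "country_concept_id", "country_source_value", "latitude",
               "longitude"),
  observation_period = c("observation_period_id", "person_id",
                         "observation_period_start_date",
                         "observation_period_end_date",
                         "period_type_concept_id"),
  visit_occurrence = c("visit_occurrence_id", "person_id",
                       "visit_concept_id", "visit_start_date",
                       "visit_start_datetime", "visit_end_date",
                       "visit_end_datetime", "visit_type_concept_id",
                       "provider_id", "care_site_id", "visit_source_value",
                       "visit_source_concept_id", "admitted_from_concept_id",
                       "admitted_from_source_value",
                       "discharged_to_concept_id",
                       "discharged_to_source_value",
                       "preceding_visit_occurrence_id"),
  condition_occurrence = c("condition_occurrence_id", "person_id",
                           "condition_concept_id", "condition_start_date",
                           "condition_start_datetime", "condition_end_date",
                           "condition_end_datetime",
                           "condition_type_concept_id",
                           "condition_status_concept_id", "stop_reason",
                           "provider_id", "visit_occurrence_id",
                           "visit_detail_id", "condition_source_value",
                           "condition_source_concept_id",
                           "condition_status_source_value"),
  procedure_occurrence = c("procedure_occurrence_id", "person_id",
                           "procedure_concept_id", "procedure_date",
                           "procedure_datetime", "procedure_end_date",
                           "procedure_end_datetime",
                           "procedure_type_concept_id",
                           "modifier_concept_id", "quantity", "provider_id",
                           "visit_occurrence_id", "visit_detail_id",
                           "procedure_source_value",
                           "procedure_source_concept_id",
                           "modifier_source_value"),
  death = c("person_id", "death_date", "death_datetime",
            "death_type_concept_id", "cause_concept_id",
            "cause_source_value", "cause_source_concept_id"))

#' Load a concept map
#'
#' Reads a CSV with header `vocabulary,source_code,concept_id` mapping source
#' vocabulary codes to OMOP concept ids. The bundled default
#' ([default_concept_map()]) is a synthetic stand-in for the licensed OMOP
#' vocabulary: its concept ids are fixture-defined, not official OHDSI ids,
#' except for CDM conventions such as the female gender concept.
#'
#' @param path CSV file path.
#' @return A `concept_map` data frame.
#' @export
load_concept_map <- function(path) {
  if (!file.exists(path)) stop("concept map not found: ", path,
                               call. = FALSE)
  cm <- utils::read.csv(path, colClasses = c("character", "character",
                                             "integer"),
                        strip.white = TRUE)
  if (!identical(names(cm), c("vocabulary", "source_code", "concept_id"))) {
    stop("concept map CSV must have header vocabulary,source_code,concept_id",
         call. = FALSE)
  }
  key <- paste(cm$vocabulary, cm$source_code, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (vocabulary, source_code) rows in concept map",
         call. = FALSE)
  }
  if (anyNA(cm$concept_id) || any(cm$concept_id < 0)) {
    stop("concept ids must be non-negative integers", call. = FALSE)
  }
  class(cm) <- c("concept_map", "data.frame")
  cm
}

#' Bundled synthetic concept map
#' @return The `concept_map` shipped with the package.
#' @export
default_concept_map <- function() {
  load_concept_map(system.file("extdata", "concept-map-synthetic.csv",
                               package = "gestsynth", mustWork = TRUE))
}

#' Map a source code to an OMOP concept id
#'
#' Unmapped (or empty) codes map to 0, the CDM fallback convention; the
#' source value is preserved downstream in `*_source_value` columns either
#' way.
#'
#' @param cm A `concept_map`.
#' @param vocabulary Source vocabulary name (vectorized).
#' @param code Source code (vectorized).
#' @return Integer concept id(s); 0 where unmapped.
#' @export
map_concept <- function(cm, vocabulary, code) {
  key <- paste(vocabulary, code, sep = "|")
  idx <- match(key, paste(cm$vocabulary, cm$source_code, sep = "|"))
  out <- cm$concept_id[idx]
  out[is.na(out) | is.na(code) | !nzchar(ifelse(is.na(code), "", code))] <- 0L
  as.integer(out)
}

record_type_id <- function(cm) {
  id <- map_concept(cm, "Type", "synthetic-record")
  id
}

#' Export a cohort to OMOP CDM v5.4 tables
#'
#' Builds the seven-table bundle — `person`, `location`,
#' `observation_period`, `visit_occurrence`, `condition_occurrence`,
#' `procedure_occurrence`, `death` — from a simulated cohort. Each
#' `Encounter` event becomes one visit row; each `ConditionOnset` event one
#' condition row linked to the visit active at onset; each `Procedure` event
#' one procedure row; `ConditionEnd` events close the latest open condition
#' row with the same code. `observation_period` spans each person's first to
#' last event. Locations map municipality to `city` and department to
#' `state` (DIVIPOLA codes). Rows are ordered by person id then event order,
#' so re-export of the same cohort is byte-identical.
#'
#' @param cohort List of `person_record`s with filled event logs.
#' @param cm A `concept_map`; default bundled fixture.
#' @param outdir Optional directory; when given, one CSV per table is
#'   written via [write_cdm()].
#' @return An `omop_bundle` (named list of data.tables), invisibly when
#'   `outdir` is given.
#' @export
export_cdm <- function(cohort, cm = default_concept_map(), outdir = NULL) {
  ids <- vapply(cohort, function(p) p$person_id, integer(1L))
  if (anyDuplicated(ids)) {
    stop("cohort contains duplicate person ids", call. = FALSE)
  }
  female_id <- map_concept(cm, "Gender", "F")
  type_id <- record_type_id(cm)

  pd <- data.table::data.table(
    person_id = ids,
    sex = vapply(cohort, function(p) p$sex, character(1L)),
    birthdate = as.Date(vapply(cohort, function(p) as.numeric(p$birthdate),
                               numeric(1L)), origin = "1970-01-01"),
    municipality = vapply(cohort, function(p) p$municipality, character(1L)),
    department = vapply(cohort, function(p) p$department, character(1L)))
  data.table::setorderv(pd, "person_id")

  loc <- unique(pd[, c("municipality", "department")])
  data.table::setorderv(loc, "municipality")
  loc[, location_id := seq_len(.N)]
  location <- data.table::data.table(
    location_id = loc$location_id,
    address_1 = NA_character_, address_2 = NA_character_,
    city = loc$municipality, state = loc$department,
    zip = NA_character_, county = NA_character_,
    location_source_value = loc$municipality,
    country_concept_id = map_concept(cm, "Country", "CO"),
    country_source_value = "CO",
    latitude = NA_real_, longitude = NA_real_)

  pd <- merge(pd, loc, by = c("municipality", "department"), sort = FALSE)
  data.table::setorderv(pd, "person_id")
  person <- data.table::data.table(
    person_id = pd$person_id,
    gender_concept_id = female_id,
    year_of_birth = as.integer(format(pd$birthdate, "%Y")),
    month_of_birth = as.integer(format(pd$birthdate, "%m")),
    day_of_birth = as.integer(format(pd$birthdate, "%d")),
    birth_datetime = format(pd$birthdate, "%Y-%m-%d 00:00:00"),
    race_concept_id = 0L, ethnicity_concept_id = 0L,
    location_id = pd$location_id,
    provider_id = NA_integer_, care_site_id = NA_integer_,
    person_source_value = sprintf("SYN-%06d", pd$person_id),
    gender_source_value = pd$sex,
    gender_source_concept_id = 0L,
    race_source_value = NA_character_, race_source_concept_id = 0L,
    ethnicity_source_value = NA_character_,
    ethnicity_source_concept_id = 0L)

  ev <- cohort_events(cohort)
  data.table::setorderv(ev, c("person_id", "event"))
  ev[, row_id := seq_len(.N)]

  # One visit per Encounter event (events with several codes keep one visit)
  enc <- ev[kind == "Encounter"][!duplicated(paste(person_id, event))]
  enc[, visit_occurrence_id := seq_len(.N)]
  visit_occurrence <- data.table::data.table(
    visit_occurrence_id = enc$visit_occurrence_id,
    person_id = enc$person_id,
    visit_concept_id = map_concept(cm, enc$system, enc$code),
    visit_start_date = enc$date,
    visit_start_datetime = format(enc$date, "%Y-%m-%d 00:00:00"),
    visit_end_date = enc$date,
    visit_end_datetime = format(enc$date, "%Y-%m-%d 00:00:00"),
    visit_type_concept_id = type_id,
    provider_id = NA_integer_, care_site_id = NA_integer_,
    visit_source_value = paste0(enc$code, "|", enc$display),
    visit_source_concept_id = 0L,
    admitted_from_concept_id = 0L, admitted_from_source_value = NA_character_,
    discharged_to_concept_id = 0L, discharged_to_source_value = NA_character_,
    preceding_visit_occurrence_id = NA_integer_)

  # Active visit for every event: latest Encounter at or before it
  ev[, vid := NA_integer_]
  ev[enc$row_id, vid := enc$visit_occurrence_id]
  ev[, vid := data.table::nafill(vid, type = "locf"), by = person_id]

  cond <- ev[kind == "ConditionOnset"]
  condition_occurrence <- data.table::data.table(
    condition_occurrence_id = seq_len(nrow(cond)),
    person_id = cond$person_id,
    condition_concept_id = map_concept(cm, cond$system, cond$code),
    condition_start_date = cond$date,
    condition_start_datetime = format(cond$date, "%Y-%m-%d 00:00:00"),
    condition_end_date = as.Date(NA),
    condition_end_datetime = NA_character_,
    condition_type_concept_id = type_id,
    condition_status_concept_id = 0L,
    stop_reason = NA_character_,
    provider_id = NA_integer_,
    visit_occurrence_id = as.integer(cond$vid),
    visit_detail_id = NA_integer_,
    condition_source_value = paste0(cond$code, "|", cond$display),
    condition_source_concept_id = 0L,
    condition_status_source_value = NA_character_)
  # stash for ConditionEnd resolution
  cond_key <- paste(cond$person_id, cond$code)

  ends <- ev[kind == "ConditionEnd"]
  if (nrow(ends) > 0L) {
    for (i in seq_len(nrow(ends))) {
      open <- which(cond_key == paste(ends$person_id[i], ends$code[i]) &
                      is.na(condition_occurrence$condition_end_date) &
                      condition_occurrence$condition_start_date <=
                        ends$date[i])
      if (length(open)) {
        j <- open[length(open)]
        data.table::set(condition_occurrence, i = j,
                        j = "condition_end_date", value = ends$date[i])
        data.table::set(condition_occurrence, i = j,
                        j = "condition_end_datetime",
                        value = format(ends$date[i], "%Y-%m-%d 00:00:00"))
      }
    }
  }

  proc <- ev[kind == "Procedure"]
  procedure_occurrence <- data.table::data.table(
    procedure_occurrence_id = seq_len(nrow(proc)),
    person_id = proc$person_id,
    procedure_concept_id = map_concept(cm, proc$system, proc$code),
    procedure_date = proc$date,
    procedure_datetime = format(proc$date, "%Y-%m-%d 00:00:00"),
    procedure_end_date = proc$date,
    procedure_end_datetime = format(proc$date, "%Y-%m-%d 00:00:00"),
    procedure_type_concept_id = type_id,
    modifier_concept_id = 0L,
    quantity = 1L,
    provider_id = NA_integer_,
    visit_occurrence_id = as.integer(proc$vid),
    visit_detail_id = NA_integer_,
    procedure_source_value = paste0(proc$code, "|", proc$display),
    procedure_source_concept_id = 0L,
    modifier_source_value = NA_character_)

  op <- ev[, .(start = min(date), end = max(date)), by = person_id]
  data.table::setorderv(op, "person_id")
  observation_period <- data.table::data.table(
    observation_period_id = seq_len(nrow(op)),
    person_id = op$person_id,
    observation_period_start_date = op$start,
    observation_period_end_date = op$end,
    period_type_concept_id = type_id)

  dth <- ev[kind == "Death"]
  death <- data.table::data.table(
    person_id = dth$person_id,
    death_date = dth$date,
    death_datetime = format(dth$date, "%Y-%m-%d 00:00:00"),
    death_type_concept_id = rep(type_id, nrow(dth)),
    cause_concept_id = map_concept(cm, dth$system, dth$code),
    cause_source_value = ifelse(is.na(dth$code), NA_character_,
                                paste0(dth$code, "|", dth$display)),
    cause_source_concept_id = 0L)

  bundle <- structure(list(person = person, location = location,
                           observation_period = observation_period,
                           visit_occurrence = visit_occurrence,
                           condition_occurrence = condition_occurrence,
                           procedure_occurrence = procedure_occurrence,
                           death = death),
                      class = "omop_bundle",
                      female_concept_id = female_id)
  for (tb in names(CDM_COLUMNS)) {
    stopifnot(identical(names(bundle[[tb]]), CDM_COLUMNS[[tb]]))
  }
  if (!is.null(outdir)) {
    write_cdm(bundle, outdir)
    return(invisible(bundle))
  }
  bundle
}

#' @export
print.omop_bundle <- function(x, ...) {
  cat("OMOP CDM v5.4 bundle:\n")
  for (tb in names(x)) cat(sprintf("  %-22s %7d rows\n", tb, nrow(x[[tb]])))
  invisible(x)
}

#' Write an OMOP bundle as CSV files
#'
#' One RFC-4180 CSV per table, named `person.csv`, `location.csv`,
#' `observation_period.csv`, `visit_occurrence.csv`,
#' `condition_occurrence.csv`, `procedure_occurrence.csv`, `death.csv`.
#' Dates serialize ISO-8601; encoding UTF-8.
#'
#' @param bundle An `omop_bundle`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_cdm <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (tb in names(bundle)) {
    data.table::fwrite(bundle[[tb]], file.path(outdir, paste0(tb, ".csv")),
                       quote = "auto", dateTimeAs = "ISO", bom = FALSE,
                       eol = "\n", na = "")
  }
  invisible(outdir)
}

#' Check referential integrity of an OMOP bundle
#'
#' Verifies the bundle invariants: unique person ids; every foreign
#' `person_id` present in `person`; every `visit_occurrence_id` referenced by
#' a condition or procedure row present in `visit_occurrence`; source codes
#' retained in `*_source_value`; every person recorded with the generator's
#' female gender concept; and location `state` equal to the first two digits
#' of the DIVIPOLA municipality code.
#'
#' @param bundle An `omop_bundle`.
#' @return Issue data frame (zero rows when all invariants hold).
#' @export
integrity_check <- function(bundle) {
  iss <- list()
  add <- function(kind, message) {
    iss[[length(iss) + 1L]] <<- issue_df(kind, NA_character_, message,
                                         "error")
  }
  per <- bundle$person
  if (anyDuplicated(per$person_id)) add("duplicate-person",
                                        "duplicate person_id in person")
  female_id <- attr(bundle, "female_concept_id")
  if (!is.null(female_id) && any(per$gender_concept_id != female_id)) {
    add("sex", "person rows with a non-female gender concept in a pregnancy cohort")
  }
  for (tb in c("observation_period", "visit_occurrence",
               "condition_occurrence", "procedure_occurrence", "death")) {
    orphan <- setdiff(bundle[[tb]]$person_id, per$person_id)
    if (length(orphan)) {
      add("orphan-person",
          sprintf("%s references %d person_id(s) missing from person",
                  tb, length(orphan)))
    }
  }
  vids <- bundle$visit_occurrence$visit_occurrence_id
  for (tb in c("condition_occurrence", "procedure_occurrence")) {
    ref <- bundle[[tb]]$visit_occurrence_id
    orphan <- setdiff(ref[!is.na(ref)], vids)
    if (length(orphan)) {
      add("orphan-visit",
          sprintf("%s references %d visit id(s) missing from visit_occurrence",
                  tb, length(orphan)))
    }
  }
  for (tb in c("condition_occurrence", "procedure_occurrence")) {
    src <- bundle[[tb]][[sub("_occurrence", "_source_value", tb)]]
    if (nrow(bundle[[tb]]) && (anyNA(src) || any(!nzchar(src)))) {
      add("missing-source-value",
          sprintf("%s rows without a retained source code", tb))
    }
  }
  if (any(!is.na(per$location_id) &
            !per$location_id %in% bundle$location$location_id)) {
    add("orphan-location", "person references a missing location_id")
  }
  loc <- bundle$location
  if (nrow(loc) &&
      any(substr(loc$location_source_value, 1L, 2L) != loc$state)) {
    add("location-prefix",
        "location state does not prefix the municipality code")
  }
  if (length(iss)) do.call(rbind, iss) else issue_df()
}
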