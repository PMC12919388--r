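# Person generation: female sex, birthdate from a uniform age model, and
# municipality/department drawn from DIVIPOLA-coded population weights.

#' Load municipality population weights
#'
#' Reads a CSV with header `municipality,department,weight` where
#' `municipality` is a 5-digit DIVIPOLA code, `department` its 2-digit
#' department prefix, and `weight` a non-negative sampling weight (relative
#' population). Weights are normalized to sum to 1. The bundled default
#' ([default_weights()]) is a synthetic 30-municipality stand-in with
#' plausible relative populations; real census data can be supplied as a
#' user CSV in the same layout.
#'
#' @param path CSV file path.
#' @return A `location_weights` data frame with normalized weights.
#' @export
load_weights <- function(path) {
  if (!file.exists(path)) stop("weights file not found: ", path,
                               call. = FALSE)
  w <- utils::read.csv(path, colClasses = c("character", "character",
                                            "numeric"),
                       strip.white = TRUE)
  if (!identical(names(w), c("municipality", "department", "weight"))) {
    stop("weights CSV must have header municipality,department,weight",
         call. = FALSE)
  }
  if (nrow(w) == 0L) stop("weights CSV is empty", call. = FALSE)
  if (anyDuplicated(w$municipality)) {
    stop("duplicate municipality codes: ",
         paste(unique(w$municipality[duplicated(w$municipality)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(w$weight) || any(w$weight < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  if (sum(w$weight) <= 0) stop("weights must sum to a positive total",
                               call. = FALSE)
  bad <- substr(w$municipality, 1L, 2L) != w$department
  if (any(bad)) {
    stop("municipality codes not prefixed by their department code: ",
         paste(w$municipality[bad], collapse = ", "), call. = FALSE)
  }
  w$weight <- w$weight / sum(w$weight)
  class(w) <- c("location_weights", "data.frame")
  w
}

#' Bundled synthetic municipality weights
#'
#' @return The `location_weights` shipped with the package (synthetic
#'   stand-in for a national census distribution).
#' @export
default_weights <- function() {
  load_weights(system.file("extdata", "municipality-weights-synthetic.csv",
                           package = "gestsynth", mustWork = TRUE))
}

#' Restrict weights to one department
#'
#' @param w A `location_weights` object.
#' @param dept 2-digit DIVIPOLA department code.
#' @return Renormalized `location_weights` over that department's
#'   municipalities.
#' @export
filter_department <- function(w, dept) {
  keep <- w$department == dept
  if (!any(keep)) {
    stop("department '", dept, "' not present in the weight table",
         call. = FALSE)
  }
  out <- w[keep, , drop = FALSE]
  out$weight <- out$weight / sum(out$weight)
  rownames(out) <- NULL
  class(out) <- c("location_weights", "data.frame")
  out
}

#' Sample one synthetic person
#'
#' Draws municipality proportional to weight, assigns female sex (the
#' generator produces pregnancy records only), a conception (last menstrual
#' period) date uniform over `index_window`, and a birthdate such that age at
#' conception is uniform over `age_range` whole years. The draw uses the
#' stream derived from `(seed, person_id)`, so a person's demographics do not
#' depend on cohort size or ordering.
#'
#' @param w A `location_weights` object.
#' @param seed Cohort master seed.
#' @param person_id Integer person identifier.
#' @param age_range Integer vector `c(min, max)` of completed years at
#'   conception; default 15-49.
#' @param index_window `Date` vector `c(first, last)` bounding the conception
#'   date; default calendar year 2023.
#' @return A `person_record`: `person_id`, `sex` (`"F"`), `birthdate`,
#'   `municipality`, `department`, `index_date`, and an `events` slot filled
#'   by the engine.
#' @export
sample_person <- function(w, seed, person_id = 1L,
                          age_range = c(15L, 49L),
                          index_window = as.Date(c("2023-01-01",
                                                   "2023-12-31"))) {
  stopifnot(inherits(w, "location_weights"))
  with_preserved_rng({
    set.seed(person_seed(seed, person_id, 1L))
    cw <- cumsum(w$weight)
    u <- stats::runif(1L)
    idx <- which(u <= cw)[1L]
    if (is.na(idx)) idx <- nrow(w)

    span_days <- as.integer(index_window[2L] - index_window[1L]) + 1L
    index_date <- index_window[1L] +
      floor(stats::runif(1L) * span_days)
    age_years <- age_range[1L] +
      floor(stats::runif(1L) * (age_range[2L] - age_range[1L] + 1L))
    extra_days <- floor(stats::runif(1L) * 365)
    birthdate <- index_date - round(age_years * 365.25) - extra_days

    structure(list(person_id = as.integer(person_id), sex = "F",
                   birthdate = birthdate,
                   municipality = w$municipality[idx],
                   department = w$department[idx],
                   index_date = index_date, events = NULL),
              class = "person_record")
  })
}

#' @export
print.person_record <- function(x, ...) {
  cat(sprintf("Person %d (sex %s, born %s) — municipality %s, department %s, LMP %s\n",
              x$person_id, x$sex, format(x$birthdate), x$municipality,
              x$department, format(x$index_date)))
  if (!is.null(x$events)) {
    cat(sprintf("  %d clinical events\n", nrow(x$events)))
  }
  invisible(x)
}

#' Generate and simulate a full cohort
#'
#' Samples `n` person records from the weight table and walks each through
#' the module under per-person seeded streams. With `department = "all"`
#' municipalities are drawn from the full national weight table (equivalent
#' to a multinomial allocation of persons across departments by weight);
#' otherwise weights are first restricted to the requested department.
#'
#' @param n Cohort size.
#' @param seed Master seed; the whole cohort is a pure function of it.
#' @param weights A `location_weights` object; default bundled fixture.
#' @param module A `module_definition`; default calibrated gestation module.
#' @param department `"all"` or a 2-digit department code.
#' @param age_range,index_window Passed to [sample_person()].
#' @return List of `person_record`s, each with its `events` log filled.
#' @export
generate_cohort <- function(n, seed, weights = default_weights(),
                            module = default_pregnancy_module(),
                            department = "all",
                            age_range = c(15L, 49L),
                            index_window = as.Date(c("2023-01-01",
                                                     "2023-12-31"))) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("cohort size must be >= 1", call. = FALSE)
  if (!identical(department, "all")) {
    weights <- filter_department(weights, department)
  }
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    p <- sample_person(weights, seed, person_id = i,
                       age_range = age_range, index_window = index_window)
    p$events <- simulate_person(module, p, person_seed(seed, i, 2L))
    cohort[[i]] <- p
  }
  cohort
}

#' Flatten a cohort's event logs into one table
#'
#' @param cohort List of `person_record`s with filled `events`.
#' @return A `data.table` with a `person_id` column followed by the
#'   `event_log` columns.
#' @export
cohort_events <- function(cohort) {
  logs <- lapply(cohort, function(p) {
    stopifnot(inherits(p, "person_record"))
    if (is.null(p$events)) {
      stop("person ", p$person_id, " has no simulated events", call. = FALSE)
    }
    ev <- as.data.frame(p$events)
    ev$person_id <- rep(p$person_id, nrow(ev))
    ev
  })
  out <- data.table::rbindlist(logs)
  data.table::setcolorder(out, "person_id")
  out[]
}
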