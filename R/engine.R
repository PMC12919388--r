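# Generic clinical state-machine engine: typed states with probabilistic
# transitions, loaded from JSON module files and executed per person under a
# seeded random stream. Time advances in whole gestational weeks.

STATE_KINDS <- c("Initial", "Simple", "Delay", "Encounter", "ConditionOnset",
                 "ConditionEnd", "Procedure", "Observation", "SetAttribute",
                 "Death", "Terminal")
CODE_SYSTEMS <- c("SNOMED-CT", "CIE-10", "CUPS")
# Kinds that must carry >= 1 coded concept
CODED_KINDS <- c("Encounter", "ConditionOnset", "ConditionEnd", "Procedure",
                 "Observation")
# Kinds that append an event to the log (Death may carry an optional cause code)
EVENT_KINDS <- c(CODED_KINDS, "Death")

#' Create a coded clinical concept
#'
#' A concept is a (vocabulary, code, display) triple. Supported vocabularies
#' are SNOMED-CT for conditions and findings, CIE-10 (the Spanish ICD-10) for
#' diagnoses, and CUPS (Colombia's unified health-procedure classification)
#' for procedures.
#'
#' @param system One of `"SNOMED-CT"`, `"CIE-10"`, `"CUPS"`.
#' @param code Non-empty code string.
#' @param display Human-readable label; defaults to the code.
#' @return An object of class `coded_concept`.
#' @export
#' @examples
#' coded_concept("SNOMED-CT", "34801009", "Embarazo ectopico")
coded_concept <- function(system, code, display = as.character(code)) {
  if (length(system) != 1L || !system %in% CODE_SYSTEMS) {
    stop("unknown code system '", paste(system, collapse = ","),
         "'; expected one of ", paste(CODE_SYSTEMS, collapse = ", "),
         call. = FALSE)
  }
  code <- as.character(code)
  if (length(code) != 1L || is.na(code) || !nzchar(code)) {
    stop("concept code must be a single non-empty string", call. = FALSE)
  }
  structure(list(system = system, code = code,
                 display = as.character(display)),
            class = "coded_concept")
}

#' @export
print.coded_concept <- function(x, ...) {
  cat(sprintf("<%s %s> %s\n", x$system, x$code, x$display))
  invisible(x)
}

branch_spec <- function(target, probability = NA_real_, predicate = NULL) {
  list(target = as.character(target), probability = probability,
       predicate = predicate)
}

new_transition <- function(mode, branches) {
  structure(list(mode = mode, branches = branches), class = "transition")
}

#' Transition constructors
#'
#' A transition routes a walk to its next state. `transition_direct()` always
#' moves to `target`. `transition_distributed()` draws the target from a
#' discrete distribution whose probabilities must sum to 1.
#' `transition_conditional()` evaluates attribute predicates in declared order
#' and takes the first branch that holds; the final branch must be a catch-all
#' (no predicate) so a walk can never dead-end.
#'
#' @param target,targets State name(s) to route to.
#' @param probabilities Numeric vector aligned with `targets`, summing to 1.
#' @param ... For `transition_conditional()`, branches built with
#'   `conditional_branch()`.
#' @return A `transition` object.
#' @export
transition_direct <- function(target) {
  new_transition("Direct", list(branch_spec(target, 1)))
}

#' @rdname transition_direct
#' @export
transition_distributed <- function(targets, probabilities) {
  stopifnot(length(targets) == length(probabilities))
  new_transition("Distributed",
                 unname(Map(branch_spec, targets, probabilities)))
}

#' @rdname transition_direct
#' @export
transition_conditional <- function(...) {
  new_transition("Conditional", list(...))
}

#' Conditional branch with an optional attribute predicate
#'
#' @param target State name to route to.
#' @param attribute Person attribute name tested by the predicate; `NULL`
#'   makes this a catch-all branch.
#' @param op One of `"eq"`, `"ne"`, `"exists"`, `"absent"`.
#' @param value Comparison value for `eq`/`ne`.
#' @export
conditional_branch <- function(target, attribute = NULL, op = "eq",
                               value = NULL) {
  pred <- if (is.null(attribute)) NULL else
    list(attribute = attribute, op = op, value = value)
  branch_spec(target, predicate = pred)
}

#' Create a module state
#'
#' @param name State name, unique within the module.
#' @param kind One of the supported state kinds: `Initial`, `Simple`, `Delay`,
#'   `Encounter`, `ConditionOnset`, `ConditionEnd`, `Procedure`,
#'   `Observation`, `SetAttribute`, `Death`, `Terminal`.
#' @param codes List of [coded_concept()] objects; clinical kinds require at
#'   least one.
#' @param delay For `Delay` states, either a single non-negative integer
#'   (weeks) or a length-2 integer vector `c(low, high)` drawn uniformly.
#' @param attribute,value For `SetAttribute` states.
#' @param transition A `transition` object; required for every kind except
#'   `Terminal`.
#' @return An object of class `module_state`.
#' @export
module_state <- function(name, kind, codes = list(), delay = NULL,
                         attribute = NULL, value = NULL, transition = NULL) {
  structure(list(name = as.character(name), kind = as.character(kind),
                 codes = codes, delay = delay, attribute = attribute,
                 value = value, transition = transition),
            class = "module_state")
}

#' Assemble a module definition
#'
#' A module is a named directed graph of typed clinical states with
#' probabilistic transitions — the state machine a simulated person walks
#' from conception to a terminal outcome.
#'
#' @param name Module name.
#' @param states List of [module_state()] objects.
#' @param initial Name of the initial state.
#' @return An object of class `module_definition`.
#' @seealso [validate_module()], [load_module()], [simulate_person()]
#' @export
module_definition <- function(name, states, initial) {
  nms <- vapply(states, function(s) s$name, character(1L))
  if (anyDuplicated(nms)) {
    stop("duplicate state names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(states) <- nms
  structure(list(name = as.character(name), states = states,
                 initial = as.character(initial)),
            class = "module_definition")
}

#' @export
print.module_definition <- function(x, ...) {
  ct <- count_elements(x)
  cat(sprintf("Clinical module '%s': %d states (initial: %s)\n",
              x$name, ct[["states"]], x$initial))
  cat(sprintf("  encounters: %d  procedures: %d  distinct condition codes: %d  death states: %d\n",
              ct[["encounters"]], ct[["procedures"]], ct[["conditions"]],
              ct[["death"]]))
  invisible(x)
}

issue_df <- function(kind = character(), state = character(),
                     message = character(), severity = character()) {
  data.frame(kind = kind, state = state, message = message,
             severity = severity, stringsAsFactors = FALSE)
}

#' Validate a module definition
#'
#' Audits the full invariant set: a single `Initial` state matching the
#' declared entry point, existing transition targets, probability mass
#' conservation on `Distributed` transitions (tolerance 1e-9), required codes
#' on clinical states, non-negative whole-week delays, catch-all branches on
#' `Conditional` transitions, reachability of a `Terminal` state, and
#' unreachable states (reported at severity `"warning"`).
#'
#' @param m A `module_definition`.
#' @return A data frame of issues with columns `kind`, `state`, `message`,
#'   `severity`; zero rows when every invariant holds.
#' @export
validate_module <- function(m) {
  stopifnot(inherits(m, "module_definition"))
  iss <- list()
  add <- function(kind, state, message, severity = "error") {
    iss[[length(iss) + 1L]] <<- issue_df(kind, state, message, severity)
  }

  nms <- names(m$states)
  kinds <- vapply(m$states, function(s) s$kind, character(1L))

  bad_kind <- nms[!kinds %in% STATE_KINDS]
  for (s in bad_kind) {
    add("bad-kind", s, sprintf("state '%s' has unknown kind '%s'",
                               s, m$states[[s]]$kind))
  }

  inits <- nms[kinds == "Initial"]
  if (length(inits) != 1L) {
    add("initial-count", NA_character_,
        sprintf("module must have exactly one Initial state, found %d",
                length(inits)))
  }
  if (!m$initial %in% nms) {
    add("initial-missing", m$initial,
        sprintf("declared initial state '%s' does not exist", m$initial))
  } else if (m$states[[m$initial]]$kind != "Initial") {
    add("initial-kind", m$initial,
        sprintf("declared initial state '%s' has kind '%s', not Initial",
                m$initial, m$states[[m$initial]]$kind))
  }

  for (s in m$states) {
    if (s$kind %in% CODED_KINDS && length(s$codes) == 0L) {
      add("missing-codes", s$name,
          sprintf("state '%s' (%s) must carry at least one coded concept",
                  s$name, s$kind))
    }
    for (cc in s$codes) {
      if (!is.list(cc) || is.null(cc$system) || is.null(cc$code) ||
          !cc$system %in% CODE_SYSTEMS || !nzchar(as.character(cc$code))) {
        add("bad-code", s$name,
            sprintf("state '%s' carries a malformed coded concept", s$name))
      }
    }
    if (s$kind == "Delay") {
      d <- s$delay
      if (is.null(d) || !is.numeric(d) || !length(d) %in% 1:2 ||
          anyNA(d) || any(d < 0) || any(d != floor(d)) ||
          (length(d) == 2L && d[1L] > d[2L])) {
        add("bad-delay", s$name,
            sprintf("state '%s' needs a non-negative whole-week delay (scalar or low <= high range)",
                    s$name))
      }
    }
    if (s$kind == "SetAttribute" &&
        (is.null(s$attribute) || !nzchar(s$attribute))) {
      add("bad-attribute", s$name,
          sprintf("SetAttribute state '%s' needs an attribute name", s$name))
    }
    if (s$kind == "Terminal") {
      if (!is.null(s$transition)) {
        add("terminal-transition", s$name,
            sprintf("Terminal state '%s' must not carry a transition", s$name))
      }
      next
    }
    tr <- s$transition
    if (is.null(tr)) {
      add("missing-transition", s$name,
          sprintf("state '%s' (%s) has no transition", s$name, s$kind))
      next
    }
    for (b in tr$branches) {
      if (!b$target %in% nms) {
        add("unknown-target", s$name,
            sprintf("state '%s' transitions to unknown target '%s'",
                    s$name, b$target))
      }
    }
    if (tr$mode == "Direct") {
      ok <- length(tr$branches) == 1L &&
        isTRUE(all.equal(tr$branches[[1L]]$probability, 1))
      if (!ok) {
        add("bad-direct", s$name,
            sprintf("state '%s': Direct transition needs exactly one branch with probability 1",
                    s$name))
      }
    } else if (tr$mode == "Distributed") {
      p <- vapply(tr$branches, function(b) as.numeric(b$probability),
                  numeric(1L))
      if (anyNA(p) || any(p < 0) || any(p > 1)) {
        add("bad-probability", s$name,
            sprintf("state '%s': Distributed branch probabilities must lie in [0, 1]",
                    s$name))
      } else if (abs(sum(p) - 1) > 1e-9) {
        add("probability-mass", s$name,
            sprintf("state '%s': Distributed probabilities sum to %.12g, not 1",
                    s$name, sum(p)))
      }
    } else if (tr$mode == "Conditional") {
      if (length(tr$branches) == 0L ||
          !is.null(tr$branches[[length(tr$branches)]]$predicate)) {
        add("missing-catchall", s$name,
            sprintf("state '%s': Conditional transition needs a final catch-all branch",
                    s$name))
      }
    } else {
      add("bad-mode", s$name,
          sprintf("state '%s': unknown transition mode '%s'", s$name, tr$mode))
    }
  }

  # Reachability from the initial state
  if (m$initial %in% nms) {
    seen <- new.env(parent = emptyenv())
    queue <- m$initial
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      if (!is.null(seen[[cur]])) next
      seen[[cur]] <- TRUE
      tr <- m$states[[cur]]$transition
      if (!is.null(tr)) {
        for (b in tr$branches) {
          if (b$target %in% nms && is.null(seen[[b$target]])) {
            queue <- c(queue, b$target)
          }
        }
      }
    }
    reached <- nms[vapply(nms, function(n) !is.null(seen[[n]]), logical(1L))]
    for (s in setdiff(nms, reached)) {
      add("unreachable", s,
          sprintf("state '%s' is unreachable from '%s'", s, m$initial),
          severity = "warning")
    }
    if (!any(kinds[nms %in% reached] == "Terminal")) {
      add("no-terminal", NA_character_,
          "no Terminal state is reachable from the initial state")
    }
  }

  if (length(iss)) do.call(rbind, iss) else issue_df()
}

#' Write validation issues to disk
#'
#' @param issues Issue data frame from [validate_module()] or
#'   [integrity_check()].
#' @param path Output file.
#' @param format `"text"` (one line per issue) or `"json"`.
#' @export
write_issues <- function(issues, path, format = c("text", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(issues, path, dataframe = "rows", na = "null")
  } else {
    lines <- if (nrow(issues) == 0L) "no issues" else
      sprintf("[%s] %s: %s", issues$severity, issues$kind, issues$message)
    writeLines(lines, path)
  }
  invisible(path)
}

concept_from_list <- function(x) {
  coded_concept(x$system, x$code,
                if (is.null(x$display)) as.character(x$code) else x$display)
}

transition_from_list <- function(x) {
  branches <- lapply(x$branches, function(b) {
    branch_spec(b$target,
                probability = if (is.null(b$probability)) NA_real_
                              else as.numeric(b$probability),
                predicate = b$predicate)
  })
  new_transition(x$mode, branches)
}

module_from_list <- function(x) {
  if (is.null(x$name) || is.null(x$states) || is.null(x$initial)) {
    stop("module JSON must have 'name', 'states' and 'initial' fields",
         call. = FALSE)
  }
  states <- lapply(names(x$states), function(nm) {
    s <- x$states[[nm]]
    if (is.null(s$kind)) {
      stop("state '", nm, "' is missing its 'kind' field", call. = FALSE)
    }
    delay <- s$delay
    if (!is.null(delay) && is.list(delay)) {
      delay <- c(as.numeric(delay$low), as.numeric(delay$high))
    }
    module_state(
      name = nm, kind = s$kind,
      codes = lapply(s$codes, concept_from_list),
      delay = delay,
      attribute = s$attribute, value = s$value,
      transition = if (is.null(s$transition)) NULL
                   else transition_from_list(s$transition))
  })
  module_definition(x$name, states, x$initial)
}

#' Load and validate a JSON module definition
#'
#' Parses a module file in the package's JSON dialect (schema shipped at
#' `system.file("schema", "module-schema.json", package = "gestsynth")`),
#' builds the `module_definition`, and raises a single error listing every
#' invariant violation if any check at severity `"error"` fails. Unreachable
#' states are tolerated at load time but reported by [validate_module()].
#'
#' @param path Path to a UTF-8 JSON module file.
#' @return A valid `module_definition`.
#' @export
load_module <- function(path) {
  if (!file.exists(path)) stop("module file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stop("malformed module JSON in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  m <- module_from_list(raw)
  issues <- validate_module(m)
  bad <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(bad) > 0L) {
    stop("invalid module '", m$name, "':\n",
         paste0("  - ", bad$message, collapse = "\n"), call. = FALSE)
  }
  m
}

delay_to_list <- function(d) {
  if (is.null(d) || length(d) == 1L) d else list(low = d[1L], high = d[2L])
}

#' Serialize a module definition to JSON
#'
#' @param m A `module_definition`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_module <- function(m, path) {
  stopifnot(inherits(m, "module_definition"))
  states <- lapply(m$states, function(s) {
    out <- list(kind = s$kind)
    if (length(s$codes)) {
      out$codes <- lapply(s$codes, function(cc) {
        list(system = cc$system, code = cc$code, display = cc$display)
      })
    }
    if (!is.null(s$delay)) out$delay <- delay_to_list(s$delay)
    if (!is.null(s$attribute)) {
      out$attribute <- s$attribute
      out$value <- s$value
    }
    if (!is.null(s$transition)) {
      out$transition <- list(
        mode = s$transition$mode,
        branches = lapply(s$transition$branches, function(b) {
          br <- list(target = b$target)
          if (!is.na(b$probability)) br$probability <- b$probability
          if (!is.null(b$predicate)) br$predicate <- b$predicate
          br
        }))
    }
    out
  })
  jsonlite::write_json(list(name = m$name, initial = m$initial,
                            states = states),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Count module elements by kind
#'
#' Inventory of the model: total states, `Encounter` states, `Procedure`
#' states, distinct `ConditionOnset` codes, `Observation` states and `Death`
#' states.
#'
#' @param m A `module_definition`.
#' @return Named integer vector with elements `states`, `encounters`,
#'   `procedures`, `conditions`, `observations`, `death`.
#' @export
count_elements <- function(m) {
  stopifnot(inherits(m, "module_definition"))
  kinds <- vapply(m$states, function(s) s$kind, character(1L))
  cond_codes <- unlist(lapply(m$states[kinds == "ConditionOnset"],
                              function(s) {
                                vapply(s$codes, function(cc) {
                                  paste(cc$system, cc$code, sep = "|")
                                }, character(1L))
                              }))
  c(states = length(m$states),
    encounters = sum(kinds == "Encounter"),
    procedures = sum(kinds == "Procedure"),
    conditions = length(unique(cond_codes)),
    observations = sum(kinds == "Observation"),
    death = sum(kinds == "Death"))
}

predicate_holds <- function(p, attrs) {
  val <- get0(p$attribute, envir = attrs, inherits = FALSE)
  switch(p$op,
         eq = !is.null(val) && isTRUE(all.equal(val, p$value)),
         ne = is.null(val) || !isTRUE(all.equal(val, p$value)),
         exists = !is.null(val),
         absent = is.null(val),
         stop("unknown predicate op '", p$op, "'", call. = FALSE))
}

next_state <- function(tr, attrs) {
  if (tr$mode == "Direct") return(tr$branches[[1L]]$target)
  if (tr$mode == "Distributed") {
    u <- stats::runif(1L)
    acc <- 0
    for (b in tr$branches) {
      acc <- acc + b$probability
      if (u <= acc) return(b$target)
    }
    return(tr$branches[[length(tr$branches)]]$target)
  }
  for (b in tr$branches) {
    if (is.null(b$predicate) || predicate_holds(b$predicate, attrs)) {
      return(b$target)
    }
  }
  stop("Conditional transition fell through every branch", call. = FALSE)
}

with_preserved_rng <- function(expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

#' Derive a per-person random seed from a cohort master seed
#'
#' Cohort seed `k` derives person `i`'s stream deterministically from
#' `(k, i, stage)`, so cohorts are order-independent: person `i` draws the
#' same trajectory whether generated alone or within any cohort ordering.
#' Stages separate the demographic draw from the clinical walk.
#'
#' @param master Cohort master seed (integer).
#' @param i Person id.
#' @param stage Integer stream selector (0 = generic, 1 = demographics,
#'   2 = simulation).
#' @return A 32-bit integer seed.
#' @export
person_seed <- function(master, i, stage = 0L) {
  m <- 2147483647
  x <- (as.numeric(master) %% m) * 48271 %% m
  x <- (x + as.numeric(i) * 69621 + as.numeric(stage) * 1013904 + 12345) %% m
  as.integer(x)
}

#' Simulate one person's walk through a module
#'
#' Executes the state machine from its initial state to a terminal state.
#' `Delay` states advance the clock in whole weeks; clinical states append one
#' event per coded concept to the log; `Distributed` transitions draw from the
#' seeded stream. The walk is a pure function of `(module, person, seed)`:
#' identical inputs give identical event logs, and the caller's RNG state is
#' left untouched.
#'
#' Gestational weeks are recorded on events while the person attribute
#' `pregnant` is true (set by the module via `SetAttribute` states) and are
#' `NA` otherwise, so postpartum events carry no gestational week.
#'
#' @param module A valid `module_definition`.
#' @param person A `person_record` (needs `index_date`, the date the walk
#'   starts — for the gestation module, the last menstrual period).
#' @param seed Integer seed for this person's stream.
#' @param max_steps Step budget guarding against authoring cycles
#'   (default 10,000).
#' @return An `event_log` data frame: `event`, `date`, `gestational_week`,
#'   `state`, `kind`, `system`, `code`, `display`.
#' @export
simulate_person <- function(module, person, seed, max_steps = 10000L) {
  stopifnot(inherits(module, "module_definition"))
  if (is.null(person$index_date)) {
    stop("person must carry an index_date", call. = FALSE)
  }
  with_preserved_rng({
    set.seed(as.integer(seed))
    states <- list2env(module$states, parent = emptyenv())
    attrs <- new.env(parent = emptyenv())

    cap <- 64L
    n <- 0L
    ev_id <- integer(cap); ev_date <- numeric(cap); ev_week <- integer(cap)
    ev_state <- character(cap); ev_kind <- character(cap)
    ev_system <- character(cap); ev_code <- character(cap)
    ev_display <- character(cap)

    day <- as.numeric(as.Date(person$index_date))
    week <- 0L
    cur <- module$initial
    steps <- 0L
    eid <- 0L

    repeat {
      steps <- steps + 1L
      if (steps > max_steps) {
        stop("simulation of module '", module$name,
             "' exceeded the step budget (", max_steps,
             " steps); check the module for cycles", call. = FALSE)
      }
      s <- states[[cur]]
      if (is.null(s)) stop("walk reached unknown state '", cur, "'",
                           call. = FALSE)
      kind <- s$kind
      if (kind == "Delay") {
        d <- s$delay
        dw <- if (length(d) == 2L) {
          d[1L] + floor(stats::runif(1L) * (d[2L] - d[1L] + 1L))
        } else d
        week <- week + as.integer(dw)
        day <- day + 7 * dw
      } else if (kind == "SetAttribute") {
        assign(s$attribute, s$value, envir = attrs)
      } else if (kind %in% EVENT_KINDS) {
        gw <- if (isTRUE(get0("pregnant", envir = attrs, inherits = FALSE))) {
          week
        } else NA_integer_
        codes <- s$codes
        if (length(codes) == 0L) {
          codes <- list(list(system = NA_character_, code = NA_character_,
                             display = NA_character_))
        }
        eid <- eid + 1L
        for (cc in codes) {
          n <- n + 1L
          if (n > cap) {
            cap <- cap * 2L
            length(ev_id) <- cap; length(ev_date) <- cap
            length(ev_week) <- cap; length(ev_state) <- cap
            length(ev_kind) <- cap; length(ev_system) <- cap
            length(ev_code) <- cap; length(ev_display) <- cap
          }
          ev_id[n] <- eid; ev_date[n] <- day; ev_week[n] <- gw
          ev_state[n] <- cur; ev_kind[n] <- kind
          ev_system[n] <- cc$system; ev_code[n] <- cc$code
          ev_display[n] <- cc$display
        }
      } else if (kind == "Terminal") {
        break
      }
      cur <- next_state(s$transition, attrs)
    }

    idx <- seq_len(n)
    structure(
      data.frame(event = ev_id[idx],
                 date = as.Date(ev_date[idx], origin = "1970-01-01"),
                 gestational_week = ev_week[idx],
                 state = ev_state[idx], kind = ev_kind[idx],
                 system = ev_system[idx], code = ev_code[idx],
                 display = ev_display[idx], stringsAsFactors = FALSE),
      class = c("event_log", "data.frame"))
  })
}
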