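# State-machine engine: module loading, validation, counting, simulation.

test_that("a minimal module loads from JSON and simulates one condition event", {
  path <- write_module_json(toy_module())
  m <- load_module(path)
  expect_s3_class(m, "module_definition")
  expect_length(m$states, 3L)
  expect_identical(unname(count_elements(m)[c("states", "conditions")]),
                   c(3L, 1L))

  log <- simulate_person(m, toy_person(), seed = 7L)
  expect_s3_class(log, "event_log")
  expect_identical(sum(log$kind == "ConditionOnset"), 1L)
  expect_identical(log$code, "111")
})

test_that("load_module rejects malformed files with informative errors", {
  bad_json <- tempfile(fileext = ".json")
  writeLines("{not json", bad_json)
  expect_error(load_module(bad_json), "malformed")

  m <- split_module(0.6)
  m$states$fork$transition$branches[[2L]]$probability <- 0.5
  expect_error(load_module(write_module_json(m)), "fork")

  m2 <- toy_module()
  m2$states$cond$transition <- transition_direct("nowhere")
  expect_error(load_module(write_module_json(m2)), "unknown target")
})

test_that("validate_module reports every violation as data and passes clean modules", {
  expect_identical(nrow(validate_module(toy_module())), 0L)
  expect_identical(nrow(validate_module(split_module(0.5))), 0L)

  m <- toy_module()
  m$states$orphan <- module_state("orphan", "Simple",
                                  transition = transition_direct("end"))
  iss <- validate_module(m)
  expect_identical(iss$kind, "unreachable")
  expect_identical(iss$state, "orphan")
  expect_identical(iss$severity, "warning")

  # several violations surface at once
  m2 <- split_module(0.6)
  m2$states$fork$transition$branches[[2L]]$probability <- 0.5
  m2$states$a$codes <- list()
  iss2 <- validate_module(m2)
  expect_setequal(iss2$kind, c("probability-mass", "missing-codes"))
})

test_that("state and transition invariants are enforced", {
  # Terminal must not carry a transition
  m <- toy_module()
  m$states$end$transition <- transition_direct("start")
  expect_match(validate_module(m)$kind, "terminal-transition", all = FALSE)

  # Delay needs whole non-negative weeks
  m <- module_definition("d", list(
    module_state("start", "Initial", transition = transition_direct("w")),
    module_state("w", "Delay", delay = -1,
                 transition = transition_direct("end")),
    module_state("end", "Terminal")), initial = "start")
  expect_match(validate_module(m)$kind, "bad-delay", all = FALSE)

  # Conditional transitions require a final catch-all
  m <- module_definition("c", list(
    module_state("start", "Initial", transition = transition_conditional(
      conditional_branch("end", attribute = "x", op = "exists"))),
    module_state("end", "Terminal")), initial = "start")
  expect_match(validate_module(m)$kind, "missing-catchall", all = FALSE)

  # exactly one Initial state
  m <- toy_module()
  m$states$cond$kind <- "Initial"
  m$states$cond$codes <- list()
  expect_match(validate_module(m)$kind, "initial-count", all = FALSE)
})

test_that("simulation is a pure function of (module, person, seed)", {
  m <- default_pregnancy_module()
  p <- toy_person()
  a <- simulate_person(m, p, seed = 123L)
  b <- simulate_person(m, p, seed = 123L)
  expect_identical(a, b)

  # and it does not disturb the caller's RNG stream
  set.seed(99)
  u1 <- runif(1)
  set.seed(99)
  invisible(simulate_person(m, p, seed = 123L))
  expect_identical(runif(1), u1)
})

test_that("degenerate and distributed branches behave as drawn", {
  # probability 1 to one branch: always taken
  m <- split_module(1)
  hits <- vapply(1:25, function(s) {
    simulate_person(m, toy_person(), seed = s)$code
  }, character(1L))
  expect_true(all(hits == "A1"))

  # empirical branch frequency over many draws within 4 standard errors
  p <- 0.3
  m <- split_module(p)
  n <- 100000L
  took_a <- vapply(seq_len(n), function(s) {
    simulate_person(m, toy_person(), seed = s)$code == "A1"
  }, logical(1L))
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(took_a) - p), 4 * se)
})

test_that("delays advance the clock in whole weeks and ranges stay in bounds", {
  m <- module_definition("delays", list(
    module_state("start", "Initial", transition = transition_direct("p0")),
    module_state("p0", "SetAttribute", attribute = "pregnant", value = TRUE,
                 transition = transition_direct("w1")),
    module_state("w1", "Delay", delay = 3L,
                 transition = transition_direct("e1")),
    module_state("e1", "Encounter",
                 codes = list(coded_concept("SNOMED-CT", "E", "visit")),
                 transition = transition_direct("w2")),
    module_state("w2", "Delay", delay = c(2L, 5L),
                 transition = transition_direct("e2")),
    module_state("e2", "Encounter",
                 codes = list(coded_concept("SNOMED-CT", "E", "visit")),
                 transition = transition_direct("end")),
    module_state("end", "Terminal")), initial = "start")
  p <- toy_person()
  for (s in 1:50) {
    log <- simulate_person(m, p, seed = s)
    expect_identical(log$gestational_week[1L], 3L)
    expect_true(log$gestational_week[2L] %in% 5:8)
    expect_identical(as.integer(log$date[2L] - log$date[1L]),
                     7L * (log$gestational_week[2L] - 3L))
  }
})

test_that("a cyclic module without terminal progress hits the step budget", {
  m <- module_definition("loop", list(
    module_state("start", "Initial", transition = transition_direct("a")),
    module_state("a", "Simple", transition = transition_direct("b")),
    module_state("b", "Simple", transition = transition_direct("a")),
    module_state("end", "Terminal")), initial = "start")
  expect_error(simulate_person(m, toy_person(), seed = 1L, max_steps = 500L),
               "step budget")
})

test_that("conditional transitions route on person attributes in order", {
  mk <- function(val) module_definition("cond", list(
    module_state("start", "Initial", transition = transition_direct("set")),
    module_state("set", "SetAttribute", attribute = "flag", value = val,
                 transition = transition_direct("route")),
    module_state("route", "Simple", transition = transition_conditional(
      conditional_branch("yes", attribute = "flag", op = "eq", value = TRUE),
      conditional_branch("no"))),
    module_state("yes", "ConditionOnset",
                 codes = list(coded_concept("SNOMED-CT", "Y", "y")),
                 transition = transition_direct("end")),
    module_state("no", "ConditionOnset",
                 codes = list(coded_concept("SNOMED-CT", "N", "n")),
                 transition = transition_direct("end")),
    module_state("end", "Terminal")), initial = "start")
  expect_identical(simulate_person(mk(TRUE), toy_person(), 1L)$code, "Y")
  expect_identical(simulate_person(mk(FALSE), toy_person(), 1L)$code, "N")
})

test_that("modules round-trip through their JSON serialization", {
  m <- default_pregnancy_module()
  path <- write_module_json(m)
  m2 <- load_module(path)
  expect_identical(count_elements(m2), count_elements(m))
  expect_identical(names(m2$states), names(m$states))
  p <- toy_person()
  expect_identical(simulate_person(m2, p, 11L), simulate_person(m, p, 11L))
})

test_that("the shipped gestation module JSON matches the built-in builder", {
  path <- system.file("extdata", "gestation-module.json",
                      package = "gestsynth")
  m <- load_module(path)
  expect_identical(count_elements(m), count_elements(default_pregnancy_module()))
  p <- toy_person()
  expect_identical(simulate_person(m, p, 5L),
                   simulate_person(default_pregnancy_module(), p, 5L))
})

test_that("issue reports emit as text and JSON", {
  m <- toy_module()
  m$states$orphan <- module_state("orphan", "Simple",
                                  transition = transition_direct("end"))
  iss <- validate_module(m)
  txt <- tempfile(fileext = ".txt")
  js <- tempfile(fileext = ".json")
  write_issues(iss, txt, "text")
  write_issues(iss, js, "json")
  expect_match(readLines(txt), "unreachable", all = FALSE)
  parsed <- jsonlite::fromJSON(js)
  expect_identical(parsed$kind, "unreachable")
})
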