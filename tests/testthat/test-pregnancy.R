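# Gestation module: calibration algebra, inventory, trimester placement.
# The enumeration oracle lives in helper-oracles.R.

test_that("conditional gate probabilities follow the survivor algebra", {
  g <- conditional_from_marginals(default_gates())
  # no prior gates: conditional equals the marginal
  expect_equal(g$conditional[g$code == "34801009"], 218 / 10637,
               tolerance = 1e-12)
  # after the ectopic gate removes its mass
  expect_equal(g$conditional[g$code == "19169002"], 1714 / 10419,
               tolerance = 1e-12)
  # after both first-trimester terminating gates
  expect_equal(g$conditional[g$code == "85116003"], 636 / 8705,
               tolerance = 1e-12)
  # among the 8069 women reaching delivery
  expect_equal(g$conditional[g$code == "367494004"], 603 / 8069,
               tolerance = 1e-12)
  expect_equal(g$conditional[g$code == "47821001"], 1443 / 8069,
               tolerance = 1e-12)
})

test_that("enumeration of gate sequences recovers the input marginals", {
  g <- conditional_from_marginals(default_gates())
  marg <- enumerate_marginals(g$conditional, g$terminates_pregnancy)
  expect_equal(marg, g$marginal, tolerance = 1e-12)
  # forward product identity: conditional * survivor mass before the gate
  expect_equal(g$conditional * g$survivor_before, g$marginal,
               tolerance = 1e-12)
})

test_that("infeasible marginal sets are rejected", {
  g <- default_gates()
  g$marginal[g$code == "34801009"] <- 0.999
  expect_error(conditional_from_marginals(g), "infeasible")
  g2 <- default_gates()
  g2$marginal[1L] <- 1.2
  expect_error(conditional_from_marginals(g2), "\\[0, 1\\]")
})

test_that("the gestation module carries the reference inventory", {
  ct <- count_elements(default_pregnancy_module())
  expect_identical(unname(ct["conditions"]), 16L)
  expect_identical(unname(ct["encounters"]), 16L)
  expect_identical(unname(ct["death"]), 1L)

  # ectopic pregnancy is coded on its onset state
  m <- default_pregnancy_module()
  ect <- m$states$ectopic_pregnancy_onset
  expect_identical(ect$kind, "ConditionOnset")
  expect_identical(ect$codes[[1L]]$code, "34801009")

  # vaccination procedures per the antenatal guideline
  proc_names <- names(m$states)[vapply(m$states, function(s)
    s$kind == "Procedure", logical(1L))]
  expect_true(all(c("tetanus_vaccination", "influenza_vaccination",
                    "pertussis_vaccination") %in% proc_names))

  # the maternal death branch carries probability 0 by default
  br <- m$states$gate_maternal_death$transition$branches
  expect_identical(br[[1L]]$target, "maternal_death")
  expect_identical(br[[1L]]$probability, 0)
  expect_identical(nrow(validate_module(m)[
    validate_module(m)$severity == "error", ]), 0L)
})

test_that("literature reference ranges match the design table", {
  rr <- default_reference_ranges()
  expect_identical(nrow(rr), 14L)
  get <- function(code) unlist(rr[rr$code == code, c("lower", "upper")],
                               use.names = FALSE)
  expect_identical(get("47821001"), c(4, 6))     # postpartum hemorrhage
  expect_identical(get("367494004"), c(7.2, 7.2)) # preterm newborn (point)
  expect_identical(get("44223004"), c(8, 10))    # PROM
  expect_identical(get("19169002"), c(10, 20))   # abortion, 1st trimester
  expect_true(all(rr$lower >= 0 & rr$lower <= rr$upper & rr$upper <= 100))
})

test_that("complications onset in their clinical window on a simulated cohort", {
  m <- default_pregnancy_module()
  coh <- generate_cohort(1500L, seed = 77L)
  ev <- cohort_events(coh)
  cond <- ev[ev$kind == "ConditionOnset", ]

  wk <- function(code) cond$gestational_week[cond$code == code]
  expect_true(all(wk("34801009") <= 13))             # ectopic: 1st trimester
  expect_true(all(wk("19169002") <= 13))             # abortion T1
  expect_true(all(wk("85116003") >= 14 & wk("85116003") <= 26)) # abortion T2
  expect_true(all(wk("106004004") >= 27))            # 3rd-trimester hemorrhage
  expect_true(all(wk("367494004") >= 33 & wk("367494004") < 37)) # preterm birth

  # postpartum hemorrhage only after a delivery admission, never during
  # pregnancy (its gestational week is NA because the pregnancy has ended)
  pph <- ev[ev$code == "47821001" & ev$kind == "ConditionOnset", ]
  expect_true(all(is.na(pph$gestational_week)))
  deliv <- ev[ev$state == "delivery_admission", ]
  expect_true(all(pph$person_id %in% deliv$person_id))
  dd <- deliv$date[match(pph$person_id, deliv$person_id)]
  expect_true(all(pph$date >= dd))

  # gestational weeks never decrease while the pregnancy is active
  mono <- tapply(ev$gestational_week, ev$person_id, function(w) {
    w <- w[!is.na(w)]
    !is.unsorted(w)
  })
  expect_true(all(mono))

  # term deliveries happen at weeks 37-41
  term_wk <- ev$gestational_week[ev$state == "delivery_admission"]
  preterm_ids <- unique(cond$person_id[cond$code == "367494004"])
  term_only <- term_wk[!deliv$person_id %in% preterm_ids]
  expect_true(all(term_only >= 37 & term_only <= 41))
})

test_that("every simulated person is female and PROM never fires by default", {
  coh <- generate_cohort(800L, seed = 3L)
  expect_true(all(vapply(coh, function(p) p$sex, character(1L)) == "F"))
  ev <- cohort_events(coh)
  expect_identical(nrow(ev[ev$code == "44223004", ]), 0L)
})

test_that("gate marginals are honoured at modest cohort size", {
  coh <- generate_cohort(2000L, seed = 11L)
  tab <- tabulate_conditions(coh)
  g <- conditional_from_marginals(default_gates())
  tg <- g[match(tab$code, g$code), ]
  se <- sqrt(tg$marginal * (1 - tg$marginal) / 2000)
  expect_true(all(abs(tab$count / 2000 - tg$marginal) <= 4 * se + 1e-12))
})

test_that("overriding a gate marginal rewires the module", {
  g <- default_gates()
  g$marginal[g$code == "44223004"] <- 0.5   # force PROM common
  m <- build_pregnancy_module(g)
  coh <- lapply(1:200, function(i) {
    p <- toy_person(i)
    p$events <- simulate_person(m, p, seed = 1000L + i)
    p
  })
  tab <- tabulate_conditions(coh)
  expect_gt(tab$count[tab$code == "44223004"], 0L)
})
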