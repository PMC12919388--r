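# The Colombian gestation pathway: prenatal encounter schedule,
# trimester-anchored complication gates, vaccinations, delivery and
# postpartum care. Gate probabilities are calibrated so cohort-level
# marginal frequencies reproduce the reference 10,637-woman cohort.

#' Reference cohort size used for the default calibration
#' @export
REFERENCE_COHORT_SIZE <- 10637L

#' Default complication gates
#'
#' The ordered gate table that calibrates the gestation module. Each row is a
#' scheduled Bernoulli decision point ("gate") where a complication may onset:
#' `marginal` is the target fraction of the *full* cohort with the condition,
#' `week` the gestational week of the gate, and `terminates_pregnancy` flags
#' gates that end the pathway (ectopic pregnancy and the two abortion gates).
#' Marginals for the 14 reported conditions are the observed counts of the
#' reference cohort over 10,637; placenta previa and abruptio placentae are
#' not reported there and default to 0.005 each (configurable placeholders
#' that complete the 16-condition inventory). Premature rupture of membranes
#' has marginal 0, so the default cohort never generates it. The postpartum
#' hemorrhage gate sits after delivery (`week = NA`).
#'
#' @param cohort_size Denominator for count-based marginals.
#' @return A `gate_spec` data frame with columns `system`, `code`, `display`,
#'   `count`, `marginal`, `week`, `terminates_pregnancy`.
#' @export
default_gates <- function(cohort_size = REFERENCE_COHORT_SIZE) {
  g <- data.frame(
    system = "SNOMED-CT",
    code = c("34801009", "19169002", "85116003",
             "48194001", "38341003", "37618003", "398254007", "198992004",
             "40801000119106", "22033007", "106004004", "36813001",
             "44223004", "415105001", "367494004", "47821001"),
    display = c("Embarazo ectópico",
                "Aborto en el primer trimestre",
                "Aborto en el segundo trimestre",
                "Hipertensión inducida por el embarazo",
                "Hipertensión arterial, trastornos",
                "Complicación de hipertensión arterial en el embarazo",
                "Preeclampsia",
                "Eclampsia",
                "Diabetes mellitus gestacional",
                "Restricción del crecimiento fetal",
                "Complicaciones hemorrágicas del embarazo",
                "Placenta previa",
                "Ruptura prematura de membranas",
                "Abruptio de placenta",
                "Recién nacido prematuro",
                "Hemorragia posparto"),
    count = c(218L, 1714L, 636L, 107L, 604L, 92L, 802L, 445L, 696L, 30L,
              172L, NA, 0L, NA, 603L, 1443L),
    week = c(8L, 10L, 16L, 20L, 20L, 20L, 22L, 24L, 26L, 28L, 28L, 28L,
             30L, 30L, 32L, NA),
    terminates_pregnancy = c(TRUE, TRUE, TRUE, rep(FALSE, 13L)),
    stringsAsFactors = FALSE)
  g$marginal <- ifelse(is.na(g$count), 0.005, g$count / cohort_size)
  class(g) <- c("gate_spec", "data.frame")
  g
}

#' Derive conditional gate probabilities from cohort marginals
#'
#' Converts target marginal frequencies into the per-gate conditional
#' probabilities the state machine actually draws. Gates fire in order; a
#' terminating gate removes its mass from the pool still pregnant, so for
#' gate g the conditional probability among women reaching it is
#' `marginal(g) / (1 - sum of marginals of earlier terminating gates)`.
#' Forward-multiplying each conditional by the survivor mass before its gate
#' recovers the input marginals exactly.
#'
#' @param gates A `gate_spec` data frame ordered by gate position
#'   (terminating first-trimester gates before later gates).
#' @return `gates` with columns `conditional` and `survivor_before`
#'   (survivor mass entering each gate) appended.
#' @examples
#' g <- conditional_from_marginals(default_gates())
#' g$conditional[g$code == "34801009"]  # 218/10637, no prior gates
#' @export
conditional_from_marginals <- function(gates) {
  stopifnot(is.data.frame(gates),
            all(c("marginal", "terminates_pregnancy") %in% names(gates)))
  if (any(gates$marginal < 0 | gates$marginal > 1)) {
    stop("gate marginals must lie in [0, 1]", call. = FALSE)
  }
  n <- nrow(gates)
  cond <- numeric(n)
  surv_before <- numeric(n)
  surv <- 1
  for (i in seq_len(n)) {
    if (surv <= 0) {
      stop("infeasible calibration: survivor mass is ", surv,
           " entering gate '", gates$code[i], "'", call. = FALSE)
    }
    surv_before[i] <- surv
    cond[i] <- gates$marginal[i] / surv
    if (cond[i] > 1 + 1e-12) {
      stop("infeasible calibration: gate '", gates$code[i],
           "' needs conditional probability ", format(cond[i]),
           " > 1", call. = FALSE)
    }
    cond[i] <- min(cond[i], 1)
    if (gates$terminates_pregnancy[i]) surv <- surv - gates$marginal[i]
  }
  gates$conditional <- cond
  gates$survivor_before <- surv_before
  gates
}

#' Literature reference ranges for the reported conditions
#'
#' Percent prevalence ranges from the obstetric literature used by the
#' validation report; point estimates have `lower == upper`.
#'
#' @return A data frame with columns `system`, `code`, `display`, `lower`,
#'   `upper` (percent), one row per reported condition (14 rows).
#' @export
default_reference_ranges <- function() {
  g <- default_gates()
  keep <- !g$code %in% c("36813001", "415105001")
  out <- g[keep, c("system", "code", "display")]
  lit <- list(
    "34801009" = c(2, 2), "19169002" = c(10, 20), "85116003" = c(5, 5),
    "48194001" = c(2, 8), "38341003" = c(2, 8), "37618003" = c(2, 8),
    "398254007" = c(2, 8), "198992004" = c(2, 8),
    "40801000119106" = c(2, 5), "22033007" = c(8, 10),
    "367494004" = c(7.2, 7.2), "44223004" = c(8, 10),
    "106004004" = c(4, 4), "47821001" = c(4, 6))
  out$lower <- vapply(out$code, function(cd) lit[[cd]][1L], numeric(1L))
  out$upper <- vapply(out$code, function(cd) lit[[cd]][2L], numeric(1L))
  stopifnot(all(out$lower <= out$upper))
  rownames(out) <- NULL
  out
}

sn <- function(code, display) list(coded_concept("SNOMED-CT", code, display))
cups <- function(code, display) list(coded_concept("CUPS", code, display))

#' Build the Colombian gestation module
#'
#' Assembles the full pathway as a `module_definition`: a weekly delay
#' backbone to week 43, ten prenatal controls plus two ultrasound visits, an
#' emergency visit, a delivery admission, a postpartum control and a
#' pregnancy-loss management visit (16 Encounter states); 16 distinct
#' condition codes on trimester-anchored gates; vaccination procedures
#' (tetanus, influenza, pertussis) per the Colombian antenatal guideline; and
#' one maternal-death outcome state whose inbound probability defaults to 0,
#' mirroring a model in which no maternal deaths are generated.
#'
#' Terminating gates (ectopic, first- and second-trimester abortion) route to
#' a loss-management visit and end the pathway. Preterm birth is drawn at
#' week 32 and shortens the delivery delay (delivery at weeks 33–36 versus
#' 37–41 at term); the preterm-newborn condition is recorded at delivery.
#' Postpartum hemorrhage is drawn immediately after delivery.
#'
#' @param gates Gate table; defaults to the calibrated [default_gates()].
#'   A `conditional` column is derived via [conditional_from_marginals()]
#'   when absent.
#' @param p_maternal_death Probability of the maternal-death branch after
#'   postpartum hemorrhage; default 0.
#' @param name Module name.
#' @return A valid `module_definition`.
#' @export
build_pregnancy_module <- function(gates = default_gates(),
                                   p_maternal_death = 0,
                                   name = "colombian_gestation") {
  if (!"conditional" %in% names(gates)) {
    gates <- conditional_from_marginals(gates)
  }
  pg <- function(code) {
    p <- gates$conditional[match(code, gates$code)]
    if (is.na(p)) stop("gate table is missing condition code ", code,
                       call. = FALSE)
    p
  }
  cg <- function(code) {
    i <- match(code, gates$code)
    list(coded_concept(gates$system[i], gates$code[i], gates$display[i]))
  }

  st <- list()
  add <- function(s) st[[length(st) + 1L]] <<- s
  # A complication gate: Distributed draw between onset and the next state.
  gate <- function(gate_name, onset_name, code, after_onset, next_name) {
    add(module_state(gate_name, "Simple",
                     transition = transition_distributed(
                       c(onset_name, next_name), c(pg(code), 1 - pg(code)))))
    add(module_state(onset_name, "ConditionOnset", codes = cg(code),
                     transition = transition_direct(after_onset)))
  }
  delay <- function(name, weeks, next_name) {
    add(module_state(name, "Delay", delay = weeks,
                     transition = transition_direct(next_name)))
  }
  encounter <- function(name, codes, next_name) {
    add(module_state(name, "Encounter", codes = codes,
                     transition = transition_direct(next_name)))
  }
  procedure <- function(name, codes, next_name) {
    add(module_state(name, "Procedure", codes = codes,
                     transition = transition_direct(next_name)))
  }

  control_code <- function(i) {
    sn("424525001", sprintf("Control prenatal %d", i))
  }

  add(module_state("start", "Initial",
                   transition = transition_direct("set_pregnant")))
  add(module_state("set_pregnant", "SetAttribute", attribute = "pregnant",
                   value = TRUE,
                   transition = transition_direct("delay_to_week_8")))

  # --- First trimester -----------------------------------------------------
  delay("delay_to_week_8", 8L, "prenatal_control_1")
  encounter("prenatal_control_1", control_code(1L), "gate_ectopic")
  gate("gate_ectopic", "ectopic_pregnancy_onset", "34801009",
       "loss_management_visit", "delay_to_week_10")
  delay("delay_to_week_10", 2L, "gate_abortion_t1")
  gate("gate_abortion_t1", "abortion_t1_onset", "19169002",
       "loss_management_visit", "delay_to_week_12")
  delay("delay_to_week_12", 2L, "prenatal_control_2")
  encounter("prenatal_control_2", control_code(2L), "ultrasound_visit_1")
  encounter("ultrasound_visit_1",
            sn("169230002", "Visita para ecografía obstétrica"),
            "ultrasound_scan_1")
  procedure("ultrasound_scan_1",
            cups("881431", "Ecografía obstétrica"),
            "delay_to_week_16")

  # --- Second trimester ----------------------------------------------------
  delay("delay_to_week_16", 4L, "prenatal_control_3")
  encounter("prenatal_control_3", control_code(3L), "gate_abortion_t2")
  gate("gate_abortion_t2", "abortion_t2_onset", "85116003",
       "loss_management_visit", "delay_to_week_20")
  delay("delay_to_week_20", 4L, "prenatal_control_4")
  encounter("prenatal_control_4", control_code(4L), "gate_pih")
  gate("gate_pih", "pih_onset", "48194001",
       "gate_chronic_hypertension", "gate_chronic_hypertension")
  gate("gate_chronic_hypertension", "chronic_hypertension_onset", "38341003",
       "gate_hypertension_complication", "gate_hypertension_complication")
  gate("gate_hypertension_complication", "hypertension_complication_onset",
       "37618003", "delay_to_week_22", "delay_to_week_22")
  delay("delay_to_week_22", 2L, "prenatal_control_5")
  encounter("prenatal_control_5", control_code(5L), "ultrasound_visit_2")
  encounter("ultrasound_visit_2",
            sn("169230002", "Visita para ecografía de detalle"),
            "ultrasound_scan_2")
  procedure("ultrasound_scan_2",
            cups("881431", "Ecografía obstétrica de detalle"),
            "gate_preeclampsia")
  gate("gate_preeclampsia", "preeclampsia_onset", "398254007",
       "delay_to_week_24", "delay_to_week_24")
  delay("delay_to_week_24", 2L, "prenatal_control_6")
  encounter("prenatal_control_6", control_code(6L), "tetanus_vaccination")
  procedure("tetanus_vaccination",
            sn("127786006", "Vacunación antitetánica"),
            "gate_eclampsia")
  gate("gate_eclampsia", "eclampsia_onset", "198992004",
       "delay_to_week_26", "delay_to_week_26")
  delay("delay_to_week_26", 2L, "prenatal_control_7")
  encounter("prenatal_control_7", control_code(7L), "influenza_vaccination")
  procedure("influenza_vaccination",
            sn("86198006", "Vacunación contra la influenza"),
            "gate_gestational_diabetes")
  gate("gate_gestational_diabetes", "gestational_diabetes_onset",
       "40801000119106", "delay_to_week_28", "delay_to_week_28")

  # --- Third trimester -----------------------------------------------------
  delay("delay_to_week_28", 2L, "prenatal_control_8")
  encounter("prenatal_control_8", control_code(8L), "pertussis_vaccination")
  procedure("pertussis_vaccination",
            sn("399014008", "Vacunación contra la tos ferina"),
            "gate_growth_restriction")
  gate("gate_growth_restriction", "growth_restriction_onset", "22033007",
       "gate_hemorrhagic_complication", "gate_hemorrhagic_complication")
  gate("gate_hemorrhagic_complication", "hemorrhagic_complication_onset",
       "106004004", "emergency_visit", "gate_placenta_previa")
  encounter("emergency_visit",
            sn("50849002", "Admisión al servicio de urgencias"),
            "gate_placenta_previa")
  gate("gate_placenta_previa", "placenta_previa_onset", "36813001",
       "delay_to_week_30", "delay_to_week_30")
  delay("delay_to_week_30", 2L, "prenatal_control_9")
  encounter("prenatal_control_9", control_code(9L), "gate_prom")
  gate("gate_prom", "prom_onset", "44223004",
       "gate_abruptio_placentae", "gate_abruptio_placentae")
  gate("gate_abruptio_placentae", "abruptio_placentae_onset", "415105001",
       "delay_to_week_32", "delay_to_week_32")
  delay("delay_to_week_32", 2L, "prenatal_control_10")
  encounter("prenatal_control_10", control_code(10L), "gate_preterm")

  # Gestational length: preterm (delivery weeks 33-36) at the calibrated
  # conditional probability, term (uniform weeks 37-41) otherwise.
  add(module_state("gate_preterm", "Simple",
                   transition = transition_distributed(
                     c("set_preterm_true", "set_preterm_false"),
                     c(pg("367494004"), 1 - pg("367494004")))))
  add(module_state("set_preterm_true", "SetAttribute",
                   attribute = "preterm", value = TRUE,
                   transition = transition_direct("delay_preterm_delivery")))
  add(module_state("set_preterm_false", "SetAttribute",
                   attribute = "preterm", value = FALSE,
                   transition = transition_direct("delay_term_delivery")))
  delay("delay_preterm_delivery", c(1L, 4L), "delivery_admission")
  delay("delay_term_delivery", c(5L, 9L), "delivery_admission")

  # --- Delivery and postpartum --------------------------------------------
  add(module_state("delivery_admission", "Encounter",
                   codes = sn("183460006", "Admisión para el parto"),
                   transition = transition_conditional(
                     conditional_branch("preterm_newborn_onset",
                                        attribute = "preterm", op = "eq",
                                        value = TRUE),
                     conditional_branch("delivery_procedure"))))
  add(module_state("preterm_newborn_onset", "ConditionOnset",
                   codes = cg("367494004"),
                   transition = transition_direct("delivery_procedure")))
  procedure("delivery_procedure", sn("48782003", "Atención del parto"),
            "gestational_age_observation")
  add(module_state("gestational_age_observation", "Observation",
                   codes = sn("412726003",
                              "Duración de la gestación al nacer"),
                   transition = transition_direct("pregnancy_delivered")))
  add(module_state("pregnancy_delivered", "SetAttribute",
                   attribute = "pregnant", value = FALSE,
                   transition = transition_direct("gate_pph")))
  gate("gate_pph", "postpartum_hemorrhage_onset", "47821001",
       "gate_maternal_death", "delay_postpartum")
  add(module_state("gate_maternal_death", "Simple",
                   transition = transition_distributed(
                     c("maternal_death", "delay_postpartum"),
                     c(p_maternal_death, 1 - p_maternal_death))))
  add(module_state("maternal_death", "Death",
                   codes = sn("21243004", "Muerte materna"),
                   transition = transition_direct("terminal_death")))
  add(module_state("terminal_death", "Terminal"))
  delay("delay_postpartum", 2L, "postpartum_control")
  encounter("postpartum_control",
            sn("133906008", "Control posparto"), "terminal_completed")
  add(module_state("terminal_completed", "Terminal"))

  # --- Pregnancy-loss management (ectopic / abortion) ----------------------
  encounter("loss_management_visit",
            sn("386637004", "Atención por pérdida gestacional"),
            "uterine_evacuation")
  procedure("uterine_evacuation", cups("695101", "Legrado uterino"),
            "pregnancy_lost")
  add(module_state("pregnancy_lost", "SetAttribute", attribute = "pregnant",
                   value = FALSE,
                   transition = transition_direct("terminal_loss")))
  add(module_state("terminal_loss", "Terminal"))

  m <- module_definition(name, st, initial = "start")
  issues <- validate_module(m)
  bad <- issues[issues$severity == "error", , drop = FALSE]
  if (nrow(bad) > 0L) {
    stop("pregnancy module failed validation:\n",
         paste0("  - ", bad$message, collapse = "\n"), call. = FALSE)
  }
  m
}

.module_cache <- new.env(parent = emptyenv())

#' Default calibrated gestation module (cached)
#'
#' @return The `module_definition` built by [build_pregnancy_module()] with
#'   default gates.
#' @export
default_pregnancy_module <- function() {
  if (is.null(.module_cache$default)) {
    .module_cache$default <- build_pregnancy_module()
  }
  .module_cache$default
}
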