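# Small modules and persons built in code for the engine tests.

toy_person <- function(id = 1L) {
  structure(list(person_id = id, sex = "F",
                 birthdate = as.Date("1995-05-01"),
                 municipality = "05001", department = "05",
                 index_date = as.Date("2023-03-01"), events = NULL),
            class = "person_record")
}

# Initial -> ConditionOnset -> Terminal
toy_module <- function() {
  module_definition("toy", list(
    module_state("start", "Initial",
                 transition = transition_direct("cond")),
    module_state("cond", "ConditionOnset",
                 codes = list(coded_concept("SNOMED-CT", "111", "Toy")),
                 transition = transition_direct("end")),
    module_state("end", "Terminal")),
    initial = "start")
}

# Initial -> Distributed(p -> A-onset, 1-p -> B-onset) -> Terminal
split_module <- function(p) {
  module_definition("split", list(
    module_state("start", "Initial",
                 transition = transition_direct("fork")),
    module_state("fork", "Simple",
                 transition = transition_distributed(c("a", "b"),
                                                     c(p, 1 - p))),
    module_state("a", "ConditionOnset",
                 codes = list(coded_concept("SNOMED-CT", "A1", "A")),
                 transition = transition_direct("end")),
    module_state("b", "ConditionOnset",
                 codes = list(coded_concept("CIE-10", "B1", "B")),
                 transition = transition_direct("end")),
    module_state("end", "Terminal")),
    initial = "start")
}

write_module_json <- function(m) {
  path <- tempfile(paste0(m$name, "-"), fileext = ".json")
  write_module(m, path)
  path
}
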