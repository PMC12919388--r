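# gestsynth

Fully synthetic maternal-health records for the Colombian gestation care
pathway, exported to the OMOP Common Data Model v5.4.

Clinical data on pregnancy are hard to obtain and share: gestational start,
end and age are encoded inconsistently in electronic records, access to
primary sources is restricted, and pregnant women are under-represented in
the datasets used to build and test health software and AI models.
`gestsynth` addresses this for researchers and developers working on
maternal health in Colombia (and anyone needing OMOP-shaped obstetric test
data): it simulates longitudinal care trajectories — prenatal controls,
complications, procedures, delivery and postpartum care — as a clinical
state machine, with complication frequencies calibrated to a 10,637-woman
reference cohort, and writes standard CDM v5.4 CSV tables.

## The model in brief

A woman's record is a walk through a directed graph of typed states
(encounters, condition onsets, procedures, observations, delays in whole
gestational weeks) with `Direct`, `Distributed` and `Conditional`
transitions. Complications are Bernoulli *gates* anchored to their clinical
trimester: ectopic pregnancy (week 8) and abortion (weeks 10 and 16)
terminate the pathway; hypertensive disorders, preeclampsia, eclampsia and
gestational diabetes sit in the second trimester; growth restriction,
hemorrhagic complications, placenta previa, PROM and abruptio in the third;
postpartum hemorrhage after delivery.

Gates are configured by *marginal* cohort frequencies m_g and drawn at the
*conditional* probability among women still pregnant at the gate,

    c_g = m_g / (1 − Σ_{t<g, terminating} m_t),

so that forward multiplication recovers the marginals exactly. With the
default targets: ectopic 218/10637, first-trimester abortion 1714/10419,
second-trimester abortion 636/8705, and every later gate among the 8,069
women reaching delivery (e.g. preterm birth 603/8069, postpartum hemorrhage
1443/8069).

Demographics: always female, age at conception uniform 15–49, municipality
drawn from DIVIPOLA-coded population weights (a synthetic 30-municipality
fixture ships in-repo; a real census table is a drop-in CSV).

## Worked example

```r
library(gestsynth)

cohort <- generate_cohort(10637, seed = 1)   # ~15 s
frequency_report(cohort)
```

```
 code           condition                observed n (%) literature (%) difference (%)
 34801009       Embarazo ectópico        227 (2.1)      2              0.1
 19169002       Aborto en el primer ...  1736 (16.3)    10-20          6.3 a -3.7
 85116003       Aborto en el segundo ... 627 (5.9)      5              0.9
 48194001       Hipertensión inducida... 115 (1.1)      2-8            -0.9 a -6.9
 38341003       Hipertensión arterial... 620 (5.8)      2-8            3.8 a -2.2
 37618003       Complicación de hiper... 84 (0.8)       2-8            -1.2 a -7.2
 398254007      Preeclampsia             788 (7.4)      2-8            5.4 a -0.6
 198992004      Eclampsia                422 (4.0)      2-8            2.0 a -4.0
 40801000119106 Diabetes mellitus ges... 721 (6.8)      2-5            4.8 a 1.8
 22033007       Restricción del creci... 26 (0.2)       8-10           -7.8 a -9.8
 106004004      Complicaciones hemorr... 173 (1.6)      4              -2.4
 44223004       Ruptura prematura de ... 0 (0.0)        8-10           -8.0 a -10.0
 367494004      Recién nacido prematuro  583 (5.5)      7.2            -1.7
 47821001       Hemorragia posparto      1434 (13.5)    4-6            9.5 a 7.5
```

Each row is a SNOMED-CT-coded condition: the distinct-person count and
percentage observed in the simulated cohort, the literature prevalence
(range or point), and the distance *observed minus reference* to each bound
— e.g. the simulated postpartum-hemorrhage frequency of 13.5 % sits 9.5
points above the literature lower bound of 4 % and 7.5 above the upper
bound of 6 %. Premature rupture of membranes is 0 by construction (its
default marginal is 0).

Export to OMOP and check referential integrity:

```r
bundle <- export_cdm(cohort, outdir = "cdm-out")  # person.csv, visit_occurrence.csv, ...
integrity_check(bundle)                           # zero rows when clean
```

Or run everything from a shell:

```sh
Rscript inst/cli/gestsynth.R --n 10637 --seed 1 --outdir out --format omop-csv,report
Rscript inst/cli/gestsynth.R --n 500 --seed 9 --department 05 --outdir antioquia
```

Every run is a pure function of its seed: rerunning with the same
configuration produces byte-identical CSVs, and `manifest.json` records the
seed and a configuration fingerprint.

## Documentation

The methods vignette (`vignettes/gestation-pathway-simulation.Rmd`) covers
the state-machine semantics, the marginal-to-conditional calibration
algebra, every default parameter and why, what the generator does and does
not emulate about real obstetric data, and the OMOP mapping decisions. The
module JSON dialect is specified in `inst/schema/module-schema.json`, and
the shipped pathway itself in `inst/extdata/gestation-module.json`.
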