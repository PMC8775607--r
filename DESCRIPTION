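Package: ultraflow
Title: Discrete-Event Simulation of Ultrasound Appointment Scheduling and
    Examination-Room Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A seeded discrete-event simulator for patient flow through a
    hospital ultrasound department with multiple examination rooms, multiple
    patient classes (outpatient, inpatient, emergency), sex-constrained
    examinations, and pluggable room-assignment policies (cumulative
    examination points, cumulative examination time, random, weighted
    cumulative points). Includes a synthetic case-hospital profile,
    declarative random-variate specifications with seeded substreams,
    replication-sizing statistics (confidence half-widths, coefficient of
    variation, required replication counts), warm-up diagnostics, and a
    constrained grid search over outpatient appointment intervals and batch
    sizes that minimizes class-weighted mean waiting time subject to
    utilization and throughput constraints.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
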