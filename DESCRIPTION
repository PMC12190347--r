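Package: hepatwin
Title: Mechanistic Digital Twin of Liver Regeneration After Partial Hepatectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds patient-specific digital twins of liver regeneration after
    partial hepatectomy from longitudinal blood gene expression. Provides
    preprocessing of longitudinal expression matrices (cross-patient
    imputation, negative-value correction, log2(1+x) transform, fold-change
    computation and differential-expression filtering), weighted co-expression
    network analysis with topological overlap and self-organizing-map
    refinement into temporal gene clusters, a mechanistic ordinary
    differential equation model of quiescent/primed/replicating hepatocyte
    transitions coupled to a TNF/IL-6/STAT3/SOCS3 cytokine cascade and
    extracellular-matrix turnover, feed-forward neural maps between cluster
    expression and mechanistic state, a forecasting loop that simulates a
    patient forward and reverse-maps the simulated state to future expression,
    and a seeded synthetic-cohort generator so every stage is testable without
    donor data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
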