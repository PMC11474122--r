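Package: echovhd
Title: Rule-Based Extraction of Valve Stenosis and Regurgitation Severity
    from Echocardiography Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reads free-text transthoracic echocardiography (TTE) reports and
    determines, for each of the four heart valves (aortic, mitral, tricuspid,
    pulmonic), the presence and severity grade of stenosis and regurgitation,
    plus prosthetic-valve status. The pipeline segments templated reports into
    sections, normalizes and sentence-splits the included prose, matches a
    versioned lexicon of lesion, severity, negation, history and prosthetic
    phrases with longest-match semantics and abbreviation disambiguation,
    filters negated and historical mentions, and resolves report-level findings
    by a fixed severity priority. Ships a validation harness (per-category
    positive predictive value, sensitivity, F1 against gold annotations) and a
    synthetic report generator with exact ground truth so every stage is
    testable without clinical data.
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
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
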