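# echovhd

Rule-based extraction of valvular heart disease status from free-text
transthoracic echocardiography (TTE) reports.

For every report, `echovhd` determines the status of **stenosis** and
**regurgitation** on each of the four heart valves (aortic, mitral,
tricuspid, pulmonic) — always 8 findings per report — where a status is one
of `no_evidence`, a severity grade, `sclerosis` (aortic stenosis axis only),
or `prosthetic`. It is aimed at EHR phenotyping work: turning narrative echo
reports into analyzable variables, with every decision auditable back to a
verbatim text span.

## The algorithm

Reports are segmented by their templated headers; only findings, impression,
summary and per-valve subsections are scanned (the indication block holds
referral diagnoses, the measurements block holds "ms" readings — both are
excluded). Each sentence of the included prose is lowercased, spelling-
corrected from a curated map, tokenized, and passed through four rule steps:

1. **Term search** — longest-match over a lexicon of lesion phrases and
   abbreviations; generic nouns resolve their valve from coordination
   ("aortic or mitral stenosis") or the enclosing subsection; the ambiguous
   abbreviations *as* / *ms* / *tr* pass a disambiguation rule table
   (conjunction "as", millisecond "ms", trace "tr" are rejected).
2. **Negation** — NegEx-style forward scope: a cue ("no", "without evidence
   of") negates mentions within 5 tokens unless a scope breaker intervenes.
3. **History** — mentions preceded by "prior study", "previously", "known"
   etc. describe an earlier exam and are dropped; prosthetic status is
   exempt ("status post TAVR" is current).
4. **Severity** — longest-matched severity phrases attach to their nearest
   unclaimed mention (pre-modifier preferred, post-modifier within 3
   tokens); conflicts resolve by the fixed priority

   `prosthetic > very severe > severe > moderate to severe > moderate >
   mild to moderate > mild > trace to mild > trace > sclerosis >
   unknown severity`

   with *trace* grades admissible only for regurgitation and *sclerosis*
   only for aortic stenosis.

Report-level resolution applies the same priority across sentences; any
prosthetic mention makes the whole valve prosthetic. The validation module
scores predictions against gold annotations per category with
PPV = TP/(TP+FP), sensitivity = TP/(TP+FN) and
F1 = 2·PPV·sensitivity/(PPV+sensitivity), the standard arithmetic for this
kind of chart-review validation. A synthetic report generator with exact,
analytically derived ground truth makes the whole pipeline testable without
clinical data.

## A worked example

```r
library(echovhd)
library(dplyr)

reports <- tibble::tibble(
  report_id = "demo-1",
  text = paste(
    "INDICATION: follow up of known severe aortic stenosis.",
    "FINDINGS:",
    "Aortic Valve:",
    "the valve is sclerotic. no stenosis.",
    "Mitral Valve:",
    "mild to moderate mitral regurgitaton.",
    "IMPRESSION:",
    "aortic valve sclerosis without stenosis.",
    sep = "\n"
  )
)

fit <- extract_valve_findings(reports)
fit
#> <valve_extraction>
#>   reports:   1
#>   sentences: 8
#>   mentions:  4  (1 negated, 0 historical)
#>   findings: 8 (2 with evidence)

tidy(fit) |> filter(status != "no_evidence")
#> # A tibble: 2 × 5
#>   report_id valve  lesion        status           n_supporting_mentions
#>   <chr>     <chr>  <chr>         <chr>                            <int>
#> 1 demo-1    aortic stenosis      sclerosis                            2
#> 2 demo-1    mitral regurgitation mild_to_moderate                     1
```

Four rules are visible at once: the "severe aortic stenosis" in the
indication is a referral diagnosis and never scanned; "no stenosis" is
negated; the sclerotic valve lands on the aortic stenosis axis as status
`sclerosis`; and the misspelled "regurgitaton" was corrected before
matching. `tidy()` returns the findings, `glance()` a one-row summary,
`autoplot()` a severity-distribution plot.

Scoring a synthetic corpus against its ground truth:

```r
corpus  <- generate_corpus(clean_mode(synth_config(n_reports = 50, seed = 7)))
metrics <- score_against_gold(tidy(extract_valve_findings(corpus$reports)),
                              corpus$gold)
glance(metrics)
#> # A tibble: 1 × 6
#>   n_categories n_populated n_perfect micro_ppv micro_sensitivity micro_f1
#>          <int>       <int>     <int>     <dbl>             <dbl>    <dbl>
#> 1           97          55        55       100               100        1
```

Every populated (valve, lesion, status) category is recovered perfectly on a
noise-free corpus; `tidy(metrics)` gives the per-category TP/FP/FN and
metric columns, `format_metrics()` the display rounding used in validation
tables.

A command-line wrapper over the same functions ships at
`inst/cli/echovhd.R` with subcommands `extract`, `validate`, `synth`,
`summarize` and `mine-misspellings`.

## Package layout

| module | contents |
|---|---|
| `R/lexicon.R` | lexicon loading/validation, longest-match phrase search |
| `R/report_io.R` | JSONL/CSV/txt-dir report input, JSONL output |
| `R/segment.R` | header-driven section and valve-subsection segmentation |
| `R/preprocess.R` | normalization, sentence splitting, misspelling mining |
| `R/extraction.R` | term search, disambiguation, negation, history, severity |
| `R/aggregation.R` | report-level resolution, findings I/O, cohort summaries |
| `R/metrics.R` | PPV/sensitivity/F1 scoring against gold annotations |
| `R/synth.R` | synthetic corpus generator with exact ground truth |

The methods vignette (`vignettes/extracting-valve-findings.Rmd`) documents
the model, its parameters, the generator's scope and the package's known
limitations.
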