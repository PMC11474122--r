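---
title: "Extracting valve stenosis and regurgitation severity from echo reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting valve stenosis and regurgitation severity from echo reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echovhd)
library(dplyr)
```

## The problem

Transthoracic echocardiography (TTE) reports are templated but free-text:
a cardiologist's prose, organized under headers such as FINDINGS, IMPRESSION
and per-valve subsections, states whether each of the four heart valves
(aortic, mitral, tricuspid, pulmonic) shows stenosis or regurgitation, at
what severity, and whether the valve is prosthetic. Research and surveillance
uses of the EHR need those statements as structured variables, one status per
(valve, lesion) pair per report. `echovhd` implements a deterministic,
rule-based extractor for exactly this task, together with the validation
arithmetic used to benchmark it (per-category PPV, sensitivity, F1 against
gold annotations) and a synthetic report generator with exact ground truth,
so the whole pipeline can be exercised and regression-tested without any
clinical data.

A rule-based design is a deliberate choice for this problem: reports are
templated, the label space is small and clinically standardized, every
decision must be auditable sentence by sentence, and a site can adapt the
system by editing a vocabulary file rather than retraining a model.

## The pipeline

Each report passes through a fixed sequence:

1. **Segmentation** (`segment_report()`). Header lines — a known pattern,
   case-insensitive, optionally followed by `:` or `-` — partition the text
   into sections; valve subsection headers ("Aortic Valve:") inside the
   findings/impression/summary regions attach a valve context to their span.
   Only findings/results, impression, summary/conclusion, valve subsections
   and unlabeled text are scanned. The title/indication block is excluded
   because it carries *referral* diagnoses ("follow up of severe aortic
   stenosis") that are not findings of the current exam; the
   dimensions/measurements block is excluded because it is dense with
   numeric readings whose unit "ms" (millisecond) collides with the
   abbreviation for mitral stenosis. A report with no recognizable headers is
   scanned whole, so nothing is silently dropped.

2. **Normalization** (`normalize_text()`). Lowercasing, then token-wise
   replacement of misspellings from a curated map. Replacement is token-wise
   so every normalized token keeps its original character offsets, and the
   map's keys are required to be disjoint from the canonical vocabulary, which
   makes normalization idempotent.

3. **Sentence splitting** (`split_sentences()`). Rule-based: boundaries at
   `.`, `;` and newline, guarded against decimal points ("2.5 m/s") and
   listed non-breaking abbreviations ("dr."). A statistical sentence model
   would add a dependency and nondeterminism for no benefit on templated
   prose; the rule set is configurable through the lexicon.

4. **Term search** (`find_lesion_mentions()`). Longest-match search over the
   lesion vocabulary, token-anchored, so "moderate to severe" never splits
   into its sub-phrases and no phrase matches inside a word. Valve-specific
   phrases ("aortic stenosis", "mr") resolve directly; generic lesion nouns
   ("stenosis") resolve from a preceding valve-word coordination chain
   ("aortic or mitral stenosis" yields one mention per valve) or from the
   enclosing subsection's valve. A bare lesion noun with no resolvable valve
   is discarded rather than guessed.

5. **Abbreviation disambiguation** (`disambiguate_abbreviation()`). "as",
   "ms" and "tr" have competing readings (conjunction, millisecond, trace).
   A deterministic rule table accepts them as lesion terms only with
   supporting evidence: an immediately preceding severity phrase or
   sclerosis/prosthetic cue, or the matching valve context — and never when
   the surface form marks the other reading ("450 ms", "as expected",
   "tr mr" where "tr" grades the following mention as trace).

6. **Negation** (`apply_negation()`). Forward scope from a cue ("no",
   "without evidence of") over at most `negation_window` tokens (default 5),
   broken by "but", "however" or a comma. Coordinated lesions share one cue.
   The window and cue list are configuration, since the scope convention is a
   design choice rather than something the label definitions dictate.

7. **History** (`apply_history_filter()`). A history cue ("prior study",
   "previously", "known") anywhere earlier in the sentence marks the mention
   historical — findings of an earlier exam are not findings of this one.
   Scope is the whole sentence because history cues tend to open the clause.
   Prosthetic cues are exempt: "known severe as, now status post tavr" drops
   the graded stenosis (it belongs to the pre-operative history) but keeps
   the prosthetic status, which describes the valve as it stands.

8. **Severity** (`assign_severity()`). Severity phrases are longest-matched
   and attached left to right, each to its nearest unclaimed mention,
   preferring the pre-modifier direction and allowing a post-modifier within
   3 tokens ("aortic stenosis, severe"). A phrase whose candidates are all
   claimed still contributes to the nearest mention, so in "moderate to
   borderline severe calcific mitral stenosis" — where "borderline" breaks
   the "moderate to severe" range phrase — both "moderate" and "severe"
   attach and the priority order picks "severe". A severity phrase before a
   slash list ("mild as/ai/mr") grades only the first term by default; the
   `distribute_severity_over_lists` option implements the arguably-correct
   distribution so both behaviours are pinned by tests. Grades inadmissible
   for a lesion (trace on a stenosis, sclerosis off the aortic stenosis axis)
   are refused with a warning rather than silently kept.

9. **Resolution** (`resolve_report()`). Per (valve, lesion), the
   highest-priority surviving grade wins, on the fixed scale prosthetic >
   very severe > severe > moderate-to-severe > moderate > mild-to-moderate >
   mild > trace-to-mild > trace > sclerosis > unknown severity. Any
   prosthetic mention makes the whole valve prosthetic under both lesions —
   a prosthetic valve is a valve-level state. Ungraded mentions count as
   evidence (status `unknown_severity`) only when no graded mention exists;
   no surviving mention at all is `no_evidence`. Every report yields exactly
   8 findings. The priority rule is applied both within sentences (competing
   severity phrases) and across the report (competing sentences); the two
   levels compose because the order is total.

Aortic **sclerosis** deserves a note: it is valve thickening *without*
stenosis, reported on the stenosis axis as its own lowest-priority status.
A sclerosis term with no graded stenosis mention in the sentence becomes a
standalone finding ("the aortic valve is sclerotic"); alongside a graded
stenosis it behaves as a modifier and loses to any true grade.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `negation_window` | 5 tokens | max gap between a negation cue and its target |
| `severity_post_window` | 3 tokens | how far a severity phrase may trail its lesion |
| `distribute_severity_over_lists` | off | grade every member of "mild as/ai/mr" |
| `numeric_grades` | off | map "1+".."4+" to mild..severe via the lexicon table |

The vocabulary itself (lesion terms, severity phrases and their hyphen/range
variants, cues, misspelling map, header patterns) lives in a YAML file
bundled at `system.file("extdata", "default_lexicon.yml", package =
"echovhd")`. It is a reconstruction assembled from standard echocardiography
vocabulary — full valve names, the standard abbreviations, "insufficiency"
as a regurgitation synonym, NegEx-style negation cues — and is deliberately
data, not code: sites extend it to match their own templates, and
`load_lexicon()` validates every invariant (lowercase phrases, no phrase
under two grades, misspelling keys disjoint from the vocabulary) with named
errors. The numeric-grade table (1+–4+) is included but off by default, as
its use varies across sites.

`mine_misspellings()` supports growing the misspelling map offline: it ranks
corpus tokens by character edit-distance similarity to each canonical term
and writes a review file. Nothing enters the runtime map without a human
accepting it.

## The synthetic generator, and what passing tests show

`generate_corpus()` renders templated reports (indication, measurements,
findings with per-valve subsections, impression, signature) from a sampled
ground truth, and derives the gold findings analytically from that truth by
the same priority rules — never by running the extractor, so end-to-end
comparisons are non-circular. Default prevalences make regurgitation common
(trace/mild dominant) and mitral/tricuspid/pulmonic stenosis rare, with a
30% sclerosis share on the aortic stenosis axis and a 4% per-valve
prosthetic rate; these are fixed study conditions chosen to exercise every
status, not estimates of any cohort. Noise channels are independently
switchable: negated-finding sentences, historical-finding sentences,
millisecond and conjunction-"as" traps, and misspellings drawn only from the
curated map's keys. `clean_mode()` zeroes all of them.

The acceptance suite demands *exact* recovery (PPV = sensitivity = 100%,
F1 = 1.00 for every populated category) on 200 clean reports and on 200
noisy ones. Test problem sizes — 200-report corpora, 1,000-case property
suites, a ~800-sentence grammar enumeration against an independently written
rule oracle — are chosen so the full suite runs in a few minutes on one
core. Passing shows the rules are internally consistent and robust to the
modelled noise; it does **not** bound performance on real reports, whose
phrasing diversity, typos outside the curated map, and template drift the
generator cannot represent. On real data the validation harness
(`score_against_gold()`) against a chart-review gold standard is the only
meaningful measure. The bundled `validation_counts()` table shows the shape
such a validation takes and anchors the metric arithmetic: recomputing
PPV/sensitivity/F1 from its count columns reproduces the printed cells —
with one documented exception, an unknown-severity pulmonic stenosis row
whose printed PPV (50.0) is arithmetically impossible given its own printed
counts (TP = 2, FP = 1 implies 66.7); the tests pin the recomputed value.

## Numerical and design choices

* **Offsets** are 0-based, half-open, character-level throughout; sections
  partition the report exactly and sentences partition their section, so
  every mention is traceable to a verbatim span.
* **Ties** between equal-priority severity candidates resolve to the nearer,
  then earlier phrase — deterministic by construction.
* **Determinism**: the extractor has no randomness; the generator is fully
  determined by its seed. Identical inputs give byte-identical outputs.
* **Degenerate inputs**: empty text yields 8 `no_evidence` findings; a
  headerless report is scanned whole; an empty findings stream writes a
  header-only file.
* **"severity detected"** in validation output uses any-grade matching (was
  *some* grade found on both sides), with per-grade rows carrying exactness —
  both views are emitted, as summary and grade rows answer different
  questions.
* The congenital-morphology shorthands "systemic av" and "subpulmonic av"
  are ignored entirely, since their meaning inverts outside congenital
  disease; this mirrors the scope of the validated rule set.

## Known limitations

* No cross-sentence coreference: "There is stenosis. It is severe." grades
  the first sentence only.
* The first-term-only severity behaviour on slash lists under-labels the
  remaining terms unless `distribute_severity_over_lists` is set.
* History and negation are surface-cue driven; clause structure beyond the
  scope-breaker list is invisible.
* Measurement-derived severity (e.g. grading aortic stenosis from peak
  velocity) is out of scope: only textual grades are read.

## A worked example

```{r example}
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
tidy(fit) |> filter(status != "no_evidence")
```

The referral diagnosis in the indication is never scanned; the negated
stenosis is dropped; sclerosis lands on the aortic stenosis axis; and the
misspelled "regurgitaton" is corrected before matching.

```{r corpus}
corpus <- generate_corpus(clean_mode(synth_config(n_reports = 50, seed = 7)))
metrics <- score_against_gold(tidy(extract_valve_findings(corpus$reports)),
                              corpus$gold)
glance(metrics)
```
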