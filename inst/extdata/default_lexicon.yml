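# Default echovhd lexicon.
#
# All phrases must be lowercase. Phrases are matched on token sequences after
# normalization (hyphens act as separators, so "mild-to-moderate" matches the
# "mild to moderate" entry). Sites can copy and extend this file to match the
# vocabulary of their own reporting templates; see ?load_lexicon for the schema.

lesion_terms:
  aortic:
    stenosis:
      - aortic stenosis
      - aortic valve stenosis
      - as
    regurgitation:
      - aortic regurgitation
      - aortic valve regurgitation
      - aortic insufficiency
      - aortic valve insufficiency
      - ai
      - ar
  mitral:
    stenosis:
      - mitral stenosis
      - mitral valve stenosis
      - ms
    regurgitation:
      - mitral regurgitation
      - mitral valve regurgitation
      - mitral insufficiency
      - mitral valve insufficiency
      - mr
  tricuspid:
    stenosis:
      - tricuspid stenosis
      - tricuspid valve stenosis
      - ts
    regurgitation:
      - tricuspid regurgitation
      - tricuspid valve regurgitation
      - tricuspid insufficiency
      - tr
  pulmonic:
    stenosis:
      - pulmonic stenosis
      - pulmonic valve stenosis
      - pulmonary stenosis
      - pulmonary valve stenosis
      - ps
    regurgitation:
      - pulmonic regurgitation
      - pulmonic valve regurgitation
      - pulmonic insufficiency
      - pulmonary regurgitation
      - pulmonary valve regurgitation
      - pulmonary insufficiency
      - pr
  # generic lesion nouns resolve their valve from preceding valve words or the
  # enclosing valve subsection
  generic:
    stenosis:
      - stenosis
      - stenotic
    regurgitation:
      - regurgitation
      - regurgitant
      - insufficiency

# valve adjectives used for backward valve resolution of generic lesion nouns
valve_words:
  aortic: [aortic]
  mitral: [mitral]
  tricuspid: [tricuspid]
  pulmonic: [pulmonic, pulmonary]

severity_terms:
  very_severe:
    - very severe
    - critical
  severe:
    - severe
  moderate_to_severe:
    - moderate to severe
    - moderate severe
    - moderately to severely
    - moderately severe
  moderate:
    - moderate
    - moderately
  mild_to_moderate:
    - mild to moderate
    - mild moderate
    - mildly to moderately
  mild:
    - mild
    - mildly
  trace_to_mild:
    - trace to mild
    - trace mild
    - trivial to mild
  trace:
    - trace
    - trivial
  sclerosis:
    - sclerosis
    - sclerotic
    - sclerosed

# optional numeric regurgitation grades, disabled unless
# extraction_options(numeric_grades = TRUE)
numeric_grades:
  "1+": mild
  "2+": moderate
  "3+": moderate_to_severe
  "4+": severe

negation_cues:
  - "no"   # quoted: bare no/yes parse as booleans in YAML 1.1
  - not
  - without
  - no evidence of
  - without evidence of
  - no significant
  - absence of
  - free of
  - negative for

history_cues:
  - prior study
  - prior studies
  - a prior study
  - previous study
  - previously
  - history of
  - known
  - prior echocardiogram
  - previous echocardiogram
  - on prior

prosthetic_terms:
  generic:
    - prosthetic
    - prosthesis
    - bioprosthetic
    - bioprosthesis
    - mechanical valve
    - prosthetic valve
    - valve replacement
    - valve prosthesis
    - well seated
  aortic:
    - avr
    - tavr
    - savr
    - aortic valve replacement
  mitral:
    - mvr
    - mitral valve replacement
  tricuspid:
    - tvr
    - tricuspid valve replacement
  pulmonic:
    - pulmonic valve replacement
    - pulmonary valve replacement

sclerosis_terms:
  - sclerosis
  - sclerotic
  - sclerosed

misspelling_map:
  regurgitaton: regurgitation
  regurgiation: regurgitation
  regurgitration: regurgitation
  stenois: stenosis
  stensois: stenosis
  stenosys: stenosis
  aortric: aortic
  aotic: aortic
  mitrial: mitral
  mitreal: mitral
  tricupsid: tricuspid
  tricsupid: tricuspid
  pulmonc: pulmonic
  moderte: moderate
  modrate: moderate
  sevre: severe
  milld: mild
  scleroisis: sclerosis
  prostetic: prosthetic

# tokens whose acceptance as a lesion term goes through a disambiguation rule
ambiguous_abbrevs:
  as: as_rule
  ms: ms_rule
  tr: tr_rule

# tokens that immediately follow conjunction-"as" (eg "as seen previously");
# such an "as" is never read as aortic stenosis
as_conjunction_followers:
  - a
  - an
  - the
  - well
  - is
  - was
  - are
  - were
  - seen
  - noted
  - compared
  - described
  - expected
  - before
  - previously
  - above
  - below
  - per
  - in
  - on
  - with
  - follows

# tokens ignored entirely (congenital-morphology shorthand with a different
# meaning outside congenital disease)
ignored_phrases:
  - systemic av
  - subpulmonic av

section_headers:
  title: title_demographics
  indication: title_demographics
  procedure indication: title_demographics
  patient demographics: title_demographics
  procedure: title_demographics
  referring physician: title_demographics
  exam quality: exam_quality
  study quality: exam_quality
  image quality: exam_quality
  measurements: dimensions_measurements
  dimensions: dimensions_measurements
  dimensions and measurements: dimensions_measurements
  findings: findings_results
  results: findings_results
  impression: impression
  miscellaneous: miscellaneous
  comments: miscellaneous
  summary: summary_conclusion
  conclusion: summary_conclusion
  conclusions: summary_conclusion
  signature: signature
  electronically signed: signature
  signed by: signature

subsection_headers:
  aortic valve: aortic
  mitral valve: mitral
  tricuspid valve: tricuspid
  pulmonic valve: pulmonic
  pulmonary valve: pulmonic

# period-terminated abbreviations that never end a sentence
nonbreaking_abbrevs:
  - dr
  - vs
  - approx
  - pt
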