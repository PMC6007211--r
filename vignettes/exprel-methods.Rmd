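---
title: "Methods: mining differential-expression statements from abstracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining differential-expression statements from abstracts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprel)
```

## The task

Small-scale expression studies report their central finding in one or two
sentences of the abstract: a gene or microRNA is expressed more (or less) in
a disease sample than in a baseline. `exprel` extracts these statements into
curatable records with five components: the expressed gene or microRNA
(normalized to an NCBI Gene ID or a miRBase-style name), the expression
level (`High`/`Low`), the associated disease (normalized to a Disease
Ontology ID), the disease sample named in the sentence, and — for explicit
comparisons — the compared sample.

Statements fall into three families:

* **Type A** — an explicit comparison: *"Expression of Shp2 protein was
  significantly upregulated in OSCC tissues compared with the normal
  tissues."* The components are the **scale indicator** (SI, "upregulated"),
  the **compared aspect** (CA, the expression phrase), the two **compared
  entities** (CE1, CE2) and the **entity separator** (ES, "compared with"),
  which is verified but not extracted as an argument.
* **Type B** — a level statement without an explicit baseline: *"miR-155
  expression was high in pancreatic cancer tissues."* Components are the
  **level indicator** (LI), **expressed aspect** (EA) and **expressed
  location** (EL).
* **Type C** — statements connecting an expression level to a disease
  outcome or process ("over-expression of X enhanced cell growth"). These do
  not state that the expression change is observed in the disease, so they
  are deliberately not extracted; the argument-type constraints reject them.

## Pipeline

Abstracts (Medline XML, TSV, or plain-text files) are split into sentences;
the title is sentence 0 and participates in extraction and disease
inference. Sentences without an expression/comparison trigger are dropped by
a prefilter and never parsed. Surviving sentences are analyzed into
dependency graphs; declarative patterns extract candidate Type A/B
relations; entity taggers type the argument phrases; and an assembly stage
filters by argument type, extracts the final fields, and emits records.

## Dependency analysis

The extraction patterns are written over an enhanced dependency
representation: preposition-collapsed nominal modifiers (`nmod:in`,
`nmod:of`), passive subjects (`nsubj:pass`), adjectival/nominal modifiers,
and conjunct propagation (each conjunct inherits its first conjunct's
governors, so "the expression of miR-143 and -195" carries an `nmod:of` edge
to both microRNAs). Entity-separator phrases receive a dedicated treatment:
a fronted or verb-attached separator phrase ("Compared to controls, ...",
"... compared with normal tissues") attaches its entity to the clause
predicate as `nmod:es`, and "than in X" keeps the conventional `nmod:in`
label with the head additionally flagged as separator-attached.

The analyzer itself is a deterministic rule-based component: noun-phrase
chunking over a closed-lexicon part-of-speech tagger, clause predicate
detection (copular, passive and active verb groups), and attachment rules
for prepositional, separator and coordinated phrases. It is specialized for
the declarative sentence families in which expression findings are reported;
it parses any input without failing, but sentences far outside those
families (relative clauses, multi-clause comparisons) carry no fidelity
guarantee. This is a deliberate scope decision: the extraction patterns, not
the parser, are the contribution, and the pattern layer is insulated from
the analyzer by a canonical label set, so a different dependency source
(e.g. precomputed parses) can be substituted behind the same interface.

## Patterns

Patterns live in editable YAML files (`inst/patterns/`), one entry per
construction: node constraints (regexes over POS/lemma/surface, or
membership in a named trigger set) and edge constraints (label regexes).
The engine finds all injective variable bindings, deduplicated and in
deterministic order; ill-formed patterns fail at load time. The shipped
Type A families are:

* **P1** — comparative adjective as main predicate ("X was higher in CE1
  than in CE2"), with a variant for a compared entity attached to the CA
  ("the expression of X in CE1 was higher than that in CE2");
* **P2** — scale-indicator verb as main predicate ("X levels were increased
  in CE1 compared with CE2");
* **P3** — observation verb as predicate with the SI modifying the subject
  ("Increased X expression was observed in CE1 than in CE2");
* **P5** — compared entity as subject ("patients with CLL presented a lower
  expression level of X").

Separator-initial constructions ("Compared to CE2, ..." — the P4 family)
need no dedicated pattern: the fronted phrase attaches to the main predicate
as `nmod:es`, so the P1–P3/P5 geometries cover them. After matching, the
extractor canonicalizes CE order (a separator-attached or fronted entity is
CE2), verifies the separator, drops negated predicates, and keeps one
relation per SI token, preferring the binding whose entities are nearest the
SI (a locality tie-break; the source material is silent on ties).

Type B families Q1 (LI as predicate), Q2 (observation predicate, LI as
modifier of the EA) and Q3 (agentive subject "we/authors", EA as object)
mirror the Type A geometries. Comparison takes precedence: a trigger that
participates in a full comparison (both CEs found, separator verified) is
consumed by Type A; otherwise an implicit-class trigger falls through to
Type B. When several `nmod:in` candidates exist, the EL nearest the LI wins
("GALNT2 is over-expressed in OSCC, especially in the carcinoma cells"
yields EL "OSCC").

One rendering subtlety is worth documenting: in the reference component
tables a comparative (implicit-class) LI modifier is part of the expressed
aspect ("Higher level of BRF2 expression") while a plain-class one is not
("TRIM32 expression levels" from "High TRIM32 expression levels ..."). The
EA yield therefore keeps an implicit-class modifier and excludes a
plain-class one; this is the only rule consistent with all reference rows.

## Entities and normalization

* **Genes** — longest-match, case-insensitive, token-aligned lookup in a
  TSV lexicon mapping names to NCBI Gene IDs. Genes and proteins are not
  distinguished. A reader for precomputed offset-format annotation files is
  provided as an alternative tagger.
* **microRNAs** — a regex family implementing the miRBase naming
  convention, with optional species prefix and arm suffix
  (`hsa-miR-1-3p`). Normalization lowercases the stem to `mir`, drops the
  species prefix and keeps the arm in a secondary field (database keys in
  expression resources are typically arm-agnostic; both are kept to avoid
  information loss). Elided coordinated stems ("miR-143 and -195") inherit
  the stem of the preceding full mention.
* **Diseases** — lexicon lookup normalized to DOIDs, on surfaces and lemmas
  (plural mentions match singular entries). Parenthetically defined
  abbreviations are linked per abstract with the classic long-form/
  short-form character-matching algorithm, so "OSCC" inherits the DOID of
  "Oral Squamous Cell Carcinoma". A MEDIC-to-DOID table supports annotation
  files whose disease identifiers are MEDIC.
* **Phrase typing** — an *expression* phrase has an expression trigger as
  its head noun or is itself a gene/microRNA mention; a *disease sample*
  phrase contains a disease mention or has a disease-sample or generic
  disease head ("tissues", "patients", "tumor", "cancer"). Bare organ nouns
  ("ovaries", "brain") are included in the default sample-head list because
  compared entities such as "normal ovaries" require them; the list is
  config-extensible.

## Disease inference from context

When a compared entity or expressed location only names a generic sample
("cancer tissues"), the disease is searched for elsewhere in the abstract in
a fixed order: **title**, **first body sentence**, **investigation
sentences** (an investigation trigger — "investigated", "examined",
"analyzed", ... — whose subject is an author/purpose word or which is in
the passive), **experiment-setup sentences** (a passive analyzed trigger —
"enrolled", "tested", "collected", ... — whose theme phrase contains a
count, as in "A total of 140 patients with colorectal cancer were
enrolled"), and finally the **conclusion sentences** (the last two body
sentences; behind a configuration flag, since it is unclear whether
unstructured abstracts should contribute a conclusion location). The first
disease mention found wins; ties within a sentence go to the earliest
offset. Title and first-sentence cues rank first because they are the
highest-precision locations; the order is configurable. "Compared" is both
an investigation trigger and an entity separator; the agent/voice conditions
on investigation sentences prevent the collision. Records whose disease
never resolves are emitted with an absent DOID rather than dropped —
curator-facing output should expose near-misses — and the relevance filter
excludes them later.

## Frame of reference

Type A comparisons are classified by their baseline: `Control` when exactly
one compared entity contains a control modifier ("control", "normal",
"healthy", "adjacent", ...) — that entity becomes the compared sample and
the other the disease sample; `Not_Control` otherwise (two disease states,
as in "T1 bladder carcinoma vs Ta carcinomas"). If both entities carry
control modifiers the case is ambiguous and conservatively classified
`Not_Control` with a warning. Type B relations are `Control_Implicit` when
the LI presupposes a baseline ("overexpressed", "increased", "higher") and
`none` when it merely states a level ("high", "low"). For `Not_Control`
comparisons the assignment CE1 → disease sample, CE2 → compared sample is a
convention (both entities are diseased; the source material does not define
which is "the" sample).

The relevance filter for tumor-vs-normal curation keeps records whose DOID
lies in the cancer subtree (root `DOID:162`, transitive `is_a` closure) and
whose frame is `Control` or `Control_Implicit`. A miniature hand-assembled
excerpt of the ontology (~30 real DOIDs with decoy non-cancer branches)
ships in `inst/extdata/` so the filter is testable offline; point
`do_subtree()` at a full OBO file for production use.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| trigger lexicons | bundled YAML | all SI/LI/ES/sample/control/context trigger sets; every set quoted in the method's description plus orthographic variants |
| `es_extension` | `FALSE` | adds "after"/"following" as entity separators; off by default because before/after-treatment comparisons are a documented miss of the method, shipped as an opt-in extension |
| `context_order` | title, first, investigation, analyzed, conclusion | disease-inference search order |
| `conclusion_fallback` | `TRUE` | whether conclusion sentences participate in inference |
| pattern files | bundled YAML | the P/Q construction inventory |

## Evaluation scoring

`score()` performs exact-match set comparison on a configurable component
tuple (default: abstract id, normalized entity, level, DOID): an instance is
a true positive only when every component matches. Percentages are reported
to two decimals with a mixed convention: precision and recall are
*truncated* while the F-score (computed from the untruncated values) is
*rounded*. The reference result tables are internally inconsistent on this
point — one table truncates its recall (83.69 from 83.6956...) but rounds
its F-score (88.51 from 88.5057...), while another rounds its recall and
truncates its F-score, and a third printed precision does not follow from
its own counts at all — so no single rule reproduces every printed value.
The package convention reproduces the primary evaluation triple exactly and
is applied uniformly.

## The synthetic corpus

`generate_fixtures()` produces seed-deterministic abstracts, each
instantiating one construction family (P1–P5, Q1–Q3, Type C, or a
trigger-free distractor) with slot fillers drawn from the bundled lexicons,
surrounded by trigger-free filler sentences, together with the complete gold
record. A quarter of the eligible instances state only "cancer tissues" in
the relation sentence and place the disease in the title or in a
patient-count methods sentence, exercising context inference; Type A
instances include two-disease (`Not_Control`) comparisons; Type B instances
mix implicit and plain indicators.

The generator emulates the *sentence constructions* of real abstracts, not
their noise: every relation sentence is grammatical, every entity is in the
bundled lexicons, and there are no misparses, tagger errors, anaphora or
cross-clause comparisons. Exact gold recovery (precision = recall = 1.0 on
200 generated abstracts, the regression suite's main end-to-end check)
therefore demonstrates that the pipeline implements the intended mapping
from covered constructions to records — it does not estimate real-corpus
accuracy, which is limited by parser fidelity, lexicon coverage and the
documented unhandled phenomena. The test suite uses corpora of 40–200
abstracts; these sizes give full coverage of every family and context case
while keeping the suite fast.

## Degenerate inputs and numerical choices

Empty input text yields empty token tables and no records; a sentence the
analyzer cannot process is skipped, never fatal. Negated predicates ("was
not higher") are dropped rather than inverted. Multi-relation sentences emit
all non-overlapping matches (one record per trigger token). Percentage
truncation uses a small epsilon guard against binary floating-point
representation (so 83.69 never truncates to 83.68).

## Known limitations

Comparisons spanning clauses ("normal cells express low levels of X;
cancer cells have increased X expression") and anaphoric aspects ("the same
microRNAs were detected at high levels ...") are not attempted — both are
documented failure modes of this rule-based approach. Quantitative
magnitudes ("twofold higher") are dropped; only the direction is kept.
Abstracts only; full text would require extending disease inference beyond
the title/first/conclusion heuristics. The bundled gene and disease
lexicons are deliberately small demonstration sets; production use should
supply organism-scale lexicons (or precomputed annotation files) through
the same interfaces.
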