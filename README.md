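# exprel

Rule-based extraction of gene and microRNA differential-expression relations
from biomedical abstracts.

## The problem

Expression databases that record which genes are up- or down-regulated in
which diseases are fed by two sources: large-scale experiments and manual
curation of the literature. The literature side lags badly — thousands of
small-scale studies report a differential-expression finding in one sentence
of their abstract, and curators cannot keep up. `exprel` is a text-mining
tool for that bottleneck: it reads abstract collections and emits curatable
records of the form *entity — level — disease — sample — compared sample*,
with entities normalized to NCBI Gene IDs / miRBase-style microRNA names and
diseases to Disease Ontology IDs (DOIDs). It is aimed at curators of
expression resources (tumor-vs-normal databases in particular) and at
researchers who want a structured view of expression claims for a gene set
or a disease.

## The model

Extraction is pattern matching over enhanced dependency graphs. Two sentence
families are extracted:

* **Type A (comparative)** — components SI/CA/CE/ES:

  > The expression of GPC5 gene **[CA]** was lower **[SI]** in lung cancer
  > tissues **[CE1]** than **[ES]** in adjacent non-cancerous tissues
  > **[CE2]**.

  The scale indicator (SI) is the comparative word; the compared aspect (CA)
  is the expression phrase; the compared entities (CE) are the two samples;
  the entity separator (ES — "than", "compared with", "versus") is verified
  but not extracted. Patterns follow the dependency edges: `nsubj` from the
  SI to the CA head, `nmod:in` edges from the SI to the CE heads.

* **Type B (level statement)** — components LI/EA/EL:

  > GALNT2 **[EA]** is frequently over-expressed **[LI]** in OSCC **[EL]**.

  Implicit-class indicators ("over-expressed", "increased") presuppose an
  unstated baseline and set an implicit-comparison flag; plain indicators
  ("high", "low") do not.

Downstream, argument-type constraints discard non-expression comparisons and
outcome statements (Type C), the level is normalized to High/Low, the
disease is read from the sample phrase or inferred from the abstract (title,
first sentence, investigation/methods sentences, conclusion), and each
comparison is classified by its frame of reference: `Control`,
`Control_Implicit`, `Not_Control` or `none`. A relevance filter keeps
records suitable for tumor-vs-normal databases: disease in the cancer
subtree of the Disease Ontology (root DOID:162) and frame
`Control`/`Control_Implicit`. See `vignette("exprel-methods")` for the full
account.

## Worked example

```r
library(exprel)
config <- exprel_config()
abs <- abstract("24439919", "Shp2 expression in oral squamous cell carcinoma.",
  paste("Expression of Shp2 protein was significantly upregulated in",
        "Oral Squamous Cell Carcinoma (OSCC) tissues compared with the",
        "normal tissues."))
rec <- assemble(abs, config)
t(as.data.frame(rec))
```

```
pmid               "24439919"
sentence_index     "1"
relation_type      "A"
entity_text        "Shp2"
entity_kind        "gene"
gene_id            "5781"
level              "High"
disease_text       "Oral Squamous Cell Carcinoma"
doid               "DOID:0050866"
disease_sample     "OSCC tissues"
compared_sample    "normal tissues"
frame_of_reference "Control"
disease_source     "sentence"
```

Reading: Shp2 (NCBI Gene ID 5781) is reported High in oral squamous cell
carcinoma (DOID:0050866), observed in "OSCC tissues" against "normal
tissues" — an explicit comparison to a control baseline (`Control`), so the
record passes `bioxpress_filter()` for tumor-vs-normal curation.

Evaluation scoring is exact-match per component tuple:

```r
score_from_counts(77, 5, 15)
#> TP 77  FP 5  FN 15  P 93.90  R 83.69  F 88.51
```

## Command line

A thin wrapper is installed at `exec/exprel` inside the package
installation; all subcommands are also callable via `exprel_cli()`:

```sh
Rscript -e 'exprel::exprel_cli(commandArgs(TRUE))' fixtures --n 50 --seed 1 --out corpus/
Rscript -e 'exprel::exprel_cli(commandArgs(TRUE))' extract --input corpus/abstracts.tsv \
    --output records.jsonl --bioxpress
Rscript -e 'exprel::exprel_cli(commandArgs(TRUE))' report --input records.jsonl
```

`extract` accepts Medline XML, `pmid<TAB>title<TAB>abstract` TSV, or a
directory of text files, and writes JSONL or TSV records.

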