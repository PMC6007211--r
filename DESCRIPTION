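Package: exprel
Title: Rule-Based Extraction of Gene and microRNA Differential-Expression
    Relations from Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A curation-oriented text-mining tool that extracts statements of
    differential gene and microRNA expression in disease contexts from Medline
    abstracts. Sentences are tokenized and analyzed into enhanced dependency
    graphs; declarative dependency patterns recover comparative (Type A) and
    plain expression-level (Type B) relations; entity taggers normalize genes
    to NCBI Gene identifiers, microRNAs to miRBase-style names and diseases to
    Disease Ontology identifiers; and an assembly stage infers the disease
    from abstract context where the sentence only names a generic sample,
    classifies the frame of reference of the comparison, and emits curatable
    records. Includes a cancer-subtree relevance filter, an exact-match
    evaluation scorer, a deterministic synthetic-abstract generator for
    regression testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    tibble,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
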