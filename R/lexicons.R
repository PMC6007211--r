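# Trigger, gene and disease lexicons. All matching is case-insensitive and
# operates on lowercased surface forms and lemmas.

#' Load the trigger lexicons
#'
#' Reads the YAML trigger file (default: the bundled one) and derives the
#' union sets the extractors use: `si` (scale indicators), `li` (all level
#' indicators), `li_implicit`, `li_plain`, `high`, `low` and the entity
#' separators (optionally extended with "after"/"following").
#'
#' @param path Path to a triggers YAML file.
#' @param es_extension Include the opt-in entity-separator extensions?
#' @return An object of class `exprel_triggers` (a named list of lowercase
#'   character sets).
#' @export
load_trigger_lexicons <- function(path = exprel_file("lexicons", "triggers.yaml"),
                                  es_extension = FALSE) {
  raw <- yaml::read_yaml(path)
  need <- c("expression_nouns", "si_high", "si_low", "li_implicit_high",
            "li_implicit_low", "li_plain_high", "li_plain_low",
            "entity_separators", "disease_sample_heads", "control_modifiers",
            "generic_disease_phrases", "agent_words", "purpose_words",
            "investigation_triggers", "analyzed_triggers", "observation_verbs")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("trigger lexicon file lacks sets: ", paste(missing, collapse = ", "))
  lex <- lapply(raw, function(x) unique(tolower(as.character(x))))
  stopifnot(length(intersect(lex$si_high, lex$si_low)) == 0L,
            length(intersect(union(lex$li_implicit_high, lex$li_plain_high),
                             union(lex$li_implicit_low, lex$li_plain_low))) == 0L,
            length(intersect(union(lex$li_implicit_high, lex$li_implicit_low),
                             union(lex$li_plain_high, lex$li_plain_low))) == 0L)
  lex$si <- union(lex$si_high, lex$si_low)
  lex$li_implicit <- union(lex$li_implicit_high, lex$li_implicit_low)
  lex$li_plain <- union(lex$li_plain_high, lex$li_plain_low)
  lex$li <- union(lex$li_implicit, lex$li_plain)
  lex$high <- Reduce(union, list(lex$si_high, lex$li_implicit_high, lex$li_plain_high))
  lex$low <- Reduce(union, list(lex$si_low, lex$li_implicit_low, lex$li_plain_low))
  lex$es <- lex$entity_separators
  if (es_extension) lex$es <- union(lex$es, lex$es_extension)
  structure(lex, class = "exprel_triggers")
}

# membership test on surface or lemma
trig_has <- function(set, surface, lemma = surface) {
  tolower(surface) %in% set | tolower(lemma) %in% set
}

#' Load a name-to-identifier lexicon
#'
#' Reads a two-column TSV (`name<TAB>id`). Names are lowercased; lookup is
#' longest-match and case-insensitive.
#'
#' @param path TSV path.
#' @param id_col Name of the identifier column (second column is used if the
#'   header does not match).
#' @return A list with `map` (named character vector), `max_words` (longest
#'   entry in tokens).
#' @keywords internal
.load_name_lexicon <- function(path, id_col) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("lexicon must have two tab-separated columns: ", path)
  nm <- tolower(trimws(tab[[1]]))
  id <- as.character(tab[[2]])
  keep <- nzchar(nm) & nzchar(id)
  map <- stats::setNames(id[keep], nm[keep])
  list(map = map,
       max_words = max(1L, lengths(strsplit(names(map), "[ -]+"))))
}

#' Load the gene lexicon (name to NCBI Gene ID)
#' @param path TSV path (`name<TAB>ncbi_gene_id`).
#' @return A gene lexicon object.
#' @export
load_gene_lexicon <- function(path = exprel_file("lexicons", "genes.tsv")) {
  structure(.load_name_lexicon(path, "ncbi_gene_id"), class = "exprel_gene_lexicon")
}

#' Load the disease lexicon (name to DOID)
#'
#' @param path TSV path (`name<TAB>doid`).
#' @param medic_map Optional TSV mapping MEDIC identifiers to DOIDs, used when
#'   reading precomputed annotation files whose disease identifiers are MEDIC.
#' @return A disease lexicon object.
#' @export
load_disease_lexicon <- function(path = exprel_file("lexicons", "diseases.tsv"),
                                 medic_map = exprel_file("lexicons", "medic_doid.tsv")) {
  lex <- .load_name_lexicon(path, "doid")
  lex$medic <- character(0)
  if (!is.null(medic_map) && file.exists(medic_map)) {
    mm <- utils::read.delim(medic_map, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, quote = "")
    lex$medic <- stats::setNames(as.character(mm[[2]]), toupper(trimws(mm[[1]])))
  }
  structure(lex, class = "exprel_disease_lexicon")
}

#' Locate a file bundled with the package
#' @param ... Path components below `inst/`.
#' @return Absolute path.
#' @export
exprel_file <- function(...) {
  p <- system.file(..., package = "exprel", mustWork = FALSE)
  if (!nzchar(p)) stop("bundled file not found: ", file.path(...))
  p
}

#' Build a pipeline configuration
#'
#' Bundles the trigger lexicons, gene/disease lexicons, the Type A/B pattern
#' sets and the tunable options into one object consumed by
#' [extract_expression()] and [assemble()].
#'
#' @param triggers,genes,diseases Lexicon objects (defaults: bundled files).
#' @param patterns_a,patterns_b Pattern sets (defaults: bundled files).
#' @param es_extension Enable "after"/"following" as entity separators.
#' @param conclusion_fallback Consult the final (conclusion) sentences during
#'   disease-context inference.
#' @param context_order Search order for disease-context inference.
#' @return An `exprel_config` object.
#' @export
exprel_config <- function(triggers = NULL, genes = NULL, diseases = NULL,
                          patterns_a = NULL, patterns_b = NULL,
                          es_extension = FALSE, conclusion_fallback = TRUE,
                          context_order = c("title", "first", "investigation",
                                            "analyzed", "conclusion")) {
  if (is.null(triggers)) triggers <- load_trigger_lexicons(es_extension = es_extension)
  if (is.null(genes)) genes <- load_gene_lexicon()
  if (is.null(diseases)) diseases <- load_disease_lexicon()
  if (is.null(patterns_a)) patterns_a <- load_patterns(exprel_file("patterns", "type_a.yaml"), triggers)
  if (is.null(patterns_b)) patterns_b <- load_patterns(exprel_file("patterns", "type_b.yaml"), triggers)
  structure(list(triggers = triggers, genes = genes, diseases = diseases,
                 patterns_a = patterns_a, patterns_b = patterns_b,
                 conclusion_fallback = conclusion_fallback,
                 context_order = match.arg(context_order, several.ok = TRUE)),
            class = "exprel_config")
}
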