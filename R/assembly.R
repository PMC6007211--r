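# Assembly: argument-type filtering, gene/level/disease/sample extraction,
# disease-context inference, frame-of-reference classification, and record
# emission.

#' Verify the argument types of a relation
#'
#' Type A: the compared aspect must be an expression phrase and both compared
#' entities disease samples. Type B: the expressed aspect must be a gene or
#' gene-expression phrase and the expressed location a disease sample.
#'
#' @param relation A relation from the extractors.
#' @param mentions Mention table for the sentence.
#' @param triggers Trigger lexicons.
#' @return TRUE, or FALSE with a `reason` attribute naming the failed slot.
#' @export
filter_by_type <- function(relation, mentions, triggers) {
  g <- relation$graph
  fail <- function(code) structure(FALSE, reason = code)
  if (inherits(relation, "exprel_relation_a")) {
    if (!type_expression_phrase(g, relation$ca, mentions, triggers))
      return(fail("ca-not-expression"))
    if (!type_disease_sample(g, relation$ce1, mentions, triggers))
      return(fail("ce1-not-disease-sample"))
    if (!type_disease_sample(g, relation$ce2, mentions, triggers))
      return(fail("ce2-not-disease-sample"))
  } else {
    if (!type_expression_phrase(g, relation$ea, mentions, triggers))
      return(fail("ea-not-expression"))
    if (!type_disease_sample(g, relation$el, mentions, triggers))
      return(fail("el-not-disease-sample"))
  }
  TRUE
}

#' Extract the expressed gene or microRNA from a relation
#'
#' Looks for gene/microRNA mentions inside the compared/expressed aspect span
#' (including of-complements). When conjunction expansion has pinned an
#' entity head on the relation, only the mention covering that head is used.
#'
#' @inheritParams filter_by_type
#' @return data.frame of candidate entities (`entity_kind`, `entity_text`,
#'   `gene_id`, `mirna_norm`), zero rows when none found.
#' @export
extract_gene <- function(relation, mentions) {
  g <- relation$graph
  span <- if (inherits(relation, "exprel_relation_a")) relation$ca_span else relation$ea_span
  if (!is.null(relation$entity_head)) {
    tokr <- g$nodes[relation$entity_head, ]
    hits <- .mention_covering(mentions, tokr$start, tokr$end, c("GENE", "MIRNA"))
  } else {
    hits <- .mentions_in_range(mentions, span$start, span$end, c("GENE", "MIRNA"))
  }
  if (!nrow(hits)) {
    return(data.frame(entity_kind = character(0), entity_text = character(0),
                      gene_id = character(0), mirna_norm = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    entity_kind = ifelse(hits$etype == "GENE", "gene", "mirna"),
    entity_text = hits$surface,
    gene_id = ifelse(hits$etype == "GENE", hits$norm_id, NA_character_),
    mirna_norm = ifelse(hits$etype == "MIRNA", hits$norm_id, NA_character_),
    stringsAsFactors = FALSE)
}

#' Normalize a scale/level indicator to High or Low
#'
#' @param token_surface Surface form of the SI/LI token.
#' @param triggers Trigger lexicons.
#' @param token_lemma Lemma (defaults to the surface).
#' @return `"High"`, `"Low"`, or `NA` if the token is in neither direction
#'   set (cannot occur for relations produced by the extractors).
#' @export
normalize_level <- function(token_surface, triggers, token_lemma = token_surface) {
  if (trig_has(triggers$high, token_surface, token_lemma)) return("High")
  if (trig_has(triggers$low, token_surface, token_lemma)) return("Low")
  NA_character_
}

# control-modifier content of a compared-entity span
.has_control <- function(graph, span, triggers) {
  tok <- graph$nodes
  inside <- tok$idx >= span$from & tok$idx <= span$to
  any(trig_has(triggers$control_modifiers, tok$surface[inside], tok$lemma[inside]))
}

#' Classify the frame of reference of a relation
#'
#' Type A: `Control` when exactly one compared entity contains a control
#' modifier ("control", "normal", "healthy", "adjacent", ...) — that entity
#' is the compared sample; `Not_Control` otherwise (including the ambiguous
#' both-control case, with a warning). Type B: `Control_Implicit` when the
#' level indicator is of the implicit-comparison class, else `none`.
#'
#' @inheritParams filter_by_type
#' @return List with `frame`, and for Type A `sample_ce` / `compared_ce`
#'   (which CE is the disease sample vs the baseline).
#' @export
classify_frame_of_reference <- function(relation, mentions, triggers) {
  if (inherits(relation, "exprel_relation_b")) {
    return(list(frame = if (relation$implicit_comparison) "Control_Implicit" else "none"))
  }
  g <- relation$graph
  c1 <- .has_control(g, relation$ce1_span, triggers)
  c2 <- .has_control(g, relation$ce2_span, triggers)
  if (c1 && c2) {
    warning("both compared entities contain control modifiers; Not_Control",
            call. = FALSE)
    return(list(frame = "Not_Control", sample_ce = "ce1", compared_ce = "ce2"))
  }
  if (c1) return(list(frame = "Control", sample_ce = "ce2", compared_ce = "ce1"))
  if (c2) return(list(frame = "Control", sample_ce = "ce1", compared_ce = "ce2"))
  list(frame = "Not_Control", sample_ce = "ce1", compared_ce = "ce2")
}

# render a sample span for the record: compress a parenthetically defined
# abbreviation ("Long Form (SF) tissues" -> "SF tissues"), strip a leading
# determiner, collapse whitespace
.render_sample <- function(text) {
  out <- text
  if (grepl("\\(\\s*[A-Za-z0-9][A-Za-z0-9-]{1,9}\\s*\\)", out)) {
    out <- sub("^[^()]+\\(\\s*([A-Za-z0-9][A-Za-z0-9-]{1,9})\\s*\\)\\s*", "\\1 ", out)
  }
  out <- sub("^(?i)(the|a|an|this|these|those)\\s+", "", out, perl = TRUE)
  out <- gsub("\\s+", " ", trimws(out))
  out
}

# disease mention search within a span (earliest, then longest)
.disease_in_span <- function(mentions, span) {
  hits <- .mentions_in_range(mentions, span$start, span$end, "DISEASE")
  if (!nrow(hits)) return(NULL)
  hits <- hits[order(hits$start, -(hits$end - hits$start)), , drop = FALSE]
  hits[1L, , drop = FALSE]
}

# --- abstract context ------------------------------------------------------

# per-abstract context: parsed graphs and mentions for every sentence
.abstract_context <- function(abs, config) {
  aliases <- link_abbreviations(abs$sentences, config$diseases, config$genes)
  lapply(abs$sentences, function(s) {
    g <- tryCatch(parse_sentence(s, config$triggers), error = function(e) NULL)
    m <- tag_sentence(s, config, aliases)
    list(sentence = s, graph = g, mentions = m)
  })
}

.is_investigation_sentence <- function(ctx, triggers) {
  g <- ctx$graph
  if (is.null(g)) return(FALSE)
  tok <- g$nodes
  trig <- which(trig_has(triggers$investigation_triggers, tok$surface, tok$lemma) &
                  tok$pos %in% c("V", "VBNmod"))
  for (t in trig) {
    subj <- g$edges$dep[g$edges$gov == t & grepl("^nsubj", g$edges$label)]
    passive <- any(g$edges$gov == t & g$edges$label == "nsubj:pass")
    if (passive) return(TRUE)
    for (s in subj) {
      if (trig_has(union(triggers$agent_words, triggers$purpose_words),
                   tok$surface[s], tok$lemma[s])) return(TRUE)
    }
  }
  FALSE
}

.is_analyzed_sentence <- function(ctx, triggers) {
  g <- ctx$graph
  if (is.null(g)) return(FALSE)
  tok <- g$nodes
  trig <- which(trig_has(triggers$analyzed_triggers, tok$surface, tok$lemma) &
                  tok$pos %in% c("V", "VBNmod"))
  for (t in trig) {
    theme <- g$edges$dep[g$edges$gov == t & g$edges$label == "nsubj:pass"]
    for (th in theme) {
      sp <- np_yield(g, th)
      inside <- tok$idx >= sp$from & tok$idx <= sp$to
      if (any(tok$pos[inside] == "CD")) return(TRUE)
    }
  }
  FALSE
}

#' Infer the associated disease from abstract context
#'
#' When a relation's compared entity or expressed location only names a
#' generic sample ("cancer tissues"), the disease is searched for elsewhere
#' in the abstract, in a fixed location order: title, first body sentence,
#' investigation sentences (an investigation trigger with an author/purpose
#' agent or in the passive), experiment-setup sentences (a passive analyzed
#' trigger whose theme contains a count of patients/samples), and finally
#' the conclusion sentences (configurable). The first disease mention found
#' wins; ties within a sentence go to the earliest offset.
#'
#' @param context Abstract context from the assembly pipeline (one element
#'   per sentence: `sentence`, `graph`, `mentions`).
#' @param triggers Trigger lexicons.
#' @param order Location search order.
#' @param conclusion_fallback Consult conclusion sentences?
#' @return List (`disease_text`, `doid`, `disease_source`) or `NULL`.
#' @export
infer_disease_from_context <- function(context, triggers,
                                       order = c("title", "first",
                                                 "investigation", "analyzed",
                                                 "conclusion"),
                                       conclusion_fallback = TRUE) {
  pick <- function(idx, source) {
    for (i in idx) {
      m <- context[[i]]$mentions
      hits <- m[m$etype == "DISEASE", , drop = FALSE]
      if (nrow(hits)) {
        hits <- hits[order(hits$start), , drop = FALSE]
        return(list(disease_text = hits$surface[1L],
                    doid = hits$norm_id[1L], disease_source = source))
      }
    }
    NULL
  }
  hints <- vapply(context, function(c) c$sentence$section_hint, character(1))
  for (loc in order) {
    res <- switch(loc,
      title = pick(which(hints == "TITLE"), "title"),
      first = pick(which(hints == "FIRST"), "first"),
      investigation = pick(Filter(function(i)
        .is_investigation_sentence(context[[i]], triggers),
        seq_along(context)), "investigation"),
      analyzed = pick(Filter(function(i)
        .is_analyzed_sentence(context[[i]], triggers),
        seq_along(context)), "analyzed"),
      conclusion = if (conclusion_fallback)
        pick(which(hints == "CONCLUSION"), "conclusion") else NULL)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Extract the associated disease for a relation
#'
#' Checks the disease-sample argument (for Type A, the non-control compared
#' entity; for Type B, the expressed location) for a disease mention; falls
#' back to [infer_disease_from_context()] when the argument is generic.
#'
#' @inheritParams filter_by_type
#' @param sample_span The span of the disease-sample argument.
#' @param context Abstract context.
#' @param config Pipeline configuration.
#' @return List (`disease_text`, `doid`, `disease_source`), possibly with
#'   `NA` fields when no disease was found anywhere.
#' @export
extract_disease <- function(relation, mentions, sample_span, context, config) {
  hit <- .disease_in_span(mentions, sample_span)
  if (!is.null(hit)) {
    return(list(disease_text = hit$surface, doid = hit$norm_id,
                disease_source = "sentence"))
  }
  res <- infer_disease_from_context(context, config$triggers,
                                    order = config$context_order,
                                    conclusion_fallback = config$conclusion_fallback)
  if (!is.null(res)) return(res)
  list(disease_text = NA_character_, doid = NA_character_,
       disease_source = NA_character_)
}

#' Assemble curatable records from one abstract
#'
#' Runs the full per-abstract pipeline: abbreviation linking, per-sentence
#' prefiltering, dependency analysis, entity tagging, Type A/B relation
#' extraction with comparison precedence, conjunction expansion, argument
#' filtering, and field extraction (entity, level, disease with context
#' inference, samples, frame of reference). Per-stage failures drop the
#' relation with a reason code (attribute `log`), never the abstract.
#'
#' @param abs An `exprel_abstract`.
#' @param config An [exprel_config()].
#' @return Record tibble, sorted by (pmid, sentence index, entity span);
#'   attribute `log` holds the reason-code table.
#' @export
assemble <- function(abs, config = exprel_config()) {
  context <- .abstract_context(abs, config)
  triggers <- config$triggers
  records <- list()
  log <- data.frame(pmid = character(0), sentence_index = integer(0),
                    stage = character(0), code = character(0),
                    stringsAsFactors = FALSE)
  note <- function(idx, stage, code) {
    log[nrow(log) + 1L, ] <<- list(abs$pmid, idx, stage, code)
  }
  for (ctx in context) {
    s <- ctx$sentence
    if (!prefilter(s, triggers)) next
    g <- ctx$graph
    if (is.null(g)) { note(s$index, "parse", "parser-failure"); next }
    mentions <- ctx$mentions
    rels_a <- extract_type_a(g, triggers, config$patterns_a)
    consumed <- vapply(rels_a, function(r) r$si, integer(1))
    rels_b <- extract_type_b(g, triggers, config$patterns_b, consumed = consumed)
    rels <- expand_conjunctions(c(rels_a, rels_b), g)
    for (rel in rels) {
      ok <- filter_by_type(rel, mentions, triggers)
      if (!isTRUE(ok)) { note(s$index, "type-filter", attr(ok, "reason")); next }
      is_a <- inherits(rel, "exprel_relation_a")
      ents <- extract_gene(rel, mentions)
      if (!nrow(ents)) { note(s$index, "gene", "no-expressed-entity"); next }
      trig_tok <- if (is_a) rel$si else rel$li
      level <- normalize_level(g$nodes$surface[trig_tok], triggers,
                               g$nodes$lemma[trig_tok])
      if (is.na(level)) { note(s$index, "level", "no-direction"); next }
      fr <- classify_frame_of_reference(rel, mentions, triggers)
      if (is_a) {
        sample_span <- rel[[paste0(fr$sample_ce, "_span")]]
        compared_span <- rel[[paste0(fr$compared_ce, "_span")]]
      } else {
        sample_span <- rel$el_span
        compared_span <- NULL
      }
      dis <- extract_disease(rel, mentions, sample_span, context, config)
      if (is.na(dis$doid)) note(s$index, "disease", "unresolved-disease")
      for (e in seq_len(nrow(ents))) {
        records[[length(records) + 1L]] <- tibble::tibble(
          pmid = abs$pmid, sentence_index = s$index, sentence_text = s$text,
          relation_type = if (is_a) "A" else "B",
          entity_text = ents$entity_text[e],
          entity_kind = ents$entity_kind[e],
          gene_id = ents$gene_id[e], mirna_norm = ents$mirna_norm[e],
          level = level,
          disease_text = dis$disease_text, doid = dis$doid,
          disease_sample = .render_sample(sample_span$text),
          compared_sample = if (is_a) .render_sample(compared_span$text) else NA_character_,
          frame_of_reference = fr$frame,
          disease_source = dis$disease_source)
      }
    }
  }
  out <- if (length(records)) do.call(rbind, records) else empty_records()
  out <- out[order(out$pmid, out$sentence_index, out$entity_text), ]
  attr(out, "log") <- log
  out
}

#' Run the extraction pipeline over a collection of abstracts
#'
#' @param abstracts List of `exprel_abstract` objects.
#' @param config An [exprel_config()].
#' @return Record tibble (all abstracts, sorted), with the combined reason
#'   log in attribute `log`.
#' @export
extract_expression <- function(abstracts, config = exprel_config()) {
  parts <- lapply(abstracts, assemble, config = config)
  out <- do.call(rbind, c(parts, list(empty_records())))
  logs <- do.call(rbind, lapply(parts, attr, "log"))
  out <- out[order(out$pmid, out$sentence_index, out$entity_text), ]
  attr(out, "log") <- logs
  out
}
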