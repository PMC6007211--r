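# Entity detection and phrase typing: genes (lexicon, NCBI Gene IDs),
# microRNAs (miRBase-convention regex), diseases (lexicon + in-abstract
# abbreviation linking, DOIDs), expression phrases and disease samples.

.empty_mentions <- function() {
  data.frame(start = integer(0), end = integer(0), surface = character(0),
             etype = character(0), norm_id = character(0),
             arm = character(0), stringsAsFactors = FALSE)
}

.MIRNA_RE <- paste0(
  "(?i)(?<![A-Za-z0-9-])",
  "((?:[a-z]{2,4}-)?)",                 # optional species prefix (hsa-)
  "(microrna|micro-rna|mirna|mir|let)", # stem
  "[-\\s]?",
  "(\\d+)([a-z]?)",                     # number + optional letter suffix
  "((?:-\\d+)?)",                       # optional paralog variant (-1, -2)
  "((?:-[35]p)?)",                      # optional arm suffix
  "(?![A-Za-z0-9])"
)

#' Tag microRNA mentions
#'
#' Matches the miRBase naming convention (miR-21, microRNA1, hsa-miR-1-3p,
#' let-7a, ...). The normalized name lowercases the stem to `mir` (or `let`),
#' restores hyphenation and drops the species prefix; the arm suffix (3p/5p)
#' is kept in a secondary `arm` field. Elided coordinated stems
#' ("miR-143 and -195") are expanded: a bare "-NNN" token coordinated with a
#' full mention inherits its stem.
#'
#' @param sentence Sentence object (list with `text` and `tokens`) or string.
#' @return Mention data.frame (`start`/`end` 0-based half-open, `surface`,
#'   `etype` = "MIRNA", `norm_id`, `arm`).
#' @export
tag_mirnas <- function(sentence) {
  if (is.character(sentence)) {
    text <- normalize_text(sentence)
    sentence <- list(text = text, tokens = tokenize(text))
  }
  text <- sentence$text
  m <- stringi::stri_match_all_regex(text, .MIRNA_RE)[[1]]
  loc <- stringi::stri_locate_all_regex(text, .MIRNA_RE)[[1]]
  out <- .empty_mentions()
  if (!anyNA(m[, 1]) && nrow(m)) {
    stem <- ifelse(tolower(m[, 3]) == "let", "let", "mir")
    norm <- paste0(stem, "-", m[, 4], tolower(m[, 5]), tolower(m[, 6]))
    arm <- sub("^-", "", tolower(m[, 7]))
    out <- data.frame(start = loc[, 1] - 1L, end = loc[, 2],
                      surface = m[, 1], etype = "MIRNA", norm_id = norm,
                      arm = arm, stringsAsFactors = FALSE)
  }
  # coordination expansion for elided stems
  tok <- sentence$tokens
  if (nrow(out) && nrow(tok)) {
    stubs <- which(grepl("^-\\d+[a-z]?(-[35]p)?$", tok$surface))
    for (s in stubs) {
      if (any(out$start <= tok$start[s] & out$end >= tok$end[s])) next
      before <- out[out$end <= tok$start[s], , drop = FALSE]
      if (!nrow(before)) next
      cc_between <- any(tok$pos == "CC" &
                          tok$start >= max(before$end) & tok$end <= tok$start[s])
      if (!cc_between) next
      donor <- before[which.max(before$end), ]
      stem <- sub("-.*$", "", donor$norm_id)
      body <- sub("^-", "", tok$surface[s])
      arm <- ""
      if (grepl("-[35]p$", body)) {
        arm <- sub("^.*-([35]p)$", "\\1", body)
        body <- sub("-[35]p$", "", body)
      }
      out <- rbind(out, data.frame(start = tok$start[s], end = tok$end[s],
                                   surface = tok$surface[s], etype = "MIRNA",
                                   norm_id = paste0(stem, "-", tolower(body)),
                                   arm = arm, stringsAsFactors = FALSE))
    }
  }
  out[order(out$start), , drop = FALSE]
}

# longest-match, token-boundary-aligned n-gram lookup against a name map
.tag_by_lexicon <- function(sentence, map, max_words, etype,
                            extra = character(0), skip_spans = NULL) {
  tok <- sentence$tokens
  out <- .empty_mentions()
  if (!nrow(tok)) return(out)
  full <- c(map, extra)
  wordish <- which(!tok$pos %in% "PUNCT")
  taken <- rep(FALSE, nrow(tok))
  if (!is.null(skip_spans) && nrow(skip_spans)) {
    for (k in seq_len(nrow(skip_spans)))
      taken <- taken | (tok$start >= skip_spans$start[k] &
                          tok$end <= skip_spans$end[k])
  }
  i <- 1L
  while (i <= length(wordish)) {
    ti <- wordish[i]
    if (taken[ti]) { i <- i + 1L; next }
    hit_len <- 0L; hit_id <- NA_character_
    for (L in seq(min(max_words, length(wordish) - i + 1L), 1L)) {
      idxs <- wordish[i:(i + L - 1L)]
      if (any(taken[idxs])) next
      if (any(diff(idxs) > 1L)) next          # punctuation gap
      surf <- tolower(paste(tok$surface[idxs], collapse = " "))
      lem <- tolower(paste(tok$lemma[idxs], collapse = " "))
      id <- full[surf]
      if (is.na(id)) id <- full[lem]
      if (!is.na(id)) { hit_len <- L; hit_id <- unname(id); break }
    }
    if (hit_len) {
      idxs <- wordish[i:(i + hit_len - 1L)]
      st <- tok$start[idxs[1]]; en <- tok$end[idxs[hit_len]]
      out <- rbind(out, data.frame(
        start = st, end = en,
        surface = substr(sentence$text, st + 1L, en),
        etype = etype, norm_id = hit_id, arm = "", stringsAsFactors = FALSE))
      taken[idxs] <- TRUE
      i <- i + hit_len
    } else i <- i + 1L
  }
  out
}

#' Tag gene mentions with a lexicon
#'
#' Longest-match, case-insensitive, token-boundary-aligned lookup against the
#' gene lexicon; each mention carries its NCBI Gene ID. Spans overlapping a
#' microRNA mention are skipped (the microRNA regex is the more specific
#' pattern). Genes and proteins are not distinguished.
#'
#' @param sentence Sentence object or string.
#' @param lexicon A gene lexicon from [load_gene_lexicon()].
#' @param mirnas Optional precomputed microRNA mentions for overlap exclusion.
#' @param aliases Named character vector of per-abstract abbreviation aliases
#'   (lowercase short form -> gene id).
#' @return Mention data.frame with `etype` = "GENE".
#' @export
tag_genes <- function(sentence, lexicon, mirnas = NULL, aliases = character(0)) {
  if (is.character(sentence)) {
    text <- normalize_text(sentence)
    sentence <- list(text = text, tokens = tokenize(text))
  }
  if (is.null(mirnas)) mirnas <- tag_mirnas(sentence)
  .tag_by_lexicon(sentence, lexicon$map, lexicon$max_words, "GENE",
                  extra = aliases, skip_spans = mirnas)
}

#' Tag disease mentions with a lexicon
#'
#' Longest-match lookup against the disease lexicon (surface and lemma forms,
#' so plural mentions match singular entries); resolved mentions carry a
#' DOID. Per-abstract abbreviation aliases let a short form defined
#' parenthetically ("... (OSCC)") inherit the long form's DOID.
#'
#' @inheritParams tag_genes
#' @param lexicon A disease lexicon from [load_disease_lexicon()].
#' @return Mention data.frame with `etype` = "DISEASE".
#' @export
tag_diseases <- function(sentence, lexicon, aliases = character(0)) {
  if (is.character(sentence)) {
    text <- normalize_text(sentence)
    sentence <- list(text = text, tokens = tokenize(text))
  }
  .tag_by_lexicon(sentence, lexicon$map, max(lexicon$max_words, 6L),
                  "DISEASE", extra = aliases)
}

#' Detect parenthetically defined abbreviations in an abstract
#'
#' Classic long-form/short-form matching: for every "long form (SF)" pair the
#' short form's characters are matched right-to-left inside the preceding
#' words. Returns aliases usable by the taggers: short forms whose long form
#' resolves in the disease (or gene) lexicon inherit its identifier.
#'
#' @param sentences List of sentence objects.
#' @param diseases Disease lexicon.
#' @param genes Gene lexicon.
#' @return List with `disease` and `gene` named alias vectors.
#' @export
link_abbreviations <- function(sentences, diseases = NULL, genes = NULL) {
  dis <- character(0); gen <- character(0)
  for (s in sentences) {
    tok <- s$tokens
    opens <- which(tok$surface == "(")
    for (o in opens) {
      if (o < 2L || o + 2L > nrow(tok)) next
      if (tok$surface[o + 2L] != ")") next
      sf <- tok$surface[o + 1L]
      if (nchar(sf) < 2L || nchar(sf) > 10L || !grepl("[A-Za-z]", sf)) next
      nw <- min(nchar(sf) + 5L, nchar(sf) * 2L)
      lo <- max(1L, o - nw)
      cand_idx <- lo:(o - 1L)
      cand_idx <- cand_idx[tok$pos[cand_idx] != "PUNCT"]
      if (!length(cand_idx)) next
      lf <- .best_long_form(sf, tok$surface[cand_idx])
      if (is.null(lf)) next
      lf_txt <- tolower(paste(lf, collapse = " "))
      if (!is.null(diseases) && !is.na(diseases$map[lf_txt]))
        dis[tolower(sf)] <- unname(diseases$map[lf_txt])
      if (!is.null(genes) && !is.na(genes$map[lf_txt]))
        gen[tolower(sf)] <- unname(genes$map[lf_txt])
    }
  }
  list(disease = dis, gene = gen)
}

# right-to-left character matching of the short form in the candidate words;
# returns the long-form word vector or NULL
.best_long_form <- function(sf, words) {
  l <- tolower(paste(words, collapse = " "))
  s <- tolower(gsub("[^a-z0-9]", "", tolower(sf)))
  i <- nchar(s); j <- nchar(l)
  while (i > 0L) {
    c <- substr(s, i, i)
    while (j > 0L) {
      lc <- substr(l, j, j)
      if (lc == c && !(i == 1L && j > 1L &&
                       grepl("[a-z0-9]", substr(l, j - 1L, j - 1L)))) break
      j <- j - 1L
    }
    if (j == 0L) return(NULL)
    i <- i - 1L; j <- j - 1L
  }
  # word containing position j+1 starts the long form
  starts <- cumsum(c(1L, nchar(words)[-length(words)] + 1L))
  w0 <- max(which(starts <= j + 1L))
  words[w0:length(words)]
}

#' Tag all entity mentions in a sentence
#'
#' Runs the microRNA, gene and disease taggers and returns one mention table.
#' Mentions of the same type never overlap; gene and microRNA mentions never
#' overlap each other.
#'
#' @param sentence Sentence object.
#' @param config An [exprel_config()].
#' @param aliases Abbreviation aliases from [link_abbreviations()].
#' @return Mention data.frame.
#' @export
tag_sentence <- function(sentence, config,
                         aliases = list(disease = character(0),
                                        gene = character(0))) {
  mir <- tag_mirnas(sentence)
  gen <- tag_genes(sentence, config$genes, mirnas = mir,
                   aliases = aliases$gene)
  dis <- tag_diseases(sentence, config$diseases, aliases = aliases$disease)
  out <- rbind(mir, gen, dis)
  out[order(out$start, out$end), , drop = FALSE]
}

# mentions of a type covering a token
.mention_covering <- function(mentions, tok_start, tok_end, etypes) {
  mentions[mentions$etype %in% etypes & mentions$start <= tok_start &
             mentions$end >= tok_end, , drop = FALSE]
}

# mentions overlapping a character range
.mentions_in_range <- function(mentions, start, end, etypes) {
  mentions[mentions$etype %in% etypes & mentions$start < end &
             mentions$end > start, , drop = FALSE]
}

#' Is a noun phrase an expression phrase?
#'
#' True iff the head noun is an expression trigger ("expression", "level",
#' "over-expression", ...) or the head is itself a gene/microRNA mention (the
#' expressed entity then is the phrase).
#'
#' @param graph Dependency graph of the sentence.
#' @param np_head Token index of the phrase head.
#' @param mentions Mention table for the sentence.
#' @param triggers Trigger lexicons.
#' @return Logical.
#' @export
type_expression_phrase <- function(graph, np_head, mentions, triggers) {
  tokr <- graph$nodes[np_head, ]
  if (trig_has(triggers$expression_nouns, tokr$surface, tokr$lemma)) return(TRUE)
  nrow(.mention_covering(mentions, tokr$start, tokr$end,
                         c("GENE", "MIRNA"))) > 0L
}

#' Is a noun phrase a disease sample?
#'
#' True iff the phrase contains a disease mention, or its head is a
#' disease-sample trigger ("tissues", "cells", "patients", ...) or a generic
#' disease phrase ("tumor", "cancer", ...).
#'
#' @inheritParams type_expression_phrase
#' @return Logical.
#' @export
type_disease_sample <- function(graph, np_head, mentions, triggers) {
  tokr <- graph$nodes[np_head, ]
  if (trig_has(triggers$disease_sample_heads, tokr$surface, tokr$lemma)) return(TRUE)
  if (trig_has(triggers$generic_disease_phrases, tokr$surface, tokr$lemma)) return(TRUE)
  sp <- np_yield(graph, np_head)
  nrow(.mentions_in_range(mentions, sp$start, sp$end, "DISEASE")) > 0L
}

#' Read a precomputed entity-annotation file (offset format)
#'
#' Reads tab-separated precomputed annotations
#' (`pmid<TAB>start<TAB>end<TAB>text<TAB>type<TAB>id`) as an alternative to
#' the bundled lexicon taggers. Disease identifiers in MEDIC form are mapped
#' to DOIDs via the lexicon's mapping table; unmapped identifiers are kept
#' with an absent norm and counted in the attribute `skipped`.
#'
#' @param path Annotation file.
#' @param diseases Disease lexicon (for the MEDIC-to-DOID map).
#' @return data.frame with columns `pmid`, `start`, `end`, `surface`,
#'   `etype`, `norm_id`.
#' @export
read_pubtator <- function(path, diseases = load_disease_lexicon()) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("pmid", "start", "end", "surface",
                                         "type", "id"))
  etype <- toupper(tab$type)
  etype[etype == "GENE"] <- "GENE"
  etype[etype %in% c("DISEASE")] <- "DISEASE"
  norm <- as.character(tab$id)
  skipped <- 0L
  medic <- grepl("^(MESH|OMIM):", norm)
  if (any(medic)) {
    mapped <- diseases$medic[toupper(norm[medic])]
    skipped <- sum(is.na(mapped))
    norm[medic] <- ifelse(is.na(mapped), NA_character_, mapped)
  }
  out <- data.frame(pmid = as.character(tab$pmid), start = tab$start,
                    end = tab$end, surface = tab$surface, etype = etype,
                    norm_id = norm, stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}
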