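# Abbreviations whose trailing period never ends a sentence.
.ABBREV <- c(
  "et al", "al", "fig", "figs", "e.g", "i.e", "vs", "ca", "approx", "no",
  "dr", "mr", "mrs", "ms", "st", "resp", "cf", "ref", "refs", "suppl"
)

#' Normalize text for tokenization
#'
#' Applies Unicode NFKC normalization and maps typographic dashes and quotes
#' to their ASCII equivalents so that lexicon matching is stable across
#' Medline's character repertoire.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @export
normalize_text <- function(text) {
  out <- stringi::stri_trans_nfkc(text)
  out <- stringi::stri_replace_all_regex(out, "[‒–—―]", "-")
  out <- stringi::stri_replace_all_regex(out, "[‘’]", "'")
  out <- stringi::stri_replace_all_regex(out, "[“”]", "\"")
  out
}

#' Split text into sentences
#'
#' Conservative rule-based splitter: a sentence ends at `.`, `!` or `?`
#' followed by whitespace and an upper-case letter or digit, unless the period
#' belongs to a known abbreviation (e.g. "et al.", "Fig.", "vs.") or sits
#' between digits. The concatenation of the result (modulo inter-sentence
#' whitespace) equals the input.
#'
#' @param text A single character string.
#' @return Character vector of sentences (zero-length for empty input).
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L)
  text <- normalize_text(text)
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  chars <- stringi::stri_sub(text, seq_len(nchar(text)), length = 1L)
  n <- length(chars)
  breaks <- integer(0)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (!ch %in% c(".", "!", "?")) next
    # look ahead: require whitespace then capital/digit (or end of text)
    j <- i + 1L
    while (j <= n && chars[j] %in% c(" ", "\t", "\n", "\r")) j <- j + 1L
    if (j == i + 1L && j <= n) next              # no whitespace after
    if (j <= n && !grepl("[A-Z0-9\"'(]", chars[j])) next
    if (ch == ".") {
      # digit on both sides -> decimal or enumeration, keep
      if (i > 1L && i < n && grepl("[0-9]", chars[i - 1L]) &&
          grepl("[0-9]", chars[i + 1L])) next
      # trailing abbreviation check
      prev <- substr(text, max(1L, i - 8L), i - 1L)
      word <- tolower(sub(".*[ \t\n(]", "", prev))
      if (word %in% .ABBREV) next
    }
    breaks <- c(breaks, i)
  }
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, n)
  keep <- starts <= ends
  sents <- substring(text, starts[keep], ends[keep])
  sents <- trimws(sents)
  sents[nzchar(sents)]
}

# --- tokenization ----------------------------------------------------------

.TOKEN_RE <- paste0(
  "[A-Za-z0-9][A-Za-z0-9\\-_/'.]*[A-Za-z0-9]",  # words, ids, numbers
  "|-[A-Za-z0-9][A-Za-z0-9\\-]*",               # elided stems ("-195"), "-positive"
  "|[A-Za-z0-9]",
  "|[^\\s]"                                      # punctuation, one char each
)

.DET <- c("the", "a", "an", "this", "these", "that", "those", "both",
          "each", "its", "their", "our", "such")
.PREP <- c("in", "of", "with", "to", "from", "by", "for", "at", "on",
           "between", "among", "under", "into", "through", "during",
           "within", "after", "before", "following", "per", "as")
.CC <- c("and", "or", "but", "nor")
.BE <- c("is", "are", "was", "were", "be", "been", "being", "am")
.HAVE <- c("have", "has", "had")
.PRON <- c("we", "it", "they", "he", "she", "i", "who", "which", "that")
.NUM_WORDS <- c("one", "two", "three", "four", "five", "six", "seven",
                "eight", "nine", "ten", "eleven", "twelve", "twenty",
                "thirty", "forty", "fifty", "hundred")
.ADJ <- c(
  "high", "low", "normal", "healthy", "adjacent", "significant", "human",
  "primary", "metastatic", "benign", "malignant", "cancerous",
  "non-cancerous", "noncancerous", "cancer-free", "non-tumor", "nontumor",
  "non-malignant", "frequent", "right", "left", "chronic", "acute",
  "abundant", "strong", "weak", "absent", "undetectable", "several", "many",
  "most", "other", "new", "invasive", "positive", "negative", "total",
  "epithelial", "clinical", "renal", "adrenocortical", "gastric", "hepatic",
  "pancreatic", "ovarian", "colorectal", "oral", "squamous", "urothelial",
  "papillary", "differential", "different", "differently", "free", "whole",
  "same", "novel", "present", "early", "late", "advanced"
)
.VERB <- c(
  "found", "find", "finds", "detect", "detected", "detects", "observe",
  "observed", "note", "noted", "show", "showed", "shown", "shows",
  "demonstrate", "demonstrated", "reveal", "revealed", "presented",
  "present", "presents", "report", "reported", "exhibit", "exhibited",
  "display", "displayed", "seen", "see", "identify", "identified",
  "investigate", "investigated", "examine", "examined", "analyze",
  "analyzed", "analyse", "analysed", "evaluate", "evaluated", "studied",
  "compare", "compared", "test", "tested", "enrolled", "enroll", "collected",
  "collect", "measured", "measure", "explored", "explore", "assessed",
  "assess", "recruited", "express", "expressed", "increase", "increased",
  "decrease", "decreased", "elevated", "reduced", "raised", "diminished",
  "upregulated", "up-regulated", "downregulated", "down-regulated",
  "overexpressed", "over-expressed", "underexpressed", "under-expressed",
  "enhanced", "enhance", "promoted", "promote", "suppressed", "suppress",
  "inhibited", "inhibit", "induced", "induce", "associated", "correlate",
  "correlated", "suggest", "suggested", "indicate", "indicated", "remain",
  "remained", "play", "played", "plays", "regulate", "regulated", "derive",
  "derived", "conduct", "conducted", "perform", "performed", "obtain",
  "obtained", "include", "included", "use", "used", "modulate", "modulated",
  "established"
)
.JJR <- c("higher", "lower", "greater", "smaller", "less", "more", "better",
          "worse", "larger")

.IRREG_LEMMA <- c(
  was = "be", were = "be", is = "be", are = "be", been = "be", being = "be",
  am = "be", found = "find", shown = "show", seen = "see", has = "have",
  had = "have", did = "do", men = "man", women = "woman", sera = "serum",
  analyses = "analysis", diagnoses = "diagnosis"
)
.S_SINGULAR <- c("analysis", "diagnosis", "prognosis", "vs", "series",
                 "species", "less", "this", "thus", "its", "various",
                 "previous", "numerous")

.lemma_of <- function(surface, pos) {
  lo <- tolower(surface)
  if (lo %in% names(.IRREG_LEMMA)) return(unname(.IRREG_LEMMA[lo]))
  if (identical(pos, "NNS")) {
    if (grepl("ies$", lo) && nchar(lo) > 4L) return(sub("ies$", "y", lo))
    if (grepl("sses$", lo)) return(sub("es$", "", lo))
    if (grepl("[^su]s$", lo) && !grepl("ss$", lo)) return(sub("s$", "", lo))
  }
  lo
}

.pos_of <- function(surface, lower) {
  if (grepl("^[^A-Za-z0-9]$", surface)) return("PUNCT")
  if (lower %in% .DET) return("DT")
  if (lower %in% c("than")) return("ES")
  if (lower %in% .PREP) return("IN")
  if (lower %in% .CC) return("CC")
  if (lower %in% .BE) return("VBE")
  if (lower %in% .HAVE) return("VH")
  if (lower %in% .PRON) return("PRP")
  if (lower == "not" || lower == "no") return("NEG")
  if (grepl("^[0-9]+([.,][0-9]+)*$", lower) || lower %in% .NUM_WORDS) return("CD")
  if (lower %in% .JJR) return("JJR")
  if (lower %in% .VERB) return("V")
  if (lower %in% .ADJ || grepl("(ous|ive|ic|-positive|-negative|-free|-related|-matched|-induced|-derived)$", lower))
    return("JJ")
  if (grepl("fold$", lower)) return("RB")   # "twofold", "2-fold" degree adverbs
  if (grepl("ly$", lower) || lower %in% c("especially", "conversely",
      "however", "also", "often", "further", "thus", "so", "then", "here",
      "there", "only", "still", "yet", "even", "well")) return("RB")
  if (grepl("^[A-Z0-9-]+$", surface)) return("NN")   # all-caps symbol
  if (grepl("[^su]s$", lower) && !grepl("ss$", lower) &&
      !lower %in% .S_SINGULAR && nchar(lower) > 3L) return("NNS")
  "NN"
}

#' Tokenize a sentence
#'
#' Produces word tokens with 0-based half-open character offsets into the
#' (normalized) sentence, a coarse POS tag and a lowercased lemma. Hyphenated
#' biomedical tokens ("over-expressed", "miR-1-5p") are kept whole; elided
#' coordination stems ("-195") come out as single tokens.
#'
#' @param text A single sentence (already normalized).
#' @return A data.frame with columns `idx`, `surface`, `lemma`, `pos`,
#'   `start`, `end` (0-based half-open).
#' @export
tokenize <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(idx = integer(0), surface = character(0),
                      lemma = character(0), pos = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  loc <- stringi::stri_locate_all_regex(text, .TOKEN_RE)[[1]]
  if (anyNA(loc[, 1])) {
    return(data.frame(idx = integer(0), surface = character(0),
                      lemma = character(0), pos = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  surface <- stringi::stri_sub(text, loc[, 1], loc[, 2])
  # a trailing period glued onto a word ("tissues.") – the token regex keeps
  # internal periods; strip a final one unless it is a known abbreviation
  fix <- grepl("[A-Za-z0-9]\\.$", surface) &
    !tolower(sub("\\.$", "", surface)) %in% .ABBREV &
    !grepl("^[0-9.]+$", surface)
  if (any(fix)) {
    surface[fix] <- sub("\\.$", "", surface[fix])
    loc[fix, 2] <- loc[fix, 2] - 1L
  }
  lower <- tolower(surface)
  pos <- mapply(.pos_of, surface, lower, USE.NAMES = FALSE)
  # contextual repair: participle used as a prenominal modifier
  n <- length(surface)
  for (i in seq_len(n)) {
    if (pos[i] != "V") next
    prev <- if (i > 1L) pos[i - 1L] else "START"
    nxt <- i + 1L
    while (nxt <= n && pos[nxt] %in% c("RB", "JJ", "JJR", "CD")) nxt <- nxt + 1L
    follows_nominal <- nxt <= n && pos[nxt] %in% c("NN", "NNS")
    if (follows_nominal && prev %in% c("START", "DT", "JJ", "JJR", "CC", "V",
                                       "VH", "PUNCT", "IN")) {
      if (prev %in% c("START", "DT", "JJ", "JJR", "CC", "VH", "IN") ||
          (prev == "V")) pos[i] <- "VBNmod"
    }
  }
  lemma <- mapply(.lemma_of, surface, pos, USE.NAMES = FALSE)
  data.frame(idx = seq_len(n), surface = surface, lemma = lemma, pos = pos,
             start = loc[, 1] - 1L, end = loc[, 2],
             stringsAsFactors = FALSE)
}
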