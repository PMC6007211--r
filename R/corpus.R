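# Abstract readers, sentence objects and the trigger prefilter.

.SECTION_MAP <- c(
  "METHODS" = "METHODS", "METHOD" = "METHODS",
  "MATERIALS AND METHODS" = "METHODS", "PATIENTS AND METHODS" = "METHODS",
  "CONCLUSION" = "CONCLUSION", "CONCLUSIONS" = "CONCLUSION"
)

.make_sentence <- function(abstract_id, index, text, hint) {
  text <- normalize_text(text)
  list(abstract_id = abstract_id, index = index, text = text,
       tokens = tokenize(text), section_hint = hint)
}

#' Construct an abstract object
#'
#' The title is sentence index 0 (section hint TITLE) and participates in
#' extraction and disease-context inference. Body sentences carry structured
#' section labels where present (inline "METHODS:" prefixes are stripped into
#' the hint); otherwise the hint falls back to position: FIRST for the first
#' body sentence, CONCLUSION for the last two, BODY elsewhere.
#'
#' @param pmid Identifier.
#' @param title Title text.
#' @param body Abstract text (may be empty).
#' @param labels Optional character vector of structured-abstract labels, one
#'   per body segment, when the body is supplied pre-segmented as a character
#'   vector.
#' @return An `exprel_abstract`.
#' @export
abstract <- function(pmid, title, body, labels = NULL) {
  segs <- if (length(body) > 1L) body else c(body)
  if (is.null(labels)) labels <- rep(NA_character_, length(segs))
  stopifnot(length(labels) == length(segs))
  sent_text <- character(0); sent_lab <- character(0)
  for (k in seq_along(segs)) {
    ss <- split_sentences(segs[k])
    lab <- labels[k]
    for (s in ss) {
      m <- regmatches(s, regexec("^([A-Z][A-Z /]{2,}):\\s*", s))[[1]]
      if (length(m)) {
        lab <- m[2]
        s <- sub("^([A-Z][A-Z /]{2,}):\\s*", "", s)
      }
      if (!nzchar(s)) next
      sent_text <- c(sent_text, s)
      sent_lab <- c(sent_lab, lab)
    }
  }
  nb <- length(sent_text)
  hints <- rep("BODY", nb)
  mapped <- .SECTION_MAP[toupper(sent_lab)]
  hints[!is.na(mapped)] <- mapped[!is.na(mapped)]
  free <- is.na(sent_lab) | is.na(.SECTION_MAP[toupper(sent_lab)])
  if (nb >= 1L && free[1L]) hints[1L] <- "FIRST"
  if (nb >= 1L) {
    last2 <- seq(max(1L, nb - 1L), nb)
    hints[last2][free[last2] & hints[last2] == "BODY"] <- "CONCLUSION"
  }
  sentences <- vector("list", nb + 1L)
  sentences[[1L]] <- .make_sentence(pmid, 0L, title, "TITLE")
  for (k in seq_len(nb))
    sentences[[k + 1L]] <- .make_sentence(pmid, k, sent_text[k], hints[k])
  structure(list(pmid = as.character(pmid), title = title,
                 body = paste(segs, collapse = " "), sentences = sentences),
            class = "exprel_abstract")
}

#' @export
print.exprel_abstract <- function(x, ...) {
  cat("<exprel_abstract> PMID ", x$pmid, ", ", length(x$sentences),
      " sentences (incl. title)\n", sep = "")
  invisible(x)
}

#' Read abstracts from a PubMed/Medline XML file
#'
#' One abstract per `PubmedArticle` with non-empty abstract text; structured
#' section labels (`<AbstractText Label="METHODS">`) are preserved into the
#' sentence section hints. Articles without abstract text are skipped with a
#' warning; malformed XML raises a parse error.
#'
#' @param path XML file.
#' @return List of `exprel_abstract` objects.
#' @export
read_medline_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed XML in '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
  out <- list()
  for (a in arts) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//MedlineCitation/PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    segs <- xml2::xml_find_all(a, ".//Abstract/AbstractText")
    txt <- trimws(xml2::xml_text(segs))
    keep <- nzchar(txt)
    if (!length(segs) || !any(keep)) {
      warning("PMID ", pmid, ": no abstract text, skipped", call. = FALSE)
      next
    }
    labels <- xml2::xml_attr(segs, "Label")[keep]
    out[[length(out) + 1L]] <- abstract(pmid, title, txt[keep], labels = labels)
  }
  out
}

#' Read abstracts from a tab-separated file
#'
#' Expects `pmid<TAB>title<TAB>abstract`, one per line. Lines with a wrong
#' field count are skipped with a warning naming the line number.
#'
#' @param path TSV file.
#' @return List of `exprel_abstract` objects, in file order.
#' @export
read_abstract_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  out <- list()
  for (k in seq_along(lines)) {
    if (!nzchar(lines[k])) next
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L) {
      warning("line ", k, ": expected 3 tab-separated fields, got ",
              length(f), "; skipped", call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- abstract(f[1], f[2], f[3])
  }
  out
}

#' Read abstracts from a directory of plain-text files
#'
#' One abstract per file: the first line is the title, the remainder the
#' body; the file name (without extension) is the identifier.
#'
#' @param dir Directory of `.txt` files.
#' @return List of `exprel_abstract` objects.
#' @export
read_abstract_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  lapply(files, function(f) {
    lines <- readLines(f, warn = FALSE, encoding = "UTF-8")
    if (!length(lines)) lines <- ""
    abstract(tools::file_path_sans_ext(basename(f)), lines[1],
             paste(lines[-1], collapse = " "))
  })
}

#' Trigger prefilter
#'
#' TRUE iff the sentence contains at least one expression or comparison
#' trigger (a scale indicator, level indicator or expression noun), matched
#' case-insensitively on surface forms and lemmas. Sentences failing the
#' prefilter are not parsed.
#'
#' @param sentence Sentence object.
#' @param triggers Trigger lexicons.
#' @return Logical.
#' @export
prefilter <- function(sentence, triggers) {
  tok <- sentence$tokens
  if (!nrow(tok)) return(FALSE)
  any(trig_has(triggers$si, tok$surface, tok$lemma) |
        trig_has(triggers$li, tok$surface, tok$lemma) |
        trig_has(triggers$expression_nouns, tok$surface, tok$lemma))
}
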