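# Shared fixtures: one lazily built config, the worked-example sentences and
# their expected component tables, a brute-force pattern-match oracle, and
# small normalization helpers.

test_config <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- exprel_config()
    cfg
  }
})

# comparative (Type A) worked examples and their expected components
ex6_sentences <- function() c(
  "Plasma miR-187 was significantly higher in OSCC patients than in normal individuals.",
  "miR-181a expression was lower in HepG2 cells compared to Hep3B cells.",
  "miR-95 levels were increased in human prostate cancer specimens compared with normal tissues.",
  "Higher miR-210 expression was found in metastatic tumors compared to primary tumors.",
  "Increased TP expression was observed in ovarian cancers than in normal ovaries.",
  "In comparison to normal brain tissues, FOXD3 expression was significantly decreased in HGG tissues at both mRNA and protein levels.",
  "Compared to controls, patients with CLL presented a lower expression level of PTEN mRNA (P < 0.001)."
)

ex6_expected <- function() data.frame(
  si = c("higher", "lower", "increased", "higher", "increased", "decreased", "lower"),
  ca = c("plasma mir-187", "mir-181a expression", "mir-95 levels",
         "mir-210 expression", "tp expression", "foxd3 expression",
         "expression level of pten mrna"),
  ce1 = c("oscc patients", "hepg2 cells", "human prostate cancer specimens",
          "metastatic tumors", "ovarian cancers", "hgg tissues",
          "patients with cll"),
  ce2 = c("normal individuals", "hep3b cells", "normal tissues",
          "primary tumors", "normal ovaries", "normal brain tissues",
          "controls"),
  stringsAsFactors = FALSE
)

# plain expression-level (Type B) worked examples
ex7_sentences <- function() c(
  "GALNT2 is frequently over-expressed in OSCC, especially in the carcinoma cells at the invasive front.",
  "IGF1R expression levels were higher in the right adrenocortical tumor.",
  "The levels of miR-373 expression were low in pancreatic cancer cell lines.",
  "Higher level of BRF2 expression was found in NSCLC tissues.",
  "High TRIM32 expression levels were detected in gastric cancer tissues.",
  "We found high expression levels of FKBP51 in melanoma cells."
)

ex7_expected <- function() data.frame(
  li = c("over-expressed", "higher", "low", "higher", "high", "high"),
  ea = c("galnt2", "igf1r expression levels", "levels of mir-373 expression",
         "higher level of brf2 expression", "trim32 expression levels",
         "expression levels of fkbp51"),
  el = c("oscc", "right adrenocortical tumor", "pancreatic cancer cell lines",
         "nsclc tissues", "gastric cancer tissues", "melanoma cells"),
  implicit = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
  stringsAsFactors = FALSE
)

# case- and determiner-insensitive phrase normalization for comparisons
norm_phrase <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("^(the|a|an|this|these|those)\\s+", "", x)
  gsub("\\s+", " ", x)
}

# independent brute-force subgraph matcher: enumerates every injective
# assignment of pattern variables to graph nodes and keeps those satisfying
# all constraints; must agree with dep_match() on small graphs
brute_match <- function(pattern, graph, triggers) {
  vars <- names(pattern$nodes)
  n <- nrow(graph$nodes)
  if (n == 0L) return(character(0))
  node_ok <- lapply(vars, function(v) {
    nc <- pattern$nodes[[v]]
    vapply(seq_len(n), function(i) {
      tokr <- graph$nodes[i, ]
      ok <- TRUE
      if (!is.null(nc$pos)) ok <- ok && grepl(nc$pos, tokr$pos)
      if (!is.null(nc$lemma)) ok <- ok && grepl(nc$lemma, tokr$lemma, ignore.case = TRUE)
      if (!is.null(nc$surface)) ok <- ok && grepl(nc$surface, tokr$surface, ignore.case = TRUE)
      if (!is.null(nc$lexicon))
        ok <- ok && (tolower(tokr$surface) %in% triggers[[nc$lexicon]] ||
                       tolower(tokr$lemma) %in% triggers[[nc$lexicon]])
      ok
    }, logical(1))
  })
  edge_mat <- lapply(pattern$edges, function(e) {
    m <- matrix(FALSE, n, n)
    hit <- grepl(e$label, graph$edges$label)
    if (any(hit)) m[cbind(graph$edges$gov[hit], graph$edges$dep[hit])] <- TRUE
    m
  })
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), length(vars))))
  colnames(combos) <- vars
  ok <- rep(TRUE, nrow(combos))
  for (k in seq_along(vars)) ok <- ok & node_ok[[k]][combos[, k]]
  if (length(vars) > 1L) {
    for (i in seq_len(length(vars) - 1L))
      for (j in (i + 1L):length(vars))
        ok <- ok & combos[, i] != combos[, j]
  }
  for (m in seq_along(pattern$edges)) {
    e <- pattern$edges[[m]]
    ok <- ok & edge_mat[[m]][cbind(combos[, e$from], combos[, e$to])]
  }
  hits <- combos[ok, pattern$result, drop = FALSE]
  sort(unique(apply(hits, 1L, paste, collapse = ",")))
}

match_keys <- function(bindings) {
  sort(unique(vapply(bindings, paste, collapse = ",", FUN.VALUE = character(1))))
}

one_sentence_abstract <- function(text, pmid = "1", title = "A title.") {
  abstract(pmid, title, text)
}
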