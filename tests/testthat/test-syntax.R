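# Dependency analysis, the pattern engine and noun-phrase yields.

has_edge <- function(g, gov_surface, dep_surface, label_re) {
  any(vapply(seq_len(nrow(g$edges)), function(k) {
    e <- g$edges[k, ]
    grepl(label_re, e$label) &&
      g$nodes$surface[e$gov] == gov_surface &&
      g$nodes$surface[e$dep] == dep_surface
  }, logical(1)))
}

test_that("passive predicates and collapsed prepositions come out canonically", {
  cfg <- test_config()
  g <- parse_sentence("MicroRNA-224 is frequently over-expressed in colorectal cancers",
                      cfg$triggers)
  expect_true(has_edge(g, "over-expressed", "MicroRNA-224", "^nsubj:pass$"))
  expect_true(has_edge(g, "over-expressed", "cancers", "^nmod:in$"))
})

test_that("a comparative predicate carries subject and both in-modifiers", {
  cfg <- test_config()
  g <- parse_sentence(ex6_sentences()[1], cfg$triggers)
  expect_true(has_edge(g, "higher", "miR-187", "^nsubj$"))
  expect_true(has_edge(g, "higher", "patients", "^nmod:in$"))
  expect_true(has_edge(g, "higher", "individuals", "^nmod:in$"))
  # the second entity is flagged as separator-attached
  ind <- which(g$nodes$surface == "individuals")
  expect_true(ind %in% g$es_links$head)
})

test_that("conjunct propagation copies the shared governor to each conjunct", {
  cfg <- test_config()
  g <- parse_sentence("the expression of miR-143 and -195 in cancer tissues was significantly lower compared to that in normal tissues.",
                      cfg$triggers)
  expect_true(has_edge(g, "expression", "miR-143", "^nmod:of$"))
  expect_true(has_edge(g, "expression", "-195", "^nmod:of$"))
  expect_true(has_edge(g, "miR-143", "-195", "^conj$"))
})

test_that("analysis is deterministic", {
  cfg <- test_config()
  g1 <- parse_sentence(ex6_sentences()[6], cfg$triggers)
  g2 <- parse_sentence(ex6_sentences()[6], cfg$triggers)
  expect_identical(g1$edges, g2$edges)
  expect_identical(g1$root, g2$root)
})

test_that("pattern matching equals brute-force enumeration on small graphs", {
  cfg <- test_config()
  sents <- c(
    "miR-21 was higher in tumors than in controls.",
    "EGFR was overexpressed in melanoma.",
    "High EGFR levels were detected in melanoma samples.",
    "We found low PTEN levels in tumors.",
    "PTEN levels were decreased in tumors compared with controls.",
    "Increased EGFR expression was observed in tumors.")
  pats <- c(cfg$patterns_a, cfg$patterns_b)
  checked <- 0L
  for (s in sents) {
    g <- parse_sentence(s, cfg$triggers)
    expect_lte(nrow(g$nodes), 12L)
    for (pat in pats) {
      expect_identical(match_keys(dep_match(pat, g, cfg$triggers)),
                       brute_match(pat, g, cfg$triggers),
                       info = paste(pat$name, "|", s))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 40L)
})

test_that("trivial and unsatisfiable patterns behave", {
  cfg <- test_config()
  g <- parse_sentence(ex6_sentences()[1], cfg$triggers)
  single <- list(name = "x", family = "x",
                 nodes = list(a = list(lemma = "^higher$")),
                 edges = list(), result = "a")
  expect_length(dep_match(single, g, cfg$triggers), 1L)
  none <- list(name = "x", family = "x",
               nodes = list(a = list(pos = "^ZZZ$")),
               edges = list(), result = "a")
  expect_length(dep_match(none, g, cfg$triggers), 0L)
})

test_that("ill-formed patterns fail at load time", {
  cfg <- test_config()
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("patterns:",
               "  - name: broken",
               "    nodes:",
               "      a: {lemma: x}",
               "      b: {lemma: y}",
               "    edges: []",
               "    result: [a, b]"), tf)
  expect_error(load_patterns(tf, cfg$triggers), "disconnected")
  writeLines(c("patterns:",
               "  - name: badlex",
               "    nodes:",
               "      a: {lexicon: nosuchset}",
               "    edges: []",
               "    result: [a]"), tf)
  expect_error(load_patterns(tf, cfg$triggers), "unknown trigger set")
})

test_that("np_yield covers modifiers and of-complements, not separators", {
  cfg <- test_config()
  g <- parse_sentence(ex6_sentences()[1], cfg$triggers)
  h <- which(g$nodes$surface == "miR-187")
  expect_identical(np_yield(g, h)$text, "Plasma miR-187")

  g7 <- parse_sentence(ex6_sentences()[7], cfg$triggers)
  lvl <- which(g7$nodes$surface == "level")
  si <- which(g7$nodes$surface == "lower")
  expect_identical(norm_phrase(np_yield(g7, lvl, exclude = si)$text),
                   "expression level of pten mrna")

  # single-token head
  g1 <- parse_sentence("EGFR was overexpressed in melanoma.", cfg$triggers)
  m <- which(g1$nodes$surface == "melanoma")
  expect_identical(np_yield(g1, m)$text, "melanoma")

  # yields never cross entity separators
  for (s in ex6_sentences()) {
    g <- parse_sentence(s, cfg$triggers)
    for (h in g$nodes$idx[g$nodes$pos %in% c("NN", "NNS")]) {
      sp <- np_yield(g, h)
      inside <- g$nodes$idx >= sp$from & g$nodes$idx <= sp$to
      expect_false(any(tolower(g$nodes$surface[inside]) %in%
                         c("than", "compared", "versus", "vs")), info = s)
      expect_true(h >= sp$from && h <= sp$to)
    }
  }
})
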