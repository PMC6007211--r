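# Entity taggers, abbreviation linking and phrase typing.

test_that("gene tagging is lexicon-driven with NCBI identifiers", {
  cfg <- test_config()
  m <- tag_genes("Expression of Shp2 protein was significantly upregulated in tumors.",
                 cfg$genes)
  expect_identical(nrow(m), 1L)
  expect_identical(m$surface, "Shp2")
  expect_identical(m$norm_id, "5781")

  expect_identical(nrow(tag_genes("No known symbols here.", cfg$genes)), 0L)

  # token-boundary alignment: the mention covers the symbol only
  m2 <- tag_genes("The GPC5 gene was studied.", cfg$genes)
  expect_identical(m2$surface, "GPC5")
  expect_identical(m2$norm_id, "2262")
})

test_that("microRNA tagging follows the naming convention and normalizes", {
  m <- tag_mirnas("MicroRNA-224 is frequently over-expressed in colorectal cancers.")
  expect_identical(m$surface[1], "MicroRNA-224")
  expect_identical(m$norm_id[1], "mir-224")

  m2 <- tag_mirnas("hsa-miR-1-3p was studied.")
  expect_identical(nrow(m2), 1L)
  expect_identical(m2$norm_id, "mir-1")
  expect_identical(m2$arm, "3p")

  # coordination expansion of elided stems
  m3 <- tag_mirnas("the expression of miR-143 and -195 in cancer tissues")
  expect_identical(sort(m3$norm_id), c("mir-143", "mir-195"))

  # case-insensitive idempotent normalization
  for (v in c("MIR-21", "miR-21", "microRNA-21", "miRNA-21"))
    expect_identical(tag_mirnas(paste(v, "was studied."))$norm_id, "mir-21",
                     info = v)
})

test_that("disease tagging resolves DOIDs and links abbreviations", {
  cfg <- test_config()
  s <- "Expression was upregulated in Oral Squamous Cell Carcinoma (OSCC) tissues."
  a <- one_sentence_abstract(s)
  al <- link_abbreviations(a$sentences, cfg$diseases, cfg$genes)
  expect_identical(unname(al$disease["oscc"]), "DOID:0050866")
  m <- tag_diseases(a$sentences[[2]], cfg$diseases, aliases = al$disease)
  expect_true("DOID:0050866" %in% m$norm_id)
  long <- m[m$surface == "Oral Squamous Cell Carcinoma", ]
  expect_identical(long$norm_id, "DOID:0050866")

  m2 <- tag_diseases("miR-155 expression was high in pancreatic cancer tissues.",
                     cfg$diseases)
  expect_identical(m2$surface, "pancreatic cancer")

  # generic phrases are not disease mentions
  expect_identical(nrow(tag_diseases("The tumor was large.", cfg$diseases)), 0L)
})

test_that("abbreviation linking requires a plausible long form", {
  cfg <- test_config()
  a <- one_sentence_abstract("The study used a special cohort (ZZZ) for validation.")
  al <- link_abbreviations(a$sentences, cfg$diseases, cfg$genes)
  expect_length(al$disease, 0L)
})

test_that("expression-phrase and disease-sample typing follow head nouns", {
  cfg <- test_config()
  g <- parse_sentence("The expression of GPC5 gene was lower in lung cancer tissues than in adjacent non-cancerous tissues.",
                      cfg$triggers)
  a <- one_sentence_abstract(g$text)
  m <- tag_sentence(a$sentences[[2]], cfg)
  expr_head <- which(g$nodes$surface == "expression")
  expect_true(type_expression_phrase(g, expr_head, m, cfg$triggers))
  t1 <- which(g$nodes$surface == "tissues")[1]
  expect_true(type_disease_sample(g, t1, m, cfg$triggers))
  expect_false(type_expression_phrase(g, t1, m, cfg$triggers))

  g2 <- parse_sentence("miR-95 levels were increased in human prostate cancer specimens compared with normal tissues.",
                       cfg$triggers)
  m2 <- tag_sentence(one_sentence_abstract(g2$text)$sentences[[2]], cfg)
  lv <- which(g2$nodes$surface == "levels")
  expect_true(type_expression_phrase(g2, lv, m2, cfg$triggers))
  mi <- which(g2$nodes$surface == "miR-95")
  expect_true(type_expression_phrase(g2, mi, m2, cfg$triggers))

  g3 <- parse_sentence("Sera were tested for AFP-L3 level using the glycan microarray.",
                       cfg$triggers)
  m3 <- tag_sentence(one_sentence_abstract(g3$text)$sentences[[2]], cfg)
  mic <- which(g3$nodes$surface == "microarray")
  expect_false(type_disease_sample(g3, mic, m3, cfg$triggers))
  ov <- parse_sentence("Higher TP expression was observed in ovarian cancers than in normal ovaries.",
                       cfg$triggers)
  mo <- tag_sentence(one_sentence_abstract(ov$text)$sentences[[2]], cfg)
  ovh <- which(ov$nodes$surface == "ovaries")
  expect_true(type_disease_sample(ov, ovh, mo, cfg$triggers))
})

test_that("mentions of one type never overlap; microRNA wins over gene", {
  cfg <- test_config()
  fx <- generate_fixtures(40, seed = 5)
  n_mentions <- 0L
  for (a in fx$abstracts) {
    for (s in a$sentences) {
      m <- tag_sentence(s, cfg)
      n_mentions <- n_mentions + nrow(m)
      for (et in unique(m$etype)) {
        sub <- m[m$etype == et, ]
        if (nrow(sub) < 2L) next
        sub <- sub[order(sub$start), ]
        expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]), info = s$text)
      }
      gm <- m[m$etype %in% c("GENE", "MIRNA"), ]
      if (nrow(gm) >= 2L) {
        gm <- gm[order(gm$start), ]
        expect_true(all(gm$start[-1] >= gm$end[-nrow(gm)]), info = s$text)
      }
    }
  }
  expect_gt(n_mentions, 100L)
})

test_that("precomputed annotation files are read and MEDIC ids mapped", {
  cfg <- test_config()
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t0\t4\tShp2\tGene\t5781",
               "1\t20\t37\tpancreatic cancer\tDisease\tMESH:D010190",
               "1\t50\t60\trare thing\tDisease\tMESH:D999999"), tf)
  ann <- read_pubtator(tf, cfg$diseases)
  expect_identical(ann$norm_id[1], "5781")
  expect_identical(ann$norm_id[2], "DOID:1793")
  expect_true(is.na(ann$norm_id[3]))
  expect_identical(attr(ann, "skipped"), 1L)
})
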