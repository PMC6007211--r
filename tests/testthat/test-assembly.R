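# Argument filtering, field extraction, disease inference, frame
# classification and record assembly.

test_that("the worked example assembles into the expected record", {
  cfg <- test_config()
  a <- abstract("24439919", "Shp2 in oral cancer.",
                "Expression of Shp2 protein was significantly upregulated in Oral Squamous Cell Carcinoma (OSCC) tissues compared with the normal tissues.")
  rec <- assemble(a, cfg)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$gene_id, "5781")
  expect_identical(rec$level, "High")
  expect_identical(rec$doid, "DOID:0050866")
  expect_identical(norm_phrase(rec$disease_sample), "oscc tissues")
  expect_identical(norm_phrase(rec$compared_sample), "normal tissues")
  expect_identical(rec$frame_of_reference, "Control")
  expect_identical(rec$relation_type, "A")
  expect_identical(rec$disease_source, "sentence")
})

test_that("level normalization follows the trigger direction sets", {
  cfg <- test_config()
  expect_identical(normalize_level("upregulated", cfg$triggers), "High")
  expect_identical(normalize_level("Lower", cfg$triggers), "Low")
  expect_identical(normalize_level("decreased", cfg$triggers), "Low")
  expect_identical(normalize_level("overexpressed", cfg$triggers), "High")
  expect_true(is.na(normalize_level("unchanged", cfg$triggers)))
})

test_that("argument-type constraints reject non-expression comparisons", {
  cfg <- test_config()
  # survival comparison: compared aspect is not an expression phrase
  a <- abstract("1", "A trial.",
                "Overall survival was longer in arm A than in arm B.")
  expect_identical(nrow(assemble(a, cfg)), 0L)
  # outcome statements (expression -> consequence) are not extracted
  a2 <- abstract("2", "A study.",
                 "Over-expression of C1GALT1 enhanced breast cancer cell growth, migration and invasion in vitro as well as tumor growth in vivo.")
  expect_identical(nrow(assemble(a2, cfg)), 0L)
  # missing expressed entity inside the aspect phrase
  a3 <- abstract("3", "A study.",
                 "The expression levels were higher in tumor tissues than in normal tissues.")
  expect_identical(nrow(assemble(a3, cfg)), 0L)
})

test_that("disease comes from the sample argument when present", {
  cfg <- test_config()
  a <- abstract("25190548", "Gliomas.",
                "expression levels of miR-454-3p were higher in high grade gliomas than in low grade gliomas.")
  rec <- assemble(a, cfg)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$doid, "DOID:3070")
  expect_identical(rec$disease_source, "sentence")
  expect_identical(rec$frame_of_reference, "Not_Control")
})

test_that("generic samples trigger ordered context inference", {
  cfg <- test_config()
  # title wins
  a <- abstract("24649051", "miR-143 and miR-195 in gastric cancer.",
                "Conversely, the expression of miR-143 and -195 in cancer tissues was significantly lower compared to that in normal tissues.")
  rec <- assemble(a, cfg)
  expect_identical(nrow(rec), 2L)
  expect_setequal(rec$mirna_norm, c("mir-143", "mir-195"))
  expect_identical(unique(rec$doid), "DOID:10534")
  expect_identical(unique(rec$disease_source), "title")

  # investigation sentence (agentive trigger)
  a2 <- abstract("9", "A study.",
                 c("Reliable biomarkers are needed for early diagnosis.",
                   "So the authors investigated the expression of TP in bladder cancer.",
                   "miR-21 expression was significantly higher in cancer tissues than in normal tissues."))
  r2 <- assemble(a2, cfg)
  expect_identical(r2$disease_source, "investigation")
  expect_identical(r2$doid, "DOID:11054")

  # experiment-setup sentence (passive trigger, counted theme)
  a3 <- abstract("10", "A study.",
                 c("Reliable biomarkers are needed for early diagnosis.",
                   "METHODS: A total of 140 patients with colorectal cancer and 280 cancer-free frequency-matched controls were enrolled.",
                   "miR-21 expression was significantly higher in cancer tissues than in normal tissues."))
  r3 <- assemble(a3, cfg)
  expect_identical(r3$disease_source, "analyzed")
  expect_identical(r3$doid, "DOID:9256")

  # a disease mention in a middle sentence without a qualifying trigger is
  # never used (locality property)
  a4 <- abstract("11", "A study.",
                 c("Reliable biomarkers are needed for early diagnosis.",
                   "Several regions showed gastric cancer involvement.",
                   "miR-21 expression was significantly higher in cancer tissues than in normal tissues.",
                   "Further validation in larger cohorts is warranted.",
                   "These findings may have therapeutic implications."))
  r4 <- assemble(a4, cfg)
  expect_identical(nrow(r4), 1L)
  expect_true(is.na(r4$doid))
  expect_true(is.na(r4$disease_source))
})

test_that("frame-of-reference taxonomy distinguishes all four classes", {
  cfg <- test_config()
  frames <- list(
    list("Higher TP expression was observed in ovarian cancers than in normal ovaries.",
         "Control"),
    list("The expression of PDECGF in T1 bladder carcinoma was twofold higher than that in Ta carcinomas.",
         "Not_Control"),
    list("Expression of GCS was high in estrogen receptor (ER)-positive and HER-2 negative samples.",
         "none"),
    list("MicroRNA-224 is frequently over-expressed in colorectal cancers.",
         "Control_Implicit"))
  for (f in frames) {
    rec <- assemble(one_sentence_abstract(f[[1]]), cfg)
    expect_identical(nrow(rec), 1L, info = f[[1]])
    expect_identical(rec$frame_of_reference, f[[2]], info = f[[1]])
  }
  # Control: the control-marked entity is the compared sample
  r <- assemble(one_sentence_abstract(frames[[1]][[1]]), cfg)
  expect_identical(norm_phrase(r$compared_sample), "normal ovaries")
  expect_identical(norm_phrase(r$disease_sample), "ovarian cancers")
})

test_that("record invariants hold on the synthetic corpus", {
  cfg <- test_config()
  fx <- generate_fixtures(60, seed = 23)
  rec <- extract_expression(fx$abstracts, cfg)
  expect_true(all(rec$level %in% c("High", "Low")))
  expect_true(all(xor(is.na(rec$gene_id), is.na(rec$mirna_norm))))
  expect_true(all(is.na(rec$compared_sample) == (rec$relation_type == "B")))
  expect_true(all(rec$relation_type[rec$frame_of_reference == "Control_Implicit"] == "B"))
  ctrl <- rec[rec$frame_of_reference == "Control", ]
  mods <- cfg$triggers$control_modifiers
  for (cs in ctrl$compared_sample) {
    toks <- tolower(strsplit(cs, "[ -]")[[1]])
    expect_true(any(toks %in% mods), info = cs)
  }
})
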