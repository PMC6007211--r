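# Scoring, the ontology relevance filter, the fixture generator and the CLI.

test_that("scorer reproduces the reference count arithmetic", {
  s <- score_from_counts(77, 5, 15)
  expect_identical(s$precision, 93.90)
  expect_identical(s$recall, 83.69)
  expect_identical(s$f, 88.51)

  g <- data.frame(pmid = "1", entity_norm = c("a", "b"), level = "High",
                  doid = "DOID:1")
  s2 <- score(g, g)
  expect_identical(c(s2$precision, s2$recall, s2$f), c(100, 100, 100))
})

test_that("swapping gold and predicted swaps precision and recall", {
  gold <- data.frame(pmid = as.character(1:8), entity_norm = "x",
                     level = "High", doid = "DOID:1")
  pred <- gold[1:5, ]
  pred <- rbind(pred, data.frame(pmid = c("90", "91"), entity_norm = "x",
                                 level = "High", doid = "DOID:1"))
  s1 <- score(gold, pred)
  s2 <- score(pred, gold)
  expect_identical(s1$tp, s2$tp)
  expect_identical(s1$fp, s2$fn)
  expect_identical(s1$precision, s2$recall)
  expect_identical(s1$recall, s2$precision)
  expect_identical(s1$f, s2$f)
})

test_that("the ontology subtree is transitive and the filter selective", {
  st <- do_subtree()
  expect_true(in_subtree(st, "DOID:162"))
  expect_true(in_subtree(st, "DOID:0050866"))   # two is_a hops below carcinoma
  expect_true(in_subtree(st, "DOID:3908"))
  expect_false(in_subtree(st, "DOID:2043"))     # hepatitis B decoy
  expect_false(in_subtree(st, "DOID:4"))        # ancestor of the root

  rec <- empty_records()
  rec <- rbind(rec, tibble::tibble(
    pmid = c("1", "2", "3", "4"), sentence_index = 1L, sentence_text = "s",
    relation_type = c("A", "A", "B", "B"), entity_text = "g",
    entity_kind = "gene", gene_id = "5781", mirna_norm = NA_character_,
    level = "High",
    disease_text = "d",
    doid = c("DOID:0050866", "DOID:0050866", "DOID:2043", "DOID:1324"),
    disease_sample = "x", compared_sample = NA_character_,
    frame_of_reference = c("Control", "Not_Control", "Control_Implicit",
                           "Control_Implicit"),
    disease_source = "sentence"))
  kept <- bioxpress_filter(rec, st)
  expect_identical(kept$pmid, c("1", "4"))
  # subset of input and idempotent
  expect_true(all(kept$pmid %in% rec$pmid))
  expect_identical(bioxpress_filter(kept, st), kept)
})

test_that("cycle detection rejects a looped ontology", {
  tf <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: DOID:162", "name: cancer",
               "", "[Term]", "id: DOID:8", "name: a", "is_a: DOID:9",
               "", "[Term]", "id: DOID:9", "name: b", "is_a: DOID:8"), tf)
  expect_error(do_subtree(tf), "cycle")
})

test_that("fixture generation is deterministic and respects the mix", {
  f0 <- generate_fixtures(0, seed = 1)
  expect_length(f0$abstracts, 0L)
  expect_identical(nrow(f0$gold), 0L)

  f1 <- generate_fixtures(10, seed = 1)
  f2 <- generate_fixtures(10, seed = 1)
  expect_identical(lapply(f1$abstracts, `[[`, "body"),
                   lapply(f2$abstracts, `[[`, "body"))
  expect_identical(f1$gold, f2$gold)
  f3 <- generate_fixtures(10, seed = 2)
  expect_false(identical(lapply(f1$abstracts, `[[`, "body"),
                         lapply(f3$abstracts, `[[`, "body")))

  only_b <- generate_fixtures(15, seed = 4, mix = c(Q1 = 1))
  expect_true(all(only_b$gold$relation_type == "B"))
})

test_that("pipeline recovers generator gold exactly on a mixed corpus", {
  cfg <- test_config()
  fx <- generate_fixtures(60, seed = 17)
  rec <- extract_expression(fx$abstracts, cfg)
  rec$entity_norm <- ifelse(rec$entity_kind == "gene", rec$gene_id, rec$mirna_norm)
  s <- score(fx$gold, rec,
             components = c("pmid", "entity_norm", "level", "doid",
                            "frame_of_reference"))
  expect_identical(s$fp, 0L)
  expect_identical(s$fn, 0L)
  # disease provenance agrees with the generator's construction
  merged <- merge(as.data.frame(rec), as.data.frame(fx$gold),
                  by = "pmid", suffixes = c("", ".gold"))
  expect_true(all(merged$disease_source == merged$disease_source.gold))
})

test_that("the command-line interface drives extract, score and report", {
  dir <- withr::local_tempdir()
  expect_identical(exprel_cli(character(0)), 2L)
  exprel_cli(c("fixtures", "--n", "12", "--seed", "3", "--out", dir))
  expect_true(file.exists(file.path(dir, "abstracts.tsv")))
  out <- file.path(dir, "records.jsonl")
  code <- exprel_cli(c("extract", "--input", file.path(dir, "abstracts.tsv"),
                       "--output", out))
  expect_identical(code, 0L)
  rec <- read_records(out)
  expect_gt(nrow(rec), 0L)
  rep <- report_records(rec)
  expect_true(all(rep$n_abstracts >= 1L))
  expect_identical(sum(rep$n_abstracts >= 1L), nrow(rep))

  # relevance-filtered extraction is a subset
  out2 <- file.path(dir, "records_bx.jsonl")
  exprel_cli(c("extract", "--input", file.path(dir, "abstracts.tsv"),
               "--output", out2, "--bioxpress"))
  rec2 <- read_records(out2)
  expect_lte(nrow(rec2), nrow(rec))
  expect_true(all(rec2$frame_of_reference %in% c("Control", "Control_Implicit")))
})
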