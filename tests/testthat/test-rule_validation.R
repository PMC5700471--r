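wl <- default_word_lists()

test_that("entity-variation structures are identified", {
  txt <- "We found abnormalities of the ear. We saw defects of the outer, middle, and inner ear. Nothing else was found."
  sents <- preprocess_document(txt, "d")
  got1 <- rule_entity_variations(sents[[1]], wl, txt)
  expect_equal(got1$surface, "abnormalities of the ear")
  expect_equal(phenorec:::substr0(txt, got1$start, got1$end), got1$surface)
  got2 <- rule_entity_variations(sents[[2]], wl, txt)
  expect_equal(got2$surface, "defects of the outer, middle, and inner ear")
  expect_equal(nrow(rule_entity_variations(sents[[3]], wl, txt)), 0L)
})

test_that("boundary expansion crosses coordination in both directions", {
  txt <- "There were spine and rib anomalies in most patients."
  sent <- preprocess_document(txt, "d")[[1]]
  seeded <- cand_at(txt, "rib anomalies")
  got <- rule_longer_entities(sent, seeded, txt)
  expect_equal(got$surface, "spine and rib anomalies")
  expect_equal(got$origin, "expansion")

  # no coordination adjacent: unchanged
  txt2 <- "Rib anomalies were found."
  sent2 <- preprocess_document(txt2, "d")[[1]]
  expect_equal(nrow(rule_longer_entities(sent2, cand_at(txt2, "Rib anomalies"),
                                         txt2)), 0L)

  # constructed fixture: "X and Y anomalies" with "Y anomalies" seeded
  txt3 <- "Both skull and femur anomalies appeared."
  sent3 <- preprocess_document(txt3, "d")[[1]]
  got3 <- rule_longer_entities(sent3, cand_at(txt3, "femur anomalies"), txt3)
  expect_equal(got3$surface, "skull and femur anomalies")
})

test_that("coordinated candidates split into component entities", {
  txt <- "He had pits of the palms and soles. Later, pits of the soles recurred."
  sent <- preprocess_document(txt, "d")[[1]]
  parent <- cand_at(txt, "pits of the palms and soles")
  got <- rule_smaller_entities(sent, parent, wl, txt)
  expect_true("pits of the palms" %in% got$surface)
  # the distributed second form anchors to its own occurrence in the text
  expect_true("pits of the soles" %in% got$surface)
  ps <- got[got$surface == "pits of the soles", ]
  expect_equal(phenorec:::substr0(txt, ps$start, ps$end), "pits of the soles")

  # two-token entity without coordination: unchanged
  txt2 <- "We saw renal dysplasia."
  sent2 <- preprocess_document(txt2, "d")[[1]]
  expect_equal(nrow(rule_smaller_entities(sent2, cand_at(txt2, "renal dysplasia"),
                                          wl, txt2)), 0L)
})

test_that("removal rules mark the stated error classes with reasons", {
  cands <- cand("d", 0:7, 20:27,
                c("36", "ab", "abnormalities and malformations",
                  "anomalies of", "anomalies of the", "cognitive development",
                  "cognitive development impairment", "renal dysplasia"))
  out <- rule_stop_words(
    rule_negative_connotation(
      rule_incorrect_structure(rule_general_errors(cands, wl), wl), wl), wl)
  expect_equal(out$status, c("removed", "removed", "removed", "removed",
                             "removed", "removed", "active", "active"))
  expect_equal(out$reason[1:3], c("general:digits_only", "general:too_short",
                                  "general:multiple_common_nouns"))
  expect_equal(out$reason[4:5], rep("structure:bad_ending", 2))
  expect_equal(out$reason[6], "connotation:positive_pair")

  # unbalanced quote / parenthesis
  ub <- rule_general_errors(cand("d", 0:1, 30:31,
                                 c("kidney (left", "ataxia'")), wl)
  expect_equal(ub$reason, rep("general:unbalanced", 2))

  # stop-word semantics: exact vs partial
  sw <- rule_stop_words(cand("d", 0:2, 30:32,
                             c("hippocampus", "enlarged hippocampus",
                               "wild type strain")), wl)
  expect_equal(sw$status, c("removed", "active", "removed"))
  expect_equal(sw$reason[c(1, 3)], c("stop:exact", "stop:partial"))
})

test_that("validate runs the pipeline in order with an audit trail", {
  onto <- load_ontology(write_mini_obo())
  dict <- build_dictionary(onto, generate = TRUE, word_lists = wl)
  txt <- "The scan showed tumours of the nervous system. Assessment of cognitive development was normal."
  res <- validate(NULL, txt, "d", dict, wl)
  surf <- tolower(res$entities$surface)
  # nested superclass and subclass dictionary mentions both retained
  expect_true("tumours" %in% surf)
  expect_true("tumours of the nervous system" %in% surf)
  expect_false("cognitive development" %in% surf)
  aud <- res$audit
  expect_true(all(aud$status %in% c("active", "removed")))
  expect_true(all(!is.na(aud$reason[aud$status == "removed"])))
  # removal reasons reconcile with before/after totals
  expect_equal(nrow(res$entities) + sum(aud$status == "removed"), nrow(aud))
  # ids attached by dictionary lookup
  expect_equal(res$entities$hpo_id[surf == "tumours"], "HP_0002664")

  # disabled pipeline is the identity on CRF predictions
  pred <- data.frame(start = 4L, end = 8L, surface = "scan")
  off <- validate(pred, txt, "d", dict, wl,
                  validation_config(identification = FALSE, removal = FALSE))
  expect_equal(off$entities$surface, "scan")
  expect_equal(nrow(off$audit), 1L)

  # empty everything
  nothing <- validate(NULL, "Plain text only.", "d", NULL, wl)
  expect_equal(nrow(nothing$entities), 0L)
})

test_that("leading digit tokens are corrected (36 schwannomas case)", {
  txt <- "MRI revealed 36 schwannomas overall."
  pred <- cand_at(txt, "36 schwannomas")[c("start", "end", "surface")]
  res <- validate(pred, txt, "d", NULL, wl)
  expect_true("schwannomas" %in% res$entities$surface)
  expect_false("36 schwannomas" %in% res$entities$surface)
  aud <- res$audit
  expect_equal(aud$reason[aud$surface == "36 schwannomas"],
               "structure:leading_digit")
})

test_that("identification only adds, removal only removes, passes converge", {
  fx <- fx_default()
  onto <- fx$ontology
  dict <- build_dictionary(onto, fx$corpus$annotations, word_lists = wl)
  for (i in seq_len(3)) {
    id <- fx$corpus$documents$doc_id[i]
    txt <- fx$corpus$documents$text[i]
    sents <- preprocess_document(txt, id)
    ident <- validate(NULL, txt, id, dict, wl,
                      validation_config(removal = FALSE), sents)
    expect_true(all(ident$audit$status == "active"))  # no removals
    full <- validate(NULL, txt, id, dict, wl, validation_config(), sents)
    # removal phase only flips active -> removed, never adds spans
    expect_setequal(paste(full$audit$start, full$audit$end),
                    paste(ident$audit$start, ident$audit$end))
    # a third identification pass adds nothing (fixed point after two)
    cfg <- validation_config()
    more <- phenorec:::run_identification_pass(ident$audit, sents, wl, txt,
                                               cfg, "third_pass")
    more <- phenorec:::dedupe_candidates(more)
    expect_equal(nrow(more), nrow(phenorec:::dedupe_candidates(ident$audit)))
  }
})
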