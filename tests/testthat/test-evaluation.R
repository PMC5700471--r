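mk_ann <- function(doc_id, start, surface, hpo_id = "HP_0000001") {
  data.frame(doc_id = doc_id, start = as.integer(start),
             end = as.integer(start) + nchar(surface), hpo_id = hpo_id,
             surface = surface, stringsAsFactors = FALSE)
}

test_that("exact-span micro scores follow the P/R/F definitions", {
  gold <- rbind(mk_ann("d1", 0, "ataxia"), mk_ann("d2", 5, "seizure"))
  expect_equal(score_entities(gold, gold)$f_measure, 1)

  pred <- rbind(mk_ann("d1", 0, "ataxia"), mk_ann("d1", 20, "spam"),
                mk_ann("d2", 40, "more"))
  s <- score_entities(pred, gold)
  expect_equal(s$precision, 1 / 3)
  expect_equal(s$recall, 1 / 2)
  expect_equal(s$f_measure, 0.4)

  # formula consistency with the published benchmark row: P 0.65, R 0.49
  expect_equal(round(2 * 0.65 * 0.49 / (0.65 + 0.49), 2), 0.56)

  empty <- phenorec:::empty_annotations()
  z <- score_entities(empty, empty)
  expect_equal(c(z$precision, z$recall, z$f_measure), c(0, 0, 0))

  # symmetry: swapping predicted and gold exchanges P and R
  a <- score_entities(pred, gold)
  b <- score_entities(gold, pred)
  expect_equal(a$precision, b$recall)
  expect_equal(a$recall, b$precision)

  # id-strict mode separates span-equal, id-different annotations
  pred2 <- gold
  pred2$hpo_id[1] <- "HP_9999999"
  expect_equal(score_entities(pred2, gold)$f_measure, 1)
  expect_lt(score_entities(pred2, gold, id_strict = TRUE)$f_measure, 1)
})

test_that("scores serialize to plain JSON", {
  gold <- mk_ann("d1", 0, "ataxia")
  path <- tempfile(fileext = ".json")
  write_scores_json(list(pooled = score_entities(gold, gold)), path)
  back <- jsonlite::read_json(path)
  expect_equal(back$pooled$f_measure, 1)
  expect_equal(back$pooled$tp, 1L)
})

test_that("the false-positive filter drops only dictionary-known misses", {
  onto <- load_ontology(write_mini_obo())
  gold <- mk_ann("d1", 10, "renal dysplasia", "HP_0000110")
  dict <- build_dictionary(onto, gold, generate = TRUE)
  pred <- rbind(
    mk_ann("d1", 10, "renal dysplasia", "HP_0000110"),  # tp: kept
    mk_ann("d1", 40, "Tumours", "HP_0002664"),          # fp in dict: dropped
    mk_ann("d1", 60, "randomness", ""))                 # fp not in dict: kept
  filt <- filter_false_positives(pred, gold, dict)
  expect_setequal(filt$surface, c("renal dysplasia", "randomness"))

  s0 <- score_entities(pred, gold)
  s1 <- score_entities(filt, gold)
  expect_equal(s1$recall, s0$recall)     # recall invariant by construction
  expect_gte(s1$f_measure, s0$f_measure)
})

test_that("corpus extension appends exactly the dictionary-confirmed spans", {
  fx <- fx_default()
  unann <- fx$ledger[!fx$ledger$annotated & !is.na(fx$ledger$hpo_id), ]
  pred <- unann[c("doc_id", "start", "end", "surface", "hpo_id")]
  res <- build_gsc_plus(fx$corpus, pred, fx$ontology)
  # expected additions, derived from the ledger alone: unannotated planted
  # spans whose surface exact-matches an ontology name/synonym or a gold
  # surface (coordinated/pluralized forms do not qualify)
  norm <- phenorec:::normalize_surface
  known <- c(norm(unname(fx$ontology$terms)),
             norm(unlist(fx$ontology$synonyms, use.names = FALSE)),
             norm(fx$corpus$annotations$surface))
  qualifying <- unann[norm(unann$surface) %in% known, ]
  expect_gt(nrow(qualifying), 0L)
  expect_setequal(phenorec:::ann_key(res$additions, with_id = FALSE),
                  unique(phenorec:::ann_key(qualifying, with_id = FALSE)))
  d <- diff_corpora(fx$corpus, res$corpus)
  expect_equal(unname(d$counts["removed"]), 0L)
  expect_equal(unname(d$counts["added"]), nrow(res$additions))

  # already-annotated span is not duplicated; unknown surfaces are skipped
  again <- build_gsc_plus(res$corpus, pred, fx$ontology)
  expect_equal(nrow(again$additions), 0L)
  junk <- data.frame(doc_id = fx$corpus$documents$doc_id[1], start = 0L,
                     end = 3L, surface = "The", hpo_id = NA_character_)
  expect_equal(nrow(build_gsc_plus(fx$corpus, junk, fx$ontology)$additions), 0L)
})

test_that("nested superclass mentions matching the ontology are added", {
  onto <- load_ontology(write_mini_obo())
  txt <- "Intracranial tumours were resected."
  corpus <- phenorec:::new_corpus(
    data.frame(doc_id = "d1", text = txt, stringsAsFactors = FALSE),
    mk_ann("d1", 0, "Intracranial tumours", "HP_0001425"))
  s <- regexpr("tumours", txt) - 1L
  pred <- mk_ann("d1", s, "tumours", "")
  res <- build_gsc_plus(corpus, pred, onto)
  expect_equal(nrow(res$additions), 1L)
  expect_equal(res$additions$hpo_id, "HP_0002664")  # resolved from ontology
})

test_that("inconsistency report flags the four suspect classes", {
  onto <- load_ontology(write_mini_obo())
  wl <- default_word_lists()

  # class 1: surface used three times, annotated twice
  t1 <- "Tumours grew. More tumours grew. Further tumours grew."
  p1 <- gregexpr("[Tt]umours", t1)[[1]]
  ann1 <- rbind(mk_ann("c1", p1[1] - 1L, "Tumours", "HP_0002664"),
                mk_ann("c1", p1[2] - 1L, "tumours", "HP_0002664"))
  c1 <- phenorec:::new_corpus(
    data.frame(doc_id = "c1", text = t1, stringsAsFactors = FALSE), ann1)
  rep1 <- inconsistency_report(c1, onto, wl)
  expect_equal(nrow(rep1$occurrence), 1L)
  expect_equal(rep1$occurrence$occurrences, 3L)
  expect_equal(rep1$occurrence$annotated, 2L)

  # class 2: annotated surface with no ontology meaning
  t2 <- "Severe calcium metabolism was noted."
  ann2 <- mk_ann("c2", regexpr("calcium", t2) - 1L, "calcium metabolism",
                 "HP_0000001")
  c2 <- phenorec:::new_corpus(
    data.frame(doc_id = "c2", text = t2, stringsAsFactors = FALSE), ann2)
  rep2 <- inconsistency_report(c2, onto, wl)
  expect_equal(rep2$meaning$surface, "calcium metabolism")

  # classes 3/4: nested dictionary surface unannotated in one doc only
  t3 <- "Tumours of the nervous system appeared."
  ann3a <- rbind(mk_ann("c3", 0, "Tumours of the nervous system",
                        "HP_0001425"),
                 mk_ann("c3", 0, "Tumours", "HP_0002664"))
  c3a <- phenorec:::new_corpus(
    data.frame(doc_id = "c3", text = t3, stringsAsFactors = FALSE), ann3a)
  rep3a <- inconsistency_report(c3a, onto, wl)
  expect_equal(nrow(rep3a$nested), 0L)  # inner span IS annotated

  ann3b <- mk_ann("c3", 0, "Tumours of the nervous system", "HP_0001425")
  c3b <- phenorec:::new_corpus(
    data.frame(doc_id = "c3", text = t3, stringsAsFactors = FALSE), ann3b)
  rep3b <- inconsistency_report(c3b, onto, wl)
  expect_gte(nrow(rep3b$nested), 1L)
  expect_equal(rep3b$nested$unannotated_inner[1], "tumours")

  # fully consistent corpus: empty report
  t4 <- "Renal dysplasia was present."
  ann4 <- mk_ann("c4", 0, "Renal dysplasia", "HP_0000110")
  c4 <- phenorec:::new_corpus(
    data.frame(doc_id = "c4", text = t4, stringsAsFactors = FALSE), ann4)
  rep4 <- inconsistency_report(c4, onto, wl)
  expect_true(all(vapply(rep4, nrow, integer(1)) == 0L))
})
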