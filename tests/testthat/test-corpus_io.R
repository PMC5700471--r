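test_that("annotation lines parse to 0-based half-open character spans", {
  a <- parse_annotation_line("[27::42] HP_0000110 | renal dysplasia", "2888021")
  expect_equal(a$start, 27L)
  expect_equal(a$end, 42L)
  expect_equal(a$hpo_id, "HP_0000110")
  expect_equal(a$surface, "renal dysplasia")
  expect_equal(a$end - a$start, nchar(a$surface))  # forces the convention

  b <- parse_annotation_line("[0::1] HP_0000001 | a", "x")
  expect_equal(c(b$start, b$end), c(0L, 1L))

  # Unicode divider and colon-form id are accepted and normalized
  u <- parse_annotation_line("[5::11] HP:0000077 ∣ kidney", "x")
  expect_equal(u$hpo_id, "HP_0000077")

  expect_error(parse_annotation_line("[5::20] HP_0000077", "x", 3, "f.txt"),
               "malformed.*line 3.*f\\.txt")
  expect_error(parse_annotation_line("[7::7] HP_0000077 | x", "x"), "empty")
})

test_that("corpus write/read round-trips, including unicode offsets", {
  corpus <- make_mini_corpus()
  expect_equal(nrow(corpus$documents), 3L)
  expect_equal(nrow(corpus$annotations), 7L)

  dd <- tempfile("docs"); ad <- tempfile("anns")
  write_corpus(corpus, dd, ad)
  back <- read_corpus(dd, ad)
  expect_equal(back$documents, corpus$documents)
  expect_equal(back$annotations[order(back$annotations$doc_id,
                                      back$annotations$start), ],
               corpus$annotations[order(corpus$annotations$doc_id,
                                        corpus$annotations$start), ],
               ignore_attr = TRUE)
  expect_equal(nrow(attr(back, "validation")), 0L)

  # character (not byte) offsets: multibyte char before the entity
  utxt <- "A μ-variant showed ataxia here."
  s <- as.integer(regexpr("ataxia", utxt)) - 1L
  uc <- phenorec:::new_corpus(
    data.frame(doc_id = "u1", text = utxt, stringsAsFactors = FALSE),
    data.frame(doc_id = "u1", start = s, end = s + 6L, hpo_id = "HP_0001251",
               surface = "ataxia", stringsAsFactors = FALSE))
  d2 <- tempfile(); a2 <- tempfile()
  write_corpus(uc, d2, a2)
  back2 <- read_corpus(d2, a2)
  expect_equal(nrow(attr(back2, "validation")), 0L)
  expect_equal(back2$annotations$start, s)

  # empty annotation file: document retained with zero annotations
  d3 <- tempfile(); a3 <- tempfile()
  dir.create(d3); dir.create(a3)
  writeLines("Some text.", file.path(d3, "solo.txt"))
  writeLines(character(), file.path(a3, "solo.txt"))
  solo <- read_corpus(d3, a3)
  expect_equal(solo$documents$doc_id, "solo")
  expect_equal(nrow(solo$annotations), 0L)

  # empty corpus round trip
  ec <- phenorec:::new_corpus(
    data.frame(doc_id = character(), text = character()),
    phenorec:::empty_annotations())
  d4 <- tempfile(); a4 <- tempfile()
  write_corpus(ec, d4, a4)
  expect_equal(nrow(read_corpus(d4, a4)$documents), 0L)
})

test_that("orphan annotation files and span mismatches are caught", {
  dd <- tempfile(); ad <- tempfile()
  dir.create(dd); dir.create(ad)
  writeLines("renal dysplasia here.", file.path(dd, "a.txt"))
  writeLines("[0::15] HP_0000110 | renal dysplasia", file.path(ad, "a.txt"))
  writeLines("[0::3] HP_0000001 | foo", file.path(ad, "b.txt"))
  expect_error(read_corpus(dd, ad), "without a matching document.*b")
  file.remove(file.path(ad, "b.txt"))

  # shift the span so the text no longer matches
  writeLines("[2::17] HP_0000110 | renal dysplasia", file.path(ad, "a.txt"))
  lax <- read_corpus(dd, ad)
  expect_equal(nrow(attr(lax, "validation")), 1L)
  expect_equal(lax$annotations$start, 2L)  # file offsets kept
  expect_error(read_corpus(dd, ad, strict = TRUE), "mismatch")
})

test_that("diff_corpora classifies added/removed/modified and is symmetric", {
  corpus <- make_mini_corpus()
  self <- diff_corpora(corpus, corpus)
  expect_equal(unname(self$counts), c(0L, 0L, 0L))

  extended <- corpus
  inject <- data.frame(doc_id = c("d1", "d3"), start = c(0L, 2L),
                       end = c(8L, 7L), hpo_id = c("HP_0000002", "HP_0000003"),
                       surface = c("Patients", "study"),
                       stringsAsFactors = FALSE)
  extended$annotations <- rbind(corpus$annotations, inject)
  d <- diff_corpora(corpus, extended)
  expect_equal(unname(d$counts), c(2L, 0L, 0L))

  # same span, different id => modified
  mod <- corpus
  mod$annotations$hpo_id[1] <- "HP_9999999"
  dm <- diff_corpora(corpus, mod)
  expect_equal(unname(dm$counts["modified"]), 1L)
  expect_equal(unname(dm$counts["added"]), 0L)

  # added(a,b) equals removed(b,a) as sets
  fwd <- diff_corpora(corpus, extended)
  rev <- diff_corpora(extended, corpus)
  expect_setequal(phenorec:::ann_key(fwd$added), phenorec:::ann_key(rev$removed))

  other <- corpus
  other$documents <- other$documents[-1, ]
  other$annotations <- other$annotations[other$annotations$doc_id != "d1", ]
  expect_error(diff_corpora(corpus, other), "document sets differ")
})

test_that("OBO loading keeps live terms, synonyms and parents", {
  onto <- load_ontology(write_mini_obo())
  expect_length(onto$terms, 5L)                 # obsolete term excluded
  expect_false("HP_0009999" %in% names(onto$terms))
  expect_match(tolower(onto$terms[["HP_0000077"]]),
               "abnormality of the kidney")
  expect_equal(onto$synonyms[["HP_0000077"]], "Kidney abnormality")
  expect_null(onto$synonyms[["HP_0001425"]])    # term without synonyms
  expect_equal(onto$parents[["HP_0000110"]], "HP_0000077")
  expect_error(load_ontology(tempfile()), "no such OBO")
  bad <- tempfile(); writeLines("not an obo", bad)
  expect_error(load_ontology(bad), "OBO")
})
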