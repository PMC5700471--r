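test_that("variation generation covers both rewrite directions", {
  wl <- default_word_lists()
  v1 <- generate_variations("abnormalities of the kidney",
                            wl$connector_phrases, wl$common_hpo_nouns)
  expect_true(all(c("abnormalities of the kidney",
                    "kidney abnormalities") %in% v1))
  v2 <- generate_variations("kidney abnormalities",
                            wl$connector_phrases, wl$common_hpo_nouns)
  expect_true("abnormalities of the kidney" %in% v2)
  expect_equal(generate_variations("seizure", wl$connector_phrases,
                                   wl$common_hpo_nouns), "seizure")

  # content safety: connectors aside, generated forms carry exactly the
  # original content words (up to the singular/plural toggle on common nouns)
  base <- c("pits", "of", "the", "palms")
  conns <- unique(unlist(strsplit(wl$connector_phrases, " ")))
  for (v in generate_variations("pits of the palms", wl$connector_phrases,
                                wl$common_hpo_nouns)) {
    words <- setdiff(strsplit(v, " ")[[1]], conns)
    norm <- sub("s$", "", words)
    expect_setequal(norm, setdiff(sub("s$", "", base), conns))
  }
})

test_that("dictionaries contain names, synonyms, training surfaces, variations", {
  onto <- load_ontology(write_mini_obo())
  train <- data.frame(doc_id = "d", start = 0L, end = 1L,
                      hpo_id = c("HP_0000110", "HP_0000077", "HP_0002664"),
                      surface = c("renal dysplasia", "kidney trouble",
                                  "Tumours"),
                      stringsAsFactors = FALSE)

  plain <- build_dictionary(onto, train, generate = FALSE)
  # 5 names + 3 synonyms + 3 training surfaces, deduplicated by
  # (surface, id): "tumours"/"renal dysplasia" collide with ontology entries
  expect_setequal(
    phenorec:::dictionary_surfaces(plain),
    c("all", "abnormality of the kidney", "kidney abnormality",
      "renal dysplasia", "dysplastic kidneys", "tumours of the nervous system",
      "tumours", "neoplasia", "kidney trouble"))
  src <- plain$entries$source[plain$entries$surface == "tumours"]
  expect_equal(src, "ontology_name")  # earliest source wins

  empty <- build_dictionary(onto, NULL, generate = FALSE)
  expect_setequal(unique(empty$entries$source),
                  c("ontology_name", "ontology_synonym"))
  expect_true("abnormality of the kidney" %in%
                phenorec:::dictionary_surfaces(empty))
  expect_equal(phenorec:::dictionary_lookup(empty, "Abnormality of the Kidney"),
               "HP_0000077")

  gen <- build_dictionary(onto, NULL, generate = TRUE)
  expect_true("kidney abnormalities" %in% phenorec:::dictionary_surfaces(gen))
})

test_that("dictionary matching is exact, boundary-aware and nest-friendly", {
  onto <- load_ontology(write_mini_obo())
  dict <- build_dictionary(onto, generate = FALSE)
  txt <- "Severe renal dysplasia and tumours of the nervous system appeared."

  hits <- find_dictionary_mentions(txt, dict)
  # independent brute-force scanner over every substring position
  oracle <- list()
  low <- tolower(txt)
  for (s in phenorec:::dictionary_surfaces(dict)) {
    for (i in seq_len(nchar(low) - nchar(s) + 1L)) {
      if (substr(low, i, i + nchar(s) - 1L) == s) {
        before_ok <- i == 1L || !grepl("[a-z0-9]", substr(low, i - 1, i - 1))
        after_ok <- i + nchar(s) > nchar(low) ||
          !grepl("[a-z0-9]", substr(low, i + nchar(s), i + nchar(s)))
        if (before_ok && after_ok) {
          oracle[[length(oracle) + 1L]] <- c(i - 1L, i - 1L + nchar(s))
        }
      }
    }
  }
  oracle <- unique(do.call(rbind, oracle))
  expect_setequal(paste(hits$start, hits$end),
                  paste(oracle[, 1], oracle[, 2]))
  # nested mentions across distinct entries are both reported
  expect_true("tumours" %in% tolower(hits$surface))
  expect_true("tumours of the nervous system" %in% tolower(hits$surface))
  # "ear" must not fire inside "appeared"
  expect_false(any(hits$surface == "ear"))

  none <- find_dictionary_mentions("nothing relevant here", dict)
  expect_equal(nrow(none), 0L)
  expect_equal(phenorec:::substr0(txt, hits$start[1], hits$end[1]),
               hits$surface[1])
})

test_that("per-fold dictionaries never leak test-fold-only surfaces", {
  fx <- fx_default()
  plan <- make_folds(fx$corpus$documents$doc_id, k = 4, seed = 3)
  ann <- fx$corpus$annotations
  onto_empty <- structure(list(terms = c(HP_0000001 = "root"),
                               synonyms = list(), parents = list()),
                          class = "hpo_ontology")
  for (f in seq_len(plan$k)) {
    test_ids <- names(plan$assignment)[plan$assignment == f]
    train_ann <- ann[!(ann$doc_id %in% test_ids), ]
    test_ann <- ann[ann$doc_id %in% test_ids, ]
    dict <- build_dictionary(onto_empty, train_ann, generate = FALSE)
    test_only <- setdiff(phenorec:::normalize_surface(test_ann$surface),
                         phenorec:::normalize_surface(train_ann$surface))
    expect_length(intersect(test_only,
                            phenorec:::dictionary_surfaces(dict)), 0L)
  }
})
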