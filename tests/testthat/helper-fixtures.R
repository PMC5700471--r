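# Shared fixtures, built in code and cached for the session.

# default stated-world fixture (all phenomena at their default rates)
fx_default <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_fixture(fixture_spec())
    cache
  }
})

# clean separable fixture: no coordination/nesting/under-annotation or
# distractors; used for the end-to-end CRF property
fx_clean <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_fixture(fixture_spec(
        coordination_rate = 0, nesting_rate = 0, unannotated_rate = 0,
        positive_distractor_rate = 0, stop_distractor_rate = 0, seed = 7))
    }
    cache
  }
})

# hand-built 3-document / 7-annotation corpus with known content
make_mini_corpus <- function() {
  t1 <- "Patients showed renal dysplasia and severe scoliosis early."
  t2 <- "We observed abnormality of the kidney twice, then ataxia."
  t3 <- "A study of microcephaly, nystagmus and renal dysplasia cases."
  docs <- data.frame(doc_id = c("d1", "d2", "d3"), text = c(t1, t2, t3),
                     stringsAsFactors = FALSE)
  span <- function(text, surface) {
    s <- regexpr(surface, text, fixed = TRUE)
    c(as.integer(s) - 1L, as.integer(s) - 1L + nchar(surface))
  }
  rows <- list(
    c("d1", span(t1, "renal dysplasia"), "HP_0000110", "renal dysplasia"),
    c("d1", span(t1, "severe scoliosis"), "HP_0002650", "severe scoliosis"),
    c("d2", span(t2, "abnormality of the kidney"), "HP_0000077",
      "abnormality of the kidney"),
    c("d2", span(t2, "ataxia"), "HP_0001251", "ataxia"),
    c("d3", span(t3, "microcephaly"), "HP_0000252", "microcephaly"),
    c("d3", span(t3, "nystagmus"), "HP_0000639", "nystagmus"),
    c("d3", span(t3, "renal dysplasia"), "HP_0000110", "renal dysplasia"))
  ann <- do.call(rbind, lapply(rows, function(r) {
    data.frame(doc_id = r[1], start = as.integer(r[2]), end = as.integer(r[3]),
               hpo_id = r[4], surface = r[5], stringsAsFactors = FALSE)
  }))
  phenorec:::new_corpus(docs, ann)
}

# tiny OBO file: 5 live terms (3 with synonyms), one obsolete, is_a links
write_mini_obo <- function(path = tempfile(fileext = ".obo")) {
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: HP:0000001", "name: All", "",
    "[Term]", "id: HP:0000077", "name: Abnormality of the kidney",
    "synonym: \"Kidney abnormality\" EXACT []",
    "is_a: HP:0000001 ! All", "",
    "[Term]", "id: HP:0000110", "name: Renal dysplasia",
    "synonym: \"Dysplastic kidneys\" EXACT []",
    "is_a: HP:0000077 ! Abnormality of the kidney", "",
    "[Term]", "id: HP:0001425", "name: Tumours of the nervous system",
    "is_a: HP:0000001 ! All", "",
    "[Term]", "id: HP:0002664", "name: Tumours",
    "synonym: \"Neoplasia\" EXACT []",
    "is_a: HP:0000001 ! All", "",
    "[Term]", "id: HP:0009999", "name: Gone",
    "is_obsolete: true", ""), path)
  path
}

# simple candidate data.frame builder for rule tests
cand <- function(doc_id, start, end, surface, origin = "crf") {
  phenorec:::new_candidates(doc_id, as.integer(start), as.integer(end),
                            surface, NA_character_, origin)
}

# candidate anchored at a surface's first occurrence in a text
cand_at <- function(text, surface, doc_id = "d") {
  s <- as.integer(regexpr(surface, text, fixed = TRUE)) - 1L
  stopifnot(s >= 0)
  cand(doc_id, s, s + nchar(surface), surface)
}
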