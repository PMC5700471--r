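# Self-contained synthetic fixtures: a toy phenotype ontology, a
# gold-standard-format corpus with controlled phenomena, word lists, and a
# machine-readable ledger of every planted mention. The vocabulary comes
# from a small closed template grammar (body parts x abnormality nouns x
# single-word terms) so dictionary variations are generable and checkable
# by hand; entity vocabulary is disjoint from the filler sentences, which
# is what makes the end-to-end CRF property testable. Abstracts are a
# single line without a title, matching the corpus convention.

.fx_parts <- c("kidney", "ear", "heart", "spine", "rib", "palm", "sole",
               "liver", "retina", "skull", "femur", "thyroid", "cornea",
               "tongue", "larynx", "pancreas", "ulna", "sternum")
.fx_singles <- c("microcephaly", "nystagmus", "scoliosis", "ataxia",
                 "polydactyly", "craniosynostosis", "hypertelorism",
                 "micrognathia")
.fx_fillers <- c(
  "The family history was unremarkable.",
  "Genetic testing was performed during infancy.",
  "Follow-up visits occurred annually.",
  "Parental consent was obtained for this study.",
  "Laboratory values remained stable over time.")

#' Specification of a synthetic fixture
#'
#' The rates give, per planted mention (or per document for the
#' distractors), the probability of each controlled phenomenon. Generation
#' is deterministic given `seed`.
#'
#' @param n_terms number of ontology terms (>= 4; capped by the template
#'   vocabulary).
#' @param n_docs number of documents.
#' @param seed RNG seed.
#' @param variation_rate mention rendered as a rewrite variation of the term
#'   name ("X of the Y" <-> "Y X").
#' @param coordination_rate mention rendered as a coordinated pair
#'   ("spine and rib abnormalities").
#' @param nesting_rate probability that the inner conjunct of a coordinated
#'   mention is ALSO annotated (nested gold span).
#' @param unannotated_rate mention planted in the text but deliberately left
#'   out of the gold annotations (exercises the false-positive filter,
#'   corpus extension and inconsistency detection).
#' @param positive_distractor_rate per document: plant a two-token
#'   positive-connotation phrase ("cognitive development").
#' @param stop_distractor_rate per document: plant a bare stop-list word
#'   ("hippocampus").
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_terms = 15L, n_docs = 12L, seed = 42L,
                         variation_rate = 0.3, coordination_rate = 0.2,
                         nesting_rate = 0.5, unannotated_rate = 0.15,
                         positive_distractor_rate = 0.3,
                         stop_distractor_rate = 0.3) {
  rates <- c(variation_rate, coordination_rate, nesting_rate,
             unannotated_rate, positive_distractor_rate, stop_distractor_rate)
  stopifnot(all(rates >= 0 & rates <= 1), n_terms >= 4, n_docs >= 1)
  structure(list(n_terms = as.integer(n_terms), n_docs = as.integer(n_docs),
                 seed = as.integer(seed), variation_rate = variation_rate,
                 coordination_rate = coordination_rate,
                 nesting_rate = nesting_rate,
                 unannotated_rate = unannotated_rate,
                 positive_distractor_rate = positive_distractor_rate,
                 stop_distractor_rate = stop_distractor_rate),
            class = "fixture_spec")
}

fixture_ontology <- function(spec) {
  n_part_terms <- min(spec$n_terms - 1L - min(length(.fx_singles),
                                              spec$n_terms %/% 3L),
                      length(.fx_parts))
  n_single <- min(spec$n_terms - 1L - n_part_terms, length(.fx_singles))
  ids <- sprintf("HP_%07d", seq_len(1L + n_part_terms + n_single))
  terms <- c("Phenotypic abnormality (synthetic)",
             paste0("Abnormality of the ", .fx_parts[seq_len(n_part_terms)]),
             .fx_singles[seq_len(n_single)])
  names(terms) <- ids
  synonyms <- setNames(vector("list", length(ids)), ids)
  for (i in seq_len(n_part_terms)) {
    synonyms[[ids[1L + i]]] <- paste0(.fx_parts[i], " abnormality")
  }
  synonyms <- synonyms[lengths(synonyms) > 0]
  parents <- setNames(as.list(rep(ids[1], length(ids) - 1L)), ids[-1])
  structure(list(terms = terms, synonyms = synonyms, parents = parents),
            class = "hpo_ontology")
}

ontology_to_obo <- function(ontology) {
  out <- c("format-version: 1.2", "")
  for (id in names(ontology$terms)) {
    out <- c(out, "[Term]", paste0("id: ", sub("_", ":", id)),
             paste0("name: ", ontology$terms[[id]]))
    for (s in ontology$synonyms[[id]]) {
      out <- c(out, paste0("synonym: \"", s, "\" EXACT []"))
    }
    for (p in ontology$parents[[id]]) {
      out <- c(out, paste0("is_a: ", sub("_", ":", p), " ! ",
                           ontology$terms[[p]]))
    }
    out <- c(out, "")
  }
  out
}

# incremental single-line document builder tracking character offsets
doc_builder <- function(doc_id) {
  env <- new.env(parent = emptyenv())
  env$doc_id <- doc_id
  env$text <- ""
  env$ledger <- list()
  env$add_text <- function(s) env$text <- paste0(env$text, s)
  env$add_mention <- function(surface, hpo_id, annotated, kind) {
    start <- nchar(env$text)
    env$add_text(surface)
    env$ledger[[length(env$ledger) + 1L]] <- data.frame(
      doc_id = doc_id, start = start, end = start + nchar(surface),
      hpo_id = hpo_id, surface = surface, annotated = annotated, kind = kind,
      stringsAsFactors = FALSE)
  }
  env
}

#' Generate a synthetic fixture
#'
#' Builds an ontology, a corpus in gold-standard format, word lists and a
#' complete ledger of planted mentions (annotated or deliberately not).
#' When `dir` is given, everything is also written to disk in exactly the
#' formats the corpus and lexicon readers consume
#' (`ontology.obo`, `docs/`, `annotations/`, `word_lists/`, `ledger.tsv`).
#'
#' @param spec a [fixture_spec()].
#' @param dir optional output directory.
#' @return list with `ontology`, `corpus` (`gsc_corpus`), `word_lists`,
#'   `ledger` (data.frame) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  ontology <- fixture_ontology(spec)
  wl <- default_word_lists()
  with_seed(spec$seed, {
    part_ids <- names(ontology$terms)[startsWith(unname(ontology$terms),
                                                 "Abnormality of the ")]
    single_ids <- setdiff(names(ontology$terms)[-1], part_ids)
    part_of <- sub("^Abnormality of the ", "", ontology$terms[part_ids])

    docs <- list(); ledgers <- list()
    for (d in seq_len(spec$n_docs)) {
      b <- doc_builder(sprintf("doc%03d", d))
      n_sent <- sample(4:6, 1)
      for (s in seq_len(n_sent)) {
        kind <- sample(c("mention", "mention", "filler"), 1)
        if (kind == "filler") {
          b$add_text(paste0(sample(.fx_fillers, 1), " "))
          next
        }
        openers <- c("The patient presented with ",
                     "Clinical examination revealed ",
                     "Radiographs demonstrated ",
                     "The proband exhibited ")
        b$add_text(sample(openers, 1))
        if (stats::runif(1) < spec$coordination_rate && length(part_ids) >= 2) {
          pick <- sample(seq_along(part_ids), 2)
          surface <- paste0(part_of[pick[1]], " and ", part_of[pick[2]],
                            " abnormalities")
          annotated <- stats::runif(1) >= spec$unannotated_rate
          start_full <- nchar(b$text)
          b$add_mention(surface, part_ids[pick[1]], annotated, "coordinated")
          if (stats::runif(1) < spec$nesting_rate) {
            inner <- paste0(part_of[pick[2]], " abnormalities")
            inner_start <- start_full + nchar(surface) - nchar(inner)
            ledg <- b$ledger[[length(b$ledger)]]
            b$ledger[[length(b$ledger) + 1L]] <- data.frame(
              doc_id = ledg$doc_id, start = inner_start,
              end = inner_start + nchar(inner), hpo_id = part_ids[pick[2]],
              surface = inner, annotated = annotated, kind = "nested_inner",
              stringsAsFactors = FALSE)
          }
        } else {
          use_single <- length(single_ids) && stats::runif(1) < 0.4
          annotated <- stats::runif(1) >= spec$unannotated_rate
          if (use_single) {
            id <- sample(single_ids, 1)
            b$add_mention(unname(ontology$terms[id]), id, annotated, "plain")
          } else {
            i <- sample(seq_along(part_ids), 1)
            if (stats::runif(1) < spec$variation_rate) {
              b$add_mention(paste0(part_of[i], " abnormality"), part_ids[i],
                            annotated, "variation")
            } else {
              b$add_mention(paste0("abnormality of the ", part_of[i]),
                            part_ids[i], annotated, "plain")
            }
          }
        }
        b$add_text(". ")
      }
      if (stats::runif(1) < spec$positive_distractor_rate) {
        b$add_text("Assessment of ")
        b$add_mention("cognitive development", NA_character_, FALSE,
                      "distractor_positive")
        b$add_text(" was repeated. ")
      }
      if (stats::runif(1) < spec$stop_distractor_rate) {
        b$add_text("Imaging of the ")
        b$add_mention("hippocampus", NA_character_, FALSE, "distractor_stop")
        b$add_text(" was unremarkable. ")
      }
      b$text <- trimws(b$text)
      docs[[d]] <- data.frame(doc_id = b$doc_id, text = b$text,
                              stringsAsFactors = FALSE)
      ledgers[[d]] <- if (length(b$ledger)) do.call(rbind, b$ledger)
    }
    documents <- do.call(rbind, docs)
    ledger <- do.call(rbind, ledgers)
    rownames(ledger) <- NULL
    ann <- ledger[ledger$annotated & !is.na(ledger$hpo_id),
                  c("doc_id", "start", "end", "hpo_id", "surface")]
    rownames(ann) <- NULL
    corpus <- new_corpus(documents, ann)

    out <- list(ontology = ontology, corpus = corpus, word_lists = wl,
                ledger = ledger, spec = spec)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      writeLines(ontology_to_obo(ontology), file.path(dir, "ontology.obo"))
      write_corpus(corpus, file.path(dir, "docs"),
                   file.path(dir, "annotations"))
      write_word_lists(wl, file.path(dir, "word_lists"))
      utils::write.table(ledger, file.path(dir, "ledger.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    out
  })
}
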