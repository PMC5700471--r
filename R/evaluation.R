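# Exact-span micro-averaged evaluation, the false-positive filter
# experiment, corpus extension with consistent automatic annotations, and
# the annotation-inconsistency report.

#' Exact-span micro precision / recall / F-measure
#'
#' A prediction is a true positive when its (doc_id, start, end) key equals
#' a gold annotation's; ontology ids are not required to match by default
#' (id assignment for CRF-origin entities is best-effort), but
#' `id_strict = TRUE` adds the id to the key. Counts are pooled over all
#' documents before computing the metrics (micro-averaging).
#'
#' @param predicted,gold annotation data.frames with `doc_id`, `start`,
#'   `end` (and `hpo_id` when `id_strict`).
#' @param id_strict require ontology id equality too.
#' @return an `ner_score`: tp, fp, fn, precision, recall, f_measure.
#' @export
score_entities <- function(predicted, gold, id_strict = FALSE) {
  pk <- unique(ann_key(predicted, with_id = id_strict))
  gk <- unique(ann_key(gold, with_id = id_strict))
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f_measure = f),
            class = "ner_score")
}

#' @export
print.ner_score <- function(x, ...) {
  cat(sprintf("P = %.3f  R = %.3f  F = %.3f  (tp %d, fp %d, fn %d)\n",
              x$precision, x$recall, x$f_measure, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Filter false positives that exist in a phenotype dictionary
#'
#' Drops predictions that are NOT in the gold annotations (by span key) but
#' whose surface exact-matches a dictionary entry — the under-annotation
#' probe: such "false" positives are phenotype mentions the gold standard
#' simply missed. True positives are never touched, so recall is unchanged
#' by construction and F cannot decrease.
#'
#' @param predicted prediction data.frame (`doc_id`, `start`, `end`,
#'   `surface`).
#' @param gold gold annotation data.frame.
#' @param dictionary an `hpo_dictionary` built from the ontology plus gold
#'   annotations.
#' @return the filtered predictions.
#' @export
filter_false_positives <- function(predicted, gold, dictionary) {
  if (!nrow(predicted)) return(predicted)
  in_gold <- ann_key(predicted, with_id = FALSE) %in%
    ann_key(gold, with_id = FALSE)
  in_dict <- normalize_surface(predicted$surface) %in%
    dictionary_surfaces(dictionary)
  predicted[in_gold | !in_dict, , drop = FALSE]
}

#' Extend a gold-standard corpus with consistent automatic annotations
#'
#' Predictions whose surface exact-matches (case-insensitive, whitespace
#' normalized; `strict_case` disables the case folding) an ontology name or
#' synonym, or an existing gold annotation surface, and whose span is not
#' already annotated, are appended to the corpus. This includes nested
#' superclass mentions ("tumours" inside "intracranial tumours") that match
#' the ontology even when only the longer mention was annotated.
#'
#' @param corpus a `gsc_corpus`.
#' @param predicted prediction data.frame with `doc_id`, `start`, `end`,
#'   `surface` and optionally `hpo_id`.
#' @param ontology an `hpo_ontology`.
#' @param strict_case require exact case.
#' @return list with `corpus` (extended, a valid `gsc_corpus`) and
#'   `additions` (the appended annotations).
#' @export
build_gsc_plus <- function(corpus, predicted, ontology, strict_case = FALSE) {
  stopifnot(inherits(corpus, "gsc_corpus"), inherits(ontology, "hpo_ontology"))
  norm <- if (strict_case) {
    function(x) gsub("[[:space:]]+", " ", trimws(x))
  } else {
    normalize_surface
  }
  known <- unique(c(norm(unname(ontology$terms)),
                    norm(unlist(ontology$synonyms, use.names = FALSE)),
                    norm(corpus$annotations$surface)))
  if (!nrow(predicted)) {
    return(list(corpus = corpus, additions = empty_annotations()))
  }
  span_known <- ann_key(predicted, with_id = FALSE) %in%
    ann_key(corpus$annotations, with_id = FALSE)
  qualifies <- !span_known & norm(predicted$surface) %in% known
  add <- predicted[qualifies, , drop = FALSE]
  add <- add[!duplicated(ann_key(add, with_id = FALSE)), , drop = FALSE]
  if (!nrow(add)) {
    return(list(corpus = corpus, additions = empty_annotations()))
  }
  if (is.null(add$hpo_id)) add$hpo_id <- NA_character_
  # resolve missing ids from the ontology (name/synonym surface match)
  surf2id <- c(setNames(names(ontology$terms), norm(unname(ontology$terms))),
               setNames(rep(names(ontology$synonyms),
                            lengths(ontology$synonyms)),
                        norm(unlist(ontology$synonyms, use.names = FALSE))),
               setNames(corpus$annotations$hpo_id,
                        norm(corpus$annotations$surface)))
  miss <- is.na(add$hpo_id) | !nzchar(add$hpo_id)
  add$hpo_id[miss] <- unname(surf2id[norm(add$surface[miss])])
  add <- add[!is.na(add$hpo_id), , drop = FALSE]
  additions <- add[c("doc_id", "start", "end", "hpo_id", "surface")]
  rownames(additions) <- NULL
  extended <- new_corpus(corpus$documents,
                         rbind(corpus$annotations, additions))
  list(corpus = extended, additions = additions)
}

#' Write scores (or any results list) as JSON
#'
#' @param scores an `ner_score`, or a list of them, or any plain list.
#' @param path output file.
#' @export
write_scores_json <- function(scores, path) {
  strip <- function(x) {
    if (inherits(x, "ner_score")) unclass(x)
    else if (is.list(x)) lapply(x, strip)
    else x
  }
  jsonlite::write_json(strip(scores), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

count_occurrences <- function(text, surface) {
  m <- gregexpr(boundary_pattern(normalize_surface(surface)), tolower(text),
                perl = TRUE)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

#' Report annotation inconsistencies in a corpus
#'
#' Four classes of suspects, each a data.frame in the returned list:
#' \describe{
#'   \item{occurrence}{surfaces annotated in some but not all of their
#'     occurrences within a document (counts reported).}
#'   \item{meaning}{annotated surfaces matching no ontology name, synonym or
#'     generated variation (the surface has no standalone meaning in the
#'     ontology).}
#'   \item{nested}{annotations containing an unannotated dictionary surface
#'     inside their own span.}
#'   \item{superclass}{annotations containing a dictionary surface
#'     (a superclass mention) that also occurs elsewhere in the document
#'     without being annotated.}
#' }
#'
#' @param corpus a `gsc_corpus`.
#' @param ontology an `hpo_ontology`.
#' @param word_lists a `word_lists` (feeds the variation grammar).
#' @return an `inconsistency_report` (list of four data.frames).
#' @export
inconsistency_report <- function(corpus, ontology,
                                 word_lists = default_word_lists()) {
  dict <- build_dictionary(ontology, generate = TRUE, word_lists = word_lists)
  dict_surf <- dictionary_surfaces(dict)
  ann <- corpus$annotations
  occ <- list(); meaning <- list(); nested <- list(); super <- list()
  for (id in corpus$documents$doc_id) {
    text <- doc_text(corpus, id)
    da <- ann[ann$doc_id == id, , drop = FALSE]
    if (!nrow(da)) next
    da$norm <- normalize_surface(da$surface)
    for (s in unique(da$norm)) {
      n_occ <- count_occurrences(text, s)
      n_ann <- sum(da$norm == s)
      if (n_occ > n_ann) {
        occ[[length(occ) + 1L]] <- data.frame(
          doc_id = id, surface = s, occurrences = n_occ, annotated = n_ann,
          stringsAsFactors = FALSE)
      }
    }
    unknown <- !(da$norm %in% dict_surf)
    if (any(unknown)) {
      meaning[[length(meaning) + 1L]] <-
        cbind(da[unknown, c("doc_id", "start", "end", "hpo_id", "surface")])
    }
    span_keys <- ann_key(da, with_id = FALSE)
    for (r in seq_len(nrow(da))) {
      inner <- dict_surf[dict_surf != da$norm[r]]
      inner <- inner[vapply(inner, function(x) {
        grepl(boundary_pattern(x), da$norm[r], perl = TRUE)
      }, logical(1))]
      for (x in inner) {
        # locate the nested occurrence inside this annotation's span
        seg <- tolower(substr0(text, da$start[r], da$end[r]))
        m <- regexpr(boundary_pattern(x), seg, perl = TRUE)
        if (m == -1L) next
        xs <- da$start[r] + as.integer(m) - 1L
        xe <- xs + attr(m, "match.length")
        key <- paste(id, xs, xe, sep = "\r")
        if (!(key %in% span_keys)) {
          nested[[length(nested) + 1L]] <- data.frame(
            doc_id = id, start = da$start[r], end = da$end[r],
            surface = da$surface[r], unannotated_inner = x,
            stringsAsFactors = FALSE)
        }
        # the same inner surface elsewhere in the document, unannotated
        mm <- gregexpr(boundary_pattern(x), tolower(text), perl = TRUE)[[1]]
        if (mm[1] != -1L) {
          for (k in seq_along(mm)) {
            os <- as.integer(mm[k]) - 1L
            oe <- os + attr(mm, "match.length")[k]
            if (os >= da$start[r] && oe <= da$end[r]) next
            okey <- paste(id, os, oe, sep = "\r")
            covered <- any(da$start <= os & da$end >= oe)
            if (!(okey %in% span_keys) && !covered) {
              super[[length(super) + 1L]] <- data.frame(
                doc_id = id, subclass = da$surface[r], superclass = x,
                start = os, end = oe, stringsAsFactors = FALSE)
              break
            }
          }
        }
      }
    }
  }
  bindf <- function(l, proto) {
    if (length(l)) unique(do.call(rbind, l)) else proto
  }
  structure(list(
    occurrence = bindf(occ, data.frame(doc_id = character(),
                                       surface = character(),
                                       occurrences = integer(),
                                       annotated = integer())),
    meaning = bindf(meaning, empty_annotations()),
    nested = bindf(nested, data.frame(doc_id = character(), start = integer(),
                                      end = integer(), surface = character(),
                                      unannotated_inner = character())),
    superclass = bindf(super, data.frame(doc_id = character(),
                                         subclass = character(),
                                         superclass = character(),
                                         start = integer(), end = integer()))),
    class = "inconsistency_report")
}

#' @export
print.inconsistency_report <- function(x, ...) {
  cat("<inconsistency_report>\n")
  for (nm in names(x)) cat("  ", nm, ": ", nrow(x[[nm]]), " suspect(s)\n",
                           sep = "")
  invisible(x)
}
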