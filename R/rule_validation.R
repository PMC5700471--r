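# Dictionary-plus-rules validation of CRF output.
#
# Two monotone phases: identification rules only ever ADD candidates
# (dictionary mentions, head-noun structures, boundary expansion over
# coordination, splitting of coordinated entities, then a single second
# pass over the enlarged entity list); removal rules only ever mark
# candidates removed (general errors, incorrect structure, negative
# connotation, stop words). Every removal records its reason so rule-level
# counts reconcile with before/after totals.

.noun_pos <- c("NN", "NNS", "NNP")
.nounish <- c("NN", "NNS", "NNP", "JJ")
.prepositions <- c("of", "in", "on", "at", "by", "with", "from", "for",
                   "to", "as", "into", "during", "without", "within")
.determiners <- c("the", "a", "an", "this", "that", "these", "those")

new_candidates <- function(doc_id = character(), start = integer(),
                           end = integer(), surface = character(),
                           hpo_id = character(), origin = character()) {
  data.frame(doc_id = doc_id, start = start, end = end, surface = surface,
             hpo_id = hpo_id, origin = origin,
             status = rep("active", length(start)),
             reason = rep(NA_character_, length(start)),
             stringsAsFactors = FALSE)
}

candidate_row <- function(doc_id, start, end, surface, origin,
                          hpo_id = NA_character_) {
  new_candidates(doc_id, as.integer(start), as.integer(end), surface,
                 hpo_id, origin)
}

# token indices of a sentence covered by a character span, or NULL when the
# span does not lie on token boundaries inside this sentence
span_tokens <- function(tokens, start, end) {
  idx <- which(tokens$start >= start & tokens$end <= end)
  if (!length(idx)) return(NULL)
  if (tokens$start[idx[1]] != start || tokens$end[idx[length(idx)]] != end) {
    return(NULL)
  }
  idx
}

is_cc <- function(tokens, i) tokens$pos[i] == "CC" || tokens$text[i] == ","

# maximal coordinated nominal run starting at token k; returns the index of
# the last noun reached, or NA when no noun occurs
scan_nominal_run <- function(tokens, k) {
  n <- nrow(tokens)
  last_noun <- NA_integer_
  p <- k
  while (p <= n) {
    if (tokens$pos[p] %in% .nounish) {
      if (tokens$pos[p] %in% .noun_pos) last_noun <- p
      p <- p + 1L
    } else if (is_cc(tokens, p)) {
      q <- p + 1L                     # ", and" = consecutive coordinators
      while (q <= n && is_cc(tokens, q)) q <- q + 1L
      if (q <= n && tokens$pos[q] %in% .nounish) p <- q else break
    } else {
      break
    }
  }
  last_noun
}

# match a multi-word connector phrase at token j; returns index after the
# connector or NA
match_connector <- function(tokens, j, connectors) {
  n <- nrow(tokens)
  for (cn in connectors[order(-lengths(strsplit(connectors, " ")))]) {
    cw <- strsplit(cn, " ", fixed = TRUE)[[1]]
    k <- j + length(cw) - 1L
    if (k <= n && all(tolower(tokens$text[j:k]) == cw)) return(k + 1L)
  }
  NA_integer_
}

#' Identification rule: entity variations
#'
#' Finds the structure `<common HPO noun> <connector> <nominal phrase>`,
#' where the nominal phrase may be a noun ("abnormalities of the ear") or a
#' coordinated adjective group ending in a noun ("defects of the outer,
#' middle, and inner ear").
#'
#' @param sentence a preprocessed sentence (list with `tokens`, `doc_id`).
#' @param word_lists a `word_lists`.
#' @param doc_text document text.
#' @return candidate data.frame (origin `"variation"`).
#' @export
rule_entity_variations <- function(sentence, word_lists, doc_text) {
  tokens <- sentence$tokens
  out <- list()
  n <- nrow(tokens)
  for (i in seq_len(n)) {
    if (!(tolower(tokens$text[i]) %in% word_lists$common_hpo_nouns)) next
    k <- match_connector(tokens, i + 1L, word_lists$connector_phrases)
    if (is.na(k) || k > n) next
    last_noun <- scan_nominal_run(tokens, k)
    if (is.na(last_noun)) next
    s <- tokens$start[i]; e <- tokens$end[last_noun]
    out[[length(out) + 1L]] <- candidate_row(
      sentence$doc_id, s, e, substr0(doc_text, s, e), "variation")
  }
  if (length(out)) do.call(rbind, out) else new_candidates()
}

#' Identification rule: longer entities
#'
#' Expands candidate boundaries across coordination in either direction:
#' a candidate preceded by `<noun/adjective> <and|,>` grows to cover it
#' ("rib anomalies" inside "spine and rib anomalies"), and symmetrically to
#' the right. The original candidate is retained alongside the expansion.
#'
#' @param sentence preprocessed sentence.
#' @param candidates current candidate data.frame (CRF + dictionary + rules).
#' @param doc_text document text.
#' @return new candidates only (origin `"expansion"`).
#' @export
rule_longer_entities <- function(sentence, candidates, doc_text) {
  tokens <- sentence$tokens
  n <- nrow(tokens)
  out <- list()
  act <- candidates[candidates$status == "active", , drop = FALSE]
  for (r in seq_len(nrow(act))) {
    idx <- span_tokens(tokens, act$start[r], act$end[r])
    if (is.null(idx)) next
    f <- idx[1]; l <- idx[length(idx)]
    # leftward over "<run> <and|,>" immediately before the candidate
    p <- f
    while (p - 2L >= 1L && is_cc(tokens, p - 1L) &&
           tokens$pos[p - 2L] %in% .nounish) {
      p <- p - 2L
      while (p - 1L >= 1L && tokens$pos[p - 1L] %in% .nounish) p <- p - 1L
    }
    # rightward over "<and|,> <run>" immediately after the candidate
    q <- l
    while (q + 2L <= n && is_cc(tokens, q + 1L) &&
           tokens$pos[q + 2L] %in% .nounish) {
      q <- q + 2L
      while (q + 1L <= n && tokens$pos[q + 1L] %in% .noun_pos) q <- q + 1L
    }
    if (p < f || q > l) {
      s <- tokens$start[p]; e <- tokens$end[q]
      out[[length(out) + 1L]] <- candidate_row(
        act$doc_id[r], s, e, substr0(doc_text, s, e), "expansion")
    }
  }
  if (length(out)) do.call(rbind, out) else new_candidates()
}

#' Identification rule: smaller entities
#'
#' Splits coordinated candidates into their component entities, keeping the
#' parent: tail coordination `"<head> <conn> <A> and <B>"` yields
#' `"<head> <conn> <A>"` (and, with `distribute`, `"<head> <conn> <B>"`);
#' head coordination `"<A> and <B> <noun>"` yields `"<B> <noun>"` (and, with
#' `distribute`, `"<A> <noun>"`). Candidates led by digit-only tokens also
#' shed them (the `"36 schwannomas"` -> `"schwannomas"` correction; the
#' digit-led parent is later dropped by [rule_incorrect_structure()]).
#'
#' @param sentence preprocessed sentence.
#' @param candidates current candidate data.frame.
#' @param word_lists a `word_lists`.
#' @param doc_text document text.
#' @param distribute also emit the distributed second form.
#' @return new candidates only (origin `"split"`).
#' @export
rule_smaller_entities <- function(sentence, candidates, word_lists, doc_text,
                                  distribute = TRUE) {
  tokens <- sentence$tokens
  out <- list()
  emit <- function(doc_id, i1, i2) {
    s <- tokens$start[i1]; e <- tokens$end[i2]
    out[[length(out) + 1L]] <<- candidate_row(
      doc_id, s, e, substr0(doc_text, s, e), "split")
  }
  act <- candidates[candidates$status == "active", , drop = FALSE]
  for (r in seq_len(nrow(act))) {
    idx <- span_tokens(tokens, act$start[r], act$end[r])
    if (is.null(idx) || length(idx) < 2L) next
    f <- idx[1]; l <- idx[length(idx)]
    # leading digit-only tokens
    lead <- f
    while (lead <= l && grepl("^[0-9]+$", tokens$text[lead])) lead <- lead + 1L
    if (lead > f && lead <= l) emit(act$doc_id[r], lead, l)
    # coordination inside the candidate
    ccs <- idx[vapply(idx, function(i) is_cc(tokens, i), logical(1))]
    ccs <- ccs[ccs > f & ccs < l]
    if (!length(ccs)) next
    cc <- max(ccs)  # rightmost coordination carries the final conjunct
    conn_end <- NA_integer_
    for (j in f:(cc - 1L)) {
      k <- match_connector(tokens, j, word_lists$connector_phrases)
      if (!is.na(k) && k <= cc) conn_end <- k - 1L
    }
    if (!is.na(conn_end) && conn_end < cc) {
      # tail coordination: head..connector fixed, conjuncts follow
      a_end <- cc - 1L
      while (a_end > conn_end && is_cc(tokens, a_end)) a_end <- a_end - 1L
      if (a_end > conn_end) emit(act$doc_id[r], f, a_end)
      if (distribute && cc + 1L <= l) {
        # "<head conn> <B>": head+connector span then the final conjunct
        s <- tokens$start[f]
        e1 <- tokens$end[conn_end]
        sB <- tokens$start[cc + 1L]; eB <- tokens$end[l]
        surf <- paste(substr0(doc_text, s, e1), substr0(doc_text, sB, eB))
        out[[length(out) + 1L]] <- candidate_row(
          act$doc_id[r], NA_integer_, NA_integer_, surf, "split")
      }
    } else {
      # head coordination: final conjunct + trailing head noun(s)
      if (cc + 1L <= l) emit(act$doc_id[r], cc + 1L, l)
      if (distribute) {
        # "<A> <headnoun>": first conjunct plus the final noun
        head_i <- l
        a_end <- cc - 1L
        while (a_end > f && is_cc(tokens, a_end)) a_end <- a_end - 1L
        if (a_end >= f && head_i > cc) {
          surf <- paste(substr0(doc_text, tokens$start[f], tokens$end[a_end]),
                        tokens$text[head_i])
          out[[length(out) + 1L]] <- candidate_row(
            act$doc_id[r], NA_integer_, NA_integer_, surf, "split")
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else new_candidates()
  # distributed forms have no contiguous span; anchor them to their own
  # occurrences in the document if any, else drop (span is the eval key)
  if (any(is.na(res$start))) {
    anchored <- list()
    for (r in which(is.na(res$start))) {
      m <- gregexpr(boundary_pattern(normalize_surface(res$surface[r])),
                    tolower(doc_text), perl = TRUE)[[1]]
      if (m[1] == -1L) next
      s <- as.integer(m[1]) - 1L
      anchored[[length(anchored) + 1L]] <- candidate_row(
        res$doc_id[r], s, s + attr(m, "match.length")[1],
        substr0(doc_text, s, s + attr(m, "match.length")[1]), "split")
    }
    res <- rbind(res[!is.na(res$start), , drop = FALSE],
                 if (length(anchored)) do.call(rbind, anchored))
  }
  res
}

# --- removal rules -------------------------------------------------------

mark_removed <- function(candidates, which, reason) {
  hit <- which & candidates$status == "active"
  candidates$status[hit] <- "removed"
  candidates$reason[hit] <- reason
  candidates
}

surface_words <- function(surface) {
  w <- regmatches(surface, gregexpr("[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^[:space:]]",
                                    surface, perl = TRUE))[[1]]
  w
}

#' Removal rule: general errors
#'
#' Removes digit-only surfaces, surfaces with unbalanced quotes or
#' parentheses, surfaces shorter than 3 characters, and surfaces containing
#' two or more common HPO nouns ("abnormalities and malformations").
#'
#' @param candidates candidate data.frame.
#' @param word_lists a `word_lists`.
#' @return candidates with removals marked.
#' @export
rule_general_errors <- function(candidates, word_lists) {
  s <- candidates$surface
  digit_only <- grepl("^[0-9 ]+$", s)
  candidates <- mark_removed(candidates, digit_only, "general:digits_only")
  nquote <- nchar(gsub("[^']", "", s)) %% 2 == 1
  ndq <- nchar(gsub('[^"]', "", s)) %% 2 == 1
  npar <- nchar(gsub("[^(]", "", s)) != nchar(gsub("[^)]", "", s))
  candidates <- mark_removed(candidates, nquote | ndq | npar,
                             "general:unbalanced")
  candidates <- mark_removed(candidates, nchar(s) < 3, "general:too_short")
  n_common <- vapply(s, function(x) {
    sum(tolower(surface_words(x)) %in% word_lists$common_hpo_nouns)
  }, integer(1))
  mark_removed(candidates, n_common >= 2, "general:multiple_common_nouns")
}

#' Removal rule: incorrect structure
#'
#' Removes candidates ending in a comma, a full stop, a preposition or a
#' determiner, and candidates starting with a digit-only token.
#'
#' @inheritParams rule_general_errors
#' @export
rule_incorrect_structure <- function(candidates, word_lists) {
  last_word <- vapply(candidates$surface, function(x) {
    w <- surface_words(x)
    if (length(w)) tolower(w[length(w)]) else ""
  }, character(1))
  first_word <- vapply(candidates$surface, function(x) {
    w <- surface_words(x)
    if (length(w)) w[1] else ""
  }, character(1))
  bad_end <- last_word %in% c(",", ".") |
    last_word %in% .prepositions | last_word %in% .determiners
  candidates <- mark_removed(candidates, bad_end, "structure:bad_ending")
  lead_digit <- grepl("^[0-9]+$", first_word) &
    lengths(lapply(candidates$surface, surface_words)) > 1L
  mark_removed(candidates, lead_digit, "structure:leading_digit")
}

#' Removal rule: negative connotation analysis
#'
#' Phenotype terms denote abnormalities; a two-token candidate containing a
#' noun with positive connotation ("cognitive development") cannot, by
#' itself, denote one. Longer candidates are never touched
#' ("cognitive development impairment" is kept).
#'
#' @inheritParams rule_general_errors
#' @export
rule_negative_connotation <- function(candidates, word_lists) {
  hit <- vapply(candidates$surface, function(x) {
    w <- tolower(surface_words(x))
    length(w) == 2L && any(w %in% word_lists$positive_connotation_nouns)
  }, logical(1))
  mark_removed(candidates, hit, "connotation:positive_pair")
}

#' Removal rule: stop words
#'
#' The exact list removes a candidate only when its whole (normalized)
#' surface equals a listed phrase; the partial list removes a candidate when
#' a listed phrase occurs anywhere inside it (word-boundary match).
#'
#' @inheritParams rule_general_errors
#' @export
rule_stop_words <- function(candidates, word_lists) {
  norm <- normalize_surface(candidates$surface)
  candidates <- mark_removed(candidates, norm %in% word_lists$stop_exact,
                             "stop:exact")
  if (length(word_lists$stop_partial)) {
    pat <- paste0("(", paste(vapply(word_lists$stop_partial, boundary_pattern,
                                    character(1)), collapse = ")|("), ")")
    hit <- grepl(pat, norm, perl = TRUE)
    candidates <- mark_removed(candidates, hit, "stop:partial")
  }
  candidates
}

#' Validation pipeline configuration
#'
#' @param identification,removal phase switches (the rule-ablation axes).
#' @param dictionary_mentions,entity_variations,longer_entities,
#'   smaller_entities,second_validation,general_errors,incorrect_structure,
#'   negative_connotation,stop_words individual rule switches.
#' @param distribute emit distributed conjunct forms when splitting.
#' @return a `validation_config` list.
#' @export
validation_config <- function(identification = TRUE, removal = TRUE,
                              dictionary_mentions = TRUE,
                              entity_variations = TRUE,
                              longer_entities = TRUE,
                              smaller_entities = TRUE,
                              second_validation = TRUE,
                              general_errors = TRUE,
                              incorrect_structure = TRUE,
                              negative_connotation = TRUE,
                              stop_words = TRUE,
                              distribute = TRUE) {
  structure(as.list(environment()), class = "validation_config")
}

run_identification_pass <- function(candidates, sentences, word_lists,
                                    doc_text, config, origin_override = NULL) {
  relabel <- function(df) {
    if (!is.null(origin_override) && nrow(df)) df$origin <- origin_override
    df
  }
  for (sent in sentences) {
    if (isTRUE(config$entity_variations)) {
      candidates <- rbind(candidates,
                          relabel(rule_entity_variations(sent, word_lists,
                                                         doc_text)))
    }
    if (isTRUE(config$longer_entities)) {
      candidates <- rbind(candidates,
                          relabel(rule_longer_entities(sent, candidates,
                                                       doc_text)))
    }
    if (isTRUE(config$smaller_entities)) {
      candidates <- rbind(candidates,
                          relabel(rule_smaller_entities(sent, candidates,
                                                        word_lists, doc_text,
                                                        config$distribute)))
    }
  }
  candidates
}

dedupe_candidates <- function(candidates) {
  key <- paste(candidates$start, candidates$end)
  candidates[!duplicated(key), , drop = FALSE]
}

#' Validate CRF predictions for one document
#'
#' Runs the full pipeline in its defined order: dictionary mentions ->
#' entity variations -> longer entities -> smaller entities -> one second
#' identification pass over the enlarged entity list -> general errors ->
#' incorrect structure -> negative connotation -> stop words. Candidates are
#' deduplicated by span (earliest phase wins); removed candidates stay in
#' the audit trail with their reason. Identification-only and removal-only
#' modes support the rule-ablation experiment.
#'
#' @param predictions data.frame of CRF spans (`start`, `end`, `surface`).
#' @param doc_text document text.
#' @param doc_id document id.
#' @param dictionary the per-fold `hpo_dictionary` (must exclude test-fold
#'   annotations).
#' @param word_lists a `word_lists`.
#' @param config a [validation_config()].
#' @param sentences optional preprocessed sentences (recomputed if NULL).
#' @return list with `entities` (active candidates) and `audit` (all
#'   candidates incl. removals).
#' @export
validate <- function(predictions, doc_text, doc_id,
                     dictionary = NULL, word_lists = default_word_lists(),
                     config = validation_config(), sentences = NULL) {
  if (is.null(sentences)) sentences <- preprocess_document(doc_text, doc_id)
  n_pred <- if (is.null(predictions)) 0L else nrow(predictions)
  candidates <- if (n_pred) {
    new_candidates(rep(doc_id, n_pred), as.integer(predictions$start),
                   as.integer(predictions$end), predictions$surface,
                   rep(NA_character_, n_pred), rep("crf", n_pred))
  } else {
    new_candidates()
  }
  if (isTRUE(config$identification)) {
    if (isTRUE(config$dictionary_mentions) && !is.null(dictionary)) {
      dm <- find_dictionary_mentions(doc_text, dictionary)
      dm <- dm[!duplicated(paste(dm$start, dm$end)), , drop = FALSE]
      if (nrow(dm)) {
        candidates <- rbind(candidates,
                            new_candidates(rep(doc_id, nrow(dm)), dm$start,
                                           dm$end, dm$surface, dm$hpo_id,
                                           rep("dictionary", nrow(dm))))
      }
    }
    candidates <- run_identification_pass(candidates, sentences, word_lists,
                                          doc_text, config)
    if (isTRUE(config$second_validation)) {
      candidates <- run_identification_pass(candidates, sentences, word_lists,
                                            doc_text, config,
                                            origin_override = "second_pass")
    }
  }
  candidates <- dedupe_candidates(candidates)
  if (isTRUE(config$removal)) {
    if (isTRUE(config$general_errors)) {
      candidates <- rule_general_errors(candidates, word_lists)
    }
    if (isTRUE(config$incorrect_structure)) {
      candidates <- rule_incorrect_structure(candidates, word_lists)
    }
    if (isTRUE(config$negative_connotation)) {
      candidates <- rule_negative_connotation(candidates, word_lists)
    }
    if (isTRUE(config$stop_words)) {
      candidates <- rule_stop_words(candidates, word_lists)
    }
  }
  # attach ids by dictionary lookup where missing (best effort)
  if (!is.null(dictionary) && nrow(candidates)) {
    need <- which(is.na(candidates$hpo_id) | !nzchar(candidates$hpo_id))
    for (r in need) {
      ids <- dictionary_lookup(dictionary, candidates$surface[r])
      if (length(ids)) candidates$hpo_id[r] <- ids[1]
    }
  }
  rownames(candidates) <- NULL
  list(entities = candidates[candidates$status == "active", , drop = FALSE],
       audit = candidates)
}

#' Write a validation audit trail as TSV
#'
#' @param audit the `audit` component of [validate()].
#' @param path output file.
#' @export
write_audit <- function(audit, path) {
  utils::write.table(audit[c("doc_id", "start", "end", "surface", "hpo_id",
                             "origin", "status", "reason")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
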