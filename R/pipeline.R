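# End-to-end pipeline: corpus -> preprocessing -> features -> CRF (k-fold
# cross-validation) -> rule validation -> exact-span scores; plus the
# feature-ablation, rule-ablation and false-positive-filter experiments.

# small English function-word list feeding the lexical (stop-word) feature
.stopwords_en <- c("the", "a", "an", "of", "in", "on", "at", "by", "with",
                   "and", "or", "but", "to", "for", "from", "as", "was",
                   "were", "is", "are", "be", "been", "this", "that",
                   "these", "those", "it", "its", "not", "no", "during",
                   "into", "over", "after", "before")

# preprocess every document once; returns named list doc_id -> sentences
preprocess_corpus <- function(corpus) {
  out <- lapply(seq_len(nrow(corpus$documents)), function(i) {
    preprocess_document(corpus$documents$text[i], corpus$documents$doc_id[i])
  })
  setNames(out, corpus$documents$doc_id)
}

# labeled feature sequences for a set of documents
build_sequences <- function(corpus, pre, doc_ids, feature_cfg,
                            stop_list = .stopwords_en) {
  seqs <- list()
  for (id in doc_ids) {
    ann <- corpus$annotations[corpus$annotations$doc_id == id, , drop = FALSE]
    for (sent in pre[[id]]) {
      if (!nrow(sent$tokens)) next
      seqs[[length(seqs) + 1L]] <- list(
        doc_id = id, sentence = sent,
        features = sentence_features(sent$tokens, feature_cfg, stop_list),
        labels = as.character(encode_bio(sent$tokens, ann)))
    }
  }
  seqs
}

decode_predictions <- function(seqs, labels, corpus) {
  out <- list()
  for (i in seq_along(seqs)) {
    id <- seqs[[i]]$doc_id
    spans <- decode_bio(seqs[[i]]$sentence$tokens, labels[[i]],
                        doc_text(corpus, id))
    if (nrow(spans)) {
      spans$doc_id <- id
      out[[length(out) + 1L]] <- spans
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), surface = character(),
               doc_id = character(), stringsAsFactors = FALSE)
}

#' Run the full pipeline under document-level cross-validation
#'
#' For each fold: a CRF is trained on the training documents' labeled
#' sequences, applied to the held-out documents, and its decoded spans are
#' passed through the validation stage with a dictionary built ONLY from
#' the ontology and the training fold's annotations (test-fold annotations
#' never enter a rule). Predictions are pooled over folds (each document is
#' predicted exactly once) and scored against the gold annotations.
#'
#' @param corpus a `gsc_corpus`.
#' @param ontology an `hpo_ontology` (NULL disables the dictionary).
#' @param word_lists a `word_lists`.
#' @param feature_cfg a [feature_config()]. When its `brown_clusters` slot
#'   is NULL and the `other` family is on, clusters are trained on the
#'   corpus text (unsupervised; no label leakage).
#' @param crf_cfg a [crf_config()].
#' @param val_cfg a [validation_config()]; `NULL` skips validation entirely
#'   (raw CRF output is scored).
#' @param k,seed fold plan parameters.
#' @param folds restrict to a subset of fold indices (e.g. `1L` for the
#'   single-iteration ablation protocol); scores then cover those folds'
#'   documents only.
#' @return list with `score` (pooled `ner_score`), `per_fold`,
#'   `crf_predictions`, `entities` (post-validation), `fold_plan`.
#' @export
run_crossvalidation <- function(corpus, ontology = NULL,
                                word_lists = default_word_lists(),
                                feature_cfg = feature_config(),
                                crf_cfg = crf_config(),
                                val_cfg = validation_config(),
                                k = 10L, seed = 42L, folds = NULL) {
  pre <- preprocess_corpus(corpus)
  if (isTRUE(feature_cfg$other) && is.null(feature_cfg$brown_clusters)) {
    toks <- unlist(lapply(pre, function(sents) {
      lapply(sents, function(s) s$tokens$text)
    }), recursive = FALSE)
    feature_cfg$brown_clusters <- brown_clusters(toks)
  }
  plan <- make_folds(corpus$documents$doc_id, k = k, seed = seed)
  use_folds <- if (is.null(folds)) seq_len(plan$k) else as.integer(folds)
  all_crf <- list(); all_ent <- list(); per_fold <- list()
  for (f in use_folds) {
    test_ids <- names(plan$assignment)[plan$assignment == f]
    train_ids <- setdiff(corpus$documents$doc_id, test_ids)
    train_seqs <- build_sequences(corpus, pre, train_ids, feature_cfg)
    test_seqs <- build_sequences(corpus, pre, test_ids, feature_cfg)
    model <- crf_train(train_seqs, crf_cfg)
    labels <- crf_predict(model, test_seqs)
    crf_pred <- decode_predictions(test_seqs, labels, corpus)
    all_crf[[f]] <- crf_pred
    if (!is.null(val_cfg)) {
      dict <- if (!is.null(ontology)) {
        train_ann <- corpus$annotations[
          corpus$annotations$doc_id %in% train_ids, , drop = FALSE]
        build_dictionary(ontology, train_ann, generate = TRUE,
                         word_lists = word_lists)
      }
      ents <- lapply(test_ids, function(id) {
        validate(crf_pred[crf_pred$doc_id == id, , drop = FALSE],
                 doc_text(corpus, id), id, dict, word_lists, val_cfg,
                 sentences = pre[[id]])$entities
      })
      ents <- do.call(rbind, ents)
    } else {
      ents <- crf_pred
      ents$doc_id <- ents$doc_id
    }
    all_ent[[f]] <- ents
    gold_f <- corpus$annotations[corpus$annotations$doc_id %in% test_ids, ,
                                 drop = FALSE]
    per_fold[[f]] <- score_entities(ents, gold_f)
  }
  entities <- do.call(rbind, all_ent)
  crf_predictions <- do.call(rbind, all_crf)
  covered <- names(plan$assignment)[plan$assignment %in% use_folds]
  gold <- corpus$annotations[corpus$annotations$doc_id %in% covered, ,
                             drop = FALSE]
  list(score = score_entities(entities, gold),
       per_fold = per_fold[use_folds],
       crf_predictions = crf_predictions,
       entities = entities, fold_plan = plan, gold = gold)
}

.family_flags <- c("linguistic", "orthographic", "morphological", "context",
                   "lexical", "other")

family_config <- function(families) {
  flags <- setNames(as.list(.family_flags %in% families), .family_flags)
  do.call(feature_config, flags)
}

#' Feature-ablation experiment
#'
#' Reproduces the single-iteration protocol: each feature family is scored
#' individually on one cross-validation fold, then cumulatively in the
#' fixed order linguistic, orthographic, morphological, context, lexical,
#' other. The baseline row uses the current token text only.
#'
#' @inheritParams run_crossvalidation
#' @param fold which fold to use (single iteration).
#' @return data.frame with columns `condition`, `precision`, `recall`,
#'   `f_measure`.
#' @export
feature_ablation <- function(corpus, ontology = NULL,
                             word_lists = default_word_lists(),
                             crf_cfg = crf_config(), k = 10L, seed = 42L,
                             fold = 1L) {
  conditions <- c(list(baseline = character()),
                  setNames(as.list(.family_flags), .family_flags),
                  lapply(seq_along(.family_flags)[-1], function(i) {
                    .family_flags[seq_len(i)]
                  }))
  names(conditions)[(length(.family_flags) + 2L):length(conditions)] <-
    vapply(seq_along(.family_flags)[-1], function(i) {
      paste(.family_flags[seq_len(i)], collapse = "+")
    }, character(1))
  rows <- lapply(names(conditions), function(nm) {
    cfg <- family_config(conditions[[nm]])
    res <- run_crossvalidation(corpus, ontology, word_lists, cfg, crf_cfg,
                               val_cfg = NULL, k = k, seed = seed,
                               folds = fold)
    data.frame(condition = nm, precision = res$score$precision,
               recall = res$score$recall, f_measure = res$score$f_measure,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rule-ablation experiment
#'
#' Scores the pipeline under the four validation conditions: no rules,
#' identification rules only, removal rules only, all rules.
#'
#' @inheritParams run_crossvalidation
#' @return data.frame with one row per condition.
#' @export
rule_ablation <- function(corpus, ontology, word_lists = default_word_lists(),
                          feature_cfg = feature_config(),
                          crf_cfg = crf_config(), k = 10L, seed = 42L,
                          folds = NULL) {
  conds <- list(
    no_rules = validation_config(identification = FALSE, removal = FALSE),
    identification_only = validation_config(removal = FALSE),
    removal_only = validation_config(identification = FALSE),
    all_rules = validation_config())
  rows <- lapply(names(conds), function(nm) {
    res <- run_crossvalidation(corpus, ontology, word_lists, feature_cfg,
                               crf_cfg, conds[[nm]], k = k, seed = seed,
                               folds = folds)
    data.frame(condition = nm, precision = res$score$precision,
               recall = res$score$recall, f_measure = res$score$f_measure,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' False-positive-filter experiment
#'
#' Scores a prediction set before and after removing predictions that are
#' absent from the gold annotations but present in a phenotype dictionary
#' built from the ontology plus the corpus annotations (the
#' under-annotation probe). Recall is identical in both rows by
#' construction.
#'
#' @param predictions prediction data.frame (`doc_id`, `start`, `end`,
#'   `surface`).
#' @param corpus the gold `gsc_corpus`.
#' @param ontology an `hpo_ontology`.
#' @param word_lists a `word_lists`.
#' @return data.frame with rows `no_filter` and `with_filter`.
#' @export
fp_filter_experiment <- function(predictions, corpus, ontology,
                                 word_lists = default_word_lists()) {
  dict <- build_dictionary(ontology, corpus$annotations, generate = TRUE,
                           word_lists = word_lists)
  gold <- corpus$annotations
  before <- score_entities(predictions, gold)
  filtered <- filter_false_positives(predictions, gold, dict)
  after <- score_entities(filtered, gold)
  data.frame(
    condition = c("no_filter", "with_filter"),
    precision = c(before$precision, after$precision),
    recall = c(before$recall, after$recall),
    f_measure = c(before$f_measure, after$f_measure),
    stringsAsFactors = FALSE)
}
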