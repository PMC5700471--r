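# CRF training / prediction and cross-validation fold planning.

#' CRF training configuration
#'
#' Defaults follow the published setup: stochastic gradient descent with an
#' L2 term (`l2sgd`), L1 coefficient 0.9833, L2 coefficient 1, and all
#' states/transitions parameterised (`possible_states` and
#' `possible_transitions` on). With only the B/I/O label alphabet the two
#' `possible_*` switches are saturated — every state and transition weight
#' exists regardless — so they are recorded but have no further effect.
#'
#' @param algorithm only `"l2sgd"` is provided.
#' @param c1,c2 L1 / L2 regularization coefficients (>= 0).
#' @param possible_states,possible_transitions recorded for fidelity.
#' @param max_iterations SGD epochs.
#' @param eta0 initial SGD learning rate.
#' @param epsilon relative loss-change stopping threshold.
#' @param seed RNG seed for the epoch shuffles.
#' @return a `crf_config` list.
#' @export
crf_config <- function(algorithm = "l2sgd", c1 = 0.9833, c2 = 1,
                       possible_states = TRUE, possible_transitions = TRUE,
                       max_iterations = 60L, eta0 = 0.3, epsilon = 1e-5,
                       seed = 42L) {
  stopifnot(identical(algorithm, "l2sgd"), c1 >= 0, c2 >= 0,
            max_iterations >= 1)
  structure(list(algorithm = algorithm, c1 = c1, c2 = c2,
                 possible_states = possible_states,
                 possible_transitions = possible_transitions,
                 max_iterations = as.integer(max_iterations),
                 eta0 = eta0, epsilon = epsilon, seed = as.integer(seed)),
            class = "crf_config")
}

BIO_LABELS <- c("B", "I", "O")

#' Train the linear-chain CRF
#'
#' @param sequences list of labeled sequences; each element is a list with
#'   `features` (list of character vectors, one per token) and `labels`
#'   (character vector over `{B, I, O}`).
#' @param config a [crf_config()].
#' @return a `crf_model`: attribute vocabulary, weight matrices and the
#'   training loss log.
#' @export
crf_train <- function(sequences, config = crf_config()) {
  sequences <- Filter(function(s) length(s$labels) > 0, sequences)
  if (!length(sequences)) stop("empty training data", call. = FALSE)
  labs <- unlist(lapply(sequences, `[[`, "labels"))
  bad <- setdiff(unique(labs), BIO_LABELS)
  if (length(bad)) stop("labels outside {B,I,O}: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (length(unique(labs)) == 1L) {
    warning("degenerate training data: only label ",
            sQuote(unique(labs)), " observed", call. = FALSE)
  }
  attrs <- unique(unlist(lapply(sequences, function(s) unlist(s$features))))
  feat_seqs <- lapply(sequences, function(s) {
    lapply(s$features, function(f) match(f, attrs) - 1L)
  })
  label_seqs <- lapply(sequences, function(s) {
    match(s$labels, BIO_LABELS) - 1L
  })
  fit <- .crf_train_cpp(feat_seqs, label_seqs, length(attrs),
                        length(BIO_LABELS), config$c1, config$c2,
                        config$max_iterations, config$eta0, config$seed,
                        config$epsilon)
  structure(list(attrs = attrs, labels = BIO_LABELS, state = fit$state,
                 trans = fit$trans, init = fit$init, final = fit$final,
                 loss = fit$loss, config = config),
            class = "crf_model")
}

#' @export
print.crf_model <- function(x, ...) {
  cat("<crf_model> ", length(x$attrs), " attributes, ",
      length(x$loss), " epochs, final loss ",
      formatC(tail(x$loss, 1), digits = 4, format = "g"), "\n", sep = "")
  invisible(x)
}

#' Predict BIO labels with a trained CRF
#'
#' Attributes unseen at training time are dropped. The Viterbi output is
#' already a valid label sequence but is passed through the same BIO repair
#' as any external labeling when decoded.
#'
#' @param model a `crf_model`.
#' @param sequences list of sequences (`features` as in [crf_train()]).
#' @return list of character label vectors.
#' @export
crf_predict <- function(model, sequences) {
  stopifnot(inherits(model, "crf_model"))
  lapply(sequences, function(s) {
    if (!length(s$features)) return(character())
    ids <- lapply(s$features, function(f) {
      m <- match(f, model$attrs) - 1L
      m[!is.na(m)]
    })
    y <- .crf_viterbi_cpp(ids, model$state, model$trans, model$init,
                          model$final)
    model$labels[y + 1L]
  })
}

#' Save / load a CRF model
#'
#' @param model a `crf_model`.
#' @param path file path.
#' @export
crf_save <- function(model, path) {
  stopifnot(inherits(model, "crf_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname crf_save
#' @export
crf_load <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "crf_model"))
  m
}

#' Plan a document-level k-fold cross-validation
#'
#' Folds partition documents (never sentences), preventing train/test
#' leakage within an abstract; fold sizes differ by at most one and the
#' assignment is deterministic given the seed.
#'
#' @param doc_ids character vector of document ids.
#' @param k number of folds.
#' @param seed RNG seed.
#' @return a `fold_plan`: list with `k`, `seed` and `assignment`
#'   (named integer vector, doc_id -> fold).
#' @export
make_folds <- function(doc_ids, k = 10L, seed = 42L) {
  doc_ids <- unique(doc_ids)
  if (k > length(doc_ids)) {
    stop("k = ", k, " exceeds the number of documents (", length(doc_ids),
         ")", call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(doc_ids))
  assignment <- setNames(rep(seq_len(k), length.out = length(shuffled)),
                         shuffled)[doc_ids]
  structure(list(k = as.integer(k), seed = as.integer(seed),
                 assignment = assignment),
            class = "fold_plan")
}

#' Brown-style word clusters from a token corpus
#'
#' Greedy agglomerative clustering of the corpus vocabulary that merges the
#' pair of word classes losing the least average mutual information of the
#' class bigram distribution; every word receives the bit-string path of its
#' class in the merge tree. Trained on the corpus at build time.
#'
#' @param sentences list of character vectors (token texts per sentence) or
#'   of token data.frames.
#' @param n_clusters working number of classes (default 50).
#' @param min_count drop words rarer than this from clustering.
#' @return named character vector, lower-cased word -> bit path.
#' @export
brown_clusters <- function(sentences, n_clusters = 50L, min_count = 1L) {
  toks <- lapply(sentences, function(s) {
    w <- if (is.data.frame(s)) s$text else s
    tolower(w[grepl("[a-z0-9]", tolower(w))])
  })
  counts <- sort(table(unlist(toks)), decreasing = TRUE)
  counts <- counts[counts >= min_count]
  vocab <- names(counts)
  if (!length(vocab)) return(setNames(character(), character()))
  id_seqs <- lapply(toks, function(w) match(w, vocab) - 1L)
  id_seqs <- lapply(id_seqs, function(v) v[!is.na(v)])
  paths <- .brown_cluster_cpp(id_seqs, length(vocab), as.integer(n_clusters))
  setNames(as.character(paths), vocab)
}
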