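# Per-token feature extraction for the CRF, plus BIO label projection.
#
# Six switchable families: linguistic (lemma, POS of the current token),
# orthographic (word case, symbol presence), morphological (prefixes 2-3,
# suffixes 1-4, word shape, character bigrams), context (lemma +/-2,
# POS +/-4, shape +/-2, neighbour prefixes/suffixes +/-1), lexical
# (stop words within +/-4) and other (Brown cluster path, length class).
# The current-token text is always emitted and constitutes the baseline.

#' Feature configuration
#'
#' Window size `w` for a context feature means offsets `-w..+w` excluding 0;
#' the current token is covered by the corresponding non-context family. The
#' lexical stop-word window includes offset 0 (no non-context stop-word
#' feature exists). Positions beyond the sentence emit boundary sentinels.
#'
#' @param linguistic,orthographic,morphological,context,lexical,other
#'   family on/off switches.
#' @param prefix_lengths,suffix_lengths affix lengths for the current token.
#' @param lemma_window,pos_window,shape_window,affix_window,stopword_window
#'   context window sizes.
#' @param affix_prefix_lengths,affix_suffix_lengths affix lengths used for
#'   neighbouring tokens (the context family).
#' @param length_breaks upper bounds of the token-length classes
#'   (1, 2-3, 4-6, 7-10, 11+).
#' @param brown_clusters optional named integer-path map from
#'   [brown_clusters()]; `NULL` disables the cluster feature.
#' @return a `feature_config` list.
#' @export
feature_config <- function(linguistic = TRUE, orthographic = TRUE,
                           morphological = TRUE, context = TRUE,
                           lexical = TRUE, other = TRUE,
                           prefix_lengths = 2:3, suffix_lengths = 1:4,
                           lemma_window = 2L, pos_window = 4L,
                           shape_window = 2L, affix_window = 1L,
                           affix_prefix_lengths = c(1L, 4L),
                           affix_suffix_lengths = c(1L, 4L),
                           stopword_window = 4L,
                           length_breaks = c(1L, 3L, 6L, 10L),
                           brown_clusters = NULL) {
  stopifnot(lemma_window >= 0, pos_window >= 0, shape_window >= 0,
            affix_window >= 0, stopword_window >= 0,
            all(diff(length_breaks) > 0))
  structure(list(linguistic = linguistic, orthographic = orthographic,
                 morphological = morphological, context = context,
                 lexical = lexical, other = other,
                 prefix_lengths = prefix_lengths,
                 suffix_lengths = suffix_lengths,
                 lemma_window = lemma_window, pos_window = pos_window,
                 shape_window = shape_window, affix_window = affix_window,
                 affix_prefix_lengths = affix_prefix_lengths,
                 affix_suffix_lengths = affix_suffix_lengths,
                 stopword_window = stopword_window,
                 length_breaks = length_breaks,
                 brown_clusters = brown_clusters),
            class = "feature_config")
}

#' Baseline configuration: current token text only
#' @export
baseline_config <- function() {
  feature_config(linguistic = FALSE, orthographic = FALSE,
                 morphological = FALSE, context = FALSE, lexical = FALSE,
                 other = FALSE)
}

#' Word shape of a token
#'
#' Upper-case letters map to `X`, lower-case to `x`, digits to `d`; any other
#' character is kept verbatim. The collapsed variant squeezes runs of the
#' same symbol.
#'
#' @param text non-empty token text.
#' @return named character vector with elements `shape` and `collapsed`.
#' @examples
#' word_shape("HP_0000077")  # "XX_ddddddd", collapsed "X_d"
#' @export
word_shape <- function(text) {
  stopifnot(nzchar(text))
  shape <- chartr(paste0(paste(LETTERS, collapse = ""),
                         paste(letters, collapse = ""), "0123456789"),
                  paste0(strrep("X", 26), strrep("x", 26), strrep("d", 10)),
                  text)
  c(shape = shape, collapsed = gsub("(.)\\1+", "\\1", shape))
}

word_case <- function(text) {
  if (grepl("^[A-Z]+$", text)) "upper"
  else if (grepl("^[a-z]+$", text)) "lower"
  else if (grepl("^[A-Z][a-z]+$", text)) "title"
  else if (grepl("[A-Za-z]", text)) "mixed"
  else "none"
}

.symbol_flags <- c(digit = "[0-9]", lbracket = "\\[", rbracket = "\\]",
                   slash = "/", dash = "-", quote = "'", dquote = '"',
                   lparen = "\\(", rparen = "\\)")

char_bigrams <- function(text) {
  if (nchar(text) < 2) return(character())
  unique(substring(text, 1:(nchar(text) - 1), 2:nchar(text)))
}

length_class <- function(n, breaks) {
  i <- findInterval(n, c(-Inf, breaks))
  labs <- c(paste0("<=", breaks), paste0(">", breaks[length(breaks)]))
  labs[i]
}

# safe accessor: out-of-sentence positions yield the boundary sentinel
.ctx <- function(v, i, sentinel = "_BOS_", sentinel_r = "_EOS_") {
  n <- length(v)
  if (i < 1L) sentinel else if (i > n) sentinel_r else v[i]
}

#' Features of one token in a sentence
#'
#' @param tokens the sentence's token data.frame (from [tokenize_and_tag()]).
#' @param index 1-based token position.
#' @param config a [feature_config()].
#' @param stop_list character vector of stop words (lower-case).
#' @return character vector of `name=value` attribute strings.
#' @export
token_features <- function(tokens, index, config = feature_config(),
                           stop_list = character()) {
  stopifnot(index >= 1L, index <= nrow(tokens))
  txt <- tokens$text[index]
  feats <- paste0("w=", txt)

  if (isTRUE(config$linguistic)) {
    feats <- c(feats, paste0("lemma=", tokens$lemma[index]),
               paste0("pos=", tokens$pos[index]))
  }
  if (isTRUE(config$orthographic)) {
    feats <- c(feats, paste0("case=", word_case(txt)))
    present <- vapply(.symbol_flags, function(p) grepl(p, txt), logical(1))
    feats <- c(feats, paste0("sym_", names(.symbol_flags)[present]))
  }
  if (isTRUE(config$morphological)) {
    nc <- nchar(txt)
    for (l in config$prefix_lengths) {
      if (nc >= l) feats <- c(feats, paste0("pre", l, "=", substr(txt, 1, l)))
    }
    for (l in config$suffix_lengths) {
      if (nc >= l) feats <- c(feats, paste0("suf", l, "=",
                                            substr(txt, nc - l + 1, nc)))
    }
    sh <- word_shape(txt)
    feats <- c(feats, paste0("shape=", sh[["shape"]]),
               paste0("shapec=", sh[["collapsed"]]),
               paste0("bg=", char_bigrams(txt)))
  }
  if (isTRUE(config$context)) {
    for (off in setdiff(-config$lemma_window:config$lemma_window, 0L)) {
      feats <- c(feats, paste0("lemma[", off, "]=",
                               .ctx(tokens$lemma, index + off)))
    }
    for (off in setdiff(-config$pos_window:config$pos_window, 0L)) {
      feats <- c(feats, paste0("pos[", off, "]=",
                               .ctx(tokens$pos, index + off)))
    }
    for (off in setdiff(-config$shape_window:config$shape_window, 0L)) {
      t2 <- .ctx(tokens$text, index + off)
      sh <- if (t2 %in% c("_BOS_", "_EOS_")) t2 else
        word_shape(t2)[["shape"]]
      feats <- c(feats, paste0("shape[", off, "]=", sh))
    }
    for (off in setdiff(-config$affix_window:config$affix_window, 0L)) {
      t2 <- .ctx(tokens$text, index + off)
      if (t2 %in% c("_BOS_", "_EOS_")) {
        feats <- c(feats, paste0("affix[", off, "]=", t2))
      } else {
        nc2 <- nchar(t2)
        for (l in config$affix_prefix_lengths) {
          if (nc2 >= l) feats <- c(feats, paste0("pre", l, "[", off, "]=",
                                                 substr(t2, 1, l)))
        }
        for (l in config$affix_suffix_lengths) {
          if (nc2 >= l) feats <- c(feats, paste0("suf", l, "[", off, "]=",
                                                 substr(t2, nc2 - l + 1, nc2)))
        }
      }
    }
  }
  if (isTRUE(config$lexical) && length(stop_list)) {
    for (off in -config$stopword_window:config$stopword_window) {
      t2 <- .ctx(tokens$text, index + off)
      if (!(t2 %in% c("_BOS_", "_EOS_")) && tolower(t2) %in% stop_list) {
        feats <- c(feats, paste0("stop[", off, "]"))
      }
    }
  }
  if (isTRUE(config$other)) {
    feats <- c(feats, paste0("lenclass=",
                             length_class(nchar(txt), config$length_breaks)))
    bc <- config$brown_clusters
    if (!is.null(bc)) {
      path <- bc[tolower(txt)]
      if (!is.na(path)) {
        feats <- c(feats, paste0("brown=", path),
                   paste0("brown4=", substr(path, 1, 4)),
                   paste0("brown6=", substr(path, 1, 6)))
      }
    }
  }
  feats
}

#' Features for every token of a sentence
#'
#' @inheritParams token_features
#' @return list of character vectors, one per token.
#' @export
sentence_features <- function(tokens, config = feature_config(),
                              stop_list = character()) {
  lapply(seq_len(nrow(tokens)), token_features, tokens = tokens,
         config = config, stop_list = stop_list)
}

#' Project character-offset annotations onto BIO token labels
#'
#' A token is covered by an annotation when their spans overlap; gold spans
#' that cross token boundaries are extended to the covering tokens (recall
#' preserving), and such misalignments are counted in the `"misaligned"`
#' attribute. Overlapping annotations are resolved longest-span-first (a CRF
#' cannot emit overlapping labels; nested mentions are recovered later by the
#' validation rules).
#'
#' @param tokens sentence token data.frame.
#' @param annotations annotation data.frame (`start`, `end` document offsets).
#' @return character vector of labels in `{B, I, O}`, one per token.
#' @export
encode_bio <- function(tokens, annotations) {
  n <- nrow(tokens)
  labels <- rep("O", n)
  misaligned <- 0L
  if (n == 0L || is.null(annotations) || nrow(annotations) == 0L) {
    attr(labels, "misaligned") <- misaligned
    return(labels)
  }
  ord <- order(-(annotations$end - annotations$start), annotations$start)
  for (k in ord) {
    a_s <- annotations$start[k]; a_e <- annotations$end[k]
    cover <- which(tokens$start < a_e & tokens$end > a_s)
    if (!length(cover)) next
    if (any(labels[cover] != "O")) next  # longest span wins
    if (tokens$start[cover[1]] != a_s || tokens$end[cover[length(cover)]] != a_e) {
      misaligned <- misaligned + 1L
    }
    labels[cover[1]] <- "B"
    if (length(cover) > 1L) labels[cover[-1]] <- "I"
  }
  attr(labels, "misaligned") <- misaligned
  labels
}

#' Recover entity spans from BIO labels
#'
#' A stray `I` after `O` (or at sentence start) is repaired to `B` before
#' decoding; repairs are counted in the `"repaired"` attribute.
#'
#' @param tokens sentence token data.frame.
#' @param labels character vector of `{B, I, O}`.
#' @param doc_text full document text (for surface extraction).
#' @return data.frame with `start`, `end`, `surface`.
#' @export
decode_bio <- function(tokens, labels, doc_text) {
  stopifnot(nrow(tokens) == length(labels))
  repaired <- 0L
  lab <- as.character(labels)
  prev <- "O"
  for (i in seq_along(lab)) {
    if (lab[i] == "I" && prev == "O") {
      lab[i] <- "B"
      repaired <- repaired + 1L
    }
    prev <- lab[i]
  }
  starts <- which(lab == "B")
  out <- lapply(starts, function(s) {
    e <- s
    while (e < length(lab) && lab[e + 1L] == "I") e <- e + 1L
    data.frame(start = tokens$start[s], end = tokens$end[e],
               surface = substr0(doc_text, tokens$start[s], tokens$end[e]),
               stringsAsFactors = FALSE)
  })
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), surface = character(),
               stringsAsFactors = FALSE)
  attr(res, "repaired") <- repaired
  res
}
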