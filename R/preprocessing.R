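# Sentence splitting, tokenization, POS tagging and lemmatization.
#
# The contract: Penn Treebank tags, lower-case lemmas, and character offsets
# that always slice back to the token text. Downstream rule logic depends
# only on tag classes (noun / adjective / preposition / determiner /
# coordination), so the bundled tagger is a compact lexicon + suffix
# heuristic rather than a full statistical tagger; a different backend can
# be substituted as long as it honours the same contract.

ABBREVIATIONS <- c("e.g", "i.e", "etc", "vs", "al", "fig", "figs", "dr",
                   "prof", "st", "no", "ca", "cf", "approx", "resp")

#' Split a document into sentences
#'
#' Boundary = sentence punctuation (`.`, `!`, `?`) followed by whitespace and
#' an upper-case letter or digit, unless the full stop terminates a known
#' abbreviation or sits inside a number. Spans are trimmed of surrounding
#' whitespace, so concatenating sentence substrings plus the inter-sentence
#' gaps reconstructs the document.
#'
#' @param doc a `DocumentRecord`-like list/row with `text`, or a string.
#' @return data.frame with columns `start`, `end` (0-based, half-open).
#' @export
split_sentences <- function(doc) {
  text <- if (is.character(doc)) doc else doc$text
  stopifnot(length(text) == 1L)
  if (!nzchar(trimws(text))) {
    return(data.frame(start = integer(), end = integer()))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  # candidate boundaries: position i (1-based) holds . ! or ?
  cuts <- integer()
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?", "\"", ")", "'")) {
        j <- j + 1L
      }
      rest <- if (j < n) paste(chars[(j + 1L):min(n, j + 3L)], collapse = "") else ""
      follows <- grepl("^[[:space:]]+[A-Z0-9]", rest) || j == n ||
        grepl("^[[:space:]]*$", substring(text, j + 1L))
      before <- substring(text, max(1L, i - 12L), i - 1L)
      word <- tolower(sub(".*[^A-Za-z.]", "", before))
      word <- sub("\\.$", "", word)
      in_number <- ch == "." && i > 1L && i < n &&
        grepl("[0-9]", chars[i - 1L]) && grepl("[0-9]", chars[i + 1L])
      if (follows && !in_number && !(ch == "." && word %in% ABBREVIATIONS)) {
        cuts <- c(cuts, j)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  bounds <- unique(c(0L, cuts, n))
  spans <- data.frame(start = head(bounds, -1L), end = tail(bounds, -1L))
  # trim whitespace off both ends of each span
  for (k in seq_len(nrow(spans))) {
    s <- spans$start[k]; e <- spans$end[k]
    while (s < e && grepl("^[[:space:]]$", chars[s + 1L])) s <- s + 1L
    while (e > s && grepl("^[[:space:]]$", chars[e])) e <- e - 1L
    spans$start[k] <- s; spans$end[k] <- e
  }
  spans[spans$start < spans$end, , drop = FALSE]
}

# --- tagging lexicons (closed classes + a small open-class seed) ---------

.tag_lexicon <- local({
  lex <- c(
    setNames(rep("DT", 8), c("the", "a", "an", "this", "that", "these",
                             "those", "each")),
    setNames(rep("IN", 16), c("of", "in", "on", "at", "by", "with", "from",
                              "for", "as", "into", "during", "without",
                              "within", "between", "after", "before")),
    to = "TO",
    setNames(rep("CC", 4), c("and", "or", "but", "nor")),
    setNames(rep("PRP", 6), c("he", "she", "it", "they", "we", "i")),
    setNames(rep("PRP$", 4), c("his", "her", "its", "their")),
    setNames(rep("MD", 5), c("can", "could", "may", "should", "would")),
    is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB",
    been = "VBN", has = "VBZ", have = "VBP", had = "VBD",
    shows = "VBZ", show = "VBP", showed = "VBD", shown = "VBN",
    not = "RB", also = "RB", only = "RB", here = "RB", there = "EX",
    then = "RB", now = "RB", often = "RB", never = "RB", again = "RB",
    soon = "RB", twice = "RB", once = "RB", later = "RB", overall = "RB",
    very = "RB", most = "RBS", more = "RBR",
    no = "DT", all = "DT", some = "DT",
    other = "JJ", same = "JJ", several = "JJ", both = "DT",
    # adjectives the coordination rules rely on
    outer = "JJ", middle = "JJ", inner = "JJ", upper = "JJ", lower = "JJ",
    left = "JJ", right = "JJ", mild = "JJ", severe = "JJ", small = "JJ",
    large = "JJ", normal = "JJ", cognitive = "JJ", mental = "JJ",
    renal = "JJ", genital = "JJ", bilateral = "JJ", congenital = "JJ",
    proximal = "JJ", distal = "JJ", enlarged = "JJ", atactic = "JJ",
    jerky = "JJ", absent = "JJ", delayed = "JJ", broad = "JJ", short = "JJ"
  )
  lex
})

.adj_suffixes <- c("al", "ic", "ous", "ive", "ary", "ar", "ile", "oid",
                   "ish", "less", "ful", "able", "ible")

tag_token <- function(text, first_in_sentence = FALSE) {
  low <- tolower(text)
  if (grepl("^[0-9]+([.,][0-9]+)*$", text)) return("CD")
  if (text == ",") return(",")
  if (text %in% c(".", "!", "?")) return(".")
  if (text %in% c("(", "[", "{")) return("(")
  if (text %in% c(")", "]", "}")) return(")")
  if (text %in% c(":", ";", "-", "--")) return(":")
  if (!grepl("[A-Za-z0-9]", text)) return("SYM")
  if (!is.na(.tag_lexicon[low])) return(unname(.tag_lexicon[low]))
  if (grepl("ly$", low) && nchar(low) > 3) return("RB")
  if (grepl("ing$", low) && nchar(low) > 4) return("VBG")
  if (grepl("ed$", low) && nchar(low) > 4) return("VBN")
  for (sfx in .adj_suffixes) {
    if (grepl(paste0(sfx, "$"), low) && nchar(low) > nchar(sfx) + 2) {
      return("JJ")
    }
  }
  if (grepl("[A-Z]", substr(text, 1, 1)) && !first_in_sentence) return("NNP")
  if (grepl("s$", low) && !grepl("(ss|us|is)$", low) && nchar(low) > 3) {
    return("NNS")
  }
  "NN"
}

.irregular_plurals <- c(feet = "foot", teeth = "tooth", men = "man",
                        women = "woman", children = "child", mice = "mouse",
                        criteria = "criterion", data = "datum",
                        vertebrae = "vertebra", foramina = "foramen")

lemma_token <- function(text, pos) {
  low <- tolower(text)
  if (pos == "NNS") {
    if (!is.na(.irregular_plurals[low])) return(unname(.irregular_plurals[low]))
    if (grepl("ies$", low) && nchar(low) > 4) return(sub("ies$", "y", low))
    if (grepl("(ses|xes|zes|ches|shes)$", low)) return(sub("es$", "", low))
    if (grepl("s$", low)) return(sub("s$", "", low))
  }
  if (pos == "VBG" && grepl("ing$", low)) {
    stem <- sub("ing$", "", low)
    if (grepl("([a-z])\\1$", stem)) stem <- sub(".$", "", stem)
    return(stem)
  }
  if (pos %in% c("VBD", "VBN") && grepl("ed$", low) && nchar(low) > 4) {
    return(sub("ed$", "", low))
  }
  low
}

#' Tokenize a sentence and attach POS tags and lemmas
#'
#' Token pattern: alphanumeric runs (hyphenated and apostrophe-joined words
#' stay single tokens, since phenotype vocabulary is hyphen-rich), decimal
#' numbers, or a single non-space symbol. Offsets are absolute document
#' offsets; `doc_text[start:end] == text` holds for every token.
#'
#' @param sentence a one-row data.frame (or list) with `start`, `end`.
#' @param doc_text the full document text the spans index into.
#' @return data.frame with columns `text`, `start`, `end`, `pos`, `lemma`.
#' @export
tokenize_and_tag <- function(sentence, doc_text) {
  s <- sentence$start[1]; e <- sentence$end[1]
  stopifnot(s >= 0, e <= nchar(doc_text))
  sub <- substr0(doc_text, s, e)
  pat <- "[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|[^[:space:]]"
  m <- gregexpr(pat, sub, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(text = character(), start = integer(), end = integer(),
                      pos = character(), lemma = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- s + as.integer(m) - 1L
  lens <- attr(m, "match.length")
  texts <- substring(sub, as.integer(m), as.integer(m) + lens - 1L)
  pos <- vapply(seq_along(texts), function(i) {
    tag_token(texts[i], first_in_sentence = (i == 1L))
  }, character(1))
  lemma <- vapply(seq_along(texts), function(i) {
    lemma_token(texts[i], pos[i])
  }, character(1))
  data.frame(text = texts, start = starts, end = starts + lens,
             pos = pos, lemma = lemma, stringsAsFactors = FALSE)
}

#' Preprocess a whole document
#'
#' @param text document text (or a `DocumentRecord`-like object).
#' @param doc_id optional id carried through.
#' @return list of sentences; each is a list with `doc_id`, `start`, `end`
#'   and a `tokens` data.frame.
#' @export
preprocess_document <- function(text, doc_id = NA_character_) {
  if (!is.character(text)) {
    if (is.na(doc_id) && !is.null(text$doc_id)) doc_id <- text$doc_id
    text <- text$text
  }
  spans <- split_sentences(text)
  lapply(seq_len(nrow(spans)), function(i) {
    list(doc_id = doc_id, start = spans$start[i], end = spans$end[i],
         tokens = tokenize_and_tag(spans[i, ], text))
  })
}
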