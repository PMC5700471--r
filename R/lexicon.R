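# Validation dictionary and configurable word lists.
#
# The dictionary holds normalized surface forms (lower-case, collapsed
# whitespace; no stemming — phenotype surfaces are inflection-sensitive)
# mapped to HPO ids, built from ontology names + synonyms, training-fold
# annotation surfaces, and generated variations. The five word lists are
# configuration shipped as editable text files, not code.

.wl_files <- c(common_hpo_nouns = "common_hpo_nouns.txt",
               connector_phrases = "connector_phrases.txt",
               positive_connotation_nouns = "positive_connotation_nouns.txt",
               stop_exact = "stop_exact.txt",
               stop_partial = "stop_partial.txt")

#' Read the five rule word lists from a directory
#'
#' Each file holds one phrase per line; `#` starts a comment. Lists are
#' lower-cased on load.
#'
#' @param dir directory holding the list files (see
#'   `system.file("extdata/word_lists", package = "phenorec")`).
#' @return a `word_lists` object.
#' @export
read_word_lists <- function(dir) {
  out <- lapply(.wl_files, function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) return(character())
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    unique(tolower(lines[nzchar(lines)]))
  })
  structure(setNames(out, names(.wl_files)), class = "word_lists")
}

#' Write word lists in the one-phrase-per-line format
#'
#' @param lists a `word_lists` object.
#' @param dir output directory.
#' @export
write_word_lists <- function(lists, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.wl_files)) {
    writeLines(lists[[nm]], file.path(dir, .wl_files[[nm]]))
  }
  invisible(dir)
}

#' The word lists bundled with the package
#' @return a `word_lists` object.
#' @export
default_word_lists <- function() {
  read_word_lists(system.file("extdata", "word_lists", package = "phenorec"))
}

#' Generate surface variations of a term
#'
#' Two rewrite patterns, both exemplified by the pair
#' "abnormalities of the kidney" / "kidney abnormalities":
#' a term `"<head> <connector> <tail>"` (connector drawn from the connector
#' list, longest match first) also yields `"<tail> <head>"`; a two-word term
#' `"<modifier> <head>"` whose head is a common HPO noun also yields
#' `"<head> of the <modifier>"`. The original term is always included, and
#' for forms headed by a common HPO noun the singular/plural counterpart of
#' that noun is added too.
#'
#' @param term surface string.
#' @param connector_phrases,common_nouns word lists (lower-case).
#' @return character vector of normalized surface forms (term included).
#' @export
generate_variations <- function(term,
                                connector_phrases = c("of", "of the", "in the"),
                                common_nouns = character()) {
  term <- normalize_surface(term)
  out <- term
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  n <- length(words)
  conns <- connector_phrases[order(-nchar(connector_phrases))]
  if (n >= 3) {
    head_w <- words[1]
    rest <- paste(words[-1], collapse = " ")
    for (cn in conns) {
      pref <- paste0(cn, " ")
      if (startsWith(rest, pref)) {
        tail_w <- substring(rest, nchar(pref) + 1L)
        if (nzchar(tail_w)) out <- c(out, paste(tail_w, head_w))
        break
      }
    }
  }
  if (n == 2 && words[2] %in% common_nouns) {
    out <- c(out, paste(words[2], "of the", words[1]))
  }
  # singular/plural toggling of common-noun heads only
  toggle <- function(w) {
    if (grepl("ies$", w)) sub("ies$", "y", w)
    else if (grepl("y$", w)) sub("y$", "ies", w)
    else if (grepl("s$", w)) sub("s$", "", w)
    else paste0(w, "s")
  }
  extra <- character()
  for (v in out) {
    vw <- strsplit(v, " ", fixed = TRUE)[[1]]
    hits <- which(vw %in% common_nouns)
    for (h in hits) {
      vw2 <- vw
      vw2[h] <- toggle(vw[h])
      extra <- c(extra, paste(vw2, collapse = " "))
    }
  }
  unique(c(out, extra))
}

#' Build the validation dictionary
#'
#' Contains every ontology name and synonym, every training-fold annotation
#' surface, and (optionally) generated variations of all of these.
#' Annotations from the held-out test fold must not be passed in — the
#' per-fold pipeline enforces this upstream.
#'
#' @param ontology an `hpo_ontology`.
#' @param training_annotations annotation data.frame (or NULL).
#' @param generate add [generate_variations()] of every entry.
#' @param word_lists a `word_lists` (connectors and common nouns feed the
#'   variation grammar).
#' @return an `hpo_dictionary`: data.frame `entries` with columns `surface`
#'   (normalized), `hpo_id`, `source`.
#' @export
build_dictionary <- function(ontology, training_annotations = NULL,
                             generate = TRUE,
                             word_lists = default_word_lists()) {
  stopifnot(inherits(ontology, "hpo_ontology"))
  rows <- list()
  ids <- names(ontology$terms)
  rows$name <- data.frame(surface = normalize_surface(unname(ontology$terms)),
                          hpo_id = ids, source = "ontology_name",
                          stringsAsFactors = FALSE)
  if (length(ontology$synonyms)) {
    syn_id <- rep(names(ontology$synonyms), lengths(ontology$synonyms))
    syn <- unlist(ontology$synonyms, use.names = FALSE)
    if (length(syn)) {
      rows$syn <- data.frame(surface = normalize_surface(syn), hpo_id = syn_id,
                             source = "ontology_synonym",
                             stringsAsFactors = FALSE)
    }
  }
  if (!is.null(training_annotations) && nrow(training_annotations)) {
    rows$train <- data.frame(
      surface = normalize_surface(training_annotations$surface),
      hpo_id = training_annotations$hpo_id, source = "training_annotation",
      stringsAsFactors = FALSE)
  }
  entries <- do.call(rbind, rows)
  entries <- entries[nzchar(entries$surface), , drop = FALSE]
  if (generate) {
    var_rows <- lapply(seq_len(nrow(entries)), function(i) {
      v <- generate_variations(entries$surface[i],
                               word_lists$connector_phrases,
                               word_lists$common_hpo_nouns)
      v <- setdiff(v, entries$surface[i])
      if (!length(v)) return(NULL)
      data.frame(surface = v, hpo_id = entries$hpo_id[i],
                 source = "generated_variation", stringsAsFactors = FALSE)
    })
    entries <- rbind(entries, do.call(rbind, var_rows))
  }
  # dedupe on (surface, hpo_id); earliest source wins (source order above)
  entries <- entries[!duplicated(paste(entries$surface, entries$hpo_id)), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries), class = "hpo_dictionary")
}

#' @export
print.hpo_dictionary <- function(x, ...) {
  cat("<hpo_dictionary> ", length(unique(x$entries$surface)),
      " surface forms, ", nrow(x$entries), " (surface, id) entries\n",
      sep = "")
  invisible(x)
}

dictionary_surfaces <- function(dictionary) {
  unique(dictionary$entries$surface)
}

dictionary_lookup <- function(dictionary, surface) {
  s <- normalize_surface(surface)
  unique(dictionary$entries$hpo_id[dictionary$entries$surface == s])
}

#' Export a dictionary as TSV
#'
#' @param dictionary an `hpo_dictionary`.
#' @param path output file (columns surface, hpo_id, source).
#' @export
write_dictionary <- function(dictionary, path) {
  utils::write.table(dictionary$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Find exact dictionary mentions in a document
#'
#' Case-insensitive exact matching at word boundaries. Matches of a single
#' entry never overlap (longest-match first); matches of distinct entries
#' may nest, which is how superclass mentions inside subclass mentions are
#' surfaced.
#'
#' @param text document text.
#' @param dictionary an `hpo_dictionary`.
#' @return data.frame with `start`, `end`, `surface` (text as found) and
#'   `hpo_id` (one row per matched id).
#' @export
find_dictionary_mentions <- function(text, dictionary) {
  surfaces <- dictionary_surfaces(dictionary)
  surfaces <- surfaces[order(-nchar(surfaces))]
  low <- tolower(text)
  out <- list()
  for (s in surfaces) {
    m <- gregexpr(boundary_pattern(s), low, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m) - 1L
    ends <- starts + attr(m, "match.length")
    ids <- dictionary_lookup(dictionary, s)
    out[[s]] <- data.frame(
      start = rep(starts, each = length(ids)),
      end = rep(ends, each = length(ids)),
      surface = substr0(text, rep(starts, each = length(ids)),
                        rep(ends, each = length(ids))),
      hpo_id = rep(ids, times = length(starts)),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), surface = character(),
               hpo_id = character(), stringsAsFactors = FALSE)
  res <- res[!duplicated(paste(res$start, res$end, res$hpo_id)), , drop = FALSE]
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}
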