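#' Parse one gold-standard annotation line
#'
#' Annotation files carry one record per line in the form
#' `"[27::42] HP_0000110 | renal dysplasia"`: a 0-based half-open character
#' span, the HPO accession, and the annotated surface text. Both the ASCII
#' pipe and the Unicode divider (U+2223) are accepted as separators; HPO ids
#' are normalized to the canonical `HP_nnnnnnn` form.
#'
#' @param line a single annotation record.
#' @param doc_id document identifier to attach (the file stem).
#' @param line_no,file optional context used in error messages.
#' @return a one-row data.frame with columns `doc_id`, `start`, `end`,
#'   `hpo_id`, `surface`.
#' @examples
#' parse_annotation_line("[27::42] HP_0000110 | renal dysplasia", "2888021")
#' @export
parse_annotation_line <- function(line, doc_id = NA_character_,
                                  line_no = NA_integer_, file = NULL) {
  pat <- "^\\[([0-9]+)::([0-9]+)\\][ \t]+(HP[:_][0-9]+)[ \t]*[|∣][ \t]*(.*\\S)[ \t]*$"
  m <- regmatches(line, regexec(pat, line, perl = TRUE))[[1]]
  if (length(m) != 5L) {
    where <- if (!is.null(file)) paste0(" in ", file) else ""
    at <- if (!is.na(line_no)) paste0(" at line ", line_no) else ""
    stop("malformed annotation line", at, where, ": ", sQuote(line),
         call. = FALSE)
  }
  start <- as.integer(m[2]); end <- as.integer(m[3])
  if (start >= end) {
    stop("annotation span [", start, "::", end, "] is empty or inverted",
         call. = FALSE)
  }
  data.frame(doc_id = doc_id, start = start, end = end,
             hpo_id = canonical_hpo_id(m[4]), surface = m[5],
             stringsAsFactors = FALSE)
}

format_annotation_line <- function(ann) {
  sprintf("[%d::%d] %s | %s", ann$start, ann$end, ann$hpo_id, ann$surface)
}

new_corpus <- function(documents, annotations) {
  stopifnot(all(c("doc_id", "text") %in% names(documents)))
  if (anyDuplicated(documents$doc_id)) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(documents$doc_id[duplicated(documents$doc_id)]),
               collapse = ", "), call. = FALSE)
  }
  orphan <- setdiff(annotations$doc_id, documents$doc_id)
  if (length(orphan)) {
    stop("annotations reference unknown documents: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(documents = documents, annotations = annotations),
            class = "gsc_corpus")
}

#' @export
print.gsc_corpus <- function(x, ...) {
  cat("<gsc_corpus> ", nrow(x$documents), " documents, ",
      nrow(x$annotations), " annotations\n", sep = "")
  invisible(x)
}

doc_text <- function(corpus, doc_id) {
  i <- match(doc_id, corpus$documents$doc_id)
  if (is.na(i)) stop("no such document: ", doc_id, call. = FALSE)
  corpus$documents$text[i]
}

#' Read a gold-standard corpus from disk
#'
#' Expects one `*.txt` file per abstract under `doc_dir` (a single text block,
#' no title line) and a matching annotation file per abstract under `ann_dir`
#' (same file stem; one record per line, empty files allowed). Documents
#' without an annotation file get zero annotations; an annotation file with no
#' matching document is an error.
#'
#' Each annotation's span is checked against the document text (after
#' whitespace normalization). Mismatches are collected in the
#' `"validation"` attribute of the result; with `strict = TRUE` they raise an
#' error instead. File offsets are kept either way, since offsets are the
#' evaluation key.
#'
#' @param doc_dir,ann_dir directories holding document and annotation files.
#' @param strict fail on span/text mismatches instead of recording them.
#' @return a `gsc_corpus` object.
#' @export
read_corpus <- function(doc_dir, ann_dir, strict = FALSE) {
  stopifnot(dir.exists(doc_dir), dir.exists(ann_dir))
  doc_files <- sort(list.files(doc_dir, pattern = "\\.txt$", full.names = TRUE))
  stems <- tools::file_path_sans_ext(basename(doc_files))
  ann_files <- sort(list.files(ann_dir, full.names = TRUE))
  ann_stems <- tools::file_path_sans_ext(basename(ann_files))
  orphan <- setdiff(ann_stems, stems)
  if (length(orphan)) {
    stop("annotation file(s) without a matching document: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  texts <- vapply(doc_files, function(f) {
    paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  }, character(1), USE.NAMES = FALSE)
  documents <- data.frame(doc_id = stems, text = texts, stringsAsFactors = FALSE)

  anns <- list(); problems <- list()
  for (i in seq_along(ann_files)) {
    f <- ann_files[i]; id <- ann_stems[i]
    lines <- readLines(f, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) next
    parsed <- lapply(seq_along(lines), function(j) {
      parse_annotation_line(lines[j], doc_id = id, line_no = j, file = f)
    })
    anns[[id]] <- do.call(rbind, parsed)
  }
  annotations <- if (length(anns)) do.call(rbind, anns) else empty_annotations()
  rownames(annotations) <- NULL
  corpus <- new_corpus(documents, annotations)

  if (nrow(annotations)) {
    txt <- documents$text[match(annotations$doc_id, documents$doc_id)]
    seen <- substr0(txt, annotations$start, annotations$end)
    ok <- normalize_surface(seen) == normalize_surface(annotations$surface) &
      annotations$end <= nchar(txt)
    if (any(!ok)) {
      bad <- annotations[!ok, , drop = FALSE]
      bad$found <- seen[!ok]
      if (strict) {
        stop("span/text mismatch for ", nrow(bad), " annotation(s), e.g. ",
             sQuote(bad$surface[1]), " vs document text ",
             sQuote(bad$found[1]), call. = FALSE)
      }
      problems <- bad
    }
  }
  attr(corpus, "validation") <- if (length(problems)) problems else
    cbind(empty_annotations(), data.frame(found = character()))
  corpus
}

#' Write a corpus in gold-standard directory layout
#'
#' Emits one `<doc_id>.txt` per document and one annotation file per document
#' (ASCII `|` separator), such that [read_corpus()] recovers an identical
#' structure.
#'
#' @param corpus a `gsc_corpus`.
#' @param doc_dir,ann_dir output directories (created if missing).
#' @export
write_corpus <- function(corpus, doc_dir, ann_dir) {
  stopifnot(inherits(corpus, "gsc_corpus"))
  dir.create(doc_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(ann_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_len(nrow(corpus$documents))) {
    id <- corpus$documents$doc_id[i]
    writeLines(corpus$documents$text[i], file.path(doc_dir, paste0(id, ".txt")),
               useBytes = FALSE)
    ann <- corpus$annotations[corpus$annotations$doc_id == id, , drop = FALSE]
    lines <- if (nrow(ann)) format_annotation_line(ann) else character()
    writeLines(lines, file.path(ann_dir, paste0(id, ".txt")))
  }
  invisible(c(doc_dir = doc_dir, ann_dir = ann_dir))
}

#' Diff two corpora over the same documents
#'
#' Annotations are keyed by (doc_id, start, end, hpo_id). An annotation in
#' `new` whose full key is absent from `old` but whose span (doc_id, start,
#' end) is present counts as *modified* (different id or surface on the same
#' span); a span absent from `old` entirely is *added*; symmetrically for
#' *removed*.
#'
#' @param old,new two `gsc_corpus` objects over the same document ids.
#' @return a list with data.frames `added`, `removed`, `modified` and a
#'   `counts` vector.
#' @export
diff_corpora <- function(old, new) {
  stopifnot(inherits(old, "gsc_corpus"), inherits(new, "gsc_corpus"))
  d <- union(setdiff(old$documents$doc_id, new$documents$doc_id),
             setdiff(new$documents$doc_id, old$documents$doc_id))
  if (length(d)) {
    stop("document sets differ: ", paste(d, collapse = ", "), call. = FALSE)
  }
  oa <- old$annotations; na <- new$annotations
  full_old <- ann_key(oa); full_new <- ann_key(na)
  span_old <- ann_key(oa, with_id = FALSE)
  span_new <- ann_key(na, with_id = FALSE)

  new_only <- !(full_new %in% full_old)
  modified <- na[new_only & span_new %in% span_old, , drop = FALSE]
  added <- na[new_only & !(span_new %in% span_old), , drop = FALSE]
  old_only <- !(full_old %in% full_new)
  removed <- oa[old_only & !(span_old %in% span_new), , drop = FALSE]
  rownames(added) <- rownames(removed) <- rownames(modified) <- NULL
  list(added = added, removed = removed, modified = modified,
       counts = c(added = nrow(added), removed = nrow(removed),
                  modified = nrow(modified)))
}

#' Write a corpus diff as TSV
#'
#' @param diff result of [diff_corpora()].
#' @param path output file.
#' @export
write_diff_report <- function(diff, path) {
  rows <- do.call(rbind, lapply(c("added", "removed", "modified"), function(s) {
    d <- diff[[s]]
    if (!nrow(d)) return(NULL)
    cbind(d[c("doc_id", "start", "end", "hpo_id", "surface")], status = s)
  }))
  if (is.null(rows)) {
    rows <- cbind(empty_annotations(), data.frame(status = character()))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an HPO-style ontology from an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas for id, name, synonyms (any scope), `is_a` parents
#' and the obsolete flag. Obsolete terms are dropped; ids are normalized to
#' `HP_nnnnnnn`. Alongside the original strings, lower-case normalized copies
#' are kept for dictionary building.
#'
#' @param obo_path path to the OBO file.
#' @return an `hpo_ontology`: list with `terms` (named character, id -> name),
#'   `synonyms` (named list, id -> character vector) and `parents` (named
#'   list, id -> ids).
#' @export
load_ontology <- function(obo_path) {
  if (!file.exists(obo_path)) stop("no such OBO file: ", obo_path, call. = FALSE)
  lines <- readLines(obo_path, warn = FALSE, encoding = "UTF-8")
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("not an OBO file (no stanzas): ", obo_path,
                            call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  terms <- character(); synonyms <- list(); parents <- list()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    block <- lines[(starts[i] + 1L):(bounds[i + 1L] - 1L)]
    get1 <- function(key) {
      v <- sub(paste0("^", key, ": *"), "", grep(paste0("^", key, ":"), block,
                                                 value = TRUE))
      if (length(v)) v else character()
    }
    id <- get1("id"); name <- get1("name")
    if (!length(id) || !length(name)) next
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- canonical_hpo_id(id[1])
    terms[id] <- name[1]
    syn_lines <- get1("synonym")
    syns <- regmatches(syn_lines, regexpr('"[^"]*"', syn_lines))
    syns <- substr(syns, 2L, nchar(syns) - 1L)
    synonyms[[id]] <- unique(syns[nzchar(syns)])
    par_lines <- get1("is_a")
    pars <- regmatches(par_lines, regexpr("^HP[:_][0-9]+", par_lines))
    if (length(pars)) {
      pars <- canonical_hpo_id(pars)
      parents[[id]] <- setdiff(unique(pars), id)  # no self-parenting
    }
  }
  if (!length(terms)) stop("no usable [Term] stanzas in ", obo_path,
                           call. = FALSE)
  synonyms <- synonyms[lengths(synonyms) > 0]
  synonyms <- synonyms[intersect(names(synonyms), names(terms))]
  parents <- lapply(parents[intersect(names(parents), names(terms))],
                    intersect, names(terms))
  structure(list(terms = terms, synonyms = synonyms, parents = parents),
            class = "hpo_ontology")
}

#' @export
print.hpo_ontology <- function(x, ...) {
  cat("<hpo_ontology> ", length(x$terms), " terms, ",
      sum(lengths(x$synonyms)), " synonyms\n", sep = "")
  invisible(x)
}
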