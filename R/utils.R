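#' @keywords internal
"_PACKAGE"

#' @useDynLib phenorec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils head tail write.table read.table
NULL

# Character slice with 0-based half-open offsets (the annotation convention).
substr0 <- function(x, start, end) substring(x, start + 1L, end)

# Surface normalization shared by the lexicon and evaluation modules:
# lower-case, collapse internal whitespace, trim. Idempotent.
normalize_surface <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Canonical HPO accession: "HP_" + 7 digits. Accepts "HP:0000077",
# "HP_0000077" or a bare number.
canonical_hpo_id <- function(id) {
  id <- trimws(id)
  num <- sub("^HP[:_]", "", id)
  bad <- !grepl("^[0-9]+$", num)
  if (any(bad)) {
    stop("not a valid HPO accession: ", paste(id[bad], collapse = ", "),
         call. = FALSE)
  }
  sprintf("HP_%07d", as.integer(num))
}

# Run code with a private RNG stream; the global .Random.seed is restored.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

empty_annotations <- function() {
  data.frame(doc_id = character(), start = integer(), end = integer(),
             hpo_id = character(), surface = character(),
             stringsAsFactors = FALSE)
}

ann_key <- function(ann, with_id = TRUE) {
  if (nrow(ann) == 0) return(character())
  if (with_id) {
    paste(ann$doc_id, ann$start, ann$end, ann$hpo_id, sep = "\r")
  } else {
    paste(ann$doc_id, ann$start, ann$end, sep = "\r")
  }
}

# Literal word-boundary regex for a surface form: no alphanumeric may touch
# either side, so "ear" never matches inside "heart".
boundary_pattern <- function(surface) {
  paste0("(?<![A-Za-z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", surface),
         "(?![A-Za-z0-9])")
}
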