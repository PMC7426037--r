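#' Build a stop-word list
#'
#' Lowercases, deduplicates, and removes all single-character entries from a
#' raw word list. Single-letter "words" in mathematical prose are almost
#' always variables, so they must not act as stop words (they are scrubbed
#' to placeholders instead).
#'
#' @param base_list Character vector of stop words (any case, may contain
#'   duplicates and single letters).
#' @return Character vector of lowercase stop words, each of length >= 2.
#' @export
#' @examples
#' build_stop_list(c("A", "an", "the", "I", "of"))
build_stop_list <- function(base_list) {
  if (length(base_list) == 0L) {
    stop("stop list source is empty; a non-empty base list is required")
  }
  tokens <- unique(tolower(trimws(base_list)))
  tokens <- tokens[nchar(tokens) >= 2L]
  if (length(tokens) == 0L) {
    stop("stop list contains no multi-character words")
  }
  sort(tokens)
}

#' Read a stop list from a plain-text file (one word per line)
#'
#' @param path Path to the word list.
#' @return Character vector as from [build_stop_list()].
#' @export
read_stop_list <- function(path) {
  build_stop_list(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' Default English stop-word list shipped with the package
#'
#' @return Character vector of stop words.
#' @export
default_stop_list <- function() {
  read_stop_list(system.file("extdata", "stopwords_en.txt",
                             package = "exposnet", mustWork = TRUE))
}

# Sentence segmentation: split on . ! ? followed by whitespace (or end of
# text). Deliberately rule-based so results are reproducible; a toolkit
# segmenter can be substituted upstream by pre-splitting into lines.
split_sentences <- function(text) {
  pieces <- stringi::stri_split_regex(text, "[.!?]+(?=\\s|$)")[[1]]
  pieces <- trimws(pieces)
  pieces[nchar(pieces) > 0L]
}

# Word tokenization within a sentence: maximal runs of letters, digits or
# '#'. Everything else (math symbols, punctuation) delimits tokens.
tokenize_words <- function(sentence) {
  toks <- stringi::stri_extract_all_regex(sentence, "[\\p{L}\\p{Nd}#]+")[[1]]
  toks[!is.na(toks)]
}

#' Normalize raw text into cleaned token sentences
#'
#' Applies, in order: Unicode NFKD normalization; hyphen-to-space
#' replacement; sentence and word tokenization; per-token lemmatization;
#' replacement of any token containing a digit by the placeholder `"#"`;
#' removal of tokens not composed solely of letters and `"#"`; lowercasing.
#' Runs of `"#"` collapse to a single `"#"`. Empty sentences are dropped.
#'
#' @param raw_text Single character string (UTF-8).
#' @param lemmatizer Function mapping a character vector of word tokens to
#'   their dictionary forms; default is the identity.
#' @return List of character vectors, one per sentence (not yet
#'   variable-scrubbed; see [scrub_variables()]).
#' @export
#' @examples
#' normalize_document("Self-adjoint operators. Let A2 = B.")
normalize_document <- function(raw_text, lemmatizer = identity) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L)
  if (!nzchar(raw_text)) stop("raw_text is empty")
  txt <- stringi::stri_trans_nfkd(raw_text)
  # hyphens (ASCII and typographic) become spaces so compounds split
  txt <- stringi::stri_replace_all_regex(txt, "[-‐‑‒–—]", " ")
  sentences <- split_sentences(txt)
  out <- lapply(sentences, function(s) {
    toks <- tokenize_words(s)
    if (length(toks) == 0L) return(character(0))
    toks <- lemmatizer(toks)
    has_digit <- stringi::stri_detect_regex(toks, "\\p{Nd}")
    toks[has_digit] <- "#"
    toks[stringi::stri_detect_regex(toks, "^#+$")] <- "#"
    keep <- stringi::stri_detect_regex(toks, "^[\\p{L}#]+$")
    tolower(toks[keep])
  })
  out[lengths(out) > 0L]
}

has_vowel <- function(tokens) {
  stringi::stri_detect_regex(tokens, "[aeiouy]")
}

#' Scrub variable-like tokens to the "VAR" placeholder
#'
#' Expositional math text converted from typeset sources is littered with
#' remnants of variables and equations. Tokens are examined in a fixed rule
#' order: the `"#"` placeholder is kept as is; any token without a vowel
#' (vowels are a, e, i, o, u, y) becomes `"VAR"`; any token of length at
#' most two not on the stop list becomes `"VAR"`; any token of length 3 or
#' 4 that is not on the stop list and fails the spell check becomes
#' `"VAR"`. Stop-list membership exempts a token from the spell-check rule
#' (stop words are common English and carry no variable risk).
#'
#' @param sentences List of token vectors from [normalize_document()].
#' @param stop_list Character vector from [build_stop_list()].
#' @param spell_checker Function: character vector -> logical vector, TRUE
#'   where the word spell-checks. Default accepts everything (no
#'   dictionary assumption); inject a real checker for noisy text.
#' @param source_id Document identifier stored on the result.
#' @return A `tokenized_document`: list with elements `sentences` (list of
#'   token vectors over the alphabet letters-only / `"#"` / `"VAR"`),
#'   `n_sentences`, and `source_id`.
#' @export
scrub_variables <- function(sentences, stop_list,
                            spell_checker = function(w) rep(TRUE, length(w)),
                            source_id = "document") {
  stopifnot(is.list(sentences), length(sentences) >= 1L)
  scrubbed <- lapply(sentences, function(toks) {
    if (length(toks) == 0L) return(toks)
    is_hash <- toks == "#"
    is_var <- toks == "VAR"
    fixed <- is_hash | is_var
    in_stop <- toks %in% stop_list
    n <- nchar(toks)
    # rule order matters: vowel-less, then short non-stop, then spell check
    to_var <- !fixed & !has_vowel(toks)
    to_var <- to_var | (!fixed & !to_var & n <= 2L & !in_stop)
    need_spell <- !fixed & !to_var & n %in% c(3L, 4L) & !in_stop
    if (any(need_spell)) {
      ok <- spell_checker(toks[need_spell])
      to_var[need_spell][!ok] <- TRUE
    }
    toks[to_var] <- "VAR"
    toks
  })
  structure(
    list(sentences = scrubbed,
         n_sentences = length(scrubbed),
         source_id = source_id),
    class = "tokenized_document"
  )
}

#' Full preprocessing pipeline: raw text to tokenized document
#'
#' Convenience wrapper running [normalize_document()] then
#' [scrub_variables()].
#'
#' @inheritParams normalize_document
#' @inheritParams scrub_variables
#' @return A `tokenized_document`.
#' @export
preprocess_document <- function(raw_text, stop_list,
                                lemmatizer = identity,
                                spell_checker = function(w) rep(TRUE, length(w)),
                                source_id = "document") {
  scrub_variables(normalize_document(raw_text, lemmatizer),
                  stop_list, spell_checker, source_id = source_id)
}

#' @export
print.tokenized_document <- function(x, ...) {
  n_tok <- sum(lengths(x$sentences))
  n_var <- sum(vapply(x$sentences, function(s) sum(s == "VAR"), integer(1)))
  n_hash <- sum(vapply(x$sentences, function(s) sum(s == "#"), integer(1)))
  cat(sprintf("<tokenized_document '%s': %d sentences, %d tokens (%d VAR, %d #)>\n",
              x$source_id, x$n_sentences, n_tok, n_var, n_hash))
  invisible(x)
}

#' Write a tokenized document as JSON lines (one sentence per line)
#'
#' @param doc A `tokenized_document`.
#' @param path Output file path.
#' @export
write_tokens <- function(doc, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (s in doc$sentences) {
    writeLines(jsonlite::toJSON(s), con)
  }
  invisible(path)
}

#' Read a tokenized document written by [write_tokens()]
#'
#' @param path Input file path.
#' @param source_id Document identifier to attach.
#' @return A `tokenized_document`.
#' @export
read_tokens <- function(path, source_id = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  sentences <- lapply(lines, function(l) as.character(jsonlite::fromJSON(l)))
  structure(
    list(sentences = sentences, n_sentences = length(sentences),
         source_id = source_id),
    class = "tokenized_document"
  )
}
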