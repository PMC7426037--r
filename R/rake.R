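#' Generate candidate keyphrases from a tokenized document
#'
#' Within each sentence, maximal runs of tokens that are neither stop words
#' nor the placeholders `"#"`/`"VAR"` become candidate phrases (the classic
#' RAKE chunking step, with the placeholders acting as extra delimiters).
#' Runs longer than `max_phrase_len` are discarded. Every occurrence is
#' kept, so the result is a multiset.
#'
#' @param doc A `tokenized_document`.
#' @param stop_list Character vector of stop words.
#' @param max_phrase_len Maximum phrase length in words (default 4).
#' @return Character vector of phrase occurrences (words joined by single
#'   spaces), in reading order; possibly empty (with a warning).
#' @export
generate_candidates <- function(doc, stop_list, max_phrase_len = 4L) {
  stopifnot(inherits(doc, "tokenized_document"))
  out <- vector("list", doc$n_sentences)
  for (i in seq_along(doc$sentences)) {
    toks <- doc$sentences[[i]]
    is_delim <- toks %in% stop_list | toks == "#" | toks == "VAR"
    if (all(is_delim)) next
    runs <- rle(is_delim)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- !runs$values & runs$lengths <= max_phrase_len
    if (!any(keep)) next
    out[[i]] <- vapply(which(keep), function(j) {
      paste(toks[starts[j]:ends[j]], collapse = " ")
    }, character(1))
  }
  phrases <- unlist(out, use.names = FALSE)
  if (is.null(phrases)) phrases <- character(0)
  if (length(phrases) == 0L) {
    warning("no candidate keyphrases found")
  }
  phrases
}

#' Keyword co-occurrence statistics
#'
#' For every word appearing in the candidate phrases, computes `freq` (the
#' number of candidate occurrences containing the word) and `deg` (the sum,
#' over those occurrences, of the phrase length in words — the word's
#' degree in the RAKE keyword co-occurrence graph, self-co-occurrence
#' included).
#'
#' @param candidates Character vector of phrase occurrences from
#'   [generate_candidates()].
#' @return Data frame with columns `word`, `freq`, `deg`; `deg >= freq >= 1`.
#' @export
keyword_stats <- function(candidates) {
  if (length(candidates) == 0L) stop("no candidates supplied")
  words_per_phrase <- strsplit(candidates, " ", fixed = TRUE)
  lens <- lengths(words_per_phrase)
  word <- unlist(words_per_phrase, use.names = FALSE)
  len_rep <- rep(lens, lens)
  freq <- tapply(rep(1L, length(word)), word, sum)
  deg <- tapply(len_rep, word, sum)
  res <- data.frame(word = names(freq),
                    freq = as.integer(freq),
                    deg = as.integer(deg[names(freq)]),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$word), , drop = FALSE]
}

#' Score candidate keyphrases (frequency-penalized RAKE)
#'
#' The classic RAKE score of a phrase k with words k_i is
#' `score_RAKE(k) = sum_i deg(k_i) / freq(k_i)`; it favours words that
#' co-occur with many others but are not themselves frequent. To demote
#' phrases that are common in ordinary (non-technical) prose, the final
#' score divides by one plus the phrase's count in a reference corpus:
#' `score(k) = score_RAKE(k) / (1 + ref_count(k))`.
#'
#' @param candidates Phrase occurrence vector from [generate_candidates()].
#' @param stats Keyword statistics from [keyword_stats()] on the same
#'   candidates.
#' @param ref_corpus_counts Named numeric vector or two-column data frame
#'   (`phrase`, `count`) of reference-corpus phrase frequencies; phrases
#'   absent from the table count 0.
#' @return Data frame of unique phrases with columns `phrase`,
#'   `n_occurrences`, `rake_score`, `ref_count`, `final_score`, ordered by
#'   decreasing `final_score` (ties: lexicographic, then first occurrence).
#' @export
score_keyphrases <- function(candidates, stats, ref_corpus_counts = NULL) {
  if (length(candidates) == 0L) stop("no candidates supplied")
  ref <- normalize_ref_counts(ref_corpus_counts)
  first_occ <- match(unique(candidates), candidates)
  phrase <- unique(candidates)
  n_occ <- as.integer(table(candidates)[phrase])
  deg_over_freq <- stats$deg / stats$freq
  names(deg_over_freq) <- stats$word
  rake_score <- vapply(strsplit(phrase, " ", fixed = TRUE), function(ws) {
    vals <- deg_over_freq[ws]
    if (anyNA(vals)) {
      stop("phrase contains a keyword missing from the statistics table: ",
           paste(ws[is.na(vals)], collapse = ", "))
    }
    sum(vals)
  }, numeric(1))
  ref_count <- ifelse(phrase %in% names(ref), ref[phrase], 0)
  final_score <- rake_score / (1 + ref_count)
  res <- data.frame(phrase = phrase, n_occurrences = n_occ,
                    rake_score = rake_score,
                    ref_count = as.numeric(ref_count),
                    final_score = final_score,
                    first_occurrence = first_occ,
                    stringsAsFactors = FALSE, row.names = NULL)
  res[order(-res$final_score, res$phrase, res$first_occurrence), ,
      drop = FALSE]
}

normalize_ref_counts <- function(ref_corpus_counts) {
  if (is.null(ref_corpus_counts)) return(numeric(0))
  if (is.data.frame(ref_corpus_counts)) {
    stopifnot(all(c("phrase", "count") %in% names(ref_corpus_counts)))
    ref <- as.numeric(ref_corpus_counts$count)
    names(ref) <- ref_corpus_counts$phrase
    return(ref)
  }
  stopifnot(is.numeric(ref_corpus_counts), !is.null(names(ref_corpus_counts)))
  ref_corpus_counts
}

#' Read a reference-corpus phrase-count table (TSV: phrase, count)
#'
#' @param path Path to a tab-separated file with header columns `phrase`
#'   and `count`.
#' @return Named numeric vector of counts.
#' @export
read_reference_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  normalize_ref_counts(tab)
}

#' Select the concept index set from scored keyphrases
#'
#' Keeps the top `n` phrases by final score. When `n` is `NULL` the default
#' rule keeps all phrases scoring strictly above the median final score,
#' capped at `max_default` (expositional texts do not come with a canonical
#' index size; the median rule adapts to the score distribution).
#'
#' @param scored Data frame from [score_keyphrases()].
#' @param n Number of concepts to keep, or `NULL` for the median rule.
#' @param max_default Cap applied by the median rule (default 500).
#' @return An `index_set`: the selected rows of `scored` with a `rank`
#'   column, in rank order.
#' @export
select_index <- function(scored, n = NULL, max_default = 500L) {
  stopifnot(is.data.frame(scored), nrow(scored) >= 1L)
  ord <- scored[order(-scored$final_score, scored$phrase,
                      scored$first_occurrence), , drop = FALSE]
  if (is.null(n)) {
    n <- min(sum(ord$final_score > stats::median(ord$final_score)),
             max_default)
    n <- max(n, 1L)
  }
  if (n < 1L) stop("index size n must be >= 1")
  n <- min(n, nrow(ord))
  res <- ord[seq_len(n), , drop = FALSE]
  res$rank <- seq_len(n)
  rownames(res) <- NULL
  class(res) <- c("index_set", "data.frame")
  res
}

#' Extract the concept index set from a tokenized document
#'
#' Runs candidate generation, keyword statistics, scoring and selection in
#' one call.
#'
#' @inheritParams generate_candidates
#' @inheritParams score_keyphrases
#' @inheritParams select_index
#' @return An `index_set`.
#' @export
extract_index <- function(doc, stop_list, ref_corpus_counts = NULL,
                          n = NULL, max_phrase_len = 4L,
                          max_default = 500L) {
  cands <- generate_candidates(doc, stop_list, max_phrase_len)
  scored <- score_keyphrases(cands, keyword_stats(cands), ref_corpus_counts)
  select_index(scored, n = n, max_default = max_default)
}

index_phrases <- function(index) {
  if (inherits(index, "index_set") || is.data.frame(index)) {
    as.character(index$phrase)
  } else {
    as.character(index)
  }
}

#' Write an index set as TSV
#'
#' Columns: rank, phrase, rake_score, ref_count, final_score.
#'
#' @param index An `index_set`.
#' @param path Output path.
#' @export
write_index <- function(index, path) {
  cols <- c("rank", "phrase", "rake_score", "ref_count", "final_score")
  utils::write.table(index[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an index set written by [write_index()]
#'
#' @param path Input path.
#' @return An `index_set`.
#' @export
read_index <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  class(tab) <- c("index_set", "data.frame")
  tab
}
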