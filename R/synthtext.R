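#' Specify a latent model for synthetic expositional documents
#'
#' The latent structure is a planted core-periphery graph with periphery
#' communities: core-core pairs connect with probability `p_cc`,
#' core-periphery with `p_cp`, periphery pairs within one community with
#' `p_pp_in`, and across communities with `p_pp_out`. A document then
#' "exposes" this graph sentence by sentence, with `core_bias`
#' controlling how strongly core-incident relations concentrate early.
#'
#' Defaults plant a clearly detectable structure (a dense 15-node core,
#' 45 periphery nodes in 5 communities) in a document long enough for most
#' relations to be mentioned naturally.
#'
#' @param n_core,n_periph Core and periphery node counts.
#' @param n_comm Number of periphery communities (sizes as equal as
#'   possible).
#' @param p_cc,p_cp,p_pp_in,p_pp_out Pairwise connection probabilities.
#' @param core_bias Nonnegative real; 0 gives an unbiased exposition
#'   schedule, larger values delay pure-periphery relations.
#' @param n_sentences Number of randomly scheduled sentences (a forced
#'   sweep may append further sentences so that every latent relation is
#'   mentioned at least once).
#' @param filler_rate Expected stop-word filler tokens per sentence.
#' @param seed Integer seed used by [generate_latent_graph()] and
#'   [generate_document()] unless overridden there.
#' @return A `latent_model` list.
#' @export
latent_model <- function(n_core = 15L, n_periph = 45L, n_comm = 5L,
                         p_cc = 0.9, p_cp = 0.3, p_pp_in = 0.6,
                         p_pp_out = 0.02, core_bias = 5,
                         n_sentences = 1000L, filler_rate = 4,
                         seed = 1L) {
  probs <- c(p_cc = p_cc, p_cp = p_cp, p_pp_in = p_pp_in,
             p_pp_out = p_pp_out)
  stopifnot(all(probs >= 0 & probs <= 1), core_bias >= 0,
            n_core >= 1L, n_periph >= 0L, n_comm >= 1L,
            n_sentences >= 1L, filler_rate >= 0)
  structure(list(n_core = as.integer(n_core),
                 n_periph = as.integer(n_periph),
                 n_comm = as.integer(n_comm),
                 p_cc = p_cc, p_cp = p_cp, p_pp_in = p_pp_in,
                 p_pp_out = p_pp_out, core_bias = core_bias,
                 n_sentences = as.integer(n_sentences),
                 filler_rate = filler_rate, seed = as.integer(seed)),
            class = "latent_model")
}

#' Sample the latent concept graph of a synthetic document
#'
#' @param m A [latent_model()].
#' @param seed Integer seed (default `m$seed`).
#' @return List with `graph` (unit-weight `igraph`, vertex names
#'   `core01..`, `periph01..`), and `labels` (data frame: `node`, `role`
#'   core/periphery, `community` id or NA for core nodes).
#' @export
generate_latent_graph <- function(m, seed = m$seed) {
  stopifnot(inherits(m, "latent_model"))
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- m$n_core + m$n_periph
  pad <- function(prefix, k) {
    sprintf("%s%0*d", prefix, max(2L, nchar(as.character(k))), seq_len(k))
  }
  nodes <- c(pad("core", m$n_core),
             if (m$n_periph > 0L) pad("periph", m$n_periph))
  role <- rep(c("core", "periphery"), c(m$n_core, m$n_periph))
  community <- rep(NA_integer_, n)
  if (m$n_periph > 0L) {
    community[role == "periphery"] <-
      sort(rep_len(seq_len(m$n_comm), m$n_periph))
  }
  pairs <- utils::combn(n, 2L)
  i <- pairs[1L, ]; j <- pairs[2L, ]
  both_core <- role[i] == "core" & role[j] == "core"
  both_periph <- role[i] == "periphery" & role[j] == "periphery"
  p <- ifelse(both_core, m$p_cc,
              ifelse(both_periph,
                     ifelse(community[i] == community[j],
                            m$p_pp_in, m$p_pp_out),
                     m$p_cp))
  keep <- stats::runif(ncol(pairs)) < p
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- nodes
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(nodes[i[keep]], nodes[j[keep]]),
                           attr = list(weight = rep(1, sum(keep))))
  }
  if (igraph::count_components(g) > 1L) {
    message("latent graph is disconnected (",
            igraph::count_components(g), " components)")
  }
  list(graph = g,
       labels = data.frame(node = nodes, role = role,
                           community = community,
                           stringsAsFactors = FALSE))
}

#' Common content words used as synthetic filler
#'
#' The single-word entries with nonzero counts in the packaged synthetic
#' reference-count table. Mixed into generated sentences as ordinary
#' (non-stop, non-concept) vocabulary.
#'
#' @return Character vector of words.
#' @export
synth_mundane_words <- function() {
  tab <- utils::read.delim(
    system.file("extdata", "synthetic_reference_counts.tsv",
                package = "exposnet", mustWork = TRUE),
    stringsAsFactors = FALSE)
  tab$phrase[tab$count > 0 & !grepl(" ", tab$phrase)]
}

#' Packaged synthetic reference phrase-count table
#'
#' A small stand-in for a reference-corpus frequency table (the counts
#' are synthetic, not measured from any corpus); real analyses should
#' supply their own table via [read_reference_counts()].
#'
#' @return Named numeric vector of counts.
#' @export
synth_reference_counts <- function() {
  read_reference_counts(
    system.file("extdata", "synthetic_reference_counts.tsv",
                package = "exposnet", mustWork = TRUE))
}

# Deterministic nonsense lexicon: pronounceable consonant-vowel words of
# length >= 6, so no real-word dictionary or stop list can collide with
# them and the VAR-scrubbing rules never fire on a concept token.
synth_lexicon <- function(n_words, seed) {
  consonants <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r",
                  "s", "t", "v", "z")
  vowels <- c("a", "e", "i", "o", "u")
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  words <- character(0)
  while (length(words) < n_words) {
    batch <- vapply(seq_len(n_words), function(i) {
      paste0(paste0(sample(consonants, 3L, replace = TRUE),
                    sample(vowels, 3L, replace = TRUE)),
             collapse = "")
    }, character(1))
    words <- unique(c(words, batch))
  }
  words[seq_len(n_words)]
}

#' Generate a synthetic expositional document from a latent graph
#'
#' Emits sentences that mention pairs of latent concepts. Each scheduled
#' sentence samples one latent relation (u, v) with probability
#' proportional to `exp(-core_bias * (1 - t) * periphery(u, v))`, where
#' `t` is the normalized sentence position and `periphery(u, v)` is 1 for
#' relations between two periphery nodes: pure-periphery relations are
#' suppressed early, so core-incident structure concentrates at the start
#' when `core_bias > 0`, and the schedule is uniform when it is 0. After
#' the scheduled sentences, any latent relation never sampled is emitted
#' once in a forced sweep, so the recovered co-occurrence network equals
#' the latent edge set exactly. Concept names are one- or two-word
#' nonsense phrases; filler tokens are drawn from the stop list.
#'
#' @param m A [latent_model()].
#' @param latent Output of [generate_latent_graph()] (regenerated from
#'   `m` when `NULL`).
#' @param stop_list Stop words used as filler (default
#'   [default_stop_list()]).
#' @param mundane Common content words mixed into the filler (default
#'   [synth_mundane_words()]); they are not stop words, so — like the
#'   ordinary vocabulary of real prose — they form low-value candidate
#'   keyphrases that the reference-corpus penalty should demote.
#' @param mundane_frac Fraction of filler tokens drawn from `mundane`
#'   rather than the stop list (default 0.25).
#' @param seed Integer seed (default `m$seed`).
#' @return List with `text` (single string), `index` (data frame: `node`,
#'   `phrase`), `labels`, `graph` (the latent graph with phrases as an
#'   attribute), and `spell_checker` (accepts the synthetic lexicon).
#' @export
generate_document <- function(m, latent = NULL,
                              stop_list = default_stop_list(),
                              mundane = synth_mundane_words(),
                              mundane_frac = 0.25,
                              seed = m$seed) {
  stopifnot(inherits(m, "latent_model"))
  if (is.null(latent)) latent <- generate_latent_graph(m, seed = seed)
  g <- latent$graph
  labels <- latent$labels
  n <- igraph::vcount(g)
  old <- globalenv()$.Random.seed
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed + 1L)

  words <- synth_lexicon(2L * n, seed = seed + 2L)
  two_word <- seq_len(n) %% 3L == 0L   # every third concept is a bigram
  phrase <- ifelse(two_word,
                   paste(words[seq_len(n)], words[n + seq_len(n)]),
                   words[seq_len(n)])
  if (anyDuplicated(phrase)) stop("vocabulary collision in synthetic lexicon")
  first_words <- vapply(strsplit(phrase, " "), `[`, character(1), 1L)
  if (anyDuplicated(first_words)) {
    stop("vocabulary collision: one phrase is a prefix of another")
  }
  names(phrase) <- labels$node

  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0L) stop("latent graph has no relations to expose")
  is_periph <- labels$role == "periphery"
  names(is_periph) <- labels$node
  edge_periph <- is_periph[el[, 1L]] & is_periph[el[, 2L]]

  n_sched <- m$n_sentences
  chosen <- integer(n_sched)
  for (s in seq_len(n_sched)) {
    t_norm <- if (n_sched > 1L) (s - 1L) / (n_sched - 1L) else 1
    wts <- exp(-m$core_bias * (1 - t_norm) * edge_periph)
    chosen[s] <- sample.int(nrow(el), 1L, prob = wts)
  }
  unseen <- setdiff(seq_len(nrow(el)), unique(chosen))
  schedule <- c(chosen, unseen)

  stop_pool <- stop_list[nchar(stop_list) >= 3L]
  sentences <- vapply(schedule, function(e) {
    u <- phrase[el[e, 1L]]; v <- phrase[el[e, 2L]]
    n_fill <- stats::rpois(1L, m$filler_rate)
    fill <- if (n_fill > 0L) {
      # content (mundane) filler words never sit adjacent to each other:
      # as in ordinary prose, function words separate them
      from_mundane <- stats::runif(n_fill) < mundane_frac &
        length(mundane) > 0L
      if (n_fill > 1L) {
        for (i in 2:n_fill) {
          if (from_mundane[i - 1L]) from_mundane[i] <- FALSE
        }
      }
      ifelse(from_mundane,
             sample(mundane, n_fill, replace = TRUE),
             sample(stop_pool, n_fill, replace = TRUE))
    } else {
      character(0)
    }
    k <- length(fill)
    cut1 <- sample.int(k + 1L, 1L) - 1L
    cut2 <- if (k > cut1) cut1 + sample.int(k - cut1 + 1L, 1L) - 1L else cut1
    parts <- c(fill[seq_len(cut1)], u,
               fill[seq_len(cut2 - cut1) + cut1], v,
               if (cut2 < k) fill[(cut2 + 1L):k])
    paste0(paste(parts, collapse = " "), ".")
  }, character(1))

  lexicon <- unique(c(unlist(strsplit(phrase, " ")), stop_list, mundane))
  list(text = paste(sentences, collapse = " "),
       index = data.frame(node = labels$node, phrase = unname(phrase),
                          stringsAsFactors = FALSE),
       labels = labels,
       graph = g,
       n_scheduled = n_sched,
       n_sentences = length(schedule),
       spell_checker = function(w) w %in% lexicon)
}

#' Run the full pipeline on a synthetic document with known ground truth
#'
#' Convenience wrapper: generates latent graph and document, preprocesses
#' the text, and builds the total network and sentence filtration using
#' the ground-truth index phrases.
#'
#' @param m A [latent_model()].
#' @param seed Integer seed (default `m$seed`).
#' @param stop_list Stop words (default [default_stop_list()]).
#' @return List with `doc` (tokenized document), `network`, `filtration`,
#'   `phrases` (ground-truth index), `labels` translated to phrase names,
#'   `latent` (the generator output), and `model`.
#' @export
synth_pipeline <- function(m = latent_model(), seed = m$seed,
                           stop_list = default_stop_list()) {
  latent <- generate_latent_graph(m, seed = seed)
  synth <- generate_document(m, latent, stop_list = stop_list, seed = seed)
  doc <- preprocess_document(synth$text, stop_list,
                             spell_checker = synth$spell_checker,
                             source_id = sprintf("synth-%d", seed))
  phrases <- synth$index$phrase
  labels <- synth$labels
  labels$phrase <- synth$index$phrase[match(labels$node, synth$index$node)]
  list(doc = doc,
       network = build_total_network(doc, phrases),
       filtration = build_sentence_filtration(doc, phrases),
       phrases = phrases,
       labels = labels,
       latent = synth,
       model = m)
}
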