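# Internal: occurrences of index phrases in one token sentence, with the
# subsumption rule applied (an occurrence strictly inside a longer matched
# phrase occurrence does not count on its own).
# Returns data.frame(phrase, start, end).
match_occurrences <- function(tokens, phrase_tokens) {
  n <- length(tokens)
  if (n == 0L) return(data.frame(phrase = character(0), start = integer(0),
                                 end = integer(0)))
  occ_phrase <- character(0); occ_start <- integer(0); occ_end <- integer(0)
  for (p in names(phrase_tokens)) {
    pt <- phrase_tokens[[p]]
    L <- length(pt)
    if (L > n) next
    starts <- which(tokens == pt[1L])
    starts <- starts[starts + L - 1L <= n]
    if (L > 1L) {
      ok <- vapply(starts, function(s) {
        all(tokens[s:(s + L - 1L)] == pt)
      }, logical(1))
      starts <- starts[ok]
    }
    if (length(starts)) {
      occ_phrase <- c(occ_phrase, rep(p, length(starts)))
      occ_start <- c(occ_start, starts)
      occ_end <- c(occ_end, starts + L - 1L)
    }
  }
  if (length(occ_phrase) == 0L) {
    return(data.frame(phrase = character(0), start = integer(0),
                      end = integer(0)))
  }
  len <- occ_end - occ_start + 1L
  keep <- vapply(seq_along(occ_phrase), function(i) {
    contained <- occ_start <= occ_start[i] & occ_end >= occ_end[i] &
      len > len[i]
    !any(contained)
  }, logical(1))
  data.frame(phrase = occ_phrase[keep], start = occ_start[keep],
             end = occ_end[keep], stringsAsFactors = FALSE)
}

#' Concepts matched in a single sentence
#'
#' Returns every index phrase whose token sequence occurs contiguously in
#' the sentence. An occurrence strictly contained inside a longer matched
#' index-phrase occurrence does not count on its own ("vector space"
#' suppresses the inner "space"), preventing artifactual edges between a
#' phrase and its sub-phrases.
#'
#' @param sentence Character vector of tokens (same pipeline as the index).
#' @param index An `index_set` or character vector of phrases.
#' @return Character vector of matched concepts (sorted, unique).
#' @export
match_concepts <- function(sentence, index) {
  phrases <- index_phrases(index)
  pt <- strsplit(phrases, " ", fixed = TRUE)
  names(pt) <- phrases
  occ <- match_occurrences(sentence, pt)
  sort(unique(occ$phrase))
}

# Internal: matched occurrence tables for every sentence, using a
# first-word inverted index to skip phrases that cannot occur.
match_document <- function(doc, index) {
  phrases <- index_phrases(index)
  if (anyDuplicated(phrases)) stop("index contains duplicate phrases")
  pt <- strsplit(phrases, " ", fixed = TRUE)
  names(pt) <- phrases
  first_word <- vapply(pt, `[`, character(1), 1L)
  lapply(doc$sentences, function(toks) {
    cand <- phrases[first_word %in% toks]
    if (length(cand) == 0L) {
      return(data.frame(phrase = character(0), start = integer(0),
                        end = integer(0)))
    }
    match_occurrences(toks, pt[cand])
  })
}

sorted_pair_keys <- function(u, v) {
  lo <- pmin(u, v)
  hi <- pmax(u, v)
  paste(lo, hi, sep = "\r")
}

split_pair_keys <- function(keys) {
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(u = vapply(parts, `[`, character(1), 1L),
             v = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Build the total weighted semantic network
#'
#' One node per index concept that is matched at least once; an edge
#' between two concepts carries an integer weight equal to the number of
#' sentences in which both are matched (within-sentence multiplicity does
#' not add weight).
#'
#' @param doc A `tokenized_document`.
#' @param index An `index_set` or character vector of phrases.
#' @return An undirected `igraph` graph with vertex attribute `name` and
#'   edge attribute `weight`.
#' @export
build_total_network <- function(doc, index) {
  occs <- match_document(doc, index)
  matched_sets <- lapply(occs, function(o) sort(unique(o$phrase)))
  nodes <- sort(unique(unlist(matched_sets, use.names = FALSE)))
  all_phrases <- index_phrases(index)
  missing <- setdiff(all_phrases, nodes)
  if (length(missing)) {
    message(length(missing), " index concepts never matched; excluded from network")
  }
  pair_keys <- unlist(lapply(matched_sets, function(s) {
    if (length(s) < 2L) return(character(0))
    cmb <- utils::combn(s, 2L)
    sorted_pair_keys(cmb[1L, ], cmb[2L, ])
  }), use.names = FALSE)
  if (length(nodes) == 0L) {
    warning("no index concepts matched; returning empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (length(pair_keys)) {
    tab <- table(pair_keys)
    uv <- split_pair_keys(names(tab))
    g <- igraph::add_edges(g, rbind(uv$u, uv$v),
                           attr = list(weight = as.integer(tab)))
  }
  g
}

#' Construct a filtration object
#'
#' Low-level constructor; most users should call
#' [build_sentence_filtration()] or [build_oaat_filtration()].
#'
#' @param node_birth Named integer vector: concept -> birth step.
#' @param edge_birth Data frame with columns `u`, `v`, `birth`.
#' @param n_steps Total number of filtration steps N.
#' @param kind Label, e.g. `"sentence"`, `"oaat"`, or a null-model name.
#' @param validate Check the nesting invariants (default TRUE).
#' @return A `filtration` object.
#' @export
new_filtration <- function(node_birth, edge_birth, n_steps, kind,
                           validate = TRUE) {
  node_birth <- node_birth[order(names(node_birth))]
  storage.mode(node_birth) <- "integer"
  if (nrow(edge_birth)) {
    lo <- pmin(edge_birth$u, edge_birth$v)
    hi <- pmax(edge_birth$u, edge_birth$v)
    edge_birth <- data.frame(u = lo, v = hi,
                             birth = as.integer(edge_birth$birth),
                             stringsAsFactors = FALSE)
    edge_birth <- edge_birth[order(edge_birth$birth, edge_birth$u,
                                   edge_birth$v), , drop = FALSE]
    rownames(edge_birth) <- NULL
  } else {
    edge_birth <- data.frame(u = character(0), v = character(0),
                             birth = integer(0), stringsAsFactors = FALSE)
  }
  f <- structure(
    list(node_birth = node_birth, edge_birth = edge_birth,
         n_steps = as.integer(n_steps), kind = kind),
    class = "filtration"
  )
  if (validate) validate_filtration(f)
  f
}

#' Validate filtration nesting invariants
#'
#' Checks that all births lie in `[1, N]`, that no edge is born before
#' either endpoint, that endpoints exist, and that there are no duplicate
#' edges or self-loops. Errors on violation.
#'
#' @param f A `filtration`.
#' @return `f`, invisibly.
#' @export
validate_filtration <- function(f) {
  stopifnot(inherits(f, "filtration"))
  nb <- f$node_birth
  eb <- f$edge_birth
  if (length(nb) && (min(nb) < 1L || max(nb) > f$n_steps)) {
    stop("node births outside [1, N]")
  }
  if (nrow(eb)) {
    if (min(eb$birth) < 1L || max(eb$birth) > f$n_steps) {
      stop("edge births outside [1, N]")
    }
    if (any(eb$u == eb$v)) stop("self-loop in filtration")
    if (anyDuplicated(paste(eb$u, eb$v, sep = "\r"))) {
      stop("duplicate edge in filtration")
    }
    if (!all(eb$u %in% names(nb)) || !all(eb$v %in% names(nb))) {
      stop("edge endpoint missing from node set")
    }
    if (any(eb$birth < pmax(nb[eb$u], nb[eb$v]))) {
      stop("edge born before one of its endpoints")
    }
  }
  invisible(f)
}

#' @export
print.filtration <- function(x, ...) {
  cat(sprintf("<filtration (%s): %d nodes, %d edges, N = %d steps>\n",
              x$kind, length(x$node_birth), nrow(x$edge_birth), x$n_steps))
  invisible(x)
}

#' Binary graph at a filtration step
#'
#' @param f A `filtration`.
#' @param step Step index k (default N); returns G_k, the graph of all
#'   elements born at or before k.
#' @return An unweighted undirected `igraph` graph.
#' @export
filtration_graph <- function(f, step = f$n_steps) {
  nodes <- names(f$node_birth)[f$node_birth <= step]
  eb <- f$edge_birth[f$edge_birth$birth <= step, , drop = FALSE]
  g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
  igraph::V(g)$name <- nodes
  if (nrow(eb)) g <- igraph::add_edges(g, rbind(eb$u, eb$v))
  g
}

#' Build the expositional (sentence-level) filtration
#'
#' Each concept is born at the first sentence in which it is matched; each
#' edge at the first sentence in which its endpoints are matched together.
#' N equals the number of sentences. Edge weights are disregarded (the
#' growing graphs are binary); the step-N graph equals the binarized total
#' network.
#'
#' @param doc A `tokenized_document`.
#' @param index An `index_set` or character vector of phrases.
#' @return A `filtration` with `kind = "sentence"`.
#' @export
build_sentence_filtration <- function(doc, index) {
  occs <- match_document(doc, index)
  matched_sets <- lapply(occs, function(o) sort(unique(o$phrase)))
  node_birth <- integer(0)
  edge_birth_env <- new.env(parent = emptyenv())
  for (k in seq_along(matched_sets)) {
    s <- matched_sets[[k]]
    if (length(s) == 0L) next
    new_nodes <- setdiff(s, names(node_birth))
    if (length(new_nodes)) {
      nb <- rep(k, length(new_nodes))
      names(nb) <- new_nodes
      node_birth <- c(node_birth, nb)
    }
    if (length(s) >= 2L) {
      cmb <- utils::combn(s, 2L)
      keys <- sorted_pair_keys(cmb[1L, ], cmb[2L, ])
      for (key in keys) {
        if (is.null(edge_birth_env[[key]])) edge_birth_env[[key]] <- k
      }
    }
  }
  keys <- ls(edge_birth_env)
  eb <- if (length(keys)) {
    uv <- split_pair_keys(keys)
    data.frame(u = uv$u, v = uv$v,
               birth = vapply(keys, function(k) edge_birth_env[[k]],
                              numeric(1)),
               stringsAsFactors = FALSE)
  } else {
    data.frame(u = character(0), v = character(0), birth = integer(0))
  }
  new_filtration(node_birth, eb, n_steps = doc$n_sentences,
                 kind = "sentence")
}

#' Build the one-at-a-time (OAAT) filtration
#'
#' Refines the sentence filtration so that exactly one element is
#' introduced per step, exposing sub-sentence structure and making
#' persistence comparable across documents of different sentence counts.
#' Within a sentence, new nodes are added first (ordered by first
#' occurrence position, ties lexicographic), then new edges (ordered by
#' the later endpoint's position, ties lexicographic on the sorted pair).
#' Collapsing consecutive steps belonging to one sentence recovers the
#' sentence filtration.
#'
#' @inheritParams build_sentence_filtration
#' @return A `filtration` with `kind = "oaat"` and attribute
#'   `sentence_of_step` mapping each OAAT step to its source sentence.
#' @export
build_oaat_filtration <- function(doc, index) {
  occs <- match_document(doc, index)
  node_birth <- integer(0)
  edge_seen <- new.env(parent = emptyenv())
  eb_u <- character(0); eb_v <- character(0); eb_birth <- integer(0)
  sentence_of_step <- integer(0)
  step <- 0L
  for (k in seq_along(occs)) {
    o <- occs[[k]]
    if (nrow(o) == 0L) next
    pos <- tapply(o$start, o$phrase, min)
    s <- names(pos)
    new_nodes <- setdiff(s, names(node_birth))
    new_nodes <- new_nodes[order(pos[new_nodes], new_nodes)]
    for (v in new_nodes) {
      step <- step + 1L
      nb <- step; names(nb) <- v
      node_birth <- c(node_birth, nb)
      sentence_of_step <- c(sentence_of_step, k)
    }
    if (length(s) >= 2L) {
      cmb <- utils::combn(sort(s), 2L)
      keys <- sorted_pair_keys(cmb[1L, ], cmb[2L, ])
      is_new <- vapply(keys, function(key) is.null(edge_seen[[key]]),
                       logical(1))
      if (any(is_new)) {
        u <- pmin(cmb[1L, is_new], cmb[2L, is_new])
        v <- pmax(cmb[1L, is_new], cmb[2L, is_new])
        epos <- pmax(pos[u], pos[v])
        ord <- order(epos, u, v)
        for (j in ord) {
          step <- step + 1L
          eb_u <- c(eb_u, u[j]); eb_v <- c(eb_v, v[j])
          eb_birth <- c(eb_birth, step)
          edge_seen[[sorted_pair_keys(u[j], v[j])]] <- TRUE
          sentence_of_step <- c(sentence_of_step, k)
        }
      }
    }
  }
  f <- new_filtration(node_birth,
                      data.frame(u = eb_u, v = eb_v, birth = eb_birth,
                                 stringsAsFactors = FALSE),
                      n_steps = max(step, 1L), kind = "oaat")
  attr(f, "sentence_of_step") <- sentence_of_step
  f
}

#' Write a filtration as TSV
#'
#' Columns: `element_type` (node/edge), `u`, `v` (blank for nodes),
#' `birth_step`; rows ordered by birth then lexicographically.
#'
#' @param f A `filtration`.
#' @param path Output path.
#' @export
write_filtration <- function(f, path) {
  nodes <- data.frame(element_type = rep("node", length(f$node_birth)),
                      u = names(f$node_birth),
                      v = rep("", length(f$node_birth)),
                      birth_step = as.integer(f$node_birth),
                      stringsAsFactors = FALSE)
  edges <- data.frame(element_type = rep("edge", nrow(f$edge_birth)),
                      u = f$edge_birth$u,
                      v = f$edge_birth$v,
                      birth_step = f$edge_birth$birth,
                      stringsAsFactors = FALSE)
  tab <- rbind(nodes, edges)
  tab <- tab[order(tab$birth_step, tab$element_type, tab$u, tab$v), ,
             drop = FALSE]
  header <- sprintf("# n_steps=%d kind=%s", f$n_steps, f$kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a filtration written by [write_filtration()]
#'
#' @param path Input path.
#' @return A `filtration`.
#' @export
read_filtration <- function(path) {
  header <- readLines(path, n = 1L)
  meta <- regmatches(header,
                     regexec("n_steps=(\\d+) kind=(\\S+)", header))[[1]]
  if (length(meta) != 3L) stop("malformed filtration header")
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  nodes <- tab[tab$element_type == "node", , drop = FALSE]
  edges <- tab[tab$element_type == "edge", , drop = FALSE]
  nb <- nodes$birth_step
  names(nb) <- nodes$u
  new_filtration(nb,
                 data.frame(u = edges$u, v = edges$v,
                            birth = edges$birth_step,
                            stringsAsFactors = FALSE),
                 n_steps = as.integer(meta[2L]), kind = meta[3L])
}

#' Write a weighted network as a TSV edge list (u, v, w)
#'
#' @param g Weighted `igraph` graph.
#' @param path Output path.
#' @export
write_edgelist <- function(g, path) {
  el <- igraph::as_data_frame(g, what = "edges")
  names(el)[1:2] <- c("u", "v")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
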