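# Small deterministic fixtures built in code.

make_doc <- function(sentences, source_id = "fixture") {
  structure(list(sentences = sentences, n_sentences = length(sentences),
                 source_id = source_id),
            class = "tokenized_document")
}

# a tiny dictionary-based spell checker for preprocess tests
tiny_dictionary <- c("the", "map", "set", "sum", "zero", "base", "form",
                     "rank", "row", "one", "two", "ten")
tiny_spell <- function(w) w %in% tiny_dictionary

# random Erdos-Renyi graph with a random valid filtration: node births
# uniform, edge births at least the later endpoint's birth
random_filtration <- function(n, p, seed, n_steps = NULL) {
  set.seed(seed)
  nodes <- sprintf("v%02d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  if (is.null(n_steps)) n_steps <- n + sum(keep)
  nb <- sample.int(max(1L, n_steps %/% 2L), n, replace = TRUE)
  names(nb) <- nodes
  if (any(keep)) {
    u <- pairs[1L, keep]; v <- pairs[2L, keep]
    lo <- pmax(nb[u], nb[v])
    eb <- data.frame(u = u, v = v,
                     birth = lo + sample.int(max(1L, n_steps %/% 2L),
                                             sum(keep), replace = TRUE) - 1L,
                     stringsAsFactors = FALSE)
    eb$birth <- pmin(eb$birth, n_steps)
  } else {
    eb <- data.frame(u = character(0), v = character(0), birth = integer(0))
  }
  new_filtration(nb, eb, n_steps = max(n_steps, nb, eb$birth),
                 kind = "random-fixture")
}

# random weighted graph for meso-scale oracle tests
random_weighted_graph <- function(n, p, seed, max_w = 4L) {
  set.seed(seed)
  nodes <- if (n <= 26L) letters[seq_len(n)] else sprintf("n%03d", seq_len(n))
  pairs <- utils::combn(nodes, 2L)
  keep <- stats::runif(ncol(pairs)) < p
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- nodes
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(pairs[1L, keep], pairs[2L, keep]),
                           attr = list(weight = sample.int(max_w, sum(keep),
                                                           replace = TRUE)))
  }
  g
}

unit_graph <- function(edges) {
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- 1
  g
}

two_triangles <- function() {
  unit_graph(cbind(c("a", "b", "a", "d", "e", "d"),
                   c("b", "c", "c", "e", "f", "f")))
}
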