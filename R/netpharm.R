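# Network-pharmacology stage: confidence-filtered gene-interaction graphs,
# eight topological centralities with top-k hub lists (CytoHubba-style),
# strict hub consensus, and hypergeometric fold enrichment.

CENTRALITY_METHODS <- c("MCC", "MNC", "Degree", "EPC", "Closeness",
                        "Betweenness", "Radiality", "Stress")

# run expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Load a confidence-filtered gene-interaction graph
#'
#' Reads an edge TSV (`geneA`, `geneB`, `combined_score`) such as a STRING
#' export, keeps edges with `combined_score > min_confidence`, drops
#' self-loops and duplicate undirected edges, and returns the graph over the
#' remaining edges (so isolated nodes are excluded). Scores gate edges and
#' are then discarded: path-based centralities treat the graph as
#' unweighted.
#'
#' @param path TSV path, or a data frame with those three columns.
#' @param min_confidence Edges with score strictly above this are kept
#'   (default 0.9, "highest confidence").
#' @return An undirected `igraph` graph.
#' @export
load_graph <- function(path, min_confidence = 0.9) {
  tab <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("edge file not found: ", path)
    utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  need <- c("geneA", "geneB", "combined_score")
  if (!all(need %in% names(tab))) {
    stop("edge table needs columns: ", paste(need, collapse = ", "))
  }
  tab$combined_score <- suppressWarnings(as.numeric(tab$combined_score))
  if (anyNA(tab$combined_score) || !all(nzchar(tab$geneA) & nzchar(tab$geneB))) {
    stop("malformed edge row(s): empty symbol or non-numeric score")
  }
  tab <- tab[tab$combined_score > min_confidence, , drop = FALSE]
  tab <- tab[tab$geneA != tab$geneB, , drop = FALSE]
  a <- pmin(tab$geneA, tab$geneB)
  b <- pmax(tab$geneA, tab$geneB)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  if (!any(keep)) {
    warning("no edges pass the confidence threshold; graph is empty")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  igraph::graph_from_data_frame(
    data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE),
    directed = FALSE)
}

#' Read a gene-set file (one symbol per line)
#'
#' @param path File path.
#' @return Character vector of unique, non-empty symbols.
#' @export
load_gene_set <- function(path) {
  if (!file.exists(path)) stop("gene-set file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}

#' Overlap of predicted peptide targets with a disease gene set
#'
#' @param peptide_sets List of character vectors (one predicted target set
#'   per peptide) or a single character vector.
#' @param disease Character vector of disease-associated gene symbols.
#' @return Sorted character vector: (union of peptide sets) intersected with
#'   the disease set.
#' @export
overlap_targets <- function(peptide_sets, disease) {
  if (!is.list(peptide_sets)) peptide_sets <- list(peptide_sets)
  sort(intersect(unique(unlist(peptide_sets)), unique(disease)))
}

# ---- internal graph helpers -------------------------------------------------

.adj_list <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

# number of shortest paths between every ordered pair (unweighted graph)
.path_counts <- function(adj, dist) {
  n <- nrow(dist)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- dist[s, ]
    sig <- numeric(n)
    sig[s] <- 1
    for (v in order(d)) {
      if (v == s || !is.finite(d[v])) next
      preds <- adj[[v]][d[adj[[v]]] == d[v] - 1]
      sig[v] <- sum(sig[preds])
    }
    sigma[s, ] <- sig
  }
  sigma
}

.stress_scores <- function(g) {
  n <- igraph::vcount(g)
  dist <- igraph::distances(g)
  adj <- .adj_list(g)
  sigma <- .path_counts(adj, dist)
  scores <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) {
      if (s == v) next
      for (t in (s + 1):n) {
        if (t == v || !is.finite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          tot <- tot + sigma[s, v] * sigma[v, t]
        }
      }
    }
    scores[v] <- tot
  }
  scores
}

.mcc_scores <- function(g) {
  n <- igraph::vcount(g)
  scores <- numeric(n)
  cliques <- igraph::max_cliques(g)
  for (cl in cliques) {
    idx <- as.integer(cl)
    scores[idx] <- scores[idx] + factorial(length(idx) - 1L)
  }
  scores
}

.mnc_scores <- function(g) {
  vapply(seq_len(igraph::vcount(g)), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (length(nb) == 0L) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    max(igraph::components(sub)$csize)
  }, numeric(1))
}

.harmonic_closeness <- function(g) {
  dist <- igraph::distances(g)
  diag(dist) <- Inf
  rowSums(1 / dist)
}

.radiality_scores <- function(g) {
  n <- igraph::vcount(g)
  dist <- igraph::distances(g)
  comp <- igraph::components(g)
  scores <- numeric(n)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2L) next  # singleton: radiality 0
    d <- dist[members, members, drop = FALSE]
    delta <- max(d)
    for (i in seq_along(members)) {
      scores[members[i]] <-
        sum(delta + 1 - d[i, -i]) / (length(members) - 1L)
    }
  }
  scores
}

.epc_scores <- function(g, reps, keep_prob, seed) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (m == 0L) return(numeric(n))
  .with_seed(seed, {
    scores <- numeric(n)
    for (r in seq_len(reps)) {
      keep <- which(stats::runif(m) < keep_prob)
      sub <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
      cc <- igraph::components(sub)
      scores <- scores + cc$csize[cc$membership]
    }
    scores / reps
  })
}

# ---- public centrality API --------------------------------------------------

#' Topological centrality with top-k hub list
#'
#' Implements the eight hub-ranking methods popularised by CytoHubba:
#' \describe{
#'   \item{Degree}{neighbour count.}
#'   \item{MNC}{maximum neighbourhood component: size of the largest
#'     connected component of the subgraph induced by the node's neighbours.}
#'   \item{MCC}{maximal clique centrality: sum of `(|C| - 1)!` over the
#'     maximal cliques `C` containing the node.}
#'   \item{Closeness}{harmonic closeness, `sum(1 / d(v, u))` over reachable
#'     `u` (unreachable nodes contribute 0, so disconnected graphs are
#'     handled).}
#'   \item{Betweenness}{shortest-path betweenness.}
#'   \item{Stress}{number of shortest paths passing through the node.}
#'   \item{Radiality}{within each connected component,
#'     `mean(diam + 1 - d(v, u))` over the other members, with `diam` the
#'     component diameter; singletons score 0.}
#'   \item{EPC}{edge-percolated component: Monte-Carlo mean size of the
#'     node's connected component when each edge is independently retained
#'     with probability `keep_prob`; requires a seed for reproducibility.}
#' }
#' Top-k ties are broken by lexicographic node name.
#'
#' @param graph Undirected `igraph` graph with named vertices.
#' @param method One of `r paste(CENTRALITY_METHODS, collapse = ", ")`.
#' @param k Size of the hub list (default 10).
#' @param epc_reps,epc_keep_prob,epc_seed EPC Monte-Carlo parameters;
#'   `epc_seed` is mandatory when `method = "EPC"`.
#' @return A `centrality_result`: list with `method`, named numeric `scores`
#'   and the ordered character vector `top_k`.
#' @export
centrality <- function(graph, method, k = 10L,
                       epc_reps = 1000L, epc_keep_prob = 0.5, epc_seed = NULL) {
  stopifnot(igraph::is_igraph(graph))
  if (igraph::vcount(graph) == 0L) stop("graph has no nodes")
  if (!method %in% CENTRALITY_METHODS) {
    stop("unknown centrality method '", method, "'; available: ",
         paste(CENTRALITY_METHODS, collapse = ", "))
  }
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(graph)))
  scores <- switch(method,
    Degree = as.numeric(igraph::degree(graph)),
    MNC = .mnc_scores(graph),
    MCC = .mcc_scores(graph),
    Closeness = .harmonic_closeness(graph),
    Betweenness = as.numeric(igraph::betweenness(graph, directed = FALSE)),
    Stress = .stress_scores(graph),
    Radiality = .radiality_scores(graph),
    EPC = {
      if (is.null(epc_seed)) stop("EPC requires epc_seed for reproducibility")
      .epc_scores(graph, reps = epc_reps, keep_prob = epc_keep_prob,
                  seed = epc_seed)
    }
  )
  names(scores) <- nm
  ord <- order(-scores, nm)
  structure(list(method = method, scores = scores,
                 top_k = nm[ord][seq_len(min(k, length(nm)))]),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  cat("<centrality_result>", x$method, "- top:",
      paste(x$top_k, collapse = ", "), "\n")
  invisible(x)
}

#' Centrality table across methods
#'
#' @param graph Undirected `igraph` graph.
#' @param methods Methods to run (default all eight).
#' @param k Hub-list size.
#' @param epc_reps,epc_keep_prob,epc_seed EPC parameters (see [centrality()]).
#' @return List of `centrality_result`, named by method.
#' @export
centrality_panel <- function(graph, methods = CENTRALITY_METHODS, k = 10L,
                             epc_reps = 1000L, epc_keep_prob = 0.5,
                             epc_seed = NULL) {
  out <- lapply(methods, centrality, graph = graph, k = k,
                epc_reps = epc_reps, epc_keep_prob = epc_keep_prob,
                epc_seed = epc_seed)
  names(out) <- methods
  out
}

#' Hub consensus: strict intersection of top-k lists
#'
#' @param results List of `centrality_result` objects, or a plain list of
#'   character vectors (externally computed top-k columns).
#' @return Sorted character vector of genes present in every list.
#' @export
consensus_hubs <- function(results) {
  stopifnot(is.list(results), length(results) >= 2L)
  lists <- lapply(results, function(r) {
    if (inherits(r, "centrality_result")) r$top_k else as.character(r)
  })
  sort(Reduce(intersect, lists))
}

#' Fold enrichment and hypergeometric tail probability
#'
#' For `k` hits of a functional category among `n` selected genes, with `K`
#' category members in a background of `N` genes: fold enrichment is
#' `(k / n) / (K / N)` and the p-value is the upper-tail hypergeometric
#' `P(X >= k)`. This is the plain hypergeometric statistic, not any
#' tool-specific modification of it.
#'
#' @param selected Character vector of selected genes (subset of background).
#' @param category Character vector of category genes (subset of background).
#' @param background Character vector: the gene universe.
#' @return List with `k`, `n`, `K`, `N`, `fold_enrichment`, `p_value`.
#' @export
enrichment <- function(selected, category, background) {
  background <- unique(background)
  N <- length(background)
  if (N == 0L) stop("background gene set is empty")
  selected <- unique(selected)
  category <- unique(category)
  if (!all(selected %in% background)) stop("selected genes must be in the background")
  if (!all(category %in% background)) stop("category genes must be in the background")
  n <- length(selected)
  K <- length(category)
  k <- length(intersect(selected, category))
  fold <- if (n == 0L || K == 0L) 0 else (k / n) / (K / N)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, n = n, K = K, N = N, fold_enrichment = fold, p_value = p)
}
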