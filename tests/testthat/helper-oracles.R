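# Independent brute-force oracles used by the property tests. These are
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the package implementations they check.

# ---- digestion oracle -------------------------------------------------------

oracle_spec_match <- function(chars, bond, spec) {
  ctx <- c(p2 = bond - 1L, p1 = bond, p1prime = bond + 1L, p2prime = bond + 2L)
  for (pos in names(ctx)) {
    set <- spec[[pos]]
    if (is.null(set) || length(set) == 0L) next
    ri <- ctx[[pos]] + 1L
    if (ri < 1L || ri > length(chars)) return(FALSE)
    if (!chars[ri] %in% set) return(FALSE)
  }
  TRUE
}

oracle_sites <- function(residues, rule) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  out <- integer(0)
  for (i in 0:(n - 2L)) {
    if (chars[i + 1L] == "X" || chars[i + 2L] == "X") next
    m <- any(vapply(rule$specs, function(s) oracle_spec_match(chars, i, s),
                    logical(1)))
    e <- length(rule$exceptions) &&
      any(vapply(rule$exceptions, function(s) oracle_spec_match(chars, i, s),
                 logical(1)))
    if (m && !e) out <- c(out, i)
  }
  out
}

random_rule <- function() {
  aa20 <- setdiff(pepprospect::AA_ALPHABET, "X")
  rand_spec <- function() {
    pos <- sample(c("p2", "p1", "p1prime", "p2prime"), sample(1:2, 1))
    stats::setNames(lapply(pos, function(p) sample(aa20, sample(1:5, 1))), pos)
  }
  pepprospect::enzyme_rule(
    name = "rand",
    specs = replicate(sample(1:2, 1), rand_spec(), simplify = FALSE),
    exceptions = if (stats::runif(1) < 0.5)
      replicate(1, rand_spec(), simplify = FALSE) else list()
  )
}

random_chain_string <- function(max_len = 30L, x_prob = 0.05) {
  n <- sample(2:max_len, 1)
  aa <- c(setdiff(pepprospect::AA_ALPHABET, "X"))
  chars <- sample(aa, n, replace = TRUE)
  xs <- stats::runif(n) < x_prob
  chars[xs] <- "X"
  paste(chars, collapse = "")
}

# ---- naive substring counting ----------------------------------------------

oracle_count_occurrences <- function(chain, patterns) {
  total <- 0L
  n <- nchar(chain)
  for (p in patterns) {
    w <- nchar(p)
    if (w > n) next
    for (s in seq_len(n - w + 1L)) {
      if (substr(chain, s, s + w - 1L) == p) total <- total + 1L
    }
  }
  total
}

# ---- graph oracles (adjacency-matrix based, tiny n) -------------------------

adj_from_igraph <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

oracle_floyd_warshall <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[A > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# enumerate all shortest simple paths between s and t by BFS-depth DFS
oracle_shortest_paths <- function(A, s, t) {
  d <- oracle_floyd_warshall(A)
  if (!is.finite(d[s, t])) return(list())
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] > 0)) {
      # stay on a shortest path: each step must reduce distance to t
      if (d[w, t] == d[v, t] - 1) walk(c(path, w))
    }
  }
  walk(s)
  paths
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_shortest_paths(A, s, t)
      if (length(paths) == 0L) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        thru <- sum(vapply(paths, function(p) v %in% p[-c(1, length(p))],
                           logical(1)))
        out[v] <- out[v] + thru / length(paths)
      }
    }
  }
  out
}

oracle_stress <- function(A) {
  n <- nrow(A)
  out <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_shortest_paths(A, s, t)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        out[v] <- out[v] + sum(vapply(paths, function(p)
          v %in% p[-c(1, length(p))], logical(1)))
      }
    }
  }
  out
}

oracle_harmonic_closeness <- function(A) {
  d <- oracle_floyd_warshall(A)
  diag(d) <- Inf
  rowSums(1 / d)
}

oracle_degree <- function(A) rowSums(A)

oracle_components <- function(A) {
  n <- nrow(A)
  comp <- rep(0L, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1]
      queue <- queue[-1]
      nb <- which(A[u, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

oracle_mnc <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0L) return(0)
    sub <- A[nb, nb, drop = FALSE]
    max(table(oracle_components(sub)))
  }, numeric(1))
}

# all maximal cliques by subset enumeration; MCC per node
oracle_mcc <- function(A) {
  n <- nrow(A)
  is_clique <- function(S) {
    if (length(S) < 2L) return(TRUE)
    all(A[S, S][upper.tri(diag(length(S)))] > 0)
  }
  subsets <- lapply(seq_len(2^n - 1L), function(mask)
    which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0))
  cliques <- Filter(is_clique, subsets)
  keys <- vapply(cliques, function(S) paste(S, collapse = ","), character(1))
  maximal <- vapply(cliques, function(S) {
    !any(vapply(setdiff(seq_len(n), S), function(w)
      is_clique(sort(c(S, w))), logical(1)))
  }, logical(1))
  out <- numeric(n)
  for (S in cliques[maximal]) out[S] <- out[S] + factorial(length(S) - 1L)
  out
}

oracle_radiality <- function(A) {
  n <- nrow(A)
  d <- oracle_floyd_warshall(A)
  comp <- oracle_components(A)
  out <- numeric(n)
  for (ci in unique(comp)) {
    members <- which(comp == ci)
    if (length(members) < 2L) next
    dc <- d[members, members, drop = FALSE]
    delta <- max(dc)
    for (i in seq_along(members)) {
      out[members[i]] <- sum(delta + 1 - dc[i, -i]) / (length(members) - 1L)
    }
  }
  out
}

# exact edge-percolation expectation by summation over all edge subsets
oracle_epc_exact <- function(A, keep_prob) {
  n <- nrow(A)
  el <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  m <- nrow(el)
  stopifnot(m <= 14L)  # 2^m subsets
  out <- numeric(n)
  for (mask in 0:(2^m - 1L)) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    pr <- keep_prob^sum(keep) * (1 - keep_prob)^sum(!keep)
    B <- matrix(0, n, n)
    if (any(keep)) {
      kept <- el[keep, , drop = FALSE]
      B[kept] <- 1
      B[kept[, c(2, 1), drop = FALSE]] <- 1
    }
    comp <- oracle_components(B)
    sizes <- table(comp)
    out <- out + pr * as.numeric(sizes[as.character(comp)])
  }
  out
}

# ---- graph generators for enumeration tests ---------------------------------

graph_from_adj <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- LETTERS[seq_len(nrow(A))]
  g
}

all_connected_graphs <- function(n) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m - 1L)) {
    keep <- bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0
    A <- matrix(0, n, n)
    kept <- pairs[keep, , drop = FALSE]
    A[kept] <- 1
    A[kept[, c(2, 1), drop = FALSE]] <- 1
    if (max(oracle_components(A)) == 1L) out[[length(out) + 1L]] <- A
  }
  out
}

random_connected_adj <- function(n, p = 0.4) {
  repeat {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < p]
    A[on] <- 1
    A <- A + t(A)
    if (max(oracle_components(A)) == 1L) return(A)
  }
}
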