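# Independent brute-force oracles, written against plain edge lists with
# hand-rolled loops (no igraph) so they share nothing with the implementation
# they check.

# edges: 2-column character matrix; nodes: character vector including
# isolated nodes. Returns adjacency list of integer indices.
oracle_adj <- function(nodes, edges) {
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  for (i in seq_along(adj)) adj[[i]] <- integer()
  if (length(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- match(edges[r, 1L], nodes)
      j <- match(edges[r, 2L], nodes)
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  lapply(adj, function(x) sort(unique(x)))
}

oracle_degree <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  stats::setNames(lengths(adj), nodes)
}

oracle_clustering <- function(nodes, edges) {
  adj <- oracle_adj(nodes, edges)
  out <- numeric(length(nodes))
  for (i in seq_along(nodes)) {
    nb <- adj[[i]]
    k <- length(nb)
    if (k < 2L) { out[i] <- 0; next }
    e_n <- 0L
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
      if (nb[b] %in% adj[[nb[a]]]) e_n <- e_n + 1L
    out[i] <- e_n / (k * (k - 1) / 2)
  }
  stats::setNames(out, nodes)
}

# union-find component count
oracle_components <- function(nodes, edges) {
  parent <- seq_along(nodes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (length(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- find(match(edges[r, 1L], nodes))
      j <- find(match(edges[r, 2L], nodes))
      if (i != j) parent[i] <- j
    }
  }
  length(unique(vapply(seq_along(nodes), find, 0L)))
}

# exhaustive shortest-path enumeration: BFS distances, then recursive
# enumeration of all geodesics per ordered pair (counted once per unordered
# pair); returns relative betweenness with the (n-1)(n-2)/2 normalization.
oracle_rel_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  adj <- oracle_adj(nodes, edges)
  cb <- numeric(n)
  if (n >= 3L) {
    bfs_dist <- function(s) {
      d <- rep(NA_integer_, n)
      d[s] <- 0L
      q <- s
      while (length(q) > 0L) {
        v <- q[1L]; q <- q[-1L]
        for (w in adj[[v]]) if (is.na(d[w])) { d[w] <- d[v] + 1L; q <- c(q, w) }
      }
      d
    }
    for (s in 1:(n - 1L)) {
      ds <- bfs_dist(s)
      for (t in (s + 1L):n) {
        if (is.na(ds[t])) next
        # enumerate every shortest s->t path by walking down the distance
        paths <- list()
        walk <- function(v, acc) {
          if (v == s) { paths[[length(paths) + 1L]] <<- acc; return() }
          for (w in adj[[v]]) if (!is.na(ds[w]) && ds[w] == ds[v] - 1L)
            walk(w, c(w, acc))
        }
        walk(t, t)
        sigma <- length(paths)
        through <- table(unlist(lapply(paths, function(p)
          p[-c(1L, length(p))])))
        if (length(through) > 0L) {
          idx <- as.integer(names(through))
          cb[idx] <- cb[idx] + as.numeric(through) / sigma
        }
      }
    }
    cb <- cb / ((n - 1) * (n - 2) / 2)
  }
  stats::setNames(cb, nodes)
}

# one-sided two-sample KS statistic by explicit sweep over every candidate
# point of both samples
oracle_dplus <- function(obs, null) {
  best <- 0
  for (z in c(obs, null)) {
    d <- mean(null <= z) - mean(obs <= z)
    if (d > best) best <- d
  }
  best
}

# two-sided KS statistic by the same sweep
oracle_dtwo <- function(a, b) {
  best <- 0
  for (z in c(a, b)) {
    d <- abs(mean(a <= z) - mean(b <= z))
    if (d > best) best <- d
  }
  best
}

# hypergeometric upper tail P[X >= k] by direct summation of choose() terms
oracle_hyper_tail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# all ancestors of a term by naive repeated expansion over the edge table
oracle_ancestors <- function(term, dag) {
  anc <- character()
  frontier <- term
  while (length(frontier) > 0L) {
    ps <- unique(dag$parent[dag$child %in% frontier])
    ps <- setdiff(ps, anc)
    anc <- c(anc, ps)
    frontier <- ps
  }
  sort(anc)
}
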