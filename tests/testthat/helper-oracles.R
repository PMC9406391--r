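# Test-only oracles and generators, independent of the package internals:
# the d-separation oracle enumerates simple paths by plain DFS over the edge
# list and applies the chain/fork/collider blocking rules directly, whereas
# the package uses the moralized-ancestral-graph criterion.

oracle_d_separated <- function(g, a, b, given = character(0)) {
  edges <- g$edges
  ids <- g$nodes$id
  adj <- lapply(stats::setNames(nm = ids), function(v)
    unique(c(edges[edges[, 1L] == v, 2L], edges[edges[, 2L] == v, 1L])))
  desc_of <- function(v) {
    seen <- character(0); frontier <- v
    while (length(frontier)) {
      kids <- unique(edges[edges[, 1L] %in% frontier, 2L])
      frontier <- setdiff(kids, seen)
      seen <- union(seen, frontier)
    }
    setdiff(seen, v)
  }
  has_edge <- function(u, v) any(edges[, 1L] == u & edges[, 2L] == v)
  open_path <- function(p) {
    if (length(p) < 3L) return(TRUE)
    for (i in 2:(length(p) - 1L)) {
      u <- p[i - 1L]; v <- p[i]; w <- p[i + 1L]
      if (has_edge(u, v) && has_edge(w, v)) {       # collider
        if (!(v %in% given) && !any(desc_of(v) %in% given)) return(FALSE)
      } else if (v %in% given) return(FALSE)        # chain or fork
    }
    TRUE
  }
  connected <- FALSE
  dfs <- function(path) {
    if (connected) return()
    v <- path[length(path)]
    if (v %in% b) {
      if (open_path(path)) connected <<- TRUE
      return()
    }
    for (w in adj[[v]])
      if (!(w %in% path)) dfs(c(path, w))
  }
  for (s in a) {
    dfs(s)
    if (connected) break
  }
  !connected
}

# random DAG over n variable nodes: edges i -> j only for i < j in a fixed
# node order, so acyclicity holds by construction
random_dag <- function(n, p = 0.35) {
  ids <- paste0("N", seq_len(n))
  em <- NULL
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (stats::runif(1) < p) em <- rbind(em, c(ids[i], ids[j]))
  if (is.null(em)) causal_graph(nodes = ids)
  else causal_graph(em, nodes = ids)
}

# random selection diagram: a random DAG plus k selection nodes, each
# pointing at one or two random variable nodes
random_selection_diagram <- function(n, k = 2L, p = 0.35) {
  g <- random_dag(n, p)
  em <- g$edges
  vids <- g$nodes$id
  sids <- paste0("S", seq_len(k))
  for (s in sids) {
    targets <- sample(vids, sample(1:2, 1L))
    em <- rbind(em, cbind(s, targets))
  }
  causal_graph(em, selection = sids, nodes = c(vids, sids))
}
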