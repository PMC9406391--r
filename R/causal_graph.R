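# Causal diagrams and selection diagrams: construction, do-operator surgery,
# d-separation, back-door analysis, do-calculus rule checks, S-admissibility,
# and minimal adjustment-set search.
#
# Graphs are small by design (clinical diagrams); simple-path enumeration is
# exponential in the worst case, so enumeration-based operations guard on a
# node budget (default 25 nodes).

PATH_NODE_BUDGET <- 25L

# ---- construction -----------------------------------------------------------

parse_edges <- function(edges) {
  if (is.null(edges) || (is.character(edges) && length(edges) == 0L)) {
    return(matrix(character(0), ncol = 2L,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.matrix(edges) || is.data.frame(edges)) {
    m <- as.matrix(edges)
    if (ncol(m) != 2L)
      abort2("edges must have two columns (from, to)",
             "oncocausal_argument_error")
    storage.mode(m) <- "character"
    dimnames(m) <- list(NULL, c("from", "to"))
    return(m)
  }
  if (is.character(edges)) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      abort2("edge strings must have the form 'A -> B'",
             "oncocausal_argument_error")
    m <- cbind(from = trimws(vapply(parts, `[`, "", 1L)),
               to   = trimws(vapply(parts, `[`, "", 2L)))
    return(m)
  }
  abort2("edges must be a character vector of 'A -> B' strings or a two-column matrix",
         "oncocausal_argument_error")
}

new_causal_graph <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "causal_graph")
}

#' Construct a causal diagram (DAG, optionally with selection nodes)
#'
#' A causal diagram is a directed acyclic graph over variable nodes (treatment,
#' outcome, covariates, mediators, confounders) and optional *selection nodes*
#' marking variables whose distribution shifts between populations. Selection
#' nodes may only have outgoing arrows: diagrams with arrows pointing *into* a
#' selection node encode sampling/selection bias, which is outside the scope of
#' the transportability checks implemented here and is rejected.
#'
#' @param edges character vector of `"A -> B"` strings, or a two-column
#'   from/to character matrix.
#' @param selection character vector of node ids to mark as selection nodes.
#' @param nodes extra (possibly isolated) node ids to declare beyond those
#'   appearing in `edges`.
#' @param labels optional named character vector of display labels, names are
#'   node ids. Labels are display-only; identity is the case-sensitive id.
#' @return An object of class `causal_graph` with components `nodes`
#'   (data frame: `id`, `kind`, `label`) and `edges` (two-column character
#'   matrix).
#' @examples
#' g <- causal_graph(c("X -> Y", "Z -> Y", "S -> Z"), selection = "S")
#' g
#' @export
causal_graph <- function(edges = character(0), selection = character(0),
                         nodes = NULL, labels = NULL) {
  em <- parse_edges(edges)
  ids <- unique(c(nodes, em[, "from"], em[, "to"]))
  if (length(ids) == 0L)
    abort2("a causal diagram needs at least one node",
           "oncocausal_argument_error")
  if (!all(nzchar(ids)) || anyNA(ids))
    abort2("node ids must be non-empty strings", "oncocausal_argument_error")
  unknown_sel <- setdiff(selection, ids)
  if (length(unknown_sel))
    abort2(paste0("selection node(s) not present in the graph: ",
                  paste(unknown_sel, collapse = ", ")),
           "oncocausal_reference_error")
  lab <- rep("", length(ids))
  names(lab) <- ids
  if (!is.null(labels)) lab[names(labels)] <- unname(labels)
  ndf <- data.frame(id = ids,
                    kind = ifelse(ids %in% selection, "selection", "variable"),
                    label = unname(lab),
                    stringsAsFactors = FALSE)
  g <- new_causal_graph(ndf, em)
  validate_causal_graph(g)
  g
}

validate_causal_graph <- function(g, allow_isolated_selection = FALSE) {
  ids <- g$nodes$id
  if (anyDuplicated(ids))
    abort2("duplicate node ids", "oncocausal_structural_error")
  em <- g$edges
  dangling <- setdiff(c(em), ids)
  if (length(dangling))
    abort2(paste0("edge endpoint(s) reference undeclared node(s): ",
                  paste(dangling, collapse = ", ")),
           "oncocausal_reference_error")
  if (any(em[, "from"] == em[, "to"]))
    abort2("self-loops are not allowed", "oncocausal_structural_error")
  if (anyDuplicated(paste(em[, "from"], em[, "to"], sep = "\r")))
    abort2("duplicate edges are not allowed", "oncocausal_structural_error")
  sel <- ids[g$nodes$kind == "selection"]
  if (length(sel)) {
    incoming <- intersect(sel, em[, "to"])
    if (length(incoming))
      abort2(paste0("arrow(s) into selection node(s) ",
                    paste(incoming, collapse = ", "),
                    " encode selection bias; only transportability diagrams ",
                    "(selection nodes with outgoing arrows) are supported"),
             "oncocausal_scope_error")
    if (!allow_isolated_selection) {
      isolated <- setdiff(sel, em[, "from"])
      if (length(isolated))
        abort2(paste0("selection node(s) without outgoing arrows: ",
                      paste(isolated, collapse = ", ")),
               "oncocausal_structural_error")
    }
  }
  ig <- as_igraph(g)
  if (!igraph::is_dag(ig)) {
    comp <- igraph::components(ig, mode = "strong")
    big <- which(comp$csize > 1L)[1L]
    cyc <- names(comp$membership)[comp$membership == big]
    abort2(paste0("cycle among variable nodes: ",
                  paste(cyc, collapse = " -> ")),
           "oncocausal_structural_error")
  }
  invisible(g)
}

as_igraph <- function(g, directed = TRUE) {
  d <- data.frame(from = g$edges[, "from"], to = g$edges[, "to"],
                  stringsAsFactors = FALSE)
  ig <- igraph::graph_from_data_frame(d, directed = directed,
                                      vertices = g$nodes$id)
  ig
}

# ---- accessors --------------------------------------------------------------

node_ids <- function(g) g$nodes$id

#' Variable and selection nodes of a causal diagram
#'
#' @param g a `causal_graph`.
#' @return Character vector of node ids of the requested kind (possibly
#'   empty for `selection_nodes`).
#' @export
variable_nodes <- function(g) g$nodes$id[g$nodes$kind == "variable"]

#' @rdname variable_nodes
#' @export
selection_nodes <- function(g) g$nodes$id[g$nodes$kind == "selection"]

check_known <- function(g, ids, what = "node") {
  unknown <- setdiff(ids, node_ids(g))
  if (length(unknown))
    abort2(paste0("unknown ", what, " id(s): ",
                  paste(unknown, collapse = ", ")),
           "oncocausal_reference_error")
  invisible(ids)
}

graph_parents <- function(g, id) g$edges[g$edges[, "to"] == id, "from"]
graph_children <- function(g, id) g$edges[g$edges[, "from"] == id, "to"]

# proper descendants (excluding the seed nodes themselves, graph is acyclic)
descendants <- function(g, ids) {
  seen <- character(0)
  frontier <- ids
  while (length(frontier)) {
    kids <- unique(g$edges[g$edges[, "from"] %in% frontier, "to"])
    frontier <- setdiff(kids, seen)
    seen <- union(seen, frontier)
  }
  setdiff(seen, ids)
}

ancestors_incl <- function(g, ids) {
  seen <- ids
  frontier <- ids
  while (length(frontier)) {
    pars <- unique(g$edges[g$edges[, "to"] %in% frontier, "from"])
    frontier <- setdiff(pars, seen)
    seen <- union(seen, frontier)
  }
  seen
}

#' @export
print.causal_graph <- function(x, ...) {
  nv <- sum(x$nodes$kind == "variable")
  ns <- sum(x$nodes$kind == "selection")
  cat(sprintf("Causal diagram: %d variable node%s, %d selection node%s, %d edge%s\n",
              nv, if (nv == 1) "" else "s",
              ns, if (ns == 1) "" else "s",
              nrow(x$edges), if (nrow(x$edges) == 1) "" else "s"))
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, "from"], " -> ", x$edges[, "to"]), sep = "\n")
  iso <- setdiff(x$nodes$id, c(x$edges))
  if (length(iso))
    cat("  isolated:", paste(iso, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.causal_graph <- function(x, ...) {
  ig <- as_igraph(x)
  shape <- ifelse(x$nodes$kind == "selection", "square", "circle")
  igraph::plot.igraph(ig, vertex.shape = shape, vertex.color = "white",
                      vertex.label.color = "black", edge.arrow.size = 0.5, ...)
  invisible(x)
}

# ---- do-operator surgery ----------------------------------------------------

#' Graph surgery for the do() operator
#'
#' Intervening on a treatment set X, written do(X = x), removes every arrow
#' entering the treatment nodes while leaving the rest of the causal model
#' unchanged.
#'
#' @param g a `causal_graph`.
#' @param treatment character vector of variable-node ids intervened on.
#' @return The surgically modified `causal_graph`.
#' @examples
#' g <- figure_fixture("4A")
#' do_surgery(g, "X")
#' @export
do_surgery <- function(g, treatment) {
  check_known(g, treatment, "treatment node")
  if (any(treatment %in% selection_nodes(g)))
    abort2("treatment nodes must be variable nodes",
           "oncocausal_argument_error")
  keep <- !(g$edges[, "to"] %in% treatment)
  g2 <- new_causal_graph(g$nodes, g$edges[keep, , drop = FALSE])
  validate_causal_graph(g2, allow_isolated_selection = TRUE)
  g2
}

# remove arrows pointing OUT of the treatment nodes (back-door view)
remove_outgoing <- function(g, treatment) {
  keep <- !(g$edges[, "from"] %in% treatment)
  new_causal_graph(g$nodes, g$edges[keep, , drop = FALSE])
}

# ---- d-separation (moralized ancestral graph criterion) ---------------------

#' Test d-separation between two node sets
#'
#' Implements full Pearl d-separation: chains and forks are blocked when their
#' middle node is conditioned on; colliders block unless the collider or one of
#' its descendants is conditioned on. Computed via the moralized ancestral
#' graph criterion (restrict to ancestors of all involved nodes, marry parents
#' of common children, drop directions, delete the conditioning set, test
#' connectivity), which is equivalent to path-by-path blocking.
#'
#' @param g a `causal_graph`.
#' @param a,b disjoint character vectors of node ids.
#' @param given conditioning set (node ids), disjoint from `a` and `b`.
#' @return `TRUE` if every path between `a` and `b` is blocked given `given`.
#' @examples
#' soda <- causal_graph(c("Z -> X", "Z -> Y"))
#' is_d_separated(soda, "X", "Y", given = "Z")
#' @export
is_d_separated <- function(g, a, b, given = character(0)) {
  check_known(g, c(a, b, given))
  if (length(a) == 0L || length(b) == 0L)
    abort2("'a' and 'b' must be non-empty", "oncocausal_argument_error")
  if (length(intersect(a, b)) || length(intersect(a, given)) ||
      length(intersect(b, given)))
    abort2("'a', 'b' and 'given' must be pairwise disjoint",
           "oncocausal_argument_error")
  anc <- ancestors_incl(g, c(a, b, given))
  em <- g$edges[g$edges[, "from"] %in% anc & g$edges[, "to"] %in% anc, ,
                drop = FALSE]
  und <- list(em[, c("from", "to"), drop = FALSE])
  for (v in unique(em[, "to"])) {
    pa <- em[em[, "to"] == v, "from"]
    if (length(pa) >= 2L) {
      prs <- utils::combn(sort(pa), 2L)
      und[[length(und) + 1L]] <- cbind(from = prs[1L, ], to = prs[2L, ])
    }
  }
  und <- do.call(rbind, und)
  verts <- setdiff(anc, given)
  keep <- und[, 1L] %in% verts & und[, 2L] %in% verts
  und <- und[keep, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    data.frame(from = und[, 1L], to = und[, 2L], stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  memb <- igraph::components(ig)$membership
  !any(memb[a] %in% memb[b])
}

# ---- paths ------------------------------------------------------------------

new_path <- function(g, nodes) {
  structure(list(nodes = nodes, roles = classify_path(g, nodes)),
            class = "causal_path")
}

# role of each interior node along a path: chain, fork or collider
classify_path <- function(g, nodes) {
  n <- length(nodes)
  if (n < 3L) return(character(0))
  has_edge <- function(a, b)
    any(g$edges[, "from"] == a & g$edges[, "to"] == b)
  vapply(seq(2L, n - 1L), function(i) {
    u <- nodes[i - 1L]; v <- nodes[i]; w <- nodes[i + 1L]
    if (has_edge(u, v) && has_edge(w, v)) "collider"
    else if (has_edge(v, u) && has_edge(v, w)) "fork"
    else "chain"
  }, "")
}

#' @export
print.causal_path <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.causal_path <- function(x, ...) {
  n <- x$nodes
  if (length(n) == 1L) return(n)
  out <- n[1L]
  for (i in seq_len(length(n) - 1L)) {
    arrow <- if (!is.null(attr(x, "arrows"))) attr(x, "arrows")[i] else NULL
    out <- paste0(out, " ", arrow %||% "--", " ", n[i + 1L])
  }
  out
}

render_path <- function(g, nodes) {
  has_edge <- function(a, b)
    any(g$edges[, "from"] == a & g$edges[, "to"] == b)
  out <- nodes[1L]
  for (i in seq_len(length(nodes) - 1L)) {
    arrow <- if (has_edge(nodes[i], nodes[i + 1L])) "->" else "<-"
    out <- paste0(out, " ", arrow, " ", nodes[i + 1L])
  }
  out
}

# all simple paths between two nodes in the skeleton (edge direction ignored)
all_skeleton_paths <- function(g, from, to, exclude = character(0),
                               max_nodes = PATH_NODE_BUDGET) {
  if (nrow(g$nodes) > max_nodes)
    abort2(sprintf("graph has %d nodes; path enumeration is limited to %d",
                   nrow(g$nodes), max_nodes),
           "oncocausal_size_error")
  verts <- setdiff(node_ids(g), exclude)
  if (!all(c(from, to) %in% verts)) return(list())
  keep <- g$edges[, "from"] %in% verts & g$edges[, "to"] %in% verts
  em <- g$edges[keep, , drop = FALSE]
  ig <- igraph::graph_from_data_frame(
    data.frame(from = em[, "from"], to = em[, "to"], stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  ps <- igraph::all_simple_paths(ig, from = from, to = to, mode = "all")
  lapply(ps, igraph::as_ids)
}

# is the path d-connecting given the conditioning set?
path_is_open <- function(g, nodes, given) {
  roles <- classify_path(g, nodes)
  interior <- nodes[seq_len(length(roles)) + 1L]
  for (i in seq_along(roles)) {
    v <- interior[i]
    if (roles[i] == "collider") {
      if (!(v %in% given) && !any(descendants(g, v) %in% given)) return(FALSE)
    } else {
      if (v %in% given) return(FALSE)
    }
  }
  TRUE
}

#' Enumerate back-door paths from a treatment set to an outcome
#'
#' A back-door path is a non-causal path from a treatment node to the outcome:
#' a path that survives deletion of all arrows pointing out of the treatment
#' nodes, beginning with an arrow *into* the treatment node. Paths are simple
#' and do not pass through other treatment nodes.
#'
#' @param g a `causal_graph`.
#' @param treatment non-empty character vector of treatment node ids.
#' @param outcome a single outcome node id (not in `treatment`).
#' @return A list of `causal_path` objects.
#' @examples
#' backdoor_paths(figure_fixture("4G"), "X", "Y")
#' @export
backdoor_paths <- function(g, treatment, outcome) {
  check_known(g, c(treatment, outcome))
  if (length(treatment) == 0L)
    abort2("treatment must be non-empty", "oncocausal_argument_error")
  if (outcome %in% treatment)
    abort2("outcome must not be a treatment node", "oncocausal_argument_error")
  g2 <- remove_outgoing(g, treatment)
  out <- list()
  for (t in sort(treatment)) {
    ps <- all_skeleton_paths(g2, t, outcome,
                             exclude = setdiff(treatment, t))
    for (p in ps) {
      # first edge must point into the treatment node
      if (any(g2$edges[, "from"] == p[2L] & g2$edges[, "to"] == t)) {
        pathobj <- new_path(g2, p)
        attr(pathobj, "display") <- render_path(g2, p)
        out[[length(out) + 1L]] <- pathobj
      }
    }
  }
  out
}

#' Back-door criterion (do-calculus Rule 2)
#'
#' An adjustment set satisfies the back-door criterion for (treatment,
#' outcome) when it blocks every back-door path and contains no descendant of
#' a treatment node. When it holds, `P(Y | do(X = x), C) = P(Y | X = x, C)`:
#' conditioning on the adjustment set substitutes for randomization, under the
#' unverifiable assumption of no unmeasured confounding.
#'
#' @inheritParams backdoor_paths
#' @param adjustment character vector of variable-node ids (no treatment,
#'   outcome or selection nodes).
#' @return `TRUE` or `FALSE`.
#' @examples
#' satisfies_backdoor(figure_fixture("4G"), "X", "Y", adjustment = "C")
#' @export
satisfies_backdoor <- function(g, treatment, outcome, adjustment = character(0)) {
  check_known(g, c(treatment, outcome, adjustment))
  if (length(treatment) == 0L)
    abort2("treatment must be non-empty", "oncocausal_argument_error")
  if (outcome %in% c(treatment, adjustment))
    abort2("outcome must not be in treatment or adjustment",
           "oncocausal_argument_error")
  if (length(intersect(treatment, adjustment)))
    abort2("treatment and adjustment must be disjoint",
           "oncocausal_argument_error")
  if (any(adjustment %in% selection_nodes(g)))
    abort2("selection nodes cannot be adjusted for",
           "oncocausal_argument_error")
  if (any(adjustment %in% descendants(g, treatment))) return(FALSE)
  g2 <- remove_outgoing(g, treatment)
  is_d_separated(g2, treatment, outcome, given = adjustment)
}

#' No-causal-effect check (do-calculus Rule 3)
#'
#' Returns `TRUE` when no directed (forward-arrow) path leads from any
#' treatment node to the outcome, in which case
#' `P(Y | do(X = x), Z) = P(Y | Z)`: the intervention has no causal effect on
#' the outcome.
#'
#' @inheritParams backdoor_paths
#' @return `TRUE` or `FALSE`.
#' @examples
#' rule3_no_effect(figure_fixture("4I"), "X", "Y")
#' @export
rule3_no_effect <- function(g, treatment, outcome) {
  check_known(g, c(treatment, outcome))
  !(outcome %in% descendants(g, treatment))
}

# ---- S-admissibility --------------------------------------------------------

#' S-admissibility of an adjustment set for transport
#'
#' An adjustment set Z is S-admissible for transporting the effect of
#' treatment X on outcome Y when
#' `P(Y | do(X = x), Z) = P(Y | do(X = x), Z, S)` for the selection nodes S:
#' after removing all arrows into the treatment nodes, the selection nodes
#' must be d-separated from the outcome given the adjustment set together with
#' the treatment. When the criterion fails, the verdict carries the unblocked
#' witness paths from selection nodes to the outcome.
#'
#' @inheritParams backdoor_paths
#' @param adjustment character vector of variable-node ids; selection nodes
#'   are never admissible adjustment variables.
#' @return An object of class `transport_verdict`: list with elements
#'   `admissible` (logical) and `open_witness` (list of `causal_path`,
#'   empty iff admissible), plus the query.
#' @examples
#' s_admissible(figure_fixture("6A"), "X", "Y", adjustment = "Z")
#' @export
s_admissible <- function(g, treatment, outcome, adjustment = character(0)) {
  check_known(g, c(treatment, outcome, adjustment))
  sel <- selection_nodes(g)
  if (any(adjustment %in% sel))
    abort2("selection nodes cannot be part of an adjustment set",
           "oncocausal_argument_error")
  if (any(c(treatment, outcome) %in% sel))
    abort2("treatment and outcome must be variable nodes",
           "oncocausal_argument_error")
  if (length(intersect(treatment, adjustment)) ||
      outcome %in% c(treatment, adjustment))
    abort2("treatment, outcome and adjustment must be disjoint",
           "oncocausal_argument_error")
  verdict <- function(adm, wit) {
    structure(list(admissible = adm, open_witness = wit,
                   treatment = treatment, outcome = outcome,
                   adjustment = adjustment),
              class = "transport_verdict")
  }
  if (length(sel) == 0L) return(verdict(TRUE, list()))
  g2 <- do_surgery(g, treatment)
  cond <- union(adjustment, treatment)
  adm <- is_d_separated(g2, sel, outcome, given = cond)
  wit <- list()
  for (s in sel) {
    for (p in all_skeleton_paths(g2, s, outcome)) {
      if (path_is_open(g2, p, cond)) {
        pathobj <- new_path(g2, p)
        attr(pathobj, "display") <- render_path(g2, p)
        wit[[length(wit) + 1L]] <- pathobj
      }
    }
  }
  # the moral-graph verdict and the path-enumeration witnesses are two
  # independent routes to the same criterion; they must agree
  if (adm != (length(wit) == 0L))
    stop("internal error: d-separation verdict and witness paths disagree")
  verdict(adm, wit)
}

#' @export
print.transport_verdict <- function(x, ...) {
  cat(sprintf("Transport query: effect of {%s} on %s adjusting for {%s}\n",
              paste(x$treatment, collapse = ", "), x$outcome,
              paste(x$adjustment, collapse = ", ")))
  if (x$admissible) {
    cat("S-admissible: the adjustment set licenses transport across populations.\n")
  } else {
    cat("NOT S-admissible; unblocked selection-to-outcome path(s):\n")
    for (p in x$open_witness)
      cat("  ", attr(p, "display") %||% paste(p$nodes, collapse = " -- "), "\n")
  }
  invisible(x)
}

#' Minimal S-admissible adjustment sets
#'
#' Exhaustively searches subsets of a candidate pool for inclusion-minimal
#' S-admissible adjustment sets. Admissibility is not monotone (enlarging a
#' set can open a collider path), so every subset size is examined; a set is
#' minimal when no proper subset is itself admissible. Results are ordered by
#' size, then lexicographically.
#'
#' @inheritParams backdoor_paths
#' @param candidates variable-node ids eligible for adjustment (at most 20).
#' @return List of character vectors (possibly containing only the empty set).
#' @examples
#' g <- figure_fixture("9A")
#' minimal_admissible_sets(g, "X", "Y", candidates = c("B1", "B2", "Z", "M1", "M2"))
#' @export
minimal_admissible_sets <- function(g, treatment, outcome, candidates) {
  if (length(candidates) > 20L)
    abort2("candidate pool larger than 20 nodes; exhaustive search refused",
           "oncocausal_size_error")
  check_known(g, c(treatment, outcome, candidates))
  if (any(candidates %in% selection_nodes(g)) ||
      any(candidates %in% treatment) || outcome %in% candidates)
    abort2("candidates must exclude treatment, outcome and selection nodes",
           "oncocausal_argument_error")
  cand <- sort(unique(candidates))
  admissible <- list()
  minimal <- list()
  for (k in 0:length(cand)) {
    subsets <- if (k == 0L) list(character(0))
               else apply(utils::combn(cand, k), 2L, identity, simplify = FALSE)
    for (s in subsets) {
      ok <- s_admissible(g, treatment, outcome, adjustment = s)$admissible
      if (!ok) next
      has_adm_subset <- any(vapply(admissible, function(a)
        length(a) < length(s) && all(a %in% s), TRUE))
      admissible[[length(admissible) + 1L]] <- s
      if (!has_adm_subset) minimal[[length(minimal) + 1L]] <- s
    }
  }
  minimal
}
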