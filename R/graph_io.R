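# Figure fixtures (the canonical clinical diagrams the package ships) and
# graph serialization: a strict JSON edge-list dialect plus DOT export.

fixture_labels <- c(
  X = "treatment choice", Y = "outcome (DFS)", Z = "prognostic covariates",
  B = "biomarker (RCC histology)", C = "confounder",
  M = "mediator (immune microenvironment)", W = "auxiliary covariate",
  K = "collider", B1 = "biomarker 1 (immune signature)",
  B2 = "biomarker 2 (angiogenic signature)",
  M1 = "mediator 1 (immune microenvironment)",
  M2 = "mediator 2 (angiogenic microenvironment)",
  S = "population shift", S1 = "population shift 1",
  S2 = "population shift 2", S3 = "population shift 3")

fixture_specs <- list(
  `1A` = list(edges = "X -> Y"),
  `1C` = list(edges = c("X -> Y", "Z -> Y")),
  `1E` = list(edges = c("X -> Y", "C -> X", "C -> Y")),
  `2A` = list(edges = c("X -> M", "M -> Y")),
  `4A` = list(edges = c("X -> Y", "Z -> Y", "C -> X", "C -> Y")),
  `4D` = list(edges = c("X -> Y", "X -> W", "C -> X", "C -> Y", "C -> W")),
  `4G` = list(edges = c("X -> Y", "C -> X", "C -> Y")),
  `4I` = list(edges = c("Z -> X", "Z -> Y")),
  `5A` = list(edges = c("X -> Y", "Z -> Y")),
  `5C` = list(edges = c("X -> M", "B -> M", "M -> Y")),
  `6A` = list(edges = c("X -> Y", "Z -> Y", "S -> Z"), selection = "S"),
  `6C` = list(edges = c("X -> Y", "Z -> Y", "C -> Z", "C -> Y",
                        "S1 -> Z", "S2 -> C"), selection = c("S1", "S2")),
  `7B` = list(edges = c("X -> M", "M -> Y", "B -> M", "S -> B"),
              selection = "S"),
  `7D` = list(edges = c("X -> M", "M -> Y", "B -> M", "B -> Y", "S -> B"),
              selection = "S"),
  `8A` = list(edges = c("X -> M", "M -> Y", "B -> M", "Z -> Y",
                        "S1 -> Z", "S2 -> B"), selection = c("S1", "S2")),
  `8C` = list(edges = c("X -> M", "M -> Y", "B -> M", "B -> Y", "Z -> Y",
                        "S1 -> Z", "S2 -> B"), selection = c("S1", "S2")),
  `8D` = list(edges = c("X -> M", "M -> Y", "B -> M", "B -> Y", "B -> Z",
                        "Z -> Y", "S1 -> Z", "S2 -> B"),
              selection = c("S1", "S2")),
  `9A` = list(edges = c("B1 -> M1", "B2 -> M2", "X -> M1", "X -> M2",
                        "M1 -> Y", "M2 -> Y", "B1 -> X", "B2 -> X", "Z -> Y",
                        "S1 -> B1", "S2 -> B2", "S3 -> Z"),
              selection = c("S1", "S2", "S3")))

#' Canonical clinical diagram fixtures
#'
#' Returns one of the diagrams the package ships as worked examples: the
#' simple treatment/outcome/confounder/mediator motifs, the do-operator
#' surgery examples, the additive risk-modeling selection diagrams, the
#' biomarker effect-modification diagrams, and the two-mediator diagram.
#'
#' @param id one of `"1A"`, `"1C"`, `"1E"`, `"2A"`, `"4A"`, `"4D"`, `"4G"`,
#'   `"4I"`, `"5A"`, `"5C"`, `"6A"`, `"6C"`, `"7B"`, `"7D"`, `"8A"`, `"8C"`,
#'   `"8D"`, `"9A"`.
#' @return A `causal_graph`.
#' @examples
#' figure_fixture("6A")
#' @export
figure_fixture <- function(id) {
  if (!is_string(id) || !id %in% names(fixture_specs))
    abort2(paste0("unknown figure id: ", paste(id, collapse = ", "),
                  "; available: ", paste(names(fixture_specs), collapse = ", ")),
           "oncocausal_lookup_error")
  sp <- fixture_specs[[id]]
  ids <- unique(unlist(strsplit(sp$edges, " -> ", fixed = TRUE)))
  causal_graph(sp$edges, selection = sp$selection %||% character(0),
               labels = fixture_labels[intersect(names(fixture_labels), ids)])
}

#' List the available figure fixture ids
#' @return Character vector of ids accepted by [figure_fixture()].
#' @export
figure_fixture_ids <- function() names(fixture_specs)

# ---- JSON dialect -----------------------------------------------------------

#' Read a causal diagram from its JSON document
#'
#' The dialect is strict:
#' `{"nodes": [{"id": "X", "kind": "variable", "label": "..."}, ...],
#'   "edges": [["S1", "Z"], ["X", "Y"]]}`.
#' `kind` defaults to `"variable"`; unknown top-level or node keys are
#' rejected, as are edges referencing undeclared nodes.
#'
#' @param file path to a JSON file, or a JSON string.
#' @return A validated `causal_graph`.
#' @seealso [write_causal_graph()]
#' @export
read_causal_graph <- function(file) {
  txt <- if (is_string(file) && !grepl("{", file, fixed = TRUE) &&
             file.exists(file)) {
    paste(readLines(file, warn = FALSE), collapse = "\n")
  } else file
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  if (!is.list(doc) || length(setdiff(names(doc), c("nodes", "edges"))))
    abort2("graph document may only contain 'nodes' and 'edges'",
           "oncocausal_argument_error")
  if (is.null(doc$nodes))
    abort2("graph document must declare 'nodes'", "oncocausal_argument_error")
  ids <- character(0); kinds <- character(0); labels <- character(0)
  for (nd in doc$nodes) {
    if (!is.list(nd) || is.null(nd$id) ||
        length(setdiff(names(nd), c("id", "kind", "label"))))
      abort2("each node must be an object with keys among id/kind/label",
             "oncocausal_argument_error")
    kind <- nd$kind %||% "variable"
    if (!kind %in% c("variable", "selection"))
      abort2(paste0("unknown node kind: ", kind), "oncocausal_argument_error")
    ids <- c(ids, nd$id)
    kinds <- c(kinds, kind)
    labels <- c(labels, nd$label %||% "")
  }
  em <- matrix(character(0), ncol = 2L)
  for (e in doc$edges %||% list()) {
    if (length(e) != 2L)
      abort2("each edge must be a [from, to] pair", "oncocausal_argument_error")
    em <- rbind(em, c(e[[1L]], e[[2L]]))
  }
  dangling <- setdiff(c(em), ids)
  if (length(dangling))
    abort2(paste0("edge endpoint(s) reference undeclared node(s): ",
                  paste(dangling, collapse = ", ")),
           "oncocausal_reference_error")
  names(labels) <- ids
  causal_graph(em, selection = ids[kinds == "selection"], nodes = ids,
               labels = labels)
}

#' Write a causal diagram as its JSON document
#'
#' @param g a `causal_graph`.
#' @param file output path.
#' @return `file`, invisibly. `read_causal_graph(write_causal_graph(g, f))`
#'   round-trips exactly.
#' @export
write_causal_graph <- function(g, file) {
  nodes <- lapply(seq_len(nrow(g$nodes)), function(i) {
    nd <- list(id = g$nodes$id[i], kind = g$nodes$kind[i])
    if (nzchar(g$nodes$label[i])) nd$label <- g$nodes$label[i]
    nd
  })
  edges <- lapply(seq_len(nrow(g$edges)), function(i)
    c(g$edges[i, "from"], g$edges[i, "to"]))
  jsonlite::write_json(list(nodes = nodes, edges = edges), file,
                       auto_unbox = TRUE)
  invisible(file)
}

#' Render a causal diagram in DOT format
#'
#' Selection nodes are drawn as square boxes (a display convention only; DOT
#' output is not re-imported).
#'
#' @param g a `causal_graph`.
#' @return A single character string of DOT source.
#' @export
as_dot <- function(g) {
  esc <- function(x) gsub('"', '\\"', x, fixed = TRUE)
  lines <- c("digraph causal_diagram {")
  for (i in seq_len(nrow(g$nodes))) {
    shape <- if (g$nodes$kind[i] == "selection") "box" else "ellipse"
    label <- if (nzchar(g$nodes$label[i])) g$nodes$label[i] else g$nodes$id[i]
    lines <- c(lines, sprintf('  "%s" [shape=%s, label="%s"];',
                              esc(g$nodes$id[i]), shape, esc(label)))
  }
  for (i in seq_len(nrow(g$edges)))
    lines <- c(lines, sprintf('  "%s" -> "%s";',
                              esc(g$edges[i, "from"]), esc(g$edges[i, "to"])))
  paste(c(lines, "}"), collapse = "\n")
}
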