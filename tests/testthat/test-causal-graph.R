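# Construction, validation, serialization, surgery, back-door analysis and
# S-admissibility of causal diagrams.

test_that("construction validates structure, scope and references", {
  g <- causal_graph(c("X -> Y"))
  expect_s3_class(g, "causal_graph")
  expect_identical(sort(g$nodes$id), c("X", "Y"))

  # directed cycle among variable nodes, named in the message
  expect_error(causal_graph(c("A -> B", "B -> C", "C -> A")),
               class = "oncocausal_structural_error")
  expect_error(causal_graph(c("A -> B", "B -> C", "C -> A")),
               regexp = "cycle")
  # arrows into a selection node encode selection bias: out of scope
  expect_error(causal_graph(c("Y -> S"), selection = "S"),
               class = "oncocausal_scope_error")
  # self-loops and duplicate edges
  expect_error(causal_graph("X -> X"),
               class = "oncocausal_structural_error")
  expect_error(causal_graph(c("X -> Y", "X -> Y")),
               class = "oncocausal_structural_error")
  # selection node must point somewhere
  expect_error(causal_graph("X -> Y", selection = "S", nodes = "S"),
               class = "oncocausal_structural_error")
})

test_that("JSON dialect reads, rejects unknown keys and round-trips", {
  minimal <- '{"nodes":[{"id":"X"},{"id":"Y"}],"edges":[["X","Y"]]}'
  g <- read_causal_graph(minimal)
  expect_identical(g$nodes$id, c("X", "Y"))
  expect_identical(unname(g$edges[1, ]), c("X", "Y"))

  expect_error(read_causal_graph(
    '{"nodes":[{"id":"X"}],"edges":[],"extra":1}'),
    class = "oncocausal_argument_error")
  expect_error(read_causal_graph(
    '{"nodes":[{"id":"X","colour":"red"}],"edges":[]}'),
    class = "oncocausal_argument_error")
  # dangling endpoint
  expect_error(read_causal_graph(
    '{"nodes":[{"id":"X"}],"edges":[["X","Y"]]}'),
    class = "oncocausal_reference_error")
  # arrow into a selection node rejected at parse time
  expect_error(read_causal_graph(
    '{"nodes":[{"id":"Y"},{"id":"S","kind":"selection"}],"edges":[["Y","S"]]}'),
    class = "oncocausal_scope_error")

  for (id in figure_fixture_ids()) {
    g <- figure_fixture(id)
    f <- withr::local_tempfile(fileext = ".json")
    write_causal_graph(g, f)
    g2 <- read_causal_graph(f)
    expect_identical(g2$nodes, g$nodes, label = paste("fixture", id))
    expect_identical(g2$edges[, 1:2], g$edges[, 1:2],
                     label = paste("fixture", id))
  }
})

test_that("figure fixtures match their drawn structure and invariants", {
  g4d <- figure_fixture("4D")
  expect_setequal(g4d$nodes$id, c("X", "Y", "W", "C"))
  expect_setequal(paste(g4d$edges[, 1], g4d$edges[, 2]),
                  c("X Y", "X W", "C X", "C Y", "C W"))
  g8a <- figure_fixture("8A")
  expect_setequal(paste(g8a$edges[, 1], g8a$edges[, 2]),
                  c("S1 Z", "S2 B", "B M", "X M", "M Y", "Z Y"))
  expect_setequal(selection_nodes(g8a), c("S1", "S2"))
  # every fixture passes construction-time validation
  for (id in figure_fixture_ids())
    expect_s3_class(figure_fixture(id), "causal_graph")
  expect_error(figure_fixture("3B"), class = "oncocausal_lookup_error")
})

test_that("DOT export draws selection nodes as boxes", {
  dot <- as_dot(figure_fixture("6A"))
  expect_match(dot, '"S" \\[shape=box')
  expect_match(dot, '"X" -> "Y"')
})

test_that("do-operator surgery removes exactly the arrows into treatment", {
  g <- figure_fixture("4A")
  g2 <- do_surgery(g, "X")
  expect_setequal(paste(g2$edges[, 1], g2$edges[, 2]),
                  c("C Y", "Z Y", "X Y"))
  # nothing to remove when the treatment has no parents
  g0 <- figure_fixture("1A")
  expect_identical(do_surgery(g0, "X")$edges, g0$edges)
  expect_error(do_surgery(g, "Q"), class = "oncocausal_reference_error")
})

test_that("surgery is idempotent and drops exactly the prior in-degree", {
  set.seed(42)
  for (rep in 1:25) {
    g <- random_dag(sample(3:8, 1L))
    trt <- sample(g$nodes$id, sample(1:2, 1L))
    g1 <- do_surgery(g, trt)
    expect_identical(do_surgery(g1, trt)$edges, g1$edges)
    indeg <- sum(g$edges[, 2] %in% trt)
    expect_equal(nrow(g$edges) - nrow(g1$edges), indeg)
    expect_false(any(g1$edges[, 2] %in% trt))
  }
})

test_that("d-separation handles forks, colliders and isolated nodes", {
  soda <- causal_graph(c("Z -> X", "Z -> Y"))
  expect_false(is_d_separated(soda, "X", "Y"))
  expect_true(is_d_separated(soda, "X", "Y", given = "Z"))

  iso <- causal_graph(nodes = c("A", "B"))
  expect_true(is_d_separated(iso, "A", "B"))

  coll <- causal_graph(c("X -> K", "Y -> K"))
  expect_true(is_d_separated(coll, "X", "Y"))
  expect_false(is_d_separated(coll, "X", "Y", given = "K"))
  # conditioning on a descendant of the collider also opens it
  coll2 <- causal_graph(c("X -> K", "Y -> K", "K -> D"))
  expect_false(is_d_separated(coll2, "X", "Y", given = "D"))

  expect_error(is_d_separated(soda, "X", "Y", given = "X"),
               class = "oncocausal_argument_error")
})

test_that("back-door paths are enumerated and classified", {
  g <- figure_fixture("4G")
  bp <- backdoor_paths(g, "X", "Y")
  expect_length(bp, 1L)
  expect_identical(bp[[1]]$nodes, c("X", "C", "Y"))
  expect_identical(bp[[1]]$roles, "fork")

  # after surgery no arrows into X remain, so no back-door paths
  expect_length(backdoor_paths(do_surgery(g, "X"), "X", "Y"), 0L)
  expect_error(backdoor_paths(g, "X", "X"),
               class = "oncocausal_argument_error")
})

test_that("back-door criterion blocks the confounder path and vetoes descendants", {
  g <- figure_fixture("4G")
  expect_true(satisfies_backdoor(g, "X", "Y", adjustment = "C"))
  expect_false(satisfies_backdoor(g, "X", "Y"))
  # a descendant of treatment is never a valid adjustment variable
  gw <- causal_graph(c("C -> X", "C -> Y", "X -> Y", "X -> W"))
  expect_false(satisfies_backdoor(gw, "X", "Y", adjustment = c("C", "W")))
  expect_error(satisfies_backdoor(figure_fixture("6A"), "X", "Y",
                                  adjustment = "S"),
               class = "oncocausal_argument_error")
})

test_that("Rule 3 detects absence of any directed treatment-outcome path", {
  expect_true(rule3_no_effect(figure_fixture("4I"), "X", "Y"))
  expect_false(rule3_no_effect(figure_fixture("1A"), "X", "Y"))
  expect_false(rule3_no_effect(figure_fixture("2A"), "X", "Y"))
})

test_that("S-admissibility reproduces the clinical diagram verdicts", {
  expect_true(s_admissible(figure_fixture("6A"), "X", "Y",
                           adjustment = "Z")$admissible)
  v <- s_admissible(figure_fixture("6C"), "X", "Y", adjustment = "Z")
  expect_false(v$admissible)
  expect_gt(length(v$open_witness), 0L)
  expect_true(s_admissible(figure_fixture("6C"), "X", "Y",
                           adjustment = c("Z", "C"))$admissible)
  expect_true(s_admissible(figure_fixture("7D"), "X", "Y",
                           adjustment = "B")$admissible)
  g9 <- figure_fixture("9A")
  expect_true(s_admissible(g9, "X", "Y",
                           adjustment = c("B1", "B2", "Z"))$admissible)
  for (s in list(c("B1", "B2"), c("B1", "Z"), c("B2", "Z")))
    expect_false(s_admissible(g9, "X", "Y", adjustment = s)$admissible)
  # verdict and witness list must be consistent by definition
  expect_identical(v$admissible, length(v$open_witness) == 0L)
  expect_error(s_admissible(figure_fixture("6A"), "X", "Y",
                            adjustment = c("Z", "S")),
               class = "oncocausal_argument_error")
})

test_that("admissibility is not monotone: enlarging a set can open a collider", {
  g <- causal_graph(c("X -> Y", "S -> W", "W -> K", "Y -> K"),
                    selection = "S")
  expect_true(s_admissible(g, "X", "Y")$admissible)
  expect_false(s_admissible(g, "X", "Y", adjustment = "K")$admissible)
})

test_that("minimal admissible sets: clinical case, vacuous case, budget", {
  g9 <- figure_fixture("9A")
  sets <- minimal_admissible_sets(g9, "X", "Y",
                                  candidates = c("B1", "B2", "Z", "M1", "M2"))
  expect_true(any(vapply(sets, function(s)
    setequal(s, c("B1", "B2", "Z")), TRUE)))
  # every returned set is admissible; sets are sorted by size
  for (s in sets)
    expect_true(s_admissible(g9, "X", "Y", adjustment = s)$admissible)
  expect_true(!is.unsorted(lengths(sets)))

  # no selection nodes: the empty set is the unique minimal answer
  expect_identical(minimal_admissible_sets(figure_fixture("4A"), "X", "Y",
                                           candidates = c("C", "Z")),
                   list(character(0)))
  expect_error(minimal_admissible_sets(g9, "X", "Y",
                                       candidates = paste0("c", 1:21)),
               class = "oncocausal_size_error")
})

test_that("minimal sets agree with an exhaustive subset oracle on random diagrams", {
  set.seed(7)
  done <- 0L
  while (done < 12L) {
    g <- random_selection_diagram(5L, k = 2L)
    vids <- variable_nodes(g)
    trt <- vids[1L]; out <- vids[length(vids)]
    if (out %in% c(trt)) next
    cand <- setdiff(vids, c(trt, out))
    if (length(cand) < 2L) next
    sets <- minimal_admissible_sets(g, trt, out, candidates = cand)
    # oracle: test every subset directly
    all_subsets <- unlist(lapply(0:length(cand), function(k)
      if (k == 0L) list(character(0))
      else apply(utils::combn(sort(cand), k), 2L, identity, simplify = FALSE)),
      recursive = FALSE)
    adm <- Filter(function(s)
      s_admissible(g, trt, out, adjustment = s)$admissible, all_subsets)
    oracle_min <- Filter(function(s) {
      !any(vapply(adm, function(a)
        length(a) < length(s) && all(a %in% s), TRUE))
    }, adm)
    expect_equal(length(sets), length(oracle_min))
    for (s in sets)
      expect_true(any(vapply(oracle_min, function(o) setequal(o, s), TRUE)))
    done <- done + 1L
  }
})
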