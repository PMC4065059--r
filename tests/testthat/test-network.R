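# network builder: expansion, bait attachment, filter pipeline, expression

test_that("expansion follows BFS levels on a path graph", {
  st <- pmd_store(make_records(c("s", "a", "b"), c("a", "b", "c")))
  n1 <- expand(st, "s", depth = 1)
  expect_setequal(n1$nodes$id, c("a", "s"))
  expect_equal(n1$edges$pair, "a_s")
  n3 <- expand(st, "s", depth = 3)
  expect_setequal(n3$nodes$id, c("s", "a", "b", "c"))
  expect_equal(n3$nodes$level[match(c("s", "a", "b", "c"), n3$nodes$id)], 0:3)
  expect_error(expand(st, character()), "empty seed")
  expect_error(expand(st, "s", depth = 4), "depth")
})

test_that("expansion equals the independent BFS + induced-pair oracle", {
  for (sd in 1:25) {
    synth <- synth_store(synthetic_store_spec(
      n_proteins = 30L, n_metabolites = 4L, n_drugs = 2L, rng_seed = sd))
    st <- synth$store
    prot <- sort(unique(st$entities$id[st$entities$kind == "protein"]))
    set.seed(sd)
    seeds <- sample(prot, 2)
    depth <- sample(1:3, 1)
    met <- sample(c(TRUE, FALSE), 1); drg <- sample(c(TRUE, FALSE), 1)
    net <- expand(st, seeds, depth, met, drg)
    want_nodes <- oracle_expand_nodes(st, seeds, depth, met, drg)
    expect_setequal(net$nodes$id, want_nodes)
    expect_setequal(net$edges$pair, oracle_induced_pairs(st, want_nodes))
  }
})

test_that("expansion is monotone in depth and induced-complete", {
  synth <- synth_store(synthetic_store_spec(n_proteins = 40L, rng_seed = 3))
  st <- synth$store
  seeds <- c("P0001", "P0010")
  prev <- character()
  for (d in 1:3) {
    net <- expand(st, seeds, d, TRUE, TRUE)
    expect_true(all(prev %in% net$nodes$id))
    prev <- net$nodes$id
    # no store pair among retained nodes is missing from the edge set
    expect_setequal(net$edges$pair, oracle_induced_pairs(st, net$nodes$id))
  }
})

test_that("expansion attaches scores, levels, degrees and p-values", {
  st <- tiny_store()
  net <- expand(st, "P1", depth = 3, include_metabolites = TRUE,
                include_drugs = TRUE, background_organism = "orgA")
  expect_true(all(!is.na(net$edges$class_total)))
  expect_true(all(!is.na(net$edges$fsw)))
  expect_true(all(net$nodes$degree ==
                    table(c(net$edges$id_a, net$edges$id_b))[net$nodes$id]))
  expect_true(all(net$nodes$p_value > 0 & net$nodes$p_value < 1))
  # P1-P2: experimental, pubs {600 (HT), 10 (non-HT)}, shared CC01 -> A
  expect_equal(net$edges$class_label[net$edges$pair == "P1_P2"], "A")
  # P3-P4: predicted, unpublished, same CC -> total 1, unclassified
  expect_equal(net$edges$class_total[net$edges$pair == "P3_P4"], 1L)
  expect_equal(net$edges$class_label[net$edges$pair == "P3_P4"], "unclassified")
  # metabolite/drug display shapes
  expect_equal(net$nodes$shape[net$nodes$id == "HMDB0000001"], "RECTANGLE")
  expect_equal(net$nodes$shape[net$nodes$id == "DB00001"], "TRIANGLE")
})

test_that("bait attachment adds novel class-E edges only where needed", {
  st <- tiny_store()
  net <- expand(st, c("P3", "P4"), depth = 1)
  # bait B9X001 not in store: every prey gets a novel class-E edge
  net2 <- attach_bait(net, "B9X001", c("P3", "P4"), st)
  nov <- net2$edges[net2$edges$novel, ]
  expect_equal(nrow(nov), 2L)
  expect_true(all(nov$class_label == "E"))
  expect_true(all(nov$width == 0.5))
  expect_true(all(nov$n_pubs == 0L))
  expect_equal(net2$nodes$level[net2$nodes$id == "B9X001"], 0L)
  # prey already evidenced with the bait keeps its scored edge, no duplicate
  net3 <- expand(st, c("P1", "P3"), depth = 1)
  net4 <- attach_bait(net3, "P2", c("P1", "P3"), st)
  e12 <- net4$edges[net4$edges$pair == "P1_P2", ]
  expect_equal(nrow(e12), 1L)
  expect_false(e12$novel)
  expect_equal(e12$class_label, "A")
  # empty prey list: only the bait node is added
  net5 <- attach_bait(net, "B9X001", character(), st)
  expect_equal(nrow(net5$edges[net5$edges$novel, ]), 0L)
  expect_true("B9X001" %in% net5$nodes$id)
  # bait equal to a prey: self-edge skipped with warning
  expect_warning(attach_bait(net, "P3", c("P3", "P4"), st), "self-edge")
})

test_that("filter order matches the sequential rule-by-rule oracle", {
  for (sd in 1:30) {
    synth <- synth_store(synthetic_store_spec(
      n_proteins = 25L, n_metabolites = 3L, n_drugs = 0L,
      evidence_fsw_coupling = 0.5, rng_seed = sd))
    st <- synth$store
    prot <- sort(unique(st$entities$id[st$entities$kind == "protein"]))
    set.seed(1000 + sd)
    seeds <- sample(prot, 3)
    net <- expand(st, seeds, 2, TRUE, TRUE, background_organism = "orgA")
    got <- apply_filters(net, class_cutoff = "D", pvalue_cutoff = 0.8,
                         delete_degree_01 = TRUE, fsw_cutoff = 0.01)

    # oracle: re-apply the four rules sequentially and independently
    nodes <- net$nodes$id
    edges <- net$edges[, c("pair", "id_a", "id_b", "class_label", "fsw")]
    edges <- edges[edges$class_label %in% c("A", "B", "C", "D"), ]
    pv <- stats::setNames(net$nodes$p_value, net$nodes$id)
    nodes <- nodes[!(!is.na(pv[nodes]) & pv[nodes] > 0.8)]
    edges <- edges[edges$id_a %in% nodes & edges$id_b %in% nodes, ]
    deg <- stats::setNames(rep(0L, length(nodes)), nodes)
    tab <- table(c(edges$id_a, edges$id_b))
    deg[names(tab)] <- as.integer(tab)
    nodes <- nodes[deg[nodes] >= 2]
    edges <- edges[edges$id_a %in% nodes & edges$id_b %in% nodes, ]
    edges <- edges[edges$fsw >= 0.01, ]

    expect_setequal(got$nodes$id, nodes)
    expect_setequal(got$edges$pair, edges$pair)
  }
})

test_that("filters with no cutoffs are the identity", {
  st <- tiny_store()
  net <- expand(st, "P1", 2)
  out <- apply_filters(net)
  expect_identical(out$nodes, net$nodes)
  expect_identical(out$edges, net$edges)
  expect_equal(nrow(attr(out, "filter_report")), 0L)
})

test_that("class cutoff keeps at-or-above classes only", {
  nodes <- data.frame(id = c("a", "b", "c", "d"), stringsAsFactors = FALSE)
  edges <- data.frame(id_a = c("a", "a", "a"), id_b = c("b", "c", "d"),
                      class_label = c("A", "C", "E"), stringsAsFactors = FALSE)
  net <- pmd_network(nodes, edges)
  out <- apply_filters(net, class_cutoff = "C")
  expect_setequal(out$edges$class_label, c("A", "C"))
})

test_that("degree prune is a single simultaneous pass, seeds included", {
  # star: center + 3 leaves; leaves removed, center survives isolated
  nodes <- data.frame(id = c("hub", "l1", "l2", "l3"),
                      seed = c(FALSE, TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  edges <- data.frame(id_a = "hub", id_b = c("l1", "l2", "l3"),
                      stringsAsFactors = FALSE)
  net <- pmd_network(nodes, edges)
  out <- prune_low_degree(net)
  expect_equal(out$nodes$id, "hub")
  expect_equal(nrow(out$edges), 0L)
  # iterated variant empties the star completely
  out2 <- prune_low_degree(net, iterate = TRUE)
  expect_equal(nrow(out2$nodes), 0L)
  # triangle unchanged
  tri <- pmd_network(data.frame(id = c("a", "b", "c")),
                     data.frame(id_a = c("a", "b", "c"), id_b = c("b", "c", "a")))
  expect_equal(nrow(prune_low_degree(tri)$nodes), 3L)
  # empty network stays empty
  emp <- pmd_network(data.frame(id = character()),
                     data.frame(id_a = character(), id_b = character()))
  expect_equal(nrow(prune_low_degree(emp)$nodes), 0L)
  # no surviving node had entry degree <= 1
  set.seed(5)
  synth <- synth_store(synthetic_store_spec(n_proteins = 40L, rng_seed = 5))
  net3 <- expand(synth$store, "P0001", 2)
  entry_deg <- stats::setNames(net3$nodes$degree, net3$nodes$id)
  out3 <- prune_low_degree(net3)
  expect_true(all(entry_deg[out3$nodes$id] >= 2))
})

test_that("fold-change reader parses signed values and flags bad lines", {
  path <- withr::local_tempfile()
  writeLines(c("P12345\t2.5", "GSY1\t-1.8"), path)
  tab <- read_foldchange_table(path)
  expect_equal(tab$token, c("P12345", "GSY1"))
  expect_equal(tab$fold_change, c(2.5, -1.8))
  writeLines(c("P12345\t2.5", "GSY1\tnot_a_number"), path)
  expect_error(read_foldchange_table(path), "line 2")
})

test_that("expression annotation uses closed cutoff boundaries", {
  nodes <- data.frame(id = c("u", "d", "m", "x"), stringsAsFactors = FALSE)
  net <- pmd_network(nodes, data.frame(id_a = character(), id_b = character()))
  tab <- data.frame(token = c("u", "d", "m"), fold_change = c(1.3, -1.3, 1.0),
                    stringsAsFactors = FALSE)
  out <- annotate_expression(net, tab, up_cutoff = 1.3, down_cutoff = -1.3)
  reg <- stats::setNames(out$nodes$regulation, out$nodes$id)
  expect_equal(unname(reg[c("u", "d", "m", "x")]),
               c("up", "down", "unchanged", "none"))
  # colors override: up red, down green
  col <- stats::setNames(out$nodes$color, out$nodes$id)
  expect_equal(unname(col["u"]), "#FF0000")
  expect_equal(unname(col["d"]), "#00FF00")
  # size proportional to |fc|
  expect_equal(out$nodes$size[out$nodes$id == "u"],
               out$nodes$size[out$nodes$id == "d"])
  # duplicate identifiers: last wins with warning
  tab2 <- data.frame(token = c("u", "u"), fold_change = c(2.0, -2.0))
  expect_warning(out2 <- annotate_expression(net, tab2), "last value wins")
  expect_equal(out2$nodes$regulation[out2$nodes$id == "u"], "down")
})
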