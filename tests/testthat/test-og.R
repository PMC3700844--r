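# The operation graph: construction, Anc, decompression (full and
# partial), pruning, and the cost/load measures, checked against
# independent replay / path-enumeration oracles.

chain_og <- function(n_mut = 2, L = 12) {
  # root(explicit) -> m1 -> ... -> mk, unit costs
  og <- operation_graph(sequence_genotype(strrep("A", L)))
  ids <- og$root$id
  for (i in seq_len(n_mut)) {
    ids <- c(ids, og_add_mutation(og, ids[length(ids)],
                                  op_point_mutation(i, "C")))
  }
  list(og = og, ids = ids)
}

test_that("a mutation chain is a tree with one edge per non-root node", {
  x <- chain_og(10)
  expect_equal(og_node_count(x$og), 11L)
  expect_equal(og_edge_count(x$og), 10L)
  for (id in x$ids[-1]) expect_length(og_parents(x$og, id), 1L)
  expect_length(og_parents(x$og, x$ids[1]), 0L)
  expect_error(og_add_mutation(x$og, 999L, op_point_mutation(1, "C")),
               "no node")
})

test_that("recombination nodes have in-degree two and the edge-count identity holds", {
  og <- operation_graph(sequence_genotype("ACGTACGTAC"))
  m1 <- og_add_mutation(og, 1L, op_point_mutation(1, "C"))
  m2 <- og_add_mutation(og, 1L, op_point_mutation(2, "G"))
  r1 <- og_add_recombination(og, m1, m2, op_crossover(5))
  expect_length(og_parents(og, r1), 2L)
  expect_equal(og_parents(og, r1), c(m1, m2))
  expect_equal(og_edge_count(og),
               (og_node_count(og) - 1L) + og$recomb_count)
  # self-recombination is allowed and counts two edges
  r2 <- og_add_recombination(og, m1, m1, op_crossover(3))
  expect_equal(og_parents(og, r2), c(m1, m1))
  expect_equal(og_edge_count(og), (og_node_count(og) - 1L) + 2L)
})

test_that("decompression equals full-history replay on random graphs", {
  for (seed in 1:150) {
    og <- random_og(n_nodes = sample(1:30, 1), recomb_fraction = 0.25,
                    seed = seed)
    root_str <- as.character(og_label(og, og$root$id))
    for (id in og_node_ids(og)) {
      expect_identical(as.character(og_decompress(og, id)),
                       oracle_replay(og, id, root_str))
    }
  }
})

test_that("decompression is unchanged when intermediate nodes are made explicit", {
  for (seed in 1:20) {
    og <- random_og(25, recomb_fraction = 0.2, seed = seed)
    ids <- og_node_ids(og)
    before <- vapply(ids, function(i) as.character(og_decompress(og, i)), "")
    for (id in sample(ids, 5)) og_set_explicit(og, id)
    after <- vapply(ids, function(i) as.character(og_decompress(og, i)), "")
    expect_identical(after, before)
  }
})

test_that("partial decompression equals indexing the full decompression", {
  set.seed(99)
  for (seed in 1:40) {
    og <- random_og(20, recomb_fraction = 0.3, seed = seed)
    for (id in sample(og_node_ids(og), 5, replace = TRUE)) {
      full <- unclass(og_decompress(og, id))
      pos <- sample(length(full), 3, replace = TRUE)
      for (p in pos) {
        expect_identical(og_partial_decompress(og, id, p), full[p])
      }
    }
    expect_error(og_partial_decompress(og, 1L, 10^6), "out of range")
  }
})

test_that("Anc returns the lowest explicit ancestors", {
  x <- chain_og(2)
  og <- x$og
  expect_equal(og_anc(og, x$ids[1]), x$ids[1])   # explicit: itself
  expect_equal(og_anc(og, x$ids[3]), x$ids[1])
  og_set_explicit(og, x$ids[2])
  expect_equal(og_anc(og, x$ids[3]), x$ids[2])
  # compressed child of a recombination with both parents explicit
  og2 <- operation_graph(sequence_genotype("AAAAAAAAAA"))
  m1 <- og_add_mutation(og2, 1L, op_point_mutation(1, "C"))
  m2 <- og_add_mutation(og2, 1L, op_point_mutation(2, "G"))
  r <- og_add_recombination(og2, m1, m2, op_crossover(4))
  og_set_explicit(og2, m1)
  og_set_explicit(og2, m2)
  expect_equal(og_anc(og2, r), sort(c(m1, m2)))
  # and against the oracle on random graphs
  for (seed in 1:20) {
    og3 <- random_og(20, recomb_fraction = 0.25, seed = seed)
    for (id in sample(og_node_ids(og3), 4)) og_set_explicit(og3, id)
    for (id in og_node_ids(og3)) {
      expect_equal(og_anc(og3, id), oracle_anc(og3, id))
    }
  }
})

test_that("cost and cost_between follow the endpoint convention", {
  x <- chain_og(2)
  og <- x$og
  r <- x$ids[1]; m1 <- x$ids[2]; m2 <- x$ids[3]
  expect_equal(og_cost(og, r), 0)            # explicit
  expect_equal(og_cost(og, m2), 2)           # c(m1) + c(m2)
  expect_equal(og_cost_between(og, m2, m1), 1)
  expect_equal(og_cost_between(og, m2, r), 2)
  # waypoint off every decompression path
  s1 <- og_add_mutation(og, r, op_point_mutation(5, "G"))
  expect_equal(og_cost_between(og, m2, s1), 0)
  expect_equal(og_cost_between(og, m2, m2), og_op(og, m2)$cost)
})

test_that("cost and load agree with path-enumeration oracles on random graphs", {
  for (seed in 1:15) {
    og <- random_og(18, recomb_fraction = 0.25, seed = seed)
    for (id in sample(og_node_ids(og), 3)) og_set_explicit(og, id)
    ids <- og_node_ids(og)
    for (id in ids) {
      expect_equal(og_cost(og, id), oracle_cost(og, id))
      expect_equal(og_load(og, id), oracle_load(og, id))
    }
    pair <- sample(ids, 2)
    expect_equal(og_cost_between(og, pair[1], pair[2]),
                 oracle_cost_between(og, pair[1], pair[2]))
  }
})

test_that("load of a chain matches the definition directly", {
  x <- chain_og(2)
  og <- x$og
  og_set_weight(og, x$ids[3], 1)
  expect_equal(og_load(og, x$ids[2]), 1)   # w(m2) * cost(m2, m1)
  expect_equal(og_load(og, x$ids[1]), 2)   # root serves m2 at cost 2
  og2 <- chain_og(2)$og                    # no active nodes at all
  expect_equal(og_load(og2, 2L), 0)
})

test_that("pruning a lost branch stops at the root, at active nodes, and at out-degree-2 nodes", {
  # root -> m1 -> m2 with w(m2) = 0: both mutations removed, root kept
  x <- chain_og(2)
  expect_equal(og_prune_lost(x$og, x$ids[3]), x$ids[2:3])
  expect_equal(og_node_ids(x$og), x$ids[1])
  # lost internal node with surviving descendants: nothing deleted
  y <- chain_og(2)
  og_set_weight(y$og, y$ids[3], 2)
  expect_identical(og_prune_lost(y$og, y$ids[2]), integer(0))
  expect_equal(og_node_count(y$og), 3L)
  # lost leaf under an active parent: only the leaf goes
  z <- chain_og(2)
  og_set_weight(z$og, z$ids[2], 1)
  expect_equal(og_prune_lost(z$og, z$ids[3]), z$ids[3])
  expect_equal(og_node_count(z$og), 2L)
  # active nodes cannot be pruned
  w <- chain_og(1)
  og_set_weight(w$og, w$ids[2], 1)
  expect_error(og_prune_lost(w$og, w$ids[2]), "active")
  # out-degree-2 stop: two leaves under one inactive fork
  f <- chain_og(1)
  a <- og_add_mutation(f$og, f$ids[2], op_point_mutation(3, "C"))
  b <- og_add_mutation(f$og, f$ids[2], op_point_mutation(4, "C"))
  og_set_weight(f$og, b, 1)
  expect_equal(og_prune_lost(f$og, a), a)  # fork node m1 kept (still has b)
  expect_true(all(c(f$ids[2], b) %in% og_node_ids(f$og)))
})

test_that("active genotypes decompress identically after arbitrary pruning", {
  for (seed in 1:25) {
    og <- random_og(25, recomb_fraction = 0.2, seed = seed)
    act <- og_active_ids(og)
    before <- vapply(act, function(i) as.character(og_decompress(og, i)), "")
    for (id in rev(og_node_ids(og))) {
      nd_ids <- og_node_ids(og)
      if (id %in% nd_ids && !(id %in% og_active_ids(og)) &&
          length(og_children(og, id)) == 0L) {
        og_prune_lost(og, id)
      }
    }
    after <- vapply(act, function(i) as.character(og_decompress(og, i)), "")
    expect_identical(after, before)
    expect_true(all(act %in% og_node_ids(og)))
  }
})

test_that("data requests propagate up to, but not through, explicit ancestors", {
  x <- chain_og(2)
  og <- x$og
  og_record_request(og, x$ids[1])          # explicit: only itself
  expect_equal(og_request_count(og, x$ids[1]), 1)
  og_record_request(og, x$ids[3])          # m2 and m1, not the explicit root
  expect_equal(og_request_count(og, x$ids[3]), 1)
  expect_equal(og_request_count(og, x$ids[2]), 1)
  expect_equal(og_request_count(og, x$ids[1]), 1)
  og_set_explicit(og, x$ids[2])
  og_record_request(og, x$ids[3], count = 5)
  expect_equal(og_request_count(og, x$ids[3]), 6)
  expect_equal(og_request_count(og, x$ids[2]), 1)  # now an explicit stop
})

test_that("required flags mark exactly the nodes serving active genotypes", {
  og <- build_example_og()
  flags <- og_required_flags(og)
  expect_true(flags[["12"]])               # node l
  expect_true(all(flags[as.character(og_active_ids(og))]))
  # nodes above i are no longer required on i's behalf once i is explicit
  og_set_explicit(og, og$letters[["i"]])
  flags <- og_required_flags(og)
  expect_false(flags[[as.character(og$letters[["f"]])]])
  expect_true(flags[[as.character(og$letters[["c"]])]])   # still serves e
  # a required node can have zero recorded requests
  x <- chain_og(1)
  og_set_weight(x$og, x$ids[2], 3)
  f2 <- og_required_flags(x$og)
  expect_true(f2[[as.character(x$ids[2])]])
  expect_equal(og_request_count(x$og, x$ids[2]), 0)
})

test_that("a compressed root is an integrity error on decompression", {
  x <- chain_og(1)
  og_set_explicit(x$og, x$ids[2])
  og_compress(x$og, x$ids[1])
  expect_error(og_decompress(x$og, x$ids[1]), "integrity")
  expect_identical(as.character(og_decompress(x$og, x$ids[2])),
                   as.character(og_label(x$og, x$ids[2])))
  # and C(V) may never be emptied
  expect_error(og_compress(x$og, x$ids[2]), "last explicit")
})
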