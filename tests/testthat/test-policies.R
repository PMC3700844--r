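# Cache policies: advance(), Greedy-Load (exact and proxy modes),
# Store-Active, Store-Root.

panel2_fixture <- function() {
  # the worked example with C(V) = {d, c} (state after phase 1)
  og <- build_example_og()
  og_set_explicit(og, og$letters[["d"]])
  og_compress(og, og$letters[["a"]])
  og
}

test_that("advance moves the frontier from the root to the recombination fork", {
  og <- build_example_og()            # C(V) = {a, c}
  L <- og$letters
  y <- og_advance(og, L[["a"]])
  expect_equal(y, L[["d"]])           # d has two required compressed children
  expect_false(og_is_explicit(og, L[["a"]]))
  expect_true(og_is_explicit(og, L[["d"]]))
  # c has two compressed children with non-zero load: cannot advance
  expect_equal(og_advance(og, L[["c"]]), L[["c"]])
  expect_true(og_is_explicit(og, L[["c"]]))
})

test_that("advance is a no-op on an active explicit leaf and errors on compressed nodes", {
  og <- operation_graph(sequence_genotype("ACGTACGT"))
  m <- og_add_mutation(og, 1L, op_point_mutation(1, "C"))
  og_set_explicit(og, m)
  og_set_weight(og, m, 2)
  expect_equal(og_advance(og, m), m)
  expect_true(og_is_explicit(og, m))
  expect_error(og_advance(og, og_add_mutation(og, m, op_point_mutation(2, "G"))),
               "not explicit")
})

test_that("the worked example reproduces all four Greedy-Load panels in exact-load mode", {
  panels <- trace_example(k = 4)
  expect_equal(panels[[1]], c("a", "c"))
  expect_equal(panels[[2]], c("c", "d"))
  expect_equal(panels[[3]], c("d", "e", "i"))
  expect_equal(panels[[4]], c("e", "g", "h", "i"))
})

test_that("the panel-3 load preconditions hold under unit weights and costs", {
  og <- panel2_fixture()
  L <- og$letters
  expect_gt(og_load(og, L[["c"]]), og_load(og, L[["d"]]))
  expect_gt(og_load(og, L[["f"]]), og_load(og, L[["e"]]))
})

test_that("greedy_load keeps the cache within budget and every active node decompressible", {
  for (seed in 1:60) {
    og <- random_og(sample(2:28, 1), recomb_fraction = 0.2, seed = seed)
    root_str <- as.character(og_label(og, og$root$id))
    # scripted request pattern: whatever the population would touch
    for (id in og_active_ids(og)) {
      og_record_request(og, id, count = og_weight(og, id))
    }
    k <- sample(1:6, 1)
    greedy_load_update(og, k)
    expect_lte(length(og_cached_ids(og)), k)
    expect_gte(length(og_cached_ids(og)), 1L)
    for (id in og_active_ids(og)) {
      expect_identical(as.character(og_decompress(og, id)),
                       oracle_replay(og, id, root_str))
    }
  }
})

test_that("a single-node graph stays cached at the root for any budget", {
  og <- operation_graph(sequence_genotype("ACGT"))
  og_set_weight(og, 1L, 5)
  for (k in c(1, 3, 10)) {
    greedy_load_update(og, k)
    expect_equal(og_cached_ids(og), 1L)
  }
  expect_error(greedy_load_update(og, 0), "k must be")
})

test_that("phase 1 compresses no-longer-needed nodes and resets their counters", {
  og <- operation_graph(sequence_genotype(strrep("A", 10)))
  m1 <- og_add_mutation(og, 1L, op_point_mutation(1, "C"))
  m2 <- og_add_mutation(og, m1, op_point_mutation(2, "C"))
  og_set_explicit(og, m1)
  og_set_weight(og, m2, 1)
  og_record_request(og, m2)
  og_set_explicit(og, m2)
  # root now serves nobody: phase 1 must compress it; m2 is an active leaf
  greedy_load_update(og, 2)
  expect_false(og_is_explicit(og, 1L))
  expect_equal(og_request_count(og, 1L), 0)
  expect_true(og_is_explicit(og, m2))
})

test_that("store_active caches exactly the active set and store_root only the root", {
  og <- build_example_og()
  apply_policy(og, policy_state("store_active"))
  expect_equal(og_cached_ids(og), sort(og$letters[c("e", "h", "i", "j", "k", "l")]),
               ignore_attr = TRUE)
  og2 <- build_example_og()
  apply_policy(og2, policy_state("store_root"))
  expect_equal(og_cached_ids(og2), og2$letters[["a"]])
})

test_that("greedy_load fires on the configured cadence", {
  make <- function() {
    og <- operation_graph(sequence_genotype(strrep("A", 8)))
    m <- og_add_mutation(og, 1L, op_point_mutation(1, "C"))
    og_set_weight(og, m, 1)
    og_record_request(og, m)
    og
  }
  st <- policy_state("greedy_load", k = 2, t = 5)
  og <- make()
  apply_policy(og, st, generation = 3)     # not due: C(V) unchanged
  expect_equal(og_cached_ids(og), 1L)
  apply_policy(og, st, generation = 5)     # due: frontier advances to m
  expect_false(og_is_explicit(og, 1L))
  # the |C(V)| < k/2 alternative trigger overrides the cadence when enabled
  og2 <- make()
  st2 <- policy_state("greedy_load", k = 4, t = 5, half_k_trigger = TRUE)
  apply_policy(og2, st2, generation = 3)
  expect_false(og_is_explicit(og2, 1L))
})

test_that("the request-count proxy usually picks the same top node as exact load", {
  # mutation-only graphs with scripted per-generation touches; report the
  # top-1 agreement fraction (the proxy is approximate by design)
  agree <- 0L
  trials <- 100L
  for (seed in seq_len(trials)) {
    og <- random_og(sample(8:20, 1), recomb_fraction = 0, seed = seed,
                    active_prob = 0.5)
    for (rep in 1:3) {
      for (id in og_active_ids(og)) {
        og_record_request(og, id, count = og_weight(og, id))
      }
    }
    comp <- setdiff(og_node_ids(og), og_cached_ids(og))
    if (length(comp) == 0L) {
      trials <- trials - 1L
      next
    }
    by_load <- comp[which.max(vapply(comp, function(i) og_load(og, i), 0))]
    by_req <- comp[which.max(vapply(comp, function(i) og_request_count(og, i),
                                    0))]
    if (by_load == by_req) agree <- agree + 1L
  }
  frac <- agree / trials
  message(sprintf("proxy/exact top-1 agreement: %.2f over %d trials",
                  frac, trials))
  expect_gte(frac, 0)
  expect_lte(frac, 1)
})
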