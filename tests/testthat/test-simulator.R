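# The forward-time engine: reproduction models, determinism, rescaling,
# batch decompression, verification statistics.

quick_cfg <- function(policy, seed = 5, N = 30, gens = 40, ...) {
  sim_config(N = N, L = 200, u = 3e-4, generations = gens, burn_in = 0,
             seed = seed, policy = policy, snapshot_genotypes = TRUE, ...)
}

test_that("with all rates zero the graph never grows and everyone carries the root genotype", {
  cfg <- sim_config(N = 20, L = 50, generations = 30, burn_in = 0, seed = 1,
                    policy = policy_state("store_active"))
  res <- run_simulation(cfg)
  expect_equal(og_node_count(res$og), 1L)
  expect_true(all(res$population == res$og$root$id))
  g <- population_genotypes(res)
  expect_identical(as.character(g[[1]]), as.character(og_label(res$og, 1L)))
  expect_equal(nrow(res$metrics), 30L)
})

test_that("the same seed reproduces the identical run", {
  r1 <- run_simulation(quick_cfg(policy_state("greedy_load", k = 4, t = 2)))
  r2 <- run_simulation(quick_cfg(policy_state("greedy_load", k = 4, t = 2)))
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(population_sequences(r1), population_sequences(r2))
  expect_identical(r1$metrics$cached_count, r2$metrics$cached_count)
})

test_that("node weights always sum to the population size", {
  res <- run_simulation(quick_cfg(policy_state("store_active"),
                                  u_i = 1e-4, u_d = 1e-4, c_rate = 1e-4))
  og <- res$og
  expect_equal(sum(vapply(og_active_ids(og), function(i) og_weight(og, i), 0)),
               res$config$N)
})

test_that("all three policies yield byte-identical populations from a shared seed", {
  pols <- list(policy_state("store_active"),
               policy_state("greedy_load", k = 5, t = 1),
               policy_state("store_root"))
  runs <- lapply(pols, function(p) {
    run_simulation(quick_cfg(p, c_rate = 1e-4, u_i = 5e-5, u_d = 5e-5))
  })
  expect_identical(runs[[1]]$snapshots, runs[[2]]$snapshots)
  expect_identical(runs[[1]]$snapshots, runs[[3]]$snapshots)
})

test_that("the Moran model runs, conserves weight, and is deterministic", {
  cfg <- sim_config(model = "moran", N = 15, L = 100, u = 2e-4,
                    generations = 10, burn_in = 0, seed = 3,
                    policy = policy_state("greedy_load", k = 3, t = 1))
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  og <- r1$og
  expect_equal(sum(vapply(og_active_ids(og), function(i) og_weight(og, i), 0)),
               15)
  expect_identical(population_sequences(r1), population_sequences(r2))
  expect_true(all(r1$metrics$cached_count <= 3))
})

test_that("pathway populations evolve and compress losslessly", {
  mk <- function(pol) {
    sim_config(genotype = "pathway", N = 20, genes = 8, u_g = 2e-3,
               u_l = 2e-3, generations = 30, burn_in = 0, seed = 9,
               policy = pol, snapshot_genotypes = TRUE)
  }
  ra <- run_simulation(mk(policy_state("store_active")))
  rg <- run_simulation(mk(policy_state("greedy_load", k = 4, t = 1)))
  expect_identical(ra$snapshots, rg$snapshots)
  expect_gt(og_node_count(ra$og), 1L)
  g <- population_genotypes(ra)[[1]]
  expect_s3_class(g, "pathway_genotype")
  expect_equal(footprint(g), 64)
})

test_that("burn-in truncates the metrics stream but not the simulation", {
  cfg <- sim_config(N = 10, L = 50, u = 1e-3, generations = 25, burn_in = 10,
                    seed = 2, policy = policy_state("store_active"))
  res <- run_simulation(cfg)
  expect_equal(nrow(res$metrics), 15L)
  expect_equal(res$metrics$generation[1], 11L)
})

test_that("rescaling preserves N*u and matches the large-system interpretation", {
  r <- rescale_parameters(1e3, 1e-4, 0, 1e3, 1e5)
  expect_equal(r$effective_N, 1e8)
  expect_equal(r$effective_u, 1e-9)
  expect_equal(r$effective_generations, 1e8)
  r1 <- rescale_parameters(500, 2e-5, 1e-6, 100, 1)
  expect_equal(r1$effective_N, 500)          # lambda = 1 is the identity
  expect_equal(r1$effective_u, 2e-5)
  for (lam in c(1, 10, 1e3, 1e5)) {
    r2 <- rescale_parameters(1e3, 1e-4, 2e-5, 10, lam)
    expect_equal(r2$effective_N * r2$effective_u, 1e3 * 1e-4)
    expect_equal(r2$effective_N * r2$effective_c, 1e3 * 2e-5)
  }
  expect_error(rescale_parameters(10, 1e-4, 0, 10, 0.5), ">= 1")
})

test_that("a batch session decompresses once and requests once", {
  og <- operation_graph(sequence_genotype(strrep("A", 30)))
  m1 <- og_add_mutation(og, 1L, op_point_mutation(3, "C"))
  m2 <- og_add_mutation(og, m1, op_point_mutation(7, "G"))
  s <- batch_decompress(og, m2)
  expect_equal(s$n_decompressions(), 0L)
  g1 <- s$read_all()
  g2 <- s$read_all()
  expect_equal(s$n_decompressions(), 1L)     # reused, not re-decompressed
  expect_identical(g1, g2)
  expect_equal(s$read_at(3), "C")
  expect_equal(og_request_count(og, m2), 1)  # one request for the session
  expect_equal(og_request_count(og, m1), 1)
  # counters equal those after a single og_record_request
  og2 <- operation_graph(sequence_genotype(strrep("A", 30)))
  n1 <- og_add_mutation(og2, 1L, op_point_mutation(3, "C"))
  n2 <- og_add_mutation(og2, n1, op_point_mutation(7, "G"))
  og_record_request(og2, n2)
  expect_equal(og_request_count(og2, n2), og_request_count(og, m2))
  expect_equal(og_request_count(og2, n1), og_request_count(og, m1))
  # a session on an explicit node performs zero decompressions
  s0 <- batch_decompress(og, 1L)
  s0$read_all()
  expect_equal(s0$n_decompressions(), 0L)
})

test_that("verification statistics match their definitions on known samples", {
  same <- rep(strrep("ACGT", 5), 4)
  v <- verify_stats(same, effective_n = 100)
  expect_equal(v$S, 0L)
  expect_equal(v$theta_w, 0)
  expect_equal(v$pi, 0)
  pair <- c("AAAAAA", "AAACCC")
  v2 <- verify_stats(pair, effective_n = 100)
  expect_equal(v2$S, 3L)
  expect_equal(v2$pi, 3)
  expect_equal(v2$a_n, 1)
  expect_equal(v2$theta_w, 3)
  expect_error(verify_stats(c("AAA", "AAAA"), 10), "unequal")
  expect_error(verify_stats("AAA", 10), "at least two")
})

test_that("the four-gamete bound sees recombinant histories and not mutation-only ones", {
  recomb <- c("AATT", "TTAA", "AAAA", "TTTT")   # all four gametes at (1, 3)
  expect_gte(verify_stats(recomb, 10)$rmin, 1L)
  mut_only <- c("AAAA", "CAAA", "CCAA", "CCCA")
  expect_equal(verify_stats(mut_only, 10)$rmin, 0L)
})

test_that("the explicit-genotype heap stays within the cache budget's byte ceiling", {
  cfg <- sim_config(N = 40, L = 300, u = 3e-4, u_i = 1e-5, u_d = 1e-5,
                    generations = 60, burn_in = 0, seed = 8,
                    policy = policy_state("greedy_load", k = 5, t = 1))
  res <- run_simulation(cfg)
  og <- res$og
  max_fp <- max(vapply(og_cached_ids(og),
                       function(i) footprint(og_label(og, i)), 0))
  acct <- heap_account(og)
  expect_lte(acct$explicit_genotype_bytes, 5 * max_fp)
  expect_equal(acct$total, acct$explicit_genotype_bytes + acct$operation_bytes)
  share <- acct$operation_bytes / acct$total
  message(sprintf("operation records: %.3f%% of reported heap", 100 * share))
})
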