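# Neutral forward-time simulation engine driving genotype events through the
# operation graph and cache-policy layers.
#
# Documented RNG draw order, fixed so that two runs with the same seed and
# rates share the entire event stream regardless of cache policy (the
# policies themselves never consume randomness):
#   per generation: (1) N parent indices; (2) per offspring in index order:
#   crossover uniform [one partner index and one breakpoint when it fires],
#   then insertion/deletion/point-mutation draws in the order documented in
#   sample_events().  Genotype reads (pre-mutation bases) never draw.

#' Simulation configuration
#'
#' @param model Reproduction model: `"wright_fisher"` (non-overlapping
#'   generations, multinomial resampling) or `"moran"` (one birth-death
#'   replacement per step, `N` steps reported as one generation).
#' @param genotype `"sequence"` or `"pathway"`.
#' @param N Population size (number of haploid individuals / genotypes).
#' @param L Sequence length in bases (sequence model).
#' @param genes Gene count (pathway model).
#' @param u,u_i,u_d Per-base point-mutation / insertion / deletion rates per
#'   generation.
#' @param c_rate Per-base crossover (recombination) rate per generation;
#'   sequence model only.  Note the field reuses the symbol c for this rate;
#'   it is distinct from the operation-cost function.
#' @param u_l,u_g Pathway binding-site loss / gain rates per gene pair per
#'   generation.
#' @param indel_mean Mean indel length (geometric lengths).
#' @param generations Number of generations to simulate.
#' @param burn_in Generations excluded from the metrics stream (standard
#'   equilibration discard).  Default `10 * N`, the conventional coalescent
#'   burn-in; pass 0 to record from the start.
#' @param lambda_scale Rescaling factor `lambda >= 1`: the run is interpreted
#'   as a population `lambda` times larger evolving `lambda` times longer
#'   with rates `lambda` times smaller (products like `N*u` preserved); see
#'   [rescale_parameters()].
#' @param seed Integer RNG seed (`NULL` to use the current RNG state).
#' @param policy A [policy_state()].
#' @param fitness_requests Emit one (weighted) data request per active
#'   genotype per generation, emulating the genotype reads of a fitness
#'   evaluation; neutral reproduction is unaffected, but the request
#'   counters then reflect genotype frequencies, which is what the
#'   Greedy-Load proxy feeds on.
#' @param snapshot_genotypes Record the full population's genotypes every
#'   generation (as strings / edge-list strings).  Expensive; used to prove
#'   losslessness across policies.
#' @param og_snapshot_dir Optional directory receiving a Graphviz snapshot
#'   of the operation graph (`og_gen<i>.dot`) every `max(t, 1)`
#'   generations.
#' @param initial_genotype Optional explicit root genotype; by default a
#'   uniform random sequence of length `L`, or a pathway with no binding
#'   sites.
#' @return A validated `sim_config`.
#' @export
sim_config <- function(model = c("wright_fisher", "moran"),
                       genotype = c("sequence", "pathway"),
                       N, L = 1000L, genes = 50L,
                       u = 0, u_i = 0, u_d = 0, c_rate = 0,
                       u_l = 0, u_g = 0, indel_mean = 3,
                       generations = 100L, burn_in = NULL,
                       lambda_scale = 1, seed = NULL,
                       policy = policy_state("store_active"),
                       fitness_requests = TRUE,
                       snapshot_genotypes = FALSE,
                       og_snapshot_dir = NULL,
                       initial_genotype = NULL) {
  model <- match.arg(model)
  genotype <- match.arg(genotype)
  N <- as.integer(N)
  generations <- as.integer(generations)
  if (is.na(N) || N < 1L) stop("N must be a positive integer")
  if (is.na(generations) || generations < 1L) {
    stop("generations must be a positive integer")
  }
  rates <- event_rates(u = u, u_i = u_i, u_d = u_d, u_l = u_l, u_g = u_g,
                       indel_mean = indel_mean)
  if (c_rate < 0) stop("c_rate must be non-negative")
  if (c_rate > 0 && genotype != "sequence") {
    stop("c_rate (crossover) is meaningful only for sequence genotypes")
  }
  if (lambda_scale < 1) stop("lambda_scale must be >= 1")
  if (is.null(burn_in)) burn_in <- 10L * N
  burn_in <- as.integer(burn_in)
  if (is.na(burn_in) || burn_in < 0L) stop("burn_in must be >= 0")
  stopifnot(inherits(policy, "policy_state"))
  structure(list(model = model, genotype = genotype, N = N,
                 L = as.integer(L), genes = as.integer(genes),
                 rates = rates, c_rate = c_rate,
                 generations = generations, burn_in = burn_in,
                 lambda_scale = lambda_scale, seed = seed, policy = policy,
                 fitness_requests = fitness_requests,
                 snapshot_genotypes = snapshot_genotypes,
                 og_snapshot_dir = og_snapshot_dir,
                 initial_genotype = initial_genotype),
            class = "sim_config")
}

#' Rescale simulation parameters
#'
#' The standard speed-up trade: simulate a `lambda` times smaller population
#' for `lambda` times fewer generations at `lambda` times higher rates.  The
#' compound parameters `N*u` and `N*c` are preserved, so the simulated
#' diversity matches the larger, slower system.
#'
#' @param N,u,c_rate,generations Parameters of the run actually executed.
#' @param lambda_scale `lambda >= 1`.
#' @return List of effective (equivalent large-system) parameters:
#'   `effective_N = N*lambda`, `effective_generations = generations*lambda`,
#'   `effective_u = u/lambda`, `effective_c = c_rate/lambda`.
#' @examples
#' rescale_parameters(1e3, 1e-4, 0, 1e3, 1e5)$effective_N  # 1e8
#' @export
rescale_parameters <- function(N, u, c_rate = 0, generations = 1L,
                               lambda_scale = 1) {
  if (lambda_scale < 1) stop("lambda_scale must be >= 1")
  list(effective_N = N * lambda_scale,
       effective_generations = generations * lambda_scale,
       effective_u = u / lambda_scale,
       effective_c = c_rate / lambda_scale)
}

#' Batch-decompression session
#'
#' Opens a read session on one node so that an event touching several bases
#' decompresses the genotype (and records a data request) once, rather than
#' per base.  `read_all()` materialises the genotype on first use and
#' reuses it; `read_at(pos)` serves single positions through partial
#' decompression (or from the materialised copy when available);
#' `touch()` records the session's data request without reading;
#' `n_decompressions()` reports how many full decompressions the session
#' performed (0 for a session on an explicit node).
#'
#' @param og An [operation_graph()].
#' @param id Node id.
#' @return A list of closures: `read_at(pos)`, `read_all()`, `touch()`,
#'   `n_decompressions()`.
#' @export
batch_decompress <- function(og, id) {
  nd <- og_node(og, id)
  requested <- FALSE
  ndec <- 0L
  full <- NULL
  touch <- function() {
    if (!requested) {
      og_record_request(og, nd$id)
      requested <<- TRUE
    }
    invisible(NULL)
  }
  read_all <- function() {
    touch()
    if (is.null(full)) {
      if (!is.null(nd$label)) {
        full <<- og_wrap(og, nd$label)      # explicit: no decompression
      } else {
        full <<- og_decompress(og, nd$id)
        ndec <<- ndec + 1L
      }
    }
    full
  }
  read_at <- function(pos) {
    touch()
    if (!is.null(full)) return(unclass(full)[pos])
    partial_read_nd(nd, pos)
  }
  list(read_at = read_at, read_all = read_all, touch = touch,
       n_decompressions = function() ndec)
}

# Reassign node weights from the vector of per-individual node ids.
set_population_weights <- function(og, pop_nodes) {
  ids <- vapply(pop_nodes, function(nd) nd$id, 0L)
  prev_keys <- ls(og$active)
  for (key in prev_keys) og$active[[key]]$w <- 0
  uq <- unique(ids)
  cnt <- tabulate(match(ids, uq))
  for (j in seq_along(uq)) {
    key <- as.character(uq[j])
    nd <- og$nodes[[key]]
    nd$w <- cnt[j]
    assign(key, nd, envir = og$active)
  }
  for (key in prev_keys) {
    nd <- og$active[[key]]
    if (!is.null(nd) && nd$w == 0) rm(list = key, envir = og$active)
  }
  invisible(prev_keys)
}

chain_ops <- function(og, nd, evs) {
  for (op in evs) {
    nid <- og_add_mutation(og, nd$id, op)
    nd <- og$nodes[[as.character(nid)]]
  }
  nd
}

# Produce one offspring from parent node `nd` (and possibly a partner from
# `pop`): crossover first, then indels, then point mutations, each adding an
# operation-graph node.  Returns the offspring's node env.
make_offspring <- function(og, nd, pop, N, cfg) {
  if (cfg$genotype == "sequence" && cfg$c_rate > 0) {
    pr <- 1 - exp(-cfg$c_rate * nd$glen)
    if (stats::runif(1L) < pr) {
      partner <- pop[[sample.int(N, 1L)]]
      minlen <- min(nd$glen, partner$glen)
      if (minlen >= 2L) {
        bp <- if (minlen == 2L) 1L else sample.int(minlen - 1L, 1L)
        og_record_request(og, nd$id)       # both inputs are read
        og_record_request(og, partner$id)
        nid <- og_add_recombination(og, nd$id, partner$id, op_crossover(bp))
        nd <- og$nodes[[as.character(nid)]]
      }
    }
  }
  r <- cfg$rates
  if (cfg$genotype == "sequence") {
    if (r$u > 0 || r$u_i > 0 || r$u_d > 0) {
      session <- NULL
      base_id <- nd$id
      rb <- function(pos) {
        if (is.null(session)) session <<- batch_decompress(og, base_id)
        session$read_at(pos)
      }
      evs <- sample_sequence_events(nd$glen, r, rb)
      if (length(evs)) {
        if (is.null(session)) og_record_request(og, base_id)
        nd <- chain_ops(og, nd, evs)
      }
    }
  } else if (r$u_l > 0 || r$u_g > 0) {
    evs <- sample_pathway_events(cfg$genes, r)
    if (length(evs)) {
      og_record_request(og, nd$id)
      nd <- chain_ops(og, nd, evs)
    }
  }
  nd
}

end_of_generation <- function(og, pop, cfg) {
  prev_keys <- set_population_weights(og, pop)
  # prune branches that just died out (leaves only; interior zero-weight
  # nodes wait until the climb reaches them)
  for (key in prev_keys) {
    nd <- og$nodes[[key]]
    if (!is.null(nd) && nd$w == 0 && length(nd$children) == 0L) {
      og_prune_lost(og, nd$id)
    }
  }
  # fitness evaluation stub: each individual's genotype is read once,
  # issuing frequency-weighted data requests
  if (cfg$fitness_requests) {
    for (key in ls(og$active)) {
      nd <- og$active[[key]]
      og_record_request(og, nd$id, count = nd$w)
    }
  }
  invisible(NULL)
}

snapshot_population <- function(og, pop) {
  ids <- vapply(pop, function(nd) nd$id, 0L)
  uq <- unique(ids)
  vals <- og_decompress_all(og, uq)
  strs <- vapply(vals, function(g) {
    if (inherits(g, "pathway_genotype")) {
      bs <- binding_sites(g)
      paste(bs[, 1L], bs[, 2L], sep = ">", collapse = ";")
    } else {
      paste(unclass(g), collapse = "")
    }
  }, "")
  strs[match(ids, uq)]
}

#' Run a forward-time simulation
#'
#' Evolves `N` neutral genotypes for `generations` generations under the
#' configured reproduction model, recording every evolutionary event in an
#' operation graph managed by the configured cache policy.  Per-generation
#' instrumentation (wall seconds, heap bytes under the deterministic byte
#' model, `|C(V)|`, node/edge counts, compression ratio and space savings)
#' is collected after the burn-in.
#'
#' @param config A [sim_config()].
#' @return An `ogsim_result`: list with `metrics` (data.frame, one row per
#'   post-burn-in generation), `og` (the final operation graph),
#'   `population` (node id per individual), `snapshots` (per-generation
#'   genotype strings when requested), and `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  if (!is.null(cfg$og_snapshot_dir) && !dir.exists(cfg$og_snapshot_dir) &&
      !dir.create(cfg$og_snapshot_dir, recursive = TRUE)) {
    stop("cannot create og_snapshot_dir ", cfg$og_snapshot_dir)  # fail fast
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  g0 <- cfg$initial_genotype
  if (is.null(g0)) {
    g0 <- if (cfg$genotype == "sequence") {
      random_sequence_genotype(cfg$L)
    } else {
      pathway_genotype(cfg$genes)
    }
  }
  og <- operation_graph(g0)
  N <- cfg$N
  pop <- rep(list(og$root), N)
  og_set_weight(og, og$root$id, N)

  gens <- cfg$generations
  rec <- list(generation = integer(gens), seconds_per_generation = numeric(gens),
              heap_bytes = numeric(gens), cached_count = integer(gens),
              node_count = integer(gens), edge_count = integer(gens),
              compression_ratio = numeric(gens), space_savings = numeric(gens))
  nrec <- 0L
  snaps <- if (cfg$snapshot_genotypes) vector("list", gens) else NULL

  for (gen in seq_len(gens)) {
    t0 <- proc.time()[["elapsed"]]
    if (cfg$model == "wright_fisher") {
      par_idx <- sample.int(N, N, replace = TRUE)
      new_pop <- vector("list", N)
      r <- cfg$rates
      fast <- cfg$genotype == "sequence" && cfg$c_rate == 0 &&
        r$u_i == 0 && r$u_d == 0
      if (fast) {
        # mutation-only fast path: population-wide Poisson counts, then
        # per-individual positions/bases for the mutated offspring only
        lens <- vapply(pop, function(nd) nd$glen, 0L)[par_idx]
        n_mut <- if (r$u > 0) stats::rpois(N, r$u * lens) else integer(N)
        for (i in seq_len(N)) {
          nd <- pop[[par_idx[i]]]
          if (n_mut[i] > 0L) {
            session <- batch_decompress(og, nd$id)
            evs <- sample_sequence_events_core(nd$glen, 0L, 0L, n_mut[i],
                                               r, session$read_at)
            nd <- chain_ops(og, nd, evs)
          }
          new_pop[[i]] <- nd
        }
      } else {
        for (i in seq_len(N)) {
          new_pop[[i]] <- make_offspring(og, pop[[par_idx[i]]], pop, N, cfg)
        }
      }
      pop <- new_pop
    } else {  # moran: N single birth-death replacements = one generation
      for (step in seq_len(N)) {
        dead <- sample.int(N, 1L)
        parent <- sample.int(N, 1L)
        pop[[dead]] <- make_offspring(og, pop[[parent]], pop, N, cfg)
      }
    }
    end_of_generation(og, pop, cfg)
    apply_policy(og, cfg$policy, generation = gen)
    dt <- proc.time()[["elapsed"]] - t0
    if (gen > cfg$burn_in) {
      nrec <- nrec + 1L
      rec$generation[nrec] <- gen
      rec$seconds_per_generation[nrec] <- dt
      rec$heap_bytes[nrec] <- og$cached_bytes + og$op_bytes
      rec$cached_count[nrec] <- og$cached_count
      rec$node_count[nrec] <- og$live_count
      rec$edge_count[nrec] <- og$edge_count
      rec$compression_ratio[nrec] <- og$cached_count / N
      rec$space_savings[nrec] <- (1 - og$cached_count / N) * 100
    }
    if (cfg$snapshot_genotypes) snaps[[gen]] <- snapshot_population(og, pop)
    if (!is.null(cfg$og_snapshot_dir) &&
        gen %% max(cfg$policy$t, 1L) == 0L) {
      og_to_dot(og, file.path(cfg$og_snapshot_dir,
                              sprintf("og_gen%d.dot", gen)))
    }
  }

  metrics <- as.data.frame(lapply(rec, function(v) v[seq_len(nrec)]))
  structure(list(metrics = metrics, og = og,
                 population = vapply(pop, function(nd) nd$id, 0L),
                 snapshots = snaps, config = cfg),
            class = "ogsim_result")
}

#' @export
print.ogsim_result <- function(x, ...) {
  cat("<ogsim_result> ", x$config$model, " run: N=", x$config$N,
      ", ", x$config$generations, " generations, policy=",
      x$config$policy$policy, "\n", sep = "")
  print(x$og)
  invisible(x)
}

#' Decompress the final population's genotypes
#'
#' @param result An `ogsim_result`.
#' @return `population_genotypes`: list of genotypes, one per individual.
#'   `population_sequences`: character vector of sequence strings.
#' @export
population_genotypes <- function(result) {
  stopifnot(inherits(result, "ogsim_result"))
  ids <- result$population
  uq <- unique(ids)
  vals <- og_decompress_all(result$og, uq)
  vals[match(ids, uq)]
}

#' @rdname population_genotypes
#' @export
population_sequences <- function(result) {
  vapply(population_genotypes(result), as.character, "")
}

# ---- population-genetic verification ---------------------------------------

#' Verification statistics for simulated sequences
#'
#' Standard estimators used to check that the simulator reproduces the
#' diversity its input rates imply, for a sample of aligned equal-length
#' sequences (run verification with indels disabled): the number of
#' segregating sites `S`, Watterson's `theta_W = S / a_n` with
#' `a_n = sum(1/i, i = 1..n-1)`, the mean pairwise difference count `pi`,
#' and the implied per-base mutation rate.  Under the haploid reproduction
#' models simulated here the coalescent expectation is
#' `E[theta_W] = 2*N*u*L` (per sequence), so the rate estimate is
#' `estimated_u = theta_W / (2 * effective_N * L)`, comparable to the
#' effective (rescaled) input rate.  `rmin` is the Hudson-Kaplan
#' four-gamete lower bound on the number of recombination events in the
#' sample's history, and `estimated_c = (rmin / a_n) / (2 * effective_N *
#' L)` is the analogous (conservative, lower-bound) rate index: expect it
#' near zero without recombination and positive with it.
#'
#' @param sequences Character vector of sequence strings, or a list of
#'   [sequence_genotype()]s.
#' @param effective_n Effective (rescaled) population size; from a
#'   [sim_config()] this is `N * lambda_scale`.
#' @return List: `n`, `L`, `S`, `a_n`, `theta_w`, `theta_w_site`, `pi`,
#'   `pi_site`, `estimated_u`, `rmin`, `estimated_c`.
#' @export
verify_stats <- function(sequences, effective_n) {
  if (is.list(sequences)) {
    sequences <- vapply(sequences, as.character, "")
  }
  n <- length(sequences)
  if (n < 2L) stop("verify_stats needs at least two sequences")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    stop("sequences have unequal lengths; verification requires an ",
         "indel-free configuration (u_i = u_d = 0)")
  }
  L <- lens[1L]
  m <- matrix(unlist(strsplit(sequences, "", fixed = TRUE), use.names = FALSE),
              nrow = n, byrow = TRUE)
  n_alleles <- apply(m, 2L, function(col) length(unique(col)))
  seg <- which(n_alleles > 1L)
  S <- length(seg)
  a_n <- sum(1 / seq_len(n - 1L))
  theta_w <- S / a_n
  # mean pairwise differences
  tot <- 0
  if (S > 0L) {
    ms <- m[, seg, drop = FALSE]
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        tot <- tot + sum(ms[i, ] != ms[j, ])
      }
    }
  }
  pi <- tot / (n * (n - 1L) / 2L)
  # Hudson-Kaplan four-gamete lower bound on recombination events
  rmin <- NA_integer_
  if (S <= 2000L) {
    bi <- seg[n_alleles[seg] == 2L]
    rmin <- 0L
    if (length(bi) >= 2L) {
      ivl <- list()
      for (ii in seq_len(length(bi) - 1L)) {
        for (jj in (ii + 1L):length(bi)) {
          gam <- unique(paste0(m[, bi[ii]], m[, bi[jj]]))
          if (length(gam) == 4L) {
            ivl[[length(ivl) + 1L]] <- c(bi[ii], bi[jj])
          }
        }
      }
      if (length(ivl)) {
        ends <- vapply(ivl, `[`, 0L, 2L)
        ord <- order(ends)
        last <- -Inf
        for (x in ivl[ord]) {
          if (x[1L] >= last) {
            rmin <- rmin + 1L
            last <- x[2L]
          }
        }
      }
    }
  }
  list(n = n, L = L, S = S, a_n = a_n,
       theta_w = theta_w, theta_w_site = theta_w / L,
       pi = pi, pi_site = pi / L,
       estimated_u = theta_w / (2 * effective_n * L),
       rmin = rmin,
       estimated_c = if (is.na(rmin)) NA_real_ else {
         (rmin / a_n) / (2 * effective_n * L)
       })
}
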