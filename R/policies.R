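# Cache-management policies deciding which genotypes stay explicit:
#
#  * greedy_load -- keeps |C(V)| <= k, re-evaluated every t generations,
#    advancing the explicit frontier towards the leaves/active genotypes and
#    caching high-load nodes (the package's core algorithm);
#  * store_active -- C(V) = A(OG): every active genotype explicit (what
#    conventional simulators do; no compression of the living population);
#  * store_root -- C(V) = root set (maximum compression, slowest access).
#
# Greedy-Load runs in two load modes.  Exact mode evaluates load() by brute
# force and is meant for tests and small graphs (the cost of exact load
# grows exponentially with recombination).  Proxy mode, the default in
# simulations, ranks nodes by their accumulated data-request counters and
# tests "non-zero load" with the boolean required flag, since a node can
# carry load without having received requests.

#' Cache-policy state
#'
#' @param policy One of `"greedy_load"`, `"store_active"`, `"store_root"`.
#' @param k Positive integer cache budget: after any Greedy-Load
#'   application, at most `k` genotypes are explicit.
#' @param t Generations between Greedy-Load applications; `t = 0` (like
#'   `t = 1`) applies it every generation.
#' @param exact_load Use exact load instead of the request-count proxy.
#' @param half_k_trigger Additionally re-run Greedy-Load whenever
#'   `|C(V)| < k/2` (an alternative trigger useful with overlapping
#'   generations); off by default.
#' @return An object of class `policy_state`.
#' @export
policy_state <- function(policy = c("greedy_load", "store_active",
                                    "store_root"),
                         k = 10L, t = 1L, exact_load = FALSE,
                         half_k_trigger = FALSE) {
  policy <- match.arg(policy)
  k <- as.integer(k)
  t <- as.integer(t)
  if (policy == "greedy_load" && (is.na(k) || k < 1L)) {
    stop("greedy_load requires a cache budget k >= 1")
  }
  if (is.na(t) || t < 0L) stop("t must be a non-negative integer")
  structure(list(policy = policy, k = k, t = t, exact_load = exact_load,
                 half_k_trigger = half_k_trigger),
            class = "policy_state")
}

# Subtract y's request counter from its former explicit ancestors' counters
# (floored at zero).  The exact decrement semantics are unspecified ground;
# this one rule is isolated here so it can be swapped.
og_transfer_requests <- function(og, y) {
  anc <- og_anc(og, y$id)
  for (a in anc) {
    nd <- og$nodes[[as.character(a)]]
    nd$req <- max(0, nd$req - y$req)
  }
  invisible(og)
}

#' Advance the explicit frontier from a cached node
#'
#' Maximally advances the decompression from explicit node `x` towards the
#' leaves: among the nodes requiring `x` (and `x` itself), the highest node
#' `y` that is (a) a leaf, (b) active (non-zero weight), or (c) has at
#' least two children each required by some active genotype and not in
#' `C(V)`, is decompressed, and `x` is compressed.  If `y = x`, nothing
#' changes.  "Highest" is measured as fewest edges below `x`, ties broken
#' by smaller id.  `C(V)` is never left empty.
#'
#' @param og An [operation_graph()].
#' @param id Id of an explicit node.
#' @return The id of the node that is explicit after the move (`id` itself
#'   when no advance was possible).
#' @export
og_advance <- function(og, id) {
  og_advance_impl(og, id, NULL, NULL)
}

og_advance_impl <- function(og, id, on_decompress, on_compress) {
  x <- og_node(og, id)
  if (is.null(x$label)) {
    stop("og_advance: node ", id, " is not explicit")
  }
  qualifies <- function(v) {
    if (length(v$children) == 0L) return(TRUE)              # (a) leaf
    if (v$w > 0) return(TRUE)                               # (b) active
    n_req <- 0L                                             # (c)
    for (ch in v$children) {
      if (is.null(ch$label) && og_required_dyn(og, ch)) n_req <- n_req + 1L
      if (n_req >= 2L) return(TRUE)
    }
    FALSE
  }
  # breadth-first down from x through compressed *required* nodes (the
  # loaded part of U(x): nodes whose decompression depends on x and that
  # still serve some active genotype), level by level, smallest id first
  y <- NULL
  if (qualifies(x)) {
    y <- x
  } else {
    og$stamp2 <- og$stamp2 + 1L
    st0 <- og$stamp2   # separate mark: og_required_dyn uses the main stamp
    x$mark2 <- st0
    level <- x$children
    while (length(level) && is.null(y)) {
      keep <- list()
      for (ch in level) {
        if (identical(ch$mark2, st0) || !is.null(ch$label)) next
        ch$mark2 <- st0
        if (!og_required_dyn(og, ch)) next
        keep[[length(keep) + 1L]] <- ch
      }
      if (length(keep)) {
        ord <- order(vapply(keep, function(v) v$id, 0L))
        for (v in keep[ord]) {
          if (qualifies(v)) { y <- v; break }
        }
      }
      if (is.null(y)) {
        nxt <- list()
        for (v in keep) for (ch in v$children) {
          nxt[[length(nxt) + 1L]] <- ch
        }
        level <- nxt
      }
    }
  }
  if (is.null(y) || identical(y, x)) return(id)
  if (!is.null(on_decompress)) on_decompress(y)
  og_set_explicit(og, y$id)
  og_compress(og, x$id)
  if (!is.null(on_compress)) on_compress(x)
  y$id
}

#' Run one Greedy-Load update
#'
#' The two-phase update applied every `t` generations (on the first
#' application `C(V)` is just the root).  Phase 1 sweeps the current
#' `C(V)`: nodes no longer needed for any active genotype's decompression
#' are compressed (always keeping at least one explicit node); the rest are
#' advanced towards the leaves.  Phase 2 grows `C(V)` back up to `k` by
#' repeatedly decompressing the max-load child of the max-load cached node
#' and advancing both, until the budget is reached or no further node can
#' be added.  After completion `|C(V)| <= k`.
#'
#' In proxy mode (the default), load comparisons use the per-node data
#' request counters; a node compressed in phase 1 has its counter reset,
#' and a node decompressed in phase 2 has its counter subtracted from its
#' former explicit ancestors' counters.
#'
#' @param og An [operation_graph()].
#' @param k Cache budget (>= 1).
#' @param exact_load Use exact [og_load()] instead of the proxy.
#' @param trace When `TRUE`, return the list of `C(V)` snapshots: one after
#'   phase 1 and one after each phase-2 iteration.
#' @return Sorted ids of the final `C(V)` (or the snapshot list when
#'   `trace = TRUE`), invisibly.
#' @export
greedy_load_update <- function(og, k, exact_load = FALSE, trace = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("greedy_load_update: k must be >= 1")
  load_of <- if (exact_load) {
    function(nd) og_load(og, nd$id)
  } else {
    function(nd) nd$req
  }
  snapshots <- list()

  # Phase 1: compress unneeded cached nodes, advance the rest.
  for (id in og_cached_ids(og)) {
    nd <- og$nodes[[as.character(id)]]
    if (is.null(nd) || is.null(nd$label)) next  # pruned or already moved
    needed <- if (exact_load) og_load(og, id) > 0 else og_required_dyn(og, nd)
    if (!needed) {
      if (og$cached_count > 1L) {
        og_compress(og, id)
        nd$req <- 0
      }
    } else {
      moved_to <- og_advance_impl(og, id, NULL, NULL)
      if (moved_to != id) nd$req <- 0  # nd was compressed by the advance
    }
  }
  if (trace) snapshots[[length(snapshots) + 1L]] <- og_cached_ids(og)

  # Phase 2: grow C(V) by caching the max-load child of the max-load
  # cached node, then advancing both.
  on_dec <- if (exact_load) NULL else function(y) og_transfer_requests(og, y)
  on_cmp <- NULL
  repeat {
    if (og$cached_count >= k) break
    prev <- og_cached_ids(og)
    best_x <- NULL
    best_l <- -Inf
    for (id in prev) {
      nd <- og$nodes[[as.character(id)]]
      has_child <- FALSE
      for (ch in nd$children) {
        if (is.null(ch$label) && og_required_dyn(og, ch)) {
          has_child <- TRUE
          break
        }
      }
      if (!has_child) next
      l <- load_of(nd)
      if (l > best_l) {  # ascending id iteration: ties keep the smaller id
        best_l <- l
        best_x <- nd
      }
    }
    if (is.null(best_x)) break  # no other nodes may be added
    best_y <- NULL
    best_yl <- -Inf
    ord <- order(vapply(best_x$children, function(v) v$id, 0L))
    for (ch in best_x$children[ord]) {
      if (!is.null(ch$label) || !og_required_dyn(og, ch)) next
      l <- load_of(ch)
      if (l > best_yl) {
        best_yl <- l
        best_y <- ch
      }
    }
    if (!is.null(on_dec)) on_dec(best_y)
    og_set_explicit(og, best_y$id)
    og_advance_impl(og, best_y$id, on_dec, on_cmp)
    if (!is.null(best_x$label)) {
      og_advance_impl(og, best_x$id, on_dec, on_cmp)
    }
    if (trace) snapshots[[length(snapshots) + 1L]] <- og_cached_ids(og)
    if (identical(og_cached_ids(og), prev)) break  # no net progress
  }
  if (trace) snapshots else invisible(og_cached_ids(og))
}

#' Apply a cache policy for the current generation
#'
#' Called once per generation by the simulator.  `store_active`
#' decompresses every active node and compresses every inactive one;
#' `store_root` compresses everything except the root; `greedy_load` runs
#' [greedy_load_update()] when `generation` is a multiple of `max(t, 1)`
#' (and additionally, with `half_k_trigger`, whenever `|C(V)| < k/2`).
#'
#' @param og An [operation_graph()].
#' @param state A [policy_state()].
#' @param generation Generation counter (0-based).
#' @return `og`, invisibly.
#' @export
apply_policy <- function(og, state, generation = 0L) {
  stopifnot(inherits(state, "policy_state"))
  switch(state$policy,
    store_active = {
      ids <- og_active_ids(og)
      new_ids <- ids[!vapply(ids, function(i) og_is_explicit(og, i), TRUE)]
      if (length(new_ids)) {
        vals <- og_decompress_all(og, new_ids)
        for (i in seq_along(new_ids)) {
          og_set_explicit(og, new_ids[i], vals[[i]])
        }
      }
      for (id in og_cached_ids(og)) {
        if (og$nodes[[as.character(id)]]$w == 0) og_compress(og, id)
      }
    },
    store_root = {
      root_id <- og$root$id
      if (is.null(og$root$label)) og_set_explicit(og, root_id)
      for (id in og_cached_ids(og)) {
        if (id != root_id) og_compress(og, id)
      }
    },
    greedy_load = {
      due <- generation %% max(state$t, 1L) == 0L
      if (state$half_k_trigger && og$cached_count < state$k / 2) due <- TRUE
      if (due) {
        greedy_load_update(og, state$k, exact_load = state$exact_load)
      }
    }
  )
  invisible(og)
}
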