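# The operation graph (OG): a rooted, labeled, weighted DAG OG = (V, E, l,
# f, w, c) that compresses the genotype space explored by a simulation.
# Each node records one evolutionary operation f(v) with cost c(v); l(v) is
# the genotype label (nil when compressed); w(v) the number of individuals
# currently carrying the genotype.  A node is *explicit* (cached) when
# l(v) != nil; the cached set C(V) always contains at least one node.
# Nodes with one incoming edge are mutations, with two, recombinations.
#
# Nodes are stored as small environments (reference semantics; O(1) field
# updates) hashed by id.  Ids are monotonically increasing integers, so a
# parent always has a smaller id than its children and sorting by id is a
# topological order; ties anywhere in the package are broken by smaller id,
# which makes runs deterministic.

#' Create an operation graph
#'
#' The graph starts with a single explicit root node holding
#' `root_genotype`; the root operation is the identity with cost
#' `root_cost` (default 0: no computation is needed where the explicit
#' label is stored).
#'
#' @param root_genotype A [sequence_genotype()] or [pathway_genotype()].
#' @param root_cost Cost `c(v)` of the root operation.
#' @return An object of class `operation_graph` (an environment; all
#'   `og_*` functions mutate it in place).
#' @export
operation_graph <- function(root_genotype, root_cost = 0) {
  if (!(inherits(root_genotype, "sequence_genotype") ||
        inherits(root_genotype, "pathway_genotype"))) {
    stop("root_genotype must be a sequence_genotype or pathway_genotype")
  }
  og <- new.env(parent = emptyenv())
  og$type <- if (inherits(root_genotype, "pathway_genotype")) {
    "pathway"
  } else {
    "sequence"
  }
  og$nodes <- new.env(hash = TRUE, parent = emptyenv())
  og$cached <- new.env(hash = TRUE, parent = emptyenv())   # id -> node env
  og$active <- new.env(hash = TRUE, parent = emptyenv())   # id -> node env
  og$next_id <- 1L
  og$stamp <- 0L
  og$stamp2 <- 0L
  og$live_count <- 0L
  og$edge_count <- 0L
  og$recomb_count <- 0L
  og$cached_count <- 0L
  og$cached_bytes <- 0
  og$op_bytes <- 0
  class(og) <- "operation_graph"

  root <- og_new_node(og, op_root(root_cost), NULL, NULL)
  og$root <- root
  og_set_label(og, root, unclass(root_genotype))
  root$glen <- genotype_size(root_genotype)
  og
}

#' @export
print.operation_graph <- function(x, ...) {
  cat("<operation_graph> ", og_node_count(x), " nodes, ", og_edge_count(x),
      " edges (", x$recomb_count, " recombination nodes), |C(V)| = ",
      x$cached_count, ", ", x$type, " genotypes\n", sep = "")
  invisible(x)
}

# ---- internal node plumbing -------------------------------------------------

og_new_node <- function(og, op, parent_a, parent_b) {
  nd <- new.env(parent = emptyenv())
  id <- og$next_id
  og$next_id <- id + 1L
  nd$id <- id
  nd$op <- op
  nd$p1 <- parent_a
  nd$p2 <- parent_b
  nd$children <- list()
  nd$w <- 0
  nd$req <- 0
  nd$required <- FALSE
  nd$label <- NULL
  nd$glen <- NA_integer_
  nd$mark <- 0L
  nd$vstamp <- 0L
  nd$val <- NULL
  assign(as.character(id), nd, envir = og$nodes)
  og$live_count <- og$live_count + 1L
  og$op_bytes <- og$op_bytes + op_payload_bytes(op)
  nd
}

og_node <- function(og, id) {
  nd <- og$nodes[[as.character(id)]]
  if (is.null(nd)) stop("operation graph has no node with id ", id)
  nd
}

og_wrap <- function(og, raw) {
  structure(raw, class = if (og$type == "pathway") "pathway_genotype"
                         else "sequence_genotype")
}

og_set_label <- function(og, nd, raw) {
  key <- as.character(nd$id)
  if (is.null(nd$label)) {
    og$cached_count <- og$cached_count + 1L
    assign(key, nd, envir = og$cached)
  } else {
    og$cached_bytes <- og$cached_bytes - raw_footprint(og, nd$label)
  }
  nd$label <- raw
  og$cached_bytes <- og$cached_bytes + raw_footprint(og, raw)
  invisible(nd)
}

og_clear_label <- function(og, nd) {
  if (is.null(nd$label)) return(invisible(nd))
  og$cached_bytes <- og$cached_bytes - raw_footprint(og, nd$label)
  og$cached_count <- og$cached_count - 1L
  nd$label <- NULL
  rm(list = as.character(nd$id), envir = og$cached)
  invisible(nd)
}

raw_footprint <- function(og, raw) {
  if (og$type == "pathway") as.numeric(nrow(raw))^2 else length(raw)
}

og_apply_raw <- function(og, op, a, b = NULL) {
  if (og$type == "pathway") apply_op_pathway(op, a) else apply_op_seq(op, a, b)
}

new_stamp <- function(og) {
  og$stamp <- og$stamp + 1L
  og$stamp
}

sorted_env_ids <- function(e) sort(as.integer(ls(e)))

# ---- construction -----------------------------------------------------------

#' Add a mutation-derived node
#'
#' Adds one node and one edge (parent to new node).  The new node is created
#' compressed (label nil); the caller decides its weight and, through the
#' cache policy, whether it becomes explicit.
#'
#' @param og An [operation_graph()].
#' @param parent_id Id of the input genotype's node.
#' @param op The `og_op` deriving the child genotype (any non-crossover
#'   kind).
#' @return The new node's id (invisibly mutates `og`).
#' @export
og_add_mutation <- function(og, parent_id, op) {
  stopifnot(inherits(op, "og_op"))
  if (op$kind == "crossover") {
    stop("use og_add_recombination() for crossover operations")
  }
  p <- og_node(og, parent_id)
  nd <- og_new_node(og, op, p, NULL)
  p$children[[length(p$children) + 1L]] <- nd
  og$edge_count <- og$edge_count + 1L
  nd$glen <- op_output_length(op, p$glen)
  nd$id
}

#' Add a recombination-derived node
#'
#' Adds one node with two incoming edges.  Parent order is meaningful and
#' recorded: the first parent donates the prefix `[1..breakpoint]`.  The two
#' parents may coincide (self-recombination yields a copy).  New nodes have
#' no children, so acyclicity is preserved by construction.
#'
#' @param og An [operation_graph()].
#' @param parent_a_id,parent_b_id Ids of the two input nodes (prefix donor
#'   first).
#' @param op An `og_op` of kind `crossover`.
#' @return The new node's id.
#' @export
og_add_recombination <- function(og, parent_a_id, parent_b_id, op) {
  stopifnot(inherits(op, "og_op"))
  if (op$kind != "crossover") {
    stop("og_add_recombination requires a crossover operation")
  }
  pa <- og_node(og, parent_a_id)
  pb <- og_node(og, parent_b_id)
  nd <- og_new_node(og, op, pa, pb)
  pa$children[[length(pa$children) + 1L]] <- nd
  pb$children[[length(pb$children) + 1L]] <- nd
  og$edge_count <- og$edge_count + 2L
  og$recomb_count <- og$recomb_count + 1L
  nd$glen <- op_output_length(op, pa$glen, pb$glen)
  nd$id
}

# ---- weights and the active set --------------------------------------------

#' Node weights (genotype frequencies)
#'
#' `w(v)` is the number of individuals in the current population carrying
#' node `v`'s genotype.  Nodes with non-zero weight form the active set
#' `A(OG)`.
#'
#' @param og An [operation_graph()].
#' @param id Node id.
#' @param w New non-negative weight.
#' @return `og_weight` returns the weight; `og_active_ids` the sorted ids of
#'   active nodes.
#' @export
og_set_weight <- function(og, id, w) {
  if (w < 0) stop("weights must be non-negative")
  nd <- og_node(og, id)
  key <- as.character(id)
  if (w > 0 && nd$w == 0) assign(key, nd, envir = og$active)
  if (w == 0 && nd$w > 0) rm(list = key, envir = og$active)
  nd$w <- w
  invisible(og)
}

#' @rdname og_set_weight
#' @export
og_weight <- function(og, id) og_node(og, id)$w

#' @rdname og_set_weight
#' @export
og_active_ids <- function(og) sorted_env_ids(og$active)

# ---- basic accessors --------------------------------------------------------

#' Operation-graph accessors
#'
#' @param og An [operation_graph()].
#' @param id Node id.
#' @return `og_node_ids`: sorted ids of all live nodes.  `og_node_count`,
#'   `og_edge_count`: counts.  `og_parents`, `og_children`: ids (parents in
#'   recorded order, prefix donor first).  `og_is_explicit`: whether
#'   `l(v) != nil`.  `og_cached_ids`: sorted ids of `C(V)`.  `og_label`: the
#'   stored genotype or `NULL`.  `og_request_count`: the node's data-request
#'   counter.  `og_op`: the node's operation.
#' @name og_accessors
NULL

#' @rdname og_accessors
#' @export
og_node_ids <- function(og) sorted_env_ids(og$nodes)

#' @rdname og_accessors
#' @export
og_node_count <- function(og) og$live_count

#' @rdname og_accessors
#' @export
og_edge_count <- function(og) og$edge_count

#' @rdname og_accessors
#' @export
og_parents <- function(og, id) {
  nd <- og_node(og, id)
  out <- integer(0)
  if (!is.null(nd$p1)) out <- c(out, nd$p1$id)
  if (!is.null(nd$p2)) out <- c(out, nd$p2$id)
  out
}

#' @rdname og_accessors
#' @export
og_children <- function(og, id) {
  nd <- og_node(og, id)
  sort(vapply(nd$children, function(x) x$id, 0L))
}

#' @rdname og_accessors
#' @export
og_is_explicit <- function(og, id) !is.null(og_node(og, id)$label)

#' @rdname og_accessors
#' @export
og_cached_ids <- function(og) sorted_env_ids(og$cached)

#' @rdname og_accessors
#' @export
og_label <- function(og, id) {
  l <- og_node(og, id)$label
  if (is.null(l)) NULL else og_wrap(og, l)
}

#' @rdname og_accessors
#' @export
og_request_count <- function(og, id) og_node(og, id)$req

#' @rdname og_accessors
#' @export
og_op <- function(og, id) og_node(og, id)$op

#' Make a node explicit / compress a node
#'
#' `og_set_explicit` decompresses node `id` (unless a `value` is supplied by
#' the caller, e.g. the genotype it just constructed) and stores the label;
#' `og_compress` sets the label back to nil.  Compressing the last explicit
#' node is refused: `C(V)` may never be empty.
#'
#' @param og An [operation_graph()].
#' @param id Node id.
#' @param value Optional genotype to store as the label.
#' @return The node id, invisibly.
#' @export
og_set_explicit <- function(og, id, value = NULL) {
  nd <- og_node(og, id)
  raw <- if (is.null(value)) unclass(og_decompress(og, id)) else unclass(value)
  og_set_label(og, nd, raw)
  invisible(id)
}

#' @rdname og_set_explicit
#' @export
og_compress <- function(og, id) {
  nd <- og_node(og, id)
  if (!is.null(nd$label) && og$cached_count <= 1L) {
    stop("refusing to compress the last explicit node: C(V) may not be empty")
  }
  og_clear_label(og, nd)
  invisible(id)
}

# ---- Anc and decompression --------------------------------------------------

#' Lowest explicit ancestors of a node
#'
#' `Anc(x)` is the set of all lowest explicit nodes between `x` and the
#' root: explicit nodes reached from `x` by walking up through compressed
#' nodes only.  If `x` is itself explicit, `Anc(x) = {x}`.
#'
#' @param og An [operation_graph()].
#' @param id Node id.
#' @return Sorted integer vector of node ids.
#' @export
og_anc <- function(og, id) {
  nd <- og_node(og, id)
  if (!is.null(nd$label)) return(nd$id)
  st <- new_stamp(og)
  out <- integer(0)
  stack <- list(nd)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v$mark == st) next
    v$mark <- st
    if (!is.null(v$label) && !identical(v, nd)) {
      out <- c(out, v$id)
      next
    }
    if (!is.null(v$p1)) stack[[length(stack) + 1L]] <- v$p1
    if (!is.null(v$p2)) stack[[length(stack) + 1L]] <- v$p2
  }
  sort(unique(out))
}

# Collect the decompression set D(x): the nodes whose operations must be
# applied to decompress x (empty when x is explicit), plus the explicit
# ancestors read along the way.  Used by the exact cost/load measures.
og_decomp_sets <- function(og, nd) {
  if (!is.null(nd$label)) {
    return(list(applied = list(), anc = list(nd)))
  }
  st <- new_stamp(og)
  applied <- list()
  anc <- list()
  stack <- list(nd)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v$mark == st) next
    v$mark <- st
    if (!is.null(v$label) && !identical(v, nd)) {
      anc[[length(anc) + 1L]] <- v
      next
    }
    applied[[length(applied) + 1L]] <- v
    if (!is.null(v$p1)) stack[[length(stack) + 1L]] <- v$p1
    if (!is.null(v$p2)) stack[[length(stack) + 1L]] <- v$p2
  }
  list(applied = applied, anc = anc)
}

#' Decompress a node's genotype
#'
#' Reconstructs the explicit genotype of node `id` by applying the
#' operations on the path(s) from its lowest explicit ancestors `Anc(id)`
#' down to `id`.  Recombination nodes pull from both parents; shared
#' sub-paths are evaluated once per call (memoisation), and no label is
#' permanently changed.  `og_decompress_all` shares that memo across several
#' targets, which is how whole-population snapshots are taken.
#'
#' @param og An [operation_graph()].
#' @param id Node id (for `og_decompress_all`, a vector of ids).
#' @return The genotype (a list of genotypes for `og_decompress_all`).
#' @export
og_decompress <- function(og, id) {
  og_decompress_all(og, id)[[1L]]
}

#' @rdname og_decompress
#' @export
og_decompress_all <- function(og, id) {
  targets <- lapply(id, function(i) og_node(og, i))
  st <- new_stamp(og)
  need <- list()
  stack <- targets
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v$mark == st) next
    v$mark <- st
    if (!is.null(v$label)) next
    if (is.null(v$p1)) {
      stop("integrity error: compressed root node ", v$id,
           " cannot be decompressed")
    }
    need[[length(need) + 1L]] <- v
    stack[[length(stack) + 1L]] <- v$p1
    if (!is.null(v$p2)) stack[[length(stack) + 1L]] <- v$p2
  }
  if (length(need)) {
    ord <- order(vapply(need, function(v) v$id, 0L))  # ids are topological
    val_of <- function(p) if (is.null(p$label)) p$val else p$label
    for (v in need[ord]) {
      a <- val_of(v$p1)
      b <- if (is.null(v$p2)) NULL else val_of(v$p2)
      v$val <- og_apply_raw(og, v$op, a, b)
      v$vstamp <- st
    }
  }
  out <- lapply(targets, function(v) {
    og_wrap(og, if (is.null(v$label)) v$val else v$label)
  })
  for (v in need) v$val <- NULL  # free scratch values
  out
}

#' Partially decompress: read one base of a node's genotype
#'
#' Walks up the operation graph mapping the queried coordinate through each
#' operation ([apply_at()]) until an operation that wrote the base, or an
#' explicit ancestor, is found.  A crossover is followed only into the
#' parent that owns the mapped coordinate, so (unlike full decompression)
#' the walk touches a single root-ward path.  Sequence genotypes only.
#'
#' @param og An [operation_graph()].
#' @param id Node id.
#' @param position 1-based position in node `id`'s genotype.
#' @return A single base.
#' @export
og_partial_decompress <- function(og, id, position) {
  if (og$type != "sequence") {
    stop("partial decompression is defined for sequence genotypes")
  }
  nd <- og_node(og, id)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > nd$glen) {
    stop("position ", position, " out of range for node ", id,
         " (length ", nd$glen, ")")
  }
  partial_read_nd(nd, position)
}

# validation-free walk on node environments (hot path)
partial_read_nd <- function(nd, position) {
  repeat {
    if (!is.null(nd$label)) return(nd$label[position])
    if (is.null(nd$p1)) {
      stop("integrity error: compressed root node ", nd$id,
           " cannot be decompressed")
    }
    r <- apply_at_core(nd$op, position)
    if (!is.null(r$value)) return(r$value)
    nd <- if (!is.na(r$parent) && r$parent == 2L) nd$p2 else nd$p1
    position <- r$position
  }
}

# ---- data requests and required flags ---------------------------------------

#' Record a data request on a node
#'
#' The cheap proxy for load: each decompression demand increments the
#' request counter of the requested node and of every *compressed* node on
#' its decompression path(s), stopping at (and excluding) explicit
#' ancestors.  Counters start at zero when a node is created.
#'
#' @param og An [operation_graph()].
#' @param id Node id.
#' @param count Number of requests to record (a batch of `count` identical
#'   requests).
#' @return `og`, invisibly.
#' @export
og_record_request <- function(og, id, count = 1) {
  nd <- og_node(og, id)
  nd$req <- nd$req + count
  if (!is.null(nd$label)) return(invisible(og))
  st <- new_stamp(og)
  nd$mark <- st
  stack <- list()
  if (!is.null(nd$p1)) stack[[1L]] <- nd$p1
  if (!is.null(nd$p2)) stack[[length(stack) + 1L]] <- nd$p2
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v$mark == st) next
    v$mark <- st
    if (!is.null(v$label)) next  # explicit ancestor: stop, do not count
    v$req <- v$req + count
    if (!is.null(v$p1)) stack[[length(stack) + 1L]] <- v$p1
    if (!is.null(v$p2)) stack[[length(stack) + 1L]] <- v$p2
  }
  invisible(og)
}

#' Compute the boolean "required" flags
#'
#' A node is required when it lies on some decompression path of some
#' active genotype: the active node itself, every compressed node between
#' it and its lowest explicit ancestors, and those explicit ancestors
#' (whose labels are read).  The computation walks up from each active node
#' and visits each required node once.  These flags stand in for "non-zero
#' load" in the proxy-mode Greedy-Load, since a node can have non-zero load
#' but no recorded data requests.
#'
#' @param og An [operation_graph()].
#' @return Named logical vector over all live node ids (also stored on the
#'   nodes for the policies' use).
#' @export
og_required_flags <- function(og) {
  ids <- og_node_ids(og)
  for (i in ids) og$nodes[[as.character(i)]]$required <- FALSE
  st <- new_stamp(og)
  for (key in ls(og$active)) {
    stack <- list(og$active[[key]])
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (v$mark == st) next
      v$mark <- st
      v$required <- TRUE
      if (!is.null(v$label)) next  # explicit: label read, nothing above
      if (!is.null(v$p1)) stack[[length(stack) + 1L]] <- v$p1
      if (!is.null(v$p2)) stack[[length(stack) + 1L]] <- v$p2
    }
  }
  out <- vapply(ids, function(i) og$nodes[[as.character(i)]]$required, TRUE)
  names(out) <- ids
  out
}

# Dynamic point query of the same property, used inside the policies while
# C(V) is changing: is some active genotype's decompression dependent on
# `nd` under the current labels?  Searches down from `nd` through
# compressed nodes for an active node.
og_required_dyn <- function(og, nd) {
  if (nd$w > 0) return(TRUE)
  st <- new_stamp(og)
  nd$mark <- st
  stack <- nd$children
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v$mark == st) next
    v$mark <- st
    if (!is.null(v$label)) next  # explicit child decompresses from itself
    if (v$w > 0) return(TRUE)
    for (ch in v$children) stack[[length(stack) + 1L]] <- ch
  }
  FALSE
}

# ---- cost and load ----------------------------------------------------------

#' Decompression cost measures
#'
#' `og_cost(og, x)` is the total operation cost of decompressing `x`: the
#' sum of `c(v)` over all nodes on paths from `Anc(x)` to `x` (each node
#' counted once across paths).  The endpoint convention is: `x`'s own cost
#' is included, the explicit ancestors' costs are not (their labels are
#' read, not computed), so `og_cost` of an explicit node is 0.
#'
#' `og_cost_between(og, x, y)` is the part of that cost incurred from
#' waypoint `y` downwards: the sum of `c(v)` over nodes of the
#' decompression set of `x` that lie strictly below `y` plus `x` itself,
#' and 0 when `y` is on no decompression path of `x`.  As the one special
#' case, `og_cost_between(og, x, x)` for a compressed `x` is `c(x)`.
#'
#' @param og An [operation_graph()].
#' @param id,waypoint_id Node ids.
#' @return Non-negative number.
#' @export
og_cost <- function(og, id) {
  nd <- og_node(og, id)
  d <- og_decomp_sets(og, nd)
  sum(vapply(d$applied, function(v) v$op$cost, 0))
}

#' @rdname og_cost
#' @export
og_cost_between <- function(og, id, waypoint_id) {
  nd <- og_node(og, id)
  y <- og_node(og, waypoint_id)
  if (identical(nd, y)) {
    return(if (is.null(nd$label)) nd$op$cost else 0)
  }
  d <- og_decomp_sets(og, nd)
  on_path <- vapply(c(d$applied, d$anc), function(v) identical(v, y), TRUE)
  if (!any(on_path)) return(0)
  below <- og_descendant_ids(og, y)
  sum(vapply(d$applied, function(v) {
    if (v$id %in% below && !identical(v, y)) v$op$cost else 0
  }, 0))
}

og_descendant_ids <- function(og, nd) {
  st <- new_stamp(og)
  out <- integer(0)
  stack <- nd$children
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v$mark == st) next
    v$mark <- st
    out <- c(out, v$id)
    for (ch in v$children) stack[[length(stack) + 1L]] <- ch
  }
  out
}

#' Exact load of a node
#'
#' `load(x) = sum over y in U(x) of w(y) * cost(y, x)`, where `U(x)` is the
#' set of nodes that require `x` for their decompression (reading `x`'s
#' label or applying `x`'s operation); `x` itself belongs to `U(x)` when it
#' is compressed, contributing `w(x) * c(x)`.  This is the exact, brute
#' force measure used as the oracle for the request-count proxy and by the
#' exact-load mode of Greedy-Load on small graphs; its cost grows quickly
#' with recombination, which is why simulations use the proxy.
#'
#' @param og An [operation_graph()].
#' @param id Node id.
#' @return Non-negative number.
#' @export
og_load <- function(og, id) {
  x <- og_node(og, id)
  total <- 0
  for (key in ls(og$active)) {
    y <- og$active[[key]]
    if (identical(y, x)) {
      if (is.null(x$label)) total <- total + x$w * x$op$cost
      next
    }
    d <- og_decomp_sets(og, y)
    needs_x <- any(vapply(c(d$applied, d$anc),
                          function(v) identical(v, x), TRUE))
    if (needs_x) total <- total + y$w * og_cost_between(og, y$id, x$id)
  }
  total
}

# ---- pruning ----------------------------------------------------------------

#' Prune the graph after a genotype is lost
#'
#' Called when node `id`'s genotype has left the population (`w = 0`).  If
#' the node is not a leaf, nothing is deleted (active genotypes may sit
#' below it).  Otherwise the branch is removed up to, but excluding, each
#' lowest stopping node on the root-ward paths -- a node that is active, has
#' out-degree two (another surviving branch hangs off it), or is the root.
#' Equivalently: starting from `id`, zero-weight non-root nodes that become
#' childless are removed iteratively.  Every remaining active node is still
#' decompressible afterwards, since removed nodes can have had no surviving
#' descendants.
#'
#' @param og An [operation_graph()].
#' @param id Id of a node with `w = 0`.
#' @return Sorted integer vector of deleted node ids (possibly empty).
#' @export
og_prune_lost <- function(og, id) {
  nd <- og_node(og, id)
  if (nd$w > 0) stop("og_prune_lost: node ", id, " is active (w > 0)")
  if (length(nd$children) > 0L) return(integer(0))  # not a leaf: no update
  deleted <- integer(0)
  stack <- list(nd)
  while (length(stack)) {
    v <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (v$w > 0 || is.null(v$p1) || length(v$children) > 0L) next
    if (is.null(og$nodes[[as.character(v$id)]])) next  # already deleted
    # delete v
    deleted <- c(deleted, v$id)
    parents <- if (!is.null(v$p2)) list(v$p1, v$p2) else list(v$p1)
    for (p in parents) {
      keep <- !vapply(p$children, function(ch) identical(ch, v), TRUE)
      og$edge_count <- og$edge_count - sum(!keep)
      p$children <- p$children[keep]
    }
    if (!is.null(v$p2)) og$recomb_count <- og$recomb_count - 1L
    og_clear_label(og, v)
    og$op_bytes <- og$op_bytes - op_payload_bytes(v$op)
    og$live_count <- og$live_count - 1L
    rm(list = as.character(v$id), envir = og$nodes)
    for (p in unique(parents)) stack[[length(stack) + 1L]] <- p
  }
  sort(deleted)
}
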