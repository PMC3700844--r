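# Deterministic fixtures: the twelve-node worked-example operation graph
# whose Greedy-Load walk-through the package reproduces panel by panel, and
# a seeded random-OG generator backing the property tests.

#' Build the twelve-node worked-example operation graph
#'
#' A rooted OG of 12 operations labeled `a` to `l` connected by 12 edges:
#' `a` is the root; all nodes are point mutations except `d`, a
#' recombination of `b` and `c`; the leaves are `e, h, j, k, l`; the active
#' genotypes (unit weight) are the leaves plus the internal node `i`; all
#' operation costs are 1, and the initial cached set is `C(V) = {a, c}`.
#' Concrete genotypes are attached (a fixed 20-base root; each mutation
#' writes a distinct position) so decompression is fully exercisable.
#' Topology: a->b, a->c, b->d, c->d, c->e, c->f, d->g, d->h, f->i, g->j,
#' g->k, i->l.
#'
#' @return An [operation_graph()] carrying a `letters` map (named integer
#'   vector, letter -> node id) in its environment.
#' @export
build_example_og <- function() {
  root <- sequence_genotype(strrep("A", 20L))
  og <- operation_graph(root, root_cost = 1)
  add <- function(parent_letter, letter, pos) {
    id <- og_add_mutation(og, og$letters[[parent_letter]],
                          op_point_mutation(pos, "C", cost = 1))
    og$letters[letter] <- id
    id
  }
  og$letters <- c(a = og$root$id)
  add("a", "b", 1L)
  add("a", "c", 2L)
  og$letters["d"] <- og_add_recombination(og, og$letters[["b"]],
                                          og$letters[["c"]],
                                          op_crossover(10L, cost = 1))
  add("c", "e", 3L)
  add("c", "f", 4L)
  add("d", "g", 5L)
  add("d", "h", 6L)
  add("f", "i", 7L)
  add("g", "j", 8L)
  add("g", "k", 9L)
  add("i", "l", 10L)
  for (letter in c("e", "h", "i", "j", "k", "l")) {
    og_set_weight(og, og$letters[[letter]], 1)
  }
  og_set_explicit(og, og$letters[["c"]])  # C(V) = {a, c}
  og
}

#' Trace the worked example's Greedy-Load execution
#'
#' Runs one exact-load Greedy-Load application with cache budget `k` on the
#' [build_example_og()] fixture and returns the `C(V)` snapshots: the
#' initial set, the set after phase 1, and the set after each phase-2
#' iteration.  With the default `k = 4` the panels are
#' `{a,c} -> {d,c} -> {d,i,e} -> {e,g,h,i}`.
#'
#' @param k Cache budget.
#' @return List of character vectors of node letters (sorted).
#' @export
trace_example <- function(k = 4L) {
  og <- build_example_og()
  to_letters <- function(ids) {
    sort(names(og$letters)[match(ids, og$letters)])
  }
  initial <- og_cached_ids(og)
  snaps <- greedy_load_update(og, k, exact_load = TRUE, trace = TRUE)
  c(list(to_letters(initial)), lapply(snaps, to_letters))
}

#' Generate a random small operation graph
#'
#' Seeded generator for property tests: starting from a random root
#' sequence, each further node derives from uniformly chosen existing
#' parent(s), as a crossover with probability `recomb_fraction` (when two
#' usable parents exist) and otherwise as a point mutation, insertion, or
#' deletion (7:1.5:1.5 mix).  A random subset of nodes is made active with
#' small random weights; the root is the only explicit node.
#'
#' @param n_nodes Total node count (>= 1).
#' @param recomb_fraction Probability a new node is recombination-derived.
#' @param seed Optional RNG seed.
#' @param root_length Root sequence length.
#' @param active_prob Probability each node is active.
#' @return An [operation_graph()].
#' @export
random_og <- function(n_nodes, recomb_fraction = 0, seed = NULL,
                      root_length = 30L, active_prob = 0.4) {
  stopifnot(n_nodes >= 1L, recomb_fraction >= 0, recomb_fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  og <- operation_graph(random_sequence_genotype(root_length))
  ids <- og$root$id
  for (i in seq_len(n_nodes - 1L)) {
    pa <- og$nodes[[as.character(ids[sample.int(length(ids), 1L)])]]
    made <- NA_integer_
    if (stats::runif(1L) < recomb_fraction) {
      pb <- og$nodes[[as.character(ids[sample.int(length(ids), 1L)])]]
      minlen <- min(pa$glen, pb$glen)
      if (minlen >= 2L) {
        bp <- if (minlen == 2L) 1L else sample.int(minlen - 1L, 1L)
        made <- og_add_recombination(og, pa$id, pb$id, op_crossover(bp))
      }
    }
    if (is.na(made)) {
      kind <- sample.int(10L, 1L)
      op <- if (kind <= 7L || pa$glen < 2L) {
        op_point_mutation(sample.int(pa$glen, 1L),
                          DNA_BASES[sample.int(4L, 1L)])
      } else if (kind <= 8L) {
        op_insertion(sample.int(pa$glen + 1L, 1L),
                     DNA_BASES[sample.int(4L, 1L + stats::rgeom(1L, 0.5),
                                          replace = TRUE)])
      } else {
        pos <- sample.int(pa$glen, 1L)
        maxlen <- if (pos == 1L) pa$glen - 1L else pa$glen - pos + 1L
        op_deletion(pos, sample.int(maxlen, 1L))
      }
      made <- og_add_mutation(og, pa$id, op)
    }
    ids <- c(ids, made)
  }
  for (id in ids) {
    if (stats::runif(1L) < active_prob) {
      og_set_weight(og, id, sample.int(3L, 1L))
    }
  }
  og
}
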