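# Independent oracles used across the suite.  They work on plain strings
# with substr/paste (not the package's vector kernels) and recompute
# genotypes, costs and loads from first principles, so agreement with the
# package is a genuine cross-check.

oracle_apply <- function(op, a, b = NULL) {
  p <- op$params
  switch(op$kind,
    root = a,
    point_mutation = {
      substr(a, p$position, p$position) <- p$base
      a
    },
    insertion = paste0(substr(a, 1L, p$position - 1L),
                       paste(p$bases, collapse = ""),
                       substr(a, p$position, nchar(a))),
    deletion = {
      last <- min(p$position + p$length - 1L, nchar(a))
      paste0(substr(a, 1L, p$position - 1L), substr(a, last + 1L, nchar(a)))
    },
    crossover = paste0(substr(a, 1L, p$breakpoint),
                       substr(b, p$breakpoint + 1L, nchar(b))),
    stop("oracle_apply: unsupported kind ", op$kind))
}

# Recompute a node's genotype by replaying the full event history down from
# the root genotype, ignoring every stored label.
oracle_replay <- function(og, id, root_str) {
  rec <- function(i) {
    ps <- og_parents(og, i)
    if (length(ps) == 0L) return(root_str)
    a <- rec(ps[1L])
    b <- if (length(ps) == 2L) rec(ps[2L]) else NULL
    oracle_apply(og_op(og, i), a, b)
  }
  rec(id)
}

# Set of nodes whose operations are applied when decompressing x under the
# current labels (empty when x is explicit).
oracle_applied_set <- function(og, x) {
  if (og_is_explicit(og, x)) return(integer(0))
  out <- x
  for (p in og_parents(og, x)) {
    out <- union(out, oracle_applied_set(og, p))
  }
  sort(out)
}

oracle_anc <- function(og, x) {
  if (og_is_explicit(og, x)) return(x)
  out <- integer(0)
  for (p in og_parents(og, x)) {
    out <- union(out, if (og_is_explicit(og, p)) p else oracle_anc(og, p))
  }
  sort(out)
}

oracle_cost <- function(og, x) {
  sum(vapply(oracle_applied_set(og, x), function(i) og_op(og, i)$cost, 0))
}

oracle_is_descendant <- function(og, node, of) {
  ps <- og_parents(og, node)
  if (length(ps) == 0L) return(FALSE)
  any(ps == of) || any(vapply(ps, function(p) {
    oracle_is_descendant(og, p, of)
  }, TRUE))
}

oracle_cost_between <- function(og, x, y) {
  if (x == y) {
    return(if (og_is_explicit(og, x)) 0 else og_op(og, x)$cost)
  }
  d <- oracle_applied_set(og, x)
  if (!(y %in% d || y %in% oracle_anc(og, x))) return(0)
  below <- d[vapply(d, function(v) {
    v != y && oracle_is_descendant(og, v, y)
  }, TRUE)]
  sum(vapply(below, function(i) og_op(og, i)$cost, 0))
}

oracle_load <- function(og, x) {
  total <- 0
  for (y in og_active_ids(og)) {
    if (y == x) {
      if (!og_is_explicit(og, x)) {
        total <- total + og_weight(og, x) * og_op(og, x)$cost
      }
      next
    }
    needs <- x %in% oracle_applied_set(og, y) || x %in% oracle_anc(og, y)
    if (needs) {
      total <- total + og_weight(og, y) * oracle_cost_between(og, y, x)
    }
  }
  total
}

rand_seq_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
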