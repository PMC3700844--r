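# Evolutionary operations: the unit stored per operation-graph node.
# Each operation has a kind, kind-specific parameters, and a non-negative
# computational cost c(v) used by the load measures.  Default costs: 1 for
# point mutation / deletion / binding-site gain or loss, the inserted length
# for insertions, 2 for crossover, 0 for the root (identity).
#
# Conventions (documented package-wide):
#  * all positions and gene indices are 1-based;
#  * crossover is single-breakpoint, output = first parent's prefix
#    [1..breakpoint] followed by the second parent's suffix [breakpoint+1..];
#    the prefix donor is always the first recorded parent;
#  * deletions are clipped at the sequence end at application time, but the
#    event sampler only ever emits in-range deletions that leave at least one
#    base, so stored operations map coordinates unambiguously.

OP_KINDS <- c("root", "point_mutation", "insertion", "deletion",
              "crossover", "bs_gain", "bs_loss")

new_og_op <- function(kind, params, cost) {
  if (!is.numeric(cost) || length(cost) != 1L || is.na(cost) || cost < 0) {
    stop("operation cost must be a single non-negative number")
  }
  structure(list(kind = kind, params = params, cost = as.numeric(cost)),
            class = "og_op")
}

#' @export
print.og_op <- function(x, ...) {
  ps <- vapply(x$params, function(p) paste(format(p), collapse = ""), "")
  cat("<og_op> ", x$kind,
      if (length(ps)) paste0("(", paste(names(x$params), ps, sep = "=",
                                        collapse = ", "), ")"),
      " cost=", x$cost, "\n", sep = "")
  invisible(x)
}

#' Operation constructors
#'
#' One constructor per evolutionary event kind.  The root operation carries
#' no parent dependency and applies as the identity on the stored initial
#' genotype; all other operations take exactly one input genotype except
#' crossover, which takes two.
#'
#' @param position 1-based position in the input sequence (for
#'   `op_insertion`, the output position at which the first inserted base
#'   will sit; bases formerly at `position` and beyond are shifted right).
#' @param base Replacement base, one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param bases Character vector (or single string) of inserted bases.
#' @param length Number of bases removed by a deletion.
#' @param breakpoint Crossover breakpoint: the output takes positions
#'   `1..breakpoint` from the first parent and `breakpoint+1..` from the
#'   second.
#' @param regulator,target 1-based gene indices of a binding site.
#' @param cost Non-negative computational cost `c(v)` of applying the
#'   operation; defaults as described above.
#' @return An object of class `og_op`.
#' @name og_operations
NULL

#' @rdname og_operations
#' @export
op_root <- function(cost = 0) new_og_op("root", list(), cost)

#' @rdname og_operations
#' @export
op_point_mutation <- function(position, base, cost = 1) {
  stopifnot(length(position) == 1L, position >= 1L, base %in% DNA_BASES)
  new_og_op("point_mutation",
            list(position = as.integer(position), base = base), cost)
}

#' @rdname og_operations
#' @export
op_insertion <- function(position, bases, cost = NULL) {
  bases <- unclass(sequence_genotype(bases))
  if (length(bases) < 1L) stop("op_insertion: empty insertion")
  stopifnot(length(position) == 1L, position >= 1L)
  if (is.null(cost)) cost <- length(bases)
  new_og_op("insertion",
            list(position = as.integer(position), bases = bases), cost)
}

#' @rdname og_operations
#' @export
op_deletion <- function(position, length, cost = 1) {
  stopifnot(position >= 1L, length >= 1L)
  new_og_op("deletion",
            list(position = as.integer(position),
                 length = as.integer(length)), cost)
}

#' @rdname og_operations
#' @export
op_crossover <- function(breakpoint, cost = 2) {
  stopifnot(length(breakpoint) == 1L, breakpoint >= 1L)
  new_og_op("crossover", list(breakpoint = as.integer(breakpoint)), cost)
}

#' @rdname og_operations
#' @export
op_bs_gain <- function(regulator, target, cost = 1) {
  stopifnot(regulator >= 1L, target >= 1L)
  new_og_op("bs_gain", list(regulator = as.integer(regulator),
                            target = as.integer(target)), cost)
}

#' @rdname og_operations
#' @export
op_bs_loss <- function(regulator, target, cost = 1) {
  stopifnot(regulator >= 1L, target >= 1L)
  new_og_op("bs_loss", list(regulator = as.integer(regulator),
                            target = as.integer(target)), cost)
}

#' Apply an operation to one or two genotypes
#'
#' Deterministically derives the output genotype.  Inputs are not modified.
#' Crossover requires exactly two input genotypes (the first donates the
#' prefix); every other kind exactly one.  Binding-site gain of an existing
#' edge and loss of an absent edge are no-ops, keeping application total.
#'
#' @param op An `og_op`.
#' @param a Input genotype.
#' @param b Second input genotype, supplied iff `op` is a crossover.
#' @return The derived genotype (same class as the inputs).
#' @examples
#' g <- sequence_genotype("ACCAAAT")
#' as.character(apply_op(op_point_mutation(3, "T"), g))  # "ACTAAAT"
#' @export
apply_op <- function(op, a, b = NULL) {
  stopifnot(inherits(op, "og_op"))
  if (op$kind == "crossover") {
    if (is.null(b)) stop("crossover requires two input genotypes")
  } else if (!is.null(b)) {
    stop("operation '", op$kind, "' takes exactly one input genotype")
  }
  if (inherits(a, "pathway_genotype")) {
    return(apply_op_pathway(op, a))
  }
  cls <- class(a)
  out <- apply_op_seq(op, unclass(a), if (!is.null(b)) unclass(b))
  structure(out, class = cls)
}

# Internal sequence kernel on plain character vectors (hot path shared with
# decompression).
apply_op_seq <- function(op, a, b = NULL) {
  p <- op$params
  switch(op$kind,
    root = a,
    point_mutation = {
      if (p$position > length(a)) {
        stop("point mutation position ", p$position,
             " beyond sequence length ", length(a))
      }
      a[p$position] <- p$base
      a
    },
    insertion = {
      if (p$position > length(a) + 1L) {
        stop("insertion position ", p$position,
             " beyond sequence length ", length(a))
      }
      append(a, p$bases, after = p$position - 1L)
    },
    deletion = {
      if (p$position > length(a)) {
        stop("deletion position ", p$position,
             " beyond sequence length ", length(a))
      }
      last <- min(p$position + p$length - 1L, length(a))
      if (p$position == 1L && last == length(a)) {
        stop("deletion would empty the sequence")
      }
      a[-(p$position:last)]
    },
    crossover = {
      bp <- p$breakpoint
      if (bp >= length(a) + 1L || bp >= length(b)) {
        stop("crossover breakpoint ", bp, " out of range for parent lengths ",
             length(a), ", ", length(b))
      }
      c(a[seq_len(bp)], b[(bp + 1L):length(b)])
    },
    stop("operation '", op$kind, "' does not apply to sequence genotypes")
  )
}

apply_op_pathway <- function(op, a) {
  k <- nrow(a)
  p <- op$params
  switch(op$kind,
    root = a,
    bs_gain = {
      if (p$regulator > k || p$target > k) {
        stop("binding site (", p$regulator, ",", p$target,
             ") outside [1,", k, "]")
      }
      a[p$regulator, p$target] <- TRUE   # no-op if already present
      a
    },
    bs_loss = {
      if (p$regulator > k || p$target > k) {
        stop("binding site (", p$regulator, ",", p$target,
             ") outside [1,", k, "]")
      }
      a[p$regulator, p$target] <- FALSE  # no-op if already absent
      a
    },
    stop("operation '", op$kind, "' does not apply to pathway genotypes")
  )
}

#' Apply a sequence operation at a single output position
#'
#' The per-position counterpart of [apply_op()], used for partial
#' decompression: instead of materialising the whole output sequence, it
#' reports either the base the operation itself writes at `position`, or the
#' input coordinate the caller must look up further up the operation graph.
#' Composed along a decompression path, `apply_at` agrees with indexing into
#' the fully applied result at every position.
#'
#' @param op An `og_op` of a sequence kind (including `root`).
#' @param position 1-based position in the operation's *output* sequence.
#' @return A list with components `value` (a base, or `NULL` when an
#'   upstream lookup is needed), `parent` (1 or 2: which input genotype owns
#'   the mapped coordinate), and `position` (the mapped input coordinate, or
#'   `NA` when `value` is returned directly).
#' @examples
#' apply_at(op_point_mutation(3, "T"), 3)$value      # "T"
#' apply_at(op_deletion(2, 2), 4)$position           # 6
#' @export
apply_at <- function(op, position) {
  stopifnot(inherits(op, "og_op"), length(position) == 1L)
  position <- as.integer(position)
  if (is.na(position) || position < 1L) {
    stop("apply_at: position must be a positive integer")
  }
  apply_at_core(op, position)
}

# validation-free kernel (hot path of partial decompression)
apply_at_core <- function(op, position) {
  p <- op$params
  switch(op$kind,
    root = list(value = NULL, parent = 1L, position = position),
    point_mutation = {
      if (position == p$position) {
        list(value = p$base, parent = NA_integer_, position = NA_integer_)
      } else {
        list(value = NULL, parent = 1L, position = position)
      }
    },
    insertion = {
      ni <- length(p$bases)
      if (position < p$position) {
        list(value = NULL, parent = 1L, position = position)
      } else if (position < p$position + ni) {
        list(value = p$bases[position - p$position + 1L],
             parent = NA_integer_, position = NA_integer_)
      } else {
        list(value = NULL, parent = 1L, position = position - ni)
      }
    },
    deletion = {
      if (position < p$position) {
        list(value = NULL, parent = 1L, position = position)
      } else {
        list(value = NULL, parent = 1L, position = position + p$length)
      }
    },
    crossover = {
      if (position <= p$breakpoint) {
        list(value = NULL, parent = 1L, position = position)
      } else {
        list(value = NULL, parent = 2L, position = position)
      }
    },
    stop("apply_at is defined for sequence operations only")
  )
}

# Output length of an operation given its input length(s); lengths are the
# cheap per-node metadata that lets event sampling and partial decompression
# run without materialising genotypes.
op_output_length <- function(op, len_a, len_b = NA_integer_) {
  p <- op$params
  switch(op$kind,
    root = len_a,
    point_mutation = len_a,
    bs_gain = len_a,
    bs_loss = len_a,
    insertion = len_a + length(p$bases),
    deletion = len_a - (min(p$position + p$length - 1L, len_a) -
                          p$position + 1L),
    crossover = len_b,  # prefix [1..bp] of a + suffix [bp+1..len_b] of b
    stop("unknown operation kind")
  )
}

#' Payload bytes of an operation record
#'
#' The deterministic byte model for operation storage, used by the heap
#' account: a point mutation carries 1 payload byte (the new base), an
#' insertion carries one byte per inserted base, a deletion and a crossover
#' carry a fixed 2 bytes (position and length / breakpoint), binding-site
#' events carry 2 bytes (the gene pair), and the root carries none (its
#' genotype is accounted as an explicit label).
#'
#' @param op An `og_op`.
#' @return Non-negative integer payload byte count.
#' @export
op_payload_bytes <- function(op) {
  switch(op$kind,
    root = 0L,
    point_mutation = 1L,
    insertion = length(op$params$bases),
    deletion = 2L,
    crossover = 2L,
    bs_gain = 2L,
    bs_loss = 2L,
    stop("unknown operation kind"))
}
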