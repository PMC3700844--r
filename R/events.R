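# Stochastic sampling of evolutionary events.  Event counts per genotype per
# generation are Poisson with mean rate * size (size = bases for sequences,
# gene_count^2 for pathway binding-site events); positions are uniform.
#
# Documented draw order (fixed so that runs sharing a seed share the full
# event stream regardless of cache policy): insertions, then deletions, then
# point mutations; for each event, position first, then kind-specific
# payload draws.  Reading the pre-mutation base never consumes randomness.

#' Per-base event rates
#'
#' @param u Point-mutation rate per base per generation.
#' @param u_i,u_d Insertion / deletion rates per base per generation.
#' @param u_l,u_g Pathway binding-site loss / gain rates per gene pair per
#'   generation.
#' @param indel_mean Mean indel length; lengths are geometric on
#'   `{1, 2, ...}` with this mean (the field standard gives no canonical
#'   length model; geometric is the usual parsimonious choice).
#' @return A list of validated rates of class `event_rates`.
#' @export
event_rates <- function(u = 0, u_i = 0, u_d = 0, u_l = 0, u_g = 0,
                        indel_mean = 3) {
  r <- list(u = u, u_i = u_i, u_d = u_d, u_l = u_l, u_g = u_g,
            indel_mean = indel_mean)
  num <- vapply(r, function(x) is.numeric(x) && length(x) == 1L && !is.na(x),
                TRUE)
  if (!all(num)) stop("event_rates: all rates must be single numbers")
  if (any(unlist(r[c("u", "u_i", "u_d", "u_l", "u_g")]) < 0)) {
    stop("event_rates: rates must be non-negative")
  }
  if (indel_mean < 1) stop("event_rates: indel_mean must be >= 1")
  structure(r, class = "event_rates")
}

# Geometric indel length with mean m on support {1, 2, ...}.
rindel_length <- function(m) 1L + stats::rgeom(1L, prob = 1 / m)

# Internal kernel: sample sequence events for one genotype of starting
# length `len`, reading pre-mutation bases through `read_base(pos)` (a
# closure over either a materialised sequence or an operation-graph partial
# decompression).  Reads for later events see earlier pending events through
# a local coordinate overlay, so no intermediate sequence is materialised.
sample_sequence_events <- function(len, rates, read_base) {
  len <- as.integer(len)
  n_ins <- if (rates$u_i > 0) stats::rpois(1L, rates$u_i * len) else 0L
  n_del <- if (rates$u_d > 0) stats::rpois(1L, rates$u_d * len) else 0L
  n_mut <- if (rates$u > 0) stats::rpois(1L, rates$u * len) else 0L
  sample_sequence_events_core(len, n_ins, n_del, n_mut, rates, read_base)
}

# Count-conditioned core, shared with the simulator's vectorised
# mutation-only fast path (which draws the Poisson counts for the whole
# population in one call).
sample_sequence_events_core <- function(len, n_ins, n_del, n_mut, rates,
                                        read_base) {
  if (n_ins + n_del + n_mut == 0L) return(list())

  ops <- vector("list", n_ins + n_del + n_mut)
  n_ops <- 0L
  cur_len <- len

  # read position `pos` of the sequence after the pending ops in `ops`
  read_through <- function(pos) {
    j <- n_ops
    while (j >= 1L) {
      r <- apply_at_core(ops[[j]], pos)
      if (!is.null(r$value)) return(r$value)
      pos <- r$position
      j <- j - 1L
    }
    read_base(pos)
  }

  for (i in seq_len(n_ins)) {
    pos <- sample.int(cur_len + 1L, 1L)
    ilen <- rindel_length(rates$indel_mean)
    bases <- DNA_BASES[sample.int(4L, ilen, replace = TRUE)]
    n_ops <- n_ops + 1L
    ops[[n_ops]] <- op_insertion(pos, bases)
    cur_len <- cur_len + ilen
  }
  for (i in seq_len(n_del)) {
    if (cur_len <= 1L) next  # a deletion may never empty the sequence
    repeat {
      pos <- sample.int(cur_len, 1L)
      dlen <- min(rindel_length(rates$indel_mean), cur_len - pos + 1L)
      if (!(pos == 1L && dlen == cur_len)) break
    }
    n_ops <- n_ops + 1L
    ops[[n_ops]] <- op_deletion(pos, dlen)
    cur_len <- cur_len - dlen
  }
  for (i in seq_len(n_mut)) {
    pos <- sample.int(cur_len, 1L)
    shift <- sample.int(3L, 1L)
    old <- read_through(pos)
    new <- DNA_BASES[(match(old, DNA_BASES) - 1L + shift) %% 4L + 1L]
    n_ops <- n_ops + 1L
    ops[[n_ops]] <- op_point_mutation(pos, new)
  }
  ops[seq_len(n_ops)]
}

sample_pathway_events <- function(k, rates) {
  npairs <- as.numeric(k)^2
  n_loss <- if (rates$u_l > 0) stats::rpois(1L, rates$u_l * npairs) else 0L
  n_gain <- if (rates$u_g > 0) stats::rpois(1L, rates$u_g * npairs) else 0L
  if (n_loss + n_gain == 0L) return(list())
  ops <- vector("list", n_loss + n_gain)
  for (i in seq_len(n_loss)) {
    ops[[i]] <- op_bs_loss(sample.int(k, 1L), sample.int(k, 1L))
  }
  for (i in seq_len(n_gain)) {
    ops[[n_loss + i]] <- op_bs_gain(sample.int(k, 1L), sample.int(k, 1L))
  }
  ops
}

#' Sample the evolutionary events hitting one genotype in one generation
#'
#' Event counts are Poisson (mean = rate times genotype size), positions
#' uniform, indel lengths geometric with mean `rates$indel_mean`, and
#' point-mutation replacement bases uniform over the three non-identical
#' bases.  Deletions are clipped at the sequence end and a deletion that
#' would empty the sequence is resampled.  Deterministic under a fixed RNG
#' seed.  Crossover is not sampled here: it involves a second parent and is
#' drawn by the simulator's reproduction step.
#'
#' @param g A genotype ([sequence_genotype()] or [pathway_genotype()]).
#' @param rates An [event_rates()] record.
#' @return A list of `og_op` in application order (insertions, deletions,
#'   then point mutations).
#' @export
sample_events <- function(g, rates) {
  stopifnot(inherits(rates, "event_rates"))
  if (inherits(g, "pathway_genotype")) {
    sample_pathway_events(nrow(g), rates)
  } else {
    bases <- unclass(g)
    sample_sequence_events(length(bases), rates,
                           read_base = function(pos) bases[pos])
  }
}
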