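# Genotype representations evolved by the simulator: DNA sequences and
# regulatory pathways.  Sequences are character vectors over {A,C,G,T};
# pathways are gene_count plus a logical adjacency matrix of binding sites
# (regulator -> target).  Positions and gene indices are 1-based throughout.

DNA_BASES <- c("A", "C", "G", "T")

#' Construct a DNA sequence genotype
#'
#' A sequence genotype is an ordered collection of bases over the alphabet
#' `{A, C, G, T}`.  Its length may change over a simulation through
#' insertions and deletions, and its reported memory footprint is one unit
#' (byte) per base.
#'
#' @param bases Either a single string (e.g. `"ACCAAAT"`) or a character
#'   vector of single bases.  An empty sequence is allowed.
#' @return An object of class `sequence_genotype`: a character vector of
#'   single bases carrying the class attribute.
#' @examples
#' g <- sequence_genotype("ACCAAAT")
#' length(g)
#' footprint(g)
#' @export
sequence_genotype <- function(bases = character()) {
  if (length(bases) == 1L && nchar(bases) != 1L) {
    bases <- strsplit(bases, "", fixed = TRUE)[[1L]]
  }
  bases <- as.character(bases)
  bad <- !(bases %in% DNA_BASES)
  if (any(bad)) {
    stop("sequence_genotype: symbols outside {A,C,G,T}: ",
         paste(unique(bases[bad]), collapse = ", "))
  }
  structure(bases, class = "sequence_genotype")
}

#' Generate a uniform random DNA sequence genotype
#'
#' @param length Number of bases.
#' @return A [sequence_genotype()] of the requested length.  Uses the
#'   current RNG state; seed it with [set.seed()] for reproducibility.
#' @export
random_sequence_genotype <- function(length) {
  structure(DNA_BASES[sample.int(4L, length, replace = TRUE)],
            class = "sequence_genotype")
}

#' @export
print.sequence_genotype <- function(x, ...) {
  n <- length(x)
  shown <- paste(utils::head(unclass(x), 60L), collapse = "")
  cat("<sequence_genotype> length ", n, ": ", shown,
      if (n > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
as.character.sequence_genotype <- function(x, ...) {
  paste(unclass(x), collapse = "")
}

#' Construct a regulatory pathway genotype
#'
#' A pathway genotype over `gene_count` genes is a set of directed binding
#' sites (regulator, target), both 1-based gene indices.  Its reported
#' memory footprint is `gene_count^2` (dense adjacency storage).
#'
#' @param gene_count Positive integer number of genes.
#' @param binding_sites Optional two-column matrix (or data.frame) of
#'   (regulator, target) pairs.
#' @return An object of class `pathway_genotype`: a logical
#'   `gene_count x gene_count` adjacency matrix, `[i, j]` `TRUE` when gene
#'   `i` has a binding site regulating gene `j`.
#' @examples
#' p <- pathway_genotype(4, rbind(c(1, 2), c(2, 3)))
#' footprint(p)  # 16
#' @export
pathway_genotype <- function(gene_count, binding_sites = NULL) {
  gene_count <- as.integer(gene_count)
  if (is.na(gene_count) || gene_count < 1L) {
    stop("pathway_genotype: gene_count must be a positive integer")
  }
  adj <- matrix(FALSE, gene_count, gene_count)
  if (!is.null(binding_sites) && NROW(binding_sites) > 0L) {
    bs <- as.matrix(binding_sites)
    storage.mode(bs) <- "integer"
    if (ncol(bs) != 2L || any(bs < 1L) || any(bs > gene_count)) {
      stop("pathway_genotype: binding sites must be (regulator, target) ",
           "pairs in [1, gene_count]")
    }
    adj[bs] <- TRUE
  }
  structure(adj, class = "pathway_genotype")
}

#' @export
print.pathway_genotype <- function(x, ...) {
  cat("<pathway_genotype> ", nrow(x), " genes, ", sum(x),
      " binding sites\n", sep = "")
  invisible(x)
}

#' Binding sites of a pathway genotype as an edge list
#'
#' @param g A [pathway_genotype()].
#' @return Integer matrix with columns `regulator` and `target`, one row per
#'   binding site, ordered by regulator then target.
#' @export
binding_sites <- function(g) {
  stopifnot(inherits(g, "pathway_genotype"))
  idx <- which(unclass(g), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  colnames(idx) <- c("regulator", "target")
  idx
}

#' Memory footprint of a genotype
#'
#' The deterministic byte model used for all memory accounting: a DNA
#' sequence of length `L` occupies `L` bytes, a pathway of `k` genes
#' occupies `k^2` bytes (dense adjacency).
#'
#' @param g A genotype.
#' @return Non-negative integer (double for very large genotypes).
#' @export
footprint <- function(g) UseMethod("footprint")

#' @export
footprint.sequence_genotype <- function(g) length(unclass(g))

#' @export
footprint.pathway_genotype <- function(g) as.numeric(nrow(g))^2

#' Number of genes in a pathway genotype
#' @param g A [pathway_genotype()].
#' @return Integer gene count.
#' @export
gene_count <- function(g) {
  stopifnot(inherits(g, "pathway_genotype"))
  nrow(g)
}

# Internal: length-like size used for event sampling (bases for sequences,
# genes for pathways).
genotype_size <- function(g) {
  if (inherits(g, "pathway_genotype")) nrow(g) else length(unclass(g))
}
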