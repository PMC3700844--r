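# Instrumentation and file output: compression metrics, the deterministic
# byte model of the genotype heap, and writers for the per-generation
# metrics stream, FASTA samples, pathway edge lists, and OG snapshots.
#
# Memory is reported through the byte model (1 byte per base, genes^2 bytes
# per pathway, the documented per-operation payloads) rather than process
# RSS, so every reported number is hardware- and GC-independent and exactly
# reproducible.

#' Compression ratio and space savings
#'
#' The data compression ratio of a simulation state is
#' `cached_count / N` (explicit genotypes over population size) and the
#' space savings is `1 - cached_count/N`, reported as a percentage.  A run
#' holding 5 explicit genotypes for a population of 100 has ratio 0.05
#' (1:20) and savings 95%.
#'
#' @param cached_count Number of explicit genotypes `|C(V)|`.
#' @param N Population size.
#' @return List with `ratio` and `savings_percent`.
#' @export
compression_metrics <- function(cached_count, N) {
  if (cached_count < 1) stop("cached_count must be at least 1")
  if (cached_count > N) {
    stop("accounting error: cached_count (", cached_count,
         ") exceeds population size (", N, ")")
  }
  ratio <- cached_count / N
  list(ratio = ratio, savings_percent = (1 - ratio) * 100)
}

#' Cache budget implied by a memory ceiling
#'
#' `k = floor(ceiling_mb / genotype_mb)`, at least 1: the number of explicit
#' genotypes that fit under a memory ceiling.  For sequences, MB per
#' genotype is roughly `L / 1e6`.
#'
#' @param ceiling_mb Memory ceiling in MB.
#' @param genotype_mb MB per explicit genotype.
#' @return Positive integer `k`.  When a single genotype exceeds the
#'   ceiling, returns 1 with a warning (the ceiling then cannot be met, only
#'   approached).
#' @examples
#' memory_ceiling_k(100, 1)    # 100 explicit 1 Mb sequences
#' memory_ceiling_k(100, 10)   # 10
#' @export
memory_ceiling_k <- function(ceiling_mb, genotype_mb) {
  if (ceiling_mb <= 0 || genotype_mb <= 0) {
    stop("ceiling_mb and genotype_mb must be positive")
  }
  if (genotype_mb > ceiling_mb) {
    warning("one explicit genotype (", genotype_mb,
            " MB) already exceeds the ", ceiling_mb, " MB ceiling; k = 1")
    return(1L)
  }
  max(1L, as.integer(floor(ceiling_mb / genotype_mb)))
}

#' Heap account of an operation graph
#'
#' The byte-model memory account: explicit genotype bytes (sum of
#' footprints over `C(V)`), operation-record payload bytes (see
#' [op_payload_bytes()]), and their total.  Operation storage is
#' unconstrained by the cache policies, but it takes a million point
#' mutations to equal one uncompressed megabase sequence, so the genotype
#' term dominates.
#'
#' @param og An [operation_graph()].
#' @return List with `explicit_genotype_bytes`, `operation_bytes`, `total`.
#' @export
heap_account <- function(og) {
  list(explicit_genotype_bytes = og$cached_bytes,
       operation_bytes = og$op_bytes,
       total = og$cached_bytes + og$op_bytes)
}

#' Write the per-generation metrics stream
#'
#' `write_metrics_csv` writes one CSV row per generation (comma separator,
#' header, `.` decimal, no quoting); `write_metrics_jsonl` writes the same
#' rows as JSON lines.
#'
#' @param metrics The `metrics` data.frame of an `ogsim_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
write_metrics_jsonl <- function(metrics, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(metrics))) {
    writeLines(jsonlite::toJSON(as.list(metrics[i, , drop = FALSE]),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Write a FASTA sample of the final population
#'
#' Standard FASTA (70-column wrap) with record ids
#' `ind<individual>_node<og node id>`.
#'
#' @param result An `ogsim_result` from a sequence-model run.
#' @param path Output file path.
#' @param n Number of individuals to write (the first `n`; default all).
#' @return `path`, invisibly.
#' @export
write_fasta_sample <- function(result, path, n = NULL) {
  stopifnot(inherits(result, "ogsim_result"))
  if (result$config$genotype != "sequence") {
    stop("FASTA output applies to sequence genotypes")
  }
  seqs <- population_sequences(result)
  if (!is.null(n)) seqs <- utils::head(seqs, n)
  ids <- utils::head(result$population, length(seqs))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- paste0("ind", seq_along(seqs), "_node", ids)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write a pathway genotype as a tab-separated edge list
#'
#' @param g A [pathway_genotype()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_edges <- function(g, path) {
  bs <- binding_sites(g)
  utils::write.table(as.data.frame(bs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an operation graph for inspection
#'
#' `og_to_dot` renders the OG in Graphviz DOT (explicit nodes boxed, labels
#' carrying kind/weight/request count); `og_to_graphml` writes GraphML via
#' igraph with node attributes `explicit`, `weight`, `request_count`,
#' `kind`.  Edges are directed parent to child.
#'
#' @param og An [operation_graph()].
#' @param path Output file path (for `og_to_dot`, `NULL` returns the DOT
#'   text instead).
#' @return The DOT text (invisibly when written to a file), or `path`.
#' @export
og_to_dot <- function(og, path = NULL) {
  ids <- og_node_ids(og)
  lines <- c("digraph og {", "  rankdir=TB;")
  for (id in ids) {
    nd <- og$nodes[[as.character(id)]]
    shape <- if (!is.null(nd$label)) "box" else "ellipse"
    lab <- sprintf("%d\\n%s\\nw=%g req=%g", id, nd$op$kind, nd$w, nd$req)
    lines <- c(lines, sprintf("  n%d [shape=%s, label=\"%s\"];",
                              id, shape, lab))
  }
  for (id in ids) {
    nd <- og$nodes[[as.character(id)]]
    for (ch in nd$children) {
      lines <- c(lines, sprintf("  n%d -> n%d;", id, ch$id))
    }
  }
  lines <- c(lines, "}")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname og_to_dot
#' @export
og_to_graphml <- function(og, path) {
  ids <- og_node_ids(og)
  verts <- data.frame(
    name = as.character(ids),
    explicit = vapply(ids, function(i) og_is_explicit(og, i), TRUE),
    weight = vapply(ids, function(i) og$nodes[[as.character(i)]]$w, 0),
    request_count = vapply(ids, function(i) og$nodes[[as.character(i)]]$req,
                           0),
    kind = vapply(ids, function(i) og$nodes[[as.character(i)]]$op$kind, ""),
    stringsAsFactors = FALSE)
  from <- character(0)
  to <- character(0)
  for (id in ids) {
    nd <- og$nodes[[as.character(id)]]
    for (ch in nd$children) {
      from <- c(from, as.character(id))
      to <- c(to, as.character(ch$id))
    }
  }
  gr <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = TRUE, vertices = verts)
  igraph::write_graph(gr, path, format = "graphml")
  invisible(path)
}

#' Write all standard outputs of a run
#'
#' Emits `metrics.csv`, `metrics.jsonl`, and `sample.fasta` (sequence runs)
#' or `pathway.edges.tsv` (pathway runs; the first individual's genotype)
#' into a directory.
#'
#' @param result An `ogsim_result`.
#' @param dir Output directory (created if missing).
#' @param og_snapshot Also write `og.dot` and `og.graphml` snapshots of the
#'   final graph.
#' @return `dir`, invisibly.
#' @export
emit_outputs <- function(result, dir, og_snapshot = FALSE) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory ", dir)
  }
  write_metrics_csv(result$metrics, file.path(dir, "metrics.csv"))
  write_metrics_jsonl(result$metrics, file.path(dir, "metrics.jsonl"))
  if (result$config$genotype == "sequence") {
    write_fasta_sample(result, file.path(dir, "sample.fasta"))
  } else {
    write_pathway_edges(population_genotypes(result)[[1L]],
                        file.path(dir, "pathway.edges.tsv"))
  }
  if (og_snapshot) {
    og_to_dot(result$og, file.path(dir, "og.dot"))
    og_to_graphml(result$og, file.path(dir, "og.graphml"))
  }
  invisible(dir)
}
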