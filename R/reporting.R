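#' Sample-by-node observation matrix
#'
#' Tallies the reads of each sample landing in each final node — the
#' standard input to downstream alpha-/beta-diversity analyses.
#' Samples are ordered by first appearance in the input; nodes by total
#' size descending (ties by id). Reads in discarded lineages are
#' excluded, so each sample's row sums to its reads surviving the M
#' filter.
#'
#' @param topology a `med_topology` from [med_decompose()].
#' @return An object of class `ObservationMatrix`: list with `samples`,
#'   `node_ids`, `counts` (integer samples x nodes matrix) and
#'   `percents` (row-normalized to 100; all-zero rows stay zero).
#' @export
observation_matrix <- function(topology) {
  stopifnot(inherits(topology, "med_topology"))
  fin <- final_nodes(topology)
  samples <- topology$samples
  counts <- matrix(0L, nrow = length(samples), ncol = length(fin),
                   dimnames = list(samples, fin))
  for (id in fin) {
    idx <- topology$nodes[[id]]$unique_idx
    counts[, id] <- as.integer(
      colSums(topology$uniques$sample_counts[idx, , drop = FALSE]))
  }
  rs <- rowSums(counts)
  percents <- counts * 0
  nz <- rs > 0
  if (any(nz)) {
    percents[nz, ] <- sweep(counts[nz, , drop = FALSE], 1L, rs[nz],
                            "/") * 100
  }
  structure(list(samples = samples, node_ids = fin,
                 counts = counts, percents = percents),
            class = "ObservationMatrix")
}

#' @export
print.ObservationMatrix <- function(x, ...) {
  cat(sprintf("ObservationMatrix: %d sample(s) x %d node(s), %d reads\n",
              length(x$samples), length(x$node_ids), sum(x$counts)))
  invisible(x)
}

#' Write count and percent observation matrices as TSV
#'
#' Writes `MATRIX-COUNT.txt` and `MATRIX-PERCENT.txt` into `dir`:
#' tab-delimited, samples as rows (first column `sample`), final node
#' ids as header.
#'
#' @param om an [observation_matrix()].
#' @param dir output directory (created if missing).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_observation_matrices <- function(om, dir) {
  stopifnot(inherits(om, "ObservationMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("MATRIX-COUNT.txt", "MATRIX-PERCENT.txt"))
  for (i in 1:2) {
    m <- if (i == 1L) om$counts else om$percents
    df <- data.frame(sample = om$samples, m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, paths[i], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' Write representative sequences of final nodes as FASTA
#'
#' One entry per final node, defline `node_id|size:<reads>`, sequence =
#' the node's most abundant unique sequence with trailing gap padding
#' stripped (internal gaps, if present in pre-aligned input, are
#' preserved).
#'
#' @param topology a `med_topology`.
#' @param path output FASTA path.
#' @return `path`, invisibly. Warns and writes an empty file when there
#'   are no final nodes.
#' @export
write_representatives <- function(topology, path) {
  stopifnot(inherits(topology, "med_topology"))
  fin <- final_nodes(topology)
  if (length(fin) == 0L) {
    warning("no final nodes; writing empty representatives file")
    file.create(path)
    return(invisible(path))
  }
  seqs <- vapply(topology$nodes[fin], function(nd) {
    sub("-+$", "", nd$representative)
  }, character(1))
  sizes <- vapply(topology$nodes[fin], function(nd) nd$size, numeric(1))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- sprintf("%s|size:%d", fin, as.integer(sizes))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Export the decomposition topology
#'
#' Writes the bifurcating-tree-like record of the run in two forms: a
#' tab-delimited edge list (`parent_id`, `child_id`, `child_size`,
#' `child_status`) — the bit-stable canonical artifact — and a GML
#' graph with the same content for graph tools. Leaves carry status
#' `final` or `discarded`; inner vertices are `internal`.
#'
#' @param topology a `med_topology`.
#' @param edge_path output path for the TSV edge list.
#' @param gml_path output path for the GML file.
#' @return Invisibly, `c(edge_path, gml_path)`.
#' @export
export_topology <- function(topology, edge_path, gml_path) {
  stopifnot(inherits(topology, "med_topology"))
  write.table(topology$edges, edge_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  ids <- names(topology$nodes)
  verts <- data.frame(
    name = ids,
    size = vapply(topology$nodes, function(nd) as.integer(nd$size),
                  integer(1)),
    status = vapply(topology$nodes, `[[`, character(1), "status"),
    level = vapply(topology$nodes, function(nd) as.integer(nd$level),
                   integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(
    topology$edges[, c("parent_id", "child_id")],
    directed = TRUE, vertices = verts)
  igraph::write_graph(g, gml_path, format = "gml")
  invisible(c(edge_path, gml_path))
}

#' Summarize a completed decomposition
#'
#' Read accounting (input = final + discarded), node counts by status,
#' the parameters used, and the per-iteration total weighted entropy
#' trace (non-increasing over the run).
#'
#' @param topology a `med_topology`.
#' @return An object of class `med_summary`.
#' @export
run_summary <- function(topology) {
  stopifnot(inherits(topology, "med_topology"))
  st <- vapply(topology$nodes, `[[`, character(1), "status")
  sizes <- vapply(topology$nodes, function(nd) nd$size, numeric(1))
  structure(list(
    input_reads = topology$n_reads,
    final_reads = sum(sizes[st == "final"]),
    discarded_reads = sum(sizes[st == "discarded"]),
    n_final = sum(st == "final"),
    n_internal = sum(st == "internal"),
    n_discarded = sum(st == "discarded"),
    alignment_length = topology$alignment_length,
    n_samples = length(topology$samples),
    params = topology$params,
    entropy_trace = topology$iteration_log$total_weighted_entropy
  ), class = "med_summary")
}

#' @export
print.med_summary <- function(x, ...) {
  cat("MED run summary\n")
  cat(sprintf("  input reads      : %d\n", x$input_reads))
  cat(sprintf("  reads in final   : %d (%.1f%%)\n", as.integer(x$final_reads),
              100 * x$final_reads / x$input_reads))
  cat(sprintf("  reads discarded  : %d\n", as.integer(x$discarded_reads)))
  cat(sprintf("  nodes final/internal/discarded : %d/%d/%d\n",
              x$n_final, x$n_internal, x$n_discarded))
  cat(sprintf("  params           : M=%d, m0=%g, c=%d, normalize_m=%s\n",
              x$params$M, x$params$m0, x$params$c, x$params$normalize_m))
  if (length(x$entropy_trace) > 0L) {
    cat(sprintf("  weighted entropy : %.4f -> %.4f over %d iterations\n",
                x$entropy_trace[1L], x$entropy_trace[length(x$entropy_trace)],
                length(x$entropy_trace)))
  }
  invisible(x)
}

# key=value RUNINFO log; `extra` adds run-configuration entries
# (input path, subsampling, seed) so a run is reproducible from it.
write_runinfo <- function(topology, path, extra = NULL) {
  s <- run_summary(topology)
  kv <- c(
    input_reads = s$input_reads,
    final_reads = as.integer(s$final_reads),
    discarded_reads = as.integer(s$discarded_reads),
    final_nodes = s$n_final,
    internal_nodes = s$n_internal,
    discarded_nodes = s$n_discarded,
    alignment_length = s$alignment_length,
    samples = s$n_samples,
    M = s$params$M,
    m0 = s$params$m0,
    c = s$params$c,
    normalize_m = s$params$normalize_m,
    iterations = length(s$entropy_trace),
    initial_weighted_entropy = signif(s$entropy_trace[1L], 8),
    final_weighted_entropy = signif(s$entropy_trace[length(s$entropy_trace)], 8)
  )
  if (!is.null(extra)) kv <- c(kv, unlist(extra))
  writeLines(paste0(names(kv), "=", unname(kv)), path)
  invisible(path)
}
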