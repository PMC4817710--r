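#' Decomposition parameters
#'
#' Bundles the tunable parameters of the decomposition.
#'
#' @param M minimum substantive abundance: a node whose most abundant
#'   unique sequence occurs fewer than `M` times is discarded as noise.
#'   `NULL` (default) resolves at run time to [recommend_M()] of the
#'   input read count.
#' @param m0 base entropy threshold in bits; default `0.0965`, the
#'   expected column entropy of a 1%-error sequencer (see
#'   [normalized_m()]).
#' @param c maximum number of discriminant positions used
#'   simultaneously in one decomposition step; default `4`. A small `c`
#'   needs more iterations to converge; a large `c` fragments nodes
#'   into more children and therefore discards more reads under `M`.
#' @param normalize_m logical; scale `m0` per node by node size
#'   relative to the dataset's most abundant unique read frequency
#'   (default `TRUE`). With `FALSE` the raw `m0` is used for every
#'   node.
#' @return An object of class `med_params`.
#' @export
med_params <- function(M = NULL, m0 = 0.0965, c = 4L, normalize_m = TRUE) {
  if (!is.null(M)) {
    M <- as.integer(M)
    if (is.na(M) || M < 1L) stop("M must be a positive integer (or NULL)")
  }
  if (!is.numeric(m0) || m0 <= 0) stop("m0 must be > 0")
  c <- as.integer(c)
  if (is.na(c) || c < 1L) stop("c must be a positive integer")
  structure(list(M = M, m0 = m0, c = c,
                 normalize_m = isTRUE(normalize_m)),
            class = "med_params")
}

#' @export
print.med_params <- function(x, ...) {
  cat(sprintf("med_params: M=%s, m0=%g, c=%d, normalize_m=%s\n",
              if (is.null(x$M)) "auto" else x$M, x$m0, x$c,
              x$normalize_m))
  invisible(x)
}

#' Recommended minimum substantive abundance
#'
#' The recommended noise filter for a dataset of `total_reads` reads:
#' one per 10 000 reads, rounded up, never below 1. Larger values
#' remove more low-abundance noise at the cost of discarding more
#' reads.
#'
#' @param total_reads number of reads in the dataset (>= 1).
#' @return Integer `max(1, ceiling(total_reads / 10000))`.
#' @examples
#' recommend_M(373474)  # 38
#' @export
recommend_M <- function(total_reads) {
  total_reads <- as.numeric(total_reads)
  if (is.na(total_reads) || total_reads < 1) {
    stop("total_reads must be >= 1")
  }
  max(1L, as.integer(ceiling(total_reads / 10000)))
}

#' Minimum substantive abundance filter
#'
#' A node passes when its most abundant unique sequence occurs at least
#' `M` times. The criterion looks at the top *unique* count, not the
#' node size: a large node composed entirely of rare unique sequences
#' is still judged noise.
#'
#' @param node a node from a [med_topology] (any list with a
#'   `top_unique_count` field).
#' @param M minimum substantive abundance (>= 1).
#' @return `TRUE` iff the node's top unique count is >= `M`.
#' @export
passes_M_filter <- function(node, M) {
  top <- node$top_unique_count
  if (is.null(top)) stop("node lacks a top_unique_count field")
  top >= M
}

#' Group sequences by the characters at discriminant positions
#'
#' The splitting primitive of the decomposition: sequences are grouped
#' by the exact character tuple (the "oligonucleotide") they carry at
#' the given positions, one child group per distinct tuple. Children
#' are ordered by size (total count) descending, ties broken by tuple
#' lexicographic ascending.
#'
#' @param sequences character vector of uniform-length sequences.
#' @param counts numeric read counts, parallel to `sequences`.
#' @param positions 1-based alignment positions (non-empty, in range).
#' @return List of child groups, each a list with `indices` (into
#'   `sequences`, ascending), `size` (sum of counts) and `tuple` (the
#'   shared character tuple).
#' @export
split_node <- function(sequences, counts, positions) {
  if (length(positions) == 0L) stop("positions must be non-empty")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have uniform length")
  positions <- as.integer(positions)
  if (any(is.na(positions)) || any(positions < 1L) || any(positions > L)) {
    stop("positions out of range 1..", L)
  }
  key <- do.call(paste0, lapply(positions,
                                function(j) substr(sequences, j, j)))
  groups <- split(seq_along(sequences), key)
  sizes <- vapply(groups, function(g) sum(counts[g]), numeric(1))
  ord <- order(-sizes, names(groups), method = "radix")
  lapply(ord, function(k) {
    list(indices = sort(groups[[k]]), size = sizes[k],
         tuple = names(groups)[k])
  })
}

#' Minimum entropy decomposition of an amplicon read set
#'
#' Iteratively partitions a finalized (uniform-length) read set into
#' homogeneous terminal nodes. The input dataset enters a FIFO
#' decomposition pool as the root node; at each iteration one node is
#' removed and either
#' \enumerate{
#'   \item discarded, if its most abundant unique sequence occurs fewer
#'     than `M` times ([passes_M_filter()]);
#'   \item stored as a final node, if its entropy profile has no
#'     position above the node's normalized threshold m'
#'     ([is_converged()]); or
#'   \item decomposed: up to `c` positions with entropy above m' are
#'     selected ([select_discriminant_positions()]), reads are grouped
#'     by their character tuple at those positions ([split_node()]),
#'     and the children join the pool.
#' }
#' The loop ends when the pool is empty. Each discriminant position has
#' zero entropy within every child it produced, so the size-weighted
#' total entropy of the dataset decreases monotonically; its trace is
#' recorded in the iteration log.
#'
#' The threshold m' is computed per node by [normalized_m()] with `n` =
#' node size and `N` = the frequency of the most abundant unique read
#' of the whole dataset (fixed once at the start), unless
#' `normalize_m = FALSE` in which case `m0` is used directly.
#'
#' Node ids encode lineage: the root is `"0"` and the children of a
#' node get its id plus `"."` and their rank (size descending, tuple
#' ascending), e.g. `"0.1.2"`.
#'
#' @param reads a finalized [read_set()] (see [pad_reads()]).
#' @param params a [med_params()] object.
#' @return A `med_topology` object: a list with
#'   \describe{
#'     \item{nodes}{named list of node records (id, parent_id, level,
#'       status in `pending/internal/final/discarded`, size,
#'       top_unique_count, representative, profile, m_prime,
#'       discriminant_positions, child_ids, unique_idx)}
#'     \item{root_id}{`"0"`}
#'     \item{edges}{data.frame parent_id/child_id/child_size/child_status}
#'     \item{iteration_log}{data.frame iteration/node_id/action/
#'       total_weighted_entropy, action in
#'       `discarded/finalized/decomposed`}
#'     \item{uniques}{the dataset [dereplicate_reads()] table}
#'     \item{params}{the parameters with `M` resolved}
#'     \item{n_reads, alignment_length, samples}{input bookkeeping}
#'   }
#' @seealso [observation_matrix()], [write_representatives()],
#'   [export_topology()], [run_summary()], [med_run()]
#' @export
med_decompose <- function(reads, params = med_params()) {
  stopifnot(inherits(reads, "ReadSet"), inherits(params, "med_params"))
  n_total <- length(reads)
  if (n_total == 0L) stop("empty dataset")
  if (is.na(reads$alignment_length) ||
      any(nchar(reads$sequence) != reads$alignment_length)) {
    stop("reads must be finalized to uniform length; see pad_reads()")
  }
  M <- params$M %||% recommend_M(n_total)
  params$M <- M

  uniq <- dereplicate_reads(reads)
  U <- encode_sequences(uniq$sequence)
  cnt <- as.numeric(uniq$count)
  N_ref <- uniq$count[1L]   # most abundant unique read of the dataset

  node_weight <- function(nd) nd$size / n_total * sum(nd$profile)
  new_node <- function(id, parent, level, idx) {
    idx <- sort(idx)  # global unique order is count desc, seq asc
    cm <- column_state_counts(U, idx, cnt[idx])
    list(node_id = id, parent_id = parent, level = level,
         status = "pending", size = sum(uniq$count[idx]),
         top_unique_count = uniq$count[idx[1L]],
         representative = uniq$sequence[idx[1L]],
         profile = entropy_from_counts(cm),
         m_prime = NA_real_, discriminant_positions = integer(0),
         child_ids = character(0), unique_idx = idx)
  }

  nodes <- list()
  root <- new_node("0", NA_character_, 0L, seq_along(uniq$count))
  nodes[["0"]] <- root
  queue <- "0"
  tw <- node_weight(root)
  log_iter <- integer(0); log_id <- character(0)
  log_action <- character(0); log_tw <- numeric(0)
  it <- 0L

  while (length(queue) > 0L) {
    id <- queue[[1L]]; queue <- queue[-1L]
    it <- it + 1L
    nd <- nodes[[id]]
    if (!passes_M_filter(nd, M)) {
      nd$status <- "discarded"
      tw <- tw - node_weight(nd)
      action <- "discarded"
    } else {
      mp <- if (params$normalize_m) {
        normalized_m(nd$size, N_ref, params$m0)
      } else {
        params$m0
      }
      nd$m_prime <- mp
      if (is_converged(nd$profile, mp)) {
        nd$status <- "final"
        action <- "finalized"
      } else {
        pos <- select_discriminant_positions(nd$profile, mp, params$c)
        key <- do.call(paste0, lapply(pos, function(j) {
          MED_ALPHABET[U[nd$unique_idx, j]]
        }))
        groups <- split(nd$unique_idx, key)
        if (length(groups) < 2L) {
          stop("internal error: split produced a single child at node ", id)
        }
        gsz <- vapply(groups, function(g) sum(uniq$count[g]), numeric(1))
        ord <- order(-gsz, names(groups), method = "radix")
        child_ids <- paste0(id, ".", seq_along(ord))
        for (k in seq_along(ord)) {
          ch <- new_node(child_ids[k], id, nd$level + 1L,
                         groups[[ord[k]]])
          nodes[[child_ids[k]]] <- ch
          tw <- tw + node_weight(ch)
        }
        tw <- tw - node_weight(nd)
        queue <- c(queue, child_ids)
        nd$status <- "internal"
        nd$discriminant_positions <- pos
        nd$child_ids <- child_ids
        action <- "decomposed"
      }
    }
    nodes[[id]] <- nd
    log_iter[it] <- it; log_id[it] <- id
    log_action[it] <- action; log_tw[it] <- max(tw, 0)
  }

  non_root <- Filter(function(nd) !is.na(nd$parent_id), nodes)
  edges <- data.frame(
    parent_id = vapply(non_root, `[[`, character(1), "parent_id"),
    child_id = vapply(non_root, `[[`, character(1), "node_id"),
    child_size = vapply(non_root, function(nd) as.integer(nd$size),
                        integer(1)),
    child_status = vapply(non_root, `[[`, character(1), "status"),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(
    list(nodes = nodes, root_id = "0", edges = edges,
         iteration_log = data.frame(
           iteration = log_iter, node_id = log_id, action = log_action,
           total_weighted_entropy = log_tw, stringsAsFactors = FALSE),
         uniques = uniq, params = params, n_reads = n_total,
         alignment_length = reads$alignment_length,
         samples = colnames(uniq$sample_counts)),
    class = "med_topology"
  )
}

#' @export
print.med_topology <- function(x, ...) {
  st <- vapply(x$nodes, `[[`, character(1), "status")
  cat(sprintf(paste0(
    "med_topology: %d reads -> %d final node(s) ",
    "(%d internal, %d discarded; M=%d, m0=%g, c=%d)\n"),
    x$n_reads, sum(st == "final"), sum(st == "internal"),
    sum(st == "discarded"), x$params$M, x$params$m0, x$params$c))
  invisible(x)
}

#' Final node ids of a decomposition
#'
#' @param topology a `med_topology` from [med_decompose()].
#' @return Character vector of final (terminal) node ids, ordered by
#'   node size descending, ties by id ascending.
#' @export
final_nodes <- function(topology) {
  stopifnot(inherits(topology, "med_topology"))
  st <- vapply(topology$nodes, `[[`, character(1), "status")
  ids <- names(topology$nodes)[st == "final"]
  if (length(ids) == 0L) return(character(0))
  sizes <- vapply(topology$nodes[ids], function(nd) nd$size, numeric(1))
  ids[order(-sizes, ids, method = "radix")]
}

#' Unique sequences of one node
#'
#' @param topology a `med_topology`.
#' @param node_id a node id present in the topology.
#' @return data.frame of the node's unique sequences with counts,
#'   ordered count descending (ties sequence ascending); the first row
#'   is the node's representative.
#' @export
node_uniques <- function(topology, node_id) {
  stopifnot(inherits(topology, "med_topology"))
  nd <- topology$nodes[[node_id]]
  if (is.null(nd)) stop("no such node: ", node_id)
  idx <- nd$unique_idx
  data.frame(sequence = topology$uniques$sequence[idx],
             count = topology$uniques$count[idx],
             stringsAsFactors = FALSE)
}
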