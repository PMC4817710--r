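#' Shannon entropy of one alignment column
#'
#' Computes the base-2 Shannon entropy `-sum(p * log2(p))` of the
#' character distribution at a single alignment position. High entropy
#' marks information-rich positions; a column occupied by a single
#' residue has entropy 0 and a column split evenly over k residues has
#' entropy `log2(k)`. Base 2 (bits) is used throughout the package: it
#' is the base under which a column with a 99% consensus base and a 1%
#' error rate spread evenly over the three alternative bases has
#' entropy 0.0966 bits, the origin of the default noise threshold
#' `m0 = 0.0965` (see [med_params()]).
#'
#' @param x either a character vector of residues (the column contents,
#'   one element per read), or a numeric vector of per-character counts
#'   or weights (names optional). Gap (`-`) and `N` characters count as
#'   ordinary states.
#' @return Entropy in bits (non-negative scalar).
#' @examples
#' shannon_entropy(rep("A", 10))              # 0
#' shannon_entropy(c(A = 5, T = 5))           # 1
#' shannon_entropy(c(A = 4, C = 4, G = 4, T = 4))  # 2
#' shannon_entropy(c(0.99, 0.01 / 3, 0.01 / 3, 0.01 / 3))  # ~0.0966
#' @export
shannon_entropy <- function(x) {
  if (length(x) == 0L) stop("empty column")
  if (is.character(x)) {
    counts <- as.numeric(table(x))
  } else if (is.numeric(x)) {
    if (any(x < 0)) stop("counts must be non-negative")
    counts <- x[x > 0]
    if (length(counts) == 0L) stop("empty column")
  } else {
    stop("x must be a character vector of residues or a numeric count vector")
  }
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Column entropies (bits) from a 6 x L matrix of per-character counts.
entropy_from_counts <- function(cm) {
  tot <- colSums(cm)
  if (any(tot <= 0)) stop("empty column in count matrix")
  p <- sweep(cm, 2L, tot, "/")
  plogp <- p * log2(p)
  plogp[cm == 0] <- 0
  pmax(-colSums(plogp), 0)
}

#' Per-column entropy profile of a set of sequences
#'
#' Computes the Shannon entropy of every alignment column across a set
#' of uniform-length sequences, each weighted by its read count. The
#' profile of a homogeneous node is flat (all positions at or near
#' zero); entropy peaks mark the positions that can direct a
#' decomposition step.
#'
#' @param seqs character vector of uniform-length sequences over
#'   `{A,C,G,T,N,-}`.
#' @param counts optional numeric weights (e.g. dereplicated unique
#'   sequence counts); default 1 per sequence. Weighting unique
#'   sequences by count gives the same profile as expanding them.
#' @return Numeric vector of entropies in bits, one per position, each
#'   in `[0, log2(6)]`.
#' @examples
#' entropy_profile(c("AAAA", "AATA"), counts = c(5, 5))  # 0 0 1 0
#' @export
entropy_profile <- function(seqs, counts = NULL) {
  if (length(seqs) == 0L) stop("at least one sequence is required")
  if (is.null(counts)) counts <- rep(1, length(seqs))
  if (length(counts) != length(seqs)) {
    stop("counts must have one weight per sequence")
  }
  U <- encode_sequences(seqs)
  cm <- column_state_counts(U, seq_len(nrow(U)), as.numeric(counts))
  entropy_from_counts(cm)
}

#' Dynamically normalized entropy threshold m'
#'
#' The entropy threshold below which a position is treated as noise.
#' For a node of `n` reads in a dataset whose most abundant unique read
#' occurs `N` times, the base threshold `m0` is scaled down
#' proportionally to `n / N` and clamped at `m0`:
#' `m' = min(m0, m0 * n / N)`. The default `m0 = 0.0965` bits is the
#' expected column entropy generated by a sequencer with a 1% error
#' rate, so positions whose variation is indistinguishable from that
#' noise floor do not trigger decomposition in large nodes, while small
#' nodes are held to a stricter threshold.
#'
#' @param n node size (reads in the node), >= 1.
#' @param N frequency of the most abundant unique read in the whole
#'   dataset, >= 1.
#' @param m0 base threshold in bits, > 0.
#' @return The normalized threshold m' (> 0).
#' @export
normalized_m <- function(n, N, m0 = 0.0965) {
  if (!is.numeric(n) || !is.numeric(N) || !is.numeric(m0)) {
    stop("n, N and m0 must be numeric")
  }
  if (n < 1 || N < 1 || m0 <= 0) {
    stop("n >= 1, N >= 1 and m0 > 0 are required")
  }
  min(m0, m0 * n / N)
}

#' Select discriminant positions for a decomposition step
#'
#' Ranks alignment positions with entropy strictly greater than the
#' threshold `m_prime` by entropy descending, breaking ties in favour
#' of the left-most (smallest-index) position, keeps at most `c` of
#' them, and returns the retained positions in ascending positional
#' order ready for splitting. An empty result means the node has
#' converged.
#'
#' @param profile numeric entropy profile (bits), as from
#'   [entropy_profile()].
#' @param m_prime threshold in bits; positions must exceed it strictly.
#' @param c maximum number of positions retained (>= 1).
#' @return Integer vector of 1-based positions (possibly empty),
#'   ascending.
#' @export
select_discriminant_positions <- function(profile, m_prime, c = 4L) {
  c <- as.integer(c)
  if (is.na(c) || c < 1L) stop("c must be a positive integer")
  idx <- which(profile > m_prime)
  if (length(idx) == 0L) return(integer(0))
  ranked <- idx[order(-profile[idx], idx)]
  sort(ranked[seq_len(min(c, length(ranked)))])
}

#' Has a node's entropy profile converged?
#'
#' A node has converged (is terminal) when no position of its entropy
#' profile exceeds the normalized threshold strictly — i.e. when the
#' profile contains no discernible entropy peak.
#'
#' @inheritParams select_discriminant_positions
#' @return `TRUE` iff no position has entropy > `m_prime`.
#' @export
is_converged <- function(profile, m_prime) {
  !any(profile > m_prime)
}

#' Total weighted entropy of a set of nodes
#'
#' The size-weighted sum of per-node total entropies:
#' `sum_v (size_v / total_reads) * sum(profile_v)`. Splitting a node at
#' any set of positions can never increase this quantity (grouping
#' property of Shannon entropy), so it decreases monotonically over a
#' decomposition and is logged per iteration by [med_decompose()].
#'
#' @param sizes numeric vector of node sizes (reads per node).
#' @param profiles list of entropy profiles, parallel to `sizes`.
#' @param total_reads the denominator; defaults to `sum(sizes)`. Pass
#'   the original input read count to keep the scale fixed while nodes
#'   are being discarded.
#' @return Weighted entropy in bits (non-negative scalar).
#' @export
total_weighted_entropy <- function(sizes, profiles,
                                   total_reads = sum(sizes)) {
  if (length(sizes) == 0L) return(0)
  if (length(profiles) != length(sizes)) {
    stop("profiles must be parallel to sizes")
  }
  if (total_reads <= 0) stop("total_reads must be positive")
  sum(sizes / total_reads * vapply(profiles, sum, numeric(1)))
}
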