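#' Construct a ReadSet
#'
#' A `ReadSet` is the package's container for sample-tagged amplicon
#' reads: parallel vectors of read ids, sample names and sequences, plus
#' the alignment length once the set has been finalized to uniform
#' length. Sequences are uppercase strings over `{A,C,G,T,N,-}`.
#'
#' @param id character vector of unique read identifiers.
#' @param sample character vector of sample names (same length as `id`).
#' @param sequence character vector of sequences (same length as `id`).
#' @param alignment_length integer alignment length, or `NA` while read
#'   lengths still vary. Set automatically by [pad_reads()].
#' @return An object of class `ReadSet`.
#' @seealso [read_amplicon_fasta()], [pad_reads()], [dereplicate_reads()]
#' @export
read_set <- function(id, sample, sequence, alignment_length = NA_integer_) {
  id <- as.character(id); sample <- as.character(sample)
  sequence <- as.character(sequence)
  n <- length(id)
  if (length(sample) != n || length(sequence) != n) {
    stop("id, sample and sequence must have equal length")
  }
  if (n > 0L) {
    if (anyDuplicated(id)) stop("read ids must be unique")
    if (any(!nzchar(sample))) stop("sample names must be non-empty")
    if (any(!nzchar(sequence))) stop("sequences must be non-empty")
  }
  lens <- nchar(sequence)
  if (is.na(alignment_length) && n > 0L && length(unique(lens)) == 1L) {
    alignment_length <- lens[1L]
  }
  if (!is.na(alignment_length) && n > 0L && any(lens != alignment_length)) {
    stop("alignment_length does not match sequence lengths")
  }
  structure(
    list(id = id, sample = sample, sequence = sequence,
         alignment_length = as.integer(alignment_length)),
    class = "ReadSet"
  )
}

#' @export
length.ReadSet <- function(x) length(x$id)

#' @export
print.ReadSet <- function(x, ...) {
  cat(sprintf("ReadSet: %d reads, %d sample(s), alignment length %s\n",
              length(x), length(unique(x$sample)),
              if (is.na(x$alignment_length)) "variable"
              else x$alignment_length))
  invisible(x)
}

#' Read a sample-tagged amplicon FASTA file
#'
#' Parses a FASTA file of quality-filtered amplicon reads and extracts
#' the sample of origin of each read from its defline using a regular
#' expression with one capture group. The default pattern takes
#' everything before a final `_<number>` (e.g. `>spongeA_0031` belongs
#' to sample `spongeA`), the common amplicon defline convention.
#'
#' Sequences are uppercased; residues outside `{A,C,G,T,N,-}` are
#' rejected. Internal gap characters in pre-aligned input are accepted
#' verbatim.
#'
#' @param path path to a FASTA file.
#' @param sample_pattern regular expression with exactly one capture
#'   group; applied to each full defline to obtain the sample name.
#' @return A [read_set()] with one record per FASTA entry.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1_1", "ACGT", ">s2_1", "acgt"), fa)
#' reads <- read_amplicon_fasta(fa)
#' reads$sample     # "s1" "s2"
#' reads$sequence   # both uppercased
#' @export
read_amplicon_fasta <- function(path, sample_pattern = "^(.+)_\\d+$") {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  deflines <- names(x)
  if (is.null(deflines) || any(!nzchar(deflines))) {
    stop("malformed FASTA in '", path, "': entry with empty defline")
  }
  seqs <- toupper(as.character(x))

  bad_pos <- regexpr("[^ACGTN-]", seqs)
  if (any(bad_pos > 0L)) {
    i <- which(bad_pos > 0L)[1L]
    stop("invalid character '", substr(seqs[i], bad_pos[i], bad_pos[i]),
         "' in entry '", deflines[i],
         "'; allowed alphabet is {A,C,G,T,N,-}")
  }

  m <- regexec(sample_pattern, deflines)
  hits <- regmatches(deflines, m)
  ok <- vapply(hits, length, integer(1)) >= 2L
  if (!all(ok)) {
    offenders <- head(deflines[!ok], 5L)
    stop("defline(s) not matching sample_pattern '", sample_pattern,
         "' (need one capture group): ",
         paste(sQuote(offenders), collapse = ", "),
         if (sum(!ok) > 5L) sprintf(" ... and %d more", sum(!ok) - 5L))
  }
  samples <- vapply(hits, `[`, character(1), 2L)
  if (any(!nzchar(samples))) {
    stop("sample_pattern produced an empty sample name for defline '",
         deflines[which(!nzchar(samples))[1L]], "'")
  }
  ids <- vapply(strsplit(deflines, "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicated read id in FASTA: '", ids[duplicated(ids)][1L], "'")
  }
  read_set(ids, samples, seqs)
}

#' Pad reads to uniform length with trailing gaps
#'
#' Appends trailing `-` characters to every read shorter than the
#' longest read, finalizing the set for entropy analysis. Appropriate
#' when read-length differences represent biologically meaningful
#' variation rather than alignment errors; in the latter case an
#' external alignment step is required instead. Idempotent; read order
#' is preserved and only trailing gaps are ever added.
#'
#' @param reads a [read_set()].
#' @return A finalized `ReadSet` whose `alignment_length` is the
#'   maximum input read length.
#' @export
pad_reads <- function(reads) {
  stopifnot(inherits(reads, "ReadSet"))
  if (length(reads) == 0L) stop("empty ReadSet")
  lens <- nchar(reads$sequence)
  L <- max(lens)
  short <- lens < L
  if (any(short)) {
    reads$sequence[short] <- paste0(reads$sequence[short],
                                    strrep("-", L - lens[short]))
  }
  reads$alignment_length <- as.integer(L)
  reads
}

#' Dereplicate a finalized ReadSet into unique sequences
#'
#' Collapses identical sequences into a table of unique sequences with
#' total and per-sample counts and the member read ids. The ordering is
#' total, deterministic: count descending, ties broken by sequence
#' lexicographic ascending (byte order). The first entry is therefore
#' the dataset's most abundant unique read, whose frequency anchors the
#' dynamic entropy threshold normalization in [med_decompose()].
#'
#' @param reads a finalized (uniform-length) [read_set()].
#' @return An object of class `UniqueSet`: a list with
#'   \describe{
#'     \item{sequence}{character vector of distinct sequences}
#'     \item{count}{integer total counts, `sum(count) == length(reads)`}
#'     \item{sample_counts}{integer matrix, unique x sample, samples in
#'       order of first appearance in the input}
#'     \item{members}{list of member read-id vectors}
#'   }
#' @export
dereplicate_reads <- function(reads) {
  stopifnot(inherits(reads, "ReadSet"))
  if (length(reads) == 0L) stop("empty ReadSet")
  if (is.na(reads$alignment_length) ||
      any(nchar(reads$sequence) != reads$alignment_length)) {
    stop("reads must be finalized to uniform length; see pad_reads()")
  }
  seq_levels <- sort(unique(reads$sequence), method = "radix")
  f <- factor(reads$sequence, levels = seq_levels)
  samp_levels <- unique(reads$sample)
  sf <- factor(reads$sample, levels = samp_levels)

  groups <- split(seq_along(reads$id), f)
  counts <- lengths(groups)
  sc <- unclass(table(f, sf))          # unique x sample
  dimnames(sc) <- list(NULL, samp_levels)

  ord <- order(-counts, seq_levels, method = "radix")
  structure(
    list(sequence = seq_levels[ord],
         count = as.integer(counts[ord]),
         sample_counts = sc[ord, , drop = FALSE],
         members = unname(lapply(groups[ord], function(i) reads$id[i]))),
    class = "UniqueSet"
  )
}

#' @export
print.UniqueSet <- function(x, ...) {
  cat(sprintf("UniqueSet: %d unique sequences from %d reads, %d sample(s)\n",
              length(x$sequence), sum(x$count), ncol(x$sample_counts)))
  invisible(x)
}

#' Randomly subsample reads to a per-sample cap
#'
#' Samples uniformly at random without replacement within each sample
#' that exceeds `cap` reads; samples at or below the cap are untouched.
#' The relative order of retained reads is preserved and the result is
#' deterministic for a given `seed`. Subsampling is advisable when read
#' counts across samples differ by orders of magnitude, to avoid biasing
#' the entropy profiles toward deeply sequenced samples.
#'
#' @param reads a [read_set()].
#' @param cap maximum reads retained per sample (>= 1).
#' @param seed integer random seed.
#' @return A `ReadSet` with at most `cap` reads per sample.
#' @export
subsample_reads <- function(reads, cap, seed) {
  stopifnot(inherits(reads, "ReadSet"))
  cap <- as.integer(cap)
  if (is.na(cap) || cap < 1L) stop("cap must be a positive integer")
  keep <- with_seed(seed, {
    idx <- split(seq_along(reads$id), factor(reads$sample,
                                             levels = unique(reads$sample)))
    sort(unlist(lapply(idx, function(i) {
      if (length(i) > cap) sample(i, cap) else i
    }), use.names = FALSE))
  })
  read_set(reads$id[keep], reads$sample[keep], reads$sequence[keep],
           alignment_length = reads$alignment_length)
}

#' Write a ReadSet to FASTA
#'
#' @param reads a [read_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  stopifnot(inherits(reads, "ReadSet"))
  x <- Biostrings::BStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
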