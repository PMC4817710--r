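# Residue alphabet shared by every module. Order fixes the integer
# encoding used by the C++ column tally, so never reorder.
MED_ALPHABET <- c("A", "C", "G", "T", "N", "-")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode uniform-length sequences as an integer matrix
#'
#' One row per sequence, one column per alignment position, values
#' 1..6 indexing `c("A","C","G","T","N","-")`.
#'
#' @param seqs character vector of equal-length sequences.
#' @return integer matrix, `length(seqs)` x alignment length.
#' @keywords internal
#' @noRd
encode_sequences <- function(seqs) {
  if (length(seqs) == 0L) stop("no sequences to encode")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("sequences must have uniform length (see pad_reads())")
  }
  flat <- unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE)
  m <- matrix(match(flat, MED_ALPHABET),
              nrow = length(seqs), ncol = lens[1L], byrow = TRUE)
  if (anyNA(m)) {
    bad <- setdiff(unique(flat), MED_ALPHABET)
    stop("invalid residue(s): ", paste(bad, collapse = ", "),
         "; allowed alphabet is {A,C,G,T,N,-}")
  }
  m
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so simulation helpers do not perturb user sessions.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
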